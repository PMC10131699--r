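# Grouped cross-validation and evaluation runners.

test_that("grouped folds partition reviews and balance instance counts", {
  inst <- tibble::tibble(review_id = rep(sprintf("r%02d", 1:20), each = 3))
  folds <- grouped_kfold(inst, k = 10, seed = 1)
  expect_equal(nrow(folds), 20L)
  expect_equal(as.integer(table(folds$fold)), rep(2L, 10))
  expect_equal(anyDuplicated(folds$review_id), 0L)
  expect_error(grouped_kfold(inst, k = 25), "exceeds the number")

  # greedy balancing is near the exhaustive optimum on 6 reviews
  sizes <- c(9L, 7L, 5L, 4L, 2L, 1L)
  inst2 <- tibble::tibble(
    review_id = rep(sprintf("s%d", 1:6), times = sizes))
  g <- grouped_kfold(inst2, k = 3, seed = 2)
  fold_sizes <- tapply(sizes[match(g$review_id, sprintf("s%d", 1:6))],
                       g$fold, sum)
  spread <- max(fold_sizes) - min(fold_sizes)
  assignments <- expand.grid(rep(list(1:3), 6))
  best <- min(apply(assignments, 1L, function(a) {
    fs <- tapply(sizes, factor(a, levels = 1:3), sum)
    fs[is.na(fs)] <- 0
    max(fs) - min(fs)
  }))
  expect_lte(spread, best + max(sizes))
})

test_that("cross-validation tests every instance exactly once", {
  ds <- small_dataset()
  inst <- ds$instances
  k <- max(inst$fold)
  seen <- integer(0)
  for (t in seq_len(k)) {
    sp <- evidencegrader:::split_trial(inst, t, k)
    key <- paste(sp$test$review_id, sp$test$sof_index, sp$test$outcome_index)
    expect_length(intersect(seen, key), 0L)
    seen <- c(seen, key)
    # train, dev and test partition the data with no review overlap
    expect_length(intersect(sp$train$review_id, sp$test$review_id), 0L)
    expect_length(intersect(sp$dev$review_id, sp$test$review_id), 0L)
    expect_equal(nrow(sp$train) + nrow(sp$dev) + nrow(sp$test), nrow(inst))
  }
  expect_length(seen, nrow(inst))
})

test_that("cross_validate summarises per-trial metrics with MAD", {
  ds <- small_dataset()
  cv <- cross_validate(ds$instances, baseline_spec("majority"),
                       qoe_task("grade4"), seed = 1)
  expect_equal(nrow(cv$metrics), max(ds$instances$fold))
  g <- glance(cv)
  expect_true(all(c("mean", "mad") %in% names(g)))
  expect_true(all(g$mad >= 0))
  expect_true(all(cv$metrics$mae >= 0 & cv$metrics$mae <= 3))
  td <- tidy(cv)
  expect_true(all(c("trial", "metric", "score") %in% names(td)))
})

test_that("supplementation in CV leaves dev and test labels untouched", {
  ds <- small_dataset()
  inst <- ds$instances
  k <- max(inst$fold)
  for (t in 1:2) {
    sp <- evidencegrader:::split_trial(inst, t, k)
    before_dev <- sp$dev
    sup <- supplement_training(sp$train, ds$supplement, "inconsistency")
    expect_gte(nrow(sup), nrow(sp$train))
    expect_identical(sp$dev, before_dev)
    key <- paste(ds$supplement$review_id, ds$supplement$sof_index,
                 ds$supplement$outcome_index)
    expect_length(intersect(paste(sp$test$review_id, sp$test$sof_index,
                                  sp$test$outcome_index), key), 0L)
  }
})

test_that("ablation flags the planted-signal feature and spares inert ones", {
  ds <- cached("ablation_ds", {
    build_dataset(generate_corpus(gen_config(n_reviews = 220, seed = 111)),
                  k = 4, seed = 3)
  })
  ab <- ablation_run(ds$instances, baseline_spec("lr", variant = "nct"),
                     qoe_task("criterion", "risk_of_bias"),
                     fields = c("outcome", "year"), trials = 1L, seed = 5)
  expect_equal(ab$feature, c(".none", "outcome", "year"))
  d_outcome <- ab$d_f1[ab$feature == "outcome"]
  d_year <- ab$d_f1[ab$feature == "year"]
  # dropping the signal-bearing text hurts; dropping an inert numeric barely
  # moves the score
  expect_lt(d_outcome, -0.02)
  expect_lt(abs(d_year), 0.05)
  expect_lt(d_outcome, d_year)
})

test_that("domain holdout isolates the held-out area", {
  ds <- cached("ablation_ds", {
    build_dataset(generate_corpus(gen_config(n_reviews = 220, seed = 111)),
                  k = 4, seed = 3)
  })
  inst <- ds$instances
  area <- "mental_health"
  hd <- domain_holdout(inst, area, baseline_spec("lr", variant = "nct"),
                       qoe_task("grade2"), seed = 9)
  in_area <- grepl(area, inst$medical_area, fixed = TRUE)
  expect_gt(hd$n_test, 0)
  expect_equal(hd$n_test, sum(in_area))
  # the remainder splits into train and a non-empty dev set
  expect_lt(hd$n_train, nrow(inst) - hd$n_test)
  expect_error(domain_holdout(inst, "astrology",
                              baseline_spec("majority"), qoe_task("grade2")),
               "no instances")
  # identical generative process per area: holdout is close to in-domain
  cv <- cross_validate(inst, baseline_spec("lr", variant = "nct"),
                       qoe_task("grade2"), trials = 2L, seed = 9)
  expect_lt(abs(hd$metrics$macro_f1 - mean(cv$metrics$macro_f1)), 0.15)
})
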