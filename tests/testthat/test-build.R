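# Distant-supervision extraction, filtering, supplementation.

test_that("extraction keeps, filters and flags hand-built entries correctly", {
  rev <- manual_review(entries = list(
    manual_entry("low", "downgraded for imprecision; downgraded for heterogeneity"),
    manual_entry("moderate", "downgraded for imprecision and heterogeneity"),
    manual_entry("high")
  ))
  cand <- extract_instances(as_corpus(list(rev)))
  expect_equal(nrow(cand), 3L)
  # low with 2 one-step reasons: consistent
  expect_equal(cand$status[1], "consistent")
  expect_equal(cand$imprecision[1], 1L)
  expect_equal(cand$inconsistency[1], 1L)
  # moderate (1 expected step) with 2 detected reasons: filtered, partial
  expect_equal(cand$status[2], "inconsistent")
  expect_true(cand$partially_labeled[2])
  # high with no footnotes: kept with an empty vector
  expect_equal(cand$status[3], "skipped")
  expect_equal(steps_total(cand[3, ]), 0L)
  expect_true(cand$kept[3])
})

test_that("entries without a grade are skipped with a warning and counted", {
  e <- manual_entry("low", "downgraded for imprecision")
  e$grade <- NULL
  rev <- manual_review(entries = list(e, manual_entry("high")))
  expect_warning(cand <- extract_instances(as_corpus(list(rev))),
                 "without a grade")
  rep <- attr(cand, "report")
  expect_equal(rep$no_grade, 1L)
  expect_equal(rep$kept, 1L)
  expect_false(any(cand$kept[cand$status == "no_grade"]))
})

test_that("candidates partition into kept and filtered-out", {
  cand <- extract_instances(small_corpus())
  rep <- attr(cand, "report")
  expect_equal(rep$kept + rep$filtered_out + rep$no_grade, rep$candidates)
  expect_false(any(cand$kept & cand$status == "inconsistent"))
  # every kept non-high instance satisfies the arithmetic exactly
  kept <- cand[cand$kept & cand$grade < 3L, ]
  expect_true(all(pmin(steps_total(kept), 3L) == 3L - kept$grade))
  # supplement pool and instances never overlap
  ds <- small_dataset()
  key <- function(d) paste(d$review_id, d$sof_index, d$outcome_index)
  expect_length(intersect(key(ds$instances), key(ds$supplement)), 0L)
})

test_that("supplementation adds exactly the matching positives", {
  ds <- small_dataset()
  train <- ds$instances[ds$instances$fold != 1L, ]
  pool <- ds$supplement
  for (cr in criteria()) {
    sup <- supplement_training(train, pool, cr)
    expect_equal(nrow(sup), nrow(train) + sum(pool[[cr]] > 0L))
    expect_gte(sum(sup[[cr]] > 0L), sum(train[[cr]] > 0L))
  }
  expect_identical(supplement_training(train, pool[0, ], "imprecision"),
                   train)
  bad <- pool
  bad[1, criteria()] <- 0L
  expect_error(supplement_training(train, bad, "imprecision"),
               "no positive label")
})

test_that("supplementation raises positive counts for all five criteria", {
  corpus <- cached("supp_corpus",
                   generate_corpus(gen_config(n_reviews = 500,
                                              corrupt_fraction = 0.2,
                                              seed = 303)))
  ds <- build_dataset(corpus, k = 5, seed = 1)
  before <- vapply(criteria(), function(cr) sum(ds$instances[[cr]] > 0L),
                   integer(1))
  after <- vapply(criteria(), function(cr) {
    sum(supplement_training(ds$instances, ds$supplement, cr)[[cr]] > 0L)
  }, integer(1))
  expect_true(all(after > before))
})

test_that("corruption rate drives the filtered-out fraction", {
  clean <- clean_corpus_2k()
  cand <- extract_instances(clean)
  expect_equal(attr(cand, "report")$filtered_out, 0L)

  corrupt <- cached("corrupt_corpus",
                    generate_corpus(gen_config(n_reviews = 500,
                                               corrupt_fraction = 0.2,
                                               seed = 404)))
  truth <- ground_truth(corrupt)
  cand2 <- extract_instances(corrupt)
  n <- nrow(cand2)
  p_nonhigh <- mean(truth$grade < 3L)
  expected <- 0.2 * p_nonhigh
  got <- attr(cand2, "report")$filtered_out / n
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(got - expected), 3 * se)
})

test_that("corpus summaries match direct counting", {
  ds <- small_dataset()
  s <- summarize_corpus(ds$instances)
  expect_equal(sum(s$grades$n), nrow(ds$instances))
  expect_equal(sum(s$grades$pct), 100)
  expect_equal(s$n_reviews, length(unique(ds$instances$review_id)))
  # one instance per grade gives 25% each
  four <- ds$instances[match(0:3, ds$instances$grade), ]
  expect_equal(summarize_corpus(four)$grades$pct, rep(25, 4))
  # printed class counts reproduce the high-quality share
  counts <- table3_grade_counts
  fake <- tibble::tibble(
    review_id = "r", n_included_studies = 1, n_sofs = 1,
    grade = rep(3:0, times = counts[c("high", "moderate", "low", "very_low")]))
  for (cr in criteria()) fake[[cr]] <- 0L
  expect_equal(
    round(summarize_corpus(fake)$grades$pct[
      summarize_corpus(fake)$grades$grade == 3L], 1), 14.2)
  # co-occurrence equals brute-force pair counting
  inst <- ds$instances
  top2 <- c("risk_of_bias", "imprecision")
  brute <- mean(inst$risk_of_bias > 0 & inst$imprecision > 0)
  co <- s$co_occurrence
  expect_equal(co$rate[co$criterion_a == top2[1] & co$criterion_b == top2[2]],
               brute)
  expect_error(summarize_corpus(ds$instances[0, ]), "no instances")
})
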