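# The multi-view predictor and the baselines.

split_small <- function() {
  inst <- small_dataset()$instances
  list(train = inst[!inst$fold %in% c(1L, 2L), ],
       dev = inst[inst$fold == 2L, ],
       test = inst[inst$fold == 1L, ])
}

fast_config <- function(...) {
  args <- utils::modifyList(
    list(numeric_hidden = c(16L, 16L, 16L), cat_dim = 4L, text_dim = 8L,
         hash_bits = 10L, agg_dim = 16L, epochs = 6L, patience = 3L,
         batch_size = 64L, seed = 3L),
    list(...))
  do.call(model_config, args)
}

test_that("class weights follow N/(2 Nc) and flag empty classes", {
  y <- c(1L, 1L, 0L, 0L)
  expect_equal(unname(class_weights(y)), c(1, 1))
  y2 <- c(1L, 0L, 0L, 0L)
  expect_equal(class_weights(y2)[["positive"]], 4 / 2)
  expect_equal(class_weights(y2)[["negative"]], 4 / 6)
  expect_error(class_weights(rep(0L, 4)), "supplement_training")
})

test_that("head losses match hand arithmetic", {
  # binary cross-entropy on a 4-example batch, to 1e-9
  p <- c(0.9, 0.2, 0.6, 0.5)
  y <- c(1, 0, 1, 0)
  hand <- -mean(log(c(0.9, 0.8, 0.6, 0.5)))
  expect_equal(model_loss("binary", p, y), hand, tolerance = 1e-9)
  # weighted equals unweighted when prevalences are equal
  w <- ifelse(y == 1, 1, 1)
  expect_equal(model_loss("binary", p, y, w), model_loss("binary", p, y),
               tolerance = 1e-12)
  # perfect regression scores zero
  expect_equal(model_loss("regression", c(1, 2, 3), c(1, 2, 3)), 0)
  # multiclass cross-entropy against direct softmax arithmetic
  z <- rbind(c(2, 0, 0, 0), c(0, 0, 1, 0))
  yc <- c(0L, 2L)
  sm1 <- exp(2) / (exp(2) + 3)
  sm2 <- exp(1) / (exp(1) + 3)
  expect_equal(model_loss("multiclass", z, yc),
               -mean(log(c(sm1, sm2))), tolerance = 1e-9)
})

test_that("training learns planted signal, is deterministic, validates inputs", {
  sp <- split_small()
  task <- qoe_task("criterion", "risk_of_bias")
  fit <- fit_evidencegrader(sp$train, sp$dev, task, fast_config())
  log <- tidy(fit)
  # loss decreases over the first epochs on learnable data
  expect_lt(log$train_loss[3], log$train_loss[1])
  # beats the majority baseline on dev
  maj <- fit_baseline(sp$train, task, "majority")
  y_dev <- as.integer(sp$dev$risk_of_bias > 0)
  f1_maj <- prf(y_dev, predict(maj, sp$dev)$.pred, 0:1)$f1[2]
  expect_gt(fit$dev_score, 0)
  y_te <- as.integer(sp$test$risk_of_bias > 0)
  f1_fit <- prf(y_te, predict(fit, sp$test)$.pred, 0:1)$f1[2]
  expect_gt(f1_fit, f1_maj - 0.05)

  # determinism: identical seeds give identical scores and predictions
  fit2 <- fit_evidencegrader(sp$train, sp$dev, task, fast_config())
  expect_identical(tidy(fit2)$dev_score, log$dev_score)
  expect_identical(predict(fit2, sp$test), predict(fit, sp$test))

  # permuting training rows leaves results unchanged (canonical order)
  perm <- sp$train[sample.int(nrow(sp$train)), ]
  fit3 <- fit_evidencegrader(perm, sp$dev, task, fast_config())
  expect_identical(predict(fit3, sp$test), predict(fit, sp$test))

  expect_error(fit_evidencegrader(sp$train, sp$dev[0, ], task, fast_config()),
               "dev set is empty")
  expect_error(fit_evidencegrader(sp$train, sp$train[1:5, ], task,
                                  fast_config()),
               "share reviews")
})

test_that("every head produces valid predictions and encodings", {
  sp <- split_small()
  cfgs <- fast_config(epochs = 2L)
  for (task in list(qoe_task("grade4"), qoe_task("grade2"),
                    qoe_task("regression"), qoe_task("multilabel"))) {
    fit <- fit_evidencegrader(sp$train, sp$dev, task, cfgs)
    pred <- predict(fit, sp$test)
    expect_equal(nrow(pred), nrow(sp$test))
    if (task$kind == "grade4") {
      expect_true(all(pred$.pred %in% 0:3))
      expect_equal(unname(rowSums(as.matrix(pred[paste0("prob_", 0:3)]))),
                   rep(1, nrow(pred)), tolerance = 1e-9)
    }
    if (task$kind == "regression") {
      expect_identical(pred$.pred, scalar_to_grade(pred$.pred_raw))
    }
    if (task$kind == "multilabel") {
      for (cr in criteria()) {
        expect_identical(pred[[paste0("pred_", cr)]],
                         as.integer(pred[[paste0("prob_", cr)]] > 0.5))
      }
    }
    a <- encode(fit, sp$test[1:7, ])
    expect_equal(dim(a), c(7L, cfgs$agg_dim))
  }
})

test_that("empty text contributes a zero block to the representation", {
  sp <- split_small()
  fit <- fit_evidencegrader(sp$train, sp$dev, qoe_task("grade2"),
                            fast_config(epochs = 1L))
  blank <- sp$test[1:3, ]
  for (f in c("outcome", "abstract_conclusion", "plain_language_summary",
              "full_abstract", "authors_conclusions")) {
    blank[[f]] <- ""
  }
  mats <- transform_view(fit$prep, blank)
  fwd <- evidencegrader:::nn_forward(fit$params, mats, fit$config)
  expect_equal(unname(as.matrix(fwd$blocks$txt)),
               matrix(0, 3, ncol(fwd$blocks$txt)), tolerance = 1e-6)
})

test_that("majority baseline reproduces the documented behaviours", {
  # 4-tier majority on labels shaped like the published class counts: low
  counts <- round(table3_grade_counts / 10)
  train <- tibble::tibble(grade = rep(c(0L, 1L, 2L, 3L),
                                      times = counts[c("very_low", "low",
                                                       "moderate", "high")]))
  for (cr in criteria()) train[[cr]] <- 0L
  # risk of bias + imprecision is the strictly most frequent combination
  pos <- seq_len(nrow(train)) <= 0.6 * nrow(train)
  train$risk_of_bias <- as.integer(pos)
  train$imprecision <- train$risk_of_bias
  maj <- fit_baseline(train, qoe_task("grade4"), "majority")
  expect_equal(unique(predict(maj, train)$.pred), grade_value("low"))
  # most frequent criterion combination drives criteria predictions
  majc <- fit_baseline(train, qoe_task("multilabel"), "majority")
  pred <- predict(majc, train[1:4, ])
  expect_equal(unique(pred$pred_risk_of_bias), 1L)
  expect_equal(unique(pred$pred_imprecision), 1L)
  expect_equal(unique(pred$pred_inconsistency), 0L)
  majr <- fit_baseline(train, qoe_task("criterion", "risk_of_bias"),
                       "majority")
  expect_equal(unique(predict(majr, train[1:6, ])$.pred), 1L)
})

test_that("random baseline frequencies match its stated distribution", {
  task <- qoe_task("grade4")
  rb <- fit_baseline(NULL, task, "random", seed = 5)
  draws <- predict(rb, tibble::tibble(.rows = 1e5))$.pred
  counts <- table(factor(draws, levels = 0:3))
  # each label frequency within 0.01 of 1/4 (about 7 binomial SDs at n = 1e5)
  expect_true(all(abs(prop.table(counts) - 0.25) < 0.01))
  # seeded: identical on replay
  expect_identical(draws, predict(rb, tibble::tibble(.rows = 1e5))$.pred)
})

test_that("zero planted signal leaves models at baseline level", {
  cfg0 <- gen_config(n_reviews = 220, seed = 909,
                     signal_strength = stats::setNames(rep(0, 5), criteria()))
  ds <- build_dataset(generate_corpus(cfg0), k = 4, seed = 2)
  inst <- ds$instances
  train <- inst[!inst$fold %in% c(1L, 2L), ]
  dev <- inst[inst$fold == 2L, ]
  test <- inst[inst$fold == 1L, ]
  task <- qoe_task("criterion", "risk_of_bias")
  y <- as.integer(test$risk_of_bias > 0)
  p <- mean(as.integer(train$risk_of_bias > 0))
  f1_expected_majority <- 2 * p / (1 + p)
  lr <- fit_baseline(train, task, "lr", variant = "nct")
  f1_lr <- prf(y, predict(lr, test)$.pred, 0:1)$f1[2]
  expect_lt(f1_lr, f1_expected_majority + 0.05)
  fitn <- fit_evidencegrader(train, dev, task, fast_config(epochs = 4L))
  f1_nn <- prf(y, predict(fitn, test)$.pred, 0:1)$f1[2]
  expect_lt(f1_nn, f1_expected_majority + 0.05)
})
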