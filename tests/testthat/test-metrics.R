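# Metrics and the closed-form baseline oracles.

test_that("prf covers perfect, degenerate and algebraic cases", {
  truth <- c(1, 0, 1, 1, 0)
  out <- prf(truth, truth, 0:1)
  expect_true(all(out$f1 == 1))
  # always-positive predictor: positive F1 = 2p/(1+p)
  set.seed(3)
  p <- 0.3
  y <- rbinom(5000, 1, p)
  always <- prf(y, rep(1L, 5000), 0:1)
  phat <- mean(y)
  expect_equal(always$f1[always$class == "1"], 2 * phat / (1 + phat),
               tolerance = 1e-12)
  # never-predicted class scores zero
  expect_equal(always$f1[always$class == "0"], 0)
  expect_equal(always$precision[always$class == "0"], 0)
  expect_error(prf(1:3, 1:4), "equal length")
})

test_that("binary micro-F1 from pooled counts equals accuracy", {
  set.seed(8)
  y <- rbinom(500, 1, 0.4)
  pred <- rbinom(500, 1, 0.5)
  tab <- prf(y, pred, 0:1)
  # pooled one-vs-rest counts over both classes: micro-F1 reduces to accuracy
  tp_pool <- sum(y == pred)
  micro <- 2 * tp_pool / (2 * tp_pool + sum(y != pred) + sum(y != pred))
  expect_equal(micro, mean(y == pred))
})

test_that("grade MAE matches hand values and is permutation invariant", {
  expect_equal(mae_grade(c(0, 1, 2), c(0, 1, 2)), 0)
  # constant 'low' against truth with the published class counts
  truth <- rep(c(0L, 1L, 2L, 3L),
               times = table3_grade_counts[c("very_low", "low", "moderate",
                                             "high")])
  expect_equal(round(mae_grade(rep(1L, length(truth)), truth), 4), 0.8026)
  set.seed(2)
  pred <- sample(0:3, 100, replace = TRUE)
  tr <- sample(0:3, 100, replace = TRUE)
  perm <- sample.int(100)
  expect_equal(mae_grade(pred, tr), mae_grade(pred[perm], tr[perm]))
  expect_error(mae_grade(1:3, 1:4), "equal length")
})

test_that("multilabel scores match row logic and a pooled-count oracle", {
  perfect <- matrix(rbinom(250, 1, 0.4), 50, 5,
                    dimnames = list(NULL, criteria()))
  out <- multilabel_scores(perfect, perfect)
  expect_equal(out$exact_match, 1)
  expect_equal(out$micro_f1, 1)
  # one wrong criterion disqualifies the row from exact match
  pred <- perfect
  pred[1, 1] <- 1 - pred[1, 1]
  expect_equal(multilabel_scores(pred, perfect)$exact_match, 49 / 50)
  # micro-F1 equals the pooled-contingency computation
  set.seed(13)
  truth <- matrix(rbinom(250, 1, 0.35), 50, 5,
                  dimnames = list(NULL, criteria()))
  guess <- matrix(rbinom(250, 1, 0.5), 50, 5,
                  dimnames = list(NULL, criteria()))
  got <- multilabel_scores(guess, truth)
  tp <- sum(guess & truth); fp <- sum(guess & !truth)
  fn <- sum(!guess & truth)
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  expect_equal(got$micro_f1, 2 * prec * rec / (prec + rec))
})

test_that("fold MAD matches its definition", {
  expect_equal(mad_across_folds(rep(0.7, 10)), 0)
  expect_equal(mad_across_folds(c(0.1, 0.2, 0.3)), 0.1)
  set.seed(4)
  for (i in 1:20) {
    x <- runif(sample(3:12, 1))
    expect_equal(mad_across_folds(x), median(abs(x - median(x))))
  }
})

test_that("closed-form majority metrics reproduce the analytic forms", {
  dist <- stats::setNames(as.numeric(table3_grade_counts / table3_n),
                          names(table3_grade_counts))
  maj <- expected_baseline_metrics(dist, "majority", "grade4")
  p_low <- dist[["low"]]
  expect_equal(maj$f1[maj$class == "low"], 2 * p_low / (1 + p_low))
  expect_equal(attr(maj, "macro_f1"), 2 * p_low / (1 + p_low) / 4)
  expect_equal(attr(maj, "mae"),
               dist[["very_low"]] * 1 + dist[["moderate"]] * 1 +
                 dist[["high"]] * 2)
  # uniform 2-class majority: F1 = 2/3
  two <- expected_baseline_metrics(c(negative = 0.5, positive = 0.5),
                                   "majority", "criterion",
                                   predicted_class = "positive")
  expect_equal(two$f1[two$class == "positive"], 2 / 3)
  expect_error(expected_baseline_metrics(c(a = 0.7, b = 0.2), "majority"),
               "summing to 1")
})

test_that("Monte-Carlo baselines agree with the closed forms at n = 1e5", {
  n <- 1e5
  dist <- stats::setNames(as.numeric(table3_grade_counts / table3_n),
                          names(table3_grade_counts))
  set.seed(606)
  truth <- sample(0:3, n, replace = TRUE, prob = dist[grade_label(0:3)])
  chunk <- rep(1:10, each = n / 10)
  chunk_se <- function(x_by_chunk) stats::sd(x_by_chunk) / sqrt(10)

  # majority (always 'low')
  maj_tab <- expected_baseline_metrics(dist, "majority", "grade4")
  f1_chunks <- vapply(1:10, function(ch) {
    y <- truth[chunk == ch]
    prf(y, rep(1L, length(y)), 0:3)$f1[2]
  }, numeric(1))
  expect_lt(abs(mean(f1_chunks) - maj_tab$f1[maj_tab$class == "low"]),
            3 * chunk_se(f1_chunks) + 1e-6)
  mae_chunks <- vapply(1:10, function(ch) {
    mae_grade(rep(1L, sum(chunk == ch)), truth[chunk == ch])
  }, numeric(1))
  expect_lt(abs(mean(mae_chunks) - attr(maj_tab, "mae")),
            3 * chunk_se(mae_chunks))

  # random uniform and empirical
  for (variant in c("random_uniform", "random_empirical")) {
    tab <- expected_baseline_metrics(dist, variant, "grade4")
    pr <- if (variant == "random_uniform") rep(0.25, 4) else
      unname(dist[grade_label(0:3)])
    pred <- sample(0:3, n, replace = TRUE, prob = pr)
    for (g in c(1L, 2L)) {
      f1c <- vapply(1:10, function(ch) {
        prf(truth[chunk == ch], pred[chunk == ch], 0:3)$f1[g + 1]
      }, numeric(1))
      expect_lt(abs(mean(f1c) - tab$f1[g + 1]), 3 * chunk_se(f1c) + 1e-6)
    }
    maec <- vapply(1:10, function(ch) {
      mae_grade(pred[chunk == ch], truth[chunk == ch])
    }, numeric(1))
    expect_lt(abs(mean(maec) - attr(tab, "mae")), 3 * chunk_se(maec))
  }
})
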