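# Grouped cross-validation, evaluation runners, ablation and domain holdout.

#' Grouped k-fold assignment over reviews
#'
#' All bodies of evidence from the same systematic review land in the same
#' fold, preventing leakage of near-duplicate instances between training and
#' test partitions. Reviews are assigned greedily (largest review first,
#' seeded shuffle for ties) to the currently smallest fold, balancing fold
#' sizes in instances.
#'
#' @param instances Instance tibble with `review_id`.
#' @param k Number of folds; must not exceed the number of distinct reviews.
#' @param seed Shuffle seed.
#' @return A tibble (`review_id`, `fold`) covering every review exactly once.
#' @export
grouped_kfold <- function(instances, k = 10L, seed = 1L) {
  counts <- dplyr::count(instances, .data$review_id)
  if (k > nrow(counts)) {
    stop("k = ", k, " exceeds the number of distinct reviews (",
         nrow(counts), ")", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  counts <- counts[sample.int(nrow(counts)), ]
  counts <- counts[order(-counts$n), ]
  sizes <- numeric(k)
  fold <- integer(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    f <- which.min(sizes)
    fold[i] <- f
    sizes[f] <- sizes[f] + counts$n[i]
  }
  tibble::tibble(review_id = counts$review_id, fold = fold)
}

split_trial <- function(instances, t, k) {
  test_f <- t
  dev_f <- t %% k + 1L
  list(train = instances[!instances$fold %in% c(test_f, dev_f), ],
       dev = instances[instances$fold == dev_f, ],
       test = instances[instances$fold == test_f, ])
}

fit_spec <- function(spec, train, dev, task, ablation, seed) {
  if (inherits(spec, "qoe_model_config")) {
    spec$seed <- seed
    fit_evidencegrader(train, dev, task, spec, ablation)
  } else if (inherits(spec, "qoe_baseline_spec")) {
    fit_baseline(train, task, type = spec$type, variant = spec$variant,
                 random_dist = spec$random_dist, ablation = ablation,
                 seed = seed)
  } else {
    stop("spec must be a model_config() or baseline_spec()", call. = FALSE)
  }
}

#' Describe a baseline for the evaluation runners
#'
#' @inheritParams fit_baseline
#' @return A `qoe_baseline_spec` accepted by [cross_validate()],
#'   [ablation_run()] and [domain_holdout()].
#' @export
baseline_spec <- function(type = c("random", "majority", "lr"),
                          variant = c("nct", "nc", "n"),
                          random_dist = c("uniform", "empirical")) {
  structure(list(type = match.arg(type), variant = match.arg(variant),
                 random_dist = match.arg(random_dist)),
            class = "qoe_baseline_spec")
}

trial_metrics <- function(task, pred, test) {
  y <- task_labels(task, test)
  if (task$kind %in% c("criterion", "grade2")) {
    tab <- prf(y, pred$.pred, classes = c(0L, 1L))
    tibble::tibble(
      positive_f1 = tab$f1[tab$class == "1"],
      macro_f1 = attr(tab, "macro_f1"),
      macro_precision = attr(tab, "macro_precision"),
      macro_recall = attr(tab, "macro_recall"))
  } else if (task$kind == "grade4") {
    tab <- prf(y, pred$.pred, classes = 0:3)
    out <- tibble::tibble(
      macro_f1 = attr(tab, "macro_f1"),
      macro_precision = attr(tab, "macro_precision"),
      macro_recall = attr(tab, "macro_recall"),
      mae = mae_grade(pred$.pred, y))
    for (g in 0:3) {
      out[[paste0("f1_", grade_label(g))]] <- tab$f1[tab$class == as.character(g)]
    }
    out
  } else if (task$kind == "regression") {
    tab <- prf(y, pred$.pred, classes = 0:3)
    tibble::tibble(mae = mae_grade(pred$.pred_raw, y),
                   mae_rounded = mae_grade(pred$.pred, y),
                   macro_f1 = attr(tab, "macro_f1"))
  } else {
    pm <- as.matrix(pred[paste0("pred_", criteria())])
    colnames(pm) <- criteria()
    multilabel_scores(pm, y)
  }
}

#' Grouped cross-validated evaluation
#'
#' Runs the 10-fold protocol: per trial, one fold is the test set, the next
#' fold the dev set, the remaining k-2 folds the training set. Optionally
#' supplements the training folds (only) with partially labeled positives
#' for criterion tasks. Returns per-trial metrics; [generics::glance()]
#' summarises them with the mean and the median absolute deviation across
#' trials.
#'
#' @param instances Instance tibble with `fold` assigned (see
#'   [build_dataset()] / [grouped_kfold()]).
#' @param spec A [model_config()] or [baseline_spec()].
#' @param task A [qoe_task()].
#' @param trials Number of trials to run (default: all `k`).
#' @param supplement Optional partially labeled pool for
#'   [supplement_training()].
#' @param ablation Passed to the model ([build_view()]).
#' @param seed Base seed; trial `t` uses `seed + t`.
#' @return A `qoe_cv` object with `metrics` (one row per trial).
#' @export
cross_validate <- function(instances, spec, task, trials = NULL,
                           supplement = NULL, ablation = NULL, seed = 1L) {
  stopifnot(inherits(task, "qoe_task"), "fold" %in% names(instances),
            !anyNA(instances$fold))
  k <- max(instances$fold)
  trials <- trials %||% k
  stopifnot(trials >= 1, trials <= k)
  rows <- lapply(seq_len(trials), function(t) {
    sp <- split_trial(instances, t, k)
    train <- sp$train
    if (!is.null(supplement) && task$kind == "criterion") {
      train <- supplement_training(train, supplement, task$criterion)
    }
    fit <- fit_spec(spec, train, sp$dev, task, ablation, seed + t)
    pred <- stats::predict(fit, sp$test)
    dplyr::bind_cols(tibble::tibble(trial = t, n_test = nrow(sp$test)),
                     trial_metrics(task, pred, sp$test))
  })
  structure(list(metrics = dplyr::bind_rows(rows), task = task,
                 spec = spec, k = k),
            class = "qoe_cv")
}

#' @export
print.qoe_cv <- function(x, ...) {
  cat("<qoe_cv> ", nrow(x$metrics), " trials, task ", x$task$kind, "\n",
      sep = "")
  print(glance(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.qoe_cv <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, -c("trial", "n_test"),
                      names_to = "metric", values_to = "score")
}

#' @exportS3Method generics::glance
glance.qoe_cv <- function(x, ...) {
  tidy(x) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$score),
                     mad = mad_across_folds(.data$score), .groups = "drop")
}

#' Drop-one-feature ablation analysis
#'
#' Runs a reference evaluation, then one evaluation per listed feature with
#' that feature removed, on identical folds and seeds, and reports the
#' changes in precision, recall and F1 relative to the reference. Deltas are
#' reported per feature, never assumed additive.
#'
#' @param instances Instance tibble with folds.
#' @param spec,task,seed,trials,supplement As in [cross_validate()].
#' @param fields Features to drop, defaulting to every inventory field
#'   present.
#' @return A `qoe_ablation` tibble: one reference row (`feature = ".none"`)
#'   and one row per dropped feature with `d_precision`, `d_recall`, `d_f1`.
#' @export
ablation_run <- function(instances, spec, task, fields = NULL, trials = 1L,
                         supplement = NULL, seed = 1L) {
  fields <- fields %||% intersect(table1_fields()$field, names(instances))
  run <- function(ablation) {
    cv <- cross_validate(instances, spec, task, trials = trials,
                         supplement = supplement, ablation = ablation,
                         seed = seed)
    colMeans(x = cv$metrics[c("macro_precision", "macro_recall", "macro_f1")])
  }
  base <- run(NULL)
  rows <- lapply(fields, function(f) {
    m <- run(f)
    tibble::tibble(feature = f,
                   precision = m[["macro_precision"]],
                   recall = m[["macro_recall"]],
                   f1 = m[["macro_f1"]],
                   d_precision = m[["macro_precision"]] - base[["macro_precision"]],
                   d_recall = m[["macro_recall"]] - base[["macro_recall"]],
                   d_f1 = m[["macro_f1"]] - base[["macro_f1"]])
  })
  out <- dplyr::bind_rows(
    tibble::tibble(feature = ".none",
                   precision = base[["macro_precision"]],
                   recall = base[["macro_recall"]],
                   f1 = base[["macro_f1"]],
                   d_precision = 0, d_recall = 0, d_f1 = 0),
    dplyr::bind_rows(rows))
  class(out) <- c("qoe_ablation", class(out))
  out
}

#' Out-of-domain evaluation on one medical area
#'
#' Instances whose medical-area set contains `area` form the test set; all
#' remaining instances are split by review into training and dev sets. The
#' model never sees the held-out area during training.
#'
#' @param instances Instance tibble.
#' @param area A medical area present in the data.
#' @param spec,task,ablation As in [cross_validate()].
#' @param dev_fraction Fraction of training reviews used as the dev set.
#' @param seed Seed for the dev split and fit.
#' @return List with `metrics` (one-row tibble), `n_test`, `n_train`.
#' @export
domain_holdout <- function(instances, area, spec, task, ablation = NULL,
                           dev_fraction = 0.1, seed = 1L) {
  in_area <- purrr::map_lgl(strsplit(instances$medical_area, ";", fixed = TRUE),
                            function(a) area %in% a)
  if (!any(in_area)) stop("no instances in area '", area, "'", call. = FALSE)
  test <- instances[in_area, ]
  rest <- instances[!in_area, ]
  reviews <- unique(rest$review_id)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  dev_reviews <- sample(reviews, max(1L, round(dev_fraction * length(reviews))))
  dev <- rest[rest$review_id %in% dev_reviews, ]
  train <- rest[!rest$review_id %in% dev_reviews, ]
  fit <- fit_spec(spec, train, dev, task, ablation, seed)
  pred <- stats::predict(fit, test)
  list(metrics = trial_metrics(task, pred, test),
       n_test = nrow(test), n_train = nrow(train), area = area)
}
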