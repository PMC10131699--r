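# Trivial and logistic-regression baselines.

#' Fit a baseline predictor
#'
#' Three reference predictors for any task:
#' * `random` — draws labels from a discrete uniform distribution over the
#'   task's label space (or from the training distribution with
#'   `random_dist = "empirical"`); seeded.
#' * `majority` — always the most frequent training class; for criteria
#'   tasks, membership of the criterion in the most frequent training label
#'   *combination* (ties resolve to the earlier class / smaller combination).
#' * `lr` — logistic regression (ridge at a negligible fixed penalty) with
#'   three input variants: `n` numeric features only, `nc` adds categorical
#'   one-hot counts, `nct` adds text bag-of-word counts.
#'
#' @param train Training instances (required for `majority` and `lr`).
#' @param task A [qoe_task()]; `lr` supports the classification tasks
#'   (`criterion`, `grade2`, `grade4`).
#' @param type `"random"`, `"majority"` or `"lr"`.
#' @param variant LR input variant: `"n"`, `"nc"` or `"nct"`.
#' @param random_dist Sampling distribution of the random baseline.
#' @param ablation For `lr`: passed to [build_view()] (field drops, `"-txt"`,
#'   `"+PS"`).
#' @param seed Seed of the random baseline.
#' @return A `qoe_baseline` with a [predict.qoe_baseline()] method.
#' @export
fit_baseline <- function(train, task,
                         type = c("random", "majority", "lr"),
                         variant = c("nct", "nc", "n"),
                         random_dist = c("uniform", "empirical"),
                         ablation = NULL, seed = 1L) {
  type <- match.arg(type)
  variant <- match.arg(variant)
  random_dist <- match.arg(random_dist)
  stopifnot(inherits(task, "qoe_task"))
  fit <- switch(type,
    random = {
      emp <- NULL
      if (random_dist == "empirical") {
        y <- task_labels(task, train)
        emp <- if (is.matrix(y)) colMeans(y) else
          prop.table(table(factor(y, levels = task_label_space(task))))
      }
      list(dist = random_dist, empirical = emp, seed = as.integer(seed))
    },
    majority = majority_fit(train, task),
    lr = lr_fit(train, task, variant, ablation)
  )
  structure(list(type = type, task = task, variant = variant, fit = fit),
            class = "qoe_baseline")
}

task_label_space <- function(task) {
  switch(task$kind, grade4 = 0:3, regression = 0:3, 0:1)
}

majority_fit <- function(train, task) {
  if (is.null(train) || !nrow(train)) {
    stop("majority baseline needs training labels", call. = FALSE)
  }
  if (task$kind %in% c("criterion", "multilabel")) {
    m <- matrix(vapply(criteria(), function(cr) train[[cr]] > 0L,
                       logical(nrow(train))), ncol = 5L)
    combos <- apply(m, 1L, function(r) paste(criteria()[r], collapse = "+"))
    tab <- sort(table(combos), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    combo <- sort(top)[1]
    list(combination = strsplit(combo, "+", fixed = TRUE)[[1]])
  } else {
    y <- task_labels(task, train)
    tab <- table(factor(y, levels = task_label_space(task)))
    list(class = as.integer(names(tab)[which.max(tab)]))
  }
}

lr_design <- function(prep, data, variant) {
  sc <- scale_features(data, prep$scaler)
  x <- Matrix::Matrix(cbind(sc$x, sc$mask), sparse = TRUE)
  if (variant %in% c("nc", "nct")) {
    for (f in prep$cat_fields) {
      x <- cbind(x, cat_matrix(data[[f]], prep$cat_vocab[[f]],
                               normalize = FALSE))
    }
  }
  if (variant == "nct") {
    for (f in prep$text_fields) {
      toks <- tokenize_text(data[[f]], ngram_max = 1L)
      ii <- rep(seq_along(toks), lengths(toks))
      jj <- match(unlist(toks), prep$lr_vocab)
      keep <- !is.na(jj)
      m <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep],
                                x = rep(1, sum(keep)),
                                dims = c(length(toks),
                                         length(prep$lr_vocab)))
      x <- cbind(x, m)
    }
  }
  x
}

lr_fit <- function(train, task, variant, ablation = NULL) {
  if (is.null(train) || !nrow(train)) {
    stop("logistic regression needs training data", call. = FALSE)
  }
  if (!task$kind %in% c("criterion", "grade2", "grade4")) {
    stop("the LR baseline supports the classification tasks", call. = FALSE)
  }
  view <- build_view(train, ablation)
  prep <- fit_preprocessor(view)
  if (variant == "nct") {
    toks <- unlist(lapply(prep$text_fields, function(f) {
      unlist(tokenize_text(train[[f]], ngram_max = 1L))
    }))
    tab <- table(toks)
    prep$lr_vocab <- sort(names(tab)[tab >= 2L])
  }
  x <- lr_design(prep, train, variant)
  y <- task_labels(task, train)
  family <- if (task$kind == "grade4") "multinomial" else "binomial"
  lambda <- 1e-3
  fit <- glmnet::glmnet(x, if (family == "binomial") factor(y, levels = 0:1)
                           else factor(y, levels = 0:3),
                        family = family, alpha = 0,
                        lambda = c(0.1, 0.01, lambda), standardize = TRUE)
  list(prep = prep, glmnet = fit, lambda = lambda, family = family)
}

#' Predict from a baseline
#'
#' @param object A [fit_baseline()] result.
#' @param new_data Instance tibble.
#' @param ... Unused.
#' @return A tibble shaped like the corresponding
#'   [predict.evidencegrader()] output (`.pred`, plus `pred_*` columns for
#'   the multilabel task).
#' @export
predict.qoe_baseline <- function(object, new_data, ...) {
  task <- object$task
  n <- nrow(new_data)
  if (object$type == "random") {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()))
    set.seed(object$fit$seed)
    if (task$kind == "multilabel") {
      pm <- sapply(criteria(), function(cr) {
        pr <- if (object$fit$dist == "empirical") {
          object$fit$empirical[[cr]]
        } else 0.5
        stats::rbinom(n, 1L, pr)
      })
      pm <- matrix(pm, ncol = 5L,
                   dimnames = list(NULL, paste0("pred_", criteria())))
      return(tibble::as_tibble(pm))
    }
    space <- task_label_space(task)
    pr <- if (object$fit$dist == "empirical") {
      as.numeric(object$fit$empirical)
    } else rep(1 / length(space), length(space))
    return(tibble::tibble(.pred = sample(space, n, replace = TRUE,
                                         prob = pr)))
  }
  if (object$type == "majority") {
    if (task$kind == "criterion") {
      hit <- task$criterion %in% object$fit$combination
      return(tibble::tibble(.pred = rep(as.integer(hit), n)))
    }
    if (task$kind == "multilabel") {
      pm <- matrix(rep(as.integer(criteria() %in% object$fit$combination),
                       each = n), nrow = n,
                   dimnames = list(NULL, paste0("pred_", criteria())))
      return(tibble::as_tibble(pm))
    }
    return(tibble::tibble(.pred = rep(object$fit$class, n)))
  }
  # logistic regression
  x <- lr_design(object$fit$prep, new_data, object$variant)
  if (object$fit$family == "binomial") {
    pr <- as.numeric(stats::predict(object$fit$glmnet, x, s = object$fit$lambda,
                                    type = "response"))
    tibble::tibble(.prob = pr, .pred = as.integer(pr > 0.5))
  } else {
    pr <- stats::predict(object$fit$glmnet, x, s = object$fit$lambda,
                         type = "response")[, , 1]
    pred <- max.col(pr, ties.method = "first") - 1L
    colnames(pr) <- paste0("prob_", 0:3)
    dplyr::bind_cols(tibble::as_tibble(pr), tibble::tibble(.pred = pred))
  }
}

#' @export
print.qoe_baseline <- function(x, ...) {
  cat("<qoe_baseline> ", x$type,
      if (x$type == "lr") paste0("-", x$variant),
      " for task ", x$task$kind, "\n", sep = "")
  invisible(x)
}
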