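# The multi-view quality-of-evidence predictor: numeric / categorical /
# hashed-text encoders, linear aggregation, four task heads.

TASK_KINDS <- c("criterion", "multilabel", "grade4", "grade2", "regression")

#' Define a prediction task
#'
#' The modelling subtasks share one architecture and differ only in the
#' output head:
#' * `criterion` — binary detection of one downgrading criterion;
#' * `multilabel` — joint detection of all five criteria (sigmoid units, a
#'   unit above 0.5 fires);
#' * `grade4` — 4-tier grade as multiclass classification;
#' * `grade2` — 2-tier grade (high+moderate vs low+very low) as binary
#'   classification;
#' * `regression` — grade as a scalar on the 0--3 scale (reported raw and via
#'   [scalar_to_grade()]).
#'
#' @param kind One of the task kinds above.
#' @param criterion For `kind = "criterion"`: one of [criteria()].
#' @return A `qoe_task`.
#' @export
qoe_task <- function(kind = TASK_KINDS, criterion = NULL) {
  kind <- match.arg(kind)
  if (kind == "criterion") {
    if (is.null(criterion) || !criterion %in% criteria()) {
      stop("a criterion task needs `criterion` among: ",
           paste(criteria(), collapse = ", "), call. = FALSE)
    }
  } else criterion <- NULL
  structure(list(kind = kind, criterion = criterion), class = "qoe_task")
}

task_head <- function(task) {
  switch(task$kind,
         criterion = "binary", grade2 = "binary",
         multilabel = "multilabel", grade4 = "multiclass",
         regression = "regression")
}

task_out_dim <- function(task) {
  switch(task$kind, criterion = 1L, grade2 = 1L, multilabel = 5L,
         grade4 = 4L, regression = 1L)
}

task_labels <- function(task, data) {
  switch(task$kind,
    criterion = as.integer(data[[task$criterion]] > 0L),
    grade2 = as.integer(data$grade >= 2L),
    multilabel = {
      m <- sapply(criteria(), function(cr) as.integer(data[[cr]] > 0L))
      matrix(m, ncol = 5L, dimnames = list(NULL, criteria()))
    },
    grade4 = as.integer(data$grade),
    regression = as.numeric(data$grade))
}

#' Model configuration
#'
#' Architecture and optimisation settings of the multi-view predictor. The
#' numeric block (scaled values plus missing mask) passes through a 3-layer
#' feed-forward encoder; categorical tokens through learned embeddings
#' (token vectors averaged within a field, fields concatenated); each text
#' field through a deterministic hashed bag-of-1--2-grams with a learned
#' linear projection, one vector per field, concatenated. Every encoder
#' output is layer-normalised, then a linear layer aggregates the blocks and
#' the task head reads the aggregate. These defaults are artifact constants
#' declared here, not tuned values.
#'
#' @param numeric_hidden Sizes of the three feed-forward layers.
#' @param cat_dim Categorical embedding width.
#' @param text_dim Per-field text projection width.
#' @param hash_bits Hashed text space is `2^hash_bits` wide.
#' @param ngram_max Maximum text n-gram order.
#' @param agg_dim Width of the linear aggregation layer.
#' @param class_weighting Weight examples inversely proportionally to class
#'   frequency (`w_c = N / (2 N_c)`) in the binary/multilabel losses.
#' @param lr,epochs,batch_size Adam learning rate, maximum epochs, minibatch
#'   size.
#' @param patience Early-stopping patience on the dev score (macro-F1 for
#'   classification heads, negative MAE for regression).
#' @param seed Seed for initialisation and batch shuffling.
#' @param hash_seed Seed of the text token hash.
#' @return A `qoe_model_config`.
#' @export
model_config <- function(numeric_hidden = c(32L, 32L, 32L),
                         cat_dim = 8L, text_dim = 16L, hash_bits = 12L,
                         ngram_max = 2L, agg_dim = 32L,
                         class_weighting = TRUE, lr = 3e-3, epochs = 30L,
                         batch_size = 64L, patience = 5L, seed = 1L,
                         hash_seed = 7L) {
  stopifnot(length(numeric_hidden) == 3L, all(numeric_hidden > 0),
            cat_dim > 0, text_dim > 0, hash_bits > 0, agg_dim > 0,
            lr > 0, epochs >= 1, batch_size >= 1, patience >= 1)
  structure(list(numeric_hidden = as.integer(numeric_hidden),
                 cat_dim = as.integer(cat_dim),
                 text_dim = as.integer(text_dim),
                 hash_bits = as.integer(hash_bits),
                 ngram_max = as.integer(ngram_max),
                 agg_dim = as.integer(agg_dim),
                 class_weighting = isTRUE(class_weighting),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 hash_seed = as.integer(hash_seed)),
            class = "qoe_model_config")
}

#' Inverse-class-frequency weights
#'
#' `w_c = N / (2 N_c)` for a binary label vector, so balanced data yields
#' weight 1 for both classes. A class with zero training instances errors
#' with a pointer to [supplement_training()].
#'
#' @param y 0/1 integer vector.
#' @return Named vector `c(negative = w0, positive = w1)`.
#' @export
class_weights <- function(y) {
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("a class has no training instances; consider supplement_training()",
         call. = FALSE)
  }
  c(negative = length(y) / (2 * n0), positive = length(y) / (2 * n1))
}

#' Head losses
#'
#' The training losses of the task heads, exposed for direct computation:
#' weighted binary cross-entropy (binary and multilabel heads),
#' cross-entropy over four grades (multiclass head), mean squared error
#' (regression head). With weighting disabled or balanced weights this is
#' the plain loss.
#'
#' @param head `"binary"`, `"multilabel"`, `"multiclass"` or `"regression"`.
#' @param scores Probabilities (binary/multilabel), logits (multiclass), or
#'   predicted scalars (regression); vector or matrix.
#' @param labels 0/1 vector or matrix, class integers 0--3, or numeric
#'   targets, matching the head.
#' @param weights Optional per-observation (or per-cell) weights.
#' @return Scalar loss.
#' @export
model_loss <- function(head, scores, labels, weights = NULL) {
  head <- match.arg(head, c("binary", "multilabel", "multiclass",
                            "regression"))
  if (head %in% c("binary", "multilabel")) {
    pr <- as.matrix(scores)
    y <- as.matrix(labels)
    stopifnot(all(dim(pr) == dim(y)))
    w <- if (is.null(weights)) 1 else weights
    eps <- 1e-12
    -mean(w * (y * log(pr + eps) + (1 - y) * log(1 - pr + eps)))
  } else if (head == "multiclass") {
    z <- as.matrix(scores)
    zmax <- apply(z, 1L, max)
    ez <- exp(z - zmax)
    sm <- ez / rowSums(ez)
    -mean(log(sm[cbind(seq_len(nrow(z)), labels + 1L)] + 1e-12))
  } else {
    mean((as.numeric(scores) - as.numeric(labels))^2)
  }
}

make_weights <- function(task, labels, on) {
  if (!on) return(NULL)
  if (task$kind %in% c("criterion", "grade2")) {
    w <- class_weights(labels)
    matrix(ifelse(labels == 1L, w[["positive"]], w[["negative"]]),
           ncol = 1L)
  } else if (task$kind == "multilabel") {
    out <- matrix(1, nrow(labels), ncol(labels))
    for (j in seq_len(ncol(labels))) {
      w <- class_weights(labels[, j])
      out[, j] <- ifelse(labels[, j] == 1L, w[["positive"]], w[["negative"]])
    }
    out
  } else NULL
}

dev_score <- function(task, pred, labels) {
  switch(task$kind,
    criterion = ,
    grade2 = macro_f1(labels, pred$.pred, classes = c(0L, 1L)),
    multilabel = {
      pm <- as.matrix(pred[paste0("pred_", criteria())])
      colnames(pm) <- criteria()
      multilabel_scores(pm, labels)$macro_f1
    },
    grade4 = macro_f1(labels, pred$.pred, classes = 0:3),
    regression = -mae_grade(pred$.pred, labels))
}

#' Fit the multi-view quality predictor
#'
#' Trains the encoder/aggregation/head network with Adam and minibatches,
#' early-stopping on the dev-set score (macro-F1, or negative MAE for the
#' regression head) and returning the best-dev checkpoint. Training is
#' deterministic given `config$seed`. Train and dev must be disjoint by
#' review.
#'
#' @param train,dev Instance tibbles; `dev` must be non-empty.
#' @param task A [qoe_task()].
#' @param config A [model_config()].
#' @param ablation Passed to [build_view()] (e.g. `"-txt"`, `"+PS"`, field
#'   names to drop).
#' @return An `evidencegrader` fit; see [predict.evidencegrader()],
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
fit_evidencegrader <- function(train, dev, task, config = model_config(),
                               ablation = NULL) {
  stopifnot(inherits(task, "qoe_task"), inherits(config, "qoe_model_config"))
  if (is.null(dev) || !nrow(dev)) stop("dev set is empty", call. = FALSE)
  if (any(dev$review_id %in% train$review_id)) {
    stop("train and dev share reviews; split by review first", call. = FALSE)
  }
  # canonical row order: results depend on the seed, not on how the caller
  # happened to order the training rows
  ord_cols <- intersect(c("review_id", "sof_index", "outcome_index"),
                        names(train))
  if (length(ord_cols)) train <- dplyr::arrange(train,
                                                dplyr::across(dplyr::all_of(ord_cols)))
  view <- build_view(train, ablation)
  prep <- fit_preprocessor(view, hash_bits = config$hash_bits,
                           hash_seed = config$hash_seed,
                           ngram_max = config$ngram_max)
  mats <- transform_view(prep, train)
  dev_mats <- transform_view(prep, dev)
  y <- task_labels(task, train)
  y_dev <- task_labels(task, dev)
  weights <- make_weights(task, y, config$class_weighting)
  head <- task_head(task)
  blocks <- block_spec(mats, config, task_out_dim(task))

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  p <- init_params(blocks, config)
  opt <- adam_init(p)
  n <- mats$n
  best <- list(score = -Inf, params = p, epoch = 0L)
  log <- list()
  stale <- 0L
  for (epoch in seq_len(config$epochs)) {
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    epoch_loss <- 0
    for (b in batches) {
      bm <- slice_mats(mats, b)
      by <- if (is.matrix(y)) y[b, , drop = FALSE] else y[b]
      bw <- if (is.null(weights)) NULL else weights[b, , drop = FALSE]
      fwd <- nn_forward(p, bm, config)
      lg <- head_loss_grad(head, fwd$logits, by, bw)
      g <- nn_backward(p, bm, config, fwd, lg$dlogits)
      res <- adam_step(p, g, opt, config$lr)
      p <- res$p; opt <- res$state
      epoch_loss <- epoch_loss + lg$loss * length(b)
    }
    fit_tmp <- structure(list(params = p, prep = prep, config = config,
                              task = task, ablation = ablation),
                         class = "evidencegrader")
    pred_dev <- predict_mats(fit_tmp, dev_mats)
    score <- dev_score(task, pred_dev, y_dev)
    log[[epoch]] <- tibble::tibble(epoch = epoch,
                                   train_loss = epoch_loss / n,
                                   dev_score = score)
    if (score > best$score + 1e-9) {
      best <- list(score = score, params = p, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  structure(list(params = best$params, prep = prep, config = config,
                 task = task, ablation = ablation,
                 best_epoch = best$epoch, dev_score = best$score,
                 log = dplyr::bind_rows(log), n_train = n),
            class = "evidencegrader")
}

#' @export
print.evidencegrader <- function(x, ...) {
  cat("<evidencegrader> task ", x$task$kind,
      if (!is.null(x$task$criterion)) paste0(" (", x$task$criterion, ")"),
      "; best dev score ", round(x$dev_score, 4),
      " at epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

predict_mats <- function(object, mats) {
  fwd <- nn_forward(object$params, mats, object$config)
  logits <- fwd$logits
  task <- object$task
  switch(task$kind,
    criterion = ,
    grade2 = {
      pr <- stats::plogis(logits[, 1])
      tibble::tibble(.prob = pr, .pred = as.integer(pr > 0.5))
    },
    multilabel = {
      pr <- stats::plogis(logits)
      colnames(pr) <- paste0("prob_", criteria())
      fired <- matrix(as.integer(pr > 0.5), nrow(pr),
                      dimnames = list(NULL, paste0("pred_", criteria())))
      dplyr::bind_cols(tibble::as_tibble(pr), tibble::as_tibble(fired))
    },
    grade4 = {
      zmax <- apply(logits, 1L, max)
      ez <- exp(logits - zmax)
      sm <- ez / rowSums(ez)
      colnames(sm) <- paste0("prob_", 0:3)
      # ties resolve to the lowest grade index
      pred <- max.col(sm, ties.method = "first") - 1L
      dplyr::bind_cols(tibble::as_tibble(sm), tibble::tibble(.pred = pred))
    },
    regression = tibble::tibble(.pred_raw = logits[, 1],
                                .pred = scalar_to_grade(logits[, 1])))
}

#' Predict from a fitted multi-view model
#'
#' @param object An `evidencegrader` fit.
#' @param new_data Instance tibble.
#' @param ... Unused.
#' @return A tibble: binary tasks give `.prob` and `.pred` (0.5 threshold);
#'   the multilabel head gives per-criterion `prob_*`/`pred_*` (units above
#'   0.5 fire); the 4-tier head gives class probabilities and the arg-max
#'   `.pred` (ties to the lowest grade); regression gives `.pred_raw` and the
#'   rounded `.pred`.
#' @export
predict.evidencegrader <- function(object, new_data, ...) {
  predict_mats(object, transform_view(object$prep, new_data))
}

#' Aggregated representation of instances
#'
#' Runs the fitted encoders and the linear aggregation, returning the
#' representation the task head reads (one row per instance, `agg_dim`
#' columns).
#'
#' @param object An `evidencegrader` fit.
#' @param new_data Instance tibble.
#' @return Numeric matrix.
#' @export
encode <- function(object, new_data) {
  stopifnot(inherits(object, "evidencegrader"))
  mats <- transform_view(object$prep, new_data)
  nn_forward(object$params, mats, object$config)$A
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.evidencegrader <- function(x, ...) x$log

#' @exportS3Method generics::glance
glance.evidencegrader <- function(x, ...) {
  tibble::tibble(task = x$task$kind,
                 criterion = x$task$criterion %||% NA_character_,
                 n_train = x$n_train,
                 best_epoch = x$best_epoch,
                 dev_score = x$dev_score,
                 epochs_run = nrow(x$log))
}
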