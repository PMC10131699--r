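# Model-ready feature views: numeric scaling with missingness masks,
# categorical vocabularies, hashed text, ablation masks.

#' Fit a min-max scaler on training rows
#'
#' Learns per-feature minimum, maximum and median on the training fold only.
#' At transform time values are scaled to `(x - min) / (max - min)`, clipped
#' to \[0, 1\] when out of the training range, constant features map to 0,
#' and missing values are imputed with the scaled training median while a
#' parallel missing-mask records where imputation happened.
#'
#' @param train Data frame of training rows.
#' @param fields Numeric fields to scale (defaults to the numeric inventory
#'   fields present in `train`).
#' @return A `qoe_scaler`.
#' @seealso [scale_features()]
#' @export
fit_scaler <- function(train, fields = NULL) {
  if (is.null(fields)) {
    fields <- intersect(field_names("num", include_ps = TRUE), names(train))
  }
  stopifnot(length(fields) > 0, all(fields %in% names(train)))
  stats_ <- lapply(fields, function(f) {
    x <- train[[f]]
    if (all(is.na(x))) return(c(min = 0, max = 0, median = 0))
    c(min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE),
      median = stats::median(x, na.rm = TRUE))
  })
  structure(list(fields = fields,
                 stats = do.call(rbind, stats_)),
            class = "qoe_scaler")
}

#' Apply a fitted min-max scaler
#'
#' @param data Data frame containing the scaler's fields.
#' @param scaler A [fit_scaler()] result.
#' @return List with `x` (matrix of scaled values, imputed) and `mask`
#'   (matrix, 1 where the value was missing).
#' @export
scale_features <- function(data, scaler) {
  if (!inherits(scaler, "qoe_scaler")) {
    stop("transform before fit: pass a qoe_scaler from fit_scaler()",
         call. = FALSE)
  }
  n <- nrow(data)
  x <- matrix(0, n, length(scaler$fields),
              dimnames = list(NULL, scaler$fields))
  mask <- x
  for (j in seq_along(scaler$fields)) {
    f <- scaler$fields[j]
    st <- scaler$stats[j, ]
    v <- as.numeric(data[[f]])
    rng <- st[["max"]] - st[["min"]]
    scaled <- if (rng > 0) pmin(1, pmax(0, (v - st[["min"]]) / rng)) else
      rep(0, n)
    med <- if (rng > 0) min(1, max(0, (st[["median"]] - st[["min"]]) / rng))
           else 0
    miss <- is.na(v)
    scaled[miss] <- med
    x[, j] <- scaled
    mask[, j] <- as.numeric(miss)
  }
  list(x = x, mask = mask)
}

#' Build a feature view with optional ablation
#'
#' A view selects which inventory fields feed each model block (numeric,
#' categorical, text), in the fixed inventory order. Ablations: a character
#' set of field names to drop; the macro `"-txt"` removes all text fields;
#' the macro `"+PS"` enables the primary-study-derived fields (which must be
#' present on the instances, see [attach_study_features()]). Macros and field
#' names can be combined. Unknown names error, listing the valid fields.
#'
#' @param data Instance tibble.
#' @param ablation `NULL`, or character vector of field names and/or the
#'   macros `"-txt"`, `"+PS"`.
#' @return A `qoe_view`: list with `data` and the active `numeric_fields`,
#'   `cat_fields`, `text_fields`.
#' @export
build_view <- function(data, ablation = NULL) {
  include_ps <- "+PS" %in% ablation
  inv <- table1_fields(include_ps = include_ps)
  drop_txt <- "-txt" %in% ablation
  drops <- setdiff(ablation, c("-txt", "+PS"))
  unknown <- setdiff(drops, inv$field)
  if (length(unknown)) {
    stop("unknown field(s) in ablation: ", paste(unknown, collapse = ", "),
         "; valid fields: ", paste(inv$field, collapse = ", "),
         call. = FALSE)
  }
  if (include_ps) {
    miss <- setdiff(inv$field[inv$ps], names(data))
    if (length(miss)) {
      stop("+PS requested but primary-study columns are absent; run ",
           "attach_study_features() first", call. = FALSE)
    }
  }
  active <- inv[!(inv$field %in% drops), ]
  if (drop_txt) active <- active[active$type != "text", ]
  active <- active[active$field %in% names(data), ]
  structure(list(
    data = data,
    numeric_fields = active$field[active$type == "num"],
    cat_fields = active$field[active$type == "cat"],
    text_fields = active$field[active$type == "text"],
    ablation = ablation
  ), class = "qoe_view")
}

#' @export
print.qoe_view <- function(x, ...) {
  cat("<qoe_view> ", nrow(x$data), " rows; ",
      length(x$numeric_fields), " num / ", length(x$cat_fields), " cat / ",
      length(x$text_fields), " text fields\n", sep = "")
  invisible(x)
}

UNK_TOKEN <- "<unk>"

# categorical fields hold single tokens or ";"-joined token sets
cat_tokens <- function(x) {
  x[is.na(x)] <- UNK_TOKEN
  strsplit(as.character(x), ";", fixed = TRUE)
}

fit_cat_vocab <- function(data, fields) {
  lapply(stats::setNames(fields, fields), function(f) {
    toks <- sort(unique(unlist(cat_tokens(data[[f]]))))
    c(UNK_TOKEN, setdiff(toks, UNK_TOKEN))
  })
}

# sparse indicator matrix of a categorical field, row-normalised for the
# embedding encoder (token vectors averaged within the field) or raw 0/1
# counts; unknown tokens at transform time map to the reserved <unk> id
cat_matrix <- function(x, vocab, normalize = TRUE) {
  toks <- cat_tokens(x)
  ii <- rep(seq_along(toks), lengths(toks))
  jj <- match(unlist(toks), vocab)
  jj[is.na(jj)] <- 1L
  vals <- if (normalize) 1 / lengths(toks)[ii] else rep(1, length(ii))
  Matrix::sparseMatrix(i = ii, j = jj, x = vals,
                       dims = c(length(toks), length(vocab)))
}

tokenize_text <- function(x, ngram_max = 2L) {
  x[is.na(x)] <- ""
  toks <- strsplit(tolower(x), "[^a-z0-9]+")
  lapply(toks, function(t) {
    t <- t[nzchar(t)]
    if (ngram_max >= 2L && length(t) >= 2L) {
      t <- c(t, paste(t[-length(t)], t[-1], sep = "_"))
    }
    t
  })
}

# deterministic polynomial string hash into [1, 2^bits]
hash_tokens <- function(tokens, bits, seed = 7L) {
  m <- 2^bits
  u <- unique(tokens)
  h <- vapply(u, function(t) {
    v <- (seed %% m)
    for (code in utf8ToInt(t)) v <- (v * 31 + code) %% m
    v
  }, numeric(1), USE.NAMES = FALSE)
  (h[match(tokens, u)]) + 1
}

# sparse hashed term-frequency matrix, rows L1-normalised
text_matrix <- function(x, bits, seed = 7L, ngram_max = 2L) {
  toks <- tokenize_text(x, ngram_max)
  n <- length(toks)
  lens <- lengths(toks)
  if (sum(lens) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, 2^bits)))
  }
  ii <- rep(seq_len(n), lens)
  jj <- hash_tokens(unlist(toks), bits, seed)
  vals <- 1 / pmax(lens, 1L)[ii]
  Matrix::sparseMatrix(i = ii, j = jj, x = vals, dims = c(n, 2^bits))
}

#' Fit the model preprocessor on a training view
#'
#' Combines the min-max scaler (numeric block), per-field categorical
#' vocabularies with a reserved unknown id, and the deterministic hashed
#' text configuration. Fit only ever sees training rows; transforms of dev or
#' test rows depend exclusively on training statistics.
#'
#' @param view Training `qoe_view` from [build_view()].
#' @param hash_bits Width of the hashed text space (`2^hash_bits` columns).
#' @param hash_seed Seed of the token hash.
#' @param ngram_max Maximum n-gram order (1 or 2).
#' @return A `qoe_preprocessor`.
#' @export
fit_preprocessor <- function(view, hash_bits = 12L, hash_seed = 7L,
                             ngram_max = 2L) {
  stopifnot(inherits(view, "qoe_view"))
  scaler <- if (length(view$numeric_fields)) {
    fit_scaler(view$data, view$numeric_fields)
  }
  structure(list(
    scaler = scaler,
    cat_vocab = fit_cat_vocab(view$data, view$cat_fields),
    numeric_fields = view$numeric_fields,
    cat_fields = view$cat_fields,
    text_fields = view$text_fields,
    hash_bits = as.integer(hash_bits),
    hash_seed = as.integer(hash_seed),
    ngram_max = as.integer(ngram_max)
  ), class = "qoe_preprocessor")
}

#' Transform instances into model matrices
#'
#' @param prep A [fit_preprocessor()] result.
#' @param data Instance tibble (any fold).
#' @return List of blocks: `num` (list `x`, `mask`), `cat` (named list of
#'   sparse row-normalised indicator matrices), `txt` (named list of sparse
#'   hashed term-frequency matrices), `n` rows.
#' @export
transform_view <- function(prep, data) {
  stopifnot(inherits(prep, "qoe_preprocessor"))
  num <- if (!is.null(prep$scaler)) scale_features(data, prep$scaler)
  cats <- lapply(stats::setNames(prep$cat_fields, prep$cat_fields),
                 function(f) cat_matrix(data[[f]], prep$cat_vocab[[f]]))
  txts <- lapply(stats::setNames(prep$text_fields, prep$text_fields),
                 function(f) text_matrix(data[[f]], prep$hash_bits,
                                         prep$hash_seed, prep$ngram_max))
  list(num = num, cat = cats, txt = txts, n = nrow(data))
}
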