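# Review-corpus schema (JSONL), dataset CSV export, field inventory.

SCHEMA_VERSION <- "1.0"

ROB_COMPONENTS <- c("random_sequence_generation", "allocation_concealment",
                    "blinding", "incomplete_outcome_data",
                    "selective_reporting")
ROB_JUDGEMENTS <- c("low", "high", "unclear")

BODY_TEXT_FIELDS <- c("abstract_conclusion", "plain_language_summary",
                      "full_abstract", "authors_conclusions")
STUDY_COUNT_FIELDS <- c("included", "ongoing", "other", "additional",
                        "excluded")

#' Risk-of-bias components of primary studies
#'
#' The per-study risk-of-bias components carried by the corpus schema, each
#' judged low / high / unclear with a free-text justification.
#'
#' @return Character vector of component names.
#' @export
rob_components <- function() ROB_COMPONENTS

#' Data-field inventory of the flat dataset
#'
#' The support features attached to every body of evidence: categorical,
#' numeric and text fields drawn from review metadata, the summary-of-findings
#' entry and the review body text, plus the optional per-risk-of-bias-component
#' features derived from aligned primary studies (`ps = TRUE`).
#'
#' @param include_ps Include the primary-study-derived fields.
#' @return A tibble with columns `field`, `type` (`num`/`cat`/`text`),
#'   `source`, and `ps`.
#' @export
#' @examples
#' table1_fields()
table1_fields <- function(include_ps = FALSE) {
  base <- tibble::tribble(
    ~field,                  ~type,  ~source,
    "review_type",           "cat",  "metadata",
    "medical_area",          "cat",  "metadata",
    "type_of_effect",        "cat",  "sof",
    "year",                  "num",  "metadata",
    "n_sofs",                "num",  "sof",
    "n_participants",        "num",  "sof",
    "upper_ci",              "num",  "sof",
    "lower_ci",              "num",  "sof",
    "n_outcomes",            "num",  "sof",
    "relative_effect",       "num",  "sof",
    "n_studies",             "num",  "sof",
    "n_included_studies",    "num",  "metadata",
    "n_ongoing_studies",     "num",  "metadata",
    "n_other_studies",       "num",  "metadata",
    "n_additional_studies",  "num",  "metadata",
    "n_excluded_studies",    "num",  "metadata",
    "outcome",               "text", "sof",
    "abstract_conclusion",   "text", "body_text",
    "plain_language_summary","text", "body_text",
    "full_abstract",         "text", "body_text",
    "authors_conclusions",   "text", "body_text"
  )
  base$ps <- FALSE
  if (!include_ps) return(base)
  ps <- dplyr::bind_rows(
    tibble::tibble(field = "ps_methods", type = "text",
                   source = "primary_studies"),
    tibble::tibble(field = paste0("ps_judgement_", ROB_COMPONENTS),
                   type = "cat", source = "primary_studies"),
    tidyr::expand_grid(prefix = c("ps_n_low_", "ps_n_high_", "ps_n_unclear_",
                                  "ps_prop_high_"),
                       comp = ROB_COMPONENTS) |>
      dplyr::transmute(field = paste0(.data$prefix, .data$comp), type = "num",
                       source = "primary_studies")
  )
  ps$ps <- TRUE
  dplyr::bind_rows(base, ps)
}

field_names <- function(type = NULL, include_ps = FALSE) {
  inv <- table1_fields(include_ps)
  if (!is.null(type)) inv <- inv[inv$type %in% type, ]
  inv$field
}

stop_line <- function(line, msg) {
  stop(sprintf("%s at line %d", msg, line), call. = FALSE)
}

validate_review <- function(rec, line) {
  for (f in c("review_id", "review_type", "year")) {
    if (is.null(rec[[f]]) || !length(rec[[f]]) || is.na(rec[[f]][1]) ||
        !nzchar(as.character(rec[[f]][1]))) {
      stop_line(line, paste0("missing ", f))
    }
  }
  counts <- unlist(rec$study_counts)
  if (length(counts) && any(!is.na(counts) & counts < 0)) {
    stop_line(line, "negative study_counts")
  }
  for (sof in rec$sofs) {
    for (e in sof$entries) {
      lo <- e$ci_lower; hi <- e$ci_upper
      if (!is.null(lo) && !is.null(hi) && !is.na(lo) && !is.na(hi) && lo > hi) {
        stop_line(line, "ci_lower > ci_upper")
      }
      if (!is.null(e$grade) && !is.na(e$grade) &&
          !(e$grade %in% GRADE_LABELS)) {
        stop_line(line, paste0("invalid grade '", e$grade, "'"))
      }
    }
  }
  invisible(rec)
}

#' Read a review corpus from JSON lines
#'
#' One review per line, UTF-8, schema-validated (`review_id`, `review_type`
#' and `year` required; CI bounds ordered; grades among the four levels).
#' Unknown fields are preserved in the returned records but ignored by the
#' pipeline.
#'
#' @param path Path to a `.jsonl` corpus file.
#' @return A list of review records (class `qoe_corpus`).
#' @seealso [write_corpus()], [generate_corpus()]
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) stop_line(i, paste0("malformed JSON (", conditionMessage(e), ")"))
    )
    validate_review(rec, i)
    ids[i] <- rec$review_id
    recs[[i]] <- rec
  }
  if (anyDuplicated(ids)) {
    stop("duplicate review_id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  structure(recs, class = "qoe_corpus")
}

#' Write a review corpus as JSON lines
#'
#' @param corpus A list of review records ([read_corpus()] /
#'   [generate_corpus()] output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(rec) {
    rec$schema_version <- rec$schema_version %||% SCHEMA_VERSION
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.qoe_corpus <- function(x, ...) {
  n_out <- sum(vapply(x, function(r) {
    sum(vapply(r$sofs, function(s) length(s$entries), integer(1)))
  }, integer(1)))
  cat("<qoe_corpus> ", length(x), " reviews, ", n_out, " outcomes\n", sep = "")
  invisible(x)
}

DATASET_LABEL_COLS <- c("grade", "risk_of_bias", "imprecision",
                        "inconsistency", "indirectness", "publication_bias",
                        "review_id", "fold")

#' Write the flat dataset CSV
#'
#' One row per body of evidence; columns are the [table1_fields()] inventory
#' followed by the grade, the five per-criterion step columns, `review_id`
#' and `fold` (RFC-4180, header mandatory). Primary-study-derived columns are
#' included when present in `instances`. Missing values are written as empty
#' cells, never as 0.
#'
#' @param instances Instance tibble (from [extract_instances()] or
#'   [build_dataset()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(instances, path) {
  if (!nrow(instances)) stop("dataset is empty", call. = FALSE)
  base <- field_names()
  ps <- intersect(field_names(include_ps = TRUE), names(instances))
  ps <- setdiff(ps, base)
  cols <- c(base, ps, DATASET_LABEL_COLS)
  out <- instances
  for (m in setdiff(cols, names(out))) out[[m]] <- NA
  out <- out[cols]
  out$grade <- grade_label(out$grade)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read back a flat dataset CSV
#'
#' Inverse of [write_dataset_csv()]: grades return to their integer coding,
#' criterion steps and fold to integers, and empty cells to `NA`.
#'
#' @param path Path to a dataset CSV.
#' @return A tibble.
#' @export
read_dataset_csv <- function(path) {
  num <- field_names("num")
  txt <- c(field_names(c("text", "cat")), "review_id")
  spec <- c(
    stats::setNames(rep(list(readr::col_double()), length(num)), num),
    stats::setNames(rep(list(readr::col_character()), length(txt)), txt),
    list(grade = readr::col_character(), fold = readr::col_integer()),
    stats::setNames(rep(list(readr::col_integer()), 5L), criteria())
  )
  out <- readr::read_csv(path, col_types = do.call(readr::cols, spec),
                         na = "", progress = FALSE)
  out$grade <- grade_value(out$grade)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
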