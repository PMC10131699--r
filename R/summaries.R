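# Corpus summaries and external validation of the extraction.

#' Summarise a labeled instance set
#'
#' Class counts and percentages per grade, per-criterion annotation counts
#' (with both the all-instance and the non-high-instance denominators),
#' review counts, studies and summary-of-findings tables per review, and
#' pairwise criterion co-occurrence rates.
#'
#' @param instances Non-empty instance tibble.
#' @return A `qoe_summary`: list of tibbles `grades`, `criteria`,
#'   `co_occurrence`, and scalars `n_instances`, `n_reviews`,
#'   `studies_per_review` (mean, sd), `sofs_per_review` (mean, sd).
#' @export
summarize_corpus <- function(instances) {
  if (!nrow(instances)) stop("no instances to summarise", call. = FALSE)
  grades <- instances |>
    dplyr::count(grade = .data$grade) |>
    dplyr::mutate(label = grade_label(.data$grade),
                  pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$grade))
  non_high <- sum(instances$grade != 3L, na.rm = TRUE)
  n_pos <- vapply(criteria(), function(cr) sum(instances[[cr]] > 0L),
                  integer(1))
  crit <- tibble::tibble(
    criterion = criteria(),
    n_positive = unname(n_pos),
    pct_all = 100 * unname(n_pos) / nrow(instances),
    pct_non_high = 100 * unname(n_pos) / max(non_high, 1L)
  )
  pairs <- utils::combn(criteria(), 2L)
  n_both <- apply(pairs, 2L, function(p) {
    sum(instances[[p[1]]] > 0L & instances[[p[2]]] > 0L)
  })
  co <- tibble::tibble(
    criterion_a = pairs[1, ],
    criterion_b = pairs[2, ],
    n_both = n_both,
    rate = n_both / nrow(instances)
  )
  per_review <- instances |>
    dplyr::group_by(.data$review_id) |>
    dplyr::summarise(n_studies = .data$n_included_studies[1],
                     n_sofs = .data$n_sofs[1], .groups = "drop")
  structure(list(
    grades = grades,
    criteria = crit,
    co_occurrence = dplyr::arrange(co, dplyr::desc(.data$rate)),
    n_instances = nrow(instances),
    n_reviews = dplyr::n_distinct(instances$review_id),
    studies_per_review = c(mean = mean(per_review$n_studies, na.rm = TRUE),
                           sd = stats::sd(per_review$n_studies)),
    sofs_per_review = c(mean = mean(per_review$n_sofs, na.rm = TRUE),
                        sd = stats::sd(per_review$n_sofs))
  ), class = "qoe_summary")
}

#' @export
print.qoe_summary <- function(x, ...) {
  cat("<qoe_summary> ", x$n_instances, " instances from ", x$n_reviews,
      " reviews\n", sep = "")
  print(x$grades)
  print(x$criteria)
  invisible(x)
}

#' Validate extracted fields against a reference annotation table
#'
#' Joins the extracted table to an externally annotated reference on a key
#' and reports per-field exact-match accuracy over the joined rows (two `NA`s
#' count as a match). Unjoined rows on either side are reported as
#' attributes, not errors.
#'
#' @param extracted,reference Data frames sharing `key` columns and `fields`.
#' @param fields Character vector of fields to compare.
#' @param key Join key columns (default the body-of-evidence key).
#' @return A tibble (`field`, `accuracy`, `n`) with attributes
#'   `"unjoined_extracted"` and `"unjoined_reference"`.
#' @export
validate_extraction <- function(extracted, reference, fields,
                                key = c("review_id", "sof_index",
                                        "outcome_index")) {
  stopifnot(all(key %in% names(extracted)), all(key %in% names(reference)),
            all(fields %in% names(extracted)),
            all(fields %in% names(reference)))
  joined <- dplyr::inner_join(
    extracted[c(key, fields)], reference[c(key, fields)],
    by = key, suffix = c("_ext", "_ref"))
  if (!nrow(joined)) stop("no joinable rows between extracted and reference",
                          call. = FALSE)
  acc <- vapply(fields, function(f) {
    a <- joined[[paste0(f, "_ext")]]
    b <- joined[[paste0(f, "_ref")]]
    mean((is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b))
  }, numeric(1))
  out <- tibble::tibble(field = fields, accuracy = unname(acc),
                        n = nrow(joined))
  attr(out, "unjoined_extracted") <- nrow(extracted) - nrow(joined)
  attr(out, "unjoined_reference") <- nrow(reference) - nrow(joined)
  out
}
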