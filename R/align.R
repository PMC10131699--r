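# Alignment of bodies of evidence to primary studies by constrained
# minimum-edit-distance matching, and study-derived support features.

#' Align one body of evidence to primary studies
#'
#' Each meta-analysis study reference is matched to at most one primary
#' study: an exact label match wins outright; otherwise the study at minimum
#' character-level Levenshtein distance is taken, provided the distance is at
#' most `max_distance` *and* the reference-side constraints (type of effect,
#' size of the effect at 2-decimal rounding, number of studies) equal the
#' entry's values exactly. Ties break to the lexicographically smallest study
#' label. A body of evidence counts as aligned only if every reference
#' matched.
#'
#' @param boe List or one-row data frame with `effect_type`,
#'   `relative_effect` and `n_studies` of the summary-of-findings entry.
#' @param refs Character vector of study references (non-empty).
#' @param studies List of primary studies (each with `study_label`) or a
#'   character vector of labels.
#' @param constraints List with the reference-side `effect_type`,
#'   `effect_size`, `n_studies` recorded with the meta-analysis data.
#' @param max_distance Maximum edit distance for a fuzzy match (default 3:
#'   tolerates suffix letters such as "2004a" without crossing authors).
#' @return A tibble with one row per reference: `ref`, `study_label` (`NA` if
#'   unmatched), `method` (`"exact"` / `"edit"` / `NA`), `distance`.
#' @export
align_primary_studies <- function(boe, refs, studies, constraints,
                                  max_distance = 3L) {
  if (!length(refs)) stop("refs must be non-empty", call. = FALSE)
  labels <- if (is.character(studies)) studies else
    vapply(studies, `[[`, character(1), "study_label")
  constraints_ok <-
    identical(as.character(constraints$effect_type),
              as.character(boe$effect_type)) &&
    isTRUE(round(as.numeric(constraints$effect_size), 2) ==
             round(as.numeric(boe$relative_effect), 2)) &&
    isTRUE(as.integer(constraints$n_studies) == as.integer(boe$n_studies))
  out <- lapply(refs, function(r) {
    if (r %in% labels) {
      return(tibble::tibble(ref = r, study_label = r, method = "exact",
                            distance = 0L))
    }
    if (constraints_ok && length(labels)) {
      d <- as.integer(utils::adist(r, labels))
      dmin <- min(d)
      if (dmin <= max_distance) {
        best <- sort(labels[d == dmin])[1]
        return(tibble::tibble(ref = r, study_label = best, method = "edit",
                              distance = dmin))
      }
    }
    tibble::tibble(ref = r, study_label = NA_character_,
                   method = NA_character_, distance = NA_integer_)
  })
  dplyr::bind_rows(out)
}

#' Align every body of evidence in a corpus
#'
#' Applies [align_primary_studies()] to each outcome that carries
#' meta-analysis study references, and reports the retained fraction (bodies
#' of evidence whose references all matched). Unaligned bodies of evidence
#' are reported, never an error.
#'
#' @param corpus A `qoe_corpus`.
#' @param max_distance Maximum edit distance for fuzzy matches.
#' @return A tibble (`review_id`, `sof_index`, `outcome_index`, `ref`,
#'   `study_label`, `method`, `distance`, `aligned`), with the per-corpus
#'   retained fraction attached as attribute `"retained_fraction"`.
#' @export
align_corpus <- function(corpus, max_distance = 3L) {
  out <- list()
  for (rec in corpus) {
    labels <- vapply(rec$primary_studies, `[[`, character(1), "study_label")
    for (key in names(rec$meta_analysis_refs)) {
      meta <- rec$meta_analysis_refs[[key]]
      idx <- as.integer(strsplit(sub("^s", "", key), "_o")[[1]])
      entry <- rec$sofs[[idx[1]]]$entries[[idx[2]]]
      al <- align_primary_studies(
        boe = entry, refs = unlist(meta$refs), studies = labels,
        constraints = meta, max_distance = max_distance)
      al$review_id <- rec$review_id
      al$sof_index <- idx[1]
      al$outcome_index <- idx[2]
      al$aligned <- !anyNA(al$study_label)
      out[[length(out) + 1L]] <- al
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) stop("corpus carries no meta-analysis references",
                       call. = FALSE)
  res <- dplyr::select(res, "review_id", "sof_index", "outcome_index",
                       "ref", "study_label", "method", "distance", "aligned")
  boe <- dplyr::distinct(res, .data$review_id, .data$sof_index,
                         .data$outcome_index, .data$aligned)
  attr(res, "retained_fraction") <- mean(boe$aligned)
  res
}

#' Support features derived from matched primary studies
#'
#' For each risk-of-bias component: the counts of low / high / unclear
#' judgements, the proportion of high judgements
#' (`high / (low + high + unclear)`), and the modal judgement; plus the
#' concatenated methods text of the matched studies.
#'
#' @param matched Non-empty list of primary-study records.
#' @return A one-row tibble with the `ps_*` columns of
#'   `table1_fields(include_ps = TRUE)`.
#' @export
derive_study_features <- function(matched) {
  if (!length(matched)) stop("matched studies must be non-empty", call. = FALSE)
  out <- list(ps_methods = paste(
    vapply(matched, `[[`, character(1), "methods_text"), collapse = " "))
  for (comp in ROB_COMPONENTS) {
    j <- vapply(matched, function(st) st$rob_components[[comp]]$judgement,
                character(1))
    n <- vapply(ROB_JUDGEMENTS, function(v) sum(j == v), integer(1))
    out[[paste0("ps_n_low_", comp)]] <- as.numeric(n[["low"]])
    out[[paste0("ps_n_high_", comp)]] <- as.numeric(n[["high"]])
    out[[paste0("ps_n_unclear_", comp)]] <- as.numeric(n[["unclear"]])
    out[[paste0("ps_prop_high_", comp)]] <- n[["high"]] / sum(n)
    # modal judgement; ties resolve to the canonical judgement order
    out[[paste0("ps_judgement_", comp)]] <-
      ROB_JUDGEMENTS[which.max(n[ROB_JUDGEMENTS])]
  }
  tibble::as_tibble(out)
}

#' Attach primary-study features to aligned instances
#'
#' Joins the `ps_*` support features ([derive_study_features()]) onto the
#' instance tibble for every body of evidence whose references all aligned;
#' unaligned instances keep `NA` in those columns.
#'
#' @param instances Instance tibble.
#' @param corpus The corpus the instances came from.
#' @param alignment Output of [align_corpus()]; computed if missing.
#' @param max_distance Passed to [align_corpus()] when `alignment` is `NULL`.
#' @return `instances` with the `ps_*` columns added.
#' @export
attach_study_features <- function(instances, corpus, alignment = NULL,
                                  max_distance = 3L) {
  if (is.null(alignment)) alignment <- align_corpus(corpus, max_distance)
  by_review <- stats::setNames(corpus, vapply(corpus, `[[`, character(1),
                                              "review_id"))
  keys <- dplyr::filter(alignment, .data$aligned) |>
    dplyr::group_by(.data$review_id, .data$sof_index, .data$outcome_index) |>
    dplyr::summarise(labels = list(unique(.data$study_label)),
                     .groups = "drop")
  feats <- purrr::pmap(keys, function(review_id, sof_index, outcome_index,
                                      labels) {
    rec <- by_review[[review_id]]
    all_labels <- vapply(rec$primary_studies, `[[`, character(1),
                         "study_label")
    matched <- rec$primary_studies[match(labels, all_labels)]
    dplyr::bind_cols(tibble::tibble(review_id = review_id,
                                    sof_index = sof_index,
                                    outcome_index = outcome_index),
                     derive_study_features(matched))
  })
  feats <- dplyr::bind_rows(feats)
  ps_cols <- setdiff(field_names(include_ps = TRUE), field_names())
  for (col in intersect(ps_cols, names(instances))) {
    instances[[col]] <- NULL
  }
  if (!nrow(feats)) {
    for (col in ps_cols) instances[[col]] <- NA
    return(instances)
  }
  dplyr::left_join(instances, feats,
                   by = c("review_id", "sof_index", "outcome_index"))
}
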