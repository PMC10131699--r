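# Distant-supervision dataset construction: candidate instances from SoF
# entries, footnote-label extraction, arithmetic consistency filtering,
# partially-labeled supplementation.

candidate_row <- function(rec, s, o, entry, n_sofs, lexicon) {
  steps <- footnotes_to_vector(entry$footnotes, lexicon)
  has_grade <- !is.null(entry$grade) && !is.na(entry$grade)
  grade <- if (has_grade) grade_value(entry$grade) else NA_integer_
  status <- if (!has_grade) "no_grade" else
    is_consistent(grade, sum(steps))
  counts <- rec$study_counts %||% list()
  tibble::tibble(
    review_id = rec$review_id,
    sof_index = s,
    outcome_index = o,
    review_type = rec$review_type %||% NA_character_,
    medical_area = paste(unlist(rec$medical_areas), collapse = ";"),
    type_of_effect = entry$effect_type %||% NA_character_,
    year = as.numeric(rec$year %||% NA),
    n_sofs = as.numeric(n_sofs),
    n_participants = as.numeric(entry$n_participants %||% NA),
    upper_ci = as.numeric(entry$ci_upper %||% NA),
    lower_ci = as.numeric(entry$ci_lower %||% NA),
    n_outcomes = as.numeric(length(rec$sofs[[s]]$entries)),
    relative_effect = as.numeric(entry$relative_effect %||% NA),
    n_studies = as.numeric(entry$n_studies %||% NA),
    n_included_studies = as.numeric(counts$included %||% NA),
    n_ongoing_studies = as.numeric(counts$ongoing %||% NA),
    n_other_studies = as.numeric(counts$other %||% NA),
    n_additional_studies = as.numeric(counts$additional %||% NA),
    n_excluded_studies = as.numeric(counts$excluded %||% NA),
    outcome = entry$outcome_text %||% NA_character_,
    abstract_conclusion = rec$body_text$abstract_conclusion %||% NA_character_,
    plain_language_summary = rec$body_text$plain_language_summary %||% NA_character_,
    full_abstract = rec$body_text$full_abstract %||% NA_character_,
    authors_conclusions = rec$body_text$authors_conclusions %||% NA_character_,
    grade = grade,
    !!!as.list(steps),
    status = status,
    partially_labeled = FALSE,
    fold = NA_integer_
  )
}

#' Extract candidate instances from a corpus
#'
#' One candidate per summary-of-findings entry. The downgrade vector is read
#' from the entry's footnotes via [map_footnote()]; the instance is kept when
#' the step total explains the grade ([is_consistent()] returns `consistent`
#' or `skipped`). Filtered-out instances with at least one detected reason
#' are flagged `partially_labeled`: their positive labels are trusted even
#' though the full vector is incomplete, and they populate the supplement
#' pool. Entries without a grade are skipped with a warning and counted in
#' the build report.
#'
#' @param corpus A `qoe_corpus`.
#' @param lexicon A `qoe_lexicon`; [default_lexicon()] by default.
#' @return A tibble of all candidates with feature columns, `grade`, the five
#'   criterion step columns, `status` (`consistent` / `inconsistent` /
#'   `skipped` / `no_grade`), `kept` and `partially_labeled`. A build report
#'   (stage counts) is attached as attribute `"report"`.
#' @export
extract_instances <- function(corpus, lexicon = default_lexicon()) {
  stopifnot(inherits(lexicon, "qoe_lexicon"))
  rows <- list()
  for (rec in corpus) {
    n_sofs <- length(rec$sofs)
    for (s in seq_len(n_sofs)) {
      entries <- rec$sofs[[s]]$entries
      for (o in seq_along(entries)) {
        rows[[length(rows) + 1L]] <-
          candidate_row(rec, s, o, entries[[o]], n_sofs, lexicon)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) stop("corpus contains no summary-of-findings entries",
                       call. = FALSE)
  n_no_grade <- sum(out$status == "no_grade")
  if (n_no_grade > 0L) {
    warning(n_no_grade, " entr", if (n_no_grade == 1L) "y" else "ies",
            " without a grade skipped", call. = FALSE)
  }
  out$kept <- out$status %in% c("consistent", "skipped")
  out$partially_labeled <- out$status == "inconsistent" &
    steps_total(out) > 0L
  report <- list(
    candidates = nrow(out),
    no_grade = n_no_grade,
    kept = sum(out$kept),
    filtered_out = sum(out$status == "inconsistent"),
    supplement_pool = sum(out$partially_labeled)
  )
  attr(out, "report") <- report
  out
}

#' Build the labeled dataset from a corpus
#'
#' Runs [extract_instances()], splits kept instances (the dataset D) from the
#' partially labeled supplement pool (D'), and assigns grouped
#' cross-validation folds over reviews ([grouped_kfold()]).
#'
#' @param corpus A `qoe_corpus`.
#' @param lexicon A `qoe_lexicon`.
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @return A `qoe_dataset`: list with `instances` (kept, with `fold`),
#'   `supplement` (partially labeled pool; never overlaps `instances`) and
#'   `report`.
#' @export
build_dataset <- function(corpus, lexicon = default_lexicon(), k = 10L,
                          seed = 1L) {
  cand <- extract_instances(corpus, lexicon)
  instances <- dplyr::filter(cand, .data$kept)
  supplement <- dplyr::filter(cand, .data$partially_labeled)
  folds <- grouped_kfold(instances, k = k, seed = seed)
  instances <- dplyr::left_join(dplyr::select(instances, -"fold"), folds,
                                by = "review_id")
  instances <- dplyr::select(instances, -"kept")
  supplement <- dplyr::select(supplement, -"kept")
  structure(list(instances = instances, supplement = supplement,
                 report = attr(cand, "report")),
            class = "qoe_dataset")
}

#' @export
print.qoe_dataset <- function(x, ...) {
  cat("<qoe_dataset> ", nrow(x$instances), " instances, ",
      nrow(x$supplement), " partially labeled supplements\n", sep = "")
  invisible(x)
}

#' Supplement training data with partially labeled positives
#'
#' Adds to the training rows those pool instances that are positive for the
#' criterion being trained. Only training folds are ever supplemented; dev
#' and test sets never pass through this function, so their label
#' distributions are untouched by construction.
#'
#' @param train Training-instance tibble.
#' @param pool Partially labeled pool (from [build_dataset()]); every pool
#'   instance must carry at least one positive criterion.
#' @param criterion The criterion being trained, one of [criteria()].
#' @return `train` plus the matching pool rows.
#' @export
supplement_training <- function(train, pool, criterion) {
  stopifnot(criterion %in% criteria())
  if (!nrow(pool)) return(train)
  if (any(steps_total(pool) == 0L)) {
    stop("supplement pool contains an instance with no positive label",
         call. = FALSE)
  }
  extra <- pool[pool[[criterion]] > 0L, , drop = FALSE]
  dplyr::bind_rows(train, extra)
}
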