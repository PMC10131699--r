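# GRADE step arithmetic: grades, downgrading criteria, consistency checking.

GRADE_LABELS <- c("very_low", "low", "moderate", "high")

#' The five GRADE downgrading criteria
#'
#' Canonical names and order of the criteria that can lower certainty in a
#' body of evidence: risk of bias, imprecision, inconsistency, indirectness
#' and publication bias. All per-criterion columns produced by this package
#' (step counts, labels, predictions) use these names in this order.
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' criteria()
criteria <- function() {
  c("risk_of_bias", "imprecision", "inconsistency", "indirectness",
    "publication_bias")
}

#' GRADE certainty levels
#'
#' Levels are coded 0--3: 0 = very low, 1 = low, 2 = moderate, 3 = high.
#' `grade_label()` and `grade_value()` convert between the integer code and
#' the label; both are vectorised.
#'
#' @param value Integer vector in 0:3.
#' @param label Character vector of labels (`"very_low"`, `"low"`,
#'   `"moderate"`, `"high"`).
#' @return `grade_levels()` returns the four labels in increasing order of
#'   certainty; `grade_label()` a character vector; `grade_value()` an
#'   integer vector.
#' @export
#' @examples
#' grade_label(0:3)
#' grade_value("moderate")
grade_levels <- function() GRADE_LABELS

#' @rdname grade_levels
#' @export
grade_label <- function(value) {
  stopifnot(all(is.na(value) | value %in% 0:3))
  GRADE_LABELS[as.integer(value) + 1L]
}

#' @rdname grade_levels
#' @export
grade_value <- function(label) {
  out <- match(label, GRADE_LABELS) - 1L
  if (any(is.na(out) & !is.na(label))) {
    bad <- unique(label[is.na(out) & !is.na(label)])
    stop("unknown grade label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Build a downgrade vector
#'
#' A downgrade vector records, for each of the five criteria, by how many
#' steps (0, 1 or 2) certainty was lowered for that reason. A single
#' criterion can lower the grade by at most 2 steps; the overall grade drops
#' by at most 3.
#'
#' @param ... Named integer step counts, names among [criteria()]. Unnamed
#'   criteria default to 0.
#' @return Named integer vector over all five criteria.
#' @export
#' @examples
#' downgrade_vector(imprecision = 2, risk_of_bias = 1)
downgrade_vector <- function(...) {
  args <- c(...)
  v <- stats::setNames(integer(5L), criteria())
  if (length(args)) {
    if (is.null(names(args)) || any(!nzchar(names(args)))) {
      stop("all step counts must be named", call. = FALSE)
    }
    bad <- setdiff(names(args), criteria())
    if (length(bad)) {
      stop("unknown criterion: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(!args %in% 0:2)) {
      stop("per-criterion steps must be 0, 1 or 2", call. = FALSE)
    }
    v[names(args)] <- as.integer(args)
  }
  v
}

#' Total downgrading steps
#'
#' Sums the per-criterion steps. Accepts a named downgrade vector or a data
#' frame with the five criterion columns (one row per instance).
#'
#' @param v Named integer vector from [downgrade_vector()], or a data frame
#'   containing the five criterion columns.
#' @return Integer vector of totals.
#' @export
#' @examples
#' steps_total(downgrade_vector(imprecision = 2, risk_of_bias = 1))
steps_total <- function(v) {
  if (is.data.frame(v)) {
    miss <- setdiff(criteria(), names(v))
    if (length(miss)) {
      stop("missing criterion column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    return(as.integer(rowSums(as.matrix(v[criteria()]))))
  }
  as.integer(sum(v))
}

#' Map downgrading steps to a GRADE level
#'
#' Evidence from randomised trials starts at high certainty (3) and loses one
#' level per downgrading step, to a floor of very low (0):
#' `grade = 3 - min(total steps, 3)`.
#'
#' @param v Downgrade vector, data frame of step columns, or an integer
#'   vector of step totals.
#' @return Integer grade value(s) in 0:3.
#' @export
#' @examples
#' grade_label(steps_to_grade(downgrade_vector(imprecision = 2, risk_of_bias = 1)))
steps_to_grade <- function(v) {
  total <- if (is.data.frame(v) || (length(v) == 5L && !is.null(names(v)) &&
                                    setequal(names(v), criteria()))) {
    steps_total(v)
  } else {
    as.integer(v)
  }
  3L - pmin(total, 3L)
}

#' Arithmetic consistency between a grade and its downgrade vector
#'
#' The distant-supervision filter: the total number of extracted downgrading
#' steps must explain the assigned grade. High-grade evidence is skipped (no
#' reason is expected to exist there); otherwise the instance is consistent
#' iff `min(total, 3) == 3 - grade`. Totals above 3 are accepted for very-low
#' grades because the overall grade is capped at a 3-level drop.
#'
#' @param grade Integer grade value(s) in 0:3 (see [grade_levels()]).
#' @param total Integer step total(s), e.g. from [steps_total()].
#' @return Character vector: `"consistent"`, `"inconsistent"` or `"skipped"`.
#' @export
#' @examples
#' is_consistent(grade_value("low"), 2)      # consistent
#' is_consistent(grade_value("moderate"), 2) # inconsistent
#' is_consistent(grade_value("high"), 1)     # skipped
is_consistent <- function(grade, total) {
  stopifnot(all(grade %in% 0:3), all(total >= 0))
  n <- max(length(grade), length(total))
  grade <- rep_len(as.integer(grade), n)
  total <- rep_len(as.integer(total), n)
  out <- ifelse(grade == 3L, "skipped",
                ifelse(pmin(total, 3L) == 3L - grade, "consistent",
                       "inconsistent"))
  out
}

#' Collapse the four GRADE levels to two tiers
#'
#' High and moderate certainty merge into the positive tier (evidence a
#' guideline panel could act on with a strong recommendation), low and very
#' low into the negative tier.
#'
#' @param grade Integer grade value(s) in 0:3.
#' @return Character vector `"positive"` / `"negative"`.
#' @export
#' @examples
#' binarize_grade(grade_value(c("high", "moderate", "low", "very_low")))
binarize_grade <- function(grade) {
  stopifnot(all(grade %in% 0:3))
  ifelse(grade >= 2L, "positive", "negative")
}

#' Convert a regression score to a GRADE level
#'
#' The regression head scores quality on the continuous 0--3 scale; scores
#' are rounded half away from zero to the nearest integer and clipped to
#' \[0, 3\].
#'
#' @param s Finite numeric vector.
#' @return Integer grade value(s) in 0:3.
#' @export
#' @examples
#' scalar_to_grade(c(2.6, 1.4, -0.4, 3.7))
scalar_to_grade <- function(s) {
  if (any(!is.finite(s))) stop("scores must be finite", call. = FALSE)
  r <- sign(s) * floor(abs(s) + 0.5)
  as.integer(pmax(0, pmin(3, r)))
}
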