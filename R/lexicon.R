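# Downgrading-term lexicon and footnote-to-criterion mapping.

#' Read a downgrading-term lexicon
#'
#' The lexicon maps normalised terms/phrases found in summary-of-findings
#' footnotes to the downgrading criterion they trigger (e.g. "heterogeneity"
#' triggers inconsistency), plus step-multiplier phrases ("two levels") that
#' mark a 2-step downgrade. The YAML layout is:
#'
#' ```yaml
#' schema_version: "1.0"
#' terms:
#'   heterogeneity: inconsistency
#'   imprecision: imprecision
#' multipliers:
#'   two levels: 2
#' ```
#'
#' Lookup is case-insensitive and whitespace-normalised; no term may map to
#' two criteria.
#'
#' @param path Path to a lexicon YAML file.
#' @return A `qoe_lexicon` object.
#' @seealso [default_lexicon()], [map_footnote()]
#' @export
read_lexicon <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$terms) || !length(raw$terms)) {
    stop("lexicon has no terms: ", path, call. = FALSE)
  }
  terms <- vapply(raw$terms, as.character, character(1))
  names(terms) <- normalize_text(names(raw$terms))
  mult <- integer(0)
  if (!is.null(raw$multipliers)) {
    mult <- vapply(raw$multipliers, as.integer, integer(1))
    names(mult) <- normalize_text(names(raw$multipliers))
  }
  new_lexicon(terms, mult)
}

new_lexicon <- function(terms, multipliers = integer(0)) {
  bad <- setdiff(unname(terms), criteria())
  if (length(bad)) {
    stop("lexicon maps to unknown criteria: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(names(terms))) {
    dup <- names(terms)[duplicated(names(terms))]
    stop("term maps to two criteria: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  structure(list(terms = terms, multipliers = multipliers),
            class = "qoe_lexicon")
}

#' @export
print.qoe_lexicon <- function(x, ...) {
  cat("<qoe_lexicon> ", length(x$terms), " terms, ",
      length(x$multipliers), " multiplier phrases\n", sep = "")
  invisible(x)
}

#' Built-in downgrading-term lexicon
#'
#' Reads the lexicon shipped with the package (`inst/extdata/lexicon.yaml`),
#' covering common footnote vocabulary for the five criteria and the 2-step
#' multiplier phrases. The synthetic corpus generator renders footnotes from
#' this same lexicon.
#'
#' @return A `qoe_lexicon` object.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon.yaml",
                           package = "evidencegrader", mustWork = TRUE))
}

#' Synonyms of a criterion in a lexicon
#'
#' @param lexicon A `qoe_lexicon`.
#' @param criterion One of [criteria()].
#' @return Character vector of terms mapping to `criterion`.
#' @export
lexicon_terms <- function(lexicon, criterion) {
  stopifnot(inherits(lexicon, "qoe_lexicon"), criterion %in% criteria())
  names(lexicon$terms)[lexicon$terms == criterion]
}

normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Non-overlapping, longest-match-first occurrences of `phrases` in `text`.
# Returns a data frame with phrase, start, end (character positions).
match_phrases <- function(text, phrases) {
  taken <- logical(nchar(text))
  out <- list()
  for (ph in phrases[order(-nchar(phrases))]) {
    m <- gregexpr(ph, text, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- nchar(ph)
    for (s in as.integer(m)) {
      span <- s:(s + len - 1L)
      if (any(taken[span])) next
      taken[span] <- TRUE
      out[[length(out) + 1L]] <- list(phrase = ph, start = s, end = s + len - 1L)
    }
  }
  if (!length(out)) {
    return(data.frame(phrase = character(0), start = integer(0),
                      end = integer(0)))
  }
  df <- do.call(rbind, lapply(out, as.data.frame))
  df[order(df$start), , drop = FALSE]
}

map_footnote_one <- function(text, lexicon, window = 15L) {
  v <- stats::setNames(integer(5L), criteria())
  text <- normalize_text(text)
  if (!nzchar(text)) return(v)
  hits <- match_phrases(text, names(lexicon$terms))
  if (!nrow(hits)) return(v)
  occ_steps <- rep(1L, nrow(hits))
  if (length(lexicon$multipliers)) {
    mhits <- match_phrases(text, names(lexicon$multipliers))
    for (i in seq_len(nrow(mhits))) {
      # A multiplier applies to the nearest term occurrence within `window`
      # characters; a following term is preferred ("two levels for
      # imprecision") by penalising backward gaps.
      gap_fwd <- hits$start - mhits$end[i] - 1L  # term after the multiplier
      gap_bwd <- mhits$start[i] - hits$end - 1L  # term before the multiplier
      gap <- pmin(ifelse(gap_fwd >= 0L & gap_fwd <= window, gap_fwd, NA),
                  ifelse(gap_bwd >= 0L & gap_bwd <= window,
                         gap_bwd + window, NA),
                  na.rm = TRUE)
      if (all(is.na(gap))) next
      j <- which.min(gap)
      occ_steps[j] <- max(occ_steps[j],
                          unname(lexicon$multipliers[mhits$phrase[i]]))
    }
  }
  for (i in seq_len(nrow(hits))) {
    crit <- unname(lexicon$terms[hits$phrase[i]])
    v[crit] <- min(2L, v[crit] + occ_steps[i])
  }
  v
}

#' Extract a downgrade vector from footnote text
#'
#' Scans footnote text for lexicon terms (longest-match, non-overlapping) and
#' increments the matched criterion once per occurrence. A step-multiplier
#' phrase ("two levels", "2 levels") adjacent to a matched term raises that
#' occurrence to 2 steps. Per-criterion steps are capped at 2. Text with no
#' recognised term yields an all-zero vector.
#'
#' @param text Character vector of footnote strings (each may contain several
#'   reasons). `NA` is treated as empty.
#' @param lexicon A `qoe_lexicon`, e.g. [default_lexicon()].
#' @return A tibble with one row per element of `text` and one integer column
#'   per criterion.
#' @export
#' @examples
#' map_footnote("downgraded two levels for imprecision and one for risk of bias",
#'               default_lexicon())
map_footnote <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "qoe_lexicon"))
  text[is.na(text)] <- ""
  rows <- lapply(text, map_footnote_one, lexicon = lexicon)
  out <- tibble::as_tibble(do.call(rbind, c(rows, list(deparse.level = 0))))
  names(out) <- criteria()
  out
}

# Combine the footnotes attached to one grade cell into a single downgrade
# vector (per-criterion cap of 2 applied across footnotes).
footnotes_to_vector <- function(footnotes, lexicon) {
  if (!length(footnotes)) return(stats::setNames(integer(5L), criteria()))
  per <- map_footnote(unlist(footnotes, use.names = FALSE), lexicon)
  stats::setNames(pmin(2L, as.integer(colSums(as.matrix(per)))), criteria())
}
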