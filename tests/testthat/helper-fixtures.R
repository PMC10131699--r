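# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# ~230 outcomes: fast unit-test corpus
small_corpus <- function() {
  cached("small_corpus", generate_corpus(gen_config(n_reviews = 60, seed = 101)))
}

small_dataset <- function() {
  cached("small_dataset", build_dataset(small_corpus(), k = 5, seed = 7))
}

# ~2,000 outcomes, no corruption: extraction/alignment acceptance conditions
clean_corpus_2k <- function() {
  cached("clean_corpus_2k",
         generate_corpus(gen_config(n_reviews = 500, corrupt_fraction = 0,
                                    seed = 202)))
}

# hand-built review record with fully controlled entries
manual_review <- function(review_id = "CD000001", entries, year = 2015) {
  list(
    schema_version = "1.0",
    review_id = review_id,
    review_type = "intervention",
    medical_areas = list("cardiology"),
    year = year,
    body_text = list(abstract_conclusion = "text a",
                     plain_language_summary = "text b",
                     full_abstract = "text c",
                     authors_conclusions = "text d"),
    study_counts = list(included = 4, ongoing = 0, other = 0,
                        additional = 0, excluded = 2),
    sofs = list(list(entries = entries)),
    primary_studies = list(),
    meta_analysis_refs = list()
  )
}

manual_entry <- function(grade, footnotes = character(0),
                         outcome = "mortality", n_participants = 100,
                         n_studies = 3, relative_effect = 0.8,
                         ci = c(0.6, 1.1), effect_type = "RR") {
  list(outcome_text = outcome, n_participants = n_participants,
       n_studies = n_studies, relative_effect = relative_effect,
       ci_lower = ci[1], ci_upper = ci[2], effect_type = effect_type,
       grade = grade, footnotes = as.list(footnotes))
}

as_corpus <- function(reviews) structure(reviews, class = "qoe_corpus")

# independent dynamic-programming Levenshtein distance (test oracle)
lev_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(a) + 1L, length(b) + 1L)
  d[, 1] <- 0:length(a); d[1, ] <- 0:length(b)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (a[i] != b[j]))
    }
  }
  d[length(a) + 1L, length(b) + 1L]
}

table3_grade_counts <- c(very_low = 2737, low = 4562, moderate = 4232,
                         high = 1909)
table3_criterion_counts <- c(risk_of_bias = 7969, imprecision = 7377,
                             inconsistency = 2208, indirectness = 1388,
                             publication_bias = 667)
table3_n <- 13440
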