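# Synthetic review-corpus generator with planted, configurable signal.

MEDICAL_AREAS <- c("cardiology", "oncology", "mental_health", "dentistry",
                   "neurology", "respiratory", "infectious_disease",
                   "endocrinology", "gynaecology", "paediatrics",
                   "orthopaedics", "anaesthesia")

EFFECT_TYPES <- c("RR", "OR", "HR", "MD", "SMD")

SIGNAL_TOKENS <- list(
  risk_of_bias     = c("unblinded", "unconcealed", "dropouts"),
  imprecision      = c("imprecise", "sparse", "fewevents"),
  inconsistency    = c("heterogeneity", "inconsistent", "varied"),
  indirectness     = c("indirect", "surrogate", "narrowpopulation"),
  publication_bias = c("asymmetry", "unpublished", "industry")
)

FILLER_VOCAB <- c(
  "patients", "intervention", "control", "outcome", "effect", "treatment",
  "evidence", "studies", "trials", "review", "compared", "placebo", "risk",
  "benefit", "harm", "followup", "randomised", "assessed", "reported",
  "analysis", "results", "pooled", "estimate", "reduction", "increase",
  "moderate", "clinical", "care", "therapy", "dose", "duration", "adults",
  "children", "hospital", "community", "primary", "secondary", "events",
  "mortality", "morbidity"
)

OUTCOME_PHRASES <- c(
  "all cause mortality", "serious adverse events", "pain relief",
  "quality of life", "hospital admission", "symptom improvement",
  "treatment failure", "functional recovery", "relapse rate",
  "wound healing", "blood pressure reduction", "depression score")

SURNAMES <- c(
  "Smith", "Jones", "Brown", "Wilson", "Taylor", "Lee", "Chen", "Wang",
  "Kumar", "Patel", "Garcia", "Martin", "Rossi", "Muller", "Silva",
  "Kim", "Park", "Tanaka", "Sato", "Novak", "Kowalski", "Ivanov",
  "Andersson", "Nielsen", "Dubois", "Moreau", "Costa", "Santos",
  "Okafor", "Mensah", "Haddad", "Rahman", "Nguyen", "Tran", "Ali",
  "Hassan", "Lopez", "Hernandez", "Schmidt", "Fischer")

#' Configuration for the synthetic corpus generator
#'
#' Defaults reproduce the study conditions the pipeline assumes: the grade
#' distribution and per-criterion annotation marginals of the 13,440-instance
#' quality-of-evidence dataset (high 14.2%, moderate 31.5%, low 33.9%, very
#' low 20.4%; risk of bias 59.3%, imprecision 54.9%, inconsistency 16.4%,
#' indirectness 10.3%, publication bias 5.0%), a mean of 2 summary-of-findings
#' tables per review, and a mean of 20 primary studies per review.
#'
#' Per-criterion step allocation weights are calibrated at construction time
#' (exact enumeration + fixed point) so that the marginal probability that a
#' criterion is positive matches `criterion_marginals` while the grade
#' marginal matches `grade_distribution`; infeasible combinations error.
#'
#' @param n_reviews Number of reviews to generate.
#' @param sofs_per_review_mean Mean summary-of-findings tables per review
#'   (1 + Poisson).
#' @param outcomes_per_sof Integer range (min, max) of outcomes per table.
#' @param grade_distribution Probabilities for very low / low / moderate /
#'   high (named, sums to 1).
#' @param criterion_marginals Named probabilities that each criterion is
#'   positive for an outcome.
#' @param corrupt_fraction Probability that a non-high outcome's footnote
#'   omits one detected reason, creating an arithmetically inconsistent
#'   instance.
#' @param signal_strength Named log-odds coefficients of the planted
#'   generative model, one per criterion; 0 removes all signal for that
#'   criterion.
#' @param studies_per_review_mean,studies_per_review_size Negative-binomial
#'   parameters for the number of primary studies per review.
#' @param perturb_refs List with `prob` (probability a meta-analysis study
#'   reference is perturbed) and `max_edits` (maximum character edits).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `qoe_gen_config` object.
#' @seealso [generate_corpus()]
#' @export
gen_config <- function(n_reviews = 100L,
                       sofs_per_review_mean = 2,
                       outcomes_per_sof = c(1L, 3L),
                       grade_distribution = c(very_low = 2737, low = 4562,
                                              moderate = 4232, high = 1909) / 13440,
                       criterion_marginals = c(risk_of_bias = 7969,
                                               imprecision = 7377,
                                               inconsistency = 2208,
                                               indirectness = 1388,
                                               publication_bias = 667) / 13440,
                       corrupt_fraction = 0.1,
                       signal_strength = c(risk_of_bias = 2.5,
                                           imprecision = 2.5,
                                           inconsistency = 2.5,
                                           indirectness = 2.5,
                                           publication_bias = 2.5),
                       studies_per_review_mean = 20,
                       studies_per_review_size = 1.2,
                       perturb_refs = list(prob = 0.3, max_edits = 2L),
                       seed = 1L) {
  stopifnot(n_reviews >= 1, sofs_per_review_mean >= 1,
            length(outcomes_per_sof) == 2L,
            outcomes_per_sof[1] >= 1, outcomes_per_sof[2] >= outcomes_per_sof[1])
  gd <- grade_distribution[GRADE_LABELS]
  if (any(is.na(gd)) || any(gd < 0) || abs(sum(gd) - 1) > 1e-9) {
    stop("grade_distribution must be named over the four levels and sum to 1",
         call. = FALSE)
  }
  cm <- criterion_marginals[criteria()]
  if (any(is.na(cm)) || any(cm < 0 | cm > 1)) {
    stop("criterion_marginals must be named probabilities over the five criteria",
         call. = FALSE)
  }
  ss <- signal_strength[criteria()]
  if (any(is.na(ss))) stop("signal_strength must cover all five criteria",
                           call. = FALSE)
  stopifnot(corrupt_fraction >= 0, corrupt_fraction <= 1,
            perturb_refs$prob >= 0, perturb_refs$prob <= 1,
            perturb_refs$max_edits >= 1)
  cal <- calibrate_step_weights(gd, cm)
  structure(list(
    n_reviews = as.integer(n_reviews),
    sofs_per_review_mean = sofs_per_review_mean,
    outcomes_per_sof = as.integer(outcomes_per_sof),
    grade_distribution = gd,
    criterion_marginals = cm,
    step_weights = cal$weights,
    double_prob = cal$double_prob,
    corrupt_fraction = corrupt_fraction,
    signal_strength = ss,
    studies_per_review_mean = studies_per_review_mean,
    studies_per_review_size = studies_per_review_size,
    perturb_refs = perturb_refs,
    seed = as.integer(seed)
  ), class = "qoe_gen_config")
}

#' @export
print.qoe_gen_config <- function(x, ...) {
  cat("<qoe_gen_config> ", x$n_reviews, " reviews, seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

# Step vectors are allocated per outcome from the total T = 3 - grade:
# with probability `double_prob` (for T >= 2) one criterion takes a 2-step
# downgrade, the remaining steps go to distinct criteria drawn without
# replacement proportionally to weights `w`. `double_prob` is set so the
# expected number of repeated steps exactly absorbs the gap between the
# expected total steps (from the grade distribution) and the sum of the
# criterion marginals; `w` is then calibrated by exact enumeration + fixed
# point so each criterion's positive marginal matches its target.

# P(criterion c is in a without-replacement sample of k distinct criteria
# drawn sequentially with weights w), by enumeration (k <= 3, 5 criteria).
p_in_distinct <- function(w, k) {
  pos <- numeric(5L)
  rec <- function(chosen, p, left) {
    if (left == 0L) {
      pos[chosen] <<- pos[chosen] + p
      return(invisible(NULL))
    }
    avail <- setdiff(seq_len(5L), chosen)
    wz <- w[avail] / sum(w[avail])
    for (j in seq_along(avail)) {
      rec(c(chosen, avail[j]), p * wz[j], left - 1L)
    }
  }
  rec(integer(0), 1, k)
  pos
}

induced_positive_given_t <- function(w, t, double_prob) {
  if (t == 0L) return(numeric(5L))
  if (t == 1L) return(w)
  if (t == 2L) {
    return(double_prob * w + (1 - double_prob) * p_in_distinct(w, 2L))
  }
  # t == 3: one double (chosen ~ w) plus one distinct other, or 3 distinct
  p_double <- w + vapply(seq_len(5L), function(ci) {
    sum(w[-ci] * w[ci] / (1 - w[-ci]))
  }, numeric(1))
  double_prob * p_double + (1 - double_prob) * p_in_distinct(w, 3L)
}

induced_marginals <- function(w, grade_distribution, double_prob) {
  t_probs <- rev(unname(grade_distribution))  # index t+1 = P(T = t)
  out <- numeric(5L)
  for (t in 0:3) {
    if (t_probs[t + 1] <= 0) next
    out <- out + t_probs[t + 1] * induced_positive_given_t(w, t, double_prob)
  }
  out
}

calibrate_step_weights <- function(grade_distribution, criterion_marginals,
                                   max_iter = 1000L, tol = 1e-12) {
  target <- unname(criterion_marginals)
  gd <- rev(unname(grade_distribution))       # P(T = 0..3)
  e_total <- sum((0:3) * gd)
  excess <- e_total - sum(target)             # expected repeated steps
  denom <- gd[3] + gd[4]                      # P(T = 2) + P(T = 3)
  if (excess < -1e-9) {
    stop("infeasible config: criterion marginals sum to more than the ",
         "expected total downgrading steps (", signif(e_total, 4), ")",
         call. = FALSE)
  }
  double_prob <- if (denom > 0) excess / denom else 0
  if (double_prob > 1 + 1e-9) {
    stop("infeasible config: criterion marginals are too concentrated for ",
         "the grade distribution (would need more than one 2-step ",
         "downgrade per instance)", call. = FALSE)
  }
  double_prob <- min(max(double_prob, 0), 1)
  p_pos_max <- 1 - grade_distribution[["high"]]
  if (any(target > p_pos_max + 1e-12)) {
    stop("infeasible config: a criterion marginal exceeds P(any downgrade) = ",
         signif(p_pos_max, 4), call. = FALSE)
  }
  w <- target / sum(target)
  for (i in seq_len(max_iter)) {
    cur <- induced_marginals(w, grade_distribution, double_prob)
    if (max(abs(cur - target)) < tol) break
    ratio <- ifelse(cur > 0, target / cur, 1)
    w <- w * ratio
    w <- pmax(w, 1e-12)
    w <- w / sum(w)
  }
  cur <- induced_marginals(w, grade_distribution, double_prob)
  if (max(abs(cur - target)) > 1e-6) {
    stop("infeasible config: criterion marginals not attainable under the ",
         "grade distribution (max deviation ",
         signif(max(abs(cur - target)), 3), ")", call. = FALSE)
  }
  list(weights = stats::setNames(w, criteria()), double_prob = double_prob)
}

mix_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + i * 9679) %% 2147483647)
}

sample_distinct <- function(w, k, exclude = integer(0)) {
  chosen <- integer(0)
  for (j in seq_len(k)) {
    avail <- setdiff(seq_len(5L), c(chosen, exclude))
    pick <- avail[sample.int(length(avail), 1L, prob = w[avail])]
    chosen <- c(chosen, pick)
  }
  chosen
}

sample_step_vector <- function(grade, w, double_prob) {
  steps <- stats::setNames(integer(5L), criteria())
  t <- 3L - grade
  if (t == 0L) return(steps)
  if (t >= 2L && stats::runif(1) < double_prob) {
    dbl <- sample_distinct(w, 1L)
    steps[dbl] <- 2L
    if (t == 3L) {
      steps[sample_distinct(w, 1L, exclude = dbl)] <- 1L
    }
  } else {
    steps[sample_distinct(w, t)] <- 1L
  }
  steps
}

render_footnotes <- function(steps, lexicon) {
  pos <- names(steps)[steps > 0L]
  if (!length(pos)) return(character(0))
  clauses <- vapply(pos, function(cr) {
    term <- sample(lexicon_terms(lexicon, cr), 1L)
    if (steps[[cr]] == 2L) {
      sprintf(sample(c("downgraded two levels for %s",
                       "downgraded 2 levels due to %s"), 1L), term)
    } else {
      sprintf(sample(c("downgraded one level for %s",
                       "downgraded for %s",
                       "downgraded due to %s"), 1L), term)
    }
  }, character(1))
  if (length(clauses) > 1L && stats::runif(1) < 0.5) {
    cut <- sample.int(length(clauses) - 1L, 1L)
    c(paste(clauses[seq_len(cut)], collapse = "; "),
      paste(clauses[-seq_len(cut)], collapse = "; "))
  } else {
    paste(clauses, collapse = "; ")
  }
}

signal_bag <- function(steps, ss, base = -1.6, draws = 2L) {
  out <- character(0)
  for (cr in criteria()) {
    p <- stats::plogis(base + ss[[cr]] * steps[[cr]])
    hit <- stats::runif(draws) < p
    if (any(hit)) {
      out <- c(out, sample(SIGNAL_TOKENS[[cr]], sum(hit), replace = TRUE))
    }
  }
  out
}

filler_text <- function(n_min = 8L, n_max = 15L) {
  paste(sample(FILLER_VOCAB, sample(n_min:n_max, 1L), replace = TRUE),
        collapse = " ")
}

perturb_label <- function(label, max_edits, forbidden) {
  alphabet <- c(letters, as.character(0:9))
  for (try in 1:20) {
    x <- label
    for (e in seq_len(sample.int(max_edits, 1L))) {
      chars <- strsplit(x, "", fixed = TRUE)[[1]]
      op <- sample(c("sub", "ins", "del"), 1L,
                   prob = c(0.5, 0.3, if (length(chars) > 3L) 0.2 else 0))
      pos <- sample.int(length(chars), 1L)
      chars <- switch(op,
        sub = { chars[pos] <- sample(alphabet, 1L); chars },
        ins = append(chars, sample(alphabet, 1L), after = pos),
        del = chars[-pos])
      x <- paste(chars, collapse = "")
    }
    if (x != label && !(x %in% forbidden)) return(x)
  }
  paste0(label, "x")
}

generate_primary_studies <- function(n, mean_rob_steps, ss_rob) {
  labels <- paste(sample(SURNAMES, n, replace = TRUE),
                  sample(1995:2019, n, replace = TRUE))
  dup <- duplicated(labels)
  while (any(dup)) {
    labels[dup] <- paste0(labels[dup],
                          sample(letters[1:6], sum(dup), replace = TRUE))
    dup <- duplicated(labels)
  }
  p_high <- stats::plogis(-1.4 + ss_rob * mean_rob_steps)
  lapply(seq_len(n), function(i) {
    comps <- lapply(ROB_COMPONENTS, function(comp) {
      u <- stats::runif(1)
      j <- if (u < p_high) "high"
           else if (u < p_high + (1 - p_high) * 0.65) "low" else "unclear"
      list(judgement = j,
           justification = paste(j, "concern for", gsub("_", " ", comp)))
    })
    names(comps) <- ROB_COMPONENTS
    list(study_label = labels[i],
         methods_text = filler_text(5L, 10L),
         rob_components = comps)
  })
}

generate_review <- function(cfg, i, lexicon) {
  set.seed(mix_seed(cfg$seed, i))
  ss <- cfg$signal_strength
  review_id <- sprintf("CD%06d", i)
  n_sofs <- 1L + stats::rpois(1L, cfg$sofs_per_review_mean - 1)
  n_primary <- 2L + stats::rnbinom(1L, mu = cfg$studies_per_review_mean - 2,
                                   size = cfg$studies_per_review_size)
  n_primary <- min(n_primary, 150L)

  # outcomes first: labels drive the planted signal everywhere else
  sofs <- vector("list", n_sofs)
  truth <- list()
  refs_meta <- list()
  all_steps <- list()
  for (s in seq_len(n_sofs)) {
    n_out <- sample(cfg$outcomes_per_sof[1]:cfg$outcomes_per_sof[2], 1L)
    entries <- vector("list", n_out)
    for (o in seq_len(n_out)) {
      grade <- sample(0:3, 1L, prob = unname(cfg$grade_distribution))
      steps <- sample_step_vector(grade, cfg$step_weights, cfg$double_prob)
      grade <- steps_to_grade(steps)  # arithmetic truth by construction
      all_steps[[length(all_steps) + 1L]] <- steps

      rel_imp <- ss[["imprecision"]] / 2.5
      n_studies_boe <- min(1L + stats::rpois(1L, 4L), n_primary)
      n_participants <- round(exp(stats::rnorm(
        1, 4.6 + 0.5 * log(n_studies_boe) -
          0.5 * rel_imp * steps[["imprecision"]], 0.5)))
      relative_effect <- round(exp(stats::rnorm(1, 0, 0.35)), 2)
      hw <- exp(stats::rnorm(
        1, -1.2 + 0.55 * rel_imp * steps[["imprecision"]], 0.35))
      effect_type <- sample(EFFECT_TYPES, 1L,
                            prob = c(0.4, 0.25, 0.1, 0.15, 0.1))
      outcome_text <- paste(
        c(sample(OUTCOME_PHRASES, 1L), signal_bag(steps, ss)),
        collapse = " ")

      corrupted <- FALSE
      rendered <- steps
      if (grade < 3L && sum(steps) > 0L &&
          stats::runif(1) < cfg$corrupt_fraction) {
        drop <- sample(rep(names(steps)[steps > 0L], 2L), 1L)
        rendered[drop] <- 0L
        corrupted <- TRUE
      }
      footnotes <- render_footnotes(rendered, lexicon)

      entries[[o]] <- list(
        outcome_text = outcome_text,
        n_participants = n_participants,
        n_studies = n_studies_boe,
        relative_effect = relative_effect,
        ci_lower = round(relative_effect * exp(-hw), 2),
        ci_upper = round(relative_effect * exp(hw), 2),
        effect_type = effect_type,
        grade = grade_label(grade),
        footnotes = as.list(footnotes)
      )
      truth[[length(truth) + 1L]] <- tibble::tibble(
        review_id = review_id, sof_index = s, outcome_index = o,
        grade = grade, !!!as.list(steps), corrupted = corrupted)
    }
    sofs[[s]] <- list(entries = entries)
  }

  mean_steps <- colMeans(do.call(rbind, all_steps))
  primary <- generate_primary_studies(n_primary, mean_steps[["risk_of_bias"]],
                                      ss[["risk_of_bias"]])
  labels <- vapply(primary, `[[`, character(1), "study_label")

  # meta-analysis study references per outcome, with name perturbation
  for (s in seq_len(n_sofs)) {
    for (o in seq_along(sofs[[s]]$entries)) {
      e <- sofs[[s]]$entries[[o]]
      chosen <- sample(labels, e$n_studies)
      refs <- vapply(chosen, function(l) {
        if (stats::runif(1) < cfg$perturb_refs$prob) {
          perturb_label(l, cfg$perturb_refs$max_edits, labels)
        } else l
      }, character(1), USE.NAMES = FALSE)
      refs_meta[[sprintf("s%d_o%d", s, o)]] <- list(
        refs = as.list(refs),
        effect_type = e$effect_type,
        effect_size = e$relative_effect,
        n_studies = e$n_studies)
    }
  }

  body <- lapply(stats::setNames(BODY_TEXT_FIELDS, BODY_TEXT_FIELDS),
                 function(f) {
    paste(c(filler_text(), signal_bag(mean_steps, ss, base = -1.4, draws = 2L)),
          collapse = " ")
  })

  list(
    schema_version = SCHEMA_VERSION,
    review_id = review_id,
    review_type = sample(c("intervention", "diagnostic"), 1L,
                         prob = c(0.9, 0.1)),
    medical_areas = as.list(sample(MEDICAL_AREAS,
                                   sample(1:2, 1L, prob = c(0.7, 0.3)))),
    year = sample(2002:2020, 1L),
    body_text = body,
    study_counts = list(included = n_primary,
                        ongoing = stats::rpois(1L, 1),
                        other = stats::rpois(1L, 0.5),
                        additional = stats::rpois(1L, 0.5),
                        excluded = stats::rpois(1L, 8)),
    sofs = sofs,
    primary_studies = primary,
    meta_analysis_refs = refs_meta,
    .truth = dplyr::bind_rows(truth)
  )
}

#' Generate a synthetic review corpus
#'
#' Emits review records with the statistical structure the pipeline assumes:
#' per-outcome downgrade vectors whose totals explain the grade (sampled so
#' both the configured grade distribution and per-criterion marginals hold),
#' footnotes rendered from the lexicon (with synonym noise and two-level
#' phrases), support features drawn from a planted generative model (wide
#' confidence intervals and small sample sizes track imprecision; signal
#' tokens such as "heterogeneity" track their criterion in the outcome and
#' conclusion texts; the proportion of high-risk judgements in primary
#' studies tracks risk of bias), a configurable fraction of arithmetically
#' corrupted footnotes, and perturbed meta-analysis study references.
#'
#' Generation is deterministic given `cfg$seed`: each review uses its own
#' seeded substream, so a corpus is reproducible independent of how many
#' reviews are generated.
#'
#' @param cfg A [gen_config()].
#' @param lexicon Lexicon used to render footnotes; [default_lexicon()] by
#'   default.
#' @return A `qoe_corpus` (list of review records) carrying the generator's
#'   true labels as an attribute; see [ground_truth()].
#' @export
generate_corpus <- function(cfg, lexicon = default_lexicon()) {
  stopifnot(inherits(cfg, "qoe_gen_config"))
  reviews <- lapply(seq_len(cfg$n_reviews), function(i) {
    generate_review(cfg, i, lexicon)
  })
  truth <- dplyr::bind_rows(lapply(reviews, `[[`, ".truth"))
  reviews <- lapply(reviews, function(r) { r$.truth <- NULL; r })
  structure(reviews, class = "qoe_corpus", ground_truth = truth)
}

#' True labels of a generated corpus
#'
#' Returns the generator's pre-corruption labels: the sampled grade and the
#' full downgrade vector for every outcome, plus a `corrupted` flag marking
#' outcomes whose rendered footnote omits one reason. Available for corpora
#' produced by [generate_corpus()] in the current session, or from the truth
#' CSV written by [run_pipeline()].
#'
#' @param corpus A `qoe_corpus` from [generate_corpus()].
#' @return A tibble keyed by `review_id`, `sof_index`, `outcome_index`.
#' @export
ground_truth <- function(corpus) {
  truth <- attr(corpus, "ground_truth")
  if (is.null(truth)) {
    stop("corpus carries no ground truth (was it read from disk? ",
         "use the truth CSV emitted at generation time)", call. = FALSE)
  }
  truth
}
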