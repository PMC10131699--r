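# Constrained edit-distance alignment and study-derived features.

boe_stub <- function(effect_type = "RR", relative_effect = 0.8,
                     n_studies = 2L) {
  list(effect_type = effect_type, relative_effect = relative_effect,
       n_studies = n_studies)
}

test_that("exact matches win and fuzzy matches respect the constraints", {
  studies <- c("Smith 2004", "Jones 2010")
  cons <- list(effect_type = "RR", effect_size = 0.8, n_studies = 2L)
  al <- align_primary_studies(boe_stub(), c("Smith 2004"), studies, cons)
  expect_equal(al$method, "exact")
  expect_equal(al$distance, 0L)

  al2 <- align_primary_studies(boe_stub(), c("Smith 2004a"),
                               c("Smith 2004b", "Jones 2010"), cons)
  expect_equal(al2$study_label, "Smith 2004b")
  expect_equal(al2$method, "edit")
  expect_equal(al2$distance, lev_oracle("Smith 2004a", "Smith 2004b"))

  # any constraint mismatch blocks fuzzy matching regardless of distance
  for (bad in list(list(effect_type = "OR", effect_size = 0.8, n_studies = 2L),
                   list(effect_type = "RR", effect_size = 0.81, n_studies = 2L),
                   list(effect_type = "RR", effect_size = 0.8, n_studies = 3L))) {
    al3 <- align_primary_studies(boe_stub(), c("Smith 2004a"),
                                 c("Smith 2004b"), bad)
    expect_true(is.na(al3$study_label))
  }
  # but exact label matches survive a constraint mismatch
  al4 <- align_primary_studies(boe_stub(), c("Smith 2004"), studies,
                               list(effect_type = "OR", effect_size = 1,
                                    n_studies = 9L))
  expect_equal(al4$method, "exact")
  expect_error(align_primary_studies(boe_stub(), character(0), studies, cons),
               "non-empty")
})

test_that("minimum distance and lexicographic tie-breaks follow the oracle", {
  set.seed(99)
  labels <- paste(sample(LETTERS, 20, replace = TRUE),
                  sample(2000:2010, 20, replace = TRUE))
  labels <- unique(labels)
  cons <- list(effect_type = "RR", effect_size = 0.8, n_studies = 2L)
  for (i in 1:15) {
    ref <- paste0(sample(labels, 1), sample(letters, 1))
    al <- align_primary_studies(boe_stub(), ref, labels, cons,
                                max_distance = 3L)
    d <- vapply(labels, lev_oracle, integer(1), a = ref)
    if (ref %in% labels) next
    if (min(d) <= 3L) {
      expect_equal(al$distance, min(d))
      expect_equal(al$study_label, sort(labels[d == min(d)])[1])
    } else {
      expect_true(is.na(al$study_label))
    }
  }
})

test_that("retention is 1.0 with consistent constraints and 0.0 scrambled", {
  corpus <- clean_corpus_2k()
  al <- align_corpus(corpus)
  expect_equal(attr(al, "retained_fraction"), 1.0)

  scrambled <- cached("scrambled_corpus", {
    cfg <- gen_config(n_reviews = 120, corrupt_fraction = 0,
                      perturb_refs = list(prob = 1, max_edits = 2L),
                      seed = 505)
    cc <- generate_corpus(cfg)
    structure(lapply(cc, function(rec) {
      rec$meta_analysis_refs <- lapply(rec$meta_analysis_refs, function(m) {
        m$effect_size <- m$effect_size + 1
        m
      })
      rec
    }), class = "qoe_corpus")
  })
  al2 <- align_corpus(scrambled)
  expect_equal(attr(al2, "retained_fraction"), 0.0)
})

test_that("study features match hand counts and a brute-force recount", {
  mk_study <- function(label, judgements) {
    comps <- lapply(judgements, function(j) list(judgement = j,
                                                 justification = ""))
    names(comps) <- rob_components()
    list(study_label = label, methods_text = paste("methods of", label),
         rob_components = comps)
  }
  s1 <- mk_study("A 2001", rep("high", 5))
  s2 <- mk_study("B 2002", rep("low", 5))
  sf <- derive_study_features(list(s1, s2))
  expect_equal(sf$ps_n_high_blinding, 1)
  expect_equal(sf$ps_n_low_blinding, 1)
  expect_equal(sf$ps_n_unclear_blinding, 0)
  expect_equal(sf$ps_prop_high_blinding, 0.5)
  expect_match(sf$ps_methods, "methods of A 2001 methods of B 2002")
  # all unclear: proportion high is 0
  s3 <- mk_study("C 2003", rep("unclear", 5))
  expect_equal(derive_study_features(list(s3))$ps_prop_high_blinding, 0)
  expect_error(derive_study_features(list()), "non-empty")

  set.seed(7)
  for (i in 1:100) {
    n <- sample(1:6, 1)
    studies <- lapply(seq_len(n), function(k) {
      mk_study(paste("S", k),
               sample(c("low", "high", "unclear"), 5, replace = TRUE))
    })
    sf <- derive_study_features(studies)
    for (comp in rob_components()) {
      j <- vapply(studies, function(s) s$rob_components[[comp]]$judgement,
                  character(1))
      expect_equal(sf[[paste0("ps_prop_high_", comp)]], sum(j == "high") / n)
      expect_equal(sf[[paste0("ps_n_unclear_", comp)]], sum(j == "unclear"))
    }
  }
})

test_that("attach_study_features fills aligned instances only", {
  corpus <- small_corpus()
  ds <- small_dataset()
  al <- align_corpus(corpus)
  inst <- attach_study_features(ds$instances, corpus, al)
  aligned_keys <- unique(al[al$aligned, c("review_id", "sof_index",
                                          "outcome_index")])
  joined <- dplyr::semi_join(inst, aligned_keys,
                             by = c("review_id", "sof_index", "outcome_index"))
  expect_true(all(!is.na(joined$ps_prop_high_blinding)))
  expect_true(all(c("ps_methods", paste0("ps_judgement_", rob_components()))
                  %in% names(inst)))
})

test_that("extraction validation scores exact field agreement", {
  ds <- small_dataset()
  ext <- ds$instances
  ref <- ext
  out <- validate_extraction(ext, ref, c("grade", "n_studies"))
  expect_true(all(out$accuracy == 1))

  ref2 <- ref
  ref2$n_studies[1] <- -1
  out2 <- validate_extraction(ext[1:10, ], ref2[1:10, ],
                              c("n_studies", "grade"))
  expect_equal(out2$accuracy[out2$field == "n_studies"], 0.9)
  expect_equal(out2$accuracy[out2$field == "grade"], 1.0)

  # randomized corruption agrees with an independent recount
  set.seed(11)
  ref3 <- ref
  flip <- runif(nrow(ref3)) < 0.3
  ref3$grade[flip] <- (ref3$grade[flip] + 1L) %% 4L
  out3 <- validate_extraction(ext, ref3, "grade")
  expect_equal(out3$accuracy, mean(ext$grade == ref3$grade))

  expect_error(validate_extraction(ext[1:5, ], ref[6:10, ], "grade"),
               "no joinable rows")
  att <- validate_extraction(ext[1:8, ], ref[5:12, ], "grade")
  expect_equal(attr(att, "unjoined_extracted"), 4L)
  expect_equal(attr(att, "unjoined_reference"), 4L)
})
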