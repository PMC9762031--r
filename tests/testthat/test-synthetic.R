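test_that("drug ontology labels follow the 14-digit segment structure", {
  d <- small_data()
  ont <- d$ontologies$drug
  leaves <- ontology_leaves(ont)
  expect_length(leaves, small_config()$n_drug_leaves)
  expect_true(all(nchar(leaves) == 14L))
  expect_true(all(grepl("^86[1-9][0-9]{11}$", leaves)))
  # parent chain passes through product, enterprise, category and country
  anc <- ancestor_set(ont, leaves[1L])
  expect_identical(anc[2L], substr(leaves[1L], 1L, 13L))  # product
  expect_identical(anc[3L], substr(leaves[1L], 1L, 8L))   # enterprise
  expect_identical(anc[4L], substr(leaves[1L], 1L, 3L))   # category
  expect_identical(anc[5L], "86")                         # country
  expect_identical(anc[length(anc)], ont$labels[ont$root])
})

test_that("diagnosis ontology labels are ICD-10-like with category parents", {
  ont <- small_data()$ontologies$diagnosis
  leaves <- ontology_leaves(ont)
  expect_true(all(grepl("^[A-Z][0-9]{2}\\.[0-9]$", leaves)))
  for (lf in leaves[1:5]) {
    anc <- ancestor_set(ont, lf)
    expect_identical(anc[2L], substr(lf, 1L, 3L))   # e.g. J98.4 -> J98
    expect_identical(anc[3L], substr(lf, 1L, 1L))   # chapter letter
  }
})

test_that("degenerate one-leaf ontologies are single root paths", {
  cfg <- synthetic_config(n_diag_leaves = 1L, n_drug_leaves = 1L,
                          n_symptoms = 1L, n_single_visit_patients = 1L,
                          n_multi_visit_patients = 0L, seed = 5L)
  for (kind in c("diagnosis", "drug")) {
    ont <- generate_ontology(kind, cfg)
    expect_length(ont$leaves, 1L)
    anc <- ancestor_set(ont, ontology_leaves(ont))
    # the ancestor set is the whole root path and covers every node
    expect_setequal(anc, ont$labels)
  }
})

test_that("leaf requests beyond the label space raise a capacity error", {
  cfg <- small_config()
  cfg$n_diag_leaves <- 30000L
  expect_error(generate_ontology("diagnosis", cfg), "exceeds")
})

test_that("disease profiles are deterministic, normalised and sparse", {
  d <- small_data()
  cfg <- small_config()
  p1 <- generate_disease_profiles(d$ontologies, d$symptoms, cfg)
  p2 <- generate_disease_profiles(d$ontologies, d$symptoms, cfg)
  expect_identical(p1, p2)
  expect_setequal(names(p1), ontology_leaves(d$ontologies$diagnosis))
  for (pr in p1) {
    expect_equal(sum(pr$drug_distribution), 1)
    expect_true(all(pr$drug_distribution >= 0))
    expect_gt(sum(pr$drug_distribution > 0), 0)
  }
})

test_that("profile support size matches the sparsity parameter (Monte Carlo)", {
  cfg <- synthetic_config(n_diag_leaves = 1000L, n_drug_leaves = 100L,
                          n_symptoms = 10L, n_single_visit_patients = 1L,
                          n_multi_visit_patients = 0L,
                          profile_sparsity = 0.1, seed = 11L)
  onts <- list(diagnosis = generate_ontology("diagnosis", cfg),
               drug = generate_ontology("drug", cfg))
  profs <- generate_disease_profiles(onts, symptom_dictionary(10L), cfg)
  support <- vapply(profs, function(p) sum(p$drug_distribution > 0), numeric(1))
  expect_equal(mean(support), 0.1 * 100, tolerance = 0.05)
})

test_that("single-visit corpus matches configured per-visit means", {
  cfg <- synthetic_config(n_single_visit_patients = 10000L,
                          n_multi_visit_patients = 0L, seed = 3L)
  onts <- list(diagnosis = generate_ontology("diagnosis", cfg),
               drug = generate_ontology("drug", cfg))
  profs <- generate_disease_profiles(onts, symptom_dictionary(cfg$n_symptoms), cfg)
  corpus <- generate_single_visit_corpus(profs, cfg)
  s <- corpus_summary(corpus)
  expect_equal(s$avg_diagnoses, 2.233, tolerance = 0.1)
  expect_equal(s$avg_drugs, 16.77, tolerance = 0.1)
  expect_equal(s$avg_symptoms, 1.0, tolerance = 0.1)
  # every record has at least one diagnosis and one drug; ids unique
  visits <- corpus
  expect_true(all(vapply(visits, function(v) length(v$diagnoses) >= 1L, logical(1))))
  expect_true(all(vapply(visits, function(v) length(v$drugs) >= 1L, logical(1))))
  expect_false(anyDuplicated(vapply(visits, `[[`, character(1), "patient_id")) > 0)
})

test_that("zero patients gives an empty corpus", {
  d <- small_data()
  cfg <- small_config(); cfg$n_single_visit_patients <- 0L
  expect_length(generate_single_visit_corpus(d$profiles, cfg), 0L)
  expect_error(generate_single_visit_corpus(list(), cfg), "empty")
})

test_that("multi-visit corpus has the configured sequence shape", {
  cfg <- synthetic_config(n_single_visit_patients = 0L,
                          n_multi_visit_patients = 1000L, seed = 9L)
  onts <- list(diagnosis = generate_ontology("diagnosis", cfg),
               drug = generate_ontology("drug", cfg))
  profs <- generate_disease_profiles(onts, symptom_dictionary(cfg$n_symptoms), cfg)
  corpus <- generate_multi_visit_corpus(profs, cfg)
  tv <- vapply(corpus, `[[`, integer(1), "T")
  expect_true(all(tv >= 2L))
  expect_true(all(tv <= cfg$max_visits))
  expect_equal(mean(tv), 2.27, tolerance = 0.1)
  h <- corpus[[1L]]
  expect_true(all(vapply(h$visits, `[[`, character(1), "patient_id") == h$patient_id))
  # admission ids carry strictly increasing visit indices
  idx <- as.integer(sub(".*-", "", vapply(h$visits, `[[`, character(1), "admission_id")))
  expect_identical(idx, seq_len(h$T))
})

test_that("full chronic persistence with one profile freezes the diagnosis set", {
  cfg <- synthetic_config(n_diag_leaves = 1L, n_drug_leaves = 10L,
                          n_symptoms = 4L, n_single_visit_patients = 0L,
                          n_multi_visit_patients = 20L,
                          chronic_persistence = 1, seed = 2L)
  onts <- list(diagnosis = generate_ontology("diagnosis", cfg),
               drug = generate_ontology("drug", cfg))
  profs <- generate_disease_profiles(onts, symptom_dictionary(4L), cfg)
  corpus <- generate_multi_visit_corpus(profs, cfg)
  for (h in corpus) {
    sets <- lapply(h$visits, `[[`, "diagnoses")
    expect_true(all(vapply(sets, identical, logical(1), sets[[1L]])))
  }
})

test_that("identical configs give byte-identical corpora", {
  cfg <- small_config(seed = 77L)
  a <- simulate_corpus(cfg)
  b <- simulate_corpus(cfg)
  expect_identical(a$single, b$single)
  expect_identical(a$multi, b$multi)
  expect_identical(a$ontologies, b$ontologies)
})

test_that("emitted codes are ontology leaves and symptoms are in the dictionary", {
  d <- small_data()
  dl <- ontology_leaves(d$ontologies$diagnosis)
  ml <- ontology_leaves(d$ontologies$drug)
  visits <- c(d$single, unlist(lapply(d$multi, `[[`, "visits"), recursive = FALSE))
  expect_true(all(unlist(lapply(visits, `[[`, "diagnoses")) %in% dl))
  expect_true(all(unlist(lapply(visits, `[[`, "drugs")) %in% ml))
  expect_true(all(unlist(lapply(visits, `[[`, "symptoms")) %in% d$symptoms))
})

test_that("corpus_summary agrees with a brute-force recount", {
  d <- small_data()
  s <- corpus_summary(d$multi)
  visits <- unlist(lapply(d$multi, `[[`, "visits"), recursive = FALSE)
  expect_identical(s$n_records, length(visits))
  expect_identical(s$n_patients, length(d$multi))
  expect_equal(s$avg_drugs, mean(sapply(visits, function(v) length(v$drugs))))
  expect_identical(s$max_diagnoses,
                   max(sapply(visits, function(v) length(v$diagnoses))))
  expect_equal(s$avg_visits, mean(sapply(d$multi, `[[`, "T")))
  # hand-checkable miniature
  one <- visit_record("p", "a", c("A01.1", "A01.2", "A01.3"), "86111111111111")
  two <- list(patient_history("p1", list(visit_record("p1", "a1"), visit_record("p1", "a2"))),
              patient_history("p2", lapply(1:4, function(i) visit_record("p2", paste0("b", i)))))
  expect_equal(corpus_summary(list(one))$avg_diagnoses, 3)
  expect_equal(corpus_summary(list(one))$avg_visits, 1)
  expect_equal(corpus_summary(two)$avg_visits, 3)
  expect_equal(corpus_summary(two)$max_visits, 4)
  expect_error(corpus_summary(list()), "empty")
})

test_that("diagnosis-aware lookup beats the label-frequency recommender", {
  # the generator's learnability guarantee: conditioning on the diagnosis
  # must carry real information about the drug set
  d <- small_data()
  vocabs <- small_vocabs()
  splits <- split_patients(d$multi, seed = 1L)
  train_visits <- c(d$single,
                    unlist(lapply(splits$train, `[[`, "visits"), recursive = FALSE))
  rec <- profile_lookup_recommender(train_visits, vocabs)
  drug_codes <- vocabs$drug$tokens[-seq_len(4L)]
  freq <- Reduce(`+`, lapply(train_visits, function(v) {
    rxrec:::multi_hot(vocabs$drug, v$drugs)
  })) / length(train_visits)
  test_visits <- unlist(lapply(splits$test, `[[`, "visits"), recursive = FALSE)
  truth <- lapply(test_visits, `[[`, "drugs")
  k <- vapply(truth, length, integer(1))
  top_k <- function(p, k) drug_codes[order(p, decreasing = TRUE)[seq_len(k)]]
  j_lookup <- jaccard_score(truth, lapply(seq_along(test_visits), function(i) {
    top_k(rec(test_visits[[i]]), k[i])
  }))
  j_freq <- jaccard_score(truth, lapply(seq_along(test_visits), function(i) {
    top_k(freq, k[i])
  }))
  expect_gt(j_lookup, j_freq)
})
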