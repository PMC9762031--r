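# Shared fixtures: one small synthetic study data set, built once per test
# run and memoised, plus factories for miniature models.

.fixture_env <- new.env(parent = emptyenv())

small_config <- function(seed = 42L) {
  synthetic_config(
    n_diag_leaves = 20L, n_drug_leaves = 40L, n_symptoms = 12L,
    n_single_visit_patients = 300L, n_multi_visit_patients = 40L,
    seed = seed
  )
}

small_data <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_corpus(small_config())
  }
  .fixture_env$small
}

small_vocabs <- function() {
  if (is.null(.fixture_env$vocabs)) {
    d <- small_data()
    .fixture_env$vocabs <- build_vocabularies(c(d$single, d$multi))
  }
  .fixture_env$vocabs
}

# a narrow model over the small corpus (fast to evaluate and differentiate)
small_model <- function(l = 16L, seed = 7L, use_ontology = TRUE) {
  d <- small_data()
  visit_model(small_vocabs(), d$ontologies, l = l, ff = 2L * l,
              enc_heads = 4L, gat_heads = 4L,
              max_len = c(diagnosis = 8L, drug = 16L, symptom = 4L),
              use_ontology = use_ontology, seed = seed)
}

# an independently written per-diagnosis drug-frequency recommender: for
# each diagnosis, the empirical per-drug frequency over training visits
# containing it; a visit's score is the mean over its diagnoses
profile_lookup_recommender <- function(train_visits, vocabularies) {
  vm <- vocabularies$drug
  diag_codes <- vocabularies$diagnosis$tokens[-seq_len(4L)]
  lookup <- lapply(diag_codes, function(dc) {
    hits <- Filter(function(v) dc %in% v$diagnoses, train_visits)
    if (length(hits) == 0L) return(rep(0, vm$n_codes))
    Reduce(`+`, lapply(hits, function(v) {
      v_hot <- numeric(vm$n_codes)
      idx <- match(v$drugs, vm$tokens) - 4L
      v_hot[idx[!is.na(idx) & idx > 0L]] <- 1
      v_hot
    })) / length(hits)
  })
  names(lookup) <- diag_codes
  global <- Reduce(`+`, lookup) / length(lookup)
  function(visit) {
    known <- intersect(visit$diagnoses, diag_codes)
    if (length(known) == 0L) return(global)
    Reduce(`+`, lookup[known]) / length(known)
  }
}

expect_tree_equal <- function(a, b, tol = 0) {
  expect_lte(rxrec:::tree_max_abs_diff(a, b), tol)
}

# a briefly pre-trained small model, shared across test files (memoised)
small_pretrained <- function() {
  if (is.null(.fixture_env$pretrained_small)) {
    d <- small_data()
    m <- small_model(l = 16L, seed = 3L)
    .fixture_env$pretrained_small <-
      run_pretraining(d$single, m, epochs = 8L, batch_size = 32L,
                      lr = 2e-3, seed = 3L)
  }
  .fixture_env$pretrained_small
}

# shared miniature fine-tuning setup
mini_ft <- function() {
  if (is.null(.fixture_env$mini_ft)) {
    d <- small_data()
    m <- small_model(l = 16L, seed = 5L)
    train <- Filter(function(h) h$T >= 2L, d$multi[1:10])
    prep <- lapply(train, rxrec:::prepare_history, model = m)
    pred <- rxrec:::with_seed(6L, prediction_init(16L, m$vocabularies$drug$n_codes))
    .fixture_env$mini_ft <- list(
      m = m, pred = pred,
      bt = lapply(prep, `[[`, "toks"),
      tg = lapply(prep, `[[`, "targets"),
      sz = vapply(prep, `[[`, integer(1), "T")
    )
  }
  .fixture_env$mini_ft
}

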