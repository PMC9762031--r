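test_that("Jaccard reproduces hand-computed set overlaps exactly", {
  expect_equal(as.numeric(jaccard_score(list(c("a", "b", "c")),
                                        list(c("b", "c", "d")))), 0.5)
  expect_equal(as.numeric(jaccard_score(list(c("x", "y")), list(c("x", "y")))), 1)
  expect_equal(as.numeric(jaccard_score(list(character(0)), list(character(0)))), 1)
  expect_identical(attr(jaccard_score(list(character(0)), list(character(0))),
                        "empty_matches"), 1L)
  expect_error(jaccard_score(list("a"), list()), "length")
})

test_that("average F1 reproduces hand-computed values and edge rules", {
  expect_equal(average_f1(list(c("a", "b", "c")), list(c("b", "c", "d"))), 2 / 3)
  expect_equal(average_f1(list(c("a", "b")), list(c("c", "d"))), 0)
  expect_equal(average_f1(list(character(0)), list("a")), 0)
  expect_equal(average_f1(list("a"), list(character(0))), 0)
})

test_that("set metrics agree with arithmetic oracles on random pairs", {
  set.seed(11)
  universe <- letters
  for (rep in 1:1000) {
    y <- sample(universe, sample(0:6, 1L))
    yh <- sample(universe, sample(0:6, 1L))
    inter <- length(intersect(y, yh))
    uni <- length(union(y, yh))
    j_oracle <- if (uni == 0L) 1 else inter / uni
    expect_identical(as.numeric(jaccard_score(list(y), list(yh))), j_oracle)
    f_oracle <- if (length(y) == 0L || length(yh) == 0L) 0 else {
      p <- inter / length(y); r <- inter / length(yh)
      if (p + r == 0) 0 else 2 * p * r / (p + r)
    }
    expect_identical(average_f1(list(y), list(yh)), f_oracle)
    # F1 is symmetric under swapping truth and prediction
    expect_identical(average_f1(list(yh), list(y)), f_oracle)
  }
})

test_that("PR-AUC matches an exhaustive-threshold oracle", {
  # perfect ranking -> 1
  expect_equal(pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # a single positive pair -> 1 at any score
  expect_equal(pr_auc(0.37, 1), 1)
  expect_error(pr_auc(c(0.5, 0.5), c(0, 0)), "positive")
  ap_oracle <- function(s, y) {
    # step integration over every distinct threshold, descending
    th <- sort(unique(s), decreasing = TRUE)
    prev_r <- 0; auc <- 0
    for (t in th) {
      sel <- s >= t
      p <- sum(y[sel]) / sum(sel)
      r <- sum(y[sel]) / sum(y)
      auc <- auc + (r - prev_r) * p
      prev_r <- r
    }
    auc
  }
  set.seed(12)
  for (rep in 1:200) {
    n <- sample(3:40, 1L)
    s <- round(runif(n), sample(1:3, 1L))  # induce ties
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0L) y[sample(n, 1L)] <- 1L
    expect_equal(pr_auc(s, y), ap_oracle(s, y), tolerance = 1e-9)
  }
})

test_that("metric reports stay in the unit interval", {
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(1:10, 1L)
    truth <- lapply(seq_len(n), function(i) sample(letters, sample(0:4, 1L)))
    pred <- lapply(seq_len(n), function(i) sample(letters, sample(0:4, 1L)))
    j <- as.numeric(jaccard_score(truth, pred))
    f <- average_f1(truth, pred)
    expect_true(j >= 0 && j <= 1)
    expect_true(f >= 0 && f <= 1)
  }
})

test_that("evaluate_model is self-consistent with its dumped predictions", {
  fit <- small_pretrained()
  d <- small_data()
  pred <- rxrec:::with_seed(21L,
                            prediction_init(16L, fit$model$vocabularies$drug$n_codes))
  test <- Filter(function(h) h$T >= 2L, d$multi[1:8])
  rep <- evaluate_model(fit$model, pred, test, theta = 0.3)
  expect_true(all(unlist(rep[c("jaccard", "f1", "pr_auc")]) >= 0))
  expect_true(all(unlist(rep[c("jaccard", "f1", "pr_auc")]) <= 1))
  sc <- attr(rep, "scores"); tr <- attr(rep, "truth")
  redo_sets <- lapply(seq_len(nrow(sc)), function(i) {
    recommendation_set(sc[i, ], 0.3)
  })
  expect_equal(rep$jaccard, as.numeric(jaccard_score(tr, redo_sets)))
  expect_equal(rep$f1, average_f1(tr, redo_sets))
  # an oracle recommender scores 1 on every metric
  truth_mat <- do.call(rbind, lapply(seq_along(tr), function(i) {
    rxrec:::multi_hot(fit$model$vocabularies$drug, tr[[i]])
  }))
  oracle_scores <- truth_mat * 0.98 + 0.01
  colnames(oracle_scores) <- fit$model$vocabularies$drug$tokens[-(1:4)]
  oracle_rep <- rxrec:::score_predictions(
    oracle_scores, tr, truth_mat, 0.3, length(test))
  expect_equal(oracle_rep$jaccard, 1)
  expect_equal(oracle_rep$f1, 1)
  expect_equal(oracle_rep$pr_auc, 1)
  # patients with a single visit are skipped with a warning
  one <- patient_history("solo", list(visit_record("solo", "s1", "A00.0")))
  expect_warning(evaluate_model(fit$model, pred, c(test, list(one))), "skipping")
})

test_that("random-probability recommendations sit near the density expectation", {
  # with uniform scores and threshold theta, a fraction (1 - theta) of the
  # vocabulary is recommended; expected Jaccard is approximately
  # (1 - theta) k / ((1 - theta) V + theta k) for k true drugs of V
  set.seed(14)
  V <- 200L; k <- 8L; theta <- 0.3
  truth <- lapply(1:300, function(i) as.character(sample(V, k)))
  pred <- lapply(1:300, function(i) {
    recommendation_set(stats::setNames(runif(V), as.character(1:V)), theta)
  })
  expected <- (1 - theta) * k / ((1 - theta) * V + theta * k)
  expect_equal(as.numeric(jaccard_score(truth, pred)), expected, tolerance = 0.15)
})

test_that("the logistic baseline dominates frequency and random baselines", {
  d <- small_data()
  vocabs <- small_vocabs()
  splits <- split_patients(d$multi, seed = 3L)
  lr <- suppressWarnings(lr_baseline(splits, vocabs, theta = 0.3))
  fq <- frequency_baseline(splits, vocabs, theta = 0.3)
  rnd <- random_baseline(splits, vocabs, theta = 0.3, seed = 3L)
  expect_gt(lr$pr_auc, fq$pr_auc)
  expect_gt(lr$pr_auc, rnd$pr_auc)
  expect_identical(lr$n_visits, fq$n_visits)
})

test_that("perfectly separable toy data gives the LR baseline Jaccard 1", {
  # each diagnosis maps to exactly one fixed drug
  drugs <- sprintf("86%012d", 1:3)
  diags <- c("A00.0", "B11.1", "C22.2")
  mk_h <- function(pid, i, j) {
    patient_history(pid, list(
      visit_record(pid, paste0(pid, "-1"), diags[i], drugs[i]),
      visit_record(pid, paste0(pid, "-2"), diags[j], drugs[j])
    ))
  }
  set.seed(15)
  hs <- lapply(1:12, function(p) {
    mk_h(sprintf("p%02d", p), sample(3, 1L), sample(3, 1L))
  })
  vocabs <- build_vocabularies(hs)
  splits <- split_patients(hs, seed = 1L)
  rep <- suppressWarnings(lr_baseline(splits, vocabs, theta = 0.5, lambda = 1e-4))
  expect_equal(rep$jaccard, 1)
})

test_that("variant flags decode the ablation grid", {
  expect_length(ablation_variants(), 8L)
  fl <- rxrec:::variant_flags("K-P-")
  expect_false(fl$use_ontology)
  expect_false(fl$use_pretraining)
  expect_true(fl$adversarial)
  full <- rxrec:::variant_flags("full")
  expect_true(full$use_ontology && full$use_pretraining && full$adversarial)
  none <- rxrec:::variant_flags("K-P-A-")
  expect_false(none$use_ontology || none$use_pretraining || none$adversarial)
})
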