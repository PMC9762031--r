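#' Mean Jaccard similarity between true and recommended drug sets
#'
#' Mean over evaluated visits of `|Y intersect Yhat| / |Y union Yhat|`.
#' A visit where both sets are empty contributes 1 (an exact empty match;
#' each occurrence is counted in the `"empty_matches"` attribute).
#'
#' @param truth,predicted lists of character vectors (paired per visit).
#' @return scalar in `[0, 1]`.
#' @export
jaccard_score <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stopf("set lists differ in length")
  empties <- 0L
  js <- vapply(seq_along(truth), function(i) {
    y <- unique(truth[[i]]); yh <- unique(predicted[[i]])
    u <- length(union(y, yh))
    if (u == 0L) {
      empties <<- empties + 1L
      return(1)
    }
    length(intersect(y, yh)) / u
  }, numeric(1))
  structure(mean(js), empty_matches = empties)
}

#' Mean per-visit F1 between true and recommended drug sets
#'
#' Per visit, with `I = |Y intersect Yhat|`, the two rates are `I / |Y|` and
#' `I / |Yhat|` (F1 is symmetric in the pair, so their conventional naming
#' does not affect the score); `F1 = 2PR / (P + R)`. Visits with an empty
#' set on either side (zero denominator) contribute 0.
#'
#' @inheritParams jaccard_score
#' @return scalar in `[0, 1]`.
#' @export
average_f1 <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stopf("set lists differ in length")
  f1 <- vapply(seq_along(truth), function(i) {
    y <- unique(truth[[i]]); yh <- unique(predicted[[i]])
    if (length(y) == 0L || length(yh) == 0L) return(0)
    inter <- length(intersect(y, yh))
    p <- inter / length(y)
    r <- inter / length(yh)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

#' Micro-averaged PR-AUC (average precision)
#'
#' All (visit, drug) score/label pairs are pooled; the precision-recall
#' curve is traced over the distinct score thresholds (descending) and
#' integrated as `sum (R_i - R_{i-1}) * P_i` — the standard average
#' precision without interpolation.
#'
#' @param scores numeric matrix (visits x drugs) or vector of probabilities.
#' @param truth 0/1 matrix or vector of the same shape.
#' @return scalar in `[0, 1]`.
#' @export
pr_auc <- function(scores, truth) {
  s <- as.vector(scores); y <- as.vector(truth)
  stopifnot(length(s) == length(y))
  npos <- sum(y == 1)
  if (npos == 0L) stopf("PR-AUC is undefined without any positive label")
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  tp <- cumsum(y)
  n <- length(s)
  # evaluate at the last index of each tied-score block
  last <- c(which(s[-n] != s[-1L]), n)
  prec <- tp[last] / last
  rec <- tp[last] / npos
  sum(diff(c(0, rec)) * prec)
}

metric_report <- function(jaccard, f1, prauc, n_patients, n_visits) {
  structure(list(jaccard = as.numeric(jaccard), f1 = f1, pr_auc = prauc,
                 n_patients = n_patients, n_visits = n_visits),
            class = "metric_report")
}

#' @exportS3Method base::print
print.metric_report <- function(x, ...) {
  cat(sprintf("Jaccard %.4f | F1 %.4f | PR-AUC %.4f  (%d patients, %d visits)\n",
              x$jaccard, x$f1, x$pr_auc, x$n_patients, x$n_visits))
  invisible(x)
}

# shared scoring path: per-visit probability rows -> report
score_predictions <- function(prob_rows, truth_sets, truth_mat, theta,
                              n_patients) {
  pred_sets <- lapply(seq_len(nrow(prob_rows)), function(i) {
    recommendation_set(prob_rows[i, ], theta, colnames(prob_rows))
  })
  metric_report(jaccard_score(truth_sets, pred_sets),
                average_f1(truth_sets, pred_sets),
                pr_auc(prob_rows, truth_mat),
                n_patients, nrow(prob_rows))
}

#' Evaluate a trained model on test patients
#'
#' Scores visits `t = 2..T` of every test patient with at least two visits
#' (single-visit patients are skipped with a warning), thresholds the
#' probabilities at `theta` and reports Jaccard, average F1 and PR-AUC.
#'
#' @param model a trained [visit_model()].
#' @param pred the trained prediction head.
#' @param test list of [patient_history()].
#' @param theta decision threshold (default 0.3).
#' @return a `metric_report`; the per-visit probabilities and truth sets are
#'   attached as attributes `"scores"` and `"truth"`.
#' @export
evaluate_model <- function(model, pred, test, theta = 0.3) {
  keep <- vapply(test, function(h) h$T >= 2L, logical(1))
  if (any(!keep)) {
    warning(sprintf("skipping %d patient(s) with fewer than 2 visits", sum(!keep)))
  }
  test <- test[keep]
  if (length(test) == 0L) stopf("no evaluable patients (all have T < 2)")
  rows <- list(); truth_sets <- list(); truth_rows <- list()
  for (h in test) {
    pr <- predict_history(h, model, pred)
    for (t in 2L:h$T) {
      rows[[length(rows) + 1L]] <- pr[t - 1L, ]
      truth_sets[[length(truth_sets) + 1L]] <- h$visits[[t]]$drugs
      truth_rows[[length(truth_rows) + 1L]] <-
        multi_hot(model$vocabularies$drug, h$visits[[t]]$drugs)
    }
  }
  prob_rows <- do.call(rbind, rows)
  truth_mat <- do.call(rbind, truth_rows)
  rep <- score_predictions(prob_rows, truth_sets, truth_mat, theta, length(test))
  attr(rep, "scores") <- prob_rows
  attr(rep, "truth") <- truth_sets
  rep
}

#' Calibrate the recommendation threshold on validation data
#'
#' Thresholded set metrics are sensitive to where the decision cut sits in
#' the model's probability scale; the conventional fixed 30% cut is a
#' reasonable default but not optimal for every model. This helper sweeps a
#' grid of thresholds over the validation split and returns the one with
#' the best validation Jaccard (ties resolve to the smaller threshold).
#' The grid floor of 0.1 keeps recommendation sets clinically plausible.
#'
#' @param model a trained [visit_model()].
#' @param pred the trained prediction head.
#' @param validation list of [patient_history()].
#' @param grid candidate thresholds.
#' @return the selected threshold (scalar); the validation Jaccard per
#'   candidate is attached as attribute `"profile"`.
#' @export
calibrate_threshold <- function(model, pred, validation,
                                grid = seq(0.1, 0.5, by = 0.05)) {
  val <- evaluate_model(model, pred, validation, theta = grid[1L])
  sc <- attr(val, "scores"); tr <- attr(val, "truth")
  vj <- vapply(grid, function(th) {
    sets <- lapply(seq_len(nrow(sc)), function(i) {
      recommendation_set(sc[i, ], th, colnames(sc))
    })
    as.numeric(jaccard_score(tr, sets))
  }, numeric(1))
  structure(grid[which.max(vj)], profile = stats::setNames(vj, grid))
}

## ---- baselines -------------------------------------------------------------

# features/labels for the per-visit logistic baseline
lr_design <- function(histories, vocabularies) {
  vd <- vocabularies$diagnosis; vm <- vocabularies$drug; vs <- vocabularies$symptom
  X <- list(); Y <- list(); truth_sets <- list(); pat <- integer(0)
  for (pi in seq_along(histories)) {
    h <- histories[[pi]]
    if (h$T < 2L) next
    d_hot <- lapply(h$visits, function(v) multi_hot(vd, v$diagnoses))
    m_hot <- lapply(h$visits, function(v) multi_hot(vm, v$drugs))
    s_hot <- lapply(h$visits, function(v) multi_hot(vs, v$symptoms))
    for (t in 2L:h$T) {
      hist_idx <- seq_len(t - 1L)
      X[[length(X) + 1L]] <- c(Reduce(`+`, d_hot[hist_idx]),
                               Reduce(`+`, m_hot[hist_idx]),
                               Reduce(`+`, s_hot[hist_idx]),
                               d_hot[[t]], s_hot[[t]])
      Y[[length(Y) + 1L]] <- m_hot[[t]]
      truth_sets[[length(truth_sets) + 1L]] <- h$visits[[t]]$drugs
      pat <- c(pat, pi)
    }
  }
  list(X = do.call(rbind, X), Y = do.call(rbind, Y),
       truth_sets = truth_sets, n_patients = length(unique(pat)))
}

#' Logistic-regression baseline
#'
#' The standard shallow baseline for sequential medication recommendation:
#' for each target visit the features are the element-wise sums of the
#' multi-hot code vectors over the prior visits (diagnoses, drugs,
#' symptoms) plus the current visit's diagnosis and symptom multi-hots, and
#' one independent penalised logistic classifier per drug predicts the
#' drug's presence. Drugs with single-class training labels fall back to a
#' constant class-rate predictor.
#'
#' @param splits output of [split_patients()].
#' @param vocabularies output of [build_vocabularies()].
#' @param theta decision threshold (default 0.3).
#' @param lambda ridge penalty of the per-drug logistic fits.
#' @return a `metric_report` on the test split.
#' @export
lr_baseline <- function(splits, vocabularies, theta = 0.3, lambda = 0.01) {
  train <- lr_design(c(splits$train, splits$validation), vocabularies)
  test <- lr_design(splits$test, vocabularies)
  Xtr <- Matrix::Matrix(train$X, sparse = TRUE)
  Xte <- Matrix::Matrix(test$X, sparse = TRUE)
  ML <- ncol(train$Y)
  P <- matrix(0, nrow(test$X), ML)
  for (j in seq_len(ML)) {
    yj <- train$Y[, j]
    if (min(tabulate(yj + 1L, 2L)) < 2L) {
      # degenerate labels (all/almost all one class): constant class rate
      P[, j] <- min(max(mean(yj), 1e-6), 1 - 1e-6)
    } else {
      fit <- glmnet::glmnet(Xtr, yj, family = "binomial", alpha = 0,
                            lambda = c(10, 1, 0.1, lambda),
                            standardize = FALSE)
      P[, j] <- as.vector(stats::predict(fit, Xte, s = lambda,
                                         type = "response"))
    }
  }
  colnames(P) <- vocabularies$drug$tokens[-seq_len(vocabularies$drug$n_special)]
  score_predictions(P, test$truth_sets, test$Y, theta, test$n_patients)
}

#' Label-frequency baseline
#'
#' Scores every drug with its training-set per-visit frequency, identically
#' for every test visit — the floor any informative recommender must beat.
#'
#' @inheritParams lr_baseline
#' @return a `metric_report` on the test split.
#' @export
frequency_baseline <- function(splits, vocabularies, theta = 0.3) {
  vm <- vocabularies$drug
  train_visits <- unlist(lapply(c(splits$train, splits$validation),
                                `[[`, "visits"), recursive = FALSE)
  freq <- Reduce(`+`, lapply(train_visits, function(v) multi_hot(vm, v$drugs))) /
    length(train_visits)
  test <- lr_design(splits$test, vocabularies)
  P <- matrix(freq, nrow(test$Y), length(freq), byrow = TRUE)
  colnames(P) <- vm$tokens[-seq_len(vm$n_special)]
  score_predictions(P, test$truth_sets, test$Y, theta, test$n_patients)
}

#' Uniform-random baseline
#'
#' Seeded uniform probabilities per (visit, drug) — the chance floor.
#'
#' @inheritParams lr_baseline
#' @param seed integer seed.
#' @return a `metric_report` on the test split.
#' @export
random_baseline <- function(splits, vocabularies, theta = 0.3, seed = 1L) {
  vm <- vocabularies$drug
  test <- lr_design(splits$test, vocabularies)
  P <- with_seed(seed, matrix(stats::runif(nrow(test$Y) * vm$n_codes),
                              nrow(test$Y), vm$n_codes))
  colnames(P) <- vm$tokens[-seq_len(vm$n_special)]
  score_predictions(P, test$truth_sets, test$Y, theta, test$n_patients)
}

## ---- ablation harness ------------------------------------------------------

#' Variant flags of the ablation study
#'
#' `"full"` plus the seven removals: `K-` replaces ontology attention with a
#' plain leaf-code lookup embedding, `P-` skips pre-training (random encoder
#' initialisation, no alternation), `A-` disables the adversarial pass, and
#' the pairwise/triple combinations. `"K-P-A-"` is the bare MLP over lookup
#' embeddings.
#'
#' @return character vector of the eight variant names.
#' @export
ablation_variants <- function() {
  c("full", "K-", "P-", "A-", "K-P-", "K-A-", "P-A-", "K-P-A-")
}

variant_flags <- function(variant) {
  list(use_ontology = !grepl("K-", variant, fixed = TRUE),
       use_pretraining = !grepl("P-", variant, fixed = TRUE),
       adversarial = !grepl("A-", variant, fixed = TRUE))
}

#' Run the ablation suite
#'
#' Trains the full model and the requested toggled variants on identical
#' data, splits and seeds (the split fingerprint is asserted across
#' variants) and reports test metrics per (variant, seed).
#'
#' @param data a [simulate_corpus()] result (or list with the same fields).
#' @param config an [experiment_config()].
#' @param variants subset of [ablation_variants()] (default: all eight).
#' @param seeds integer vector of training seeds.
#' @param calibrate if `TRUE` (default) each trained variant's decision
#'   threshold is calibrated on the validation split with
#'   [calibrate_threshold()]; otherwise `config$theta` is used as is.
#' @param verbose print progress.
#' @return data.frame (variant, seed, theta, jaccard, f1, pr_auc,
#'   n_patients, n_visits), plus attribute `"loss_logs"` (per run) for
#'   loss-curve inspection.
#' @export
ablation_suite <- function(data, config = experiment_config(),
                           variants = ablation_variants(), seeds = 1L,
                           calibrate = TRUE, verbose = FALSE) {
  stopifnot(all(variants %in% ablation_variants()))
  out <- NULL
  logs <- list()
  pretrain_cache <- new.env(parent = emptyenv())
  for (seed in seeds) {
    splits <- split_patients(data$multi, config$split_ratio, seed = seed)
    fingerprint <- paste(vapply(splits$test, `[[`, character(1), "patient_id"),
                         collapse = ",")
    for (variant in variants) {
      fl <- variant_flags(variant)
      cfg <- config
      cfg$use_ontology <- fl$use_ontology
      cfg$use_pretraining <- fl$use_pretraining
      if (!fl$adversarial) cfg$eps <- 0
      cfg$seed <- seed
      splits_v <- split_patients(data$multi, config$split_ratio, seed = seed)
      fp_v <- paste(vapply(splits_v$test, `[[`, character(1), "patient_id"),
                    collapse = ",")
      stopifnot(identical(fp_v, fingerprint))  # identical data across variants
      run <- alternating_train(data$single, splits_v, data$ontologies, cfg,
                               verbose = FALSE,
                               pretrain_cache = pretrain_cache)
      theta <- if (calibrate) {
        as.numeric(calibrate_threshold(run$model, run$pred, splits_v$validation))
      } else cfg$theta
      rep <- evaluate_model(run$model, run$pred, splits_v$test, theta)
      out <- rbind(out, data.frame(variant = variant, seed = seed,
                                   theta = theta,
                                   jaccard = rep$jaccard, f1 = rep$f1,
                                   pr_auc = rep$pr_auc,
                                   n_patients = rep$n_patients,
                                   n_visits = rep$n_visits))
      logs[[paste0(variant, "@", seed)]] <- run$logs
      if (verbose) {
        message(sprintf("[ablate] %s seed %d: jaccard %.4f", variant, seed,
                        rep$jaccard))
      }
    }
  }
  rownames(out) <- NULL
  attr(out, "loss_logs") <- logs
  out
}
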