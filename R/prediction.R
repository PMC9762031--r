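#' Prediction head parameters
#'
#' A single transformation `y_t = sigmoid(W x_t + b)` over the concatenation
#' of five width-l blocks: the means over the previous visits of the
#' diagnosis, symptom and drug visit embeddings, plus the current visit's
#' diagnosis and symptom embeddings (current drugs are the target and never
#' enter the input). `W` therefore has `ML` rows (drug codes) and `5 l`
#' columns.
#'
#' @param l model width.
#' @param ML drug-code vocabulary size (code block only).
#' @param init_scale weight initialisation scale.
#' @return list with `W` (ML x 5l) and `b` (length ML).
#' @export
prediction_init <- function(l, ML, init_scale = 0.1) {
  list(W = matrix(stats::rnorm(ML * 5L * l, sd = sqrt(2 / (5 * l + ML))), ML, 5L * l),
       b = numeric(ML))
}

#' Average the visit embeddings of a patient's history
#'
#' Arithmetic means over visits `1..t-1`, per field.
#'
#' @param embeddings list of `visit_embedding` objects (all visits before
#'   the one being predicted; at least one).
#' @return list with vectors `v_d`, `v_s`, `v_m` (each length l).
#' @export
aggregate_history <- function(embeddings) {
  if (length(embeddings) < 1L) {
    stopf("prediction needs at least one prior visit (t >= 2)")
  }
  list(
    v_d = colMeans(do.call(rbind, lapply(embeddings, `[[`, "v_d"))),
    v_s = colMeans(do.call(rbind, lapply(embeddings, `[[`, "v_s"))),
    v_m = colMeans(do.call(rbind, lapply(embeddings, `[[`, "v_m")))
  )
}

#' Predict medication probabilities for the current visit
#'
#' @param history output of [aggregate_history()] over visits `1..t-1`.
#' @param v_d_t,v_s_t current visit's diagnosis and symptom embeddings.
#' @param pred a [prediction_init()] parameter list.
#' @return numeric vector of per-drug probabilities in (0,1), length ML.
#' @export
predict_medications <- function(history, v_d_t, v_s_t, pred) {
  x <- c(history$v_d, history$v_s, history$v_m, v_d_t, v_s_t)
  if (length(x) != ncol(pred$W)) {
    stopf("concatenated input length %d does not match W columns %d",
          length(x), ncol(pred$W))
  }
  sigmoid(drop(pred$W %*% x) + pred$b)
}

#' Threshold probabilities into a recommended drug set
#'
#' @param y probability vector (optionally named by drug code).
#' @param theta decision threshold in (0,1); default 0.3.
#' @param codes optional drug-code names for `y`.
#' @return character vector of recommended codes (may be empty); if no
#'   names are available, the selected indices.
#' @export
recommendation_set <- function(y, theta = 0.3, codes = names(y)) {
  stopifnot(theta > 0, theta < 1)
  sel <- which(y > theta)
  if (is.null(codes)) sel else codes[sel]
}

#' Multi-visit prediction loss
#'
#' Mean over visits `t = 2..T` of the multi-label binary cross entropy
#' between the predicted probabilities and the true drug multi-hot.
#' Prediction starts from the second visit: visit 1 is history only.
#'
#' @param y list (t = 2..T) of probability vectors.
#' @param truth list (t = 2..T) of 0/1 multi-hot vectors.
#' @return scalar loss, non-negative.
#' @export
prediction_loss <- function(y, truth) {
  if (length(y) < 1L) stopf("prediction loss needs T >= 2 (no visits to score)")
  stopifnot(length(y) == length(truth))
  per_t <- vapply(seq_along(y), function(i) {
    p <- pmin(pmax(y[[i]], 1e-12), 1 - 1e-12)
    -sum(truth[[i]] * log(p) + (1 - truth[[i]]) * log(1 - p))
  }, numeric(1))
  mean(per_t)
}

#' FGM adversarial perturbation
#'
#' `r_adv = sign * epsilon * g / ||g||_2`. The default `sign_factor = +1`
#' is the loss-ascent direction that makes the perturbation adversarial
#' (the formulation's stated intent); `sign_factor = -1` reproduces the
#' printed descent-direction variant. The zero gradient maps to the zero
#' perturbation.
#'
#' @param g gradient array.
#' @param eps perturbation magnitude, non-negative.
#' @param sign_factor `+1` (default, adversarial) or `-1` (as printed).
#' @return array of the same shape with L2 norm `eps` (or 0 if `g` is 0).
#' @export
fgm_perturbation <- function(g, eps, sign_factor = 1) {
  stopifnot(eps >= 0)
  nrm <- sqrt(sum(g^2))
  if (nrm == 0 || eps == 0) return(g * 0)
  sign_factor * eps * g / nrm
}

## ---- fine-tuning internals -------------------------------------------------

# Forward + backward of the recommendation loss over a batch of patients.
# `perturb` optionally disturbs the diagnosis/drug code-embedding tables
# (the FGM pass). Returns loss, gradient tree, and the gradients w.r.t. the
# two ontology-embedding code tables (needed to build the perturbation).
finetune_batch_pass <- function(model, pred, batch_toks, batch_targets,
                                batch_sizes, perturb = NULL, reuse = NULL) {
  params <- model$params
  l <- model$config$l
  if (is.null(reuse)) {
    tables <- model_tables(model, perturb = perturb)
  } else {
    # second (adversarial) pass: same parameters, so the ontology forward
    # pass and the symptom-field encoding are identical and can be reused
    tables <- reuse$tables
    tables$code_tables$d <- tables$code_tables$d + perturb$d
    tables$code_tables$m <- tables$code_tables$m + perturb$m
    tables$E$diagnosis <- rbind(params$spec_d, tables$code_tables$d)
    tables$E$drug <- rbind(params$spec_m, tables$code_tables$m)
  }
  toks_flat <- unlist(batch_toks, recursive = FALSE)
  if (is.null(reuse)) {
    fwd <- encode_batch(model, toks_flat, tables)
  } else {
    fwd <- encode_batch_fields(model, toks_flat, tables, c("diagnosis", "drug"))
    fwd$symptom <- reuse$fwd_symptom
  }
  Vd <- fwd$diagnosis$cls; Vm <- fwd$drug$cls; Vs <- fwd$symptom$cls

  nP <- length(batch_sizes)
  offs <- cumsum(c(0L, batch_sizes))
  n_ex <- sum(batch_sizes - 1L)
  X <- matrix(0, n_ex, 5L * l)
  Tm <- matrix(0, n_ex, length(pred$b))
  wex <- numeric(n_ex)
  ex_patient <- integer(n_ex); ex_t <- integer(n_ex)
  e <- 0L
  for (p in seq_len(nP)) {
    Tp <- batch_sizes[p]
    rows <- offs[p] + seq_len(Tp)
    for (t in 2L:Tp) {
      e <- e + 1L
      h <- rows[seq_len(t - 1L)]
      X[e, ] <- c(colMeans(Vd[h, , drop = FALSE]),
                  colMeans(Vs[h, , drop = FALSE]),
                  colMeans(Vm[h, , drop = FALSE]),
                  Vd[rows[t], ], Vs[rows[t], ])
      Tm[e, ] <- batch_targets[[p]][[t]]
      wex[e] <- 1 / ((Tp - 1L) * nP)
      ex_patient[e] <- p; ex_t[e] <- t
    }
  }

  Z <- X %*% t(pred$W) + matrix(pred$b, n_ex, length(pred$b), byrow = TRUE)
  loss <- sum(wex * rowSums(pmax(Z, 0) - Z * Tm + log1p(exp(-abs(Z)))))
  dZ <- (sigmoid(Z) - Tm) * wex
  gpred <- list(W = crossprod(dZ, X), b = colSums(dZ))
  dX <- dZ %*% pred$W

  dVd <- matrix(0, nrow(Vd), l); dVs <- matrix(0, nrow(Vs), l)
  dVm <- matrix(0, nrow(Vm), l)
  i1 <- seq_len(l); i2 <- l + i1; i3 <- 2L * l + i1; i4 <- 3L * l + i1; i5 <- 4L * l + i1
  for (e in seq_len(n_ex)) {
    p <- ex_patient[e]; t <- ex_t[e]
    rows <- offs[p] + seq_len(batch_sizes[p])
    h <- rows[seq_len(t - 1L)]
    dVd[h, ] <- dVd[h, ] + matrix(dX[e, i1] / (t - 1L), length(h), l, byrow = TRUE)
    dVs[h, ] <- dVs[h, ] + matrix(dX[e, i2] / (t - 1L), length(h), l, byrow = TRUE)
    dVm[h, ] <- dVm[h, ] + matrix(dX[e, i3] / (t - 1L), length(h), l, byrow = TRUE)
    dVd[rows[t], ] <- dVd[rows[t], ] + dX[e, i4]
    dVs[rows[t], ] <- dVs[rows[t], ] + dX[e, i5]
  }

  bk_d <- encoder_backward(params$enc_d, fwd$diagnosis, dVd)
  bk_m <- encoder_backward(params$enc_m, fwd$drug, dVm)
  bk_s <- encoder_backward(params$enc_s, fwd$symptom, dVs)

  grads <- list(enc_d = bk_d$grads, enc_m = bk_m$grads, enc_s = bk_s$grads)
  grads <- tree_add(grads, table_backward(model, params, tables, "diagnosis", bk_d$dE))
  grads <- tree_add(grads, table_backward(model, params, tables, "drug", bk_m$dE))
  grads <- tree_add(grads, table_backward(model, params, tables, "symptom", bk_s$dE))

  # gradients w.r.t. the code-embedding tables (input of the FGM disturbance)
  dtab_d <- bk_d$dE[-seq_len(4L), , drop = FALSE]
  dtab_m <- bk_m$dE[-seq_len(4L), , drop = FALSE]

  list(loss = loss, grads = grads, pred_grads = gpred,
       dtab = list(d = dtab_d, m = dtab_m),
       tables = tables, fwd_symptom = fwd$symptom)
}

#' One adversarial fine-tuning step
#'
#' (1) a normal forward/backward pass of the recommendation loss; (2) the
#' FGM disturbances for the diagnosis and drug ontology embeddings are built
#' from that pass's gradients; (3) a second forward/backward pass on the
#' disturbed embeddings; (4) the disturbance is discarded (the embedding
#' tables are restored untouched); (5) one Adam update on the combined
#' gradient (the mean of the two passes; with `eps = 0` the step is exactly
#' a plain step). With `eps = 0` the second pass is skipped.
#'
#' @param model a [visit_model()].
#' @param pred a [prediction_init()] head.
#' @param batch_toks list (per patient) of lists of tokenised visits.
#' @param batch_targets list (per patient) of lists of drug multi-hots.
#' @param batch_sizes integer vector of visit counts.
#' @param opt Adam state over `list(model, pred)`.
#' @param eps FGM magnitude.
#' @param fgm_sign `+1` (default) or `-1`.
#' @param diagnostics if `TRUE`, attach per-pass gradients, perturbations
#'   and before/after embedding tables (for contract checks).
#' @return list with updated `model_params`, `pred`, `opt`, `loss`,
#'   `adv_loss`, and (with `diagnostics`) `diag`.
#' @export
adversarial_step <- function(model, pred, batch_toks, batch_targets,
                             batch_sizes, opt, eps = 0.5, fgm_sign = 1,
                             diagnostics = FALSE) {
  pass1 <- finetune_batch_pass(model, pred, batch_toks, batch_targets, batch_sizes)
  if (!is.finite(pass1$loss)) stopf("fine-tuning diverged (non-finite loss)")
  tables_before <- pass1$tables$code_tables

  if (eps > 0) {
    r_d <- fgm_perturbation(pass1$dtab$d, eps, fgm_sign)
    r_m <- fgm_perturbation(pass1$dtab$m, eps, fgm_sign)
    pass2 <- finetune_batch_pass(model, pred, batch_toks, batch_targets,
                                 batch_sizes, perturb = list(d = r_d, m = r_m),
                                 reuse = list(tables = pass1$tables,
                                              fwd_symptom = pass1$fwd_symptom))
    if (!is.finite(pass2$loss)) stopf("adversarial pass diverged (non-finite loss)")
    grads <- tree_scale(tree_add(pass1$grads, pass2$grads), 0.5)
    gpred <- tree_scale(tree_add(pass1$pred_grads, pass2$pred_grads), 0.5)
    adv_loss <- pass2$loss
  } else {
    r_d <- pass1$dtab$d * 0; r_m <- pass1$dtab$m * 0
    grads <- pass1$grads
    gpred <- pass1$pred_grads
    adv_loss <- pass1$loss
  }

  all_params <- list(model = model$params, pred = pred)
  upd <- adam_step(all_params, list(model = grads, pred = gpred), opt)

  out <- list(model_params = upd$params$model, pred = upd$params$pred,
              opt = upd$state, loss = pass1$loss, adv_loss = adv_loss)
  if (diagnostics) {
    # the disturbance was applied to copies; the model's own parameters (and
    # hence the recomputed embedding tables) are bit-identical afterwards
    out$diag <- list(r_d = r_d, r_m = r_m,
                     grads_pass1 = pass1$grads,
                     pred_grads_pass1 = pass1$pred_grads,
                     grads_combined = grads,
                     tables_before = tables_before,
                     tables_after = model_tables(model)$code_tables)
  }
  out
}

# tokenise a history's visits and build its drug targets
prepare_history <- function(history, model) {
  toks <- lapply(history$visits, tokenize_visit,
                 vocabularies = model$vocabularies,
                 max_len = model$config$max_len)
  targets <- lapply(history$visits, function(v) {
    multi_hot(model$vocabularies$drug, v$drugs)
  })
  list(toks = toks, targets = targets, T = history$T)
}

# forward-only loss over a set of prepared histories
finetune_eval_loss <- function(model, pred, prepared, batch_patients = 16L) {
  tot <- 0
  n <- length(prepared)
  for (start in seq(1L, n, by = batch_patients)) {
    idx <- start:min(start + batch_patients - 1L, n)
    bt <- lapply(prepared[idx], `[[`, "toks")
    tg <- lapply(prepared[idx], `[[`, "targets")
    sz <- vapply(prepared[idx], `[[`, integer(1), "T")
    loss <- finetune_forward_loss(model, pred, bt, tg, sz)
    tot <- tot + loss * length(idx)
  }
  tot / n
}

# loss without backward (cheaper validation path)
finetune_forward_loss <- function(model, pred, batch_toks, batch_targets,
                                  batch_sizes) {
  l <- model$config$l
  tables <- model_tables(model)
  toks_flat <- unlist(batch_toks, recursive = FALSE)
  fwd <- encode_batch(model, toks_flat, tables)
  Vd <- fwd$diagnosis$cls; Vm <- fwd$drug$cls; Vs <- fwd$symptom$cls
  nP <- length(batch_sizes)
  offs <- cumsum(c(0L, batch_sizes))
  loss <- 0
  for (p in seq_len(nP)) {
    Tp <- batch_sizes[p]
    rows <- offs[p] + seq_len(Tp)
    lp <- 0
    for (t in 2L:Tp) {
      h <- rows[seq_len(t - 1L)]
      x <- c(colMeans(Vd[h, , drop = FALSE]), colMeans(Vs[h, , drop = FALSE]),
             colMeans(Vm[h, , drop = FALSE]), Vd[rows[t], ], Vs[rows[t], ])
      z <- drop(pred$W %*% x) + pred$b
      tm <- batch_targets[[p]][[t]]
      lp <- lp + sum(pmax(z, 0) - z * tm + log1p(exp(-abs(z))))
    }
    loss <- loss + lp / (Tp - 1L)
  }
  loss / nP
}

#' Fine-tune the recommendation model on multi-visit patients
#'
#' Epochs of [adversarial_step()] over shuffled patient minibatches. Each
#' patient contributes one training example per visit `t in 2..T`. The
#' per-epoch training and validation losses are logged and the parameters
#' with the best validation loss are returned.
#'
#' @param train,validation lists of [patient_history()] (e.g. from
#'   [split_patients()]).
#' @param model a [visit_model()] (typically pre-trained).
#' @param pred optional [prediction_init()] head (created if `NULL`).
#' @param epochs fine-tuning epochs (default 10).
#' @param batch_patients patients per minibatch (default 16).
#' @param lr Adam learning rate (default 5e-4).
#' @param eps FGM magnitude (default 0.5; 0 disables adversarial training).
#' @param fgm_sign `+1` (default) or `-1`.
#' @param seed integer seed.
#' @param opt optional optimiser state to continue from.
#' @param verbose print per-epoch losses.
#' @return list with `model`, `pred` (best-validation), `log` (epoch,
#'   train_loss, adv_loss, val_loss), `opt`, `final_model`, `final_pred`.
#' @export
fine_tune <- function(train, validation, model, pred = NULL, epochs = 10L,
                      batch_patients = 16L, lr = 5e-4, eps = 0.5,
                      fgm_sign = 1, seed = 1L, opt = NULL, verbose = FALSE) {
  if (length(train) == 0L) stopf("training set is empty")
  train <- Filter(function(h) h$T >= 2L, train)
  if (length(train) == 0L) stopf("no training patient has 2 or more visits")
  if (is.null(pred)) {
    pred <- with_seed(derive_seed(seed, "pred"),
                      prediction_init(model$config$l,
                                      model$vocabularies$drug$n_codes))
  }
  prep_train <- lapply(train, prepare_history, model = model)
  prep_val <- lapply(Filter(function(h) h$T >= 2L, validation),
                     prepare_history, model = model)
  if (is.null(opt)) {
    opt <- adam_init(list(model = model$params, pred = pred), lr = lr)
  }
  best <- list(val = Inf, model_params = model$params, pred = pred)
  log <- NULL
  set.seed(derive_seed(seed, "finetune"))
  n <- length(prep_train)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_adv <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_patients)) {
      idx <- ord[start:min(start + batch_patients - 1L, n)]
      bt <- lapply(prep_train[idx], `[[`, "toks")
      tg <- lapply(prep_train[idx], `[[`, "targets")
      sz <- vapply(prep_train[idx], `[[`, integer(1), "T")
      step <- adversarial_step(model, pred, bt, tg, sz, opt, eps, fgm_sign)
      model$params <- step$model_params; pred <- step$pred; opt <- step$opt
      ep_loss <- ep_loss + step$loss; ep_adv <- ep_adv + step$adv_loss
      nb <- nb + 1L
    }
    val_loss <- if (length(prep_val) > 0L) {
      finetune_eval_loss(model, pred, prep_val, batch_patients)
    } else ep_loss / nb
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                 adv_loss = ep_adv / nb, val_loss = val_loss))
    if (val_loss < best$val) {
      best <- list(val = val_loss, model_params = model$params, pred = pred)
    }
    if (verbose) {
      message(sprintf("finetune epoch %d: train %.4f val %.4f", ep,
                      ep_loss / nb, val_loss))
    }
  }
  best_model <- model; best_model$params <- best$model_params
  final_model <- model
  rownames(log) <- NULL
  list(model = best_model, pred = best$pred, log = log, opt = opt,
       final_model = final_model, final_pred = pred)
}

#' Per-visit drug probabilities for a patient history
#'
#' Applies the trained model to visits `t = 2..T` of one history.
#'
#' @param history a [patient_history()] with `T >= 2`.
#' @param model a trained [visit_model()].
#' @param pred a trained prediction head.
#' @return matrix ((T-1) x ML) of probabilities, rows named by visit index,
#'   columns by drug code.
#' @export
predict_history <- function(history, model, pred) {
  if (history$T < 2L) stopf("prediction needs at least two visits")
  prep <- prepare_history(history, model)
  tables <- model_tables(model)
  fwd <- encode_batch(model, prep$toks, tables)
  Vd <- fwd$diagnosis$cls; Vm <- fwd$drug$cls; Vs <- fwd$symptom$cls
  drug_codes <- model$vocabularies$drug$tokens[-seq_len(4L)]
  out <- matrix(0, history$T - 1L, length(drug_codes),
                dimnames = list(2:history$T, drug_codes))
  for (t in 2L:history$T) {
    h <- seq_len(t - 1L)
    x <- c(colMeans(Vd[h, , drop = FALSE]), colMeans(Vs[h, , drop = FALSE]),
           colMeans(Vm[h, , drop = FALSE]), Vd[t, ], Vs[t, ])
    out[t - 1L, ] <- sigmoid(drop(pred$W %*% x) + pred$b)
  }
  out
}
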