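#' Pre-training heads
#'
#' Six linear scoring maps with logistic outputs, one per (task, target
#' field): three self heads score a field's full code set from that field's
#' own visit embedding (the masked EMR-field task), and three cross heads
#' score a field's code set from *another* field's embedding (the
#' correlation task; the head for target field f is shared across both
#' source fields). Output dimension is the target vocabulary's code count
#' (special tokens excluded).
#'
#' @param l model width.
#' @param vocabularies output of [build_vocabularies()].
#' @param init_scale weight initialisation scale.
#' @return parameter tree with heads `self_d`, `self_m`, `self_s`,
#'   `cross_d`, `cross_m`, `cross_s`, each `list(W, b)` with `W` (l x V).
#' @export
pretrain_heads_init <- function(l, vocabularies, init_scale = 0.1) {
  mk <- function(V) list(W = matrix(stats::rnorm(l * V, sd = sqrt(2 / (l + V))), l, V),
                         b = numeric(V))
  Vd <- vocabularies$diagnosis$n_codes
  Vm <- vocabularies$drug$n_codes
  Vs <- vocabularies$symptom$n_codes
  list(self_d = mk(Vd), self_m = mk(Vm), self_s = mk(Vs),
       cross_d = mk(Vd), cross_m = mk(Vm), cross_s = mk(Vs))
}

## multi-label BCE with logits (numerically stable); loss summed over the
## vocabulary, averaged over the batch. Returns grads for head and source.
bce_head <- function(v, targets, head) {
  if (ncol(head$W) != ncol(targets)) {
    stopf("head output dimension %d does not match target dimension %d",
          ncol(head$W), ncol(targets))
  }
  B <- nrow(v)
  Z <- v %*% head$W + matrix(head$b, B, length(head$b), byrow = TRUE)
  # sum_j [ max(z,0) - z*t + log1p(exp(-|z|)) ]
  loss <- sum(pmax(Z, 0) - Z * targets + log1p(exp(-abs(Z)))) / B
  P <- sigmoid(Z)
  dZ <- (P - targets) / B
  list(loss = loss, dv = dZ %*% t(head$W),
       dW = crossprod(v, dZ), db = colSums(dZ), P = P)
}

#' Self-prediction loss (masked EMR-field task)
#'
#' Multi-label binary cross entropy between the scores produced from one
#' field's visit embedding and that field's full code multi-hot:
#' `-sum_{c present} log P(c|v) - sum_{c absent} log(1 - P(c|v))`,
#' averaged over the batch.
#'
#' @param v visit-embedding matrix (batch x l) or a single vector.
#' @param targets multi-hot matrix (batch x V) or vector.
#' @param head one head from [pretrain_heads_init()].
#' @return scalar loss (non-negative).
#' @export
self_prediction_loss <- function(v, targets, head) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  if (is.null(dim(targets))) targets <- matrix(targets, nrow = 1L)
  bce_head(v, targets, head)$loss
}

#' Correlation-prediction losses
#'
#' Cross-field mutual prediction: `L_dm` scores diagnoses from the drug
#' embedding plus drugs from the diagnosis embedding; `L_ds` and `L_ms`
#' analogously for the symptom pairings. Each term is the same multi-label
#' BCE as [self_prediction_loss()].
#'
#' @param v_d,v_m,v_s visit-embedding matrices (batch x l) from one batch.
#' @param targets list with multi-hot matrices `d`, `m`, `s`.
#' @param heads output of [pretrain_heads_init()].
#' @return named numeric vector `c(L_dm, L_ds, L_ms)`.
#' @export
correlation_loss <- function(v_d, v_m, v_s, targets, heads) {
  as1 <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1L) else x
  v_d <- as1(v_d); v_m <- as1(v_m); v_s <- as1(v_s)
  targets <- lapply(targets, as1)
  c(L_dm = bce_head(v_m, targets$d, heads$cross_d)$loss +
      bce_head(v_d, targets$m, heads$cross_m)$loss,
    L_ds = bce_head(v_s, targets$d, heads$cross_d)$loss +
      bce_head(v_d, targets$s, heads$cross_s)$loss,
    L_ms = bce_head(v_s, targets$m, heads$cross_m)$loss +
      bce_head(v_m, targets$s, heads$cross_s)$loss)
}

#' Combined pre-training loss
#'
#' Unweighted sum of the three self-prediction losses and the three
#' correlation losses.
#'
#' @param components numeric vector of the six component losses.
#' @return scalar.
#' @export
pretrain_loss <- function(components) {
  stopifnot(length(components) == 6L)
  sum(components)
}

#' Randomly mask a tokenised visit
#'
#' Each non-special code token is masked (replaced by `[MASK]`) independently
#' with probability `mask_rate`; if a non-empty field ends up with no masked
#' token, one is masked anyway (floor rule), so every non-empty field always
#' contributes a masked prediction. Targets (the full code multi-hot per
#' field) are unaffected by masking.
#'
#' @param tokenized output of [tokenize_visit()].
#' @param vocabularies the matching vocabularies.
#' @param mask_rate probability in `[0,1]` (default 0.15).
#' @return list per field: masked `tokens`, `valid`, logical `mask_pos`,
#'   `original` tokens, and `target` multi-hot over the field's code block.
#' @export
mask_visit <- function(tokenized, vocabularies, mask_rate = 0.15) {
  stopifnot(mask_rate >= 0, mask_rate <= 1)
  out <- lapply(c(diagnosis = "diagnosis", drug = "drug", symptom = "symptom"),
                function(f) {
    tk <- tokenized[[f]]
    vb <- vocabularies[[f]]
    mask_id <- match("[MASK]", vb$tokens)
    n_special <- vb$n_special
    is_code <- tk$valid == 1L & tk$tokens > n_special
    mask_pos <- is_code & stats::runif(length(tk$tokens)) < mask_rate
    if (any(is_code) && !any(mask_pos)) {
      mask_pos[resample(which(is_code), 1L)] <- TRUE
    }
    tokens <- tk$tokens
    tokens[mask_pos] <- mask_id
    target <- numeric(vb$n_codes)
    target[tk$tokens[is_code] - n_special] <- 1
    list(tokens = tokens, valid = tk$valid, mask_pos = mask_pos,
         original = tk$tokens, target = target)
  })
  out
}

## one pre-training forward/backward over a batch of masked visits;
## returns loss components and the full gradient tree
pretrain_batch_pass <- function(model, heads, masked) {
  params <- model$params
  tables <- model_tables(model)
  fwd <- encode_batch(model, masked, tables)
  v_d <- fwd$diagnosis$cls; v_m <- fwd$drug$cls; v_s <- fwd$symptom$cls
  Td <- do.call(rbind, lapply(masked, function(x) x$diagnosis$target))
  Tm <- do.call(rbind, lapply(masked, function(x) x$drug$target))
  Ts <- do.call(rbind, lapply(masked, function(x) x$symptom$target))

  h_sd <- bce_head(v_d, Td, heads$self_d)
  h_sm <- bce_head(v_m, Tm, heads$self_m)
  h_ss <- bce_head(v_s, Ts, heads$self_s)
  h_md <- bce_head(v_m, Td, heads$cross_d)   # d targets from v_m
  h_dm <- bce_head(v_d, Tm, heads$cross_m)   # m targets from v_d
  h_sd2 <- bce_head(v_s, Td, heads$cross_d)  # d targets from v_s
  h_ds <- bce_head(v_d, Ts, heads$cross_s)   # s targets from v_d
  h_sm2 <- bce_head(v_s, Tm, heads$cross_m)  # m targets from v_s
  h_ms <- bce_head(v_m, Ts, heads$cross_s)   # s targets from v_m

  components <- c(L_s_d = h_sd$loss, L_s_m = h_sm$loss, L_s_s = h_ss$loss,
                  L_dm = h_md$loss + h_dm$loss,
                  L_ds = h_sd2$loss + h_ds$loss,
                  L_ms = h_sm2$loss + h_ms$loss)

  dv_d <- h_sd$dv + h_dm$dv + h_ds$dv
  dv_m <- h_sm$dv + h_md$dv + h_ms$dv
  dv_s <- h_ss$dv + h_sd2$dv + h_sm2$dv

  bk_d <- encoder_backward(params$enc_d, fwd$diagnosis, dv_d)
  bk_m <- encoder_backward(params$enc_m, fwd$drug, dv_m)
  bk_s <- encoder_backward(params$enc_s, fwd$symptom, dv_s)

  grads <- list(
    enc_d = bk_d$grads, enc_m = bk_m$grads, enc_s = bk_s$grads
  )
  grads <- tree_add(grads, table_backward(model, params, tables, "diagnosis", bk_d$dE))
  grads <- tree_add(grads, table_backward(model, params, tables, "drug", bk_m$dE))
  grads <- tree_add(grads, table_backward(model, params, tables, "symptom", bk_s$dE))

  head_grads <- list(
    self_d = list(W = h_sd$dW, b = h_sd$db),
    self_m = list(W = h_sm$dW, b = h_sm$db),
    self_s = list(W = h_ss$dW, b = h_ss$db),
    cross_d = list(W = h_md$dW + h_sd2$dW, b = h_md$db + h_sd2$db),
    cross_m = list(W = h_dm$dW + h_sm2$dW, b = h_dm$db + h_sm2$db),
    cross_s = list(W = h_ds$dW + h_ms$dW, b = h_ds$db + h_ms$db)
  )
  list(components = components, loss = pretrain_loss(components),
       grads = grads, head_grads = head_grads)
}

# loss-only evaluation (no masking rng consumed outside; caller masks)
pretrain_eval_loss <- function(model, heads, masked_list, batch_size = 64L) {
  n <- length(masked_list)
  tot <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    tables <- model_tables(model)
    fwd <- encode_batch(model, masked_list[idx], tables)
    v_d <- fwd$diagnosis$cls; v_m <- fwd$drug$cls; v_s <- fwd$symptom$cls
    Td <- do.call(rbind, lapply(masked_list[idx], function(x) x$diagnosis$target))
    Tm <- do.call(rbind, lapply(masked_list[idx], function(x) x$drug$target))
    Ts <- do.call(rbind, lapply(masked_list[idx], function(x) x$symptom$target))
    comp <- c(bce_head(v_d, Td, heads$self_d)$loss,
              bce_head(v_m, Tm, heads$self_m)$loss,
              bce_head(v_s, Ts, heads$self_s)$loss,
              bce_head(v_m, Td, heads$cross_d)$loss +
                bce_head(v_d, Tm, heads$cross_m)$loss,
              bce_head(v_s, Td, heads$cross_d)$loss +
                bce_head(v_d, Ts, heads$cross_s)$loss,
              bce_head(v_s, Tm, heads$cross_m)$loss +
                bce_head(v_m, Ts, heads$cross_s)$loss)
    tot <- tot + sum(comp) * length(idx)
  }
  tot / n
}

#' Pre-train the visit model on a single-visit corpus
#'
#' Epochs of masked-batch optimisation of the combined loss (three
#' self-prediction components plus three correlation components) with Adam.
#' A held-out fraction of the corpus is used as a validation set; the
#' parameters with the best validation loss are returned. Deterministic
#' given `seed`.
#'
#' @param corpus list of [visit_record()]s (single-visit pool).
#' @param model a [visit_model()]; its vocabularies must cover the corpus.
#' @param heads optional [pretrain_heads_init()] tree (created if `NULL`).
#' @param epochs number of epochs (default 5).
#' @param batch_size minibatch size (default 64).
#' @param lr Adam learning rate (default 5e-4).
#' @param mask_rate masking probability (default 0.15).
#' @param val_fraction held-out fraction for validation (default 0.1).
#' @param seed integer seed.
#' @param opt optional pre-existing optimiser state (to continue training
#'   across alternation cycles).
#' @param verbose print per-epoch losses.
#' @return list with `model` (best-validation parameters), `heads`, `log`
#'   (data.frame: epoch, the six components, L_pr, val_L_pr), `opt`, and
#'   `final_model`/`final_heads` (last-epoch state, used when alternating).
#' @export
run_pretraining <- function(corpus, model, heads = NULL, epochs = 5L,
                            batch_size = 64L, lr = 5e-4, mask_rate = 0.15,
                            val_fraction = 0.1, seed = 1L, opt = NULL,
                            verbose = FALSE) {
  if (length(corpus) == 0L) stopf("pre-training corpus is empty")
  if (is.null(heads)) {
    heads <- with_seed(derive_seed(seed, "heads"),
                       pretrain_heads_init(model$config$l, model$vocabularies))
  }
  toks <- lapply(corpus, tokenize_visit, vocabularies = model$vocabularies,
                 max_len = model$config$max_len)
  n <- length(toks)
  n_val <- max(1L, floor(n * val_fraction))
  val_idx <- with_seed(derive_seed(seed, "valsplit"), sample.int(n, n_val))
  train_idx <- setdiff(seq_len(n), val_idx)
  # fixed validation masking so the validation loss is comparable across epochs
  val_masked <- with_seed(derive_seed(seed, "valmask"),
                          lapply(toks[val_idx], mask_visit,
                                 vocabularies = model$vocabularies,
                                 mask_rate = mask_rate))

  all_params <- list(model = model$params, heads = heads)
  if (is.null(opt)) opt <- adam_init(all_params, lr = lr)
  best <- list(val = Inf, params = all_params)
  log <- NULL
  # length-bucketed batching: visits of similar drug-sequence length share a
  # batch so little compute goes to padding; ties and batch order stay
  # randomly shuffled per epoch
  drug_len <- vapply(toks, function(tk) sum(tk$drug$valid), integer(1))
  set.seed(derive_seed(seed, "pretrain"))
  for (ep in seq_len(epochs)) {
    ord <- resample(train_idx, length(train_idx))
    ord <- ord[order(drug_len[ord])]
    starts <- seq(1L, length(ord), by = batch_size)
    comp_sum <- numeric(6L); nb <- 0L
    for (start in resample(starts, length(starts))) {
      idx <- ord[start:min(start + batch_size - 1L, length(ord))]
      masked <- lapply(toks[idx], mask_visit,
                       vocabularies = model$vocabularies, mask_rate = mask_rate)
      model$params <- all_params$model
      pass <- pretrain_batch_pass(model, all_params$heads, masked)
      if (!is.finite(pass$loss)) {
        stopf("pre-training diverged (non-finite loss) at epoch %d", ep)
      }
      grads <- list(model = pass$grads, heads = pass$head_grads)
      upd <- adam_step(all_params, grads, opt)
      all_params <- upd$params; opt <- upd$state
      comp_sum <- comp_sum + pass$components; nb <- nb + 1L
    }
    model$params <- all_params$model
    val_lpr <- pretrain_eval_loss(model, all_params$heads, val_masked, batch_size)
    comp <- comp_sum / nb
    log <- rbind(log, data.frame(
      epoch = ep, L_s_d = comp[1L], L_s_m = comp[2L], L_s_s = comp[3L],
      L_dm = comp[4L], L_ds = comp[5L], L_ms = comp[6L],
      L_pr = sum(comp), val_L_pr = val_lpr))
    if (val_lpr < best$val) best <- list(val = val_lpr, params = all_params)
    if (verbose) {
      message(sprintf("pretrain epoch %d: L_pr %.4f (val %.4f)", ep, sum(comp), val_lpr))
    }
  }
  best_model <- model; best_model$params <- best$params$model
  final_model <- model; final_model$params <- all_params$model
  rownames(log) <- NULL
  list(model = best_model, heads = best$params$heads, log = log, opt = opt,
       final_model = final_model, final_heads = all_params$heads)
}
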