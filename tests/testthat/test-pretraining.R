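test_that("masking replaces code tokens and leaves targets untouched", {
  vocabs <- small_vocabs()
  d <- small_data()
  v <- d$single[[1L]]
  tk <- tokenize_visit(v, vocabs, c(diagnosis = 8L, drug = 16L, symptom = 4L))
  set.seed(1)
  full <- mask_visit(tk, vocabs, mask_rate = 1)
  code_pos <- tk$drug$valid == 1L & tk$drug$tokens > 4L
  expect_true(all(full$drug$tokens[code_pos] == 3L))  # [MASK]
  # targets cover the tokenised codes (the sequence cap truncates the rest)
  expect_identical(sum(full$drug$target),
                   as.numeric(min(length(intersect(v$drugs, vocabs$drug$tokens)),
                                  15L)))
  # floor rule: rate 0 still masks one token of a non-empty field
  none <- mask_visit(tk, vocabs, mask_rate = 0)
  expect_identical(sum(none$drug$mask_pos), 1L)
  expect_identical(none$drug$target, full$drug$target)
  # masking never alters validity or the [CLS] slot
  expect_identical(full$drug$valid, tk$drug$valid)
  expect_identical(full$drug$tokens[1L], 2L)
})

test_that("empirical mask fraction matches the rate", {
  vocabs <- small_vocabs()
  d <- small_data()
  toks <- lapply(d$single, tokenize_visit, vocabularies = vocabs,
                 max_len = c(diagnosis = 8L, drug = 24L, symptom = 4L))
  set.seed(2)
  masked <- 0L; total <- 0L
  for (tk in toks) {
    mk <- mask_visit(tk, vocabs, mask_rate = 0.15)
    # long fields only, where the at-least-one floor rule is a negligible
    # upward bias (< 0.012 at 12 codes)
    for (f in c("diagnosis", "drug")) {
      n_codes <- sum(tk[[f]]$valid == 1L & tk[[f]]$tokens > 4L)
      if (n_codes >= 12L) {
        masked <- masked + sum(mk[[f]]$mask_pos)
        total <- total + n_codes
      }
    }
  }
  expect_gt(total, 2000L)
  expect_lt(abs(masked / total - 0.15), 0.02)
})

test_that("self-prediction loss has its closed forms and loop oracle", {
  # all-0.5 probabilities: vocab 4, any targets -> 4 log 2
  head0 <- list(W = matrix(0, 3L, 4L), b = numeric(4L))
  v <- rnorm(3L)
  expect_equal(self_prediction_loss(v, c(1, 1, 0, 0), head0), 4 * log(2),
               tolerance = 1e-12)
  # perfect prediction limit -> 0
  head_perfect <- list(W = matrix(0, 1L, 2L), b = c(50, -50))
  expect_equal(self_prediction_loss(0, c(1, 0), head_perfect), 0, tolerance = 1e-12)
  expect_error(self_prediction_loss(v, c(1, 0), head0), "dimension")
  # element-wise loop oracle on random inputs
  set.seed(3)
  for (rep in 1:30) {
    l <- sample(2:5, 1L); V <- sample(2:6, 1L); B <- sample(1:3, 1L)
    head <- list(W = matrix(rnorm(l * V), l, V), b = rnorm(V))
    vm <- matrix(rnorm(B * l), B, l)
    tg <- matrix(rbinom(B * V, 1, 0.4), B, V)
    got <- self_prediction_loss(vm, tg, head)
    oracle <- 0
    for (b in seq_len(B)) for (j in seq_len(V)) {
      p <- 1 / (1 + exp(-(sum(vm[b, ] * head$W[, j]) + head$b[j])))
      oracle <- oracle - (tg[b, j] * log(p) + (1 - tg[b, j]) * log(1 - p))
    }
    expect_equal(got, oracle / B, tolerance = 1e-6)
    expect_gte(got, 0)
  }
})

test_that("correlation losses pair cross-heads symmetrically", {
  set.seed(4)
  l <- 4L
  heads <- pretrain_heads_init(l, list(
    diagnosis = vocabulary(c("A00.0", "A00.1")),
    drug = vocabulary(c("86111111111111", "86111111111112")),
    symptom = vocabulary("fever")
  ))
  targets <- list(d = c(1, 0), m = c(0, 1), s = 1)
  v <- rnorm(l)
  # identical embeddings + shared heads + identical d/m targets:
  # the two summands of L_dm coincide, so L_dm = 2 * one term
  heads_sym <- heads
  heads_sym$cross_d <- heads$cross_m
  t_sym <- list(d = c(1, 0), m = c(1, 0), s = 1)
  out <- correlation_loss(v, v, v, t_sym, heads_sym)
  one_term <- self_prediction_loss(v, t_sym$d, heads_sym$cross_d)
  expect_equal(unname(out["L_dm"]), 2 * one_term, tolerance = 1e-9)
  # perfect cross-heads give zero loss
  perfect <- function(tg) list(W = matrix(0, l, length(tg)),
                               b = ifelse(tg == 1, 50, -50))
  heads_p <- list(cross_d = perfect(targets$d), cross_m = perfect(targets$m),
                  cross_s = perfect(targets$s))
  out_p <- correlation_loss(v, v, v, targets, heads_p)
  expect_equal(unname(out_p), c(0, 0, 0), tolerance = 1e-10)
  # loop-oracle equivalence
  for (rep in 1:20) {
    vd <- rnorm(l); vm <- rnorm(l); vs <- rnorm(l)
    tg <- list(d = rbinom(2, 1, 0.5), m = rbinom(2, 1, 0.5), s = rbinom(1, 1, 0.5))
    got <- correlation_loss(vd, vm, vs, tg, heads)
    expect_equal(unname(got["L_dm"]),
                 self_prediction_loss(vm, tg$d, heads$cross_d) +
                   self_prediction_loss(vd, tg$m, heads$cross_m),
                 tolerance = 1e-6)
    expect_equal(unname(got["L_ms"]),
                 self_prediction_loss(vs, tg$m, heads$cross_m) +
                   self_prediction_loss(vm, tg$s, heads$cross_s),
                 tolerance = 1e-6)
  }
})

test_that("the combined objective is the plain sum of its six components", {
  expect_identical(pretrain_loss(rep(0, 6)), 0)
  expect_identical(pretrain_loss(rep(1, 6)), 6)
  set.seed(5)
  x <- runif(6)
  expect_equal(pretrain_loss(x), sum(x))
  expect_error(pretrain_loss(1:5))
})

test_that("pre-training reduces the loss and is reproducible", {
  fit <- small_pretrained()
  expect_lt(tail(fit$log$L_pr, 1L), fit$log$L_pr[1L])
  expect_true(all(is.finite(fit$log$L_pr)))
  expect_identical(names(fit$log),
                   c("epoch", "L_s_d", "L_s_m", "L_s_s", "L_dm", "L_ds",
                     "L_ms", "L_pr", "val_L_pr"))
  # same seed, same log
  d <- small_data()
  again <- run_pretraining(d$single, small_model(l = 16L, seed = 3L),
                           epochs = 2L, batch_size = 32L, lr = 2e-3, seed = 3L)
  expect_identical(again$log, fit$log[1:2, ])
})

test_that("masked-code recovery beats the frequency baseline after pre-training", {
  fit <- small_pretrained()
  model <- fit$model; heads <- fit$heads
  d <- small_data()
  vocabs <- model$vocabularies
  # top-k (k = field size) recovery of the drug field from the masked
  # visit embedding, on a slice of the corpus, against a frequency ranker
  toks <- lapply(d$single[251:300], tokenize_visit, vocabularies = vocabs,
                 max_len = model$config$max_len)
  set.seed(6)
  masked <- lapply(toks, mask_visit, vocabularies = vocabs, mask_rate = 0.15)
  tables <- rxrec:::model_tables(model)
  fwd <- rxrec:::encode_batch(model, masked, tables)
  P <- rxrec:::bce_head(fwd$drug$cls,
                        do.call(rbind, lapply(masked, function(x) x$drug$target)),
                        heads$self_m)$P
  freq <- Reduce(`+`, lapply(d$single[1:250], function(v) {
    rxrec:::multi_hot(vocabs$drug, v$drugs)
  })) / 250
  hit <- function(scores, i) {
    truth <- which(masked[[i]]$drug$target == 1)
    k <- length(truth)
    if (k == 0L) return(NA_real_)
    mean(order(scores, decreasing = TRUE)[seq_len(k)] %in% truth)
  }
  hits_model <- mean(vapply(seq_along(masked), function(i) hit(P[i, ], i),
                            numeric(1)), na.rm = TRUE)
  hits_freq <- mean(vapply(seq_along(masked), function(i) hit(freq, i),
                           numeric(1)), na.rm = TRUE)
  expect_gt(hits_model, hits_freq)
})
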