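mk_emb <- function(l, seed) {
  set.seed(seed)
  structure(list(v_d = rnorm(l), v_m = rnorm(l), v_s = rnorm(l)),
            class = "visit_embedding")
}

test_that("history aggregation is the arithmetic mean per field", {
  e1 <- mk_emb(6L, 1); e2 <- mk_emb(6L, 2); e3 <- mk_emb(6L, 3)
  # t = 2: the mean of one visit is that visit
  expect_identical(aggregate_history(list(e1)),
                   list(v_d = e1$v_d, v_s = e1$v_s, v_m = e1$v_m))
  # identical embeddings average to themselves
  same <- aggregate_history(list(e1, e1, e1))
  expect_equal(same$v_m, e1$v_m)
  # loop oracle on random histories
  agg <- aggregate_history(list(e1, e2, e3))
  expect_equal(agg$v_d, (e1$v_d + e2$v_d + e3$v_d) / 3, tolerance = 1e-12)
  expect_equal(agg$v_s, (e1$v_s + e2$v_s + e3$v_s) / 3, tolerance = 1e-12)
  expect_error(aggregate_history(list()), "t >= 2")
})

test_that("predict_medications applies the five-block logistic map", {
  l <- 2L; ML <- 2L
  zero <- list(W = matrix(0, ML, 5L * l), b = numeric(ML))
  hist <- list(v_d = rnorm(l), v_s = rnorm(l), v_m = rnorm(l))
  y <- predict_medications(hist, rnorm(l), rnorm(l), zero)
  expect_equal(y, c(0.5, 0.5))
  expect_length(y, ML)
  # hand-computed toy: W picks single coordinates
  W <- matrix(0, 2L, 10L); W[1L, 1L] <- 2; W[2L, 7L] <- -1; b <- c(0.5, 0)
  hist2 <- list(v_d = c(1, 0), v_s = c(0, 0), v_m = c(0, 0))
  v_d_t <- c(3, 0); v_s_t <- c(0, 0)
  y2 <- predict_medications(hist2, v_d_t, v_s_t, list(W = W, b = b))
  expect_equal(y2, c(plogis(2 * 1 + 0.5), plogis(-3)), tolerance = 1e-12)
  expect_error(predict_medications(hist2, rnorm(3L), v_s_t, list(W = W, b = b)),
               "match")
})

test_that("recommendation sets threshold and shrink monotonically", {
  y <- c(a = 0.9, b = 0.1)
  expect_identical(recommendation_set(y, 0.5), "a")
  expect_identical(recommendation_set(c(0.2, 0.1), 0.5), integer(0))
  # the 30% convention recommends anything above 0.3
  expect_setequal(recommendation_set(c(a = 0.35, b = 0.25, c = 0.95), 0.3),
                  c("a", "c"))
  set.seed(7)
  for (rep in 1:20) {
    y <- runif(30)
    sizes <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th) {
      length(recommendation_set(y, th))
    }, numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
  expect_error(recommendation_set(y, 0))
})

test_that("prediction loss matches closed forms and a loop oracle", {
  # perfect probabilities -> 0 (clipped logs stay finite)
  truth <- list(c(1, 0, 1, 0), c(0, 0, 1, 1))
  expect_equal(prediction_loss(truth, truth), 0, tolerance = 1e-9)
  # uniform 0.5: ML log 2 per visit
  half <- lapply(truth, function(x) rep(0.5, 4L))
  expect_equal(prediction_loss(half, truth), 4 * log(2), tolerance = 1e-12)
  expect_error(prediction_loss(list(), list()), "T >= 2")
  set.seed(8)
  for (rep in 1:30) {
    Tn <- sample(2:5, 1L); ML <- sample(3:6, 1L)
    y <- lapply(seq_len(Tn - 1L), function(i) runif(ML, 0.01, 0.99))
    tg <- lapply(seq_len(Tn - 1L), function(i) rbinom(ML, 1, 0.4))
    got <- prediction_loss(y, tg)
    oracle <- 0
    for (t in seq_along(y)) for (j in seq_len(ML)) {
      oracle <- oracle - (tg[[t]][j] * log(y[[t]][j]) +
                            (1 - tg[[t]][j]) * log(1 - y[[t]][j]))
    }
    expect_equal(got, oracle / (Tn - 1L), tolerance = 1e-6)
  }
})

test_that("FGM perturbations have norm eps and handle degenerate input", {
  r <- fgm_perturbation(c(3, 4), 1, sign_factor = -1)
  expect_equal(r, c(-0.6, -0.8))
  expect_equal(sqrt(sum(r^2)), 1, tolerance = 1e-12)
  expect_identical(fgm_perturbation(c(3, 4), 0), c(0, 0))
  expect_identical(fgm_perturbation(c(0, 0), 1), c(0, 0))
  # ascent default: along +g
  expect_equal(fgm_perturbation(c(3, 4), 2), c(1.2, 1.6))
  set.seed(9)
  for (rep in 1:100) {
    g <- matrix(rnorm(2L * sample(2:20, 1L)), nrow = 2L)
    eps <- runif(1, 0.1, 5)
    expect_equal(sqrt(sum(fgm_perturbation(g, eps)^2)), eps, tolerance = 1e-6)
  }
})

test_that("an eps = 0 adversarial step equals a plain gradient step", {
  fx <- mini_ft()
  opt <- adam_init(list(model = fx$m$params, pred = fx$pred), lr = 5e-4)
  step <- adversarial_step(fx$m, fx$pred, fx$bt, fx$tg, fx$sz, opt, eps = 0,
                           diagnostics = TRUE)
  # plain step computed independently from one forward/backward pass
  pass <- rxrec:::finetune_batch_pass(fx$m, fx$pred, fx$bt, fx$tg, fx$sz)
  upd <- adam_step(list(model = fx$m$params, pred = fx$pred),
                   list(model = pass$grads, pred = pass$pred_grads), opt)
  expect_tree_equal(step$model_params, upd$params$model, tol = 1e-7)
  expect_tree_equal(step$pred, upd$params$pred, tol = 1e-7)
  expect_identical(step$loss, pass$loss)
})

test_that("adversarial steps restore embeddings bit-exactly", {
  fx <- mini_ft()
  opt <- adam_init(list(model = fx$m$params, pred = fx$pred), lr = 5e-4)
  step <- adversarial_step(fx$m, fx$pred, fx$bt, fx$tg, fx$sz, opt, eps = 1,
                           diagnostics = TRUE)
  expect_identical(step$diag$tables_before, step$diag$tables_after)
  expect_equal(sqrt(sum(step$diag$r_d^2)), 1, tolerance = 1e-6)
  expect_equal(sqrt(sum(step$diag$r_m^2)), 1, tolerance = 1e-6)
})

test_that("the accumulated gradient combines the two passes as documented", {
  fx <- mini_ft()
  opt <- adam_init(list(model = fx$m$params, pred = fx$pred), lr = 5e-4)
  step <- adversarial_step(fx$m, fx$pred, fx$bt, fx$tg, fx$sz, opt, eps = 0.5,
                           diagnostics = TRUE)
  # recompute the disturbed pass independently from the returned perturbation
  pass2 <- rxrec:::finetune_batch_pass(fx$m, fx$pred, fx$bt, fx$tg, fx$sz,
                                       perturb = list(d = step$diag$r_d,
                                                      m = step$diag$r_m))
  expected <- rxrec:::tree_scale(
    rxrec:::tree_add(step$diag$grads_pass1, pass2$grads), 0.5)
  expect_tree_equal(step$diag$grads_combined, expected, tol = 1e-12)
})

test_that("fine-tuning descends and is seed-reproducible", {
  d <- small_data()
  fit <- small_pretrained()
  splits <- split_patients(d$multi, seed = 2L)
  ft <- fine_tune(splits$train, splits$validation, fit$model, epochs = 4L,
                  batch_patients = 8L, eps = 1, seed = 4L)
  expect_lt(ft$log$train_loss[4L], ft$log$train_loss[1L])
  expect_true(all(is.finite(ft$log$val_loss)))
  ft2 <- fine_tune(splits$train, splits$validation, fit$model, epochs = 4L,
                   batch_patients = 8L, eps = 1, seed = 4L)
  expect_identical(ft$log, ft2$log)
  expect_error(fine_tune(list(), splits$validation, fit$model), "empty")
  # prediction surface: per-visit probability matrix over the drug vocabulary
  h <- Filter(function(h) h$T >= 2L, splits$test)[[1L]]
  P <- predict_history(h, ft$model, ft$pred)
  expect_identical(dim(P), c(h$T - 1L, ft$model$vocabularies$drug$n_codes))
  expect_true(all(P > 0 & P < 1))
})
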