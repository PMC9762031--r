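# Internal numeric helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == as.integer(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# sample() that never falls into the 1:x trap on length-1 numeric input
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# Derive a reproducible child seed from a base seed and a string tag.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## ---- parameter trees -------------------------------------------------------
## Model parameters are nested named lists whose leaves are numeric arrays.
## Gradients mirror the same structure. The helpers below walk both trees.

# elementwise combine two parameter trees (same shape)
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- tree_map2(a[[nm]], b[[nm]], f)
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- tree_map(a[[nm]], f)
    out
  } else {
    f(a)
  }
}

# sum of two gradient trees; b may omit branches (treated as zero)
tree_add <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.null(a)) return(b)
  if (is.list(a)) {
    out <- a
    for (nm in names(b)) out[[nm]] <- tree_add(a[[nm]], b[[nm]])
    out
  } else {
    a + b
  }
}

tree_zeros_like <- function(a) tree_map(a, function(x) x * 0)

tree_scale <- function(a, s) tree_map(a, function(x) x * s)

# largest absolute difference between two trees (used in tests and
# restoration checks)
tree_max_abs_diff <- function(a, b) {
  if (is.list(a)) {
    m <- 0
    for (nm in names(a)) m <- max(m, tree_max_abs_diff(a[[nm]], b[[nm]]))
    m
  } else {
    if (length(a) == 0L) 0 else max(abs(a - b))
  }
}

## ---- Adam optimiser --------------------------------------------------------

#' Create an Adam optimiser state for a parameter tree
#'
#' Standard adaptive-moment estimation. State tensors mirror the parameter
#' tree; `adam_step()` returns both the updated parameters and the advanced
#' state so that training loops stay purely functional (which is what makes
#' checkpoint round-trips and determinism checks exact).
#'
#' @param params nested named list of numeric arrays.
#' @param lr learning rate (the fine-tuning default elsewhere is 5e-4).
#' @param beta1,beta2,eps Adam moment decays and stabiliser.
#' @return an opaque optimiser-state list.
#' @keywords internal
adam_init <- function(params, lr = 5e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    m = tree_zeros_like(params),
    v = tree_zeros_like(params)
  )
}

adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) state$beta1 * m + (1 - state$beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) state$beta2 * v + (1 - state$beta2) * g^2)
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v) {
    state$lr * (m / bc1) / (sqrt(v / bc2) + state$eps)
  })
  params <- tree_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}
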