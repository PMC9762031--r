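#' Medical code ontologies
#'
#' A `code_ontology` is a rooted tree whose leaves are the observable medical
#' codes: ICD-10-style diagnosis codes (e.g. `"J98.4"` under the category
#' `"J98"` under its chapter) or 14-digit NDC-style drug codes whose label is
#' segmented country(2)/category(1)/enterprise(5)/product(5)/final(1), with an
#' internal node at every segment boundary. Internal nodes carry the shared
#' classification knowledge that the graph-attention embedding injects into
#' each leaf code.
#'
#' @param labels character vector of node labels (unique).
#' @param parent integer vector; `parent[i]` is the index of node `i`'s parent,
#'   `NA` for the root.
#' @param kind `"diagnosis"` or `"drug"`.
#' @return an object of class `code_ontology` with fields `labels`, `parent`,
#'   `leaves` (integer indices), `kind`, `root`.
#' @export
code_ontology <- function(labels, parent, kind = c("diagnosis", "drug")) {
  kind <- match.arg(kind)
  labels <- as.character(labels)
  parent <- as.integer(parent)
  if (anyDuplicated(labels)) stopf("ontology labels must be unique")
  if (length(labels) != length(parent)) stopf("labels/parent length mismatch")
  root <- which(is.na(parent))
  if (length(root) != 1L) stopf("ontology must have exactly one root")
  n <- length(labels)
  # acyclicity + reachability: walk each node to the root
  for (i in seq_len(n)) {
    seen <- integer(0)
    j <- i
    while (!is.na(parent[j])) {
      if (j %in% seen) stopf("cycle detected in ontology at node '%s'", labels[i])
      seen <- c(seen, j)
      j <- parent[j]
      if (length(seen) > n) stopf("cycle detected in ontology")
    }
    if (j != root) stopf("node '%s' not connected to the root", labels[i])
  }
  has_child <- rep(FALSE, n)
  has_child[parent[!is.na(parent)]] <- TRUE
  leaves <- which(!has_child)
  structure(
    list(labels = labels, parent = parent, leaves = leaves,
         kind = kind, root = root),
    class = "code_ontology"
  )
}

#' @exportS3Method base::print
print.code_ontology <- function(x, ...) {
  cat(sprintf("<code_ontology kind=%s nodes=%d leaves=%d root=%s>\n",
              x$kind, length(x$labels), length(x$leaves), x$labels[x$root]))
  invisible(x)
}

#' Leaf codes of an ontology
#' @param ontology a [code_ontology()].
#' @return character vector of leaf labels, in tree order.
#' @export
ontology_leaves <- function(ontology) ontology$labels[ontology$leaves]

# index of a leaf label within ontology_leaves(), internal
leaf_index <- function(ontology, code) {
  i <- match(code, ontology$labels[ontology$leaves])
  if (is.na(i)) stopf("unknown leaf code '%s' in %s ontology", code, ontology$kind)
  i
}

#' Ancestor set of a leaf code
#'
#' The node set a leaf attends over: the leaf itself followed by every
#' ancestor on its root path, ordered leaf-to-root.
#'
#' @param ontology a [code_ontology()].
#' @param leaf a leaf label.
#' @return character vector of node labels, leaf first, root last.
#' @export
ancestor_set <- function(ontology, leaf) {
  i <- match(leaf, ontology$labels)
  if (is.na(i)) stopf("unknown node '%s'", leaf)
  if (!(i %in% ontology$leaves)) stopf("node '%s' is not a leaf", leaf)
  ontology$labels[ancestor_indices(ontology, i)]
}

# integer root-path (node index, leaf first) — internal fast path
ancestor_indices <- function(ontology, i) {
  path <- i
  while (!is.na(ontology$parent[i])) {
    i <- ontology$parent[i]
    path <- c(path, i)
  }
  path
}

# precompute root paths for all leaves (list of integer vectors)
leaf_ancestor_list <- function(ontology) {
  lapply(ontology$leaves, function(i) ancestor_indices(ontology, i))
}

#' Read / write an ontology as a parent-child edge list
#'
#' Two-column text files (tab- or comma-separated, no header): each row is
#' `parent, child` with labels being the code strings. The root is the one
#' label that never appears as a child.
#'
#' @param path file path.
#' @param kind `"diagnosis"` or `"drug"`.
#' @rdname ontology_io
#' @export
read_ontology <- function(path, kind = c("diagnosis", "drug")) {
  kind <- match.arg(kind)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          colClasses = "character", quote = "\"")
  if (ncol(df) != 2L) stopf("edge list must have two columns")
  labels <- unique(c(df[[1L]], df[[2L]]))
  parent <- rep(NA_integer_, length(labels))
  parent[match(df[[2L]], labels)] <- match(df[[1L]], labels)
  code_ontology(labels, parent, kind)
}

#' @param ontology a [code_ontology()].
#' @param sep column separator, `"\t"` (default) or `","`.
#' @rdname ontology_io
#' @export
write_ontology <- function(ontology, path, sep = "\t") {
  child <- which(!is.na(ontology$parent))
  df <- data.frame(parent = ontology$labels[ontology$parent[child]],
                   child = ontology$labels[child])
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- graph-attention embedding --------------------------------------------

#' Initialise graph-attention embedding parameters for an ontology
#'
#' Each ontology node j owns a learned vector h_j (row of `H`). The embedding
#' of a leaf code c is the concatenation over K attention heads of
#' `sigma(sum_{j in N_c} a^k_{c,j} W^k h_j)` where N_c is the leaf plus its
#' ancestors and the coefficients a^k are a softmax over a leaky-rectified
#' pairwise score of the transformed centre and neighbour vectors (the
#' standard GAT scorer). The per-head width is `d = l / K` so the
#' concatenated embedding has the model width `l`.
#'
#' @param n_nodes number of ontology nodes.
#' @param l output embedding width (must be divisible by `heads`).
#' @param heads number of attention heads K (default 4).
#' @param m node-table width (defaults to `l`).
#' @param sigma nonlinearity applied per head: `"elu"` (default), `"tanh"`,
#'   `"relu"` or `"identity"`.
#' @param init_scale standard deviation scale of the normal initialisation.
#' @return parameter tree with `H` (n_nodes x m), per-head `W` (m x d) and
#'   attention vectors `a_self`, `a_nb` (length d).
#' @export
gat_init <- function(n_nodes, l = 64L, heads = 4L, m = l,
                     sigma = c("elu", "tanh", "relu", "identity"),
                     init_scale = 0.1) {
  sigma <- match.arg(sigma)
  if (l %% heads != 0L) stopf("embedding width l=%d not divisible by heads=%d", l, heads)
  d <- l %/% heads
  params <- list(
    H = matrix(stats::rnorm(n_nodes * m, sd = init_scale), n_nodes, m),
    heads = lapply(seq_len(heads), function(k) {
      list(W = matrix(stats::rnorm(m * d, sd = sqrt(2 / (m + d))), m, d),
           a_self = stats::rnorm(d, sd = init_scale),
           a_nb = stats::rnorm(d, sd = init_scale))
    })
  )
  attr(params, "config") <- list(l = l, K = heads, d = d, m = m,
                                 sigma = sigma, leaky_slope = 0.2)
  params
}

gat_config <- function(params) attr(params, "config")

act_forward <- function(u, sigma) {
  switch(sigma,
         elu = ifelse(u > 0, u, exp(u) - 1),
         tanh = tanh(u),
         relu = pmax(u, 0),
         identity = u)
}

act_grad <- function(u, z, sigma) {
  switch(sigma,
         elu = ifelse(u > 0, 1, z + 1),
         tanh = 1 - z^2,
         relu = as.numeric(u > 0),
         identity = rep(1, length(u)))
}

#' Normalised attention coefficients for one head
#'
#' @param params a [gat_init()] parameter tree.
#' @param center node vector index (row of `params$H`) of the centre node.
#' @param neighbors integer vector of neighbour node indices (the set the
#'   softmax normalises over; for a leaf this is its ancestor set).
#' @param head head index in `1..K`.
#' @return numeric vector of non-negative weights summing to 1, one per
#'   neighbour.
#' @export
attention_coefficients <- function(params, center, neighbors, head) {
  cfg <- gat_config(params)
  if (length(neighbors) == 0L) stopf("neighbor list must be non-empty")
  if (!is_count(head) || head < 1 || head > cfg$K) stopf("head out of range")
  hp <- params$heads[[head]]
  Wh <- params$H[c(center, neighbors), , drop = FALSE] %*% hp$W
  s_self <- drop(Wh[1L, , drop = FALSE] %*% hp$a_self)
  s_nb <- drop(Wh[-1L, , drop = FALSE] %*% hp$a_nb)
  p <- s_self + s_nb
  e <- ifelse(p > 0, p, cfg$leaky_slope * p)
  softmax(e)
}

#' Ontology embedding of a single leaf code
#'
#' @param params a [gat_init()] parameter tree.
#' @param ontology the matching [code_ontology()].
#' @param code a leaf label.
#' @return numeric vector of length `l` (K heads concatenated).
#' @export
embed_code <- function(params, ontology, code) {
  i <- match(code, ontology$labels)
  if (is.na(i) || !(i %in% ontology$leaves)) stopf("unknown leaf code '%s'", code)
  anc <- ancestor_indices(ontology, i)
  cfg <- gat_config(params)
  out <- numeric(0)
  for (k in seq_len(cfg$K)) {
    hp <- params$heads[[k]]
    Wh <- params$H[anc, , drop = FALSE] %*% hp$W
    alpha <- attention_coefficients(params, anc[1L], anc, k)
    u <- drop(crossprod(Wh, alpha))
    out <- c(out, act_forward(u, cfg$sigma))
  }
  out
}

#' Embed every leaf of an ontology
#'
#' @inheritParams embed_code
#' @return matrix (n_leaves x l) with leaf labels as row names; row order
#'   follows [ontology_leaves()].
#' @export
embed_all_leaves <- function(params, ontology) {
  anc_list <- leaf_ancestor_list(ontology)
  O <- gat_forward(params, anc_list)$O
  rownames(O) <- ontology$labels[ontology$leaves]
  O
}

## internal batched forward/backward over precomputed ancestor lists --------

gat_forward <- function(params, anc_list) {
  cfg <- gat_config(params)
  nl <- length(anc_list)
  depths <- lengths(anc_list)
  groups <- lapply(split(seq_len(nl), depths), function(idx) {
    list(idx = idx,
         anc = do.call(rbind, anc_list[idx]))   # nq x q index matrix
  })
  O <- matrix(0, nl, cfg$l)
  cache <- vector("list", cfg$K)
  slope <- cfg$leaky_slope
  for (k in seq_len(cfg$K)) {
    hp <- params$heads[[k]]
    Wh <- params$H %*% hp$W                 # n_nodes x d
    s_self <- drop(Wh %*% hp$a_self)
    s_nb <- drop(Wh %*% hp$a_nb)
    U <- matrix(0, nl, cfg$d)
    gcache <- vector("list", length(groups))
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      q <- ncol(g$anc)
      P <- matrix(s_nb[g$anc], nrow(g$anc), q) + s_self[g$anc[, 1L]]
      E <- P * ((P > 0) + slope * (P <= 0))
      A <- exp(E - E[cbind(seq_len(nrow(E)), max.col(E, ties.method = "first"))])
      A <- A / rowSums(A)
      Ug <- matrix(0, length(g$idx), cfg$d)
      for (j in seq_len(q)) {
        Ug <- Ug + A[, j] * Wh[g$anc[, j], , drop = FALSE]
      }
      U[g$idx, ] <- Ug
      gcache[[gi]] <- list(A = A, P = P)
    }
    Z <- act_forward(U, cfg$sigma)
    O[, (k - 1L) * cfg$d + seq_len(cfg$d)] <- Z
    cache[[k]] <- list(Wh = Wh, gcache = gcache, us = U, Z = Z)
  }
  list(O = O, cache = list(heads = cache, groups = groups))
}

# dO: n_leaves x l. Returns gradient tree mirroring params.
gat_backward <- function(params, cache, dO) {
  cfg <- gat_config(params)
  groups <- cache$groups
  n_nodes <- nrow(params$H)
  dH <- matrix(0, n_nodes, ncol(params$H))
  slope <- cfg$leaky_slope
  gheads <- vector("list", cfg$K)
  for (k in seq_len(cfg$K)) {
    hp <- params$heads[[k]]
    ck <- cache$heads[[k]]
    cols <- (k - 1L) * cfg$d + seq_len(cfg$d)
    dU <- dO[, cols, drop = FALSE] * act_grad(ck$us, ck$Z, cfg$sigma)
    dWh <- matrix(0, n_nodes, cfg$d)
    ds_self <- numeric(n_nodes)
    ds_nb <- numeric(n_nodes)
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      q <- ncol(g$anc)
      A <- ck$gcache[[gi]]$A
      P <- ck$gcache[[gi]]$P
      dUg <- dU[g$idx, , drop = FALSE]
      dA <- matrix(0, nrow(A), q)
      for (j in seq_len(q)) {
        dA[, j] <- rowSums(dUg * ck$Wh[g$anc[, j], , drop = FALSE])
      }
      # one fused scatter over all (leaf, ancestor) pairs
      stacked <- do.call(rbind, lapply(seq_len(q), function(j) A[, j] * dUg))
      acc <- rowsum(stacked, group = as.vector(g$anc))
      rid <- as.integer(rownames(acc))
      dWh[rid, ] <- dWh[rid, ] + acc
      dE <- A * (dA - rowSums(A * dA))
      dP <- dE * ((P > 0) + slope * (P <= 0))
      ds_self[g$anc[, 1L]] <- ds_self[g$anc[, 1L]] + rowSums(dP)
      accp <- rowsum(as.vector(dP), group = as.vector(g$anc))
      ridp <- as.integer(rownames(accp))
      ds_nb[ridp] <- ds_nb[ridp] + accp
    }
    dWh <- dWh + ds_self %o% hp$a_self + ds_nb %o% hp$a_nb
    da_self <- drop(crossprod(ck$Wh, ds_self))
    da_nb <- drop(crossprod(ck$Wh, ds_nb))
    dH <- dH + dWh %*% t(hp$W)
    gheads[[k]] <- list(W = crossprod(params$H, dWh),
                        a_self = da_self, a_nb = da_nb)
  }
  list(H = dH, heads = gheads)
}
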