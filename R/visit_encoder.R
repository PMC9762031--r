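#' Transformer encoder parameters for one visit field
#'
#' Two layers (default) of masked multi-head self-attention with residual
#' connections, layer normalisation and a ReLU feed-forward block. No
#' positional encodings: a visit field is a set of codes, and omitting the
#' position term (together with key-side padding masks) makes the [CLS]
#' output invariant to token order and extra padding.
#'
#' @param l model width (divisible by `heads`).
#' @param layers number of encoder layers (default 2).
#' @param heads number of attention heads (default 4).
#' @param ff feed-forward inner width (default `2 * l`).
#' @param init_scale standard deviation of the normal weight initialisation.
#' @return parameter tree (`$layers` is a list of per-layer parameter lists).
#' @export
encoder_init <- function(l = 64L, layers = 2L, heads = 4L, ff = 2L * l,
                         init_scale = 0.1) {
  if (l %% heads != 0L) stopf("width l=%d not divisible by heads=%d", l, heads)
  # Glorot-scaled transforms; init_scale only sets embedding-table scales
  mk <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
  layer <- function() {
    list(Wq = mk(l, l), Wk = mk(l, l), Wv = mk(l, l), Wo = mk(l, l),
         bq = numeric(l), bk = numeric(l), bv = numeric(l), bo = numeric(l),
         g1 = rep(1, l), be1 = numeric(l),
         W1 = mk(l, ff), c1 = numeric(ff), W2 = mk(ff, l), c2 = numeric(l),
         g2 = rep(1, l), be2 = numeric(l))
  }
  params <- list(layers = lapply(seq_len(layers), function(i) layer()))
  attr(params, "config") <- list(l = l, layers = layers, heads = heads, ff = ff)
  params
}

# normalise C++ gradient lists (1-row matrices back to plain vectors) so the
# gradient tree matches the parameter tree shape exactly
normalize_layer_grads <- function(glist, params) {
  out <- lapply(seq_along(glist), function(i) {
    g <- glist[[i]]
    p <- params$layers[[i]]
    g <- lapply(stats::setNames(names(p), names(p)), function(nm) {
      x <- g[[nm]]
      if (is.matrix(x) && !is.matrix(p[[nm]])) drop(x) else x
    })
    g
  })
  list(layers = out)
}

# Forward a batch of tokenised sequences through a field encoder.
# tokens, valid: B x L integer matrices; E: embedding table (V x l).
# Returns cls (B x l) plus the cache needed for the backward pass.
encoder_forward <- function(params, E, tokens, valid, keep_cache = TRUE) {
  cfg <- attr(params, "config")
  idx <- as.vector(t(tokens))
  X <- E[idx, , drop = FALSE]
  out <- .enc_forward_cpp(X, valid, params$layers, cfg$heads, keep_cache)
  list(cls = out$cls, cache = out$cache, idx = idx, valid = valid,
       V = nrow(E))
}

# Backward: dcls (B x l) -> list(grads = encoder grad tree, dE = V x l).
encoder_backward <- function(params, fwd, dcls) {
  cfg <- attr(params, "config")
  bk <- .enc_backward_cpp(dcls, fwd$valid, params$layers, fwd$cache, cfg$heads)
  dE <- matrix(0, fwd$V, ncol(dcls))
  agg <- rowsum(bk$dX, group = fwd$idx)
  dE[as.integer(rownames(agg)), ] <- agg
  list(grads = normalize_layer_grads(bk$layers, params), dE = dE)
}

# canonical short keys of the three visit fields (d / m / s)
field_key <- function(field) {
  c(diagnosis = "d", drug = "m", symptom = "s")[[field]]
}

## ---- visit model ----------------------------------------------------------

#' Assemble the visit model
#'
#' Bundles everything needed to embed a visit: the two ontology
#' graph-attention embeddings (or plain lookup tables when
#' `use_ontology = FALSE`, the knowledge-removed ablation), the symptom
#' dictionary embedding, learned vectors for the special tokens, and one
#' transformer encoder per field (separate weights, shared hyperparameters).
#'
#' @param vocabularies output of [build_vocabularies()] on the training
#'   corpora.
#' @param ontologies list with `diagnosis` and `drug` [code_ontology()]s.
#' @param l model width (default 64).
#' @param enc_layers,enc_heads encoder depth and heads (defaults 2 and 4).
#' @param gat_heads attention heads of the ontology embedding (default 4).
#' @param ff encoder feed-forward width (default `2 * l`).
#' @param max_len named per-field sequence caps (including `[CLS]`).
#' @param use_ontology if `FALSE`, diagnosis/drug codes use plain learned
#'   lookup embeddings instead of ontology attention.
#' @param sigma GAT output nonlinearity.
#' @param init_scale weight initialisation scale.
#' @param seed integer seed for the initialisation.
#' @return a `visit_model` list with `params` (trainable tree), `config`,
#'   `vocabularies`, `ontologies` and precomputed leaf index maps.
#' @export
visit_model <- function(vocabularies, ontologies,
                        l = 64L, enc_layers = 2L, enc_heads = 4L,
                        gat_heads = 4L, ff = 2L * l,
                        max_len = c(diagnosis = 32L, drug = 72L, symptom = 8L),
                        use_ontology = TRUE,
                        sigma = "elu",
                        init_scale = 0.1,
                        seed = 1L) {
  vb_d <- vocabularies$diagnosis; vb_m <- vocabularies$drug
  vb_s <- vocabularies$symptom
  map_leaf <- function(vocab, ontology) {
    codes <- vocab$tokens[-seq_len(vocab$n_special)]
    i <- match(codes, ontology$labels[ontology$leaves])
    if (anyNA(i)) {
      stopf("corpus %s code(s) not found among ontology leaves (e.g. '%s')",
            ontology$kind, codes[which(is.na(i))[1L]])
    }
    i
  }
  map_d <- map_leaf(vb_d, ontologies$diagnosis)
  map_m <- map_leaf(vb_m, ontologies$drug)
  params <- with_seed(seed, {
    p <- list(
      spec_d = matrix(stats::rnorm(4L * l, sd = init_scale), 4L, l),
      spec_m = matrix(stats::rnorm(4L * l, sd = init_scale), 4L, l),
      spec_s = matrix(stats::rnorm(4L * l, sd = init_scale), 4L, l),
      sym_table = matrix(stats::rnorm(vb_s$n_codes * l, sd = init_scale),
                         max(vb_s$n_codes, 1L), l),
      enc_d = encoder_init(l, enc_layers, enc_heads, ff, init_scale),
      enc_m = encoder_init(l, enc_layers, enc_heads, ff, init_scale),
      enc_s = encoder_init(l, enc_layers, enc_heads, ff, init_scale)
    )
    if (use_ontology) {
      p$gat_d <- gat_init(length(ontologies$diagnosis$labels), l, gat_heads,
                          sigma = sigma, init_scale = init_scale)
      p$gat_m <- gat_init(length(ontologies$drug$labels), l, gat_heads,
                          sigma = sigma, init_scale = init_scale)
    } else {
      p$lookup_d <- matrix(stats::rnorm(vb_d$n_codes * l, sd = init_scale),
                           vb_d$n_codes, l)
      p$lookup_m <- matrix(stats::rnorm(vb_m$n_codes * l, sd = init_scale),
                           vb_m$n_codes, l)
    }
    p
  })
  structure(
    list(params = params,
         config = list(l = l, enc_layers = enc_layers, enc_heads = enc_heads,
                       gat_heads = gat_heads, ff = ff, max_len = max_len,
                       use_ontology = use_ontology, sigma = sigma,
                       init_scale = init_scale, seed = seed),
         vocabularies = vocabularies,
         ontologies = ontologies,
         map_d = map_d, map_m = map_m,
         anc_d = leaf_ancestor_list(ontologies$diagnosis),
         anc_m = leaf_ancestor_list(ontologies$drug)),
    class = "visit_model"
  )
}

#' @exportS3Method base::print
print.visit_model <- function(x, ...) {
  cat(sprintf("<visit_model l=%d layers=%d heads=%d %s>\n", x$config$l,
              x$config$enc_layers, x$config$enc_heads,
              if (x$config$use_ontology) "ontology-embedding" else "lookup-embedding"))
  invisible(x)
}

# Compute the full token-embedding tables for the three fields.
# With ontology embeddings on, the diagnosis/drug code rows are the
# graph-attention leaf embeddings; caches are kept for the backward pass.
# `perturb` optionally adds a fixed matrix to a field's code-embedding block
# (the FGM adversarial disturbance).
model_tables <- function(model, params = model$params, perturb = NULL) {
  l <- model$config$l
  if (model$config$use_ontology) {
    fd <- gat_forward(params$gat_d, model$anc_d)
    fm <- gat_forward(params$gat_m, model$anc_m)
    O_d <- fd$O[model$map_d, , drop = FALSE]
    O_m <- fm$O[model$map_m, , drop = FALSE]
    caches <- list(d = fd$cache, m = fm$cache)
  } else {
    O_d <- params$lookup_d
    O_m <- params$lookup_m
    caches <- NULL
  }
  if (!is.null(perturb$d)) O_d <- O_d + perturb$d
  if (!is.null(perturb$m)) O_m <- O_m + perturb$m
  list(
    E = list(diagnosis = rbind(params$spec_d, O_d),
             drug = rbind(params$spec_m, O_m),
             symptom = rbind(params$spec_s, params$sym_table)),
    gat_caches = caches,
    code_tables = list(d = O_d, m = O_m)
  )
}

# Scatter a field's dE back into parameter gradients.
# Returns a partial gradient tree for that field's embedding sources.
table_backward <- function(model, params, tables, field, dE) {
  n_special <- 4L
  dspec <- dE[seq_len(n_special), , drop = FALSE]
  dcodes <- dE[-seq_len(n_special), , drop = FALSE]
  if (field == "symptom") {
    g <- list(spec_s = dspec)
    if (nrow(dcodes) > 0L) g$sym_table <- dcodes
    return(g)
  }
  key <- if (field == "diagnosis") "d" else "m"
  g <- list()
  g[[paste0("spec_", key)]] <- dspec
  if (model$config$use_ontology) {
    # lift code-row gradients to the full leaf table, then through the GAT
    gp <- params[[paste0("gat_", key)]]
    map <- model[[paste0("map_", key)]]
    dO <- matrix(0, length(model[[paste0("anc_", key)]]), ncol(dE))
    dO[map, ] <- dO[map, ] + dcodes
    g[[paste0("gat_", key)]] <- gat_backward(gp, tables$gat_caches[[key]], dO)
  } else {
    g[[paste0("lookup_", key)]] <- dcodes
  }
  g
}

#' Token embeddings for one field of a tokenised visit
#'
#' Diagnosis and drug positions carry the ontology embedding of their leaf
#' code; symptom positions carry the dictionary embedding at the symptom's
#' index; `[CLS]`, `[PAD]`, `[MASK]`, `[UNK]` carry learned vectors. No
#' positional term is added.
#'
#' @param tokens integer token vector (vocabulary indices).
#' @param field `"diagnosis"`, `"drug"` or `"symptom"`.
#' @param model a [visit_model()].
#' @return matrix (length(tokens) x l).
#' @export
token_embeddings <- function(tokens, field = c("diagnosis", "drug", "symptom"),
                             model) {
  field <- match.arg(field)
  vb <- model$vocabularies[[field]]
  if (any(tokens < 1L | tokens > vb$size)) {
    stopf("token index out of range for %s vocabulary", field)
  }
  tables <- model_tables(model)
  tables$E[[field]][tokens, , drop = FALSE]
}

#' Encode one visit into its three field embeddings
#'
#' Each field sequence is encoded independently by that field's transformer;
#' the visit embedding v_d / v_m / v_s is the final hidden state at the
#' `[CLS]` position.
#'
#' @param tokenized output of [tokenize_visit()].
#' @param model a [visit_model()].
#' @return a `visit_embedding` list with vectors `v_d`, `v_m`, `v_s`.
#' @export
encode_visit <- function(tokenized, model) {
  tables <- model_tables(model)
  out <- lapply(c(diagnosis = "diagnosis", drug = "drug", symptom = "symptom"),
                function(f) {
    tk <- tokenized[[f]]
    if (tk$tokens[1L] != match("[CLS]", model$vocabularies[[f]]$tokens)) {
      stopf("%s sequence does not start with [CLS]", f)
    }
    enc <- model$params[[paste0("enc_", field_key(f))]]
    fwd <- encoder_forward(enc, tables$E[[f]],
                           matrix(tk$tokens, nrow = 1L),
                           matrix(tk$valid, nrow = 1L))
    drop(fwd$cls)
  })
  structure(list(v_d = out$diagnosis, v_m = out$drug, v_s = out$symptom),
            class = "visit_embedding")
}

# Batched field encoding of a list of tokenised visits. Returns per-field
# cls matrices plus forward caches (for the training backward pass).
encode_batch <- function(model, toks, tables) {
  encode_batch_fields(model, toks, tables,
                      c("diagnosis", "drug", "symptom"))
}

encode_batch_fields <- function(model, toks, tables, fields) {
  fields <- stats::setNames(fields, fields)
  lapply(fields, function(f) {
    tokens <- do.call(rbind, lapply(toks, function(tk) tk[[f]]$tokens))
    valid <- do.call(rbind, lapply(toks, function(tk) tk[[f]]$valid))
    # all-pad tail columns contribute exactly zero through the attention
    # mask, so dropping them is bit-equivalent and saves their compute
    Lb <- max(max.col(valid, ties.method = "last"))
    if (Lb < ncol(tokens)) {
      tokens <- tokens[, seq_len(Lb), drop = FALSE]
      valid <- valid[, seq_len(Lb), drop = FALSE]
    }
    enc <- model$params[[paste0("enc_", field_key(f))]]
    encoder_forward(enc, tables$E[[f]], tokens, valid)
  })
}
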