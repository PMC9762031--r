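#' Experiment configuration
#'
#' Collects every tunable of the training pipeline with the published
#' defaults where stated (2 encoder layers with 4 heads, 4 ontology
#' attention heads, learning rate 5e-4, a 4:1:1 patient split) and the
#' package's own defaults elsewhere (width 64, mask rate 0.15, FGM
#' magnitude 0.5, threshold 0.3, 3 alternation cycles of 5 pre-training +
#' 10 fine-tuning epochs).
#'
#' @param l model width.
#' @param enc_layers,enc_heads encoder depth/heads.
#' @param gat_heads ontology-attention heads.
#' @param ff encoder feed-forward width.
#' @param max_len per-field token caps (incl. `[CLS]`).
#' @param lr fine-tuning (prediction) learning rate, 5e-4.
#' @param lr_pretrain pre-training learning rate (default 1e-3; the
#'   pre-training rate is a free choice).
#' @param mask_rate masking probability.
#' @param eps FGM magnitude (0 disables). @param fgm_sign +1 or -1.
#' @param theta recommendation threshold.
#' @param cycles,k_pre,k_fit alternation schedule: `cycles` repetitions of
#'   `k_pre` pre-training epochs followed by `k_fit` fine-tuning epochs.
#' @param batch_size pre-training minibatch (visits).
#' @param batch_patients fine-tuning minibatch (patients).
#' @param split_ratio train/validation/test weights.
#' @param use_ontology,use_pretraining ablation toggles.
#' @param sigma GAT nonlinearity. @param init_scale init scale.
#' @param seed integer seed.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(l = 64L, enc_layers = 2L, enc_heads = 4L,
                              gat_heads = 4L, ff = 2L * l,
                              max_len = c(diagnosis = 32L, drug = 72L, symptom = 8L),
                              lr = 5e-4, lr_pretrain = 1e-3,
                              mask_rate = 0.15, eps = 0.5,
                              fgm_sign = 1, theta = 0.3,
                              cycles = 3L, k_pre = 5L, k_fit = 10L,
                              batch_size = 64L, batch_patients = 16L,
                              split_ratio = c(4, 1, 1),
                              use_ontology = TRUE, use_pretraining = TRUE,
                              sigma = "elu", init_scale = 0.1, seed = 1L) {
  for (v in list(l, enc_layers, enc_heads, gat_heads, ff, cycles, k_pre,
                 k_fit, batch_size, batch_patients)) {
    if (!is_count(v) || v < 1) stopf("config counts must be positive integers")
  }
  stopifnot(lr > 0, lr_pretrain > 0, mask_rate >= 0, mask_rate <= 1, eps >= 0,
            fgm_sign %in% c(-1, 1), theta > 0, theta < 1,
            length(split_ratio) == 3L, all(split_ratio > 0),
            all(max_len >= 2L))
  structure(
    list(l = as.integer(l), enc_layers = as.integer(enc_layers),
         enc_heads = as.integer(enc_heads), gat_heads = as.integer(gat_heads),
         ff = as.integer(ff), max_len = max_len, lr = lr,
         lr_pretrain = lr_pretrain,
         mask_rate = mask_rate, eps = eps, fgm_sign = fgm_sign,
         theta = theta, cycles = as.integer(cycles),
         k_pre = as.integer(k_pre), k_fit = as.integer(k_fit),
         batch_size = as.integer(batch_size),
         batch_patients = as.integer(batch_patients),
         split_ratio = split_ratio, use_ontology = use_ontology,
         use_pretraining = use_pretraining, sigma = sigma,
         init_scale = init_scale, seed = as.integer(seed),
         # interpretation note: the combined pre-training objective is
         # Ls(v_d)+Ls(v_m)+Ls(v_s)+L_dm+L_ds+L_ms
         loss_combination = "Ls_d+Ls_m+Ls_s+Ldm+Lds+Lms"),
    class = "experiment_config"
  )
}

#' Read an experiment + generator configuration from YAML
#'
#' The file may contain an `experiment:` block (fields of
#' [experiment_config()]) and a `synthetic:` block (fields of
#' [synthetic_config()]); missing fields take the defaults.
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file's experiment block.
#' @return list with `experiment` and `synthetic` configs.
#' @export
config_from_yaml <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  exp_args <- raw$experiment %||% list()
  for (nm in names(overrides)) exp_args[[nm]] <- overrides[[nm]]
  if (!is.null(exp_args$max_len)) exp_args$max_len <- unlist(exp_args$max_len)
  if (!is.null(exp_args$split_ratio)) exp_args$split_ratio <- unlist(exp_args$split_ratio)
  syn_args <- raw$synthetic %||% list()
  for (nm in c("single_means", "multi_means")) {
    if (!is.null(syn_args[[nm]])) syn_args[[nm]] <- unlist(syn_args[[nm]])
  }
  list(experiment = do.call(experiment_config, exp_args),
       synthetic = do.call(synthetic_config, syn_args))
}

#' Alternating pre-training / fine-tuning schedule
#'
#' For each of `cycles` cycles, runs `k_pre` pre-training epochs on the
#' single-visit corpus and then `k_fit` adversarial fine-tuning epochs on
#' the multi-visit training split, with the ontology tables, encoders and
#' pre-training heads shared across phases (which is what lets fine-tuning
#' and pre-training keep correcting each other and limits forgetting). The
#' prediction head is created at the first fine-tuning cycle. With
#' `use_pretraining = FALSE` the schedule degenerates to a single
#' fine-tuning run of `cycles * k_fit` epochs.
#'
#' @param single list of single-visit [visit_record()]s.
#' @param splits multi-visit [split_patients()] output.
#' @param ontologies list with `diagnosis`/`drug` [code_ontology()]s.
#' @param config an [experiment_config()].
#' @param verbose print per-epoch losses.
#' @param pretrain_cache optional environment used to share the (identical)
#'   pre-training stage across single-cycle variant runs.
#' @return list with `model` + `pred` (best fine-tuning validation loss
#'   across all cycles), `logs` (`$pretrain`, `$finetune` with a cycle
#'   column), `vocabularies`, `config`.
#' @export
alternating_train <- function(single, splits, ontologies, config,
                              verbose = FALSE, pretrain_cache = NULL) {
  if (config$cycles < 1L) stopf("cycle count must be at least 1")
  vocabs <- build_vocabularies(c(single, splits$train))
  model <- visit_model(vocabs, ontologies, l = config$l,
                       enc_layers = config$enc_layers,
                       enc_heads = config$enc_heads,
                       gat_heads = config$gat_heads, ff = config$ff,
                       max_len = config$max_len,
                       use_ontology = config$use_ontology,
                       sigma = config$sigma,
                       init_scale = config$init_scale, seed = config$seed)
  heads <- NULL; pred <- NULL
  opt_pre <- NULL; opt_fit <- NULL
  best <- list(val = Inf, model = NULL, pred = NULL)
  pre_log <- NULL; fit_log <- NULL
  n_cycles <- if (config$use_pretraining) config$cycles else 1L
  k_fit <- if (config$use_pretraining) config$k_fit else config$cycles * config$k_fit
  # with a single cycle the pre-training stage is a pure function of the
  # corpus and config (fine-tuning has not touched the model yet), so
  # callers training several fine-tune variants may pass an environment to
  # share it; with cycles > 1 the phases interleave and nothing is shared
  cache_key <- if (!is.null(pretrain_cache) && n_cycles == 1L) {
    paste(config$seed, config$use_ontology, config$k_pre,
          config$lr_pretrain, config$batch_size, config$mask_rate, sep = "|")
  } else NULL
  for (cy in seq_len(n_cycles)) {
    if (config$use_pretraining) {
      if (!is.null(cache_key) && !is.null(pretrain_cache[[cache_key]])) {
        pr <- pretrain_cache[[cache_key]]
      } else {
        pr <- run_pretraining(single, model, heads, epochs = config$k_pre,
                              batch_size = config$batch_size,
                              lr = config$lr_pretrain,
                              mask_rate = config$mask_rate,
                              seed = derive_seed(config$seed, paste0("cycle", cy)),
                              opt = opt_pre, verbose = verbose)
        if (!is.null(cache_key)) pretrain_cache[[cache_key]] <- pr
      }
      model <- pr$final_model; heads <- pr$final_heads; opt_pre <- pr$opt
      pre_log <- rbind(pre_log, cbind(cycle = cy, pr$log))
    }
    ft <- fine_tune(splits$train, splits$validation, model, pred,
                    epochs = k_fit, batch_patients = config$batch_patients,
                    lr = config$lr, eps = config$eps,
                    fgm_sign = config$fgm_sign,
                    seed = derive_seed(config$seed, paste0("fit", cy)),
                    opt = opt_fit, verbose = verbose)
    model <- ft$final_model; pred <- ft$final_pred; opt_fit <- ft$opt
    fit_log <- rbind(fit_log, cbind(cycle = cy, ft$log))
    cycle_best <- min(ft$log$val_loss)
    if (cycle_best < best$val) {
      best <- list(val = cycle_best, model = ft$model, pred = ft$pred)
    }
  }
  list(model = best$model, pred = best$pred,
       final_model = model, final_pred = pred,
       logs = list(pretrain = pre_log, finetune = fit_log),
       vocabularies = vocabs, config = config)
}

## ---- checkpointing ---------------------------------------------------------

CKPT_VERSION <- "rxrec-checkpoint-1"

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the visit model, the prediction head, the
#' pre-training heads (if any) and the experiment config, with a format
#' version tag. Round-trips are bit-exact.
#'
#' @param bundle named list (typically `model`, `pred`, `heads`, `config`).
#' @param path file path (`.rds`).
#' @rdname checkpoint
#' @export
save_checkpoint <- function(bundle, path) {
  stopifnot(is.list(bundle))
  bundle$version <- CKPT_VERSION
  saveRDS(bundle, path, version = 3L)
  invisible(path)
}

#' @rdname checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stopf("no such checkpoint: %s", path)
  bundle <- tryCatch(readRDS(path),
                     error = function(e) stopf("unreadable checkpoint '%s': %s",
                                               path, conditionMessage(e)))
  if (!identical(bundle$version, CKPT_VERSION)) {
    stopf("checkpoint version mismatch: found '%s', expected '%s'",
          bundle$version %||% "<none>", CKPT_VERSION)
  }
  bundle
}

## ---- command-line interface ------------------------------------------------

cli_usage <- function(cmd = NULL) {
  u <- c(
    simulate = "rxrec simulate --config <yaml> --out <dir> [--seed <int>]",
    pretrain = "rxrec pretrain --data <dir> --out <ckpt> [--config <yaml>] [--seed <int>]",
    train = "rxrec train --data <dir> --out <ckpt> [--pretrained <ckpt>] [--config <yaml>] [--seed <int>]",
    evaluate = "rxrec evaluate --model <ckpt> --data <dir> [--out <json>]",
    ablate = "rxrec ablate --data <dir> --out <csv> [--config <yaml>] [--seeds <n>]"
  )
  if (is.null(cmd)) {
    c("usage: rxrec <simulate|pretrain|train|evaluate|ablate> [options]", u)
  } else u[[cmd]]
}

parse_cli_flags <- function(args, allowed) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stopf("unexpected argument '%s'", a)
    key <- substring(a, 3L)
    if (key == "help") return("help")
    if (!(key %in% allowed)) stopf("unknown flag '--%s'", key)
    if (i == length(args)) stopf("flag '--%s' needs a value", key)
    out[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  out
}

cli_load_data <- function(dir) {
  list(
    ontologies = list(
      diagnosis = read_ontology(file.path(dir, "ontology_diagnosis.tsv"), "diagnosis"),
      drug = read_ontology(file.path(dir, "ontology_drug.tsv"), "drug")),
    symptoms = readLines(file.path(dir, "symptoms.txt")),
    single = unlist(lapply(read_emr_table(file.path(dir, "single_visit.csv")),
                           `[[`, "visits"), recursive = FALSE),
    multi = read_emr_table(file.path(dir, "multi_visit.csv"))
  )
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (generate a synthetic study data set),
#' `pretrain` (pre-train the visit model), `train` (full alternating
#' schedule; with `--pretrained` continues from a checkpoint's model),
#' `evaluate` (test-split metrics of a checkpoint) and `ablate` (the
#' eight-variant ablation study). A thin executable wrapper is installed at
#' `exec/rxrec`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L || args[[1L]] %in% c("--help", "-h", "help")) {
      writeLines(cli_usage())
      return(invisible(0L))
    }
    cmd <- args[[1L]]
    if (!(cmd %in% c("simulate", "pretrain", "train", "evaluate", "ablate"))) {
      stopf("unknown subcommand '%s'", cmd)
    }
    fl <- parse_cli_flags(args[-1L],
                          c("config", "out", "seed", "data", "pretrained",
                            "model", "seeds"))
    if (identical(fl, "help")) {
      writeLines(cli_usage(cmd))
      return(invisible(0L))
    }
    seed <- as.integer(fl$seed %||% 1L)
    cfgs <- if (!is.null(fl$config)) {
      config_from_yaml(fl$config, overrides = list(seed = seed))
    } else {
      list(experiment = experiment_config(seed = seed),
           synthetic = synthetic_config(seed = seed))
    }
    switch(cmd,
      simulate = {
        if (is.null(fl$out)) stopf("simulate needs --out <dir>")
        syn <- cfgs$synthetic; syn$seed <- seed
        simulate_corpus(syn, out_dir = fl$out)
        message(sprintf("wrote synthetic corpus to %s", fl$out))
      },
      pretrain = {
        if (is.null(fl$data) || is.null(fl$out)) {
          stopf("pretrain needs --data <dir> and --out <ckpt>")
        }
        data <- cli_load_data(fl$data)
        cfg <- cfgs$experiment
        vocabs <- build_vocabularies(c(data$single, data$multi))
        model <- visit_model(vocabs, data$ontologies, l = cfg$l,
                             enc_layers = cfg$enc_layers,
                             enc_heads = cfg$enc_heads,
                             gat_heads = cfg$gat_heads, ff = cfg$ff,
                             max_len = cfg$max_len,
                             use_ontology = cfg$use_ontology,
                             sigma = cfg$sigma, init_scale = cfg$init_scale,
                             seed = seed)
        pr <- run_pretraining(data$single, model, epochs = cfg$k_pre,
                              batch_size = cfg$batch_size, lr = cfg$lr,
                              mask_rate = cfg$mask_rate, seed = seed)
        save_checkpoint(list(model = pr$model, heads = pr$heads,
                             config = cfg, log = pr$log), fl$out)
        message(sprintf("pre-trained model saved to %s", fl$out))
      },
      train = {
        if (is.null(fl$data) || is.null(fl$out)) {
          stopf("train needs --data <dir> and --out <ckpt>")
        }
        data <- cli_load_data(fl$data)
        cfg <- cfgs$experiment
        splits <- split_patients(data$multi, cfg$split_ratio, seed = seed)
        run <- alternating_train(data$single, splits, data$ontologies, cfg)
        save_checkpoint(list(model = run$model, pred = run$pred,
                             config = cfg, logs = run$logs), fl$out)
        message(sprintf("trained model saved to %s", fl$out))
      },
      evaluate = {
        if (is.null(fl$model) || is.null(fl$data)) {
          stopf("evaluate needs --model <ckpt> and --data <dir>")
        }
        ck <- load_checkpoint(fl$model)
        data <- cli_load_data(fl$data)
        splits <- split_patients(data$multi, ck$config$split_ratio,
                                 seed = as.integer(ck$config$seed))
        rep <- evaluate_model(ck$model, ck$pred, splits$test, ck$config$theta)
        print(rep)
        if (!is.null(fl$out)) {
          jsonlite::write_json(unclass(rep), fl$out, auto_unbox = TRUE,
                               digits = NA)
        }
      },
      ablate = {
        if (is.null(fl$data) || is.null(fl$out)) {
          stopf("ablate needs --data <dir> and --out <csv>")
        }
        data <- cli_load_data(fl$data)
        res <- ablation_suite(data, cfgs$experiment,
                              seeds = seq_len(as.integer(fl$seeds %||% 1L)),
                              verbose = TRUE)
        utils::write.csv(res, fl$out, row.names = FALSE)
        message(sprintf("ablation table written to %s", fl$out))
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
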