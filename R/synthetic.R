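#' Configuration of the synthetic EMR generator
#'
#' The generator emulates the data regime the recommender targets: a large
#' pool of single-visit records (used only for pre-training) and a small pool
#' of multi-visit patients (used for fine-tuning and evaluation), with
#' per-visit code-count means matching the shape of a small regional EMR
#' extract: single visits average about 2.233 diagnosis codes, 16.77 drug
#' codes and 1.0 symptom term; multi-visit records are sparser (1.400 / 3.943
#' / 0.774) and patients average about 2.27 visits with at most 8.
#'
#' Counts per visit follow zero-truncated Poisson distributions whose rates
#' are solved so the truncated means hit the targets; the visit-count
#' distribution is a Poisson shifted to start at 2 visits, truncated at
#' `max_visits`.
#'
#' @param n_diag_leaves,n_drug_leaves,n_symptoms vocabulary sizes.
#' @param n_single_visit_patients,n_multi_visit_patients corpus sizes.
#' @param single_means,multi_means named numeric vectors with entries `diag`,
#'   `drug`, `sym`: target mean codes per visit.
#' @param mean_visits,max_visits multi-visit sequence shape (mean 2.27, max 8).
#' @param profile_sparsity expected fraction of the drug vocabulary with
#'   nonzero weight in one disease profile.
#' @param chronic_persistence probability that a diagnosis recurs at the next
#'   visit, which is what gives patient history predictive value.
#' @param branch_affinity probability that a profile drug is drawn from the
#'   profile's home branch of the drug ontology (rather than anywhere),
#'   making the ontology informative.
#' @param background_mix weight of a uniform background distribution mixed
#'   into every visit's drug/symptom sampling (co-medication noise).
#' @param seed integer seed; the whole generator is deterministic given the
#'   config.
#' @return a `synthetic_config` list, validated.
#' @export
synthetic_config <- function(n_diag_leaves = 50L,
                             n_drug_leaves = 100L,
                             n_symptoms = 30L,
                             n_single_visit_patients = 2000L,
                             n_multi_visit_patients = 300L,
                             single_means = c(diag = 2.233, drug = 16.77, sym = 1.0),
                             multi_means = c(diag = 1.400, drug = 3.943, sym = 0.774),
                             mean_visits = 2.27,
                             max_visits = 8L,
                             profile_sparsity = 0.1,
                             chronic_persistence = 0.7,
                             branch_affinity = 0.7,
                             background_mix = 0.1,
                             seed = 1L) {
  for (v in list(n_diag_leaves, n_drug_leaves, n_symptoms, max_visits)) {
    if (!is_count(v) || v < 1) stopf("counts must be positive integers")
  }
  if (!is_count(n_single_visit_patients) || !is_count(n_multi_visit_patients)) {
    stopf("corpus sizes must be non-negative integers")
  }
  for (p in c(profile_sparsity, chronic_persistence, branch_affinity, background_mix)) {
    if (!is.numeric(p) || p < 0 || p > 1) stopf("probabilities must lie in [0,1]")
  }
  if (profile_sparsity <= 0) stopf("profile_sparsity must be in (0,1]")
  stopifnot(all(c("diag", "drug", "sym") %in% names(single_means)),
            all(c("diag", "drug", "sym") %in% names(multi_means)),
            all(single_means > 0), all(multi_means > 0))
  if (max_visits < 2L) stopf("max_visits must be at least 2")
  vdist <- visit_count_distribution(mean_visits, max_visits)
  cfg <- list(
    n_diag_leaves = as.integer(n_diag_leaves),
    n_drug_leaves = as.integer(n_drug_leaves),
    n_symptoms = as.integer(n_symptoms),
    n_single_visit_patients = as.integer(n_single_visit_patients),
    n_multi_visit_patients = as.integer(n_multi_visit_patients),
    single_means = single_means, multi_means = multi_means,
    mean_visits = mean_visits, max_visits = as.integer(max_visits),
    visit_count_distribution = vdist,
    profile_sparsity = profile_sparsity,
    chronic_persistence = chronic_persistence,
    branch_affinity = branch_affinity,
    background_mix = background_mix,
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  cfg
}

# categorical distribution over {2..max_visits}: shifted Poisson, rate solved
# so the truncated mean equals `mean_visits`; remaining tail mass on the max.
visit_count_distribution <- function(mean_visits, max_visits) {
  if (mean_visits <= 2 || mean_visits >= max_visits) {
    stopf("mean_visits must lie in (2, max_visits)")
  }
  ks <- 2:max_visits
  mean_of <- function(lam) {
    p <- stats::dpois(ks - 2L, lam)
    p[length(p)] <- p[length(p)] + stats::ppois(max_visits - 2L, lam, lower.tail = FALSE)
    sum(ks * p)
  }
  lam <- stats::uniroot(function(l) mean_of(l) - mean_visits,
                        c(1e-8, 4 * mean_visits))$root
  p <- stats::dpois(ks - 2L, lam)
  p[length(p)] <- p[length(p)] + stats::ppois(max_visits - 2L, lam, lower.tail = FALSE)
  stats::setNames(p / sum(p), ks)
}

# rate of a zero-truncated Poisson with the requested mean
ztpois_lambda <- function(target_mean) {
  if (target_mean <= 1) return(1e-8)  # degenerates to "always 1"
  stats::uniroot(function(l) l / (1 - exp(-l)) - target_mean,
                 c(1e-8, target_mean + 10))$root
}

rztpois <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  x <- stats::qpois(stats::runif(n, stats::dpois(0, lambda), 1), lambda)
  pmax(x, 1L)
}

## ---- ontology generation ---------------------------------------------------

#' Generate a synthetic code ontology
#'
#' Diagnosis trees mimic ICD-10: leaves are `letter + 2 digits + "." + digit`
#' (e.g. `"J98.4"`), their parent is the 3-character category (`"J98"`), the
#' grandparent the chapter letter, under a single root. Drug trees mimic the
#' 14-digit Chinese national drug code: the label segments are
#' country(2)/category(1)/enterprise(5)/product(5)/final(1) and an internal
#' node sits at every segment boundary, so e.g. `"86900450000011"` descends
#' root -> `"86"` -> `"869"` -> `"86900450"` -> `"8690045000001"` -> leaf.
#' Leaves cluster under shared parents so that sibling structure exists for
#' the graph-attention embedding to exploit.
#'
#' @param kind `"diagnosis"` or `"drug"`.
#' @param config a [synthetic_config()].
#' @param seed integer seed (defaults to a seed derived from the config).
#' @return a [code_ontology()] with exactly the requested number of leaves.
#' @export
generate_ontology <- function(kind = c("diagnosis", "drug"), config,
                              seed = derive_seed(config$seed, paste0("ontology-", kind[1]))) {
  kind <- match.arg(kind)
  n <- if (kind == "diagnosis") config$n_diag_leaves else config$n_drug_leaves
  with_seed(seed, {
    if (kind == "diagnosis") generate_icd_tree(n) else generate_ndc_tree(n)
  })
}

generate_icd_tree <- function(n_leaves) {
  if (n_leaves > 26L * 100L * 10L) {
    stopf("requested %d diagnosis leaves exceeds the ICD-10-like label space (26000)", n_leaves)
  }
  n_cat <- min(2600L, max(1L, ceiling(n_leaves / 4)))
  chapters <- sample(LETTERS, min(26L, max(1L, ceiling(n_cat / 8))))
  cats <- character(0)
  while (length(cats) < n_cat) {
    cand <- paste0(sample(chapters, n_cat * 2L, replace = TRUE),
                   sprintf("%02d", sample(0:99, n_cat * 2L, replace = TRUE)))
    cats <- unique(c(cats, cand))
  }
  cats <- cats[seq_len(n_cat)]
  leaves <- character(n_leaves)
  used <- stats::setNames(vector("list", n_cat), cats)
  for (i in seq_len(n_leaves)) {
    repeat {
      cat_i <- resample(cats, 1L)
      free <- setdiff(0:9, used[[cat_i]])
      if (length(free) > 0L) break
    }
    dgt <- resample(free, 1L)
    used[[cat_i]] <- c(used[[cat_i]], dgt)
    leaves[i] <- paste0(cat_i, ".", dgt)
  }
  cats_present <- unique(substr(leaves, 1L, 3L))
  chap_present <- unique(substr(cats_present, 1L, 1L))
  labels <- c("ICD10", chap_present, cats_present, leaves)
  parent <- c(NA_integer_,
              rep(1L, length(chap_present)),
              match(substr(cats_present, 1L, 1L), labels),
              match(substr(leaves, 1L, 3L), labels))
  code_ontology(labels, parent, "diagnosis")
}

generate_ndc_tree <- function(n_leaves) {
  if (n_leaves > 9L * 99999L) {
    stopf("requested %d drug leaves exceeds the supported NDC-like label space", n_leaves)
  }
  n_ent <- max(1L, ceiling(n_leaves / 6))
  n_cat <- min(9L, max(1L, ceiling(n_ent / 5)))
  cats <- resample(1:9, n_cat)
  ent_ids <- resample(1:99999, n_ent)
  ent_cat <- resample(cats, n_ent, replace = TRUE)
  ent_of_leaf <- resample(seq_len(n_ent), n_leaves, replace = TRUE)
  count <- integer(n_ent)
  leaves <- character(n_leaves)
  for (i in seq_len(n_leaves)) {
    e <- ent_of_leaf[i]
    count[e] <- count[e] + 1L
    prod <- (count[e] - 1L) %/% 3L + 1L     # up to 3 final-digit siblings
    fin <- (count[e] - 1L) %% 3L + 1L
    leaves[i] <- sprintf("86%1d%05d%05d%1d", ent_cat[e], ent_ids[e], prod, fin)
  }
  prods <- unique(substr(leaves, 1L, 13L))
  ents <- unique(substr(leaves, 1L, 8L))
  catn <- unique(substr(leaves, 1L, 3L))
  labels <- c("NDC", "86", catn, ents, prods, leaves)
  parent <- c(NA_integer_, 1L,
              rep(2L, length(catn)),
              match(substr(ents, 1L, 3L), labels),
              match(substr(prods, 1L, 8L), labels),
              match(substr(leaves, 1L, 13L), labels))
  code_ontology(labels, parent, "drug")
}

## ---- disease profiles ------------------------------------------------------

# leaves (as indices into ontology_leaves) descending from each internal node
descendant_leaf_index <- function(ontology) {
  anc <- leaf_ancestor_list(ontology)
  idx <- new.env(parent = emptyenv())
  for (li in seq_along(anc)) {
    for (node in anc[[li]][-1L]) {
      key <- as.character(node)
      idx[[key]] <- c(idx[[key]], li)
    }
  }
  idx
}

#' Generate per-diagnosis disease profiles
#'
#' Every diagnosis leaf receives a profile: a sparse distribution over drug
#' leaves (its typical prescriptions), a sparse distribution over symptom
#' terms, and a persistence probability. Profile drugs are drawn
#' preferentially from one branch of the drug ontology (the profile's "home"
#' enterprise/category), so drugs that are ontology siblings get correlated
#' weights and the code hierarchy carries real signal.
#'
#' @param ontologies list with elements `diagnosis` and `drug`
#'   ([code_ontology()] objects).
#' @param symptoms character vector: the symptom dictionary.
#' @param config a [synthetic_config()].
#' @param seed integer seed (derived from the config by default).
#' @return named list (one element per diagnosis leaf) of `disease_profile`
#'   lists with fields `diagnosis_leaf`, `drug_distribution` (named, sums to
#'   1), `symptom_distribution`, `persistence`; the diagnosis prevalence
#'   distribution is attached as attribute `"prevalence"`.
#' @export
generate_disease_profiles <- function(ontologies, symptoms, config,
                                      seed = derive_seed(config$seed, "profiles")) {
  diag_leaves <- ontology_leaves(ontologies$diagnosis)
  drug_leaves <- ontology_leaves(ontologies$drug)
  nd <- length(drug_leaves)
  desc <- descendant_leaf_index(ontologies$drug)
  branch_nodes <- ls(desc)
  with_seed(seed, {
    profiles <- lapply(diag_leaves, function(dl) {
      support_size <- max(1L, stats::rbinom(1L, nd, config$profile_sparsity))
      home <- resample(branch_nodes, 1L)
      home_leaves <- desc[[home]]
      n_home <- stats::rbinom(1L, support_size, config$branch_affinity)
      picks <- unique(c(
        if (n_home > 0L) resample(home_leaves, min(n_home, length(home_leaves))) else integer(0),
        sample.int(nd, support_size)
      ))[seq_len(support_size)]
      w <- numeric(nd)
      w[picks] <- stats::rgamma(length(picks), shape = 2)
      sy_size <- min(length(symptoms), 1L + stats::rpois(1L, 1.5))
      sw <- numeric(length(symptoms))
      sw[sample(seq_along(symptoms), sy_size)] <- stats::rgamma(sy_size, shape = 2)
      structure(
        list(diagnosis_leaf = dl,
             drug_distribution = stats::setNames(w / sum(w), drug_leaves),
             symptom_distribution = stats::setNames(
               if (sum(sw) > 0) sw / sum(sw) else sw, symptoms),
             persistence = config$chronic_persistence),
        class = "disease_profile"
      )
    })
    names(profiles) <- diag_leaves
    prevalence <- stats::rgamma(length(diag_leaves), shape = 0.8)
    attr(profiles, "prevalence") <- stats::setNames(prevalence / sum(prevalence),
                                                    diag_leaves)
    profiles
  })
}

#' Default symptom dictionary
#'
#' Pre-tokenised symptom terms (free-text synthesis is out of scope); a fixed
#' list of common presenting complaints, padded with generated terms when more
#' are requested.
#'
#' @param n number of terms.
#' @return character vector of length `n`.
#' @export
symptom_dictionary <- function(n) {
  base <- c("fever", "cough", "headache", "fatigue", "nausea", "vomiting",
            "dizziness", "dyspnea", "chest pain", "abdominal pain", "diarrhea",
            "constipation", "rash", "pruritus", "edema", "palpitations",
            "back pain", "joint pain", "sore throat", "rhinorrhea", "chills",
            "weight loss", "anorexia", "insomnia", "hemoptysis", "dysuria",
            "polyuria", "syncope", "tremor", "anxiety")
  if (n <= length(base)) base[seq_len(n)] else {
    c(base, sprintf("symptom%03d", seq_len(n - length(base))))
  }
}

## ---- corpora ---------------------------------------------------------------

# draw one visit's code sets given active profiles
draw_visit_fields <- function(profiles, active, config, means) {
  prof <- profiles[active]
  drug_mix <- Reduce(`+`, lapply(prof, `[[`, "drug_distribution")) / length(prof)
  drug_mix <- (1 - config$background_mix) * drug_mix +
    config$background_mix / length(drug_mix)
  sym_mix <- Reduce(`+`, lapply(prof, `[[`, "symptom_distribution")) / length(prof)
  if (sum(sym_mix) == 0) sym_mix[] <- 1
  sym_mix <- (1 - config$background_mix) * sym_mix +
    config$background_mix / length(sym_mix)
  nm <- min(rztpois(1L, ztpois_lambda(means[["drug"]])), length(drug_mix))
  ns <- min(stats::rpois(1L, means[["sym"]]), length(sym_mix))
  drugs <- sample(names(drug_mix), nm, prob = drug_mix)
  syms <- if (ns > 0L) sample(names(sym_mix), ns, prob = sym_mix) else character(0)
  list(drugs = sort(drugs), symptoms = sort(syms))
}

draw_diagnoses <- function(profiles, n, prevalence) {
  n <- min(n, length(profiles))
  sort(sample(names(profiles), n, prob = prevalence))
}

#' Generate the single-visit pre-training corpus
#'
#' One visit per patient. Diagnoses are drawn from the prevalence
#' distribution; drugs and symptoms from the mixture of the selected
#' diagnoses' profiles (plus a uniform background); counts follow
#' zero-truncated Poisson distributions with the configured single-visit
#' means. Every record has at least one diagnosis and one drug.
#'
#' @param profiles output of [generate_disease_profiles()].
#' @param config a [synthetic_config()].
#' @param seed integer seed (derived from the config by default).
#' @return list of [visit_record()]s with unique patient ids.
#' @export
generate_single_visit_corpus <- function(profiles, config,
                                         seed = derive_seed(config$seed, "single")) {
  if (length(profiles) == 0L) stopf("profile map is empty")
  n <- config$n_single_visit_patients
  if (n == 0L) return(list())
  prevalence <- attr(profiles, "prevalence")
  lam_d <- ztpois_lambda(config$single_means[["diag"]])
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      diags <- draw_diagnoses(profiles, rztpois(1L, lam_d), prevalence)
      f <- draw_visit_fields(profiles, diags, config, config$single_means)
      visit_record(patient_id = sprintf("S%06d", i),
                   admission_id = sprintf("S%06d-1", i),
                   diagnoses = diags, drugs = f$drugs, symptoms = f$symptoms)
    })
  })
}

#' Generate the multi-visit fine-tuning corpus
#'
#' Each patient has at least two visits; the visit count follows the
#' configured distribution over `{2..max_visits}`. With probability
#' `chronic_persistence` each diagnosis recurs at the next visit (chronic
#' conditions), which is what makes patient history informative; drug and
#' symptom sets are re-sampled from the active profiles at every visit.
#'
#' @inheritParams generate_single_visit_corpus
#' @return list of [patient_history()] objects.
#' @export
generate_multi_visit_corpus <- function(profiles, config,
                                        seed = derive_seed(config$seed, "multi")) {
  if (length(profiles) == 0L) stopf("profile map is empty")
  vdist <- config$visit_count_distribution
  if (any(as.integer(names(vdist)) < 2L & vdist > 0)) {
    stopf("visit_count_distribution must not place mass below 2 visits")
  }
  n <- config$n_multi_visit_patients
  if (n == 0L) return(list())
  prevalence <- attr(profiles, "prevalence")
  lam_d <- ztpois_lambda(config$multi_means[["diag"]])
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      pid <- sprintf("M%06d", i)
      T_n <- as.integer(resample(names(vdist), 1L, prob = vdist))
      visits <- vector("list", T_n)
      diags <- draw_diagnoses(profiles, rztpois(1L, lam_d), prevalence)
      for (t in seq_len(T_n)) {
        if (t > 1L) {
          keep <- diags[stats::runif(length(diags)) <
                          vapply(profiles[diags], `[[`, numeric(1), "persistence")]
          target_n <- max(length(keep), rztpois(1L, lam_d))
          extra_n <- min(target_n, length(profiles)) - length(keep)
          extra <- if (extra_n > 0L) {
            pool <- setdiff(names(profiles), keep)
            sample(pool, min(extra_n, length(pool)), prob = prevalence[pool])
          } else character(0)
          diags <- sort(c(keep, extra))
          if (length(diags) == 0L) diags <- draw_diagnoses(profiles, 1L, prevalence)
        }
        f <- draw_visit_fields(profiles, diags, config, config$multi_means)
        visits[[t]] <- visit_record(patient_id = pid,
                                    admission_id = sprintf("%s-%d", pid, t),
                                    diagnoses = diags, drugs = f$drugs,
                                    symptoms = f$symptoms)
      }
      patient_history(pid, visits)
    })
  })
}

## ---- summary ---------------------------------------------------------------

#' Summary statistics of a corpus
#'
#' The statistics conventionally reported for EMR extracts: record/patient
#' counts, distinct-code counts, and average/maximum codes per visit and
#' visits per patient.
#'
#' @param records a list of [visit_record()]s, a list of
#'   [patient_history()]s, or a mix.
#' @return a `corpus_summary` list of scalars.
#' @export
corpus_summary <- function(records) {
  if (length(records) == 0L) stopf("corpus is empty")
  histories <- lapply(records, function(r) {
    if (inherits(r, "patient_history")) r
    else if (inherits(r, "visit_record")) patient_history(r$patient_id, list(r))
    else stopf("records must be visit_record or patient_history objects")
  })
  visits <- unlist(lapply(histories, `[[`, "visits"), recursive = FALSE)
  nd <- vapply(visits, function(v) length(v$diagnoses), integer(1))
  nm <- vapply(visits, function(v) length(v$drugs), integer(1))
  ns <- vapply(visits, function(v) length(v$symptoms), integer(1))
  tv <- vapply(histories, function(h) h$T, integer(1))
  out <- list(
    n_records = length(visits),
    n_patients = length(unique(vapply(histories, `[[`, character(1), "patient_id"))),
    n_diagnosis_codes = length(unique(unlist(lapply(visits, `[[`, "diagnoses")))),
    n_drug_codes = length(unique(unlist(lapply(visits, `[[`, "drugs")))),
    n_symptoms = length(unique(unlist(lapply(visits, `[[`, "symptoms")))),
    avg_diagnoses = mean(nd), avg_drugs = mean(nm), avg_symptoms = mean(ns),
    max_diagnoses = max(nd), max_drugs = max(nm), max_symptoms = max(ns),
    avg_visits = mean(tv), max_visits = max(tv)
  )
  class(out) <- "corpus_summary"
  out
}

#' @exportS3Method base::print
print.corpus_summary <- function(x, ...) {
  cat("Corpus summary\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm,
                format(x[[nm]], digits = 4)))
  }
  invisible(x)
}

#' Generate a complete synthetic study data set
#'
#' Convenience wrapper: ontologies, symptom dictionary, disease profiles,
#' single- and multi-visit corpora, optionally written to `out_dir` (EMR
#' tables in CSV, ontologies as edge lists, symptoms one per line).
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional output directory.
#' @return list with `ontologies`, `symptoms`, `profiles`, `single`, `multi`,
#'   `config`.
#' @export
simulate_corpus <- function(config = synthetic_config(), out_dir = NULL) {
  ontologies <- list(diagnosis = generate_ontology("diagnosis", config),
                     drug = generate_ontology("drug", config))
  symptoms <- symptom_dictionary(config$n_symptoms)
  profiles <- generate_disease_profiles(ontologies, symptoms, config)
  single <- generate_single_visit_corpus(profiles, config)
  multi <- generate_multi_visit_corpus(profiles, config)
  out <- list(ontologies = ontologies, symptoms = symptoms, profiles = profiles,
              single = single, multi = multi, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_ontology(ontologies$diagnosis, file.path(out_dir, "ontology_diagnosis.tsv"))
    write_ontology(ontologies$drug, file.path(out_dir, "ontology_drug.tsv"))
    writeLines(symptoms, file.path(out_dir, "symptoms.txt"))
    write_emr_table(single, file.path(out_dir, "single_visit.csv"))
    write_emr_table(multi, file.path(out_dir, "multi_visit.csv"))
  }
  out
}
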