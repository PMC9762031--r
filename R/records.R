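#' EMR visit records and patient histories
#'
#' A `visit_record` holds one admission's three code sets: diagnoses (ICD-10
#' leaf codes), drugs (NDC leaf codes) and symptom terms. A
#' `patient_history` is a patient's admission-ordered visit sequence.
#'
#' @param patient_id,admission_id identifiers (SUBJECT ID / HADM ID).
#' @param diagnoses,drugs,symptoms character vectors; duplicates are dropped
#'   (visit fields are sets).
#' @return a `visit_record` object.
#' @export
visit_record <- function(patient_id, admission_id, diagnoses = character(0),
                         drugs = character(0), symptoms = character(0)) {
  structure(
    list(patient_id = as.character(patient_id),
         admission_id = as.character(admission_id),
         diagnoses = sort(unique(as.character(diagnoses))),
         drugs = sort(unique(as.character(drugs))),
         symptoms = sort(unique(as.character(symptoms)))),
    class = "visit_record"
  )
}

#' @param visits ordered list of [visit_record()]s (admission order).
#' @rdname visit_record
#' @export
patient_history <- function(patient_id, visits) {
  if (length(visits) < 1L) stopf("a patient history needs at least one visit")
  if (!all(vapply(visits, inherits, logical(1), "visit_record"))) {
    stopf("visits must be visit_record objects")
  }
  pids <- vapply(visits, `[[`, character(1), "patient_id")
  if (!all(pids == as.character(patient_id))) {
    stopf("all visits must share the patient id '%s'", patient_id)
  }
  structure(
    list(patient_id = as.character(patient_id), visits = visits,
         T = length(visits)),
    class = "patient_history"
  )
}

#' @exportS3Method base::print
print.visit_record <- function(x, ...) {
  cat(sprintf("<visit %s/%s: %d dx, %d rx, %d sym>\n", x$patient_id,
              x$admission_id, length(x$diagnoses), length(x$drugs),
              length(x$symptoms)))
  invisible(x)
}

#' @exportS3Method base::print
print.patient_history <- function(x, ...) {
  cat(sprintf("<patient %s: %d visits>\n", x$patient_id, x$T))
  invisible(x)
}

emr_columns <- c("SUBJECT ID", "HADM ID", "ICD-10", "NDC", "SYM")

## ---- table I/O -------------------------------------------------------------

#' Read an EMR table into patient histories
#'
#' The table has five columns, `SUBJECT ID`, `HADM ID`, `ICD-10`, `NDC` and
#' `SYM`; one row per admission; multi-valued cells are delimiter-joined
#' (semicolon by default). Rows are grouped by patient and visit order is the
#' row order within each patient (admission sequence).
#'
#' @param path file path.
#' @param dialect `"csv"` or `"jsonl"` (JSON-lines, one object per row).
#' @param delim delimiter inside multi-valued cells.
#' @return list of [patient_history()] objects (file order of first
#'   appearance).
#' @export
read_emr_table <- function(path, dialect = c("csv", "jsonl"), delim = ";") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("no such file: %s", path)
  rows <- if (dialect == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    missing <- setdiff(emr_columns, names(df))
    if (length(missing) > 0L) {
      stopf("missing column(s) in EMR table: %s", paste(missing, collapse = ", "))
    }
    df
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
      as.data.frame(stats::setNames(rep(list(character(0)), 5L), emr_columns),
                    check.names = FALSE)
    } else {
      recs <- lapply(lines, function(l) jsonlite::fromJSON(l))
      missing <- setdiff(emr_columns, names(recs[[1L]]))
      if (length(missing) > 0L) {
        stopf("missing column(s) in EMR table: %s", paste(missing, collapse = ", "))
      }
      as.data.frame(do.call(rbind, lapply(recs, function(r) {
        unlist(r[emr_columns])
      })), check.names = FALSE, stringsAsFactors = FALSE) |>
        stats::setNames(emr_columns)
    }
  }
  if (nrow(rows) == 0L) return(list())
  if (anyDuplicated(rows[["HADM ID"]])) {
    dup <- rows[["HADM ID"]][duplicated(rows[["HADM ID"]])][1L]
    stopf("duplicate admission id '%s' in EMR table", dup)
  }
  split_cell <- function(x) {
    if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, delim, fixed = TRUE)[[1L]]
  }
  records <- lapply(seq_len(nrow(rows)), function(i) {
    visit_record(rows[["SUBJECT ID"]][i], rows[["HADM ID"]][i],
                 split_cell(rows[["ICD-10"]][i]),
                 split_cell(rows[["NDC"]][i]),
                 split_cell(rows[["SYM"]][i]))
  })
  pids <- rows[["SUBJECT ID"]]
  lapply(unique(pids), function(p) {
    patient_history(p, records[pids == p])
  })
}

#' Write visit records or patient histories as an EMR table
#'
#' Deterministic row order (patient then visit); re-readable by
#' [read_emr_table()].
#'
#' @param records list of [visit_record()]s and/or [patient_history()]s.
#' @inheritParams read_emr_table
#' @export
write_emr_table <- function(records, path, dialect = c("csv", "jsonl"),
                            delim = ";") {
  dialect <- match.arg(dialect)
  visits <- unlist(lapply(records, function(r) {
    if (inherits(r, "patient_history")) r$visits else list(r)
  }), recursive = FALSE)
  df <- data.frame(
    `SUBJECT ID` = vapply(visits, `[[`, character(1), "patient_id"),
    `HADM ID` = vapply(visits, `[[`, character(1), "admission_id"),
    `ICD-10` = vapply(visits, function(v) paste(v$diagnoses, collapse = delim), character(1)),
    NDC = vapply(visits, function(v) paste(v$drugs, collapse = delim), character(1)),
    SYM = vapply(visits, function(v) paste(v$symptoms, collapse = delim), character(1)),
    check.names = FALSE
  )
  if (dialect == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (nrow(df) > 0L) {
      for (i in seq_len(nrow(df))) {
        writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                    auto_unbox = TRUE), con)
      }
    }
  }
  invisible(path)
}

#' Segment a symptom phrase into terms
#'
#' Delimiter-based segmentation: split on whitespace/punctuation separators,
#' lower-case, drop stopwords ("pause words"), deduplicate. Stands in for
#' full clinical word segmentation; synthetic symptom fields are already
#' pre-tokenised.
#'
#' @param text character scalar (possibly empty).
#' @param stopwords character vector of terms to drop.
#' @param split regular expression used to split.
#' @return character vector (a set) of symptom terms.
#' @export
segment_symptoms <- function(text, stopwords = character(0),
                             split = "[,;/]+|\\s+") {
  if (length(text) == 0L || is.na(text) || !nzchar(trimws(text))) {
    return(character(0))
  }
  terms <- tolower(strsplit(trimws(text), split)[[1L]])
  terms <- terms[nzchar(terms)]
  unique(setdiff(terms, tolower(stopwords)))
}

## ---- vocabularies and tokenisation ----------------------------------------

special_tokens <- c("[PAD]", "[CLS]", "[MASK]", "[UNK]")

#' Build a vocabulary for one EMR field
#'
#' Indices are 1-based and contiguous; the four special tokens `[PAD]`,
#' `[CLS]`, `[MASK]`, `[UNK]` occupy indices 1-4 and observed codes follow in
#' sorted order, so rebuilding on the same corpus always yields identical
#' indices.
#'
#' @param codes character vector of observed codes/terms.
#' @return a `vocabulary` object: fields `tokens` (character), `n_special`,
#'   `size` (total), `n_codes` (codes only).
#' @export
vocabulary <- function(codes) {
  codes <- sort(unique(as.character(codes)))
  if (any(codes %in% special_tokens)) stopf("codes collide with special tokens")
  structure(
    list(tokens = c(special_tokens, codes),
         n_special = length(special_tokens),
         size = length(special_tokens) + length(codes),
         n_codes = length(codes)),
    class = "vocabulary"
  )
}

#' @exportS3Method base::print
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary: %d codes + %d specials>\n", x$n_codes, x$n_special))
  invisible(x)
}

vocab_index <- function(vocab, codes) {
  i <- match(codes, vocab$tokens)
  i[is.na(i)] <- match("[UNK]", vocab$tokens)
  i
}

vocab_code_index <- function(vocab, codes) {
  # index into the code-only block (1..n_codes); unknown codes are dropped
  i <- match(codes, vocab$tokens) - vocab$n_special
  i[!is.na(i) & i > 0L]
}

#' Build the three field vocabularies of a corpus
#'
#' @param records list of [visit_record()]s and/or [patient_history()]s.
#' @return list with elements `diagnosis`, `drug`, `symptom`, each a
#'   [vocabulary()].
#' @export
build_vocabularies <- function(records) {
  if (length(records) == 0L) stopf("corpus is empty")
  visits <- unlist(lapply(records, function(r) {
    if (inherits(r, "patient_history")) r$visits else list(r)
  }), recursive = FALSE)
  list(
    diagnosis = vocabulary(unlist(lapply(visits, `[[`, "diagnoses"))),
    drug = vocabulary(unlist(lapply(visits, `[[`, "drugs"))),
    symptom = vocabulary(unlist(lapply(visits, `[[`, "symptoms")))
  )
}

#' Tokenise one visit into three padded index sequences
#'
#' Each field becomes `[CLS]` followed by the field's codes (ordered by
#' vocabulary index — visit fields are sets, so a deterministic order is
#' imposed), truncated to `max_len` positions, right-padded with `[PAD]`.
#' Codes absent from the vocabulary map to `[UNK]`. A validity flag marks
#' the non-pad positions; padded positions are excluded from encoder
#' attention.
#'
#' @param record a [visit_record()].
#' @param vocabularies output of [build_vocabularies()].
#' @param max_len named integer vector with entries `diagnosis`, `drug`,
#'   `symptom`: total sequence length per field (including `[CLS]`), each at
#'   least 2.
#' @return list with elements `diagnosis`, `drug`, `symptom`; each has
#'   integer `tokens` and 0/1 `valid`, both of length `max_len[field]`.
#' @export
tokenize_visit <- function(record, vocabularies,
                           max_len = c(diagnosis = 32L, drug = 72L, symptom = 8L)) {
  if (any(max_len < 2L)) stopf("max_len must be at least 2 for every field")
  fields <- list(diagnosis = record$diagnoses, drug = record$drugs,
                 symptom = record$symptoms)
  out <- lapply(names(fields), function(f) {
    vb <- vocabularies[[f]]
    idx <- sort(vocab_index(vb, fields[[f]]))
    L <- max_len[[f]]
    idx <- idx[seq_len(min(length(idx), L - 1L))]
    tokens <- c(match("[CLS]", vb$tokens), idx,
                rep(match("[PAD]", vb$tokens), L - 1L - length(idx)))
    valid <- c(rep(1L, 1L + length(idx)), rep(0L, L - 1L - length(idx)))
    list(tokens = as.integer(tokens), valid = as.integer(valid))
  })
  names(out) <- names(fields)
  out
}

#' Split multi-visit patients into train / validation / test sets
#'
#' Patient-level split (no patient spans two sets) with a seeded shuffle.
#' With the default 4:1:1 ratio, validation and test each get `round(n/6)`
#' (at least 1) patients and the remainder trains.
#'
#' @param histories list of [patient_history()] objects.
#' @param ratio length-3 positive weights for train/validation/test.
#' @param seed integer seed for the shuffle.
#' @return list with elements `train`, `validation`, `test` (lists of
#'   histories).
#' @export
split_patients <- function(histories, ratio = c(4, 1, 1), seed = 1L) {
  n <- length(histories)
  if (n < 6L) stopf("need at least 6 patients to split, got %d", n)
  stopifnot(length(ratio) == 3L, all(ratio > 0))
  w <- ratio / sum(ratio)
  n_val <- max(1L, round(n * w[2L]))
  n_test <- max(1L, round(n * w[3L]))
  perm <- with_seed(seed, sample.int(n))
  list(
    train = histories[perm[seq_len(n - n_val - n_test)]],
    validation = histories[perm[n - n_val - n_test + seq_len(n_val)]],
    test = histories[perm[n - n_test + seq_len(n_test)]]
  )
}

# multi-hot target over the code block of a vocabulary (specials excluded)
multi_hot <- function(vocab, codes) {
  v <- numeric(vocab$n_codes)
  v[vocab_code_index(vocab, codes)] <- 1
  v
}
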