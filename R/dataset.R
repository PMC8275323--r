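# Binding records are plain data frames with columns epitope, tcr, label and
# tcr_id. TCR identity defaults to the exact sequence string, so duplicated
# sequences collapse to one id and cross-fold leakage is sequence-level.

#' @keywords internal
validate_records <- function(records, require_label = TRUE) {
  if (!is.data.frame(records)) stop("records must be a data frame")
  need <- c("epitope", "tcr", if (require_label) "label")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records are missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(records)) stop("records contain no rows")
  if (is.null(records$tcr_id)) records$tcr_id <- records$tcr
  if (require_label && !all(records$label %in% c(0, 1)))
    stop("labels must be 0 or 1")
  ok <- valid_sequence(records$epitope) & valid_sequence(records$tcr)
  if (!all(ok)) stop(sprintf("%d records carry sequences outside the alphabet", sum(!ok)))
  records
}

#' @keywords internal
valid_sequence <- function(x) {
  !is.na(x) & nzchar(x) &
    !grepl(sprintf("[^%s]", paste(gsub("\\*", "\\\\*", .AA_ALPHABET), collapse = "")), x)
}

#' Load binding records from a delimited file
#'
#' Reads a CSV or TSV table of (epitope, TCR, label) rows into the package's
#' binding-record data frame. Rows whose sequences are empty or contain
#' characters outside [aa_alphabet()], or whose label is not 0/1, are
#' dropped with a message reporting the count.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"tsv"`.
#' @param column_map Named character vector mapping the record fields to the
#'   file's column names, e.g.
#'   `c(epitope = "antigen.epitope", tcr = "cdr3", label = "bind")`. A
#'   `tcr_id` entry is optional; when absent the TCR sequence is its own id.
#' @return A data frame with columns `epitope`, `tcr`, `label`, `tcr_id`.
#' @export
load_records <- function(path, format = c("csv", "tsv"),
                         column_map = c(epitope = "epitope", tcr = "tcr",
                                        label = "label")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (format == "csv") utils::read.csv(path, stringsAsFactors = FALSE)
        else utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("epitope", "tcr", "label")
  if (!all(need %in% names(column_map)))
    stop("column_map must name columns for: ", paste(need, collapse = ", "))
  miss <- setdiff(unname(column_map), names(df))
  if (length(miss))
    stop("mapped columns absent from file: ", paste(miss, collapse = ", "))
  out <- data.frame(epitope = toupper(as.character(df[[column_map[["epitope"]]]])),
                    tcr = toupper(as.character(df[[column_map[["tcr"]]]])),
                    label = suppressWarnings(as.numeric(df[[column_map[["label"]]]])),
                    stringsAsFactors = FALSE)
  out$tcr_id <- if ("tcr_id" %in% names(column_map))
    as.character(df[[column_map[["tcr_id"]]]]) else out$tcr
  ok <- valid_sequence(out$epitope) & valid_sequence(out$tcr) &
    !is.na(out$label) & out$label %in% c(0, 1)
  if (any(!ok)) message(sprintf("dropped %d invalid rows", sum(!ok)))
  out <- out[ok, , drop = FALSE]
  if (!nrow(out)) stop("no valid rows in ", path)
  rownames(out) <- NULL
  out
}

#' Curation settings
#'
#' @param min_tcrs_per_epitope Epitopes with fewer associated TCRs are
#'   removed entirely (default 15).
#' @param max_tcrs_per_epitope Epitopes with more TCRs are randomly
#'   downsampled to this many (default 400).
#' @param rng_seed Seed for the downsampling draw.
#' @return An object of class `curation_config`.
#' @export
curation_config <- function(min_tcrs_per_epitope = 15L,
                            max_tcrs_per_epitope = 400L, rng_seed = 1L) {
  stopifnot(min_tcrs_per_epitope >= 1L,
            min_tcrs_per_epitope <= max_tcrs_per_epitope)
  structure(list(min_tcrs_per_epitope = as.integer(min_tcrs_per_epitope),
                 max_tcrs_per_epitope = as.integer(max_tcrs_per_epitope),
                 rng_seed = as.integer(rng_seed)),
            class = "curation_config")
}

#' Curate a positive binding dataset
#'
#' Deduplicates TCRs within each epitope, removes epitopes with fewer than
#' `min_tcrs_per_epitope` associated TCRs, and uniformly downsamples (without
#' replacement, seeded) epitopes with more than `max_tcrs_per_epitope`.
#' Idempotent: curating an already-curated dataset changes nothing.
#'
#' @param records Positive records only (all labels 1).
#' @param config A [curation_config()].
#' @return The curated record data frame, in the original row order
#'   restricted to the surviving rows.
#' @export
curate_dataset <- function(records, config = curation_config()) {
  records <- validate_records(records, require_label = TRUE)
  if (!all(records$label == 1)) stop("curate_dataset expects positive records only")
  dup <- duplicated(records[, c("epitope", "tcr_id")])
  records <- records[!dup, , drop = FALSE]
  census <- table(records$epitope)
  keep_epi <- names(census)[census >= config$min_tcrs_per_epitope]
  if (!length(keep_epi)) {
    msg <- paste(sprintf("%s:%d", names(census), as.integer(census)), collapse = ", ")
    stop("no epitope passes the minimum TCR count; census: ", msg)
  }
  records <- records[records$epitope %in% keep_epi, , drop = FALSE]
  keep <- with_seed(config$rng_seed, {
    idx <- logical(nrow(records))
    for (e in sort(unique(records$epitope))) {
      rows <- which(records$epitope == e)
      if (length(rows) > config$max_tcrs_per_epitope)
        rows <- sort(sample(rows, config$max_tcrs_per_epitope))
      idx[rows] <- TRUE
    }
    idx
  })
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate negatives by shuffling TCR-epitope pairings
#'
#' Pairs each TCR with epitopes it has not been observed to bind, producing
#' exactly as many label-0 records per TCR as it has label-1 records, so the
#' returned dataset is balanced 50/50. When `scope` (a fold id per record)
#' is given, shuffling happens strictly within each fold, preserving
#' fold-level disjointness of TCRs and epitopes.
#'
#' @param records Positive records only.
#' @param scope Optional integer vector of fold ids aligned with `records`.
#' @param rng_seed Seed; the negative set is reproducible bit for bit.
#' @return The input records plus the generated negatives (with a `fold`
#'   column when `scope` was given). TCRs for which no non-bound epitope
#'   exists in scope contribute no negatives, with a warning.
#' @export
generate_negatives <- function(records, scope = NULL, rng_seed = 1L) {
  records <- validate_records(records, require_label = TRUE)
  if (!all(records$label == 1)) stop("generate_negatives expects positive records only")
  scoped <- !is.null(scope)
  if (!scoped) scope <- rep(1L, nrow(records))
  stopifnot(length(scope) == nrow(records))
  pos_key <- paste(records$epitope, records$tcr_id, sep = "\r")
  negs <- with_seed(rng_seed, {
    out <- vector("list", 0L)
    dropped <- 0L
    for (f in sort(unique(scope))) {
      in_f <- scope == f
      epis <- sort(unique(records$epitope[in_f]))
      by_tcr <- split(which(in_f), records$tcr_id[in_f])
      for (id in names(by_tcr)) {
        rows <- by_tcr[[id]]
        m <- length(rows)
        cand <- setdiff(epis, records$epitope[rows])
        if (!length(cand)) { dropped <- dropped + m; next }
        drawn <- if (length(cand) >= m) sample(cand, m)
                 else sample(cand, m, replace = TRUE)
        out[[length(out) + 1L]] <- data.frame(
          epitope = drawn, tcr = records$tcr[rows[1L]], label = 0,
          tcr_id = id, fold = f, stringsAsFactors = FALSE)
      }
    }
    if (dropped > 0L)
      warning(sprintf("no admissible negative epitope for %d positive records; negatives omitted",
                      dropped))
    do.call(rbind, out)
  })
  records$fold <- scope
  out <- rbind(records[, c("epitope", "tcr", "label", "tcr_id", "fold")],
               negs)
  if (!scoped) out$fold <- NULL
  rownames(out) <- NULL
  out
}

#' Assign records to cross-validation folds
#'
#' Two protocols:
#' \describe{
#'   \item{`tcr_split`}{TCRs are randomly assigned to folds (shuffled
#'     round-robin) and every record follows its TCR, so no TCR spans two
#'     folds; epitopes may.}
#'   \item{`strict_split`}{epitopes are assigned to folds by greedy record-
#'     count balancing (largest epitope first into the currently smallest
#'     fold, seeded shuffle among equal sizes); records follow their
#'     epitope. A TCR that then appears with epitopes of several folds is
#'     kept only in the fold holding most of its records (ties to the lowest
#'     fold index); its records elsewhere are dropped.}
#' }
#'
#' @param records Binding records (typically curated positives; negatives
#'   are generated per fold afterwards with [generate_negatives()]).
#' @param n_folds Number of folds (default 10).
#' @param mode `"tcr_split"` or `"strict_split"`.
#' @param rng_seed Seed for the random assignments.
#' @return An object of class `fold_assignment`: list with `n_folds`,
#'   `mode`, `fold_of` (integer per record, `NA` for records dropped in
#'   strict mode) and `n_dropped`.
#' @export
make_folds <- function(records, n_folds = 10L,
                       mode = c("tcr_split", "strict_split"), rng_seed = 1L) {
  mode <- match.arg(mode)
  records <- validate_records(records, require_label = FALSE)
  n_folds <- as.integer(n_folds)
  stopifnot(n_folds >= 1L)
  n_dropped <- 0L
  if (mode == "tcr_split") {
    ids <- unique(records$tcr_id)
    if (n_folds > length(ids))
      stop(sprintf("n_folds = %d exceeds the %d distinct TCRs", n_folds, length(ids)))
    fold_of_id <- with_seed(rng_seed, {
      perm <- sample(ids)
      stats::setNames(rep_len(seq_len(n_folds), length(ids)), perm)
    })
    fold_of <- unname(fold_of_id[records$tcr_id])
  } else {
    epis <- unique(records$epitope)
    if (n_folds > length(epis))
      stop(sprintf("n_folds = %d exceeds the %d distinct epitopes", n_folds, length(epis)))
    counts <- table(records$epitope)
    fold_of_epi <- with_seed(rng_seed, {
      ord <- names(counts)[order(-as.integer(counts), sample(length(counts)))]
      sizes <- integer(n_folds)
      assign <- stats::setNames(integer(length(ord)), ord)
      for (e in ord) {
        f <- which.min(sizes)
        assign[e] <- f
        sizes[f] <- sizes[f] + counts[[e]]
      }
      assign
    })
    fold_of <- unname(fold_of_epi[records$epitope])
    # resolve TCRs spanning folds: keep the fold with most of their records
    tab <- table(records$tcr_id, fold_of)
    multi <- rownames(tab)[rowSums(tab > 0) > 1L]
    for (id in multi) {
      keep_fold <- as.integer(colnames(tab)[which.max(tab[id, ])])
      drop_rows <- which(records$tcr_id == id & fold_of != keep_fold)
      fold_of[drop_rows] <- NA_integer_
      n_dropped <- n_dropped + length(drop_rows)
    }
    if (n_dropped > 0L)
      message(sprintf("strict split: dropped %d records of TCRs spanning several folds",
                      n_dropped))
  }
  structure(list(n_folds = n_folds, mode = mode, fold_of = fold_of,
                 n_dropped = n_dropped, rng_seed = as.integer(rng_seed)),
            class = "fold_assignment")
}

#' Attach fold ids to records
#'
#' @param records The records passed to [make_folds()].
#' @param fa The resulting `fold_assignment`.
#' @return The records with a `fold` column; rows dropped by the strict
#'   split are removed.
#' @export
apply_folds <- function(records, fa) {
  stopifnot(inherits(fa, "fold_assignment"),
            length(fa$fold_of) == nrow(records))
  records$fold <- fa$fold_of
  out <- records[!is.na(records$fold), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment: %s, %d folds, %d records%s>\n", x$mode,
              x$n_folds, sum(!is.na(x$fold_of)),
              if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""))
  invisible(x)
}

#' Preprocess a compound-protein interaction table for pretraining
#'
#' Treats every listed (ligand SMILES, protein) pair as binding (label 1),
#' discards ligands longer than `max_smiles_tokens` SMILES tokens and
#' proteins longer than `max_protein_len` residues, generates an equal-sized
#' negative set by randomly re-assigning ligands to proteins (rejecting
#' draws that reproduce a listed pair), and splits into training and
#' validation parts.
#'
#' @param pairs Data frame with columns `smiles` and `protein` (an
#'   `affinity` column, if present, is ignored after binarization).
#' @param max_smiles_tokens Maximum tokenized SMILES length (default 250).
#' @param max_protein_len Maximum protein length in residues (default 1028).
#' @param train_fraction Fraction of examples used for training (default
#'   0.9).
#' @param rng_seed Seed for negative sampling and the split.
#' @return A list with data frames `train` and `validation`, each with
#'   columns `smiles`, `protein`, `label`.
#' @export
preprocess_cpi <- function(pairs, max_smiles_tokens = 250L,
                           max_protein_len = 1028L, train_fraction = 0.9,
                           rng_seed = 1L) {
  if (!is.data.frame(pairs) || !all(c("smiles", "protein") %in% names(pairs)))
    stop("pairs must be a data frame with columns 'smiles' and 'protein'")
  if (!nrow(pairs)) stop("empty CPI table")
  ntok <- vapply(pairs$smiles, function(s) length(smiles_token_strings(s)), integer(1))
  ok <- ntok <= max_smiles_tokens & nchar(pairs$protein) <= max_protein_len
  pairs <- pairs[ok, c("smiles", "protein"), drop = FALSE]
  if (!nrow(pairs)) stop("no CPI pairs survive the length filters")
  pairs$label <- 1
  pos_key <- paste(pairs$smiles, pairs$protein, sep = "\r")
  out <- with_seed(rng_seed, {
    ligands <- unique(pairs$smiles)
    neg <- pairs
    neg$label <- 0
    for (i in seq_len(nrow(neg))) {
      for (try in 1:100) {
        lig <- sample(ligands, 1L)
        if (!(paste(lig, neg$protein[i], sep = "\r") %in% pos_key)) break
        lig <- NA_character_
      }
      neg$smiles[i] <- lig
    }
    if (anyNA(neg$smiles)) {
      warning(sprintf("dropped %d negatives without admissible ligand", sum(is.na(neg$smiles))))
      neg <- neg[!is.na(neg$smiles), , drop = FALSE]
    }
    all <- rbind(pairs, neg)
    n_train <- floor(train_fraction * nrow(all))
    tr_idx <- sample(nrow(all), n_train)
    list(train = all[sort(tr_idx), , drop = FALSE],
         validation = all[-sort(tr_idx), , drop = FALSE])
  })
  rownames(out$train) <- rownames(out$validation) <- NULL
  out
}

#' Write a curated dataset with its provenance sidecar
#'
#' @param records Records (optionally with a `fold` column).
#' @param path Output CSV path; a JSON sidecar `<path>.json` records the
#'   per-epitope census and the seed.
#' @param rng_seed Seed recorded in the sidecar.
#' @return Invisibly, the paths written.
#' @export
write_records <- function(records, path, rng_seed = NA_integer_) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  census <- as.list(table(records$epitope))
  side <- list(n_records = nrow(records),
               n_positive = if (!is.null(records$label)) sum(records$label == 1) else NA,
               epitope_census = census, rng_seed = rng_seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(c(path, paste0(path, ".json")))
}
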