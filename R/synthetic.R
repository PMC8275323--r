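# Synthetic repertoires emulate the shape of curated TCR-epitope data: tens
# of epitopes, each paired with many CDR3-like sequences, balanced labels,
# and a recoverable binding rule so that learnability is verifiable.

#' Settings for the synthetic benchmark generator
#'
#' @param n_epitopes Number of distinct epitopes (default 30).
#' @param tcrs_per_epitope Positive TCRs per epitope: a single count
#'   (default 100) or a range `c(lo, hi)` from which per-epitope counts are
#'   drawn uniformly (e.g. `c(15, 400)` to exercise curation).
#' @param epitope_len Length range of the random epitopes (default 8-11).
#' @param cdr3_len Length range of the random CDR3-like TCR sequences
#'   (default 10-18).
#' @param motif_len Length of the planted contiguous binding motif
#'   (default 3).
#' @param label_noise Probability in [0, 0.5) that a label is flipped
#'   (default 0.05).
#' @param rule `"motif_match"`: an epitope binds exactly the TCRs carrying
#'   its motif, and generated non-binders carry no motif at all.
#'   `"epitope_class_only"`: binding depends only on the epitope's own
#'   Bernoulli base rate, so the TCR sequence carries no signal -- the
#'   degenerate regime in which a model can only act as an epitope
#'   classifier.
#' @param rng_seed Seed; generation is reproducible bit for bit.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_epitopes = 30L, tcrs_per_epitope = 100L,
                             epitope_len = c(8L, 11L), cdr3_len = c(10L, 18L),
                             motif_len = 3L, label_noise = 0.05,
                             rule = c("motif_match", "epitope_class_only"),
                             rng_seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(n_epitopes >= 2L, all(tcrs_per_epitope >= 1L),
            length(epitope_len) == 2L, epitope_len[1] <= epitope_len[2],
            length(cdr3_len) == 2L, cdr3_len[1] <= cdr3_len[2],
            motif_len >= 1L, motif_len < cdr3_len[1],
            label_noise >= 0, label_noise < 0.5)
  structure(list(n_epitopes = as.integer(n_epitopes),
                 tcrs_per_epitope = as.integer(tcrs_per_epitope),
                 epitope_len = as.integer(epitope_len),
                 cdr3_len = as.integer(cdr3_len),
                 motif_len = as.integer(motif_len),
                 label_noise = label_noise, rule = rule,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

#' @keywords internal
random_aa <- function(n, len_range) {
  lens <- if (len_range[1] == len_range[2]) rep(len_range[1], n)
          else sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(.STANDARD_AA, L, replace = TRUE), collapse = ""), character(1))
}

#' Generate a synthetic binding benchmark with a planted rule
#'
#' Draws random epitopes and CDR3-like TCR sequences (uniform composition
#' over the 20 standard residues). Under the `motif_match` rule each epitope
#' is assigned a unique contiguous motif; its positive TCRs carry that motif
#' at a random internal position (and no other epitope's motif), while
#' paired negatives carry no motif at all, giving an exactly balanced
#' dataset before noise. Under `epitope_class_only` every TCR is unrelated
#' to its label, which follows the epitope's Bernoulli base rate. Labels
#' are then flipped independently with probability `label_noise`.
#'
#' @param config A [synthetic_config()].
#' @return A list with `records` (data frame: `epitope`, `tcr`, `label`,
#'   `tcr_id`) and `rule`, the planted-rule manifest (class `planted_rule`)
#'   holding the epitope-to-motif map or the base rates plus the settings.
#' @export
generate_benchmark <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$rng_seed, {
    epitopes <- character(0)
    while (length(unique(epitopes)) < config$n_epitopes)
      epitopes <- unique(c(epitopes, random_aa(config$n_epitopes, config$epitope_len)))
    epitopes <- epitopes[seq_len(config$n_epitopes)]

    counts <- if (length(config$tcrs_per_epitope) == 2L)
      sample(seq(config$tcrs_per_epitope[1], config$tcrs_per_epitope[2]),
             config$n_epitopes, replace = TRUE)
    else rep(config$tcrs_per_epitope, config$n_epitopes)

    if (config$rule == "motif_match") {
      motifs <- character(0)
      for (try in 1:1000) {
        motifs <- unique(random_aa(config$n_epitopes * 2L,
                                   rep(config$motif_len, 2L)))
        if (length(motifs) >= config$n_epitopes) break
      }
      motifs <- motifs[seq_len(config$n_epitopes)]
      names(motifs) <- epitopes
      contains_any <- function(s) {
        for (m in motifs) if (grepl(m, s, fixed = TRUE)) return(TRUE)
        FALSE
      }
      recs <- vector("list", config$n_epitopes * 2L)
      for (i in seq_len(config$n_epitopes)) {
        e <- epitopes[i]; m <- motifs[[i]]; n <- counts[i]
        pos <- character(n); neg <- character(n)
        for (j in seq_len(n)) {
          # positive: random CDR3 with the motif spliced in at an internal
          # position, rejected if any other epitope's motif appears
          repeat {
            s <- random_aa(1L, config$cdr3_len)
            at <- sample(seq(2L, nchar(s) - config$motif_len), 1L)
            substr(s, at, at + config$motif_len - 1L) <- m
            hit <- FALSE
            for (mm in motifs) if (mm != m && grepl(mm, s, fixed = TRUE)) { hit <- TRUE; break }
            if (!hit && grepl(m, s, fixed = TRUE)) { pos[j] <- s; break }
          }
          repeat {  # negative: motif-free random CDR3
            s <- random_aa(1L, config$cdr3_len)
            if (!contains_any(s)) { neg[j] <- s; break }
          }
        }
        recs[[2L * i - 1L]] <- data.frame(epitope = e, tcr = pos, label = 1,
                                          stringsAsFactors = FALSE)
        recs[[2L * i]] <- data.frame(epitope = e, tcr = neg, label = 0,
                                     stringsAsFactors = FALSE)
      }
      records <- do.call(rbind, recs)
      rule <- structure(list(rule = "motif_match", motifs = as.list(motifs),
                             config = unclass(config)), class = "planted_rule")
    } else {
      base_rates <- stats::runif(config$n_epitopes, 0.2, 0.8)
      names(base_rates) <- epitopes
      recs <- vector("list", config$n_epitopes)
      for (i in seq_len(config$n_epitopes)) {
        n <- counts[i]
        recs[[i]] <- data.frame(epitope = epitopes[i],
                                tcr = random_aa(n, config$cdr3_len),
                                label = stats::rbinom(n, 1L, base_rates[i]),
                                stringsAsFactors = FALSE)
      }
      records <- do.call(rbind, recs)
      rule <- structure(list(rule = "epitope_class_only",
                             base_rates = as.list(base_rates),
                             config = unclass(config)), class = "planted_rule")
    }
    if (config$label_noise > 0) {
      flip <- stats::runif(nrow(records)) < config$label_noise
      records$label[flip] <- 1 - records$label[flip]
    }
    records$tcr_id <- records$tcr
    rownames(records) <- NULL
    list(records = records, rule = rule)
  })
}

#' @export
print.planted_rule <- function(x, ...) {
  cat(sprintf("<planted_rule: %s, %d epitopes, noise %.2f>\n", x$rule,
              length(if (x$rule == "motif_match") x$motifs else x$base_rates),
              x$config$label_noise))
  invisible(x)
}

#' Write a synthetic benchmark to disk
#'
#' Writes the records as a CSV in the input dialect of [load_records()] and
#' the planted rule as a JSON manifest, so a benchmark can be audited and
#' reloaded.
#'
#' @param records,rule As returned by [generate_benchmark()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_benchmark <- function(records, rule, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "records.csv")
  js <- file.path(out_dir, "rule.json")
  utils::write.csv(records[, c("epitope", "tcr", "label", "tcr_id")], csv,
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(rule), js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv, js))
}
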