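#' Extract per-token attention maps from a model
#'
#' Runs the model in evaluation mode over (TCR, epitope) pairs and returns
#' one attention row per pair for each stream. Each channel produces its own
#' softmax attention; the reported map is the mean over channels, which
#' itself sums to one.
#'
#' @param model A `titan_model`.
#' @param pairs Data frame with columns `tcr` and `epitope`.
#' @param batch_size Scoring batch size.
#' @return A list with two `attention_matrix` objects, `tcr` and `epitope`:
#'   numeric matrices (rows = pairs, columns = token positions) with
#'   attributes `reference` (the row's own sequence) and `context` (the
#'   partner sequence).
#' @export
extract_attention <- function(model, pairs, batch_size = 256L) {
  stopifnot(inherits(model, "titan_model"))
  pairs <- validate_records(pairs, require_label = FALSE)
  data <- encode_binding_data(pairs, model$config)
  n <- nrow(data$tok_t)
  mt <- matrix(NA_real_, n, model$config$tcr_len)
  me <- matrix(NA_real_, n, model$config$epitope_len)
  for (s in seq(1L, n, by = batch_size)) {
    rows <- s:min(s + batch_size - 1L, n)
    fw <- titan_forward(model, data$tok_t[rows, , drop = FALSE],
                        data$tok_e[rows, , drop = FALSE],
                        keep_attention = TRUE)
    mt[rows, ] <- Reduce(`+`, fw$attention$tcr) / length(fw$attention$tcr)
    me[rows, ] <- Reduce(`+`, fw$attention$epi) / length(fw$attention$epi)
  }
  list(tcr = structure(mt, class = c("attention_matrix", "matrix"),
                       reference = pairs$tcr, context = pairs$epitope),
       epitope = structure(me, class = c("attention_matrix", "matrix"),
                           reference = pairs$epitope, context = pairs$tcr))
}

#' Attention variance statistics
#'
#' Quantifies how much the attention maps adapt to the input and to the
#' binding partner:
#' \describe{
#'   \item{inter}{variance, per token position, of the group-mean attention
#'     across groups (e.g. across different TCRs), averaged over tokens --
#'     how much attention differs between reference sequences;}
#'   \item{intra}{variance, per token position, across the rows within a
#'     group (the same reference under different contexts), averaged over
#'     tokens and then over groups -- how much attention adapts to the
#'     context.}
#' }
#'
#' @param matrix An `attention_matrix` (or plain matrix of attention rows).
#' @param groups Grouping factor over the rows, typically the reference
#'   sequence; defaults to the `reference` attribute.
#' @param estimator `"population"` (divide by n) or `"sample"` (divide by
#'   n - 1).
#' @return List with `inter` and `intra`; `intra` is `NA` when no group
#'   has at least two rows.
#' @export
attention_variances <- function(matrix, groups = attr(matrix, "reference"),
                                estimator = c("population", "sample")) {
  estimator <- match.arg(estimator)
  m <- unclass(matrix)
  if (is.null(groups)) stop("no grouping available")
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups for the inter variance")
  vfun <- if (estimator == "population")
    function(x) mean((x - mean(x))^2) else stats::var
  gmeans <- rowsum(m, groups) / as.vector(table(groups))
  inter <- mean(apply(gmeans, 2L, vfun))
  sizes <- table(groups)
  multi <- names(sizes)[sizes >= 2L]
  intra <- if (!length(multi)) NA_real_ else
    mean(vapply(multi, function(g)
      mean(apply(m[groups == g, , drop = FALSE], 2L, vfun)), numeric(1)))
  list(inter = inter, intra = intra)
}

#' Compress epitopes to their high-attention residues
#'
#' Reduces each epitope to the ordered chain of residues whose attention
#' weight strictly exceeds `threshold`, and reports how many of the
#' compressed strings remain unique within the set. A near-total uniqueness
#' despite heavy compression indicates the attention acts as a fixed
#' epitope fingerprint (the model classifies epitopes) rather than reading
#' their composition.
#'
#' @param epitopes Character vector of epitope sequences.
#' @param alpha Residue-aligned attention: a matrix with one row per
#'   epitope whose first `nchar(epitope)` columns carry the residue
#'   weights (e.g. from [residue_attention()]), or a list of numeric
#'   vectors.
#' @param threshold Keep residues with attention strictly above this value
#'   (default 0.1). At 0 the compression is the identity.
#' @return List with `compressed` (character vector), `n_unique` (number of
#'   epitopes whose compressed string occurs exactly once) and
#'   `fraction_unique`.
#' @export
compress_epitopes <- function(epitopes, alpha, threshold = 0.1) {
  n <- length(epitopes)
  if (is.matrix(alpha)) alpha <- lapply(seq_len(n), function(i) alpha[i, ])
  stopifnot(length(alpha) == n)
  compressed <- vapply(seq_len(n), function(i) {
    chars <- strsplit(epitopes[i], "", fixed = TRUE)[[1]]
    a <- alpha[[i]][seq_along(chars)]
    paste(chars[a > threshold], collapse = "")
  }, character(1))
  counts <- table(compressed)
  # index by position, not name: empty compressed strings are legal keys
  n_unique <- sum(counts[match(compressed, names(counts))] == 1L)
  list(compressed = compressed, n_unique = as.integer(n_unique),
       fraction_unique = n_unique / n)
}

#' Residue-aligned attention rows
#'
#' Slices the flank and padding columns off an `attention_matrix`, leaving
#' per-row vectors aligned with the residues (or SMILES tokens) of the
#' reference sequences.
#'
#' @param matrix An `attention_matrix`.
#' @param sequences Reference sequences; defaults to the `reference`
#'   attribute. Content length is taken as `nchar(sequence)` (use token
#'   counts for SMILES streams).
#' @param lengths Optional explicit content lengths overriding `sequences`.
#' @return A list of numeric vectors, one per row.
#' @export
residue_attention <- function(matrix, sequences = attr(matrix, "reference"),
                              lengths = NULL) {
  m <- unclass(matrix)
  if (is.null(lengths)) lengths <- nchar(sequences)
  stopifnot(length(lengths) == nrow(m))
  lapply(seq_len(nrow(m)), function(i) m[i, 1L + seq_len(lengths[i])])
}

#' Average attention rows per unique reference
#'
#' When the same epitope occurs under many TCR contexts, its compression
#' should use the context-averaged attention row (the intra-reference
#' variance is typically negligible). Returns one row per unique reference.
#'
#' @param matrix An `attention_matrix`.
#' @return A list with `references` and `alpha` (matrix, one row per unique
#'   reference).
#' @export
aggregate_attention <- function(matrix) {
  refs <- attr(matrix, "reference")
  m <- unclass(matrix)
  f <- factor(refs, levels = unique(refs))
  avg <- rowsum(m, f) / as.vector(table(f))
  dimnames(avg) <- NULL
  list(references = levels(f), alpha = avg)
}

#' @export
print.attention_matrix <- function(x, ...) {
  cat(sprintf("<attention_matrix: %d rows x %d positions>\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Heatmap of attention rows
#'
#' @param x An `attention_matrix`.
#' @param max_cols Trim the position axis (default: up to the longest
#'   content plus flanks).
#' @param ... Passed to [graphics::image()].
#' @export
plot.attention_matrix <- function(x, max_cols = NULL, ...) {
  m <- unclass(x)
  if (is.null(max_cols))
    max_cols <- min(ncol(m), max(nchar(attr(x, "reference"))) + 2L)
  m <- m[, seq_len(max_cols), drop = FALSE]
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  xlab = "token position", ylab = "pair",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Export attention rows as TSV
#'
#' @param x An `attention_matrix`.
#' @param path Output path (positions as columns).
#' @return The path, invisibly.
#' @export
write_attention_tsv <- function(x, path) {
  df <- as.data.frame(unclass(x))
  names(df) <- paste0("pos", seq_len(ncol(df)))
  df <- cbind(reference = attr(x, "reference"), context = attr(x, "context"), df)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
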