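#' Tokenize an amino-acid sequence
#'
#' Converts a protein (or peptide) sequence into a fixed-length vector of
#' integer token indices: a <START> flank (index 1), one token per residue,
#' a <STOP> flank (index 1 again, the two flanks share an index), and zero
#' padding up to `max_len`.
#'
#' @param seq Non-empty uppercase amino-acid string over [aa_alphabet()].
#' @param max_len Total padded length (default 500). The sequence itself may
#'   be at most `max_len - 2` residues to leave room for the flanks.
#' @return An object of class `token_sequence`: a list with `tokens`
#'   (integer vector of length `max_len`), `content_length` (number of
#'   residue tokens), `max_len` and `kind = "protein"`.
#' @examples
#' ts <- tokenize_protein("CASS", max_len = 10)
#' ts$tokens  # 1, then residue tokens, then 1, then zeros
#' @export
tokenize_protein <- function(seq, max_len = 500L) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("'seq' must be a single non-empty string")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, .AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop(sprintf("sequence contains characters outside the amino-acid alphabet: %s",
                 paste(bad, collapse = ", ")))
  }
  n <- length(idx)
  if (n > max_len - 2L)
    stop(sprintf("sequence of %d residues does not fit in max_len = %d (need %d)",
                 n, max_len, n + 2L))
  tokens <- integer(max_len)
  tokens[1L] <- .FLANK_INDEX
  tokens[1L + seq_len(n)] <- idx + 1L  # residue tokens start at index 2
  tokens[n + 2L] <- .FLANK_INDEX
  structure(list(tokens = tokens, content_length = n,
                 max_len = as.integer(max_len), kind = "protein"),
            class = "token_sequence")
}

#' Embed a token sequence as a numeric matrix
#'
#' Looks every token index up in the embedding table of `spec`. Padding
#' positions map to the all-zero pad row.
#'
#' @param ts A `token_sequence` (from [tokenize_protein()] or
#'   [tokenize_smiles()]).
#' @param spec An [embedding_spec()].
#' @return A `max_len` x `dim` numeric matrix; row i is the embedding of
#'   token i.
#' @export
embed_tokens <- function(ts, spec) {
  stopifnot(inherits(ts, "token_sequence"), inherits(spec, "embedding_spec"))
  if (max(ts$tokens) + 1L > nrow(spec$table))
    stop(sprintf("token index %d has no row in the embedding table (%d rows)",
                 max(ts$tokens), nrow(spec$table)))
  spec$table[ts$tokens + 1L, , drop = FALSE]
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("<token_sequence: %s, %d content tokens, padded to %d>\n",
              x$kind, x$content_length, x$max_len))
  invisible(x)
}

# Tokenize many sequences into a matrix (rows = sequences); used by the
# model pipeline. Caches per unique sequence.
#' @keywords internal
tokenize_protein_matrix <- function(seqs, max_len) {
  uq <- unique(seqs)
  tok <- vapply(uq, function(s) tokenize_protein(s, max_len)$tokens,
                integer(max_len))
  t(tok)[match(seqs, uq), , drop = FALSE]
}
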