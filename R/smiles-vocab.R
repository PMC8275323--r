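# Atom-level SMILES tokenization: bracket expressions, two-letter elements
# (Cl, Br), ring-closure digits (including %nn), and bond/branch symbols are
# each one token.

.SMILES_TOKEN_RE <- paste0(
  "\\[[^][]*\\]",          # bracket atom, e.g. [C@@H], [nH]
  "|Br|Cl",                # two-letter organic-subset elements
  "|%[0-9]{2}",            # two-digit ring closure
  "|[BCNOSPFIbcnosp]",     # one-letter elements (aromatic lowercase)
  "|[0-9]",                # ring closure digit
  "|[=#$:/\\\\+\\-().*@H]" # bonds, branches, charges, bare stereo/H
)

#' Split a SMILES string into atom-level tokens
#'
#' @param text SMILES string.
#' @return Character vector of tokens whose concatenation reproduces the
#'   input exactly.
#' @examples
#' smiles_token_strings("C(Cl)Br")  # "C" "(" "Cl" ")" "Br"
#' @export
smiles_token_strings <- function(text) {
  text <- as.character(text)
  m <- gregexpr(.SMILES_TOKEN_RE, text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (paste(toks, collapse = "") != text) {
    covered <- strsplit(paste(toks, collapse = ""), "")[[1]]
    stop("SMILES contains untokenizable characters: ", text)
  }
  toks
}

#' Build a SMILES token vocabulary from a corpus
#'
#' Token indices are stable: 0 is padding, 1 the shared <START>/<STOP>
#' flank, 2 the unknown token, and the corpus tokens follow in sorted
#' order. To make the vocabulary closed under augmentation, include some
#' randomized SMILES of the corpus molecules (see [augment_smiles()]) in
#' `smiles`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return An object of class `smiles_vocabulary`.
#' @export
build_smiles_vocab <- function(smiles) {
  toks <- sort(unique(unlist(lapply(smiles, smiles_token_strings))))
  if (!length(toks)) stop("empty SMILES corpus")
  structure(list(tokens = toks,
                 index = stats::setNames(seq_along(toks) + 2L, toks),
                 unk_index = 2L),
            class = "smiles_vocabulary")
}

#' @keywords internal
vocab_size <- function(vocab) {
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  length(vocab$tokens) + 3L  # pad, flank, unk + tokens
}

#' @export
print.smiles_vocabulary <- function(x, ...) {
  cat(sprintf("<smiles_vocabulary: %d tokens (+pad/flank/unk)>\n", length(x$tokens)))
  invisible(x)
}

#' Persist / restore a SMILES vocabulary
#'
#' @param vocab A `smiles_vocabulary`.
#' @param path JSON file path.
#' @return `save_smiles_vocab` returns the path invisibly;
#'   `load_smiles_vocab` the restored vocabulary.
#' @export
save_smiles_vocab <- function(vocab, path) {
  jsonlite::write_json(list(tokens = vocab$tokens), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname save_smiles_vocab
#' @export
load_smiles_vocab <- function(path) {
  toks <- jsonlite::read_json(path, simplifyVector = TRUE)$tokens
  structure(list(tokens = toks,
                 index = stats::setNames(seq_along(toks) + 2L, toks),
                 unk_index = 2L),
            class = "smiles_vocabulary")
}

#' Tokenize a SMILES string to a padded token sequence
#'
#' Atom-level tokens are mapped through the vocabulary, flanked by the
#' <START>/<STOP> token and zero-padded, mirroring the protein tokenizer.
#' Tokens missing from the vocabulary map to the unknown index with a
#' warning.
#'
#' @param s SMILES string.
#' @param vocab A [build_smiles_vocab()] vocabulary.
#' @param max_len Total padded length.
#' @return A `token_sequence` with `kind = "smiles"`.
#' @export
tokenize_smiles <- function(s, vocab, max_len = 500L) {
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  toks <- smiles_token_strings(s)
  idx <- unname(vocab$index[toks])
  if (anyNA(idx)) {
    warning(sprintf("%d SMILES tokens not in vocabulary mapped to <UNK>: %s",
                    sum(is.na(idx)),
                    paste(unique(toks[is.na(idx)]), collapse = " ")))
    idx[is.na(idx)] <- vocab$unk_index
  }
  n <- length(idx)
  if (n > max_len - 2L)
    stop(sprintf("SMILES of %d tokens does not fit in max_len = %d", n, max_len))
  tokens <- integer(max_len)
  tokens[1L] <- .FLANK_INDEX
  tokens[1L + seq_len(n)] <- idx
  tokens[n + 2L] <- .FLANK_INDEX
  structure(list(tokens = tokens, content_length = n,
                 max_len = as.integer(max_len), kind = "smiles"),
            class = "token_sequence")
}
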