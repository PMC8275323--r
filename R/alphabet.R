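# Token conventions shared by both input streams: index 0 is padding, index 1
# is the shared <START>/<STOP> flank token, residue/atom tokens start at 2.

#' @keywords internal
.PAD_INDEX <- 0L

#' @keywords internal
.FLANK_INDEX <- 1L

# 26-symbol amino-acid alphabet: the 20 standard residues in BLOSUM row order,
# the ambiguity codes B (Asx), Z (Glx), X (any), the rare translated residues
# U (Sec) and O (Pyl), and the stop/terminator symbol '*'.
.AA_ALPHABET <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
  "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "U", "O", "*"
)

.STANDARD_AA <- .AA_ALPHABET[1:20]

#' Amino-acid alphabet accepted by the tokenizer
#'
#' Returns the 26-symbol alphabet used for protein tokenization: the 20
#' standard amino acids plus the ambiguity codes B, Z, X, the rare residues
#' U and O, and the terminator `*`.
#'
#' @return Character vector of length 26.
#' @export
aa_alphabet <- function() .AA_ALPHABET

# BLOSUM62 substitution scores over the 26-symbol alphabet. Values for the
# 24 symbols present in the published matrix are the published integers;
# U and O have no BLOSUM62 entry and carry all-zero rows/columns.
.blosum62_matrix <- local({
  m <- c(
      4,  -1,  -2,  -2,   0,  -1,  -1,   0,  -2,  -1,  -1,  -1,  -1,  -2,  -1,   1,   0,  -3,  -2,   0,  -2,  -1,  -1,   0,   0,  -4,
     -1,   5,   0,  -2,  -3,   1,   0,  -2,   0,  -3,  -2,   2,  -1,  -3,  -2,  -1,  -1,  -3,  -2,  -3,  -1,   0,  -1,   0,   0,  -4,
     -2,   0,   6,   1,  -3,   0,   0,   0,   1,  -3,  -3,   0,  -2,  -3,  -2,   1,   0,  -4,  -2,  -3,   4,   0,  -1,   0,   0,  -4,
     -2,  -2,   1,   6,  -3,   0,   2,  -1,  -1,  -3,  -4,  -1,  -3,  -3,  -1,   0,  -1,  -4,  -3,  -3,   4,   1,  -1,   0,   0,  -4,
      0,  -3,  -3,  -3,   9,  -3,  -4,  -3,  -3,  -1,  -1,  -3,  -1,  -2,  -3,  -1,  -1,  -2,  -2,  -1,  -3,  -3,  -1,   0,   0,  -4,
     -1,   1,   0,   0,  -3,   5,   2,  -2,   0,  -3,  -2,   1,   0,  -3,  -1,   0,  -1,  -2,  -1,  -2,   0,   4,  -1,   0,   0,  -4,
     -1,   0,   0,   2,  -4,   2,   5,  -2,   0,  -3,  -3,   1,  -2,  -3,  -1,   0,  -1,  -3,  -2,  -2,   1,   4,  -1,   0,   0,  -4,
      0,  -2,   0,  -1,  -3,  -2,  -2,   6,  -2,  -4,  -4,  -2,  -3,  -3,  -2,   0,  -2,  -2,  -3,  -3,  -1,  -2,  -1,   0,   0,  -4,
     -2,   0,   1,  -1,  -3,   0,   0,  -2,   8,  -3,  -3,  -1,  -2,  -1,  -2,  -1,  -2,  -2,   2,  -3,   0,   0,  -1,   0,   0,  -4,
     -1,  -3,  -3,  -3,  -1,  -3,  -3,  -4,  -3,   4,   2,  -3,   1,   0,  -3,  -2,  -1,  -3,  -1,   3,  -3,  -3,  -1,   0,   0,  -4,
     -1,  -2,  -3,  -4,  -1,  -2,  -3,  -4,  -3,   2,   4,  -2,   2,   0,  -3,  -2,  -1,  -2,  -1,   1,  -4,  -3,  -1,   0,   0,  -4,
     -1,   2,   0,  -1,  -3,   1,   1,  -2,  -1,  -3,  -2,   5,  -1,  -3,  -1,   0,  -1,  -3,  -2,  -2,   0,   1,  -1,   0,   0,  -4,
     -1,  -1,  -2,  -3,  -1,   0,  -2,  -3,  -2,   1,   2,  -1,   5,   0,  -2,  -1,  -1,  -1,  -1,   1,  -3,  -1,  -1,   0,   0,  -4,
     -2,  -3,  -3,  -3,  -2,  -3,  -3,  -3,  -1,   0,   0,  -3,   0,   6,  -4,  -2,  -2,   1,   3,  -1,  -3,  -3,  -1,   0,   0,  -4,
     -1,  -2,  -2,  -1,  -3,  -1,  -1,  -2,  -2,  -3,  -3,  -1,  -2,  -4,   7,  -1,  -1,  -4,  -3,  -2,  -2,  -1,  -1,   0,   0,  -4,
      1,  -1,   1,   0,  -1,   0,   0,   0,  -1,  -2,  -2,   0,  -1,  -2,  -1,   4,   1,  -3,  -2,  -2,   0,   0,  -1,   0,   0,  -4,
      0,  -1,   0,  -1,  -1,  -1,  -1,  -2,  -2,  -1,  -1,  -1,  -1,  -2,  -1,   1,   5,  -2,  -2,   0,  -1,  -1,  -1,   0,   0,  -4,
     -3,  -3,  -4,  -4,  -2,  -2,  -3,  -2,  -2,  -3,  -2,  -3,  -1,   1,  -4,  -3,  -2,  11,   2,  -3,  -4,  -2,  -1,   0,   0,  -4,
     -2,  -2,  -2,  -3,  -2,  -1,  -2,  -3,   2,  -1,  -1,  -2,  -1,   3,  -3,  -2,  -2,   2,   7,  -1,  -3,  -2,  -1,   0,   0,  -4,
      0,  -3,  -3,  -3,  -1,  -2,  -2,  -3,  -3,   3,   1,  -2,   1,  -1,  -2,  -2,   0,  -3,  -1,   4,  -3,  -2,  -1,   0,   0,  -4,
     -2,  -1,   4,   4,  -3,   0,   1,  -1,   0,  -3,  -4,   0,  -3,  -3,  -2,   0,  -1,  -4,  -3,  -3,   4,   0,  -1,   0,   0,  -4,
     -1,   0,   0,   1,  -3,   4,   4,  -2,   0,  -3,  -3,   1,  -1,  -3,  -1,   0,  -1,  -2,  -2,  -2,   0,   4,  -1,   0,   0,  -4,
     -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,   0,   0,  -4,
      0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,
      0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,
     -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,   0,   0,   1
  )
  matrix(m, nrow = 26, byrow = TRUE, dimnames = list(.AA_ALPHABET, .AA_ALPHABET))
})

#' BLOSUM62 rows over the 26-symbol alphabet
#'
#' The BLOSUM62 substitution matrix extended to the package's 26-symbol
#' alphabet. U and O are absent from the published matrix and carry zero
#' rows and columns; all other entries are the published integer scores.
#'
#' @return A 26 x 26 integer matrix with the alphabet as dimnames.
#' @export
blosum62_table <- function() .blosum62_matrix

# Seven physicochemical properties per standard residue: molecular weight of
# the free amino acid, residue weight after water loss, pKa of the alpha
# carboxyl group, pKb of the alpha amino group, pKx of the ionizable side
# chain (0 when none), isoelectric point, and hydrophobicity at pH 2
# (normalized retention scale, Gly = 0). Values from standard physicochemical
# reference tables.
.biophysical_matrix <- local({
  p <- c(
    #     mw  res_mw  pka   pkb    pkx    pi   hphob_ph2
    A = c( 89.10,  71.08, 2.34,  9.69,  0.00,  6.00,  47),
    R = c(174.20, 156.19, 2.17,  9.04, 12.48, 10.76, -26),
    N = c(132.12, 114.11, 2.02,  8.80,  0.00,  5.41, -41),
    D = c(133.10, 115.09, 1.88,  9.60,  3.65,  2.77, -18),
    C = c(121.16, 103.15, 1.96, 10.28,  8.18,  5.07,  52),
    Q = c(146.15, 128.13, 2.17,  9.13,  0.00,  5.65, -18),
    E = c(147.13, 129.12, 2.19,  9.67,  4.25,  3.22,   8),
    G = c( 75.07,  57.05, 2.34,  9.60,  0.00,  5.97,   0),
    H = c(155.16, 137.14, 1.82,  9.17,  6.00,  7.59, -42),
    I = c(131.18, 113.16, 2.36,  9.60,  0.00,  6.02, 100),
    L = c(131.18, 113.16, 2.36,  9.60,  0.00,  5.98, 100),
    K = c(146.19, 128.18, 2.18,  8.95, 10.53,  9.74, -37),
    M = c(149.21, 131.20, 2.28,  9.21,  0.00,  5.74,  74),
    F = c(165.19, 147.18, 1.83,  9.13,  0.00,  5.48,  92),
    P = c(115.13,  97.12, 1.99, 10.60,  0.00,  6.30, -46),
    S = c(105.09,  87.08, 2.21,  9.15,  0.00,  5.68,  -7),
    T = c(119.12, 101.11, 2.09,  9.10,  0.00,  5.60,  13),
    W = c(204.23, 186.22, 2.83,  9.39,  0.00,  5.89,  84),
    Y = c(181.19, 163.18, 2.20,  9.11, 10.07,  5.66,  49),
    V = c(117.15,  99.13, 2.32,  9.62,  0.00,  5.96,  79)
  )
  m <- matrix(p, nrow = 20, byrow = TRUE,
              dimnames = list(.STANDARD_AA,
                              c("mw", "residue_mw", "pka", "pkb", "pkx",
                                "pi", "hydrophobicity_ph2")))
  m
})

#' Biophysical property table for the 20 standard amino acids
#'
#' @param normalized If `TRUE` (default), each property column is centred and
#'   scaled to unit variance over the 20 standard residues, which puts the
#'   heterogeneous units on a comparable scale for use as an embedding.
#' @return A 20 x 7 numeric matrix.
#' @export
biophysical_table <- function(normalized = TRUE) {
  m <- .biophysical_matrix
  if (normalized) m <- scale(m)[, , drop = FALSE]
  structure(m, "scaled:center" = NULL, "scaled:scale" = NULL)
}

#' Embedding specification for a token stream
#'
#' Builds the lookup table that maps token indices to numeric vectors.
#' Three schemes are supported for amino-acid streams:
#' \describe{
#'   \item{`blosum62`}{each residue is embedded as its 26-dimensional
#'     BLOSUM62 row (zero rows for U and O, which the matrix does not cover);}
#'   \item{`biophysical`}{each residue is embedded as 7 normalized
#'     physicochemical properties (ambiguity codes get zero vectors);}
#'   \item{`learned`}{a trainable table (default 32 dimensions) with seeded
#'     random initialization, also used for SMILES token streams.}
#' }
#' The padding row (token 0) is always all-zero. The flank token (1, shared
#' <START>/<STOP>) has a zero row for the fixed schemes and a trainable row
#' for the learned scheme.
#'
#' @param scheme One of `"blosum62"`, `"biophysical"`, `"learned"`.
#' @param dim Embedding dimension; fixed at 26 (blosum62) and 7 (biophysical),
#'   defaults to 32 for the learned scheme.
#' @param n_tokens Number of token indices covered (including pad and flank).
#'   Defaults to the protein alphabet (28 rows); pass the vocabulary size for
#'   SMILES streams.
#' @param rng_seed Seed for the learned initialization.
#' @return An object of class `embedding_spec` with elements `scheme`, `dim`,
#'   `table` (n_tokens x dim matrix, rows indexed by token + 1) and
#'   `trainable`.
#' @export
embedding_spec <- function(scheme = c("blosum62", "biophysical", "learned"),
                           dim = NULL, n_tokens = length(.AA_ALPHABET) + 2L,
                           rng_seed = 1L) {
  scheme <- match.arg(scheme)
  n_aa_tokens <- length(.AA_ALPHABET) + 2L
  if (scheme == "blosum62") {
    if (!is.null(dim) && dim != 26L) stop("blosum62 embeddings are 26-dimensional")
    if (n_tokens != n_aa_tokens) stop("blosum62 scheme requires the protein alphabet")
    tab <- matrix(0, n_tokens, 26L)
    tab[2L + seq_len(26L), ] <- .blosum62_matrix
    trainable <- FALSE
    dim <- 26L
  } else if (scheme == "biophysical") {
    if (!is.null(dim) && dim != 7L) stop("biophysical embeddings are 7-dimensional")
    if (n_tokens != n_aa_tokens) stop("biophysical scheme requires the protein alphabet")
    tab <- matrix(0, n_tokens, 7L)
    tab[2L + seq_len(20L), ] <- biophysical_table(normalized = TRUE)
    trainable <- FALSE
    dim <- 7L
  } else {
    if (is.null(dim)) dim <- 32L
    tab <- with_seed(rng_seed, {
      m <- matrix(stats::rnorm(n_tokens * dim, sd = 0.1), n_tokens, dim)
      m[1L, ] <- 0  # pad row stays zero
      m
    })
    trainable <- TRUE
  }
  structure(list(scheme = scheme, dim = as.integer(dim),
                 n_tokens = as.integer(n_tokens), table = tab,
                 trainable = trainable),
            class = "embedding_spec")
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
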