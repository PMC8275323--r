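# ChemmineR/OpenBabel act as the independent chemistry oracle: they parse the
# written SMILES and report molecular formulas without touching the package's
# graph code.

mf_oracle <- function(smiles) {
  ChemmineR::MF(suppressWarnings(ChemmineR::smiles2sdf(smiles)), addH = TRUE)
}

norm_formula <- function(f) {
  parts <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
  paste(sort(parts), collapse = " ")
}

test_that("single residues and dipeptides give textbook molecules", {
  g <- peptide_to_smiles("G")
  expect_s3_class(g, "smiles_string")
  expect_identical(norm_formula(mf_oracle(as.character(g))),
                   norm_formula("C2H5NO2"))
  gg <- peptide_to_smiles("GG")
  expect_identical(norm_formula(mf_oracle(as.character(gg))),
                   norm_formula("C4H8N2O3"))
  # canonicalization is idempotent
  expect_identical(as.character(canonicalize_smiles(g)), as.character(g))
  expect_error(peptide_to_smiles("AXB"), "non-standard")
  expect_error(peptide_to_smiles(""), "non-empty")
})

test_that("peptide formulas follow condensation stoichiometry", {
  # residue formulas from the oracle, peptide formula must equal their sum
  # minus (n-1) waters
  set.seed(31)
  aa_formula <- new.env()
  count_of <- function(f) {
    out <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
    for (p in regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]) {
      e <- gsub("[0-9]", "", p)
      k <- suppressWarnings(as.integer(gsub("[A-Za-z]", "", p)))
      out[e] <- out[e] + ifelse(is.na(k), 1L, k)
    }
    out
  }
  for (a in strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
    assign(a, count_of(mf_oracle(as.character(peptide_to_smiles(a)))), aa_formula)
  for (i in 1:12) {
    n <- sample(2:10, 1)
    pep <- random_peptide(n)
    want <- Reduce(`+`, lapply(strsplit(pep, "")[[1]], get, envir = aa_formula))
    want["H"] <- want["H"] - 2 * (n - 1)
    want["O"] <- want["O"] - (n - 1)
    got <- count_of(mf_oracle(as.character(peptide_to_smiles(pep))))
    expect_identical(got, want, info = pep)
  }
})

test_that("peptides carry exactly n-1 backbone amide bonds", {
  # count C(=O)-N bonds in the assembled graph
  amide_count <- function(g) {
    is_carbonyl <- vapply(seq_along(g$elements), function(a) {
      g$elements[a] == "C" &&
        any((g$bonds[, 1] == a & g$bonds[, 3] == 2 &
               g$elements[g$bonds[, 2]] == "O") |
            (g$bonds[, 2] == a & g$bonds[, 3] == 2 &
               g$elements[g$bonds[, 1]] == "O"))
    }, logical(1))
    sum(vapply(seq_len(nrow(g$bonds)), function(r) {
      i <- g$bonds[r, 1]; j <- g$bonds[r, 2]
      g$bonds[r, 3] == 1 &&
        ((is_carbonyl[i] && g$elements[j] == "N") ||
         (is_carbonyl[j] && g$elements[i] == "N"))
    }, logical(1)))
  }
  # sequences without side-chain amides/guanidines so backbone count is exact
  for (pep in c("GG", "ACDEFG", "LMPSTV")) {
    g <- titan:::peptide_graph(pep)
    expect_identical(amide_count(g), nchar(pep) - 1L, info = pep)
  }
})

test_that("augmentation changes the string but never the molecule", {
  set.seed(32)
  for (i in 1:8) {
    pep <- random_peptide(sample(4:10, 1))
    s <- peptide_to_smiles(pep)
    variants <- vapply(1:10, function(sd)
      as.character(augment_smiles(s, rng_seed = sd)), "")
    expect_true(all(canonicalize_smiles_batch(variants) == as.character(s)),
                info = pep)
    # randomization contract: distinct seeds usually give distinct strings
    expect_gt(length(unique(variants)), 1)
  }
  # deterministic per seed
  s <- peptide_to_smiles("ACDE")
  expect_identical(as.character(augment_smiles(s, 7)),
                   as.character(augment_smiles(s, 7)))
  # a single-atom molecule has no permutation freedom
  expect_identical(as.character(augment_smiles(smiles_string("C"), 1)), "C")
})

test_that("the SMILES tokenizer is atom-level", {
  expect_identical(smiles_token_strings("CCO"), c("C", "C", "O"))
  expect_identical(smiles_token_strings("C(Cl)Br"),
                   c("C", "(", "Cl", ")", "Br"))
  expect_identical(smiles_token_strings("[C@@H]1CC=1"),
                   c("[C@@H]", "1", "C", "C", "=", "1"))
  expect_length(smiles_token_strings("N[C@@H](C)C(=O)O"), 11)
})

test_that("vocabularies cover augmented forms and persist to JSON", {
  peps <- c("ACDG", "WYKL", "PQRS")
  canon <- lapply(peps, peptide_to_smiles)
  aug <- unlist(lapply(canon, function(s)
    vapply(1:3, function(sd) as.character(augment_smiles(s, sd)), "")))
  vocab <- build_smiles_vocab(c(vapply(canon, as.character, ""), aug))
  # closure: canonical and augmented forms tokenize without unknowns
  for (s in c(vapply(canon, as.character, ""), aug)) {
    ts <- tokenize_smiles(s, vocab, max_len = 200)
    expect_false(any(ts$tokens == vocab$unk_index))
    expect_identical(ts$content_length, length(smiles_token_strings(s)))
    expect_identical(ts$tokens[1], 1L)
    expect_identical(ts$tokens[ts$content_length + 2L], 1L)
  }
  # unknown tokens warn and map to the unknown index
  expect_warning(ts <- tokenize_smiles("CCOP", vocab, 50), "UNK")
  expect_true(any(ts$tokens == vocab$unk_index))
  # round trip through disk
  path <- tempfile(fileext = ".json")
  save_smiles_vocab(vocab, path)
  back <- load_smiles_vocab(path)
  expect_identical(back$tokens, vocab$tokens)
  expect_identical(unname(back$index[vocab$tokens]),
                   unname(vocab$index[vocab$tokens]))
})
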