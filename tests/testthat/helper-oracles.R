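# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# textbook dynamic-programming edit distance
dp_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- c(i, integer(m))
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (ca[i] != cb[j]))
    }
    prev <- cur
  }
  as.integer(prev[m + 1])
}

# Eq-style pair distance computed with the DP oracle
oracle_pair_distance <- function(e1, t1, e2, t2) {
  dp_levenshtein(e1, e2) / nchar(e2) + dp_levenshtein(t1, t2) / nchar(t2)
}

# brute-force K-NN: full sort of all training distances, stable on ties
oracle_knn_score <- function(train, e, t, k) {
  d <- vapply(seq_len(nrow(train)), function(i)
    oracle_pair_distance(train$epitope[i], train$tcr[i], e, t), numeric(1))
  ord <- order(d, seq_along(d))
  mean(train$label[ord[seq_len(k)]])
}

# AUC by exhaustive concordant-pair counting (ties count one half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

random_peptide <- function(n, alphabet = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a small labelled record table
toy_records <- function(n = 20, n_epi = 4, seed = 1) {
  set.seed(seed)
  data.frame(
    epitope = sample(vapply(seq_len(n_epi), function(i) random_peptide(9), ""),
                     n, replace = TRUE),
    tcr = vapply(seq_len(n), function(i) random_peptide(sample(10:16, 1)), ""),
    label = sample(c(0, 1), n, replace = TRUE),
    stringsAsFactors = FALSE)
}
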