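att_model <- function(...) {
  cfg <- titan_config_reduced(tcr_len = 14L, epitope_len = 12L, filters = 4L,
                              attention_dim = 5L, dense_sizes = c(8L, 6L), ...)
  build_model(cfg, rng_seed = 81)
}

att_pairs <- function(n, seed = 82) {
  set.seed(seed)
  data.frame(tcr = vapply(seq_len(n), function(i) random_peptide(10), ""),
             epitope = vapply(seq_len(n), function(i) random_peptide(8), ""),
             stringsAsFactors = FALSE)
}

test_that("extracted attention rows are normalized and deterministic", {
  m <- att_model()
  pairs <- att_pairs(6)
  att <- extract_attention(m, pairs)
  expect_identical(dim(att$tcr), c(6L, 14L))
  expect_identical(dim(att$epitope), c(6L, 12L))
  expect_equal(rowSums(att$tcr), rep(1, 6), tolerance = 1e-6)
  expect_equal(rowSums(att$epitope), rep(1, 6), tolerance = 1e-6)
  # the same pair scored twice gives identical rows
  att2 <- extract_attention(m, pairs[c(1, 1, 2), ])
  expect_equal(att2$tcr[1, ], att2$tcr[2, ], tolerance = 1e-12)
  expect_equal(unclass(att2$tcr)[1:2, ], unclass(att$tcr)[c(1, 1), ],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("all-zero embeddings yield uniform attention everywhere", {
  m <- att_model(tcr_scheme = "learned", epitope_scheme = "learned")
  for (nm in c("emb.tcr", "emb.epi")) m$params[[nm]][] <- 0
  att <- extract_attention(m, att_pairs(3))
  expect_equal(unclass(att$tcr), matrix(1 / 14, 3, 14), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(att$epitope), matrix(1 / 12, 3, 12), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("variance statistics follow their definitions on constructed rows", {
  # identical rows: both variances vanish
  m <- matrix(rep(c(0.2, 0.3, 0.5), 4), 4, 3, byrow = TRUE)
  v <- attention_variances(m, groups = c("a", "a", "b", "b"))
  expect_equal(v$inter, 0)
  expect_equal(v$intra, 0)
  # constant-but-different rows per group: intra 0, inter > 0
  m2 <- rbind(matrix(rep(c(0.6, 0.3, 0.1), 2), 2, byrow = TRUE),
              matrix(rep(c(0.1, 0.3, 0.6), 2), 2, byrow = TRUE))
  v2 <- attention_variances(m2, groups = c("a", "a", "b", "b"))
  expect_equal(v2$intra, 0)
  expect_gt(v2$inter, 0)
  # 3 x 4 toy matrix against direct arithmetic
  m3 <- matrix(c(0.1, 0.2, 0.3, 0.4,
                 0.3, 0.3, 0.2, 0.2,
                 0.4, 0.1, 0.1, 0.4), 3, 4, byrow = TRUE)
  g3 <- c("a", "a", "b")
  pv <- function(x) mean((x - mean(x))^2)
  gm <- rbind(colMeans(m3[1:2, ]), m3[3, ])
  expect_equal(attention_variances(m3, g3)$inter, mean(apply(gm, 2, pv)))
  expect_equal(attention_variances(m3, g3)$intra,
               mean(apply(m3[1:2, ], 2, pv)))
  # sample estimator and error handling
  vs <- attention_variances(m3, g3, estimator = "sample")
  expect_equal(vs$intra, mean(apply(m3[1:2, ], 2, stats::var)))
  expect_error(attention_variances(m3, c("a", "a", "a")), "two groups")
})

test_that("epitope compression keeps exactly the high-attention residues", {
  epis <- c("ACDEF", "ACDEG", "WYKLM", "WYKLN", "PQRST")
  # rows built so that epitopes 1/2 collide after compression and 3/4 stay
  # distinct through their differing last residue
  alpha <- rbind(c(0.3, 0.3, 0.2, 0.15, 0.05),
                 c(0.3, 0.3, 0.2, 0.15, 0.05),
                 c(0.2, 0.2, 0.2, 0.05, 0.35),
                 c(0.2, 0.2, 0.2, 0.05, 0.35),
                 c(0.5, 0.3, 0.19, 0.005, 0.005))
  out <- compress_epitopes(epis, alpha, threshold = 0.1)
  expect_identical(out$compressed,
                   c("ACDE", "ACDE", "WYKM", "WYKN", "PQR"))
  expect_identical(out$n_unique, 3L)           # the two "ACDE" collide
  expect_equal(out$fraction_unique, 3 / 5)
  # threshold 0 is the identity compression
  id <- compress_epitopes(epis, alpha, threshold = 0)
  expect_identical(id$compressed, epis)
  expect_identical(id$n_unique, 5L)
  # attention entirely below the threshold compresses to empty strings
  low <- compress_epitopes(epis, alpha * 0.1, threshold = 0.1)
  expect_true(all(low$compressed == ""))
  expect_identical(low$n_unique, 0L)
})

test_that("raising the threshold never increases uniqueness on these fixtures", {
  set.seed(83)
  epis <- vapply(1:12, function(i) random_peptide(8), "")
  alpha <- matrix(runif(12 * 8), 12, 8)
  alpha <- alpha / rowSums(alpha)
  prev <- Inf
  for (th in c(0, 0.05, 0.1, 0.15, 0.2, 0.3)) {
    nu <- compress_epitopes(epis, alpha, threshold = th)$n_unique
    expect_lte(nu, prev)
    prev <- nu
  }
})

test_that("per-class constant attention keeps epitopes distinguishable", {
  # one attention pattern per epitope, constant across its contexts: the
  # compressed strings act as unique fingerprints (implicit classification)
  set.seed(84)
  epis <- unique(vapply(1:25, function(i) random_peptide(9), ""))
  alpha <- t(vapply(seq_along(epis), function(i) {
    a <- rep(0.02, 9)
    a[sample(9, 4)] <- 0.23  # four strong positions per epitope
    a / sum(a)
  }, numeric(9)))
  out <- compress_epitopes(epis, alpha, threshold = 0.1)
  expect_gt(out$fraction_unique, 0.9)
  expect_true(all(nchar(out$compressed) == 4))
})

test_that("context-averaged rows feed compression when epitopes repeat", {
  m <- att_model()
  pairs <- att_pairs(4, seed = 85)
  pairs <- pairs[c(1, 1, 2, 3, 3, 3), ]
  pairs$tcr <- att_pairs(6, seed = 86)$tcr  # same epitopes, varying contexts
  att <- extract_attention(m, pairs)
  agg <- aggregate_attention(att$epitope)
  expect_identical(agg$references, unique(pairs$epitope))
  expect_equal(rowSums(agg$alpha), rep(1, 3), tolerance = 1e-6)
  expect_equal(agg$alpha[1, ],
               colMeans(unclass(att$epitope)[1:2, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
  res <- residue_attention(att$epitope)
  expect_length(res[[1]], nchar(pairs$epitope[1]))
})
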