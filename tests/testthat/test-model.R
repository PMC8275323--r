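small_cfg <- function(...) {
  titan_config_reduced(tcr_len = 12L, epitope_len = 10L, filters = 4L,
                       attention_dim = 5L, dense_sizes = c(8L, 6L), ...)
}

test_that("the base configuration matches the published architecture", {
  cfg <- titan_config()
  expect_identical(cfg$kernel_sizes_tcr, c(3L, 5L, 11L))
  expect_true(cfg$residual_channel)
  expect_identical(cfg$dense_sizes, c(368L, 184L))
  expect_identical(cfg$attention_dim, 16L)
  expect_identical(cfg$tcr_len, 500L)
  m <- build_model(cfg, rng_seed = 1)
  expect_identical(m$n_channels, 4L)  # 3 conv + 1 residual per stream
  # pretraining variant
  vocab <- build_smiles_vocab(c("CCO", "NCC(=O)O"))
  cfgp <- titan_config_pretrain(vocab)
  expect_identical(cfgp$tcr_len, 1028L)
  expect_identical(cfgp$attention_dim, 256L)
  expect_identical(cfgp$kernel_sizes_tcr, c(3L, 7L, 13L, 19L))
  expect_identical(cfgp$kernel_sizes_epitope, c(3L, 7L, 9L, 13L))
  expect_identical(cfgp$dense_sizes, c(2048L, 1024L, 512L))
  expect_error(titan_config(kernel_sizes_tcr = c(3, 5),
                            kernel_sizes_epitope = c(3, 5, 7)), "channels")
})

test_that("parameter shapes, counts and seeding are exact", {
  cfg <- small_cfg()
  m1 <- build_model(cfg, rng_seed = 9)
  m2 <- build_model(cfg, rng_seed = 9)
  m3 <- build_model(cfg, rng_seed = 10)
  expect_identical(m1$params, m2$params)   # bit-identical under the seed
  expect_false(identical(m1$params, m3$params))
  p <- m1$params
  expect_identical(dim(p[["conv.tcr.ch1.W"]]), c(3L * 26L, 4L))
  expect_identical(dim(p[["conv.tcr.ch3.W"]]), c(11L * 26L, 4L))
  expect_identical(dim(p[["att.tcr.ch1.W3"]]), c(12L, 10L))
  expect_identical(dim(p[["att.epi.ch1.W3"]]), c(10L, 12L))
  expect_identical(dim(p[["att.tcr.ch4.W1"]]), c(26L, 5L))  # residual channel
  expect_length(p[["att.tcr.ch1.v"]], 5L)
  n_feat <- 2L * (3L * 4L + 26L)
  expect_identical(dim(p[["dense.1.W"]]), c(n_feat, 8L))
  # parameter count is a pure function of the configuration
  expect_identical(n_parameters(m1), n_parameters(m3))
  expect_identical(n_parameters(build_model(titan_config_reduced(), 1)),
                   n_parameters(build_model(titan_config_reduced(), 2)))
})

test_that("context attention reproduces a literal dense-math recomputation", {
  set.seed(51)
  for (i in 1:50) {
    T <- sample(3:9, 1); U <- sample(3:9, 1)
    H <- sample(2:6, 1); K <- sample(2:6, 1); A <- sample(2:6, 1)
    X1 <- matrix(rnorm(T * H), T, H)
    X2 <- matrix(rnorm(U * K), U, K)
    par <- list(W1 = matrix(rnorm(H * A), H, A),
                W2 = matrix(rnorm(K * A), K, A),
                W3 = matrix(rnorm(T * U), T, U),
                v = rnorm(A))
    am <- context_attention(X1, X2, par)
    u <- drop(tanh(X1 %*% par$W1 + par$W3 %*% (X2 %*% par$W2)) %*% par$v)
    alpha <- exp(u - max(u)); alpha <- alpha / sum(alpha)
    expect_lt(max(abs(am$alpha - alpha)), 1e-6)
    expect_lt(max(abs(am$filtered - drop(crossprod(X1, alpha)))), 1e-6)
    expect_equal(sum(am$alpha), 1, tolerance = 1e-9)
    expect_true(all(am$alpha > 0))
  }
})

test_that("zero inputs give uniform attention; shape errors name the offender", {
  X1 <- matrix(0, 6, 3); X2 <- matrix(0, 4, 2)
  par <- list(W1 = matrix(1, 3, 5), W2 = matrix(1, 2, 5),
              W3 = matrix(1, 6, 4), v = rep(1, 5))
  am <- context_attention(X1, X2, par)
  expect_equal(am$alpha, rep(1 / 6, 6))
  bad <- par; bad$W1 <- matrix(1, 4, 5)
  expect_error(context_attention(X1, X2, bad), "W1")
  bad2 <- par; bad2$W3 <- matrix(1, 6, 5)
  expect_error(context_attention(X1, X2, bad2), "W3")
})

test_that("forward pass is a probability, deterministic, batch-order invariant", {
  cfg <- small_cfg()
  m <- build_model(cfg, rng_seed = 12)
  recs <- data.frame(
    epitope = vapply(1:6, function(i) random_peptide(7), ""),
    tcr = vapply(1:6, function(i) random_peptide(9), ""),
    stringsAsFactors = FALSE)
  p1 <- predict(m, recs)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, predict(m, recs))
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(predict(m, recs[perm, ]), p1[perm], tolerance = 1e-6)
  lk <- predict(m, recs, type = "link")
  expect_equal(stats::plogis(lk), p1, tolerance = 1e-12)
})

test_that("trainable scopes freeze exactly the epitope stream", {
  cfg <- small_cfg(tcr_scheme = "learned", epitope_scheme = "learned")
  m <- build_model(cfg, rng_seed = 13)
  m <- set_trainable_scopes(m, "semifrozen")
  frozen <- names(m$trainable)[!m$trainable]
  expect_true(all(grepl("^(emb\\.epi|conv\\.epi|att\\.epi)", frozen)))
  moving <- names(m$trainable)[m$trainable]
  expect_true(any(grepl("^conv\\.tcr", moving)))
  expect_true(any(grepl("^dense\\.", moving)))
  expect_true("emb.tcr" %in% moving)
  # toggling back restores trainability without touching values
  before <- m$params
  m2 <- set_trainable_scopes(m, "all")
  expect_true(all(m2$trainable[grepl("conv\\.epi", names(m2$trainable))]))
  expect_identical(m2$params, before)
  expect_error(set_trainable_scopes(m, "nonsense"))
  # fixed embeddings stay frozen even under "all"
  mb <- set_trainable_scopes(build_model(small_cfg(), 1), "all")
  expect_false(mb$trainable[["emb.tcr"]])
})
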