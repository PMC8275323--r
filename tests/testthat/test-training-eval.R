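test_that("evaluate matches enumeration and pROC on tied and untied scores", {
  ev <- evaluate(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_equal(ev$roc_auc, 0.75)
  # perfectly separated scores
  ev2 <- evaluate(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(ev2$roc_auc, 1)
  expect_equal(ev2$balanced_accuracy, 1)
  # chance level for label-independent scores
  set.seed(61)
  n <- 4000
  ev3 <- evaluate(runif(n), sample(c(0, 1), n, TRUE))
  expect_lt(abs(ev3$roc_auc - 0.5), 0.05)
  # exhaustive concordant-pair oracle on many random inputs, with ties
  for (i in 1:25) {
    m <- sample(8:40, 1)
    scores <- sample(seq(0, 1, 0.1), m, TRUE)
    labels <- c(0, 1, sample(c(0, 1), m - 2, TRUE))
    expect_equal(evaluate(scores, labels)$roc_auc, oracle_auc(scores, labels))
  }
  # independent library cross-check
  skip_if_not_installed("pROC")
  set.seed(62)
  scores <- runif(300); labels <- rbinom(300, 1, plogis(3 * scores - 1.5))
  if (length(unique(labels)) == 2) {
    want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
    expect_equal(evaluate(scores, labels)$roc_auc, want, tolerance = 1e-10)
  }
})

test_that("balanced accuracy is the sensitivity/specificity mean at 0.5", {
  scores <- c(0.9, 0.6, 0.4, 0.2, 0.8, 0.1)
  labels <- c(1, 0, 1, 0, 1, 0)
  ev <- evaluate(scores, labels)
  sens <- mean(scores[labels == 1] > 0.5)
  spec <- mean(scores[labels == 0] <= 0.5)
  expect_equal(ev$balanced_accuracy, (sens + spec) / 2)
  expect_error(evaluate(c(0.1, 0.9), c(1, 1)), "undefined")
})

test_that("a single epoch trains, records its loss and stays finite", {
  bench <- generate_benchmark(synthetic_config(n_epitopes = 4,
                                               tcrs_per_epitope = 8,
                                               rng_seed = 63))
  cfg <- titan_config_reduced(tcr_len = 20L, epitope_len = 13L, filters = 4L,
                              dense_sizes = c(8L, 6L))
  fit <- titan(bench$records, cfg,
               train_config(epochs = 1, batch_size = 16, rng_seed = 64))
  expect_length(fit$loss_trace, 1)
  expect_true(is.finite(fit$loss_trace))
  expect_true(fit$fitted)
  # training is reproducible under the seed
  fit2 <- titan(bench$records, cfg,
                train_config(epochs = 1, batch_size = 16, rng_seed = 64))
  expect_identical(fit$params, fit2$params)
})

test_that("labels independent of the input drive the loss to the entropy floor", {
  # identical inputs with half-and-half labels: the best any model can do is
  # predict 0.5, i.e. binary cross entropy ln 2
  recs <- data.frame(epitope = "SIINFEKL", tcr = "CASSLGQAYEQYF",
                     label = rep(c(0, 1), 32), stringsAsFactors = FALSE)
  cfg <- titan_config_reduced(tcr_len = 20L, epitope_len = 13L, filters = 4L,
                              dense_sizes = c(8L, 6L), dropout = 0)
  fit <- titan(recs, cfg, train_config(epochs = 15, batch_size = 32,
                                       learning_rate = 1e-3, rng_seed = 65))
  expect_lt(abs(utils::tail(fit$loss_trace, 1) - log(2)), 0.02)
})

test_that("semifrozen training moves no epitope-stream parameter", {
  bench <- generate_benchmark(synthetic_config(n_epitopes = 4,
                                               tcrs_per_epitope = 8,
                                               rng_seed = 66))
  cfg <- titan_config_reduced(tcr_len = 20L, epitope_len = 13L, filters = 4L,
                              dense_sizes = c(8L, 6L),
                              tcr_scheme = "learned", epitope_scheme = "learned")
  m0 <- build_model(cfg, rng_seed = 67)
  m0 <- set_trainable_scopes(m0, "semifrozen")
  fit <- train_model(m0, bench$records,
                     train_config(epochs = 1, batch_size = 16, rng_seed = 68))
  epi_names <- grep("^(emb\\.epi|conv\\.epi|att\\.epi)", names(m0$params),
                    value = TRUE)
  for (nm in epi_names)
    expect_identical(fit$params[[nm]], m0$params[[nm]])
  # TCR stream and dense stack did move
  expect_false(identical(fit$params[["conv.tcr.ch1.W"]],
                         m0$params[["conv.tcr.ch1.W"]]))
  expect_false(identical(fit$params[["dense.1.W"]], m0$params[["dense.1.W"]]))
  # under "all", every trainable parameter receives gradient on a generic batch
  m1 <- set_trainable_scopes(build_model(cfg, 69), "all")
  data <- titan:::encode_binding_data(bench$records[1:16, ], cfg)
  fw <- titan:::titan_forward(m1, data$tok_t, data$tok_e, train = TRUE)
  gr <- titan:::titan_backward(m1, fw$caches, (fw$prob - data$labels) / 16)
  for (nm in names(m1$trainable)[m1$trainable])
    expect_gt(max(abs(gr[[nm]])), 0)
})

test_that("the cross-validation harness matches a manual fold loop for K-NN", {
  bench <- generate_benchmark(synthetic_config(n_epitopes = 8,
                                               tcrs_per_epitope = 15,
                                               rng_seed = 70))
  pos <- bench$records[bench$records$label == 1, ]
  cv <- cross_validate(pos, "tcr_split", n_folds = 2, model = "knn", k = 5,
                       rng_seed = 71)
  expect_identical(nrow(cv$folds), 2L)
  # manual loop with the same split and negatives
  fa <- make_folds(pos, 2, "tcr_split", 71)
  d <- apply_folds(pos, fa)
  full <- generate_negatives(d[, c("epitope", "tcr", "label", "tcr_id")],
                             scope = d$fold, rng_seed = 72)
  for (f in 1:2) {
    tr <- full[full$fold != f, ]; te <- full[full$fold == f, ]
    want <- evaluate(predict(knn_model(tr, 5), te), te$label)$roc_auc
    expect_equal(cv$folds$roc_auc[cv$folds$fold == f], want)
  }
  # summary statistics are the mean and population SD of the fold metrics
  expect_equal(cv$mean_roc_auc, mean(cv$folds$roc_auc))
  expect_equal(cv$sd_roc_auc,
               sqrt(mean((cv$folds$roc_auc - mean(cv$folds$roc_auc))^2)))
})

test_that("strict-mode cross-validation isolates held-out epitopes", {
  bench <- generate_benchmark(synthetic_config(n_epitopes = 10,
                                               tcrs_per_epitope = 15,
                                               rng_seed = 73))
  pos <- bench$records[bench$records$label == 1, ]
  # the harness itself asserts train/test epitope and TCR disjointness per
  # fold; a completed run certifies the property
  cv <- suppressMessages(
    cross_validate(pos, "strict_split", n_folds = 3, model = "knn", k = 3,
                   rng_seed = 74))
  expect_identical(nrow(cv$folds), 3L)
  expect_true(all(cv$folds$n_test > 0))
})
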