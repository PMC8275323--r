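#' Optimization settings
#'
#' Adam with binary cross-entropy loss. Defaults follow the reference
#' protocol (learning rate 1e-4, betas 0.9/0.999, epsilon 1e-8, batch size
#' 512); desk-scale runs typically lower the batch size and raise the
#' learning rate (see [train_control_reduced()]).
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training data.
#' @param augment_smiles Re-draw a randomized SMILES for every epitope at
#'   each epoch (only meaningful for a SMILES epitope stream).
#' @param rng_seed Seed governing shuffling, dropout and augmentation.
#' @param verbose Print one line per epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, batch_size = 512L, epochs = 10L,
                         augment_smiles = FALSE, rng_seed = 1L,
                         verbose = FALSE) {
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            epsilon > 0, batch_size >= 1L, epochs >= 1L)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 augment_smiles = isTRUE(augment_smiles),
                 rng_seed = as.integer(rng_seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' @rdname train_config
#' @param ... Overrides passed on to [train_config()].
#' @details `train_control_reduced()` is the desk-scale companion of
#'   [titan_config_reduced()]: batch size 64 and learning rate 2e-3, chosen
#'   once so that small planted-rule benchmarks converge within a few dozen
#'   epochs on a single CPU.
#' @export
train_control_reduced <- function(...) {
  do.call(train_config, utils::modifyList(
    list(learning_rate = 2e-3, batch_size = 64L, epochs = 30L), list(...)))
}

# Tokenize a record table into the model's two input matrices.
#' @keywords internal
encode_binding_data <- function(records, config, augment_seed = NULL) {
  tok_t <- tokenize_protein_matrix(records$tcr, config$tcr_len)
  if (config$epitope_scheme == "smiles") {
    uq <- unique(records$epitope)
    smi <- vapply(uq, function(e) {
      s <- peptide_to_smiles(e)
      if (!is.null(augment_seed))
        s <- augment_smiles(s, rng_seed = augment_seed + match(e, uq))
      as.character(s)
    }, character(1))
    tok <- vapply(smi, function(s)
      tokenize_smiles(s, config$smiles_vocab, config$epitope_len)$tokens,
      integer(config$epitope_len))
    tok_e <- t(tok)[match(records$epitope, uq), , drop = FALSE]
  } else {
    tok_e <- tokenize_protein_matrix(records$epitope, config$epitope_len)
  }
  list(tok_t = tok_t, tok_e = tok_e,
       labels = if (!is.null(records$label)) as.numeric(records$label))
}

#' Train a bimodal attention model
#'
#' Minimizes binary cross-entropy with Adam over minibatches. Each epoch
#' shuffles the data; with `augment_smiles` the epitope SMILES are redrawn
#' every epoch so the model sees a different valid atom ordering of the
#' same molecule at each pass. When a validation set is supplied the
#' parameters of the epoch with the best validation ROC-AUC are kept
#' (epoch-wise validation tracking); otherwise the final-epoch parameters
#' are returned. Training is deterministic given the seed.
#'
#' @param model A `titan_model` from [build_model()] (possibly with
#'   restricted scopes, see [set_trainable_scopes()]).
#' @param records Labelled binding records.
#' @param config A [train_config()].
#' @param validation Optional labelled records scored after each epoch.
#' @return The trained model; `$loss_trace` holds the mean training loss
#'   per epoch and `$val_trace` the per-epoch validation ROC-AUC.
#' @export
train_model <- function(model, records, config = train_config(),
                        validation = NULL) {
  stopifnot(inherits(model, "titan_model"), inherits(config, "train_config"))
  records <- validate_records(records, require_label = TRUE)
  data <- encode_binding_data(records, model$config)
  val <- if (!is.null(validation))
    encode_binding_data(validation, model$config)
  n <- nrow(data$tok_t)
  state <- list(t = 0L, m = list(), v = list())
  loss_trace <- numeric(config$epochs)
  val_trace <- numeric(0)
  best_auc <- -Inf
  best_params <- NULL
  with_seed(config$rng_seed, {
    for (ep in seq_len(config$epochs)) {
      if (config$augment_smiles && model$config$epitope_scheme == "smiles") {
        aug_seed <- sample.int(2^30, 1L)
        data <- encode_binding_data(records, model$config, augment_seed = aug_seed)
      }
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, n)]
        B <- length(rows)
        fw <- titan_forward(model, data$tok_t[rows, , drop = FALSE],
                            data$tok_e[rows, , drop = FALSE], train = TRUE)
        z <- fw$logit; y <- data$labels[rows]
        loss <- mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at epoch %d (logit range %.3g..%.3g)",
                       ep, min(z), max(z)))
        ep_loss <- ep_loss + loss * B
        dlogit <- (fw$prob - y) / B
        grads <- titan_backward(model, fw$caches, dlogit)
        upd <- adam_step(model$params, grads, state, model$trainable,
                         lr = config$learning_rate, beta1 = config$beta1,
                         beta2 = config$beta2, eps = config$epsilon)
        model$params <- upd$params
        state <- upd$state
      }
      loss_trace[ep] <- ep_loss / n
      if (!is.null(val)) {
        pv <- predict_tokens(model, val$tok_t, val$tok_e)
        auc <- evaluate(pv, val$labels)$roc_auc
        val_trace <- c(val_trace, auc)
        if (auc > best_auc) {
          best_auc <- auc
          best_params <- model$params
        }
      }
      if (config$verbose)
        message(sprintf("epoch %3d  loss %.4f%s", ep, loss_trace[ep],
                        if (!is.null(val)) sprintf("  val auc %.4f",
                                                   utils::tail(val_trace, 1)) else ""))
    }
  })
  if (!is.null(best_params)) model$params <- best_params
  model$loss_trace <- loss_trace
  model$val_trace <- val_trace
  model$fitted <- TRUE
  model
}

# batched evaluation-mode scoring on pre-tokenized inputs
#' @keywords internal
predict_tokens <- function(model, tok_t, tok_e, batch_size = 256L) {
  n <- nrow(tok_t)
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    rows <- s:min(s + batch_size - 1L, n)
    out[rows] <- titan_forward(model, tok_t[rows, , drop = FALSE],
                               tok_e[rows, , drop = FALSE])$prob
  }
  out
}

#' Predict binding probabilities
#'
#' Evaluation-mode forward pass (dropout off): deterministic and invariant
#' to the order of samples in a batch.
#'
#' @param object A trained (or built) `titan_model`.
#' @param newdata Records with `epitope` and `tcr` columns.
#' @param type `"prob"` for binding probabilities, `"link"` for logits,
#'   `"class"` for calls at 0.5.
#' @param batch_size Scoring batch size.
#' @param ... Unused.
#' @return Numeric vector (or integer for `"class"`).
#' @export
predict.titan_model <- function(object, newdata,
                                type = c("prob", "link", "class"),
                                batch_size = 256L, ...) {
  type <- match.arg(type)
  newdata <- validate_records(newdata, require_label = FALSE)
  data <- encode_binding_data(newdata, object$config)
  n <- nrow(data$tok_t)
  out <- numeric(n)
  lk <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    rows <- s:min(s + batch_size - 1L, n)
    fw <- titan_forward(object, data$tok_t[rows, , drop = FALSE],
                        data$tok_e[rows, , drop = FALSE])
    out[rows] <- fw$prob
    lk[rows] <- fw$logit
  }
  switch(type, prob = out, link = lk, class = as.integer(out > 0.5))
}

#' Fit the bimodal attention model to binding records
#'
#' Convenience fitting front-end: builds the network, optionally restricts
#' the trainable scopes, and trains it.
#'
#' @param records Labelled binding records (data frame with `epitope`,
#'   `tcr`, `label`).
#' @param config A [titan_config()].
#' @param control A [train_config()].
#' @param scopes `"all"` or `"semifrozen"` (see [set_trainable_scopes()]).
#' @param validation Optional validation records for epoch-wise tracking.
#' @param rng_seed Seed for parameter initialization.
#' @return A fitted `titan_model`.
#' @examples
#' \donttest{
#' bench <- generate_benchmark(synthetic_config(n_epitopes = 5,
#'                                              tcrs_per_epitope = 10))
#' fit <- titan(bench$records, titan_config_reduced(),
#'              train_control_reduced(epochs = 2))
#' predict(fit, bench$records[1:3, ])
#' }
#' @export
titan <- function(records, config = titan_config(), control = train_config(),
                  scopes = "all", validation = NULL, rng_seed = control$rng_seed) {
  model <- build_model(config, rng_seed = rng_seed)
  model <- set_trainable_scopes(model, scopes)
  train_model(model, records, control, validation = validation)
}

#' @export
plot.titan_model <- function(x, ...) {
  if (!length(x$loss_trace)) stop("model has no training history")
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "training loss", ...)
  if (length(x$val_trace)) {
    graphics::par(new = TRUE)
    graphics::plot(seq_along(x$val_trace), x$val_trace, type = "l", lty = 2,
                   axes = FALSE, xlab = "", ylab = "", col = "grey40")
    graphics::axis(4)
    graphics::mtext("validation ROC-AUC", side = 4, line = 2.5)
  }
  invisible(x)
}

#' Cross-validated evaluation of a binding model
#'
#' Splits positive records into folds with [make_folds()], generates
#' negatives by shuffling within each fold (or uses given labels), then for
#' every fold trains on the remaining folds and scores the held-out fold.
#' In strict mode the harness asserts that no held-out epitope or TCR
#' occurs in the corresponding training folds.
#'
#' @param records Binding records. With `negatives = "shuffle"` these must
#'   be positives only; with `"given"` they carry their labels already.
#' @param mode `"tcr_split"` or `"strict_split"`.
#' @param n_folds Number of folds (default 10).
#' @param model `"knn"` or `"titan"`.
#' @param k Neighbourhood size for the K-NN model.
#' @param config,control Architecture and optimization settings for the
#'   network model.
#' @param scopes Trainable scopes for the network model.
#' @param negatives `"shuffle"` to generate balanced negatives within each
#'   fold, `"given"` to use the labels in `records`.
#' @param rng_seed Seed for splitting, negative generation and training.
#' @param test_folds Folds to hold out and score; defaults to all of them.
#'   A single fold gives a plain held-out evaluation.
#' @return An object of class `titan_cv`: per-fold metric table plus mean
#'   and population SD of ROC-AUC and balanced accuracy.
#' @export
cross_validate <- function(records, mode = c("tcr_split", "strict_split"),
                           n_folds = 10L, model = c("knn", "titan"),
                           k = 13L, config = NULL, control = NULL,
                           scopes = "all",
                           negatives = c("shuffle", "given"),
                           rng_seed = 1L, test_folds = NULL) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  negatives <- match.arg(negatives)
  records <- validate_records(records, require_label = TRUE)
  fa <- make_folds(records, n_folds, mode, rng_seed)
  recs <- apply_folds(records, fa)
  if (negatives == "shuffle") {
    if (!all(recs$label == 1))
      stop("negatives = 'shuffle' expects positive records only")
    recs <- generate_negatives(recs[, c("epitope", "tcr", "label", "tcr_id")],
                               scope = recs$fold, rng_seed = rng_seed + 1L)
  }
  if (is.null(test_folds)) test_folds <- sort(unique(recs$fold))
  rows <- lapply(test_folds, function(f) {
    tr <- recs[recs$fold != f, , drop = FALSE]
    te <- recs[recs$fold == f, , drop = FALSE]
    stopifnot(length(intersect(tr$tcr_id, te$tcr_id)) == 0L)
    if (mode == "strict_split")
      stopifnot(length(intersect(tr$epitope, te$epitope)) == 0L)
    scores <- if (model == "knn") {
      predict(knn_model(tr, k = k), te)
    } else {
      if (is.null(config)) config <- titan_config_reduced()
      if (is.null(control)) control <- train_control_reduced()
      control$rng_seed <- rng_seed + 100L + f
      fit <- titan(tr, config, control, scopes = scopes,
                   rng_seed = rng_seed + 200L + f)
      predict(fit, te)
    }
    ev <- evaluate(scores, te$label)
    data.frame(fold = f, roc_auc = ev$roc_auc,
               balanced_accuracy = ev$balanced_accuracy,
               n_train = nrow(tr), n_test = nrow(te))
  })
  tab <- do.call(rbind, rows)
  structure(list(model = model, mode = mode, folds = tab,
                 mean_roc_auc = mean(tab$roc_auc),
                 sd_roc_auc = pop_sd_na(tab$roc_auc),
                 mean_balanced_accuracy = mean(tab$balanced_accuracy),
                 sd_balanced_accuracy = pop_sd_na(tab$balanced_accuracy)),
            class = "titan_cv")
}

#' @export
print.titan_cv <- function(x, ...) {
  cat(sprintf("%s, %s: %d evaluated fold(s)\n", toupper(x$model), x$mode,
              nrow(x$folds)))
  cat(sprintf("  ROC-AUC            %.3f +/- %.3f\n", x$mean_roc_auc, x$sd_roc_auc))
  cat(sprintf("  balanced accuracy  %.3f +/- %.3f\n", x$mean_balanced_accuracy,
              x$sd_balanced_accuracy))
  invisible(x)
}
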