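#' Architecture configuration for the bimodal attention model
#'
#' Both input streams (TCR and epitope) run through parallel channels: one
#' 1D convolution per kernel size plus, optionally, a residual channel that
#' passes the raw embeddings through unchanged. Each channel owns a pair of
#' context-attention layers (one per direction: TCR attended under the
#' epitope as context, and vice versa); the attention-filtered channel
#' readouts of both streams are concatenated and fed to a dense stack that
#' ends in a single logistic binding-probability output.
#'
#' @param tcr_len,epitope_len Padded token lengths of the two streams.
#' @param tcr_scheme Embedding scheme for the TCR stream (see
#'   [embedding_spec()]).
#' @param epitope_scheme `"blosum62"`, `"biophysical"` or `"learned"` for an
#'   amino-acid epitope stream, or `"smiles"` for an atom-level stream
#'   (learned embedding over a SMILES vocabulary).
#' @param filters Number of convolutional filters per channel, shared by
#'   both streams.
#' @param kernel_sizes_tcr,kernel_sizes_epitope Odd kernel sizes of the
#'   convolutional channels.
#' @param residual_channel Add the convolution-free residual channel
#'   (default `TRUE`).
#' @param attention_dim Size of the shared attention space.
#' @param dense_sizes Hidden sizes of the final dense stack.
#' @param dropout Dropout probability applied after every convolutional and
#'   dense ReLU during training.
#' @param learned_dim Dimension of learned embeddings (default 32).
#' @param smiles_vocab A `smiles_vocabulary` (required when
#'   `epitope_scheme = "smiles"`).
#' @return An object of class `titan_config`.
#' @details `titan_config()` with no arguments gives the base architecture:
#'   kernel sizes 3/5/11 plus a residual channel, attention space 16 and
#'   dense sizes 368/184 at padded length 500. [titan_config_pretrain()]
#'   gives the enlarged compound-protein-interaction pretraining variant
#'   (TCR length 1028, attention space 256, kernels 3/7/13/19 for the TCR
#'   and 3/7/9/13 for the ligand, dense 2048/1024/512).
#'   [titan_config_reduced()] is a small configuration for desk-scale
#'   experiments. The per-channel filter count is not pinned down by the
#'   reference architecture; 32 is the package default and it is fully
#'   configurable.
#' @export
titan_config <- function(tcr_len = 500L, epitope_len = 500L,
                         tcr_scheme = "blosum62",
                         epitope_scheme = "blosum62",
                         filters = 32L,
                         kernel_sizes_tcr = c(3L, 5L, 11L),
                         kernel_sizes_epitope = c(3L, 5L, 11L),
                         residual_channel = TRUE,
                         attention_dim = 16L,
                         dense_sizes = c(368L, 184L),
                         dropout = 0.5,
                         learned_dim = 32L,
                         smiles_vocab = NULL) {
  stopifnot(tcr_len >= 3L, epitope_len >= 3L, filters >= 1L,
            attention_dim >= 1L, all(dense_sizes >= 1L),
            dropout >= 0, dropout < 1,
            all(kernel_sizes_tcr %% 2L == 1L),
            all(kernel_sizes_epitope %% 2L == 1L))
  if (length(kernel_sizes_tcr) != length(kernel_sizes_epitope))
    stop("the two streams must have the same number of channels")
  if (identical(epitope_scheme, "smiles") && is.null(smiles_vocab))
    stop("epitope_scheme = 'smiles' requires a smiles_vocab")
  structure(list(
    tcr_len = as.integer(tcr_len), epitope_len = as.integer(epitope_len),
    tcr_scheme = tcr_scheme, epitope_scheme = epitope_scheme,
    filters = as.integer(filters),
    kernel_sizes_tcr = as.integer(kernel_sizes_tcr),
    kernel_sizes_epitope = as.integer(kernel_sizes_epitope),
    residual_channel = isTRUE(residual_channel),
    attention_dim = as.integer(attention_dim),
    dense_sizes = as.integer(dense_sizes), dropout = dropout,
    learned_dim = as.integer(learned_dim), smiles_vocab = smiles_vocab
  ), class = "titan_config")
}

#' @rdname titan_config
#' @param ... Overrides passed on to [titan_config()].
#' @export
titan_config_pretrain <- function(smiles_vocab, ...) {
  args <- list(tcr_len = 1028L, epitope_len = 500L,
               epitope_scheme = "smiles", smiles_vocab = smiles_vocab,
               kernel_sizes_tcr = c(3L, 7L, 13L, 19L),
               kernel_sizes_epitope = c(3L, 7L, 9L, 13L),
               residual_channel = FALSE,
               attention_dim = 256L, dense_sizes = c(2048L, 1024L, 512L))
  do.call(titan_config, utils::modifyList(args, list(...)))
}

#' @rdname titan_config
#' @export
titan_config_reduced <- function(...) {
  args <- list(tcr_len = 24L, epitope_len = 16L, filters = 16L,
               dropout = 0.25)
  do.call(titan_config, utils::modifyList(args, list(...)))
}

#' @keywords internal
stream_embedding <- function(scheme, config, rng_seed) {
  if (scheme == "smiles")
    embedding_spec("learned", dim = config$learned_dim,
                   n_tokens = vocab_size(config$smiles_vocab), rng_seed = rng_seed)
  else if (scheme == "learned")
    embedding_spec("learned", dim = config$learned_dim, rng_seed = rng_seed)
  else embedding_spec(scheme)
}

#' Build an untrained bimodal attention model
#'
#' Allocates and seeds every parameter of the architecture described by a
#' [titan_config()]: the embedding tables, one convolution per channel and
#' stream, the per-channel per-direction context-attention parameters
#' (W1, W2, W3, v), and the dense stack. Initialization is Glorot-uniform
#' for weight matrices and zero for biases; the same seed reproduces the
#' parameters bit for bit.
#'
#' @param config A [titan_config()].
#' @param rng_seed Integer seed.
#' @return An object of class `titan_model` with elements `config`,
#'   `params` (flat named list of arrays), `trainable` (named logical),
#'   `scope_mode`, and an empty training history.
#' @export
build_model <- function(config = titan_config(), rng_seed = 1L) {
  stopifnot(inherits(config, "titan_config"))
  emb_t <- stream_embedding(config$tcr_scheme, config, rng_seed)
  emb_e <- stream_embedding(config$epitope_scheme, config, rng_seed + 1L)
  Tlen <- config$tcr_len; Ulen <- config$epitope_len
  A <- config$attention_dim; Hf <- config$filters
  n_ch <- length(config$kernel_sizes_tcr) + config$residual_channel
  # channel feature dims: conv channels have `filters`, the residual channel
  # passes the embedding through
  dim_t <- c(rep(Hf, length(config$kernel_sizes_tcr)),
             if (config$residual_channel) emb_t$dim)
  dim_e <- c(rep(Hf, length(config$kernel_sizes_epitope)),
             if (config$residual_channel) emb_e$dim)
  params <- list()
  trainable <- logical(0)
  add <- function(name, value, train = TRUE) {
    params[[name]] <<- value
    trainable[[name]] <<- train
  }
  with_seed(rng_seed, {
    add("emb.tcr", emb_t$table, emb_t$trainable)
    add("emb.epi", emb_e$table, emb_e$trainable)
    for (i in seq_along(config$kernel_sizes_tcr)) {
      k <- config$kernel_sizes_tcr[i]
      add(sprintf("conv.tcr.ch%d.W", i), glorot(k * emb_t$dim, Hf, fan_in = k * emb_t$dim))
      add(sprintf("conv.tcr.ch%d.b", i), numeric(Hf))
      k <- config$kernel_sizes_epitope[i]
      add(sprintf("conv.epi.ch%d.W", i), glorot(k * emb_e$dim, Hf, fan_in = k * emb_e$dim))
      add(sprintf("conv.epi.ch%d.b", i), numeric(Hf))
    }
    for (i in seq_len(n_ch)) {
      # TCR as reference, epitope as context
      add(sprintf("att.tcr.ch%d.W1", i), glorot(dim_t[i], A))
      add(sprintf("att.tcr.ch%d.W2", i), glorot(dim_e[i], A))
      add(sprintf("att.tcr.ch%d.W3", i), glorot(Tlen, Ulen, fan_in = Ulen, fan_out = Tlen))
      add(sprintf("att.tcr.ch%d.v", i), stats::runif(A, -0.1, 0.1))
      # epitope as reference, TCR as context
      add(sprintf("att.epi.ch%d.W1", i), glorot(dim_e[i], A))
      add(sprintf("att.epi.ch%d.W2", i), glorot(dim_t[i], A))
      add(sprintf("att.epi.ch%d.W3", i), glorot(Ulen, Tlen, fan_in = Tlen, fan_out = Ulen))
      add(sprintf("att.epi.ch%d.v", i), stats::runif(A, -0.1, 0.1))
    }
    n_feat <- sum(dim_t) + sum(dim_e)
    sizes <- c(n_feat, config$dense_sizes, 1L)
    for (j in seq_len(length(sizes) - 1L)) {
      add(sprintf("dense.%d.W", j), glorot(sizes[j], sizes[j + 1L]))
      add(sprintf("dense.%d.b", j), numeric(sizes[j + 1L]))
    }
  })
  structure(list(config = config, params = params, trainable = trainable,
                 scope_mode = "all", n_channels = n_ch,
                 dim_t = dim_t, dim_e = dim_e,
                 loss_trace = numeric(0), val_trace = numeric(0),
                 rng_seed = as.integer(rng_seed), fitted = FALSE),
            class = "titan_model")
}

#' Number of parameters of a model
#'
#' @param model A `titan_model`.
#' @return Total number of scalar parameters (a pure function of the
#'   configuration).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Restrict which parameter groups training may update
#'
#' `"all"` makes every parameter trainable (fixed embedding tables such as
#' BLOSUM62 stay frozen). `"semifrozen"` additionally freezes the whole
#' epitope input stream -- its embedding table, its convolutions and the
#' attention layer that attends over the epitope -- leaving only the TCR
#' stream and the final dense stack free to move. This protects an epitope
#' channel pretrained on chemically diverse ligands from being unlearned
#' when fine-tuning on data with very few distinct epitopes.
#'
#' @param model A `titan_model`.
#' @param mode `"all"` or `"semifrozen"`.
#' @return The model with updated trainability flags.
#' @export
set_trainable_scopes <- function(model, mode = c("all", "semifrozen")) {
  mode <- match.arg(mode)
  tr <- model$trainable
  emb_fixed <- c(
    if (!stream_embedding_trainable(model$config$tcr_scheme)) "emb.tcr",
    if (!stream_embedding_trainable(model$config$epitope_scheme)) "emb.epi")
  tr[] <- TRUE
  tr[names(tr) %in% emb_fixed] <- FALSE
  if (mode == "semifrozen")
    tr[grepl("^(emb\\.epi|conv\\.epi|att\\.epi)", names(tr))] <- FALSE
  model$trainable <- tr
  model$scope_mode <- mode
  model
}

#' @keywords internal
stream_embedding_trainable <- function(scheme) scheme %in% c("learned", "smiles")

# Full forward pass over a token batch.
# tok_t: B x T integer matrix; tok_e: B x U.
# When train = TRUE, dropout is sampled from the current RNG stream and all
# intermediates are cached for the backward pass.
#' @keywords internal
titan_forward <- function(model, tok_t, tok_e, train = FALSE,
                          keep_attention = FALSE) {
  cfg <- model$config
  p <- model$params
  B <- nrow(tok_t)
  Tlen <- cfg$tcr_len; Ulen <- cfg$epitope_len
  stopifnot(ncol(tok_t) == Tlen, ncol(tok_e) == Ulen, nrow(tok_e) == B)
  rowidx <- list(tcr = as.vector(t(tok_t)) + 1L,
                 epi = as.vector(t(tok_e)) + 1L)
  # embedded matrices are only materialized for the residual channel; the
  # convolutions gather from the collapsed table-times-weights form directly
  X_t <- if (cfg$residual_channel)
    p[["emb.tcr"]][rowidx$tcr, , drop = FALSE]
  X_e <- if (cfg$residual_channel)
    p[["emb.epi"]][rowidx$epi, , drop = FALSE]
  n_conv <- length(cfg$kernel_sizes_tcr)
  n_ch <- model$n_channels
  feats <- vector("list", 2L * n_ch)
  caches <- if (train) list(tok_t = tok_t, tok_e = tok_e,
                            conv = vector("list", n_ch), att = vector("list", n_ch))
  att_maps <- if (keep_attention) list(tcr = vector("list", n_ch),
                                       epi = vector("list", n_ch))
  kernels <- list(tcr = cfg$kernel_sizes_tcr, epi = cfg$kernel_sizes_epitope)
  stream_feats <- function(X, stream, i, T) {
    if (i > n_conv) return(list(out = X, cache = NULL))  # residual channel
    emb <- p[[paste0("emb.", stream)]]
    k <- kernels[[stream]][i]
    TW <- tw_stack(emb, p[[sprintf("conv.%s.ch%d.W", stream, i)]], k)
    cv <- conv_token_forward(rowidx[[stream]], TW,
                             p[[sprintf("conv.%s.ch%d.b", stream, i)]],
                             T, B, k, nrow(emb))
    rl <- relu_forward(cv$out)
    mask <- if (train && cfg$dropout > 0)
      dropout_mask(nrow(rl$out), ncol(rl$out), cfg$dropout)
    out <- if (is.null(mask)) rl$out else rl$out * mask
    list(out = out, cache = list(conv = cv$cache, relu = rl$cache, mask = mask))
  }
  for (i in seq_len(n_ch)) {
    ft <- stream_feats(X_t, "tcr", i, Tlen)
    fe <- stream_feats(X_e, "epi", i, Ulen)
    at <- attention_forward(ft$out, fe$out,
                            att_par(p, "tcr", i), Tlen, Ulen, B)
    ae <- attention_forward(fe$out, ft$out,
                            att_par(p, "epi", i), Ulen, Tlen, B)
    feats[[2L * i - 1L]] <- at$filtered
    feats[[2L * i]] <- ae$filtered
    if (train) {
      caches$conv[[i]] <- list(t = ft$cache, e = fe$cache)
      caches$att[[i]] <- list(t = at$cache, e = ae$cache)
    }
    if (keep_attention) {
      att_maps$tcr[[i]] <- matrix(at$alpha, B, Tlen, byrow = TRUE)
      att_maps$epi[[i]] <- matrix(ae$alpha, B, Ulen, byrow = TRUE)
    }
  }
  Fmat <- do.call(cbind, feats)  # B x n_feat
  n_dense <- length(cfg$dense_sizes) + 1L
  H <- Fmat
  dense_cache <- if (train) vector("list", n_dense)
  for (j in seq_len(n_dense)) {
    Z <- sweep(H %*% p[[sprintf("dense.%d.W", j)]], 2L,
               p[[sprintf("dense.%d.b", j)]], `+`)
    if (j < n_dense) {
      rl <- relu_forward(Z)
      mask <- if (train && cfg$dropout > 0)
        dropout_mask(nrow(Z), ncol(Z), cfg$dropout)
      Hnew <- if (is.null(mask)) rl$out else rl$out * mask
      if (train) dense_cache[[j]] <- list(H = H, relu = rl$cache, mask = mask)
      H <- Hnew
    } else {
      if (train) dense_cache[[j]] <- list(H = H)
      H <- Z
    }
  }
  logit <- drop(H)
  if (train) caches$dense <- dense_cache
  list(prob = stats::plogis(logit), logit = logit, caches = caches,
       attention = att_maps)
}

# Backward pass: dlogit is dL/dlogit per sample. Returns the gradient list
# keyed like model$params.
#' @keywords internal
titan_backward <- function(model, caches, dlogit) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  n_dense <- length(cfg$dense_sizes) + 1L
  dH <- matrix(dlogit, ncol = 1L)
  for (j in rev(seq_len(n_dense))) {
    cc <- caches$dense[[j]]
    if (j < n_dense) {
      if (!is.null(cc$mask)) dH <- dH * cc$mask
      dH <- dH * cc$relu
    }
    grads[[sprintf("dense.%d.W", j)]] <- crossprod(cc$H, dH)
    grads[[sprintf("dense.%d.b", j)]] <- colSums(dH)
    dH <- tcrossprod(dH, p[[sprintf("dense.%d.W", j)]])
  }
  # split the feature gradient back into the per-channel blocks
  n_ch <- model$n_channels
  n_conv <- length(cfg$kernel_sizes_tcr)
  widths <- as.vector(rbind(model$dim_t, model$dim_e))
  offs <- c(0L, cumsum(widths))
  need_t <- isTRUE(model$trainable[["emb.tcr"]])
  need_e <- isTRUE(model$trainable[["emb.epi"]])
  dX_t <- 0; dX_e <- 0
  dTab_t <- if (need_t) matrix(0, nrow(p[["emb.tcr"]]), ncol(p[["emb.tcr"]]))
  dTab_e <- if (need_e) matrix(0, nrow(p[["emb.epi"]]), ncol(p[["emb.epi"]]))
  for (i in seq_len(n_ch)) {
    dFt <- dH[, (offs[2L * i - 1L] + 1L):offs[2L * i], drop = FALSE]
    dFe <- dH[, (offs[2L * i] + 1L):offs[2L * i + 1L], drop = FALSE]
    bt <- attention_backward(dFt, att_par(p, "tcr", i), caches$att[[i]]$t)
    be <- attention_backward(dFe, att_par(p, "epi", i), caches$att[[i]]$e)
    for (nm in names(bt$grads))
      grads[[sprintf("att.tcr.ch%d.%s", i, nm)]] <- bt$grads[[nm]]
    for (nm in names(be$grads))
      grads[[sprintf("att.epi.ch%d.%s", i, nm)]] <- be$grads[[nm]]
    dOut_t <- bt$dX1 + be$dX2
    dOut_e <- bt$dX2 + be$dX1
    if (i <= n_conv) {
      cc <- caches$conv[[i]]$t
      if (!is.null(cc$mask)) dOut_t <- dOut_t * cc$mask
      dOut_t <- dOut_t * cc$relu
      cb <- conv_token_backward(dOut_t, p[["emb.tcr"]],
                                p[[sprintf("conv.tcr.ch%d.W", i)]], cc$conv,
                                need_table_grad = need_t)
      grads[[sprintf("conv.tcr.ch%d.W", i)]] <- cb$dW
      grads[[sprintf("conv.tcr.ch%d.b", i)]] <- cb$db
      if (need_t) dTab_t <- dTab_t + cb$dTab
      cc <- caches$conv[[i]]$e
      if (!is.null(cc$mask)) dOut_e <- dOut_e * cc$mask
      dOut_e <- dOut_e * cc$relu
      cb <- conv_token_backward(dOut_e, p[["emb.epi"]],
                                p[[sprintf("conv.epi.ch%d.W", i)]], cc$conv,
                                need_table_grad = need_e)
      grads[[sprintf("conv.epi.ch%d.W", i)]] <- cb$dW
      grads[[sprintf("conv.epi.ch%d.b", i)]] <- cb$db
      if (need_e) dTab_e <- dTab_e + cb$dTab
    } else {
      # residual channel: attention gradients hit the embeddings directly
      if (need_t) dX_t <- dX_t + dOut_t
      if (need_e) dX_e <- dX_e + dOut_e
    }
  }
  if (need_t) {
    g <- dTab_t
    if (!identical(dX_t, 0))
      g <- g + embedding_grad(dX_t, caches$tok_t, nrow(p[["emb.tcr"]]))
    grads[["emb.tcr"]] <- g
  }
  if (need_e) {
    g <- dTab_e
    if (!identical(dX_e, 0))
      g <- g + embedding_grad(dX_e, caches$tok_e, nrow(p[["emb.epi"]]))
    grads[["emb.epi"]] <- g
  }
  grads
}

#' @keywords internal
embedding_grad <- function(dX, tok, n_rows) {
  idx <- as.vector(t(tok)) + 1L
  g <- rowsum(dX, idx)
  out <- matrix(0, n_rows, ncol(dX))
  out[as.integer(rownames(g)), ] <- g
  out[1L, ] <- 0  # pad embedding is pinned to zero
  out
}

#' @keywords internal
att_par <- function(p, stream, i) {
  list(W1 = p[[sprintf("att.%s.ch%d.W1", stream, i)]],
       W2 = p[[sprintf("att.%s.ch%d.W2", stream, i)]],
       W3 = p[[sprintf("att.%s.ch%d.W3", stream, i)]],
       v = p[[sprintf("att.%s.ch%d.v", stream, i)]])
}

#' Context attention over a reference sequence
#'
#' The fusing operation of the bimodal model, exposed on plain matrices:
#' given reference features `X1` (T x H) and context features `X2` (U x K),
#' computes \deqn{u = \tanh(X_1 W_1 + W_3 (X_2 W_2))\,v,\qquad
#' \alpha = \mathrm{softmax}(u),} and returns the attention weights over
#' the T reference positions together with the alpha-weighted sum of
#' reference rows (the filtered readout passed on to the dense stack).
#'
#' @param X1 Reference feature matrix, T x H.
#' @param X2 Context feature matrix, U x K.
#' @param params List with `W1` (H x A), `W2` (K x A), `W3` (T x U) and `v`
#'   (length A).
#' @return An object of class `attention_map`: list with `alpha` (length T,
#'   non-negative, summing to 1) and `filtered` (length H).
#' @export
context_attention <- function(X1, X2, params) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  need <- c("W1", "W2", "W3", "v")
  if (!all(need %in% names(params))) stop("params must contain W1, W2, W3, v")
  A <- length(params$v)
  chk <- function(ok, what, got, want) {
    if (!ok) stop(sprintf("%s has dimension %s, expected %s", what,
                          paste(got, collapse = "x"), paste(want, collapse = "x")))
  }
  chk(nrow(params$W1) == ncol(X1) && ncol(params$W1) == A, "W1",
      dim(params$W1), c(ncol(X1), A))
  chk(nrow(params$W2) == ncol(X2) && ncol(params$W2) == A, "W2",
      dim(params$W2), c(ncol(X2), A))
  chk(nrow(params$W3) == nrow(X1) && ncol(params$W3) == nrow(X2), "W3",
      dim(params$W3), c(nrow(X1), nrow(X2)))
  fw <- attention_forward(X1, X2, params, nrow(X1), nrow(X2), 1L)
  structure(list(alpha = fw$alpha, filtered = drop(fw$filtered)),
            class = "attention_map")
}

#' @export
print.titan_model <- function(x, ...) {
  cfg <- x$config
  cat("Bimodal context-attention binding model\n")
  cat(sprintf("  TCR stream:     %s embedding, length %d\n", cfg$tcr_scheme, cfg$tcr_len))
  cat(sprintf("  epitope stream: %s embedding, length %d\n", cfg$epitope_scheme, cfg$epitope_len))
  cat(sprintf("  channels: conv kernels [%s]%s, %d filters; attention space %d\n",
              paste(cfg$kernel_sizes_tcr, collapse = ", "),
              if (cfg$residual_channel) " + residual" else "", cfg$filters,
              cfg$attention_dim))
  cat(sprintf("  dense stack: %s -> 1; dropout %.2f\n",
              paste(cfg$dense_sizes, collapse = " -> "), cfg$dropout))
  cat(sprintf("  parameters: %d; scope: %s; %s\n", n_parameters(x), x$scope_mode,
              if (x$fitted) sprintf("trained for %d epochs", length(x$loss_trace))
              else "untrained"))
  invisible(x)
}

#' @export
summary.titan_model <- function(object, ...) {
  print(object)
  if (length(object$loss_trace)) {
    cat(sprintf("  final training loss: %.4f\n", utils::tail(object$loss_trace, 1L)))
    if (length(object$val_trace))
      cat(sprintf("  best validation ROC-AUC: %.4f (epoch %d)\n",
                  max(object$val_trace), which.max(object$val_trace)))
  }
  invisible(object)
}
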