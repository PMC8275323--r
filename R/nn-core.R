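# Dense-matrix neural-network primitives for the bimodal attention model.
#
# Batches of sequences are stored as (B*T) x D matrices in which row
# r = t + (b-1)*T holds position t of sample b ("position-fastest" layout).
# All layers come in forward/backward pairs; forward passes return a cache
# consumed by the corresponding backward pass.

# index vector realizing a within-sample shift by `off` positions;
# out-of-range positions point to the extra all-zero row B*T + 1
#' @keywords internal
shift_index <- function(T, B, off) {
  base <- rep(seq_len(T), B) + off
  idx <- base + rep((seq_len(B) - 1L) * T, each = T)
  idx[base < 1L | base > T] <- T * B + 1L
  idx
}

# 1D convolution with same-padding over the position axis.
# W is a (k*D) x H matrix; offset block o covers rows (o-1)*D + 1 .. o*D and
# corresponds to relative position o - (k+1)/2 (k odd).
#' @keywords internal
conv1d_forward <- function(X, W, bias, T, B) {
  D <- ncol(X)
  k <- nrow(W) / D
  h <- (k - 1L) / 2L
  n <- nrow(X)
  Xp <- rbind(X, 0)
  # unfolded input: column block o holds the input shifted by o - h - 1
  Xu <- matrix(0, n, k * D)
  idxs <- vector("list", k)
  for (o in seq_len(k)) {
    idx <- shift_index(T, B, o - h - 1L)
    idxs[[o]] <- idx
    Xu[, ((o - 1L) * D + 1L):(o * D)] <- Xp[idx, , drop = FALSE]
  }
  out <- Xu %*% W
  out <- sweep(out, 2L, bias, `+`)
  list(out = out, cache = list(Xu = Xu, idxs = idxs, k = k, D = D))
}

#' @keywords internal
conv1d_backward <- function(dOut, W, cache, need_dx = TRUE) {
  k <- cache$k; D <- cache$D
  n <- nrow(cache$Xu)
  dW <- crossprod(cache$Xu, dOut)
  dX <- NULL
  if (need_dx) {
    # the input gradient is only needed when the embedding table upstream
    # is itself trainable
    dXu <- tcrossprod(dOut, W)
    dXp <- matrix(0, n + 1L, D)
    for (o in seq_len(k)) {
      idx <- cache$idxs[[o]]
      # shifts are injective on valid rows, so gather-add is a plain add
      dXp[idx, ] <- dXp[idx, , drop = FALSE] +
        dXu[, ((o - 1L) * D + 1L):(o * D), drop = FALSE]
    }
    dX <- dXp[seq_len(n), , drop = FALSE]
  }
  list(dW = dW, db = colSums(dOut), dX = dX)
}

#' @keywords internal
relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}

#' @keywords internal
dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

# Convolution over an embedded token stream, exploiting that the conv input
# is a table lookup: conv(embed(tok)) at position t equals the sum over
# offsets o of (table %*% W_o)[token(t+o), ], so the whole layer reduces to
# k gathers from the small (k * n_rows) x H matrix TW = (I_k (x) table) W.
# Out-of-range positions map to the pad row, whose embedding is zero.

#' @keywords internal
tw_stack <- function(table, W, k) {
  D <- ncol(table)
  do.call(rbind, lapply(seq_len(k), function(o)
    table %*% W[((o - 1L) * D + 1L):(o * D), , drop = FALSE]))
}

#' @keywords internal
conv_token_forward <- function(tokrow, TW, bias, T, B, k, n_rows) {
  h <- (k - 1L) %/% 2L
  n <- length(tokrow)
  tokp <- c(tokrow, 1L)  # out-of-range -> pad row
  out <- matrix(bias, n, length(bias), byrow = TRUE)
  stv <- vector("list", k)
  for (o in seq_len(k)) {
    idx <- shift_index(T, B, o - h - 1L)
    rows <- tokp[idx] + (o - 1L) * n_rows
    stv[[o]] <- rows
    out <- out + TW[rows, , drop = FALSE]
  }
  list(out = out, cache = list(stv = stv, k = k, n_rows = n_rows))
}

#' @keywords internal
conv_token_backward <- function(dOut, table, W, cache, need_table_grad = FALSE) {
  k <- cache$k; n_rows <- cache$n_rows
  D <- ncol(table); H <- ncol(dOut)
  dW <- matrix(0, k * D, H)
  dTab <- if (need_table_grad) matrix(0, nrow(table), D)
  for (o in seq_len(k)) {
    grp <- cache$stv[[o]] - (o - 1L) * n_rows
    part <- rowsum(dOut, grp)                        # per-token-row sums
    full <- matrix(0, n_rows, H)
    full[as.integer(rownames(part)), ] <- part
    full[1L, ] <- 0                                  # pad row is pinned
    rows <- ((o - 1L) * D + 1L):(o * D)
    dW[rows, ] <- crossprod(table, full)
    if (need_table_grad)
      dTab <- dTab + tcrossprod(full, W[rows, , drop = FALSE])
  }
  list(dW = dW, db = colSums(dOut), dTab = dTab)
}

# reshape helpers between (B*T) x A matrices and per-sample T x A blocks
#' @keywords internal
stack_to_wide <- function(M, T, B) {
  # (B*T) x A, position-fastest  ->  T x (A*B) with sample blocks of A cols
  A <- ncol(M)
  matrix(aperm(array(M, c(T, B, A)), c(1L, 3L, 2L)), nrow = T)
}

#' @keywords internal
wide_to_stack <- function(Wd, T, B) {
  # T x (A*B)  ->  (B*T) x A
  A <- ncol(Wd) / B
  matrix(aperm(array(Wd, c(T, A, B)), c(1L, 3L, 2L)), nrow = T * B)
}

# Context attention over a reference stream, driven by a context stream.
# X1: (B*T) x H reference features; X2: (B*U) x K context features.
# par: list(W1 H x A, W2 K x A, W3 T x U, v length A).
# Computes u = tanh(X1 W1 + W3 (X2 W2)) v per sample, alpha = softmax(u)
# over the T reference positions, and the alpha-weighted sum of reference
# positions as the filtered readout.
#' @keywords internal
attention_forward <- function(X1, X2, par, T, U, B) {
  P1 <- X1 %*% par$W1                       # (B*T) x A
  P2 <- X2 %*% par$W2                       # (B*U) x A
  P2w <- stack_to_wide(P2, U, B)            # U x (A*B)
  Qw <- par$W3 %*% P2w                      # T x (A*B)
  Q <- wide_to_stack(Qw, T, B)              # (B*T) x A
  Tn <- tanh(P1 + Q)
  u <- drop(Tn %*% par$v)                   # length B*T
  um <- matrix(u, T, B)
  um <- exp(um - rep(apply(um, 2L, max), each = T))
  alpha <- as.vector(um) / rep(colSums(um), each = T)
  filt <- colSums(array(X1 * alpha, c(T, B, ncol(X1))))  # B x H
  list(filtered = filt, alpha = alpha,
       cache = list(X1 = X1, X2 = X2, P2w = P2w, Tn = Tn, alpha = alpha,
                    T = T, U = U, B = B))
}

#' @keywords internal
attention_backward <- function(dFilt, par, cache) {
  T <- cache$T; U <- cache$U; B <- cache$B
  alpha <- cache$alpha
  rows <- rep(seq_len(B), each = T)
  dFilt_rows <- dFilt[rows, , drop = FALSE]         # (B*T) x H
  dX1 <- alpha * dFilt_rows
  dalpha <- rowSums(cache$X1 * dFilt_rows)
  s <- rep(colSums(matrix(alpha * dalpha, T, B)), each = T)
  du <- alpha * (dalpha - s)
  dTn <- outer(du, par$v) * (1 - cache$Tn^2)        # (B*T) x A
  dW1 <- crossprod(cache$X1, dTn)
  dX1 <- dX1 + tcrossprod(dTn, par$W1)
  dQw <- stack_to_wide(dTn, T, B)                   # T x (A*B)
  dW3 <- tcrossprod(dQw, cache$P2w)                 # T x U
  dP2w <- crossprod(par$W3, dQw)                    # U x (A*B)
  dP2 <- wide_to_stack(dP2w, U, B)
  dW2 <- crossprod(cache$X2, dP2)
  dX2 <- tcrossprod(dP2, par$W2)
  dv <- drop(crossprod(cache$Tn, du))
  list(dX1 = dX1, dX2 = dX2,
       grads = list(W1 = dW1, W2 = dW2, W3 = dW3, v = dv))
}

# Glorot-uniform initialization
#' @keywords internal
glorot <- function(nr, nc, fan_in = nr, fan_out = nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# One Adam update over a flat named list of arrays. Only names with
# trainable[name] == TRUE move. state holds first/second moments and the
# step counter.
#' @keywords internal
adam_step <- function(params, grads, state, trainable,
                      lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (!isTRUE(trainable[[nm]])) next
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}
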