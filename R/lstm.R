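# Internal LSTM-FC numerical core.
#
# Many-to-one network: input sequences (n x T x d) -> LSTM (h units, single
# bias, gate order i/f/g/o) -> last hidden state -> FC1 (eLU) -> FC2 ->
# softmax over {rest, grasp}. Batched forward, full backpropagation through
# time (including gradients with respect to the inputs, needed for
# integrated-gradients attribution), Adam updates, inverted dropout on the
# LSTM output and the FC1 output.

sigmoid <- function(x) 1 / (1 + exp(-x))
elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
elu_grad <- function(x, y) ifelse(x > 0, 1, y + 1)   # y = elu(x)

# He-normal initialized parameter set. d inputs, h LSTM units, f1 FC1 units.
lstm_init <- function(d, h, f1, out = 2L) {
  he <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  list(W  = he(d, 4 * h, d),     # input weights, gates stacked [i f g o]
       U  = he(h, 4 * h, h),     # recurrent weights
       b  = numeric(4 * h),
       W1 = he(h, f1, h), b1 = numeric(f1),
       W2 = he(f1, out, f1), b2 = numeric(out))
}

lstm_n_params <- function(p) sum(vapply(p, length, integer(1)))

# Forward pass. X: n x T x d array. Dropout masks (already scaled, or NULL)
# apply to the LSTM output and FC1 output. Returns probabilities, logits and
# (if keep_cache) everything the backward pass needs.
lstm_forward <- function(p, X, drop_h = NULL, drop_f = NULL, keep_cache = FALSE) {
  n <- dim(X)[1]; Tt <- dim(X)[2]
  h <- ncol(p$U)/4
  H <- matrix(0, n, h); C <- matrix(0, n, h)
  cache <- if (keep_cache) vector("list", Tt) else NULL
  gi <- 1:h; gf <- h + gi; gg <- 2*h + gi; go <- 3*h + gi
  for (t in seq_len(Tt)) {
    Xt <- matrix(X[, t, ], nrow = n)
    Z <- Xt %*% p$W + H %*% p$U
    Z <- sweep(Z, 2, p$b, "+")
    i_ <- sigmoid(Z[, gi, drop = FALSE])
    f_ <- sigmoid(Z[, gf, drop = FALSE])
    g_ <- tanh(Z[, gg, drop = FALSE])
    o_ <- sigmoid(Z[, go, drop = FALSE])
    C_prev <- C; H_prev <- H
    C <- f_ * C_prev + i_ * g_
    tC <- tanh(C)
    H <- o_ * tC
    if (keep_cache) {
      cache[[t]] <- list(Xt = Xt, H_prev = H_prev, C_prev = C_prev,
                         i = i_, f = f_, g = g_, o = o_, tC = tC)
    }
  }
  Hd <- if (is.null(drop_h)) H else H * drop_h
  A1 <- sweep(Hd %*% p$W1, 2, p$b1, "+")
  Y1 <- elu(A1)
  Y1d <- if (is.null(drop_f)) Y1 else Y1 * drop_f
  logits <- sweep(Y1d %*% p$W2, 2, p$b2, "+")
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, logits = logits,
       cache = if (keep_cache) list(steps = cache, H = H, Hd = Hd, A1 = A1,
                                    Y1 = Y1, Y1d = Y1d,
                                    drop_h = drop_h, drop_f = drop_f))
}

# Backward pass from a gradient on the logits (n x out). Returns weight
# gradients and, if want_dX, gradients with respect to the inputs (n x T x d).
lstm_backward <- function(p, X, fw, dlogits, want_dX = FALSE) {
  n <- dim(X)[1]; Tt <- dim(X)[2]; d <- dim(X)[3]
  h <- ncol(p$U)/4
  ca <- fw$cache
  gW2 <- t(ca$Y1d) %*% dlogits
  gb2 <- colSums(dlogits)
  dY1d <- dlogits %*% t(p$W2)
  dY1 <- if (is.null(ca$drop_f)) dY1d else dY1d * ca$drop_f
  dA1 <- dY1 * elu_grad(ca$A1, ca$Y1)
  gW1 <- t(ca$Hd) %*% dA1
  gb1 <- colSums(dA1)
  dHd <- dA1 %*% t(p$W1)
  dH <- if (is.null(ca$drop_h)) dHd else dHd * ca$drop_h
  gW <- matrix(0, nrow(p$W), ncol(p$W))
  gU <- matrix(0, h, 4 * h)
  gb <- numeric(4 * h)
  dX <- if (want_dX) array(0, dim(X)) else NULL
  dC <- matrix(0, n, h)
  gi <- 1:h; gf <- h + gi; gg <- 2*h + gi; go <- 3*h + gi
  for (t in rev(seq_len(Tt))) {
    st <- ca$steps[[t]]
    do_ <- dH * st$tC
    dC <- dC + dH * st$o * (1 - st$tC^2)
    di <- dC * st$g
    dg <- dC * st$i
    df <- dC * st$C_prev
    dZ <- matrix(0, n, 4 * h)
    dZ[, gi] <- di * st$i * (1 - st$i)
    dZ[, gf] <- df * st$f * (1 - st$f)
    dZ[, gg] <- dg * (1 - st$g^2)
    dZ[, go] <- do_ * st$o * (1 - st$o)
    gW <- gW + t(st$Xt) %*% dZ
    gU <- gU + t(st$H_prev) %*% dZ
    gb <- gb + colSums(dZ)
    if (want_dX) dX[, t, ] <- dZ %*% t(p$W)
    dH <- dZ %*% t(p$U)
    dC <- dC * st$f
  }
  list(grads = list(W = gW, U = gU, b = gb, W1 = gW1, b1 = gb1,
                    W2 = gW2, b2 = gb2),
       dX = dX)
}

adam_init <- function(p) {
  list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0),
       t = 0L)
}

adam_step <- function(p, grads, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (k in names(p)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * grads[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- st$m[[k]] / (1 - beta1^st$t)
    vhat <- st$v[[k]] / (1 - beta2^st$t)
    p[[k]] <- p[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = p, state = st)
}
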