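# Native neural-network core.
#
# No deep-learning backend is assumed: layers, backpropagation and the
# Adam optimizer are implemented directly on BLAS-backed matrix ops.
# Batches are stored sample-major: a batch of n windows of length L with C
# channels is an (n*L) x C matrix whose rows (i-1)*L + 1 .. i*L hold
# sample i. Every backward pass is validated against finite differences in
# the test suite.

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.rows_at_time <- function(n, L, t) (0:(n - 1L)) * L + t

# ---- multi-head self-attention -------------------------------------------

attn_init <- function(C, D) {
  list(Wq = .glorot(C, D), bq = numeric(D),
       Wk = .glorot(C, D), bk = numeric(D),
       Wv = .glorot(C, D), bv = numeric(D),
       Wo = .glorot(D, D), bo = numeric(D),
       Win = .glorot(C, D), bin = numeric(D))
}

# X: (n*L) x C. Output: (n*L) x D (sequence length preserved).
# A learned input projection is added residually to the attention output:
# without it the softmax mixing at initialization is near-uniform over
# positions and erases the positional information the downstream CNN and
# BiLSTM need.
attn_forward <- function(p, X, n, L, heads) {
  D <- ncol(p$Wq)
  dk <- D %/% heads
  Q <- X %*% p$Wq + rep(p$bq, each = nrow(X))
  K <- X %*% p$Wk + rep(p$bk, each = nrow(X))
  V <- X %*% p$Wv + rep(p$bv, each = nrow(X))
  O <- matrix(0, nrow(X), D)
  Pcache <- vector("list", n)
  scale <- 1 / sqrt(dk)
  for (i in seq_len(n)) {
    ri <- ((i - 1L) * L + 1L):(i * L)
    Pi <- vector("list", heads)
    for (h in seq_len(heads)) {
      ch <- ((h - 1L) * dk + 1L):(h * dk)
      S <- tcrossprod(Q[ri, ch, drop = FALSE], K[ri, ch, drop = FALSE]) * scale
      S <- exp(S - apply(S, 1, max))
      P <- S / rowSums(S)
      O[ri, ch] <- P %*% V[ri, ch, drop = FALSE]
      Pi[[h]] <- P
    }
    Pcache[[i]] <- Pi
  }
  out <- O %*% p$Wo + rep(p$bo, each = nrow(X)) +
    X %*% p$Win + rep(p$bin, each = nrow(X))
  list(out = out, cache = list(X = X, Q = Q, K = K, V = V, O = O,
                               P = Pcache, n = n, L = L, heads = heads,
                               dk = dk))
}

attn_backward <- function(p, cache, dOut) {
  X <- cache$X; Q <- cache$Q; K <- cache$K; V <- cache$V; O <- cache$O
  n <- cache$n; L <- cache$L; heads <- cache$heads; dk <- cache$dk
  scale <- 1 / sqrt(dk)
  g <- list(Wo = crossprod(O, dOut), bo = colSums(dOut))
  dO <- tcrossprod(dOut, p$Wo)
  dQ <- matrix(0, nrow(Q), ncol(Q))
  dK <- dQ; dV <- dQ
  for (i in seq_len(n)) {
    ri <- ((i - 1L) * L + 1L):(i * L)
    for (h in seq_len(heads)) {
      ch <- ((h - 1L) * dk + 1L):(h * dk)
      P <- cache$P[[i]][[h]]
      dOih <- dO[ri, ch, drop = FALSE]
      dV[ri, ch] <- crossprod(P, dOih)
      dP <- tcrossprod(dOih, V[ri, ch, drop = FALSE])
      dS <- P * (dP - rowSums(dP * P))
      dQ[ri, ch] <- (dS %*% K[ri, ch, drop = FALSE]) * scale
      dK[ri, ch] <- (crossprod(dS, Q[ri, ch, drop = FALSE])) * scale
    }
  }
  g$Wq <- crossprod(X, dQ); g$bq <- colSums(dQ)
  g$Wk <- crossprod(X, dK); g$bk <- colSums(dK)
  g$Wv <- crossprod(X, dV); g$bv <- colSums(dV)
  g$Win <- crossprod(X, dOut); g$bin <- colSums(dOut)
  dX <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv) +
    dOut %*% t(p$Win)
  list(grads = g, dX = dX)
}

# ---- 1-D convolution (valid padding, stride 1, ReLU) ---------------------

conv_init <- function(Cin, k, filters) {
  list(W = .glorot(k * Cin, filters), b = numeric(filters), k = k)
}

.im2col_rows <- function(n, L, Lout, j) {
  rep((0:(n - 1L)) * L, each = Lout) + rep(seq_len(Lout), n) + (j - 1L)
}

conv_forward <- function(p, X, n, L) {
  k <- p$k
  Lout <- L - k + 1L
  if (Lout < 1L) stop("conv kernel larger than input length", call. = FALSE)
  Xcol <- do.call(cbind, lapply(seq_len(k), function(j) {
    X[.im2col_rows(n, L, Lout, j), , drop = FALSE]
  }))
  Z <- Xcol %*% p$W + rep(p$b, each = nrow(Xcol))
  A <- Z * (Z > 0)
  list(out = A, cache = list(Xcol = Xcol, mask = Z > 0, n = n, L = L,
                             Lout = Lout, Cin = ncol(X)))
}

conv_backward <- function(p, cache, dA) {
  dZ <- dA * cache$mask
  g <- list(W = crossprod(cache$Xcol, dZ), b = colSums(dZ), k = NULL)
  dXcol <- dZ %*% t(p$W)
  n <- cache$n; L <- cache$L; Lout <- cache$Lout; Cin <- cache$Cin
  dX <- matrix(0, n * L, Cin)
  for (j in seq_len(p$k)) {
    rows <- .im2col_rows(n, L, Lout, j)
    dX[rows, ] <- dX[rows, ] + dXcol[, ((j - 1L) * Cin + 1L):(j * Cin),
                                     drop = FALSE]
  }
  list(grads = g, dX = dX)
}

# ---- temporal max pooling (size = stride) --------------------------------

pool_forward <- function(X, n, L, size) {
  Lout <- L %/% size
  if (Lout < 1L) stop("pool size larger than input length", call. = FALSE)
  base <- rep((0:(n - 1L)) * L, each = Lout) +
    rep(seq(1L, by = size, length.out = Lout), n)
  out <- X[base, , drop = FALSE]
  win <- matrix(1L, nrow(out), ncol(out))
  if (size > 1L) {
    for (j in 2:size) {
      cand <- X[base + (j - 1L), , drop = FALSE]
      upd <- cand > out
      out[upd] <- cand[upd]
      win[upd] <- j
    }
  }
  list(out = out, cache = list(base = base, win = win, n = n, L = L,
                               size = size, C = ncol(X)))
}

pool_backward <- function(cache, dOut) {
  dX <- matrix(0, cache$n * cache$L, cache$C)
  for (j in seq_len(cache$size)) {
    sel <- cache$win == j
    if (!any(sel)) next
    idx <- cbind(cache$base[row(sel)[sel]] + (j - 1L), col(sel)[sel])
    dX[idx] <- dX[idx] + dOut[sel]
  }
  dX
}

# ---- flatten (n*Lout) x F -> n x (F*Lout), channel-fastest ---------------

flatten_forward <- function(X, n, Lout) {
  F <- ncol(X)
  t(matrix(t(X), F * Lout, n))
}

flatten_backward <- function(dF, n, Lout, F) {
  t(matrix(t(dF), F, Lout * n))
}

# ---- LSTM (single direction; final hidden state output) ------------------

lstm_init <- function(Din, H) {
  W <- .glorot(Din + H, 4L * H)
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1  # forget-gate bias, standard init
  list(W = W, b = b)
}

lstm_forward <- function(p, X, n, L, reverse = FALSE) {
  H <- length(p$b) %/% 4L
  ts <- if (reverse) rev(seq_len(L)) else seq_len(L)
  h <- matrix(0, n, H)
  cc <- matrix(0, n, H)
  steps <- vector("list", L)
  i1 <- 1:H; i2 <- (H + 1L):(2L * H); i3 <- (2L * H + 1L):(3L * H)
  i4 <- (3L * H + 1L):(4L * H)
  for (s in seq_len(L)) {
    t <- ts[s]
    Xt <- X[.rows_at_time(n, L, t), , drop = FALSE]
    Z <- cbind(Xt, h) %*% p$W + rep(p$b, each = n)
    gi <- .sigmoid(Z[, i1, drop = FALSE])
    gf <- .sigmoid(Z[, i2, drop = FALSE])
    go <- .sigmoid(Z[, i3, drop = FALSE])
    gg <- tanh(Z[, i4, drop = FALSE])
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    tc <- tanh(cc)
    h_prev <- h
    h <- go * tc
    steps[[s]] <- list(t = t, gi = gi, gf = gf, go = go, gg = gg,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(out = h, cache = list(steps = steps, n = n, L = L, H = H,
                             Din = ncol(X), reverse = reverse))
}

lstm_backward <- function(p, cache, X, dh_final) {
  n <- cache$n; L <- cache$L; H <- cache$H; Din <- cache$Din
  dW <- matrix(0, nrow(p$W), ncol(p$W))
  db <- numeric(length(p$b))
  dX <- matrix(0, n * L, Din)
  dh <- dh_final
  dc <- matrix(0, n, H)
  for (s in rev(seq_len(L))) {
    st <- cache$steps[[s]]
    dc <- dc + dh * st$go * (1 - st$tc^2)
    do_ <- dh * st$tc
    di <- dc * st$gg
    df <- dc * st$c_prev
    dg <- dc * st$gi
    dZ <- cbind(di * st$gi * (1 - st$gi),
                df * st$gf * (1 - st$gf),
                do_ * st$go * (1 - st$go),
                dg * (1 - st$gg^2))
    rows <- .rows_at_time(n, L, st$t)
    inp <- cbind(X[rows, , drop = FALSE], st$h_prev)
    dW <- dW + crossprod(inp, dZ)
    db <- db + colSums(dZ)
    dInp <- dZ %*% t(p$W)
    dX[rows, ] <- dX[rows, ] + dInp[, seq_len(Din), drop = FALSE]
    dh <- dInp[, Din + seq_len(H), drop = FALSE]
    dc <- dc * st$gf
  }
  list(grads = list(W = dW, b = db), dX = dX)
}

# ---- dense ---------------------------------------------------------------

dense_init <- function(nin, nout) {
  list(W = .glorot(nin, nout), b = numeric(nout))
}

dense_forward <- function(p, X, relu = FALSE) {
  Z <- X %*% p$W + rep(p$b, each = nrow(X))
  A <- if (relu) Z * (Z > 0) else Z
  list(out = A, cache = list(X = X, mask = if (relu) Z > 0 else NULL))
}

dense_backward <- function(p, cache, dA) {
  dZ <- if (is.null(cache$mask)) dA else dA * cache$mask
  list(grads = list(W = crossprod(cache$X, dZ), b = colSums(dZ)),
       dX = dZ %*% t(p$W))
}

# ---- dropout (inverted) --------------------------------------------------

dropout_forward <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(out = X, cache = NULL))
  keep <- 1 - rate
  mask <- (matrix(runif(length(X)), nrow(X), ncol(X)) < keep) / keep
  list(out = X * mask, cache = mask)
}

dropout_backward <- function(cache, dOut) {
  if (is.null(cache)) dOut else dOut * cache
}

# ---- softmax + cross-entropy ---------------------------------------------

softmax_rows <- function(Z) {
  E <- exp(Z - apply(Z, 1, max))
  E / rowSums(E)
}

# labels: integer vector in {0,1}; returns loss and dlogits.
softmax_ce <- function(logits, labels) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  Y <- matrix(0, n, ncol(P))
  Y[idx] <- 1
  list(loss = loss, prob = P, dlogits = (P - Y) / n)
}

# ---- Adam over nested parameter lists ------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like)
    else if (is.null(x)) NULL
    else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        if (is.null(g[[nm]]) || !is.numeric(p[[nm]])) next
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  # top level: params is a list of modules, each a list of arrays
  for (nm in names(params)) {
    if (is.null(grads[[nm]])) next
    r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    params[[nm]] <- r$p; state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
  }
  list(params = params, state = state)
}
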