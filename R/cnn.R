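# Internal 1D-CNN engine: forward/backward passes and the Adam optimizer.
#
# Architecture (fixed, matching build_classifier()):
#   input (width W, 1 channel)
#   -> conv1d(F filters, kernel K, valid) -> ReLU -> batchnorm -> dropout p
#   -> conv1d(F filters, kernel K, valid) -> ReLU -> batchnorm -> dropout p
#   -> maxpool(pool) -> dense(n_classes) -> softmax
#
# Activations are stored as (n, L, C) arrays flattened to n x (L*C)
# matrices (sample index fastest). Convolutions are im2col gathers (Rcpp)
# followed by one BLAS matmul with a (K*C_in) x F weight matrix whose rows
# are ordered kernel-position fastest, then input channel.

cnn_dims <- function(input_width, kernel = 25L, n_filters = 10L, pool = 10L,
                     n_classes) {
  L1 <- input_width - kernel + 1L
  L2 <- L1 - kernel + 1L
  if (L2 < pool)
    stop("input width too small for two width-", kernel,
         " convolutions plus pooling", call. = FALSE)
  P <- L2 %/% pool
  list(W = as.integer(input_width), K = as.integer(kernel),
       F = as.integer(n_filters), pool = as.integer(pool),
       L1 = L1, L2 = L2, P = P, n_flat = P * n_filters,
       n_classes = as.integer(n_classes))
}

glorot <- function(fan_in, fan_out, nr, nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

cnn_init_params <- function(d) {
  list(
    W1 = glorot(d$K, d$K * d$F, d$K, d$F),          b1 = numeric(d$F),
    g1 = rep(1, d$F), be1 = numeric(d$F),
    W2 = glorot(d$K * d$F, d$K * d$F, d$K * d$F, d$F), b2 = numeric(d$F),
    g2 = rep(1, d$F), be2 = numeric(d$F),
    Wd = glorot(d$n_flat, d$n_classes, d$n_flat, d$n_classes),
    bd = numeric(d$n_classes)
  )
}

cnn_init_state <- function(d) {
  # batchnorm running moments (inference statistics)
  list(rm1 = numeric(d$F), rv1 = rep(1, d$F),
       rm2 = numeric(d$F), rv2 = rep(1, d$F))
}

# column offsets into the flattened (n, L, C) array for each of the K*C
# patch columns (kernel position fastest, then channel)
conv_offsets <- function(n, L, K, C) {
  as.integer(as.vector(outer((0:(K - 1)) * n, (0:(C - 1)) * n * L, "+")))
}

conv_fwd <- function(X, W, b, n, L, C, K) {
  Lo <- L - K + 1L
  Xc <- im2col_cpp(X, n * Lo, conv_offsets(n, L, K, C))
  out <- Xc %*% W
  for (f in seq_along(b)) out[, f] <- out[, f] + b[f]
  list(out = out, Xc = Xc, Lo = Lo)
}

conv_bwd <- function(dOut, cache, W, n, L, C, K, need_dx = TRUE) {
  dW <- crossprod(cache$Xc, dOut)
  db <- colSums(dOut)
  dX <- NULL
  if (need_dx) {
    dXc <- dOut %*% t(W)
    dX <- col2im_cpp(dXc, n * L * C, conv_offsets(n, L, K, C))
    dim(dX) <- c(n * L, C)
  }
  list(dW = dW, db = db, dX = dX)
}

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99

# A: (rows x F) activations, one column per channel/filter
bn_fwd_train <- function(A, g, be) {
  m <- nrow(A)
  mu <- colMeans(A)
  v <- numeric(length(mu))
  Ah <- A
  for (f in seq_along(mu)) Ah[, f] <- A[, f] - mu[f]
  for (f in seq_along(mu)) v[f] <- sum(Ah[, f]^2) / m
  inv <- 1 / sqrt(v + BN_EPS)
  Y <- Ah
  for (f in seq_along(mu)) {
    Ah[, f] <- Ah[, f] * inv[f]
    Y[, f] <- Ah[, f] * g[f] + be[f]
  }
  list(Y = Y, Ah = Ah, inv = inv, mu = mu, v = v, m = m)
}

bn_fwd_eval <- function(A, g, be, rm, rv) {
  inv <- 1 / sqrt(rv + BN_EPS)
  for (f in seq_along(rm)) A[, f] <- (A[, f] - rm[f]) * inv[f] * g[f] + be[f]
  A
}

bn_bwd <- function(dY, cache, g) {
  m <- cache$m
  F_ <- length(g)
  dg <- numeric(F_); dbe <- numeric(F_)
  dA <- dY
  for (f in seq_len(F_)) {
    Ahf <- cache$Ah[, f]; dYf <- dY[, f]
    dg[f] <- sum(dYf * Ahf)
    dbe[f] <- sum(dYf)
    dAhf <- dYf * g[f]
    # standard batchnorm gradient
    dA[, f] <- (dAhf - mean(dAhf) - Ahf * mean(dAhf * Ahf)) * cache$inv[f]
  }
  list(dA = dA, dg = dg, dbe = dbe)
}

# maxpool over the spatial axis of an (n, L, F) activation stored as an
# (n*L) x F matrix; windows of length `pool`, remainder dropped
pool_fwd <- function(A, n, L, F_, pool) {
  P <- L %/% pool
  base <- as.vector(outer(seq_len(n), (pool * (0:(P - 1))) * n, "+"))
  M <- A[base, , drop = FALSE]
  amax <- matrix(1L, n * P, F_)
  for (k in 2:pool) {
    Bk <- A[base + (k - 1L) * n, , drop = FALSE]
    upd <- Bk > M
    M[upd] <- Bk[upd]
    amax[upd] <- k
  }
  list(M = M, amax = amax, base = base, P = P)
}

pool_bwd <- function(dM, cache, n, L, F_) {
  dA <- matrix(0, n * L, F_)
  rows <- cache$base + (cache$amax - 1L) * n          # (n*P) x F of row indices
  lin <- rows + matrix((0:(F_ - 1L)) * n * L, nrow(rows), F_, byrow = TRUE)
  dA[as.vector(lin)] <- as.vector(dM)
  dA
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# full forward pass; y_onehot = NULL for inference
cnn_forward <- function(params, state, X, d, training = FALSE,
                        dropout = 0.2) {
  n <- nrow(X)
  c1 <- conv_fwd(X, params$W1, params$b1, n, d$W, 1L, d$K)
  A1 <- pmax(c1$out, 0)
  if (training) {
    bn1 <- bn_fwd_train(A1, params$g1, params$be1)
    Y1 <- bn1$Y
    m1 <- matrix(runif(length(Y1)) >= dropout, nrow(Y1), ncol(Y1)) /
      (1 - dropout)
    Y1 <- Y1 * m1
  } else {
    Y1 <- bn_fwd_eval(A1, params$g1, params$be1, state$rm1, state$rv1)
    bn1 <- m1 <- NULL
  }
  c2 <- conv_fwd(Y1, params$W2, params$b2, n, d$L1, d$F, d$K)
  A2 <- pmax(c2$out, 0)
  if (training) {
    bn2 <- bn_fwd_train(A2, params$g2, params$be2)
    Y2 <- bn2$Y
    m2 <- matrix(runif(length(Y2)) >= dropout, nrow(Y2), ncol(Y2)) /
      (1 - dropout)
    Y2 <- Y2 * m2
  } else {
    Y2 <- bn_fwd_eval(A2, params$g2, params$be2, state$rm2, state$rv2)
    bn2 <- m2 <- NULL
  }
  pl <- pool_fwd(Y2, n, d$L2, d$F, d$pool)
  Mflat <- pl$M
  dim(Mflat) <- c(n, d$n_flat)
  Z <- Mflat %*% params$Wd
  for (f in seq_along(params$bd)) Z[, f] <- Z[, f] + params$bd[f]
  probs <- softmax_rows(Z)
  list(probs = probs, n = n,
       cache = if (training) list(c1 = c1, A1 = A1, bn1 = bn1, m1 = m1,
                                  c2 = c2, A2 = A2, bn2 = bn2, m2 = m2,
                                  pl = pl, Mflat = Mflat, X = X))
}

cnn_backward <- function(params, fwd, y_onehot, d, dropout = 0.2) {
  n <- fwd$n
  cc <- fwd$cache
  dZ <- (fwd$probs - y_onehot) / n
  dWd <- crossprod(cc$Mflat, dZ)
  dbd <- colSums(dZ)
  dMflat <- dZ %*% t(params$Wd)
  dM <- dMflat
  dim(dM) <- c(n * d$P, d$F)
  dY2 <- pool_bwd(dM, cc$pl, n, d$L2, d$F)
  dY2 <- dY2 * cc$m2
  bb2 <- bn_bwd(dY2, cc$bn2, params$g2)
  dA2 <- bb2$dA * (cc$A2 > 0)
  cb2 <- conv_bwd(dA2, cc$c2, params$W2, n, d$L1, d$F, d$K, need_dx = TRUE)
  dY1 <- cb2$dX * cc$m1
  bb1 <- bn_bwd(dY1, cc$bn1, params$g1)
  dA1 <- bb1$dA * (cc$A1 > 0)
  cb1 <- conv_bwd(dA1, cc$c1, params$W1, n, d$W, 1L, d$K, need_dx = FALSE)
  list(W1 = cb1$dW, b1 = cb1$db, g1 = bb1$dg, be1 = bb1$dbe,
       W2 = cb2$dW, b2 = cb2$db, g2 = bb2$dg, be2 = bb2$dbe,
       Wd = dWd, bd = dbd)
}

update_running <- function(state, fwd) {
  b1 <- fwd$cache$bn1; b2 <- fwd$cache$bn2
  mom <- BN_MOMENTUM
  state$rm1 <- mom * state$rm1 + (1 - mom) * b1$mu
  state$rv1 <- mom * state$rv1 + (1 - mom) * b1$v * b1$m / max(b1$m - 1, 1)
  state$rm2 <- mom * state$rm2 + (1 - mom) * b2$mu
  state$rv2 <- mom * state$rv2 + (1 - mom) * b2$v * b2$m / max(b2$m - 1, 1)
  state
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# predict class probabilities in evaluation mode, chunked to bound memory
cnn_probs <- function(params, state, X, d, chunk = 512L) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, d$n_classes)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e, ] <- cnn_forward(params, state, X[s:e, , drop = FALSE], d,
                              training = FALSE)$probs
  }
  out
}
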