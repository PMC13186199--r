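# The trainable head, written directly in base R matrix algebra.
#
#   G = W2 hswish(W1 Gpri + b1) + b2          (global branch, d -> 128)
#   R = W2 hswish(W1 Res  + b1) + b2          (local branch, 25 -> 128)
#   f = G o g_weight + R o r_weight           (linear-combination fusion)
#   E1 = ReLU(BN(Conv1d(f)))                  (1 -> C1 channels, k = 3, pad 1)
#   E2 = ReLU(BN(Conv1d(E1)))                 (C1 -> C2 channels)
#   yhat = Linear(BN(Linear(flatten(E2))))    (C2*W -> fc -> 1)
#
# Samples sit in rows. Convolution inputs are stored as (n*W) x C matrices
# with row index s + (p-1)*n (position-major blocks of n samples), which
# turns Conv1d into one im2col matrix product.

ENC_DIM <- 128L

#' H-swish activation
#'
#' `x * min(max(x + 3, 0), 6) / 6`: continuous, monotone non-decreasing on
#' `[-3, Inf)`, identical to the identity for `x >= 3`.
#'
#' @param x Numeric vector/matrix.
#' @return Same shape as `x`.
#' @export
hswish <- function(x) {
  x * pmin(pmax(x + 3, 0), 6) / 6
}

hswish_grad <- function(x) {
  ifelse(x <= -3, 0, ifelse(x >= 3, 1, (2 * x + 3) / 6))
}

relu6 <- function(x) pmin(pmax(x, 0), 6)

fused_width <- function(mode) {
  switch(mode,
    linear_combination = ENC_DIM,
    concatenation = 2L * ENC_DIM,
    outer_product = ENC_DIM * ENC_DIM,
    stopf("unknown fusion mode '%s'", mode)
  )
}

xavier <- function(nin, nout, dims = c(nin, nout)) {
  lim <- sqrt(6 / (nin + nout))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# Initialize all trainable tensors. Fusion weights start at all ones
# (neutral), linear/conv layers Xavier-uniform, BN affine at identity.
nn_init <- function(d, control) {
  hg <- control$hidden_global
  hl <- control$hidden_local
  C1 <- control$conv_channels[1]
  C2 <- control$conv_channels[2]
  W <- fused_width(control$fusion)
  fc <- control$fc_hidden
  par <- list(
    eg_W1 = xavier(d, hg), eg_b1 = numeric(hg),
    eg_W2 = xavier(hg, ENC_DIM), eg_b2 = numeric(ENC_DIM),
    el_W1 = xavier(LOCAL_DIM, hl), el_b1 = numeric(hl),
    el_W2 = xavier(hl, ENC_DIM), el_b2 = numeric(ENC_DIM),
    c1_K = xavier(3 * 1, C1), c1_b = numeric(C1),
    bn1_g = rep(1, C1), bn1_b = numeric(C1),
    c2_K = xavier(3 * C1, C2), c2_b = numeric(C2),
    bn2_g = rep(1, C2), bn2_b = numeric(C2),
    f1_W = xavier(C2 * W, fc), f1_b = numeric(fc),
    bn3_g = rep(1, fc), bn3_b = numeric(fc),
    f2_W = xavier(fc, 1L), f2_b = numeric(1L)
  )
  if (control$fusion == "linear_combination") {
    par$fu_g <- rep(1, ENC_DIM)
    par$fu_r <- rep(1, ENC_DIM)
  }
  bn <- list(
    bn1_rm = numeric(C1), bn1_rv = rep(1, C1),
    bn2_rm = numeric(C2), bn2_rv = rep(1, C2),
    bn3_rm = numeric(fc), bn3_rv = rep(1, fc),
    nbatches = 0L
  )
  list(par = par, bn = bn, d = d, control = control)
}

# ---- building blocks --------------------------------------------------------

enc_forward <- function(X, W1, b1, W2, b2) {
  H <- sweep(X %*% W1, 2, b1, "+")
  A <- hswish(H)
  Z <- sweep(A %*% W2, 2, b2, "+")
  list(H = H, A = A, Z = Z)
}

enc_backward <- function(dZ, X, H, A, W1, W2) {
  dW2 <- crossprod(A, dZ)
  db2 <- colSums(dZ)
  dA <- tcrossprod(dZ, W2)
  dH <- dA * hswish_grad(H)
  dW1 <- crossprod(X, dH)
  db1 <- colSums(dH)
  dX <- tcrossprod(dH, W1)
  list(dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2, dX = dX)
}

# im2col for kernel 3, padding 1 over (n*W) x Cin position-major input
conv_cols <- function(A, n, W) {
  Cin <- ncol(A)
  z <- matrix(0, n, Cin)
  Apad <- rbind(z, A, z)
  nW <- n * W
  cbind(Apad[seq_len(nW), , drop = FALSE],
        Apad[n + seq_len(nW), , drop = FALSE],
        Apad[2L * n + seq_len(nW), , drop = FALSE])
}

conv_cols_backward <- function(dXcol, n, W, Cin) {
  nW <- n * W
  dApad <- matrix(0, n * (W + 2L), Cin)
  for (j in 1:3) {
    rows <- (j - 1L) * n + seq_len(nW)
    cols <- (j - 1L) * Cin + seq_len(Cin)
    dApad[rows, ] <- dApad[rows, ] + dXcol[, cols, drop = FALSE]
  }
  dApad[n + seq_len(nW), , drop = FALSE]
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_forward <- function(X, gamma, beta, rm, rv, train) {
  if (train) {
    mu <- colMeans(X)
    v <- pmax(colMeans(X^2) - mu^2, 0)
    rm_new <- (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * mu
    rv_new <- (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * v
  } else {
    mu <- rm; v <- rv
    rm_new <- rm; rv_new <- rv
  }
  inv_std <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(X, 2, mu, "-"), 2, inv_std, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = y, xhat = xhat, inv_std = inv_std, rm = rm_new, rv = rv_new)
}

bn_backward <- function(dy, xhat, inv_std, gamma) {
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(sweep(sweep(dxhat, 2, m1, "-") - sweep(xhat, 2, m2, "*"),
                    2, inv_std, "*"), 2, 0, "+")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# fusion: returns F (n x W) plus what backward needs
fuse_forward <- function(Zg, Zl, par, control) {
  ag <- if (control$ablation == "wo_global") 0 else 1
  al <- if (control$ablation == "wo_local") 0 else 1
  mode <- control$fusion
  if (mode == "linear_combination") {
    Fm <- ag * sweep(Zg, 2, par$fu_g, "*") + al * sweep(Zl, 2, par$fu_r, "*")
  } else if (mode == "concatenation") {
    Fm <- cbind(ag * Zg, al * Zl)
  } else {
    ia <- rep(seq_len(ENC_DIM), each = ENC_DIM)
    ib <- rep(seq_len(ENC_DIM), times = ENC_DIM)
    Fm <- (ag * Zg)[, ia, drop = FALSE] * (al * Zl)[, ib, drop = FALSE]
  }
  list(Fm = Fm, ag = ag, al = al)
}

fuse_backward <- function(dF, Zg, Zl, par, control, ag, al) {
  mode <- control$fusion
  if (mode == "linear_combination") {
    dZg <- ag * sweep(dF, 2, par$fu_g, "*")
    dZl <- al * sweep(dF, 2, par$fu_r, "*")
    dfu_g <- ag * colSums(dF * Zg)
    dfu_r <- al * colSums(dF * Zl)
    list(dZg = dZg, dZl = dZl, dfu_g = dfu_g, dfu_r = dfu_r)
  } else if (mode == "concatenation") {
    list(dZg = ag * dF[, seq_len(ENC_DIM), drop = FALSE],
         dZl = al * dF[, ENC_DIM + seq_len(ENC_DIM), drop = FALSE])
  } else {
    n <- nrow(dF)
    dZg <- matrix(0, n, ENC_DIM)
    dZl <- matrix(0, n, ENC_DIM)
    for (a in seq_len(ENC_DIM)) {
      block <- dF[, (a - 1L) * ENC_DIM + seq_len(ENC_DIM), drop = FALSE]
      dZg[, a] <- rowSums(block * (al * Zl))
      dZl <- dZl + (ag * Zg[, a]) * block
    }
    list(dZg = ag * dZg, dZl = al * dZl)
  }
}

# ---- full forward / backward ------------------------------------------------

nn_forward <- function(net, Xg, Xl, train = FALSE) {
  par <- net$par
  ctl <- net$control
  n <- nrow(Xg)
  W <- fused_width(ctl$fusion)
  if (!train && net$bn$nbatches == 0L) {
    stopf("model has no BatchNorm statistics yet: train before evaluating")
  }
  eg <- enc_forward(Xg, par$eg_W1, par$eg_b1, par$eg_W2, par$eg_b2)
  el <- enc_forward(Xl, par$el_W1, par$el_b1, par$el_W2, par$el_b2)
  fu <- fuse_forward(eg$Z, el$Z, par, ctl)

  Fv <- matrix(as.vector(fu$Fm), n * W, 1L)  # (n*W) x 1, position-major
  Xc1 <- conv_cols(Fv, n, W)
  C1p <- sweep(Xc1 %*% par$c1_K, 2, par$c1_b, "+")
  b1 <- bn_forward(C1p, par$bn1_g, par$bn1_b, net$bn$bn1_rm, net$bn$bn1_rv,
                   train)
  A1 <- pmax(b1$y, 0)
  Xc2 <- conv_cols(A1, n, W)
  C2p <- sweep(Xc2 %*% par$c2_K, 2, par$c2_b, "+")
  b2 <- bn_forward(C2p, par$bn2_g, par$bn2_b, net$bn$bn2_rm, net$bn$bn2_rv,
                   train)
  A2 <- pmax(b2$y, 0)
  C2 <- ncol(A2)
  Flat <- matrix(A2, n, W * C2)  # column (p, ch) -> p + (ch-1)*W
  H3 <- sweep(Flat %*% par$f1_W, 2, par$f1_b, "+")
  b3 <- bn_forward(H3, par$bn3_g, par$bn3_b, net$bn$bn3_rm, net$bn$bn3_rv,
                   train)
  yhat <- as.numeric(b3$y %*% par$f2_W + par$f2_b)

  if (train) {
    net$bn$bn1_rm <- b1$rm; net$bn$bn1_rv <- b1$rv
    net$bn$bn2_rm <- b2$rm; net$bn$bn2_rv <- b2$rv
    net$bn$bn3_rm <- b3$rm; net$bn$bn3_rv <- b3$rv
    net$bn$nbatches <- net$bn$nbatches + 1L
  }
  cache <- list(Xg = Xg, Xl = Xl, eg = eg, el = el, fu = fu, n = n, W = W,
                Xc1 = Xc1, b1 = b1, A1 = A1, Xc2 = Xc2, b2 = b2, A2 = A2,
                Flat = Flat, b3 = b3)
  list(yhat = yhat, cache = cache, net = net)
}

nn_backward <- function(net, cache, dy) {
  par <- net$par
  ctl <- net$control
  n <- cache$n; W <- cache$W
  g <- list()
  dyM <- matrix(dy, n, 1L)

  g$f2_W <- crossprod(cache$b3$y, dyM)
  g$f2_b <- sum(dy)
  dB3 <- tcrossprod(dyM, par$f2_W)
  bb3 <- bn_backward(dB3, cache$b3$xhat, cache$b3$inv_std, par$bn3_g)
  g$bn3_g <- bb3$dgamma; g$bn3_b <- bb3$dbeta
  dH3 <- bb3$dx
  g$f1_W <- crossprod(cache$Flat, dH3)
  g$f1_b <- colSums(dH3)
  dFlat <- tcrossprod(dH3, par$f1_W)

  C2 <- ncol(cache$A2)
  dA2 <- matrix(dFlat, n * W, C2)
  dA2 <- dA2 * (cache$A2 > 0)
  bb2 <- bn_backward(dA2, cache$b2$xhat, cache$b2$inv_std, par$bn2_g)
  g$bn2_g <- bb2$dgamma; g$bn2_b <- bb2$dbeta
  dC2p <- bb2$dx
  g$c2_K <- crossprod(cache$Xc2, dC2p)
  g$c2_b <- colSums(dC2p)
  dXc2 <- tcrossprod(dC2p, par$c2_K)
  dA1 <- conv_cols_backward(dXc2, n, W, ncol(cache$A1))
  dA1 <- dA1 * (cache$A1 > 0)
  bb1 <- bn_backward(dA1, cache$b1$xhat, cache$b1$inv_std, par$bn1_g)
  g$bn1_g <- bb1$dgamma; g$bn1_b <- bb1$dbeta
  dC1p <- bb1$dx
  g$c1_K <- crossprod(cache$Xc1, dC1p)
  g$c1_b <- colSums(dC1p)
  dXc1 <- tcrossprod(dC1p, par$c1_K)
  dFv <- conv_cols_backward(dXc1, n, W, 1L)
  dF <- matrix(dFv, n, W)

  fb <- fuse_backward(dF, cache$eg$Z, cache$el$Z, par, ctl,
                      cache$fu$ag, cache$fu$al)
  if (ctl$fusion == "linear_combination") {
    g$fu_g <- fb$dfu_g; g$fu_r <- fb$dfu_r
  }
  ebg <- enc_backward(fb$dZg, cache$Xg, cache$eg$H, cache$eg$A,
                      par$eg_W1, par$eg_W2)
  g$eg_W1 <- ebg$dW1; g$eg_b1 <- ebg$db1
  g$eg_W2 <- ebg$dW2; g$eg_b2 <- ebg$db2
  ebl <- enc_backward(fb$dZl, cache$Xl, cache$el$H, cache$el$A,
                      par$el_W1, par$el_W2)
  g$el_W1 <- ebl$dW1; g$el_b1 <- ebl$db1
  g$el_W2 <- ebl$dW2; g$el_b2 <- ebl$db2
  g
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}
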