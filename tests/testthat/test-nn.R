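ns <- asNamespace("ddgfuse")

tiny_control <- function(...) {
  ddg_control(hidden_global = 6L, hidden_local = 5L,
              conv_channels = c(2L, 3L), fc_hidden = 4L, ...)
}

test_that("H-swish matches its closed form and is monotone past -3", {
  expect_equal(hswish(-3), 0)
  expect_equal(hswish(0), 0)
  expect_equal(hswish(1), 2 / 3)
  expect_equal(hswish(3), 3)
  expect_equal(hswish(10), 10)
  # continuous everywhere; minimum -0.375 at x = -1.5, monotone beyond it
  grid <- seq(-1.5, 8, by = 0.01)
  expect_true(all(diff(hswish(grid)) >= 0))
  expect_equal(hswish(-1.5), -0.375)
  expect_true(all(hswish(seq(-10, 10, by = 0.01)) >= -0.375))
  # continuity across the saturation knees
  expect_equal(hswish(-3 + 1e-9), hswish(-3), tolerance = 1e-8)
  expect_equal(hswish(3 + 1e-9), hswish(3), tolerance = 1e-8)
})

test_that("an encoder branch is the documented two-layer map", {
  # degenerate parameters: all-zero weights, output bias c
  X <- matrix(stats::rnorm(12), 3, 4)
  out <- ns$enc_forward(X, matrix(0, 4, 6), rep(0, 6), matrix(0, 6, 128),
                        rep(2.5, 128))
  expect_equal(dim(out$Z), c(3L, 128L))
  expect_true(all(out$Z == 2.5))
  # linear regime: all pre-activations >= 3, so hswish is the identity
  W1 <- diag(1, 2, 3)
  b1 <- rep(10, 3)
  W2 <- matrix(1, 3, 128)
  X2 <- matrix(abs(stats::rnorm(10)), 5, 2)
  out2 <- ns$enc_forward(X2, W1, b1, W2, rep(0, 128))
  expected <- (X2 %*% W1 + 10) %*% W2  # affine, computable by hand
  expect_equal(out2$Z, expected, tolerance = 1e-12)
})

test_that("fusion modes mask, add and produce the documented widths", {
  n <- 3L
  Zg <- matrix(stats::rnorm(n * 128), n)
  Zl <- matrix(stats::rnorm(n * 128), n)
  ctl <- tiny_control()
  par <- list(fu_g = rep(1, 128), fu_r = rep(0, 128))
  expect_equal(ns$fuse_forward(Zg, Zl, par, ctl)$Fm, Zg)
  par2 <- list(fu_g = rep(1, 128), fu_r = rep(1, 128))
  expect_equal(ns$fuse_forward(Zg, Zl, par2, ctl)$Fm, Zg + Zl)
  ctl_cat <- tiny_control(fusion = "concatenation")
  expect_equal(ncol(ns$fuse_forward(Zg, Zl, list(), ctl_cat)$Fm), 256L)
  ctl_out <- tiny_control(fusion = "outer_product")
  Fo <- ns$fuse_forward(Zg, Zl, list(), ctl_out)$Fm
  expect_equal(ncol(Fo), 16384L)
  expect_equal(Fo[1, ], as.numeric(outer(Zl[1, ], Zg[1, ])),
               tolerance = 1e-12)
})

test_that("a zeroed decoder head outputs its final bias, deterministically", {
  ctl <- tiny_control()
  net <- ddgfuse:::with_seed(5, ns$nn_init(4L, ctl))
  Xg <- matrix(stats::rnorm(8), 2, 4)
  Xl <- matrix(stats::rnorm(50), 2, 25)
  # evaluation before any training has no BatchNorm statistics
  expect_error(ns$nn_forward(net, Xg, Xl, train = FALSE), "BatchNorm")
  net <- ns$nn_forward(net, Xg, Xl, train = TRUE)$net  # populate BN stats
  net$par$f2_W[] <- 0
  net$par$f2_b <- 4.25
  y1 <- ns$nn_forward(net, Xg, Xl, train = FALSE)$yhat
  expect_equal(y1, c(4.25, 4.25))
  # eval-mode output is a pure function of (parameters, input)
  y2 <- ns$nn_forward(net, Xg, Xl, train = FALSE)$yhat
  expect_identical(y1, y2)
})

test_that("eval-mode prediction is batch-decomposition invariant", {
  ctl <- tiny_control()
  sim <- tiny_sim()
  ds <- sim$data
  net <- ddgfuse:::with_seed(5, ns$nn_init(ds$d, ctl))
  Xg <- ds$G[1:8, ]; Xl <- ds$R[1:8, ]
  net <- ns$nn_forward(net, Xg, Xl, train = TRUE)$net
  batch <- ns$nn_forward(net, Xg, Xl, train = FALSE)$yhat
  single <- vapply(1:8, function(i) {
    ns$nn_forward(net, Xg[i, , drop = FALSE], Xl[i, , drop = FALSE],
                  train = FALSE)$yhat
  }, 0)
  expect_equal(batch, single, tolerance = 1e-10)
})

test_that("analytic gradients agree with central differences", {
  set.seed(42)
  ctl <- tiny_control()
  net <- ns$nn_init(5L, ctl)
  n <- 4L
  Xg <- matrix(stats::rnorm(n * 5), n)
  Xl <- matrix(stats::rnorm(n * 25), n)
  y <- stats::rnorm(n)
  loss_fn <- function(net) {
    fw <- ns$nn_forward(net, Xg, Xl, train = TRUE)
    mean((fw$yhat - y)^2)
  }
  fw <- ns$nn_forward(net, Xg, Xl, train = TRUE)
  g <- ns$nn_backward(net, fw$cache, 2 * (fw$yhat - y) / n)
  eps <- 1e-6
  for (nm in names(g)) {
    p <- net$par[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      n2 <- net
      n2$par[[nm]][i] <- p[i] + eps
      lp <- loss_fn(n2)
      n2$par[[nm]][i] <- p[i] - eps
      lm <- loss_fn(n2)
      expect_equal(g[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-5,
                   label = sprintf("grad of %s[%d]", nm, i))
    }
  }
})

test_that("zeroing the local fusion weight reproduces the local ablation", {
  ctl_full <- tiny_control(seed = 3L)
  ctl_wo <- tiny_control(seed = 3L, ablation = "wo_local")
  net <- ddgfuse:::with_seed(3, ns$nn_init(6L, ctl_full))
  Xg <- matrix(stats::rnorm(30), 5, 6)
  Xl <- matrix(stats::rnorm(125), 5, 25)
  net <- ns$nn_forward(net, Xg, Xl, train = TRUE)$net

  surg <- net
  surg$par$fu_r[] <- 0
  ablated <- net
  ablated$control <- ctl_wo
  expect_equal(ns$nn_forward(surg, Xg, Xl, train = FALSE)$yhat,
               ns$nn_forward(ablated, Xg, Xl, train = FALSE)$yhat,
               tolerance = 1e-12)
  # the two single-branch ablations disagree on generic inputs
  ab_g <- net; ab_g$control <- tiny_control(seed = 3L, ablation = "wo_global")
  expect_false(isTRUE(all.equal(
    ns$nn_forward(ablated, Xg, Xl, train = FALSE)$yhat,
    ns$nn_forward(ab_g, Xg, Xl, train = FALSE)$yhat)))
})
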