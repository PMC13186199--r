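test_that("metrics hit their closed-form values", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  x <- stats::rnorm(20); y <- stats::rnorm(20)
  expect_equal(rmse(3 * x, 3 * y), 3 * rmse(x, y), tolerance = 1e-12)

  expect_equal(pcc(1:3, c(2, 4, 6)), 1)
  expect_equal(pcc(1:3, c(3, 2, 1)), -1)
  expect_equal(pcc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(p <- pcc(c(1, 1, 1), 1:3), "constant")
  expect_true(is.na(p))

  expect_equal(acc(c(1, -2), c(1, -2)), 1)
  expect_equal(acc(c(1, -1, 2), c(-1, 1, 3)), 1 / 3)
  expect_equal(acc(0, 0), 1)  # exact zero is stabilizing on both sides
  expect_equal(acc(c(0, -1e-12), c(1, 1)), 0.5)
  expect_error(rmse(1:2, 1:3), "mismatch")
})

test_that("metrics agree with literal-formula loop implementations", {
  brute_rmse <- function(p, t) {
    s <- 0
    for (i in seq_along(p)) s <- s + (p[i] - t[i])^2
    sqrt(s / length(p))
  }
  brute_pcc <- function(p, t) {
    mp <- sum(p) / length(p); mt <- sum(t) / length(t)
    num <- 0; dp <- 0; dt <- 0
    for (i in seq_along(p)) {
      num <- num + (p[i] - mp) * (t[i] - mt)
      dp <- dp + (p[i] - mp)^2
      dt <- dt + (t[i] - mt)^2
    }
    num / sqrt(dp * dt)
  }
  brute_acc <- function(p, t) {
    hit <- 0
    for (i in seq_along(p)) {
      hit <- hit + ((p[i] >= 0) == (t[i] >= 0))
    }
    hit / length(p)
  }
  set.seed(14)
  for (i in 1:25) {
    n <- sample(2:400, 1)
    p <- stats::rnorm(n, sd = sample(1:3, 1))
    t <- stats::rnorm(n)
    expect_equal(rmse(p, t), brute_rmse(p, t), tolerance = 1e-10)
    expect_equal(pcc(p, t), brute_pcc(p, t), tolerance = 1e-10)
    expect_equal(acc(p, t), brute_acc(p, t), tolerance = 1e-12)
  }
})

test_that("antisymmetry report captures the ideal and biased regimes", {
  x <- stats::rnorm(10)
  a <- antisymmetry_metrics(x, -x)
  expect_equal(a$rd_r, -1)
  expect_equal(a$delta_bias, 0)
  expect_equal(a$n_pairs, 10L)

  b <- antisymmetry_metrics(c(1, 2), c(-0.8, -1.8))
  expect_equal(b$delta_bias, 0.1)

  d <- stats::rnorm(8); r <- -d + stats::rnorm(8, sd = 0.1)
  base <- antisymmetry_metrics(d, r)
  shift <- antisymmetry_metrics(d, r + 3)
  expect_equal(shift$rd_r, base$rd_r, tolerance = 1e-12)
  expect_equal(shift$delta_bias, base$delta_bias + 1.5, tolerance = 1e-12)
  expect_error(antisymmetry_metrics(1:3, 1:2), "paired")
})

test_that("direct/reverse records pair by protein and inverted code", {
  v <- variant_table(c("P1", "P1", "P2", "P2", "P3"),
                     c("A2G", "G2A", "L5V", "V5L", "K7E"),
                     direction = c("direct", "reverse", "direct", "reverse",
                                   "direct"))
  pairs <- match_pairs(v, c(1, -0.9, 2, -2.2, 5))
  expect_equal(nrow(pairs), 2L)
  expect_setequal(pairs$pair_id, c("P1:A2G", "P2:L5V"))
  expect_equal(pairs$direct[pairs$pair_id == "P1:A2G"], 1)
  expect_equal(pairs$reverse[pairs$pair_id == "P1:A2G"], -0.9)
})

test_that("stratification schemes partition the records", {
  df <- data.frame(
    pred = c(1, -1, 0.5, 2, -0.3, 0),
    truth = c(0.5, -2, 1, 1.5, -0.1, 0),
    rsa = c(0.05, 0.3, 0.7, 0.5, 0.1, 0.95),
    p_helix = c(0.2, 0.6, 0.1, 0.3, 0.3, 0.2),
    p_sheet = c(0.5, 0.2, 0.2, 0.4, 0.3, 0.2),
    p_coil = c(0.3, 0.2, 0.7, 0.3, 0.4, 0.6),
    direction = rep(c("direct", "reverse"), 3)
  )
  expect_equal(rsa_class(c(0.05, 0.3, 0.7)),
               c("buried", "intermediate", "exposed"))
  expect_equal(ss_class(0.2, 0.5, 0.3), "sheet")
  for (sc in c("rsa_class", "ss_class", "direction", "stabilizing")) {
    rep_ <- stratify_metrics(df, sc)
    expect_equal(sum(rep_$n), nrow(df))  # exhaustive and disjoint
  }
  # boundary: RSA exactly 0.5 and 0.1 are intermediate
  expect_equal(rsa_class(c(0.5, 0.1)), rep("intermediate", 2))
  # empty subsets report n = 0 with NA metrics
  rep2 <- stratify_metrics(df[df$rsa > 0.55, ], "rsa_class")
  expect_equal(rep2$n[rep2$subset == "buried"], 0L)
  expect_true(is.na(rep2$rmse[rep2$subset == "buried"]))
})

test_that("self-evaluation is perfect and reports stack per scheme", {
  v <- variant_table(c("P1", "P1", "P1", "P1", "P2"),
                     c("A2G", "G2A", "L3V", "V3L", "K7E"),
                     ddg = c(1.2, -1.2, -0.4, 0.4, 2.0),
                     direction = c("direct", "reverse", "direct", "reverse",
                                   "direct"))
  ev <- evaluate_predictions(v, v$ddg)
  overall <- ev$reports[ev$reports$scheme == "overall", ]
  expect_equal(overall$rmse, 0)
  expect_equal(overall$acc, 1)
  expect_equal(ev$antisymmetry$rd_r, -1)
  f <- withr::local_tempfile(fileext = ".csv")
  t <- withr::local_tempfile(fileext = ".txt")
  write_evaluation(ev, f, t)
  tab <- utils::read.csv(f)
  expect_true(all(c("scheme", "subset", "n") %in% names(tab)))
  expect_true(any(tab$scheme == "antisymmetry"))
  expect_true(file.exists(t))
})
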