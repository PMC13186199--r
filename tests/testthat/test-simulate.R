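test_that("sequence generation is seeded, bounded and counted", {
  cfg <- sim_config(seed = 3L, n_proteins = 12L, length_range = c(30L, 45L))
  s1 <- sim_sequences(cfg)
  s2 <- sim_sequences(cfg)
  expect_identical(s1, s2)
  expect_length(s1, 12L)
  expect_true(all(nchar(s1) >= 30 & nchar(s1) <= 45))
  for (s in s1) expect_silent(ddgfuse:::check_sequence(s))
  expect_false(identical(s1, sim_sequences(sim_config(seed = 4L,
                                                      n_proteins = 12L))))
})

test_that("synthetic annotations are normalized, bounded and deterministic", {
  prov <- synthetic_annotator(6L)
  seq <- random_sequence(40)
  a1 <- sim_annotations(prov, seq, "X1")
  a2 <- sim_annotations(prov, seq, "X1")
  expect_identical(a1, a2)
  expect_equal(a1$p_helix + a1$p_sheet + a1$p_coil, rep(1, 40),
               tolerance = 1e-9)
  expect_true(all(a1$rsa >= 0 & a1$rsa <= 1))
  expect_true(all(a1$disorder >= 0 & a1$disorder <= 1))
  expect_true(all(a1$phi >= -180 & a1$phi <= 180))
  # residue-letter-dependent means: mutating a position changes its annotation
  pos <- 7L
  wt <- substr(seq, pos, pos)
  mut <- setdiff(ddgfuse:::AA_ALPHABET, wt)[1]
  seq2 <- apply_mutation(seq, paste0(wt, pos, mut))
  aw <- annotate_residue(prov, "X1", seq, pos)
  am <- annotate_residue(prov, "X1", seq2, pos)
  expect_false(isTRUE(all.equal(aw$rsa, am$rsa)))
})

test_that("a noiseless planted dataset is exactly antisymmetric", {
  sim <- sim_dataset(sim_config(seed = 12L, n_proteins = 6L,
                                n_variants = 25L, length_range = c(25L, 40L),
                                d = 6L, noise_sd = 0, k_folds = 2L))
  v <- sim$data$variants
  expect_equal(nrow(v), 50L)  # direct + reverse
  n <- 25L
  expect_identical(v$ddg[n + seq_len(n)], -v$ddg[seq_len(n)])
  # reverse records inherit the fold of their direct counterpart
  expect_identical(v$fold[n + seq_len(n)], v$fold[seq_len(n)])
})

test_that("least squares on the true features recovers the planted weights", {
  sim <- sim_dataset(sim_config(seed = 13L, n_proteins = 10L,
                                n_variants = 150L, length_range = c(30L, 50L),
                                d = 8L, noise_sd = 0.05, k_folds = 2L))
  X <- cbind(sim$data$G, sim$data$R)
  y <- sim$data$variants$ddg
  fit <- stats::lm.fit(X, y)
  w_true <- c(sim$truth$wg, sim$truth$wl)
  # the P(SS) blocks are collinear with the intercept-free design only up
  # to the planted antisymmetric combination; compare predictions instead
  expect_gt(summary(stats::lm(y ~ X - 1))$r.squared, 0.99)
  pred <- as.numeric(X %*% ifelse(is.na(fit$coefficients), 0,
                                  fit$coefficients))
  truth <- as.numeric(X %*% w_true)
  expect_equal(pred, truth, tolerance = 0.05)
})

test_that("empirical noise matches the configured sigma within 10 percent", {
  sim <- sim_dataset(sim_config(seed = 14L, n_proteins = 20L,
                                n_variants = 1000L,
                                length_range = c(40L, 60L), d = 6L,
                                noise_sd = 0.3, k_folds = 2L))
  resid <- sim$data$variants$ddg - sim$truth$signal
  expect_equal(stats::sd(resid), 0.3, tolerance = 0.1)
  # direct and reverse noise draws are independent
  n <- length(resid) / 2
  expect_lt(abs(stats::cor(resid[seq_len(n)], resid[n + seq_len(n)])), 0.15)
})

test_that("generated files feed back through every reader without errors", {
  dir <- withr::local_tempdir()
  sim <- sim_dataset(sim_config(seed = 15L, n_proteins = 5L,
                                n_variants = 20L, length_range = c(25L, 35L),
                                d = 6L, k_folds = 2L),
                     dir = dir)
  seqs <- read_fasta(file.path(dir, "sequences.fasta"))
  expect_identical(seqs, sim$sequences)
  v <- read_variants(file.path(dir, "variants.csv"))
  expect_identical(v$mutation, sim$data$variants$mutation)
  expect_equal(v$ddg, sim$data$variants$ddg, tolerance = 1e-9)
  ann <- netsurfp_annotator(file.path(dir, "annotations.csv"))
  ds <- featurize_variants(v, seqs, sim$embedder, ann)
  expect_equal(nrow(ds$variants), nrow(v))
  # file-backed annotations reproduce the synthetic provider's features
  expect_equal(ds$R, sim$data$R, tolerance = 1e-10)
  expect_equal(ds$G, sim$data$G, tolerance = 1e-12)
})
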