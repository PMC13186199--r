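# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

# A small planted study reused across unit tests.
tiny_sim <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- sim_dataset(sim_config(
      seed = 101L, n_proteins = 8L, n_variants = 40L,
      length_range = c(30L, 50L), d = 8L, noise_sd = 0.2, k_folds = 2L
    ))
  }
  .fixtures$tiny
}

# The full-scale planted recovery run (trained model + paired predictions),
# shared by the parameter-recovery and learned-antisymmetry checks.
recovery_run <- function() {
  if (is.null(.fixtures$recovery)) {
    sim <- sim_dataset(sim_config(
      seed = 2024L, n_proteins = 40L, n_variants = 1000L,
      length_range = c(60L, 120L), d = 32L, noise_sd = 0.3, k_folds = 5L
    ))
    ds <- sim$data
    hold <- which(ds$variants$fold == 5L)
    model <- ddg_fit(ds, ddg_control(seed = 1L), valid = hold)
    held <- subset_dataset(ds, hold)
    pred <- predict(model, held)
    .fixtures$recovery <- list(sim = sim, model = model, hold = hold,
                               held = held, pred = pred,
                               truth = ds$variants$ddg[hold])
  }
  .fixtures$recovery
}

random_annotation <- function() {
  p <- stats::runif(3)
  residue_annotation(
    p_helix = p[1] / sum(p), p_sheet = p[2] / sum(p), p_coil = p[3] / sum(p),
    rsa = stats::runif(1), disorder = stats::runif(1),
    phi = stats::runif(1, -180, 180), psi = stats::runif(1, -180, 180)
  )
}

random_sequence <- function(len) {
  paste(sample(ddgfuse:::AA_ALPHABET, len, replace = TRUE), collapse = "")
}
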