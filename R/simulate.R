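# Synthetic study generator: sequences, structural annotations, embeddings
# and planted-ground-truth ddG datasets with the statistical structure the
# model assumes (antisymmetric ddG that is a linear function of the fused
# features), so every module is testable without downloads. The generator
# emits the same FASTA / variant CSV / NetSurfP-dialect formats the real
# pipeline consumes.

#' Simulation configuration
#'
#' Defaults describe a desk-scale study: 40 proteins of 60-120 residues,
#' 500 mutations augmented with their reverses, embedding width 32,
#' measurement noise 0.3 kcal/mol, and planted signal of standard
#' deviation 1 kcal/mol in each branch (so the true ddG spread is about
#' 1.4 kcal/mol, comparable to curated stability datasets).
#'
#' @param seed Integer master seed; equal configurations give bit-identical
#'   output.
#' @param n_proteins,n_variants Number of proteins and of distinct direct
#'   mutations (each is also emitted as its reverse).
#' @param length_range Sequence length range (min, max).
#' @param d Embedding width of the synthetic provider.
#' @param noise_sd Gaussian measurement noise (kcal/mol), drawn
#'   independently for direct and reverse records so antisymmetry has to be
#'   learned, not copied.
#' @param signal_sd_global,signal_sd_local Standard deviation (kcal/mol) of
#'   the planted contribution of each feature branch.
#' @param context_weight Sequence-context weight of the synthetic embedder.
#' @param k_folds Folds for the round-robin by-protein fold labels.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_proteins = 40L, n_variants = 500L,
                       length_range = c(60L, 120L), d = 32L, noise_sd = 0.3,
                       signal_sd_global = 1.0, signal_sd_local = 1.0,
                       context_weight = 0.1, k_folds = 5L) {
  stopifnot(n_proteins >= 1L, n_variants >= 1L, noise_sd >= 0,
            length_range[1] >= 2L, length_range[2] >= length_range[1],
            d >= 1L, k_folds >= 2L)
  structure(
    list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
         n_variants = as.integer(n_variants),
         length_range = as.integer(length_range), d = as.integer(d),
         noise_sd = noise_sd, signal_sd_global = signal_sd_global,
         signal_sd_local = signal_sd_local,
         context_weight = context_weight, k_folds = as.integer(k_folds)),
    class = "sim_config"
  )
}

#' Generate random protein sequences
#'
#' Uniform over the 20 letters, lengths uniform in `length_range`, seeded.
#'
#' @param cfg A [sim_config()].
#' @return Named character vector (`P001`, `P002`, ...).
#' @export
sim_sequences <- function(cfg) {
  with_seed(hash_ints(c(cfg$seed, 11L)), {
    lens <- sample(seq(cfg$length_range[1], cfg$length_range[2]),
                   cfg$n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    }, "")
    stats::setNames(seqs, sprintf("P%03d", seq_len(cfg$n_proteins)))
  })
}

#' Generate clustered near-duplicate sequences
#'
#' Each cluster is one random base sequence plus copies carrying a few
#' random substitutions, giving planted high-identity groups for testing
#' homology-aware fold assignment.
#'
#' @param n_clusters,copies_per_cluster Cluster layout.
#' @param length Sequence length.
#' @param n_mutations Substitutions per copy.
#' @param seed Integer seed.
#' @return Named character vector with attribute `cluster` (integer labels).
#' @export
sim_sequence_clusters <- function(n_clusters = 10L, copies_per_cluster = 5L,
                                  length = 80L, n_mutations = 3L, seed = 1L) {
  with_seed(hash_ints(c(seed, 12L)), {
    seqs <- character(0)
    cluster <- integer(0)
    for (cl in seq_len(n_clusters)) {
      base <- paste(sample(AA_ALPHABET, length, replace = TRUE),
                    collapse = "")
      members <- base
      for (cp in seq_len(copies_per_cluster - 1L)) {
        s <- base
        pos <- sample.int(length, n_mutations)
        for (p in pos) {
          substr(s, p, p) <- sample(setdiff(AA_ALPHABET,
                                            substr(s, p, p)), 1L)
        }
        members <- c(members, s)
      }
      seqs <- c(seqs, members)
      cluster <- c(cluster, rep(cl, copies_per_cluster))
    }
    names(seqs) <- sprintf("C%02d_%02d", cluster,
                           stats::ave(cluster, cluster, FUN = seq_along))
    attr(seqs, "cluster") <- cluster
    seqs
  })
}

# ---- synthetic structural annotations ---------------------------------------

#' Deterministic synthetic annotation provider
#'
#' Emulates a per-residue structure predictor: each amino-acid letter gets
#' seed-derived baseline secondary-structure logits, RSA, disorder and
#' dihedral means, and each position adds sequence-keyed jitter. P(SS)
#' triples sum to one, RSA and disorder stay in `[0, 1]`, angles in
#' `[-180, 180]`; the letter-dependent means ensure mutations genuinely
#' change the annotations. The full mutant sequence is annotated afresh
#' (not copied from the wild type), mirroring a predictor rerun on the
#' mutant.
#'
#' @param seed Integer seed.
#' @return An annotation provider for [annotate_residue()].
#' @export
synthetic_annotator <- function(seed = 1L) {
  structure(list(seed = as.integer(seed),
                 id = sprintf("synthetic-ann-v1:s%d", seed)),
            class = c("synthetic_annotator", "ddg_annotator"))
}

aa_baseline <- function(seed, letter) {
  with_seed(hash_ints(c(seed, 101L, utf8ToInt(letter))), {
    list(
      logits = stats::rnorm(3, sd = 1.2),
      rsa = stats::runif(1, 0.05, 0.95),
      disorder = stats::runif(1, 0.05, 0.6),
      phi = stats::runif(1, -180, 180),
      psi = stats::runif(1, -180, 180)
    )
  })
}

wrap_angle <- function(a) ((a + 180) %% 360) - 180

#' @export
annotate_residue.synthetic_annotator <- function(provider, seq_id, sequence,
                                                 pos) {
  check_sequence(sequence)
  if (pos < 1L || pos > nchar(sequence)) {
    stopf("position %d out of range", pos)
  }
  letter <- substr(sequence, pos, pos)
  base <- aa_baseline(provider$seed, letter)
  seqh <- hash_string(sequence)
  jit <- with_seed(hash_ints(c(provider$seed, 102L, seqh, pos)),
                   stats::rnorm(7))
  p <- exp(base$logits + 0.5 * jit[1:3])
  p <- p / sum(p)
  residue_annotation(
    p_helix = p[1], p_sheet = p[2], p_coil = p[3],
    rsa = min(max(base$rsa + 0.15 * jit[4], 0), 1),
    disorder = min(max(base$disorder + 0.1 * jit[5], 0), 1),
    phi = wrap_angle(base$phi + 20 * jit[6]),
    psi = wrap_angle(base$psi + 20 * jit[7])
  )
}

#' Annotate a whole sequence with the synthetic provider
#'
#' @param provider A [synthetic_annotator()].
#' @param sequence Protein sequence.
#' @param id Identifier written into the `id` column.
#' @return data.frame in the layout of [read_netsurfp()].
#' @export
sim_annotations <- function(provider, sequence, id) {
  check_sequence(sequence)
  L <- nchar(sequence)
  rows <- lapply(seq_len(L), function(i) {
    a <- annotate_residue(provider, id, sequence, i)
    data.frame(id = id, n = i, aa = substr(sequence, i, i), rsa = a$rsa,
               p_helix = a$p_ss[1], p_sheet = a$p_ss[2], p_coil = a$p_ss[3],
               disorder = a$disorder, phi = a$phi, psi = a$psi,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- planted-model datasets -------------------------------------------------

#' Generate a planted-ground-truth mutation dataset
#'
#' Samples distinct mutations uniformly over proteins, positions and target
#' residues; featurizes direct and reverse records with the synthetic
#' embedding and annotation providers; plants a linear ground truth
#' `ddG = w_G . Gpri + w_R . Res` whose local weights put equal and
#' opposite loadings on the two P(SS) triples, so the noiseless ddG is
#' exactly antisymmetric; and adds independent Gaussian noise to every
#' record. Branch weights are scaled so each branch contributes its
#' configured signal standard deviation over the direct records.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional directory; when given, `sequences.fasta`,
#'   `variants.csv` and `annotations.csv` (wild-type and mutant sequences,
#'   NetSurfP dialect) are written there, so the fixture doubles as an
#'   integration test of all readers.
#' @return A list of class `"ddg_sim"`: `data` (a featurized
#'   `"ddg_dataset"` with `2 * n_variants` records), `sequences`,
#'   `embedder`, `annotator`, `truth` (planted weight vectors, noiseless
#'   signal, noise sd) and `config`.
#' @export
sim_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  seqs <- sim_sequences(cfg)
  embedder <- synthetic_embedder(cfg$seed, cfg$d, cfg$context_weight)
  annotator <- synthetic_annotator(cfg$seed)

  direct <- with_seed(hash_ints(c(cfg$seed, 22L)), {
    seen <- character(0)
    pid <- character(cfg$n_variants)
    code <- character(cfg$n_variants)
    i <- 0L
    tries <- 0L
    while (i < cfg$n_variants) {
      tries <- tries + 1L
      if (tries > 50L * cfg$n_variants) {
        stopf("could not sample %d distinct mutations", cfg$n_variants)
      }
      p <- sample(names(seqs), 1L)
      s <- seqs[[p]]
      pos <- sample.int(nchar(s), 1L)
      wt <- substr(s, pos, pos)
      mut <- sample(setdiff(AA_ALPHABET, wt), 1L)
      cd <- paste0(wt, pos, mut)
      key <- paste(p, cd)
      if (key %in% seen) next
      seen <- c(seen, key)
      i <- i + 1L
      pid[i] <- p
      code[i] <- cd
    }
    fold <- (match(pid, names(seqs)) - 1L) %% cfg$k_folds + 1L
    variant_table(pid, code, ddg = NA_real_, direction = "direct",
                  fold = fold)
  })

  all_variants <- augment_reverse(direct)
  ds <- featurize_variants(all_variants, seqs, embedder, annotator)

  n_dir <- nrow(direct)
  truth <- with_seed(hash_ints(c(cfg$seed, 33L)), {
    wg <- stats::rnorm(cfg$d)
    wl <- stats::rnorm(LOCAL_DIM)
    b <- stats::rnorm(3)
    wl[20:22] <- b
    wl[23:25] <- -b
    list(wg = wg, wl = wl)
  })
  cg <- as.numeric(ds$G[seq_len(n_dir), , drop = FALSE] %*% truth$wg)
  cl <- as.numeric(ds$R[seq_len(n_dir), , drop = FALSE] %*% truth$wl)
  sg <- stats::sd(cg); sl <- stats::sd(cl)
  truth$wg <- truth$wg * (cfg$signal_sd_global / max(sg, 1e-12))
  truth$wl <- truth$wl * (cfg$signal_sd_local / max(sl, 1e-12))
  # The planted model is antisymmetric by construction, so the reverse
  # signal is the exact negation of the direct one; computing it that way
  # (rather than re-summing the permuted feature terms) keeps the
  # noiseless antisymmetry exact in floating point as well.
  sig_direct <- as.numeric(
    ds$G[seq_len(n_dir), , drop = FALSE] %*% truth$wg +
      ds$R[seq_len(n_dir), , drop = FALSE] %*% truth$wl
  )
  signal <- c(sig_direct, -sig_direct)
  noise <- if (cfg$noise_sd > 0) {
    with_seed(hash_ints(c(cfg$seed, 44L)),
              stats::rnorm(length(signal), 0, cfg$noise_sd))
  } else {
    numeric(length(signal))
  }
  ds$variants$ddg <- signal + noise
  truth$signal <- signal
  truth$noise_sd <- cfg$noise_sd

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(seqs, file.path(dir, "sequences.fasta"))
    write_variants(ds$variants, file.path(dir, "variants.csv"))
    ann <- list()
    for (id in names(seqs)) {
      ann[[id]] <- sim_annotations(annotator, seqs[[id]], id)
    }
    for (i in seq_len(n_dir)) {
      pid <- direct$protein_id[i]
      code <- direct$mutation[i]
      mid <- mutant_annotation_id(pid, code)
      ann[[mid]] <- sim_annotations(annotator,
                                    apply_mutation(seqs[[pid]], code), mid)
    }
    write_netsurfp(do.call(rbind, ann), file.path(dir, "annotations.csv"))
  }

  structure(list(data = ds, sequences = seqs, embedder = embedder,
                 annotator = annotator, truth = truth, config = cfg),
            class = "ddg_sim")
}

#' @export
print.ddg_sim <- function(x, ...) {
  cat(sprintf(paste0("<ddg_sim> %d proteins, %d direct + %d reverse",
                     " records, d = %d, noise sd %.2f kcal/mol\n"),
              length(x$sequences),
              sum(x$data$variants$direction == "direct"),
              sum(x$data$variants$direction == "reverse"),
              x$config$d, x$config$noise_sd))
  invisible(x)
}
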