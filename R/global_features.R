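# Global change vector: difference of mean-pooled residue-level embeddings
# of the mutant and wild-type sequences, behind a pluggable provider
# contract. Backends: a deterministic synthetic provider (no downloads, any
# width d), a matrix-backed provider for embeddings precomputed externally
# (e.g. with the ESM-2 esm2_t36_650M_UR50D checkpoint, final representation
# layer, BOS/EOS rows dropped), or any user object implementing
# embed_sequence().

# pooled-embedding memoization, keyed by provider id + sequence hash
.embed_cache <- new.env(parent = emptyenv())

#' Deterministic synthetic embedding provider
#'
#' Produces residue-level pseudo-Gaussian embeddings reproducibly from a
#' seed: the row for position `i` is drawn from an RNG stream keyed by
#' (seed, residue letter, position) plus a smaller sequence-context
#' component keyed by (seed, whole-sequence hash, position), so a
#' single-residue change perturbs every pooled dimension slightly -- the
#' qualitative behaviour of a real protein language model that makes the
#' pooled difference informative.
#'
#' @param seed Integer seed.
#' @param d Embedding width (default 32; real ESM-2 650M uses 1280).
#' @param context_weight Relative weight of the sequence-context component.
#' @return An embedding provider for [embed_sequence()].
#' @export
synthetic_embedder <- function(seed = 1L, d = 32L, context_weight = 0.1) {
  stopifnot(d >= 1L, context_weight >= 0)
  structure(
    list(seed = as.integer(seed), d = as.integer(d),
         context_weight = context_weight,
         id = sprintf("synthetic-v1:s%d:d%d:c%g", seed, d, context_weight)),
    class = c("synthetic_embedder", "ddg_embedder")
  )
}

#' Embedding provider backed by precomputed matrices
#'
#' For use with real protein-language-model embeddings computed outside R:
#' supply one `L x d` matrix per sequence (special-token rows already
#' removed, so row `i` is residue `i`), keyed by the exact sequence string.
#'
#' @param matrices Named list of `L x d` matrices; names are sequence
#'   strings.
#' @param id Provider identifier recorded in caches and checkpoints.
#' @return An embedding provider for [embed_sequence()].
#' @export
matrix_embedder <- function(matrices, id = "precomputed") {
  stopifnot(is.list(matrices), !is.null(names(matrices)))
  d <- unique(vapply(matrices, ncol, 0L))
  if (length(d) != 1L) stopf("all embedding matrices must share one width")
  structure(list(matrices = matrices, d = d, id = id),
            class = c("matrix_embedder", "ddg_embedder"))
}

#' Residue-level embedding of a sequence
#'
#' @param provider An embedding provider.
#' @param sequence Protein sequence (character scalar).
#' @return `L x d` numeric matrix, row `i` corresponding to residue `i`
#'   (special tokens excluded); deterministic for a fixed provider.
#' @export
embed_sequence <- function(provider, sequence) {
  UseMethod("embed_sequence")
}

#' @export
embed_sequence.synthetic_embedder <- function(provider, sequence) {
  check_sequence(sequence)
  letters <- utf8ToInt(sequence)
  L <- length(letters)
  d <- provider$d
  seqh <- hash_string(sequence)
  out <- matrix(0, L, d)
  for (i in seq_len(L)) {
    row <- with_seed(hash_ints(c(provider$seed, 1L, letters[i], i)),
                     stats::rnorm(d))
    if (provider$context_weight > 0) {
      ctx <- with_seed(hash_ints(c(provider$seed, 2L, seqh, i)),
                       stats::rnorm(d))
      row <- row + provider$context_weight * ctx
    }
    out[i, ] <- row
  }
  out
}

#' @export
embed_sequence.matrix_embedder <- function(provider, sequence) {
  m <- provider$matrices[[sequence]]
  if (is.null(m)) {
    stopf("no precomputed embedding for this sequence (provider '%s')",
          provider$id, class = "ddg_missing_input")
  }
  if (nrow(m) != nchar(sequence)) {
    stopf("embedding has %d rows for a sequence of length %d",
          nrow(m), nchar(sequence))
  }
  m
}

#' Mean-pool an embedding matrix over residues
#'
#' @param m `L x d` matrix, `L >= 1`.
#' @return Numeric `d`-vector of column means.
#' @export
mean_pool <- function(m) {
  if (!is.matrix(m) || nrow(m) < 1L) stopf("need a matrix with >= 1 row")
  colMeans(m)
}

# Pooled embedding with in-memory (and optional on-disk) caching. A cache
# hit returns exactly the vector that was computed on the miss, so caching
# never changes downstream numbers; corrupted disk entries are recomputed.
pooled_embedding <- function(provider, sequence, cache_dir = NULL) {
  key <- paste0(provider$id, "#", hash_string(sequence), "#", nchar(sequence))
  hit <- .embed_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (!is.null(cache_dir)) {
    f <- file.path(cache_dir, paste0(gsub("[^A-Za-z0-9]", "_", key), ".rds"))
    if (file.exists(f)) {
      rec <- tryCatch(readRDS(f), error = function(e) NULL)
      if (is.list(rec) && identical(rec$provider_id, provider$id) &&
          identical(rec$d, length(rec$pooled)) && all(is.finite(rec$pooled))) {
        .embed_cache[[key]] <- rec$pooled
        return(rec$pooled)
      }
    }
  }
  v <- mean_pool(embed_sequence(provider, sequence))
  .embed_cache[[key]] <- v
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(list(provider_id = provider$id, d = length(v), pooled = v),
            file.path(cache_dir,
                      paste0(gsub("[^A-Za-z0-9]", "_", key), ".rds")))
  }
  v
}

#' Clear the in-memory pooled-embedding cache
#' @export
clear_embedding_cache <- function() {
  rm(list = ls(.embed_cache), envir = .embed_cache)
  invisible(NULL)
}

#' Global change vector of a mutation
#'
#' `mean_pool(embed(mutant)) - mean_pool(embed(wild type))`: exactly
#' antisymmetric under swapping the two sequences, which is the structural
#' basis of the model's learned antisymmetry.
#'
#' @param provider An embedding provider.
#' @param wt,mut Wild-type and mutant sequences. A warning (not an error)
#'   is raised if they differ at more than one position.
#' @param cache_dir Optional directory for the on-disk pooled-embedding
#'   cache.
#' @return Numeric `d`-vector.
#' @export
global_delta <- function(provider, wt, mut, cache_dir = NULL) {
  check_sequence(wt); check_sequence(mut)
  if (nchar(wt) == nchar(mut)) {
    ndiff <- sum(utf8ToInt(wt) != utf8ToInt(mut))
    if (ndiff > 1L) {
      warnf("sequences differ at %d positions (expected 1)", ndiff)
    }
  } else {
    warnf("sequences differ in length (%d vs %d)", nchar(wt), nchar(mut))
  }
  pooled_embedding(provider, mut, cache_dir) -
    pooled_embedding(provider, wt, cache_dir)
}

# Window long sequences around the mutation site, identically for wild type
# and mutant, so providers with a token limit (real ESM-2: 1022 residues)
# see consistent inputs.
window_pair <- function(wt, mut, pos, max_len = 1000L) {
  L <- nchar(wt)
  if (L <= max_len) return(list(wt = wt, mut = mut, pos = pos))
  half <- max_len %/% 2L
  start <- min(max(1L, pos - half), L - max_len + 1L)
  end <- start + max_len - 1L
  list(wt = substr(wt, start, end), mut = substr(mut, start, end),
       pos = pos - start + 1L)
}
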