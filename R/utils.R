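#' @keywords internal
"_PACKAGE"

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Deterministic 31-bit hashing used to derive RNG seeds for the synthetic
# providers.  Polynomial rolling hash modulo a Mersenne-adjacent prime; all
# intermediate products stay below 2^53 so the arithmetic is exact in doubles.
HASH_MOD <- 2147483629

hash_ints <- function(x) {
  h <- 17
  for (v in x) {
    h <- (h * 1000003 + (as.numeric(v) %% HASH_MOD)) %% HASH_MOD
  }
  h
}

hash_string <- function(s) {
  hash_ints(utf8ToInt(s))
}

# Evaluate `expr` under a locally seeded RNG, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max),
           kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "ddgfuse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_prob_triple <- function(p, what = "P(SS)", tol = 1e-3) {
  if (length(p) != 3L || any(!is.finite(p)) || any(p < -tol)) {
    stopf("%s must be three finite non-negative probabilities", what)
  }
  s <- sum(p)
  if (abs(s - 1) > tol) {
    stopf("%s must sum to 1 (got %.6f)", what, s)
  }
  p / s
}
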