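#' Parse a point-mutation code
#'
#' Mutation codes follow the field convention `<wt><position><mut>`, e.g.
#' `"A123G"`: alanine at (1-based) position 123 replaced by glycine. When a
#' sequence is supplied the code is validated against it.
#'
#' @param code Character scalar, e.g. `"A123G"`.
#' @param sequence Optional protein sequence (character scalar over the
#'   20-letter amino-acid alphabet) used to validate the wild-type letter
#'   and position.
#' @return A list of class `"point_mutation"` with elements `wt`, `pos`,
#'   `mut`.
#' @examples
#' parse_mutation("A2G", "MAV")
#' @export
parse_mutation <- function(code, sequence = NULL) {
  if (!is.character(code) || length(code) != 1L || is.na(code)) {
    stopf("mutation code must be a single string", class = "ddg_parse_error")
  }
  m <- regmatches(code, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", code))[[1]]
  if (length(m) != 4L) {
    stopf("malformed mutation code '%s' (expected <letter><position><letter>)",
          code, class = "ddg_parse_error")
  }
  wt <- toupper(m[2]); mut <- toupper(m[4])
  pos <- as.integer(m[3])
  for (aa in c(wt, mut)) {
    if (!aa %in% AA_ALPHABET) {
      stopf("'%s' is not a standard amino-acid letter in code '%s'", aa, code,
            class = "ddg_parse_error")
    }
  }
  if (pos < 1L) {
    stopf("mutation position must be >= 1 in code '%s'", code,
          class = "ddg_parse_error")
  }
  if (wt == mut) {
    stopf("wild-type and mutant residue are identical in code '%s'", code,
          class = "ddg_parse_error")
  }
  if (!is.null(sequence)) {
    check_sequence(sequence)
    if (pos > nchar(sequence)) {
      stopf("position %d out of range for sequence of length %d",
            pos, nchar(sequence), class = "ddg_parse_error")
    }
    have <- substr(sequence, pos, pos)
    if (have != wt) {
      stopf("sequence has '%s' at position %d, not '%s' (code '%s')",
            have, pos, wt, code, class = "ddg_parse_error")
    }
  }
  structure(list(wt = wt, pos = pos, mut = mut), class = "point_mutation")
}

format_mutation <- function(mut) {
  paste0(mut$wt, mut$pos, mut$mut)
}

#' @export
print.point_mutation <- function(x, ...) {
  cat("<point mutation>", format_mutation(x), "\n")
  invisible(x)
}

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stopf("protein sequence must be a non-empty string",
          class = "ddg_parse_error")
  }
  bad <- setdiff(strsplit(sequence, "")[[1]], AA_ALPHABET)
  if (length(bad)) {
    stopf("sequence contains non-standard letters: %s",
          paste(unique(bad), collapse = ", "), class = "ddg_parse_error")
  }
  invisible(sequence)
}

#' Apply a point mutation to a sequence
#'
#' @param sequence Protein sequence (character scalar).
#' @param mut A `"point_mutation"` or a mutation code string.
#' @return The mutant sequence; same length, differing from the input at
#'   exactly the mutated position.
#' @examples
#' apply_mutation("MAV", "A2G")
#' @export
apply_mutation <- function(sequence, mut) {
  if (is.character(mut)) mut <- parse_mutation(mut, sequence)
  if (!inherits(mut, "point_mutation")) {
    stopf("'mut' must be a point_mutation or a mutation code string")
  }
  check_sequence(sequence)
  if (mut$pos > nchar(sequence)) {
    stopf("position %d out of range for sequence of length %d",
          mut$pos, nchar(sequence), class = "ddg_parse_error")
  }
  if (substr(sequence, mut$pos, mut$pos) != mut$wt) {
    stopf("sequence has '%s' at position %d, not '%s'",
          substr(sequence, mut$pos, mut$pos), mut$pos, mut$wt,
          class = "ddg_parse_error")
  }
  out <- sequence
  substr(out, mut$pos, mut$pos) <- mut$mut
  out
}

invert_mutation_code <- function(code) {
  m <- parse_mutation(code)
  paste0(m$mut, m$pos, m$wt)
}

# ---- variant tables ---------------------------------------------------------

VARIANT_COLS <- c("protein_id", "mutation", "ddg", "direction", "fold")

#' Build or validate a variant table
#'
#' A variant table is a plain `data.frame` with one row per mutation event:
#' columns `protein_id`, `mutation` (code such as `"A123G"`), `ddg`
#' (experimental ddG in kcal/mol, `NA` for prediction-only rows),
#' `direction` (`"direct"` or `"reverse"`) and `fold` (optional integer
#' cross-validation fold label, `NA` when unassigned).
#'
#' Reverse rows keep the `protein_id` of their wild-type protein; their
#' mutation code is expressed on the mutant sequence (letters swapped), and
#' the mutant sequence is reconstructed by applying the inverted code to the
#' wild-type sequence.
#'
#' @param protein_id,mutation,ddg,direction,fold Column vectors (recycled
#'   scalars allowed for `ddg`, `direction` and `fold`).
#' @return A validated variant `data.frame`.
#' @export
variant_table <- function(protein_id, mutation, ddg = NA_real_,
                          direction = "direct", fold = NA_integer_) {
  n <- length(protein_id)
  df <- data.frame(
    protein_id = as.character(protein_id),
    mutation = as.character(mutation),
    ddg = rep_len(as.numeric(ddg), n),
    direction = rep_len(as.character(direction), n),
    fold = rep_len(as.integer(fold), n),
    stringsAsFactors = FALSE
  )
  validate_variant_table(df)
}

validate_variant_table <- function(df) {
  missing <- setdiff(c("protein_id", "mutation", "ddg"), names(df))
  if (length(missing)) {
    stopf("variant table lacks required column(s): %s",
          paste(missing, collapse = ", "), class = "ddg_parse_error")
  }
  if (is.null(df$direction)) df$direction <- "direct"
  df$direction[is.na(df$direction) | df$direction == ""] <- "direct"
  bad <- setdiff(unique(df$direction), c("direct", "reverse"))
  if (length(bad)) {
    stopf("unknown direction value(s): %s", paste(bad, collapse = ", "),
          class = "ddg_parse_error")
  }
  if (is.null(df$fold)) df$fold <- NA_integer_
  df$fold <- as.integer(df$fold)
  df$ddg <- as.numeric(df$ddg)
  for (code in unique(df$mutation)) parse_mutation(code)
  df[VARIANT_COLS]
}

#' Resolve the sequence pair of a variant record
#'
#' @param row One row of a variant table.
#' @param sequences Named character vector of wild-type protein sequences.
#' @return `list(base =, mutated =, mutation =)` where `base` is the
#'   sequence the record's mutation code applies to (the wild type for
#'   direct records, the mutant for reverse records) and `mutation` is the
#'   parsed code validated against `base`.
#' @export
variant_sequences <- function(row, sequences) {
  pid <- row$protein_id
  if (!pid %in% names(sequences)) {
    stopf("no sequence for protein id '%s'", pid, class = "ddg_missing_input")
  }
  wt_seq <- sequences[[pid]]
  if (identical(row$direction, "reverse")) {
    direct_code <- invert_mutation_code(row$mutation)
    base <- apply_mutation(wt_seq, direct_code)
    mut <- parse_mutation(row$mutation, base)
    list(base = base, mutated = wt_seq, mutation = mut)
  } else {
    mut <- parse_mutation(row$mutation, wt_seq)
    list(base = wt_seq, mutated = apply_mutation(wt_seq, mut), mutation = mut)
  }
}

#' Reverse variant records
#'
#' For every direct record `A -> B` with value `ddg`, the reverse record is
#' `B -> A` applied to the mutant sequence, with value `-ddg`; fold labels
#' are inherited so a direct/reverse pair never straddles a train/validation
#' boundary. Applying the function twice returns the original records.
#'
#' @param variants A variant table.
#' @return A variant table of the same shape with every record reversed.
#' @export
reverse_variants <- function(variants) {
  variants <- validate_variant_table(variants)
  out <- variants
  out$mutation <- vapply(variants$mutation, invert_mutation_code, "")
  out$ddg <- -variants$ddg
  out$direction <- ifelse(variants$direction == "direct", "reverse", "direct")
  rownames(out) <- NULL
  out
}

#' Augment a direct-only variant table with its reverse records
#'
#' @param variants A variant table containing only direct records.
#' @return The input followed by the reversed copy of every row.
#' @export
augment_reverse <- function(variants) {
  variants <- validate_variant_table(variants)
  if (any(variants$direction != "direct")) {
    stopf("augment_reverse() expects direct records only")
  }
  out <- rbind(variants, reverse_variants(variants))
  rownames(out) <- NULL
  out
}

#' Average duplicated measurements
#'
#' Records sharing the key (protein id, wild-type residue, position, mutant
#' residue) are collapsed to one record whose ddG is the arithmetic mean of
#' the duplicates. Output is sorted by key, so the result is deterministic;
#' re-running on its own output is the identity.
#'
#' @param variants A variant table.
#' @return A deduplicated variant table.
#' @export
deduplicate_average <- function(variants) {
  variants <- validate_variant_table(variants)
  if (nrow(variants) == 0L) return(variants)
  key <- paste(variants$protein_id, variants$mutation, sep = "\r")
  ddg <- tapply(variants$ddg, key, mean)
  first <- variants[!duplicated(key), , drop = FALSE]
  first <- first[order(paste(first$protein_id, first$mutation, sep = "\r")), ,
                 drop = FALSE]
  first$ddg <- as.numeric(ddg[sort(names(ddg))])
  rownames(first) <- NULL
  first
}

# ---- FASTA and CSV ----------------------------------------------------------

#' Read protein sequences from FASTA
#'
#' @param path FASTA file (wrapped or unwrapped lines, multi-record).
#' @return Named character vector of validated sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stopf("FASTA file not found: %s", path, class = "ddg_missing_input")
  }
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  for (s in seqs) check_sequence(s)
  if (anyDuplicated(names(seqs))) {
    stopf("duplicated sequence ids in %s", path, class = "ddg_parse_error")
  }
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a variant CSV
#'
#' Required columns `protein_id,mutation,ddg`; optional `direction` and
#' `fold`. Empty or `"NA"` ddG marks prediction-only rows. Public datasets
#' disagree on the sign convention for ddG; `flip_sign = TRUE` negates the
#' column on load (this package uses ddG >= 0 = stabilizing throughout).
#'
#' @param path CSV file with a header row.
#' @param flip_sign Negate `ddg` on load.
#' @return A validated variant table.
#' @export
read_variants <- function(path, flip_sign = FALSE) {
  if (!file.exists(path)) {
    stopf("variant file not found: %s", path, class = "ddg_missing_input")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, na.strings = c("NA", ""))
  df <- validate_variant_table(df)
  if (flip_sign) df$ddg <- -df$ddg
  df
}

#' Write a variant CSV
#'
#' @param variants A variant table.
#' @param path Output file.
#' @export
write_variants <- function(variants, path) {
  variants <- validate_variant_table(variants)
  utils::write.csv(variants, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

# ---- homology-aware fold assignment -----------------------------------------

#' Pairwise global-alignment identity
#'
#' Fraction of identical aligned positions (including gap positions in the
#' denominator) of a Needleman-Wunsch global alignment.
#'
#' @param a,b Protein sequences.
#' @return Identity fraction in `[0, 1]`.
#' @export
sequence_identity <- function(a, b) {
  check_sequence(a); check_sequence(b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5
  )
  p <- Biostrings::pid(aln, type = "PID1") / 100
  if (is.nan(p)) 0 else p  # all-gap alignment: nothing identical
}

.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

#' Homology-aware fold assignment
#'
#' Sequences are clustered by single linkage on pairwise global-alignment
#' identity at `identity_threshold`; whole clusters are then assigned
#' greedily (largest cluster first) to the currently smallest fold, so no
#' two sequences above the threshold ever land in different folds.
#' Precomputed published splits can be used instead by supplying a `fold`
#' column in the variant CSV, which takes precedence downstream.
#'
#' @param sequences Named character vector of protein sequences.
#' @param k Number of folds (>= 2).
#' @param identity_threshold Identity fraction above which two sequences
#'   must share a fold (default 0.25).
#' @return Named integer vector mapping sequence id to fold label `1..k`.
#' @export
homology_fold_split <- function(sequences, k = 5L, identity_threshold = 0.25) {
  k <- as.integer(k)
  if (k < 2L) stopf("k must be >= 2")
  if (identity_threshold <= 0 || identity_threshold >= 1) {
    stopf("identity_threshold must be in (0, 1)")
  }
  n <- length(sequences)
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids)) {
    stopf("sequences must be uniquely named")
  }
  if (n == 0L) return(stats::setNames(integer(0), character(0)))

  # union-find over sequences; join every pair at or above the threshold
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (find(i) == find(j)) next
        if (sequence_identity(sequences[[i]], sequences[[j]]) >=
            identity_threshold) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  clusters <- split(seq_len(n), root)
  # deterministic order: big clusters first, ties by smallest member index
  ord <- order(-lengths(clusters),
               vapply(clusters, min, 0L))
  clusters <- clusters[ord]
  if (length(clusters) < k) {
    warnf("only %d homology cluster(s) for %d folds; some folds are empty",
          length(clusters), k)
  }
  fold_of <- integer(n)
  load <- integer(k)
  for (cl in clusters) {
    f <- which.min(load)
    fold_of[cl] <- f
    load[f] <- load[f] + length(cl)
  }
  stats::setNames(fold_of, ids)
}
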