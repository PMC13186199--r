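# Local mutation descriptor: a 25-vector in the fixed block order
#   [dRSA (1), dV_phipsi (4), dDisorder (1), dAAP (13), P(SS)_wt (3), P(SS)_mut (3)]
# built from per-residue structural annotations at the mutated position and
# a 20 x 13 amino-acid property table.

LOCAL_DIM <- 25L

#' Load the amino-acid property table
#'
#' Thirteen scalar per-residue scales (Kyte-Doolittle hydropathy, molecular
#' weight, van der Waals volume, Grantham polarity, isoelectric point, net
#' charge at pH 7, side-chain H-bond donor and acceptor counts, flexibility
#' index, helix and sheet propensities, maximum accessible surface area,
#' aromaticity indicator), z-score normalized across the 20 residues. Users
#' may substitute their own 20-row, 13-property CSV; the column set is free
#' but the shape is enforced.
#'
#' @param path CSV with an `aa` column plus 13 numeric property columns;
#'   default is the table shipped with the package.
#' @return A 20 x 13 numeric matrix, rownames the amino-acid letters, with
#'   attributes `version` and `raw` (the unnormalized table).
#' @export
load_aap_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aap_table.csv", package = "ddgfuse",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"aa" %in% names(df)) stopf("AAP table needs an 'aa' column")
  raw <- as.matrix(df[setdiff(names(df), "aa")])
  rownames(raw) <- toupper(df$aa)
  if (nrow(raw) != 20L || !setequal(rownames(raw), AA_ALPHABET)) {
    stopf("AAP table must have one row per standard amino acid")
  }
  if (ncol(raw) != 13L) {
    stopf("AAP table must have exactly 13 property columns (got %d)",
          ncol(raw))
  }
  raw <- raw[AA_ALPHABET, , drop = FALSE]
  z <- scale(raw)  # column mean 0, sample sd 1 across the 20 residues
  tab <- matrix(as.numeric(z), 20L, 13L,
                dimnames = list(AA_ALPHABET, colnames(raw)))
  attr(tab, "version") <- paste0("aap-v1-", ncol(raw))
  attr(tab, "raw") <- raw
  tab
}

#' Maximum accessible surface area of a free residue
#'
#' @param aa Amino-acid letter(s).
#' @return Maximum ASA in square Angstrom (theoretical values).
#' @export
max_asa <- function(aa) {
  raw <- attr(load_aap_table(), "raw")
  vals <- raw[toupper(aa), "max_asa"]
  unname(vals)
}

#' Relative solvent accessibility from absolute area
#'
#' `RSA = ASA / maxASA`, clamped to `[0, 1]`. Annotation sources that
#' already report RSA (NetSurfP does) are used directly; this helper covers
#' inputs that only carry absolute areas.
#'
#' @param asa Absolute solvent-accessible surface area (square Angstrom).
#' @param max_asa Maximum ASA of the residue type (> 0).
#' @return RSA fraction in `[0, 1]`.
#' @export
rsa_from_asa <- function(asa, max_asa) {
  if (any(!is.finite(asa)) || any(asa < 0)) stopf("asa must be finite and >= 0")
  if (any(!is.finite(max_asa)) || any(max_asa <= 0)) {
    stopf("max_asa must be finite and > 0")
  }
  pmin(asa / max_asa, 1.0)
}

#' Sine/cosine encoding of backbone dihedral angles
#'
#' Maps `(phi, psi)` in degrees to `[sin(phi), cos(phi), sin(psi), cos(psi)]`,
#' removing the +/-180 degree periodicity artifact that raw angle
#' differences suffer from.
#'
#' @param phi,psi Backbone dihedral angles in degrees (any finite real;
#'   periodic).
#' @return Numeric 4-vector with components in `[-1, 1]`.
#' @export
dihedral_encoding <- function(phi, psi) {
  if (!is.finite(phi) || !is.finite(psi)) stopf("angles must be finite")
  p <- phi * pi / 180
  s <- psi * pi / 180
  c(sin(p), cos(p), sin(s), cos(s))
}

#' Amino-acid property change vector
#'
#' Componentwise `table[mut, ] - table[wt, ]` over the 13 normalized
#' properties; antisymmetric under swapping the two residues.
#'
#' @param wt,mut Amino-acid letters.
#' @param table Property table from [load_aap_table()].
#' @return Numeric 13-vector.
#' @export
delta_aap <- function(wt, mut, table = load_aap_table()) {
  for (aa in c(wt, mut)) {
    if (!toupper(aa) %in% rownames(table)) {
      stopf("unknown amino-acid letter '%s'", aa)
    }
  }
  table[toupper(mut), ] - table[toupper(wt), ]
}

#' One-residue structural annotation
#'
#' @param p_helix,p_sheet,p_coil Three-state secondary-structure
#'   probabilities (renormalized on construction; must sum to 1 within
#'   1e-3).
#' @param rsa Relative solvent accessibility, clamped to `[0, 1]`.
#' @param disorder Disorder propensity in `[0, 1]`.
#' @param phi,psi Backbone dihedrals in degrees.
#' @return A list of class `"residue_annotation"`.
#' @export
residue_annotation <- function(p_helix, p_sheet, p_coil, rsa, disorder,
                               phi, psi) {
  p <- assert_prob_triple(c(p_helix, p_sheet, p_coil))
  if (!is.finite(rsa)) stopf("rsa must be finite")
  if (!is.finite(disorder) || disorder < 0 || disorder > 1) {
    stopf("disorder must be in [0, 1]")
  }
  if (!is.finite(phi) || !is.finite(psi)) stopf("phi/psi must be finite")
  structure(
    list(p_ss = p, rsa = min(max(rsa, 0), 1), disorder = disorder,
         phi = phi, psi = psi),
    class = "residue_annotation"
  )
}

#' Build the 25-dimensional local mutation descriptor
#'
#' Block order: `dRSA` (mutant minus wild type), the four sine/cosine
#' dihedral differences, `dDisorder`, the 13 amino-acid property changes,
#' then the wild-type and mutant secondary-structure probability triples
#' copied verbatim. Under direction reversal the 19 difference components
#' negate exactly and the two probability triples exchange.
#'
#' @param wt_ann,mut_ann [residue_annotation()]s of the mutated position in
#'   the wild-type and mutant sequences.
#' @param wt,mut Wild-type and mutant amino-acid letters.
#' @param table Property table from [load_aap_table()].
#' @return Named numeric vector of length 25.
#' @export
build_local_vector <- function(wt_ann, mut_ann, wt, mut,
                               table = load_aap_table()) {
  stopifnot(inherits(wt_ann, "residue_annotation"),
            inherits(mut_ann, "residue_annotation"))
  d_rsa <- mut_ann$rsa - wt_ann$rsa
  d_v <- dihedral_encoding(mut_ann$phi, mut_ann$psi) -
    dihedral_encoding(wt_ann$phi, wt_ann$psi)
  d_dis <- mut_ann$disorder - wt_ann$disorder
  d_aap <- delta_aap(wt, mut, table)
  out <- c(d_rsa, d_v, d_dis, d_aap, wt_ann$p_ss, mut_ann$p_ss)
  names(out) <- c(
    "dRSA", "dSinPhi", "dCosPhi", "dSinPsi", "dCosPsi", "dDisorder",
    paste0("dAAP_", colnames(table)),
    paste0("pss_wt_", c("H", "E", "C")), paste0("pss_mut_", c("H", "E", "C"))
  )
  stopifnot(length(out) == LOCAL_DIM)
  out
}

# ---- NetSurfP-3.0 dialect ---------------------------------------------------

#' Read per-residue annotations in the NetSurfP-3.0 CSV dialect
#'
#' Expected columns: `id, seq, n, rsa, asa, q3, p[q3_H], p[q3_E], p[q3_C],
#' phi, psi, disorder` (extra columns ignored; `n` is the 1-based residue
#' index). Probability triples are renormalized; RSA is clamped to
#' `[0, 1]`. Mutant sequences are annotated under the id
#' `<protein_id>_<mutation>`.
#'
#' @param path CSV file.
#' @return A data.frame with columns `id, n, aa, rsa, p_helix, p_sheet,
#'   p_coil, disorder, phi, psi`.
#' @export
read_netsurfp <- function(path) {
  if (!file.exists(path)) {
    stopf("annotation file not found: %s", path, class = "ddg_missing_input")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "seq", "n", "rsa", "p[q3_H]", "p[q3_E]", "p[q3_C]",
            "phi", "psi", "disorder")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stopf("annotation file lacks column(s): %s",
          paste(missing, collapse = ", "), class = "ddg_parse_error")
  }
  p <- cbind(df[["p[q3_H]"]], df[["p[q3_E]"]], df[["p[q3_C]"]])
  s <- rowSums(p)
  if (any(abs(s - 1) > 1e-3)) {
    warnf("%d P(SS) triple(s) off unit sum by > 1e-3; renormalizing",
          sum(abs(s - 1) > 1e-3))
  }
  p <- p / s
  out <- data.frame(
    id = as.character(df$id),
    n = as.integer(df$n),
    aa = toupper(as.character(df$seq)),
    rsa = pmin(pmax(as.numeric(df$rsa), 0), 1),
    p_helix = p[, 1], p_sheet = p[, 2], p_coil = p[, 3],
    disorder = pmin(pmax(as.numeric(df$disorder), 0), 1),
    phi = as.numeric(df$phi), psi = as.numeric(df$psi),
    stringsAsFactors = FALSE
  )
  out
}

#' Write per-residue annotations in the NetSurfP-3.0 CSV dialect
#'
#' @param ann Data.frame as returned by [read_netsurfp()].
#' @param path Output CSV.
#' @export
write_netsurfp <- function(ann, path) {
  asa <- if ("asa" %in% names(ann)) ann$asa else ann$rsa * max_asa(ann$aa)
  q3 <- c("H", "E", "C")[max.col(cbind(ann$p_helix, ann$p_sheet, ann$p_coil),
                                 ties.method = "first")]
  out <- data.frame(
    id = ann$id, seq = ann$aa, n = ann$n, rsa = ann$rsa, asa = asa, q3 = q3,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  out[["p[q3_H]"]] <- ann$p_helix
  out[["p[q3_E]"]] <- ann$p_sheet
  out[["p[q3_C]"]] <- ann$p_coil
  out$phi <- ann$phi
  out$psi <- ann$psi
  out$disorder <- ann$disorder
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse 8-state secondary structure to 3 states
#'
#' `H, G, I -> helix`; `E, B -> sheet`; everything else `-> coil`.
#'
#' @param q8 Character vector of 8-state codes.
#' @return Character vector over `"H"`, `"E"`, `"C"`.
#' @export
collapse_q8 <- function(q8) {
  q8 <- toupper(q8)
  out <- rep("C", length(q8))
  out[q8 %in% c("H", "G", "I")] <- "H"
  out[q8 %in% c("E", "B")] <- "E"
  out
}

# ---- annotation providers ---------------------------------------------------

#' Annotation provider backed by a NetSurfP-style table
#'
#' @param x Path to a NetSurfP-dialect CSV or a data.frame from
#'   [read_netsurfp()].
#' @return An annotation provider for [annotate_residue()].
#' @export
netsurfp_annotator <- function(x) {
  ann <- if (is.character(x)) read_netsurfp(x) else x
  structure(list(ann = ann, id = "netsurfp-csv"),
            class = c("netsurfp_annotator", "ddg_annotator"))
}

#' Look up the annotation of one residue
#'
#' @param provider An annotation provider (`netsurfp_annotator()` or
#'   [synthetic_annotator()]).
#' @param seq_id Sequence identifier (for table-backed providers).
#' @param sequence The full sequence (used by synthetic providers, and to
#'   cross-check the residue letter).
#' @param pos 1-based residue index.
#' @return A [residue_annotation()].
#' @export
annotate_residue <- function(provider, seq_id, sequence, pos) {
  UseMethod("annotate_residue")
}

#' @export
annotate_residue.netsurfp_annotator <- function(provider, seq_id, sequence,
                                                pos) {
  rows <- provider$ann[provider$ann$id == seq_id & provider$ann$n == pos, ,
                       drop = FALSE]
  if (nrow(rows) == 0L) {
    stopf("no annotation for id '%s' position %d", seq_id, pos,
          class = "ddg_missing_annotation")
  }
  r <- rows[1L, ]
  if (!is.null(sequence) && r$aa != substr(sequence, pos, pos)) {
    stopf("annotation letter '%s' disagrees with sequence at %s:%d",
          r$aa, seq_id, pos, class = "ddg_parse_error")
  }
  residue_annotation(r$p_helix, r$p_sheet, r$p_coil, r$rsa, r$disorder,
                     r$phi, r$psi)
}
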