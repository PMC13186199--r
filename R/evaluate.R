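# Metrics and stratified analyses. Sign convention throughout: ddG >= 0 is
# stabilizing, ddG < 0 destabilizing.

#' Root-mean-square error
#'
#' @param pred,truth Equal-length numeric vectors (kcal/mol).
#' @return RMSE in kcal/mol.
#' @export
rmse <- function(pred, truth) {
  if (length(pred) != length(truth)) stopf("length mismatch")
  if (length(pred) < 1L) stopf("need at least one value")
  sqrt(mean((pred - truth)^2))
}

#' Pearson correlation coefficient
#'
#' Returns `NA` with a warning when either input is constant (the
#' correlation is undefined).
#'
#' @param pred,truth Equal-length numeric vectors, length >= 2.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
pcc <- function(pred, truth) {
  if (length(pred) != length(truth)) stopf("length mismatch")
  if (length(pred) < 2L) stopf("need at least two values")
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) {
    warnf("constant input: correlation undefined")
    return(NA_real_)
  }
  stats::cor(pred, truth)
}

#' Sign-classification accuracy
#'
#' Fraction of positions where prediction and truth fall in the same
#' stability class, with the boundary at zero and exact zero counted as
#' stabilizing on both sides (`ddG >= 0` stabilizing).
#'
#' @param pred,truth Equal-length numeric vectors.
#' @return Fraction in `[0, 1]`.
#' @export
acc <- function(pred, truth) {
  if (length(pred) != length(truth)) stopf("length mismatch")
  if (length(pred) < 1L) stopf("need at least one value")
  mean((pred >= 0) == (truth >= 0))
}

#' Metric report for one subset
#'
#' @param pred,truth Numeric vectors.
#' @param label Subset label.
#' @return One-row data.frame `subset, n, rmse, pcc, acc` (all metrics `NA`
#'   for an empty subset).
#' @export
metric_report <- function(pred, truth, label = "overall") {
  if (length(pred) == 0L) {
    return(data.frame(subset = label, n = 0L, rmse = NA_real_,
                      pcc = NA_real_, acc = NA_real_,
                      stringsAsFactors = FALSE))
  }
  data.frame(
    subset = label, n = length(pred),
    rmse = rmse(pred, truth),
    pcc = if (length(pred) >= 2L) suppressWarnings(pcc(pred, truth))
          else NA_real_,
    acc = acc(pred, truth),
    stringsAsFactors = FALSE
  )
}

#' Antisymmetry and bias of paired predictions
#'
#' For matched direct/reverse pairs: `rd_r` is the Pearson correlation
#' between the two prediction vectors (-1 for a perfectly antisymmetric
#' predictor) and the bias is the mean of `delta_i = (direct_i +
#' reverse_i) / 2` (0 for an unbiased one).
#'
#' @param pred_direct,pred_reverse Paired prediction vectors (same pairs,
#'   same order), length >= 2.
#' @return A list of class `"antisymmetry_report"`: `rd_r`, `delta_bias`
#'   (kcal/mol), `n_pairs`.
#' @export
antisymmetry_metrics <- function(pred_direct, pred_reverse) {
  if (length(pred_direct) != length(pred_reverse)) {
    stopf("direct and reverse predictions must be paired")
  }
  if (length(pred_direct) < 2L) stopf("need at least two pairs")
  structure(
    list(rd_r = suppressWarnings(pcc(pred_direct, pred_reverse)),
         delta_bias = mean((pred_direct + pred_reverse) / 2),
         n_pairs = length(pred_direct)),
    class = "antisymmetry_report"
  )
}

#' @export
print.antisymmetry_report <- function(x, ...) {
  cat(sprintf("antisymmetry over %d pairs: r_d-r = %.3f, <delta> = %.3f kcal/mol\n",
              x$n_pairs, x$rd_r, x$delta_bias))
  invisible(x)
}

#' Match direct and reverse records into pairs
#'
#' Pairs are keyed by (protein id, direct mutation code); a reverse
#' record's key is its inverted code.
#'
#' @param variants A variant table.
#' @param values Numeric vector aligned with `variants` (predictions or
#'   measurements).
#' @return data.frame `pair_id, direct, reverse`, one row per matched pair.
#' @export
match_pairs <- function(variants, values) {
  variants <- validate_variant_table(variants)
  stopifnot(length(values) == nrow(variants))
  code <- ifelse(variants$direction == "reverse",
                 vapply(variants$mutation, invert_mutation_code, ""),
                 variants$mutation)
  key <- paste(variants$protein_id, code, sep = ":")
  d_i <- which(variants$direction == "direct")
  r_i <- which(variants$direction == "reverse")
  dmap <- stats::setNames(d_i, key[d_i])
  rmap <- stats::setNames(r_i, key[r_i])
  common <- intersect(names(dmap), names(rmap))
  data.frame(pair_id = common,
             direct = values[dmap[common]],
             reverse = values[rmap[common]],
             stringsAsFactors = FALSE)
}

# ---- stratification ---------------------------------------------------------

#' Classify relative solvent accessibility
#'
#' Solvent-exposed above RSA 0.5, buried below 0.1, intermediate otherwise.
#'
#' @param rsa Numeric RSA fractions.
#' @return Character vector over `"buried"`, `"intermediate"`, `"exposed"`.
#' @export
rsa_class <- function(rsa) {
  out <- rep("intermediate", length(rsa))
  out[rsa > 0.5] <- "exposed"
  out[rsa < 0.1] <- "buried"
  out
}

#' Secondary-structure class from a probability triple
#'
#' Argmax over (helix, sheet, coil); ties resolved in that order.
#'
#' @param p_helix,p_sheet,p_coil Probability vectors.
#' @return Character vector over `"helix"`, `"sheet"`, `"coil"`.
#' @export
ss_class <- function(p_helix, p_sheet, p_coil) {
  m <- cbind(p_helix, p_sheet, p_coil)
  c("helix", "sheet", "coil")[max.col(m, ties.method = "first")]
}

#' Annotations of the mutated site of every variant
#'
#' Looks up, for each record, the annotation of the mutated position in the
#' record's own wild-type-role sequence (for reverse records that is the
#' mutant protein).
#'
#' @param variants A variant table.
#' @param sequences Named character vector of wild-type sequences.
#' @param annotator An annotation provider.
#' @return data.frame `rsa, p_helix, p_sheet, p_coil`, one row per variant.
#' @export
variant_site_annotations <- function(variants, sequences, annotator) {
  variants <- validate_variant_table(variants)
  out <- lapply(seq_len(nrow(variants)), function(i) {
    row <- variants[i, ]
    sq <- variant_sequences(row, sequences)
    base_id <- if (row$direction == "reverse") {
      mutant_annotation_id(row$protein_id, invert_mutation_code(row$mutation))
    } else {
      row$protein_id
    }
    a <- annotate_residue(annotator, base_id, sq$base, sq$mutation$pos)
    data.frame(rsa = a$rsa, p_helix = a$p_ss[1], p_sheet = a$p_ss[2],
               p_coil = a$p_ss[3])
  })
  do.call(rbind, out)
}

#' Stratified metric reports
#'
#' Splits predictions into subsets by one of four schemes and reports
#' RMSE/PCC/ACC per subset. Schemes: `"rsa_class"` (buried / intermediate /
#' exposed at the 0.1 and 0.5 RSA thresholds), `"ss_class"` (argmax of the
#' wild-type P(SS) triple), `"direction"` (direct / reverse) and
#' `"stabilizing"` (experimental ddG >= 0 vs < 0). The subsets of a scheme
#' partition the records; empty subsets are reported with `n = 0` and `NA`
#' metrics.
#'
#' @param df data.frame with columns `pred` and `truth`, plus `rsa`
#'   (for `rsa_class`), `p_helix/p_sheet/p_coil` (for `ss_class`) or
#'   `direction` as the scheme requires (see
#'   [variant_site_annotations()]).
#' @param scheme Stratification scheme.
#' @return data.frame of [metric_report()] rows, one per class of the
#'   scheme (all classes listed, even empty ones).
#' @export
stratify_metrics <- function(df, scheme = c("rsa_class", "ss_class",
                                            "direction", "stabilizing")) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("pred", "truth") %in% names(df)))
  cls <- switch(scheme,
    rsa_class = {
      stopifnot("rsa" %in% names(df))
      factor(rsa_class(df$rsa), levels = c("buried", "intermediate",
                                           "exposed"))
    },
    ss_class = {
      stopifnot(all(c("p_helix", "p_sheet", "p_coil") %in% names(df)))
      factor(ss_class(df$p_helix, df$p_sheet, df$p_coil),
             levels = c("helix", "sheet", "coil"))
    },
    direction = {
      stopifnot("direction" %in% names(df))
      factor(df$direction, levels = c("direct", "reverse"))
    },
    stabilizing = factor(ifelse(df$truth >= 0, "stabilizing",
                                "destabilizing"),
                         levels = c("stabilizing", "destabilizing"))
  )
  out <- lapply(levels(cls), function(lv) {
    i <- which(cls == lv)
    metric_report(df$pred[i], df$truth[i], lv)
  })
  do.call(rbind, out)
}

#' Export the fusion weight magnitudes of a fitted model
#'
#' Absolute values of the 128 learnable element-wise weights of each
#' branch, revealing how much the decoder draws on global versus local
#' features.
#'
#' @param model A `"ddg_model"` fitted with linear-combination fusion.
#' @param file Optional CSV destination; the table is written with one
#'   trailing `mean` row.
#' @return data.frame with 128 rows and columns `index, g_weight_abs,
#'   r_weight_abs`; the per-branch mean absolute weights are attached as
#'   attributes `g_mean` and `r_mean`.
#' @export
export_fusion_weights <- function(model, file = NULL) {
  stopifnot(inherits(model, "ddg_model"))
  if (model$control$fusion != "linear_combination") {
    stopf("fusion weights exist only for linear-combination models")
  }
  out <- data.frame(index = seq_len(ENC_DIM),
                    g_weight_abs = abs(model$net$par$fu_g),
                    r_weight_abs = abs(model$net$par$fu_r))
  attr(out, "g_mean") <- mean(out$g_weight_abs)
  attr(out, "r_mean") <- mean(out$r_weight_abs)
  if (!is.null(file)) {
    tab <- rbind(out, data.frame(index = NA_integer_,
                                 g_weight_abs = attr(out, "g_mean"),
                                 r_weight_abs = attr(out, "r_mean")))
    tab$index <- c(as.character(out$index), "mean")
    utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
  }
  out
}

# ---- full evaluation --------------------------------------------------------

#' Evaluate predictions against experimental values
#'
#' Produces overall, per-direction and stabilizing-subset metric reports,
#' plus the antisymmetry report whenever matched direct/reverse pairs
#' exist; RSA and secondary-structure stratifications are added when an
#' annotation source is supplied.
#'
#' @param variants Variant table with experimental `ddg` values.
#' @param pred Numeric predictions aligned with `variants`.
#' @param sequences,annotator Optional; enable `rsa_class` and `ss_class`
#'   stratification of the mutated sites.
#' @return A list of class `"ddg_evaluation"`: `reports` (stacked metric
#'   rows with a `scheme` column) and `antisymmetry` (`NULL` when no pairs
#'   exist).
#' @export
evaluate_predictions <- function(variants, pred, sequences = NULL,
                                 annotator = NULL) {
  variants <- validate_variant_table(variants)
  stopifnot(length(pred) == nrow(variants))
  ok <- !is.na(variants$ddg)
  if (!any(ok)) stopf("no records with experimental ddg to evaluate")
  v <- variants[ok, , drop = FALSE]
  df <- data.frame(pred = pred[ok], truth = v$ddg, direction = v$direction,
                   stringsAsFactors = FALSE)
  reports <- cbind(scheme = "overall",
                   metric_report(df$pred, df$truth, "overall"))
  for (sc in c("direction", "stabilizing")) {
    reports <- rbind(reports, cbind(scheme = sc, stratify_metrics(df, sc)))
  }
  if (!is.null(sequences) && !is.null(annotator)) {
    ann <- variant_site_annotations(v, sequences, annotator)
    df2 <- cbind(df, ann)
    for (sc in c("rsa_class", "ss_class")) {
      reports <- rbind(reports, cbind(scheme = sc, stratify_metrics(df2, sc)))
    }
  }
  pairs <- match_pairs(v, df$pred)
  antisym <- if (nrow(pairs) >= 2L) {
    antisymmetry_metrics(pairs$direct, pairs$reverse)
  }
  structure(list(reports = reports, antisymmetry = antisym,
                 n = nrow(df)),
            class = "ddg_evaluation")
}

#' @export
print.ddg_evaluation <- function(x, ...) {
  cat(sprintf("ddG evaluation over %d records\n", x$n))
  print(x$reports, row.names = FALSE, digits = 4)
  if (!is.null(x$antisymmetry)) print(x$antisymmetry)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' @param x A `"ddg_evaluation"`.
#' @param csv Path for the per-subset metric CSV.
#' @param txt Optional path for a human-readable summary.
#' @export
write_evaluation <- function(x, csv, txt = NULL) {
  stopifnot(inherits(x, "ddg_evaluation"))
  tab <- x$reports
  if (!is.null(x$antisymmetry)) {
    tab <- rbind(tab,
      data.frame(scheme = "antisymmetry", subset = "pairs",
                 n = x$antisymmetry$n_pairs, rmse = NA_real_,
                 pcc = x$antisymmetry$rd_r, acc = NA_real_),
      data.frame(scheme = "antisymmetry", subset = "delta_bias",
                 n = x$antisymmetry$n_pairs, rmse = x$antisymmetry$delta_bias,
                 pcc = NA_real_, acc = NA_real_))
  }
  utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE, na = "NA")
  if (!is.null(txt)) {
    con <- file(txt, "w")
    on.exit(close(con))
    sink(con)
    print(x)
    sink()
  }
  invisible(csv)
}
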