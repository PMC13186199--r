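# Featurized datasets, the fitting function and its S3 methods, fold
# ensembles, and checkpoints.

#' Training configuration
#'
#' Defaults: mean-squared-error loss, Adam with learning rate 1e-3, batch
#' size 64, at most 500 epochs with early stopping after 20 epochs without
#' held-out improvement. Encoder hidden widths are 256 (global) and 64
#' (local); the decoder uses two kernel-3 convolutions (1 -> 16 -> 32
#' channels) and a 64-unit fully connected layer. All randomness
#' (initialization, batch order, internal validation split) flows from
#' `seed`.
#'
#' @param loss Only `"mse"` is implemented.
#' @param optimizer Only `"adam"` is implemented.
#' @param lr Learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs) on held-out RMSE.
#' @param seed Integer seed; a fixed seed makes a training run reproducible.
#' @param ablation `"full"`, `"wo_local"` (local branch zeroed) or
#'   `"wo_global"` (global branch zeroed). Ablation hard-zeroes the excluded
#'   branch's fused contribution so decoder width stays constant and models
#'   are comparable.
#' @param fusion `"linear_combination"` (learnable element-wise weights,
#'   the default), `"concatenation"` or `"outer_product"`.
#' @param hidden_global,hidden_local Encoder hidden widths.
#' @param conv_channels Two conv channel counts.
#' @param fc_hidden Fully connected hidden width.
#' @param valid_fraction Internal validation fraction used when no
#'   validation set is supplied.
#' @param verbose Print per-epoch progress.
#' @return A list of class `"ddg_control"`.
#' @export
ddg_control <- function(loss = "mse", optimizer = "adam", lr = 1e-3,
                        batch_size = 64L, max_epochs = 500L, patience = 20L,
                        seed = 1L,
                        ablation = c("full", "wo_local", "wo_global"),
                        fusion = c("linear_combination", "concatenation",
                                   "outer_product"),
                        hidden_global = 256L, hidden_local = 64L,
                        conv_channels = c(16L, 32L), fc_hidden = 64L,
                        valid_fraction = 0.1, verbose = FALSE) {
  loss <- match.arg(loss)
  optimizer <- match.arg(optimizer)
  ablation <- match.arg(ablation)
  fusion <- match.arg(fusion)
  stopifnot(lr > 0, batch_size >= 1L, max_epochs >= 1L, patience >= 1L,
            length(conv_channels) == 2L, all(conv_channels >= 1L),
            valid_fraction > 0, valid_fraction < 1)
  structure(
    list(loss = loss, optimizer = optimizer, lr = lr,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         seed = as.integer(seed), ablation = ablation, fusion = fusion,
         hidden_global = as.integer(hidden_global),
         hidden_local = as.integer(hidden_local),
         conv_channels = as.integer(conv_channels),
         fc_hidden = as.integer(fc_hidden),
         valid_fraction = valid_fraction, verbose = isTRUE(verbose)),
    class = "ddg_control"
  )
}

# ---- featurized datasets ----------------------------------------------------

mutant_annotation_id <- function(protein_id, direct_code) {
  paste(protein_id, direct_code, sep = "_")
}

#' Featurize a variant table
#'
#' Computes, for every variant record, the global change vector (pooled
#' embedding difference, exactly antisymmetric under direction reversal)
#' and the 25-dimensional local descriptor, from pluggable embedding and
#' annotation providers. Wild-type sequences are annotated under their
#' protein id; the mutant sequence of direct code `C` under
#' `<protein_id>_C` (table-backed annotators only; synthetic annotators
#' compute from the sequence).
#'
#' @param variants A variant table (see [variant_table()]).
#' @param sequences Named character vector of wild-type sequences.
#' @param embedder An embedding provider ([synthetic_embedder()],
#'   [matrix_embedder()], or user supplied).
#' @param annotator An annotation provider ([synthetic_annotator()] or
#'   [netsurfp_annotator()]).
#' @param aap Property table from [load_aap_table()].
#' @param cache_dir Optional on-disk pooled-embedding cache directory.
#' @param skip_missing Drop (with a message) variants whose annotations are
#'   missing instead of aborting.
#' @return A list of class `"ddg_dataset"`: the (possibly reduced) variant
#'   table, the `n x d` global matrix `G`, the `n x 25` local matrix `R`,
#'   and feature-provenance metadata.
#' @export
featurize_variants <- function(variants, sequences, embedder, annotator,
                               aap = load_aap_table(), cache_dir = NULL,
                               skip_missing = FALSE) {
  variants <- validate_variant_table(variants)
  n <- nrow(variants)
  if (n == 0L) stopf("no variants to featurize")
  d <- if (!is.null(embedder$d)) embedder$d else {
    length(pooled_embedding(embedder, sequences[[1]], cache_dir))
  }
  G <- matrix(0, n, d)
  R <- matrix(0, n, LOCAL_DIM)
  bad <- character(0)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    row <- variants[i, ]
    sq <- variant_sequences(row, sequences)
    direct_code <- if (row$direction == "reverse") {
      invert_mutation_code(row$mutation)
    } else {
      row$mutation
    }
    mut_id <- mutant_annotation_id(row$protein_id, direct_code)
    if (row$direction == "reverse") {
      base_id <- mut_id; mutated_id <- row$protein_id
    } else {
      base_id <- row$protein_id; mutated_id <- mut_id
    }
    win <- window_pair(sq$base, sq$mutated, sq$mutation$pos)
    res <- tryCatch({
      gd <- global_delta(embedder, win$wt, win$mut, cache_dir)
      wt_ann <- annotate_residue(annotator, base_id, sq$base, sq$mutation$pos)
      mut_ann <- annotate_residue(annotator, mutated_id, sq$mutated,
                                  sq$mutation$pos)
      lv <- build_local_vector(wt_ann, mut_ann, sq$mutation$wt,
                               sq$mutation$mut, aap)
      list(gd = gd, lv = lv)
    }, ddg_missing_annotation = function(e) e)
    if (inherits(res, "condition")) {
      bad <- c(bad, sprintf("%s %s (%s): %s", row$protein_id, row$mutation,
                            row$direction, conditionMessage(res)))
      keep[i] <- FALSE
      next
    }
    G[i, ] <- res$gd
    R[i, ] <- res$lv
  }
  if (length(bad)) {
    if (!skip_missing) {
      stopf("missing annotations for %d variant(s):\n%s", length(bad),
            paste(" -", bad, collapse = "\n"),
            class = "ddg_missing_annotation")
    }
    message(sprintf("skipping %d variant(s) with missing annotations",
                    length(bad)))
  }
  structure(
    list(variants = variants[keep, , drop = FALSE],
         G = G[keep, , drop = FALSE], R = R[keep, , drop = FALSE],
         d = d,
         meta = list(provider_id = embedder$id %||% "unknown",
                     annotator_id = annotator$id %||% "unknown",
                     aap_version = attr(aap, "version") %||% "unknown")),
    class = "ddg_dataset"
  )
}

#' Assemble a featurized dataset from precomputed matrices
#'
#' @param variants Variant table aligned row-wise with the matrices.
#' @param G `n x d` global feature matrix.
#' @param R `n x 25` local feature matrix.
#' @param meta Feature-provenance metadata list.
#' @return A `"ddg_dataset"`.
#' @export
ddg_dataset <- function(variants, G, R, meta = list()) {
  variants <- validate_variant_table(variants)
  stopifnot(is.matrix(G), is.matrix(R), nrow(G) == nrow(variants),
            nrow(R) == nrow(variants), ncol(R) == LOCAL_DIM)
  structure(list(variants = variants, G = G, R = R, d = ncol(G),
                 meta = meta),
            class = "ddg_dataset")
}

#' @export
print.ddg_dataset <- function(x, ...) {
  cat(sprintf("<ddg_dataset> %d variants (%d direct, %d reverse), d = %d\n",
              nrow(x$variants), sum(x$variants$direction == "direct"),
              sum(x$variants$direction == "reverse"), x$d))
  cat(sprintf("  providers: %s | %s | %s\n",
              x$meta$provider_id %||% "?", x$meta$annotator_id %||% "?",
              x$meta$aap_version %||% "?"))
  invisible(x)
}

#' Row-subset a featurized dataset
#'
#' @param x A `"ddg_dataset"`.
#' @param i Row indices or logical mask.
#' @return The reduced `"ddg_dataset"`.
#' @export
subset_dataset <- function(x, i) {
  stopifnot(inherits(x, "ddg_dataset"))
  structure(list(variants = x$variants[i, , drop = FALSE],
                 G = x$G[i, , drop = FALSE], R = x$R[i, , drop = FALSE],
                 d = x$d, meta = x$meta),
            class = "ddg_dataset")
}

scale_columns <- function(X, s) sweep(X, 2, s, "/")

column_scales <- function(X) {
  s <- apply(X, 2, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  s
}

# ---- fitting ----------------------------------------------------------------

#' Fit the fusion regressor
#'
#' Trains the two-branch encoder / element-wise fusion / convolutional
#' decoder head on a featurized dataset by minibatch Adam on mean squared
#' error, with early stopping on held-out RMSE. Feature columns are
#' rescaled to unit standard deviation (no centering, so the exact
#' antisymmetry of the difference features is preserved); the scales are
#' stored in the model and applied again at prediction time.
#'
#' @param data A `"ddg_dataset"` with non-missing `ddg` values.
#' @param control A [ddg_control()].
#' @param valid Held-out data for early stopping: a `"ddg_dataset"`, a
#'   vector of row indices into `data`, or `NULL` (an internal
#'   `valid_fraction` split is carved out by seed).
#' @return An object of class `"ddg_model"` with `print`, `summary`,
#'   `coef`, `predict`, `residuals` and `plot` methods.
#' @export
ddg_fit <- function(data, control = ddg_control(), valid = NULL) {
  stopifnot(inherits(data, "ddg_dataset"))
  y_all <- data$variants$ddg
  if (anyNA(y_all)) stopf("training data contains missing ddg values")

  if (is.null(valid)) {
    n <- nrow(data$G)
    idx <- with_seed(hash_ints(c(control$seed, 909L)), sample.int(n))
    n_valid <- max(1L, round(control$valid_fraction * n))
    valid_idx <- idx[seq_len(n_valid)]
    valid_data <- subset_dataset(data, valid_idx)
    train_data <- subset_dataset(data, idx[-seq_len(n_valid)])
  } else if (inherits(valid, "ddg_dataset")) {
    train_data <- data
    valid_data <- valid
  } else {
    valid_idx <- valid
    valid_data <- subset_dataset(data, valid_idx)
    train_data <- subset_dataset(data, setdiff(seq_len(nrow(data$G)),
                                               valid_idx))
  }
  if (nrow(train_data$G) == 0L) stopf("empty training fold")
  if (nrow(valid_data$G) == 0L) stopf("empty validation fold")

  sg <- column_scales(train_data$G)
  sl <- column_scales(train_data$R)
  Xg <- scale_columns(train_data$G, sg)
  Xl <- scale_columns(train_data$R, sl)
  y <- train_data$variants$ddg
  Vg <- scale_columns(valid_data$G, sg)
  Vl <- scale_columns(valid_data$R, sl)
  vy <- valid_data$variants$ddg

  n <- nrow(Xg)
  bs <- min(control$batch_size, n)

  fit <- with_seed(control$seed, {
    net <- nn_init(data$d, control)
    opt <- adam_init(net$par)
    best <- list(rmse = Inf, par = net$par, bn = net$bn, epoch = 0L)
    hist <- vector("list", control$max_epochs)
    stall <- 0L
    for (epoch in seq_len(control$max_epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (start in seq(1L, n, by = bs)) {
        b <- ord[start:min(start + bs - 1L, n)]
        fw <- nn_forward(net, Xg[b, , drop = FALSE], Xl[b, , drop = FALSE],
                         train = TRUE)
        net <- fw$net
        err <- fw$yhat - y[b]
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          stopf("non-finite loss at epoch %d (lr too high or bad inputs)",
                epoch)
        }
        tot <- tot + loss * length(b)
        grads <- nn_backward(net, fw$cache, 2 * err / length(b))
        upd <- adam_step(net$par, grads, opt, control$lr)
        net$par <- upd$par
        opt <- upd$state
      }
      vp <- nn_forward(net, Vg, Vl, train = FALSE)$yhat
      vrmse <- sqrt(mean((vp - vy)^2))
      hist[[epoch]] <- c(epoch = epoch, train_loss = tot / n,
                         valid_rmse = vrmse)
      if (control$verbose) {
        message(sprintf("epoch %3d  train mse %.4f  valid rmse %.4f",
                        epoch, tot / n, vrmse))
      }
      if (vrmse < best$rmse - 1e-8) {
        best <- list(rmse = vrmse, par = net$par, bn = net$bn, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= control$patience) break
      }
    }
    net$par <- best$par
    net$bn <- best$bn
    list(net = net, best = best,
         history = as.data.frame(do.call(rbind, hist[!vapply(hist, is.null,
                                                             TRUE)])))
  })

  net <- fit$net
  train_pred <- nn_forward(net, Xg, Xl, train = FALSE)$yhat
  structure(
    list(net = net, control = control, d = data$d,
         scale = list(g = sg, l = sl),
         meta = data$meta,
         history = fit$history, best_epoch = fit$best$epoch,
         valid_rmse = fit$best$rmse,
         n_train = n, n_valid = length(vy),
         train_pred = train_pred, train_y = y,
         call = match.call()),
    class = "ddg_model"
  )
}

#' Predict ddG for featurized variants
#'
#' Evaluation-mode prediction (BatchNorm uses running statistics), a pure
#' function of the parameters and the input: repeated calls and any batch
#' decomposition give identical numbers.
#'
#' @param object A `"ddg_model"`.
#' @param newdata A `"ddg_dataset"`.
#' @param ... Unused.
#' @return Numeric vector of predicted ddG (kcal/mol), one per row.
#' @export
predict.ddg_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "ddg_dataset"))
  check_feature_meta(object$meta, newdata$meta)
  if (newdata$d != object$d) {
    stopf("model expects d = %d global features, data has %d",
          object$d, newdata$d, class = "ddg_version_mismatch")
  }
  Xg <- scale_columns(newdata$G, object$scale$g)
  Xl <- scale_columns(newdata$R, object$scale$l)
  nn_forward(object$net, Xg, Xl, train = FALSE)$yhat
}

check_feature_meta <- function(model_meta, data_meta) {
  for (f in c("provider_id", "annotator_id", "aap_version")) {
    a <- model_meta[[f]]; b <- data_meta[[f]]
    if (!is.null(a) && !is.null(b) && !identical(a, b)) {
      stopf("feature version mismatch (%s: model '%s' vs data '%s')",
            f, a, b, class = "ddg_version_mismatch")
    }
  }
  invisible(TRUE)
}

#' @export
print.ddg_model <- function(x, ...) {
  cat(sprintf("<ddg_model> fusion = %s, ablation = %s, d = %d\n",
              x$control$fusion, x$control$ablation, x$d))
  cat(sprintf("  trained %d epochs (best %d), held-out RMSE %.3f kcal/mol\n",
              nrow(x$history), x$best_epoch, x$valid_rmse))
  invisible(x)
}

#' @export
summary.ddg_model <- function(object, ...) {
  npar <- sum(vapply(object$net$par, length, 0L))
  res <- object$train_y - object$train_pred
  out <- list(
    fusion = object$control$fusion, ablation = object$control$ablation,
    d = object$d, n_par = npar, n_train = object$n_train,
    n_valid = object$n_valid, epochs = nrow(object$history),
    best_epoch = object$best_epoch, valid_rmse = object$valid_rmse,
    train_rmse = sqrt(mean(res^2)),
    train_pcc = if (length(res) > 1) stats::cor(object$train_pred,
                                                object$train_y) else NA_real_
  )
  class(out) <- "summary.ddg_model"
  out
}

#' @export
print.summary.ddg_model <- function(x, ...) {
  cat(sprintf("ddG fusion regressor (%s fusion, %s)\n", x$fusion, x$ablation))
  cat(sprintf("  parameters: %d | global feature width d = %d\n",
              x$n_par, x$d))
  cat(sprintf("  training:   n = %d, %d epochs (best %d)\n",
              x$n_train, x$epochs, x$best_epoch))
  cat(sprintf("  train RMSE %.3f, train PCC %.3f\n", x$train_rmse,
              x$train_pcc))
  cat(sprintf("  held-out RMSE %.3f kcal/mol (n = %d)\n", x$valid_rmse,
              x$n_valid))
  invisible(x)
}

#' Fusion weights of a fitted model
#'
#' For linear-combination fusion, the learnable element-wise weights of the
#' global and local branch, named `g_weight_1..128` and `r_weight_1..128`.
#'
#' @param object A `"ddg_model"`.
#' @param ... Unused.
#' @return Named numeric vector of length 256 (or `NULL` with a warning
#'   for other fusion modes).
#' @export
coef.ddg_model <- function(object, ...) {
  if (object$control$fusion != "linear_combination") {
    warnf("model has no fusion weights (fusion mode '%s')",
          object$control$fusion)
    return(NULL)
  }
  stats::setNames(c(object$net$par$fu_g, object$net$par$fu_r),
                  c(paste0("g_weight_", seq_len(ENC_DIM)),
                    paste0("r_weight_", seq_len(ENC_DIM))))
}

#' @export
residuals.ddg_model <- function(object, ...) {
  object$train_y - object$train_pred
}

#' @export
plot.ddg_model <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$valid_rmse, type = "l", xlab = "epoch",
                 ylab = "RMSE / loss",
                 main = "training trajectory", ...)
  graphics::lines(h$epoch, sqrt(h$train_loss), lty = 2)
  graphics::abline(v = x$best_epoch, col = "grey60", lty = 3)
  graphics::legend("topright", legend = c("held-out RMSE", "sqrt train MSE"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

# ---- fold ensembles ---------------------------------------------------------

#' Cross-validated fold ensemble
#'
#' Trains one model per fold (training on the other folds, early-stopping
#' and reporting on the held-out fold) and returns a `"ddg_ensemble"` whose
#' predictions are the arithmetic mean of the member models'.
#'
#' @param data A `"ddg_dataset"`; fold labels are taken from
#'   `data$variants$fold` unless `folds` is given.
#' @param control A [ddg_control()]; each fold model derives its seed from
#'   `control$seed` and the fold label.
#' @param folds Optional integer vector of fold labels, one per row.
#' @return A `"ddg_ensemble"` with elements `models` (one `"ddg_model"` per
#'   fold) and `cv_report` (per-fold n, PCC, RMSE plus their means).
#' @export
ddg_cv <- function(data, control = ddg_control(), folds = NULL) {
  stopifnot(inherits(data, "ddg_dataset"))
  folds <- folds %||% data$variants$fold
  if (is.null(folds) || anyNA(folds)) {
    stopf("fold labels are required (assign with homology_fold_split())")
  }
  folds <- as.integer(folds)
  labels <- sort(unique(folds))
  models <- list()
  rows <- list()
  for (f in labels) {
    hold <- which(folds == f)
    if (length(hold) == nrow(data$G)) stopf("fold %d holds every record", f)
    if (length(hold) == 0L) stopf("fold %d is empty", f)
    ctl <- control
    ctl$seed <- as.integer(hash_ints(c(control$seed, f)) %% 2147483647)
    m <- ddg_fit(data, ctl, valid = hold)
    p <- predict(m, subset_dataset(data, hold))
    yv <- data$variants$ddg[hold]
    models[[as.character(f)]] <- m
    rows[[as.character(f)]] <- data.frame(
      fold = f, n = length(hold),
      pcc = pcc(p, yv), rmse = rmse(p, yv)
    )
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(models = models, cv_report = report, control = control,
                 meta = data$meta, d = data$d),
            class = "ddg_ensemble")
}

#' @export
print.ddg_ensemble <- function(x, ...) {
  cat(sprintf("<ddg_ensemble> %d fold models (%s fusion)\n",
              length(x$models), x$control$fusion))
  print(x$cv_report, row.names = FALSE)
  cat(sprintf("  mean PCC %.3f | mean RMSE %.3f kcal/mol\n",
              mean(x$cv_report$pcc), mean(x$cv_report$rmse)))
  invisible(x)
}

#' @export
predict.ddg_ensemble <- function(object, newdata, ...) {
  stopifnot(length(object$models) >= 1L)
  archs <- unique(vapply(object$models, function(m) {
    paste(m$d, m$control$fusion, m$control$ablation)
  }, ""))
  if (length(archs) != 1L) stopf("ensemble members differ in architecture")
  preds <- vapply(object$models, predict, numeric(nrow(newdata$G)),
                  newdata = newdata)
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

# ---- checkpoints ------------------------------------------------------------

CHECKPOINT_FORMAT <- 1L

#' Save / load a model checkpoint
#'
#' Checkpoints carry every parameter tensor, the training configuration,
#' the feature-provenance metadata (embedding provider id, annotation
#' provider id, property-table version) and a format-version field.
#' Loading a checkpoint whose feature versions disagree with the data they
#' are used on is an error, not a warning.
#'
#' @param model A `"ddg_model"`.
#' @param path Destination file.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `"ddg_model"`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ddg_model"))
  obj <- unclass(model)
  obj$format_version <- CHECKPOINT_FORMAT
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stopf("checkpoint not found: %s", path, class = "ddg_missing_input")
  }
  obj <- readRDS(path)
  if (!identical(obj$format_version, CHECKPOINT_FORMAT)) {
    stopf("unsupported checkpoint format version '%s'",
          paste(obj$format_version, collapse = ","),
          class = "ddg_version_mismatch")
  }
  obj$format_version <- NULL
  class(obj) <- "ddg_model"
  obj
}
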