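#' Performance metrics from confusion counts
#'
#' Computes sensitivity `Sn = TP / (TP + FN)`, specificity
#' `Sp = TN / (TN + FP)`, accuracy `Acc = (TP + TN) / N` and the
#' Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FN)(TP+FP)(TN+FP))`.
#' When any factor of the MCC denominator is zero the coefficient is
#' reported as 0 with `mcc_degenerate = TRUE`.
#'
#' @param tp,tn,fp,fn non-negative integer counts (true/false
#'   positives/negatives); at least one must be positive.
#' @param protocol free-text tag of the evaluation protocol.
#' @return an object of class `dhs_metrics`: `sn`, `sp`, `acc` in
#'   `[0, 1]`, `mcc` in `[-1, 1]`, `mcc_degenerate`, `counts`,
#'   `protocol`.
#' @export
compute_metrics <- function(tp, tn, fp, fn, protocol = "holdout") {
  counts <- c(tp = unname(tp), tn = unname(tn), fp = unname(fp),
              fn = unname(fn))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  counts <- as.integer(counts)
  names(counts) <- c("tp", "tn", "fp", "fn")
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  if (sum(counts) == 0) stop("no evaluated examples (all counts zero)")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / sum(counts)
  denom2 <- prod(as.numeric(c(tp + fn, tn + fn, tp + fp, tn + fp)))
  degenerate <- denom2 == 0
  mcc <- if (degenerate) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom2)
  structure(list(sn = sn, sp = sp, acc = acc, mcc = mcc,
                 mcc_degenerate = degenerate, counts = counts,
                 protocol = protocol),
            class = "dhs_metrics")
}

#' @export
print.dhs_metrics <- function(x, ...) {
  cat("<dhs_metrics> protocol: ", x$protocol, "\n", sep = "")
  cat(sprintf("  TP = %d  FN = %d  TN = %d  FP = %d\n",
              x$counts["tp"], x$counts["fn"], x$counts["tn"],
              x$counts["fp"]))
  cat(sprintf("  Sn = %.2f%%  Sp = %.2f%%  Acc = %.2f%%  MCC = %.2f%s\n",
              100 * x$sn, 100 * x$sp, 100 * x$acc, x$mcc,
              if (x$mcc_degenerate) " (degenerate denominator)" else ""))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param metrics a `dhs_metrics` object.
#' @param path output file path.
#' @param extra optional named list merged into the record (e.g. the
#'   [model_params()] and seed used).
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path, extra = list()) {
  rec <- c(list(protocol = metrics$protocol,
                counts = as.list(metrics$counts),
                sn = metrics$sn, sp = metrics$sp, acc = metrics$acc,
                mcc = metrics$mcc,
                mcc_degenerate = metrics$mcc_degenerate),
           extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Aggregate held-out predictions into confusion counts.
tally_counts <- function(truth_pos, pred_pos) {
  c(tp = sum(truth_pos & pred_pos), tn = sum(!truth_pos & !pred_pos),
    fp = sum(!truth_pos & pred_pos), fn = sum(truth_pos & !pred_pos))
}

#' Jackknife (leave-one-out) evaluation
#'
#' Each sequence is in turn held out; the SVM is retrained on the
#' remaining `N - 1` encoded sequences with all four parameters frozen
#' at `params` (no re-optimization inside the loop) and the held-out
#' sequence is predicted. Counts are aggregated over all `N` rounds.
#' The protocol involves no randomness.
#'
#' @param data a fully labeled [dhs_dataset()] with `>= 2` examples per
#'   class.
#' @param params a [model_params()].
#' @param table a [property_table()].
#' @return a `dhs_metrics` report (`protocol = "jackknife"`).
#' @export
jackknife <- function(data, params = model_params(),
                      table = default_property_table()) {
  stopifnot(inherits(params, "model_params"))
  enc <- encode_dataset(data, w = params$w, lambda = params$lambda,
                        table = ensure_standardized(table))
  y <- enc$labels
  if (anyNA(y)) stop("jackknife requires a fully labeled dataset")
  if (min(sum(y > 0), sum(y < 0)) < 2)
    stop("need at least 2 examples per class")
  n <- length(y)
  pred_pos <- logical(n)
  for (i in seq_len(n)) {
    model <- tryCatch(
      svm_train(enc$features[-i, , drop = FALSE], y[-i],
                params$C, params$gamma),
      error = function(e) stop("jackknife round ", i, " (id '",
                               enc$ids[i], "'): ", conditionMessage(e),
                               call. = FALSE))
    pred_pos[i] <-
      predict(model, enc$features[i, , drop = FALSE])$label == "positive"
  }
  cnt <- tally_counts(y > 0, pred_pos)
  compute_metrics(cnt["tp"], cnt["tn"], cnt["fp"], cnt["fn"],
                  protocol = "jackknife")
}

#' Stratified k-fold cross-validated evaluation
#'
#' Stratified folds are drawn from `seed`; each fold is predicted by a
#' model trained on the others with parameters frozen at `params`.
#' With `k = N` every fold is a singleton and the counts coincide with
#' [jackknife()].
#'
#' @param data a fully labeled [dhs_dataset()].
#' @param params a [model_params()].
#' @param table a [property_table()].
#' @param k fold count, `>= 2` and at most the minority class size
#'   (or exactly `N`).
#' @param seed integer seed for the fold assignment.
#' @return a `dhs_metrics` report (`protocol = "kfold"`).
#' @export
kfold <- function(data, params = model_params(),
                  table = default_property_table(), k = 5, seed = 0) {
  stopifnot(inherits(params, "model_params"))
  enc <- encode_dataset(data, w = params$w, lambda = params$lambda,
                        table = ensure_standardized(table))
  y <- enc$labels
  if (anyNA(y)) stop("k-fold requires a fully labeled dataset")
  fold_id <- stratified_folds(y, k, seed)
  pred_pos <- logical(length(y))
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    model <- svm_train(enc$features[!test, , drop = FALSE], y[!test],
                       params$C, params$gamma)
    pred_pos[test] <-
      predict(model, enc$features[test, , drop = FALSE])$label == "positive"
  }
  cnt <- tally_counts(y > 0, pred_pos)
  compute_metrics(cnt["tp"], cnt["tn"], cnt["fp"], cnt["fn"],
                  protocol = "kfold")
}
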