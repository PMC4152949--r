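#' Model parameter tuple
#'
#' Bundles the four jointly-optimized parameters of the predictor: the
#' PseDNC weight `w` and tier count `lambda`, and the SVM cost `C` and
#' RBF kernel width `gamma`.
#'
#' @param w weight factor in `[0, 1]`.
#' @param lambda tier count, integer `>= 1`.
#' @param C SVM regularization (cost) parameter, `> 0`.
#' @param gamma RBF kernel width, `> 0`; the kernel is
#'   `K(x, y) = exp(-gamma * ||x - y||^2)`.
#' @return an object of class `model_params`.
#' @export
model_params <- function(w = 0.2, lambda = 6, C = 512, gamma = 2^-7) {
  if (!is.numeric(w) || w < 0 || w > 1) stop("`w` must be in [0, 1]")
  lambda <- check_lambda(lambda)
  if (!is.numeric(C) || C <= 0) stop("`C` must be > 0")
  if (!is.numeric(gamma) || gamma <= 0) stop("`gamma` must be > 0")
  structure(list(w = w, lambda = lambda, C = C, gamma = gamma),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> w = %g, lambda = %d, C = %g, gamma = %g\n",
              x$w, x$lambda, x$C, x$gamma))
  invisible(x)
}

#' Train the RBF-kernel SVM
#'
#' Thin wrapper around the libsvm solver ([e1071::svm()]) with the
#' radial kernel `exp(-gamma * ||x - y||^2)`. Features are used as-is
#' (PseDNC components already lie in `[0, 1]` and sum to 1, so no
#' re-scaling is applied) and no class weighting is used.
#'
#' @param features numeric matrix, one row per example.
#' @param labels numeric `+1` / `-1` labels (one example of each class
#'   required).
#' @param C,gamma SVM cost and kernel width, both `> 0`.
#' @return an object of class `dhs_svm`.
#' @importFrom e1071 svm
#' @export
svm_train <- function(features, labels, C = 512, gamma = 2^-7) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels))
    stop("`labels` length must equal the number of feature rows")
  if (!all(labels %in% c(-1, 1)))
    stop("labels must be +1 / -1")
  if (length(unique(labels)) < 2L)
    stop("training requires at least one example of each class")
  if (C <= 0 || gamma <= 0) stop("`C` and `gamma` must be > 0")
  y <- factor(ifelse(labels > 0, "positive", "negative"),
              levels = c("positive", "negative"))
  fit <- e1071::svm(x = features, y = y, type = "C-classification",
                    kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, C = C, gamma = gamma,
                 feature_dim = ncol(features)),
            class = "dhs_svm")
}

#' Predict class labels and decision values
#'
#' Applies the sign of the SVM decision function; a decision value of
#' exactly 0 is resolved to the positive class. Decision values are
#' oriented so that positive values favor the DHS (positive) class.
#'
#' @param object a `dhs_svm` model.
#' @param features numeric matrix with `object$feature_dim` columns.
#' @param ... unused.
#' @return data.frame with columns `label` (`"positive"`/`"negative"`)
#'   and `decision_value`.
#' @export
predict.dhs_svm <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != object$feature_dim)
    stop("feature dimension mismatch: model expects ", object$feature_dim,
         " columns, got ", ncol(features))
  pr <- stats::predict(object$fit, features, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # libsvm orients decision values toward the first class seen in
  # training; flip if that was "negative" so positive dv => positive call
  if (colnames(dv)[1] == "negative/positive") dv <- -dv
  dv <- as.numeric(dv)
  data.frame(label = factor(ifelse(dv >= 0, "positive", "negative"),
                            levels = c("positive", "negative")),
             decision_value = dv,
             row.names = rownames(features))
}

#' Joint grid search over (w, lambda, C, gamma)
#'
#' For every `(w, lambda)` pair the dataset is encoded once; every
#' `(C, gamma)` pair is then scored by stratified k-fold cross-validated
#' accuracy with a shared, seed-determined fold assignment. The default
#' grids are `w` in 0, 0.1, ..., 1; `lambda` in 1..10; `C` in
#' `2^-5 ... 2^15`; `gamma` in `2^-15 ... 2^-5` (exponent step 1).
#' Ties in accuracy are broken toward the simplest model: smaller `C`,
#' then smaller `gamma`, then smaller `lambda`, then smaller `w`.
#'
#' @param data a labeled [dhs_dataset()].
#' @param table a [property_table()].
#' @param w_grid,lambda_grid,C_grid,gamma_grid numeric grids.
#' @param folds number of CV folds (must not exceed the minority class
#'   size).
#' @param seed integer seed controlling the fold assignment.
#' @return list with `best` (a [model_params()]), `best_acc`, and
#'   `results` (data.frame of `w`, `lambda`, `C`, `gamma`, `acc`).
#' @export
grid_search <- function(data, table = default_property_table(),
                        w_grid = seq(0, 1, by = 0.1),
                        lambda_grid = 1:10,
                        C_grid = 2^(-5:15),
                        gamma_grid = 2^(-15:-5),
                        folds = 5, seed = 0) {
  stopifnot(inherits(data, "dhs_dataset"))
  table <- ensure_standardized(table)
  y <- ifelse(data$label == "positive", 1, -1)
  if (anyNA(y)) stop("grid search requires a fully labeled dataset")
  fold_id <- stratified_folds(y, folds, seed)
  res <- vector("list", length(w_grid) * length(lambda_grid))
  k <- 0L
  for (lam in lambda_grid) for (w in w_grid) {
    enc <- encode_dataset(data, w = w, lambda = lam, table = table)
    grid <- expand.grid(C = C_grid, gamma = gamma_grid)
    grid$acc <- vapply(seq_len(nrow(grid)), function(g)
      cv_accuracy(enc$features, y, fold_id, grid$C[g], grid$gamma[g]),
      numeric(1))
    grid$w <- w; grid$lambda <- lam
    k <- k + 1L
    res[[k]] <- grid
  }
  results <- do.call(rbind, res)[, c("w", "lambda", "C", "gamma", "acc")]
  ord <- order(-results$acc, results$C, results$gamma, results$lambda,
               results$w)
  best <- results[ord[1L], ]
  list(best = model_params(best$w, best$lambda, best$C, best$gamma),
       best_acc = best$acc, results = results)
}

cv_accuracy <- function(features, y, fold_id, C, gamma) {
  correct <- 0L
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    model <- svm_train(features[!test, , drop = FALSE], y[!test], C, gamma)
    pred <- predict(model, features[test, , drop = FALSE])
    correct <- correct +
      sum((pred$label == "positive") == (y[test] > 0))
  }
  correct / length(y)
}

# Stratified fold assignment: shuffle each class under the seed, then
# deal the concatenated order round-robin style into k folds. With
# k = N every fold is a singleton, making k-fold coincide with the
# jackknife.
stratified_folds <- function(y, k, seed) {
  n <- length(y)
  if (k < 2) stop("`folds` must be >= 2")
  if (k > min(table(y)) && k != n)
    stop("fold count ", k, " exceeds the minority class size")
  with_local_seed(seed, {
    ord <- c(sample(which(y > 0)), sample(which(y < 0)))
    fold_id <- integer(n)
    fold_id[ord] <- rep_len(seq_len(k), n)
    fold_id
  })
}

#' Save / load a trained predictor
#'
#' The archive stores the trained solver state together with the
#' [model_params()] and the checksum of the property table used for
#' encoding; [load_model()] refuses nothing, but [predict_dataset()]
#' refuses to run when the supplied table's checksum differs from the
#' training-time one.
#'
#' @param model a `dhs_svm` model.
#' @param params the [model_params()] used to train it.
#' @param table the [property_table()] used for encoding.
#' @param path file path for the archive.
#' @return `path` ([save_model()]) or the archive list ([load_model()]).
#' @export
save_model <- function(model, params, table, path) {
  saveRDS(list(model = model, params = params,
               table_checksum = property_checksum(table),
               package_version = as.character(utils::packageVersion("psedhs"))),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  archive <- readRDS(path)
  stopifnot(inherits(archive$model, "dhs_svm"),
            inherits(archive$params, "model_params"))
  archive
}

#' Predict a dataset with a saved predictor archive
#'
#' @param archive result of [load_model()] (or the list from
#'   [save_model()]'s inputs).
#' @param data a [dhs_dataset()].
#' @param table the [property_table()] to encode with; its checksum must
#'   match the training-time table.
#' @return data.frame `id`, `label`, `decision_value`.
#' @export
predict_dataset <- function(archive, data, table = default_property_table()) {
  if (!identical(property_checksum(table), archive$table_checksum))
    stop("property table checksum differs from the table used at ",
         "training time; refusing to predict")
  enc <- encode_dataset(data, w = archive$params$w,
                        lambda = archive$params$lambda, table = table)
  pred <- predict(archive$model, enc$features)
  data.frame(id = data$id, label = pred$label,
             decision_value = pred$decision_value, row.names = NULL)
}
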