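tab <- default_property_table()

# Linearly separable 22-dim toy problem with a wide margin.
separable_features <- function(n, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n * 22, 0, 0.02), n, 22)
  y <- rep(c(1, -1), length.out = n)
  x[y > 0, 1] <- x[y > 0, 1] + 0.5
  list(x = x, y = y)
}

test_that("training solves separable problems and validates inputs", {
  p <- separable_features(100)
  model <- svm_train(p$x, p$y, C = 512, gamma = 2^-7)
  pred <- predict(model, p$x)
  expect_equal(ifelse(pred$label == "positive", 1, -1), p$y)

  expect_error(svm_train(p$x, rep(1, 100)), "each class")
  expect_error(svm_train(p$x, p$y, C = -1), "> 0")
  expect_error(svm_train(p$x[1:10, ], p$y), "length")
})

test_that("two well-separated single points are both recovered", {
  x <- rbind(c(rep(0, 21), 1), c(rep(0.9, 21), 0))
  model <- svm_train(x, c(1, -1), C = 512, gamma = 2^-7)
  pred <- predict(model, x)
  expect_equal(as.character(pred$label), c("positive", "negative"))
})

test_that("prediction enforces feature dimension and the sign tie-break", {
  p <- separable_features(40)
  model <- svm_train(p$x, p$y, C = 512, gamma = 2^-7)
  expect_error(predict(model, p$x[, 1:21]), "22.*21")
  pred <- predict(model, p$x)
  expect_true(all((pred$decision_value >= 0) == (pred$label == "positive")))
})

test_that("retraining on identical inputs gives identical predictions", {
  p <- separable_features(60, seed = 4)
  m1 <- svm_train(p$x, p$y, C = 8, gamma = 0.5)
  m2 <- svm_train(p$x, p$y, C = 8, gamma = 0.5)
  expect_identical(predict(m1, p$x)$decision_value,
                   predict(m2, p$x)$decision_value)
})

test_that("grid search returns the argmax with documented tie-breaking and is order-invariant", {
  d <- simulate_dhs_dataset(n_pos = 25, n_neg = 25, delta = 3,
                            length_min = 80, length_max = 120, seed = 2)
  gs <- grid_search(d, tab, w_grid = c(0, 0.2), lambda_grid = c(1, 4),
                    C_grid = 2^c(1, 9), gamma_grid = 2^c(-7, -3),
                    folds = 5, seed = 0)
  expect_true(all(gs$results$acc >= 0 & gs$results$acc <= 1))
  expect_equal(nrow(gs$results), 2 * 2 * 2 * 2)
  expect_equal(gs$best_acc, max(gs$results$acc))
  # tie-break: simplest model among ties
  ties <- gs$results[gs$results$acc == gs$best_acc, ]
  ord <- order(ties$C, ties$gamma, ties$lambda, ties$w)
  expect_equal(unlist(ties[ord[1], c("w", "lambda", "C", "gamma")]),
               c(w = gs$best$w, lambda = gs$best$lambda, C = gs$best$C,
                 gamma = gs$best$gamma))
  # reversing grid enumeration order leaves the argmax unchanged
  gs2 <- grid_search(d, tab, w_grid = c(0.2, 0), lambda_grid = c(4, 1),
                     C_grid = 2^c(9, 1), gamma_grid = 2^c(-3, -7),
                     folds = 5, seed = 0)
  expect_equal(gs2$best, gs$best)
  # strongly separated data reaches high CV accuracy somewhere on the grid
  expect_gte(gs$best_acc, 0.95)
})

test_that("degenerate one-point grid returns that point", {
  d <- simulate_dhs_dataset(n_pos = 15, n_neg = 15, delta = 2,
                            length_min = 60, length_max = 80, seed = 3)
  gs <- grid_search(d, tab, w_grid = 0.2, lambda_grid = 6,
                    C_grid = 512, gamma_grid = 2^-7, folds = 3, seed = 1)
  expect_equal(gs$best, model_params(0.2, 6, 512, 2^-7))
  expect_equal(nrow(gs$results), 1L)
})

test_that("fold count exceeding the minority class size errors", {
  d <- simulate_dhs_dataset(n_pos = 3, n_neg = 30, delta = 1,
                            length_min = 50, length_max = 60, seed = 5)
  expect_error(grid_search(d, tab, w_grid = 0, lambda_grid = 1,
                           C_grid = 1, gamma_grid = 0.1, folds = 5),
               "minority")
})

test_that("model archives round-trip and predicting checks the table checksum", {
  d <- simulate_dhs_dataset(n_pos = 15, n_neg = 15, delta = 3,
                            length_min = 60, length_max = 80, seed = 6)
  params <- model_params(0.2, 6, 512, 2^-7)
  enc <- encode_dataset(d, params$w, params$lambda, tab)
  model <- svm_train(enc$features, enc$labels, params$C, params$gamma)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(model, params, tab, f)
  archive <- load_model(f)
  pred <- predict_dataset(archive, d, tab)
  expect_equal(nrow(pred), 30L)
  expect_named(pred, c("id", "label", "decision_value"))

  other <- standardize_properties(toy_property_table())
  expect_error(predict_dataset(archive, d, other), "checksum")
})
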