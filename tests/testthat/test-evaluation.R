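test_that("metric formulas match hand-computed values", {
  m <- compute_metrics(list(TP = 93, FN = 7, TN = 85, FP = 15))
  expect_equal(m$accuracy, 0.89)
  expect_equal(m$sensitivity, 0.93)
  expect_equal(m$specificity, 0.85)

  m2 <- compute_metrics(list(TP = 25, TN = 25, FP = 25, FN = 25))
  expect_equal(m2$accuracy, 0.5)

  # empty denominator is reported as absent, not zero
  m3 <- compute_metrics(list(TP = 80, FN = 20, TN = 0, FP = 0))
  expect_equal(m3$sensitivity, 0.8)
  expect_true(is.na(m3$specificity))

  expect_error(compute_metrics(list(TP = -1, TN = 1, FP = 1, FN = 1)),
               "non-negative")
  expect_error(compute_metrics(list(TP = 1)), "must provide")
})

test_that("stratified folds balance every class to within one sample", {
  y <- rep(c("mass", "non-mass"), c(25, 15))
  f <- stratified_kfold(y, k = 5, seed = 1)
  expect_length(f, 40L)
  expect_true(all(sort(unique(f)) == 1:5))
  tab <- table(y, f)
  expect_true(all(tab["mass", ] == 5))
  expect_true(all(tab["non-mass", ] == 3))

  # 5 + 5 samples into 5 folds: one of each class per fold
  f2 <- stratified_kfold(rep(c("a", "b"), each = 5), k = 5, seed = 2)
  expect_true(all(table(rep(c("a", "b"), each = 5), f2) == 1))

  expect_identical(stratified_kfold(y, 5, seed = 9),
                   stratified_kfold(y, 5, seed = 9))
  expect_false(identical(stratified_kfold(y, 5, seed = 9),
                         stratified_kfold(y, 5, seed = 10)))
  expect_error(stratified_kfold(rep(c("a", "b"), c(3, 20)), k = 5), "fewer than")
})

test_that("cross-validation bookkeeping covers every sample exactly once", {
  d <- generate_dataset(c(mass = 24, `non-mass` = 16), synth_params(seed = 5))
  r <- crossvalidate(d, extractor_pca(), 4, k = 4, seed = 2)
  expect_s3_class(r, "cad_eval")
  expect_equal(nrow(r$per_fold), 4L)
  # each sample appears in exactly one test fold
  expect_equal(sum(r$per_fold$TP + r$per_fold$TN + r$per_fold$FP + r$per_fold$FN),
               40)
  expect_true(all(r$per_fold$TP + r$per_fold$FN == 6))   # 24 mass / 4 folds
  expect_true(all(r$per_fold$TN + r$per_fold$FP == 4))
  # means are the arithmetic fold means
  expect_equal(r$mean_accuracy, mean(r$per_fold$accuracy), tolerance = 1e-12)
  expect_equal(r$mean_sensitivity, mean(r$per_fold$sensitivity), tolerance = 1e-12)
  # metric identity: accuracy = (sens*P + spec*N) / (P + N) per fold
  with(r$per_fold, expect_equal(
    accuracy, (sensitivity * (TP + FN) + specificity * (TN + FP)) / 10,
    tolerance = 1e-12))
})

test_that("chance-level data give chance-level accuracy (no leakage)", {
  d <- generate_dataset(c(mass = 40, `non-mass` = 40),
                        synth_params(seed = 7, blob_contrast = 0))
  r <- crossvalidate(d, extractor_pca(), 5, k = 5, seed = 3)
  expect_lt(abs(r$mean_accuracy - 0.5), 0.17)
})

test_that("benign/malignant datasets run through the identical machinery", {
  d <- generate_dataset(c(benign = 20, malignant = 20), synth_params(seed = 9))
  r <- crossvalidate(d, extractor_pca(), 4, k = 4, seed = 1)
  expect_equal(r$config$positive_class, "malignant")
  expect_equal(sum(r$per_fold$TP + r$per_fold$TN + r$per_fold$FP + r$per_fold$FN),
               40)
})

test_that("the component sweep reuses the greedy prefix consistently", {
  d <- generate_dataset(c(mass = 30, `non-mass` = 30),
                        synth_params(seed = 10, blob_contrast = 1.2))
  rng <- c(1, 2, 4, 6)
  sw <- component_sweep(d, extractor_gabor(gabor_params(n_scales = 3,
                                                        n_orientations = 3)),
                        rng, k = 3, seed = 4)
  expect_s3_class(sw, "cad_sweep")
  expect_equal(nrow(sw), length(rng))
  expect_equal(sw$n_components, rng)
  expect_true(all(c("method", "accuracy", "sensitivity", "specificity")
                  %in% names(sw)))
  # the sweep row at count n equals a direct CV run at the same n and seed
  ex <- extractor_gabor(gabor_params(n_scales = 3, n_orientations = 3))
  direct <- crossvalidate(d, ex, 6, k = 3, seed = 4)
  expect_equal(sw$accuracy[sw$n_components == 6], direct$mean_accuracy,
               tolerance = 1e-12)
  # argmax over the table is well-defined
  expect_true(is.finite(sw$n_components[which.max(sw$accuracy)]))
})

test_that("cross-validation validates labels and propagates fold errors", {
  d <- generate_dataset(c(mass = 10, `non-mass` = 10, benign = 10),
                        synth_params(seed = 3))
  expect_error(crossvalidate(d, extractor_pca(), 3, k = 2), "binary")
})
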