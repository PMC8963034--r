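test_that("normalization centers, scales, and reduces as specified", {
  set.seed(12)
  X <- matrix(rnorm(200 * 10), 200)
  st <- fit_normalization(X)
  P <- apply_normalization(st, X)
  expect_lt(max(abs(colMeans(P))), 1e-10)       # PCA input was centred
  expect_gte(st$explained, 0.95)
  expect_lte(st$n_components, 10)

  # data in an exact 3-D subspace with balanced variance keep exactly 3
  # components (fewer would fall short of 95%, more add nothing)
  basis <- qr.Q(qr(matrix(rnorm(30), 10, 3)))
  scores <- matrix(rnorm(200 * 3), 200) %*% diag(c(1, 0.9, 0.8))
  st3 <- fit_normalization(scores %*% t(basis))
  expect_identical(st3$n_components, 3L)

  Xz <- cbind(X, 7)                             # constant column dropped
  expect_warning(stz <- fit_normalization(Xz), "zero-variance")
  expect_identical(length(stz$keep), 10L)

  expect_error(fit_normalization(X[integer(0), ]), "empty")
})

test_that("subject-wise folds partition with near-equal sizes", {
  f <- make_folds(1:22, k = 5, seed = 3)
  expect_identical(sort(as.integer(table(f)), decreasing = TRUE), c(5L, 5L, 4L, 4L, 4L))
  expect_identical(sort(unique(f)), 1:5)
  expect_identical(length(f), 22L)
  expect_false(any(duplicated(names(f))))

  loso <- make_folds(1:6, k = 6, seed = 1)
  expect_identical(sort(as.integer(table(loso))), rep(1L, 6))
  expect_error(make_folds(1:4, k = 5), "more folds")

  # seeded: reproducible, and different seeds differ
  expect_identical(make_folds(1:22, 5, seed = 3), f)
  expect_false(identical(make_folds(1:22, 5, seed = 4), f))
})

test_that("confusion-matrix metrics match hand computation and brute force", {
  ident <- diag(10, 7)
  m <- compute_metrics(ident)
  expect_equal(m$accuracy, 1)
  expect_equal(unname(m$precision), rep(1, 7))
  expect_equal(unname(m$recall), rep(1, 7))

  two <- matrix(c(8, 3, 2, 7), 2)  # rows true, cols predicted
  m2 <- compute_metrics(two)
  expect_equal(m2$precision[1], 8 / 11)
  expect_equal(m2$recall[1], 8 / 10)
  expect_equal(m2$accuracy, 15 / 20)

  set.seed(13)
  cm <- matrix(rpois(49, 5), 7)
  m3 <- compute_metrics(cm)
  for (cl in 1:7) {
    expect_equal(m3$precision[cl], cm[cl, cl] / sum(cm[, cl]))
    expect_equal(m3$recall[cl], cm[cl, cl] / sum(cm[cl, ]))
  }
  expect_equal(m3$accuracy, sum(diag(cm)) / sum(cm))

  z <- matrix(0, 3, 3); z[1, 1] <- 4
  expect_true(is.nan(compute_metrics(z)$precision[2]))
  expect_error(compute_metrics(matrix(c(-1, 0, 0, 1), 2)), "nonnegative")
})

test_that("the experiment runner completes and keeps bookkeeping consistent", {
  cfg <- small_cfg(n_subjects = 3, n_positions = 1, n_repetitions = 4, seed = 31L)
  coh <- generate_cohort(cfg)
  fm <- featurize_cohort(coh, window_stride = 6)
  ec <- experiment_config(k_folds = 3, classic_epochs = 15, bilinear_epochs = 15,
                          lssvm_max_train = 200, lssvm_max_cal = 200,
                          adapt_iterations = 30, window_stride = 6)
  res <- run_experiment(coh, methods = c("lssvm", "mlp"), modalities = "fused",
                        seed = 2, config = ec, features = fm)
  expect_s3_class(res, "result_table")
  expect_identical(nrow(res$per_subject), 6L)   # 3 subjects x 2 methods
  expect_true(all(res$per_subject$accuracy >= 0 & res$per_subject$accuracy <= 1))

  # confusion totals equal the number of test windows processed
  n_windows_total <- nrow(fm$values)
  cal_windows <- sum(res$confusions[["mlp.fused"]])
  expect_identical(cal_windows, n_windows_total)  # mlp tests every window
  # lssvm holds out 2 calibration repetitions of 4
  expect_identical(sum(res$confusions[["lssvm.fused"]]),
                   as.integer(round(n_windows_total * 2 / 4)))

  # determinism of the whole experiment given the root seed
  res2 <- run_experiment(coh, methods = "mlp", modalities = "fused",
                         seed = 2, config = ec, features = fm)
  expect_identical(res2$per_subject$accuracy,
                   res$per_subject$accuracy[res$per_subject$method == "mlp"])

  # shuffled truth against fixed predictions collapses to chance
  cm <- res$confusions[["mlp.fused"]]
  pred_counts <- colSums(cm); truth_counts <- rowSums(cm)
  expect_chance <- sum(pred_counts * truth_counts) / sum(cm)^2
  expect_lt(abs(expect_chance - 1 / 7), 0.05)
})
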