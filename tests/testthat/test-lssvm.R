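make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(c)
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[c, ], n_per, ncol(centers), byrow = TRUE)))
  list(X = X, y = rep(seq_len(nrow(centers)), each = n_per))
}

test_that("LS-SVM separates well-separated blobs and validates input", {
  b <- make_blobs(30, rbind(c(0, 0), c(4, 4)))
  m <- train_lssvm(b$X, b$y)
  expect_identical(predict(m, b$X), b$y)
  expect_error(train_lssvm(b$X, rep(1, 60)), "two classes")
})

test_that("tiny-instance dual solution matches an independent dense solve", {
  b <- make_blobs(8, rbind(c(0, 0), c(2, 2), c(-2, 2)), seed = 2)
  gamma <- 0.7; sigma <- 1.3
  m <- train_lssvm(b$X, b$y, gamma = gamma, sigma = sigma)

  # oracle: explicit kernel entries and one bordered solve per class
  n <- nrow(b$X)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    K[i, j] <- exp(-sum((b$X[i, ] - b$X[j, ])^2) / (2 * sigma^2))
  for (cl in 1:3) {
    yc <- ifelse(b$y == cl, 1, -1)
    M <- rbind(cbind(K + diag(n) / gamma, rep(1, n)), c(rep(1, n), 0))
    sol <- solve(M, c(yc, 0))
    expect_lt(max(abs(m$alpha[, cl] - sol[1:n])), 1e-8)
    expect_lt(abs(m$b[cl] - sol[n + 1]), 1e-8)
  }
})

test_that("decision scores shrink under heavy regularization and survive duplication", {
  b <- make_blobs(25, rbind(c(0, 0), c(3, 3)), seed = 3)
  spreads <- vapply(c(10, 1, 0.01, 1e-4), function(g)
    stats::sd(decision_scores(train_lssvm(b$X, b$y, gamma = g, sigma = 2), b$X)),
    0)
  expect_true(all(diff(spreads) < 0))

  # duplicating every point doubles each point's squared-error weight, so
  # the decision function is preserved exactly when gamma is halved
  m1 <- train_lssvm(b$X, b$y, gamma = 1, sigma = 2)
  m2 <- train_lssvm(rbind(b$X, b$X), c(b$y, b$y), gamma = 0.5, sigma = 2)
  grid <- as.matrix(expand.grid(seq(-1, 4, 0.5), seq(-1, 4, 0.5)))
  expect_lt(max(abs(decision_scores(m1, grid) - decision_scores(m2, grid))), 1e-6)
  expect_identical(predict(m1, grid), predict(m2, grid))
})

test_that("feature permutation with a matching model permutation preserves predictions", {
  b <- make_blobs(20, rbind(c(0, 0, 1), c(2, 2, -1)), seed = 4)
  perm <- c(3, 1, 2)
  m1 <- train_lssvm(b$X, b$y, sigma = 1.5)
  m2 <- train_lssvm(b$X[, perm], b$y, sigma = 1.5)
  newx <- matrix(rnorm(30), 10)
  expect_identical(predict(m1, newx), predict(m2, newx[, perm]))
})

test_that("the calibration split takes whole repetitions and stays disjoint", {
  cfg <- small_cfg(n_subjects = 1, n_positions = 2, n_repetitions = 10)
  fm <- featurize_cohort(generate_cohort(cfg), window_stride = 6)
  sp <- split_cal_test(fm, n_cal_reps = 2, seed = 1)
  expect_equal(nrow(sp$cal$values) / nrow(fm$values), 2 / 10)
  joint <- merge(unique(sp$cal$provenance[, c("gesture", "repetition")]),
                 unique(sp$test$provenance[, c("gesture", "repetition")]))
  expect_identical(nrow(joint), 0L)
  sp2 <- split_cal_test(fm, n_cal_reps = 2, seed = 2)
  expect_identical(nrow(sp2$cal$values), nrow(sp$cal$values))
  expect_false(identical(sp$cal_reps, sp2$cal_reps))

  cfg3 <- small_cfg(n_subjects = 1, n_positions = 1, n_repetitions = 2)
  fm3 <- featurize_cohort(generate_cohort(cfg3), window_stride = 6)
  expect_error(split_cal_test(fm3, 2), "repetitions")
})

test_that("prior ranking is error-ordered, permutation-stable, and finds lookalikes", {
  b_cal <- make_blobs(15, rbind(c(0, 0), c(3, 3), c(0, 3)), seed = 5)
  good <- train_lssvm(b_cal$X, b_cal$y, sigma = 1.5)
  b_off <- make_blobs(15, rbind(c(3, 0), c(0, 3), c(3, 3)), seed = 6)  # wrong geometry
  bad <- train_lssvm(b_off$X, b_off$y, sigma = 1.5)

  r <- select_best_prior(list(bad, good), b_cal$X, b_cal$y)
  expect_identical(r$prior[1], 2L)
  r2 <- select_best_prior(list(good, bad), b_cal$X, b_cal$y)
  expect_identical(r2$prior[1], 1L)
  expect_equal(sort(r$error), sort(r2$error))

  single <- select_best_prior(list(bad), b_cal$X, b_cal$y)
  expect_identical(single$prior, 1L)
  expect_error(select_best_prior(list(), b_cal$X, b_cal$y), "no prior")
})

test_that("adaptation respects the projection set and does not lose to the best prior", {
  b_cal <- make_blobs(12, rbind(c(0, 0), c(3, 3), c(0, 3)), seed = 7)
  priors <- list(train_lssvm(make_blobs(15, rbind(c(0, 0), c(3, 3), c(0, 3)), seed = 8)$X,
                             rep(1:3, each = 15), sigma = 1.5),
                 train_lssvm(make_blobs(15, rbind(c(3, 0), c(0, 3), c(3, 3)), seed = 9)$X,
                             rep(1:3, each = 15), sigma = 1.5))
  ad <- adapt_lssvm(priors, b_cal$X, b_cal$y, iterations = 100)
  expect_true(all(ad$beta >= 0))
  expect_true(all(sqrt(colSums(ad$beta^2)) <= 1 + 1e-10))

  cal_err_adapted <- mean(predict(ad, b_cal$X) != b_cal$y)
  cal_err_best <- min(vapply(priors, function(p)
    mean(predict(p, b_cal$X) != b_cal$y), 0))
  expect_lte(cal_err_adapted, cal_err_best + 0.05)

  # degenerate case: identical priors
  ad2 <- adapt_lssvm(list(priors[[1]], priors[[1]]), b_cal$X, b_cal$y, iterations = 50)
  expect_identical(predict(ad2, b_cal$X), predict(ad2, b_cal$X))
  expect_lte(mean(predict(ad2, b_cal$X) != b_cal$y), cal_err_best + 0.05)
})
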