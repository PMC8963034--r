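fm_stub <- function(values, labels = rep(1L, nrow(values))) {
  structure(list(values = values, labels = labels,
                 provenance = data.frame(subject = 1, gesture = labels,
                                         position = 1, repetition = 1,
                                         window = seq_len(nrow(values))),
                 feature_names = colnames(values)),
            class = "feature_matrix")
}

test_that("stacking preserves blocks and round-trips", {
  a <- fm_stub(matrix(1:20, 10, 2))
  b <- fm_stub(matrix(101:120, 10, 2))
  st <- stack_training_features(list(a, b))
  expect_identical(nrow(st$values), 20L)
  expect_identical(st$subject_index, rep(1:2, each = 10))
  expect_identical(st$values[1:10, ], a$values)
  expect_identical(st$values[11:20, ], b$values)
  one <- stack_training_features(list(a))
  expect_identical(one$values, a$values)
  expect_error(stack_training_features(list(a, fm_stub(matrix(1:30, 10, 3)))),
               "dimensions differ")
})

test_that("noise-free planted models are recovered exactly up to gauge", {
  pd <- plant_bilinear_dataset(5, 30, I = 2, J = 3, noise_sd = 0, seed = 21)
  fit <- fit_bilinear(pd$observations, pd$subject_index, pd$motion_index)
  expect_lte(fit$fit_residual, 1e-8)
  expect_lt(max(principal_angles(fit$contents_shared, pd$contents)), 1)
  expect_lt(max(principal_angles(fit$styles, pd$styles)), 1)
  # content of each sample correlates perfectly with the planted one
  cc <- stats::cancor(fit$contents_shared, pd$contents)$cor
  expect_gt(min(cc), 1 - 1e-8)
})

test_that("noisy planted models reach the noise floor with a close subspace", {
  pd <- plant_bilinear_dataset(5, 40, I = 2, J = 3, noise_sd = 0.1, seed = 22)
  fit <- fit_bilinear(pd$observations, pd$subject_index, pd$motion_index)
  noise_floor <- 0.1^2 * length(pd$observations)
  expect_lt(fit$fit_residual, 1.5 * noise_floor)
  expect_lt(max(principal_angles(fit$contents_shared, pd$contents)), 5)
})

test_that("I = J = 1 reduces to the best rank-one fit (SVD oracle)", {
  # with per-row contents (no motion sharing) the I = J = 1 model is an
  # unconstrained rank-one factorization of the observation matrix
  pd <- plant_bilinear_dataset(3, 25, I = 1, J = 1, noise_sd = 0.05, seed = 23)
  fit <- fit_bilinear(pd$observations, pd$subject_index, motion_index = NULL,
                      I = 1, J = 1)
  sv <- svd(pd$observations)
  expect_equal(fit$fit_residual, sum(sv$d[-1]^2), tolerance = 1e-6)
})

test_that("the fitting residual never increases", {
  pd <- plant_bilinear_dataset(4, 20, I = 2, J = 3, noise_sd = 0.3, seed = 24)
  fit <- fit_bilinear(pd$observations, pd$subject_index, pd$motion_index)
  expect_true(all(diff(fit$residual_history) <= 1e-9 * fit$residual_history[1]))
})

test_that("content extraction aligns rows with stacked samples", {
  pd <- plant_bilinear_dataset(3, 12, noise_sd = 0, seed = 25)
  fit <- fit_bilinear(pd$observations, pd$subject_index, pd$motion_index,
                      labels = rep(1:3, 12), provenance = NULL)
  cm <- extract_content(fit)
  expect_identical(nrow(cm$values), nrow(pd$observations))
  # rows of different subjects realizing the same motion share content
  same_motion <- which(pd$motion_index == 5)
  expect_equal(cm$values[same_motion[1], ], cm$values[same_motion[2], ])
  expect_error(extract_content(structure(list(contents = NULL), class = "bilinear_model")),
               "not fitted")
})

test_that("style adaptation recovers a known subject and is homogeneous", {
  pd <- plant_bilinear_dataset(4, 30, noise_sd = 0, seed = 26)
  fit <- fit_bilinear(pd$observations, pd$subject_index, pd$motion_index)
  rows <- which(pd$subject_index == 3)[1:8]
  bmp <- adapt_style(fit, pd$observations[rows, ], fit$contents[rows, ])
  rel <- sqrt(sum((bmp$z_new - fit$styles[3, ])^2) / sum(fit$styles[3, ]^2))
  expect_lt(rel, 0.05)

  bmp2 <- adapt_style(fit, 2.5 * pd$observations[rows, ], fit$contents[rows, ])
  expect_equal(bmp2$z_new, 2.5 * bmp$z_new, tolerance = 1e-8)

  # local optimality: no random perturbation fits the calibration better
  set.seed(1)
  cal_resid <- function(z) {
    G <- asNamespace("emgfuse")$style_design(z, fit$weights, fit$J, dim(fit$weights)[3])
    sum((fit$contents[rows, ] %*% t(G) - pd$observations[rows, ])^2)
  }
  b0 <- cal_resid(bmp$z_new)
  perturbed <- replicate(100, cal_resid(bmp$z_new + rnorm(fit$I, sd = 0.1)))
  expect_true(all(b0 <= perturbed + 1e-10))

  expect_error(adapt_style(fit, pd$observations[integer(0), , drop = FALSE],
                           fit$contents[integer(0), , drop = FALSE]), "empty")
})

test_that("content projection reconstructs noise-free test data", {
  pd <- plant_bilinear_dataset(4, 30, noise_sd = 0, seed = 27)
  fit <- fit_bilinear(pd$observations, pd$subject_index, pd$motion_index)
  rows_cal <- which(pd$subject_index == 2)[1:6]
  rows_te <- setdiff(which(pd$subject_index == 2), rows_cal)
  bmp <- adapt_style(fit, pd$observations[rows_cal, ], fit$contents[rows_cal, ])
  pr <- project_content(bmp, pd$observations[rows_te, ])
  expect_identical(nrow(pr$contents), length(rows_te))
  expect_lt(max(abs(pr$reconstruction - pd$observations[rows_te, ])), 1e-8)
  cc <- stats::cancor(pr$contents, pd$contents[pd$motion_index[rows_te], ])$cor
  expect_gt(min(cc), 1 - 1e-6)
  expect_error(project_content(fit, pd$observations), "no adapted style")
})

test_that("content/IMU fusion averages across subjects in training mode", {
  content <- matrix(rnorm(12), 6, 2)
  imu <- matrix(rep(1:6, each = 2), 6, 2, byrow = TRUE) + 0
  prov <- data.frame(gesture = rep(1:3, 2), position = 1,
                     repetition = 1, window = 1, subject = rep(1:2, each = 3))
  fused <- fuse_content_imu(content, imu, "train", prov)
  expect_identical(ncol(fused), 4L)
  # motion (gesture 1) appears for subjects 1 and 2: rows 1 and 4 averaged
  expect_equal(unname(fused[1, 3:4]), unname(colMeans(imu[c(1, 4), ])))
  expect_equal(unname(fused[4, 3:4]), unname(colMeans(imu[c(1, 4), ])))

  # identical IMU features across subjects leave the average unchanged
  imu2 <- rbind(imu[1:3, ], imu[1:3, ])
  fused2 <- fuse_content_imu(content, imu2, "train", prov)
  expect_equal(unname(fused2[, 3:4]), unname(imu2))

  # single-subject training fold: the average is that subject's features
  fused1 <- fuse_content_imu(content[1:3, ], imu[1:3, ], "train", prov[1:3, ])
  expect_equal(unname(fused1[, 3:4]), unname(imu[1:3, ]))

  ft <- fuse_content_imu(content, imu, "test")
  expect_identical(unname(ft), unname(cbind(content, imu)))
  expect_error(fuse_content_imu(content, imu[1:3, ], "test"), "misaligned")
})
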