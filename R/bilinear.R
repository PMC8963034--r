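#' Symmetric bilinear style/content factorization
#'
#' Models each observation channel k of a motion sample t produced by
#' subject s as `y[t, k] = z_s' W_k x_t`, with a per-subject style vector
#' `z` (dim I = 2), a per-sample content vector `x` (dim J = 3) and
#' per-channel weight matrices `W_k`. The 64 per-window EMG features act
#' as the observation channels (eight features for each of the eight
#' electrodes, flattened). Content vectors are subject-invariant by
#' construction and serve as classifier input; a new subject's style is
#' estimated from a single calibration motion with the weights frozen.
#'
#' The factorization is estimated by alternating least squares: each block
#' update (weights, contents, styles) is an exact least-squares solve, so
#' the residual is nonincreasing. The model is identified only up to an
#' invertible gauge transform `(z, x, W) -> (A z, B x, A^-T W B^-1)`;
#' recovery tests therefore compare subspaces, not coordinates.
#'
#' @name bilinear
NULL

#' Stack per-subject feature matrices
#'
#' @param fm_list list of `feature_matrix` objects with equal feature
#'   dimension.
#' @return list with `values` (row-block concatenation), `subject_index`,
#'   `labels`, `provenance`.
#' @export
stack_training_features <- function(fm_list) {
  d <- vapply(fm_list, function(f) ncol(f$values), 0L)
  if (length(unique(d)) != 1) stop("feature dimensions differ across subjects")
  list(values = do.call(rbind, lapply(fm_list, `[[`, "values")),
       subject_index = rep(seq_along(fm_list),
                           vapply(fm_list, function(f) nrow(f$values), 0L)),
       labels = unlist(lapply(fm_list, `[[`, "labels"), use.names = FALSE),
       provenance = do.call(rbind, lapply(fm_list, `[[`, "provenance")))
}

# K x J design matrix for a fixed style: row k is z' W_k
style_design <- function(z, W, J, K) {
  matrix(vapply(seq_len(K), function(k) as.numeric(z %*% W[, , k]), numeric(J)),
         ncol = J, byrow = TRUE)
}

bilinear_residual <- function(Y, z, W, X, subject_index, motion_index) {
  K <- dim(W)[3]
  r <- 0
  Zt <- z[subject_index, , drop = FALSE]
  Xt <- X[motion_index, , drop = FALSE]
  for (k in seq_len(K)) {
    yhat <- rowSums((Zt %*% W[, , k]) * Xt)
    r <- r + sum((Y[, k] - yhat)^2)
  }
  r
}

#' Fit a bilinear style/content model
#'
#' @param Y stacked observations, N x K (rows = motion samples of all
#'   subjects).
#' @param subject_index length-N integer vector mapping rows to subjects.
#' @param motion_index length-N integer vector identifying the motion
#'   sample each row realizes; rows of different subjects with the same
#'   motion id share one content vector (the subjects all perform the
#'   same protocol). `NULL` treats every row as its own motion, which
#'   leaves the content gauge free per subject and is much harder to
#'   recover -- supply the index whenever the protocol provides it.
#' @param I,J style and content dimensions (defaults 2 and 3).
#' @param tol stop when the relative residual change falls below this.
#' @param max_iter iteration cap per start.
#' @param n_starts number of seeded style initializations (alternating
#'   least squares is nonconvex; the best of `n_starts` runs is kept).
#'   On a complete subject-by-motion grid the first start is a spectral
#'   warm start that is exact for noise-free data.
#' @param labels,provenance optional per-row bookkeeping carried through to
#'   [extract_content()].
#' @return object of class `bilinear_model` with `styles` (S x I),
#'   `contents` (N x J, per row; `contents_shared` holds the M x J
#'   per-motion matrix), `weights` (I x J x K array), `fit_residual`,
#'   `residual_history`.
#' @export
fit_bilinear <- function(Y, subject_index, motion_index = NULL, I = 2, J = 3,
                         tol = 1e-8, max_iter = 500, n_starts = 5,
                         labels = NULL, provenance = NULL) {
  Y <- as.matrix(Y)
  if (!all(is.finite(Y))) stop("observations must be finite")
  subjects <- sort(unique(subject_index))
  S <- length(subjects)
  if (S < 2) stop("need at least two subjects to separate style from content")
  N <- nrow(Y); K <- ncol(Y)
  si <- match(subject_index, subjects)
  mi <- if (is.null(motion_index)) seq_len(N)
        else match(motion_index, sort(unique(motion_index)))
  M <- max(mi)
  groups <- split(seq_len(N), si)
  complete <- N == S * M && !anyDuplicated(cbind(si, mi))

  sv <- svd(Y, nu = 0, nv = min(J, ncol(Y)))
  if (ncol(sv$v) < J || sv$d[J] <= 1e-12 * sv$d[1])
    stop("degenerate fit: data rank below the content dimension J; reduce J or add samples")

  solve_ls <- function(A, B) {
    out <- tryCatch(solve(A, B), error = function(e) NULL)
    if (is.null(out)) stop("degenerate fit: singular least-squares block; reduce I/J or add samples")
    out
  }

  als_run <- function(z, X) {
    W <- array(0, c(I, J, K))
    res_hist <- numeric(0)
    res_prev <- Inf
    for (it in seq_len(max_iter)) {
      # --- weights: per channel, regress on kron(x_m(t), z_s(t))
      Zt <- z[si, , drop = FALSE]
      Xt <- X[mi, , drop = FALSE]
      Q <- matrix(0, N, I * J)
      for (j in seq_len(J)) Q[, (j - 1) * I + seq_len(I)] <- Zt * Xt[, j]
      Wv <- solve_ls(crossprod(Q), crossprod(Q, Y))     # (I*J) x K
      W <- array(Wv, c(I, J, K))

      # --- contents: per motion, x_m = argmin sum_s ||y_{s,m} - G_s x||
      Gs <- lapply(seq_len(S), function(s) style_design(z[s, ], W, J, K))
      acc <- matrix(0, M, J)
      for (s in seq_len(S)) {
        rows <- groups[[s]]
        acc[mi[rows], ] <- acc[mi[rows], , drop = FALSE] +
          Y[rows, , drop = FALSE] %*% Gs[[s]]
      }
      if (complete) {
        A <- Reduce(`+`, lapply(Gs, crossprod))
        X <- acc %*% solve_ls(A, diag(J))
      } else {
        GtG <- lapply(Gs, crossprod)
        subj_of <- split(si, mi)
        for (m in seq_len(M)) {
          A <- Reduce(`+`, GtG[subj_of[[m]]])
          X[m, ] <- solve_ls(A, acc[m, ])
        }
      }

      # --- styles: per subject, z_s = argmin sum_t ||y_t - H_t z||, H_t[k,] = (W_k x_t)'
      for (s in seq_len(S)) {
        rows <- groups[[s]]
        Xs <- X[mi[rows], , drop = FALSE]
        Amat <- matrix(0, I, I); rhs <- numeric(I)
        for (k in seq_len(K)) {
          Hk <- Xs %*% t(W[, , k])                      # n_s x I
          Amat <- Amat + crossprod(Hk)
          rhs <- rhs + as.numeric(crossprod(Hk, Y[rows, k]))
        }
        z[s, ] <- solve_ls(Amat, rhs)
      }

      res <- bilinear_residual(Y, z, W, X, si, mi)
      res_hist <- c(res_hist, res)
      if (res <= 1e-12 * sum(Y^2)) break
      if (is.finite(res_prev) && abs(res_prev - res) <= tol * max(res_prev, 1e-300)) break
      res_prev <- res
    }
    list(z = z, X = X, W = W, res_hist = res_hist, res = res_hist[length(res_hist)])
  }

  # Content warm starts. On a complete grid the (subject x channel) by
  # motion unfolding Y[(s,k), m] = (z_s' W_k) x_m has exact rank J, so its
  # top right-singular vectors give the shared content up to one global
  # J x J gauge; the per-subject maps B_s regressed on that basis are then
  # exactly linear in z_s and an SVD across subjects recovers the styles.
  proj <- Y %*% sv$v[, seq_len(J), drop = FALSE]
  X0_rowproj <- rowsum(proj, mi) / as.numeric(table(mi))
  X0_unfold <- NULL
  if (complete) {
    Ymat <- matrix(0, S * K, M)
    for (s in seq_len(S)) {
      rows <- groups[[s]]
      Ymat[(s - 1) * K + seq_len(K), ] <- t(Y[rows[order(mi[rows])], , drop = FALSE])
    }
    X0_unfold <- svd(Ymat, nu = 0, nv = J)$v
  }
  spectral_z <- function(X0) {
    C <- t(vapply(seq_len(S), function(s) {
      rows <- groups[[s]]
      Xs <- X0[mi[rows], , drop = FALSE]
      B <- tryCatch(t(solve(crossprod(Xs), crossprod(Xs, Y[rows, , drop = FALSE]))),
                    error = function(e) matrix(0, K, J))
      as.vector(B)
    }, numeric(K * J)))
    svc <- svd(C, nu = I, nv = 0)
    svc$u %*% diag(svc$d[seq_len(I)], I)
  }

  # block coordinate descent on a nonconvex objective: a few seeded starts,
  # keep the best fit
  yss <- sum(Y^2)
  best <- NULL
  for (r in seq_len(n_starts)) {
    X0 <- if (r == 1 && complete) X0_unfold else X0_rowproj
    z0 <- if (r <= 2) spectral_z(X0)
          else with_seed(derive_seed(977L, r, S, I), matrix(rnorm(S * I), S, I))
    run <- als_run(z0, X0)
    if (is.null(best) || run$res < best$res) best <- run
    if (best$res <= 1e-10 * yss) break
  }
  z <- best$z; X <- best$X; W <- best$W; res_hist <- best$res_hist

  structure(list(styles = z, contents = X[mi, , drop = FALSE],
                 contents_shared = X, motion_index = mi,
                 weights = W, I = I, J = J,
                 subjects = subjects, subject_index = si,
                 fit_residual = res_hist[length(res_hist)],
                 residual_history = res_hist,
                 labels = labels, provenance = provenance),
            class = "bilinear_model")
}

#' Extract the content matrix
#'
#' @param model fitted `bilinear_model`.
#' @return `feature_matrix` whose `values` are the per-sample content
#'   vectors (N x J), with labels/provenance carried through.
#' @export
extract_content <- function(model) {
  if (is.null(model$contents)) stop("model is not fitted")
  structure(list(values = model$contents, labels = model$labels,
                 provenance = model$provenance,
                 feature_names = paste0("content", seq_len(model$J))),
            class = "feature_matrix")
}

#' Estimate a new subject's style from one calibration motion
#'
#' With the weight matrices frozen, the style vector is the least-squares
#' solution of `y_t ~ H(x_t) z` over the calibration windows, where the
#' content `x_t` of each calibration window is taken as known (by default
#' the mean training content of the calibration gesture).
#'
#' @param model fitted `bilinear_model`.
#' @param Ycal calibration observations, n_cal x K.
#' @param content known content: a single length-J vector (replicated) or
#'   an n_cal x J matrix.
#' @return the model with `z_new` attached (class `bilinear_model`).
#' @export
adapt_style <- function(model, Ycal, content) {
  Ycal <- as.matrix(Ycal)
  if (nrow(Ycal) == 0) stop("empty calibration set")
  W <- model$weights; I <- model$I; J <- model$J; K <- dim(W)[3]
  Xc <- if (is.matrix(content)) content
        else matrix(content, nrow(Ycal), J, byrow = TRUE)
  stopifnot(nrow(Xc) == nrow(Ycal), ncol(Xc) == J)
  Amat <- matrix(0, I, I); rhs <- numeric(I)
  for (k in seq_len(K)) {
    Hk <- Xc %*% t(W[, , k])
    Amat <- Amat + crossprod(Hk)
    rhs <- rhs + as.numeric(crossprod(Hk, Ycal[, k]))
  }
  model$z_new <- as.numeric(solve(Amat, rhs))
  model
}

#' Project new observations onto content space
#'
#' Per-sample least-squares content vectors given the adapted style and
#' frozen weights.
#'
#' @param model `bilinear_model` carrying `z_new` (see [adapt_style()]).
#' @param Ytest n x K observations.
#' @return list with `contents` (n x J) and `reconstruction` (n x K).
#' @export
project_content <- function(model, Ytest) {
  if (is.null(model$z_new)) stop("model has no adapted style; run adapt_style() first")
  Ytest <- as.matrix(Ytest)
  W <- model$weights; J <- model$J; K <- dim(W)[3]
  if (ncol(Ytest) != K) stop("observation dimension does not match the model")
  G <- style_design(model$z_new, W, J, K)
  Xn <- Ytest %*% G %*% solve(crossprod(G), diag(J))
  list(contents = Xn, reconstruction = Xn %*% t(G))
}

#' Fuse content features with IMU features
#'
#' Training mode appends, to each content row, the IMU feature vector of
#' its motion sample averaged across all training-fold subjects (samples
#' are matched by gesture/position/repetition/window provenance). Test
#' mode appends the new subject's own IMU features row-by-row.
#'
#' @param content n x J matrix of content vectors.
#' @param imu n x 12 matrix of IMU features aligned with `content` rows.
#' @param mode `"train"` or `"test"`.
#' @param provenance data frame with gesture/position/repetition/window
#'   columns (required in training mode).
#' @return n x (J + 12) matrix.
#' @export
fuse_content_imu <- function(content, imu, mode = c("train", "test"),
                             provenance = NULL) {
  mode <- match.arg(mode)
  content <- as.matrix(content); imu <- as.matrix(imu)
  if (nrow(content) != nrow(imu)) stop("content and IMU rows are misaligned")
  if (mode == "test") return(cbind(content, imu))
  if (is.null(provenance)) stop("training-mode fusion needs provenance")
  key <- interaction(provenance$gesture, provenance$position,
                     provenance$repetition, provenance$window, drop = TRUE)
  sums <- rowsum(imu, key)
  counts <- as.numeric(table(key)[rownames(sums)])
  avg <- sums / counts
  cbind(content, avg[match(as.character(key), rownames(avg)), , drop = FALSE])
}
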