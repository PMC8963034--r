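#' Least-squares SVM with multi-model transfer
#'
#' One-vs-all LS-SVM: for each class, the dual weights and bias solve the
#' bordered linear system `[[K + I/gamma, 1], [1', 0]] [alpha; b] = [y; 0]`
#' with `y` in {-1, +1}. Transfer to a new subject follows the multi-model
#' knowledge-transfer scheme: per-subject pretrained models are combined
#' with nonnegative weights `beta` (one vector per class, projected onto
#' the unit L2 ball), found by projected subgradient descent on a
#' closed-form leave-one-out loss over the calibration set, and a new
#' LS-SVM is solved on the calibration set with the beta-weighted prior
#' decision function as an offset term.
#'
#' @name adaptive_lssvm
NULL

rbf_kernel <- function(X, Y, sigma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

#' Median-heuristic RBF bandwidth
#'
#' Median pairwise Euclidean distance over (a subsample of) the rows of X.
#'
#' @param X data matrix.
#' @param max_n subsample cap.
#' @param seed subsampling seed.
#' @return bandwidth `sigma`.
#' @export
median_bandwidth <- function(X, max_n = 400, seed = 1L) {
  n <- nrow(X)
  idx <- if (n > max_n) with_seed(seed, sample.int(n, max_n)) else seq_len(n)
  d <- stats::dist(X[idx, , drop = FALSE])
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

kernel_matrix <- function(model_kernel, sigma, X, Y) {
  if (model_kernel == "linear") X %*% t(Y) else rbf_kernel(X, Y, sigma)
}

#' Train a one-vs-all LS-SVM
#'
#' @param X n x d matrix (standardized and scaled upstream).
#' @param y integer labels.
#' @param gamma regularization (larger = less regularized).
#' @param kernel `"rbf"` or `"linear"`.
#' @param sigma RBF bandwidth; `NULL` uses the median heuristic.
#' @param classes class label set (defaults to `sort(unique(y))`).
#' @return object of class `lssvm_model`.
#' @export
train_lssvm <- function(X, y, gamma = 1, kernel = c("rbf", "linear"),
                        sigma = NULL, classes = NULL) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  classes <- classes %||% sort(unique(y))
  if (length(classes) < 2) stop("need at least two classes to train")
  n <- nrow(X)
  if (n < length(classes)) stop("fewer samples than classes")
  if (is.null(sigma) && kernel == "rbf") sigma <- median_bandwidth(X)
  K <- kernel_matrix(kernel, sigma, X, X)
  M <- rbind(cbind(K + diag(n) / gamma, 1), c(rep(1, n), 0))
  Y <- vapply(classes, function(cl) ifelse(y == cl, 1, -1), numeric(n))
  sol <- tryCatch(solve(M, rbind(Y, 0)),
                  error = function(e) stop("singular LS-SVM system; increase regularization (lower gamma) or deduplicate data"))
  structure(list(X = X, alpha = sol[seq_len(n), , drop = FALSE],
                 b = sol[n + 1, ], classes = classes, kernel = kernel,
                 sigma = sigma, gamma = gamma),
            class = "lssvm_model")
}

#' Decision scores of an LS-SVM
#'
#' @param model `lssvm_model`.
#' @param X new data.
#' @return n x n_classes score matrix.
#' @export
decision_scores <- function(model, X) {
  K <- kernel_matrix(model$kernel, model$sigma, as.matrix(X), model$X)
  sweep(K %*% model$alpha, 2, model$b, "+")
}

#' @export
predict.lssvm_model <- function(object, newdata, ...) {
  s <- decision_scores(object, newdata)
  object$classes[max.col(s, ties.method = "first")]
}

# subset a feature_matrix by row index
subset_fm <- function(fm, idx) {
  structure(list(values = fm$values[idx, , drop = FALSE],
                 labels = fm$labels[idx],
                 provenance = fm$provenance[idx, , drop = FALSE],
                 feature_names = fm$feature_names),
            class = "feature_matrix")
}

#' Calibration/test split by repetition
#'
#' XCal takes all windows of `n_cal_reps` randomly chosen repetitions of
#' each gesture (across all positions); XTest is the disjoint remainder.
#'
#' @param fm `feature_matrix` of one subject.
#' @param n_cal_reps repetitions per gesture for calibration (default 2).
#' @param seed RNG seed for the repetition draw.
#' @return list with `cal` and `test` feature matrices and `cal_reps`
#'   (gesture -> chosen repetitions).
#' @export
split_cal_test <- function(fm, n_cal_reps = 2, seed = 1L) {
  pr <- fm$provenance
  gestures <- sort(unique(pr$gesture))
  cal_idx <- logical(nrow(pr))
  cal_reps <- list()
  for (g in gestures) {
    reps <- sort(unique(pr$repetition[pr$gesture == g]))
    if (length(reps) <= n_cal_reps)
      stop("need more than ", n_cal_reps, " repetitions per gesture to split")
    chosen <- with_seed(derive_seed(seed, 404L, g), sample(reps, n_cal_reps))
    cal_reps[[as.character(g)]] <- chosen
    cal_idx <- cal_idx | (pr$gesture == g & pr$repetition %in% chosen)
  }
  list(cal = subset_fm(fm, which(cal_idx)),
       test = subset_fm(fm, which(!cal_idx)),
       cal_reps = cal_reps)
}

#' Rank pretrained models on calibration data
#'
#' @param priors list of `lssvm_model`s.
#' @param Xcal,ycal calibration data and labels.
#' @return data frame with `prior` (index), `error` (misclassification
#'   rate), sorted ascending by error with ties broken by prior index.
#' @export
select_best_prior <- function(priors, Xcal, ycal) {
  if (length(priors) < 1) stop("no prior models supplied")
  if (length(ycal) == 0) stop("empty calibration set")
  err <- vapply(priors, function(m) mean(predict(m, Xcal) != ycal), 0)
  out <- data.frame(prior = seq_along(priors), error = err)
  out[order(out$error, out$prior), , drop = FALSE]
}

project_beta <- function(beta) {
  beta[beta < 0] <- 0
  nb <- sqrt(sum(beta^2))
  if (nb > 1) beta <- beta / nb
  beta
}

#' Adapt prior LS-SVM models to a new subject
#'
#' See the module description. `beta` is learned per class; the step size
#' follows a `c / sqrt(t)` schedule on the normalized subgradient.
#'
#' @param priors list of `lssvm_model`s sharing a feature space.
#' @param Xcal,ycal calibration data of the new subject.
#' @param gamma LS-SVM regularization for the adapted model.
#' @param iterations projected-subgradient iterations (default 300).
#' @param step_c step-size constant.
#' @return object of class `adaptive_lssvm`: the adapted model (calibration
#'   kernel machine + `beta` (n_priors x n_classes) + the priors).
#' @export
adapt_lssvm <- function(priors, Xcal, ycal, gamma = 1, iterations = 300,
                        step_c = 0.5) {
  stopifnot(length(priors) >= 1)
  Xcal <- as.matrix(Xcal)
  n <- nrow(Xcal)
  ref <- priors[[1]]
  classes <- ref$classes
  k <- length(priors)
  prior_scores <- lapply(priors, function(m) decision_scores(m, Xcal))

  K <- kernel_matrix(ref$kernel, ref$sigma, Xcal, Xcal)
  M <- rbind(cbind(K + diag(n) / gamma, 1), c(rep(1, n), 0))
  Minv <- solve(M)
  A <- Minv[seq_len(n), seq_len(n), drop = FALSE]
  dM <- diag(Minv)[seq_len(n)]

  ranking <- select_best_prior(priors, Xcal, ycal)
  best <- ranking$prior[1]

  beta <- matrix(0, k, length(classes))
  for (ci in seq_along(classes)) {
    yc <- ifelse(ycal == classes[ci], 1, -1)
    Fm <- vapply(prior_scores, function(s) s[, ci], numeric(n))  # n x k
    G <- (A %*% Fm) / dM                                         # d(dloo)/dbeta
    loo_loss <- function(b) {
      d <- yc - (A %*% (yc - Fm %*% b)) / dM
      sum(pmax(0, 1 - yc * d)^2)
    }
    b_cur <- project_beta(replace(numeric(k), best, 1))
    b_best <- b_cur
    l_best <- loo_loss(b_cur)
    for (t in seq_len(iterations)) {
      d <- yc - (A %*% (yc - Fm %*% b_cur)) / dM
      slack <- pmax(0, 1 - yc * as.numeric(d))
      g <- as.numeric(t(G) %*% (-2 * slack * yc))
      ng <- sqrt(sum(g^2))
      if (ng < 1e-12) break
      b_cur <- project_beta(b_cur - (step_c / sqrt(t)) * g / ng)
      l_cur <- loo_loss(b_cur)
      if (l_cur < l_best) { l_best <- l_cur; b_best <- b_cur }
    }
    beta[, ci] <- b_best
  }

  Yres <- vapply(seq_along(classes), function(ci) {
    yc <- ifelse(ycal == classes[ci], 1, -1)
    Fm <- vapply(prior_scores, function(s) s[, ci], numeric(n))
    yc - as.numeric(Fm %*% beta[, ci])
  }, numeric(n))
  sol <- Minv %*% rbind(Yres, 0)

  structure(list(X = Xcal, alpha = sol[seq_len(n), , drop = FALSE],
                 b = sol[n + 1, ], beta = beta, priors = priors,
                 classes = classes, kernel = ref$kernel, sigma = ref$sigma,
                 gamma = gamma, ranking = ranking),
            class = "adaptive_lssvm")
}

#' Decision scores of an adapted model
#' @param model `adaptive_lssvm`.
#' @param X new data.
#' @return n x n_classes score matrix (own machine + beta-weighted priors).
#' @export
adaptive_scores <- function(model, X) {
  X <- as.matrix(X)
  own <- sweep(kernel_matrix(model$kernel, model$sigma, X, model$X) %*% model$alpha,
               2, model$b, "+")
  for (j in seq_along(model$priors))
    own <- own + decision_scores(model$priors[[j]], X) *
      matrix(model$beta[j, ], nrow(X), ncol(own), byrow = TRUE)
  own
}

#' @export
predict.adaptive_lssvm <- function(object, newdata, ...) {
  s <- adaptive_scores(object, newdata)
  object$classes[max.col(s, ties.method = "first")]
}
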