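#' Subject-wise evaluation
#'
#' Normalization and reduction (Z-normalization, scaling to the margin
#' range of +/-1, PCA by SVD retaining at least 95% of the variance),
#' subject-wise k-fold assignment, the cross-validation orchestration for
#' all three classifiers and both sensor modalities, and confusion-matrix
#' metrics. Normalization state is always fitted on training-fold
#' subjects only and applied unchanged to test subjects.
#'
#' @name evaluation
NULL

#' Fit the normalization/reduction state
#'
#' Z-normalize each feature, scale to `[-1, 1]`, then project onto the
#' smallest PCA basis (computed by SVD) whose cumulative explained
#' variance reaches `var_target`. Zero-variance features are dropped with
#' a warning.
#'
#' @param X training matrix.
#' @param var_target retained-variance threshold (default 0.95).
#' @return object of class `normalization_state` (with `n_components`).
#' @export
fit_normalization <- function(X, var_target = 0.95) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty training matrix")
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  keep <- which(is.finite(s) & s > 0)
  if (length(keep) < ncol(X))
    warning("dropping ", ncol(X) - length(keep), " zero-variance feature(s)")
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], "/")
  lo <- apply(Z, 2, min); hi <- apply(Z, 2, max)
  rng <- pmax(hi - lo, .Machine$double.eps)
  Zs <- sweep(sweep(Z, 2, lo), 2, rng / 2, "/") - 1
  ctr <- colMeans(Zs)
  Zc <- sweep(Zs, 2, ctr)
  sv <- svd(Zc, nu = 0)
  ev <- sv$d^2
  ev <- ev / sum(ev)
  ncomp <- which(cumsum(ev) >= var_target - 1e-12)[1]
  structure(list(mu = mu[keep], sd = s[keep], keep = keep, lo = lo, rng = rng,
                 center = ctr, rotation = sv$v[, seq_len(ncomp), drop = FALSE],
                 explained = sum(ev[seq_len(ncomp)]), n_components = ncomp,
                 var_target = var_target),
            class = "normalization_state")
}

#' @rdname fit_normalization
#' @param state a fitted `normalization_state`.
#' @export
apply_normalization <- function(state, X) {
  X <- as.matrix(X)[, state$keep, drop = FALSE]
  Z <- sweep(sweep(X, 2, state$mu), 2, state$sd, "/")
  Zs <- sweep(sweep(Z, 2, state$lo), 2, state$rng / 2, "/") - 1
  sweep(Zs, 2, state$center) %*% state$rotation
}

# plain column-wise Z-normalization (used for bilinear inputs/outputs)
fit_zscale <- function(X) {
  mu <- colMeans(X); s <- apply(X, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  list(mu = mu, sd = s)
}
apply_zscale <- function(zs, X) sweep(sweep(as.matrix(X), 2, zs$mu), 2, zs$sd, "/")

#' Subject-wise fold assignment
#'
#' Seeded random partition of subjects into k folds with sizes differing
#' by at most one (22 subjects into 5 folds gives sizes 5, 5, 4, 4, 4).
#'
#' @param subject_ids vector of subject ids.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return named integer vector: subject id -> fold.
#' @export
make_folds <- function(subject_ids, k = 5, seed = 1L) {
  n <- length(subject_ids)
  if (k > n) stop("more folds than subjects")
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  shuffled <- with_seed(seed, sample(subject_ids))
  fold <- rep(seq_len(k), sizes)
  stats::setNames(fold[match(subject_ids, shuffled)], subject_ids)
}

#' Confusion-matrix metrics
#'
#' Rows index the true class, columns the predicted class.
#' `precision_c = TP_c / colsum_c`, `recall_c = TP_c / rowsum_c`,
#' `accuracy = trace / total`; zero denominators yield `NaN`.
#'
#' @param confusion square nonnegative count matrix.
#' @return list with `accuracy`, `precision`, `recall`.
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) stop("confusion counts must be nonnegative")
  tp <- diag(confusion)
  list(accuracy = sum(tp) / sum(confusion),
       precision = tp / colSums(confusion),
       recall = tp / rowSums(confusion))
}

confusion_matrix <- function(truth, pred, classes = 1:7) {
  tab <- table(factor(truth, classes), factor(pred, classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(true = classes, pred = classes))
  m
}

#' Experiment configuration
#'
#' Reference defaults follow the full protocol (5 subject-wise folds,
#' 2 calibration repetitions, 300 adaptation iterations, 300 / 100 MLP
#' epochs, every window kept). The `*_max` caps and `window_stride` exist
#' so large simulation studies fit a compute budget; they subsample
#' deterministically and are reported alongside results.
#'
#' @param k_folds subject-wise folds.
#' @param n_cal_reps calibration repetitions per gesture (adaptive LS-SVM).
#' @param lssvm_gamma,lssvm_kernel LS-SVM hyperparameters.
#' @param lssvm_max_train,lssvm_max_cal row caps for prior training and
#'   calibration (seeded subsamples; `Inf` disables).
#' @param adapt_iterations projected-subgradient iterations.
#' @param bilinear_I,bilinear_J style/content dimensions.
#' @param bilinear_max_iter,bilinear_starts ALS budget for the bilinear fit.
#' @param bilinear_epochs,classic_epochs MLP training epochs.
#' @param classic_restarts validation-selected restarts for the classic
#'   network (see [train_classic_mlp()]).
#' @param batch_size minibatch size for both networks.
#' @param window_stride keep every n-th window when featurizing.
#' @param segment_source `"truth"` or `"detect"` (see [featurize_cohort()]).
#' @param pca_var retained-variance target.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(k_folds = 5, n_cal_reps = 2, lssvm_gamma = 1,
                              lssvm_kernel = "rbf", lssvm_max_train = 800,
                              lssvm_max_cal = 600, adapt_iterations = 300,
                              bilinear_I = 2, bilinear_J = 3,
                              bilinear_max_iter = 200, bilinear_starts = 3,
                              bilinear_epochs = 300, classic_epochs = 100,
                              classic_restarts = 1,
                              batch_size = 32, window_stride = 1L,
                              segment_source = "truth", pca_var = 0.95) {
  structure(as.list(environment()), class = "experiment_config")
}

subsample_rows <- function(n, cap, seed) {
  if (n <= cap) seq_len(n) else sort(with_seed(seed, sample.int(n, cap)))
}

#' Run the subject-wise cross-validation experiment
#'
#' For every fold iteration, fits normalization and models on the
#' training-fold subjects and runs each test subject through the
#' method-specific calibration/test protocol: the adaptive LS-SVM
#' calibrates on two repetitions per gesture, the bilinear classifier on
#' one wrist-flexion repetition in one arm position, the classic MLP uses
#' no calibration.
#'
#' @param cohort a cohort from [generate_cohort()] (ignored if `features`
#'   is supplied).
#' @param methods subset of `c("lssvm", "bilinear", "mlp")`.
#' @param modalities subset of `c("emg", "fused")`.
#' @param seed root seed; all internal seeds derive from it.
#' @param config an [experiment_config()].
#' @param features optional precomputed [featurize_cohort()] output.
#' @return object of class `result_table`: `per_subject` data frame,
#'   `summary` data frame (mean/sd/range over subjects), `confusions`
#'   (named list of 7 x 7 count matrices), `n_components` bookkeeping.
#' @export
run_experiment <- function(cohort, methods = c("lssvm", "bilinear", "mlp"),
                           modalities = c("emg", "fused"), seed = 1L,
                           config = experiment_config(), features = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  modalities <- match.arg(modalities, several.ok = TRUE)
  fm <- features %||% featurize_cohort(cohort, config$segment_source,
                                       config$window_stride)
  classes <- sort(unique(fm$labels))
  ids <- sort(unique(fm$provenance$subject))
  folds <- make_folds(ids, config$k_folds, derive_seed(seed, 11L))
  rows_of <- split(seq_len(nrow(fm$values)), fm$provenance$subject)

  per_subject <- list()
  confusions <- list()
  ncomp_log <- list()
  record <- function(method, modality, subject, truth, pred) {
    cm <- confusion_matrix(truth, pred, classes)
    key <- paste(method, modality, sep = ".")
    confusions[[key]] <<- if (is.null(confusions[[key]])) cm else confusions[[key]] + cm
    per_subject[[length(per_subject) + 1]] <<-
      data.frame(subject = subject, method = method, modality = modality,
                 accuracy = mean(pred == truth))
  }

  for (fold in sort(unique(folds))) {
    train_ids <- ids[folds[as.character(ids)] != fold]
    test_ids <- ids[folds[as.character(ids)] == fold]
    train_rows <- unlist(rows_of[as.character(train_ids)], use.names = FALSE)

    for (modality in modalities) {
      cols <- modality_columns(modality)
      Xtr_all <- fm$values[train_rows, cols, drop = FALSE]

      if ("lssvm" %in% methods || "mlp" %in% methods) {
        norm <- fit_normalization(Xtr_all, config$pca_var)
        ncomp_log[[paste(modality, fold)]] <- norm$n_components
        Ptr <- apply_normalization(norm, Xtr_all)
      }

      if ("lssvm" %in% methods) {
        sigma <- if (config$lssvm_kernel == "rbf")
          median_bandwidth(Ptr, seed = derive_seed(seed, 13L, fold)) else NULL
        priors <- lapply(train_ids, function(s) {
          rows <- rows_of[[as.character(s)]]
          pick <- rows[subsample_rows(length(rows), config$lssvm_max_train,
                                      derive_seed(seed, 17L, fold, s))]
          train_lssvm(apply_normalization(norm, fm$values[pick, cols, drop = FALSE]),
                      fm$labels[pick], gamma = config$lssvm_gamma,
                      kernel = config$lssvm_kernel, sigma = sigma,
                      classes = classes)
        })
        for (s in test_ids) {
          sub_fm <- subset_fm(fm, rows_of[[as.character(s)]])
          sp <- split_cal_test(sub_fm, config$n_cal_reps, derive_seed(seed, 19L, s))
          cal_pick <- subsample_rows(nrow(sp$cal$values), config$lssvm_max_cal,
                                     derive_seed(seed, 23L, s))
          Xcal <- apply_normalization(norm, sp$cal$values[cal_pick, cols, drop = FALSE])
          adapted <- adapt_lssvm(priors, Xcal, sp$cal$labels[cal_pick],
                                 gamma = config$lssvm_gamma,
                                 iterations = config$adapt_iterations)
          Xte <- apply_normalization(norm, sp$test$values[, cols, drop = FALSE])
          record("lssvm", modality, s, sp$test$labels, predict(adapted, Xte))
        }
      }

      if ("bilinear" %in% methods) {
        emg_cols <- modality_columns("emg")
        imu_cols <- modality_columns("imu")
        ztr <- fit_zscale(fm$values[train_rows, emg_cols, drop = FALSE])
        Ytr <- apply_zscale(ztr, fm$values[train_rows, emg_cols, drop = FALSE])
        ptr <- fm$provenance[train_rows, , drop = FALSE]
        moti <- as.integer(interaction(ptr$gesture, ptr$position,
                                       ptr$repetition, ptr$window, drop = TRUE))
        bm <- fit_bilinear(Ytr, ptr$subject, moti,
                           I = config$bilinear_I, J = config$bilinear_J,
                           max_iter = config$bilinear_max_iter,
                           n_starts = config$bilinear_starts,
                           labels = fm$labels[train_rows], provenance = ptr)
        cmat <- extract_content(bm)
        zc <- fit_zscale(cmat$values)
        Ctr <- apply_zscale(zc, cmat$values)
        if (modality == "fused") {
          zimu <- fit_zscale(fm$values[train_rows, imu_cols, drop = FALSE])
          Itr <- apply_zscale(zimu, fm$values[train_rows, imu_cols, drop = FALSE])
          Ctr <- fuse_content_imu(Ctr, Itr, "train", cmat$provenance)
        }
        net <- train_bilinear_mlp(Ctr, cmat$labels, classes = classes,
                                  epochs = config$bilinear_epochs,
                                  batch_size = config$batch_size,
                                  seed = derive_seed(seed, 29L, fold))
        # mean training content of the calibration gesture, per window index
        calg <- classes[1]                   # wrist flexion
        sel <- cmat$labels == calg
        csum <- rowsum(cmat$values[sel, , drop = FALSE], cmat$provenance$window[sel])
        cmean <- csum / as.numeric(table(cmat$provenance$window[sel])[rownames(csum)])
        for (s in test_ids) {
          sub_fm <- subset_fm(fm, rows_of[[as.character(s)]])
          pr <- sub_fm$provenance
          wf <- pr[pr$gesture == calg, ]
          resample1 <- function(x) x[sample.int(length(x), 1)]
          pick <- with_seed(derive_seed(seed, 31L, s),
                            c(resample1(unique(wf$position)), resample1(unique(wf$repetition))))
          cal_idx <- which(pr$gesture == calg & pr$position == pick[1] &
                             pr$repetition == pick[2])
          test_idx <- setdiff(seq_len(nrow(pr)), cal_idx)
          Ycal <- apply_zscale(ztr, sub_fm$values[cal_idx, emg_cols, drop = FALSE])
          xknown <- cmean[match(pr$window[cal_idx], as.integer(rownames(cmean))), , drop = FALSE]
          bmp <- adapt_style(bm, Ycal, xknown)
          Yte <- apply_zscale(ztr, sub_fm$values[test_idx, emg_cols, drop = FALSE])
          Cte <- apply_zscale(zc, project_content(bmp, Yte)$contents)
          if (modality == "fused")
            Cte <- fuse_content_imu(Cte, apply_zscale(zimu, sub_fm$values[test_idx, imu_cols, drop = FALSE]),
                                    "test")
          record("bilinear", modality, s, sub_fm$labels[test_idx], predict(net, Cte))
        }
      }

      if ("mlp" %in% methods) {
        net <- train_classic_mlp(Ptr, fm$labels[train_rows], classes = classes,
                                 epochs = config$classic_epochs,
                                 batch_size = config$batch_size,
                                 n_restarts = config$classic_restarts,
                                 seed = derive_seed(seed, 37L, fold))
        for (s in test_ids) {
          rows <- rows_of[[as.character(s)]]
          Xte <- apply_normalization(norm, fm$values[rows, cols, drop = FALSE])
          record("mlp", modality, s, fm$labels[rows], predict(net, Xte))
        }
      }
    }
  }

  per_subject <- do.call(rbind, per_subject)
  summary <- do.call(rbind, lapply(split(per_subject, list(per_subject$method, per_subject$modality), drop = TRUE),
    function(d) data.frame(method = d$method[1], modality = d$modality[1],
                           mean_accuracy = mean(d$accuracy), sd_accuracy = stats::sd(d$accuracy),
                           min_accuracy = min(d$accuracy), max_accuracy = max(d$accuracy),
                           n_subjects = nrow(d))))
  rownames(summary) <- NULL
  structure(list(per_subject = per_subject, summary = summary,
                 confusions = confusions, n_components = ncomp_log,
                 seed = seed, config = config),
            class = "result_table")
}

#' @export
print.result_table <- function(x, ...) {
  cat("Subject-wise cross-validation results\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
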