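#' Multilayer perceptrons
#'
#' Two small feed-forward networks, implemented directly on matrices so
#' training is deterministic given a seed:
#'
#' * the content-classifier network: input -> 50 (ReLU) -> dropout 20% ->
#'   batch norm -> 20 (ReLU) -> dropout 20% -> softmax over 7 classes,
#'   trained with cross-entropy and Adam (lr 0.001, decay 1e-6) for 300
#'   epochs;
#' * the classic network: input -> 300 -> 200 -> 100 (logistic
#'   activations) -> linear scalar output, trained as a regression on
#'   Z-standardized integer labels with plain SGD (lr 0.2, no momentum),
#'   using an internal 80/20 train/validation split; predictions are
#'   un-standardized, rounded to the nearest integer (half away from
#'   zero) and clamped to the label range.
#'
#' Dropout is inverted dropout (active only during training); batch norm
#' keeps running statistics (momentum 0.9) for inference.
#'
#' @name mlp
NULL

act_forward <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         logistic = 1 / (1 + exp(-z)),
         linear = z,
         softmax = {
           e <- exp(z - apply(z, 1, max))
           e / rowSums(e)
         })
}

act_backward <- function(delta, a, act) {
  switch(act,
         relu = delta * (a > 0),
         logistic = delta * a * (1 - a),
         linear = delta)
}

# Glorot-uniform; logistic layers use the x4 gain recommended for
# sigmoid units (without it a 3-deep logistic stack barely moves)
glorot_init <- function(n_in, n_out, act = "linear") {
  gain <- if (act == "logistic") 4 else 1
  lim <- gain * sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

new_layer <- function(type, ...) c(list(type = type), list(...))

build_net <- function(layers, seed) {
  with_seed(seed, {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (l$type == "dense") {
        layers[[i]]$W <- glorot_init(l$n_in, l$n_out, l$act)
        layers[[i]]$b <- numeric(l$n_out)
      } else if (l$type == "batchnorm") {
        layers[[i]]$gamma <- rep(1, l$dim); layers[[i]]$beta <- numeric(l$dim)
        layers[[i]]$run_mean <- numeric(l$dim); layers[[i]]$run_var <- rep(1, l$dim)
      }
    }
    layers
  })
}

net_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  a <- X
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "dense") {
      z <- sweep(a %*% l$W, 2, l$b, "+")
      out <- act_forward(z, l$act)
      caches[[i]] <- list(input = a, out = out)
      a <- out
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        mask <- matrix(stats::rbinom(length(a), 1, 1 - l$rate), nrow(a)) / (1 - l$rate)
        caches[[i]] <- list(mask = mask)
        a <- a * mask
      }
    } else if (l$type == "batchnorm") {
      eps <- 1e-5
      if (training) {
        mu <- colMeans(a)
        v <- colMeans(sweep(a, 2, mu)^2)
        xc <- sweep(a, 2, mu)
        ivar <- 1 / sqrt(v + eps)
        xhat <- sweep(xc, 2, ivar, "*")
        caches[[i]] <- list(xc = xc, ivar = ivar, xhat = xhat, mu = mu, v = v)
      } else {
        xhat <- sweep(sweep(a, 2, l$run_mean), 2, 1 / sqrt(l$run_var + eps), "*")
      }
      a <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
    }
  }
  list(output = a, caches = caches)
}

# delta: dL/d(output of the last layer's pre-activation) already combined
# with the loss for softmax+CE / linear+MSE; returns per-layer gradients
net_backward <- function(layers, caches, delta) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "dense") {
      cache <- caches[[i]]
      # softmax+CE and linear+MSE give delta at pre-activation directly for
      # the output layer; hidden layers arrive with delta at activations
      if (!(l$act %in% c("softmax")) && !is.null(attr(delta, "post_act")))
        delta <- act_backward(delta, cache$out, l$act)
      grads[[i]] <- list(dW = crossprod(cache$input, delta),
                         db = colSums(delta))
      delta <- delta %*% t(l$W)
      attr(delta, "post_act") <- TRUE
    } else if (l$type == "dropout") {
      if (!is.null(caches[[i]])) {
        pa <- attr(delta, "post_act")
        delta <- delta * caches[[i]]$mask
        attr(delta, "post_act") <- pa
      }
    } else if (l$type == "batchnorm") {
      cache <- caches[[i]]
      pa <- attr(delta, "post_act")
      m <- nrow(delta)
      dgamma <- colSums(delta * cache$xhat)
      dbeta <- colSums(delta)
      dxhat <- sweep(delta, 2, l$gamma, "*")
      dvar <- colSums(dxhat * cache$xc) * (-0.5) * cache$ivar^3
      dmu <- colSums(sweep(dxhat, 2, -cache$ivar, "*")) +
        dvar * colMeans(-2 * cache$xc)
      delta <- sweep(dxhat, 2, cache$ivar, "*") +
        sweep(cache$xc, 2, 2 * dvar / m, "*") +
        matrix(dmu / m, m, length(dmu), byrow = TRUE)
      attr(delta, "post_act") <- pa
      grads[[i]] <- list(dgamma = dgamma, dbeta = dbeta)
    }
  }
  grads
}

train_net <- function(layers, X, Y, loss = c("ce", "mse"), optimizer = c("adam", "sgd"),
                      lr = 0.001, decay = 0, epochs = 300, batch_size = 32, seed = 1L,
                      val_X = NULL, val_Y = NULL, eval_every = 5L, patience = Inf) {
  loss <- match.arg(loss); optimizer <- match.arg(optimizer)
  n <- nrow(X)
  layers <- build_net(layers, derive_seed(seed, 1L))
  best <- list(layers = layers, val = Inf)
  misses <- 0L
  val_loss <- function(ly) {
    out <- net_forward(ly, val_X, training = FALSE)$output
    if (loss == "mse") mean((out - val_Y)^2)
    else -mean(log(pmax(out[cbind(seq_len(nrow(val_Y)), max.col(val_Y))], 1e-12)))
  }
  # Adam state
  if (optimizer == "adam") {
    state <- lapply(layers, function(l) {
      if (l$type == "dense") list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
      else if (l$type == "batchnorm") list(mg = l$gamma * 0, vg = l$gamma * 0,
                                           mb = l$beta * 0, vb = l$beta * 0)
      else NULL
    })
  }
  step <- 0L
  with_seed(derive_seed(seed, 2L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        xb <- X[idx, , drop = FALSE]
        yb <- Y[idx, , drop = FALSE]
        fw <- net_forward(layers, xb, training = TRUE)
        m <- nrow(xb)
        delta <- (fw$output - yb) / m          # softmax+CE or linear+0.5*MSE
        grads <- net_backward(layers, fw$caches, delta)
        for (i in seq_along(layers)) {         # batch-norm running stats
          if (layers[[i]]$type == "batchnorm" && !is.null(fw$caches[[i]])) {
            layers[[i]]$run_mean <- 0.9 * layers[[i]]$run_mean + 0.1 * fw$caches[[i]]$mu
            layers[[i]]$run_var <- 0.9 * layers[[i]]$run_var + 0.1 * fw$caches[[i]]$v
          }
        }
        step <- step + 1L
        lr_t <- lr / (1 + decay * step)
        for (i in seq_along(layers)) {
          l <- layers[[i]]; g <- grads[[i]]
          if (is.null(g)) next
          if (l$type == "dense") {
            if (optimizer == "adam") {
              st <- state[[i]]
              st$mW <- 0.9 * st$mW + 0.1 * g$dW; st$vW <- 0.999 * st$vW + 0.001 * g$dW^2
              st$mb <- 0.9 * st$mb + 0.1 * g$db; st$vb <- 0.999 * st$vb + 0.001 * g$db^2
              mhatW <- st$mW / (1 - 0.9^step); vhatW <- st$vW / (1 - 0.999^step)
              mhatb <- st$mb / (1 - 0.9^step); vhatb <- st$vb / (1 - 0.999^step)
              layers[[i]]$W <- l$W - lr_t * mhatW / (sqrt(vhatW) + 1e-8)
              layers[[i]]$b <- l$b - lr_t * mhatb / (sqrt(vhatb) + 1e-8)
              state[[i]] <- st
            } else {
              layers[[i]]$W <- l$W - lr_t * g$dW
              layers[[i]]$b <- l$b - lr_t * g$db
            }
          } else if (l$type == "batchnorm") {
            if (optimizer == "adam") {
              st <- state[[i]]
              st$mg <- 0.9 * st$mg + 0.1 * g$dgamma; st$vg <- 0.999 * st$vg + 0.001 * g$dgamma^2
              st$mb <- 0.9 * st$mb + 0.1 * g$dbeta; st$vb <- 0.999 * st$vb + 0.001 * g$dbeta^2
              layers[[i]]$gamma <- l$gamma - lr_t * (st$mg / (1 - 0.9^step)) /
                (sqrt(st$vg / (1 - 0.999^step)) + 1e-8)
              layers[[i]]$beta <- l$beta - lr_t * (st$mb / (1 - 0.9^step)) /
                (sqrt(st$vb / (1 - 0.999^step)) + 1e-8)
              state[[i]] <- st
            } else {
              layers[[i]]$gamma <- l$gamma - lr_t * g$dgamma
              layers[[i]]$beta <- l$beta - lr_t * g$dbeta
            }
          }
        }
        if (!all(is.finite(fw$output)))
          stop("training diverged (non-finite outputs); lower the learning rate")
      }
      # validation-tracked early stopping with best-weight snapshot
      if (!is.null(val_X) && ep %% eval_every == 0) {
        v <- val_loss(layers)
        if (v < best$val - 1e-6) {
          best <- list(layers = layers, val = v)
          misses <- 0L
        } else {
          misses <- misses + 1L
          if (misses >= patience) break
        }
      }
    }
  })
  if (!is.null(val_X) && is.finite(best$val)) list(layers = best$layers, val = best$val)
  else list(layers = layers, val = NA_real_)
}

mlp_predict_raw <- function(layers, X) net_forward(layers, X, training = FALSE)$output

#' Train the content-classifier network
#'
#' @param X n x d matrix of (Z-normalized) content (+ IMU) features.
#' @param y integer gesture labels.
#' @param classes label set (default `1:7`).
#' @param epochs,lr,decay,dropout,batch_size,seed training controls; the
#'   defaults are the reference configuration (300 epochs, Adam lr 0.001,
#'   decay 1e-6, dropout 0.2).
#' @return object of class `bilinear_mlp`.
#' @export
train_bilinear_mlp <- function(X, y, classes = 1:7, epochs = 300, lr = 0.001,
                               decay = 1e-6, dropout = 0.2, batch_size = 32,
                               seed = 1L) {
  X <- as.matrix(X)
  C <- length(classes)
  Y <- outer(y, classes, "==") * 1
  layers <- list(
    new_layer("dense", n_in = ncol(X), n_out = 50, act = "relu"),
    new_layer("dropout", rate = dropout),
    new_layer("batchnorm", dim = 50),
    new_layer("dense", n_in = 50, n_out = 20, act = "relu"),
    new_layer("dropout", rate = dropout),
    new_layer("dense", n_in = 20, n_out = C, act = "softmax"))
  fit <- train_net(layers, X, Y, loss = "ce", optimizer = "adam",
                   lr = lr, decay = decay, epochs = epochs,
                   batch_size = batch_size, seed = seed)
  structure(list(layers = fit$layers, classes = classes), class = "bilinear_mlp")
}

#' @export
predict.bilinear_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  p <- mlp_predict_raw(object$layers, as.matrix(newdata))
  if (match.arg(type) == "prob") return(p)
  object$classes[max.col(p, ties.method = "first")]
}

#' Label standardization
#'
#' @param y integer labels.
#' @return object of class `label_scaler` with `mean`, `sd`.
#' @export
label_scaler <- function(y) {
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) stop("labels have zero variance")
  structure(list(mean = mean(y), sd = s), class = "label_scaler")
}

scale_labels <- function(scaler, y) (y - scaler$mean) / scaler$sd

#' Un-standardize, round and clamp network outputs to labels
#'
#' Rounding is half away from zero; outputs are clamped to
#' `[min(classes), max(classes)]`.
#'
#' @param raw raw network outputs (standardized-label scale).
#' @param scaler a [label_scaler()].
#' @param classes label range (default `1:7`).
#' @return integer labels.
#' @export
predict_and_round <- function(raw, scaler, classes = 1:7) {
  y <- raw * scaler$sd + scaler$mean
  y <- sign(y) * floor(abs(y) + 0.5)       # round half away from zero
  pmin(pmax(y, min(classes)), max(classes))
}

#' Train the classic regression-on-labels network
#'
#' The 300/200/100 logistic network trained by SGD on Z-standardized
#' labels, with an internal 80/20 train/validation split (the validation
#' fifth is held out from weight updates and its MSE reported).
#'
#' @param X n x d matrix (standardized + PCA-reduced upstream).
#' @param y integer gesture labels.
#' @param classes label set.
#' @param epochs,lr,batch_size,seed training controls (reference: SGD
#'   lr 0.2, momentum 0). `epochs` caps training; the validation MSE is
#'   evaluated every 5 epochs, the best weights are kept and training
#'   stops once the validation loss has not improved for 20 epochs.
#' @param val_frac internal validation fraction (default 0.2).
#' @param n_restarts train this many networks from different seeded
#'   initializations and keep the one with the lowest validation MSE
#'   (plain SGD on a deep logistic net has run-to-run variance).
#' @param patience early-stopping patience in 5-epoch evaluation rounds;
#'   `Inf` trains to the epoch cap.
#' @return object of class `classic_mlp` with the fitted layers, the
#'   [label_scaler()], the split indices and `val_mse`.
#' @export
train_classic_mlp <- function(X, y, classes = 1:7, epochs = 100, lr = 0.2,
                              batch_size = 32, seed = 1L, val_frac = 0.2,
                              n_restarts = 1, patience = 4L) {
  X <- as.matrix(X)
  n <- nrow(X)
  scaler <- label_scaler(y)
  ys <- matrix(scale_labels(scaler, y), ncol = 1)
  val_idx <- with_seed(derive_seed(seed, 3L),
                       sample.int(n, max(1, round(val_frac * n))))
  tr_idx <- setdiff(seq_len(n), val_idx)
  arch <- list(
    new_layer("dense", n_in = ncol(X), n_out = 300, act = "logistic"),
    new_layer("dense", n_in = 300, n_out = 200, act = "logistic"),
    new_layer("dense", n_in = 200, n_out = 100, act = "logistic"),
    new_layer("dense", n_in = 100, n_out = 1, act = "linear"))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- train_net(arch, X[tr_idx, , drop = FALSE], ys[tr_idx, , drop = FALSE],
                     loss = "mse", optimizer = "sgd", lr = lr, decay = 0,
                     epochs = epochs, batch_size = batch_size,
                     seed = derive_seed(seed, 41L, r),
                     val_X = X[val_idx, , drop = FALSE],
                     val_Y = ys[val_idx, , drop = FALSE],
                     eval_every = 5L, patience = patience)
    if (is.null(best) || fit$val < best$val) best <- fit
  }
  structure(list(layers = best$layers, scaler = scaler, classes = classes,
                 train_idx = tr_idx, val_idx = val_idx, val_mse = best$val),
            class = "classic_mlp")
}

#' @export
predict.classic_mlp <- function(object, newdata, ...) {
  raw <- mlp_predict_raw(object$layers, as.matrix(newdata))
  as.integer(predict_and_round(as.numeric(raw), object$scaler, object$classes))
}
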