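# Area-specific autoencoder (AAE): a stochastic encoder mapping a feature
# vector to a Gaussian latent (mu, sigma^2), a reparameterized sample, a
# decoder reconstructing the input, and an affine prediction head; trained
# with reconstruction MSE plus a gamma-weighted supervised MSE. Note this is
# NOT an adversarial autoencoder; the name is "area-specific".
#
# All networks are small MLPs with hand-written forward/backward passes and
# Adam updates (matrix ops only), which is both sufficient at this scale and
# keeps the package dependency-free.

relu <- function(x) pmax(x, 0)

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -s, s), n_in, n_out)
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Initialize area-specific autoencoder parameters
#'
#' Encoder and decoder are two-layer perceptrons with rectified-linear
#' hidden units; the encoder emits a latent mean and a raw log-variance
#' (variance via `exp`, floored at 1e-6); the prediction head is a single
#' affine map from the latent.
#'
#' @param d_in Input feature dimension.
#' @param latent_dim Latent dimension (default 16).
#' @param hidden Hidden width (default 64).
#' @param gamma Supervised-loss weight (>= 0, default 1).
#' @param kl_weight Optional prior-matching weight (default 0: the training
#'   objective is reconstruction + gamma * supervised only).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `aae_params`.
#' @export
aae_init <- function(d_in, latent_dim = 16, hidden = 64, gamma = 1,
                     kl_weight = 0, seed = 1L) {
  check_number(d_in, "d_in", lower = 1, integerish = TRUE)
  check_number(latent_dim, "latent_dim", lower = 1, integerish = TRUE)
  check_number(gamma, "gamma", lower = 0)
  w <- with_seed(substream_seed(seed, "aae-init"), list(
    W_e1 = glorot(d_in, hidden),      b_e1 = rep(0, hidden),
    W_mu = glorot(hidden, latent_dim), b_mu = rep(0, latent_dim),
    W_lv = glorot(hidden, latent_dim) * 0.1, b_lv = rep(-2, latent_dim),
    W_d1 = glorot(latent_dim, hidden), b_d1 = rep(0, hidden),
    W_d2 = glorot(hidden, d_in),      b_d2 = rep(0, d_in),
    W_p = glorot(latent_dim, 1),      b_p = 0))
  structure(list(weights = w, d_in = d_in, latent_dim = latent_dim,
                 hidden = hidden, gamma = gamma, kl_weight = kl_weight,
                 x_center = rep(0, d_in), x_scale = rep(1, d_in),
                 y_center = 0, y_scale = 1),
            class = "aae_params")
}

#' @export
print.aae_params <- function(x, ...) {
  cat(sprintf("<aae_params> %d -> %d (hidden %d), gamma = %g\n",
              x$d_in, x$latent_dim, x$hidden, x$gamma))
  invisible(x)
}

# Forward pass through the encoder for a batch (rows = items). Returns the
# intermediates needed by backprop.
encoder_forward <- function(X, w) {
  A1 <- sweep(X %*% w$W_e1, 2, w$b_e1, `+`)
  H1 <- relu(A1)
  mu <- sweep(H1 %*% w$W_mu, 2, w$b_mu, `+`)
  logvar <- sweep(H1 %*% w$W_lv, 2, w$b_lv, `+`)
  var <- pmax(exp(logvar), 1e-6)
  list(A1 = A1, H1 = H1, mu = mu, logvar = logvar, var = var)
}

decoder_forward <- function(Z, w) {
  A1 <- sweep(Z %*% w$W_d1, 2, w$b_d1, `+`)
  H1 <- relu(A1)
  Xhat <- sweep(H1 %*% w$W_d2, 2, w$b_d2, `+`)
  list(A1 = A1, H1 = H1, Xhat = Xhat)
}

standardize_x <- function(X, params) {
  sweep(sweep(X, 2, params$x_center), 2, params$x_scale, `/`)
}

#' Encode a feature vector to a latent code
#'
#' Maps (standardized) input features to a Gaussian latent distribution and
#' draws a reparameterized sample `mu + sqrt(var) * eps`. With
#' `deterministic = TRUE` (or `seed = NULL`) the sample equals the mean.
#'
#' @param x Numeric feature vector (or matrix with rows as items) matching
#'   the trained input schema.
#' @param params An `aae_params` object.
#' @param deterministic If `TRUE`, `sample = mean` (no noise).
#' @param seed Integer seed for the reparameterization draw.
#' @return A list of class `latent_code`: `mean`, `variance`, `sample`
#'   (matrices, rows = items).
#' @export
encode <- function(x, params, deterministic = FALSE, seed = 1L) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != params$d_in) {
    odcast_abort(sprintf("Input has %d features; the encoder expects %d.",
                         ncol(X), params$d_in), "odcast_shape_error")
  }
  Xs <- standardize_x(X, params)
  ef <- encoder_forward(Xs, params$weights)
  smp <- if (deterministic) ef$mu else {
    eps <- with_seed(substream_seed(seed, "aae-sample"),
                     matrix(rnorm(length(ef$mu)), nrow(ef$mu)))
    ef$mu + sqrt(ef$var) * eps
  }
  structure(list(mean = ef$mu, variance = ef$var, sample = smp),
            class = "latent_code")
}

#' Decode a latent vector back to feature space
#'
#' @param z Latent vector (or matrix with rows as items) of length
#'   `latent_dim`.
#' @param params An `aae_params` object.
#' @return Reconstructed features on the original (unstandardized) scale.
#' @export
decode <- function(z, params) {
  Z <- if (is.null(dim(z))) matrix(z, nrow = 1) else as.matrix(z)
  if (ncol(Z) != params$latent_dim) {
    odcast_abort(sprintf("Latent has %d entries; the decoder expects %d.",
                         ncol(Z), params$latent_dim), "odcast_shape_error")
  }
  df <- decoder_forward(Z, params$weights)
  sweep(sweep(df$Xhat, 2, params$x_scale, `*`), 2, params$x_center, `+`)
}

#' Mean-squared reconstruction loss
#'
#' `(1/N) * sum_i ||x_i - xhat_i||^2` over a batch (rows = items).
#'
#' @param batch_x,batch_x_hat Equal-shape matrices (or vectors).
#' @return Nonnegative scalar.
#' @export
reconstruction_loss <- function(batch_x, batch_x_hat) {
  X <- if (is.null(dim(batch_x))) matrix(batch_x, nrow = 1) else
    as.matrix(batch_x)
  Xh <- if (is.null(dim(batch_x_hat))) matrix(batch_x_hat, nrow = 1) else
    as.matrix(batch_x_hat)
  if (!all(dim(X) == dim(Xh))) {
    odcast_abort("Batches must have equal shapes.", "odcast_shape_error")
  }
  if (nrow(X) == 0) {
    odcast_abort("Empty batch.", "odcast_domain_error")
  }
  sum((X - Xh)^2) / nrow(X)
}

#' Supervised prediction loss from latent codes
#'
#' Applies the affine prediction head to each latent vector and returns the
#' mean squared error against the labels:
#' `(1/N) * sum_i (y_i - f_pred(z_i))^2`.
#'
#' @param batch_z Matrix of latent vectors (rows = items).
#' @param batch_y Numeric labels, one per row of `batch_z`.
#' @param params An `aae_params` object.
#' @return Nonnegative scalar.
#' @export
supervised_loss <- function(batch_z, batch_y, params) {
  Z <- if (is.null(dim(batch_z))) matrix(batch_z, nrow = 1) else
    as.matrix(batch_z)
  if (length(batch_y) == 0 || nrow(Z) == 0) {
    odcast_abort("No labeled items in the batch.", "odcast_domain_error")
  }
  yhat <- drop(Z %*% params$weights$W_p) + params$weights$b_p
  mean((batch_y - yhat)^2)
}

#' Combined autoencoder objective
#'
#' @param recon Reconstruction loss (nonnegative).
#' @param sup Supervised loss (nonnegative).
#' @param gamma Supervised weight (>= 0).
#' @return `recon + gamma * sup`.
#' @export
total_loss <- function(recon, sup, gamma) {
  if (recon < 0 || sup < 0 || gamma < 0) {
    odcast_abort("Loss components and gamma must be nonnegative.",
                 "odcast_domain_error")
  }
  recon + gamma * sup
}

# One full forward+backward pass on a standardized batch; returns loss
# components and gradients for every weight. Supervision uses standardized
# labels ys; eps is the reparameterization noise (zero matrix in
# deterministic mode).
aae_grads <- function(Xs, ys, w, gamma, kl_weight, eps) {
  N <- nrow(Xs)
  ef <- encoder_forward(Xs, w)
  sdv <- sqrt(ef$var)
  Z <- ef$mu + sdv * eps
  df <- decoder_forward(Z, w)
  yhat <- drop(Z %*% w$W_p) + w$b_p

  R <- df$Xhat - Xs                       # N x d
  recon <- sum(R^2) / N
  sup <- mean((ys - yhat)^2)
  kl <- if (kl_weight > 0) {
    0.5 * sum(ef$mu^2 + ef$var - ef$logvar - 1) / N
  } else 0
  loss <- recon + gamma * sup + kl_weight * kl

  # ---- backward ----
  dXhat <- 2 * R / N
  dW_d2 <- t(df$H1) %*% dXhat
  db_d2 <- colSums(dXhat)
  dH1d <- dXhat %*% t(w$W_d2)
  dA1d <- dH1d * (df$A1 > 0)
  dW_d1 <- t(Z) %*% dA1d
  db_d1 <- colSums(dA1d)
  dZ_rec <- dA1d %*% t(w$W_d1)

  dyhat <- -2 * (ys - yhat) / N * gamma
  dW_p <- t(Z) %*% matrix(dyhat, ncol = 1)
  db_p <- sum(dyhat)
  dZ_sup <- matrix(dyhat, ncol = 1) %*% t(w$W_p)

  dZ <- dZ_rec + dZ_sup
  dmu <- dZ
  dlogvar <- dZ * eps * 0.5 * sdv        # d z / d logvar = eps * sd / 2
  if (kl_weight > 0) {
    dmu <- dmu + kl_weight * ef$mu / N
    dlogvar <- dlogvar + kl_weight * 0.5 * (ef$var - 1) / N
  }
  dH1e <- dmu %*% t(w$W_mu) + dlogvar %*% t(w$W_lv)
  dA1e <- dH1e * (ef$A1 > 0)
  grads <- list(
    W_e1 = t(Xs) %*% dA1e, b_e1 = colSums(dA1e),
    W_mu = t(ef$H1) %*% dmu, b_mu = colSums(dmu),
    W_lv = t(ef$H1) %*% dlogvar, b_lv = colSums(dlogvar),
    W_d1 = dW_d1, b_d1 = db_d1,
    W_d2 = dW_d2, b_d2 = db_d2,
    W_p = dW_p, b_p = db_p)
  list(loss = loss, recon = recon, sup = sup, kl = kl, grads = grads)
}

# Assemble AAE training examples from an augmented (or raw) panel: one row
# per region per usable quarter, with the same feature schema the
# downstream predictor uses (rates, raw test volume, lags, static); label =
# deaths at quarter t + gap + 1. No outcome history enters x.
aae_training_matrix <- function(panel, gap = 1) {
  Q <- dim(panel$dynamic)[2]
  ts <- seq_len(Q - gap - 1)
  X <- NULL; y <- NULL
  for (t in ts) {
    X <- rbind(X, node_features_at(panel, t))
    y <- c(y, panel$deaths[, t + gap + 1])
  }
  list(X = X, y = as.numeric(y))
}

#' Train the area-specific autoencoder
#'
#' Full-batch Adam on the combined loss `recon + gamma * sup` (plus an
#' optional prior-matching term, off by default), with early stopping on a
#' held-out fraction of regions and the best-validation weights returned.
#' Features are standardized over the training split (statistics stored in
#' the returned parameters); the supervised head is trained on standardized
#' labels so `gamma` stays scale-free.
#'
#' @param augmented An `augmented_panel` (or `panel_dataset`) supplying
#'   region features and death labels.
#' @param latent_dim,hidden,gamma,kl_weight Architecture and loss settings
#'   (see [aae_init()]).
#' @param epochs Maximum training epochs (default 200).
#' @param lr Adam learning rate (default 1e-3).
#' @param val_frac Fraction of rows held out for early stopping.
#' @param patience Epochs without validation improvement before stopping.
#' @param gap Quarters between the feature quarter and its label quarter
#'   (default 1, mirroring the forecasting task).
#' @param deterministic If `TRUE`, train with `z = mu` (no sampling noise).
#' @param seed Integer seed (initialization, split, sampling noise).
#' @return An object of class `aae_fit`: `params` (`aae_params`), `trace`
#'   (tibble of per-epoch losses), `best_epoch`, `config`.
#' @export
train_aae <- function(augmented, latent_dim = 16, hidden = 64, gamma = 1,
                      kl_weight = 0, epochs = 200, lr = 1e-3,
                      val_frac = 0.2, patience = 25, gap = 1,
                      deterministic = TRUE, seed = 1L) {
  tm <- aae_training_matrix(augmented, gap = gap)
  N <- nrow(tm$X)
  if (N < 4) {
    odcast_abort("Too few training rows for the autoencoder.",
                 "odcast_domain_error")
  }
  params <- aae_init(ncol(tm$X), latent_dim, hidden, gamma, kl_weight, seed)
  idx_val <- with_seed(substream_seed(seed, "aae-split"),
                       sample.int(N, max(1, floor(val_frac * N))))
  tr <- setdiff(seq_len(N), idx_val)
  params$x_center <- colMeans(tm$X[tr, , drop = FALSE])
  sds <- apply(tm$X[tr, , drop = FALSE], 2, sd)
  params$x_scale <- ifelse(sds > 1e-12, sds, 1)
  params$y_center <- mean(tm$y[tr])
  ysd <- sd(tm$y[tr])
  params$y_scale <- if (is.finite(ysd) && ysd > 1e-12) ysd else 1

  Xs_tr <- standardize_x(tm$X[tr, , drop = FALSE], params)
  Xs_va <- standardize_x(tm$X[idx_val, , drop = FALSE], params)
  ys_tr <- (tm$y[tr] - params$y_center) / params$y_scale
  ys_va <- (tm$y[idx_val] - params$y_center) / params$y_scale

  w <- params$weights
  st <- adam_state(w)
  best <- list(w = w, val = Inf, epoch = 0L)
  trace <- vector("list", epochs)
  wait <- 0L
  rng_seed <- substream_seed(seed, "aae-noise")
  for (ep in seq_len(epochs)) {
    eps <- if (deterministic) matrix(0, length(tr), latent_dim) else
      with_seed(rng_seed + ep,
                matrix(rnorm(length(tr) * latent_dim), length(tr)))
    g <- aae_grads(Xs_tr, ys_tr, w, gamma, kl_weight, eps)
    if (!is.finite(g$loss)) {
      odcast_abort(sprintf("Non-finite training loss at epoch %d.", ep),
                   "odcast_training_error")
    }
    upd <- adam_update(w, g$grads, st, lr, ep)
    w <- upd$params; st <- upd$state

    efv <- encoder_forward(Xs_va, w)
    dfv <- decoder_forward(efv$mu, w)
    yhat_va <- drop(efv$mu %*% w$W_p) + w$b_p
    val <- sum((dfv$Xhat - Xs_va)^2) / nrow(Xs_va) +
      gamma * mean((ys_va - yhat_va)^2)
    trace[[ep]] <- tibble::tibble(epoch = ep, train_loss = g$loss,
                                  train_recon = g$recon,
                                  train_sup = g$sup, val_loss = val)
    if (val < best$val - 1e-9) {
      best <- list(w = w, val = val, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  params$weights <- best$w
  structure(list(
    params = params,
    trace = dplyr::bind_rows(trace[!vapply(trace, is.null, logical(1))]),
    best_epoch = best$epoch,
    config = list(latent_dim = latent_dim, hidden = hidden, gamma = gamma,
                  kl_weight = kl_weight, epochs = epochs, lr = lr,
                  val_frac = val_frac, patience = patience, gap = gap,
                  deterministic = deterministic, seed = seed)),
    class = "aae_fit")
}

#' @export
print.aae_fit <- function(x, ...) {
  cat(sprintf(
    "<aae_fit> d_in %d -> latent %d; best epoch %d (val loss %.4g)\n",
    x$params$d_in, x$params$latent_dim, x$best_epoch,
    min(x$trace$val_loss)))
  invisible(x)
}

#' @method tidy aae_fit
#' @export
tidy.aae_fit <- function(x, ...) x$trace

#' @method glance aae_fit
#' @export
glance.aae_fit <- function(x, ...) {
  tibble::tibble(
    d_in = x$params$d_in,
    latent_dim = x$params$latent_dim,
    gamma = x$params$gamma,
    epochs_run = nrow(x$trace),
    best_epoch = x$best_epoch,
    train_loss = x$trace$train_loss[nrow(x$trace)],
    val_loss = min(x$trace$val_loss))
}

#' Plot the training trace of an autoencoder fit
#'
#' @param object An `aae_fit`.
#' @param ... Unused.
#' @return A ggplot of train and validation loss against epoch.
#' @method autoplot aae_fit
#' @export
autoplot.aae_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace,
                              cols = c("train_loss", "val_loss"),
                              names_to = "series", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Area-specific autoencoder training",
                  x = "epoch", y = "loss")
}
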