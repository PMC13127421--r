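# Spatiotemporal graph neural network: per quarter, two symmetric-normalized
# graph-convolution layers over the area adjacency propagate each area's
# (AAE-latent) features to its neighbors; an LSTM over the observation
# window carries the temporal state; an affine head emits the target-quarter
# death-count prediction. Trained with MSE and Adam, backprop written by
# hand (the problem sizes here are tiny by neural-network standards).

sigm <- function(x) 1 / (1 + exp(-x))

#' Symmetric-normalized adjacency with self-loops
#'
#' Adds a self-loop to every node and returns the matrix with entries
#' `1 / sqrt(d_i d_j)` for `j` in `N(i) U {i}` and 0 otherwise, where
#' `d_i = |N(i)| + 1` counts the self-loop — the standard renormalized
#' graph-convolution propagation matrix. Symmetric and nonnegative.
#'
#' @param graph An `area_graph`.
#' @return A dense area x area numeric matrix.
#' @export
normalized_adjacency <- function(graph) {
  A <- length(graph$area_ids)
  M <- diag(1, A)
  dimnames(M) <- list(graph$area_ids, graph$area_ids)
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, graph$area_ids)
    j <- match(graph$edges$to, graph$area_ids)
    M[cbind(i, j)] <- 1
    M[cbind(j, i)] <- 1
  }
  d <- rowSums(M)
  M * (1 / sqrt(d)) %o% (1 / sqrt(d))
}

#' Initialize STGNN parameters
#'
#' @param d_in Node feature dimension entering the first graph layer.
#' @param gcn_dims Integer vector of the two graph-layer widths.
#' @param recurrent_dim LSTM state dimension.
#' @param seed Integer seed.
#' @param y_init Initial output bias (e.g. the training-label mean).
#' @return An object of class `stgnn_params`.
#' @export
stgnn_init <- function(d_in, gcn_dims = c(32, 32), recurrent_dim = 32,
                       seed = 1L, y_init = 0) {
  stopifnot(length(gcn_dims) == 2)
  h2 <- gcn_dims[2]; r <- recurrent_dim
  w <- with_seed(substream_seed(seed, "stgnn-init"), {
    lstm_in <- function() glorot(h2, r)
    lstm_rec <- function() glorot(r, r)
    list(
      W0 = glorot(d_in, gcn_dims[1]),
      W1 = glorot(gcn_dims[1], h2),
      Wi = lstm_in(), Ui = lstm_rec(), bi = rep(0, r),
      Wf = lstm_in(), Uf = lstm_rec(), bf = rep(1, r),  # forget bias 1
      Wo = lstm_in(), Uo = lstm_rec(), bo = rep(0, r),
      Wg = lstm_in(), Ug = lstm_rec(), bg = rep(0, r),
      W_out = matrix(0, r, 1), b = y_init)
  })
  structure(list(weights = w, d_in = d_in, gcn_dims = gcn_dims,
                 recurrent_dim = recurrent_dim),
            class = "stgnn_params")
}

#' Two-layer graph convolution forward pass
#'
#' `h1 = relu(Ahat X W0)`, `h2 = relu(Ahat h1 W1)` with `Ahat` from
#' [normalized_adjacency()]. For an isolated node this reduces exactly to a
#' two-layer perceptron on its own features.
#'
#' @param node_features Area x d_in matrix aligned to the graph ordering.
#' @param graph An `area_graph` (or a precomputed `Ahat` matrix).
#' @param params An `stgnn_params` object.
#' @return Area x h2 matrix of node embeddings.
#' @export
gcn_forward <- function(node_features, graph, params) {
  Ahat <- if (is.matrix(graph)) graph else normalized_adjacency(graph)
  X <- as.matrix(node_features)
  if (ncol(X) != nrow(params$weights$W0)) {
    odcast_abort(sprintf("Node features have %d columns; W0 expects %d.",
                         ncol(X), nrow(params$weights$W0)),
                 "odcast_shape_error")
  }
  H1 <- relu(Ahat %*% X %*% params$weights$W0)
  relu(Ahat %*% H1 %*% params$weights$W1)
}

# Cached GCN forward for backprop.
gcn_forward_cached <- function(X, Ahat, w) {
  P1 <- Ahat %*% X %*% w$W0
  H1 <- relu(P1)
  P2 <- Ahat %*% H1 %*% w$W1
  list(X = X, P1 = P1, H1 = H1, P2 = P2, H2 = relu(P2))
}

# Backprop through the cached GCN given dH2; Ahat is symmetric.
gcn_backward <- function(cache, Ahat, w, dH2) {
  dP2 <- dH2 * (cache$P2 > 0)
  dW1 <- t(Ahat %*% cache$H1) %*% dP2
  dH1 <- Ahat %*% (dP2 %*% t(w$W1))
  dP1 <- dH1 * (cache$P1 > 0)
  dW0 <- t(Ahat %*% cache$X) %*% dP1
  list(dW0 = dW0, dW1 = dW1)
}

# LSTM forward over a list of input matrices (each A x h2), shared weights,
# zero initial state; caches everything BPTT needs.
lstm_forward_cached <- function(inputs, w) {
  A <- nrow(inputs[[1]]); r <- ncol(w$Wi)
  h <- matrix(0, A, r); c0 <- matrix(0, A, r)
  steps <- vector("list", length(inputs))
  cprev <- c0
  for (t in seq_along(inputs)) {
    X <- inputs[[t]]
    i <- sigm(sweep(X %*% w$Wi + h %*% w$Ui, 2, w$bi, `+`))
    f <- sigm(sweep(X %*% w$Wf + h %*% w$Uf, 2, w$bf, `+`))
    o <- sigm(sweep(X %*% w$Wo + h %*% w$Uo, 2, w$bo, `+`))
    g <- tanh(sweep(X %*% w$Wg + h %*% w$Ug, 2, w$bg, `+`))
    cc <- f * cprev + i * g
    hn <- o * tanh(cc)
    steps[[t]] <- list(X = X, h_prev = h, c_prev = cprev,
                       i = i, f = f, o = o, g = g, c = cc, h = hn)
    h <- hn; cprev <- cc
  }
  list(steps = steps, h = h)
}

# BPTT given dh at the final step; returns weight grads and per-step input
# grads (for the GCN below).
lstm_backward <- function(cache, w, dh_final) {
  r <- ncol(w$Wi)
  zeros <- function(m) m * 0
  g <- list(Wi = zeros(w$Wi), Ui = zeros(w$Ui), bi = rep(0, r),
            Wf = zeros(w$Wf), Uf = zeros(w$Uf), bf = rep(0, r),
            Wo = zeros(w$Wo), Uo = zeros(w$Uo), bo = rep(0, r),
            Wg = zeros(w$Wg), Ug = zeros(w$Ug), bg = rep(0, r))
  dX <- vector("list", length(cache$steps))
  dh <- dh_final
  dc <- zeros(dh_final)
  for (t in rev(seq_along(cache$steps))) {
    s <- cache$steps[[t]]
    tc <- tanh(s$c)
    do <- dh * tc * s$o * (1 - s$o)
    dc <- dc + dh * s$o * (1 - tc^2)
    di <- dc * s$g * s$i * (1 - s$i)
    dg <- dc * s$i * (1 - s$g^2)
    df <- dc * s$c_prev * s$f * (1 - s$f)
    dc_prev <- dc * s$f

    g$Wi <- g$Wi + t(s$X) %*% di; g$Ui <- g$Ui + t(s$h_prev) %*% di
    g$bi <- g$bi + colSums(di)
    g$Wf <- g$Wf + t(s$X) %*% df; g$Uf <- g$Uf + t(s$h_prev) %*% df
    g$bf <- g$bf + colSums(df)
    g$Wo <- g$Wo + t(s$X) %*% do; g$Uo <- g$Uo + t(s$h_prev) %*% do
    g$bo <- g$bo + colSums(do)
    g$Wg <- g$Wg + t(s$X) %*% dg; g$Ug <- g$Ug + t(s$h_prev) %*% dg
    g$bg <- g$bg + colSums(dg)

    dX[[t]] <- di %*% t(w$Wi) + df %*% t(w$Wf) +
      do %*% t(w$Wo) + dg %*% t(w$Wg)
    dh <- di %*% t(w$Ui) + df %*% t(w$Uf) +
      do %*% t(w$Uo) + dg %*% t(w$Ug)
    dc <- dc_prev
  }
  list(grads = g, dX = dX)
}

#' Recurrent pass over a window of per-quarter embeddings
#'
#' Applies a standard LSTM recurrence independently per area over the
#' quarter-ordered embedding sequence (zero initial state) and returns the
#' final per-area state.
#'
#' @param embedding_sequence List of area x h2 matrices, one per quarter in
#'   the observation window, in chronological order.
#' @param params An `stgnn_params` object.
#' @return Area x recurrent_dim matrix of final states.
#' @export
temporal_forward <- function(embedding_sequence, params) {
  if (length(embedding_sequence) == 0) {
    odcast_abort("Empty embedding sequence.", "odcast_domain_error")
  }
  lstm_forward_cached(embedding_sequence, params$weights)$h
}

#' Affine prediction head
#'
#' `y_hat = W_out s + b`, reported raw and clamped at zero (counts are
#' nonnegative; the training loss uses the raw values).
#'
#' @param states Area x recurrent_dim matrix from [temporal_forward()].
#' @param params An `stgnn_params` object.
#' @return Tibble with columns `y_pred_raw` and `y_pred` (clamped).
#' @export
predict_counts <- function(states, params) {
  raw <- drop(as.matrix(states) %*% params$weights$W_out) + params$weights$b
  tibble::tibble(y_pred_raw = raw, y_pred = pmax(raw, 0))
}

#' Mean-squared training loss of the predictor
#'
#' @param y_hat Raw (unclamped) predictions.
#' @param y Observed counts.
#' @return Mean squared error over areas.
#' @export
stgnn_loss <- function(y_hat, y) {
  if (length(y_hat) != length(y)) {
    odcast_abort("Lengths differ.", "odcast_shape_error")
  }
  if (length(y) == 0) {
    odcast_abort("Empty batch.", "odcast_domain_error")
  }
  mean((y - y_hat)^2)
}

#' Sliding forecast windows with a reporting-lag gap
#'
#' Each window uses quarters `t - obs_window + 1 ... t` as input and
#' predicts quarter `t + gap + 1` — the gap models the lag before death
#' data become available. Windows are split chronologically into train,
#' validation and test; no window's target precedes another split's inputs.
#'
#' @param dataset A `panel_dataset` (only its quarter index is used).
#' @param obs_window Observation quarters per window (default 3).
#' @param gap Reporting-lag quarters between window end and target
#'   (default 1).
#' @param val_frac,test_frac Fractions of windows (by target quarter,
#'   latest last) assigned to validation and test.
#' @return Tibble with columns `window_id`, `input_quarters` (list),
#'   `window_end`, `target_quarter`, `split`.
#' @export
build_windows <- function(dataset, obs_window = 3, gap = 1,
                          val_frac = 0.15, test_frac = 0.2) {
  check_number(obs_window, "obs_window", lower = 1, integerish = TRUE)
  check_number(gap, "gap", lower = 0, integerish = TRUE)
  Q <- length(dataset$quarters)
  need <- obs_window + gap + 1
  if (Q < need) {
    odcast_abort(sprintf(
      "Need at least %d quarters for obs_window %d and gap %d; have %d.",
      need, obs_window, gap, Q), "odcast_domain_error")
  }
  ends <- seq(obs_window, Q - gap - 1)
  W <- length(ends)
  n_test <- max(1, round(test_frac * W))
  n_val <- max(1, round(val_frac * W))
  if (n_test + n_val >= W) {
    odcast_abort("Not enough windows for the requested splits.",
                 "odcast_domain_error")
  }
  split <- rep("train", W)
  split[seq(W - n_test + 1, W)] <- "test"
  split[seq(W - n_test - n_val + 1, W - n_test)] <- "validation"
  tibble::tibble(
    window_id = seq_len(W),
    input_quarters = purrr::map(ends, ~seq(.x - obs_window + 1, .x)),
    window_end = ends,
    target_quarter = ends + gap + 1L,
    split = split)
}

# Node features for quarter t: [dynamic rates, raw test volume (log1p of
# the test denominator, the panel's only population-scale signal), lag
# means, static] — the same schema the AAE was trained on.
node_features_at <- function(dataset, t) {
  A <- dim(dataset$dynamic)[1]
  cbind(matrix(dataset$dynamic[, t, ], A),
        log1p(rowMeans(matrix(dataset$dynamic_denom[, t, ], A))),
        matrix(dataset$lag[, t, ], A),
        dataset$static)
}

# Encode quarter-t features to node inputs: AAE latent means if an encoder
# is supplied, otherwise standardized raw features.
stgnn_node_inputs <- function(dataset, t, encoder, center, scale) {
  X <- node_features_at(dataset, t)
  if (!is.null(encoder)) {
    encode(X, encoder, deterministic = TRUE)$mean
  } else {
    sweep(sweep(X, 2, center), 2, scale, `/`)
  }
}

#' Train the spatiotemporal predictor
#'
#' For every window: per-quarter features pass through the (frozen,
#' deterministic) autoencoder encoder, then two graph-convolution layers
#' over the area adjacency, then an LSTM across the window; an affine head
#' predicts the target-quarter counts. Full-batch Adam on the MSE over all
#' training windows, early stopping on validation MSE; the best weights are
#' used to emit test-split prediction records. With `encoder = NULL`, raw
#' standardized features feed the graph layers directly (the
#' no-augmentation/no-AAE ablation).
#'
#' @param dataset A `panel_dataset`.
#' @param encoder An `aae_params` object (from [train_aae()]`$params`), or
#'   `NULL` for the raw-feature ablation.
#' @param obs_window,gap Window geometry (see [build_windows()]).
#' @param gcn_dims,recurrent_dim Layer widths.
#' @param epochs,lr,patience Optimization settings.
#' @param val_frac,test_frac Chronological split fractions.
#' @param seed Integer seed.
#' @return An object of class `stgnn_fit`: `params`, `trace`,
#'   `predictions` (test-split records: `area_id`, `target_quarter`,
#'   `y_true`, `y_pred_raw`, `y_pred`, `population`, `prev_observed`,
#'   `below_threshold`), `windows`, `config`.
#' @export
train_stgnn <- function(dataset, encoder, obs_window = 3, gap = 1,
                        gcn_dims = c(32, 32), recurrent_dim = 32,
                        epochs = 300, lr = 3e-3, patience = 30,
                        val_frac = 0.15, test_frac = 0.2, seed = 1L) {
  windows <- build_windows(dataset, obs_window, gap, val_frac, test_frac)
  Ahat <- normalized_adjacency(dataset$graph)
  A <- length(dataset$graph$area_ids)

  center <- NULL; scale <- NULL
  if (is.null(encoder)) {
    tr_q <- sort(unique(unlist(
      windows$input_quarters[windows$split == "train"])))
    Xall <- do.call(rbind, lapply(tr_q, function(t)
      node_features_at(dataset, t)))
    center <- colMeans(Xall)
    sds <- apply(Xall, 2, sd)
    scale <- ifelse(sds > 1e-12, sds, 1)
    d_in <- ncol(Xall)
  } else {
    d_in <- encoder$latent_dim
  }

  # precompute per-quarter node inputs once (encoder is frozen)
  q_used <- sort(unique(unlist(windows$input_quarters)))
  inputs_by_q <- stats::setNames(lapply(q_used, function(t)
    stgnn_node_inputs(dataset, t, encoder, center, scale)),
    as.character(q_used))

  tr_ids <- which(windows$split == "train")
  va_ids <- which(windows$split == "validation")
  te_ids <- which(windows$split == "test")
  y_tr_mean <- mean(dataset$deaths[, windows$target_quarter[tr_ids]])
  params <- stgnn_init(d_in, gcn_dims, recurrent_dim, seed,
                       y_init = y_tr_mean)
  w <- params$weights
  st <- adam_state(w)

  forward_window <- function(wid, w) {
    qs <- windows$input_quarters[[wid]]
    caches <- lapply(qs, function(t)
      gcn_forward_cached(inputs_by_q[[as.character(t)]], Ahat, w))
    lc <- lstm_forward_cached(lapply(caches, `[[`, "H2"), w)
    raw <- drop(lc$h %*% w$W_out) + w$b
    list(gcn = caches, lstm = lc, raw = raw,
         y = dataset$deaths[, windows$target_quarter[wid]])
  }

  eval_mse <- function(ids, w) {
    mean(vapply(ids, function(wid) {
      fw <- forward_window(wid, w)
      mean((fw$y - fw$raw)^2)
    }, numeric(1)))
  }

  best <- list(w = w, val = Inf, epoch = 0L)
  trace <- vector("list", epochs)
  wait <- 0L
  for (ep in seq_len(epochs)) {
    grads <- NULL
    loss <- 0
    for (wid in tr_ids) {
      fw <- forward_window(wid, w)
      err <- fw$raw - fw$y
      loss <- loss + mean(err^2)
      dout <- matrix(2 * err / (A * length(tr_ids)), ncol = 1)
      dh <- dout %*% t(w$W_out)
      g <- list(W_out = t(fw$lstm$h) %*% dout, b = sum(dout))
      lb <- lstm_backward(fw$lstm, w, dh)
      g <- c(g, lb$grads)
      g$W0 <- 0 * w$W0; g$W1 <- 0 * w$W1
      for (t in seq_along(fw$gcn)) {
        gb <- gcn_backward(fw$gcn[[t]], Ahat, w, lb$dX[[t]])
        g$W0 <- g$W0 + gb$dW0
        g$W1 <- g$W1 + gb$dW1
      }
      grads <- if (is.null(grads)) g else
        purrr::map2(grads, g[names(grads)], `+`)
    }
    loss <- loss / length(tr_ids)
    if (!is.finite(loss)) {
      odcast_abort(sprintf("Non-finite training loss at epoch %d.", ep),
                   "odcast_training_error")
    }
    upd <- adam_update(w, grads[names(w)], st, lr, ep)
    w <- upd$params; st <- upd$state
    val <- eval_mse(va_ids, w)
    trace[[ep]] <- tibble::tibble(epoch = ep, train_loss = loss,
                                  val_loss = val)
    if (val < best$val - 1e-9) {
      best <- list(w = w, val = val, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  w <- best$w
  params$weights <- w

  threshold <- minimal_population((4 / 10000) / 12)
  preds <- dplyr::bind_rows(lapply(te_ids, function(wid) {
    fw <- forward_window(wid, w)
    tibble::tibble(
      area_id = dataset$graph$area_ids,
      target_quarter = windows$target_quarter[wid],
      y_true = as.integer(fw$y),
      y_pred_raw = fw$raw,
      y_pred = pmax(fw$raw, 0),
      population = dataset$graph$populations,
      prev_observed = as.integer(
        dataset$deaths[, windows$window_end[wid]]),
      below_threshold = dataset$graph$populations < threshold)
  }))
  structure(list(
    params = params,
    trace = dplyr::bind_rows(trace[!vapply(trace, is.null, logical(1))]),
    best_epoch = best$epoch,
    predictions = preds,
    windows = windows,
    config = list(obs_window = obs_window, gap = gap, gcn_dims = gcn_dims,
                  recurrent_dim = recurrent_dim, epochs = epochs, lr = lr,
                  patience = patience, val_frac = val_frac,
                  test_frac = test_frac, seed = seed,
                  used_encoder = !is.null(encoder))),
    class = "stgnn_fit")
}

#' @export
print.stgnn_fit <- function(x, ...) {
  cat(sprintf(
    "<stgnn_fit> best epoch %d (val MSE %.4g), %d test records\n",
    x$best_epoch, min(x$trace$val_loss), nrow(x$predictions)))
  invisible(x)
}

#' @method tidy stgnn_fit
#' @export
tidy.stgnn_fit <- function(x, ...) x$predictions

#' @method glance stgnn_fit
#' @export
glance.stgnn_fit <- function(x, ...) {
  m <- compute_metrics(x$predictions)
  tibble::tibble(
    epochs_run = nrow(x$trace),
    best_epoch = x$best_epoch,
    val_mse = min(x$trace$val_loss),
    test_smape_pct = m$smape_pct,
    test_mae = m$mae,
    test_rmse = m$rmse)
}

#' Plot observed against predicted counts on the test split
#'
#' @param object An `stgnn_fit`.
#' @param ... Unused.
#' @return A ggplot scatter of predicted vs observed counts.
#' @method autoplot stgnn_fit
#' @export
autoplot.stgnn_fit <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$y_true, y = .data$y_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "observed deaths", y = "predicted deaths",
                  title = "Test-quarter predictions")
}

#' Persistence baseline predictions
#'
#' Forecasts each area's target-quarter count as its last observed count
#' (the window-end quarter) — the reference point for judging whether the
#' learned model adds value.
#'
#' @param dataset A `panel_dataset`.
#' @param obs_window,gap,val_frac,test_frac Window geometry, as in
#'   [build_windows()].
#' @return Test-split prediction records in the same shape as
#'   `stgnn_fit$predictions`.
#' @export
persistence_baseline <- function(dataset, obs_window = 3, gap = 1,
                                 val_frac = 0.15, test_frac = 0.2) {
  windows <- build_windows(dataset, obs_window, gap, val_frac, test_frac)
  te <- windows[windows$split == "test", ]
  threshold <- minimal_population((4 / 10000) / 12)
  dplyr::bind_rows(lapply(seq_len(nrow(te)), function(i) {
    prev <- dataset$deaths[, te$window_end[i]]
    tibble::tibble(
      area_id = dataset$graph$area_ids,
      target_quarter = te$target_quarter[i],
      y_true = as.integer(dataset$deaths[, te$target_quarter[i]]),
      y_pred_raw = as.numeric(prev),
      y_pred = as.numeric(prev),
      population = dataset$graph$populations,
      prev_observed = as.integer(prev),
      below_threshold = dataset$graph$populations < threshold)
  }))
}
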