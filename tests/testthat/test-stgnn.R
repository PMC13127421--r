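test_that("normalized adjacency uses self-loops and symmetric scaling", {
  iso <- area_graph("X", data.frame(from = character(0),
                                    to = character(0)), 10)
  expect_equal(normalized_adjacency(iso), matrix(1, 1, 1,
               dimnames = list("X", "X")))
  path2 <- area_graph(c("A", "B"), data.frame(from = "A", to = "B"),
                      c(1, 1))
  Ahat <- normalized_adjacency(path2)
  expect_equal(unname(Ahat), matrix(0.5, 2, 2))   # d_A = d_B = 2
  g <- generate_geography(12, 3, 4, 0.1, 5, populations = rep(1, 12))
  M <- normalized_adjacency(g)
  expect_equal(M, t(M))
  expect_true(all(M >= 0))
})

test_that("graph convolution matches a dense per-node brute-force oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    # random symmetric adjacency, no self loops
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.5) A[i, j] <- A[j, i] <- 1
    }
    ids <- paste0("N", seq_len(n))
    ed <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
    g <- area_graph(ids, data.frame(from = ids[ed[, 1]],
                                    to = ids[ed[, 2]]), rep(1, n))
    d_in <- 3
    p <- stgnn_init(d_in, c(4, 5), 3, seed = rep)
    X <- matrix(rnorm(n * d_in), n)
    out <- gcn_forward(X, g, p)
    # brute force: per-node summation with 1/sqrt(d_i d_j) coefficients
    deg <- rowSums(A) + 1
    brute_layer <- function(H, W) {
      t(sapply(seq_len(n), function(i) {
        acc <- rep(0, ncol(W))
        for (j in c(i, which(A[i, ] == 1))) {
          acc <- acc + (1 / sqrt(deg[i] * deg[j])) *
            drop(H[j, ] %*% W)
        }
        pmax(acc, 0)
      }))
    }
    H1 <- brute_layer(X, p$weights$W0)
    H2 <- brute_layer(H1, p$weights$W1)
    expect_equal(unname(out), unname(H2), tolerance = 1e-6)
  }
})

test_that("an isolated node's graph convolution collapses to a perceptron", {
  iso <- area_graph("X", data.frame(from = character(0),
                                    to = character(0)), 10)
  p <- stgnn_init(3, c(4, 4), 2, seed = 2)
  x <- matrix(c(0.5, -1, 2), 1)
  out <- gcn_forward(x, iso, p)
  manual <- pmax(pmax(x %*% p$weights$W0, 0) %*% p$weights$W1, 0)
  expect_equal(unname(out), unname(manual))
  expect_equal(unname(gcn_forward(matrix(0, 1, 3), iso, p)),
               matrix(0, 1, 4))
})

test_that("the recurrence matches an independent scalar LSTM oracle", {
  p <- stgnn_init(1, c(1, 1), 2, seed = 6)
  w <- p$weights
  x1 <- matrix(0.7, 1, 1); x2 <- matrix(-0.3, 1, 1)
  out <- temporal_forward(list(x1, x2), p)
  # hand-rolled scalar recurrence, state dim 2, written independently
  sg <- function(v) 1 / (1 + exp(-v))
  h <- c(0, 0); cc <- c(0, 0)
  for (x in c(0.7, -0.3)) {
    i <- sg(x * w$Wi[1, ] + h %*% w$Ui + w$bi)
    f <- sg(x * w$Wf[1, ] + h %*% w$Uf + w$bf)
    o <- sg(x * w$Wo[1, ] + h %*% w$Uo + w$bo)
    g <- tanh(x * w$Wg[1, ] + h %*% w$Ug + w$bg)
    cc <- drop(f) * cc + drop(i) * drop(g)
    h <- drop(o) * tanh(cc)
  }
  expect_equal(drop(out), h, tolerance = 1e-12)
  # single-step window from zero initial state
  one <- temporal_forward(list(x1), p)
  expect_equal(dim(one), c(1, 2))
  expect_error(temporal_forward(list(), p),
               class = "odcast_domain_error")
})

test_that("the prediction head is affine with zero-clamped reporting", {
  p <- stgnn_init(2, c(2, 2), 3, seed = 1)
  p$weights$W_out <- matrix(c(1, -1, 2), 3)
  p$weights$b <- 3
  s0 <- matrix(0, 1, 3)
  expect_equal(predict_counts(s0, p)$y_pred_raw, 3)
  s_neg <- matrix(c(0, 3.4, 0), 1)
  pc <- predict_counts(s_neg, p)
  expect_equal(pc$y_pred_raw, -0.4)
  expect_equal(pc$y_pred, 0)
  s1 <- matrix(rnorm(3), 1); s2 <- matrix(rnorm(3), 1)
  expect_equal(predict_counts(s1 + s2, p)$y_pred_raw,
               predict_counts(s1, p)$y_pred_raw +
                 predict_counts(s2, p)$y_pred_raw - p$weights$b)
})

test_that("the training loss is the mean squared error over areas", {
  expect_equal(stgnn_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(stgnn_loss(c(2, 1), c(1, 2)), 1)
  expect_equal(stgnn_loss(4, 1), 9)
  expect_error(stgnn_loss(numeric(0), numeric(0)),
               class = "odcast_domain_error")
  expect_error(stgnn_loss(1:3, 1:2), class = "odcast_shape_error")
})

test_that("window construction respects the observation/gap/target geometry", {
  ds <- ohio_fixture(1)
  w <- build_windows(ds, obs_window = 3, gap = 1)
  expect_equal(nrow(w), 12)
  expect_true(all(w$target_quarter == w$window_end + 2))
  expect_true(all(vapply(seq_len(nrow(w)), function(i) {
    max(w$input_quarters[[i]]) < w$target_quarter[i]
  }, logical(1))))
  expect_true(all(table(w$split)[c("train", "validation", "test")] ==
                    c(8, 2, 2)))
  # chronological: every train window precedes every test window
  expect_lt(max(w$window_end[w$split == "train"]),
            min(w$window_end[w$split == "test"]))
  short <- tiny_panel_fixture()
  expect_error(build_windows(short, obs_window = 3, gap = 1),
               class = "odcast_domain_error")
})

test_that("graph convolutions are permutation equivariant", {
  ds <- ohio_fixture(1)
  p <- stgnn_init(4, c(6, 6), 3, seed = 8)
  A <- length(ds$graph$area_ids)
  X <- matrix(rnorm(A * 4), A)
  out <- gcn_forward(X, ds$graph, p)
  set.seed(12)
  perm <- sample(A)
  gperm <- area_graph(ds$graph$area_ids[perm],
                      ds$graph$edges,
                      ds$graph$populations[perm])
  out_perm <- gcn_forward(X[perm, , drop = FALSE], gperm, p)
  expect_equal(unname(out_perm), unname(out[perm, , drop = FALSE]),
               tolerance = 1e-10)
})

test_that("predictions are invariant to features after the observation window", {
  ds <- ohio_fixture(3)
  aug <- augment(ds, 30000, 60, seed = 3)
  aae <- train_aae(aug, latent_dim = 8, hidden = 32, epochs = 30, seed = 3)
  fit <- train_stgnn(ds, aae$params, epochs = 30, seed = 3)
  # perturb dynamic features in the last quarter (beyond every test window)
  ds2 <- ds
  ds2$dynamic[, 16, ] <- 0.99
  ds2$lag <- spatial_lag(ds2)
  fit2 <- train_stgnn(ds2, aae$params, epochs = 30, seed = 3)
  expect_equal(fit$predictions$y_pred_raw, fit2$predictions$y_pred_raw,
               tolerance = 1e-12)
})

test_that("deterministic training reproduces identical predictions", {
  ds <- ohio_fixture(2)
  f1 <- train_stgnn(ds, NULL, epochs = 25, seed = 9)
  f2 <- train_stgnn(ds, NULL, epochs = 25, seed = 9)
  expect_identical(f1$predictions$y_pred_raw, f2$predictions$y_pred_raw)
})

test_that("the network can memorize a small deterministic panel", {
  # 4 areas, 13 quarters -> 9 windows; large capacity, low noise
  set.seed(23)
  graph <- generate_geography(4, 2, 2, 0, 1,
                              populations = rep(1000, 4))
  Q <- 13
  dyn <- array(runif(4 * Q * 2), c(4, Q, 2),
               dimnames = list(graph$area_ids, NULL, c("udt1", "udt2")))
  deaths <- matrix(0L, 4, Q, dimnames = list(graph$area_ids, NULL))
  # target is a deterministic function of the window-end features
  for (t in 1:Q) deaths[, t] <- round(5 * dyn[, max(1, t - 2), 1])
  ds <- structure(list(graph = graph, quarters = seq_len(Q),
                       dynamic = dyn,
                       dynamic_denom = array(50L, c(4, Q, 2)),
                       static = matrix(rnorm(8), 4, 2,
                                       dimnames = list(graph$area_ids,
                                                       c("sdoh1", "sdoh2"))),
                       lag = NULL, deaths = deaths, truth = NULL),
                  class = "panel_dataset")
  ds$lag <- spatial_lag(ds)
  fit <- train_stgnn(ds, NULL, gcn_dims = c(48, 48), recurrent_dim = 48,
                     epochs = 2000, lr = 5e-3, patience = 2000, seed = 31)
  expect_lt(min(fit$trace$train_loss), 1e-2)
})
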