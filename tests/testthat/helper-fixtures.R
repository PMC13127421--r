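# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

ohio_fixture <- function(seed = 1) {
  cached(paste0("ohio", seed), function() ohio_like_preset(seed))
}

# A 3-area path graph A(20k)-B(15k)-C(9k) used by the augmentation tests.
path_graph_fixture <- function() {
  area_graph(c("A", "B", "C"),
             data.frame(from = c("A", "B"), to = c("B", "C")),
             populations = c(20000, 15000, 9000))
}

# Tiny deterministic panel with hand-set features: 2 areas, 4 quarters,
# 1 dynamic feature, 1 static feature.
tiny_panel_fixture <- function() {
  graph <- area_graph(c("A", "B"),
                      data.frame(from = "A", to = "B"),
                      populations = c(1000, 2000))
  dyn <- array(c(0.10, 0.30, 0.20, 0.40, 0.30, 0.50, 0.40, 0.60),
               c(2, 4, 1), dimnames = list(c("A", "B"), NULL, "udt1"))
  den <- array(100L, c(2, 4, 1), dimnames = dimnames(dyn))
  stat <- matrix(c(0.2, 0.5), 2, 1,
                 dimnames = list(c("A", "B"), "sdoh1"))
  deaths <- matrix(c(1L, 2L, 0L, 3L, 2L, 2L, 1L, 4L), 2, 4,
                   dimnames = list(c("A", "B"), NULL))
  ds <- structure(list(graph = graph, quarters = 1:4, dynamic = dyn,
                       dynamic_denom = den, static = stat, lag = NULL,
                       deaths = deaths, truth = NULL),
                  class = "panel_dataset")
  ds$lag <- spatial_lag(ds)
  ds
}

# A constant-risk ground truth for a given graph (bypasses the stochastic
# surface when a test needs exact Poisson means).
constant_truth <- function(graph, num_quarters, rate) {
  A <- length(graph$area_ids)
  structure(list(
    risk = matrix(rate, A, num_quarters,
                  dimnames = list(graph$area_ids, NULL)),
    u = matrix(0, A, num_quarters, dimnames = list(graph$area_ids, NULL)),
    base_rate = rate, spatial_correlation = 0, temporal_correlation = 0,
    noise_sd = 0), class = "ground_truth")
}
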