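test_that("region growth stops at the threshold and respects adjacency", {
  g1 <- area_graph("X", data.frame(from = character(0),
                                   to = character(0)), 50000)
  r <- grow_region(g1, "X", 30000)
  expect_equal(unclass(r)[1], "X")
  expect_equal(attr(r, "population"), 50000L)

  # path A(20k)-B(15k)-C(9k): from A the only frontier is B, 35k suffices
  gp <- path_graph_fixture()
  r <- grow_region(gp, "A", 30000)
  expect_setequal(as.character(r), c("A", "B"))
  expect_equal(attr(r, "population"), 35000L)

  iso <- area_graph("Z", data.frame(from = character(0),
                                    to = character(0)), 12)
  expect_error(grow_region(iso, "Z", 30000),
               class = "odcast_growth_error")
})

test_that("pooled features combine counts, weights, and external context correctly", {
  ds <- tiny_panel_fixture()
  f <- recompute_features(ds, c("A", "B"))
  # rates pool as summed positives over summed tests
  expect_equal(unname(f$dynamic[1, 1]), (0.10 * 100 + 0.30 * 100) / 200)
  # static features are population-weighted means
  expect_equal(f$static[[1]], (0.2 * 1000 + 0.5 * 2000) / 3000)
  # deaths sum exactly
  expect_equal(f$deaths, as.integer(colSums(ds$deaths)))
  # whole-component region has no external neighbors: lag 0 with flag
  expect_true(f$no_external_neighbors)
  expect_true(all(f$lag == 0))
  # single-member region keeps its own lag context
  fa <- recompute_features(ds, "A")
  expect_false(fa$no_external_neighbors)
  expect_equal(fa$lag[, 1], ds$dynamic["B", , 1])
})

test_that("population-weighted static pooling matches the worked example", {
  gp <- path_graph_fixture()
  dyn <- array(0.1, c(3, 2, 1),
               dimnames = list(c("A", "B", "C"), NULL, "udt1"))
  den <- array(100L, c(3, 2, 1), dimnames = dimnames(dyn))
  stat <- matrix(c(0.2, 0.5, 0.9), 3, 1,
                 dimnames = list(c("A", "B", "C"), "sdoh1"))
  ds <- structure(list(graph = gp, quarters = 1:2, dynamic = dyn,
                       dynamic_denom = den, static = stat, lag = NULL,
                       deaths = matrix(0L, 3, 2,
                                       dimnames = list(c("A", "B", "C"),
                                                       NULL)),
                       truth = NULL), class = "panel_dataset")
  ds$lag <- spatial_lag(ds)
  f <- recompute_features(ds, c("A", "B"))
  expect_equal(f$static[[1]], (0.2 * 20000 + 0.5 * 15000) / 35000,
               tolerance = 1e-12)
})

test_that("spatial lag equals the row-normalized adjacency product", {
  ds <- tiny_panel_fixture()
  lag <- spatial_lag(ds)
  expect_equal(lag["A", , 1], ds$dynamic["B", , 1])  # single neighbor
  # star graph: center lag is the leaf mean
  star <- area_graph(c("S", "L1", "L2", "L3"),
                     data.frame(from = rep("S", 3),
                                to = c("L1", "L2", "L3")),
                     rep(1000, 4))
  dyn <- array(c(0, 1, 2, 3), c(4, 1, 1),
               dimnames = list(c("S", "L1", "L2", "L3"), NULL, "udt1"))
  ds2 <- structure(list(graph = star, quarters = 1, dynamic = dyn,
                        dynamic_denom = array(1L, c(4, 1, 1)),
                        static = matrix(0, 4, 1), lag = NULL,
                        deaths = matrix(0L, 4, 1), truth = NULL),
                   class = "panel_dataset")
  expect_equal(spatial_lag(ds2)["S", 1, 1], 2)

  # dense-matrix oracle on a random 6-node graph
  set.seed(21)
  g6 <- generate_geography(6, 2, 3, 0, 1, populations = rep(100, 6))
  dyn6 <- array(runif(6 * 2 * 2), c(6, 2, 2),
                dimnames = list(g6$area_ids, NULL, c("udt1", "udt2")))
  ds6 <- structure(list(graph = g6, quarters = 1:2, dynamic = dyn6,
                        dynamic_denom = array(1L, c(6, 2, 2)),
                        static = matrix(0, 6, 1), lag = NULL,
                        deaths = matrix(0L, 6, 2), truth = NULL),
                   class = "panel_dataset")
  W <- matrix(0, 6, 6, dimnames = list(g6$area_ids, g6$area_ids))
  for (i in seq_len(nrow(g6$edges))) {
    W[g6$edges$from[i], g6$edges$to[i]] <- 1
    W[g6$edges$to[i], g6$edges$from[i]] <- 1
  }
  W <- W / rowSums(W)
  lag6 <- spatial_lag(ds6)
  for (t in 1:2) for (k in 1:2) {
    expect_equal(unname(lag6[, t, k]), unname(drop(W %*% dyn6[, t, k])),
                 tolerance = 1e-12)
  }
})

test_that("augmentation emits connected, above-threshold, conservative regions", {
  ds <- ohio_fixture(1)
  aug <- augment(ds, threshold = 30000, num_regions = 60, seed = 3)
  expect_true(all(aug$populations >= 30000))
  prov <- aug$provenance
  expect_true(all(vapply(seq_len(nrow(prov)), function(r) {
    members <- prov$members[[r]]
    ok_pop <- sum(ds$graph$populations[match(members, ds$graph$area_ids)]) ==
      prov$population[r]
    ok_conn <- odcast:::region_is_connected(ds$graph, members)
    idx <- match(members, ds$graph$area_ids)
    sums <- if (length(idx) == 1) ds$deaths[idx, ] else
      colSums(ds$deaths[idx, , drop = FALSE])
    ok_deaths <- all(aug$deaths[r, ] == sums)
    ok_pop && ok_conn && ok_deaths
  }, logical(1))))
  # pooled rates stay within the member range (weighted-mean boundedness)
  r1 <- prov$members[[which.max(prov$n_members)]]
  idx <- match(r1, ds$graph$area_ids)
  f <- recompute_features(ds, r1)
  for (k in seq_len(dim(ds$dynamic)[3])) {
    expect_true(all(f$dynamic[, k] >=
                      apply(ds$dynamic[idx, , k, drop = FALSE], 2, min) - 1e-12))
    expect_true(all(f$dynamic[, k] <=
                      apply(ds$dynamic[idx, , k, drop = FALSE], 2, max) + 1e-12))
  }
})

test_that("augmentation is deterministic and threshold 0 is the identity", {
  ds <- tiny_panel_fixture()
  a <- augment(ds, threshold = 0, num_regions = 10, seed = 5)
  expect_true(all(a$provenance$n_members == 1))
  for (r in seq_len(nrow(a$provenance))) {
    src <- a$provenance$seed_area[r]
    expect_equal(a$dynamic[r, , ], ds$dynamic[src, , ])
    expect_equal(unname(a$static[r, ]), unname(ds$static[src, ]))
    expect_equal(a$deaths[r, ], unname(ds$deaths[src, ]))
  }
  b <- augment(ds, threshold = 0, num_regions = 10, seed = 5)
  expect_identical(a$provenance$members, b$provenance$members)
  expect_identical(a$dynamic, b$dynamic)
})
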