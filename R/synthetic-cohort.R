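#' Area adjacency graph with populations
#'
#' Container for the spatial units of a study: ordered area identifiers, an
#' undirected edge list, per-area populations, and (optionally) per-area
#' polygon geometry for export. Built by [generate_geography()] or
#' [area_graph()].
#'
#' @param area_ids Character vector of area identifiers (unique, ordered).
#' @param edges Two-column data frame (`from`, `to`) of undirected
#'   adjacencies given as area ids; self-pairs are rejected.
#' @param populations Integer vector of per-area person counts, aligned to
#'   `area_ids`.
#' @param geometry Optional list of per-area polygons (each a matrix of x,y
#'   vertex coordinates), for GeoJSON export only.
#' @return An object of class `area_graph`.
#' @export
area_graph <- function(area_ids, edges, populations, geometry = NULL) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) {
    odcast_abort("Area ids must be unique.", "odcast_domain_error")
  }
  edges <- tibble::as_tibble(edges)
  names(edges)[1:2] <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  bad <- setdiff(c(edges$from, edges$to), area_ids)
  if (length(bad)) {
    odcast_abort(sprintf("Edges reference unknown area ids: %s.",
                         paste(head(bad, 3), collapse = ", ")),
                 "odcast_format_error")
  }
  if (any(edges$from == edges$to)) {
    odcast_abort("Self-pair edges are not allowed.", "odcast_domain_error")
  }
  # canonical undirected representation: from < to, no duplicates
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges <- dplyr::distinct(tibble::tibble(from = a, to = b))
  if (length(populations) != length(area_ids) || any(populations < 0)) {
    odcast_abort("`populations` must align with `area_ids` and be >= 0.",
                 "odcast_domain_error")
  }
  structure(list(area_ids = area_ids, edges = edges,
                 populations = as.integer(round(populations)),
                 geometry = geometry),
            class = "area_graph")
}

#' @export
print.area_graph <- function(x, ...) {
  cat(sprintf("<area_graph> %d areas, %d edges, populations %s-%s\n",
              length(x$area_ids), nrow(x$edges),
              format(min(x$populations), big.mark = ","),
              format(max(x$populations), big.mark = ",")))
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = data.frame(name = graph$area_ids))
}

#' Adjacency list of an area graph
#'
#' @param graph An `area_graph`.
#' @return Named list mapping each area id to the character vector of its
#'   neighbors (possibly empty).
#' @export
neighbors_of <- function(graph) {
  nb <- stats::setNames(
    lapply(graph$area_ids, function(a) character(0)), graph$area_ids)
  for (i in seq_len(nrow(graph$edges))) {
    f <- graph$edges$from[i]; t <- graph$edges$to[i]
    nb[[f]] <- c(nb[[f]], t)
    nb[[t]] <- c(nb[[t]], f)
  }
  nb
}

#' Generate a connected lattice-like area geography
#'
#' Lays the first `num_areas` cells of a `rows` x `cols` planar lattice,
#' connects rook-adjacent cells, then removes a random fraction `edge_drop`
#' of edges subject to keeping the graph connected. A stand-in for a real
#' administrative adjacency (ZCTAs, counties) that keeps the package free of
#' shapefile downloads.
#'
#' @param num_areas Number of areas (<= `rows * cols`).
#' @param rows,cols Lattice dimensions.
#' @param edge_drop Fraction of edges to attempt to remove, in `[0, 1)`.
#' @param seed Integer seed.
#' @param populations Optional per-area populations; default 1 (placeholders
#'   until [sample_populations()] assigns them).
#' @return An `area_graph` with unit-square cell geometry.
#' @export
generate_geography <- function(num_areas, rows, cols, edge_drop = 0,
                               seed = 1L, populations = NULL) {
  check_number(num_areas, "num_areas", lower = 1, integerish = TRUE)
  if (rows * cols < num_areas) {
    odcast_abort("`rows * cols` must be at least `num_areas`.",
                 "odcast_domain_error")
  }
  check_number(edge_drop, "edge_drop", lower = 0, upper = 1,
               strict_upper = TRUE)
  ids <- sprintf("A%03d", seq_len(num_areas))
  cell_row <- (seq_len(num_areas) - 1) %/% cols
  cell_col <- (seq_len(num_areas) - 1) %% cols
  idx <- function(r, c) r * cols + c + 1
  from <- integer(0); to <- integer(0)
  for (k in seq_len(num_areas)) {
    r <- cell_row[k]; c <- cell_col[k]
    if (c + 1 < cols && idx(r, c + 1) <= num_areas) {
      from <- c(from, k); to <- c(to, idx(r, c + 1))
    }
    if (idx(r + 1, c) <= num_areas && r + 1 < rows) {
      from <- c(from, k); to <- c(to, idx(r + 1, c))
    }
  }
  edges <- tibble::tibble(from = ids[from], to = ids[to])
  if (edge_drop > 0) {
    edges <- with_seed(substream_seed(seed, "geography"), {
      g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = data.frame(name = ids))
      n_drop <- floor(edge_drop * nrow(edges))
      order <- sample.int(nrow(edges))
      kept <- rep(TRUE, nrow(edges))
      dropped <- 0L
      for (e in order) {
        if (dropped >= n_drop) break
        trial <- edges[kept & seq_len(nrow(edges)) != e, ]
        gt <- igraph::graph_from_data_frame(
          trial, directed = FALSE, vertices = data.frame(name = ids))
        if (igraph::is_connected(gt)) {
          kept[e] <- FALSE
          dropped <- dropped + 1L
        }
      }
      edges[kept, ]
    })
  }
  geom <- lapply(seq_len(num_areas), function(k) {
    r <- cell_row[k]; c <- cell_col[k]
    cbind(x = c(c, c + 1, c + 1, c, c), y = c(r, r, r + 1, r + 1, r))
  })
  names(geom) <- ids
  if (is.null(populations)) populations <- rep(1L, num_areas)
  g <- area_graph(ids, edges, populations, geometry = geom)
  gi <- as_igraph(g)
  if (num_areas > 1 && !igraph::is_connected(gi)) {
    odcast_abort("Generated geography is not connected.",
                 "odcast_generation_error")
  }
  g
}

#' Sample heavy-tailed area populations
#'
#' Log-normal draws parameterized by the target median and mean: log-scale
#' location `log(median)` and scale `sqrt(2 log(mean / median))`, clipped to
#' `[min_pop, max_pop]` and rounded to integers. Defaults reproduce the
#' ZCTA-scale distribution used throughout: min 12, median 3,899, mean
#' 9,802, max 71,189. Clipping shifts the moments slightly.
#'
#' @param num_areas Number of areas.
#' @param median,mean Target median and mean (requires `mean >= median`).
#' @param min_pop,max_pop Clip bounds in persons.
#' @param seed Integer seed.
#' @return Integer vector of `num_areas` populations.
#' @export
sample_populations <- function(num_areas, median = 3899, mean = 9802,
                               min_pop = 12, max_pop = 71189, seed = 1L) {
  check_number(num_areas, "num_areas", lower = 1, integerish = TRUE)
  if (mean < median) {
    odcast_abort("Log-normal parameterization requires `mean >= median`.",
                 "odcast_domain_error")
  }
  if (!(min_pop <= median && median <= max_pop)) {
    odcast_abort("Need `min_pop <= median <= max_pop`.",
                 "odcast_domain_error")
  }
  sdlog <- sqrt(2 * log(mean / median))
  with_seed(substream_seed(seed, "populations"), {
    x <- stats::rlnorm(num_areas, meanlog = log(median), sdlog = sdlog)
    as.integer(round(pmin(pmax(x, min_pop), max_pop)))
  })
}

# Row-normalized neighbor averaging of a per-area vector; isolated areas
# keep their own value.
neighbor_smooth <- function(x, nb_idx) {
  vapply(seq_along(x), function(i) {
    if (length(nb_idx[[i]]) == 0) x[i] else mean(x[nb_idx[[i]]])
  }, numeric(1))
}

neighbor_index <- function(graph) {
  nb <- neighbors_of(graph)
  lapply(nb, function(v) match(v, graph$area_ids))
}

# One spatially smoothed standard-normal field: fixed point of
# x = (1 - rho) * x0 + rho * W x, recentred and rescaled to the raw field's
# mean and sd so the field stays comparable across rho.
smoothed_field <- function(graph, rho, nb_idx, tol = 1e-8, max_iter = 200) {
  x0 <- rnorm(length(graph$area_ids))
  if (rho == 0) return(x0)
  x <- x0
  for (k in seq_len(max_iter)) {
    x_new <- (1 - rho) * x0 + rho * neighbor_smooth(x, nb_idx)
    if (max(abs(x_new - x)) < tol) { x <- x_new; break }
    x <- x_new
  }
  x <- x - mean(x) + mean(x0)        # conserve the raw field mean
  s <- sd(x)
  if (s > 0) x <- mean(x0) + (x - mean(x0)) * sd(x0) / s
  x
}

#' Simulate a spatially and temporally correlated latent risk surface
#'
#' Builds a per-area, per-quarter log-risk field `u`: the initial field is
#' spatially smoothed white noise (each area pulled toward its neighbor
#' mean with weight `spatial_rho`, iterated to a fixed point); subsequent
#' quarters follow an AR(1) `u_t = temporal_rho * u_{t-1} +
#' sqrt(1 - temporal_rho^2) * e_t` with fresh smoothed innovations, so the
#' marginal variance is stationary. The risk is the log-normal field
#' `base_rate * exp(noise_sd * u - noise_sd^2 / 2)` (mean-corrected so the
#' average risk stays near `base_rate`), clipped to `(0, 0.5]`.
#'
#' @param graph An `area_graph`.
#' @param num_quarters Number of quarters.
#' @param base_rate Per-person per-quarter death probability.
#' @param spatial_rho Spatial smoothing weight in `[0, 1)`.
#' @param temporal_rho AR(1) coefficient in `[0, 1)`.
#' @param noise_sd Log-scale risk dispersion.
#' @param seed Integer seed.
#' @return An object of class `ground_truth` with fields `risk` (area x
#'   quarter matrix), `u` (latent field), `base_rate`,
#'   `spatial_correlation`, `temporal_correlation`, `noise_sd`.
#' @export
simulate_risk_surface <- function(graph, num_quarters, base_rate = 1e-4,
                                  spatial_rho = 0.4, temporal_rho = 0.7,
                                  noise_sd = 0.6, seed = 1L) {
  check_number(num_quarters, "num_quarters", lower = 1, integerish = TRUE)
  check_number(spatial_rho, "spatial_rho", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(temporal_rho, "temporal_rho", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(base_rate, "base_rate", lower = 0, upper = 0.5,
               strict_lower = TRUE)
  nb_idx <- neighbor_index(graph)
  A <- length(graph$area_ids)
  u <- matrix(0, A, num_quarters,
              dimnames = list(graph$area_ids, NULL))
  with_seed(substream_seed(seed, "risk-surface"), {
    u[, 1] <- smoothed_field(graph, spatial_rho, nb_idx)
    if (num_quarters > 1) {
      for (t in 2:num_quarters) {
        e <- smoothed_field(graph, spatial_rho, nb_idx)
        u[, t] <- temporal_rho * u[, t - 1] +
          sqrt(1 - temporal_rho^2) * e
      }
    }
  })
  risk <- base_rate * exp(noise_sd * u - noise_sd^2 / 2)
  risk <- pmin(pmax(risk, 1e-12), 0.5)
  structure(list(risk = risk, u = u, base_rate = base_rate,
                 spatial_correlation = spatial_rho,
                 temporal_correlation = temporal_rho,
                 noise_sd = noise_sd),
            class = "ground_truth")
}

#' Simulate an area-quarter feature and death-count panel
#'
#' Given a geography and a latent risk surface, draws per-area per-quarter
#' death counts (`Poisson(n * risk)` by default, exact Binomial behind
#' `count_model = "binomial"`), urine-drug-test-style dynamic positivity
#' features (Binomial positives out of `round(n * tests_per_capita)` tests
#' with logistic success linked to the latent risk), static SDoH-like
#' indices (linear in the time-averaged latent field plus noise), and
#' spatial-lag features (neighbor means of the dynamic rates).
#'
#' @param graph An `area_graph` with populations.
#' @param truth A `ground_truth` from [simulate_risk_surface()].
#' @param d_dyn,d_stat Numbers of dynamic and static features (>= 1).
#' @param tests_per_capita Tests per person per quarter.
#' @param feature_noise SD of logit-scale noise added to feature links.
#' @param seed Integer seed.
#' @param count_model `"poisson"` (default) or `"binomial"`.
#' @return An object of class `panel_dataset`: fields `graph`, `quarters`,
#'   `dynamic` and `dynamic_denom` (area x quarter x d_dyn arrays of
#'   positivity rates and test denominators), `static` (area x d_stat),
#'   `lag` (area x quarter x d_dyn neighbor means, with an `isolated_flag`
#'   attribute), `deaths` (area x quarter integer matrix), `truth`.
#' @export
simulate_panel <- function(graph, truth, d_dyn = 8, d_stat = 6,
                           tests_per_capita = 0.002, feature_noise = 0.3,
                           seed = 1L, count_model = c("poisson", "binomial")) {
  count_model <- match.arg(count_model)
  check_number(d_dyn, "d_dyn", lower = 1, integerish = TRUE)
  check_number(d_stat, "d_stat", lower = 1, integerish = TRUE)
  A <- length(graph$area_ids)
  Q <- ncol(truth$risk)
  n <- graph$populations
  # feature link coefficients: fixed per dataset, spread over plausible
  # positivity baselines, positive association with risk
  a_k <- seq(-2.2, -0.8, length.out = d_dyn)
  b_k <- seq(0.5, 1.1, length.out = d_dyn)
  dyn <- array(0, c(A, Q, d_dyn),
               dimnames = list(graph$area_ids, NULL, paste0("udt", seq_len(d_dyn))))
  denom <- array(0L, c(A, Q, d_dyn), dimnames = dimnames(dyn))
  deaths <- matrix(0L, A, Q, dimnames = list(graph$area_ids, NULL))
  with_seed(substream_seed(seed, "panel"), {
    for (t in seq_len(Q)) {
      lam <- n * truth$risk[, t]
      deaths[, t] <- if (count_model == "poisson") {
        rpois(A, lam)
      } else {
        rbinom(A, n, truth$risk[, t])
      }
      n_tests <- as.integer(round(n * tests_per_capita))
      for (k in seq_len(d_dyn)) {
        pr <- plogis(a_k[k] + b_k[k] * truth$u[, t] +
                       rnorm(A, 0, feature_noise))
        pos <- rbinom(A, n_tests, pr)
        denom[, t, k] <- n_tests
        dyn[, t, k] <- ifelse(n_tests > 0, pos / n_tests, 0)
      }
    }
    u_bar <- rowMeans(truth$u)
    c_j <- seq(-0.8, 0.8, length.out = d_stat)
    stat <- sapply(seq_len(d_stat), function(j) {
      c_j[j] * u_bar + rnorm(A, 0, feature_noise)
    })
  })
  stat <- matrix(stat, A, d_stat,
                 dimnames = list(graph$area_ids, paste0("sdoh", seq_len(d_stat))))
  ds <- structure(list(graph = graph, quarters = seq_len(Q),
                       dynamic = dyn, dynamic_denom = denom,
                       static = stat, lag = NULL, deaths = deaths,
                       truth = truth),
                  class = "panel_dataset")
  ds$lag <- spatial_lag(ds)
  ds
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf(
    "<panel_dataset> %d areas x %d quarters, %d dynamic + %d static features, %s deaths total\n",
    dim(x$dynamic)[1], dim(x$dynamic)[2], dim(x$dynamic)[3],
    ncol(x$static), format(sum(x$deaths), big.mark = ",")))
  invisible(x)
}

#' Ohio-like synthetic county panel preset
#'
#' 88 areas over 16 quarters with county-scale log-normal populations
#' (median 40,000, mean 42,000, clipped to 10,000-1,300,000, so about 82%
#' of areas exceed the 30,000 threshold), base risk 1 per 10,000
#' persons per quarter (4 per 10,000 annually), 8 dynamic and 6 static
#' features, moderate spatial (0.4) and temporal (0.7) correlation, and
#' sparse urine-drug-test volumes (2 tests per 1,000 persons per quarter,
#' the regime in which area-level positivity rates are noisy and pooling
#' neighboring areas genuinely densifies the signal).
#'
#' @param seed Integer seed.
#' @return A `panel_dataset`.
#' @export
ohio_like_preset <- function(seed = 1L) {
  pops <- sample_populations(88, median = 40000, mean = 42000,
                             min_pop = 10000, max_pop = 1300000,
                             seed = seed)
  graph <- generate_geography(88, rows = 8, cols = 11, edge_drop = 0.1,
                              seed = seed, populations = pops)
  truth <- simulate_risk_surface(graph, num_quarters = 16,
                                 base_rate = 1e-4, spatial_rho = 0.4,
                                 temporal_rho = 0.7, noise_sd = 0.6,
                                 seed = seed)
  simulate_panel(graph, truth, d_dyn = 8, d_stat = 6,
                 tests_per_capita = 0.002, feature_noise = 0.3, seed = seed)
}

#' Long-format view of a panel dataset
#'
#' @param x A `panel_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per area-quarter: `area_id`, `quarter`,
#'   `population`, `deaths`, the dynamic rate and denominator columns, the
#'   lag columns, and the (replicated) static columns.
#' @method tidy panel_dataset
#' @export
tidy.panel_dataset <- function(x, ...) {
  A <- dim(x$dynamic)[1]; Q <- dim(x$dynamic)[2]
  base <- tidyr::expand_grid(area_id = x$graph$area_ids,
                             quarter = x$quarters) |>
    dplyr::arrange(.data$quarter, .data$area_id)
  ord <- cbind(match(base$area_id, x$graph$area_ids), base$quarter)
  out <- base
  out$population <- x$graph$populations[ord[, 1]]
  out$deaths <- x$deaths[ord]
  for (k in seq_len(dim(x$dynamic)[3])) {
    out[[dimnames(x$dynamic)[[3]][k]]] <- x$dynamic[, , k][ord]
    out[[paste0(dimnames(x$dynamic)[[3]][k], "_ntests")]] <-
      x$dynamic_denom[, , k][ord]
  }
  for (k in seq_len(dim(x$lag)[3])) {
    out[[paste0("lag_", dimnames(x$dynamic)[[3]][k])]] <- x$lag[, , k][ord]
  }
  for (j in seq_len(ncol(x$static))) {
    out[[colnames(x$static)[j]]] <- x$static[ord[, 1], j]
  }
  tibble::as_tibble(out)
}

#' Summary statistics of a panel dataset
#'
#' @param x A `panel_dataset`.
#' @param ... Unused.
#' @return One-row tibble: areas, quarters, feature counts, total deaths,
#'   mean deaths per area-quarter, median population.
#' @method glance panel_dataset
#' @export
glance.panel_dataset <- function(x, ...) {
  tibble::tibble(
    n_areas = dim(x$dynamic)[1],
    n_quarters = dim(x$dynamic)[2],
    d_dyn = dim(x$dynamic)[3],
    d_stat = ncol(x$static),
    total_deaths = sum(x$deaths),
    mean_deaths = mean(x$deaths),
    median_population = stats::median(x$graph$populations))
}
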