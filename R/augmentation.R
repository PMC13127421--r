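#' Spatial-lag features: neighbor means of dynamic rates
#'
#' For each area, quarter, and dynamic feature, the unweighted mean of the
#' feature over the area's graph neighbors — equivalently the product of the
#' row-normalized adjacency matrix with the feature column. Isolated areas
#' get 0, recorded in the `isolated_flag` attribute rather than as missing
#' values, keeping downstream tensors dense.
#'
#' @param dataset A `panel_dataset`.
#' @return An area x quarter x d_dyn array of neighbor means with an
#'   `isolated_flag` logical attribute (one entry per area).
#' @export
spatial_lag <- function(dataset) {
  graph <- dataset$graph
  nb_idx <- neighbor_index(graph)
  A <- dim(dataset$dynamic)[1]
  Q <- dim(dataset$dynamic)[2]
  K <- dim(dataset$dynamic)[3]
  lag <- array(0, c(A, Q, K), dimnames = dimnames(dataset$dynamic))
  isolated <- lengths(nb_idx) == 0
  for (i in seq_len(A)) {
    if (isolated[i]) next
    js <- nb_idx[[i]]
    for (k in seq_len(K)) {
      block <- dataset$dynamic[js, , k, drop = FALSE]
      lag[i, , k] <- if (length(js) == 1) block[1, , 1] else
        colMeans(matrix(block, nrow = length(js)))
    }
  }
  attr(lag, "isolated_flag") <- isolated
  lag
}

#' Grow a connected region above a population threshold
#'
#' Starting from `seed_area`, repeatedly adds one uniformly random frontier
#' area (adjacent to the current region, not yet a member) until the summed
#' population reaches `threshold`. Errors if the frontier is exhausted
#' first (the seed's component is too small).
#'
#' @param graph An `area_graph` with populations.
#' @param seed_area Area id to start from.
#' @param threshold Target population in persons (> 0).
#' @return Character vector of member area ids (always includes
#'   `seed_area`), with attributes `population` (summed persons).
#' @export
grow_region <- function(graph, seed_area, threshold) {
  check_number(threshold, "threshold", lower = 0)
  if (!seed_area %in% graph$area_ids) {
    odcast_abort(sprintf("Unknown seed area %s.", seed_area),
                 "odcast_domain_error")
  }
  nb <- neighbors_of(graph)
  pop <- stats::setNames(graph$populations, graph$area_ids)
  members <- seed_area
  total <- pop[[seed_area]]
  frontier <- setdiff(nb[[seed_area]], members)
  while (total < threshold) {
    if (length(frontier) == 0) {
      odcast_abort(sprintf(
        "Cannot reach threshold %s from seed %s: its connected component holds only %s persons.",
        format(threshold, big.mark = ","), seed_area,
        format(total, big.mark = ",")), "odcast_growth_error")
    }
    pick <- if (length(frontier) == 1) frontier else sample(frontier, 1)
    members <- c(members, pick)
    total <- total + pop[[pick]]
    frontier <- setdiff(union(frontier, nb[[pick]]), members)
  }
  attr(members, "population") <- as.integer(total)
  members
}

#' Recompute pooled features for an aggregated region
#'
#' Pools a member set's features the way an epidemiologist would aggregate
#' areas: rate-type dynamic features as summed positives over summed test
#' denominators, static features as population-weighted means, and
#' spatial-lag features recomputed against the region's *external*
#' neighbors (areas adjacent to any member but not members themselves).
#' Zero pooled denominators and regions with no external neighbors yield 0
#' with an explicit flag instead of missing values.
#'
#' @param dataset A `panel_dataset`.
#' @param members Character vector of member area ids (nonempty).
#' @return List with `dynamic` (Q x d_dyn pooled rates), `dynamic_denom`
#'   (Q x d_dyn summed denominators), `static` (length-d_stat weighted
#'   means), `lag` (Q x d_dyn external-neighbor means), `deaths`
#'   (length-Q summed counts), `population`, and logical flags
#'   `zero_denominator`, `no_external_neighbors`.
#' @export
recompute_features <- function(dataset, members) {
  idx <- match(members, dataset$graph$area_ids)
  if (length(idx) == 0 || anyNA(idx)) {
    odcast_abort("`members` must be a nonempty set of known area ids.",
                 "odcast_domain_error")
  }
  Q <- dim(dataset$dynamic)[2]
  K <- dim(dataset$dynamic)[3]
  pops <- dataset$graph$populations[idx]
  population <- sum(pops)

  pos <- dataset$dynamic[idx, , , drop = FALSE] *
    dataset$dynamic_denom[idx, , , drop = FALSE]
  num <- apply(pos, c(2, 3), sum)
  den <- apply(dataset$dynamic_denom[idx, , , drop = FALSE], c(2, 3), sum)
  zero_denom <- den == 0
  dynamic <- ifelse(zero_denom, 0, num / pmax(den, 1))

  static <- colSums(dataset$static[idx, , drop = FALSE] * pops) /
    max(population, 1)

  nb <- neighbors_of(dataset$graph)
  external <- setdiff(unique(unlist(nb[members])), members)
  ext_idx <- match(external, dataset$graph$area_ids)
  no_ext <- length(ext_idx) == 0
  lag <- matrix(0, Q, K)
  if (!no_ext) {
    for (k in seq_len(K)) {
      block <- dataset$dynamic[ext_idx, , k, drop = FALSE]
      lag[, k] <- colMeans(matrix(block, nrow = length(ext_idx)))
    }
  }
  deaths <- if (length(idx) == 1) dataset$deaths[idx, ] else
    colSums(dataset$deaths[idx, , drop = FALSE])

  list(dynamic = dynamic, dynamic_denom = den, static = static, lag = lag,
       deaths = as.integer(deaths), population = as.integer(population),
       zero_denominator = any(zero_denom), no_external_neighbors = no_ext)
}

#' Threshold-driven region-aggregation augmentation
#'
#' Draws `num_regions` seed areas uniformly with replacement, grows each
#' into a connected region whose population meets `threshold`
#' ([grow_region()]), and recomputes pooled features and summed death
#' labels ([recompute_features()]). Regions may overlap across draws: this
#' is augmentation for representation learning, not a partition of the map.
#'
#' @param dataset A `panel_dataset`.
#' @param threshold Population threshold in persons.
#' @param num_regions Number of synthetic regions (>= 1).
#' @param seed Integer seed.
#' @return An object of class `augmented_panel`: arrays `dynamic`,
#'   `dynamic_denom`, `lag` (region x quarter x d_dyn), `static`
#'   (region x d_stat), `deaths` (region x quarter), `populations`, and a
#'   `provenance` tibble (region_id, seed_area, members, population,
#'   n_members).
#' @export
augment <- function(dataset, threshold = 30000, num_regions = 500,
                    seed = 1L) {
  check_number(num_regions, "num_regions", lower = 1, integerish = TRUE)
  A <- length(dataset$graph$area_ids)
  Q <- dim(dataset$dynamic)[2]
  K <- dim(dataset$dynamic)[3]
  res <- with_seed(substream_seed(seed, "augmentation"), {
    seeds <- sample(dataset$graph$area_ids, num_regions, replace = TRUE)
    memberships <- vector("list", num_regions)
    failures <- 0L
    for (r in seq_len(num_regions)) {
      memberships[[r]] <- tryCatch(
        grow_region(dataset$graph, seeds[r], threshold),
        odcast_growth_error = function(e) NULL)
      if (is.null(memberships[[r]])) failures <- failures + 1L
    }
    list(seeds = seeds, memberships = memberships, failures = failures)
  })
  keep <- !vapply(res$memberships, is.null, logical(1))
  if (!any(keep)) {
    odcast_abort("Every seed area fell in a component below the threshold.",
                 "odcast_growth_error")
  }
  memberships <- res$memberships[keep]
  seeds <- res$seeds[keep]
  R <- length(memberships)
  dyn <- array(0, c(R, Q, K),
               dimnames = list(NULL, NULL, dimnames(dataset$dynamic)[[3]]))
  den <- array(0, c(R, Q, K), dimnames = dimnames(dyn))
  lag <- array(0, c(R, Q, K), dimnames = dimnames(dyn))
  stat <- matrix(0, R, ncol(dataset$static),
                 dimnames = list(NULL, colnames(dataset$static)))
  deaths <- matrix(0L, R, Q)
  pops <- integer(R)
  for (r in seq_len(R)) {
    f <- recompute_features(dataset, memberships[[r]])
    dyn[r, , ] <- f$dynamic
    den[r, , ] <- f$dynamic_denom
    lag[r, , ] <- f$lag
    stat[r, ] <- f$static
    deaths[r, ] <- f$deaths
    pops[r] <- f$population
  }
  prov <- tibble::tibble(
    region_id = sprintf("R%04d", seq_len(R)),
    seed_area = seeds,
    members = purrr::map(memberships, as.character),
    n_members = lengths(memberships),
    population = pops)
  structure(list(graph = dataset$graph, quarters = dataset$quarters,
                 dynamic = dyn, dynamic_denom = den, lag = lag,
                 static = stat, deaths = deaths, populations = pops,
                 provenance = prov, threshold = threshold,
                 n_failed_seeds = res$failures),
            class = "augmented_panel")
}

#' @export
print.augmented_panel <- function(x, ...) {
  cat(sprintf(
    "<augmented_panel> %d regions (threshold %s), %d quarters, %.1f areas/region\n",
    nrow(x$provenance), format(x$threshold, big.mark = ","),
    dim(x$dynamic)[2], mean(x$provenance$n_members)))
  invisible(x)
}

# Region membership induces a connected subgraph — used by tests and the
# provenance audit.
region_is_connected <- function(graph, members) {
  if (length(members) == 1) return(TRUE)
  g <- as_igraph(graph)
  sub <- igraph::induced_subgraph(g, members)
  igraph::is_connected(sub)
}
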