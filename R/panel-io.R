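# Plain-text round-trip of a panel dataset: a long-format panel CSV, an
# edge-list TSV, a populations CSV, and (optionally) a GeoJSON
# FeatureCollection for the geometry. Counts survive exactly; reals to
# formatting precision (15 significant digits).

#' Write a panel dataset to a directory of plain-text files
#'
#' Emits `panel.csv` (long format, one row per area-quarter),
#' `edges.tsv` (`area_a`, `area_b`), `populations.csv`, and, if geometry is
#' present and `geojson = TRUE`, `areas.geojson`.
#'
#' @param dataset A `panel_dataset`.
#' @param dir Output directory (created if missing).
#' @param geojson Write the GeoJSON FeatureCollection when geometry exists.
#' @return `dir`, invisibly.
#' @export
write_panel <- function(dataset, dir, geojson = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- tidy.panel_dataset(dataset)
  readr::write_csv(long, file.path(dir, "panel.csv"))
  readr::write_tsv(
    tibble::tibble(area_a = dataset$graph$edges$from,
                   area_b = dataset$graph$edges$to),
    file.path(dir, "edges.tsv"))
  readr::write_csv(
    tibble::tibble(area_id = dataset$graph$area_ids,
                   population = dataset$graph$populations),
    file.path(dir, "populations.csv"))
  if (geojson && !is.null(dataset$graph$geometry)) {
    write_geojson(dataset$graph, file.path(dir, "areas.geojson"))
  }
  invisible(dir)
}

write_geojson <- function(graph, path) {
  features <- purrr::map(graph$area_ids, function(id) {
    poly <- graph$geometry[[id]]
    list(type = "Feature",
         properties = list(
           area_id = id,
           population = graph$populations[match(id, graph$area_ids)]),
         geometry = list(
           type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(poly)), function(i)
             as.numeric(poly[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a panel dataset written by [write_panel()]
#'
#' Validates the schema: deaths must be integers, every edge must reference
#' a known area, and all area-quarter cells must be present.
#'
#' @param dir Directory holding `panel.csv`, `edges.tsv`,
#'   `populations.csv`.
#' @return A `panel_dataset` (without ground truth).
#' @export
read_panel <- function(dir) {
  panel_path <- file.path(dir, "panel.csv")
  for (f in c(panel_path, file.path(dir, "edges.tsv"),
              file.path(dir, "populations.csv"))) {
    if (!file.exists(f)) {
      odcast_abort(sprintf("Missing file %s.", f), "odcast_format_error")
    }
  }
  long <- readr::read_csv(panel_path, show_col_types = FALSE)
  need <- c("area_id", "quarter", "population", "deaths")
  missing <- setdiff(need, names(long))
  if (length(missing)) {
    odcast_abort(sprintf("panel.csv lacks required columns: %s.",
                         paste(missing, collapse = ", ")),
                 "odcast_format_error")
  }
  bad <- which(abs(long$deaths - round(long$deaths)) > 1e-9)
  if (length(bad)) {
    odcast_abort(sprintf(
      "Non-integer death count at panel.csv row %d (value %g).",
      bad[1], long$deaths[bad[1]]), "odcast_format_error")
  }
  pops <- readr::read_csv(file.path(dir, "populations.csv"),
                          show_col_types = FALSE)
  edges <- readr::read_tsv(file.path(dir, "edges.tsv"),
                           show_col_types = FALSE)
  unknown <- which(!(edges$area_a %in% pops$area_id &
                       edges$area_b %in% pops$area_id))
  if (length(unknown)) {
    odcast_abort(sprintf("edges.tsv row %d references an unknown area id.",
                         unknown[1]), "odcast_format_error")
  }
  area_ids <- pops$area_id
  quarters <- sort(unique(long$quarter))
  A <- length(area_ids); Q <- length(quarters)
  if (nrow(long) != A * Q) {
    odcast_abort("panel.csv must contain every area-quarter cell exactly once.",
                 "odcast_format_error")
  }
  dyn_cols <- grep("^udt\\d+$", names(long), value = TRUE)
  lag_cols <- grep("^lag_udt\\d+$", names(long), value = TRUE)
  stat_cols <- grep("^sdoh\\d+$", names(long), value = TRUE)
  graph <- area_graph(area_ids,
                      tibble::tibble(from = edges$area_a, to = edges$area_b),
                      pops$population)
  ai <- match(long$area_id, area_ids)
  qi <- match(long$quarter, quarters)
  dyn <- array(0, c(A, Q, length(dyn_cols)),
               dimnames = list(area_ids, NULL, dyn_cols))
  den <- array(0L, c(A, Q, length(dyn_cols)), dimnames = dimnames(dyn))
  lag <- array(0, c(A, Q, length(dyn_cols)), dimnames = dimnames(dyn))
  for (k in seq_along(dyn_cols)) {
    dyn[cbind(ai, qi, k)] <- long[[dyn_cols[k]]]
    den[cbind(ai, qi, k)] <- long[[paste0(dyn_cols[k], "_ntests")]]
    lag[cbind(ai, qi, k)] <- long[[lag_cols[k]]]
  }
  deaths <- matrix(0L, A, Q, dimnames = list(area_ids, NULL))
  deaths[cbind(ai, qi)] <- as.integer(round(long$deaths))
  stat <- matrix(0, A, length(stat_cols),
                 dimnames = list(area_ids, stat_cols))
  first_q <- long[long$quarter == quarters[1], ]
  stat[match(first_q$area_id, area_ids), ] <-
    as.matrix(first_q[, stat_cols])
  structure(list(graph = graph, quarters = seq_len(Q), dynamic = dyn,
                 dynamic_denom = den, static = stat, lag = lag,
                 deaths = deaths, truth = NULL),
            class = "panel_dataset")
}
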