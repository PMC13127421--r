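#' Core error metrics for count predictions
#'
#' SMAPE (percent: 100 times the unweighted mean of the pointwise
#' symmetric error [smape_point()] over records), mean absolute error, and
#' root mean squared error, computed from clamped predictions.
#'
#' @param records Tibble of prediction records with columns `y_true` and
#'   `y_pred` (e.g. `stgnn_fit$predictions`).
#' @return One-row tibble: `n_records`, `smape_pct`, `mae`, `rmse`.
#' @export
compute_metrics <- function(records) {
  if (nrow(records) == 0) {
    odcast_abort("No prediction records.", "odcast_domain_error")
  }
  err <- records$y_true - records$y_pred
  tibble::tibble(
    n_records = nrow(records),
    smape_pct = 100 * mean(smape_point(records$y_true, records$y_pred)),
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)))
}

#' Three-class trend label
#'
#' Compares a count to a reference count: `"increasing"` if strictly above,
#' `"stable"` only under exact equality, `"decreasing"` if strictly below.
#' Continuous predictions are rounded to the nearest integer (half away
#' from zero) first — stability is only reachable by a prediction after
#' discretization.
#'
#' @param current Current count or continuous prediction (vectorized).
#' @param reference Reference integer count (the last observed quarter).
#' @param round_current If `TRUE` (use for predictions), round `current`
#'   before comparing.
#' @return Character vector in `{"increasing", "stable", "decreasing"}`.
#' @export
trend_label <- function(current, reference, round_current = FALSE) {
  if (any(reference < 0)) {
    odcast_abort("`reference` must be nonnegative.", "odcast_domain_error")
  }
  cur <- if (round_current) {
    sign(current) * floor(abs(current) + 0.5)  # half away from zero
  } else current
  dplyr::case_when(cur > reference ~ "increasing",
                   cur < reference ~ "decreasing",
                   TRUE ~ "stable")
}

#' Trend records from prediction records
#'
#' Labels truth (`y_true` vs `prev_observed`) and prediction (rounded
#' `y_pred` vs `prev_observed`) for every record.
#'
#' @param records Prediction records with `y_true`, `y_pred`,
#'   `prev_observed`.
#' @return Tibble with `area_id`, `target_quarter`, `true_class`,
#'   `pred_class`.
#' @export
trend_records <- function(records) {
  tibble::tibble(
    area_id = records$area_id,
    target_quarter = records$target_quarter,
    true_class = trend_label(records$y_true, records$prev_observed),
    pred_class = trend_label(records$y_pred, records$prev_observed,
                             round_current = TRUE))
}

trend_classes <- c("increasing", "stable", "decreasing")

#' Trend-classification metrics
#'
#' Overall accuracy, macro-averaged precision/recall/F1 over the three
#' classes (a class never predicted contributes precision 0; a class with
#' no support contributes recall 0), and class-wise accuracy (per-class
#' recall).
#'
#' @param trends Tibble from [trend_records()] (columns `true_class`,
#'   `pred_class`).
#' @return One-row tibble: `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `acc_increasing`, `acc_stable`, `acc_decreasing`.
#' @export
trend_metrics <- function(trends) {
  if (nrow(trends) == 0) {
    odcast_abort("No trend records.", "odcast_domain_error")
  }
  tc <- factor(trends$true_class, levels = trend_classes)
  pc <- factor(trends$pred_class, levels = trend_classes)
  cm <- table(true = tc, pred = pc)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  prec <- ifelse(predicted > 0, tp / predicted, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  tibble::tibble(
    accuracy = sum(tp) / nrow(trends),
    macro_precision = mean(prec),
    macro_recall = mean(rec),
    macro_f1 = mean(f1),
    acc_increasing = rec[["increasing"]],
    acc_stable = rec[["stable"]],
    acc_decreasing = rec[["decreasing"]])
}

bin_label <- function(population, edges) {
  n_bins <- length(edges) - 1
  labels <- character(length(population))
  fmt <- function(x) {
    if (!is.finite(x)) "inf" else if (x >= 1000) paste0(x / 1000, "k") else x
  }
  labels[population < edges[1]] <- "under"
  for (b in seq_len(n_bins)) {
    sel <- population >= edges[b] & population < edges[b + 1]
    labels[sel] <- if (is.finite(edges[b + 1])) {
      paste0(fmt(edges[b]), "-", fmt(edges[b + 1]))
    } else paste0(fmt(edges[b]), "+")
  }
  labels
}

#' Stratify prediction metrics by population bin
#'
#' Assigns each record to exactly one half-open bin `[lo, hi)` of the
#' population edges (default 10k-20k, 20k-30k, 30k-50k, 50k+; a population
#' of exactly 30,000 falls in 30k-50k) and computes per-bin SMAPE, MAE,
#' RMSE, mean population, mean observed count, and mean predicted count.
#' Records below the lowest edge land in an `"under"` audit row, so the
#' bins partition all records.
#'
#' @param records Prediction records with a `population` column.
#' @param bin_edges Ascending population edges; an implicit `Inf` closes
#'   the top bin.
#' @return Tibble with one row per nonempty bin, ordered by bin, with
#'   columns `bin`, `n_records`, `smape_pct`, `mae`, `rmse`,
#'   `mean_population`, `mean_y_true`, `mean_y_pred`.
#' @export
stratify_by_population <- function(records,
                                   bin_edges = c(1e4, 2e4, 3e4, 5e4)) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    odcast_abort("`bin_edges` must be strictly ascending.",
                 "odcast_domain_error")
  }
  edges <- c(bin_edges, Inf)
  levs <- c("under", bin_label(bin_edges, edges))
  out <- records |>
    dplyr::mutate(bin = bin_label(.data$population, edges)) |>
    dplyr::group_by(bin = factor(.data$bin, levels = levs)) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      smape_pct = 100 * mean(smape_point(.data$y_true, .data$y_pred)),
      mae = mean(abs(.data$y_true - .data$y_pred)),
      rmse = sqrt(mean((.data$y_true - .data$y_pred)^2)),
      mean_population = mean(.data$population),
      mean_y_true = mean(.data$y_true),
      mean_y_pred = mean(.data$y_pred),
      .groups = "drop") |>
    dplyr::arrange(.data$bin)
  out$bin <- as.character(out$bin)
  out
}

#' Empirical versus theoretical SMAPE by population bin
#'
#' For each population bin, pairs the empirical SMAPE of the records with
#' the closed-form expected SMAPE of a calibrated predictor evaluated at
#' the bin's mean expected count `np` (Normal regime at `np >= 1`,
#' Bernoulli below), plus their relative gap. Empty bins are omitted.
#'
#' @param records Prediction records with `population`.
#' @param p Per-person death probability per prediction period.
#' @param bin_edges Population bin edges, as in
#'   [stratify_by_population()].
#' @return Tibble with `bin`, `n_records`, `mean_np`, `empirical_smape_pct`,
#'   `theoretical_smape_pct`, `relative_gap`.
#' @export
theory_vs_empirical <- function(records, p,
                                bin_edges = c(1e4, 2e4, 3e4, 5e4)) {
  strat <- stratify_by_population(records, bin_edges)
  strat |>
    dplyr::mutate(mean_np = .data$mean_population * p) |>
    dplyr::mutate(theoretical_smape_pct = 100 * purrr::map_dbl(
      .data$mean_np, function(np) {
        pr <- risk_params(max(1, round(np / p)), p)
        if (np >= 1) expected_smape_large(pr) else expected_smape_small(pr)
      })) |>
    dplyr::transmute(
      bin = .data$bin, n_records = .data$n_records, mean_np = .data$mean_np,
      empirical_smape_pct = .data$smape_pct,
      theoretical_smape_pct = .data$theoretical_smape_pct,
      relative_gap = (.data$empirical_smape_pct -
                        .data$theoretical_smape_pct) /
        .data$theoretical_smape_pct)
}

#' Full metrics report for a set of prediction records
#'
#' Combines [compute_metrics()], [trend_metrics()] on the derived trend
#' records, and [stratify_by_population()].
#'
#' @param records Prediction records.
#' @param bin_edges Population bin edges.
#' @return List of class `metrics_report` with `overall`, `trend`,
#'   `by_population`.
#' @export
metrics_report <- function(records, bin_edges = c(1e4, 2e4, 3e4, 5e4)) {
  structure(list(
    overall = compute_metrics(records),
    trend = trend_metrics(trend_records(records)),
    by_population = stratify_by_population(records, bin_edges)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Overall:\n"); print(x$overall)
  cat("Trend classification:\n"); print(x$trend)
  cat("By population bin:\n"); print(x$by_population)
  invisible(x)
}

#' Plot per-bin SMAPE against population
#'
#' @param object A tibble from [stratify_by_population()] or a
#'   `metrics_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of SMAPE per population bin.
#' @export
plot_population_bins <- function(object, ...) {
  tab <- if (inherits(object, "metrics_report")) object$by_population else
    object
  ggplot2::ggplot(tab, ggplot2::aes(
    x = factor(.data$bin, levels = .data$bin), y = .data$smape_pct)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "population bin", y = "SMAPE (%)",
                  title = "Prediction error by population size")
}
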