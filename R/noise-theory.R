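#' Risk parameters for an area's count process
#'
#' Bundles the population size `n` and the per-person death probability `p`
#' for one analysis period. The product `np` is the expected death count and
#' drives every quantity in the noise theory: the signal-to-noise ratio
#' (SNR), the expected symmetric mean absolute percentage error (SMAPE) of a
#' perfectly calibrated predictor, and the regime (Normal for large `np`,
#' Bernoulli for rare events).
#'
#' @param n Population size in persons (positive integer).
#' @param p Per-person death probability per analysis period, in (0, 1).
#' @param period_label Free-text label for the time unit of `p`
#'   (e.g. `"month"`, `"quarter"`).
#'
#' @return An object of class `risk_params` with fields `n`, `p`,
#'   `period_label`.
#' @examples
#' risk_params(30000, 1 / 30000, "month")
#' @export
risk_params <- function(n, p, period_label = "quarter") {
  check_number(n, "n", lower = 1, integerish = TRUE)
  check_number(p, "p", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  structure(list(n = as.integer(round(n)), p = p,
                 period_label = as.character(period_label)),
            class = "risk_params")
}

#' @export
print.risk_params <- function(x, ...) {
  cat(sprintf("<risk_params> n = %d, p = %.3g per %s (np = %.4g)\n",
              x$n, x$p, x$period_label, x$n * x$p))
  invisible(x)
}

as_risk_params <- function(params) {
  if (!inherits(params, "risk_params")) {
    odcast_abort("`params` must be created with risk_params().",
                 "odcast_domain_error")
  }
  params
}

#' Signal-to-noise ratio in the large-count (Normal) regime
#'
#' When the expected count `np` is large, counts are approximately
#' Normal(np, np), so SNR = E(Y)/Std(Y) = np / sqrt(np) = sqrt(np).
#'
#' @param params A [risk_params()] object.
#' @return Dimensionless SNR, `sqrt(n * p)`.
#' @examples
#' snr_large(risk_params(120000, 1 / 30000)) # 2
#' @export
snr_large <- function(params) {
  params <- as_risk_params(params)
  sqrt(params$n * params$p)
}

#' Expected absolute deviation of a Normal(np, np) count
#'
#' Mean absolute deviation of Y ~ Normal(np, np) from its mean:
#' `sqrt(2 np / pi)`.
#'
#' @inheritParams snr_large
#' @return Expected `|Y - np|` in deaths.
#' @export
expected_abs_deviation <- function(params) {
  params <- as_risk_params(params)
  sqrt(2 * params$n * params$p / pi)
}

#' Expected SMAPE of a calibrated predictor, large-count regime
#'
#' With the prediction fixed at the true mean `np` and counts
#' Normal(np, np), the expected SMAPE is approximately
#' `2 * E|Y - np| / (2 np) = sqrt(2 / (pi * n * p))`. The approximation
#' replaces the random denominator `y + np` by its mean `2 np`; its relative
#' error decays as `np` grows and is a few percent at `np = 5`.
#'
#' @inheritParams snr_large
#' @return Expected SMAPE in `[0, 2]`.
#' @examples
#' expected_smape_large(risk_params(30000, 25 / 30000))
#' @export
expected_smape_large <- function(params) {
  params <- as_risk_params(params)
  np <- params$n * params$p
  if (np <= 0) {
    odcast_abort("Expected count n*p must be positive.", "odcast_domain_error")
  }
  min(sqrt(2 / (pi * np)), 2)
}

#' Signal-to-noise ratio in the rare-event (Bernoulli) regime
#'
#' When `np << 1` the count is approximately Bernoulli(np), with
#' Var(Y) = np(1 - np), so SNR = np / sqrt(np (1 - np)).
#'
#' @inheritParams snr_large
#' @return Dimensionless SNR.
#' @export
snr_small <- function(params) {
  params <- as_risk_params(params)
  np <- params$n * params$p
  if (np >= 1) {
    odcast_abort(sprintf(
      "Bernoulli approximation requires n*p < 1, got %g.", np),
      "odcast_domain_error")
  }
  np / sqrt(np * (1 - np))
}

#' Expected SMAPE of a calibrated predictor, rare-event regime
#'
#' With Y ~ Bernoulli(np) and prediction `np`, the exact expectation over
#' the two outcomes is `np * 2(1 - np)/(1 + np) + (1 - np) * 2`, which
#' simplifies to `2 (1 - np)(1 + 2 np) / (1 + np)`. At `np -> 0` it tends to
#' 2: an almost-surely-zero count still incurs the maximal SMAPE whenever a
#' death occurs, and the calibrated prediction `np -> 0+` scores 2 against
#' an observed death.
#'
#' @inheritParams snr_large
#' @return Expected SMAPE in `[0, 2]`.
#' @examples
#' expected_smape_small(risk_params(5000, 1e-4))
#' @export
expected_smape_small <- function(params) {
  params <- as_risk_params(params)
  np <- params$n * params$p
  if (np >= 1) {
    odcast_abort(sprintf(
      "Bernoulli approximation requires n*p < 1, got %g.", np),
      "odcast_domain_error")
  }
  np * 2 * (1 - np) / (1 + np) + (1 - np) * 2
}

#' Pointwise symmetric absolute percentage error
#'
#' `smape_point(y, y_hat)` returns `2 |y - y_hat| / (|y| + |y_hat|)`,
#' bounded in `[0, 2]`. The indeterminate case `y = y_hat = 0` is defined as
#' 0 (a perfect prediction, the limit of identical pairs). Vectorized.
#'
#' @param y Observed count(s), nonnegative.
#' @param y_hat Predicted count(s), nonnegative.
#' @return Numeric vector of SMAPE values in `[0, 2]`.
#' @examples
#' smape_point(3, 1) # 1
#' @export
smape_point <- function(y, y_hat) {
  if (any(!is.finite(y)) || any(!is.finite(y_hat)) ||
      any(y < 0) || any(y_hat < 0)) {
    odcast_abort("`y` and `y_hat` must be finite and nonnegative.",
                 "odcast_domain_error")
  }
  denom <- abs(y) + abs(y_hat)
  out <- ifelse(denom == 0, 0, 2 * abs(y - y_hat) / denom)
  as.numeric(out)
}

#' Relative deviation of an absolute error against a population
#'
#' A one-death misprediction in a community of 4 is a 25% deviation of the
#' population; in a population of 10,000 it is 0.01%.
#'
#' @param abs_error Absolute prediction error in deaths (nonnegative).
#' @param n Population size in persons (>= 1).
#' @return `abs_error / n`, a fraction.
#' @export
relative_deviation <- function(abs_error, n) {
  if (any(abs_error < 0)) {
    odcast_abort("`abs_error` must be nonnegative.", "odcast_domain_error")
  }
  if (any(n < 1)) {
    odcast_abort("`n` must be at least 1.", "odcast_domain_error")
  }
  abs_error / n
}

#' Minimal population for a target signal-to-noise ratio
#'
#' The smallest integer population `n` with `sqrt(n p) >= snr_target`,
#' i.e. `ceiling(snr_target^2 / p)`. At the default target SNR of 1 and an
#' annual death rate of 4 per 10,000 converted to a monthly probability
#' (`p = (4/10000)/12 = 1/30000`), this returns the 30,000-person threshold
#' below which count noise dominates signal.
#'
#' @param p Per-person death probability per analysis period, in (0, 1).
#' @param snr_target Required SNR (default 1, noise no larger than signal).
#' @return Integer population threshold in persons.
#' @examples
#' minimal_population((4 / 10000) / 12) # 30000
#' @export
minimal_population <- function(p, snr_target = 1) {
  check_number(p, "p", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(snr_target, "snr_target", lower = 0, strict_lower = TRUE)
  n <- ceiling(snr_target^2 / p)
  # guard against floating-point overshoot of an exact ratio
  if (sqrt((n - 1) * p) >= snr_target && n > 1) n <- n - 1
  as.integer(n)
}

#' Simulate death counts under the exact or approximate laws
#'
#' Draws `n_draws` counts under the exact Binomial(n, p) law or one of the
#' two approximations used in the theory: Normal(np, np) (truncated at 0,
#' since counts are nonnegative) or Bernoulli(np). The Binomial model is the
#' reference law against which the closed forms are validated.
#'
#' @param params A [risk_params()] object.
#' @param model One of `"binomial"`, `"normal_approx"`, `"bernoulli_approx"`.
#' @param n_draws Number of draws (>= 1).
#' @param seed Integer seed; draws are reproducible given the seed.
#' @return Numeric vector of `n_draws` nonnegative counts.
#' @export
simulate_counts <- function(params, model = c("binomial", "normal_approx",
                                              "bernoulli_approx"),
                            n_draws, seed = 1L) {
  params <- as_risk_params(params)
  model <- tryCatch(match.arg(model),
                    error = function(e) odcast_abort(
                      sprintf("Unknown model tag %s.", deparse(model[1])),
                      "odcast_usage_error"))
  check_number(n_draws, "n_draws", lower = 1, integerish = TRUE)
  np <- params$n * params$p
  with_seed(seed, switch(
    model,
    binomial = as.numeric(rbinom(n_draws, params$n, params$p)),
    normal_approx = pmax(0, rnorm(n_draws, np, sqrt(np))),
    bernoulli_approx = {
      if (np >= 1) odcast_abort(
        "bernoulli_approx requires n*p < 1.", "odcast_domain_error")
      as.numeric(rbinom(n_draws, 1L, np))
    }))
}

#' Noise-theory report over a population grid
#'
#' One row per population: expected count, variance, SNR, its reciprocal
#' NSR, expected SMAPE of a calibrated predictor, and the regime used
#' (Normal above the `regime_boundary` on `np`, Bernoulli below).
#'
#' @param p Per-person death probability per analysis period.
#' @param population_grid Ascending vector of population sizes.
#' @param regime_boundary Value of `np` at and above which the large-count
#'   Normal regime is used (default 1, matching the SNR = 1 criterion).
#' @return A tibble with columns `n`, `np`, `regime`, `expected_count`,
#'   `variance`, `snr`, `nsr`, `expected_smape`.
#' @examples
#' theory_report(1 / 30000, c(12, 3899, 9802, 30000, 71189))
#' @export
theory_report <- function(p, population_grid, regime_boundary = 1) {
  check_number(p, "p", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (length(population_grid) == 0 || is.unsorted(population_grid)) {
    odcast_abort("`population_grid` must be nonempty and ascending.",
                 "odcast_domain_error")
  }
  purrr::map_dfr(population_grid, function(n) {
    pr <- risk_params(n, p)
    np <- n * p
    large <- np >= regime_boundary
    snr <- if (large) snr_large(pr) else snr_small(pr)
    tibble::tibble(
      n = as.integer(n),
      np = np,
      regime = if (large) "large_normal" else "small_bernoulli",
      expected_count = np,
      variance = if (large) np else np * (1 - np),
      snr = snr,
      nsr = ifelse(snr > 0, 1 / snr, Inf),
      expected_smape = if (large) expected_smape_large(pr)
                       else expected_smape_small(pr))
  })
}

#' @rdname theory_report
#' @param object A tibble produced by [theory_report()].
#' @param ... Unused.
#' @method autoplot odcast_theory_report
#' @export
autoplot.odcast_theory_report <- function(object, ...) {
  plot_theory_report(object)
}

#' Plot SNR and expected-SMAPE curves from a theory report
#'
#' @param report A tibble from [theory_report()].
#' @return A ggplot object with SNR and expected SMAPE against population.
#' @export
plot_theory_report <- function(report) {
  long <- tidyr::pivot_longer(
    dplyr::select(report, "n", "snr", "expected_smape"),
    cols = c("snr", "expected_smape"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "population (persons)", y = NULL,
                  title = "Count noise against population size")
}
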