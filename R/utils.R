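#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort .data :=
#' @importFrom stats rnorm rbinom rpois runif sd var cor median qlogis plogis
#' @importFrom utils head tail
NULL

# Internal: consistent error classes so callers can condition on them.
odcast_abort <- function(message, class) {
  abort(message, class = c(class, "odcast_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    odcast_abort(sprintf("`%s` must be a single finite number.", name),
                 "odcast_domain_error")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    odcast_abort(sprintf(
      "`%s` = %g violates the bound %s%s, %s%s.", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"), "odcast_domain_error")
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    odcast_abort(sprintf("`%s` must be an integer, got %g.", name, x),
                 "odcast_domain_error")
  }
  invisible(x)
}

# Named RNG substreams: each pipeline stage draws from its own seed derived
# from the global one, so reseeding one stage leaves the others untouched.
substream_seed <- function(seed, stage) {
  check_number(seed, "seed", integerish = TRUE)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 2654435 + h * 97) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
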