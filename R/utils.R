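#' @keywords internal
"_PACKAGE"

## Classed error helper so callers/tests can condition on failure modes.
cc_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "cc_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

#' Round half away from zero
#'
#' Plain decimal rounding where .5 always rounds up (toward +Inf for positive
#' values), the convention used for the printed percentage tables. Base R's
#' `round()` rounds half to even, which disagrees on exact .5 ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Coefficient of variation of a count vector
#'
#' Sample (n-1) standard deviation divided by the mean, as a percentage.
#' This is the gating-robustness measure: the spread of a population's event
#' count across repeated gate placements. `NA` when the mean is zero
#' (population absent under every variant).
#'
#' @param counts numeric vector of per-variant counts for one population.
#' @return CV in percent, or `NA_real_`.
#' @export
count_cv <- function(counts) {
  m <- mean(counts)
  if (!is.finite(m) || m == 0) return(NA_real_)
  100 * stats::sd(counts) / m
}

## Deterministic child seeds below 2^31 derived from one user seed.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

## Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
## caller's stream afterwards so library calls don't perturb user RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  expr
}

## Scaled median absolute deviation with a floor for degenerate spreads.
mad_floored <- function(x, floor_value = 1e-8) {
  m <- stats::mad(x)
  if (!is.finite(m) || m < floor_value) floor_value else m
}
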