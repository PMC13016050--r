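#' PERT distribution parameters
#'
#' Constructs and validates the (minimum, most-likely, maximum) triple that
#' parameterizes a beta-PERT distribution for one uncertain quantity, typically
#' an annual cost in USD or an annual encounter count. The PERT distribution is
#' a beta distribution rescaled to `[min, max]` whose shape parameters are
#' chosen so that the mode sits at `mode` and, with the classic shape
#' `lambda = 4`, the mean is `(min + 4 mode + max) / 6`. Compared with a
#' triangular distribution it down-weights the extremes, which is why it is
#' the customary choice for expert-elicited cost ranges in probabilistic
#' sensitivity analysis.
#'
#' A degenerate triple with `min == max` is allowed and denotes a point mass:
#' sampling returns the constant and the variance is zero. This is how
#' deterministic cost lines (and exact oracle tests) are expressed.
#'
#' @param min Minimum plausible value.
#' @param mode Most likely value (`min <= mode <= max`).
#' @param max Maximum plausible value.
#' @param shape Positive PERT shape parameter `lambda`; 4 is the conventional
#'   default that yields the `(a + 4m + b)/6` mean weighting.
#' @return An object of class `pert_params`.
#' @examples
#' p <- pert_params(100, 200, 600)
#' pert_mean(p)      # 250
#' pert_variance(p)  # 7500
#' @export
pert_params <- function(min, mode, max, shape = 4) {
  stopifnot(is.numeric(min), is.numeric(mode), is.numeric(max),
            length(min) == 1L, length(mode) == 1L, length(max) == 1L,
            is.finite(min), is.finite(mode), is.finite(max))
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) || shape <= 0)
    stop("'shape' must be a single positive number", call. = FALSE)
  if (min > mode || mode > max)
    stop(sprintf("PERT triple must satisfy min <= mode <= max (got %g, %g, %g)",
                 min, mode, max), call. = FALSE)
  structure(list(min = as.numeric(min), mode = as.numeric(mode),
                 max = as.numeric(max), shape = as.numeric(shape)),
            class = "pert_params")
}

#' @export
print.pert_params <- function(x, ...) {
  cat(sprintf("PERT(min = %g, mode = %g, max = %g, shape = %g)\n",
              x$min, x$mode, x$max, x$shape))
  invisible(x)
}

is_point_mass <- function(p) p$min == p$max

#' Convert PERT parameters to beta shape parameters
#'
#' The beta-PERT reparameterization: a PERT triple maps to a beta distribution
#' on `[0, 1]` with
#' `alpha = 1 + shape * (mode - min) / (max - min)` and
#' `beta  = 1 + shape * (max - mode) / (max - min)`,
#' which a draw rescales back to `[min, max]`.
#'
#' @param p A [pert_params()] object with `min < max`.
#' @return A list with components `alpha` and `beta` (both `> 0`).
#' @examples
#' pert_to_beta(pert_params(0, 0.25, 1))  # alpha 2, beta 4
#' @export
pert_to_beta <- function(p) {
  stopifnot(inherits(p, "pert_params"))
  if (is_point_mass(p))
    stop("degenerate PERT range (min == max) is a point mass; no beta shape exists",
         call. = FALSE)
  range <- p$max - p$min
  list(alpha = 1 + p$shape * (p$mode - p$min) / range,
       beta  = 1 + p$shape * (p$max - p$mode) / range)
}

#' Closed-form mean of a PERT distribution
#'
#' `(min + shape * mode + max) / (shape + 2)`; with the default `shape = 4`
#' this is the familiar `(a + 4m + b) / 6`.
#'
#' @param p A [pert_params()] object.
#' @return The distribution mean.
#' @export
pert_mean <- function(p) {
  stopifnot(inherits(p, "pert_params"))
  (p$min + p$shape * p$mode + p$max) / (p$shape + 2)
}

#' Closed-form variance of a PERT distribution
#'
#' `(mean - min) * (max - mean) / (shape + 3)`, zero for a point mass.
#'
#' @param p A [pert_params()] object.
#' @return The distribution variance.
#' @export
pert_variance <- function(p) {
  stopifnot(inherits(p, "pert_params"))
  m <- pert_mean(p)
  (m - p$min) * (p$max - m) / (p$shape + 3)
}

#' Sample from a PERT distribution
#'
#' Draws `n` values as `min + (max - min) * B` with
#' `B ~ Beta(pert_to_beta(p))`, using R's current RNG stream; a point-mass
#' triple returns a constant vector. Callers control reproducibility with
#' `set.seed()`; the simulation engine assigns each cost element its own
#' seeded substream.
#'
#' @param n Number of draws (positive integer).
#' @param p A [pert_params()] object.
#' @return Numeric vector of length `n`, every value in `[min, max]`.
#' @examples
#' set.seed(1)
#' summary(rpert(1000, pert_params(0, 0.5, 1)))
#' @export
rpert <- function(n, p) {
  stopifnot(inherits(p, "pert_params"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  if (is_point_mass(p)) return(rep(p$min, n))
  sh <- pert_to_beta(p)
  p$min + (p$max - p$min) * stats::rbeta(n, sh$alpha, sh$beta)
}

#' PERT density
#'
#' Density of the beta-PERT distribution, zero outside `[min, max]`. Provided
#' for plotting and diagnostic overlays; undefined (errors) for a point mass.
#'
#' @param x Numeric vector of quantiles.
#' @param p A [pert_params()] object with `min < max`.
#' @return Numeric vector of densities.
#' @export
dpert <- function(x, p) {
  stopifnot(inherits(p, "pert_params"))
  if (is_point_mass(p))
    stop("density undefined for a point-mass PERT (min == max)", call. = FALSE)
  sh <- pert_to_beta(p)
  range <- p$max - p$min
  out <- numeric(length(x))
  inside <- x >= p$min & x <= p$max
  out[inside] <- stats::dbeta((x[inside] - p$min) / range, sh$alpha, sh$beta) / range
  out
}
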