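#' Highest density interval of posterior draws
#'
#' Shortest interval containing at least `mass` of the draws, computed by
#' the sliding-window minimum-width algorithm on the sorted sample: of
#' all windows of `ceiling(mass * n)` consecutive order statistics, the
#' narrowest (first such window on ties) is returned. For unimodal
#' posteriors this estimates the HDI.
#'
#' @param draws numeric vector of posterior draws.
#' @param mass interval mass in (0, 1), default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' hdi(seq(0, 1, by = 0.001), 0.95)  # width ~0.95
#' @export
hdi <- function(draws, mass = 0.95) {
  if (length(mass) != 1L || !is.finite(mass) || mass <= 0 || mass >= 1)
    stop("`mass` must lie strictly between 0 and 1")
  if (any(!is.finite(draws))) stop("draws must be finite")
  n <- length(draws)
  if (n < ceiling(1 / (1 - mass)))
    stop("too few draws (", n, ") for mass ", mass)
  x <- sort(draws)
  w <- ceiling(mass * n)
  starts <- seq_len(n - w + 1L)
  widths <- x[starts + w - 1L] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + w - 1L])
}

#' Probability of direction
#'
#' The proportion of posterior draws sharing the sign of the more
#' probable direction: `max(P(>0), P(<0))`, with draws exactly at zero
#' split evenly between the two directions. Lies in `[0.5, 1]`.
#'
#' @param draws numeric vector of posterior draws.
#' @return Fraction in `[0.5, 1]`.
#' @examples
#' probability_of_direction(c(-1, 2, 3, 4))  # 0.75
#' @export
probability_of_direction <- function(draws) {
  if (!length(draws)) stop("no draws")
  half_zero <- mean(draws == 0) / 2
  max(mean(draws > 0), mean(draws < 0)) + half_zero
}

#' Region of practical equivalence for a linear-model effect
#'
#' The ROPE is the symmetric band of negligible effect sizes,
#' `c(-0.05, 0.05) * sd_y` where `sd_y` is the standard deviation of the
#' dependent variable.
#'
#' @param sd_y positive standard deviation of the response.
#' @return Numeric `c(low, high)` with `low = -high`.
#' @examples
#' rope_bounds(10)  # -0.5 0.5
#' @export
rope_bounds <- function(sd_y) {
  if (length(sd_y) != 1L || !is.finite(sd_y) || sd_y <= 0)
    stop("`sd_y` must be a single positive number")
  c(-0.05 * sd_y, 0.05 * sd_y)
}

#' Posterior effect summary (median, HDI, direction, ROPE)
#'
#' Assembles the sequential effect-existence reporting quadruple from a
#' vector of posterior draws: posterior median `E_M`, highest density
#' interval, probability of direction `D_p`, and the proportion of the
#' posterior inside the region of practical equivalence `ROPE_p`
#' (closed interval; draws exactly on a bound count as inside, which is
#' conservative for the decision). The effect is declared not
#' practically equivalent to zero when `ROPE_p < 0.025`, i.e. when less
#' than 2.5% of the full posterior remains within the ROPE.
#'
#' @param draws numeric vector of posterior draws (>= 100 recommended).
#' @param sd_y standard deviation of the dependent variable, defining
#'   the ROPE via [rope_bounds()].
#' @param mass HDI mass (default 0.95).
#' @param rope_within_hdi if `TRUE`, compute `ROPE_p` over the draws
#'   inside the `mass` HDI instead of the full posterior.
#' @param min_draws floor on the number of draws accepted.
#' @return An object of class `sexit_summary`: list with `E_M`,
#'   `hdi_low`, `hdi_high`, `hdi_mass`, `D_p`, `rope_low`, `rope_high`,
#'   `ROPE_p`, `decision` (TRUE = not practically equivalent to zero)
#'   and `n_draws`. Its `format()`/`print()` methods render the standard
#'   "E_M (low, high), D_p, ROPE_p" line.
#' @examples
#' d <- generate_posterior_draws(-95.9, 40, 4000, seed = 1)
#' sexit_summary(d, sd_y = 500)
#' @export
sexit_summary <- function(draws, sd_y, mass = 0.95,
                          rope_within_hdi = FALSE, min_draws = 100) {
  if (length(draws) < min_draws)
    stop("need at least ", min_draws, " draws (got ", length(draws), ")")
  rope <- rope_bounds(sd_y)
  interval <- hdi(draws, mass)
  pool <- if (rope_within_hdi)
    draws[draws >= interval[1] & draws <= interval[2]] else draws
  rope_p <- mean(pool >= rope[1] & pool <= rope[2])
  structure(list(E_M = stats::median(draws),
                 hdi_low = interval[1], hdi_high = interval[2],
                 hdi_mass = mass,
                 D_p = probability_of_direction(draws),
                 rope_low = rope[1], rope_high = rope[2],
                 ROPE_p = rope_p,
                 decision = rope_p < 0.025,
                 n_draws = length(draws)),
            class = "sexit_summary")
}

#' @export
format.sexit_summary <- function(x, digits = 2, ...) {
  sprintf("E_M = %s (%s, %s), D_p = %s, ROPE_p = %s",
          format(round(x$E_M, digits)),
          format(round(x$hdi_low, digits)),
          format(round(x$hdi_high, digits)),
          format(round(x$D_p, digits)),
          format(round(x$ROPE_p, digits)))
}

#' @export
print.sexit_summary <- function(x, ...) {
  cat(format(x, ...), "\n")
  cat(if (x$decision) "effect not practically equivalent to zero"
      else "effect practically equivalent to zero (or undecided)",
      sprintf("[ROPE (%.4g, %.4g), %d draws]\n",
              x$rope_low, x$rope_high, x$n_draws))
  invisible(x)
}

#' @export
as.data.frame.sexit_summary <- function(x, ...) {
  data.frame(E_M = x$E_M, hdi_low = x$hdi_low, hdi_high = x$hdi_high,
             hdi_mass = x$hdi_mass, D_p = x$D_p, rope_low = x$rope_low,
             rope_high = x$rope_high, ROPE_p = x$ROPE_p,
             decision = x$decision, n_draws = x$n_draws)
}
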