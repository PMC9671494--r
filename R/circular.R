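#' @keywords internal
deg2rad <- function(x) x * pi / 180

#' @keywords internal
rad2deg <- function(x) (x * 180 / pi) %% 360

#' Circular mean and mean resultant length
#'
#' Treats each angle as a unit vector and returns the direction of the vector
#' mean together with its length (the mean resultant length, R-bar).
#' R-bar is 1 when all angles coincide and 0 when they cancel exactly; for a
#' perfectly balanced sample (e.g. 0 and 180 degrees) the mean direction is
#' undefined and reported as `NA`.
#'
#' @param angles numeric vector of angles in degrees (any real values; reduced
#'   modulo 360). `NA`s are dropped.
#' @return list with `n`, `mean_deg` (in `[0, 360)`, or `NA` when the
#'   resultant is numerically zero) and `resultant` (R-bar in `[0, 1]`).
#' @examples
#' circular_mean(c(350, 10))   # wraps to 0
#' circular_mean(c(0, 90))     # 45 degrees, R-bar = cos(45 deg)
#' @export
circular_mean <- function(angles) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 1L) stop("circular_mean() needs at least one non-missing angle")
  th <- deg2rad(angles)
  C <- mean(cos(th))
  S <- mean(sin(th))
  r <- sqrt(C^2 + S^2)
  mean_deg <- if (r < 1e-12) NA_real_ else rad2deg(atan2(S, C))
  list(n = n, mean_deg = mean_deg, resultant = min(r, 1))
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of angles departs from the uniform distribution on
#' the circle. The statistic is `z = n * R^2` where `R` is the mean resultant
#' length; the p-value uses the standard finite-n series approximation
#' `p = exp(-z) * [1 + (2z - z^2)/(4n) - (24z - 132z^2 + 76z^3 - 9z^4)/(288n^2)]`,
#' clipped into `(0, 1]`.
#'
#' Either supply the raw `angles`, or supply `n` and `resultant` directly
#' (useful to recompute a p-value from a reported summary statistic).
#'
#' @param angles numeric vector of angles in degrees, or `NULL`.
#' @param n sample size (used with `resultant` when `angles` is `NULL`).
#' @param resultant mean resultant length R-bar in `[0, 1]`.
#' @return object of class `"circ_summary"`: list with `n`, `mean_deg`
#'   (NA when computed from a summary), `resultant`, `z` and `p`.
#' @examples
#' rayleigh_test(n = 46, resultant = 0.134)
#' rayleigh_test(runif(100, 0, 360))
#' @export
rayleigh_test <- function(angles = NULL, n = NULL, resultant = NULL) {
  mean_deg <- NA_real_
  if (!is.null(angles)) {
    cm <- circular_mean(angles)
    n <- cm$n
    resultant <- cm$resultant
    mean_deg <- cm$mean_deg
  }
  if (is.null(n) || is.null(resultant)) {
    stop("supply either `angles` or both `n` and `resultant`")
  }
  if (n < 2) stop("rayleigh_test() requires n >= 2")
  if (resultant < 0 || resultant > 1) stop("`resultant` must lie in [0, 1]")
  z <- n * resultant^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(n = n, mean_deg = mean_deg, resultant = resultant,
                 z = z, p = p),
            class = "circ_summary")
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf("Rayleigh test: n = %d, R-bar = %.4f, z = %.4f, p = %.4g\n",
              x$n, x$resultant, x$z, x$p))
  if (!is.na(x$mean_deg)) cat(sprintf("  mean direction = %.1f deg\n", x$mean_deg))
  invisible(x)
}

#' Holm-Bonferroni step-down correction
#'
#' Step-down adjustment: sort the m p-values ascending, multiply the i-th by
#' (m - i + 1), enforce monotonicity with a running maximum and cap at 1.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @param alpha family-wise error rate for the reject flags.
#' @return data.frame with columns `p`, `p_adj`, `reject`, in the input order.
#'   Empty input gives an empty data.frame.
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L) {
    return(data.frame(p = numeric(0), p_adj = numeric(0), reject = logical(0)))
  }
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("all p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  o <- order(pvalues)
  adj_sorted <- pmin(cummax((m - seq_len(m) + 1) * pvalues[o]), 1)
  p_adj <- numeric(m)
  p_adj[o] <- adj_sorted
  data.frame(p = pvalues, p_adj = p_adj, reject = p_adj <= alpha)
}
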