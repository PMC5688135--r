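#' Planar point pattern
#'
#' A set of stem coordinates in a rectangular window. All analysis distances
#' are Euclidean in plot metres.
#'
#' @param x,y coordinates in metres.
#' @param window a [plot_geometry()] or a numeric `c(width, height)`.
#' @return A `point_pattern` with elements `x`, `y`, `width`, `height`, `n`.
#' @export
point_pattern <- function(x, y, window) {
  if (inherits(window, "plot_geometry")) {
    w <- window$width; h <- window$height
  } else {
    w <- window[1]; h <- window[2]
  }
  stopifnot(length(x) == length(y))
  if (length(x) && (any(x < 0 | x >= w) || any(y < 0 | y >= h)))
    stop("points outside the half-open window [0,w) x [0,h)")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 width = w, height = h, n = length(x)),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("Point pattern: %d points in %g m x %g m window\n",
              x$n, x$width, x$height))
  invisible(x)
}

#' Pair-correlation function estimate
#'
#' Kernel estimator of the univariate pair-correlation function
#' \deqn{\hat g(r) = \frac{A}{2\pi r\, n(n-1)} \sum_{i \ne j}
#'   k_b(r - d_{ij})\, w_{ij},}
#' where \eqn{A} is the window area, \eqn{k_b} a box kernel of half-width
#' `bandwidth` (Epanechnikov optional) and \eqn{w_{ij}} the Ripley isotropic
#' edge-correction weight (reciprocal of the fraction of the circle of radius
#' \eqn{d_{ij}} around point \eqn{i} inside the window); translation
#' correction and no correction are also available. Under complete spatial
#' randomness \eqn{g \equiv 1}; values above 1 indicate aggregation at that
#' distance, below 1 regularity. Estimates at radii smaller than the
#' bandwidth carry high variance and are flagged `small_r`.
#'
#' @param pattern a [point_pattern()] with at least 2 points.
#' @param radii increasing evaluation radii (m), within
#'   `(0, min(width, height)/2]`; default `1:50`.
#' @param bandwidth kernel half-width in metres (default 0.5).
#' @param edge_correction `"ripley"` (default), `"translation"` or `"none"`.
#' @param kernel `"box"` (default) or `"epanechnikov"`.
#' @return A data frame of class `pcf_estimate` with columns `r`, `g`,
#'   `small_r`; attributes `n`, `bandwidth`, `edge_correction`, `kernel`.
#' @examples
#' p <- simulate_csr(500, c(200, 200), seed = 1)
#' g <- pair_correlation(p, radii = 1:25)
#' aggregation_index(g)
#' @export
pair_correlation <- function(pattern, radii = 1:50, bandwidth = 0.5,
                             edge_correction = c("ripley", "translation",
                                                 "none"),
                             kernel = c("box", "epanechnikov")) {
  edge_correction <- match.arg(edge_correction)
  kernel <- match.arg(kernel)
  if (pattern$n < 2) stop("pair correlation needs at least 2 points")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  radii <- sort(as.numeric(radii))
  if (any(radii <= 0) || any(diff(radii) <= 0))
    stop("radii must be positive and strictly increasing")
  if (max(radii) > min(pattern$width, pattern$height) / 2)
    stop("radii must not exceed half the shorter window side")
  acc <- pcf_pairs_cpp(pattern$x, pattern$y, pattern$width, pattern$height,
                       radii, bandwidth,
                       match(edge_correction, c("none", "ripley",
                                                "translation")) - 1L,
                       match(kernel, c("box", "epanechnikov")) - 1L)
  A <- pattern$width * pattern$height
  g <- A * acc / (2 * pi * radii * pattern$n * (pattern$n - 1))
  structure(data.frame(r = radii, g = g, small_r = radii < bandwidth),
            n = pattern$n, bandwidth = bandwidth,
            edge_correction = edge_correction, kernel = kernel,
            class = c("pcf_estimate", "data.frame"))
}

#' Mean aggregation index over a distance band
#'
#' The arithmetic mean of \eqn{\hat g(r)} over the evaluation radii in
#' `(r_min, r_max]`; with the defaults this is the g0-10 index of conspecific
#' aggregation density within 10 m of a typical tree.
#'
#' @param pcf a `pcf_estimate`.
#' @param r_min,r_max band limits in metres (defaults 0 and 10).
#' @return Numeric scalar, the mean g over the band.
#' @export
aggregation_index <- function(pcf, r_min = 0, r_max = 10) {
  sel <- pcf$r > r_min & pcf$r <= r_max
  if (!any(sel)) stop("no evaluation radii in (", r_min, ", ", r_max, "]")
  mean(pcf$g[sel])
}

#' Write a pair-correlation estimate
#' @param pcf a `pcf_estimate`.
#' @param path output CSV path.
#' @param species optional species code column value.
#' @export
write_pcf <- function(pcf, path, species = NA_character_) {
  df <- data.frame(species = species, r = pcf$r, g = pcf$g,
                   n = attr(pcf, "n"), bandwidth = attr(pcf, "bandwidth"),
                   edge_correction = attr(pcf, "edge_correction"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.pcf_estimate <- function(x, ...) {
  cat(sprintf("Pair-correlation estimate: n = %d, %d radii in [%g, %g] m, %s correction, bandwidth %g m\n",
              attr(x, "n"), nrow(x), min(x$r), max(x$r),
              attr(x, "edge_correction"), attr(x, "bandwidth")))
  cat(sprintf("  mean g over (0,10] m: %.3f\n",
              tryCatch(aggregation_index(x), error = function(e) NA)))
  invisible(x)
}

#' @export
plot.pcf_estimate <- function(x, ...) {
  plot(x$r, x$g, type = "l", xlab = "r (m)", ylab = "g(r)", ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}
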