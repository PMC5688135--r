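#' Simulate complete spatial randomness
#'
#' Exactly `n` points placed independently and uniformly over the window
#' (a binomial process, i.e. CSR conditioned on the observed count, since
#' species are classified at their census abundance).
#'
#' @param n number of points.
#' @param window a [plot_geometry()] or `c(width, height)`.
#' @param seed optional integer seed for reproducibility.
#' @return A [point_pattern()].
#' @export
simulate_csr <- function(n, window, seed = NULL) {
  force(window)
  if (!is.null(seed)) set.seed(seed)
  w <- if (inherits(window, "plot_geometry")) window$width else window[1]
  h <- if (inherits(window, "plot_geometry")) window$height else window[2]
  point_pattern(runif(n, 0, w), runif(n, 0, h), c(w, h))
}

#' Fit a heterogeneous Poisson intensity from topographic covariates
#'
#' Log-linear (Poisson regression) model of the 10-m quadrat counts of a
#' species on standardised elevation, slope and convexity plus the sine and
#' cosine of aspect (quadrats with undefined aspect contribute sin = cos =
#' 0), with intercept. The fitted per-quadrat intensity is rescaled so its
#' integral over the window equals the observed count exactly.
#'
#' @param pattern a [point_pattern()] of the species' stems.
#' @param topo10 a `topo_grid` at the covariate (10-m) resolution covering
#'   the same window.
#' @param min_n minimum points for a stable fit (default 50).
#' @return An `intensity_map`: data frame `row`, `col`, `x`, `y`, `mass`
#'   (expected stems per quadrat), `lambda` (stems per square metre);
#'   attributes `coefficients`, `vcov`, `cell_size`, `n`.
#' @export
fit_hpp_intensity <- function(pattern, topo10, min_n = 50) {
  if (pattern$n < min_n)
    stop("need at least ", min_n, " points to fit an intensity")
  cs <- attr(topo10, "cell_size")
  counts <- quadrat_counts(pattern, cs,
                           geometry = plot_geometry(pattern$width,
                                                    pattern$height,
                                                    cs, cs))
  # topo rows are row-major south-west first, matching counts by (row, col)
  cnt <- counts[cbind(topo10$row, topo10$col)]
  zs <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  asp <- topo10$aspect * pi / 180
  df <- data.frame(count = cnt,
                   elevation = zs(topo10$elevation),
                   slope = zs(topo10$slope),
                   convexity = zs(topo10$convexity),
                   aspect_sin = ifelse(is.na(asp), 0, sin(asp)),
                   aspect_cos = ifelse(is.na(asp), 0, cos(asp)))
  fit <- glm(count ~ elevation + slope + convexity + aspect_sin + aspect_cos,
             family = poisson(), data = df)
  if (!fit$converged) stop("HPP intensity fit did not converge")
  mass <- as.numeric(fit$fitted.values)
  mass <- mass * pattern$n / sum(mass)  # intercept calibration
  structure(data.frame(row = topo10$row, col = topo10$col,
                       x = topo10$x, y = topo10$y,
                       mass = mass, lambda = mass / cs^2),
            coefficients = coef(fit), vcov = vcov(fit),
            cell_size = cs, n = pattern$n,
            class = c("intensity_map", "data.frame"))
}

#' @export
print.intensity_map <- function(x, ...) {
  cat(sprintf("Fitted intensity over %d quadrats (%g m); integral %.1f stems\n",
              nrow(x), attr(x, "cell_size"), sum(x$mass)))
  print(round(attr(x, "coefficients"), 3))
  invisible(x)
}

#' Simulate from a fitted heterogeneous Poisson intensity
#'
#' Exactly `n` points: quadrats drawn multinomially with probabilities
#' proportional to quadrat intensity mass, positions uniform within the
#' quadrat (the piecewise-constant intensity of the fitted model).
#'
#' @param intensity an `intensity_map` from [fit_hpp_intensity()].
#' @param n number of points (default the fitted count).
#' @param seed optional integer seed.
#' @return A [point_pattern()].
#' @export
simulate_hpp <- function(intensity, n = attr(intensity, "n"), seed = NULL) {
  force(intensity); force(n)
  if (!is.null(seed)) set.seed(seed)
  if (sum(intensity$mass) <= 0) stop("all-zero intensity")
  cs <- attr(intensity, "cell_size")
  q <- sample.int(nrow(intensity), n, replace = TRUE,
                  prob = intensity$mass)
  x <- intensity$x[q] + runif(n, 0, cs)
  y <- intensity$y[q] + runif(n, 0, cs)
  w <- max(intensity$x) + cs; h <- max(intensity$y) + cs
  # guard against landing exactly on the closed edge by floating rounding
  point_pattern(pmin(x, w - 1e-9), pmin(y, h - 1e-9), c(w, h))
}

envelope_bounds_index <- function(nsim) {
  if (nsim < 19) stop("nsim must be at least 19 to form 5%/95% bounds")
  c(lo = max(1L, as.integer(floor(0.05 * (nsim + 1)))),
    hi = min(nsim, as.integer(ceiling(0.95 * (nsim + 1)))))
}

#' Monte-Carlo simulation envelope test of a point pattern
#'
#' Compares the observed pair-correlation function with pointwise 5th/95th
#' percentile envelopes from `nsim` simulations of a null model (999 by
#' default, giving order statistics 50 and 950): at each radius the pattern
#' is classified `aggregated` if the observed g lies above the upper bound
#' (null rejected toward clustering), `regular` if below the lower bound,
#' and `random` otherwise. The null is either CSR or a heterogeneous Poisson
#' process with intensity driven by the 10-m topographic covariates; null
#' simulations condition on the observed n.
#'
#' @param pattern observed [point_pattern()] (n >= 25 recommended).
#' @param null `"csr"` or `"hpp"`.
#' @param nsim number of simulations (default 999; minimum 19).
#' @param radii evaluation radii (m).
#' @param bandwidth,edge_correction passed to [pair_correlation()].
#' @param topo10 covariate `topo_grid` (required for `null = "hpp"` unless
#'   `intensity` is given).
#' @param intensity optional pre-fitted `intensity_map`.
#' @param seed optional integer seed.
#' @return Data frame of class `envelope_result` with columns `r`, `g_obs`,
#'   `lo`, `hi`, `class`; attributes `null`, `nsim`, `n`.
#' @export
envelope_test <- function(pattern, null = c("csr", "hpp"), nsim = 999,
                          radii = 1:50, bandwidth = 0.5,
                          edge_correction = "ripley", topo10 = NULL,
                          intensity = NULL, seed = NULL) {
  null <- match.arg(null)
  bi <- envelope_bounds_index(nsim)
  force(pattern); force(topo10); force(intensity)
  if (!is.null(seed)) set.seed(seed)
  if (null == "hpp" && is.null(intensity)) {
    if (is.null(topo10)) stop("hpp null needs topo10 covariates or intensity")
    intensity <- fit_hpp_intensity(pattern, topo10)
  }
  g_obs <- pair_correlation(pattern, radii, bandwidth, edge_correction)$g
  sims <- matrix(NA_real_, nsim, length(radii))
  for (s in seq_len(nsim)) {
    sim <- if (null == "csr")
      simulate_csr(pattern$n, c(pattern$width, pattern$height))
    else simulate_hpp(intensity, pattern$n)
    sims[s, ] <- pair_correlation(sim, radii, bandwidth, edge_correction)$g
  }
  srt <- apply(sims, 2, sort)
  lo <- srt[bi["lo"], ]; hi <- srt[bi["hi"], ]
  cls <- ifelse(g_obs > hi, "aggregated",
                ifelse(g_obs < lo, "regular", "random"))
  structure(data.frame(r = radii, g_obs = g_obs, lo = lo, hi = hi,
                       class = cls, stringsAsFactors = FALSE),
            null = null, nsim = nsim, n = pattern$n,
            class = c("envelope_result", "data.frame"))
}

#' @export
print.envelope_result <- function(x, ...) {
  cat(sprintf("Envelope test (%s null, %d simulations, n = %d):\n",
              toupper(attr(x, "null")), attr(x, "nsim"), attr(x, "n")))
  print(table(factor(x$class, c("aggregated", "random", "regular"))))
  invisible(x)
}

#' @export
plot.envelope_result <- function(x, ...) {
  plot(x$r, x$g_obs, type = "n", xlab = "r (m)", ylab = "g(r)",
       ylim = range(c(x$g_obs, x$lo, x$hi)), ...)
  graphics::polygon(c(x$r, rev(x$r)), c(x$lo, rev(x$hi)),
                    col = "grey85", border = NA)
  graphics::lines(x$r, x$g_obs)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Classify every common species against a null model
#'
#' Runs [envelope_test()] for each species in `summaries` and assembles the
#' long-format classification table plus the proportion of species
#' aggregated / random / regular at each scale. Per-species failures are
#' caught, reported as warnings and skipped.
#'
#' @param census a `census_table`.
#' @param summaries a `species_summary` (already filtered to the minimum
#'   abundance).
#' @param null `"csr"` or `"hpp"`.
#' @param nsim simulations per species (default 999).
#' @param radii evaluation radii (m).
#' @param topo10 covariate grid for the HPP null.
#' @param seed optional integer seed; species s uses `seed + s`.
#' @param geometry plot geometry; defaults to the census geometry.
#' @return List with `classification` (species x radius x class long table),
#'   `proportions` (radius, frac_aggregated, frac_random, frac_regular,
#'   null_model), `g0_10` (per-species aggregation index), `failed`.
#' @export
classify_species_patterns <- function(census, summaries,
                                      null = c("csr", "hpp"), nsim = 999,
                                      radii = 1:50, topo10 = NULL,
                                      seed = NULL,
                                      geometry = attr(census, "geometry")) {
  null <- match.arg(null)
  rows <- list(); g010 <- numeric(0); failed <- character(0)
  for (k in seq_len(nrow(summaries))) {
    s <- summaries$species[k]
    res <- tryCatch({
      pat <- species_pattern(census, s, geometry)
      env <- envelope_test(pat, null, nsim, radii, topo10 = topo10,
                           seed = if (is.null(seed)) NULL else seed + k)
      g010[s] <- aggregation_index(
        structure(data.frame(r = env$r, g = env$g_obs),
                  class = c("pcf_estimate", "data.frame")))
      data.frame(species = s, r = env$r, g_obs = env$g_obs, lo = env$lo,
                 hi = env$hi, class = env$class, stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("species ", s, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, s) else rows[[s]] <- res
  }
  cls <- do.call(rbind, rows)
  rownames(cls) <- NULL
  prop <- do.call(rbind, lapply(split(cls, cls$r), function(d) {
    data.frame(r = d$r[1],
               frac_aggregated = mean(d$class == "aggregated"),
               frac_random = mean(d$class == "random"),
               frac_regular = mean(d$class == "regular"),
               null_model = null)
  }))
  prop <- prop[order(prop$r), ]
  rownames(prop) <- NULL
  list(classification = cls, proportions = prop, g0_10 = g010,
       failed = failed)
}
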