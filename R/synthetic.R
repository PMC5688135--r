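#' Generate a rugged synthetic elevation grid
#'
#' Sum of randomly placed anisotropic Gaussian hills and pits, a smooth
#' regional gradient in a random direction, and small-scale noise (white
#' noise on a coarse lattice, bilinearly smoothed), rescaled so the
#' elevation range equals `relief` exactly above `base`. With `n_hills = 0`
#' and `roughness = 0` the grid is perfectly flat at `base`. Reproducible
#' for a given seed; the defaults emulate karst terrain with ~200 m of
#' relief and slopes spanning 0-67 degrees.
#'
#' @param geometry a [plot_geometry()].
#' @param relief elevation range in metres (default 200).
#' @param n_hills number of Gaussian bumps/pits (default 8).
#' @param roughness relative amplitude of small-scale noise (default 0.5).
#' @param base base elevation in metres (default 450).
#' @param spacing lattice spacing in metres (default 10).
#' @param seed optional integer seed.
#' @return An `elevation_grid`.
#' @export
generate_dem <- function(geometry, relief = 200, n_hills = 8,
                         roughness = 0.5, base = 450, spacing = 10,
                         seed = NULL) {
  if (relief <= 0) stop("relief must be positive")
  force(geometry)  # evaluate before seeding so callers cannot perturb the RNG
  if (!is.null(seed)) set.seed(seed)
  xs <- seq(0, geometry$width, by = spacing)
  ys <- seq(0, geometry$height, by = spacing)
  gx <- matrix(rep(xs, each = length(ys)), length(ys), length(xs))
  gy <- matrix(rep(ys, length(xs)), length(ys), length(xs))
  if (n_hills == 0 && roughness == 0)
    return(elevation_grid(gx * 0 + base, spacing))
  th <- runif(1, 0, 2 * pi)
  z <- 0.35 * (cos(th) * gx + sin(th) * gy) / max(geometry$width,
                                                  geometry$height)
  for (k in seq_len(n_hills)) {
    cx <- runif(1, 0, geometry$width); cy <- runif(1, 0, geometry$height)
    sx <- runif(1, 0.06, 0.25) * geometry$width
    sy <- runif(1, 0.06, 0.25) * geometry$height
    rot <- runif(1, 0, pi); amp <- sample(c(-1, 1), 1) * runif(1, 0.4, 1)
    u <- (gx - cx) * cos(rot) + (gy - cy) * sin(rot)
    v <- -(gx - cx) * sin(rot) + (gy - cy) * cos(rot)
    z <- z + amp * exp(-(u^2 / (2 * sx^2) + v^2 / (2 * sy^2)))
  }
  if (roughness > 0) {
    coarse <- 4 * spacing
    nzx <- ceiling(geometry$width / coarse) + 2
    nzy <- ceiling(geometry$height / coarse) + 2
    noise <- matrix(rnorm(nzy * nzx), nzy, nzx)
    z <- z + roughness * 0.15 *
      matrix(bilinear_at(noise, coarse, c(gx), c(gy)), nrow(gx), ncol(gx))
  }
  z <- base + relief * (z - min(z)) / (max(z) - min(z))
  elevation_grid(z, spacing)
}

#' Simulate a Thomas cluster process
#'
#' Parents form a homogeneous Poisson process of intensity `kappa` on the
#' window extended by `4 * sigma` on every side; each parent has a
#' Poisson(`mu`) number of offspring displaced by an isotropic Gaussian of
#' standard deviation `sigma`; offspring are clipped to the window. The
#' canonical model of an aggregated tree species, with closed-form
#' pair-correlation function
#' \eqn{g(r) = 1 + \exp(-r^2 / 4\sigma^2) / (4\pi\sigma^2\kappa)}.
#'
#' @param kappa parent intensity, parents per square metre.
#' @param sigma offspring dispersal standard deviation (m).
#' @param mu mean offspring per parent.
#' @param window a [plot_geometry()] or `c(width, height)`.
#' @param seed optional integer seed.
#' @return A [point_pattern()].
#' @export
thomas_pattern <- function(kappa, sigma, mu, window, seed = NULL) {
  if (kappa <= 0 || sigma <= 0 || mu <= 0)
    stop("kappa, sigma, mu must be positive")
  force(window)
  if (!is.null(seed)) set.seed(seed)
  w <- if (inherits(window, "plot_geometry")) window$width else window[1]
  h <- if (inherits(window, "plot_geometry")) window$height else window[2]
  ext <- 4 * sigma
  np <- rpois(1, kappa * (w + 2 * ext) * (h + 2 * ext))
  px <- runif(np, -ext, w + ext); py <- runif(np, -ext, h + ext)
  no <- rpois(np, mu)
  x <- rep(px, no) + rnorm(sum(no), 0, sigma)
  y <- rep(py, no) + rnorm(sum(no), 0, sigma)
  keep <- x >= 0 & x < w & y >= 0 & y < h
  point_pattern(x[keep], y[keep], c(w, h))
}

# draw `n` species abundances from a Fisher log-series and rescale them to
# sum exactly to `total`
logseries_abundances <- function(n, total, alpha) {
  x <- total / (total + alpha)
  kmax <- 200000L
  logp <- seq_len(kmax) * log(x) - log(seq_len(kmax))
  p <- exp(logp - max(logp))
  cdf <- cumsum(p) / sum(p)
  draw <- findInterval(runif(n), cdf) + 1L
  # largest-remainder allocation: proportional rescale to the target total
  # with a floor of one stem per species
  raw <- draw * total / sum(draw)
  a <- pmax(1L, as.integer(floor(raw)))
  d <- total - sum(a)
  while (d > 0) {
    # give the shortfall to the largest fractional remainders, skipping
    # species already raised to the one-stem floor
    cand <- which(floor(raw) >= 1)
    if (!length(cand)) cand <- seq_len(n)
    give <- cand[order(raw[cand] - floor(raw[cand]),
                       decreasing = TRUE)][seq_len(min(d, length(cand)))]
    a[give] <- a[give] + 1L
    d <- total - sum(a)
  }
  while (d < 0) {
    i <- which(a > 1)
    take <- i[order(a[i], decreasing = TRUE)][seq_len(min(-d, length(i)))]
    if (!length(take)) stop("infeasible abundance target")
    a[take] <- a[take] - 1L
    d <- total - sum(a)
  }
  a
}

#' Generate a synthetic forest community with known ground truth
#'
#' Builds a multi-species census over the given terrain: species abundances
#' follow a Fisher log-series (parameter `fisher_alpha`) rescaled to
#' `total_stems`; each species receives Thomas-process cluster parameters
#' and a habitat-preference vector; stems are placed by simulating a Thomas
#' pattern and thinning it with retention probability proportional to
#' `exp(preference . standardised covariates)` of the stem's 10-m quadrat,
#' topping up until the target abundance is met exactly. DBH is 1 cm plus a
#' species-specific lognormal; phenology and endemism are Bernoulli species
#' labels. Every quantity used for generation is recorded in the returned
#' truth table, so downstream analyses can be validated against it.
#'
#' @param geometry a [plot_geometry()].
#' @param dem an `elevation_grid` covering the plot.
#' @param n_species number of species (default 30).
#' @param total_stems total community size (default 8000).
#' @param fisher_alpha log-series diversity parameter (default 15).
#' @param preference_strength scale of the habitat-preference coefficients
#'   on (standardised elevation, slope, convexity); 0 gives habitat-neutral
#'   species (default 1).
#' @param cluster_params list with `sigma_range` (m, default `c(3, 15)`)
#'   and `mu_range` (mean offspring per parent, default `c(8, 25)`). The
#'   parent intensity of each species is derived as
#'   `kappa = abundance / (mu * area)`, so abundant species have many
#'   parents and rare species few, as in real stem maps.
#' @param preferences optional `n_species x 3` matrix of explicit
#'   coefficients on (elevation, slope, convexity), overriding the random
#'   draw.
#' @param p_evergreen,p_endemic Bernoulli probabilities for the species
#'   labels (defaults 0.65 and 0.12).
#' @param seed optional integer seed.
#' @return List with `census` (a `census_table`) and `truth` (a
#'   `community_truth` data frame, one row per species).
#' @export
generate_community <- function(geometry, dem, n_species = 30,
                               total_stems = 8000, fisher_alpha = 15,
                               preference_strength = 1,
                               cluster_params = list(),
                               preferences = NULL,
                               p_evergreen = 0.65, p_endemic = 0.12,
                               seed = NULL) {
  if (n_species < 2) stop("need at least 2 species")
  if (total_stems < n_species) stop("total_stems below one stem per species")
  force(geometry); force(dem); force(preferences)
  if (!is.null(seed)) set.seed(seed)
  sig_r <- cluster_params$sigma_range %||% c(3, 15)
  mu_r <- cluster_params$mu_range %||% c(8, 25)
  topo10 <- quadrat_topography(dem, geometry, geometry$cell_covariate)
  zs <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  Z <- cbind(elevation = zs(topo10$elevation), slope = zs(topo10$slope),
             convexity = zs(topo10$convexity))
  cs <- attr(topo10, "cell_size")
  nxq <- attr(topo10, "nx")

  abundance <- logseries_abundances(n_species, total_stems, fisher_alpha)
  if (is.null(preferences)) {
    preferences <- matrix(rnorm(n_species * 3), n_species, 3)
    preferences <- preferences /
      pmax(sqrt(rowSums(preferences^2)), 1e-12) * preference_strength
  }
  colnames(preferences) <- c("elevation", "slope", "convexity")
  sigma <- exp(runif(n_species, log(sig_r[1]), log(sig_r[2])))
  mu_nom <- runif(n_species, mu_r[1], mu_r[2])
  meanlog <- runif(n_species, log(0.5), log(12))
  phen <- ifelse(runif(n_species) < p_evergreen, "evergreen", "deciduous")
  endem <- runif(n_species) < p_endemic
  A <- geometry$width * geometry$height

  quad_of <- function(x, y) {
    i <- cell_of(x, y, cs)
    (i$row - 1L) * nxq + i$col
  }
  lin_w <- exp(Z %*% t(preferences))  # quadrat x species retention weights
  lin_w <- sweep(lin_w, 2, apply(lin_w, 2, max), "/")

  kappa <- abundance / (mu_nom * A)
  stems <- vector("list", n_species)
  for (s in seq_len(n_species)) {
    target <- abundance[s]
    w <- lin_w[, s]
    pbar <- mean(w)
    xs <- numeric(0); ys <- numeric(0)
    for (it in 1:50) {
      need <- target - length(xs)
      if (need <= 0) break
      mu <- max(2, 1.3 * need / (kappa[s] * A * pbar))
      pat <- thomas_pattern(kappa[s], sigma[s], mu, geometry)
      if (pat$n == 0) next
      keep <- runif(pat$n) < w[quad_of(pat$x, pat$y)]
      xs <- c(xs, pat$x[keep]); ys <- c(ys, pat$y[keep])
    }
    if (length(xs) < target) {  # extreme preferences: biased uniform top-up
      need <- target - length(xs)
      q <- sample.int(length(w), need, replace = TRUE, prob = w)
      qx <- topo10$x[q] + runif(need, 0, cs)
      qy <- topo10$y[q] + runif(need, 0, cs)
      xs <- c(xs, pmin(qx, geometry$width - 1e-9))
      ys <- c(ys, pmin(qy, geometry$height - 1e-9))
    }
    sel <- sample.int(length(xs), target)
    stems[[s]] <- data.frame(
      species = sprintf("sp%03d", s), x = xs[sel], y = ys[sel],
      dbh = 1 + rlnorm(target, meanlog[s], 0.6),
      phenology = phen[s], endemic = endem[s], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, stems)
  df <- cbind(tag = sprintf("t%06d", seq_len(nrow(df))), df)
  census <- census_table(df, geometry)
  truth <- data.frame(
    species = sprintf("sp%03d", seq_len(n_species)),
    target_abundance = abundance,
    realized_abundance = as.integer(table(factor(df$species,
      levels = sprintf("sp%03d", seq_len(n_species))))),
    kappa = kappa, sigma = sigma, mu = mu_nom,
    pref_elevation = preferences[, 1], pref_slope = preferences[, 2],
    pref_convexity = preferences[, 3],
    dbh_meanlog = meanlog, phenology = phen, endemic = endem,
    stringsAsFactors = FALSE)
  class(truth) <- c("community_truth", "data.frame")
  list(census = census, truth = truth)
}
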