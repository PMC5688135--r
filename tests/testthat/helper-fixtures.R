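# Shared fixtures, built in code. The standard test plot is 240 m x 240 m
# (12 x 12 twenty-metre cells, 24 x 24 ten-metre quadrats); heavier shared
# objects are generated once per test run and cached.

fx_geometry <- function() plot_geometry(240, 240)

fx_cache <- new.env(parent = emptyenv())

fx_dem <- function() {
  if (is.null(fx_cache$dem))
    fx_cache$dem <- generate_dem(fx_geometry(), relief = 200, n_hills = 8,
                                 roughness = 0.5, seed = 42)
  fx_cache$dem
}

# moderately sized community with default (random) habitat preferences
fx_community <- function() {
  if (is.null(fx_cache$community))
    fx_cache$community <- generate_community(fx_geometry(), fx_dem(),
                                             n_species = 20,
                                             total_stems = 5000, seed = 99)
  fx_cache$community
}

# tiny hand-written census data frame
fx_census_df <- function() {
  data.frame(tag = c("a", "b", "c"),
             species = c("sp1", "sp1", "sp2"),
             x = c(10.5, 200, 30), y = c(20, 100, 40),
             dbh = c(2, 4, 6),
             phenology = c("evergreen", "evergreen", "deciduous"),
             endemic = c(TRUE, TRUE, FALSE),
             stringsAsFactors = FALSE)
}

# numeric oracle for the Ripley isotropic correction: fraction of the circle
# of radius r around (px, py) inside [0,W]x[0,H], by angle discretisation
ripley_weight_oracle <- function(px, py, W, H, r, K = 2e5) {
  th <- (seq_len(K) - 0.5) / K * 2 * pi
  x <- px + r * cos(th); y <- py + r * sin(th)
  1 / mean(x >= 0 & x <= W & y >= 0 & y <= H)
}

# brute-force K-function estimate with Ripley weights (independent O(n^2)
# loop used to check g-K consistency)
k_function_oracle <- function(pattern, R) {
  n <- pattern$n; A <- pattern$width * pattern$height
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt((pattern$x[i] - pattern$x[j])^2 +
              (pattern$y[i] - pattern$y[j])^2)
    if (d <= R)
      acc <- acc + forestpat:::ripley_weight_cpp(pattern$x[i], pattern$y[i],
                                                 pattern$width,
                                                 pattern$height, d)
  }
  A * acc / (n * (n - 1))
}

# independent ter Braak CCA: chi-square residuals projected onto the
# row-weighted covariate space, then eigen-analysed
cca_oracle <- function(X, Z) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  P <- X / sum(X); r <- rowSums(P); cc <- colSums(P)
  Q <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  Zw <- sweep(Z, 2, colSums(Z * r) / sum(r))
  M <- sqrt(r) * Zw
  H <- M %*% solve(crossprod(M), t(M))
  ev <- svd(H %*% Q)$d^2
  list(eig = ev[ev > 1e-12], total_inertia = sum(Q^2))
}

# closed-form pair-correlation function of a Thomas process
thomas_g <- function(r, kappa, sigma) {
  1 + exp(-r^2 / (4 * sigma^2)) / (4 * pi * sigma^2 * kappa)
}

# brute-force torus-translation null: explicit loops over every translated
# (and optionally transformed) map, statistic recomputed from scratch
ttt_oracle <- function(counts, habitat, alpha_tail = 0.025,
                       include_transforms = TRUE) {
  m <- unclass(habitat); attributes(m) <- list(dim = dim(m))
  ny <- nrow(m); nx <- ncol(m); N <- sum(counts); ncell <- nx * ny
  trs <- list(m)
  if (include_transforms)
    trs <- list(m,
                m[ny:1, nx:1, drop = FALSE],
                m[, nx:1, drop = FALSE],
                m[ny:1, , drop = FALSE])
  stat <- function(map, h)
    (sum(counts[map == h]) / sum(m == h)) / (N / ncell)
  levs <- intersect(c("hilltop", "steep_slope", "gentle_slope",
                      "depression"), m)
  levs <- c(levs, sort(setdiff(unique(c(m)), levs)))
  out <- lapply(levs, function(h) {
    nulls <- c(); obs <- NA
    for (ti in seq_along(trs)) {
      for (sy in 0:(ny - 1)) for (sx in 0:(nx - 1)) {
        map <- trs[[ti]][((seq_len(ny) - 1 - sy) %% ny) + 1,
                         ((seq_len(nx) - 1 - sx) %% nx) + 1, drop = FALSE]
        v <- stat(map, h)
        if (ti == 1 && sx == 0 && sy == 0) obs <- v else nulls <- c(nulls, v)
      }
    }
    eps <- 1e-9 * max(1, abs(obs))
    q <- (sum(nulls < obs - eps) + 0.5 * sum(abs(nulls - obs) <= eps)) /
      length(nulls)
    data.frame(habitat = h, observed_relative_density = obs,
               null_quantile = q,
               association = if (q >= 1 - alpha_tail) "positive"
                             else if (q <= alpha_tail) "negative"
                             else "neutral",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# plain data frame, extra attributes dropped, for oracle comparisons
plain_df <- function(d) {
  d <- as.data.frame(d)
  attributes(d) <- attributes(d)[c("names", "row.names", "class")]
  rownames(d) <- NULL
  d
}

# small habitat map with the four standard labels in blocks
fx_habitat_blocks <- function(ny = 8, nx = 8, cell_size = 20) {
  m <- matrix("gentle_slope", ny, nx)
  m[seq_len(ny / 2), seq_len(nx / 2)] <- "hilltop"
  m[seq_len(ny / 2), (nx / 2 + 1):nx] <- "steep_slope"
  m[(ny / 2 + 1):ny, seq_len(nx / 2)] <- "depression"
  structure(m, cell_size = cell_size, class = "habitat_map")
}

# asymmetric 8x8 map: one contiguous hilltop block, depression spread widely
# so that a hilltop-confined species misses it under (almost) every shift
fx_habitat_asym <- function(cell_size = 20) {
  m <- matrix("depression", 8, 8)
  m[1:4, 1:4] <- "hilltop"
  m[5:6, 5:6] <- "steep_slope"
  m[7:8, 7:8] <- "gentle_slope"
  structure(m, cell_size = cell_size, class = "habitat_map")
}
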