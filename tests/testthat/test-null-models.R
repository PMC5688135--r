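test_that("CSR simulation honours count, window and seed", {
  p <- simulate_csr(100, c(240, 240), seed = 7)
  expect_equal(p$n, 100)
  expect_true(all(p$x >= 0 & p$x < 240 & p$y >= 0 & p$y < 240))
  p2 <- simulate_csr(100, c(240, 240), seed = 7)
  expect_identical(p$x, p2$x)
  p3 <- simulate_csr(100, c(240, 240), seed = 8)
  expect_false(identical(p$x, p3$x))
})

test_that("CSR quadrat counts pass a chi-square uniformity calibration", {
  set.seed(20)
  pvals <- vapply(1:200, function(i) {
    cnt <- quadrat_counts(simulate_csr(200, c(200, 200)), 20)
    suppressWarnings(stats::chisq.test(c(cnt))$p.value)
  }, numeric(1))
  # rejection at 5% should occur at about the nominal rate
  expect_lt(mean(pvals < 0.05), 0.11)
  expect_gt(mean(pvals < 0.5), 0.35)
})

test_that("fitted HPP intensity integrates exactly to the observed count", {
  topo10 <- quadrat_topography(fx_dem(), fx_geometry(), 10)
  p <- simulate_csr(500, fx_geometry(), seed = 21)
  fit <- fit_hpp_intensity(p, topo10)
  expect_equal(sum(fit$mass), 500, tolerance = 1e-12)
  expect_equal(sum(fit$lambda * 100), 500, tolerance = 1e-10)
  expect_error(fit_hpp_intensity(simulate_csr(20, fx_geometry(), seed = 1),
                                 topo10), "at least 50")
})

test_that("HPP fit finds no terrain effect in CSR and recovers a planted one", {
  topo10 <- quadrat_topography(fx_dem(), fx_geometry(), 10)
  p <- simulate_csr(2000, fx_geometry(), seed = 22)
  fit <- fit_hpp_intensity(p, topo10)
  b <- attr(fit, "coefficients"); se <- sqrt(diag(attr(fit, "vcov")))
  for (v in c("elevation", "slope", "convexity"))
    expect_lt(abs(b[v] / se[v]), 3)
  # pattern with intensity proportional to exp(1.0 * standardised elevation)
  zs <- function(v) (v - mean(v)) / sd(v)
  mass <- exp(1.0 * zs(topo10$elevation))
  im <- structure(data.frame(row = topo10$row, col = topo10$col,
                             x = topo10$x, y = topo10$y,
                             mass = mass, lambda = mass / 100),
                  cell_size = 10, n = 2000,
                  class = c("intensity_map", "data.frame"))
  p2 <- simulate_hpp(im, 2000, seed = 23)
  fit2 <- fit_hpp_intensity(p2, topo10)
  b2 <- attr(fit2, "coefficients"); se2 <- sqrt(diag(attr(fit2, "vcov")))
  expect_lt(abs(b2["elevation"] - 1) / se2["elevation"], 3)
})

test_that("HPP simulation follows the intensity surface", {
  topo10 <- quadrat_topography(fx_dem(), fx_geometry(), 10)
  n_q <- nrow(topo10)
  # all mass in one quadrat puts every point there
  mass <- rep(0, n_q); mass[137] <- 1
  im <- structure(data.frame(row = topo10$row, col = topo10$col,
                             x = topo10$x, y = topo10$y,
                             mass = mass, lambda = mass / 100),
                  cell_size = 10, n = 50,
                  class = c("intensity_map", "data.frame"))
  p <- simulate_hpp(im, 50, seed = 24)
  idx <- floor(p$y / 10) * 24 + floor(p$x / 10) + 1
  expect_true(all(idx == 137))
  expect_error(simulate_hpp(within(im, mass <- 0), 10), "all-zero")
  # graded intensity: empirical frequencies near the multinomial ones
  set.seed(25)
  zs <- function(v) (v - mean(v)) / sd(v)
  mass <- exp(0.8 * zs(topo10$elevation))
  im2 <- structure(data.frame(row = topo10$row, col = topo10$col,
                              x = topo10$x, y = topo10$y,
                              mass = mass, lambda = mass / 100),
                   cell_size = 10, n = 200,
                   class = c("intensity_map", "data.frame"))
  tot <- rep(0, n_q)
  for (i in 1:100) {
    p2 <- simulate_hpp(im2, 200)
    cnt <- quadrat_counts(p2, 10, fx_geometry())
    tot <- tot + cnt[cbind(topo10$row, topo10$col)]
  }
  pr <- mass / sum(mass)
  expected <- 100 * 200 * pr
  z <- (tot - expected) / sqrt(100 * 200 * pr * (1 - pr))
  expect_lt(mean(abs(z) > 3), 0.01)
})

test_that("envelope classification matches its bounds and is seeded", {
  p <- thomas_pattern(2e-4, 5, 12, c(200, 200), seed = 26)
  env <- envelope_test(p, "csr", nsim = 99, radii = 1:20, seed = 27)
  expect_true(all(env$lo <= env$hi))
  expect_equal(env$class,
               ifelse(env$g_obs > env$hi, "aggregated",
                      ifelse(env$g_obs < env$lo, "regular", "random")))
  env2 <- envelope_test(p, "csr", nsim = 99, radii = 1:20, seed = 27)
  expect_identical(env$lo, env2$lo)
  expect_error(envelope_test(p, "csr", nsim = 10), "at least 19")
  # strong small-scale clustering is detected
  expect_true(all(env$class[env$r <= 5] == "aggregated"))
})

test_that("widening the envelope never adds non-random classifications", {
  p <- thomas_pattern(2e-4, 8, 10, c(200, 200), seed = 28)
  radii <- 1:20
  set.seed(29)
  g_obs <- pair_correlation(p, radii)$g
  sims <- t(vapply(1:99, function(i)
    pair_correlation(simulate_csr(p$n, c(200, 200)), radii)$g,
    numeric(length(radii))))
  srt <- apply(sims, 2, sort)
  nonrandom <- function(lo_i, hi_i)
    sum(g_obs > srt[hi_i, ] | g_obs < srt[lo_i, ])
  expect_lte(nonrandom(1, 99), nonrandom(5, 95))
})

test_that("species-level batch classification partitions and propagates failures", {
  com <- fx_community()
  s <- suppressMessages(summarize_species(com$census, fx_geometry(), 25))
  s <- s[order(-s$abundance)[seq_len(min(3, nrow(s)))], ]
  cl <- classify_species_patterns(com$census, s, null = "csr", nsim = 39,
                                  radii = 1:20, seed = 30)
  pr <- cl$proportions
  expect_equal(pr$frac_aggregated + pr$frac_random + pr$frac_regular,
               rep(1, nrow(pr)))
  expect_equal(sort(unique(cl$classification$species)), sort(s$species))
  expect_equal(length(cl$g0_10), nrow(s))
  # HPP null refuses species below its sample-size floor
  tiny <- s[1, ]; tiny$species <- "nope"
  expect_warning(
    cl2 <- classify_species_patterns(com$census, rbind(s[1, ], tiny),
                                     null = "csr", nsim = 39, radii = 1:10,
                                     seed = 31),
    "skipped")
  expect_equal(cl2$failed, "nope")
})
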