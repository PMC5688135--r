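test_that("terrain generator honours degenerate, deterministic and scaling contracts", {
  g <- fx_geometry()
  flat <- generate_dem(g, n_hills = 0, roughness = 0, base = 500, seed = 1)
  expect_true(all(flat$z == 500))
  a <- generate_dem(g, seed = 60); b <- generate_dem(g, seed = 60)
  expect_identical(a$z, b$z)
  expect_false(identical(a$z, generate_dem(g, seed = 61)$z))
  expect_equal(max(a$z) - min(a$z), 200, tolerance = 1e-9)
  d2 <- generate_dem(g, relief = 80, seed = 62)
  expect_equal(max(d2$z) - min(d2$z), 80, tolerance = 1e-9)
})

test_that("Thomas process has the right expected count and determinism", {
  w <- c(200, 200)
  kappa <- 2e-4; mu <- 10
  set.seed(63)
  ns <- vapply(1:200, function(i) thomas_pattern(kappa, 5, mu, w)$n,
               numeric(1))
  expected <- kappa * mu * 200 * 200
  se <- sd(ns) / sqrt(length(ns))
  expect_lt(abs(mean(ns) - expected), 3 * se)
  p1 <- thomas_pattern(kappa, 5, mu, w, seed = 64)
  p2 <- thomas_pattern(kappa, 5, mu, w, seed = 64)
  expect_identical(p1$x, p2$x)
  expect_error(thomas_pattern(-1, 5, 10, w), "positive")
})

test_that("very wide clusters are indistinguishable from CSR", {
  p <- thomas_pattern(5e-5, 400, 80, c(200, 200), seed = 65)
  pc <- pair_correlation(p, radii = 1:50)
  expect_lt(abs(mean(pc$g[pc$r >= 5]) - 1), 0.1)
})

test_that("generated censuses validate cleanly with exact abundances", {
  com <- fx_community()
  expect_equal(nrow(attr(com$census, "rejected")), 0)
  expect_equal(sum(com$truth$realized_abundance), 5000)
  expect_equal(com$truth$realized_abundance, com$truth$target_abundance)
  expect_true(all(com$truth$realized_abundance >= 1))
  expect_true(all(com$census$dbh >= 1))
  # reproducible end to end
  com2 <- generate_community(fx_geometry(), fx_dem(), n_species = 20,
                             total_stems = 5000, seed = 99)
  expect_equal(com2$census$x, com$census$x)
  expect_error(generate_community(fx_geometry(), fx_dem(), n_species = 50,
                                  total_stems = 10), "below one stem")
})

test_that("log-series draws match the generator's own distribution", {
  # choose n consistent with Fisher's S = alpha log(1 + N / alpha) so that
  # the rescaling step is nearly a no-op and the draws keep their law
  alpha <- 15; N <- 75000
  n <- round(alpha * log(1 + N / alpha))  # 128 species
  set.seed(66)
  batches <- replicate(30, forestpat:::logseries_abundances(n, N, alpha),
                       simplify = FALSE)
  expect_true(all(vapply(batches, sum, numeric(1)) == N))
  draws <- unlist(batches)
  x <- N / (N + alpha)
  k <- 1:200000
  p <- exp(k * log(x) - log(k)); p <- p / sum(p)
  breaks <- c(1, 2, 4, 8, 16, 64, 256, 1024, Inf)
  pb <- vapply(seq_len(length(breaks) - 1), function(i)
    sum(p[k >= breaks[i] & k < breaks[i + 1]]), numeric(1))
  ob <- vapply(seq_len(length(breaks) - 1), function(i)
    sum(draws >= breaks[i] & draws < breaks[i + 1]), numeric(1))
  chi <- suppressWarnings(stats::chisq.test(ob, p = pb, rescale.p = TRUE))
  expect_gt(chi$p.value, 0.001)
})

test_that("habitat-neutral species fill habitats by area share", {
  g <- fx_geometry()
  set.seed(67)
  com <- generate_community(g, fx_dem(), n_species = 6, total_stems = 4000,
                            preference_strength = 0, seed = 68)
  topo <- quadrat_topography(fx_dem(), g, 20)
  comm <- community_matrix(com$census, g)
  hab <- assign_habitats(fit_mrt(comm, topo), topo)
  lab <- c(t(unclass(hab)))   # row-major to match community rows
  counts <- tapply(rowSums(comm), lab, sum)
  share <- as.vector(table(lab)[names(counts)]) / length(lab)
  chi <- suppressWarnings(stats::chisq.test(counts, p = share))
  # clustered stems violate multinomial independence, so only a coarse check
  expect_equal(as.vector(counts / sum(counts)), share, tolerance = 0.5)
})

test_that("elevation preference shifts stems uphill, more so when stronger", {
  g <- fx_geometry()
  topo <- quadrat_topography(fx_dem(), g, 10)
  mean_elev_at <- function(strength, seed) {
    pref <- matrix(rep(c(1, 0, 0), each = 4), 4, 3) * strength
    com <- generate_community(g, fx_dem(), n_species = 4,
                              total_stems = 3000, preferences = pref,
                              seed = seed)
    idx <- floor(com$census$y / 10) * 24 + floor(com$census$x / 10) + 1
    mean(topo$elevation[idx])
  }
  plot_mean <- mean(topo$elevation)
  e0 <- mean_elev_at(0, 70); e1 <- mean_elev_at(1, 70); e2 <- mean_elev_at(3, 70)
  expect_gt(e1, plot_mean)
  expect_gt(e2, e1)
  expect_lt(abs(e0 - plot_mean), 15)
})
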