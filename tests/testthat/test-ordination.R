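test_that("CCA eigenvalues match an independent eigendecomposition", {
  set.seed(50)
  X <- matrix(rpois(15, 8), 5, 3)
  Z <- data.frame(a = rnorm(5), b = rnorm(5))
  fit <- cca_topo(X, Z)
  oracle <- cca_oracle(X, as.matrix(Z))
  expect_equal(unname(fit$eigenvalues),
               oracle$eig[seq_along(fit$eigenvalues)], tolerance = 1e-10)
  expect_equal(fit$total_inertia, oracle$total_inertia, tolerance = 1e-10)
  # inertia conservation: constrained + unconstrained = total
  expect_equal(sum(fit$ord$CCA$eig) + sum(fit$ord$CA$eig),
               fit$total_inertia, tolerance = 1e-10)
  expect_equal(fit$constrained_fraction,
               sum(fit$eigenvalues) / fit$total_inertia)
  # axis sign fixed: dominant species loads positively
  for (a in seq_len(ncol(fit$species_scores)))
    expect_gt(fit$species_scores[which.max(abs(fit$species_scores[, a])), a],
              0)
})

test_that("CCA is invariant to row duplication and global rescaling", {
  set.seed(51)
  X <- matrix(rpois(60, 6), 20, 3)
  Z <- data.frame(a = rnorm(20), b = runif(20))
  base <- cca_topo(X, Z)
  dup <- cca_topo(rbind(X, X), rbind(Z, Z))
  expect_equal(unname(dup$eigenvalues), unname(base$eigenvalues),
               tolerance = 1e-10)
  scl <- cca_topo(X * 7.3, Z)
  expect_equal(unname(scl$eigenvalues), unname(base$eigenvalues),
               tolerance = 1e-10)
  expect_equal(scl$total_inertia, base$total_inertia, tolerance = 1e-10)
})

test_that("empty sites are dropped with a warning", {
  set.seed(52)
  X <- matrix(rpois(30, 5), 10, 3)
  X[4, ] <- 0
  Z <- data.frame(a = rnorm(10), b = rnorm(10))
  expect_warning(fit <- cca_topo(X, Z), "no stems")
  expect_equal(fit$kept_rows, setdiff(1:10, 4))
})

test_that("envfit recovers a perfect axis alignment and normalises cosines", {
  set.seed(53)
  X <- matrix(rpois(200 * 5, 4), 200, 5) +
    outer(rep(1:4, 50), c(3, 0, 1, 0, 2))
  Z <- data.frame(a = rnorm(200), b = rnorm(200))
  fit <- cca_topo(X, Z)
  covs <- data.frame(ax1 = fit$site_scores[, 1], noise = rnorm(200))
  ef <- envfit_permutation(fit, covs, nperm = 199, seed = 54)
  expect_equal(ef$R2[1], 1, tolerance = 1e-8)
  expect_equal(abs(ef$CCA1[1]), 1, tolerance = 1e-6)
  expect_equal(ef$CCA1^2 + ef$CCA2^2, rep(1, 2), tolerance = 1e-6)
  expect_gte(min(ef$p), 1 / 200)  # add-one rule: p is never zero
  # constant covariate is reported missing
  expect_warning(
    ef2 <- envfit_permutation(fit, data.frame(flat = rep(1, 200)),
                              nperm = 99, seed = 55),
    "constant")
  expect_true(is.na(ef2$R2))
})

test_that("permutation p-values for a null covariate are roughly uniform", {
  set.seed(56)
  ps <- vapply(1:60, function(i) {
    X <- matrix(rpois(40 * 4, 5), 40, 4)
    Z <- data.frame(a = rnorm(40), b = rnorm(40))
    fit <- cca_topo(X, Z)
    ef <- envfit_permutation(fit, data.frame(noise = rnorm(40)), nperm = 99)
    ef$p
  }, numeric(1))
  # super-uniform at the resolution of the permutation count
  expect_lte(mean(ps <= 0.05), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 60))
  expect_gt(mean(ps), 0.3)
})

test_that("attribute tests reproduce hand-computed statistics", {
  s <- data.frame(species = paste0("s", 1:3), abundance = c(300, 200, 100),
                  mean_dbh = c(3, 5, 9), max_dbh = c(6, 10, 20),
                  abundance_class = c("abundant", "intermediate", "rare"),
                  growth_form = c("understory", "midstory", "canopy"),
                  phenology = c("evergreen", "deciduous", "evergreen"),
                  endemic = c(TRUE, FALSE, FALSE))
  g <- c(s1 = 1, s2 = 2, s3 = 3)
  res <- suppressWarnings(attribute_tests(s, g))
  rho <- res$statistic[res$test == "spearman" & res$grouping == "abundance"]
  expect_equal(rho, -1)  # perfectly antitone
  # two identical groups: Wilcoxon at its null centre, p = 1
  s2 <- data.frame(species = paste0("t", 1:8), abundance = 100,
                   mean_dbh = 5, max_dbh = 9,
                   abundance_class = rep(c("rare", "abundant"), 4),
                   growth_form = rep(c("understory", "canopy"), each = 4),
                   phenology = rep(c("evergreen", "deciduous"), each = 4),
                   endemic = rep(c(TRUE, FALSE), 4))
  g2 <- setNames(rep(c(1, 2, 3, 4), 2), s2$species)
  res2 <- suppressWarnings(attribute_tests(s2, g2))
  w <- res2[res2$test == "wilcoxon_rank_sum", ]
  expect_equal(w$statistic, 8)   # n1 n2 / 2: null mean of W
  expect_gt(w$p, 0.9)
  # Kruskal-Wallis on a 12-value dataset against the rank-sum formula
  s3 <- data.frame(species = paste0("u", 1:12), abundance = 100,
                   mean_dbh = 5, max_dbh = 9,
                   abundance_class = rep(c("rare", "intermediate",
                                           "abundant"), each = 4),
                   growth_form = "midstory", phenology = "evergreen",
                   endemic = NA)
  g3 <- setNames(c(12, 7, 9, 11, 5, 6, 8, 4, 1, 2, 3, 10), s3$species)
  res3 <- suppressWarnings(attribute_tests(s3, g3))
  kw <- res3[res3$test == "kruskal_wallis", ]
  rk <- rank(g3); grpsum <- tapply(rk, s3$abundance_class, sum)
  H <- 12 / (12 * 13) * sum(grpsum^2 / 4) - 3 * 13
  expect_equal(kw$statistic, H, tolerance = 1e-12)
  # group summaries carry n, mean, SE per level
  gs <- attr(res3, "groups")$abundance_class
  expect_equal(gs["rare", "n"], 4)
  expect_equal(gs["abundant", "mean"], mean(c(1, 2, 3, 10)))
})

test_that("tests with undersized groups are skipped with a warning", {
  s <- data.frame(species = paste0("s", 1:5), abundance = c(30, 40, 50, 60, 70),
                  mean_dbh = 5, max_dbh = 9,
                  abundance_class = "intermediate",
                  growth_form = c("canopy", "canopy", "canopy", "canopy",
                                  "understory"),
                  phenology = "evergreen", endemic = FALSE)
  g <- setNames(1:5, s$species)
  w <- testthat::capture_warnings(res <- attribute_tests(s, g))
  expect_true(any(grepl("skipped", w)))
  expect_false("kruskal_wallis" %in% res$test)
  expect_false("wilcoxon_rank_sum" %in% res$test)
})
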