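#' Canonical correspondence analysis of community against topography
#'
#' Constrained ordination (ter Braak's CCA: chi-square-standardised community
#' residuals projected onto the covariate space by row-weighted least
#' squares, then eigen-analysed) of the cell x species abundance matrix on
#' the topographic variables. Computation is delegated to [vegan::cca()];
#' this wrapper drops empty cells and aliased covariates with a warning and
#' fixes the sign of each axis so the species with the largest absolute
#' score on that axis is positive, making results reproducible across runs.
#'
#' @param community numeric cell x species abundance matrix.
#' @param covariates data frame of per-cell covariates (same row order).
#' @return A `cca_result`: list with `eigenvalues` (constrained),
#'   `total_inertia`, `constrained_fraction`, `species_scores`,
#'   `site_scores`, `biplot`, `kept_rows`, and the underlying vegan object
#'   `ord`.
#' @export
cca_topo <- function(community, covariates) {
  community <- as.matrix(community)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(community) == nrow(covariates))
  keep <- rowSums(community) > 0
  if (any(!keep)) {
    warning(sum(!keep), " cell(s) with no stems dropped from the ordination")
    community <- community[keep, , drop = FALSE]
    covariates <- covariates[keep, , drop = FALSE]
  }
  nz <- colSums(community) > 0
  community <- community[, nz, drop = FALSE]
  ord <- vegan::cca(community ~ ., data = covariates)
  if (!is.null(ord$CCA$alias))
    warning("aliased covariate(s) dropped: ",
            paste(ord$CCA$alias, collapse = ", "))
  eig <- ord$CCA$eig
  naxes <- min(2L, length(eig))
  spe <- vegan::scores(ord, display = "species", choices = seq_len(naxes),
                       scaling = 2)
  sit <- vegan::scores(ord, display = "sites", choices = seq_len(naxes),
                       scaling = 2)
  bip <- vegan::scores(ord, display = "bp", choices = seq_len(naxes),
                       scaling = 2)
  for (a in seq_len(naxes)) {
    i <- which.max(abs(spe[, a]))
    if (spe[i, a] < 0) {
      spe[, a] <- -spe[, a]; sit[, a] <- -sit[, a]; bip[, a] <- -bip[, a]
    }
  }
  structure(list(eigenvalues = eig,
                 total_inertia = ord$tot.chi,
                 constrained_fraction = sum(eig) / ord$tot.chi,
                 species_scores = spe, site_scores = sit, biplot = bip,
                 kept_rows = which(keep), ord = ord),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("CCA: %d constrained axes; constrained inertia %.4f of %.4f (%.2f%%)\n",
              length(x$eigenvalues), sum(x$eigenvalues), x$total_inertia,
              100 * x$constrained_fraction))
  print(round(x$eigenvalues, 4))
  invisible(x)
}

#' Permutation test of each topographic variable on the ordination
#'
#' Fits each covariate onto the first two ordination axes by weighted least
#' squares ([vegan::envfit()]): per variable, direction cosines on (CCA1,
#' CCA2) with CCA1^2 + CCA2^2 = 1, the determination coefficient R^2, and a
#' permutation p-value with the add-one rule
#' \eqn{p = (1 + \#\{R^2_{perm} \ge R^2\}) / (1 + nperm)}. Constant
#' variables are reported as missing with a warning.
#'
#' @param result a `cca_result`.
#' @param covariates data frame of covariates (rows matching the cells kept
#'   in the ordination, i.e. `result$kept_rows` of the original grid).
#' @param nperm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @return Data frame `variable`, `CCA1`, `CCA2`, `R2`, `p`.
#' @export
envfit_permutation <- function(result, covariates, nperm = 1000,
                               seed = NULL) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(result$site_scores)) {
    if (max(result$kept_rows) <= nrow(covariates))
      covariates <- covariates[result$kept_rows, , drop = FALSE]
    else stop("covariate rows do not match ordination sites")
  }
  const <- vapply(covariates, function(v) var(as.numeric(v)) == 0,
                  logical(1))
  if (any(const))
    warning("constant covariate(s) reported as missing: ",
            paste(names(covariates)[const], collapse = ", "))
  use <- covariates[, !const, drop = FALSE]
  force(result)
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(variable = names(covariates),
                    CCA1 = NA_real_, CCA2 = NA_real_,
                    R2 = NA_real_, p = NA_real_)
  if (ncol(use)) {
    ef <- vegan::envfit(result$site_scores[, 1:2], use, permutations = nperm)
    arr <- ef$vectors$arrows
    m <- match(rownames(arr), out$variable)
    out$CCA1[m] <- arr[, 1]; out$CCA2[m] <- arr[, 2]
    out$R2[m] <- ef$vectors$r
    out$p[m] <- ef$vectors$pvals
  }
  out
}

group_summary <- function(values, groups) {
  do.call(rbind, lapply(split(values, groups), function(v)
    data.frame(n = length(v), mean = mean(v),
               se = sd(v) / sqrt(length(v)))))
}

#' Species-attribute tests of aggregation intensity
#'
#' The standard battery relating the g0-10 aggregation index to species
#' attributes: Spearman rank correlations with abundance, mean DBH and
#' maximum DBH; Kruskal-Wallis across abundance classes; one-way ANOVA
#' across growth forms; Wilcoxon rank-sum between evergreen and deciduous
#' species; Welch two-sample t-test between endemic and non-endemic species.
#' A grouped test whose smallest group has fewer than 2 species is skipped
#' with a warning.
#'
#' @param summaries a `species_summary`.
#' @param g0_10 named (by species) or positional vector of per-species
#'   aggregation indices.
#' @return Data frame of class `group_tests`: `test`, `grouping`,
#'   `statistic`, `p`; attribute `groups` holds per-group n/mean/SE tables.
#' @export
attribute_tests <- function(summaries, g0_10) {
  if (!is.null(names(g0_10)))
    g <- g0_10[summaries$species]
  else g <- g0_10
  stopifnot(length(g) == nrow(summaries))
  ok <- is.finite(g)
  s <- summaries[ok, , drop = FALSE]; g <- g[ok]
  out <- list(); grp <- list()
  add <- function(test, grouping, statistic, p)
    out[[length(out) + 1L]] <<- data.frame(test = test, grouping = grouping,
                                           statistic = statistic, p = p)
  for (v in c("abundance", "mean_dbh", "max_dbh")) {
    ct <- suppressWarnings(cor.test(g, s[[v]], method = "spearman"))
    add("spearman", v, unname(ct$estimate), ct$p.value)
  }
  two_ok <- function(f) length(unique(f)) >= 2 && min(table(f)) >= 2
  if (two_ok(s$abundance_class)) {
    kt <- kruskal.test(g, factor(s$abundance_class))
    add("kruskal_wallis", "abundance_class", unname(kt$statistic),
        kt$p.value)
    grp$abundance_class <- group_summary(g, s$abundance_class)
  } else warning("abundance-class test skipped (group too small)")
  if (two_ok(s$growth_form)) {
    ft <- anova(aov(g ~ factor(s$growth_form)))
    add("anova_f", "growth_form", ft[1, "F value"], ft[1, "Pr(>F)"])
    grp$growth_form <- group_summary(g, s$growth_form)
  } else warning("growth-form ANOVA skipped (group too small)")
  ph <- s$phenology %in% c("evergreen", "deciduous")
  if (sum(ph) && two_ok(s$phenology[ph])) {
    wt <- suppressWarnings(
      wilcox.test(g[ph & s$phenology == "evergreen"],
                  g[ph & s$phenology == "deciduous"]))
    add("wilcoxon_rank_sum", "phenology", unname(wt$statistic), wt$p.value)
    grp$phenology <- group_summary(g[ph], s$phenology[ph])
  } else warning("phenology test skipped (group too small)")
  en <- !is.na(s$endemic)
  if (sum(en) && two_ok(s$endemic[en])) {
    tt <- t.test(g[en & s$endemic], g[en & !s$endemic])
    add("welch_t", "endemic", unname(tt$statistic), tt$p.value)
    grp$endemic <- group_summary(g[en], s$endemic[en])
  } else warning("endemism t-test skipped (group too small)")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, groups = grp, class = c("group_tests", "data.frame"))
}
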