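# toroidal shift: shifted[i, j] = m[i - sy, j - sx] (circular, 0-based shifts)
shift_torus <- function(m, sx, sy) {
  ny <- nrow(m); nx <- ncol(m)
  m[((seq_len(ny) - 1 - sy) %% ny) + 1, ((seq_len(nx) - 1 - sx) %% nx) + 1,
    drop = FALSE]
}

# the four map symmetries of the Harms torus-translation null
map_transforms <- function(m) {
  list(identity = m,
       rot180 = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
       mirror = m[, rev(seq_len(ncol(m))), drop = FALSE],
       mirror_rot180 = m[rev(seq_len(nrow(m))), , drop = FALSE])
}

#' Enumerate torus translations of a habitat map
#'
#' All toroidal translations of the habitat map in whole-cell increments
#' (`nx * ny` maps including the identity), optionally preceded by the three
#' non-trivial symmetries (180-degree rotation, mirror image, mirrored
#' rotation) of the Harms et al. procedure, giving `4 * nx * ny` maps. Order
#' is deterministic: transforms in the order identity, rot180, mirror,
#' mirror_rot180; within a transform, shifts loop x fastest. The first map is
#' always the untransformed identity.
#'
#' @param habitat a `habitat_map` (or any label matrix).
#' @param include_transforms include the three symmetries (default `FALSE`).
#' @return List of label matrices.
#' @export
torus_maps <- function(habitat, include_transforms = FALSE) {
  m <- unclass(habitat)
  attributes(m) <- list(dim = dim(m))
  trs <- if (include_transforms) map_transforms(m) else list(identity = m)
  out <- list()
  for (t in trs)
    for (sy in 0:(nrow(m) - 1))
      for (sx in 0:(ncol(m) - 1))
        out[[length(out) + 1L]] <- shift_torus(t, sx, sy)
  out
}

# circular cross-correlation of counts with an indicator matrix over all
# shifts, via 2-D FFT; entry [sy+1, sx+1] = sum(counts * shift(ind, sx, sy))
cross_correlate <- function(counts, ind) {
  Fc <- fft(counts)
  Fi <- fft(ind)
  Re(fft(Fc * Conj(Fi), inverse = TRUE)) / length(counts)
}

#' Torus-translation test of habitat association for one species
#'
#' The observed statistic per habitat is the species' relative density:
#' stems per unit area in the habitat divided by stems per unit area
#' plot-wide. Its null distribution is the same statistic recomputed over
#' every toroidal translation of the habitat map (optionally including the
#' 180-degree rotation, mirror and mirrored rotation), the untranslated map
#' itself excluded. The observed value's mid-rank quantile among the null
#' values decides the call: `positive` if the quantile is at least
#' `1 - alpha_tail`, `negative` if at most `alpha_tail`, else `neutral`.
#'
#' @param counts integer matrix of the species' stem counts on the habitat
#'   grid (same shape as `habitat`, row 1 = south).
#' @param habitat a `habitat_map`.
#' @param alpha_tail one-sided level per tail (default 0.025, 5% two-sided).
#' @param include_transforms use the full 4-symmetry Harms null set
#'   (default `TRUE`); otherwise translations only.
#' @return Data frame of class `ttt_result`: `habitat`,
#'   `observed_relative_density`, `null_quantile`, `association`.
#' @export
torus_test <- function(counts, habitat, alpha_tail = 0.025,
                       include_transforms = TRUE) {
  m <- unclass(habitat)
  attributes(m) <- list(dim = dim(m))
  counts <- as.matrix(counts)
  if (!all(dim(counts) == dim(m)))
    stop("species count grid and habitat map are not congruent")
  N <- sum(counts)
  if (N == 0) stop("species has no stems on the grid")
  ncell <- length(m)
  levels_all <- c("hilltop", "steep_slope", "gentle_slope", "depression")
  levs <- levels_all[levels_all %in% m]
  extra <- setdiff(unique(c(m)), levels_all)
  levs <- c(levs, sort(extra))
  absent <- setdiff(unique(levels_all), c(levs))
  trs <- if (include_transforms) map_transforms(m) else list(identity = m)
  out <- lapply(levs, function(h) {
    ncell_h <- sum(m == h)
    nulls <- numeric(0)
    obs <- NA_real_
    for (ti in seq_along(trs)) {
      ind <- (trs[[ti]] == h) + 0
      cc <- cross_correlate(counts, ind)
      vals <- (c(cc) / ncell_h) / (N / ncell)
      if (ti == 1L) {             # identity transform: shift (0,0) is observed
        obs <- vals[1L]
        vals <- vals[-1L]
      }
      nulls <- c(nulls, vals)
    }
    eps <- 1e-9 * max(1, abs(obs))
    q <- (sum(nulls < obs - eps) + 0.5 * sum(abs(nulls - obs) <= eps)) /
      length(nulls)
    assoc <- if (q >= 1 - alpha_tail) "positive"
             else if (q <= alpha_tail) "negative" else "neutral"
    data.frame(habitat = h, observed_relative_density = obs,
               null_quantile = q, association = assoc,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  for (h in absent)
    warning("habitat ", h, " absent from the map; skipped")
  structure(res, alpha_tail = alpha_tail,
            n_null = length(trs) * length(m) - 1L,
            class = c("ttt_result", "data.frame"))
}

#' Torus-translation tests for all common species
#'
#' Applies [torus_test()] to every species in `summaries` on the analysis
#' (20-m) grid and tallies the per-habitat counts of positive, negative and
#' neutral associations, plus the number of species associated (positively
#' or negatively) with at least one habitat.
#'
#' @param census a `census_table`.
#' @param summaries a `species_summary` filtered to the minimum abundance.
#' @param habitat a `habitat_map` on the analysis grid.
#' @param alpha_tail,include_transforms passed to [torus_test()].
#' @param geometry plot geometry; defaults to the census geometry.
#' @return List with `associations` (species x habitat long table),
#'   `habitat_summary` (per-habitat counts), `n_species`,
#'   `n_with_association`.
#' @export
ttt_batch <- function(census, summaries, habitat, alpha_tail = 0.025,
                      include_transforms = TRUE,
                      geometry = attr(census, "geometry")) {
  cs <- attr(habitat, "cell_size")
  rows <- list()
  for (s in summaries$species) {
    pat <- species_pattern(census, s, geometry)
    cnt <- quadrat_counts(pat, cs, geometry)
    r <- torus_test(cnt, habitat, alpha_tail, include_transforms)
    r <- cbind(species = s, as.data.frame(r))
    rows[[s]] <- r
  }
  assoc <- do.call(rbind, rows)
  rownames(assoc) <- NULL
  hs <- do.call(rbind, lapply(split(assoc, assoc$habitat), function(d) {
    data.frame(habitat = d$habitat[1],
               n_positive = sum(d$association == "positive"),
               n_negative = sum(d$association == "negative"),
               n_neutral = sum(d$association == "neutral"))
  }))
  rownames(hs) <- NULL
  any_assoc <- tapply(assoc$association != "neutral", assoc$species, any)
  list(associations = assoc, habitat_summary = hs,
       n_species = nrow(summaries),
       n_with_association = sum(any_assoc))
}
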