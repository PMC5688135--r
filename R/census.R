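#' Build a validated census table
#'
#' A census table is a data frame of mapped stems (one row per individual)
#' with columns `tag`, `species`, `x`, `y`, `dbh` and optional `phenology`
#' (`"evergreen"`, `"deciduous"` or `"unknown"`) and `endemic` (`TRUE`,
#' `FALSE` or `NA`). Validation enforces the census conventions: coordinates
#' inside the half-open window `[0, width) x [0, height)` and DBH of at least
#' 1 cm (the census inclusion threshold). Offending rows are dropped and
#' reported via the `"rejected"` attribute.
#'
#' @param df data frame with at least `tag`, `species`, `x`, `y`, `dbh`.
#' @param geometry a [plot_geometry()].
#' @return A `census_table` (data frame) with attributes `geometry` and
#'   `rejected` (data frame of row numbers and reasons).
#' @export
census_table <- function(df, geometry) {
  req <- c("tag", "species", "x", "y", "dbh")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("census is missing required column(s): ", paste(miss, collapse = ", "))
  df$x <- suppressWarnings(as.numeric(df$x))
  df$y <- suppressWarnings(as.numeric(df$y))
  df$dbh <- suppressWarnings(as.numeric(df$dbh))
  df$species <- as.character(df$species)
  df$tag <- as.character(df$tag)
  if (is.null(df$phenology)) df$phenology <- "unknown"
  if (is.null(df$endemic)) df$endemic <- NA
  df$endemic <- as.logical(df$endemic)

  reason <- character(nrow(df))
  bad_num <- is.na(df$x) | is.na(df$y) | is.na(df$dbh)
  reason[bad_num] <- "non-numeric coordinate or dbh"
  out <- !bad_num & (df$x < 0 | df$x >= geometry$width |
                     df$y < 0 | df$y >= geometry$height)
  reason[out] <- "coordinates outside window"
  small <- !bad_num & !out & df$dbh < 1
  reason[small] <- "dbh below 1 cm census threshold"
  keep <- reason == ""
  rejected <- data.frame(row = which(!keep), reason = reason[!keep],
                         stringsAsFactors = FALSE)
  if (nrow(rejected))
    message(nrow(rejected), " census row(s) rejected during validation")
  res <- df[keep, c(req, "phenology", "endemic"), drop = FALSE]
  rownames(res) <- NULL
  structure(res, geometry = geometry, rejected = rejected,
            class = c("census_table", "data.frame"))
}

#' Read a stem census file
#'
#' Reads a comma- or tab-separated census file (header required; delimiter
#' auto-detected) and validates it with [census_table()].
#'
#' @param path file path.
#' @param geometry a [plot_geometry()].
#' @return A `census_table`.
#' @export
read_census <- function(path, geometry) {
  if (!file.exists(path)) stop("census file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   colClasses = "character", quote = "\"", comment.char = "")
  census_table(df, geometry)
}

#' Write a census table
#'
#' @param census a `census_table`.
#' @param path output path; comma-separated, header included.
#' @export
write_census <- function(census, path) {
  write.csv(as.data.frame(census), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Growth-form classification from mean DBH
#'
#' Species are classed by mean diameter at breast height as understory
#' (< 4 cm), midstory (>= 4 and < 8 cm) or canopy (>= 8 cm); boundary values
#' fall in the larger class.
#'
#' @param mean_dbh mean DBH in cm (vectorised); must be positive.
#' @return Character vector in `{"understory","midstory","canopy"}`.
#' @export
classify_growth_form <- function(mean_dbh) {
  if (any(!is.finite(mean_dbh)) || any(mean_dbh <= 0))
    stop("mean_dbh must be positive and finite")
  ifelse(mean_dbh < 4, "understory",
         ifelse(mean_dbh < 8, "midstory", "canopy"))
}

#' Abundance-class classification
#'
#' Species are classed by density as rare (< 4 stems/ha), intermediate
#' (4-40 stems/ha) or abundant (>= 40 stems/ha); boundary densities fall in
#' the larger class.
#'
#' @param abundance stem count (vectorised), at least 1.
#' @param area_ha plot area in hectares.
#' @return Character vector in `{"rare","intermediate","abundant"}`.
#' @export
classify_abundance <- function(abundance, area_ha) {
  if (any(abundance < 1) || area_ha <= 0)
    stop("abundance must be >= 1 and area_ha positive")
  dens <- abundance / area_ha
  ifelse(dens < 4, "rare", ifelse(dens < 40, "intermediate", "abundant"))
}

#' Per-species summaries
#'
#' Computes abundance, density, mean and maximum DBH, growth form, abundance
#' class and majority trait labels per species, retaining species with at
#' least `min_abundance` individuals (the sample-size filter for point-pattern
#' analysis). Excluded species are listed in the `"excluded"` attribute so
#' that totals are preserved.
#'
#' @param census a `census_table`.
#' @param geometry a [plot_geometry()]; defaults to the census geometry.
#' @param min_abundance minimum stems per retained species (default 25).
#' @return Data frame of class `species_summary` with one row per retained
#'   species.
#' @export
summarize_species <- function(census, geometry = attr(census, "geometry"),
                              min_abundance = 25) {
  if (!nrow(census)) stop("census is empty")
  area <- plot_area_ha(geometry)
  sp <- split(seq_len(nrow(census)), census$species)
  rows <- lapply(names(sp), function(s) {
    i <- sp[[s]]
    dbh <- census$dbh[i]
    phen <- census$phenology[i]
    phen <- if (all(phen == "unknown")) "unknown" else
      names(which.max(table(phen[phen != "unknown"])))
    end <- census$endemic[i]
    end <- if (all(is.na(end))) NA else mean(end, na.rm = TRUE) >= 0.5
    data.frame(species = s, abundance = length(i),
               abundance_per_ha = length(i) / area,
               mean_dbh = mean(dbh), max_dbh = max(dbh),
               growth_form = classify_growth_form(mean(dbh)),
               abundance_class = classify_abundance(length(i), area),
               phenology = phen, endemic = end, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keep <- out$abundance >= min_abundance
  if (any(!keep))
    message(sum(!keep), " species below the ", min_abundance,
            "-stem threshold excluded from summaries")
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  structure(res,
            excluded = out[!keep, c("species", "abundance"), drop = FALSE],
            class = c("species_summary", "data.frame"))
}

#' Write species summaries
#' @param summaries a `species_summary` data frame.
#' @param path output CSV path.
#' @export
write_species_summary <- function(summaries, path) {
  write.csv(as.data.frame(summaries), path, row.names = FALSE)
  invisible(path)
}

# point pattern of one species' stems
species_pattern <- function(census, species,
                            geometry = attr(census, "geometry")) {
  i <- census$species == species
  point_pattern(census$x[i], census$y[i], geometry)
}

#' Cell-by-species community matrix
#'
#' Stem counts of each species per grid cell, rows ordered row-major from
#' the south-west corner (matching [quadrat_topography()] row order). All
#' species are retained by default: rarer species still contribute to the
#' composition used by the regression tree and the ordination even though
#' they are excluded from point-pattern analysis.
#'
#' @param census a `census_table`.
#' @param geometry plot geometry; defaults to the census geometry.
#' @param cell_size cell side in metres (default the analysis cell).
#' @param species optional character vector restricting the columns.
#' @return Integer matrix, `n_cells` x `n_species`, with species as column
#'   names.
#' @export
community_matrix <- function(census, geometry = attr(census, "geometry"),
                             cell_size = geometry$cell_analysis,
                             species = NULL) {
  d <- grid_dim(geometry, cell_size)
  sp <- species %||% sort(unique(census$species))
  idx <- cell_of(census$x, census$y, cell_size)
  cell <- (idx$row - 1L) * d[["nx"]] + idx$col
  keep <- census$species %in% sp
  tab <- table(factor(cell[keep], levels = seq_len(d[["nx"]] * d[["ny"]])),
               factor(census$species[keep], levels = sp))
  m <- matrix(as.integer(tab), nrow = d[["nx"]] * d[["ny"]],
              dimnames = list(NULL, sp))
  m
}
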