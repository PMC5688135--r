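#' Plot geometry
#'
#' Describes the rectangular census window and the two grid resolutions used
#' throughout the analysis: the 20-m cells of the habitat / community grid and
#' the 10-m quadrats carrying the covariates of the heterogeneous Poisson
#' null model. Coordinates are half-open, `[0, width) x [0, height)`, with the
#' origin at the south-west corner, x increasing eastward and y northward, so
#' every stem belongs to exactly one cell.
#'
#' @param width,height plot dimensions in metres. Must be positive integer
#'   multiples of both cell sizes.
#' @param cell_analysis side length (m) of the analysis (habitat) cells;
#'   default 20.
#' @param cell_covariate side length (m) of the covariate quadrats; default 10.
#' @return An object of class `plot_geometry`.
#' @examples
#' g <- plot_geometry(500, 500)
#' n_cells(g)          # 625 twenty-metre cells
#' @export
plot_geometry <- function(width, height = width, cell_analysis = 20,
                          cell_covariate = 10) {
  stopifnot(is.numeric(width), is.numeric(height), width > 0, height > 0,
            cell_analysis > 0, cell_covariate > 0)
  for (cs in c(cell_analysis, cell_covariate)) {
    if (abs(width / cs - round(width / cs)) > 1e-9 ||
        abs(height / cs - round(height / cs)) > 1e-9)
      stop("plot dimensions must be integer multiples of cell size ", cs, " m")
  }
  structure(list(width = as.numeric(width), height = as.numeric(height),
                 cell_analysis = cell_analysis,
                 cell_covariate = cell_covariate),
            class = "plot_geometry")
}

#' @export
print.plot_geometry <- function(x, ...) {
  cat(sprintf("Plot window %g m x %g m (%.2f ha); %d analysis cells (%g m), %d covariate quadrats (%g m)\n",
              x$width, x$height, plot_area_ha(x),
              n_cells(x), x$cell_analysis,
              n_cells(x, x$cell_covariate), x$cell_covariate))
  invisible(x)
}

#' @rdname plot_geometry
#' @param geometry a `plot_geometry`.
#' @param cell_size cell side in metres (defaults to the analysis cell).
#' @export
n_cells <- function(geometry, cell_size = geometry$cell_analysis) {
  d <- grid_dim(geometry, cell_size)
  unname(d["nx"] * d["ny"])
}

#' @rdname plot_geometry
#' @export
plot_area_ha <- function(geometry) geometry$width * geometry$height / 1e4

# number of cells along x (columns) and y (rows)
grid_dim <- function(geometry, cell_size) {
  c(nx = as.integer(round(geometry$width / cell_size)),
    ny = as.integer(round(geometry$height / cell_size)))
}

# 1-based (row, col) of the cell containing each point; row 1 = southern edge
cell_of <- function(x, y, cell_size) {
  list(row = floor(y / cell_size) + 1L, col = floor(x / cell_size) + 1L)
}

#' Quadrat counts of a point pattern
#'
#' Number of points per grid cell, as a `ny x nx` integer matrix with row 1
#' at the southern edge of the plot.
#'
#' @param pattern a [point_pattern()].
#' @param cell_size cell side in metres.
#' @param geometry optional [plot_geometry()] overriding the pattern window.
#' @return Integer matrix of counts.
#' @export
quadrat_counts <- function(pattern, cell_size, geometry = NULL) {
  w <- if (!is.null(geometry)) geometry$width else pattern$width
  h <- if (!is.null(geometry)) geometry$height else pattern$height
  nx <- as.integer(round(w / cell_size)); ny <- as.integer(round(h / cell_size))
  idx <- cell_of(pattern$x, pattern$y, cell_size)
  tab <- table(factor((idx$row - 1L) * nx + idx$col, levels = seq_len(nx * ny)))
  matrix(as.integer(tab), ny, nx, byrow = TRUE)
}
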