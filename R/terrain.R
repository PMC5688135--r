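#' Corner-elevation grid
#'
#' Elevations on a regular lattice of points covering the plot, spaced
#' `spacing` metres apart, stored as a matrix with row 1 at the southern edge
#' (y = 0) and column 1 at the western edge (x = 0). A grid for a
#' `width x height` plot has `width/spacing + 1` columns and
#' `height/spacing + 1` rows.
#'
#' @param z numeric matrix of elevations (rows = south to north).
#' @param spacing lattice spacing in metres.
#' @return An `elevation_grid`.
#' @export
elevation_grid <- function(z, spacing) {
  z <- as.matrix(z)
  if (nrow(z) < 2 || ncol(z) < 2)
    stop("elevation grid must have at least 2 rows and 2 columns")
  if (any(!is.finite(z))) stop("elevation grid contains non-finite values")
  structure(list(z = z, spacing = as.numeric(spacing)),
            class = "elevation_grid")
}

#' @export
print.elevation_grid <- function(x, ...) {
  cat(sprintf("Elevation lattice %d x %d points, %g m spacing, range %.1f-%.1f m\n",
              nrow(x$z), ncol(x$z), x$spacing, min(x$z), max(x$z)))
  invisible(x)
}

#' Read an elevation grid
#'
#' Accepts either an ESRI ASCII grid (`ncols`/`nrows`/`xllcorner`/`yllcorner`/
#' `cellsize` header, rows north to south) or a plain whitespace/comma
#' delimited matrix (rows south to north) with `spacing` supplied.
#'
#' @param path file path.
#' @param spacing lattice spacing (m); required for plain matrices, taken
#'   from `cellsize` for ESRI ASCII input.
#' @return An `elevation_grid`.
#' @export
read_elevation_grid <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("elevation file not found: ", path)
  first <- tolower(readLines(path, n = 1L))
  if (grepl("^\\s*ncols", first)) {
    hdr <- readLines(path, n = 6L)
    kv <- lapply(strsplit(trimws(hdr), "\\s+"), function(p)
      setNames(suppressWarnings(as.numeric(p[2])), tolower(p[1])))
    kv <- unlist(kv)
    nhead <- sum(names(kv) %in%
                 c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                   "nodata_value"))
    vals <- scan(path, skip = nhead, quiet = TRUE)
    z <- matrix(vals, nrow = kv[["nrows"]], ncol = kv[["ncols"]], byrow = TRUE)
    z <- z[rev(seq_len(nrow(z))), , drop = FALSE]  # to south-first rows
    elevation_grid(z, kv[["cellsize"]])
  } else {
    if (is.null(spacing)) stop("spacing must be given for a plain matrix grid")
    sep <- if (grepl(",", first)) "," else ""
    z <- as.matrix(read.table(path, header = FALSE, sep = sep))
    dimnames(z) <- NULL
    elevation_grid(z, spacing)
  }
}

#' Write an elevation grid as ESRI ASCII
#' @param grid an `elevation_grid`.
#' @param path output path.
#' @export
write_elevation_grid <- function(grid, path) {
  z <- grid$z
  hdr <- c(paste("ncols", ncol(z)), paste("nrows", nrow(z)),
           "xllcorner 0", "yllcorner 0",
           paste("cellsize", grid$spacing), "NODATA_value -9999")
  body <- apply(z[rev(seq_len(nrow(z))), , drop = FALSE], 1, paste,
                collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Bilinearly refine an elevation grid
#'
#' @param grid an `elevation_grid`.
#' @param new_spacing target spacing (m); must divide the plot extent.
#' @return An `elevation_grid` at the finer spacing.
#' @export
refine_grid <- function(grid, new_spacing) {
  z <- grid$z; s <- grid$spacing
  wx <- (ncol(z) - 1) * s; wy <- (nrow(z) - 1) * s
  nx <- round(wx / new_spacing); ny <- round(wy / new_spacing)
  if (abs(nx * new_spacing - wx) > 1e-9 || abs(ny * new_spacing - wy) > 1e-9)
    stop("new_spacing must divide the grid extent")
  xs <- seq(0, wx, by = new_spacing); ys <- seq(0, wy, by = new_spacing)
  zi <- bilinear_at(z, s, rep(xs, each = length(ys)), rep(ys, length(xs)))
  elevation_grid(matrix(zi, length(ys), length(xs)), new_spacing)
}

# bilinear interpolation of lattice z (spacing s, SW origin) at points (x, y)
bilinear_at <- function(z, s, x, y) {
  j <- pmin(pmax(floor(x / s), 0), ncol(z) - 2)
  i <- pmin(pmax(floor(y / s), 0), nrow(z) - 2)
  u <- x / s - j; v <- y / s - i
  i <- i + 1L; j <- j + 1L
  z[cbind(i, j)] * (1 - u) * (1 - v) + z[cbind(i, j + 1)] * u * (1 - v) +
    z[cbind(i + 1, j)] * (1 - u) * v + z[cbind(i + 1, j + 1)] * u * v
}

#' Per-quadrat topographic variables
#'
#' Derives the four topographic variables for every `cell_size` quadrat of
#' the plot from a corner-elevation lattice:
#' \describe{
#'   \item{elevation}{mean of the quadrat's four corner elevations (m);}
#'   \item{slope}{mean, in degrees, of the slopes of the four planes each
#'     through three of the four corners (the CTFS plot convention);}
#'   \item{aspect}{compass bearing (degrees clockwise from north) of steepest
#'     descent of the least-squares plane through the four corners, i.e. the
#'     direction the slope faces; `NA` where slope < 0.01 deg;}
#'   \item{convexity}{quadrat mean elevation minus the mean elevation of its
#'     eight neighbouring quadrats (edge quadrats use the available
#'     neighbours), positive on ridges and negative in depressions (m).}
#' }
#' If the lattice spacing does not divide `cell_size` the grid is first
#' refined bilinearly.
#'
#' @param grid an `elevation_grid` covering the plot.
#' @param geometry a [plot_geometry()].
#' @param cell_size quadrat side (m); default the analysis cell size.
#' @return A data frame of class `topo_grid` with columns `row`, `col`
#'   (1-based, row 1 south), `x`, `y` (SW corner of the quadrat), `elevation`,
#'   `slope`, `aspect`, `convexity`, ordered row-major from the south-west;
#'   attributes `nx`, `ny`, `cell_size`.
#' @export
quadrat_topography <- function(grid, geometry,
                               cell_size = geometry$cell_analysis) {
  s <- grid$spacing
  if ((ncol(grid$z) - 1) * s != geometry$width ||
      (nrow(grid$z) - 1) * s != geometry$height)
    stop("elevation grid does not cover the plot window")
  step <- cell_size / s
  if (abs(step - round(step)) > 1e-9) {
    div <- cell_size / ceiling(cell_size / s)
    grid <- refine_grid(grid, div)
    s <- grid$spacing
    step <- cell_size / s
  }
  step <- as.integer(round(step))
  z <- grid$z
  nx <- as.integer(round(geometry$width / cell_size))
  ny <- as.integer(round(geometry$height / cell_size))
  if (nx < 1 || ny < 1) stop("degenerate grid: fewer than one quadrat")

  ci <- seq(1L, nrow(z), by = step)  # corner rows at quadrat boundaries
  cj <- seq(1L, ncol(z), by = step)
  corner <- z[ci, cj, drop = FALSE]  # (ny+1) x (nx+1)
  sw <- corner[1:ny, 1:nx, drop = FALSE]
  se <- corner[1:ny, 2:(nx + 1), drop = FALSE]
  nw <- corner[2:(ny + 1), 1:nx, drop = FALSE]
  ne <- corner[2:(ny + 1), 2:(nx + 1), drop = FALSE]
  L <- cell_size

  elev <- (sw + se + nw + ne) / 4
  # slope of each plane through three corners; gradient of a right triangle
  sl3 <- function(gx, gy) atan(sqrt(gx^2 + gy^2)) * 180 / pi
  slope <- (sl3((se - sw) / L, (nw - sw) / L) +   # omit ne
            sl3((se - sw) / L, (ne - se) / L) +   # omit nw
            sl3((ne - nw) / L, (nw - sw) / L) +   # omit se
            sl3((ne - nw) / L, (ne - se) / L)) / 4  # omit sw
  # least-squares plane gradient over the 4 corners
  gx <- ((se + ne) - (sw + nw)) / (2 * L)
  gy <- ((nw + ne) - (sw + se)) / (2 * L)
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  aspect[slope < 0.01] <- NA_real_

  conv <- elev
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    ii <- max(1, i - 1):min(ny, i + 1)
    jj <- max(1, j - 1):min(nx, j + 1)
    nb <- elev[ii, jj]
    conv[i, j] <- elev[i, j] - (sum(nb) - elev[i, j]) / (length(nb) - 1)
  }

  out <- data.frame(row = rep(seq_len(ny), each = nx),
                    col = rep(seq_len(nx), ny),
                    x = rep((seq_len(nx) - 1) * cell_size, ny),
                    y = rep((seq_len(ny) - 1) * cell_size, each = nx),
                    elevation = as.vector(t(elev)),
                    slope = as.vector(t(slope)),
                    aspect = as.vector(t(aspect)),
                    convexity = as.vector(t(conv)))
  structure(out, nx = nx, ny = ny, cell_size = cell_size,
            class = c("topo_grid", "data.frame"))
}

#' Write a topographic grid
#' @param topo a `topo_grid`.
#' @param path output CSV path.
#' @export
write_topo_grid <- function(topo, path) {
  write.csv(as.data.frame(topo), path, row.names = FALSE)
  invisible(path)
}

# ny x nx matrix of one topo variable (row 1 = south)
topo_matrix <- function(topo, var) {
  matrix(topo[[var]], attr(topo, "ny"), attr(topo, "nx"), byrow = TRUE)
}
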