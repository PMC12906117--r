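# Equal-area grid rasters on a flat projected plane in metres.
#
# Conventions (used by every module):
#  * origin = lower-left corner (x0, y0); cells addressed [row, col] with
#    row 1 the southernmost row and column 1 the westernmost column;
#  * cell (i, j) covers the half-open square
#    [x0+(j-1)s, x0+j*s) x [y0+(i-1)s, y0+i*s), s = cell_size_m;
#  * all masking uses the cell-centre rule, so polygon masking and direct
#    grid classification agree exactly.

#' Construct a grid raster
#'
#' @param values numeric matrix; `values[i, j]` is the cell in row `i`
#'   (counted from the south edge) and column `j` (from the west edge).
#' @param cell_size_m cell edge length in metres.
#' @param origin numeric length-2, lower-left corner `(x0, y0)` in metres.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, cell_size_m, origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_invalid("`values` must be a numeric matrix")
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1 || cell_size_m <= 0)
    stop_invalid("`cell_size_m` must be a positive scalar")
  structure(list(values = values,
                 cell_size_m = as.numeric(cell_size_m),
                 origin = as.numeric(origin[1:2])),
            class = "grid_raster")
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Total of all cells in a raster
#' @param r a `grid_raster`.
#' @return scalar sum over cells.
#' @export
raster_total <- function(r) sum(r$values)

#' Coordinates of all cell centres
#'
#' @param r a `grid_raster` (or any object carrying `cell_size_m`, `origin`
#'   and a `values` matrix).
#' @return list with matrices `x` and `y`, same dimensions as `r$values`.
#' @export
cell_centres <- function(r) {
  d <- dim(r$values)
  s <- r$cell_size_m
  xs <- r$origin[1] + (seq_len(d[2]) - 0.5) * s
  ys <- r$origin[2] + (seq_len(d[1]) - 0.5) * s
  list(x = matrix(xs, d[1], d[2], byrow = TRUE),
       y = matrix(ys, d[1], d[2]))
}

# Geometry descriptor shared by rasters, fields, masks and isochrone sets.
grid_geometry <- function(r) {
  if (!is.null(r$geometry)) return(r$geometry)
  list(dim = dim(r$values), cell_size_m = r$cell_size_m, origin = r$origin)
}

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- grid_geometry(a); gb <- grid_geometry(b)
  identical(ga$dim, gb$dim) &&
    abs(ga$cell_size_m - gb$cell_size_m) <= tol &&
    all(abs(ga$origin - gb$origin) <= tol)
}

check_same_geometry <- function(a, b, what = "rasters") {
  if (!same_geometry(a, b))
    stop_invalid("coordinate frames of the %s do not match", what)
  invisible(TRUE)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by every GIS. Non-finite values
#' are written as the nodata sentinel.
#'
#' @param r a `grid_raster`.
#' @param path output file path (conventionally `.asc`).
#' @param nodata sentinel written for non-finite cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  v[!is.finite(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", r$origin[1]),
           sprintf("yllcorner %.10g", r$origin[2]),
           sprintf("cellsize %.10g", r$cell_size_m),
           sprintf("NODATA_value %.10g", nodata))
  # rows are written north -> south per the format
  body <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1,
                function(row) paste(format(row, trim = TRUE, digits = 15),
                                    collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param nodata_as value substituted for nodata cells (`NA` by default;
#'   travel-time fields use `Inf`).
#' @return a `grid_raster`.
#' @export
read_ascii_grid <- function(path, nodata_as = NA_real_) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to south-first rows
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- nodata_as
  grid_raster(m, hdr$cellsize, c(hdr$xllcorner, hdr$yllcorner))
}

#' @export
print.grid_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<grid_raster> %d x %d cells, %g m cells, origin (%g, %g)\n",
              d[1], d[2], x$cell_size_m, x$origin[1], x$origin[2]))
  cat(sprintf("  total %.6g, range [%.6g, %.6g]\n", sum(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}
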