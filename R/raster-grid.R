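#' Lightweight gridded raster container
#'
#' A `grid_raster` holds a rectangular grid of cell values together with its
#' georeferencing: the coordinates of the lower-left corner, a (square) cell
#' size and a free-form CRS tag. Values are stored as a matrix whose rows run
#' north to south (row 1 = northernmost row), the layout used by ESRI ASCII
#' grids. Missing cells are `NA` and are excluded from all arithmetic.
#'
#' @param values numeric matrix, rows north to south.
#' @param x_origin,y_origin coordinates of the lower-left corner of the grid
#'   (same units as `cell_size`; kilometres for projected grids).
#' @param cell_size side length of a (square) cell; must be positive.
#' @param crs_tag character tag describing the coordinate system.
#'
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, x_origin = 0, y_origin = 0, cell_size = 1,
                        crs_tag = "planar-km") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("raster values must be numeric")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  structure(
    list(values = values, x_origin = as.numeric(x_origin),
         y_origin = as.numeric(y_origin), cell_size = as.numeric(cell_size),
         crs_tag = crs_tag),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat("<grid_raster> ", nrow(v), "x", ncol(v), " cells of ", x$cell_size,
      " [", x$crs_tag, "]\n", sep = "")
  cat("  extent x: [", x$x_origin, ", ", x$x_origin + ncol(v) * x$cell_size,
      "]  y: [", x$y_origin, ", ", x$y_origin + nrow(v) * x$cell_size, "]\n",
      sep = "")
  rng <- range(v, na.rm = TRUE)
  cat("  values: [", signif(rng[1], 6), ", ", signif(rng[2], 6), "], ",
      sum(is.na(v)), " missing\n", sep = "")
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Cell-centre coordinates of every cell
#'
#' @param r a [grid_raster].
#' @return list with matrices `x` and `y` of the same shape as `r$values`
#'   giving each cell's centre coordinates.
#' @keywords internal
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  xs <- r$x_origin + (seq_len(nc) - 0.5) * r$cell_size
  # row 1 is the northernmost row
  ys <- r$y_origin + (nr - seq_len(nr) + 0.5) * r$cell_size
  list(x = matrix(xs, nr, nc, byrow = TRUE), y = matrix(ys, nr, nc))
}

#' Row/column index of the cell containing a point
#'
#' Points on a cell boundary belong to the cell to the north-east of the
#' boundary (half-open cells). Returns `NA` for points outside the extent.
#'
#' @param r a [grid_raster].
#' @param x,y point coordinates (vectors of equal length).
#' @return integer matrix with columns `row`, `col`.
#' @keywords internal
cell_index <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$x_origin) / r$cell_size) + 1L
  row_from_bottom <- floor((y - r$y_origin) / r$cell_size) + 1L
  row <- nr - row_from_bottom + 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Value of the cell containing each point
#'
#' @inheritParams cell_index
#' @return numeric vector; `NA` outside the extent or on missing cells.
#' @export
raster_value_at <- function(r, x, y) {
  idx <- cell_index(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx[, 1])
  out[ok] <- r$values[cbind(idx[ok, 1], idx[ok, 2])]
  out
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster exchange format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`nodata_value` header followed by rows of values,
#' north to south). `NA` cells are written as the nodata value.
#'
#' @param path file path.
#' @param r a [grid_raster] (for writing).
#' @param crs_tag CRS tag to attach on read (the format itself carries none).
#' @param nodata nodata sentinel written to file.
#' @return `read_asc_grid` returns a [grid_raster]; `write_asc_grid` returns
#'   `path` invisibly.
#' @export
read_asc_grid <- function(path, crs_tag = "planar-km") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ASCII grid header missing field(s): ", paste(miss, collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  grid_raster(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, crs_tag)
}

#' @rdname read_asc_grid
#' @export
write_asc_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    paste("xllcorner", format(r$x_origin, digits = 15)),
    paste("yllcorner", format(r$y_origin, digits = 15)),
    paste("cellsize", format(r$cell_size, digits = 15)),
    paste("nodata_value", nodata)
  ), con)
  apply(v, 1L, function(row)
    writeLines(paste(format(row, digits = 15, trim = TRUE), collapse = " "),
               con))
  invisible(path)
}
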