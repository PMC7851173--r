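#' Covariate stack
#'
#' Co-registered covariate rasters entering the movement model: the
#' log-distance to high spring chlorophyll-a areas (DAHCC, one layer per
#' deployment year), sea-surface temperature (one layer per day) and the
#' SST thermal-gradient magnitude (one layer per day), plus the
#' standardization constants used to z-score extracted series.
#'
#' @param log_dahcc named list of [grid_raster] keyed by year (or a single
#'   raster).
#' @param sst named list of [grid_raster] keyed by date string (or a single
#'   raster).
#' @param thermal_gradient like `sst`.
#' @param standardization optional data frame with columns `covariate`,
#'   `mean`, `sd`.
#'
#' @return object of class `covariate_stack`.
#' @export
covariate_stack <- function(log_dahcc, sst, thermal_gradient,
                            standardization = NULL) {
  as_layer_list <- function(x) if (inherits(x, "grid_raster")) list(x) else x
  structure(list(log_dahcc = as_layer_list(log_dahcc),
                 sst = as_layer_list(sst),
                 thermal_gradient = as_layer_list(thermal_gradient),
                 standardization = standardization),
            class = "covariate_stack")
}

covariate_names <- function() c("log_dahcc", "sst", "thermal_gradient")

# pick the layer for a relocation: DAHCC by year, SST/gradient by day;
# single-layer lists match everything (the synthetic stacks are static)
stack_layer <- function(stack, covariate, timestamp) {
  layers <- stack[[covariate]]
  if (length(layers) == 1L) return(layers[[1]])
  key <- if (covariate == "log_dahcc") format(timestamp, "%Y")
         else format(timestamp, "%Y-%m-%d")
  hit <- layers[[key]]
  if (is.null(hit)) stop("no ", covariate, " layer for ", key)
  hit
}

#' Distance to areas of high spring chlorophyll-a (DAHCC)
#'
#' Cells whose spring-mean chlorophyll-a concentration is at or above the
#' given percentile of the raster's distribution form the high-concentration
#' set. Every marine cell is assigned the log of the Euclidean distance (same
#' units as the raster, km for projected grids) from its centre to the
#' nearest high-set cell centre. A distance floor of half a cell width is
#' applied before the log so the high set itself takes a finite minimum
#' value.
#'
#' @param spring_chla [grid_raster] of spring-months mean chlorophyll-a
#'   (mg m^-3); `NA` cells (land) are preserved as `NA`.
#' @param percentile percentile (0-100) defining the high-concentration
#'   cut-off; the field-standard default is the 95th.
#'
#' @return [grid_raster] of log distances.
#' @export
build_dahcc <- function(spring_chla, percentile = 95) {
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie strictly between 0 and 100")
  v <- spring_chla$values
  marine <- !is.na(v)
  cut <- quantile(v[marine], probs = percentile / 100, names = FALSE)
  high <- marine & v >= cut
  if (!any(high) || all(v[marine] == v[marine][1]))
    stop("no cells exceed the ", percentile,
         "th percentile (flat chlorophyll raster)")
  cc <- cell_centers(spring_chla)
  hx <- cc$x[high]; hy <- cc$y[high]
  qx <- cc$x[marine]; qy <- cc$y[marine]
  # nearest high-set centre, chunked to bound memory on large rasters
  nearest <- numeric(length(qx))
  step <- max(1L, floor(4e6 / length(hx)))
  for (s in seq(1L, length(qx), by = step)) {
    i <- s:min(s + step - 1L, length(qx))
    d2 <- outer(qx[i], hx, "-")^2 + outer(qy[i], hy, "-")^2
    nearest[i] <- sqrt(apply(d2, 1L, min))
  }
  floor_km <- spring_chla$cell_size / 2
  out <- v
  out[marine] <- log(pmax(nearest, floor_km))
  grid_raster(out, spring_chla$x_origin, spring_chla$y_origin,
              spring_chla$cell_size, spring_chla$crs_tag)
}

#' Thermal-gradient magnitude of an SST field
#'
#' Applies a square running-median pre-filter (suppressing impulse noise in
#' the interpolated SST product) and returns the gradient magnitude
#' sqrt((dT/dx)^2 + (dT/dy)^2) in degrees C per distance unit, using central
#' differences in the interior and one-sided differences on the edges.
#'
#' @param sst [grid_raster] of SST (degrees C).
#' @param median_window odd window side length for the median pre-filter;
#'   `1` disables it.
#'
#' @return [grid_raster] of gradient magnitudes.
#' @export
thermal_gradient <- function(sst, median_window = 3) {
  v <- sst$values
  if (median_window %% 2 != 1) stop("median_window must be odd")
  if (nrow(v) < median_window || ncol(v) < median_window)
    stop("raster smaller than the median window")
  if (median_window > 1) v <- median_filter2d(v, median_window)
  h <- sst$cell_size
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 2 || nc < 2) stop("raster too small for gradients")
  # d/dx along columns (west->east), d/dy along rows (row 1 = north)
  dx <- v; dy <- v
  dx[, 2:(nc - 1)] <- (v[, 3:nc] - v[, 1:(nc - 2)]) / (2 * h)
  dx[, 1] <- (v[, 2] - v[, 1]) / h
  dx[, nc] <- (v[, nc] - v[, nc - 1]) / h
  dy[2:(nr - 1), ] <- (v[1:(nr - 2), ] - v[3:nr, ]) / (2 * h)
  dy[1, ] <- (v[1, ] - v[2, ]) / h
  dy[nr, ] <- (v[nr - 1, ] - v[nr, ]) / h
  grid_raster(sqrt(dx^2 + dy^2), sst$x_origin, sst$y_origin, sst$cell_size,
              sst$crs_tag)
}

# square running median with shrinking windows at edges; NA cells stay NA
# and are excluded from neighbours' medians
median_filter2d <- function(v, w) {
  half <- (w - 1L) / 2L
  nr <- nrow(v); nc <- ncol(v)
  out <- v
  for (i in seq_len(nr)) {
    ri <- max(1L, i - half):min(nr, i + half)
    for (j in seq_len(nc)) {
      if (is.na(v[i, j])) next
      block <- v[ri, max(1L, j - half):min(nc, j + half)]
      out[i, j] <- median(block, na.rm = TRUE)
    }
  }
  out
}

#' Mean raster value within a radius of a point
#'
#' Arithmetic mean of non-missing cell values whose centres lie within
#' `radius` of `(x, y)`. Used to extract covariates at estimated whale
#' locations while absorbing residual location error (the field-standard
#' 3 km corresponds to twice the nominal error of Argos classes 3-1).
#'
#' @param r [grid_raster].
#' @param x,y point coordinates (vectors accepted), same units as the grid.
#' @param radius search radius, same units as the grid.
#'
#' @return numeric vector of means; `NA` where the point is outside the
#'   extent (with a warning) or no non-missing cell centre falls inside the
#'   radius.
#' @export
extract_mean_radius <- function(r, x, y, radius = 3.0) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  xmax <- r$x_origin + nc * r$cell_size
  ymax <- r$y_origin + nr * r$cell_size
  outside <- x < r$x_origin | x > xmax | y < r$y_origin | y > ymax
  if (any(outside)) warning(sum(outside), " point(s) outside raster extent")
  cc <- NULL
  vapply(seq_along(x), function(k) {
    if (outside[k]) return(NA_real_)
    # candidate window of cells, then exact centre-distance test
    halo <- ceiling(radius / r$cell_size) + 1L
    idx <- cell_index(r, x[k], y[k])
    rows <- max(1L, idx[1] - halo):min(nr, idx[1] + halo)
    cols <- max(1L, idx[2] - halo):min(nc, idx[2] + halo)
    cx <- r$x_origin + (cols - 0.5) * r$cell_size
    cy <- r$y_origin + (nr - rows + 0.5) * r$cell_size
    d2 <- outer(cy - y[k], cx - x[k], function(a, b) a^2 + b^2)
    vals <- r$values[rows, cols, drop = FALSE][d2 <= radius^2]
    if (radius < r$cell_size / 2 && all(d2 > radius^2)) {
      # radius smaller than half a cell: fall back to the containing cell
      vals <- r$values[idx[1], idx[2]]
    }
    if (length(vals) == 0L || all(is.na(vals))) NA_real_
    else mean(vals, na.rm = TRUE)
  }, numeric(1))
}

#' Standardize covariate series into a design matrix
#'
#' z-scores each covariate series and replaces missing values with 0, the
#' mean of a standardized variable, so relocations with no covariate data
#' contribute no covariate signal.
#'
#' @param values data frame or matrix, one row per relocation, one column per
#'   covariate; missing entries `NA`.
#' @param stats optional data frame with columns `covariate`, `mean`, `sd`
#'   (for example a fit's training constants); by default each column's own
#'   non-missing mean and sd are used.
#'
#' @return list with `X` (the design matrix) and `stats` (the constants
#'   used).
#' @export
standardize_and_fill <- function(values, stats = NULL) {
  values <- as.matrix(as.data.frame(values))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("x", seq_len(ncol(values)))
  if (is.null(stats)) {
    mu <- apply(values, 2, mean, na.rm = TRUE)
    sdv <- apply(values, 2, sd, na.rm = TRUE)
    stats <- data.frame(covariate = colnames(values), mean = mu, sd = sdv,
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  m <- match(colnames(values), stats$covariate)
  if (anyNA(m)) stop("no standardization constants for: ",
                     paste(colnames(values)[is.na(m)], collapse = ", "))
  mu <- stats$mean[m]; sdv <- stats$sd[m]
  degenerate <- !is.finite(sdv) | sdv <= 0
  if (any(degenerate))
    stop("degenerate covariate (sd = 0): ",
         paste(colnames(values)[degenerate], collapse = ", "))
  X <- sweep(sweep(values, 2, mu, "-"), 2, sdv, "/")
  X[is.na(X)] <- 0
  list(X = X, stats = stats)
}

#' Flag strongly correlated covariate pairs
#'
#' Screening utility: computes pairwise Pearson correlations between
#' covariate columns and flags pairs at or above the screening threshold
#' (|r| >= 0.5 by default), the usual rule before entering covariates
#' jointly in a movement model.
#'
#' @param values matrix/data frame of covariate series (rows =
#'   relocations).
#' @param threshold absolute-correlation flag threshold.
#' @return data frame of all pairs with columns `a`, `b`, `r`, `flagged`.
#' @export
flag_correlated_covariates <- function(values, threshold = 0.5) {
  values <- as.matrix(as.data.frame(values))
  cn <- colnames(values)
  cm <- suppressWarnings(stats::cor(values, use = "pairwise.complete.obs"))
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  data.frame(a = cn[pairs[, 1]], b = cn[pairs[, 2]],
             r = cm[pairs],
             flagged = abs(cm[pairs]) >= threshold,
             stringsAsFactors = FALSE)
}

#' Extract the model design matrix along a path
#'
#' For each position/time, takes the 3-km-radius mean of each covariate
#' layer (matching layers by deployment year for DAHCC and by calendar day
#' for SST/gradient when the stack is dated) and standardizes the resulting
#' series.
#'
#' @param stack a [covariate_stack].
#' @param xy n x 2 matrix of planar positions (km).
#' @param timestamps POSIXct vector of length n.
#' @param radius extraction radius (km).
#' @param stats optional fixed standardization constants (see
#'   [standardize_and_fill()]).
#' @param covariates which stack layers to extract (default all).
#' @return list with `X`, `stats` and `raw` (the unstandardized series).
#' @export
extract_design_matrix <- function(stack, xy, timestamps, radius = 3.0,
                                  stats = NULL,
                                  covariates = covariate_names()) {
  raw <- sapply(covariates, function(cv) {
    vapply(seq_len(nrow(xy)), function(i) {
      layer <- stack_layer(stack, cv, timestamps[i])
      suppressWarnings(
        extract_mean_radius(layer, xy[i, 1], xy[i, 2], radius))
    }, numeric(1))
  })
  colnames(raw) <- covariates
  std <- standardize_and_fill(raw, stats)
  list(X = std$X, stats = std$stats, raw = raw)
}
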