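#' Project vessel records into a planar frame
#'
#' Adds planar `x`, `y` columns (km) under the azimuthal equidistant
#' projection centred at `proj` so vessel fixes share the coordinate frame
#' of the whale layers.
#'
#' @param records vessel record data frame (see [read_vessel_table()]).
#' @param proj list with `lon0`, `lat0` (e.g. a track's `proj` slot).
#' @return `records` with `x` and `y` columns appended.
#' @export
project_vessels <- function(records, proj) {
  xy <- aeqd_forward(records$lon, records$lat, proj$lon0, proj$lat0)
  records$x <- xy[, 1]
  records$y <- xy[, 2]
  records
}

# grid cells traversed by the straight segment (x0,y0)-(x1,y1)
# (Amanatides-Woo voxel walk); returns matrix of (row, col), in-extent only
segment_cells <- function(r, x0, y0, x1, y1) {
  cs <- r$cell_size
  u0 <- (x0 - r$x_origin) / cs; v0 <- (y0 - r$y_origin) / cs
  u1 <- (x1 - r$x_origin) / cs; v1 <- (y1 - r$y_origin) / cs
  cu <- floor(u0); cv <- floor(v0)
  eu <- floor(u1); ev <- floor(v1)
  du <- u1 - u0; dv <- v1 - v0
  step_u <- sign(du); step_v <- sign(dv)
  tmax_u <- if (du != 0) ((cu + (step_u > 0)) - u0) / du else Inf
  tmax_v <- if (dv != 0) ((cv + (step_v > 0)) - v0) / dv else Inf
  tdel_u <- if (du != 0) abs(1 / du) else Inf
  tdel_v <- if (dv != 0) abs(1 / dv) else Inf
  cells <- matrix(c(cu, cv), 1, 2)
  guard <- abs(eu - cu) + abs(ev - cv) + 4
  while ((cu != eu || cv != ev) && guard > 0) {
    if (tmax_u < tmax_v) {
      cu <- cu + step_u; tmax_u <- tmax_u + tdel_u
    } else {
      cv <- cv + step_v; tmax_v <- tmax_v + tdel_v
    }
    cells <- rbind(cells, c(cu, cv))
    guard <- guard - 1
  }
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- cells[, 1] + 1L
  row <- nr - cells[, 2]
  keep <- col >= 1L & col <= nc & row >= 1L & row <= nr
  cbind(row = row[keep], col = col[keep])
}

#' Vessel density on a grid
#'
#' For each month, counts per grid cell the daily number of unique vessels
#' crossing the cell — a vessel crosses every cell traversed by the straight
#' segments between its consecutive fixes that day (and the cells containing
#' the fixes themselves), counted once per vessel-day — sums over the days of
#' the month that have any data, and divides by that number of days. Monthly
#' layers are then averaged cell-wise into a single layer (vessels per day
#' per cell).
#'
#' @param records projected vessel records (see [project_vessels()]),
#'   typically pre-filtered to one fleet.
#' @param grid a [grid_raster] template defining extent and cell size (8 km
#'   in the standard workflow); its values are ignored, its `NA` mask kept.
#' @param months optional character vector (`"YYYY-MM"`) restricting the
#'   months used; by default all months present in `records`.
#' @param fleet optional fleet filter.
#' @param crossing `"segment"` (default: credit traversed cells) or
#'   `"containment"` (credit only cells holding a fix).
#' @return a [grid_raster] of mean daily unique-vessel counts.
#' @export
vessel_density <- function(records, grid, months = NULL, fleet = NULL,
                           crossing = c("segment", "containment")) {
  crossing <- match.arg(crossing)
  if (!is.null(fleet)) records <- records[records$fleet %in% fleet, ]
  if (is.null(records$x) || is.null(records$y))
    stop("records must be projected first (see project_vessels)")
  if (nrow(records) == 0L) stop("no vessel records to grid")
  rec_month <- format(records$timestamp, "%Y-%m")
  if (is.null(months)) months <- sort(unique(rec_month))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  monthly <- list()
  for (mo in months) {
    rm_ <- records[rec_month == mo, , drop = FALSE]
    if (nrow(rm_) == 0L) {
      warning("no vessel data in month ", mo, "; month skipped")
      next
    }
    days <- unique(format(rm_$timestamp, "%Y-%m-%d"))
    counts <- matrix(0, nr, nc)
    for (day in days) {
      rd <- rm_[format(rm_$timestamp, "%Y-%m-%d") == day, , drop = FALSE]
      for (vid in unique(rd$vessel_id)) {
        rv <- rd[rd$vessel_id == vid, , drop = FALSE]
        rv <- rv[order(rv$timestamp), , drop = FALSE]
        cells <- cell_index(grid, rv$x, rv$y)
        cells <- cells[!is.na(cells[, 1]), , drop = FALSE]
        if (crossing == "segment" && nrow(rv) > 1) {
          for (s in seq_len(nrow(rv) - 1)) {
            cells <- rbind(cells,
                           segment_cells(grid, rv$x[s], rv$y[s],
                                         rv$x[s + 1], rv$y[s + 1]))
          }
        }
        if (nrow(cells) == 0L) next
        cells <- unique(cells)  # once per vessel-day
        counts[cells] <- counts[cells] + 1
      }
    }
    monthly[[mo]] <- counts / length(days)
  }
  if (length(monthly) == 0L) stop("no months with vessel data")
  mean_v <- Reduce(`+`, monthly) / length(monthly)
  mean_v[is.na(grid$values)] <- NA_real_
  out <- grid
  out$values <- mean_v
  out
}

#' Aggregate a fine raster to a coarser grid by the mean
#'
#' Coarse cells must tile an integer number of fine cells and share the fine
#' grid's origin. Each coarse value is the mean of the covered non-missing
#' fine values (`NA` if all covered cells are missing).
#'
#' @param fine a [grid_raster] (e.g. 1-km long-term velocity).
#' @param factor integer aggregation factor (e.g. 8 for 1 km to 8 km).
#' @return a [grid_raster] with cell size `fine$cell_size * factor`.
#' @export
aggregate_mean <- function(fine, factor = 8L) {
  factor <- as.integer(factor)
  v <- fine$values
  if (nrow(v) %% factor != 0 || ncol(v) %% factor != 0)
    stop("grids misaligned: raster dimensions (", nrow(v), " x ", ncol(v),
         ") are not a multiple of the aggregation factor ", factor)
  nrc <- nrow(v) / factor; ncc <- ncol(v) / factor
  out <- matrix(NA_real_, nrc, ncc)
  for (i in seq_len(nrc)) {
    rows <- ((i - 1) * factor + 1):(i * factor)
    for (j in seq_len(ncc)) {
      block <- v[rows, ((j - 1) * factor + 1):(j * factor)]
      if (!all(is.na(block))) out[i, j] <- mean(block, na.rm = TRUE)
    }
  }
  grid_raster(out, fine$x_origin, fine$y_origin, fine$cell_size * factor,
              fine$crs_tag)
}

check_aligned <- function(...) {
  rs <- list(...)
  ref <- rs[[1]]
  for (r in rs[-1]) {
    if (!isTRUE(all.equal(dim(r$values), dim(ref$values))) ||
        abs(r$cell_size - ref$cell_size) > 1e-9 ||
        abs(r$x_origin - ref$x_origin) > 1e-9 ||
        abs(r$y_origin - ref$y_origin) > 1e-9)
      stop("rasters are not aligned")
  }
  invisible(TRUE)
}

#' Relative probability of encountering a whale (RPEW)
#'
#' `RPEW_i = N_i (1/nu_i) / sum(N_i (1/nu_i))`: encounter probability rises
#' with predicted density and with residence time `1/nu_i` (slow, low-
#' persistence movement keeps whales longer in a cell).
#'
#' @param density_n [grid_raster] of predicted whale density per cell (the
#'   external species-distribution-model output), 8-km grid.
#' @param nu8 [grid_raster] of long-term velocity aggregated to the same
#'   grid (see [aggregate_mean()]); must be positive on valid cells.
#' @return [grid_raster] summing to 1 over valid cells.
#' @export
rpew <- function(density_n, nu8) {
  check_aligned(density_n, nu8)
  N <- density_n$values; nu <- nu8$values
  valid <- !is.na(N) & !is.na(nu)
  if (any(nu[valid] <= 0)) stop("nu must be positive on valid cells")
  w <- matrix(NA_real_, nrow(N), ncol(N))
  w[valid] <- N[valid] / nu[valid]
  tot <- sum(w[valid])
  if (tot <= 0) stop("N / nu is identically zero over valid cells")
  w[valid] <- w[valid] / tot
  out <- density_n
  out$values <- w
  out
}

#' Relative probability of a vessel encountering a whale (RPVEW)
#'
#' Combines three per-cell probability fields — whale occurrence
#' `Pw_i = N_i / sum(N)`, residence time `Pt_i = (1/nu_i) / sum(1/nu)` and
#' vessel traffic `Pv_i = VD_i / sum(VD)` — as
#' `RPVEW_i = Pw_i Pt_i Pv_i / sum(Pw Pt Pv)`.
#'
#' @inheritParams rpew
#' @param vd [grid_raster] of vessel density (one fleet), aligned.
#' @return list of [grid_raster]: `pw`, `pt`, `pv`, `rpvew`, each summing to
#'   1 over valid cells.
#' @export
rpvew <- function(density_n, nu8, vd) {
  check_aligned(density_n, nu8, vd)
  N <- density_n$values; nu <- nu8$values; V <- vd$values
  valid <- !is.na(N) & !is.na(nu) & !is.na(V)
  if (any(nu[valid] <= 0)) stop("nu must be positive on valid cells")
  if (sum(V[valid]) <= 0)
    stop("vessel density is identically zero over valid cells")
  if (sum(N[valid]) <= 0) stop("whale density is identically zero")
  mk <- function(x) {
    m <- matrix(NA_real_, nrow(N), ncol(N))
    m[valid] <- x / sum(x)
    out <- density_n
    out$values <- m
    out
  }
  pw <- mk(N[valid])
  pt <- mk(1 / nu[valid])
  pv <- mk(V[valid])
  prod_w <- pw$values[valid] * pt$values[valid] * pv$values[valid]
  if (sum(prod_w) <= 0)
    stop("whale and vessel fields have disjoint support; RPVEW undefined")
  list(pw = pw, pt = pt, pv = pv, rpvew = mk(prod_w))
}

#' Distribution overlap: Schoener's D and Warren's I
#'
#' Each layer is min-max rescaled to \[0, 1\] over the jointly valid cells
#' and then normalized to sum to 1, giving discrete distributions `p` and
#' `q`; the statistics are `D = 1 - 0.5 sum |p - q|` and
#' `I = 1 - 0.5 sum (sqrt(p) - sqrt(q))^2`, both ranging from 0 (disjoint)
#' to 1 (identical).
#'
#' @param layer_a,layer_b aligned non-negative [grid_raster] layers (e.g.
#'   `N * 1/nu` and vessel density).
#' @return named numeric vector `c(D = , I = )`.
#' @export
overlap_stats <- function(layer_a, layer_b) {
  check_aligned(layer_a, layer_b)
  valid <- !is.na(layer_a$values) & !is.na(layer_b$values)
  a <- layer_a$values[valid]; b <- layer_b$values[valid]
  rescale <- function(x) {
    rng <- range(x)
    if (rng[2] - rng[1] <= 0)
      stop("constant layer: min-max rescale is degenerate")
    (x - rng[1]) / (rng[2] - rng[1])
  }
  p <- rescale(a); p <- p / sum(p)
  q <- rescale(b); q <- q / sum(q)
  c(D = 1 - 0.5 * sum(abs(p - q)),
    I = 1 - 0.5 * sum((sqrt(p) - sqrt(q))^2))
}

#' Export a raster layer as a cell table
#'
#' @param r a [grid_raster].
#' @param path CSV destination.
#' @return invisibly, the exported data frame (`row`, `col`, `x`, `y`,
#'   `value`; missing cells omitted).
#' @export
write_layer_csv <- function(r, path) {
  cc <- cell_centers(r)
  keep <- !is.na(r$values)
  d <- data.frame(row = row(r$values)[keep], col = col(r$values)[keep],
                  x = cc$x[keep], y = cc$y[keep], value = r$values[keep])
  write.csv(d, path, row.names = FALSE)
  invisible(d)
}
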