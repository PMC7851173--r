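#' @importFrom stats aggregate approx coef dnorm median na.omit optim
#'   optimHess qnorm quantile rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

VALID_LOCATION_CLASSES <- c("3", "2", "1", "0", "A", "B")
VALID_FLEETS <- c("industrial_fishery", "artisanal_fishery", "aquaculture",
                  "transport")

#' Argos track container
#'
#' One animal's ordered, time-stamped relocations with Argos quality class
#' and error-ellipse geometry, plus (after [project_track()]) planar
#' coordinates in kilometres.
#'
#' @param animal_id single string.
#' @param data data frame with columns `timestamp` (POSIXct, UTC), `lon`,
#'   `lat` (decimal degrees WGS84), `location_class` (one of 3,2,1,0,A,B),
#'   and optionally `semi_major`, `semi_minor` (metres), `orientation`
#'   (degrees clockwise from north, in \[0, 180)).
#'
#' @return object of class `argos_track` with elements `animal_id`, `data`,
#'   `xy` (n x 2 matrix, km; `NULL` until projected) and `proj` (projection
#'   centre; `NULL` until projected).
#' @export
argos_track <- function(animal_id, data) {
  if (length(animal_id) != 1L) stop("animal_id must be a single string")
  data <- validate_relocations(data)
  if (nrow(data) < 2L)
    stop("track '", animal_id, "' has fewer than 2 relocations")
  structure(list(animal_id = as.character(animal_id), data = data,
                 xy = NULL, proj = NULL),
            class = "argos_track")
}

#' @export
print.argos_track <- function(x, ...) {
  cat("<argos_track> animal ", x$animal_id, ": ", nrow(x$data),
      " relocations, ", format(min(x$data$timestamp)), " .. ",
      format(max(x$data$timestamp)),
      if (!is.null(x$xy)) " [projected]" else "", "\n", sep = "")
  invisible(x)
}

n_locations <- function(track) nrow(track$data)

validate_relocations <- function(d) {
  d <- as.data.frame(d)
  for (col in c("timestamp", "lon", "lat", "location_class"))
    if (is.null(d[[col]])) stop("missing mandatory column: ", col)
  if (!inherits(d$timestamp, "POSIXct"))
    stop("timestamp column must be POSIXct (UTC)")
  bad <- which(is.na(d$lon) | is.na(d$lat) |
               abs(d$lat) > 90 | abs(d$lon) > 180)
  if (length(bad))
    stop("coordinate out of range (lat in [-90,90], lon in [-180,180]) ",
         "at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  d$location_class <- as.character(d$location_class)
  badc <- which(!d$location_class %in% VALID_LOCATION_CLASSES)
  if (length(badc))
    stop("unknown Argos location class '", d$location_class[badc[1]],
         "' at row ", badc[1])
  for (col in c("semi_major", "semi_minor", "orientation"))
    if (is.null(d[[col]])) d[[col]] <- NA_real_
  have <- !is.na(d$semi_major) & !is.na(d$semi_minor)
  if (any(d$semi_minor[have] > d$semi_major[have]))
    stop("ellipse semi_minor exceeds semi_major")
  if (any(d$semi_minor[have] < 0)) stop("negative ellipse axis")
  d$orientation <- ifelse(is.na(d$orientation), NA_real_,
                          d$orientation %% 180)
  # time-sort, drop duplicate timestamps keeping the first occurrence
  d <- d[order(d$timestamp), , drop = FALSE]
  dup <- duplicated(d$timestamp)
  if (any(dup)) {
    message(sum(dup), " duplicate timestamp(s) dropped (kept first)")
    d <- d[!dup, , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

#' Read an Argos-style relocation table
#'
#' One row per relocation; rows are grouped by animal, time-sorted within
#' animal, and duplicate timestamps resolved by keeping the first occurrence.
#' Timestamps must be ISO-8601 and are interpreted as UTC.
#'
#' @param path path to a delimited text file (CSV).
#' @param col_map named list mapping the canonical names `id`, `timestamp`,
#'   `lon`, `lat`, `location_class` and (optionally) `semi_major`,
#'   `semi_minor`, `orientation` to the file's column names.
#' @param sep field separator.
#'
#' @return list of [argos_track] objects, one per animal.
#' @export
read_argos_table <- function(path,
                             col_map = list(id = "id",
                                            timestamp = "timestamp",
                                            lon = "lon", lat = "lat",
                                            location_class = "location_class",
                                            semi_major = "semi_major",
                                            semi_minor = "semi_minor",
                                            orientation = "orientation"),
                             sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  mandatory <- c("id", "timestamp", "lon", "lat", "location_class")
  for (key in mandatory) {
    col <- col_map[[key]]
    if (is.null(col) || !col %in% names(raw))
      stop("missing mandatory column: ", if (is.null(col)) key else col)
  }
  ts <- parse_utc(raw[[col_map$timestamp]])
  if (anyNA(ts))
    stop("unparseable timestamp at line ",
         which(is.na(ts))[1] + 1L, " of ", path)
  d <- data.frame(timestamp = ts,
                  lon = as.numeric(raw[[col_map$lon]]),
                  lat = as.numeric(raw[[col_map$lat]]),
                  location_class = as.character(raw[[col_map$location_class]]),
                  stringsAsFactors = FALSE)
  for (key in c("semi_major", "semi_minor", "orientation")) {
    col <- col_map[[key]]
    d[[key]] <- if (!is.null(col) && col %in% names(raw))
      as.numeric(raw[[col]]) else NA_real_
  }
  ids <- as.character(raw[[col_map$id]])
  tracks <- lapply(unique(ids), function(a)
    argos_track(a, d[ids == a, , drop = FALSE]))
  names(tracks) <- unique(ids)
  tracks
}

parse_utc <- function(x) {
  formats <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
               "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
               "%Y/%m/%d %H:%M:%OS", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  for (f in formats) {
    need <- which(is.na(out))
    if (!length(need)) break
    out[need] <- as.POSIXct(strptime(x[need], f, tz = "UTC"))
  }
  out
}

#' Fill missing error ellipses from per-class donor means
#'
#' Tags from deployments that did not report error-ellipse geometry receive,
#' for every relocation, the arithmetic mean semi-major, semi-minor and
#' orientation of donor relocations of the same Argos location class.
#' Relocations that already carry an ellipse are left unchanged.
#'
#' @param recipients list of [argos_track] lacking ellipse data.
#' @param donors list of [argos_track] with populated ellipse fields.
#'
#' @return `recipients` with ellipse fields filled.
#' @export
impute_ellipses_by_class <- function(recipients, donors) {
  dd <- do.call(rbind, lapply(donors, function(t) t$data))
  dd <- dd[!is.na(dd$semi_major) & !is.na(dd$semi_minor) &
           !is.na(dd$orientation), , drop = FALSE]
  if (nrow(dd) == 0L) stop("donor tracks carry no ellipse data")
  means <- aggregate(dd[c("semi_major", "semi_minor", "orientation")],
                     by = list(location_class = dd$location_class), mean)
  lapply(recipients, function(tr) {
    need <- is.na(tr$data$semi_major) | is.na(tr$data$semi_minor) |
            is.na(tr$data$orientation)
    cls <- tr$data$location_class[need]
    unknown <- setdiff(unique(cls), means$location_class)
    if (length(unknown))
      stop("no donor ellipse data for location class(es): ",
           paste(unknown, collapse = ", "))
    m <- match(cls, means$location_class)
    tr$data$semi_major[need] <- means$semi_major[m]
    tr$data$semi_minor[need] <- means$semi_minor[m]
    tr$data$orientation[need] <- means$orientation[m]
    tr
  })
}

#' Iterative maximum-speed filter
#'
#' Removes relocations implying travel speeds above `vmax` (great-circle
#' distance on the WGS84 ellipsoid over elapsed time). The filter is
#' spike-aware and iterative: while any consecutive pair implies a speed
#' above `vmax`, the interior endpoint of the worst offending leg whose
#' removal most reduces the local speed violation is dropped (ties broken by
#' dropping the later point); the first and last relocations are never
#' removed. The returned track satisfies all consecutive implied speeds
#' <= `vmax`.
#'
#' @param track an [argos_track] (unprojected coordinates are used).
#' @param vmax maximum plausible speed, m/s.
#'
#' @return the filtered [argos_track].
#' @export
speed_filter <- function(track, vmax = 3.0) {
  d <- track$data
  repeat {
    if (nrow(d) < 2L) stop("speed filter reduced track '", track$animal_id,
                           "' to fewer than 2 relocations")
    sp <- implied_speeds(d)
    if (all(sp <= vmax)) break
    worst <- which.max(sp)                      # leg (worst, worst + 1)
    cand <- c(worst, worst + 1L)
    cand <- cand[cand != 1L & cand != nrow(d)]  # endpoints protected
    if (length(cand) == 0L)
      stop("speed filter cannot repair track '", track$animal_id,
           "': terminal relocations imply speed above vmax")
    # score each candidate by the max speed remaining locally after removal
    score <- vapply(cand, function(i) {
      di <- d[-i, , drop = FALSE]
      max(implied_speeds(di)[max(1L, worst - 2L):min(nrow(di) - 1L,
                                                     worst + 1L)])
    }, numeric(1))
    best <- min(score)
    drop <- max(cand[score <= best + 1e-12])    # tie -> later point
    d <- d[-drop, , drop = FALSE]
  }
  track$data <- d
  track$xy <- NULL  # geometry changed; projection must be redone
  track
}

implied_speeds <- function(d) {
  n <- nrow(d)
  dist_m <- geosphere::distGeo(cbind(d$lon[-n], d$lat[-n]),
                               cbind(d$lon[-1], d$lat[-1]))
  dt_s <- as.numeric(difftime(d$timestamp[-1], d$timestamp[-n],
                              units = "secs"))
  dist_m / dt_s
}

#' Truncate a track at a cut-off time
#'
#' Utility for applying an externally determined cut-off (for example 24 h
#' before the onset of migratory movement): keeps relocations at or before
#' `cutoff`.
#'
#' @param track an [argos_track].
#' @param cutoff POSIXct cut-off.
#' @return the truncated [argos_track].
#' @export
truncate_after <- function(track, cutoff) {
  keep <- track$data$timestamp <= cutoff
  if (sum(keep) < 2L) stop("truncation leaves fewer than 2 relocations")
  track$data <- track$data[keep, , drop = FALSE]
  track$xy <- NULL
  track
}

# --- azimuthal equidistant projection on the mean-radius sphere -----------

EARTH_RADIUS_KM <- 6371.0088

aeqd_forward <- function(lon, lat, lon0, lat0) {
  to_rad <- pi / 180
  phi <- lat * to_rad; lam <- lon * to_rad
  phi0 <- lat0 * to_rad; lam0 <- lon0 * to_rad
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- EARTH_RADIUS_KM * k * cos(phi) * sin(lam - lam0)
  y <- EARTH_RADIUS_KM * k *
    (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  cbind(x = x, y = y)
}

aeqd_inverse <- function(x, y, lon0, lat0) {
  to_rad <- pi / 180
  phi0 <- lat0 * to_rad; lam0 <- lon0 * to_rad
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / EARTH_RADIUS_KM
  small <- rho < 1e-12
  sinc <- sin(c_ang); cosc <- cos(c_ang)
  phi <- ifelse(small, phi0,
                asin(pmin(1, pmax(-1, cosc * sin(phi0) +
                                        y * sinc * cos(phi0) / pmax(rho, 1e-300)))))
  lam <- ifelse(small, lam0,
                lam0 + atan2(x * sinc,
                             rho * cos(phi0) * cosc - y * sin(phi0) * sinc))
  cbind(lon = lam / to_rad, lat = phi / to_rad)
}

#' Project a track to planar kilometres
#'
#' Fills the track's `xy` slot with coordinates (km) under an azimuthal
#' equidistant projection centred, by default, on the track's centroid.
#' The planar frame is what the movement model operates in; the inverse
#' projection is available through [unproject_xy()] for map output.
#'
#' @param track an [argos_track].
#' @param center optional `c(lon, lat)` projection centre; defaults to the
#'   track centroid.
#' @return the track with `xy` (km) and `proj` (centre) filled.
#' @export
project_track <- function(track, center = NULL) {
  if (is.null(center))
    center <- c(mean(track$data$lon), mean(track$data$lat))
  xy <- aeqd_forward(track$data$lon, track$data$lat, center[1], center[2])
  if (max(sqrt(rowSums(xy^2))) > 1000)
    warning("track '", track$animal_id,
            "' spans > 1000 km from the projection centre; ",
            "planar distortion may be non-negligible")
  track$xy <- xy
  track$proj <- list(lon0 = center[1], lat0 = center[2])
  track
}

#' Inverse of the track projection
#'
#' @param xy n x 2 matrix of planar coordinates (km).
#' @param proj projection descriptor as stored by [project_track()].
#' @return n x 2 matrix of `lon`, `lat` (degrees).
#' @export
unproject_xy <- function(xy, proj) {
  aeqd_inverse(xy[, 1], xy[, 2], proj$lon0, proj$lat0)
}

#' Read a vessel tracking table
#'
#' @param path CSV with columns `vessel_id`, `fleet`, `timestamp` (ISO-8601,
#'   UTC), `lon`, `lat`.
#' @return data frame of vessel records (one row per fix), time-sorted within
#'   vessel. An empty file yields an empty data frame with a warning.
#' @export
read_vessel_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vessel_id", "fleet", "timestamp", "lon", "lat")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing mandatory column: ", paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("vessel table '", path, "' contains no records")
    return(data.frame(vessel_id = character(), fleet = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      lon = numeric(), lat = numeric()))
  }
  bad <- which(!raw$fleet %in% VALID_FLEETS)
  if (length(bad))
    stop("unknown fleet label '", raw$fleet[bad[1]], "' at line ",
         bad[1] + 1L, " (expected one of: ",
         paste(VALID_FLEETS, collapse = ", "), ")")
  ts <- parse_utc(raw$timestamp)
  if (anyNA(ts))
    stop("unparseable timestamp at line ", which(is.na(ts))[1] + 1L)
  out <- data.frame(vessel_id = as.character(raw$vessel_id),
                    fleet = raw$fleet, timestamp = ts,
                    lon = as.numeric(raw$lon), lat = as.numeric(raw$lat),
                    stringsAsFactors = FALSE)
  out <- out[order(out$vessel_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write tracks / vessel records to CSV
#'
#' Emits the same delimited dialect the readers consume, so generated data
#' round-trips through [read_argos_table()] / [read_vessel_table()].
#'
#' @param tracks an [argos_track] or list of them.
#' @param records vessel record data frame.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_argos_table <- function(tracks, path) {
  if (inherits(tracks, "argos_track")) tracks <- list(tracks)
  rows <- do.call(rbind, lapply(tracks, function(tr)
    cbind(id = tr$animal_id, tr$data)))
  rows$timestamp <- format(rows$timestamp, "%Y-%m-%dT%H:%M:%S")
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_argos_table
#' @export
write_vessel_table <- function(records, path) {
  out <- records[c("vessel_id", "fleet", "timestamp", "lon", "lat")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
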