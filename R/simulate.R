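#' Simulation configuration
#'
#' Bundles everything the synthetic-data generators need. The defaults
#' describe the study conditions the package is tested under: Argos-like
#' irregular sampling (0.5-2.5 h between fixes), movement scales typical of
#' a large foraging baleen whale (sigma about 4.5 km h^-3/2, beta about
#' 2 h^-1, so persistence 1.5 h and long-term velocity about 0.8 m/s), a
#' moderate covariate effect on velocity variability (slope 0.6 on the log
#' scale per standardized unit), and an Argos quality-class mixture dominated
#' by the poorer classes.
#'
#' @param seed integer; fully determines all generator output.
#' @param n_locations relocations per track.
#' @param dt_range range (hours) of the uniformly drawn intervals.
#' @param params true [movement_params].
#' @param ellipse_mix data frame with columns `class`, `prob`, `semi_major`,
#'   `semi_minor` (metres) giving the Argos class mixture.
#' @param extent_km half-width of the square study area (centred on 0).
#' @param cell_km covariate raster cell size (km).
#' @param center_lonlat geographic centre used to express synthetic planar
#'   coordinates as lon/lat.
#' @param start_time POSIXct timestamp of the first fix.
#' @param n_vessels,vessel_days,fleet,vessel_speed_kmh,corridor_frac vessel
#'   generator settings; `corridor_frac` of vessels shuttle along a fixed
#'   east-west corridor so the density grid has known high-traffic cells.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_locations = 500L,
                       dt_range = c(0.5, 2.5),
                       params = movement_params(
                         A0 = 1.5,
                         A = c(log_dahcc = 0.6, sst = 0,
                               thermal_gradient = 0),
                         eps1 = 0.2,
                         B0 = 0.7,
                         B = numeric(),
                         beta_random = FALSE),
                       ellipse_mix = data.frame(
                         class = c("3", "2", "1", "0", "A", "B"),
                         prob = c(0.08, 0.12, 0.15, 0.20, 0.20, 0.25),
                         semi_major = c(250, 500, 1200, 3000, 2500, 5000),
                         semi_minor = c(150, 300, 600, 1500, 800, 1500),
                         stringsAsFactors = FALSE),
                       extent_km = 200,
                       cell_km = 2,
                       center_lonlat = c(-73.5, -43.0),
                       start_time = as.POSIXct("2019-02-01 00:00:00",
                                               tz = "UTC"),
                       n_vessels = 12L,
                       vessel_days = 5L,
                       fleet = "aquaculture",
                       vessel_speed_kmh = 12,
                       corridor_frac = 0.5) {
  if (any(diff(dt_range) <= 0) || any(dt_range <= 0))
    stop("dt_range must be positive and increasing")
  structure(list(seed = as.integer(seed), n_locations = n_locations,
                 dt_range = dt_range, params = params,
                 ellipse_mix = ellipse_mix, extent_km = extent_km,
                 cell_km = cell_km, center_lonlat = center_lonlat,
                 start_time = start_time, n_vessels = n_vessels,
                 vessel_days = vessel_days, fleet = fleet,
                 vessel_speed_kmh = vessel_speed_kmh,
                 corridor_frac = corridor_frac),
            class = "sim_config")
}

sim_grid <- function(config, cell = config$cell_km) {
  n <- floor(2 * config$extent_km / cell)
  grid_raster(matrix(0, n, n), -config$extent_km, -config$extent_km, cell)
}

#' Synthetic covariate stack with known ground truth
#'
#' Builds a smooth chlorophyll field with Gaussian-bump high-concentration
#' patches (from which the log-distance DAHCC layer is derived), an SST
#' field combining a meridional ramp with large-scale undulation and mild
#' noise, and the thermal-gradient layer computed from the SST. Global
#' per-layer standardization constants are recorded in the stack; the truth
#' (patch centres, ramp slope) is attached as attribute `truth`.
#'
#' @param config a [sim_config].
#' @param sst_noise_sd sd of cell-level SST noise (deg C); 0 gives the
#'   analytic ramp exactly.
#' @return a [covariate_stack].
#' @export
make_covariate_stack <- function(config = sim_config(), sst_noise_sd = 0.05) {
  set.seed(config$seed + 101L)
  g <- sim_grid(config)
  cc <- cell_centers(g)
  patches <- rbind(c(-0.45, 0.35), c(0.5, -0.4)) * config$extent_km
  chl <- 0.3 + 0 * cc$x
  for (k in seq_len(nrow(patches))) {
    d2 <- (cc$x - patches[k, 1])^2 + (cc$y - patches[k, 2])^2
    chl <- chl + 4 * exp(-d2 / (2 * 30^2))
  }
  chl_r <- grid_raster(chl, g$x_origin, g$y_origin, g$cell_size)
  dahcc <- build_dahcc(chl_r, percentile = 95)

  ramp <- 0.02  # deg C per km, meridional
  sst_v <- 14 - ramp * cc$y + 0.8 * sin(cc$x / 45) * cos(cc$y / 60) +
    (if (sst_noise_sd > 0) matrix(rnorm(length(cc$x), 0, sst_noise_sd),
                                  nrow(cc$x)) else 0)
  sst <- grid_raster(sst_v, g$x_origin, g$y_origin, g$cell_size)
  grad <- thermal_gradient(sst, median_window = 3)

  std <- data.frame(
    covariate = covariate_names(),
    mean = c(mean(dahcc$values, na.rm = TRUE), mean(sst$values, na.rm = TRUE),
             mean(grad$values, na.rm = TRUE)),
    sd = c(sd(dahcc$values, na.rm = TRUE), sd(sst$values, na.rm = TRUE),
           sd(grad$values, na.rm = TRUE)),
    stringsAsFactors = FALSE)
  out <- covariate_stack(dahcc, sst, grad, standardization = std)
  attr(out, "truth") <- list(patch_centers = patches, sst_ramp = ramp,
                             chla = chl_r)
  out
}

# standardized covariate row at a planar position, using the stack's global
# constants (missing -> 0, the standardized mean)
stack_covariates_at <- function(stack, x, y) {
  raw <- vapply(covariate_names(), function(cv)
    raster_value_at(stack[[cv]][[1]], x, y), numeric(1))
  std <- stack$standardization
  z <- (raw - std$mean) / std$sd
  z[is.na(z)] <- 0
  z
}

#' Simulate a covariate-driven CTCRW track with Argos ellipse error
#'
#' Draws irregular time steps, and at each step extracts the (globally
#' standardized) covariates at the current true position, draws the
#' interval's `log sigma_t` (and `log beta_t` when beta is covariate-driven)
#' from their normal laws, propagates position and velocity by the exact
#' OU-integrated transition, and finally corrupts each true position with
#' bivariate normal error drawn from an Argos-class error-ellipse mixture.
#' Positions leaving the study square are reflected back (with one warning).
#'
#' @param config a [sim_config].
#' @param stack a [covariate_stack] from [make_covariate_stack()].
#' @param start_xy planar start position (km); the default sits near the
#'   first high-chlorophyll patch, emulating tag deployment on foraging
#'   grounds (where the covariate signal whales respond to actually varies).
#' @return list with `truth` (data frame: time, true states, latent
#'   parameters and the standardized covariates used) and `track` (a
#'   projected [argos_track] of the noisy observations).
#' @export
simulate_track <- function(config = sim_config(), stack = NULL,
                           start_xy = c(-60, 40)) {
  if (is.null(stack)) stack <- make_covariate_stack(config)
  set.seed(config$seed + 202L)
  n <- config$n_locations
  p <- config$params
  dt <- runif(n - 1, config$dt_range[1], config$dt_range[2])
  X <- matrix(0, n, length(covariate_names()),
              dimnames = list(NULL, covariate_names()))
  x <- matrix(0, n, 2)  # true positions
  v <- matrix(0, n, 2)  # true velocities
  ls <- numeric(n - 1); lb <- numeric(n - 1)
  x[1, ] <- start_xy
  X[1, ] <- stack_covariates_at(stack, x[1, 1], x[1, 2])
  act <- intersect(names(p$A), colnames(X))
  eta1_0 <- p$A0 + sum(p$A[act] * X[1, act])
  beta0 <- exp(p$B0)
  v[1, ] <- rnorm(2, 0, exp(eta1_0) / sqrt(2 * beta0))
  bounced <- FALSE
  lim <- config$extent_km
  for (t in seq_len(n - 1)) {
    z <- stack_covariates_at(stack, x[t, 1], x[t, 2])
    X[t, ] <- z
    eta1 <- p$A0 + sum(p$A[act] * z)
    ls[t] <- rnorm(1, eta1, p$eps1)
    lb[t] <- if (p$beta_fixed_flag) p$beta_fixed_value
             else if (p$beta_random) {
               actb <- intersect(names(p$B), colnames(X))
               rnorm(1, p$B0 + sum(p$B[actb] * z), p$eps2)
             } else p$B0
    tr <- ctcrw_transition(exp(lb[t]), exp(ls[t]), dt[t])
    Tb <- tr$T[1:2, 1:2]; Qb <- tr$Q[1:2, 1:2]
    ch <- chol(Qb + diag(1e-12, 2))
    for (k in 1:2) {
      m <- Tb %*% c(x[t, k], v[t, k])
      s <- m + t(ch) %*% rnorm(2)
      x[t + 1, k] <- s[1]; v[t + 1, k] <- s[2]
    }
    # reflective boundary keeps long simulations on the raster
    for (k in 1:2) {
      if (abs(x[t + 1, k]) > lim) {
        x[t + 1, k] <- sign(x[t + 1, k]) * (2 * lim - abs(x[t + 1, k]))
        v[t + 1, k] <- -v[t + 1, k]
        bounced <- TRUE
      }
    }
  }
  X[n, ] <- stack_covariates_at(stack, x[n, 1], x[n, 2])
  if (bounced)
    warning("simulated track hit the study-area boundary; reflected")

  # Argos-class ellipse noise
  mix <- config$ellipse_mix
  cls <- sample(mix$class, n, replace = TRUE, prob = mix$prob)
  mi <- match(cls, mix$class)
  M <- mix$semi_major[mi]; m_ <- mix$semi_minor[mi]
  orient <- runif(n, 0, 180)
  ec <- ellipse_to_covariance(M, m_, orient)
  obs <- x
  for (i in seq_len(n)) {
    S <- matrix(c(ec$var_x[i], ec$cov_xy[i], ec$cov_xy[i], ec$var_y[i]), 2)
    if (any(diag(S) > 0))
      obs[i, ] <- x[i, ] + t(chol(S + diag(1e-15, 2))) %*% rnorm(2)
  }

  times <- config$start_time + cumsum(c(0, dt)) * 3600
  lonlat <- aeqd_inverse(obs[, 1], obs[, 2],
                         config$center_lonlat[1], config$center_lonlat[2])
  track <- argos_track(paste0("sim", config$seed), data.frame(
    timestamp = times, lon = lonlat[, 1], lat = lonlat[, 2],
    location_class = cls, semi_major = M, semi_minor = m_,
    orientation = orient, stringsAsFactors = FALSE))
  track$xy <- obs
  track$proj <- list(lon0 = config$center_lonlat[1],
                     lat0 = config$center_lonlat[2])
  truth <- data.frame(timestamp = times, x = x[, 1], y = x[, 2],
                      vx = v[, 1], vy = v[, 2],
                      log_sigma = c(NA, ls), log_beta = c(NA, lb))
  truth <- cbind(truth, X)
  list(truth = truth, track = track)
}

#' Simulate vessel tracking records
#'
#' Per-vessel hourly fixes over `vessel_days` days. A fraction of vessels
#' shuttle back and forth along a fixed east-west corridor (so corridor
#' cells have known maximal traffic); the rest perform correlated random
#' walks with persistent headings.
#'
#' @param config a [sim_config].
#' @return projected vessel record data frame (`vessel_id`, `fleet`,
#'   `timestamp`, `lon`, `lat`, `x`, `y`).
#' @export
simulate_vessels <- function(config = sim_config()) {
  set.seed(config$seed + 303L)
  lim <- config$extent_km * 0.9
  speed <- config$vessel_speed_kmh
  n_corr <- round(config$n_vessels * config$corridor_frac)
  out <- list()
  for (vi in seq_len(config$n_vessels)) {
    corridor <- vi <= n_corr
    pos <- matrix(NA_real_, config$vessel_days * 24, 2)
    if (corridor) {
      y0 <- 0.15 * lim  # shared corridor latitude
      x0 <- runif(1, -lim, lim)
      dir <- sample(c(-1, 1), 1)
      for (h in seq_len(nrow(pos))) {
        x0 <- x0 + dir * speed
        if (abs(x0) > lim) { dir <- -dir; x0 <- sign(x0) * (2 * lim - abs(x0)) }
        pos[h, ] <- c(x0, y0 + rnorm(1, 0, 1))
      }
    } else {
      xy <- runif(2, -lim, lim)
      heading <- runif(1, 0, 2 * pi)
      for (h in seq_len(nrow(pos))) {
        heading <- heading + rnorm(1, 0, 0.4)
        step <- speed * exp(rnorm(1, 0, 0.2))
        xy <- xy + step * c(cos(heading), sin(heading))
        xy <- pmin(pmax(xy, -lim), lim)
        pos[h, ] <- xy
      }
    }
    times <- config$start_time + (seq_len(nrow(pos)) - 1) * 3600
    lonlat <- aeqd_inverse(pos[, 1], pos[, 2], config$center_lonlat[1],
                           config$center_lonlat[2])
    out[[vi]] <- data.frame(vessel_id = sprintf("V%03d", vi),
                            fleet = config$fleet, timestamp = times,
                            lon = lonlat[, 1], lat = lonlat[, 2],
                            x = pos[, 1], y = pos[, 2],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Synthetic whale-density surface
#'
#' A smooth positive density field (Gaussian aggregation areas over a low
#' background) on a coarse grid, standing in for the external species-
#' distribution-model output that the risk layers take as input. Clearly
#' synthetic: no observation process is modelled.
#'
#' @param config a [sim_config].
#' @param cell_km coarse cell size (default 8 km, the risk-grid resolution).
#' @return a [grid_raster] of expected whales per cell.
#' @export
make_density_raster <- function(config = sim_config(), cell_km = 8) {
  g <- sim_grid(config, cell = cell_km)
  cc <- cell_centers(g)
  centers <- rbind(c(-0.4, 0.3), c(0.3, -0.2)) * config$extent_km
  dens <- 0.02 + 0 * cc$x
  for (k in seq_len(nrow(centers))) {
    d2 <- (cc$x - centers[k, 1])^2 + (cc$y - centers[k, 2])^2
    dens <- dens + 0.6 * exp(-d2 / (2 * 35^2))
  }
  g$values <- dens
  g
}
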