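#' Long-term velocity of the CTCRW
#'
#' Expected speed under the stationary velocity distribution,
#' `nu = sqrt(pi) * sigma / (2 * sqrt(beta))` (km/h): the stationary velocity
#' components are independent N(0, sigma^2/(2 beta)), so speed is Rayleigh
#' with scale `sigma / sqrt(2 beta)` and mean `nu`. Higher `nu` marks more
#' transit-like movement; lower `nu` marks area-restricted search.
#'
#' @param sigma velocity variability (km h^-3/2); vectorized.
#' @param beta velocity autocorrelation (1/h); vectorized.
#' @return long-term velocity (km/h).
#' @export
long_term_velocity <- function(sigma, beta) {
  if (any(sigma <= 0) || any(beta <= 0))
    stop("sigma and beta must be positive")
  sqrt(pi) * sigma / (2 * sqrt(beta))
}

#' Per-relocation behavioural series from a fit
#'
#' @param fitted a `ctcrw_fit`.
#' @param animal_id optional id override.
#' @return data frame with one row per relocation carrying `sigma_t`,
#'   `beta_t`, persistence `p_t = 3 / beta_t` (hours), long-term velocity
#'   `nu_t` (km/h), and an empty `quadrant` (filled by [classify_states()]).
#'   The first relocation has no incoming interval and carries `NA`s.
#' @export
behavior_series <- function(fitted, animal_id = fitted$animal_id) {
  lt <- fitted$latent
  data.frame(animal_id = animal_id,
             sigma_t = lt$sigma, beta_t = lt$beta,
             p_t = 3 / lt$beta,
             nu_t = sqrt(pi) * lt$sigma / (2 * sqrt(lt$beta)),
             quadrant = NA_character_,
             stringsAsFactors = FALSE)
}

#' Post-hoc four-quadrant behavioural states
#'
#' Pools `sigma_t` and persistence `p_t` across all relocations of all
#' individuals, computes the two pooled medians, and labels each relocation
#' by its quadrant: both at or below their medians is area-restricted search
#' (`"ARS"`), both above is `"transit"`, and the two mixed combinations are
#' `"low_sigma_high_p"` and `"high_sigma_low_p"`. Values exactly equal to a
#' median count as below it (deterministic tie rule).
#'
#' @param series one `behavior_series` data frame, or a list of them (one
#'   per individual), or a pre-bound data frame.
#' @return the row-bound series with `quadrant` filled; the pooled medians
#'   are attached as attribute `medians`.
#' @export
classify_states <- function(series) {
  if (is.list(series) && !is.data.frame(series))
    series <- do.call(rbind, series)
  ok <- !is.na(series$sigma_t) & !is.na(series$p_t)
  if (!any(ok)) stop("no relocations with movement parameters to classify")
  med_s <- median(series$sigma_t[ok])
  med_p <- median(series$p_t[ok])
  low_s <- series$sigma_t <= med_s
  low_p <- series$p_t <= med_p
  series$quadrant <- ifelse(!ok, NA_character_,
                     ifelse(low_s & low_p, "ARS",
                     ifelse(!low_s & !low_p, "transit",
                     ifelse(low_s, "low_sigma_high_p", "high_sigma_low_p"))))
  attr(series, "medians") <- c(sigma = med_s, p = med_p)
  series
}

#' Predicted response of long-term velocity to one covariate
#'
#' Varies the named covariate over a grid of standardized values holding all
#' other covariates at 0 (their standardized mean), computes
#' `sigma = exp(A0 + A x)` and `beta = exp(B0 + B x)` (or the scalar/fixed
#' beta) and returns the long-term velocity curve.
#'
#' @param fitted a `ctcrw_fit`.
#' @param covariate name of a fitted covariate.
#' @param grid standardized covariate values.
#' @return data frame with the grid, `sigma`, `beta` and `nu`.
#' @export
prediction_curve <- function(fitted, covariate,
                             grid = seq(-2, 2, length.out = 101)) {
  p <- fitted$params
  if (length(p$A) && !covariate %in% names(p$A))
    stop("unknown covariate: ", covariate)
  if (!length(p$A)) stop("fit has no covariates")
  a <- p$A[covariate]
  b <- if (p$beta_random && covariate %in% names(p$B)) p$B[covariate] else 0
  sigma <- exp(p$A0 + a * grid)
  beta <- exp(p$B0 + b * grid)
  data.frame(x = grid, sigma = sigma, beta = beta,
             nu = long_term_velocity(sigma, beta))
}

#' Spatial prediction of long-term velocity
#'
#' Evaluates the fitted covariate response on every cell of a prediction
#' grid: covariates are extracted per cell, standardized with the fit's
#' training constants, and `nu_i = sqrt(pi) sigma_i / (2 sqrt(beta_i))`
#' computed from the predicted medians `sigma_i = exp(A0 + A x_i)`,
#' `beta_i = exp(B0 + B x_i)`. Cells with missing covariates use 0 (the
#' standardized mean); land (all-covariate `NA`) cells stay `NA`.
#'
#' @param fitted a `ctcrw_fit` carrying standardization constants (i.e.
#'   fitted from a covariate stack).
#' @param stack the [covariate_stack] to predict from.
#' @param cell_size prediction cell size (km); the grid spans the DAHCC
#'   layer's extent.
#' @param timestamp time used to select dated layers (defaults to the first
#'   available layer).
#' @return a [grid_raster] of predicted `nu` (km/h).
#' @export
predict_nu_raster <- function(fitted, stack, cell_size = 1,
                              timestamp = NULL) {
  if (is.null(fitted$stats))
    stop("fit carries no standardization constants; refit from a stack")
  if (!length(fitted$params$A)) stop("fit has no covariates")
  base <- stack$log_dahcc[[1]]
  nx <- floor(ncol(base$values) * base$cell_size / cell_size)
  ny <- floor(nrow(base$values) * base$cell_size / cell_size)
  out <- grid_raster(matrix(NA_real_, ny, nx), base$x_origin, base$y_origin,
                     cell_size, base$crs_tag)
  cc <- cell_centers(out)
  if (is.null(timestamp)) timestamp <- Sys.time()
  raw <- sapply(covariate_names(), function(cv) {
    layer <- stack_layer(stack, cv, timestamp)
    raster_value_at(layer, as.vector(cc$x), as.vector(cc$y))
  })
  land <- rowSums(!is.na(raw)) == 0
  m <- match(colnames(raw), fitted$stats$covariate)
  Z <- sweep(sweep(raw, 2, fitted$stats$mean[m], "-"), 2,
             fitted$stats$sd[m], "/")
  Z[is.na(Z)] <- 0
  keep <- intersect(names(fitted$params$A), colnames(Z))
  eta_s <- fitted$params$A0 +
    as.numeric(Z[, keep, drop = FALSE] %*% fitted$params$A[keep])
  eta_b <- if (fitted$params$beta_random) {
    keepb <- intersect(names(fitted$params$B), colnames(Z))
    fitted$params$B0 +
      as.numeric(Z[, keepb, drop = FALSE] %*% fitted$params$B[keepb])
  } else rep(fitted$params$B0, nrow(Z))
  nu <- long_term_velocity(exp(eta_s), exp(eta_b))
  nu[land] <- NA_real_
  out$values <- matrix(nu, ny, nx)
  out
}

#' Average long-term-velocity rasters across individuals
#'
#' Cell-wise arithmetic mean over individuals whose tracks carry more than
#' `min_locations` relocations (predictions from shorter tracks are
#' unstable and are excluded).
#'
#' @param rasters list of aligned [grid_raster] (one per individual).
#' @param locations_per_individual integer vector of track lengths, parallel
#'   to `rasters`.
#' @param min_locations exclusive threshold: an individual qualifies with
#'   strictly more than this many locations.
#' @return a [grid_raster] with the cross-individual mean.
#' @export
average_nu_rasters <- function(rasters, locations_per_individual,
                               min_locations = 200) {
  stopifnot(length(rasters) == length(locations_per_individual))
  keep <- locations_per_individual > min_locations
  if (!any(keep))
    stop("no individual has more than ", min_locations, " locations")
  rs <- rasters[keep]
  dims <- vapply(rs, function(r) dim(r$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("rasters are not aligned")
  stackv <- simplify2array(lapply(rs, function(r) r$values))
  mean_v <- apply(stackv, c(1, 2), function(z)
    if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
  out <- rs[[1]]
  out$values <- mean_v
  out
}
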