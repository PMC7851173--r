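#' Argos error ellipse to observation covariance
#'
#' Converts the per-fix Argos error ellipse (semi-major axis M, semi-minor
#' axis m, orientation c clockwise from north) to the bivariate normal
#' observation covariance of the planar (east, north) coordinates:
#' `var_x = (M^2 sin^2 c + m^2 cos^2 c)/2`,
#' `var_y = (M^2 cos^2 c + m^2 sin^2 c)/2`,
#' `cov_xy = ((M^2 - m^2)/2) sin c cos c`,
#' i.e. standard deviations M/sqrt(2) and m/sqrt(2) along the ellipse axes.
#'
#' @param semi_major,semi_minor ellipse axes in metres.
#' @param orientation degrees clockwise from north.
#' @return data frame with columns `var_x`, `var_y`, `cov_xy` in km^2.
#' @export
ellipse_to_covariance <- function(semi_major, semi_minor, orientation) {
  if (any(semi_minor > semi_major, na.rm = TRUE))
    stop("semi_minor exceeds semi_major")
  if (any(semi_minor < 0, na.rm = TRUE)) stop("negative ellipse axis")
  c_rad <- orientation * pi / 180
  M2 <- (semi_major / 1000)^2   # m -> km
  m2 <- (semi_minor / 1000)^2
  s <- sin(c_rad); co <- cos(c_rad)
  data.frame(var_x = (M2 * s^2 + m2 * co^2) / 2,
             var_y = (M2 * co^2 + m2 * s^2) / 2,
             cov_xy = ((M2 - m2) / 2) * s * co)
}

#' CTCRW transition law over one interval
#'
#' The movement process is an integrated Ornstein-Uhlenbeck velocity:
#' `dv = -beta v dt + sigma dW`, with position the time integral of `v`.
#' For one coordinate with state `(x, v)` and time step `dt` this returns the
#' exact discrete transition matrix and process covariance; the full state
#' `(x, vx, y, vy)` is two independent copies.
#'
#' @param beta velocity autocorrelation parameter (1/h); larger values mean
#'   faster decorrelation (persistence `3/beta` hours).
#' @param sigma velocity variability parameter (km h^-3/2).
#' @param dt interval length (hours).
#' @return list with `T` (4 x 4 transition matrix) and `Q` (4 x 4 process
#'   covariance) for the state `(x, vx, y, vy)`.
#' @export
ctcrw_transition <- function(beta, sigma, dt) {
  if (any(c(beta, sigma, dt) <= 0)) stop("beta, sigma, dt must be positive")
  u <- beta * dt
  e <- exp(-u)
  om <- -expm1(-u)   # 1 - e, cancellation-free
  Tb <- matrix(c(1, om / beta,
                 0, e), 2, 2, byrow = TRUE)
  s2 <- sigma^2
  # position variance involves a triple cancellation that destroys double
  # precision for small beta*dt; switch to its series there
  q11 <- if (u < 0.01) {
    s2 * dt^3 * (1 / 3 - u / 4 + 7 * u^2 / 60)
  } else {
    (s2 / beta^2) * (dt - 2 * om / beta - expm1(-2 * u) / (2 * beta))
  }
  q12 <- (s2 / (2 * beta^2)) * om^2
  q22 <- -s2 * expm1(-2 * u) / (2 * beta)
  Qb <- matrix(c(q11, q12, q12, q22), 2, 2)
  Z <- matrix(0, 2, 2)
  list(T = rbind(cbind(Tb, Z), cbind(Z, Tb)),
       Q = rbind(cbind(Qb, Z), cbind(Z, Qb)))
}

# observation matrix: picks (x, y) out of (x, vx, y, vy)
OBS_H <- matrix(c(1, 0, 0, 0,
                  0, 0, 1, 0), 2, 4, byrow = TRUE)

#' Diffuse initial position variance (km^2) used by the filter and the
#' fitted model.
#' @keywords internal
POS_PRIOR_VAR <- 1e6

obs_cov_matrix <- function(obs_cov, t) {
  matrix(c(obs_cov$var_x[t], obs_cov$cov_xy[t],
           obs_cov$cov_xy[t], obs_cov$var_y[t]), 2, 2)
}

#' Kalman filter for the CTCRW state-space model
#'
#' Runs the exact linear-Gaussian Kalman recursion for a track with
#' per-interval `(sigma_t, beta_t)` and per-relocation Argos ellipse
#' observation covariances, returning the exact marginal log-likelihood of
#' the observed positions and the filtered/predicted moments needed for
#' smoothing. The initial state is diffuse in position (variance
#' `POS_PRIOR_VAR`, centred on the first observation) and stationary in
#' velocity (variance `sigma_1^2 / (2 beta_1)`).
#'
#' @param obs n x 2 matrix of observed planar positions (km).
#' @param dt vector of n-1 interval lengths (hours), strictly positive.
#' @param sigma,beta vectors of n-1 per-interval parameters.
#' @param obs_cov data frame (`var_x`, `var_y`, `cov_xy`, km^2) with n rows.
#' @return list with `loglik` and the filter history (`at`, `Pt` predicted;
#'   `att`, `Ptt` filtered; `Tmats` transitions).
#' @keywords internal
kalman_filter <- function(obs, dt, sigma, beta, obs_cov) {
  n <- nrow(obs)
  stopifnot(length(dt) == n - 1, length(sigma) == n - 1,
            length(beta) == n - 1, nrow(obs_cov) == n)
  if (any(dt <= 0)) stop("time steps must be strictly positive")
  at <- matrix(0, 4, n); Pt <- array(0, c(4, 4, n))
  att <- matrix(0, 4, n); Ptt <- array(0, c(4, 4, n))
  Tmats <- array(0, c(4, 4, n))
  vel_var1 <- sigma[1]^2 / (2 * beta[1])
  a <- c(obs[1, 1], 0, obs[1, 2], 0)
  P <- diag(c(POS_PRIOR_VAR, vel_var1, POS_PRIOR_VAR, vel_var1))
  loglik <- 0
  for (t in seq_len(n)) {
    at[, t] <- a; Pt[, , t] <- P
    # update with observation t
    R <- obs_cov_matrix(obs_cov, t)
    v <- obs[t, ] - OBS_H %*% a
    S <- OBS_H %*% P %*% t(OBS_H) + R
    ch <- tryCatch(chol(S), error = function(e)
      stop("innovation covariance not positive definite at step ", t))
    loglik <- loglik - 0.5 * (2 * log(2 * pi) + 2 * sum(log(diag(ch))) +
                              sum(backsolve(ch, v, transpose = TRUE)^2))
    K <- P %*% t(OBS_H) %*% chol2inv(ch)
    a <- a + K %*% v
    P <- P - K %*% OBS_H %*% P
    P <- (P + t(P)) / 2
    att[, t] <- a; Ptt[, , t] <- P
    # predict to t + 1
    if (t < n) {
      tr <- ctcrw_transition(beta[t], sigma[t], dt[t])
      Tmats[, , t + 1] <- tr$T
      a <- tr$T %*% a
      P <- tr$T %*% P %*% t(tr$T) + tr$Q
    }
  }
  list(loglik = as.numeric(loglik), at = at, Pt = Pt, att = att, Ptt = Ptt,
       Tmats = Tmats)
}

#' Exact CTCRW log-likelihood of an observed track
#'
#' @param track a projected [argos_track] (see [project_track()]), or an
#'   n x 2 matrix of planar positions (km) if `dt` is supplied.
#' @param sigma,beta per-interval parameter vectors (length n-1), or scalars
#'   (recycled).
#' @param obs_cov per-relocation observation covariances (`var_x`, `var_y`,
#'   `cov_xy` in km^2); by default derived from the track's error ellipses.
#' @param dt interval lengths in hours (required when `track` is a matrix).
#' @return the exact Gaussian log-likelihood (a single number).
#' @export
kalman_loglik <- function(track, sigma, beta, obs_cov = NULL, dt = NULL) {
  g <- as_ssm_inputs(track, obs_cov, dt)
  m <- nrow(g$obs) - 1
  kalman_filter(g$obs, g$dt, rep_len(sigma, m), rep_len(beta, m),
                g$obs_cov)$loglik
}

as_ssm_inputs <- function(track, obs_cov = NULL, dt = NULL) {
  if (inherits(track, "argos_track")) {
    if (is.null(track$xy))
      stop("track must be projected first (see project_track)")
    obs <- track$xy
    dt <- as.numeric(difftime(track$data$timestamp[-1],
                              track$data$timestamp[-nrow(track$data)],
                              units = "hours"))
    if (is.null(obs_cov))
      obs_cov <- ellipse_to_covariance(track$data$semi_major,
                                       track$data$semi_minor,
                                       track$data$orientation)
  } else {
    obs <- as.matrix(track)
    if (is.null(dt)) stop("dt required when track is a coordinate matrix")
    if (is.null(obs_cov)) stop("obs_cov required for coordinate matrices")
  }
  if (anyNA(obs_cov)) stop("missing observation covariances")
  list(obs = obs, dt = dt, obs_cov = obs_cov)
}

#' Rauch-Tung-Striebel smoother
#'
#' Backward pass over a [kalman_filter()] history, yielding the smoothed
#' state means and covariances at every observation time.
#'
#' @param kf result of [kalman_filter()].
#' @return list with `mean` (4 x n) and `var` (4 x 4 x n).
#' @keywords internal
rts_smooth <- function(kf) {
  n <- ncol(kf$at)
  sm <- kf$att; sv <- kf$Ptt
  for (t in (n - 1):1) {
    Tn <- kf$Tmats[, , t + 1]
    Pp <- kf$Pt[, , t + 1]
    J <- kf$Ptt[, , t] %*% t(Tn) %*% solve(Pp)
    sm[, t] <- kf$att[, t] + J %*% (sm[, t + 1] - kf$at[, t + 1])
    sv[, , t] <- kf$Ptt[, , t] + J %*% (sv[, , t + 1] - Pp) %*% t(J)
    sv[, , t] <- (sv[, , t] + t(sv[, , t])) / 2
  }
  list(mean = sm, var = sv)
}

#' Constant-parameter CTCRW fit (stage 1)
#'
#' Maximizes the exact Kalman likelihood over scalar `(log sigma, log beta)`
#' and smooths the states; this is the plain CTCRW without behavioural
#' variation, used to obtain estimated true locations at which covariates
#' are then extracted.
#'
#' @inheritParams kalman_loglik
#' @param init optional `c(log_sigma, log_beta)` starting values.
#' @return list with `log_sigma`, `log_beta`, `loglik`, `convergence`, and
#'   `states` (data frame of smoothed `x`, `vx`, `y`, `vy` and their standard
#'   errors).
#' @export
fit_ctcrw_constant <- function(track, obs_cov = NULL, dt = NULL,
                               init = NULL) {
  g <- as_ssm_inputs(track, obs_cov, dt)
  n <- nrow(g$obs); m <- n - 1
  if (is.null(init)) {
    # moment-based start: empirical speeds give the velocity scale
    steps <- sqrt(diff(g$obs[, 1])^2 + diff(g$obs[, 2])^2)
    spd <- mean(steps / g$dt)
    init <- c(log(max(spd, 0.1)), 0)
  }
  nll <- function(par) {
    # extreme trial values can make the innovation covariance numerically
    # non-PD; treat them as very unlikely rather than aborting
    tryCatch(
      -kalman_filter(g$obs, g$dt, rep(exp(par[1]), m), rep(exp(par[2]), m),
                     g$obs_cov)$loglik,
      error = function(e) 1e10)
  }
  opt <- optim(init, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  kf <- kalman_filter(g$obs, g$dt, rep(exp(opt$par[1]), m),
                      rep(exp(opt$par[2]), m), g$obs_cov)
  sm <- rts_smooth(kf)
  states <- data.frame(x = sm$mean[1, ], vx = sm$mean[2, ],
                       y = sm$mean[3, ], vy = sm$mean[4, ],
                       se_x = sqrt(sm$var[1, 1, ]),
                       se_vx = sqrt(sm$var[2, 2, ]),
                       se_y = sqrt(sm$var[3, 3, ]),
                       se_vy = sqrt(sm$var[4, 4, ]))
  list(log_sigma = opt$par[1], log_beta = opt$par[2],
       loglik = -opt$value, convergence = opt$convergence, states = states)
}

#' Movement-parameter set for the covariate-driven CTCRW
#'
#' @param A0 intercept of the linear predictor of `log sigma_t`.
#' @param A slope vector (one per covariate) on `log sigma_t`.
#' @param eps1 standard deviation of `log sigma_t` about its predictor.
#' @param B0 intercept of the predictor of `log beta_t` (or the scalar
#'   `log beta` when beta is not covariate-driven).
#' @param B slope vector on `log beta_t` (empty when beta is scalar/fixed).
#' @param eps2 standard deviation of `log beta_t`; fixed at 0.01 (estimating
#'   it is ill-conditioned, so it is pinned at a small value).
#' @param beta_random is `log beta_t` a covariate-driven random variable?
#' @param beta_fixed_flag is `log beta` pinned at `beta_fixed_value`?
#' @param beta_fixed_value pinned value of `log beta` (log scale; 4 marks
#'   essentially uncorrelated movement, persistence `3/e^4` = 0.05 h).
#' @return a `movement_params` list.
#' @export
movement_params <- function(A0, A = numeric(), eps1 = 0.1,
                            B0 = 0, B = numeric(), eps2 = 0.01,
                            beta_random = length(B) > 0,
                            beta_fixed_flag = FALSE, beta_fixed_value = 4) {
  if (eps1 < 0 || eps2 < 0) stop("eps1 and eps2 must be non-negative")
  if (beta_fixed_flag) {
    B0 <- beta_fixed_value
    B <- numeric()
    beta_random <- FALSE
  }
  structure(list(A0 = A0, A = A, eps1 = eps1, B0 = B0, B = B, eps2 = eps2,
                 beta_random = beta_random,
                 beta_fixed_flag = beta_fixed_flag,
                 beta_fixed_value = beta_fixed_value),
            class = "movement_params")
}

#' Laplace-approximated marginal negative log-likelihood
#'
#' Marginal likelihood of the covariate-driven CTCRW: the Kalman likelihood
#' integrated over the latent per-interval parameters,
#' `integral L_K(sigma, beta) N(log sigma | A0 + A X, eps1)
#'  N(log beta | B0 + B X, eps2) d log sigma d log beta`,
#' approximated by Laplace's method. The joint mode of the latent vector is
#' found by quasi-Newton (BFGS) inner optimization and the Gaussian
#' correction uses the log-determinant of the curvature at the mode. This
#' pure-R path is exact in its Laplace sense but scales poorly with track
#' length; [fit_ctcrw()] uses the equivalent AD-based objective for fitting.
#'
#' @inheritParams kalman_loglik
#' @param X design matrix of standardized covariates, one row per interval
#'   (attributed to the interval's end relocation).
#' @param params a [movement_params] object.
#' @param inner_control list of `reltol` and `maxit` for the inner
#'   optimization.
#' @param init optional starting latent vector (defaults to the prior means).
#' @return the negative log marginal likelihood, with attributes `mode`
#'   (latent vector at the mode) and `gradient_norm`.
#' @export
laplace_marginal_nll <- function(track, X, params, obs_cov = NULL, dt = NULL,
                                 inner_control = list(reltol = 1e-10,
                                                      maxit = 5000),
                                 init = NULL) {
  g <- as_ssm_inputs(track, obs_cov, dt)
  m <- nrow(g$obs) - 1
  X <- as.matrix(X)
  if (nrow(X) != m) stop("X must have one row per interval (", m, ")")
  mu1 <- as.numeric(params$A0 + X %*% matrix(params$A, ncol = 1))
  beta_random <- isTRUE(params$beta_random) && !params$beta_fixed_flag
  mu2 <- if (beta_random)
    as.numeric(params$B0 + X %*% matrix(params$B, ncol = 1))
  else rep(params$B0, m)
  if (params$eps1 <= 0 || (beta_random && params$eps2 <= 0)) {
    # delta-function limit: plug-in parameters, no latent variation
    return(-kalman_filter(g$obs, g$dt, exp(mu1), exp(mu2), g$obs_cov)$loglik)
  }
  d <- if (beta_random) 2 * m else m
  h <- function(u) {
    us <- u[seq_len(m)]
    ub <- if (beta_random) u[m + seq_len(m)] else mu2
    -kalman_filter(g$obs, g$dt, exp(us), exp(ub), g$obs_cov)$loglik -
      sum(dnorm(us, mu1, params$eps1, log = TRUE)) -
      (if (beta_random)
         sum(dnorm(ub, mu2, params$eps2, log = TRUE)) else 0)
  }
  if (is.null(init)) init <- if (beta_random) c(mu1, mu2) else mu1
  opt <- optim(init, h, method = "BFGS",
               control = list(reltol = inner_control$reltol,
                              maxit = inner_control$maxit))
  grad <- fd_gradient(h, opt$par)
  gnorm <- sqrt(sum(grad^2))
  if (opt$convergence != 0 && gnorm > 1e-2)
    stop("inner optimization did not converge (gradient norm ",
         signif(gnorm, 3), ")")
  H <- optimHess(opt$par, h)
  ld <- determinant(H, logarithm = TRUE)
  if (ld$sign <= 0) stop("latent curvature not positive definite at mode")
  out <- opt$value - (d / 2) * log(2 * pi) + 0.5 * as.numeric(ld$modulus)
  attr(out, "mode") <- opt$par
  attr(out, "gradient_norm") <- gnorm
  out
}

fd_gradient <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- eps * max(1, abs(x[i]))
    (f(x + e) - f(x - e)) / (2 * e[i])
  }, numeric(1))
}
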