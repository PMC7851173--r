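test_that("error-ellipse covariances match geometry and Monte Carlo", {
  # circular ellipse: isotropic, sd M/sqrt(2) per axis
  circ <- ellipse_to_covariance(100, 100, 37)
  expect_equal(circ$var_x * 1e6, 5000)
  expect_equal(circ$var_y * 1e6, 5000)
  expect_equal(circ$cov_xy, 0)

  # degenerate east-west ellipse
  deg <- ellipse_to_covariance(200, 0, 90)
  expect_equal(deg$var_x * 1e6, 20000)
  expect_equal(deg$var_y * 1e6, 0, tolerance = 1e-20)
  expect_equal(deg$cov_xy * 1e6, 0, tolerance = 1e-9)

  # random ellipse vs sample covariance of simulated ellipse errors
  set.seed(11)
  M <- 347; m <- 132; cdeg <- 67
  th <- cdeg * pi / 180
  z1 <- rnorm(1e6, 0, M / sqrt(2)); z2 <- rnorm(1e6, 0, m / sqrt(2))
  east <- z1 * sin(th) + z2 * cos(th)
  north <- z1 * cos(th) - z2 * sin(th)
  got <- ellipse_to_covariance(M, m, cdeg)
  expect_equal(var(east), got$var_x * 1e6, tolerance = 0.01)
  expect_equal(var(north), got$var_y * 1e6, tolerance = 0.01)
  expect_equal(cov(east, north), got$cov_xy * 1e6, tolerance = 0.02)

  expect_error(ellipse_to_covariance(50, 100, 0), "exceeds")
})

test_that("transition law has the right limits and simulated moments", {
  # dt -> 0: identity transition, vanishing covariance
  tr <- ctcrw_transition(2, 4, 1e-10)
  expect_equal(tr$T, diag(4), tolerance = 1e-8)
  expect_lt(max(abs(tr$Q)), 1e-8)

  # beta dt >> 1: stationary velocity variance sigma^2 / (2 beta)
  tr2 <- ctcrw_transition(3, 5, 100)
  expect_equal(tr2$Q[2, 2], 25 / 6, tolerance = 1e-10)
  expect_equal(tr2$T[2, 2], 0, tolerance = 1e-12)

  # moments vs fine-step Euler-Maruyama simulation (independent oracle)
  set.seed(21)
  beta <- 1.3; sigma <- 3.1; dt <- 1.7
  nsub <- 2000; npath <- 20000
  h <- dt / nsub
  v <- rnorm(npath, 0, 1)   # arbitrary start spread to exercise T too
  x <- numeric(npath)
  for (s in seq_len(nsub)) {
    x <- x + v * h + 0.5 * (-beta * v) * h^2      # midpoint-ish position
    v <- v + (-beta * v) * h + sigma * sqrt(h) * rnorm(npath)
  }
  tr3 <- ctcrw_transition(beta, sigma, dt)
  # conditional-on-start moments: subtract the propagated start
  expect_equal(var(v), tr3$Q[2, 2] + tr3$T[2, 2]^2 * 1, tolerance = 0.03)
  expect_equal(var(x), tr3$Q[1, 1] + tr3$T[1, 2]^2 * 1, tolerance = 0.03)
  expect_equal(cov(x, v), tr3$Q[1, 2] + tr3$T[1, 2] * tr3$T[2, 2] * 1,
               tolerance = 0.05)

  expect_error(ctcrw_transition(-1, 1, 1), "positive")
})

test_that("kalman log-likelihood equals the dense multivariate-normal oracle", {
  for (n in 3:6) {
    fx <- rand_ssm_fixture(n, seed = 100 + n)
    kl <- kalman_loglik(fx$obs, fx$sig, fx$bet, fx$obs_cov, fx$dt)
    expect_equal(kl, dense_loglik_oracle(fx$obs, fx$dt, fx$sig, fx$bet,
                                         fx$obs_cov),
                 tolerance = 1e-10)
  }
})

test_that("kalman likelihood limits behave physically", {
  fx <- rand_ssm_fixture(5, seed = 7)
  # inflating one observation's noise to near-infinity removes its influence:
  # compare against the likelihood with that point's noise enormous twice over
  oc1 <- fx$obs_cov; oc1[3, ] <- c(1e10, 1e10, 0)
  oc2 <- fx$obs_cov; oc2[3, ] <- c(1e12, 1e12, 0)
  l1 <- kalman_loglik(fx$obs, fx$sig, fx$bet, oc1, fx$dt)
  l2 <- kalman_loglik(fx$obs, fx$sig, fx$bet, oc2, fx$dt)
  # once the point is uninformative, further inflation only adds its
  # (parameter-independent) Gaussian normalizer: difference = log(100)
  expect_equal(l1 - l2, log(1e2), tolerance = 1e-3)

  # straight fast track: doubling sigma away from its ML value lowers loglik
  n <- 12
  obs <- cbind(3 * (0:(n - 1)), rep(0, n))
  dt <- rep(1, n - 1)
  oc <- data.frame(var_x = rep(0.01, n), var_y = 0.01, cov_xy = 0)
  s1 <- fit_ctcrw_constant(obs, obs_cov = oc, dt = dt)
  lhat <- kalman_loglik(obs, exp(s1$log_sigma), exp(s1$log_beta), oc, dt)
  ldbl <- kalman_loglik(obs, 2 * exp(s1$log_sigma), exp(s1$log_beta), oc, dt)
  expect_lt(ldbl, lhat)
})

test_that("likelihood is invariant under rigid rotation with circular errors", {
  fx <- rand_ssm_fixture(6, seed = 31)
  oc <- data.frame(var_x = rep(1.3, 6), var_y = 1.3, cov_xy = 0)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  rot <- fx$obs %*% t(R)
  expect_equal(kalman_loglik(fx$obs, fx$sig, fx$bet, oc, fx$dt),
               kalman_loglik(rot, fx$sig, fx$bet, oc, fx$dt),
               tolerance = 1e-9)
})

test_that("laplace marginal reaches the plug-in limit and a stable mode", {
  fx <- rand_ssm_fixture(4, seed = 9)
  X <- matrix(rnorm(3), ncol = 1, dimnames = list(NULL, "c1"))
  mu1 <- 1.2 + 0.4 * X[, 1]; mu2 <- 0.5 - 0.2 * X[, 1]

  # eps -> 0: delta-function limit equals the plug-in Kalman NLL
  p0 <- movement_params(A0 = 1.2, A = c(c1 = 0.4), eps1 = 0, B0 = 0.5,
                        B = c(c1 = -0.2), eps2 = 0, beta_random = TRUE)
  plug <- -kalman_loglik(fx$obs, exp(mu1), exp(mu2), fx$obs_cov, fx$dt)
  expect_equal(as.numeric(laplace_marginal_nll(fx$obs, X, p0,
                                               obs_cov = fx$obs_cov,
                                               dt = fx$dt)),
               plug, tolerance = 1e-12)

  # monotone approach to the plug-in limit as eps shrinks
  vals <- vapply(c(0.3, 0.1, 0.03), function(e) {
    pe <- movement_params(A0 = 1.2, A = c(c1 = 0.4), eps1 = e, B0 = 0.5,
                          B = c(c1 = -0.2), eps2 = e, beta_random = TRUE)
    as.numeric(laplace_marginal_nll(fx$obs, X, pe, obs_cov = fx$obs_cov,
                                    dt = fx$dt))
  }, numeric(1))
  expect_true(all(diff(abs(vals - plug)) < 0))

  # mode is insensitive to the inner starting point
  pe <- movement_params(A0 = 1.2, A = c(c1 = 0.4), eps1 = 0.3, B0 = 0.5,
                        B = c(c1 = -0.2), eps2 = 0.15, beta_random = TRUE)
  v1 <- laplace_marginal_nll(fx$obs, X, pe, obs_cov = fx$obs_cov, dt = fx$dt)
  set.seed(77)
  v2 <- laplace_marginal_nll(fx$obs, X, pe, obs_cov = fx$obs_cov, dt = fx$dt,
                             init = c(mu1, mu2) + rnorm(6, 0, 0.5))
  expect_equal(as.numeric(v1), as.numeric(v2), tolerance = 1e-6)
})

test_that("smoothing recovers exact positions as observation noise vanishes", {
  fx <- rand_ssm_fixture(8, seed = 15)
  tiny <- data.frame(var_x = rep(1e-12, 8), var_y = 1e-12, cov_xy = 0)
  kf <- ctcrwrisk:::kalman_filter(fx$obs, fx$dt, fx$sig, fx$bet, tiny)
  sm <- ctcrwrisk:::rts_smooth(kf)
  expect_equal(t(sm$mean[c(1, 3), ]), unname(fx$obs), tolerance = 1e-4)
})

test_that("smoothed variances never exceed filtered variances", {
  fx <- rand_ssm_fixture(10, seed = 16)
  kf <- ctcrwrisk:::kalman_filter(fx$obs, fx$dt, fx$sig, fx$bet, fx$obs_cov)
  sm <- ctcrwrisk:::rts_smooth(kf)
  for (t in 1:10)
    expect_true(all(diag(sm$var[, , t]) <= diag(kf$Ptt[, , t]) + 1e-9))
})

test_that("smoothing beats raw observations in recovering the true path", {
  cfg <- sim_config(seed = 33, n_locations = 150)
  sim <- suppressWarnings(simulate_track(cfg))
  s1 <- fit_ctcrw_constant(sim$track)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  rmse_smooth <- rmse(cbind(s1$states$x, s1$states$y),
                      cbind(sim$truth$x, sim$truth$y))
  rmse_raw <- rmse(sim$track$xy, cbind(sim$truth$x, sim$truth$y))
  expect_lt(rmse_smooth, rmse_raw)
})
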