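# shared fixtures and independent oracles

# dense multivariate-normal oracle for the CTCRW likelihood: builds the joint
# normal of all observations explicitly from the transition/observation
# equations (no filtering)
dense_loglik_oracle <- function(obs, dt, sig, bet, obs_cov) {
  n <- nrow(obs)
  H <- matrix(c(1, 0, 0, 0, 0, 0, 1, 0), 2, 4, byrow = TRUE)
  vel_var1 <- sig[1]^2 / (2 * bet[1])
  Ms <- numeric(4 * n)
  Vs <- matrix(0, 4 * n, 4 * n)
  Ms[1:4] <- c(obs[1, 1], 0, obs[1, 2], 0)
  Vs[1:4, 1:4] <- diag(c(1e6, vel_var1, 1e6, vel_var1))
  for (t in 2:n) {
    tr <- ctcrw_transition(bet[t - 1], sig[t - 1], dt[t - 1])
    i <- (4 * (t - 2) + 1):(4 * (t - 1))
    j <- (4 * (t - 1) + 1):(4 * t)
    Ms[j] <- tr$T %*% Ms[i]
    for (s in 1:(t - 1)) {
      k <- (4 * (s - 1) + 1):(4 * s)
      Vs[j, k] <- tr$T %*% Vs[i, k]
      Vs[k, j] <- t(Vs[j, k])
    }
    Vs[j, j] <- tr$T %*% Vs[i, i] %*% t(tr$T) + tr$Q
  }
  Hbig <- matrix(0, 2 * n, 4 * n)
  Rbig <- matrix(0, 2 * n, 2 * n)
  for (t in 1:n) {
    Hbig[(2 * t - 1):(2 * t), (4 * t - 3):(4 * t)] <- H
    Rbig[(2 * t - 1):(2 * t), (2 * t - 1):(2 * t)] <-
      matrix(c(obs_cov$var_x[t], obs_cov$cov_xy[t],
               obs_cov$cov_xy[t], obs_cov$var_y[t]), 2)
  }
  mo <- Hbig %*% Ms
  Vo <- Hbig %*% Vs %*% t(Hbig) + Rbig
  y <- as.vector(t(obs))
  ch <- chol(Vo)
  as.numeric(-0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                     sum(backsolve(ch, y - mo, transpose = TRUE)^2)))
}

# random small state-space fixture
rand_ssm_fixture <- function(n, seed) {
  set.seed(seed)
  list(obs = cbind(cumsum(rnorm(n, 0, 3)), cumsum(rnorm(n, 0, 3))),
       dt = runif(n - 1, 0.5, 2.5),
       sig = runif(n - 1, 2, 6),
       bet = runif(n - 1, 0.5, 3),
       obs_cov = data.frame(var_x = runif(n, 0.5, 2),
                            var_y = runif(n, 0.5, 2),
                            cov_xy = runif(n, -0.3, 0.3)))
}

make_track <- function(lon, lat, hours, lc = "3", sm = 100, sn = 50,
                       or = 0, id = "w1") {
  argos_track(id, data.frame(
    timestamp = as.POSIXct("2019-02-01", tz = "UTC") + hours * 3600,
    lon = lon, lat = lat, location_class = lc,
    semi_major = sm, semi_minor = sn, orientation = or,
    stringsAsFactors = FALSE))
}

# one moderate simulated track + fit, computed once and reused
demo_fit_env <- new.env()
get_demo_fit <- function() {
  if (is.null(demo_fit_env$fit)) {
    cfg <- sim_config(seed = 555, n_locations = 150)
    st <- make_covariate_stack(cfg)
    sim <- suppressWarnings(simulate_track(cfg, st))
    demo_fit_env$stack <- st
    demo_fit_env$sim <- sim
    demo_fit_env$fit <- suppressWarnings(
      fit_ctcrw(sim$track, st, stats = st$standardization,
                attribution = "start", covariates = "log_dahcc"))
  }
  demo_fit_env
}

# fit-shaped object with chosen parameters, for prediction-layer tests
fake_fit <- function(A0, A, B0, B = numeric(), eps1 = 0.1, stats = NULL,
                     beta_random = length(B) > 0) {
  structure(list(params = movement_params(A0 = A0, A = A, eps1 = eps1,
                                          B0 = B0, B = B,
                                          beta_random = beta_random),
                 stats = stats, animal_id = "fake", n_locations = 0),
            class = "ctcrw_fit")
}
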