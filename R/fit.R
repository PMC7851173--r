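#' Fit the covariate-driven CTCRW to a track
#'
#' Two-stage fit. Stage 1 maximizes the exact Kalman likelihood of the plain
#' (constant-parameter) CTCRW and smooths the states, giving estimated true
#' locations. Stage 2 extracts covariates at those locations (3-km-radius
#' mean), standardizes them, and fits the covariate-driven model — latent
#' per-interval `log sigma_t` and `log beta_t` with covariate-linked normal
#' means — by marginal maximum likelihood. The latent parameters and states
#' are integrated out with the Laplace approximation using automatic
#' differentiation (TMB); the approximation is exact in the Gaussian state
#' dimensions, so the objective equals the Laplace-marginalized Kalman
#' likelihood of [laplace_marginal_nll()].
#'
#' Model-reduction rules applied when `beta_model = "auto"`:
#' * if no covariate effect on `log beta_t` is significant at `alpha`, the
#'   model is refitted with a single scalar `log beta`;
#' * if the scalar estimate exceeds `beta_log_cap` (default 4, where
#'   persistence drops to `3/e^4` = 0.05 h, i.e. essentially uncorrelated
#'   movement), the model is refitted with `log beta` pinned at that value.
#'
#' `eps2`, the sd of `log beta_t`, is not estimated: it is ill-conditioned
#' (tiny estimates with huge standard errors) and is fixed at 0.01.
#'
#' @param track a filtered, projected [argos_track].
#' @param stack a [covariate_stack] from which covariates are extracted at
#'   stage-1 smoothed locations; alternatively supply `X` directly.
#' @param X optional precomputed standardized design matrix with one row per
#'   relocation (the interval attribution below is applied) or one row per
#'   interval.
#' @param radius covariate extraction radius (km).
#' @param stats optional fixed standardization constants (data frame with
#'   `covariate`, `mean`, `sd`, e.g. a stack's global constants); by default
#'   constants are computed from this track's extracted series.
#' @param covariates which stack layers enter the model (default all).
#' @param attribution which relocation's covariates drive interval `t`
#'   (between relocations `t` and `t+1`): its end (`"end"`, default) or its
#'   start.
#' @param beta_model `"auto"` (reduction rules above), `"covariate"`,
#'   `"scalar"`, or `"fixed"`.
#' @param eps2 fixed sd of `log beta_t`.
#' @param alpha Wald significance threshold for the reduction rule.
#' @param beta_log_cap log-scale cap triggering the fixed-beta rule.
#' @param eps1_init starting value for `eps1`.
#' @param obs_var_floor lower bound (km^2) applied to observation variances
#'   so the objective stays positive definite.
#' @param verbose print optimization progress.
#'
#' @return an object of class `ctcrw_fit`; see [summary.ctcrw_fit()].
#'   Elements include `params` (a [movement_params] at the estimates),
#'   `coefficients` (estimate/SE/p table), `latent` (per-relocation smoothed
#'   states and per-interval latent `log sigma_t`, `log beta_t` with SEs),
#'   `log_likelihood`, `convergence`, `stage1`, `stats` (standardization
#'   constants) and `beta_mode`.
#' @export
fit_ctcrw <- function(track, stack = NULL, X = NULL, radius = 3.0,
                      stats = NULL, covariates = covariate_names(),
                      attribution = c("end", "start"),
                      beta_model = c("auto", "covariate", "scalar", "fixed"),
                      eps2 = 0.01, alpha = 0.05, beta_log_cap = 4,
                      eps1_init = 0.1, obs_var_floor = 1e-8,
                      verbose = FALSE) {
  attribution <- match.arg(attribution)
  beta_model <- match.arg(beta_model)
  g <- as_ssm_inputs(track)
  n <- nrow(g$obs)
  g$obs_cov$var_x <- pmax(g$obs_cov$var_x, obs_var_floor)
  g$obs_cov$var_y <- pmax(g$obs_cov$var_y, obs_var_floor)

  stage1 <- fit_ctcrw_constant(g$obs, obs_cov = g$obs_cov, dt = g$dt)

  if (is.null(X)) {
    if (is.null(stack)) stop("supply either a covariate stack or X")
    sm_xy <- cbind(stage1$states$x, stage1$states$y)
    ts <- if (inherits(track, "argos_track")) track$data$timestamp
          else seq_len(n)
    ext <- extract_design_matrix(stack, sm_xy, ts, radius, stats = stats,
                                 covariates = covariates)
    X <- ext$X
    stats <- ext$stats
  }
  X <- as.matrix(X)
  if (nrow(X) == n) {
    X <- if (attribution == "end") X[-1, , drop = FALSE]
         else X[-n, , drop = FALSE]
  } else if (nrow(X) != n - 1) {
    stop("X must have n or n-1 rows")
  }
  p <- ncol(X)
  if (p > 0L && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(p))
  if (p == 0L && beta_model == "covariate") beta_model <- "scalar"

  fit1 <- NULL
  if (beta_model %in% c("auto", "covariate") && p > 0L) {
    fit1 <- tmb_fit(g, X, stage1, mode = 0L, eps2 = eps2,
                    eps1_init = eps1_init, verbose = verbose)
    if (beta_model == "covariate")
      return(build_ctcrw_fit(fit1, track, X, stats, stage1, alpha))
    pB <- fit1$coefs$p_value[fit1$coefs$block == "log_beta" &
                             fit1$coefs$term != "Intercept"]
    if (any(pB < alpha, na.rm = TRUE))
      return(build_ctcrw_fit(fit1, track, X, stats, stage1, alpha))
  }

  # reduced: single scalar log beta
  if (beta_model %in% c("auto", "scalar")) {
    fit2 <- tmb_fit(g, X, stage1, mode = 1L, eps2 = eps2,
                    eps1_init = eps1_init, verbose = verbose)
    B0hat <- fit2$coefs$estimate[fit2$coefs$block == "log_beta"]
    if (beta_model == "scalar" || B0hat <= beta_log_cap)
      return(build_ctcrw_fit(fit2, track, X, stats, stage1, alpha))
  }

  # beta poorly identified / too fast-mixing: pin log beta at the cap
  fit3 <- tmb_fit(g, X, stage1, mode = 2L, eps2 = eps2,
                  eps1_init = eps1_init, beta_fixed_value = beta_log_cap,
                  verbose = verbose)
  build_ctcrw_fit(fit3, track, X, stats, stage1, alpha)
}

# one TMB optimization at a given beta mode
tmb_fit <- function(g, X, stage1, mode, eps2, eps1_init,
                    beta_fixed_value = 4, verbose = FALSE) {
  n <- nrow(g$obs); m <- n - 1; p <- ncol(X)
  Xd <- if (p == 0L) matrix(0, m, 1) else X
  pd <- ncol(Xd)
  dat <- list(obs = g$obs, dt = g$dt,
              obs_var = as.matrix(g$obs_cov[c("var_x", "var_y", "cov_xy")]),
              X = Xd, beta_mode = as.integer(mode), eps2 = eps2,
              pos_prior_var = POS_PRIOR_VAR)
  B0_init <- if (mode == 2L) beta_fixed_value else stage1$log_beta
  par <- list(A0 = stage1$log_sigma, A = rep(0, pd),
              log_eps1 = log(eps1_init), B0 = B0_init, B = rep(0, pd),
              u_sigma = rep(stage1$log_sigma, m),
              u_beta = rep(B0_init, m),
              mu = t(as.matrix(stage1$states[, c("x", "vx", "y", "vy")])))
  map <- list()
  if (p == 0L) map$A <- factor(rep(NA, pd))
  if (mode != 0L) {
    map$B <- factor(rep(NA, pd))
    map$u_beta <- factor(rep(NA, m))
  } else if (p == 0L) {
    map$B <- factor(rep(NA, pd))
  }
  if (mode == 2L) map$B0 <- factor(NA)
  random <- c("u_sigma", "mu")
  if (mode == 0L) random <- c(random, "u_beta")
  run_once <- function(par) {
    obj <- TMB::MakeADFun(data = dat, parameters = par, map = map,
                          random = random, DLL = "ctcrwrisk",
                          silent = !verbose)
    opt <- stats::nlminb(obj$par, obj$fn, obj$gr,
                         control = list(iter.max = 1000, eval.max = 2000,
                                        rel.tol = 1e-10))
    if (!opt$convergence %in% c(0, 1) || !is.finite(opt$objective))
      stop("outer optimization failed: ", opt$message)
    sdr <- suppressWarnings(TMB::sdreport(obj, getReportCovariance = FALSE))
    list(obj = obj, opt = opt, sdr = sdr)
  }
  run <- run_once(par)
  if (!isTRUE(run$sdr$pdHess)) {
    # flat spot or saddle: retry once from a more dispersed latent start
    par2 <- par
    par2$log_eps1 <- log(3 * eps1_init)
    par2$A0 <- par$A0 + 0.2
    run2 <- tryCatch(run_once(par2), error = function(e) NULL)
    if (!is.null(run2) &&
        (isTRUE(run2$sdr$pdHess) || run2$opt$objective < run$opt$objective))
      run <- run2
  }
  obj <- run$obj; opt <- run$opt; sdr <- run$sdr
  est <- as.list(sdr, "Estimate")
  se <- as.list(sdr, "Std. Error")
  hess_pd <- sdr$pdHess
  grad_norm <- max(abs(obj$gr(opt$par)))

  # coefficient table mirroring the per-individual report layout
  terms <- c("Intercept", colnames(X))
  coefs <- data.frame(
    block = c(rep("log_sigma", 1 + p), "log_eps1", rep("log_beta", 1 + p)),
    term = c(terms, "Intercept", terms),
    estimate = c(est$A0, if (p) est$A[seq_len(p)], est$log_eps1,
                 est$B0, if (p) est$B[seq_len(p)]),
    se = c(se$A0, if (p) se$A[seq_len(p)], se$log_eps1,
           se$B0, if (p) se$B[seq_len(p)]),
    stringsAsFactors = FALSE)
  if (mode != 0L && p)  # beta reduced: covariate rows are absent
    coefs <- coefs[!(coefs$block == "log_beta" & coefs$term != "Intercept"), ]
  if (mode == 2L) {     # beta pinned: no SE
    coefs$se[coefs$block == "log_beta"] <- NA_real_
  }
  coefs$z <- coefs$estimate / coefs$se
  coefs$p_value <- 2 * pnorm(-abs(coefs$z))
  rownames(coefs) <- NULL

  list(obj = obj, opt = opt, sdr = sdr, est = est, se = se, coefs = coefs,
       mode = mode, hess_pd = hess_pd, grad_norm = grad_norm,
       eps2 = eps2, beta_fixed_value = beta_fixed_value)
}

build_ctcrw_fit <- function(tf, track, X, stats, stage1, alpha) {
  n <- ncol(tf$est$mu); m <- n - 1; p <- ncol(X)
  est <- tf$est; se <- tf$se
  log_beta_t <- if (tf$mode == 0L) est$u_beta else rep(est$B0, m)
  se_log_beta_t <- if (tf$mode == 0L) se$u_beta
                   else rep(if (tf$mode == 1L) se$B0 else NA_real_, m)
  latent <- data.frame(
    x = est$mu[1, ], vx = est$mu[2, ], y = est$mu[3, ], vy = est$mu[4, ],
    se_x = se$mu[1, ], se_vx = se$mu[2, ], se_y = se$mu[3, ],
    se_vy = se$mu[4, ],
    log_sigma = c(NA, est$u_sigma), se_log_sigma = c(NA, se$u_sigma),
    log_beta = c(NA, log_beta_t), se_log_beta = c(NA, se_log_beta_t))
  latent$sigma <- exp(latent$log_sigma)
  latent$beta <- exp(latent$log_beta)
  if (inherits(track, "argos_track")) {
    latent <- cbind(timestamp = track$data$timestamp, latent)
  }
  params <- movement_params(
    A0 = est$A0, A = if (p) setNames(est$A[seq_len(p)], colnames(X))
                     else numeric(),
    eps1 = exp(est$log_eps1),
    B0 = est$B0,
    B = if (tf$mode == 0L && p) setNames(est$B[seq_len(p)], colnames(X))
        else numeric(),
    eps2 = tf$eps2,
    beta_random = tf$mode == 0L,
    beta_fixed_flag = tf$mode == 2L,
    beta_fixed_value = tf$beta_fixed_value)
  structure(list(
    params = params,
    coefficients = tf$coefs,
    latent = latent,
    log_likelihood = -tf$opt$objective,
    convergence = list(status = tf$opt$convergence,
                       message = tf$opt$message,
                       gradient_norm = tf$grad_norm,
                       hessian_pd = tf$hess_pd,
                       iterations = tf$opt$iterations),
    beta_mode = c("covariate", "scalar", "fixed")[tf$mode + 1L],
    stage1 = stage1,
    stats = stats,
    X = X,
    alpha = alpha,
    animal_id = if (inherits(track, "argos_track")) track$animal_id else NA,
    proj = if (inherits(track, "argos_track")) track$proj else NULL,
    n_locations = n),
    class = "ctcrw_fit")
}

#' @export
print.ctcrw_fit <- function(x, ...) {
  cat("<ctcrw_fit> ", x$n_locations, " relocations",
      if (!is.na(x$animal_id)) paste0(" (animal ", x$animal_id, ")"),
      "\n  log marginal likelihood: ", signif(x$log_likelihood, 8),
      "\n  beta model: ", x$beta_mode,
      if (x$beta_mode == "fixed")
        paste0(" (log beta = ", x$params$beta_fixed_value, ")"),
      "\n", sep = "")
  print(summary(x))
  invisible(x)
}

#' Coefficient summary of a CTCRW fit
#'
#' @param object a `ctcrw_fit`.
#' @param ... unused.
#' @return the coefficient table (estimate, SE, Wald z and p per term, log
#'   scale), in the per-individual layout used for reporting such fits.
#' @export
summary.ctcrw_fit <- function(object, ...) {
  out <- object$coefficients
  out$estimate <- round(out$estimate, 4)
  out$se <- round(out$se, 4)
  out$p_value <- signif(out$p_value, 3)
  out
}

#' @export
coef.ctcrw_fit <- function(object, ...) {
  setNames(object$coefficients$estimate,
           paste(object$coefficients$block, object$coefficients$term,
                 sep = "."))
}

#' @export
logLik.ctcrw_fit <- function(object, ...) {
  structure(object$log_likelihood, class = "logLik",
            df = sum(!is.na(object$coefficients$se)))
}

#' Smoothed latent states of a fitted CTCRW
#'
#' Runs the Rauch-Tung-Striebel smoother at the fit's latent parameter mode
#' (`sigma_t`, `beta_t` at their Laplace modes), returning smoothed positions
#' and velocities with standard errors conditional on those parameters. For
#' the TMB-fitted model these coincide with the posterior state modes stored
#' in `fitted$latent` (the Laplace approximation is exact in the Gaussian
#' state dimensions); this pure-R path provides the independent check and
#' the smoothed variances.
#'
#' @param fitted a `ctcrw_fit`, or the result of [fit_ctcrw_constant()]
#'   together with `track`.
#' @param track the projected [argos_track] the model was fitted to
#'   (required; fits do not retain the raw observations).
#' @return data frame of smoothed states (`x`, `vx`, `y`, `vy`), their
#'   standard errors, and the latent `log_sigma`, `log_beta` per interval.
#' @export
smooth_states <- function(fitted, track) {
  g <- as_ssm_inputs(track)
  m <- nrow(g$obs) - 1
  sig <- exp(fitted$latent$log_sigma[-1])
  bet <- exp(fitted$latent$log_beta[-1])
  kf <- kalman_filter(g$obs, g$dt, sig, bet, g$obs_cov)
  sm <- rts_smooth(kf)
  data.frame(x = sm$mean[1, ], vx = sm$mean[2, ],
             y = sm$mean[3, ], vy = sm$mean[4, ],
             se_x = sqrt(pmax(sm$var[1, 1, ], 0)),
             se_vx = sqrt(pmax(sm$var[2, 2, ], 0)),
             se_y = sqrt(pmax(sm$var[3, 3, ], 0)),
             se_vy = sqrt(pmax(sm$var[4, 4, ], 0)),
             log_sigma = fitted$latent$log_sigma,
             log_beta = fitted$latent$log_beta)
}

#' Write a fit report and latent-state table
#'
#' Serializes the coefficient table to a small structured text report and
#' the latent states to CSV.
#'
#' @param fitted a `ctcrw_fit`.
#' @param report_path path for the text report (optional).
#' @param states_path path for the latent-state CSV (optional).
#' @return invisibly, the coefficient table.
#' @export
write_fit_report <- function(fitted, report_path = NULL, states_path = NULL) {
  if (!is.null(report_path)) {
    con <- file(report_path, "w")
    on.exit(close(con))
    writeLines(c(
      paste("animal:", fitted$animal_id),
      paste("n_locations:", fitted$n_locations),
      paste("log_marginal_likelihood:", signif(fitted$log_likelihood, 10)),
      paste("beta_model:", fitted$beta_mode),
      ""), con)
    utils::write.table(format(summary(fitted), trim = TRUE), con,
                       quote = FALSE, row.names = FALSE, sep = "\t")
  }
  if (!is.null(states_path))
    write.csv(fitted$latent, states_path, row.names = FALSE)
  invisible(fitted$coefficients)
}

#' @importFrom stats pnorm
NULL
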