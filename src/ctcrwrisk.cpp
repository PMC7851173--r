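// Covariate-driven continuous-time correlated random walk.
//
// State per coordinate: (position, velocity); velocity is an
// Ornstein-Uhlenbeck process dv = -beta v dt + sigma dW and position its
// time integral. Per-interval log(sigma_t), log(beta_t) are lognormal latent
// variables with covariate-linked means; observations carry Argos
// error-ellipse covariances. Latent states and parameters are declared as
// random effects and marginalized by the Laplace approximation (exact in the
// Gaussian state dimensions).
#include <TMB.hpp>

// negative log density of a bivariate normal with covariance
// [q11 q12; q12 q22] evaluated at residual (r1, r2)
template <class Type>
Type nll_bvn(Type r1, Type r2, Type q11, Type q12, Type q22) {
  Type det = q11 * q22 - q12 * q12;
  Type quad = (q22 * r1 * r1 - Type(2.0) * q12 * r1 * r2 + q11 * r2 * r2) / det;
  return Type(0.5) * (Type(2.0) * log(Type(2.0) * M_PI) + log(det) + quad);
}

template <class Type>
Type objective_function<Type>::operator()() {
  DATA_MATRIX(obs);          // n x 2 observed planar positions (km)
  DATA_VECTOR(dt);           // n-1 interval lengths (hours)
  DATA_MATRIX(obs_var);      // n x 3: var_x, var_y, cov_xy (km^2)
  DATA_MATRIX(X);            // (n-1) x p standardized covariates
  DATA_INTEGER(beta_mode);   // 0 covariate-driven random; 1 scalar; 2 fixed
  DATA_SCALAR(eps2);         // sd of log(beta_t) when beta_mode == 0
  DATA_SCALAR(pos_prior_var);// diffuse initial position variance (km^2)

  PARAMETER(A0);             // intercept, log sigma scale
  PARAMETER_VECTOR(A);       // covariate slopes on log sigma_t
  PARAMETER(log_eps1);       // log sd of log sigma_t
  PARAMETER(B0);             // intercept / scalar / fixed value, log beta
  PARAMETER_VECTOR(B);       // covariate slopes on log beta_t
  PARAMETER_VECTOR(u_sigma); // latent log sigma_t, length n-1 (random)
  PARAMETER_VECTOR(u_beta);  // latent log beta_t, length n-1 (random iff mode 0)
  PARAMETER_MATRIX(mu);      // 4 x n latent states (x, vx, y, vy) (random)

  int n = obs.rows();
  int m = n - 1;
  Type eps1 = exp(log_eps1);
  Type nll = Type(0.0);

  vector<Type> mu1 = A0 + (X * A).array();
  vector<Type> mu2(m);
  if (beta_mode == 0) {
    mu2 = B0 + (X * B).array();
  } else {
    for (int t = 0; t < m; ++t) mu2(t) = B0;
  }

  // latent-parameter priors
  for (int t = 0; t < m; ++t) {
    nll -= dnorm(u_sigma(t), mu1(t), eps1, true);
    if (beta_mode == 0) nll -= dnorm(u_beta(t), mu2(t), eps2, true);
  }

  // initial state: diffuse position centred on the first fix, stationary
  // velocity at the first interval's parameters
  Type sigma1 = exp(u_sigma(0));
  Type beta1 = (beta_mode == 0) ? exp(u_beta(0)) : exp(B0);
  Type vel_var1 = sigma1 * sigma1 / (Type(2.0) * beta1);
  nll -= dnorm(mu(0, 0), obs(0, 0), sqrt(pos_prior_var), true);
  nll -= dnorm(mu(2, 0), obs(0, 1), sqrt(pos_prior_var), true);
  nll -= dnorm(mu(1, 0), Type(0.0), sqrt(vel_var1), true);
  nll -= dnorm(mu(3, 0), Type(0.0), sqrt(vel_var1), true);

  // OU-integrated transitions, x and y blocks independent and identical
  for (int t = 1; t < n; ++t) {
    Type sig = exp(u_sigma(t - 1));
    Type bet = (beta_mode == 0) ? exp(u_beta(t - 1)) : exp(B0);
    Type d = dt(t - 1);
    Type e = exp(-bet * d);
    Type s2 = sig * sig;
    Type q11 = (s2 / (bet * bet)) *
               (d - Type(2.0) * (Type(1.0) - e) / bet +
                (Type(1.0) - e * e) / (Type(2.0) * bet));
    Type q12 = (s2 / (Type(2.0) * bet * bet)) *
               (Type(1.0) - Type(2.0) * e + e * e);
    Type q22 = s2 * (Type(1.0) - e * e) / (Type(2.0) * bet);
    // x block
    Type mx = mu(0, t - 1) + mu(1, t - 1) * (Type(1.0) - e) / bet;
    Type mvx = mu(1, t - 1) * e;
    nll += nll_bvn(mu(0, t) - mx, mu(1, t) - mvx, q11, q12, q22);
    // y block
    Type my = mu(2, t - 1) + mu(3, t - 1) * (Type(1.0) - e) / bet;
    Type mvy = mu(3, t - 1) * e;
    nll += nll_bvn(mu(2, t) - my, mu(3, t) - mvy, q11, q12, q22);
  }

  // Argos observations with error-ellipse covariance
  for (int t = 0; t < n; ++t) {
    nll += nll_bvn(obs(t, 0) - mu(0, t), obs(t, 1) - mu(2, t),
                   obs_var(t, 0), obs_var(t, 2), obs_var(t, 1));
  }

  return nll;
}
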