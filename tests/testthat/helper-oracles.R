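# Independent reference implementations and random-case generators used
# across the suite. These deliberately avoid the package's own numerical
# paths: the equilibrium oracle is a plain nested bisection, and the
# occupancy oracle evaluates the affinity-constant form of the bound
# densities directly.

# nested bisection for the two-equation surface equilibrium:
# outer bisection on x in [0, x_T], inner bisection on r in [0, r_T]
eq_oracle <- function(params, iters = 60L) {
  g <- params$gamma_kin; mT <- params$m_T
  xT <- params$x_T; rT <- params$r_T; kap <- params$kappa
  fr <- function(x, r) {
    D <- 1 + x + r + x * r / g
    r + mT * (r + x * r / g) / D - rT
  }
  fx <- function(x, r) {
    D <- 1 + x + r + x * r / g
    x + kap * mT * (x + x * r / g) / D - xT
  }
  inner <- function(x) {
    lo <- 0; hi <- rT
    for (k in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (fr(x, mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lo <- 0; hi <- xT
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (fx(mid, inner(mid)) > 0) hi <- mid else lo <- mid
  }
  x <- (lo + hi) / 2
  list(x = x, r = inner(x))
}

# random valid scaled parameter set (gamma_kin <= gamma_off by
# construction, via a CD8-enhanced on-rate)
random_params <- function(n = 100L) {
  gamma_off <- runif(1, 0.2, 1)
  gamma_on <- runif(1, 1, 3)
  scaled_parameters(
    m_T = exp(runif(1, log(0.2), log(50))),
    x_T = runif(1, 0, 200),
    r_T = exp(runif(1, log(0.2), log(50))),
    alpha = exp(runif(1, log(0.1), log(10))),
    delta = exp(runif(1, log(0.01), log(300))),
    nu = exp(runif(1, log(0.01), log(300))),
    kappa = exp(runif(1, log(0.2), log(10))),
    gamma_off = gamma_off,
    gamma_kin = gamma_off / gamma_on,
    gamma_R = runif(1, 0.1, 1),
    n = n)
}

# random valid dimensional kinetic scheme with physiologic-ish magnitudes
random_kinetics <- function() {
  Lambda1 <- exp(runif(1, log(1e-11), log(1e-9)))
  Lambda3 <- exp(runif(1, log(1e-11), log(1e-9)))
  lambda_m1 <- exp(runif(1, log(0.05), log(5)))
  lambda_m3 <- exp(runif(1, log(0.05), log(5)))
  K1 <- lambda_m1 / Lambda1
  K3 <- lambda_m3 / Lambda3
  T_R <- runif(1, 5, 15)
  dimensional_kinetics(
    Lambda1 = Lambda1,
    Lambda2 = exp(runif(1, log(1e-11), log(1e-9))),
    Lambda3 = Lambda3,
    lambda_m1 = lambda_m1, lambda_m3 = lambda_m3,
    gamma_on = runif(1, 1, 2), gamma_off = runif(1, 0.2, 1),
    M_T = K1 * exp(runif(1, log(0.5), log(20))),
    X_T = K3 * runif(1, 0, 100),
    R_T = K1 * exp(runif(1, log(0.5), log(20))),
    T_R = T_R, T_R_star = T_R * runif(1, 0.2, 1))
}

# affinity-constant (dissociation-constant) form of the equilibrium bound
# densities, evaluated directly from K1..K4 and the free densities
densities_affinity_form <- function(kin, R, X) {
  with(kin, list(
    M_R = M_T * R / (K1 + R + X * K1 / K3 + R * X / K2),
    M_X = M_T * X / (K3 + X + R * K3 / K1 + R * X / K4),
    M_XR = M_T * X * R / (K1 * K2 + R * K2 + X * K4 + R * X)))
}

# random two-lane chain spec (rates in units of the basal rate)
random_chain_spec <- function(n) {
  chain_spec(n = n,
             forward0 = n,
             forward_star = n / runif(1, 0.1, 1),
             off0 = exp(runif(1, log(0.1), log(10))),
             off_star = exp(runif(1, log(0.05), log(10))),
             switch_on = exp(runif(1, log(0.01), log(100))),
             switch_off = exp(runif(1, log(0.01), log(100))))
}

# binomial z-statistic for an MC estimate against a reference probability,
# with the SE clamped away from zero at the resolution of the sample size
binom_z <- function(p_hat, p_ref, n) {
  p_se <- min(max(p_ref, 1 / (2 * n)), 1 - 1 / (2 * n))
  abs(p_hat - p_ref) / sqrt(p_se * (1 - p_se) / n)
}

# Family version of the 3-SE consistency check: when one MC curve is
# compared at m thresholds simultaneously, the per-point critical value
# is raised so the family-wise false-alarm probability stays at that of
# a single 3-SE comparison (Bonferroni; conservative because the points
# share samples and are positively correlated).
expect_mc_consistent <- function(p_hat, p_ref, n) {
  z <- mapply(binom_z, p_hat, p_ref, MoreArgs = list(n = n))
  zcrit <- if (length(z) > 1)
    stats::qnorm(1 - stats::pnorm(-3) / length(z)) else 3
  expect_true(all(z < zcrit))
  if (length(z) > 1) expect_gt(mean(z < 3), 0.9)
}
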