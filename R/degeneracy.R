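#' Gaussian dissociation-energy ensemble
#'
#' Ligand-to-ligand variation of the TCR/pMHCI off-rate is modelled
#' through the dissociation energy barrier: Arrhenius theory gives a mean
#' dwell time `T = T_0 * exp(DU)` with `DU` in Boltzmann units, and when
#' `DU` is the additive result of many interface contacts it is Gaussian.
#' Writing `u = DU - ln(T_R/T_0)`, the model takes `u ~ N(-mu, sigma^2)`
#' with `mu > 0`, so the scaled off-rate `alpha = exp(-u)` is log-normal
#' with `ln(alpha) ~ N(mu, sigma^2)`. The positive `mu` encodes the fact
#' that for the vast majority of ligands the dwell time falls short of
#' the triggering threshold.
#'
#' @param mu mean of `ln(alpha)` (Boltzmann units, > 0).
#' @param sigma standard deviation of `ln(alpha)` (> 0).
#' @param T_0 optional frequency factor (seconds), only needed to report
#'   dimensional dwell times.
#' @param seed integer seed used by [sample_alpha()].
#' @return An object of class `energy_ensemble`.
#' @export
energy_ensemble <- function(mu, sigma, T_0 = NULL, seed = 1L) {
  if (!is.finite(mu) || mu <= 0) stop("mu must be positive")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  structure(list(mu = mu, sigma = sigma, T_0 = T_0,
                 seed = as.integer(seed)),
            class = "energy_ensemble")
}

#' @export
print.energy_ensemble <- function(x, ...) {
  cat(sprintf(paste0("Log-normal off-rate ensemble: ln(alpha) ~ ",
                     "N(%.3g, %.3g^2), seed %d\n"),
              x$mu, x$sigma, x$seed))
  invisible(x)
}

#' Draw scaled off-rates from the ensemble
#'
#' Samples `alpha = exp(-u)` with `u ~ N(-mu, sigma^2)`; reproducible for
#' a given ensemble seed (the caller's RNG stream is left untouched).
#'
#' @param ens an [energy_ensemble()] object.
#' @param count number of samples (>= 1).
#' @return Numeric vector of positive off-rates.
#' @export
sample_alpha <- function(ens, count) {
  stopifnot(inherits(ens, "energy_ensemble"), count >= 1)
  with_seed(ens$seed,
            exp(-stats::rnorm(as.integer(count), mean = -ens$mu,
                              sd = ens$sigma)))
}

# P(w(alpha) > omega) for each omega, by exhaustive bracketing of the
# super-level set of w on a log-grid of alpha plus bracketed refinement.
# w is not assumed unimodal. Grid tails at +-span_sigma carry ~1e-15 of
# the log-normal mass and are absorbed into the flanking intervals.
superlevel_prob <- function(params, ens, omega, eq,
                            n_grid = 400L, span_sigma = 8) {
  lo <- ens$mu - span_sigma * ens$sigma
  hi <- ens$mu + span_sigma * ens$sigma
  la_grid <- seq(lo, hi, length.out = n_grid)
  a_grid <- exp(la_grid)
  wv <- w_of_alpha(params, a_grid, eq)
  vapply(omega, function(om) {
    act <- wv > om
    if (!any(act)) return(0)
    edges <- which(act[-1L] != act[-n_grid])
    cuts <- vapply(edges, function(j) {
      stats::uniroot(function(a) w_of_alpha(params, a, eq) - om,
                     lower = a_grid[j], upper = a_grid[j + 1L],
                     tol = 1e-10 * a_grid[j])$root
    }, numeric(1))
    # boundaries of the super-level intervals, in ascending alpha
    starts <- numeric(0); ends <- numeric(0)
    open <- act[1L]
    if (open) starts <- 0  # extend to alpha -> 0 (negligible mass beyond)
    for (cut in cuts) {
      if (open) ends <- c(ends, cut) else starts <- c(starts, cut)
      open <- !open
    }
    if (open) ends <- c(ends, Inf)
    sum(stats::plnorm(ends, ens$mu, ens$sigma) -
          stats::plnorm(starts, ens$mu, ens$sigma))
  }, numeric(1))
}

#' Degeneracy curve P(w > omega)
#'
#' TCR recognition degeneracy is quantified as the probability that the
#' functional sensitivity `w` of a randomly drawn ligand exceeds a
#' threshold `omega`, as a function of `omega`. Ligands differ only in
#' their scaled off-rate `alpha`, drawn from the log-normal
#' [energy_ensemble()]; the surface equilibrium is independent of `alpha`
#' and is solved once.
#'
#' Two methods are available. The default semi-analytic method scans
#' `w(alpha)` on a 400-point log-grid spanning +-8 ensemble standard
#' deviations, brackets every crossing of each threshold, refines the
#' crossings by a bracketed root search, and accumulates the exact
#' log-normal mass of the super-level intervals — this resolves tail
#' probabilities (1e-8 and below) far out of reach of sampling. The Monte
#' Carlo method reports the empirical exceedance fraction over sampled
#' off-rates and serves as an independent cross-check where the
#' probability is not too small.
#'
#' @param params a [scaled_parameters()] object (its `alpha` field is
#'   ignored; the ensemble supplies alpha).
#' @param ens an [energy_ensemble()] object.
#' @param omega_grid ascending thresholds; defaults to 60 log-spaced
#'   points spanning `[1e-4, 10] * max_alpha w(alpha)`.
#' @param method `"semi_analytic"` (default) or `"monte_carlo"`.
#' @param n_samples Monte Carlo sample count.
#' @param n_grid,span_sigma semi-analytic scan resolution and log-range.
#' @return An object of class `degeneracy_curve`: a list with `omega`,
#'   `prob`, `method`, `n_samples`, and the inputs.
#' @examples
#' p <- preset_parameters("ligand_focusing", x_T = 100)
#' ens <- energy_ensemble(mu = 2, sigma = 0.2, seed = 7)
#' dc <- degeneracy_curve(p, ens)
#' head(as.data.frame(dc))
#' @export
degeneracy_curve <- function(params, ens, omega_grid = NULL,
                             method = c("semi_analytic", "monte_carlo"),
                             n_samples = 100000L, n_grid = 400L,
                             span_sigma = 8) {
  stopifnot(inherits(params, "scaled_parameters"),
            inherits(ens, "energy_ensemble"))
  method <- match.arg(method)
  eq <- solve_equilibrium(params)
  if (is.null(omega_grid)) {
    la <- seq(ens$mu - span_sigma * ens$sigma,
              ens$mu + span_sigma * ens$sigma, length.out = n_grid)
    wmax <- max(w_of_alpha(params, exp(la), eq))
    if (wmax <= 0) wmax <- 1
    omega_grid <- exp(seq(log(1e-4 * wmax), log(10 * wmax),
                          length.out = 60L))
  }
  if (is.unsorted(omega_grid, strictly = FALSE))
    stop("omega_grid must be ascending")
  prob <- switch(method,
    semi_analytic = superlevel_prob(params, ens, omega_grid, eq,
                                    n_grid = n_grid,
                                    span_sigma = span_sigma),
    monte_carlo = {
      wv <- w_of_alpha(params, sample_alpha(ens, n_samples), eq)
      vapply(omega_grid, function(om) mean(wv > om), numeric(1))
    })
  structure(list(omega = omega_grid, prob = prob, method = method,
                 n_samples = if (method == "monte_carlo") n_samples else
                   NA_integer_,
                 params = params, ensemble = ens),
            class = "degeneracy_curve")
}

#' @export
as.data.frame.degeneracy_curve <- function(x, ...) {
  data.frame(omega = x$omega, prob = x$prob, method = x$method)
}

#' @export
print.degeneracy_curve <- function(x, ...) {
  cat(sprintf("Degeneracy curve P(w > omega), %s method, %d thresholds\n",
              x$method, length(x$omega)))
  cat(sprintf("  omega in [%.3g, %.3g]; P in [%.3g, %.3g]\n",
              min(x$omega), max(x$omega), min(x$prob), max(x$prob)))
  invisible(x)
}

#' @param y unused.
#' @param add logical; add to an existing plot.
#' @param ... passed to the underlying plot call.
#' @rdname degeneracy_curve
#' @export
plot.degeneracy_curve <- function(x, y, ..., add = FALSE) {
  keep <- x$prob > 0
  if (add) {
    graphics::lines(x$omega[keep], x$prob[keep], ...)
  } else {
    graphics::plot(x$omega[keep], x$prob[keep], type = "l", log = "xy",
                   xlab = expression(omega),
                   ylab = expression(P(w > omega)), ...)
  }
  invisible(x)
}

#' Cellular activation model
#'
#' A T-cell is taken to be activated when the TCR triggering rate
#' integrated over a conjugation exceeds a cellular threshold:
#' `Z * T_I * w > W_act`, with `Z` the presentation level of the ligand,
#' `T_I` the duration of the T-cell:APC interaction and `W_act` the
#' activation threshold. Per ligand this reduces to a critical scaled
#' sensitivity `omega_crit = W_act / (Z * T_I)`; `omega_crit` can also be
#' given directly. Normal immune function corresponds to exceedance
#' probabilities inside an operating band (defaults 1e-8 to 1e-5,
#' reflecting repertoire-size estimates).
#'
#' @param omega_crit critical scaled sensitivity (given directly), or
#'   `NULL` to derive it from `W_act/(Z*T_I)`.
#' @param Z,T_I,W_act presentation level (copies), interaction duration
#'   (s) and activation threshold, used when `omega_crit` is `NULL`.
#' @param band_lo,band_hi operating-band probability limits.
#' @return An object of class `activation_model`.
#' @export
activation_model <- function(omega_crit = NULL, Z = NULL, T_I = NULL,
                             W_act = NULL, band_lo = 1e-8,
                             band_hi = 1e-5) {
  if (is.null(omega_crit)) {
    if (is.null(Z) || is.null(T_I) || is.null(W_act))
      stop("supply omega_crit, or the triple (Z, T_I, W_act)")
    if (Z <= 0 || T_I <= 0) stop("Z and T_I must be positive")
    omega_crit <- W_act / (Z * T_I)
  }
  if (omega_crit < 0) stop("omega_crit must be nonnegative")
  if (!(band_lo < band_hi)) stop("need band_lo < band_hi")
  structure(list(omega_crit = omega_crit, Z = Z, T_I = T_I,
                 W_act = W_act, band_lo = band_lo, band_hi = band_hi),
            class = "activation_model")
}

#' Operating-band scan over CD8 density
#'
#' For each total CD8 density in `x_T_grid`, re-solves the equilibrium
#' and computes the probability that a random ligand exceeds the critical
#' sensitivity of the activation model, then flags whether the cell sits
#' below, inside, or above the operating band. The resulting profile
#' shows how a T-cell can tune its responsiveness — and its autoimmunity
#' risk — by regulating CD8 expression.
#'
#' @param act an [activation_model()].
#' @param params a [scaled_parameters()] reference set (its `x_T` is
#'   replaced by the grid values).
#' @param ens an [energy_ensemble()].
#' @param x_T_grid ascending CD8 densities.
#' @param ... passed to the semi-analytic probability evaluator
#'   (`n_grid`, `span_sigma`).
#' @return A data.frame (class `activation_band`) with columns `x_T`,
#'   `prob` and `flag` (`"below"`, `"in_band"`, `"above"`).
#' @export
activation_band_scan <- function(act, params, ens, x_T_grid, ...) {
  stopifnot(inherits(act, "activation_model"),
            inherits(params, "scaled_parameters"),
            inherits(ens, "energy_ensemble"))
  if (is.unsorted(x_T_grid)) stop("x_T_grid must be ascending")
  prob <- vapply(x_T_grid, function(xT) {
    p <- update_parameters(params, x_T = xT)
    if (act$omega_crit == 0) return(1)
    superlevel_prob(p, ens, act$omega_crit, solve_equilibrium(p), ...)
  }, numeric(1))
  flag <- ifelse(prob < act$band_lo, "below",
                 ifelse(prob > act$band_hi, "above", "in_band"))
  structure(data.frame(x_T = x_T_grid, prob = prob, flag = flag,
                       stringsAsFactors = FALSE),
            class = c("activation_band", "data.frame"),
            omega_crit = act$omega_crit,
            band = c(act$band_lo, act$band_hi))
}

#' @export
plot.activation_band <- function(x, y, ...) {
  band <- attr(x, "band")
  keep <- x$prob > 0
  graphics::plot(x$x_T[keep], x$prob[keep], type = "l", log = "y",
                 xlab = expression(x[T]),
                 ylab = sprintf("P(w > %.3g)", attr(x, "omega_crit")), ...)
  graphics::abline(h = band, lty = 2)
  invisible(x)
}

#' Size of the effective ligand universe
#'
#' Counts the peptide-MHC ligands a TCR can effectively distinguish if
#' peptides of length `n_pep` are anchored to the MHC groove at `a`
#' positions and the TCR contacts `m` of the remaining residues:
#' `20^m * choose(n_pep - a, m)` (20 amino-acid alphabet, with the
#' contacted positions free to be any of the non-anchor sites).
#'
#' @param n_pep peptide length.
#' @param a number of anchor positions.
#' @param m number of TCR-contacted residues; must satisfy
#'   `0 < m <= n_pep - a` (`m = 0` is accepted with a warning and returns
#'   1 by convention).
#' @return The exact count, as a numeric scalar.
#' @examples
#' ligand_universe_size(9, 2, 1)  # 140
#' ligand_universe_size(9, 2, 4)  # 5.6e6
#' @export
ligand_universe_size <- function(n_pep, a, m) {
  n_pep <- as.integer(n_pep); a <- as.integer(a); m <- as.integer(m)
  if (any(is.na(c(n_pep, a, m))) || n_pep < 1 || a < 0 || m < 0)
    stop("n_pep, a, m must be nonnegative integers (n_pep >= 1)")
  if (m > n_pep - a)
    stop("m must not exceed the number of non-anchor positions n_pep - a")
  if (m == 0) {
    warning("m = 0 is outside the model's stated domain; returning 1")
    return(1)
  }
  20^m * choose(n_pep - a, m)
}
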