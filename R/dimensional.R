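#' Dimensional kinetic scheme
#'
#' The four binding states of a pMHCI molecule at the T-cell:APC interface
#' (free; TCR-bound; CD8-bound; TCR- and CD8-bound) with two-dimensional
#' association rates `Lambda1..Lambda4` (cm^2 s^-1), dissociation rates
#' `lambda_m1..lambda_m4` (s^-1) and total surface densities `M_T`, `X_T`,
#' `R_T` (cm^-2). Dissociation constants are `K_i = lambda_mi / Lambda_i`
#' (cm^-2). Thermodynamic consistency requires the binding cycle to close:
#' `K1*K2 = K3*K4`, so `lambda_m2` is determined by the other rates and is
#' derived by the constructor (or validated when supplied).
#'
#' CD8 modulation enters as `Lambda4 = gamma_on * Lambda1` (enhanced
#' on-rate, `gamma_on >= 1`) and `lambda_m4 = gamma_off * lambda_m1`
#' (stabilised bond, `0 < gamma_off <= 1`); both are derived from
#' `gamma_on`/`gamma_off` here so the cycle identity holds by
#' construction. `T_R` is the TCR triggering threshold without CD8
#' (seconds; physiologically about 5-15 s) and `T_R_star <= T_R` the
#' threshold with CD8 engaged.
#'
#' @param Lambda1,Lambda2,Lambda3 association rates (cm^2 s^-1).
#' @param lambda_m1,lambda_m3 dissociation rates (s^-1).
#' @param lambda_m2 pMHCI/CD8 dissociation rate with TCR bound; derived
#'   from detailed balance when `NULL`, validated otherwise.
#' @param gamma_on on-rate enhancement by CD8 (>= 1).
#' @param gamma_off off-rate reduction by CD8 (0 < gamma_off <= 1).
#' @param M_T,X_T,R_T total surface densities (cm^-2).
#' @param T_R,T_R_star triggering thresholds (s), `T_R_star <= T_R`.
#' @return An object of class `dimensional_kinetics`, including the
#'   derived `Lambda4`, `lambda_m4` and constants `K1..K4`.
#' @export
dimensional_kinetics <- function(Lambda1, Lambda2, Lambda3,
                                 lambda_m1, lambda_m3,
                                 lambda_m2 = NULL,
                                 gamma_on = 1.5, gamma_off = 0.5,
                                 M_T, X_T, R_T, T_R = 10, T_R_star = T_R) {
  rates <- c(Lambda1, Lambda2, Lambda3, lambda_m1, lambda_m3)
  if (any(rates <= 0) || any(!is.finite(rates)))
    stop("association/dissociation rates must be finite and positive")
  if (gamma_on < 1) stop("gamma_on must be >= 1")
  if (gamma_off <= 0 || gamma_off > 1) stop("gamma_off must be in (0, 1]")
  if (any(c(M_T, X_T, R_T) < 0)) stop("densities must be nonnegative")
  if (T_R <= 0 || T_R_star <= 0 || T_R_star > T_R)
    stop("need 0 < T_R_star <= T_R")
  Lambda4 <- gamma_on * Lambda1
  lambda_m4 <- gamma_off * lambda_m1
  K1 <- lambda_m1 / Lambda1
  K3 <- lambda_m3 / Lambda3
  K4 <- lambda_m4 / Lambda4
  # cycle closure K1 K2 = K3 K4 fixes K2 and hence lambda_m2
  K2 <- K3 * K4 / K1
  lm2 <- K2 * Lambda2
  if (!is.null(lambda_m2) && abs(lambda_m2 / lm2 - 1) > 1e-8)
    stop(sprintf(paste0("supplied lambda_m2 = %.6g violates detailed ",
                        "balance (cycle closure requires %.6g)"),
                 lambda_m2, lm2))
  structure(list(Lambda1 = Lambda1, Lambda2 = Lambda2, Lambda3 = Lambda3,
                 Lambda4 = Lambda4, lambda_m1 = lambda_m1,
                 lambda_m2 = lm2, lambda_m3 = lambda_m3,
                 lambda_m4 = lambda_m4, K1 = K1, K2 = K2, K3 = K3, K4 = K4,
                 M_T = M_T, X_T = X_T, R_T = R_T, T_R = T_R,
                 T_R_star = T_R_star, gamma_on = gamma_on,
                 gamma_off = gamma_off),
            class = "dimensional_kinetics")
}

#' @export
print.dimensional_kinetics <- function(x, ...) {
  cat("Dimensional TCR/pMHCI/CD8 kinetics\n")
  cat(sprintf("  K1 = %.4g, K2 = %.4g, K3 = %.4g, K4 = %.4g cm^-2  (K1K2 = K3K4)\n",
              x$K1, x$K2, x$K3, x$K4))
  cat(sprintf("  totals: M_T = %.4g, X_T = %.4g, R_T = %.4g cm^-2\n",
              x$M_T, x$X_T, x$R_T))
  cat(sprintf("  T_R = %.3g s, T_R* = %.3g s, gamma_on = %.3g, gamma_off = %.3g\n",
              x$T_R, x$T_R_star, x$gamma_on, x$gamma_off))
  invisible(x)
}

#' Non-dimensionalise a kinetic scheme
#'
#' Maps a [dimensional_kinetics()] object onto the scaled parameter set:
#' densities are divided by `K1` (TCR side) or `K3` (CD8 side) and rates
#' by `lambda = 1/T_R`, giving `alpha = lambda_m1 * T_R`,
#' `delta = lambda_m2 * T_R`, `nu = Lambda2 * K3 * T_R`, `kappa = K1/K3`,
#' `gamma_R = T_R_star / T_R`, `gamma_kin = gamma_off / gamma_on`.
#'
#' @param kin a [dimensional_kinetics()] object.
#' @param n number of phosphorylation steps for the scaled model.
#' @return A [scaled_parameters()] object.
#' @export
to_scaled <- function(kin, n = 100L) {
  stopifnot(inherits(kin, "dimensional_kinetics"))
  lambda <- 1 / kin$T_R
  scaled_parameters(
    m_T = kin$M_T / kin$K1,
    x_T = kin$X_T / kin$K3,
    r_T = kin$R_T / kin$K1,
    alpha = kin$lambda_m1 / lambda,
    delta = kin$lambda_m2 / lambda,
    nu = kin$Lambda2 * kin$K3 / lambda,
    kappa = kin$K1 / kin$K3,
    gamma_off = kin$gamma_off,
    gamma_kin = kin$gamma_off / kin$gamma_on,
    gamma_R = kin$T_R_star / kin$T_R,
    n = n)
}

#' Equilibrium bound densities and dimensional triggering rate
#'
#' Solves the dimensional equilibrium (via the scaled system, which is
#' exact) and returns all surface densities, the normalisation factor `C`
#' of the equilibrium occupancy law, and the dimensional triggering rate
#' `W` (s^-1 cm^-2) in its dissociation-rate form
#' \deqn{W = M_R \lambda_{-1} P_0^0 + M_{XR} \lambda_{-4} P_0^*.}
#'
#' @param kin a [dimensional_kinetics()] object.
#' @param n number of phosphorylation steps.
#' @return An object of class `bound_densities` with fields `M`, `M_R`,
#'   `M_X`, `M_XR`, `X`, `R`, `C`, `W`.
#' @seealso [triggering_rate_forms()] for the association-rate form of `W`
#'   and the detailed-balance equivalence of the two.
#' @export
bound_densities <- function(kin, n = 100L) {
  stopifnot(inherits(kin, "dimensional_kinetics"))
  p <- to_scaled(kin, n)
  eq <- solve_equilibrium(p)
  X <- eq$x * kin$K3
  R <- eq$r * kin$K1
  M_T <- kin$M_T
  C <- 1 + eq$r + eq$x + eq$r * eq$x * kin$K3 / kin$K2
  forms <- triggering_rate_forms(kin, n)
  structure(list(M = M_T * eq$frac_free, M_R = M_T * eq$eps,
                 M_X = M_T * eq$frac_MX, M_XR = M_T * eq$zeta,
                 X = X, R = R, C = C, W = forms$W_dissoc),
            class = "bound_densities")
}

#' Dimensional triggering rate, both algebraic forms
#'
#' The rate at which TCR/CD3 complexes are triggered can be written from
#' the association side, \eqn{W = M \lambda_1 P_0^0 + M_X \lambda_4 P_0^*},
#' or from the dissociation side,
#' \eqn{W = M_R \lambda_{-1} P_0^0 + M_{XR} \lambda_{-4} P_0^*}; detailed
#' balance (\eqn{M \lambda_1 = M_R \lambda_{-1}},
#' \eqn{M_X \lambda_4 = M_{XR} \lambda_{-4}}) makes them equal at
#' equilibrium. Both are computed here so the identity can be verified
#' numerically; the scaled model uses (the scaled version of) the
#' dissociation form.
#'
#' @inheritParams bound_densities
#' @return A list with `W_assoc`, `W_dissoc`, `P00`, `P0_star` and the
#'   scaled-model cross-check `w_scaled = W / (M_T * lambda)`.
#' @export
triggering_rate_forms <- function(kin, n = 100L) {
  stopifnot(inherits(kin, "dimensional_kinetics"))
  p <- to_scaled(kin, n)
  eq <- solve_equilibrium(p)
  X <- eq$x * kin$K3
  R <- eq$r * kin$K1
  M <- kin$M_T * eq$frac_free
  M_R <- kin$M_T * eq$eps
  M_X <- kin$M_T * eq$frac_MX
  M_XR <- kin$M_T * eq$zeta
  tp <- triggering_probabilities(step_probabilities(p, eq$x), n)
  lambda1 <- kin$Lambda1 * R
  lambda4 <- kin$Lambda4 * R
  W_assoc <- M * lambda1 * tp$P00 + M_X * lambda4 * tp$P0_star
  W_dissoc <- M_R * kin$lambda_m1 * tp$P00 +
    M_XR * kin$lambda_m4 * tp$P0_star
  list(W_assoc = W_assoc, W_dissoc = W_dissoc,
       P00 = tp$P00, P0_star = tp$P0_star,
       w_scaled = W_dissoc * kin$T_R / kin$M_T)
}

#' HLA A*0201 CD8-binding-site variants
#'
#' Built-in table of pMHCI heavy-chain variants with altered CD8 binding
#' affinity, with solution (three-dimensional) dissociation constants from
#' surface plasmon resonance: A245V (weakened CD8 binding), wild-type,
#' Q115E (slightly enhanced), A2/a3kb (strongly enhanced).
#'
#' @return A data.frame with columns `name` and `K_D` (micromolar).
#' @export
cd8_mutants <- function() {
  data.frame(name = c("A245V", "wild-type", "Q115E", "A2/a3kb"),
             K_D = c(498, 137.1, 97.94, 10.87),
             stringsAsFactors = FALSE)
}

#' Define a pMHCI/CD8 affinity scenario
#'
#' @param name one of the built-in variants (see [cd8_mutants()]) or
#'   `"custom"`.
#' @param K_D three-dimensional dissociation constant in micromolar
#'   (required for `"custom"`, looked up otherwise).
#' @param reference_K_D the reference (wild-type) `K_D` used to form the
#'   affinity ratio `rho = K_D / reference_K_D`.
#' @return An object of class `mutant_scenario` with fields `name`, `K_D`
#'   and `rho`.
#' @export
mutant_scenario <- function(name, K_D = NULL,
                            reference_K_D = 137.1) {
  tab <- cd8_mutants()
  if (is.null(K_D)) {
    hit <- match(name, tab$name)
    if (is.na(hit)) stop("unknown variant '", name,
                         "'; supply K_D for a custom scenario")
    K_D <- tab$K_D[hit]
  }
  if (K_D <= 0 || reference_K_D <= 0) stop("K_D values must be positive")
  structure(list(name = name, K_D = K_D, rho = K_D / reference_K_D),
            class = "mutant_scenario")
}

#' Rescale a parameter set for an altered pMHCI/CD8 affinity
#'
#' Because the confinement length relating solution and membrane
#' affinities is common to all variants, the two-dimensional pMHCI/CD8
#' dissociation constant `K3` scales in proportion to the measured
#' solution `K_D`. `K3` enters the scaled parameters only through
#' `kappa = K1/K3`, `x_T = X_T/K3` and `nu = Lambda2 K3 / lambda`, so a
#' variant with affinity ratio `rho = K_D/K_D(reference)` maps the
#' reference parameter set via `kappa -> kappa/rho`, `x_T -> x_T/rho`,
#' `nu -> nu * rho`; everything else is unchanged.
#'
#' @param base the reference (wild-type) [scaled_parameters()].
#' @param scenario a [mutant_scenario()] or a positive affinity ratio
#'   `rho`.
#' @return A new [scaled_parameters()] object.
#' @examples
#' wt <- preset_parameters("mutant_panel")
#' apply_mutant(wt, mutant_scenario("A2/a3kb"))
#' @export
apply_mutant <- function(base, scenario) {
  stopifnot(inherits(base, "scaled_parameters"))
  rho <- if (inherits(scenario, "mutant_scenario")) scenario$rho else
    as.numeric(scenario)
  if (!is.finite(rho) || rho <= 0)
    stop("affinity ratio rho must be a positive number")
  update_parameters(base, kappa = base$kappa / rho, x_T = base$x_T / rho,
                    nu = base$nu * rho)
}
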