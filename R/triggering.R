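#' Per-step probabilities on the two-lane phosphorylation chain
#'
#' An engaged TCR/CD3 complex progresses through `n` ITAM phosphorylation
#' steps. At every state it competes three exponential events: the next
#' phosphorylation, dissociation of the TCR/pMHCI bond, and a lane switch
#' (CD8 binding or unbinding of the pMHCI). In units of the basal
#' triggering rate \eqn{\lambda = 1/T_R}, the competing rates are
#' `n`, `alpha`, `nu * x` in the CD8-unbound lane and `n/gamma_R`,
#' `gamma_off * alpha`, `delta` in the CD8-bound lane, giving
#'
#' \deqn{P_a^0 = \frac{n}{\alpha + n + \nu x}, \qquad
#'       P_b^0 = \frac{\nu x}{\alpha + n + \nu x},}
#' \deqn{P_a^* = \frac{n/\gamma_R}{\gamma_{off}\alpha + n/\gamma_R + \delta},
#'       \qquad
#'       P_b^* = \frac{\delta}{\gamma_{off}\alpha + n/\gamma_R + \delta}.}
#'
#' The remainders `1 - Pa - Pb` are the per-step dissociation
#' probabilities.
#'
#' @param params a [scaled_parameters()] object.
#' @param x scaled free CD8 density (typically `solve_equilibrium(params)$x`).
#' @return An object of class `chain_step_probabilities` with fields
#'   `Pa0`, `Pa_star`, `Pb0`, `Pb_star`.
#' @export
step_probabilities <- function(params, x) {
  stopifnot(inherits(params, "scaled_parameters"), x >= 0)
  n <- params$n
  den0 <- params$alpha + n + params$nu * x
  dens <- params$gamma_off * params$alpha + n / params$gamma_R + params$delta
  structure(list(Pa0 = n / den0,
                 Pb0 = params$nu * x / den0,
                 Pa_star = (n / params$gamma_R) / dens,
                 Pb_star = params$delta / dens),
            class = "chain_step_probabilities")
}

#' Triggering probabilities by backward recursion
#'
#' Computes the probability that a TCR/CD3 complex, currently at `i`
#' completed phosphorylations, ultimately reaches the triggered state
#' (all `n` steps done) before the TCR/pMHCI bond dissociates. First-step
#' analysis couples the two lanes:
#' \deqn{P_{i-1}^0 = P_a^0 P_i^0 + P_b^0 P_{i-1}^*, \qquad
#'       P_{i-1}^* = P_a^* P_i^* + P_b^* P_{i-1}^0,}
#' which solved for the (i-1)-level pair gives one backward step
#' \deqn{\binom{P_{i-1}^0}{P_{i-1}^*} = \frac{1}{1 - P_b^0 P_b^*}
#'  \begin{pmatrix} P_a^0 & P_b^0 P_a^* \\ P_b^* P_a^0 & P_a^* \end{pmatrix}
#'  \binom{P_i^0}{P_i^*}}
#' iterated down from the boundary condition \eqn{P_n^0 = P_n^* = 1}.
#' Backward iteration (n matrix-vector products on quantities in
#' \eqn{[0,1]}) is numerically stable and O(n); no matrix power is formed.
#' When the unbound lane cannot switch (`Pb0 = 0`, i.e. no free CD8) the
#' chain is the classical single-lane proofreading cascade and
#' \eqn{P_0^0 = (P_a^0)^n} is evaluated in log space.
#'
#' @param steps a `chain_step_probabilities` object (see
#'   [step_probabilities()]).
#' @param n number of phosphorylation steps.
#' @return A list with `P00`, `P0_star` (triggering probabilities for
#'   encounters that start CD8-unbound / CD8-bound) and the full success
#'   sequences `P_chain0`, `P_chain_star` for `i = 0..n`.
#' @export
triggering_probabilities <- function(steps, n) {
  stopifnot(inherits(steps, "chain_step_probabilities"), n >= 1)
  n <- as.integer(n)
  Pa0 <- steps$Pa0; Pb0 <- steps$Pb0
  Pas <- steps$Pa_star; Pbs <- steps$Pb_star
  if (Pb0 * Pbs >= 1)
    stop("degenerate chain: both lane-switch probabilities are 1, ",
         "the chain cannot progress")
  P0 <- numeric(n + 1L); Ps <- numeric(n + 1L)
  P0[n + 1L] <- 1; Ps[n + 1L] <- 1
  if (Pb0 == 0) {
    # single-lane cascade; exact power in log space
    k <- (n - 1L):0L
    P0[k + 1L] <- exp((n - k) * log(Pa0))
    for (i in n:1L)
      Ps[i] <- Pas * Ps[i + 1L] + Pbs * P0[i]
  } else {
    idet <- 1 / (1 - Pb0 * Pbs)
    for (i in n:1L) {
      P0[i] <- idet * (Pa0 * P0[i + 1L] + Pb0 * Pas * Ps[i + 1L])
      Ps[i] <- idet * (Pbs * Pa0 * P0[i + 1L] + Pas * Ps[i + 1L])
    }
  }
  list(P00 = P0[1L], P0_star = Ps[1L], P_chain0 = P0, P_chain_star = Ps)
}

#' Scaled TCR triggering rate (functional sensitivity)
#'
#' The headline quantity of the model: the scaled rate `w` at which
#' TCR/CD3 complexes attain signalosome status for a given ligand,
#' \deqn{w = \alpha\,(\epsilon P_0^0 + \zeta\,\gamma_{off} P_0^*),}
#' where \eqn{\epsilon} and \eqn{\zeta} are the equilibrium fractions of
#' pMHCI engaged by TCR alone and by TCR plus CD8, and \eqn{P_0^0},
#' \eqn{P_0^*} are the triggering probabilities for encounters beginning
#' in the respective CD8 state. Composes [solve_equilibrium()],
#' [step_probabilities()] (at the free CD8 density) and
#' [triggering_probabilities()].
#'
#' @param params a [scaled_parameters()] object.
#' @return An object of class `triggering_result` containing `w`, `P00`,
#'   `P0_star`, the success-probability chains, the `equilibrium_state`
#'   and the step probabilities.
#' @examples
#' p <- preset_parameters("ligand_focusing", alpha = 2.5, x_T = 100)
#' triggering_rate(p)
#' @export
triggering_rate <- function(params) {
  stopifnot(inherits(params, "scaled_parameters"))
  eq <- solve_equilibrium(params)
  st <- step_probabilities(params, eq$x)
  tp <- triggering_probabilities(st, params$n)
  w <- params$alpha * (eq$eps * tp$P00 +
                         eq$zeta * params$gamma_off * tp$P0_star)
  structure(c(tp, list(w = w, equilibrium = eq, steps = st,
                       params = params)),
            class = "triggering_result")
}

#' @export
print.triggering_result <- function(x, ...) {
  cat("TCR triggering (scaled)\n")
  cat(sprintf("  w          = %.6g\n", x$w))
  cat(sprintf("  P00        = %.6g  (encounter starts CD8-unbound)\n",
              x$P00))
  cat(sprintf("  P0*        = %.6g  (encounter starts CD8-bound)\n",
              x$P0_star))
  cat(sprintf("  occupancy  : eps = %.4g, zeta = %.4g\n",
              x$equilibrium$eps, x$equilibrium$zeta))
  invisible(x)
}

#' @export
summary.triggering_result <- function(object, ...) {
  cat("Two-lane kinetic proofreading, n =", object$params$n, "steps\n")
  print(object)
  st <- object$steps
  cat(sprintf("  step probs : Pa0 = %.4g, Pb0 = %.4g, Pa* = %.4g, Pb* = %.4g\n",
              st$Pa0, st$Pb0, st$Pa_star, st$Pb_star))
  cat(sprintf("  equilibrium residual %.3g\n", object$equilibrium$residual))
  invisible(object)
}

# Vectorised w(alpha) at fixed equilibrium: the equilibrium densities do
# not depend on alpha, so one solve serves a whole off-rate ensemble.
w_of_alpha <- function(params, alpha, eq = solve_equilibrium(params)) {
  n <- params$n
  nux <- params$nu * eq$x
  den0 <- alpha + n + nux
  Pa0 <- n / den0
  Pb0 <- nux / den0
  dens <- params$gamma_off * alpha + n / params$gamma_R + params$delta
  Pas <- (n / params$gamma_R) / dens
  Pbs <- params$delta / dens
  if (nux == 0) {
    P0 <- exp(n * log(Pa0))
    Ps <- rep(1, length(alpha))
    Pcur0 <- rep(1, length(alpha))
    for (i in seq_len(n)) {
      Pcur0 <- Pa0 * Pcur0
      Ps <- Pas * Ps + Pbs * Pcur0
    }
  } else {
    idet <- 1 / (1 - Pb0 * Pbs)
    P0 <- rep(1, length(alpha)); Ps <- P0
    for (i in seq_len(n)) {
      P0n <- idet * (Pa0 * P0 + Pb0 * Pas * Ps)
      Ps  <- idet * (Pbs * Pa0 * P0 + Pas * Ps)
      P0 <- P0n
    }
  }
  alpha * (eq$eps * P0 + eq$zeta * params$gamma_off * Ps)
}

#' Stochastic realisation of the triggering chain
#'
#' `simulate` method for parameter sets: runs the event-driven chain
#' simulation (see [simulate_chain()]) at the model's own equilibrium free
#' CD8 density and returns empirical triggering probabilities, as a
#' Monte Carlo check on the analytic [triggering_rate()].
#'
#' @param object a [scaled_parameters()] object.
#' @param nsim number of independent chain realisations per starting lane.
#' @param seed integer seed (required for reproducibility).
#' @param ... unused.
#' @return The list returned by [simulate_chain()].
#' @export
simulate.scaled_parameters <- function(object, nsim = 10000L, seed = 1L,
                                       ...) {
  eq <- solve_equilibrium(object)
  simulate_chain(chain_spec_from_params(object, eq$x), trials = nsim,
                 seed = seed)
}
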