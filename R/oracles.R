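#' Explicit two-lane chain specification
#'
#' The triggering chain as a continuous-time absorbing Markov chain over
#' states (lane, i) with lane in \{CD8-unbound, CD8-bound\} and
#' `i = 0..n` completed phosphorylations, plus absorbing triggered/failed
#' states. All rates are in units of the basal triggering rate
#' \eqn{\lambda}: forward `n` (unbound) and `n/gamma_R` (bound),
#' dissociation `alpha` and `gamma_off * alpha`, lane switching
#' `nu * x` (unbound to bound) and `delta` (bound to unbound).
#'
#' Used by the independent reference implementations
#' ([absorption_solve()], [simulate_chain()]) that cross-check the
#' backward recursion of [triggering_probabilities()].
#'
#' @param n number of phosphorylation steps.
#' @param forward0,forward_star forward (phosphorylation) rates per lane.
#' @param off0,off_star dissociation rates per lane.
#' @param switch_on,switch_off lane-switch rates (unbound->bound,
#'   bound->unbound).
#' @return An object of class `chain_spec`.
#' @export
chain_spec <- function(n, forward0, forward_star, off0, off_star,
                       switch_on, switch_off) {
  rates <- c(forward0, forward_star, off0, off_star, switch_on, switch_off)
  if (any(rates < 0) || any(!is.finite(rates)))
    stop("all chain rates must be finite and nonnegative")
  structure(list(n = as.integer(n), forward0 = forward0,
                 forward_star = forward_star, off0 = off0,
                 off_star = off_star, switch_on = switch_on,
                 switch_off = switch_off),
            class = "chain_spec")
}

#' @param params a [scaled_parameters()] object.
#' @param x scaled free CD8 density.
#' @rdname chain_spec
#' @export
chain_spec_from_params <- function(params, x) {
  stopifnot(inherits(params, "scaled_parameters"), x >= 0)
  chain_spec(n = params$n,
             forward0 = params$n,
             forward_star = params$n / params$gamma_R,
             off0 = params$alpha,
             off_star = params$gamma_off * params$alpha,
             switch_on = params$nu * x,
             switch_off = params$delta)
}

#' Absorption probabilities by direct linear solve
#'
#' Independent reference implementation: writes the first-step equations
#' for the success probability of every transient state of the two-lane
#' chain (2n unknowns) and solves the dense linear system directly. Must
#' agree with the O(n) backward recursion of
#' [triggering_probabilities()]; this equivalence is the headline
#' correctness property of the package and is enforced in the test suite.
#'
#' @param spec a [chain_spec()] object.
#' @return A list with `P00` and `P0_star`.
#' @export
absorption_solve <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  n <- spec$n
  T0 <- spec$forward0 + spec$off0 + spec$switch_on
  Ts <- spec$forward_star + spec$off_star + spec$switch_off
  if (T0 <= 0 || Ts <= 0)
    stop("singular chain: a lane has no outgoing rate")
  # unknowns: P_i^0 at rows 1..n (i = 0..n-1), P_i^* at rows n+1..2n
  A <- matrix(0, 2L * n, 2L * n)
  b <- numeric(2L * n)
  for (i in 0:(n - 1L)) {
    r0 <- i + 1L; rs <- n + i + 1L
    A[r0, r0] <- T0
    if (i + 1L < n) A[r0, r0 + 1L] <- -spec$forward0 else
      b[r0] <- b[r0] + spec$forward0
    A[r0, rs] <- -spec$switch_on
    A[rs, rs] <- Ts
    if (i + 1L < n) A[rs, rs + 1L] <- -spec$forward_star else
      b[rs] <- b[rs] + spec$forward_star
    A[rs, r0] <- -spec$switch_off
  }
  sol <- solve(A, b)
  list(P00 = sol[1L], P0_star = sol[n + 1L])
}

#' Event-driven stochastic simulation of the triggering chain
#'
#' Simulates independent TCR/pMHCI encounters on the two-lane chain until
#' absorption (triggered or dissociated) and reports empirical triggering
#' probabilities with binomial standard errors. Competing exponential
#' events are resolved through the embedded jump chain (one categorical
#' draw per transition, with probabilities proportional to the rates),
#' which has the same absorption law as explicit exponential clocks at a
#' fraction of the cost. All trials are advanced in lock-step vectorised
#' rounds.
#'
#' @param spec a [chain_spec()] object.
#' @param trials number of encounters simulated per starting lane.
#' @param seed integer seed; identical seeds give identical output.
#' @return A list with empirical `P00`, `P0_star`, their standard errors
#'   `se00`, `se0_star`, and `trials`.
#' @export
simulate_chain <- function(spec, trials, seed) {
  stopifnot(inherits(spec, "chain_spec"), trials >= 1)
  trials <- as.integer(trials)
  T0 <- spec$forward0 + spec$off0 + spec$switch_on
  Ts <- spec$forward_star + spec$off_star + spec$switch_off
  if (T0 <= 0 || Ts <= 0)
    stop("singular chain: a lane has no outgoing rate")
  pf0 <- spec$forward0 / T0; ps0 <- spec$switch_on / T0
  pfs <- spec$forward_star / Ts; pss <- spec$switch_off / Ts

  run_lane <- function(start_bound) {
    i <- integer(trials)
    bound <- rep(start_bound, trials)
    success <- logical(trials)
    alive <- rep(TRUE, trials)
    while (any(alive)) {
      idx <- which(alive)
      u <- stats::runif(length(idx))
      bnd <- bound[idx]
      pf <- ifelse(bnd, pfs, pf0)
      psw <- ifelse(bnd, pss, ps0)
      fwd <- u < pf
      sw  <- !fwd & u < pf + psw
      die <- !fwd & !sw
      ii <- i[idx]
      ii[fwd] <- ii[fwd] + 1L
      i[idx] <- ii
      bound[idx][sw] <- !bnd[sw]
      done_ok <- fwd & ii >= spec$n
      success[idx][done_ok] <- TRUE
      alive[idx][done_ok | die] <- FALSE
    }
    mean(success)
  }

  with_seed(seed, {
    p0 <- run_lane(FALSE)
    ps <- run_lane(TRUE)
    list(P00 = p0, P0_star = ps,
         se00 = sqrt(p0 * (1 - p0) / trials),
         se0_star = sqrt(ps * (1 - ps) / trials),
         trials = trials)
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv()) else
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
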