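#' Solve the receptor/ligand/co-receptor surface equilibrium
#'
#' Solves the nonlinear mass-action system for the scaled free CD8 density
#' `x` and free TCR density `r` in the T-cell:APC contact area. The four
#' binding states of a pMHCI molecule (free, TCR-bound, CD8-bound,
#' TCR+CD8-bound) are in equilibrium; conservation of total CD8 and total
#' TCR closes the system:
#'
#' \deqn{x_T = x + \kappa m_T (x + x r/\gamma_{kin})/D, \quad
#'       r_T = r + m_T (r + x r/\gamma_{kin})/D,}
#'
#' with \eqn{D = 1 + x + r + x r/\gamma_{kin}}. The equilibrium depends
#' only on `gamma_kin`, `kappa`, `m_T`, `x_T` and `r_T`; the kinetic
#' parameters (`alpha`, `delta`, `nu`, `gamma_off`, `gamma_R`, `n`) play no
#' role at this stage.
#'
#' A damped Newton iteration with the analytic Jacobian is used, with both
#' iterates clamped to the box \eqn{[0, x_T] \times [0, r_T]}; on failure
#' the solver falls back to a bracketed nested root search (outer in `x`,
#' inner in `r`), which is guaranteed to converge because each residual is
#' monotone and changes sign across its box edge. The case `x_T = 0` is
#' handled in closed form (single-species quadratic).
#'
#' @param params a [scaled_parameters()] object.
#' @param tol absolute residual tolerance on both equations.
#' @param max_iter maximum Newton iterations before falling back.
#' @return An object of class `equilibrium_state`: a list with the free
#'   densities `x`, `r`, the pMHCI occupancy fractions `eps` (TCR-bound,
#'   no CD8), `zeta` (TCR- and CD8-bound), `frac_free`, `frac_MX`
#'   (CD8-bound, no TCR), and the max absolute `residual`.
#' @examples
#' p <- preset_parameters("ligand_focusing")
#' solve_equilibrium(p)
#' @export
solve_equilibrium <- function(params, tol = 1e-12, max_iter = 200L) {
  stopifnot(inherits(params, "scaled_parameters"))
  g  <- params$gamma_kin
  mT <- params$m_T; xT <- params$x_T; rT <- params$r_T; kap <- params$kappa

  if (mT == 0 || (xT == 0 && rT == 0))
    return(new_equilibrium_state(xT, rT, params, tol))

  if (xT == 0) {
    # x = 0 exactly: r (1 + r) + mT r = rT (1 + r), a quadratic in r
    b <- 1 + mT - rT
    r <- (-b + sqrt(b * b + 4 * rT)) / 2
    return(new_equilibrium_state(0, r, params, tol))
  }
  if (rT == 0) {
    # r = 0: x (1 + x) + kappa mT x = xT (1 + x)
    b <- 1 + kap * mT - xT
    x <- (-b + sqrt(b * b + 4 * xT)) / 2
    return(new_equilibrium_state(x, 0, params, tol))
  }

  resid <- function(x, r) {
    D <- 1 + x + r + x * r / g
    c(x + kap * mT * (x + x * r / g) / D - xT,
      r + mT * (r + x * r / g) / D - rT)
  }

  # Newton with analytic Jacobian, damped and clamped to the box
  x <- xT / (1 + kap * mT)
  r <- rT / (1 + mT)
  ok <- FALSE
  f <- resid(x, r)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) { ok <- TRUE; break }
    D  <- 1 + x + r + x * r / g
    sx <- 1 + r / g; sr <- x / g          # d(x + xr/g)
    tx <- r / g;     tr <- 1 + x / g      # d(r + xr/g)
    Dx <- 1 + r / g; Dr <- 1 + x / g
    s <- x + x * r / g; t <- r + x * r / g
    J <- matrix(c(1 + kap * mT * (sx * D - s * Dx) / D^2,
                  kap * mT * (sr * D - s * Dr) / D^2,
                  mT * (tx * D - t * Dx) / D^2,
                  1 + mT * (tr * D - t * Dr) / D^2),
                2, 2, byrow = TRUE)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    improved <- FALSE
    for (h in 1:30) {
      xn <- min(max(x - lam * step[1], 0), xT)
      rn <- min(max(r - lam * step[2], 0), rT)
      fn <- resid(xn, rn)
      if (max(abs(fn)) < max(abs(f))) {
        x <- xn; r <- rn; f <- fn; improved <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }

  if (!ok && max(abs(f)) >= tol) {
    # bracketed nested root search: inner r(x), outer x
    inner_r <- function(x) {
      fr <- function(r) resid(x, r)[2]
      if (fr(rT) <= 0) return(rT)
      stats::uniroot(fr, c(0, rT), tol = .Machine$double.eps^0.9)$root
    }
    fx <- function(x) resid(x, inner_r(x))[1]
    x <- stats::uniroot(fx, c(0, xT), tol = .Machine$double.eps^0.9)$root
    r <- inner_r(x)
    f <- resid(x, r)
    if (max(abs(f)) >= 1e3 * tol)
      stop(sprintf(paste0("equilibrium solver failed to converge ",
                          "(residual %.3g) for parameter set: m_T=%g, ",
                          "x_T=%g, r_T=%g, kappa=%g, gamma_kin=%g"),
                   max(abs(f)), mT, xT, rT, kap, g))
  }
  if (x < 0 || r < 0)
    stop("internal error: negative equilibrium iterate")
  new_equilibrium_state(x, r, params, tol)
}

new_equilibrium_state <- function(x, r, params, tol) {
  g <- params$gamma_kin
  D <- 1 + x + r + x * r / g
  eps  <- r / D
  zeta <- (x * r / g) / D
  res <- {
    D0 <- D
    c(x + params$kappa * params$m_T * (x + x * r / g) / D0 - params$x_T,
      r + params$m_T * (r + x * r / g) / D0 - params$r_T)
  }
  # degenerate closed-form branches bypass the generic residual
  if (params$m_T == 0) res <- c(0, 0)
  structure(list(x = x, r = r, eps = eps, zeta = zeta,
                 frac_free = 1 / D, frac_MX = x / D,
                 residual = max(abs(res)), tol = tol),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("Surface-density equilibrium (scaled)\n")
  cat(sprintf("  free CD8  x = %.8g\n  free TCR  r = %.8g\n", x$x, x$r))
  cat(sprintf("  pMHCI fractions: free %.4g | TCR-bound (eps) %.4g | ",
              x$frac_free, x$eps))
  cat(sprintf("CD8-bound %.4g | ternary (zeta) %.4g\n", x$frac_MX, x$zeta))
  cat(sprintf("  max residual %.3g\n", x$residual))
  invisible(x)
}
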