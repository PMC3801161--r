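#' Scaled model parameters
#'
#' Construct the set of dimensionless parameters that govern TCR functional
#' sensitivity. All densities are scaled by the relevant two-dimensional
#' dissociation constant (TCR quantities by `K1`, CD8 quantities by `K3`)
#' and all rates by the basal triggering rate `lambda = 1/T_R`, the
#' reciprocal of the TCR triggering threshold.
#'
#' @param m_T scaled total pMHCI density (> 0).
#' @param x_T scaled total CD8 density (>= 0).
#' @param r_T scaled total TCR density (>= 0).
#' @param alpha scaled TCR/pMHCI off-rate without CD8 bound (> 0).
#' @param delta scaled pMHCI/CD8 off-rate with TCR bound (>= 0).
#' @param nu scaled kinetic effect of pMHCI/CD8 association (>= 0).
#' @param kappa ratio of dissociation constants `K1/K3` (> 0).
#' @param gamma_off factor by which CD8 reduces the TCR/pMHCI off-rate
#'   (0 < gamma_off <= 1).
#' @param gamma_kin factor by which CD8 modulates the TCR/pMHCI affinity,
#'   `gamma_off / gamma_on` (0 < gamma_kin <= 1).
#' @param gamma_R factor by which CD8 shortens the TCR triggering threshold
#'   (0 < gamma_R <= 1).
#' @param n number of phosphorylation (proofreading) steps; positive integer.
#'
#' @details
#' A CD8-enhanced on-rate (`gamma_on >= 1`) implies `gamma_kin <= gamma_off`.
#' Values with `gamma_kin > gamma_off` merely encode an on-rate *reduction*
#' and are accepted with a warning rather than rejected.
#'
#' @return An object of class `scaled_parameters` (a named list).
#' @seealso [preset_parameters()], [triggering_rate()], [solve_equilibrium()]
#' @examples
#' p <- scaled_parameters(m_T = 10, x_T = 50, r_T = 10, alpha = 2.5,
#'                        delta = 300, nu = 0.5, kappa = 5,
#'                        gamma_off = 0.5, gamma_kin = 0.5, gamma_R = 0.3,
#'                        n = 100)
#' p
#' @export
scaled_parameters <- function(m_T, x_T, r_T, alpha, delta, nu, kappa,
                              gamma_off, gamma_kin, gamma_R, n) {
  p <- list(m_T = as.numeric(m_T), x_T = as.numeric(x_T),
            r_T = as.numeric(r_T), alpha = as.numeric(alpha),
            delta = as.numeric(delta), nu = as.numeric(nu),
            kappa = as.numeric(kappa), gamma_off = as.numeric(gamma_off),
            gamma_kin = as.numeric(gamma_kin), gamma_R = as.numeric(gamma_R),
            n = as.integer(n))
  class(p) <- "scaled_parameters"
  validate_scaled_parameters(p)
}

validate_scaled_parameters <- function(p) {
  stopifnot(is.list(p))
  num1 <- function(v) length(v) == 1L && is.finite(v)
  for (f in c("m_T", "x_T", "r_T", "alpha", "delta", "nu", "kappa",
              "gamma_off", "gamma_kin", "gamma_R"))
    if (!num1(p[[f]])) stop("parameter '", f, "' must be a finite scalar")
  if (p$m_T < 0) stop("m_T must be nonnegative")
  if (p$x_T < 0) stop("x_T must be nonnegative")
  if (p$r_T < 0) stop("r_T must be nonnegative")
  if (p$alpha <= 0) stop("alpha must be strictly positive")
  if (p$delta < 0) stop("delta must be nonnegative")
  if (p$nu < 0) stop("nu must be nonnegative")
  if (p$kappa <= 0) stop("kappa must be strictly positive")
  for (f in c("gamma_off", "gamma_kin", "gamma_R")) {
    if (p[[f]] <= 0 || p[[f]] > 1)
      stop(f, " must lie in (0, 1]")
  }
  if (p$gamma_kin > p$gamma_off)
    warning("gamma_kin > gamma_off implies a CD8-reduced on-rate ",
            "(gamma_on < 1); accepted, but check the parameter set")
  if (is.na(p$n) || p$n < 1L) stop("n must be a positive integer")
  p
}

#' @export
print.scaled_parameters <- function(x, ...) {
  cat("Scaled TCR/pMHCI/CD8 model parameters\n")
  v <- coef(x)
  cat(paste0("  ", format(names(v), width = 10), format(v, digits = 6),
             collapse = "\n"), "\n")
  rat <- if (x$nu > 0) x$delta / x$nu else NA_real_
  if (is.finite(rat) && abs(rat / x$gamma_kin - 1) > 1e-8)
    cat(sprintf("  note: delta/nu = %.4g differs from gamma_kin = %.4g\n",
                rat, x$gamma_kin))
  invisible(x)
}

#' @export
coef.scaled_parameters <- function(object, ...) {
  unlist(object[c("m_T", "x_T", "r_T", "alpha", "delta", "nu", "kappa",
                  "gamma_off", "gamma_kin", "gamma_R", "n")])
}

#' Replace fields of a parameter set
#'
#' Convenience for sweeps: returns a copy of `params` with the named
#' fields replaced and the invariants re-checked.
#'
#' @param params a [scaled_parameters()] object.
#' @param ... named replacement values, e.g. `x_T = 25`.
#' @return A new `scaled_parameters` object.
#' @export
update_parameters <- function(params, ...) {
  stopifnot(inherits(params, "scaled_parameters"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) stop("unknown parameter field(s): ",
                        paste(bad, collapse = ", "))
  for (f in names(repl))
    params[[f]] <- if (f == "n") as.integer(repl[[f]]) else
      as.numeric(repl[[f]])
  validate_scaled_parameters(params)
}

#' Thermodynamic-consistency diagnostic
#'
#' In a fully consistent kinetic scheme, the scaled pMHCI/CD8 off-rate and
#' the scaled CD8 association effect satisfy `delta/nu = K2/K3 = gamma_kin`.
#' The model deliberately accepts `delta`, `nu` and `gamma_kin` as
#' independent inputs (many useful regimes violate the identity); this
#' function reports how far a parameter set departs from it.
#'
#' @param params a [scaled_parameters()] object.
#' @param tol relative tolerance before a warning is emitted.
#' @return Invisibly, a list with the ratio `delta/nu`, `gamma_kin`, and the
#'   relative discrepancy. Emits a warning when the discrepancy exceeds
#'   `tol`.
#' @export
check_consistency <- function(params, tol = 1e-8) {
  stopifnot(inherits(params, "scaled_parameters"))
  ratio <- if (params$nu > 0) params$delta / params$nu else NA_real_
  rel <- if (is.finite(ratio)) abs(ratio / params$gamma_kin - 1) else
    NA_real_
  if (is.finite(rel) && rel > tol)
    warning(sprintf(paste0("detailed-balance identity delta/nu = gamma_kin",
                           " violated: delta/nu = %.6g, gamma_kin = %.6g"),
                    ratio, params$gamma_kin))
  invisible(list(ratio = ratio, gamma_kin = params$gamma_kin,
                 rel_discrepancy = rel))
}

param_keys <- c("m_T", "x_T", "r_T", "alpha", "delta", "nu", "kappa",
                "gamma_off", "gamma_kin", "gamma_R", "n")

#' Read / write parameter sets
#'
#' Parameter sets are stored as flat YAML or JSON maps whose keys are the
#' scaled parameter names (`m_T`, `x_T`, `r_T`, `alpha`, `delta`, `nu`,
#' `kappa`, `gamma_off`, `gamma_kin`, `gamma_R`, `n`). The format is chosen
#' from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path file path.
#' @return `read_parameters` returns a [scaled_parameters()] object;
#'   `write_parameters` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported parameter file extension: '.", ext, "'"))
  missing <- setdiff(param_keys, names(raw))
  if (length(missing))
    stop("parameter file ", path, " is missing key(s): ",
         paste(missing, collapse = ", "))
  do.call(scaled_parameters, raw[param_keys])
}

#' @param params a [scaled_parameters()] object.
#' @rdname read_parameters
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "scaled_parameters"))
  ext <- tolower(tools::file_ext(path))
  out <- params[param_keys]
  attributes(out) <- list(names = param_keys)
  switch(ext,
    yaml = , yml = yaml::write_yaml(out, path),
    json = jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported parameter file extension: '.", ext, "'"))
  invisible(path)
}
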