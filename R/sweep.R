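#' Parameter sweep of the triggering model
#'
#' Evaluates equilibrium and triggering over a grid of values of one
#' scaled parameter, holding the others fixed. Returns a tidy table with
#' one row per grid point carrying all inputs and the computed outputs
#' (`x`, `r`, `eps`, `zeta`, `P00`, `P0_star`, `w`, `residual`), suitable
#' for plotting or CSV export.
#'
#' @param params a [scaled_parameters()] object, or a preset name (see
#'   [preset_parameters()]).
#' @param var name of the parameter to sweep (e.g. `"x_T"`, `"alpha"`).
#' @param grid numeric vector of values for `var`; defaults to the
#'   preset's natural sweep when `params` is a preset name.
#' @param ... field overrides applied before sweeping (e.g.
#'   `alpha = 2.5`).
#' @return A data.frame of class `sensitivity_sweep`, with the fixed
#'   parameter set and sweep variable recorded as attributes.
#' @examples
#' sw <- run_sweep("ligand_focusing", var = "x_T",
#'                 grid = seq(1, 200, length.out = 100), alpha = 2.5)
#' sw$x_T[which.min(sw$w)]
#' @export
run_sweep <- function(params, var, grid = NULL, ...) {
  if (is.character(params)) {
    if (is.null(grid)) {
      dft <- default_sweep(params)
      if (missing(var)) var <- dft$var
      grid <- seq(dft$from, dft$to, length.out = dft$length)
    }
    params <- preset_parameters(params, ...)
  } else {
    stopifnot(inherits(params, "scaled_parameters"))
    if (...length()) params <- update_parameters(params, ...)
  }
  if (!var %in% setdiff(param_keys, "n"))
    stop("unknown sweep variable '", var, "'")
  if (is.null(grid) || !length(grid)) stop("empty sweep grid")
  rows <- lapply(grid, function(v) {
    p <- do.call(update_parameters,
                 c(list(params), stats::setNames(list(v), var)))
    tr <- triggering_rate(p)
    c(coef(p),
      x = tr$equilibrium$x, r = tr$equilibrium$r,
      eps = tr$equilibrium$eps, zeta = tr$equilibrium$zeta,
      P00 = tr$P00, P0_star = tr$P0_star, w = tr$w,
      residual = tr$equilibrium$residual)
  })
  out <- as.data.frame(do.call(rbind, rows))
  structure(out, class = c("sensitivity_sweep", "data.frame"),
            sweep_var = var, base_params = params)
}

#' @export
plot.sensitivity_sweep <- function(x, y, log = "", ...) {
  v <- attr(x, "sweep_var")
  graphics::plot(x[[v]], x$w, type = "l", log = log, xlab = v,
                 ylab = "scaled functional sensitivity w", ...)
  invisible(x)
}

#' Locate the CD8-density minimum of functional sensitivity
#'
#' The functional sensitivity `w(x_T)` can have an interior minimum — a
#' CD8 density at which the T-cell is least responsive to a given ligand.
#' This scans `w` on a grid over `interval` and refines the grid argmin
#' by golden-section search between its neighbouring grid points.
#'
#' @param params a [scaled_parameters()] object or preset name.
#' @param interval length-2 range of `x_T` to search.
#' @param n_grid number of scan points.
#' @param ... overrides forwarded to the parameter constructor.
#' @return A list with `x_T` (the minimiser), `w` (the minimum), and the
#'   scan table.
#' @export
find_sensitivity_dip <- function(params, interval = c(1, 200),
                                 n_grid = 400L, ...) {
  if (is.character(params)) params <- preset_parameters(params, ...)
  else if (...length()) params <- update_parameters(params, ...)
  grid <- seq(interval[1], interval[2], length.out = n_grid)
  wfun <- function(v) triggering_rate(update_parameters(params,
                                                        x_T = v))$w
  wv <- vapply(grid, wfun, numeric(1))
  k <- which.min(wv)
  lo <- grid[max(k - 1L, 1L)]
  hi <- grid[min(k + 1L, n_grid)]
  opt <- golden_section(wfun, lo, hi, tol = 1e-6 * diff(interval))
  list(x_T = opt$x, w = opt$f,
       scan = data.frame(x_T = grid, w = wv))
}

# plain golden-section minimisation on [lo, hi]
golden_section <- function(f, lo, hi, tol = 1e-8) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - phi * (b - a); d <- a + phi * (b - a)
  fc <- f(c); fd <- f(d)
  while (b - a > tol) {
    if (fc < fd) {
      b <- d; d <- c; fd <- fc
      c <- b - phi * (b - a); fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + phi * (b - a); fd <- f(d)
    }
  }
  x <- (a + b) / 2
  list(x = x, f = f(x))
}

#' Write / read sweep tables with a provenance header
#'
#' Sweep CSVs begin with `#`-prefixed header lines recording the package
#' version, the fixed parameter set and the sweep variable, so a run can
#' be reproduced from the file alone.
#'
#' @param sweep a `sensitivity_sweep` from [run_sweep()].
#' @param path output file.
#' @return `write_sweep_csv` returns `path` invisibly; `read_sweep_csv`
#'   returns a data.frame (header lines are skipped).
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sensitivity_sweep"))
  p <- attr(sweep, "base_params")
  hdr <- c(sprintf("# tcrdegen %s",
                   as.character(utils::packageVersion("tcrdegen"))),
           sprintf("# sweep_var: %s", attr(sweep, "sweep_var")),
           sprintf("# params: %s",
                   paste(sprintf("%s=%.15g", names(coef(p)), coef(p)),
                         collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(sweep), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Degeneracy curves for a panel of CD8-affinity variants
#'
#' Applies each affinity scenario to a reference parameter set (see
#' [apply_mutant()]) and computes its degeneracy curve on a common
#' threshold grid, so the variants can be compared for dominance.
#'
#' @param base reference (wild-type) [scaled_parameters()].
#' @param ens an [energy_ensemble()].
#' @param variants data.frame with columns `name`, `K_D` (defaults to the
#'   built-in [cd8_mutants()] table); the reference `K_D` is taken from
#'   the `"wild-type"` row if present, else the first row.
#' @param omega_grid common threshold grid; defaults to the grid derived
#'   from the reference set.
#' @param ... passed to [degeneracy_curve()].
#' @return A named list of `degeneracy_curve` objects, ordered as
#'   `variants`.
#' @export
mutant_degeneracy_panel <- function(base, ens, variants = cd8_mutants(),
                                    omega_grid = NULL, ...) {
  stopifnot(all(c("name", "K_D") %in% names(variants)))
  ref_K <- if ("wild-type" %in% variants$name)
    variants$K_D[variants$name == "wild-type"][1] else variants$K_D[1]
  if (is.null(omega_grid))
    omega_grid <- degeneracy_curve(base, ens, ...)$omega
  curves <- lapply(seq_len(nrow(variants)), function(i) {
    sc <- mutant_scenario(variants$name[i], K_D = variants$K_D[i],
                          reference_K_D = ref_K)
    degeneracy_curve(apply_mutant(base, sc), ens,
                     omega_grid = omega_grid, ...)
  })
  stats::setNames(curves, variants$name)
}
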