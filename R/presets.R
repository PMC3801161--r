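#' Named parameter presets
#'
#' Ready-made scaled parameter sets for the regimes the model is designed
#' to explore, each paired (where relevant) with a default off-rate
#' ensemble and a natural sweep variable:
#'
#' * `ligand_focusing` — fast pMHCI/CD8 exchange on the TCR-bound state
#'   (`delta = 300`, `nu = 0.5`, `kappa = 5`); produces the
#'   CD8-density dip in `w(x_T)` near `x_T = 50` and the associated
#'   degeneracy-band behaviour. Ensemble `ln(alpha) ~ N(2, 0.2^2)`.
#' * `weak_coupling` — weak kinetic effect of CD8 binding
#'   (`delta = 2.5`, `nu = 0.05`, `kappa = 1`); CD8 density
#'   differentially tunes ligands with `alpha` above vs below 1.
#' * `strong_coupling` — strong kinetic effect (`delta = 3`, `nu = 300`,
#'   `gamma_kin = 0.05`, `gamma_off = 0.2`, `kappa = 2`); each ligand has
#'   an optimal CD8 level set by its off-rate.
#' * `mutant_panel` — regime for the HLA CD8-affinity variant comparison
#'   (`delta = 0.2`, `nu = 0.05`, `gamma_R = 0.2`, `x_T = 10`); ensemble
#'   `ln(alpha) ~ N(5, 0.5^2)`.
#' * `mutant_panel_fast` — as `mutant_panel` but with a strong CD8
#'   kinetic effect (`nu = 10`), which reverses the variant ordering.
#'
#' All presets use `n = 100` phosphorylation steps and scaled total
#' densities `m_T = 10`, `r_T = 10`.
#'
#' @param preset preset name.
#' @param ... optional field overrides forwarded to
#'   [update_parameters()], e.g. `alpha = 2.5` or `x_T = 100`.
#' @return A [scaled_parameters()] object. `preset_ensemble()` returns
#'   the matching [energy_ensemble()] (with the given seed);
#'   `preset_names()` lists the available presets.
#' @examples
#' preset_parameters("ligand_focusing", alpha = 2.5)
#' preset_ensemble("mutant_panel", seed = 11)
#' @export
preset_parameters <- function(preset, ...) {
  spec <- preset_table()[[preset]]
  if (is.null(spec)) stop("unknown preset '", preset, "'; available: ",
                          paste(preset_names(), collapse = ", "))
  p <- do.call(scaled_parameters, spec$params)
  if (...length()) p <- update_parameters(p, ...)
  p
}

#' @param seed seed for the returned ensemble.
#' @rdname preset_parameters
#' @export
preset_ensemble <- function(preset, seed = 1L) {
  spec <- preset_table()[[preset]]
  if (is.null(spec)) stop("unknown preset '", preset, "'; available: ",
                          paste(preset_names(), collapse = ", "))
  if (is.null(spec$ensemble))
    stop("preset '", preset, "' has no associated off-rate ensemble")
  energy_ensemble(spec$ensemble$mu, spec$ensemble$sigma, seed = seed)
}

#' @rdname preset_parameters
#' @export
preset_names <- function() names(preset_table())

preset_table <- function() {
  base <- list(m_T = 10, r_T = 10, n = 100L)
  list(
    ligand_focusing = list(
      params = c(base, list(x_T = 50, alpha = 2.5, delta = 300, nu = 0.5,
                            kappa = 5, gamma_off = 0.5, gamma_kin = 0.5,
                            gamma_R = 0.3)),
      ensemble = list(mu = 2, sigma = 0.2),
      sweep = list(var = "x_T", from = 1, to = 200, length = 400L)),
    weak_coupling = list(
      params = c(base, list(x_T = 10, alpha = 1, delta = 2.5, nu = 0.05,
                            kappa = 1, gamma_off = 0.5, gamma_kin = 0.5,
                            gamma_R = 0.5)),
      ensemble = NULL,
      sweep = list(var = "x_T", from = 0, to = 200, length = 400L)),
    strong_coupling = list(
      params = c(base, list(x_T = 10, alpha = 2, delta = 3, nu = 300,
                            kappa = 2, gamma_off = 0.2, gamma_kin = 0.05,
                            gamma_R = 0.5)),
      ensemble = NULL,
      sweep = list(var = "x_T", from = 0, to = 200, length = 400L)),
    mutant_panel = list(
      params = c(base, list(x_T = 10, alpha = 1, delta = 0.2, nu = 0.05,
                            kappa = 1, gamma_off = 0.5, gamma_kin = 0.5,
                            gamma_R = 0.2)),
      ensemble = list(mu = 5, sigma = 0.5),
      sweep = list(var = "alpha", from = 0.1, to = 100, length = 200L)),
    mutant_panel_fast = list(
      params = c(base, list(x_T = 10, alpha = 1, delta = 0.2, nu = 10,
                            kappa = 1, gamma_off = 0.5, gamma_kin = 0.5,
                            gamma_R = 0.2)),
      ensemble = list(mu = 5, sigma = 0.5),
      sweep = list(var = "alpha", from = 0.1, to = 100, length = 200L)))
}

default_sweep <- function(name) preset_table()[[name]]$sweep
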