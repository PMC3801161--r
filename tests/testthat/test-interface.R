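test_that("preset parameter values are frozen", {
  expect_setequal(preset_names(),
                  c("ligand_focusing", "weak_coupling", "strong_coupling",
                    "mutant_panel", "mutant_panel_fast"))
  expect_equal(coef(preset_parameters("ligand_focusing")),
               c(m_T = 10, x_T = 50, r_T = 10, alpha = 2.5, delta = 300,
                 nu = 0.5, kappa = 5, gamma_off = 0.5, gamma_kin = 0.5,
                 gamma_R = 0.3, n = 100))
  expect_equal(coef(preset_parameters("weak_coupling")),
               c(m_T = 10, x_T = 10, r_T = 10, alpha = 1, delta = 2.5,
                 nu = 0.05, kappa = 1, gamma_off = 0.5, gamma_kin = 0.5,
                 gamma_R = 0.5, n = 100))
  expect_equal(coef(preset_parameters("strong_coupling")),
               c(m_T = 10, x_T = 10, r_T = 10, alpha = 2, delta = 3,
                 nu = 300, kappa = 2, gamma_off = 0.2, gamma_kin = 0.05,
                 gamma_R = 0.5, n = 100))
  expect_equal(coef(preset_parameters("mutant_panel")),
               c(m_T = 10, x_T = 10, r_T = 10, alpha = 1, delta = 0.2,
                 nu = 0.05, kappa = 1, gamma_off = 0.5, gamma_kin = 0.5,
                 gamma_R = 0.2, n = 100))
  expect_equal(coef(preset_parameters("mutant_panel_fast"))[["nu"]], 10)
  ens <- preset_ensemble("ligand_focusing")
  expect_equal(c(ens$mu, ens$sigma), c(2, 0.2))
  ens5 <- preset_ensemble("mutant_panel")
  expect_equal(c(ens5$mu, ens5$sigma), c(5, 0.5))
  expect_error(preset_parameters("no_such_regime"), "unknown preset")
  expect_error(preset_parameters("ligand_focusing", bogus = 1),
               "bogus")
})

test_that("sweeps carry all inputs and outputs, one row per grid point", {
  sw <- run_sweep("ligand_focusing", var = "x_T", grid = c(10, 50, 150),
                  alpha = 2.5)
  expect_s3_class(sw, "sensitivity_sweep")
  expect_identical(nrow(sw), 3L)
  expect_true(all(c("m_T", "x_T", "alpha", "x", "r", "eps", "zeta",
                    "P00", "P0_star", "w", "residual") %in% names(sw)))
  expect_identical(sw$x_T, c(10, 50, 150))
  expect_true(all(sw$residual < 1e-10))
  # single-point grid
  one <- run_sweep(preset_parameters("weak_coupling"), var = "alpha",
                   grid = 2)
  expect_identical(nrow(one), 1L)
  expect_equal(one$w, triggering_rate(preset_parameters("weak_coupling",
                                                        alpha = 2))$w)
  expect_error(run_sweep("ligand_focusing", var = "zz", grid = 1:3),
               "zz")
})

test_that("parameter files round-trip through YAML and JSON", {
  p <- preset_parameters("strong_coupling")
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_parameters(p, f)
    expect_equal(coef(read_parameters(f)), coef(p))
  }
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(m_T = 1), f, auto_unbox = TRUE)
  expect_error(read_parameters(f), "missing key")
})

test_that("sweep CSV keeps a provenance header and round-trips the table", {
  sw <- run_sweep("ligand_focusing", var = "x_T", grid = c(5, 25, 125))
  f <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(sw, f)
  hdr <- readLines(f, n = 3)
  expect_true(all(startsWith(hdr, "#")))
  expect_match(hdr[2], "sweep_var: x_T")
  expect_match(hdr[3], "alpha=2.5")
  back <- read_sweep_csv(f)
  expect_equal(back$w, sw$w, tolerance = 1e-12)
})

test_that("model methods: print, summary, coef and stochastic simulate", {
  p <- preset_parameters("weak_coupling")
  expect_output(print(p), "Scaled TCR")
  expect_output(print(solve_equilibrium(p)), "free CD8")
  tr <- triggering_rate(p)
  expect_output(summary(tr), "proofreading")
  expect_named(coef(p)["kappa"], "kappa")
  sim <- simulate(p, nsim = 5000, seed = 17)
  expect_lt(binom_z(sim$P00, tr$P00, 5000), 4)
})

test_that("command-line entry point script ships with the package commands", {
  script <- system.file("scripts", "tcrdegen", package = "tcrdegen")
  if (!nzchar(script))
    script <- file.path("..", "..", "inst", "scripts", "tcrdegen")
  expect_true(file.exists(script))
  src <- readLines(script)
  for (cmd in c("sweep", "degeneracy", "band", "mutants", "validate"))
    expect_true(any(grepl(cmd, src, fixed = TRUE)))
})
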