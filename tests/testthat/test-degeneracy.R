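test_that("off-rate sampling matches the stated energy model", {
  # near-degenerate spread collapses onto exp(mu)
  ens0 <- energy_ensemble(mu = 2, sigma = 1e-12, seed = 4)
  expect_equal(sample_alpha(ens0, 50), rep(exp(2), 50), tolerance = 1e-9)
  # ln(alpha) ~ N(mu, sigma^2): CLT recovery of the mean at both
  # published ensemble settings
  for (ms in list(c(2, 0.2), c(5, 0.5))) {
    ens <- energy_ensemble(mu = ms[1], sigma = ms[2], seed = 8)
    la <- log(sample_alpha(ens, 1e5))
    expect_lt(abs(mean(la) - ms[1]), 3 * ms[2] / sqrt(1e5))
    expect_true(all(exp(la) > 0))
  }
})

test_that("sampling is seed-deterministic, bit for bit", {
  ens <- energy_ensemble(2, 0.2, seed = 99)
  expect_identical(sample_alpha(ens, 1000), sample_alpha(ens, 1000))
  p <- preset_parameters("ligand_focusing", x_T = 100)
  d1 <- degeneracy_curve(p, ens, method = "monte_carlo", n_samples = 5000)
  d2 <- degeneracy_curve(p, ens, method = "monte_carlo", n_samples = 5000)
  expect_identical(d1$prob, d2$prob)
})

test_that("degeneracy curve endpoints: certainty at zero, impossibility above the max", {
  p <- preset_parameters("ligand_focusing", x_T = 100)
  ens <- energy_ensemble(2, 0.2, seed = 1)
  dc <- degeneracy_curve(p, ens, omega_grid = c(0, 0.01, 1e6))
  expect_identical(dc$prob[1], 1)   # w > 0 almost surely
  expect_identical(dc$prob[3], 0)   # above the attainable maximum
})

test_that("degeneracy curves are nonincreasing for every preset regime", {
  ens <- energy_ensemble(2, 0.2, seed = 2)
  for (nm in preset_names()) {
    dc <- degeneracy_curve(preset_parameters(nm), ens)
    expect_true(all(diff(dc$prob) <= 1e-12))
    expect_true(all(dc$prob >= 0 & dc$prob <= 1))
  }
})

test_that("semi-analytic tail mass agrees with Monte Carlo where sampling can see it", {
  p <- preset_parameters("ligand_focusing", x_T = 100)
  ens <- energy_ensemble(2, 0.2, seed = 21)
  sa <- degeneracy_curve(p, ens)
  mc <- degeneracy_curve(p, ens, omega_grid = sa$omega,
                         method = "monte_carlo", n_samples = 1e5)
  idx <- which(sa$prob > 1e-3)
  expect_mc_consistent(mc$prob[idx], sa$prob[idx], 1e5)
})

test_that("unsorted threshold grids are rejected", {
  p <- preset_parameters("ligand_focusing")
  ens <- energy_ensemble(2, 0.2)
  expect_error(degeneracy_curve(p, ens, omega_grid = c(1, 0.5)),
               "ascending")
})

test_that("activation band scan flags a U-shaped operating profile", {
  act <- activation_model(omega_crit = 0.12)
  p <- preset_parameters("ligand_focusing")
  ens <- preset_ensemble("ligand_focusing", seed = 6)
  grid <- seq(1, 200, length.out = 30)
  bs <- activation_band_scan(act, p, ens, grid)
  k <- which.min(bs$prob)
  expect_gt(k, 1); expect_lt(k, nrow(bs))        # interior minimum
  # flags partition a U-shaped profile into at most 3 runs per side
  runs <- rle(bs$flag)
  expect_lte(length(runs$lengths), 5)
  # threshold derived from the cellular triple
  act2 <- activation_model(Z = 10, T_I = 100, W_act = 120)
  expect_equal(act2$omega_crit, 0.12)
  # zero activation threshold: always above band
  bs0 <- activation_band_scan(activation_model(omega_crit = 0), p, ens,
                              c(1, 50))
  expect_identical(bs0$prob, c(1, 1))
  expect_identical(unique(bs0$flag), "above")
})

test_that("CD8-affinity variant panel is ordered by binding strength", {
  wt <- preset_parameters("mutant_panel")
  ens <- preset_ensemble("mutant_panel", seed = 12)
  pan <- mutant_degeneracy_panel(wt, ens)
  probs <- sapply(pan, function(d) d$prob)
  # strongest CD8 binder (A2/a3kb, lowest K_D) dominates; weakest
  # (A245V) is dominated -- monotone pointwise in K_D order
  ord <- c("A245V", "wild-type", "Q115E", "A2/a3kb")
  for (i in 1:3)
    expect_true(all(probs[, ord[i]] <= probs[, ord[i + 1]] + 1e-12))
  # a strong kinetic effect of CD8 recruitment reverses the tail order
  fast <- preset_parameters("mutant_panel_fast")
  pan_f <- mutant_degeneracy_panel(fast, ens)
  pf <- sapply(pan_f, function(d) d$prob)
  tail_idx <- max(which(pf[, "A245V"] > 1e-6))
  expect_gt(pf[tail_idx, "A245V"], pf[tail_idx, "A2/a3kb"])
})

test_that("ligand universe counts: worked examples, domain edges, symmetry", {
  expect_identical(ligand_universe_size(9, 2, 1), 140)
  expect_identical(ligand_universe_size(9, 2, 4), 5.6e6)
  expect_warning(out <- ligand_universe_size(9, 2, 0), "m = 0")
  expect_identical(out, 1)
  expect_error(ligand_universe_size(9, 2, 8), "non-anchor")
  # binomial symmetry: count(m)/20^m == count(n-a-m)/20^(n-a-m)
  for (m in 1:6) {
    expect_equal(ligand_universe_size(9, 2, m) / 20^m,
                 ligand_universe_size(9, 2, 7 - m) / 20^(7 - m))
  }
})
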