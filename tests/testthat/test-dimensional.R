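test_that("the binding cycle closes: K1 K2 = K3 K4 by construction", {
  set.seed(31)
  for (i in 1:20) {
    kin <- random_kinetics()
    expect_equal(kin$K1 * kin$K2, kin$K3 * kin$K4, tolerance = 1e-10)
  }
  # a supplied lambda_m2 that breaks the cycle is rejected
  kin <- random_kinetics()
  expect_error(dimensional_kinetics(
    Lambda1 = kin$Lambda1, Lambda2 = kin$Lambda2, Lambda3 = kin$Lambda3,
    lambda_m1 = kin$lambda_m1, lambda_m3 = kin$lambda_m3,
    lambda_m2 = kin$lambda_m2 * 2, gamma_on = kin$gamma_on,
    gamma_off = kin$gamma_off, M_T = kin$M_T, X_T = kin$X_T,
    R_T = kin$R_T, T_R = kin$T_R, T_R_star = kin$T_R_star),
    "detailed balance")
})

test_that("non-dimensionalisation has the defining special cases", {
  kin <- dimensional_kinetics(Lambda1 = 1e-10, Lambda2 = 1e-10,
                              Lambda3 = 1e-10, lambda_m1 = 0.1,
                              lambda_m3 = 0.1, gamma_on = 1.5,
                              gamma_off = 0.6, M_T = 1e9, X_T = 1e9,
                              R_T = 1e9, T_R = 10, T_R_star = 5)
  p <- to_scaled(kin, n = 50)
  expect_equal(p$kappa, 1)          # K1 = K3
  expect_equal(p$alpha, 1)          # lambda_m1 = 1/T_R
  expect_equal(p$gamma_R, 0.5)
  expect_equal(p$gamma_kin, 0.6 / 1.5)
})

test_that("scaled occupancies reproduce dimensional densities (round trip)", {
  set.seed(32)
  for (i in 1:20) {
    kin <- random_kinetics()
    p <- to_scaled(kin, n = 60)
    eq <- solve_equilibrium(p)
    bd <- bound_densities(kin, n = 60)
    expect_equal(bd$M_R / kin$M_T, eq$eps, tolerance = 1e-10)
    expect_equal(bd$M_XR / kin$M_T, eq$zeta, tolerance = 1e-10)
    expect_equal(bd$M / kin$M_T, eq$frac_free, tolerance = 1e-10)
    # scaled triggering rate equals the dimensional rate over M_T lambda
    forms <- triggering_rate_forms(kin, n = 60)
    expect_equal(forms$w_scaled, triggering_rate(p)$w, tolerance = 1e-10)
  }
})

test_that("bound densities satisfy conservation and detailed balance", {
  set.seed(33)
  for (i in 1:20) {
    kin <- random_kinetics()
    bd <- bound_densities(kin)
    expect_equal(bd$M + bd$M_R + bd$M_X + bd$M_XR, kin$M_T,
                 tolerance = 1e-10)
    expect_equal(bd$X + bd$M_X + bd$M_XR, kin$X_T, tolerance = 1e-10)
    expect_equal(bd$R + bd$M_R + bd$M_XR, kin$R_T, tolerance = 1e-10)
    if (bd$M_R > 0) {
      # each elementary reaction individually balanced
      expect_equal(kin$Lambda1 * bd$R * bd$M, kin$lambda_m1 * bd$M_R,
                   tolerance = 1e-10 * kin$lambda_m1 * bd$M_R)
      expect_equal(kin$Lambda2 * bd$X * bd$M_R, kin$lambda_m2 * bd$M_XR,
                   tolerance = 1e-10 * max(kin$lambda_m2 * bd$M_XR,
                                           .Machine$double.xmin))
    }
  }
})

test_that("affinity-constant and gamma_kin occupancy forms agree", {
  set.seed(34)
  for (i in 1:20) {
    kin <- random_kinetics()
    bd <- bound_densities(kin)
    ref <- densities_affinity_form(kin, bd$R, bd$X)
    expect_equal(bd$M_R, ref$M_R, tolerance = 1e-12)
    expect_equal(bd$M_X, ref$M_X, tolerance = 1e-12)
    expect_equal(bd$M_XR, ref$M_XR, tolerance = 1e-12)
  }
})

test_that("association- and dissociation-rate forms of W coincide", {
  set.seed(35)
  for (i in 1:20) {
    forms <- triggering_rate_forms(random_kinetics(), n = 40)
    expect_equal(forms$W_assoc, forms$W_dissoc,
                 tolerance = 1e-10)
  }
})

test_that("degenerate totals knock out the right complexes", {
  kin <- random_kinetics()
  no_cd8 <- dimensional_kinetics(Lambda1 = kin$Lambda1,
    Lambda2 = kin$Lambda2, Lambda3 = kin$Lambda3,
    lambda_m1 = kin$lambda_m1, lambda_m3 = kin$lambda_m3,
    gamma_on = kin$gamma_on, gamma_off = kin$gamma_off, M_T = kin$M_T,
    X_T = 0, R_T = kin$R_T, T_R = kin$T_R, T_R_star = kin$T_R_star)
  bd <- bound_densities(no_cd8)
  expect_equal(bd$M_X, 0)
  expect_equal(bd$M_XR, 0)
  no_tcr <- dimensional_kinetics(Lambda1 = kin$Lambda1,
    Lambda2 = kin$Lambda2, Lambda3 = kin$Lambda3,
    lambda_m1 = kin$lambda_m1, lambda_m3 = kin$lambda_m3,
    gamma_on = kin$gamma_on, gamma_off = kin$gamma_off, M_T = kin$M_T,
    X_T = kin$X_T, R_T = 0, T_R = kin$T_R, T_R_star = kin$T_R_star)
  bd <- bound_densities(no_tcr)
  expect_equal(bd$M_R, 0)
  expect_equal(bd$M_XR, 0)
  expect_equal(bd$W, 0)
})

test_that("affinity rescaling acts on kappa, x_T and nu only, as a group action", {
  wt <- preset_parameters("mutant_panel")
  expect_equal(coef(apply_mutant(wt, 1)), coef(wt))
  sc <- mutant_scenario("A2/a3kb")
  expect_equal(sc$rho, 10.87 / 137.1)
  mut <- apply_mutant(wt, sc)
  expect_equal(mut$kappa, wt$kappa * 137.1 / 10.87)
  expect_equal(mut$x_T, wt$x_T * 137.1 / 10.87)
  expect_equal(mut$nu, wt$nu * 10.87 / 137.1)
  for (f in c("m_T", "r_T", "alpha", "delta", "gamma_off", "gamma_kin",
              "gamma_R", "n"))
    expect_identical(mut[[f]], wt[[f]])
  # weakened CD8 binding (larger K_D) means fewer effective co-receptors
  expect_lt(apply_mutant(wt, mutant_scenario("A245V"))$x_T, wt$x_T)
  # composition: rho1 then rho2 equals rho1 * rho2
  two_step <- apply_mutant(apply_mutant(wt, 1.7), 0.4)
  expect_equal(coef(two_step), coef(apply_mutant(wt, 1.7 * 0.4)),
               tolerance = 1e-14)
  expect_error(apply_mutant(wt, -2), "positive")
})
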