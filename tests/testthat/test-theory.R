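# Carnahan-Starling / BMCSL chemical potentials, partition and two-state
# equilibrium solvers, close-packing limits.

test_that("ideal partition coefficient is exp(eps_c)", {
  expect_equal(kc_ideal(0), 1)
  expect_equal(kc_ideal(7), exp(7), tolerance = 1e-12)
  ec <- seq(0, 10, by = 0.5)
  expect_true(all(diff(kc_ideal(ec)) > 0))
})

test_that("Carnahan-Starling excess chemical potential", {
  expect_equal(cs_mu_excess(0), 0)
  expect_equal(cs_mu_excess(0.3), 1.671 / 0.343, tolerance = 1e-6)
  # virial limit mu_ex -> 8 eta
  expect_lt(abs(cs_mu_excess(0.01) / 0.01 - 8), 0.5)
  expect_error(cs_mu_excess(1), "eta")
  expect_error(cs_mu_excess(-0.1), "eta")
  expect_warning(cs_mu_excess(0.6, warn = TRUE), "0.5")
})

test_that("BMCSL reduces to Carnahan-Starling for equal diameters", {
  for (eta in c(1e-4, 0.05, 0.2, 0.4, 0.6)) {
    for (split in c(0.1, 0.5, 0.9)) {
      etas <- c(split, 1 - split) * eta
      expect_lt(abs(bmcsl_mu_excess(etas, c(3, 3), 1) - cs_mu_excess(eta)),
                1e-10)
      expect_lt(abs(bmcsl_mu_excess(etas, c(3, 3), 2) - cs_mu_excess(eta)),
                1e-10)
    }
  }
  # zero-density limits
  expect_equal(bmcsl_mu_excess(c(0, 0), c(1, 2), 1), 0)
  # one species dilute: the other species' mu_ex equals its one-component
  # value; the dilute species' value is finite
  m1 <- bmcsl_mu_excess(c(0.3, 0), c(1, 5.1), 1)
  expect_equal(m1, cs_mu_excess(0.3), tolerance = 1e-10)
  expect_true(is.finite(bmcsl_mu_excess(c(0.3, 0), c(1, 5.1), 2)))
  expect_gt(bmcsl_mu_excess(c(0.3, 0), c(1, 5.1), 2), m1)
})

test_that("no-assembly partitioning: closed form, limits and exact cases", {
  p_is <- theory_params(rho_T = 3e-4, V_r = 5.03e-3, eps_c = 4,
                        mode = "ideal")
  s <- solve_partition_no_assembly(p_is)
  expect_equal(s$K_c, exp(4), tolerance = 1e-10)
  # hard-sphere with vanishing diameters matches ideal
  p_hs0 <- theory_params(rho_T = 3e-4, V_r = 5.03e-3, eps_c = 4,
                         mode = "hard_sphere", sigma_sub = 1e-5,
                         sigma_cap = 2e-5)
  expect_equal(solve_partition_no_assembly(p_hs0)$K_c, exp(4),
               tolerance = 1e-8)
  # eps_c = 0: symmetric phases
  p0 <- theory_params(rho_T = 3e-4, V_r = 5.03e-3, eps_c = 0,
                      mode = "hard_sphere")
  expect_equal(solve_partition_no_assembly(p0)$K_c, 1, tolerance = 1e-9)
})

test_that("excluded volume reduces K_c below ideal, vanishing at low density", {
  for (ec in c(2, 5, 7)) {
    prev_ratio <- 0
    for (rt in c(1e-6, 1e-4, 5e-4)) {
      p <- theory_params(rho_T = rt, V_r = 5.03e-3, eps_c = ec,
                         mode = "hard_sphere")
      s <- solve_partition_no_assembly(p)
      expect_lte(s$K_c, kc_ideal(ec) * (1 + 1e-9))
      ratio <- s$K_c / kc_ideal(ec)
      expect_true(ratio <= 1 + 1e-9)
    }
    p_dilute <- theory_params(rho_T = 1e-8, V_r = 5.03e-3, eps_c = ec,
                              mode = "hard_sphere")
    expect_equal(solve_partition_no_assembly(p_dilute)$K_c, kc_ideal(ec),
                 tolerance = 1e-3)
  }
})

test_that("phase solutions conserve mass and satisfy the yield identity", {
  for (mode in c("ideal", "hard_sphere")) {
    p <- theory_params(rho_T = 4e-4, V_r = 5e-3, eps_c = 7, eps_ss = 6,
                       mode = mode)
    s <- solve_two_state_equilibrium(p)
    # mass conservation, relative
    expect_lt(abs(s$rho_mean - p$rho_T) / p$rho_T, 1e-8)
    expect_lt(abs(s$f_c - (s$f_c_c + s$f_c_bg)), 1e-12)
    expect_true(s$f_c >= 0 && s$f_c <= 1)
    expect_true(all(c(s$rho1_c, s$rho1_bg, s$rhocap_c, s$rhocap_bg) >= 0))
  }
})

test_that("two-state solver reduces to no-assembly when dG_cap -> +Inf", {
  p <- theory_params(rho_T = 4e-4, V_r = 5e-3, eps_c = 5,
                     mode = "hard_sphere", dG_cap = Inf)
  s1 <- solve_two_state_equilibrium(p)
  s2 <- solve_partition_no_assembly(p)
  expect_equal(s1$K_c, s2$K_c, tolerance = 1e-9)
  expect_equal(s1$rhocap_c, 0)
  expect_equal(s1$f_c, 0)
})

test_that("ideal yield is monotone in density; hard-sphere yield is not", {
  grid <- 10^seq(log10(5e-5), log10(1e-3), length.out = 12)
  yi <- yield_curve(grid, model = "dodecahedron", V_r = 5e-3, eps_c = 7,
                    eps_ss = 6, mode = "ideal")
  expect_true(all(diff(yi$f_c) >= -1e-9))
  yh <- yield_curve(grid, model = "dodecahedron", V_r = 5e-3, eps_c = 7,
                    eps_ss = 6, mode = "hard_sphere")
  imax <- which.max(yh$f_c)
  expect_gt(imax, 1)
  expect_lt(imax, length(grid))
  expect_gt(max(yh$f_c) - yh$f_c[length(grid)], 0.05)
})

test_that("condensate capsid density saturates as total density grows", {
  grid <- c(4e-4, 6e-4, 8e-4, 1e-3)
  rc <- vapply(grid, function(rt) {
    solve_two_state_equilibrium(
      theory_params(rho_T = rt, V_r = 5e-3, eps_c = 7, eps_ss = 6,
                    mode = "hard_sphere"))$rhocap_c
  }, numeric(1))
  # the log-log growth rate collapses beyond the optimum
  slopes <- diff(log(rc)) / diff(log(grid))
  expect_lt(slopes[3], 0.1)
  expect_lt(slopes[3], 0.2 * slopes[1])
})

test_that("smaller capsid diameter raises the equilibrium yield at high density", {
  y_big <- solve_two_state_equilibrium(
    theory_params(rho_T = 6e-4, V_r = 5e-3, eps_c = 7, eps_ss = 6,
                  mode = "hard_sphere", sigma_cap = 5.1))$f_c
  y_small <- solve_two_state_equilibrium(
    theory_params(rho_T = 6e-4, V_r = 5e-3, eps_c = 7, eps_ss = 6,
                  mode = "hard_sphere", sigma_cap = 4.6))$f_c
  expect_gt(y_small, y_big)
})

test_that("close packing concentration and threshold volume ratio", {
  expect_equal(close_packing_concentration(1), sqrt(2), tolerance = 1e-12)
  expect_equal(close_packing_concentration(5.1), sqrt(2) / 5.1^3,
               tolerance = 1e-12)
  expect_equal(close_packing_concentration(5.1), 1.066e-2, tolerance = 1e-3)
  expect_equal(close_packing_concentration(2), sqrt(2) / 8, tolerance = 1e-12)

  vr <- threshold_volume_ratio(4.00e-4, 12, 1.28e-2)
  expect_equal(vr, 2.61e-3, tolerance = 1e-3)
  expect_error(threshold_volume_ratio(1, 12, 1.28e-2), "exceed")
  rts <- seq(1e-4, 1e-3, by = 1e-4)
  expect_true(all(diff(vapply(rts, threshold_volume_ratio, numeric(1),
                              N_cap = 12, rho_CP = 1.28e-2)) > 0))
})

test_that("close-packed yield bound", {
  expect_equal(close_packed_yield(2.61e-3, 2.61e-3), 1)
  vstar <- 2.61e-3
  expect_equal(close_packed_yield(vstar / 2, vstar),
               (1 / vstar + 1) / (2 / vstar + 1), tolerance = 1e-12)
  expect_equal(close_packed_yield(vstar / 2, vstar), 0.5006, tolerance = 1e-3)
  vr <- seq(vstar / 10, vstar, length.out = 20)
  expect_true(all(diff(close_packed_yield(vr, vstar)) > 0))
  expect_equal(close_packed_yield(10 * vstar, vstar), 1)
})

test_that("dG_cap estimator scales with binding strength", {
  d6 <- dg_capsid(6)
  d7 <- dg_capsid(7)
  expect_lt(d6, 0)
  expect_lt(d7, d6)   # stronger binding, more negative
  # per-bond well depth is twice the contact minimum
  per_bond <- -2 * pair_energy(tab_dodeca6, "A", "A", 1e-12)
  expect_equal(d6, -30 * (per_bond - 7.153), tolerance = 1e-9)
})

test_that("effective subunit diameter is physically sensible and cached", {
  sig <- effective_subunit_diameter(tpl_dodeca, tab_dodeca0,
                                    n_orient = 100, n_r = 60)
  # between the B-T contact scale and the circumsphere
  expect_gt(sig, 1.0)
  expect_lt(sig, 2 * tpl_dodeca$circumradius + 0.5)
})
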