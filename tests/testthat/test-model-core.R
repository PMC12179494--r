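test_that("rhs matches the written equations at simple states", {
  tp <- apply_temperature(dflt, 20)
  # at the origin every flux except litter input vanishes
  d0 <- awb_rhs(pool_state(0, 0, 0, 0), tp, dflt, 0.1)
  expect_equal(unname(d0), c(dflt$I, 0, 0, 0))
  # all four derivatives vanish at a solved equilibrium
  eq <- solve_equilibrium(tp, dflt, 0.1)
  expect_true(eq$feasible)
  expect_lt(max(abs(awb_rhs(eq$state, tp, dflt, 0.1))), 1e-9)
})

test_that("rhs and respiration satisfy the mass-balance identity", {
  tp <- apply_temperature(dflt, 17)
  set.seed(11)
  for (i in 1:50) {
    s <- rand_state()
    phi <- stats::runif(1, 0, 0.9)
    d <- awb_rhs(s, tp, dflt, phi)
    lhs <- sum(d)
    rhs_oracle <- dflt$I - dflt$eC * s[["C"]] - dflt$eD * s[["D"]] -
      respiration_flux(s, tp, dflt, phi)
    expect_equal(lhs, rhs_oracle, tolerance = 1e-12)
  }
})

test_that("rhs and respiration reject invalid inputs", {
  tp <- apply_temperature(dflt, 20)
  s <- pool_state(1, 1, 1, 1)
  expect_error(awb_rhs(s, tp, dflt, 1), "phi")
  expect_error(awb_rhs(s, tp, dflt, -0.1), "phi")
  expect_error(awb_rhs(c(C = -1, D = 1, M = 1, Z = 1), tp, dflt, 0.1),
               "negative pool")
  expect_error(respiration_flux(s, tp, dflt, 1.2), "phi")
})

test_that("respiration flux limits: perfect efficiency and no biomass", {
  p1 <- dflt
  p1$gM <- 1
  p1$gZ <- 1
  p1 <- do.call(awb_params, unclass(p1))
  tp1 <- apply_temperature(p1, 20)
  expect_equal(respiration_flux(pool_state(5, 1, 3, 1), tp1, p1, 0.3), 0)
  tp <- apply_temperature(dflt, 20)
  expect_equal(respiration_flux(pool_state(5, 1, 0, 1), tp, dflt, 0.3), 0)
  # at equilibrium, respiration closes the mass balance: shr = I - eC*C - eD*D
  eq <- solve_equilibrium(tp, dflt, 0.08)
  expect_equal(eq$shr,
               dflt$I - dflt$eC * eq$state[["C"]] - dflt$eD * eq$state[["D"]],
               tolerance = 1e-9)
})

test_that("equilibrium DOC closed form and infeasibility boundary", {
  tp <- apply_temperature(dflt, 20)
  # construct phi so that (1-phi)*gM*vmaxU = 2*dM: then D* = KmU exactly
  phi <- 1 - 2 * tp$dM_T / (tp$gM_T * tp$vmaxU)
  expect_equal(equilibrium_doc(tp, dflt, phi), tp$KmU)
  # denominator <= 0 is infeasible
  phi_max <- 1 - tp$dM_T / (tp$gM_T * tp$vmaxU)
  expect_true(is.na(equilibrium_doc(tp, dflt, min(phi_max + 0.01, 0.999))))
  # back-substitution: growth balances turnover at D*
  for (phi in c(0.05, 0.2, 0.6)) {
    D <- equilibrium_doc(tp, dflt, phi)
    expect_equal((1 - phi) * tp$gM_T * tp$vmaxU * D / (tp$KmU + D), tp$dM_T,
                 tolerance = 1e-12)
  }
})

test_that("solve_equilibrium agrees with long ODE integration (oracle)", {
  tp <- apply_temperature(dflt, 20)
  eq <- solve_equilibrium(tp, dflt, 0.1069)
  expect_true(eq$feasible)
  expect_match(eq$stability, "stable$")
  expect_false(grepl("unstable", eq$stability))
  pert <- eq$state * c(1.05, 0.9, 1.02, 0.95)
  final <- integrate_awb(pert, tp, dflt, 0.1069, t_end = 3e5)
  expect_equal(unname(final), unname(eq$state), tolerance = 1e-6)
})

test_that("solve_equilibrium signals infeasibility as phi -> 0 and phi -> 1", {
  tp <- apply_temperature(dflt, 20)
  # enzymes vanish: decomposition cannot feed the biomass
  expect_false(solve_equilibrium(tp, dflt, 1e-4)$feasible)
  # above phi_max the equilibrium DOC does not exist
  expect_false(solve_equilibrium(tp, dflt, 0.999)$feasible)
  expect_error(solve_equilibrium(tp, dflt, 1.5), "phi")
})

test_that("equilibrium SOC decreases strictly with allocation (default config)", {
  tp <- apply_temperature(dflt, 20)
  phis <- seq(0.03, 0.3, by = 0.015)
  Cs <- vapply(phis, function(ph) solve_equilibrium(tp, dflt, ph)$state[["C"]],
               0)
  expect_true(all(diff(Cs) < 0))
})

test_that("analytic Jacobian matches finite differences and is step-robust", {
  tp <- apply_temperature(dflt, 20)
  eq <- solve_equilibrium(tp, dflt, 0.1)
  J <- awb_jacobian(eq$state, tp, dflt, 0.1)
  Jfd <- awbevo:::fd_jacobian(eq$state, tp, dflt, 0.1)
  expect_equal(J, Jfd, tolerance = 1e-5)
  s1 <- jacobian_stability(eq$state, tp, dflt, 0.1, method = "fd",
                           fd_step = 1e-5)
  s2 <- jacobian_stability(eq$state, tp, dflt, 0.1, method = "fd",
                           fd_step = 1e-6)
  expect_identical(s1, s2)
  expect_identical(s1, jacobian_stability(eq$state, tp, dflt, 0.1))
})

test_that("stability class agrees with the integration oracle on random draws", {
  set.seed(202)
  for (i in 1:8) {
    cfg <- rand_feasible_config()
    eq <- cfg$eq
    pert <- eq$state * c(1.03, 0.97, 1.02, 0.98)
    final <- integrate_awb(pert, cfg$tp, cfg$params, cfg$phi, t_end = 5e5)
    rel <- max(abs(final - eq$state) / eq$state)
    # classified stable, so the perturbation must have decayed substantially
    expect_lt(rel, max(abs(pert - eq$state) / eq$state) / 10)
  }
})

test_that("feasible_trait_range brackets feasibility on the default config", {
  tp <- apply_temperature(dflt, 20)
  fr <- feasible_trait_range(tp, dflt)
  expect_equal(unname(fr[2]), 1 - tp$dM_T / (tp$gM_T * tp$vmaxU))
  mid <- mean(fr)
  expect_true(solve_equilibrium(tp, dflt, mid)$feasible)
  expect_false(solve_equilibrium(tp, dflt, fr[1] / 2)$feasible)
  expect_false(solve_equilibrium(tp, dflt,
                                 min((fr[2] + 1) / 2, 0.999))$feasible)
  # empty range when turnover exceeds saturated growth
  p <- dflt
  p$dM <- 1
  p <- do.call(awb_params, unclass(p))
  tp2 <- apply_temperature(p, 20)
  expect_true(all(is.na(feasible_trait_range(tp2, p))))
  # phi_max is monotone in vmaxU
  p3 <- dflt
  p3$v0U <- dflt$v0U * 2
  p3 <- do.call(awb_params, unclass(p3))
  tp3 <- apply_temperature(p3, 20)
  expect_gt(1 - tp3$dM_T / (tp3$gM_T * tp3$vmaxU), unname(fr[2]))
})
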