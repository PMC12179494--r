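test_that("competition kernel: sign, symmetry and slope at zero", {
  ker <- competition_kernel(1.5)
  expect_equal(competition_kernel_value(0, ker), 0)
  z <- c(0.01, 0.1, 0.5)
  expect_true(all(competition_kernel_value(z, ker) > 0))
  expect_equal(competition_kernel_value(-z, ker),
               -competition_kernel_value(z, ker))
  # numerical differentiation oracle for c'(0) = c0
  h <- 1e-7
  slope <- (competition_kernel_value(h, ker) -
              competition_kernel_value(-h, ker)) / (2 * h)
  expect_equal(slope, 1.5, tolerance = 1e-6)
  expect_error(competition_kernel(-1), "c0")
  expect_error(competition_kernel(1, curvature = 5), "curvature")
})

test_that("invasion fitness vanishes on the diagonal and has the c0 -> 0 limit", {
  tp <- apply_temperature(dflt, 20)
  for (phi in c(0.05, 0.1, 0.3)) {
    expect_equal(invasion_fitness(phi, phi, tp, dflt, ker_dflt), 0,
                 tolerance = 1e-15)
  }
  # c0 -> 0: s -> (1-phi_mut)/(1-phi_res) * dM - dM, so lower producers invade
  ker_tiny <- competition_kernel(1e-8)
  for (pm in c(0.02, 0.08, 0.12)) {
    s <- invasion_fitness(pm, 0.1, tp, dflt, ker_tiny)
    expect_equal(s, (1 - pm) / (1 - 0.1) * tp$dM_T - tp$dM_T,
                 tolerance = 1e-6)
    if (pm < 0.1) expect_gt(s, 0) else if (pm > 0.1) expect_lt(s, 0)
  }
  expect_error(invasion_fitness(0.1, 0.99, tp, dflt, ker_dflt),
               "no feasible equilibrium")
})

test_that("selection gradient matches finite differences of invasion fitness", {
  set.seed(77)
  h <- 1e-6
  for (i in 1:20) {
    cfg <- rand_feasible_config()
    phi <- stats::runif(1, 0.3, 0.9) * cfg$phi
    g <- selection_gradient(phi, cfg$tp, cfg$params, cfg$kernel)
    fd <- (invasion_fitness(phi + h, phi, cfg$tp, cfg$params, cfg$kernel) -
             invasion_fitness(phi - h, phi, cfg$tp, cfg$params, cfg$kernel)) /
      (2 * h)
    expect_equal(g, fd, tolerance = 1e-6)
  }
})

test_that("phi_star arithmetic, existence boundary and gradient zero", {
  # engineered ratio dM/(gM*vmaxU) = 0.2 with c0 = 2 gives phi* = 0.3
  tp <- apply_temperature(dflt, 20)
  p <- unclass(dflt)
  p$dM <- 0.2 * p$gM * tp$vmaxU
  p <- do.call(awb_params, p)
  tp2 <- apply_temperature(p, 20)
  o <- phi_star(tp2, p, competition_kernel(2))
  expect_true(o$exists)
  expect_equal(o$phi_star, 0.3, tolerance = 1e-12)
  expect_true(o$uninvadable)
  expect_true(o$convergent)
  # boundary c0 = 1/(1 - w) exactly: no positive singularity
  ob <- phi_star(tp2, p, competition_kernel(1 / (1 - 0.2)))
  expect_false(ob$exists)
  expect_identical(ob$reason, "c0_too_small")
  # turnover exceeding saturated growth
  p2 <- unclass(dflt)
  p2$dM <- 1
  p2 <- do.call(awb_params, p2)
  og <- phi_star(apply_temperature(p2, 20), p2, ker_dflt)
  expect_identical(og$reason, "growth_infeasible")
  # gradient vanishes at the closed-form optimum
  o3 <- phi_star(tp, dflt, ker_dflt)
  expect_equal(selection_gradient(o3$phi_star, tp, dflt, ker_dflt), 0,
               tolerance = 1e-12 * tp$dM_T)
})

test_that("phi_star equals the bisection zero of the gradient (oracle)", {
  set.seed(31)
  for (i in 1:6) {
    cfg <- rand_feasible_config()
    phi_max <- 1 - cfg$tp$dM_T / (cfg$tp$gM_T * cfg$tp$vmaxU)
    root <- stats::uniroot(function(ph)
      selection_gradient(ph, cfg$tp, cfg$params, cfg$kernel),
      c(1e-6, phi_max * (1 - 1e-9)), tol = 1e-12)$root
    expect_equal(cfg$phi, root, tolerance = 1e-8)
  }
})

test_that("pairwise invasibility classifies the default singularity as a convergent ESS", {
  tp <- apply_temperature(dflt, 20)
  pip <- pairwise_invasibility(tp, dflt, ker_dflt, grid_n = 81)
  expect_true(all(diag(pip$sign) == 0))
  expect_identical(pip$classification, "ESS+convergent")
  # no mutant on the grid can invade the singular resident
  expect_true(all(pip$fitness_at_star <= 1e-12 * tp$dM_T))
  # gradient sign flips across phi*
  below <- pip$phi[pip$phi < pip$optimum$phi_star - 0.01]
  above <- pip$phi[pip$phi > pip$optimum$phi_star + 0.01]
  expect_true(all(vapply(below, selection_gradient, 0, tp = tp,
                         params = dflt, kernel = ker_dflt) > 0))
  expect_true(all(vapply(above, selection_gradient, 0, tp = tp,
                         params = dflt, kernel = ker_dflt) < 0))
  expect_error(pairwise_invasibility(tp, dflt, ker_dflt, grid_n = 10),
               "grid_n")
})

test_that("phi*(T) responds to temperature as the closed form dictates", {
  Ts <- seq(0, 30, by = 2)
  ps <- vapply(Ts, function(T) {
    o <- phi_star(apply_temperature(dflt, T), dflt, ker_dflt)
    if (o$exists) o$phi_star else NA_real_
  }, 0)
  # kinetics only: strictly increasing, larger increments at low temperature
  expect_true(all(diff(ps) > 0))
  expect_true(all(diff(diff(ps)) < 0))
  # mortality more temperature-sensitive than uptake: decreasing
  sc <- thermal_scenario("mortality_arrhenius", EdM = 55, Tref = 20)
  ps_m <- vapply(Ts, function(T) {
    o <- phi_star(apply_temperature(dflt, T, sc), dflt, ker_dflt)
    if (o$exists) o$phi_star else NA_real_
  }, 0)
  expect_true(all(diff(ps_m) < 0, na.rm = TRUE))
  # lower c0 gives lower phi* at every temperature
  # c0 = 1.1 sits just above its existence threshold: the optimum only
  # exists above ~5 C, so compare on 6-30 C
  Ts_warm <- Ts[Ts >= 6]
  ps_lo <- vapply(Ts_warm, function(T) {
    o <- phi_star(apply_temperature(dflt, T), dflt, competition_kernel(1.1))
    if (o$exists) o$phi_star else NA_real_
  }, 0)
  expect_false(anyNA(ps_lo))
  expect_true(all(ps_lo < ps[match(Ts_warm, Ts)]))
})
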