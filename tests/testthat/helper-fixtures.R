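# Shared fixtures: the default configuration and seeded random draws.

dflt <- default_params()
ker_dflt <- competition_kernel(1.17)
kin_only <- thermal_scenario("kinetics_only")

# A random positive pool state (log-uniform over plausible magnitudes).
rand_state <- function() {
  pool_state(C = exp(stats::runif(1, log(1e-2), log(5e2))),
             D = exp(stats::runif(1, log(1e-5), log(1e0))),
             M = exp(stats::runif(1, log(1e-3), log(5e1))),
             Z = exp(stats::runif(1, log(1e-4), log(1e1))))
}

# Multiplicative jitter of the default parameters. Rates and pre-exponentials
# move by up to +/- `spread` log-units; efficiencies stay inside (0, 1].
jitter_params <- function(spread = 0.3) {
  jit <- function(x) x * exp(stats::runif(1, -spread, spread))
  awb_params(I = jit(dflt$I), eC = jit(dflt$eC), eD = jit(dflt$eD),
             v0D = jit(dflt$v0D), EvD = dflt$EvD,
             K0D = jit(dflt$K0D), EKD = dflt$EKD,
             v0U = jit(dflt$v0U), EvU = dflt$EvU,
             K0U = jit(dflt$K0U), EKU = dflt$EKU,
             dM = jit(dflt$dM), dZ = jit(dflt$dZ),
             gM = min(jit(dflt$gM), 0.95), gZ = min(jit(dflt$gZ), 0.95),
             Rgas = dflt$Rgas)
}

# Draw a configuration (params, temperature, kernel slope) whose ESS exists
# and whose equilibrium at phi* is feasible and stable. Rejection sampling:
# temperate temperatures keep equilibration times manageable.
rand_feasible_config <- function(max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    p <- jitter_params()
    T <- stats::runif(1, 10, 25)
    ker <- competition_kernel(stats::runif(1, 1.05, 1.6))
    tp <- apply_temperature(p, T)
    opt <- phi_star(tp, p, ker)
    if (!opt$exists || opt$phi_star <= 0.01) next
    eq <- solve_equilibrium(tp, p, opt$phi_star)
    if (eq$feasible && eq$stability %in% c("stable", "oscillatory-stable"))
      return(list(params = p, T = T, tp = tp, kernel = ker,
                  phi = opt$phi_star, eq = eq))
  }
  stop("could not draw a feasible configuration")
}

make_synthetic_grid <- function(n_lat = 18, n_lon = 10, seed = 42,
                                noise_sd = 0.5, ...) {
  generate_forcing(forcing_spec(n_lat = n_lat, n_lon = n_lon,
                                noise_sd = noise_sd, seed = seed, ...))
}
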