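#' Time derivatives of the four-pool decomposition system
#'
#' Right-hand side of the microbe-enzyme model. SOC (`C`) gains litter input
#' `I` and loses leaching `eC*C` and enzymatic decomposition
#' `vmaxD * C/(KmD + C) * Z`. DOC (`D`) gains the decomposition product plus
#' recycling of dead microbes (`dM_T * M`) and deactivated enzymes (`dZ * Z`),
#' and loses leaching `eD*D` and uptake `vmaxU * D/(KmU + D) * M`. Biomass
#' (`M`) grows with efficiency `gM_T` on the `(1 - phi)` share of uptake and
#' turns over at `dM_T`. Enzymes (`Z`) are produced with efficiency `gZ` from
#' the `phi` share of uptake and deactivate at `dZ`.
#'
#' The algebraic identity
#' `sum(rhs) == I - eC*C - eD*D - respiration_flux(...)` holds exactly for
#' every input.
#'
#' @param state pool state, see [pool_state()].
#' @param tp temperature-local parameters from [apply_temperature()].
#' @param params an [awb_params()] object.
#' @param phi exoenzyme allocation fraction, in `[0, 1)`.
#' @return Named numeric vector `(C, D, M, Z)` of time derivatives.
#' @export
awb_rhs <- function(state, tp, params, phi) {
  check_state(state)
  check_phi(phi)
  C <- state[["C"]]; D <- state[["D"]]; M <- state[["M"]]; Z <- state[["Z"]]
  dec <- tp$vmaxD * C / (tp$KmD + C) * Z
  upt <- tp$vmaxU * D / (tp$KmU + D) * M
  c(C = params$I - params$eC * C - dec,
    D = dec + tp$dM_T * M + params$dZ * Z - params$eD * D - upt,
    M = (1 - phi) * tp$gM_T * upt - tp$dM_T * M,
    Z = phi * params$gZ * upt - params$dZ * Z)
}

#' Soil heterotrophic respiration flux
#'
#' The residual carbon leaving the DOC pool that is neither assimilated into
#' biomass nor built into enzymes:
#' `uptake * (1 - phi*gZ - (1-phi)*gM_T)`, equivalently
#' `uptake * (phi*(1-gZ) + (1-phi)*(1-gM_T))`. Non-negative whenever both
#' efficiencies are at most 1; exactly zero under perfect efficiency.
#'
#' @inheritParams awb_rhs
#' @return Scalar respiration flux (mass C volume^-1 time^-1).
#' @export
respiration_flux <- function(state, tp, params, phi) {
  check_state(state)
  check_phi(phi)
  upt <- tp$vmaxU * state[["D"]] / (tp$KmU + state[["D"]]) * state[["M"]]
  upt * (1 - phi * params$gZ - (1 - phi) * tp$gM_T)
}

#' Closed-form equilibrium DOC
#'
#' At a steady state with `M > 0`, the biomass equation pins DOC at
#' `D* = KmU * dM_T / ((1 - phi) * gM_T * vmaxU - dM_T)`, independent of the
#' other pools. Returns `NA` (infeasible) when the denominator is
#' non-positive, i.e. when growth cannot offset turnover even at saturating
#' DOC.
#'
#' @inheritParams awb_rhs
#' @return `D*` as a scalar, or `NA_real_` when infeasible.
#' @export
equilibrium_doc <- function(tp, params, phi) {
  check_phi(phi)
  den <- (1 - phi) * tp$gM_T * tp$vmaxU - tp$dM_T
  if (den <= 0) return(NA_real_)
  tp$KmU * tp$dM_T / den
}

#' Solve the nontrivial steady state at fixed trait and temperature
#'
#' Reduces the four-dimensional fixed-point problem to one scalar equation in
#' equilibrium SOC. With `M* > 0`: DOC is pinned in closed form
#' ([equilibrium_doc()]); the enzyme equation gives
#' `Z* = phi*gZ*dM_T / ((1-phi)*gM_T*dZ) * M*`; total mass balance gives
#' `M*(C) = (I - eC*C - eD*D*) / r_u` with `r_u` the respiration per unit
#' biomass at equilibrium; substituting into the SOC equation leaves
#' `f(C) = I - eC*C - vmaxD*C/(KmD+C)*Z*(C) = 0`, solved by bracketed root
#' finding on `(0, (I - eD*D*)/eC)`. When several roots exist the stable one
#' is returned (the smallest stable `C*` with a warning if there are several);
#' when no sign change exists the cell is infeasible — temperatures too low to
#' support meaningful microbial activity end up here.
#'
#' @inheritParams awb_rhs
#' @param tol residual tolerance for equilibrium acceptance (model units).
#' @return An object of class `awb_equilibrium`: list with `state`, `phi`,
#'   `T`, `shr` (respiration at equilibrium), `decay_rate`
#'   (`(I - eC*C*)/C*`, the decomposition flux per unit SOC), `stability`
#'   (one of `"stable"`, `"unstable"`, `"oscillatory-stable"`,
#'   `"oscillatory-unstable"`, or `NA` if infeasible) and `feasible`.
#' @export
solve_equilibrium <- function(tp, params, phi, tol = 1e-9) {
  check_phi(phi)
  infeasible <- structure(list(state = NULL, phi = phi, T = tp$T,
                               shr = NA_real_, decay_rate = NA_real_,
                               stability = NA_character_, feasible = FALSE),
                          class = "awb_equilibrium")
  D <- equilibrium_doc(tp, params, phi)
  if (is.na(D)) return(infeasible)
  upt1 <- tp$vmaxU * D / (tp$KmU + D)                # uptake per unit biomass
  r_u <- upt1 * (1 - phi * params$gZ - (1 - phi) * tp$gM_T)
  if (r_u <= 0) return(infeasible)
  kapZ <- phi * params$gZ * upt1 / params$dZ          # Z* = kapZ * M*
  Cmax <- (params$I - params$eD * D) / params$eC
  if (Cmax <= 0) return(infeasible)
  M_of <- function(C) (params$I - params$eC * C - params$eD * D) / r_u
  f <- function(C) params$I - params$eC * C -
    tp$vmaxD * C / (tp$KmD + C) * kapZ * M_of(C)

  # locate sign changes on a log-spaced scan of the admissible interval
  Cg <- exp(seq(log(Cmax * 1e-9), log(Cmax * (1 - 1e-12)), length.out = 220L))
  fv <- f(Cg)
  idx <- which(diff(sign(fv)) != 0)
  if (length(idx) == 0L) return(infeasible)

  cands <- list()
  for (i in idx) {
    root <- tryCatch(
      stats::uniroot(f, c(Cg[i], Cg[i + 1L]), tol = .Machine$double.eps^0.75),
      error = function(e) NULL)
    if (is.null(root))
      stop("equilibrium root finding failed to converge", call. = FALSE)
    C <- root$root
    M <- M_of(C)
    if (M <= 0) next
    st <- pool_state(C = C, D = D, M = M, Z = kapZ * M)
    res <- awb_rhs(st, tp, params, phi)
    if (max(abs(res)) > tol * max(1, params$I / params$eC)) next
    stab <- jacobian_stability(st, tp, params, phi)
    cands[[length(cands) + 1L]] <- list(state = st, stability = stab)
  }
  if (length(cands) == 0L) return(infeasible)
  stable <- vapply(cands, function(x) grepl("(^|-)stable$", x$stability), TRUE)
  pick <- if (any(stable)) which(stable) else seq_along(cands)
  if (sum(stable) > 1L)
    warning("multiple stable equilibria; returning the smallest C*",
            call. = FALSE)
  Cs <- vapply(cands[pick], function(x) x$state[["C"]], 0)
  sel <- cands[pick][[which.min(Cs)]]
  st <- sel$state
  shr <- respiration_flux(st, tp, params, phi)
  structure(list(state = st, phi = phi, T = tp$T, shr = shr,
                 decay_rate = (params$I - params$eC * st[["C"]]) / st[["C"]],
                 stability = sel$stability, feasible = TRUE),
            class = "awb_equilibrium")
}

#' @export
print.awb_equilibrium <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("<awb_equilibrium> infeasible (phi = %.4g, T = %.3g C)\n",
                x$phi, x$T))
    return(invisible(x))
  }
  cat(sprintf("<awb_equilibrium> phi = %.4g, T = %.3g C [%s]\n",
              x$phi, x$T, x$stability))
  cat(sprintf("  C = %.6g  D = %.6g  M = %.6g  Z = %.6g\n",
              x$state[["C"]], x$state[["D"]], x$state[["M"]], x$state[["Z"]]))
  cat(sprintf("  SHR = %.6g  decay rate = %.6g\n", x$shr, x$decay_rate))
  invisible(x)
}

#' Analytic Jacobian of the four-pool system
#'
#' @inheritParams awb_rhs
#' @return The 4x4 Jacobian matrix d(rhs)/d(state), rows and columns ordered
#'   `(C, D, M, Z)`.
#' @export
awb_jacobian <- function(state, tp, params, phi) {
  check_state(state)
  check_phi(phi)
  C <- state[["C"]]; D <- state[["D"]]; M <- state[["M"]]; Z <- state[["Z"]]
  g  <- tp$vmaxD * C / (tp$KmD + C)
  gp <- tp$vmaxD * tp$KmD / (tp$KmD + C)^2
  h  <- tp$vmaxU * D / (tp$KmU + D)
  hp <- tp$vmaxU * tp$KmU / (tp$KmU + D)^2
  matrix(c(
    -params$eC - gp * Z, 0,                           0,                        -g,
    gp * Z,              -params$eD - hp * M,         tp$dM_T - h,              g + params$dZ,
    0,                   (1 - phi) * tp$gM_T * hp * M, (1 - phi) * tp$gM_T * h - tp$dM_T, 0,
    0,                   phi * params$gZ * hp * M,    phi * params$gZ * h,      -params$dZ),
    nrow = 4L, byrow = TRUE,
    dimnames = list(c("C", "D", "M", "Z"), c("C", "D", "M", "Z")))
}

#' Local stability classification of an equilibrium
#'
#' Classifies a state by the eigenvalues of the Jacobian: `"stable"` when all
#' real parts are below `-1e-12`, `"unstable"` otherwise, with an
#' `"oscillatory-"` prefix when any eigenvalue pair has a nonzero imaginary
#' part (a spiral approach or departure).
#'
#' @inheritParams awb_rhs
#' @param method `"analytic"` (default) or `"fd"` for a central
#'   finite-difference Jacobian.
#' @param fd_step relative step for the finite-difference Jacobian.
#' @return One of `"stable"`, `"unstable"`, `"oscillatory-stable"`,
#'   `"oscillatory-unstable"`.
#' @export
jacobian_stability <- function(state, tp, params, phi,
                               method = c("analytic", "fd"),
                               fd_step = 1e-6) {
  method <- match.arg(method)
  J <- if (method == "analytic") {
    awb_jacobian(state, tp, params, phi)
  } else {
    fd_jacobian(state, tp, params, phi, fd_step)
  }
  ev <- eigen(J, only.values = TRUE)$values
  if (any(!is.finite(ev)))
    stop("Jacobian eigenvalue computation failed", call. = FALSE)
  stable <- all(Re(ev) < -1e-12)
  osc <- any(abs(Im(ev)) > 1e-12)
  paste0(if (osc) "oscillatory-" else "", if (stable) "stable" else "unstable")
}

fd_jacobian <- function(state, tp, params, phi, rel_step = 1e-6) {
  J <- matrix(0, 4L, 4L, dimnames = list(names(state), names(state)))
  for (j in 1:4) {
    h <- rel_step * max(abs(state[[j]]), 1e-8)
    up <- dn <- state
    up[j] <- up[j] + h
    dn[j] <- max(dn[j] - h, 0)
    J[, j] <- (awb_rhs(up, tp, params, phi) - awb_rhs(dn, tp, params, phi)) /
      (up[j] - dn[j])
  }
  J
}

#' Feasible range of the allocation trait
#'
#' The upper limit comes from positivity of equilibrium DOC:
#' `phi_max = 1 - dM_T/(gM_T * vmaxU)`. The lower limit `phi_min` is the
#' smallest allocation with a feasible stable equilibrium (below it the enzyme
#' pool is too small for decomposition to feed the biomass), found by
#' bisection on the feasibility predicate. Returns `c(NA, NA)` when
#' `phi_max <= 0`. Feasibility may also fail just below `phi_max` (equilibrium
#' DOC diverges there); the returned upper end is the closed-form bound.
#'
#' @inheritParams awb_rhs
#' @param tol bisection tolerance on phi.
#' @return Numeric vector `c(phi_min, phi_max)`.
#' @export
feasible_trait_range <- function(tp, params, tol = 1e-6) {
  phi_max <- 1 - tp$dM_T / (tp$gM_T * tp$vmaxU)
  if (!is.finite(phi_max) || phi_max <= 0)
    return(c(phi_min = NA_real_, phi_max = NA_real_))
  feas <- function(phi) {
    eq <- solve_equilibrium(tp, params, phi)
    eq$feasible && grepl("stable$", eq$stability) &&
      !grepl("unstable$", eq$stability)
  }
  probe <- phi_max * seq(0.05, 0.95, by = 0.05)
  ok <- which(vapply(probe, feas, TRUE))
  if (length(ok) == 0L)
    return(c(phi_min = NA_real_, phi_max = phi_max))
  lo <- if (min(ok) == 1L) 0 else probe[min(ok) - 1L]
  hi <- probe[min(ok)]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feas(mid)) hi <- mid else lo <- mid
  }
  c(phi_min = hi, phi_max = phi_max)
}

#' Integrate the four-pool system through time
#'
#' Adaptive Cash-Karp Runge-Kutta integration of the model equations,
#' implemented in C++. Used as the independent dynamical oracle for the
#' steady-state solver: integrating from a perturbed state must converge back
#' to a stable equilibrium.
#'
#' @inheritParams awb_rhs
#' @param state initial pool state.
#' @param t_end integration horizon (model time units, hours by default).
#' @param rtol,atol relative and absolute local error tolerances.
#' @param max_steps safety cap on accepted steps.
#' @return Named numeric state at `t_end`.
#' @export
integrate_awb <- function(state, tp, params, phi, t_end,
                          rtol = 1e-8, atol = 1e-12, max_steps = 5e6) {
  check_state(state)
  check_phi(phi)
  pv <- c(params$I, params$eC, params$eD, tp$vmaxD, tp$KmD, tp$vmaxU, tp$KmU,
          tp$dM_T, params$dZ, tp$gM_T, params$gZ, phi)
  out <- awb_integrate_cpp(as.numeric(state), pv, t_end, rtol, atol,
                           as.double(max_steps))
  stats::setNames(out, c("C", "D", "M", "Z"))
}
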