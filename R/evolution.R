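#' Competition kernel between exoenzyme-allocation phenotypes
#'
#' The local competitive (dis)advantage of a mutant relative to the resident
#' is carried by an odd function `c` of the trait difference with `c(0) = 0`,
#' `c(z) > 0` iff `z > 0`, slope `c0 = c'(0) > 0` (the advantage accruing to
#' stronger enzyme producers via private access to locally decomposed DOC) and
#' curvature satisfying the evolutionary stability condition
#' `c''(0) < 2*c0^2`. The default shape is the bounded odd form
#' `c(z) = (2/pi) * atan(c0 * (pi/2) * z)`, which has `c'(0) = c0`,
#' `c''(0) = 0` and `|c| < 1` so mutant DOC access `1 + c` stays positive.
#' A custom shape can be plugged in as a function of `(z, c0)`.
#'
#' @param c0 slope at zero, must be > 0.
#' @param shape `"atan"` (default) or a function `f(z, c0)` implementing a
#'   kernel satisfying the invariants above.
#' @param curvature `c''(0)` of the supplied shape (0 for the default);
#'   validated against the stability bound.
#' @return An object of class `awb_kernel`.
#' @export
competition_kernel <- function(c0, shape = "atan", curvature = 0) {
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 <= 0)
    stop("kernel slope c0 must be a single positive number", call. = FALSE)
  if (!(identical(shape, "atan") || is.function(shape)))
    stop("kernel shape must be \"atan\" or a function(z, c0)", call. = FALSE)
  if (curvature >= 2 * c0^2)
    stop("kernel curvature c''(0) must be < 2*c0^2 for evolutionary stability",
         call. = FALSE)
  structure(list(c0 = c0, shape = shape, curvature = curvature),
            class = "awb_kernel")
}

#' Evaluate the competition kernel
#'
#' @param dphi trait difference `phi_mut - phi_res` (vectorised).
#' @param kernel an [competition_kernel()] object.
#' @return Kernel value(s), sign-matching `dphi`.
#' @export
competition_kernel_value <- function(dphi, kernel) {
  stopifnot(inherits(kernel, "awb_kernel"))
  val <- if (is.function(kernel$shape)) {
    kernel$shape(dphi, kernel$c0)
  } else {
    (2 / pi) * atan(kernel$c0 * (pi / 2) * dphi)
  }
  if (any(1 + val <= 0))
    stop("competition kernel drove mutant DOC access non-positive",
         call. = FALSE)
  val
}

#' Invasion fitness of a rare mutant
#'
#' Per-capita growth rate of a rare mutant phenotype `phi_mut` in the
#' environment set by a resident `phi_res` at its ecological equilibrium:
#' `s = (1 - phi_mut) * gM_T * vmaxU * Dt/(KmU + Dt) - dM_T` with
#' `Dt = (1 + c(phi_mut - phi_res)) * D*_res`. By construction
#' `s(phi, phi) = 0`: the resident is at demographic equilibrium in its own
#' environment.
#'
#' @param phi_mut mutant trait (vectorised).
#' @param phi_res resident trait; must have a feasible equilibrium DOC.
#' @inheritParams awb_rhs
#' @param kernel an [competition_kernel()] object.
#' @return Invasion fitness value(s) (per unit time).
#' @export
invasion_fitness <- function(phi_mut, phi_res, tp, params, kernel) {
  check_phi(phi_res)
  if (any(phi_mut < 0 | phi_mut >= 1))
    stop("mutant trait must lie in [0, 1)", call. = FALSE)
  Dres <- equilibrium_doc(tp, params, phi_res)
  if (is.na(Dres))
    stop(sprintf("resident trait phi_res = %g has no feasible equilibrium",
                 phi_res), call. = FALSE)
  Dt <- (1 + competition_kernel_value(phi_mut - phi_res, kernel)) * Dres
  (1 - phi_mut) * tp$gM_T * tp$vmaxU * Dt / (tp$KmU + Dt) - tp$dM_T
}

#' Selection gradient on the allocation trait
#'
#' Derivative of invasion fitness in the mutant trait, evaluated at
#' `phi_mut = phi_res = phi`. Closed form:
#' `dM_T * ( c0 * (1 - dM_T / ((1-phi) * gM_T * vmaxU)) - 1/(1-phi) )`.
#' Its zeros are the evolutionary singularities.
#'
#' @param phi resident trait, in the feasible range.
#' @inheritParams invasion_fitness
#' @return Scalar gradient value.
#' @export
selection_gradient <- function(phi, tp, params, kernel) {
  check_phi(phi)
  if (is.na(equilibrium_doc(tp, params, phi)))
    stop(sprintf("resident trait phi = %g has no feasible equilibrium", phi),
         call. = FALSE)
  w <- tp$dM_T / ((1 - phi) * tp$gM_T * tp$vmaxU)
  tp$dM_T * (kernel$c0 * (1 - w) - 1 / (1 - phi))
}

#' Evolutionarily stable exoenzyme allocation
#'
#' The unique evolutionary singularity of the allocation trait:
#' `phi* = 1 - dM_T/(gM_T * vmaxU) - 1/c0`. It exists (is positive) iff
#' `dM_T/(gM_T * vmaxU) < 1` and `c0 > 1 / (1 - dM_T/(gM_T * vmaxU))`: the
#' trait can evolve above zero only when the local competitive advantage to
#' stronger producers is large enough. When it exists it is convergence
#' stable, and it is uninvadable whenever the kernel curvature satisfies
#' `c''(0) < 2*c0^2` (guaranteed by [competition_kernel()]).
#'
#' @inheritParams invasion_fitness
#' @return An object of class `awb_trait_optimum`: list with `phi_star`
#'   (`NA` if absent), `exists`, `reason` (`"ok"`, `"growth_infeasible"` when
#'   turnover exceeds saturated growth, `"c0_too_small"`), `uninvadable`,
#'   `convergent`.
#' @export
phi_star <- function(tp, params, kernel) {
  stopifnot(inherits(kernel, "awb_kernel"))
  w <- tp$dM_T / (tp$gM_T * tp$vmaxU)
  if (w >= 1) {
    out <- list(phi_star = NA_real_, exists = FALSE,
                reason = "growth_infeasible",
                uninvadable = NA, convergent = NA)
  } else if (kernel$c0 <= 1 / (1 - w)) {
    out <- list(phi_star = NA_real_, exists = FALSE, reason = "c0_too_small",
                uninvadable = NA, convergent = NA)
  } else {
    ps <- 1 - w - 1 / kernel$c0
    out <- list(phi_star = ps, exists = TRUE, reason = "ok",
                uninvadable = kernel$curvature < 2 * kernel$c0^2,
                convergent = TRUE)
  }
  structure(out, class = "awb_trait_optimum")
}

#' @export
print.awb_trait_optimum <- function(x, ...) {
  if (x$exists) {
    cat(sprintf("<awb_trait_optimum> phi* = %.6g (uninvadable: %s, convergent: %s)\n",
                x$phi_star, x$uninvadable, x$convergent))
  } else {
    cat(sprintf("<awb_trait_optimum> no positive singularity (%s)\n", x$reason))
  }
  invisible(x)
}

#' Pairwise invasibility plot
#'
#' Brute-force sign matrix of invasion fitness over a resident x mutant grid
#' spanning the feasible trait range; the numerical oracle for the closed-form
#' singularity. Rows index residents, columns mutants.
#'
#' @inheritParams invasion_fitness
#' @param grid_n number of grid points per axis (>= 20).
#' @param phi_range optional `c(lo, hi)` trait range; defaults to
#'   `(phi_max/grid_n, phi_max)` shrunk slightly inside feasibility.
#' @return List with `phi` (grid), `sign` (grid_n x grid_n matrix in
#'   `{-1, 0, 1}`), `fitness` (raw values), `fitness_at_star` (mutant fitness
#'   against a resident sitting exactly at the singularity, when one exists)
#'   and `classification` (`"ESS"` when no gridded mutant invades the
#'   singular resident, plus `"convergent"` from near-diagonal quadrant
#'   signs).
#' @export
pairwise_invasibility <- function(tp, params, kernel, grid_n = 101L,
                                  phi_range = NULL) {
  if (grid_n < 20L) stop("grid_n must be >= 20", call. = FALSE)
  if (is.null(phi_range)) {
    phi_max <- 1 - tp$dM_T / (tp$gM_T * tp$vmaxU)
    if (!is.finite(phi_max) || phi_max <= 0)
      stop("no feasible trait range at these parameters", call. = FALSE)
    phi_range <- c(phi_max / grid_n, phi_max * (1 - 1e-9))
  }
  phis <- seq(phi_range[1], phi_range[2], length.out = grid_n)
  fit <- vapply(phis, function(pr)
    invasion_fitness(phis, pr, tp, params, kernel), numeric(grid_n))
  fit <- t(fit)                       # rows: resident, cols: mutant
  sg <- sign(fit)
  sg[abs(fit) < 1e-14] <- 0
  diag(sg) <- 0                       # s(phi, phi) = 0 analytically
  opt <- phi_star(tp, params, kernel)
  classification <- "no-singularity"
  fit_at_star <- NULL
  if (opt$exists && opt$phi_star >= phi_range[1] && opt$phi_star <= phi_range[2]) {
    # uninvadability is judged with the resident exactly at the singularity;
    # the nearest grid column differs from it by O(spacing) and would show
    # spurious positive entries of order gradient x spacing
    fit_at_star <- invasion_fitness(phis, opt$phi_star, tp, params, kernel)
    ess <- all(fit_at_star <= 1e-12 * tp$dM_T)
    # near-diagonal invasion steps; skip residents within one grid spacing of
    # the singularity, where a one-step mutant overshoots it
    h <- phis[2] - phis[1]
    below <- which(phis < opt$phi_star - h)
    above <- which(phis > opt$phi_star + h)
    conv_lo <- length(below) < 2L ||
      all(diag(fit[utils::head(below, -1L), utils::tail(below, -1L), drop = FALSE]) > 0)
    conv_hi <- length(above) < 2L ||
      all(diag(fit[utils::tail(above, -1L), utils::head(above, -1L), drop = FALSE]) > 0)
    classification <- paste0(if (ess) "ESS" else "invadable",
                             if (conv_lo && conv_hi) "+convergent" else "")
  }
  list(phi = phis, sign = sg, fitness = fit, classification = classification,
       fitness_at_star = fit_at_star, optimum = opt)
}
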