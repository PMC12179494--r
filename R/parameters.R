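#' Model parameters for the four-pool microbe-enzyme system
#'
#' Constructs and validates the full parameter set of the decomposition model:
#' litter input, leaching, Arrhenius pre-exponentials and activation energies
#' for decomposition and uptake kinetics, microbial and enzyme turnover, and
#' the growth / enzyme-production efficiencies. All operations are
#' unit-agnostic provided the set is self-consistent; the shipped defaults use
#' the AWB convention of mg C per cm^3 of soil and hours, with activation
#' energies in kJ/mol and `Rgas` in kJ/(mol K).
#'
#' @param I litter input flux to the SOC pool (mass C volume^-1 time^-1).
#' @param eC,eD first-order leaching rate constants for SOC and DOC (time^-1).
#'   `eC` must be strictly positive so SOC stays bounded when enzymes vanish.
#' @param v0D,EvD,K0D,EKD Arrhenius pre-exponential and activation energy for
#'   the maximum decomposition rate and its half-saturation constant.
#' @param v0U,EvU,K0U,EKU same, for microbial uptake.
#' @param dM microbial biomass turnover rate (time^-1).
#' @param dZ exoenzyme deactivation rate (time^-1).
#' @param gM microbial growth efficiency (carbon use efficiency), in (0, 1].
#' @param gZ enzyme production efficiency, in (0, 1].
#' @param Rgas gas constant in units matching the activation energies.
#'
#' @return An object of class `awb_params` (a named list).
#' @seealso [default_params()] for the shipped default configuration.
#' @export
awb_params <- function(I, eC, eD, v0D, EvD, K0D, EKD, v0U, EvU, K0U, EKU,
                       dM, dZ, gM, gZ, Rgas = 0.008314) {
  p <- list(I = I, eC = eC, eD = eD,
            v0D = v0D, EvD = EvD, K0D = K0D, EKD = EKD,
            v0U = v0U, EvU = EvU, K0U = K0U, EKU = EKU,
            dM = dM, dZ = dZ, gM = gM, gZ = gZ, Rgas = Rgas)
  validate_params(p)
  structure(p, class = "awb_params")
}

validate_params <- function(p) {
  num1 <- function(key) {
    x <- p[[key]]
    if (is.null(x) || !is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("parameter '", key, "' must be a single finite number", call. = FALSE)
    x
  }
  for (key in c("I", "eC", "eD", "v0D", "EvD", "K0D", "EKD",
                "v0U", "EvU", "K0U", "EKU", "dM", "dZ", "gM", "gZ", "Rgas"))
    num1(key)
  for (key in c("v0D", "K0D", "v0U", "K0U", "dM", "dZ", "EvD", "EKD", "EvU", "EKU"))
    if (p[[key]] < 0) stop("parameter '", key, "' must be >= 0", call. = FALSE)
  if (p$I <= 0) stop("parameter 'I' must be > 0", call. = FALSE)
  if (p$eC <= 0) stop("parameter 'eC' must be > 0", call. = FALSE)
  if (p$eD < 0) stop("parameter 'eD' must be >= 0", call. = FALSE)
  if (p$Rgas <= 0) stop("parameter 'Rgas' must be > 0", call. = FALSE)
  for (key in c("gM", "gZ"))
    if (p[[key]] <= 0 || p[[key]] > 1)
      stop("parameter '", key, "' must lie in (0, 1]", call. = FALSE)
  invisible(p)
}

#' Default model parameters
#'
#' The shipped default configuration, read from
#' `inst/extdata/default_config.json`. Values follow the AWB model family
#' (mg C cm^-3, hours): litter input `I = 5e-3`, uptake kinetics
#' `v0U = 1e5`, `EvU = 38` kJ/mol, decomposition kinetics `v0D = 1e8`,
#' `EvD = 47` kJ/mol, turnover `dM = 2e-4` and `dZ = 1e-3` per hour, growth
#' efficiency `gM = 0.31` (its 20 degree C value), `gZ = 0.5`, and small
#' abiotic leaching `eC = eD = 1e-5` per hour. Half-saturation pre-exponentials
#' are set so that at 20 degrees C, `KmD` is about 582 and `KmU` about
#' 0.30 mg C cm^-3.
#'
#' @return An `awb_params` object.
#' @export
default_params <- function() {
  cfg <- load_config(system.file("extdata", "default_config.json",
                                 package = "awbevo", mustWork = TRUE))
  cfg$params
}

#' @export
print.awb_params <- function(x, ...) {
  cat("<awb_params>\n")
  for (key in names(x)) cat(sprintf("  %-5s = %g\n", key, x[[key]]))
  invisible(x)
}

#' Pool state constructor
#'
#' A state of the four carbon pools: SOC (`C`), DOC (`D`), microbial biomass
#' (`M`) and exoenzymes (`Z`), all in mass C per volume.
#'
#' @param C,D,M,Z non-negative pool sizes.
#' @return A named numeric vector of length 4.
#' @export
pool_state <- function(C, D, M, Z) {
  s <- c(C = C, D = D, M = M, Z = Z)
  check_state(s)
  s
}

check_state <- function(s) {
  if (length(s) != 4L || !is.numeric(s) || any(!is.finite(s)))
    stop("state must be four finite numbers (C, D, M, Z)", call. = FALSE)
  if (any(s < 0))
    stop("negative pool in state: pools must be >= 0", call. = FALSE)
  invisible(s)
}

check_phi <- function(phi) {
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) ||
      phi < 0 || phi >= 1)
    stop("trait phi must lie in [0, 1)", call. = FALSE)
  invisible(phi)
}
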