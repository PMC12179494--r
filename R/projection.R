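#' Initialise grid cells at their 2010 optima
#'
#' For every cell: evaluate the ESS allocation at the first-decade
#' temperature, mark the cell inactive when no positive optimum exists (cold
#' cells where microbial activity cannot be sustained), and solve the local
#' steady state at `(T_2010, phi_0)`. Both the fixed-trait and the evolving
#' run share this initialisation, so their 2010 stocks are identical.
#'
#' @param forcing an [forcing_grid()] object whose first decade is the
#'   baseline.
#' @param params an [awb_params()] object.
#' @param kernel an [competition_kernel()] object.
#' @param scenario a [thermal_scenario()].
#' @param biome_table optional [biome_kinetics_table()]; used when the forcing
#'   carries a `biome` column.
#' @return data.frame with one row per cell: `cell`, `T0`, `phi0`, `active`,
#'   `C`, `M`, `stock`, `shr`.
#' @export
initialize_cells <- function(forcing, params, kernel,
                             scenario = thermal_scenario("kinetics_only"),
                             biome_table = NULL) {
  stopifnot(inherits(forcing, "awb_forcing"))
  if (nrow(forcing$cells) == 0L) stop("empty forcing grid", call. = FALSE)
  d0 <- min(forcing$decades)
  base <- forcing$data[forcing$data$decade == d0, ]
  base <- base[match(forcing$cells$cell, base$cell), ]
  biomes <- if ("biome" %in% names(forcing$cells) && !is.null(biome_table))
    forcing$cells$biome else rep(list(NULL), nrow(forcing$cells))
  out <- lapply(seq_len(nrow(forcing$cells)), function(i) {
    cell_solve(base$T[i], phi = NULL, params,
               I_cell = base$litter[i], kernel = kernel, scenario = scenario,
               biome = if (is.list(biomes)) NULL else biomes[i],
               biome_table = biome_table)
  })
  data.frame(cell = forcing$cells$cell,
             T0 = base$T,
             phi0 = vapply(out, `[[`, 0, "phi"),
             active = vapply(out, `[[`, TRUE, "active"),
             C = vapply(out, `[[`, 0, "C"),
             M = vapply(out, `[[`, 0, "M"),
             stock = vapply(out, `[[`, 0, "stock"),
             shr = vapply(out, `[[`, 0, "shr"))
}

# solve one cell at one temperature; phi = NULL means "use the local ESS"
cell_solve <- function(T, phi, params, I_cell = NULL, kernel = NULL,
                       scenario, biome = NULL, biome_table = NULL) {
  p <- params
  if (!is.null(I_cell) && !is.na(I_cell)) p$I <- I_cell
  tp <- apply_temperature(p, T, scenario, biome = biome, table = biome_table)
  if (is.null(phi)) {
    opt <- phi_star(tp, p, kernel)
    if (!opt$exists || opt$phi_star <= 0)
      return(list(phi = NA_real_, active = FALSE, C = NA_real_, M = NA_real_,
                  stock = NA_real_, shr = NA_real_))
    phi <- min(opt$phi_star, (1 - tp$dM_T / (tp$gM_T * tp$vmaxU)) * (1 - 1e-9))
  }
  eq <- solve_equilibrium(tp, p, phi)
  if (!eq$feasible)
    return(list(phi = phi, active = FALSE, C = NA_real_, M = NA_real_,
                stock = NA_real_, shr = NA_real_))
  list(phi = phi, active = TRUE, C = eq$state[["C"]], M = eq$state[["M"]],
       stock = eq$state[["C"]] + eq$state[["M"]], shr = eq$shr)
}

#' Run a gridded decadal steady-state projection
#'
#' For each decade and each cell active at initialisation, computes the local
#' steady state at that decade's temperature (and litter input, when the
#' forcing provides one). In `"evolving"` mode the allocation trait is
#' re-optimised to each decade's temperature; in `"fixed"` mode it stays at
#' its first-decade value. Global aggregates sum stock density times area
#' weight times a reference soil depth over all cells that solved successfully
#' in every decade; absolute totals therefore depend on the depth and
#' area-weight conventions.
#'
#' @inheritParams initialize_cells
#' @param mode `"evolving"` or `"fixed"`.
#' @param depth_cm reference soil depth factor for aggregation (default 1:
#'   stocks per square-length per centimetre of depth).
#' @return An object of class `awb_projection`: list with `cells` (per
#'   cell-decade data.frame: `cell`, `decade`, `T`, `phi`, `C`, `M`, `stock`,
#'   `shr`, `ok`), `global` (per decade: `decade`, `total_stock`,
#'   `total_shr`, `n_active`), `init` (see [initialize_cells()]) and `meta`.
#' @export
run_projection <- function(forcing, params, kernel,
                           scenario = thermal_scenario("kinetics_only"),
                           mode = c("evolving", "fixed"),
                           depth_cm = 1, biome_table = NULL) {
  mode <- match.arg(mode)
  init <- initialize_cells(forcing, params, kernel, scenario, biome_table)
  active_cells <- init$cell[init$active]
  has_litter <- "litter" %in% names(forcing$data)
  has_biome <- "biome" %in% names(forcing$cells) && !is.null(biome_table)

  dat <- forcing$data
  rows <- vector("list", length(active_cells) * length(forcing$decades))
  k <- 0L
  for (ci in seq_along(active_cells)) {
    id <- active_cells[ci]
    sub <- dat[dat$cell == id, ]
    sub <- sub[match(forcing$decades, sub$decade), ]
    phi_fix <- init$phi0[init$cell == id]
    biome <- if (has_biome) forcing$cells$biome[forcing$cells$cell == id] else NULL
    for (di in seq_along(forcing$decades)) {
      res <- cell_solve(sub$T[di],
                        phi = if (mode == "fixed") phi_fix else NULL,
                        params,
                        I_cell = if (has_litter) sub$litter[di] else NULL,
                        kernel = kernel, scenario = scenario,
                        biome = biome, biome_table = biome_table)
      k <- k + 1L
      rows[[k]] <- data.frame(cell = id, decade = forcing$decades[di],
                              T = sub$T[di], phi = res$phi, C = res$C,
                              M = res$M, stock = res$stock, shr = res$shr,
                              ok = res$active)
    }
  }
  cells <- do.call(rbind, rows)

  # aggregate over cells that solved in every decade
  ok_all <- tapply(cells$ok, cells$cell, all)
  complete <- as.numeric(names(ok_all))[ok_all]
  w <- forcing$cells$weight[match(cells$cell, forcing$cells$cell)]
  keep <- cells$cell %in% complete
  agg <- function(x) tapply(x[keep] * w[keep] * depth_cm,
                            cells$decade[keep], sum)
  global <- data.frame(decade = forcing$decades,
                       total_stock = as.numeric(agg(cells$stock)),
                       total_shr = as.numeric(agg(cells$shr)),
                       n_active = as.integer(table(cells$decade[keep])))
  structure(list(cells = cells, global = global, init = init,
                 meta = list(mode = mode, scenario = scenario$kind,
                             c0 = kernel$c0, depth_cm = depth_cm,
                             n_cells = nrow(forcing$cells),
                             n_inactive = sum(!init$active),
                             n_incomplete = length(active_cells) -
                               length(complete))),
            class = "awb_projection")
}

#' @export
print.awb_projection <- function(x, ...) {
  cat(sprintf("<awb_projection> mode = %s, scenario = %s, c0 = %g\n",
              x$meta$mode, x$meta$scenario, x$meta$c0))
  cat(sprintf("  %d cells (%d inactive, %d incomplete), decades %d..%d\n",
              x$meta$n_cells, x$meta$n_inactive, x$meta$n_incomplete,
              min(x$global$decade), max(x$global$decade)))
  s0 <- x$global$total_stock[1]
  s1 <- x$global$total_stock[nrow(x$global)]
  cat(sprintf("  global stock: %.6g -> %.6g (change %+.4g)\n", s0, s1, s1 - s0))
  invisible(x)
}

#' Effect of eco-evolutionary optimization on a projection
#'
#' Differences per cell and decade between an evolving-trait and a
#' fixed-trait run on the same grid: `delta_stock = stock_evo - stock_fixed`,
#' likewise for respiration, plus a per-unit-local-warming variant (masked
#' where warming since the first decade is below `warming_min`). Cells
#' inactive or failed in either run are absent from the deltas.
#'
#' @param evo,fixed `awb_projection` objects from [run_projection()] with
#'   modes `"evolving"` and `"fixed"` on the same forcing, scenario and c0.
#' @param warming_min minimum local warming (degrees C) for the per-unit
#'   variant (default 0.1).
#' @return List with `cells` (per cell-decade deltas: `cell`, `decade`,
#'   `warming`, `delta_stock`, `delta_shr`, `delta_stock_per_K`), `global`
#'   (per decade totals) and `cumulative` (difference of the 2010 to 2100
#'   global stock changes between the two runs).
#' @export
optimization_effect <- function(evo, fixed, warming_min = 0.1) {
  stopifnot(inherits(evo, "awb_projection"), inherits(fixed, "awb_projection"))
  if (evo$meta$mode != "evolving" || fixed$meta$mode != "fixed")
    stop("arguments must be an evolving and a fixed run, in that order",
         call. = FALSE)
  if (!identical(evo$meta$scenario, fixed$meta$scenario) ||
      !identical(evo$meta$c0, fixed$meta$c0) ||
      !identical(evo$cells$cell, fixed$cells$cell) ||
      !identical(evo$cells$decade, fixed$cells$decade))
    stop("runs do not share grid, decades, scenario and c0", call. = FALSE)
  ok <- evo$cells$ok & fixed$cells$ok
  e <- evo$cells[ok, ]
  f <- fixed$cells[ok, ]
  d0 <- min(e$decade)
  T0 <- e$T[e$decade == d0][match(e$cell, e$cell[e$decade == d0])]
  warming <- e$T - T0
  per_k <- ifelse(warming >= warming_min,
                  (e$stock - f$stock) / warming, NA_real_)
  cells <- data.frame(cell = e$cell, decade = e$decade, warming = warming,
                      delta_stock = e$stock - f$stock,
                      delta_shr = e$shr - f$shr,
                      delta_stock_per_K = per_k)
  global <- data.frame(decade = evo$global$decade,
                       delta_stock = evo$global$total_stock -
                         fixed$global$total_stock,
                       delta_shr = evo$global$total_shr -
                         fixed$global$total_shr)
  n <- nrow(evo$global)
  cumulative <- (evo$global$total_stock[n] - evo$global$total_stock[1]) -
    (fixed$global$total_stock[n] - fixed$global$total_stock[1])
  list(cells = cells, global = global, cumulative = cumulative)
}
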