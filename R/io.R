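#' Load and validate a run configuration
#'
#' Reads a JSON configuration with blocks `params` (see [awb_params()]),
#' `scenario` ([thermal_scenario()]), `kernel` ([competition_kernel()] slope
#' plus an optional `c0_values` sweep list), `projection` (mode, depth_cm),
#' `seed`, and a free-form `notes` block used for provenance comments. Every
#' value is validated before any computation starts; unknown keys fail loudly,
#' naming the offending key.
#'
#' @param path path to the JSON configuration.
#' @return A list of class `awb_config` with elements `params`, `scenario`,
#'   `kernel`, `c0_values`, `projection`, `seed`, `notes`.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("params", "scenario", "kernel", "projection", "seed", "notes")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$params)) stop("missing required block 'params'", call. = FALSE)

  pk <- c("I", "eC", "eD", "v0D", "EvD", "K0D", "EKD", "v0U", "EvU",
          "K0U", "EKU", "dM", "dZ", "gM", "gZ", "Rgas")
  extra <- setdiff(names(raw$params), pk)
  if (length(extra))
    stop("unknown parameter key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(setdiff(pk, "Rgas"), names(raw$params))
  if (length(missing))
    stop("missing required parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  params <- do.call(awb_params, raw$params)

  sc <- raw$scenario
  scenario <- if (is.null(sc)) {
    thermal_scenario("kinetics_only")
  } else {
    sk <- c("kind", "EdM", "d0M", "m", "Tref", "gM_floor")
    extra <- setdiff(names(sc), sk)
    if (length(extra))
      stop("unknown scenario key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    do.call(thermal_scenario, sc)
  }

  kn <- raw$kernel
  if (is.null(kn) || is.null(kn$c0))
    stop("missing required key 'kernel.c0'", call. = FALSE)
  extra <- setdiff(names(kn), c("c0", "c0_values"))
  if (length(extra))
    stop("unknown kernel key(s): ", paste(extra, collapse = ", "), call. = FALSE)
  kernel <- competition_kernel(kn$c0)
  c0_values <- if (!is.null(kn$c0_values)) as.numeric(kn$c0_values) else kn$c0
  if (any(c0_values <= 0)) stop("kernel.c0_values must be > 0", call. = FALSE)

  pj <- raw$projection
  projection <- list(mode = "both", depth_cm = 1)
  if (!is.null(pj)) {
    extra <- setdiff(names(pj), c("mode", "depth_cm"))
    if (length(extra))
      stop("unknown projection key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    if (!is.null(pj$mode)) {
      if (!pj$mode %in% c("evolving", "fixed", "both"))
        stop("projection.mode must be evolving, fixed or both", call. = FALSE)
      projection$mode <- pj$mode
    }
    if (!is.null(pj$depth_cm)) {
      if (pj$depth_cm <= 0) stop("projection.depth_cm must be > 0", call. = FALSE)
      projection$depth_cm <- pj$depth_cm
    }
  }

  structure(list(params = params, scenario = scenario, kernel = kernel,
                 c0_values = c0_values, projection = projection,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
                 notes = raw$notes),
            class = "awb_config")
}

#' Write a configuration back to JSON
#'
#' Serialises an `awb_config` so that `load_config(write_config(cfg, path))`
#' reproduces an identical configuration.
#'
#' @param cfg an `awb_config` from [load_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "awb_config"))
  sc <- cfg$scenario
  out <- list(
    params = unclass(cfg$params),
    scenario = Filter(Negate(is.null),
                      list(kind = sc$kind, EdM = sc$EdM, d0M = sc$d0M,
                           m = sc$m, Tref = sc$Tref, gM_floor = sc$gM_floor)),
    kernel = list(c0 = cfg$kernel$c0, c0_values = cfg$c0_values),
    projection = cfg$projection,
    seed = cfg$seed)
  if (!is.null(cfg$notes)) out$notes <- cfg$notes
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

meta_header <- function(meta) {
  c(sprintf("# awbevo %s", as.character(utils::packageVersion("awbevo"))),
    vapply(names(meta), function(k) sprintf("# %s: %s", k,
                                            paste(meta[[k]], collapse = ",")),
           character(1)))
}

write_csv_meta <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(meta), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_meta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^# ([^:]+): (.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  df <- utils::read.csv(text = paste(lines[-hdr], collapse = "\n"))
  attr(df, "meta") <- meta
  df
}

#' Write projection or comparison results to disk
#'
#' Projection results become `cells_<mode>.csv` and `global_<mode>.csv` in the
#' output directory; a model-comparison table becomes `comparison.csv`. Each
#' file carries `#`-prefixed metadata lines (package version, mode, scenario,
#' c0, seed, config hash when supplied) followed by a regular CSV body, so a
#' plain `read.csv(..., comment.char = "#")` recovers the numbers.
#'
#' @param result an `awb_projection` from [run_projection()] or a data.frame
#'   from [compare_models()].
#' @param dir output directory, created if needed.
#' @param cfg optional `awb_config`; its hash is recorded in the metadata.
#' @param seed optional integer recorded in the metadata.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(result, dir, cfg = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  if (!is.null(cfg)) meta$config_md5 <- config_hash(cfg)
  if (!is.null(seed)) meta$seed <- seed
  if (inherits(result, "awb_projection")) {
    meta <- c(list(mode = result$meta$mode, scenario = result$meta$scenario,
                   c0 = result$meta$c0, depth_cm = result$meta$depth_cm), meta)
    files <- file.path(dir, paste0(c("cells_", "global_"),
                                   result$meta$mode, ".csv"))
    write_csv_meta(result$cells, files[1], meta)
    write_csv_meta(result$global, files[2], meta)
    return(invisible(files))
  }
  if (is.data.frame(result)) {
    f <- file.path(dir, "comparison.csv")
    write_csv_meta(result, f, meta)
    return(invisible(f))
  }
  stop("unsupported result type", call. = FALSE)
}

#' Read back a results CSV written by [write_results()]
#'
#' @param path file path.
#' @return data.frame with a `meta` attribute holding the metadata lines.
#' @export
read_results <- function(path) read_csv_meta(path)

#' Write a forcing grid as long-format CSV
#'
#' Columns: `cell, lat, lon, weight, decade, T` plus optional `litter` and
#' `biome`. Numeric round-trip through [read_forcing_csv()] is exact (values
#' are written with full precision).
#'
#' @param grid an [forcing_grid()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_forcing_csv <- function(grid, path) {
  stopifnot(inherits(grid, "awb_forcing"))
  long <- merge(grid$data, grid$cells, by = "cell")
  cols <- c("cell", "lat", "lon", "weight", "decade", "T")
  if ("litter" %in% names(long)) cols <- c(cols, "litter")
  if ("biome" %in% names(long)) cols <- c(cols, "biome")
  long <- long[order(long$cell, long$decade), cols]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  body <- do.call(paste, c(lapply(long, format_full), list(sep = ",")))
  writeLines(body, con)
  invisible(path)
}

format_full <- function(x) {
  if (is.numeric(x) && !is.integer(x)) sprintf("%.17g", x) else as.character(x)
}

#' Read a long-format forcing CSV
#'
#' @param path path to a CSV with columns `cell, lat, lon, weight, decade, T`
#'   and optionally `litter`, `biome`.
#' @return An [forcing_grid()] object.
#' @export
read_forcing_csv <- function(path) {
  long <- utils::read.csv(path, comment.char = "#")
  need <- c("cell", "lat", "lon", "weight", "decade", "T")
  if (!all(need %in% names(long)))
    stop("forcing CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ccols <- c("cell", "lat", "lon", "weight",
             intersect("biome", names(long)))
  cells <- unique(long[, ccols])
  dcols <- c("cell", "decade", "T", intersect("litter", names(long)))
  forcing_grid(cells, long[, dcols])
}
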