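#' Run one virtual acquisition end to end
#'
#' Orchestrates generator -> digitizer -> coincidence sorting for a single
#' acquisition described by a config: generate labelled raw singles for
#' the preset, run the digitizer chain, sort prompt and delayed
#' coincidences, and assemble a [listmode_dataset()].
#'
#' @param config Named list (or path to a YAML file) with blocks:
#'   `seed`, `geometry` (arguments of [scanner_geometry()]), `generator`
#'   (arguments of [generator_config()] plus `preset` and `params`),
#'   `digitizer` (arguments of [digitizer_config()]), `coincidences`
#'   (`window_ps`, `offset_ps`, `min_sector_diff`), `max_prompts`
#'   (optional truncation cap). The `generator` block with `preset` is
#'   required.
#' @param geom Optional pre-built [scanner_geometry()] (overrides the
#'   geometry block; rebuilding it per acquisition is cheap but pointless
#'   in a sweep).
#' @return A [listmode_dataset()] whose `meta` carries the acquisition
#'   parameters and per-stage digitizer counts.
#' @export
run_acquisition <- function(config, geom = NULL) {
  cfg <- load_config(config)
  if (is.null(cfg$generator) || is.null(cfg$generator$preset))
    stop("config is missing the 'generator' block (with a preset)")
  if (is.null(geom))
    geom <- do.call(scanner_geometry, cfg$geometry %||% list())
  gen_args <- cfg$generator
  preset <- gen_args$preset
  params <- gen_args$params %||% list()
  gcfg <- generator_config(
    seed = cfg$seed %||% gen_args$seed %||% 1L,
    positron_range_fwhm = gen_args$positron_range_fwhm %||% 0.54,
    acollinearity_fwhm_deg = gen_args$acollinearity_fwhm_deg %||% 0.5)
  vx <- virtual_experiment(preset, params, gcfg, geom)
  dcfg <- do.call(digitizer_config, cfg$digitizer %||% list())
  det <- run_chain(vx$singles, dcfg, vx$meta$duration_s, geom)
  co <- cfg$coincidences %||% list()
  win <- co$window_ps %||% 2011.5
  off <- co$offset_ps %||% 1e5
  msd <- co$min_sector_diff %||% 2L
  prompts <- sort_prompts(det, geom, win, msd)
  delayed <- sort_delayed(det, geom, win, off, msd)
  ds <- listmode_dataset(prompts, delayed,
                         duration_s = vx$meta$duration_s,
                         activity_bq = vx$meta$activity_bq,
                         preset = preset)
  ds$meta$stage_counts <- as.list(attr(det, "stage_counts"))
  ds$meta$seed <- gcfg$seed
  if (!is.null(cfg$max_prompts)) ds <- truncate_prompts(ds, cfg$max_prompts)
  ds
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("seed", "geometry", "generator", "digitizer", "coincidences",
             "max_prompts", "output", "analysis")
  extra <- setdiff(names(config), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  config
}

#' Demo manifest mirroring the NEMA acquisition campaign
#'
#' Returns 36 acquisition configs at reduced statistics: 26 scatter-phantom
#' time points over a decaying activity schedule, 5 sensitivity
#' acquisitions with 1-5 aluminium sleeves, and 5 point sources at the
#' NEMA transverse positions.
#'
#' @param seed Base seed; each acquisition uses `seed + k`.
#' @param scale Activity scale factor relative to the full experiment
#'   (default 1e-4, desk scale).
#' @return A named list of 36 config lists for [run_acquisition()].
#' @export
demo_manifest <- function(seed = 1L, scale = 1e-4) {
  cfgs <- list()
  # 26 scatter-phantom points: activity decaying from 1.78 GBq over 16 h
  t_h <- seq(0, 16, length.out = 26)
  act <- 1.78e9 * scale * 2^(-t_h * 3600 / 6586.2)
  for (k in 1:26) {
    cfgs[[sprintf("scatter_%02d", k)]] <- list(
      seed = seed + k,
      generator = list(preset = "scatter_phantom",
                       params = list(activity_bq = act[k], duration_s = 0.5)))
  }
  for (k in 1:5) {
    cfgs[[sprintf("sensitivity_%d", k)]] <- list(
      seed = seed + 100 + k,
      generator = list(preset = "sensitivity",
                       params = list(activity_bq = 8e6 * scale * 10,
                                     duration_s = 1, n_sleeves = k)))
  }
  pos <- list(c(0, 10, 0), c(0, 100, 0), c(0, 200, 0),
              c(100, 0, 0), c(200, 0, 0))
  for (k in 1:5) {
    cfgs[[sprintf("point_%d", k)]] <- list(
      seed = seed + 200 + k,
      generator = list(preset = "point_source",
                       params = list(activity_bq = 5e5, duration_s = 1,
                                     position_mm = pos[[k]])))
  }
  cfgs
}

#' Run a manifest of acquisitions and write listmode files
#'
#' @param manifest Named list of configs (see [demo_manifest()]).
#' @param out_dir Output directory for one listmode file per acquisition.
#' @param dialect Listmode dialect to write.
#' @param quiet Suppress per-acquisition progress lines.
#' @return Invisibly, a `data.table` summary (file, preset, prompts,
#'   delayeds, duration).
#' @export
run_experiment <- function(manifest, out_dir, dialect = "binary",
                           quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- NULL
  rows <- lapply(names(manifest), function(nm) {
    cfg <- load_config(manifest[[nm]])
    if (is.null(geom))
      geom <<- do.call(scanner_geometry, cfg$geometry %||% list())
    ds <- run_acquisition(cfg, geom)
    f <- file.path(out_dir, paste0(nm, ".plm"))
    write_listmode(ds, f, dialect)
    if (!quiet)
      message(sprintf("%-14s %8d prompts  %6d delayeds  -> %s",
                      nm, sum(ds$records$window == "prompt"),
                      sum(ds$records$window == "delayed"), f))
    data.table::data.table(
      file = f, preset = ds$meta$preset,
      prompts = sum(ds$records$window == "prompt"),
      delayeds = sum(ds$records$window == "delayed"),
      duration_s = ds$meta$duration_s)
  })
  invisible(data.table::rbindlist(rows))
}
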