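#' Read a simulation/analysis configuration
#'
#' Configurations are plain YAML or JSON; every run requires an
#' explicit integer `seed` so outputs are reproducible. Physical
#' defaults (timing, geometry, contrast and activation thresholds,
#' depletion divisors) live in the configuration, not in the
#' operations.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or a list.
#' @return Validated configuration list.
#' @export
read_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  if (is.null(config$seed)) {
    stop("config must set an explicit `seed`", call. = FALSE)
  }
  config$seed <- as.integer(config$seed)
  config
}

config_from <- function(config) {
  protocol <- do.call(acquisition_protocol,
                      config$protocol %||% list())
  gt_args <- config$ground_truth %||% list()
  if (!is.null(gt_args$binding)) {
    gt_args$binding <- do.call(mono_exp_params, gt_args$binding)
  }
  if (!is.null(gt_args$nonspecific)) {
    gt_args$nonspecific <- do.call(bi_exp_params, gt_args$nonspecific)
  }
  gt <- do.call(frap_ground_truth, gt_args)
  list(protocol = protocol, gt = gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read ROI trace tables
#'
#' Tidy CSV trace format shared by the simulator and the analyzer:
#' columns `cell`, `dot`, `kind` (ON/OFF), `frame` (0 denotes the
#' pre-bleach frame), `t` (seconds, NA for the pre-bleach row) and
#' `intensity`.
#'
#' @param sims Named-by-cell list of [simulate_roi_traces()] outputs.
#' @param path CSV file path.
#' @return `write_traces_csv` returns `path` invisibly;
#'   `read_traces_csv` returns the data frame.
#' @export
write_traces_csv <- function(sims, path) {
  rows <- lapply(seq_along(sims), function(i) {
    s <- sims[[i]]
    pre <- s$prebleach
    long <- rbind(
      data.frame(cell = i, dot = pre$dot, kind = "ON", frame = 0L,
                 t = NA_real_, intensity = pre$on),
      data.frame(cell = i, dot = pre$dot, kind = "OFF", frame = 0L,
                 t = NA_real_, intensity = pre$off),
      data.frame(cell = i, dot = s$traces$dot, kind = "ON",
                 frame = s$traces$frame, t = s$traces$t,
                 intensity = s$traces$on),
      data.frame(cell = i, dot = s$traces$dot, kind = "OFF",
                 frame = s$traces$frame, t = s$traces$t,
                 intensity = s$traces$off))
    long
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Rebuild per-cell dot curves from a trace table
#'
#' @param df Trace data frame in the [write_traces_csv()] format.
#' @return Named-by-cell list of per-dot `list(on, off)` curve pairs.
#' @export
traces_to_cells <- function(df) {
  lapply(split(df, df$cell), function(cd) {
    lapply(split(cd, cd$dot), function(dd) {
      on <- dd[dd$kind == "ON", ]
      off <- dd[dd$kind == "OFF", ]
      mk <- function(sub) {
        pre <- sub$intensity[sub$frame == 0L]
        post <- sub[sub$frame > 0L, ]
        post <- post[order(post$frame), ]
        recovery_curve(post$t, post$intensity, pre,
                       kind = sub$kind[1L],
                       corrections = c(background = TRUE))
      }
      list(on = mk(on), off = mk(off))
    })
  })
}

control_curve_from_csv <- function(path) {
  df <- utils::read.csv(path)
  pre <- df$intensity[df$frame == 0L]
  post <- df[df$frame > 0L, ]
  recovery_curve(post$t, post$intensity, pre, kind = "CONTROL",
                 corrections = c(background = TRUE))
}

#' Write an image series as multi-page TIFF
#'
#' Stores the pre-bleach frame followed by the post-bleach frames as
#' 16-bit pages (counts divided by `scale`); frame times go into a
#' JSON sidecar next to the file.
#'
#' @param series Output of [simulate_image_series()].
#' @param path TIFF file path.
#' @param scale Count value mapped to the 16-bit maximum.
#' @return `path`, invisibly.
#' @export
write_image_series <- function(series, path, scale = 2^16 - 1) {
  pages <- c(list(series$prebleach),
             lapply(seq_len(dim(series$frames)[3L]),
                    function(k) series$frames[, , k]))
  pages <- lapply(pages, function(m) pmin(pmax(m / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(timebase = series$timebase, scale = scale,
         background_region = series$background_region),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image series written by [write_image_series()]
#'
#' @param path TIFF file path (expects the JSON sidecar next to it).
#' @return List with `prebleach`, `frames`, `timebase`,
#'   `background_region`, compatible with [extract_roi_trace()].
#' @export
read_image_series <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(m) m * meta$scale)
  frames <- array(0, dim = c(dim(pages[[1L]]), length(pages) - 1L))
  for (k in seq_len(length(pages) - 1L)) frames[, , k] <- pages[[k + 1L]]
  list(prebleach = pages[[1L]], frames = frames,
       timebase = as.numeric(meta$timebase),
       background_region = meta$background_region)
}

#' Generate a synthetic dataset on disk
#'
#' Simulates a cohort of patterned cells (ROI traces), a paired
#' control series, optionally a repetitive-bleach series and an image
#' series, and writes them with a ground-truth JSON sidecar and the
#' echoed configuration. Every output is a deterministic function of
#' the configuration seed.
#'
#' @param config Configuration list or YAML/JSON path; must contain
#'   `seed`. Optional entries: `n_cells`, `n_dots`, `protocol`,
#'   `ground_truth`, `write_images`, `n_depletion_cells`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the list of written file paths.
#' @export
run_simulate <- function(config, out_dir) {
  config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cf <- config_from(config)
  n_cells <- config$n_cells %||% 3L
  n_dots <- config$n_dots %||% 7L
  seed <- config$seed

  sims <- lapply(seq_len(n_cells), function(i) {
    simulate_roi_traces(cf$gt, cf$protocol, n_dots = n_dots,
                        seed = seed + i)
  })
  paths <- character()
  traces_path <- file.path(out_dir, "traces.csv")
  write_traces_csv(sims, traces_path)
  paths <- c(paths, traces_path)

  ctrl <- simulate_control_series(cf$gt, cf$protocol, seed = seed + 10000L)
  control_path <- file.path(out_dir, "control.csv")
  utils::write.csv(
    rbind(data.frame(frame = 0L, t = NA_real_, intensity = ctrl$prebleach),
          ctrl$trace),
    control_path, row.names = FALSE)
  paths <- c(paths, control_path)

  n_dep <- config$n_depletion_cells %||% 0L
  if (n_dep > 0L) {
    dep <- lapply(seq_len(n_dep), function(i) {
      s <- simulate_repetitive_bleach_series(cf$gt, seed = seed + 20000L + i)
      cbind(cell = i, s$pulses)
    })
    dep_path <- file.path(out_dir, "repetitive_bleach.csv")
    utils::write.csv(do.call(rbind, dep), dep_path, row.names = FALSE)
    paths <- c(paths, dep_path)
  }

  if (isTRUE(config$write_images)) {
    geom <- do.call(pattern_geometry, config$geometry %||% list())
    img <- simulate_image_series(cf$gt, geom, cf$protocol,
                                 seed = seed + 30000L)
    img_path <- file.path(out_dir, "cell1.tif")
    write_image_series(img, img_path)
    paths <- c(paths, img_path)
  }

  config_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  sidecar <- list(seed = seed,
                  config_md5 = unname(tools::md5sum(config_path)),
                  ground_truth = list(
                    binding = unclass(cf$gt$binding),
                    nonspecific = unclass(cf$gt$nonspecific),
                    depletion = cf$gt$depletion,
                    acq_bleach_rate = cf$gt$acq_bleach_rate,
                    noise_sd = cf$gt$noise_sd,
                    contrast = cf$gt$contrast,
                    off_prebleach = cf$gt$off_prebleach))
  gt_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(sidecar, gt_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, config_path, gt_path))
}

#' Analyze a trace dataset end to end
#'
#' Reads a trace table and control series, runs the correction chain
#' (dF per dot, pooling, pre-bleach normalization, control division,
#' depletion division), fits each cell, and writes corrected curves,
#' per-cell fits and the cohort summary as CSVs. Every applied
#' correction is recorded in the curve flags and the run log.
#'
#' @param traces Path to a traces CSV ([write_traces_csv()] format) or
#'   the data frame itself.
#' @param control Path to a control CSV or a [recovery_curve()];
#'   `NULL` proceeds with a warning and no acquisition-bleach
#'   correction.
#' @param mode `"patterned"` (mono fit of dF) or `"coated"`
#'   (bi-exponential fit; the ON trace column is treated as the
#'   whole-cell signal).
#' @param temperature Temperature label, degrees C; selects the
#'   default depletion divisor (0.88 at 22, 0.85 at 37) when
#'   `depletion` is not given.
#' @param depletion A [depletion_correction()], a divisor in (0, 1], or
#'   `NULL` for the temperature default.
#' @param minutes Optional vector of minutes-after-seeding per cell.
#' @param out_dir Optional output directory for CSVs.
#' @return List with `curves` (per-cell corrected curves), `fits`
#'   (data frame) and `summary` (cohort table).
#' @export
run_analyze <- function(traces, control = NULL,
                        mode = c("patterned", "coated"),
                        temperature = 22, depletion = NULL,
                        minutes = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  df <- if (is.character(traces)) read_traces_csv(traces) else traces
  ctrl <- if (is.character(control)) control_curve_from_csv(control) else control
  if (is.null(depletion)) {
    depletion <- depletion_correction(
      divisor = if (temperature == 37) 0.85 else 0.88,
      temperature = temperature)
  } else if (is.numeric(depletion)) {
    depletion <- depletion_correction(divisor = depletion,
                                      temperature = temperature)
  }
  cells <- traces_to_cells(df)
  ids <- as.integer(names(cells))
  fits <- list()
  curves <- list()
  for (i in seq_along(cells)) {
    mins <- if (is.null(minutes)) NA_real_ else minutes[i]
    if (mode == "patterned") {
      curve <- corrected_delta_curve(cells[[i]], control = ctrl,
                                     depletion = depletion)
      cell_curves <- list(delta = curve)
    } else {
      # whole-cell signal: single ROI per cell, stored in the ON column
      ons <- lapply(cells[[i]], function(p) p$on)
      curve <- normalize_prebleach(pool_dots(ons))
      curve$kind <- "WHOLE_CELL"
      if (!is.null(ctrl)) {
        curve <- correct_acquisition_bleach(curve, ctrl)
      } else {
        warning("no control curve supplied; acquisition bleaching not corrected")
      }
      curve <- correct_depletion(curve, depletion)
      cell_curves <- list(whole_cell = curve)
    }
    curves[[i]] <- curve
    fits[[i]] <- fit_cell(cell_curves,
                          surface_type = mode,
                          temperature = temperature,
                          cell_id = ids[i], minutes = mins)
  }
  fits <- do.call(rbind, fits)
  summary <- summarize_cohort(fits)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    curve_df <- do.call(rbind, lapply(seq_along(curves), function(i) {
      cbind(cell = ids[i], as.data.frame(curves[[i]]))
    }))
    utils::write.csv(curve_df, file.path(out_dir, "curves.csv"),
                     row.names = FALSE)
    utils::write.csv(fits, file.path(out_dir, "fits.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  list(curves = curves, fits = fits, summary = summary)
}

#' Estimate the depletion divisor from a repetitive-bleach CSV
#'
#' Thin wrapper over [estimate_depletion()] for files with columns
#' `cell`, `pulse`, `pre`, `post`.
#'
#' @param path CSV path or data frame.
#' @param temperature Optional temperature label.
#' @return A [depletion_correction()].
#' @export
run_estimate_depletion <- function(path, temperature = NA_real_) {
  df <- if (is.character(path)) utils::read.csv(path) else path
  series <- lapply(split(df, df$cell), function(cd) list(pulses = cd))
  estimate_depletion(series, temperature = temperature)
}
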