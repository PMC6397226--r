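#' Assign cells to measurement time groups
#'
#' Cells measured at 22 degrees C form a single 5-45 minute group;
#' at 37 degrees C cells are split into early (5-15 min) and late
#' (25-45 min) groups after seeding.
#'
#' @param minutes Minutes after seeding.
#' @param temperature Temperature in degrees C (22 or 37).
#' @return Character vector of group labels.
#' @export
assign_time_group <- function(minutes, temperature) {
  mapply(function(m, temp) {
    if (is.na(temp) || temp == 22) return("5-45")
    if (is.na(m)) return(NA_character_)
    if (m < 20) "5-15" else "25-45"
  }, minutes, temperature, USE.NAMES = FALSE)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Summarize per-cell fits as cohort mean +/- SEM
#'
#' Aggregates per-cell fit results by surface type, temperature and
#' time group into mean +/- SEM per parameter with cell counts,
#' mirroring a cohort summary table. Non-converged fits and fits pinned
#' at a parameter bound are excluded; exclusion counts are reported per
#' group. Groups with a single cell get an `NA` SEM and a flag.
#'
#' @param fits Data frame of per-cell fit rows as produced by
#'   [fit_cell()] (one row per cell for the primary curve kind,
#'   `DELTA` or `WHOLE_CELL`).
#' @param params Parameters to summarize.
#' @return Data frame with one row per (surface_type, temperature,
#'   time_group): `<param>_mean`, `<param>_sem`, `n_cells`,
#'   `n_excluded`.
#' @export
summarize_cohort <- function(fits,
                             params = c("tau1", "tau2", "f_m", "b", "c")) {
  stopifnot(is.data.frame(fits), nrow(fits) >= 1L)
  fits <- fits[fits$kind %in% c("DELTA", "WHOLE_CELL"), , drop = FALSE]
  fits$time_group <- assign_time_group(fits$minutes, fits$temperature)
  groups <- split(fits, interaction(fits$surface_type, fits$temperature,
                                    fits$time_group, drop = TRUE))
  rows <- lapply(groups, function(g) {
    inc <- g[g$converged & !grepl("at_bound", g$flags), , drop = FALSE]
    out <- data.frame(surface_type = g$surface_type[1L],
                      temperature = g$temperature[1L],
                      time_group = g$time_group[1L],
                      n_cells = nrow(inc),
                      n_excluded = nrow(g) - nrow(inc))
    for (p in params) {
      v <- inc[[p]]
      v <- v[is.finite(v)]
      out[[paste0(p, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(p, "_sem")]] <- if (length(v) >= 2L) sem(v) else NA_real_
    }
    out$flag <- if (nrow(inc) < 2L) "single_cell_group" else ""
    if (nrow(inc) == 0L) {
      warning(sprintf("group %s/%s/%s has no usable fits",
                      out$surface_type, out$temperature, out$time_group))
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Per-cell fit parameters versus time after seeding
#'
#' Tidy table of the key FRAP parameters (mobile fraction and the
#' unbinding time constant tau or tau2) of each cell against the
#' measurement time point, with the per-fit standard errors, ready for
#' plotting.
#'
#' @param fits Data frame of per-cell fit rows from [fit_cell()].
#' @return Data frame with columns `cell`, `surface_type`,
#'   `temperature`, `minutes`, `f_m`, `se_f_m`, `tau`, `se_tau`
#'   (empty if `fits` is empty).
#' @export
time_course <- function(fits) {
  if (is.null(fits) || nrow(fits) == 0L) {
    return(data.frame(cell = integer(), surface_type = character(),
                      temperature = numeric(), minutes = numeric(),
                      f_m = numeric(), se_f_m = numeric(),
                      tau = numeric(), se_tau = numeric()))
  }
  fits <- fits[fits$kind %in% c("DELTA", "WHOLE_CELL"), , drop = FALSE]
  data.frame(cell = fits$cell, surface_type = fits$surface_type,
             temperature = fits$temperature, minutes = fits$minutes,
             f_m = fits$f_m, se_f_m = fits$se_f_m,
             tau = fits$tau2, se_tau = fits$se_tau2)
}
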