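#' Recovery curve container
#'
#' A FRAP recovery curve: the post-bleach time base, the post-bleach
#' intensity values, the pre-bleach value kept at a sentinel position
#' of its own, the curve kind, and flags recording which corrections
#' have been applied. The flags make the correction order explicit and
#' each correction idempotent or refused on re-application.
#'
#' @param t Post-bleach times, seconds, strictly increasing.
#' @param F Post-bleach intensities, same length as `t`.
#' @param prebleach Pre-bleach intensity value.
#' @param kind One of `"ON"`, `"OFF"`, `"DELTA"`, `"WHOLE_CELL"`,
#'   `"CONTROL"`.
#' @param corrections Named logical flags `background`, `normalized`,
#'   `acq_bleach`, `depletion`.
#' @param n_dots Number of dots pooled into this curve, if any.
#' @return An object of class `recovery_curve`.
#' @export
recovery_curve <- function(t, F, prebleach,
                           kind = c("ON", "OFF", "DELTA", "WHOLE_CELL",
                                    "CONTROL"),
                           corrections = c(background = FALSE,
                                           normalized = FALSE,
                                           acq_bleach = FALSE,
                                           depletion = FALSE),
                           n_dots = NA_integer_) {
  kind <- match.arg(kind)
  stopifnot(length(t) == length(F), length(prebleach) == 1L)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("time base must be strictly increasing", call. = FALSE)
  }
  flags <- c(background = FALSE, normalized = FALSE,
             acq_bleach = FALSE, depletion = FALSE)
  flags[names(corrections)] <- corrections
  structure(list(t = as.numeric(t), F = as.numeric(F),
                 prebleach = as.numeric(prebleach), kind = kind,
                 corrections = flags, n_dots = n_dots),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  applied <- names(x$corrections)[x$corrections]
  cat(sprintf("%s recovery curve: %d post-bleach points, prebleach = %.4g\n",
              x$kind, length(x$t), x$prebleach))
  cat("  corrections applied:",
      if (length(applied)) paste(applied, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Extract a background-corrected ROI trace from an image series
#'
#' For the pre-bleach frame and each post-bleach frame, the mean pixel
#' intensity over the region minus the mean over a dot-free background
#' region.
#'
#' @param series Image series as returned by [simulate_image_series()]
#'   (a list with `prebleach` matrix, `frames` array and `timebase`),
#'   or an equivalent list.
#' @param region_idx Linear pixel indices of the region.
#' @param background_idx Linear pixel indices of the background region.
#' @param kind Curve kind to record.
#' @return A [recovery_curve()] with the `background` flag set.
#' @export
extract_roi_trace <- function(series, region_idx, background_idx,
                              kind = "ON") {
  if (length(region_idx) == 0L) stop("empty region", call. = FALSE)
  if (length(background_idx) == 0L) {
    stop("empty background region", call. = FALSE)
  }
  pre <- mean(series$prebleach[region_idx]) -
    mean(series$prebleach[background_idx])
  n <- dim(series$frames)[3L]
  vals <- vapply(seq_len(n), function(k) {
    fr <- series$frames[, , k]
    mean(fr[region_idx]) - mean(fr[background_idx])
  }, numeric(1))
  recovery_curve(series$timebase, vals, pre, kind = kind,
                 corrections = c(background = TRUE))
}

#' Specific-binding correction dF = F_ON - F_OFF
#'
#' Pointwise subtraction of the OFF (receptor-depleted) trace from the
#' ON (receptor-enriched) trace of the same dot. Cytosolic diffusion
#' and other non-specific recovery contribute equally to both regions,
#' so the difference isolates the receptor-binding component. Computed
#' per dot, before pooling.
#'
#' @param on,off [recovery_curve()]s of kind ON and OFF on identical
#'   time bases, at the same correction stage.
#' @return A [recovery_curve()] of kind DELTA whose pre-bleach value is
#'   the pre-bleach dF.
#' @export
delta_F <- function(on, off) {
  stopifnot(inherits(on, "recovery_curve"), inherits(off, "recovery_curve"))
  if (length(on$t) != length(off$t) || any(on$t != off$t)) {
    stop("ON and OFF curves must share the same time base", call. = FALSE)
  }
  if (!identical(on$corrections, off$corrections)) {
    stop("ON and OFF curves are at different correction stages",
         call. = FALSE)
  }
  recovery_curve(on$t, on$F - off$F, on$prebleach - off$prebleach,
                 kind = "DELTA", corrections = on$corrections)
}

#' Pool per-dot curves into one cell-level curve
#'
#' Pointwise mean across the retained dots of a cell; the number of
#' dots entering the pool is recorded on the result.
#'
#' @param per_dot_curves Non-empty list of [recovery_curve()]s on
#'   identical time bases.
#' @return A single pooled [recovery_curve()].
#' @export
pool_dots <- function(per_dot_curves) {
  if (length(per_dot_curves) == 0L) {
    stop("no dots to pool; cell excluded", call. = FALSE)
  }
  ref <- per_dot_curves[[1L]]
  for (cv in per_dot_curves[-1L]) {
    if (length(cv$t) != length(ref$t) || any(cv$t != ref$t)) {
      stop("curves must share the same time base", call. = FALSE)
    }
    if (!identical(cv$corrections, ref$corrections) ||
        !identical(cv$kind, ref$kind)) {
      stop("curves must be of the same kind and correction stage",
           call. = FALSE)
    }
  }
  Fmat <- vapply(per_dot_curves, function(cv) cv$F, numeric(length(ref$t)))
  pre <- mean(vapply(per_dot_curves, function(cv) cv$prebleach, numeric(1)))
  recovery_curve(ref$t, rowMeans(as.matrix(Fmat)), pre, kind = ref$kind,
                 corrections = ref$corrections,
                 n_dots = length(per_dot_curves))
}

#' Normalize a curve to its pre-bleach value
#'
#' Divides all values (including the pre-bleach point) by the
#' pre-bleach value, so the pre-bleach level becomes 1. For DELTA
#' curves the divisor is the pre-bleach dF, making the recovered
#' fraction relative to the pre-bleach pattern contrast. Idempotent:
#' renormalizing an already-normalized curve is a no-op.
#'
#' @param curve A [recovery_curve()] with `prebleach > 0`.
#' @return The normalized curve with the `normalized` flag set.
#' @export
normalize_prebleach <- function(curve) {
  stopifnot(inherits(curve, "recovery_curve"))
  if (curve$corrections[["normalized"]]) return(curve)
  if (!is.finite(curve$prebleach) || curve$prebleach <= 0) {
    stop("pre-bleach value must be > 0 for normalization", call. = FALSE)
  }
  curve$F <- curve$F / curve$prebleach
  curve$prebleach <- 1
  curve$corrections[["normalized"]] <- TRUE
  curve
}

#' Correct for photobleaching during acquisition
#'
#' Divides each post-bleach data point by the corresponding point of a
#' no-bleach control curve (normalized to its own pre-bleach value),
#' removing the readout-photobleaching envelope empirically.
#'
#' @param curve A normalized [recovery_curve()].
#' @param control_curve A [recovery_curve()] from a control (no bleach
#'   pulse) acquisition on the same time base; normalized internally if
#'   needed.
#' @return The corrected curve with the `acq_bleach` flag set.
#' @export
correct_acquisition_bleach <- function(curve, control_curve) {
  stopifnot(inherits(curve, "recovery_curve"),
            inherits(control_curve, "recovery_curve"))
  if (curve$corrections[["acq_bleach"]]) {
    stop("acquisition-bleach correction already applied", call. = FALSE)
  }
  if (!curve$corrections[["normalized"]]) {
    stop("normalize the curve before the acquisition-bleach correction",
         call. = FALSE)
  }
  control_curve <- normalize_prebleach(control_curve)
  if (length(curve$t) != length(control_curve$t) ||
      any(curve$t != control_curve$t)) {
    stop("control curve must share the FRAP time base", call. = FALSE)
  }
  if (any(control_curve$F == 0)) {
    stop("control curve contains zeros", call. = FALSE)
  }
  curve$F <- curve$F / control_curve$F
  curve$corrections[["acq_bleach"]] <- TRUE
  curve
}

#' Depletion correction factor
#'
#' The bleach pulse destroys the fraction `d` of the detected
#' fluorescent pool; post-bleach data are divided by `1 - d` to express
#' recovery relative to the remaining pool. The cohort values are
#' 0.88 (22 degrees C) and 0.85 (37 degrees C).
#'
#' @param d Depleted fraction; exactly one of `d` and `divisor` is
#'   given.
#' @param divisor Correction divisor `1 - d`.
#' @param temperature Optional temperature label, degrees C.
#' @return An object of class `depletion_correction`.
#' @export
depletion_correction <- function(d = NULL, divisor = NULL,
                                 temperature = NA_real_) {
  if (is.null(d) == is.null(divisor)) {
    stop("give exactly one of `d` or `divisor`", call. = FALSE)
  }
  if (is.null(divisor)) divisor <- 1 - d else d <- 1 - divisor
  if (divisor <= 0 || divisor > 1) {
    stop("divisor must lie in (0, 1]", call. = FALSE)
  }
  structure(list(d = d, divisor = divisor, temperature = temperature),
            class = "depletion_correction")
}

#' Correct for bleach-pulse depletion
#'
#' Divides every post-bleach point by the depletion divisor `1 - d`.
#' The pre-bleach point measures the undepleted pool and is left
#' untouched.
#'
#' @param curve A normalized [recovery_curve()].
#' @param corr A [depletion_correction()].
#' @return The corrected curve with the `depletion` flag set.
#' @export
correct_depletion <- function(curve, corr) {
  stopifnot(inherits(curve, "recovery_curve"),
            inherits(corr, "depletion_correction"))
  if (curve$corrections[["depletion"]]) {
    stop("depletion correction already applied", call. = FALSE)
  }
  if (!curve$corrections[["normalized"]]) {
    stop("normalize the curve before the depletion correction",
         call. = FALSE)
  }
  curve$F <- curve$F / corr$divisor
  curve$corrections[["depletion"]] <- TRUE
  curve
}

#' Build per-dot ON/OFF curves from simulated ROI traces
#'
#' Converts the output of [simulate_roi_traces()] into a list of
#' per-dot ON/OFF [recovery_curve()] pairs (traces are generated
#' background-corrected, so the background flag is set).
#'
#' @param sim Output of [simulate_roi_traces()].
#' @return List with one element per dot, each a list of `on` and
#'   `off` curves.
#' @export
curves_from_traces <- function(sim) {
  lapply(split(sim$traces, sim$traces$dot), function(df) {
    dot <- df$dot[1L]
    pre <- sim$prebleach[sim$prebleach$dot == dot, ]
    list(on = recovery_curve(df$t, df$on, pre$on, kind = "ON",
                             corrections = c(background = TRUE)),
         off = recovery_curve(df$t, df$off, pre$off, kind = "OFF",
                              corrections = c(background = TRUE)))
  })
}

#' Corrected cell-level dF curve from per-dot traces
#'
#' Runs the fixed correction chain for a patterned cell: per-dot
#' dF = F_ON - F_OFF, pooling across dots, pre-bleach normalization,
#' division by the control curve (if given), and division by the
#' depletion divisor (if given).
#'
#' @param dot_curves List of per-dot `list(on, off)` pairs, as from
#'   [curves_from_traces()].
#' @param control Optional control [recovery_curve()].
#' @param depletion Optional [depletion_correction()].
#' @return A corrected DELTA [recovery_curve()].
#' @export
corrected_delta_curve <- function(dot_curves, control = NULL,
                                  depletion = NULL) {
  deltas <- lapply(dot_curves, function(p) delta_F(p$on, p$off))
  curve <- normalize_prebleach(pool_dots(deltas))
  if (!is.null(control)) {
    curve <- correct_acquisition_bleach(curve, control)
  } else {
    warning("no control curve supplied; acquisition bleaching not corrected")
  }
  if (!is.null(depletion)) curve <- correct_depletion(curve, depletion)
  curve
}

#' Tidy data frame view of recovery curves
#'
#' @param x A [recovery_curve()].
#' @param ... Unused.
#' @return Data frame with columns `t`, `F`, `kind` plus the pre-bleach
#'   point at `t = NA`.
#' @export
as.data.frame.recovery_curve <- function(x, ...) {
  data.frame(t = c(NA_real_, x$t), F = c(x$prebleach, x$F), kind = x$kind)
}
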