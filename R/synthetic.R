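#' Ground truth for synthetic FRAP data
#'
#' Bundles the generative parameters of the simulator so that every
#' downstream stage can be checked by parameter recovery.
#'
#' The ON signal over a micropattern dot is modeled as the OFF
#' (non-specific) signal plus a receptor-binding component that
#' exchanges mono-exponentially; the OFF signal is a fast cytosolic plus
#' a slow non-specific component, i.e. a bi-exponential recovery. The
#' bleach pulse depletes the detected fluorescent pool by the fraction
#' `depletion`; every readout frame additionally costs the fraction
#' `acq_bleach_rate` of the remaining signal (per-frame multiplicative
#' loss, since exposures are constant while inter-frame delays vary).
#' Noise is additive Gaussian with standard deviation `noise_sd`
#' relative to the pre-bleach level of each trace.
#'
#' @param binding [mono_exp_params()] of the receptor-bound exchange,
#'   expressed relative to the pre-bleach dF level. Default from the
#'   patterned 22 degree C cohort means (tau = 14.6 s, f_m = 0.78,
#'   b = 0.12).
#' @param nonspecific [bi_exp_params()] of the OFF-area recovery,
#'   relative to the pre-bleach OFF level (fast cytosolic component
#'   around 0.3 s, slow component on the 10 s scale).
#' @param depletion Fraction of the fluorescent pool destroyed by the
#'   bleach pulse, in \[0, 1). Default 0.12.
#' @param acq_bleach_rate Per-frame multiplicative signal loss from
#'   readout illumination, in \[0, 1).
#' @param noise_sd Gaussian noise sd on normalized intensity.
#' @param contrast Pre-bleach dot contrast (F_ON - F_OFF) / F_ON used to
#'   set the ON level relative to the OFF level.
#' @param off_prebleach Pre-bleach OFF-level intensity in camera counts.
#' @return An object of class `frap_ground_truth`.
#' @export
frap_ground_truth <- function(binding = mono_exp_params(tau = 14.6,
                                                        f_m = 0.78,
                                                        b = 0.12),
                              nonspecific = bi_exp_params(tau1 = 0.3,
                                                          tau2 = 12,
                                                          f_m = 0.9,
                                                          b = 0.2,
                                                          c_frac = 0.7),
                              depletion = 0.12,
                              acq_bleach_rate = 0.002,
                              noise_sd = 0.02,
                              contrast = 0.5,
                              off_prebleach = 1000) {
  stopifnot(inherits(binding, "mono_exp_params"),
            inherits(nonspecific, "bi_exp_params"))
  if (depletion < 0 || depletion >= 1) {
    stop("depletion must lie in [0, 1)", call. = FALSE)
  }
  if (acq_bleach_rate < 0 || acq_bleach_rate >= 1) {
    stop("acq_bleach_rate must lie in [0, 1)", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(contrast <= 0) || any(contrast >= 1)) {
    stop("contrast must lie in (0, 1)", call. = FALSE)
  }
  if (off_prebleach <= 0) stop("off_prebleach must be > 0", call. = FALSE)
  structure(list(binding = binding, nonspecific = nonspecific,
                 depletion = depletion, acq_bleach_rate = acq_bleach_rate,
                 noise_sd = noise_sd, contrast = contrast,
                 off_prebleach = off_prebleach),
            class = "frap_ground_truth")
}

#' Micropattern geometry
#'
#' Describes the stamped antibody dot grid: 1 um diameter circular dots
#' at 3 um center-to-center pitch by default, rendered at a configurable
#' pixel size. The dot grid is centered in the image, surrounded by a
#' dot-free margin whose outer band serves as the background region.
#'
#' @param dot_diameter Dot diameter, um.
#' @param pitch Center-to-center dot distance, um.
#' @param pixel_size Pixel edge length, um.
#' @param n_dots_x,n_dots_y Grid dimensions in dots.
#' @param margin_px Dot-free margin width around the grid, pixels; the
#'   outermost `background_px` of it is treated as outside the cell.
#' @param background_px Width of the background band at the image edge.
#' @return An object of class `pattern_geometry` with derived fields
#'   `dot_radius_px`, `pitch_px`, `width`, `height`.
#' @export
pattern_geometry <- function(dot_diameter = 1, pitch = 3, pixel_size = 0.1,
                             n_dots_x = 3L, n_dots_y = 3L,
                             margin_px = 12L, background_px = 5L) {
  if (pitch <= dot_diameter) {
    stop("pitch must exceed the dot diameter", call. = FALSE)
  }
  pitch_px <- pitch / pixel_size
  radius_px <- dot_diameter / 2 / pixel_size
  width <- ceiling((n_dots_x - 1) * pitch_px + 2 * radius_px) + 2 * margin_px
  height <- ceiling((n_dots_y - 1) * pitch_px + 2 * radius_px) + 2 * margin_px
  if (margin_px <= background_px + radius_px) {
    stop("margin too small to hold the background band plus the annulus",
         call. = FALSE)
  }
  structure(list(dot_diameter = dot_diameter, pitch = pitch,
                 pixel_size = pixel_size,
                 n_dots_x = as.integer(n_dots_x),
                 n_dots_y = as.integer(n_dots_y),
                 margin_px = as.integer(margin_px),
                 background_px = as.integer(background_px),
                 dot_radius_px = radius_px, pitch_px = pitch_px,
                 width = as.integer(width), height = as.integer(height)),
            class = "pattern_geometry")
}

# Noiseless raw ON/OFF trace pair for one dot; k is the post-bleach
# frame index (1-based) used for the per-frame acquisition-bleach loss.
raw_dot_traces <- function(gt, tb, contrast) {
  off_pre <- gt$off_prebleach
  on_pre <- off_pre / (1 - contrast)
  amp <- on_pre - off_pre
  k <- seq_along(tb)
  envelope <- (1 - gt$depletion) * (1 - gt$acq_bleach_rate)^k
  off <- off_pre * bi_exp_model(tb, gt$nonspecific) * envelope
  on <- (off_pre * bi_exp_model(tb, gt$nonspecific) +
           amp * mono_exp_model(tb, gt$binding)) * envelope
  list(on_pre = on_pre, off_pre = off_pre, on = on, off = off)
}

#' Simulate per-dot ON/OFF ROI intensity traces
#'
#' Generates raw (background-corrected) intensity traces for `n_dots`
#' micropattern dots of one cell: for each dot a pre-bleach ON and OFF
#' value and post-bleach ON and OFF traces on the protocol's
#' logarithmic time base. The OFF trace follows the non-specific
#' bi-exponential recovery; the ON trace adds the receptor-binding
#' mono-exponential component on top. Both post-bleach traces carry the
#' bleach-pulse depletion factor (1 - d), the cumulative per-frame
#' acquisition-bleach envelope, and Gaussian noise.
#'
#' @param gt A [frap_ground_truth()].
#' @param protocol An [acquisition_protocol()].
#' @param n_dots Number of dots, >= 1.
#' @param seed Integer RNG seed (required; all randomness is explicit).
#' @return A list with elements `prebleach` (data frame: dot, on, off),
#'   `traces` (data frame: dot, frame, t, on, off), `timebase`, and the
#'   ground truth echoed back as `ground_truth`.
#' @export
simulate_roi_traces <- function(gt, protocol = acquisition_protocol(),
                                n_dots = 7L, seed) {
  stopifnot(inherits(gt, "frap_ground_truth"),
            inherits(protocol, "acquisition_protocol"))
  n_dots <- as.integer(n_dots)
  if (n_dots < 1L) stop("n_dots must be >= 1", call. = FALSE)
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  set.seed(seed)
  tb <- make_timebase(protocol)
  contrast <- rep_len(gt$contrast, n_dots)
  pre <- vector("list", n_dots)
  tr <- vector("list", n_dots)
  for (i in seq_len(n_dots)) {
    d <- raw_dot_traces(gt, tb, contrast[i])
    n <- length(tb)
    on_noise <- stats::rnorm(n, 0, gt$noise_sd * d$on_pre)
    off_noise <- stats::rnorm(n, 0, gt$noise_sd * d$off_pre)
    pre[[i]] <- data.frame(dot = i, on = d$on_pre, off = d$off_pre)
    tr[[i]] <- data.frame(dot = i, frame = seq_len(n), t = tb,
                          on = d$on + on_noise, off = d$off + off_noise)
  }
  list(prebleach = do.call(rbind, pre),
       traces = do.call(rbind, tr),
       timebase = tb,
       ground_truth = gt)
}

#' Simulate a no-bleach control series
#'
#' Same timing protocol as a FRAP acquisition but with the bleach pulse
#' replaced by a standby time: only readout photobleaching and noise
#' act, so the trace is the pre-bleach level times the per-frame
#' acquisition-bleach envelope. Divided by its pre-bleach value it is
#' the empirical correction curve for acquisition bleaching.
#'
#' @inheritParams simulate_roi_traces
#' @return A list with `prebleach` (scalar), `trace` (data frame:
#'   frame, t, intensity), and `timebase`.
#' @export
simulate_control_series <- function(gt, protocol = acquisition_protocol(),
                                    seed) {
  stopifnot(inherits(gt, "frap_ground_truth"),
            inherits(protocol, "acquisition_protocol"))
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  set.seed(seed)
  tb <- make_timebase(protocol)
  k <- seq_along(tb)
  pre <- gt$off_prebleach
  y <- pre * (1 - gt$acq_bleach_rate)^k +
    stats::rnorm(length(tb), 0, gt$noise_sd * pre)
  list(prebleach = pre,
       trace = data.frame(frame = k, t = tb, intensity = y),
       timebase = tb)
}

#' Simulate a repetitive-bleach depletion series
#'
#' Emulates the alternative FRAP protocol used to measure bleach-pulse
#' depletion: repeated 500 ms bleach pulses separated by a short gap,
#' each followed by one readout image. The fast cytosolic component
#' re-equilibrates between pulses, so from the second pulse on each
#' pulse removes the steady fraction `gt$depletion` of the detected
#' pool. The first pulse additionally bleaches slowly exchanging
#' structures (`first_pulse_extra`), which is why the estimator
#' discards it.
#'
#' @param gt A [frap_ground_truth()]; `gt$depletion` is the per-pulse
#'   depleted fraction and `gt$noise_sd` the relative readout noise.
#' @param n_pulses Number of bleach pulses, >= 5.
#' @param pulse_gap Gap between pulses, seconds (metadata only).
#' @param readout_delay Delay from pulse end to readout, seconds
#'   (metadata only).
#' @param first_pulse_extra Additional fractional loss at pulse 1 from
#'   structures that do not re-equilibrate.
#' @param seed Integer RNG seed (required).
#' @return A list with `pulses` (data frame: pulse, pre, post),
#'   `prebleach` (initial intensity) and timing metadata.
#' @export
simulate_repetitive_bleach_series <- function(gt, n_pulses = 5L,
                                              pulse_gap = 1.5,
                                              readout_delay = 1,
                                              first_pulse_extra = 0.1,
                                              seed) {
  stopifnot(inherits(gt, "frap_ground_truth"))
  n_pulses <- as.integer(n_pulses)
  if (n_pulses < 5L) {
    stop("need >= 5 pulses (pulse 1 is discarded, 4 are averaged)",
         call. = FALSE)
  }
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  set.seed(seed)
  d <- gt$depletion
  intens <- numeric(n_pulses + 1L)
  intens[1L] <- gt$off_prebleach
  intens[2L] <- intens[1L] * (1 - d) * (1 - first_pulse_extra)
  for (i in seq(2L, n_pulses)) {
    intens[i + 1L] <- intens[i] * (1 - d)
  }
  noisy <- intens + stats::rnorm(n_pulses + 1L, 0,
                                 gt$noise_sd * gt$off_prebleach)
  pulses <- data.frame(pulse = seq_len(n_pulses),
                       pre = noisy[seq_len(n_pulses)],
                       post = noisy[-1L])
  list(pulses = pulses, prebleach = noisy[1L],
       pulse_gap = pulse_gap, readout_delay = readout_delay)
}

#' Simulate a micropatterned TIRF image series
#'
#' Renders one pre-bleach frame plus the post-bleach series of a
#' micropatterned cell: circular dots on a regular grid, each pixel
#' evolving according to the ON model inside dots and the OFF model in
#' the surrounding cell area, with depletion, acquisition bleaching and
#' per-pixel Gaussian noise. The outermost image band lies outside the
#' cell and carries only the constant background level, providing the
#' background region for extraction.
#'
#' @inheritParams simulate_roi_traces
#' @param geom A [pattern_geometry()].
#' @param background_level Camera background in counts.
#' @return A list with `prebleach` (matrix), `frames` (array height x
#'   width x n frames), `timebase`, `centers` (data frame of true dot
#'   centers, pixel coordinates), `background_region` (row/col ranges),
#'   `geometry` and `ground_truth`.
#' @export
simulate_image_series <- function(gt, geom = pattern_geometry(),
                                  protocol = acquisition_protocol(),
                                  background_level = 100, seed) {
  stopifnot(inherits(gt, "frap_ground_truth"),
            inherits(geom, "pattern_geometry"))
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  set.seed(seed)
  tb <- make_timebase(protocol)
  n_frames <- length(tb)
  h <- geom$height; w <- geom$width
  contrast <- rep_len(gt$contrast, geom$n_dots_x * geom$n_dots_y)

  # true dot centers, pixel coordinates (row = y, col = x)
  first <- geom$margin_px + geom$dot_radius_px
  cx <- first + (seq_len(geom$n_dots_x) - 1L) * geom$pitch_px
  cy <- first + (seq_len(geom$n_dots_y) - 1L) * geom$pitch_px
  centers <- expand.grid(row = cy, col = cx)
  centers <- data.frame(dot = seq_len(nrow(centers)),
                        row = centers$row, col = centers$col)

  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dot_id <- matrix(0L, h, w)
  for (i in seq_len(nrow(centers))) {
    inside <- (rows - centers$row[i])^2 + (cols - centers$col[i])^2 <=
      geom$dot_radius_px^2
    dot_id[inside] <- i
  }
  bg_px <- geom$background_px
  in_cell <- rows > bg_px & rows <= h - bg_px & cols > bg_px & cols <= w - bg_px

  off_pre <- gt$off_prebleach
  on_pre <- off_pre / (1 - contrast)

  base_pre <- matrix(background_level, h, w)
  base_pre[in_cell] <- background_level + off_pre
  idx_dot <- dot_id > 0L
  base_pre[idx_dot] <- background_level + on_pre[dot_id[idx_dot]]

  noise_scale <- gt$noise_sd * matrix(off_pre, h, w)
  noise_scale[idx_dot] <- gt$noise_sd * on_pre[dot_id[idx_dot]]
  noise_scale[!in_cell] <- gt$noise_sd * background_level

  prebleach <- base_pre + stats::rnorm(h * w, 0, as.vector(noise_scale))

  frames <- array(0, dim = c(h, w, n_frames))
  off_curve <- bi_exp_model(tb, gt$nonspecific)
  bind_curve <- mono_exp_model(tb, gt$binding)
  envelope <- (1 - gt$depletion) * (1 - gt$acq_bleach_rate)^seq_len(n_frames)
  amp <- on_pre - off_pre
  for (k in seq_len(n_frames)) {
    fr <- matrix(background_level, h, w)
    fr[in_cell] <- background_level + off_pre * off_curve[k] * envelope[k]
    fr[idx_dot] <- background_level +
      (off_pre * off_curve[k] + amp[dot_id[idx_dot]] * bind_curve[k]) *
      envelope[k]
    frames[, , k] <- fr + stats::rnorm(h * w, 0, as.vector(noise_scale))
  }

  list(prebleach = prebleach, frames = frames, timebase = tb,
       centers = centers,
       background_region = list(rows = c(1L, bg_px), cols = c(1L, w)),
       dot_id = dot_id, geometry = geom, ground_truth = gt)
}

#' Simulate normalized ratiometric calcium traces
#'
#' Generates single-cell Fura-2-style ratio traces sampled at 1 Hz over
#' a 10 minute window, normalized to 1 at time zero, with known
#' ground-truth activation flags. Activated cells show a sigmoidal
#' calcium rise of amplitude well above the 0.4 activation threshold
#' with onset within the first 5 minutes; non-activated cells fluctuate
#' around baseline with slow drift that stays below threshold.
#'
#' @param n_cells Number of cells, >= 1.
#' @param activation_probability Probability that a cell activates.
#' @param seed Integer RNG seed (required).
#' @param duration Trace duration, seconds.
#' @param noise_sd Gaussian noise sd on the normalized ratio.
#' @return A list with `traces` (data frame: cell, t, ratio) and
#'   `activated` (ground-truth logical vector, one per cell).
#' @export
simulate_calcium_traces <- function(n_cells, activation_probability, seed,
                                    duration = 600, noise_sd = 0.02) {
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  if (activation_probability < 0 || activation_probability > 1) {
    stop("activation_probability must lie in [0, 1]", call. = FALSE)
  }
  if (missing(seed)) stop("an explicit `seed` is required", call. = FALSE)
  set.seed(seed)
  t <- seq(0, duration, by = 1)
  activated <- stats::runif(n_cells) < activation_probability
  traces <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    base <- rep(1, length(t))
    if (activated[i]) {
      onset <- stats::runif(1, 30, 290)       # within the first 5 min
      amp <- stats::runif(1, 0.6, 1.2)        # clear threshold crossing
      rise <- 1 / (1 + exp(-(t - onset) / 8))
      decay <- exp(-pmax(t - onset, 0) / 400) # slow return toward baseline
      base <- base + amp * rise * decay
    } else {
      drift_amp <- stats::runif(1, 0, 0.15)   # sub-threshold fluctuation
      phase <- stats::runif(1, 0, 2 * pi)
      base <- base + drift_amp * sin(2 * pi * t / duration + phase) *
        (t / duration)
    }
    y <- base + stats::rnorm(length(t), 0, noise_sd)
    y <- y / y[1L]                            # normalize to t = 0
    traces[[i]] <- data.frame(cell = i, t = t, ratio = y)
  }
  list(traces = do.call(rbind, traces), activated = activated)
}
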