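# Separable running-max / running-mean filters used by dot detection.
# radius r means a (2r+1)-pixel square window; edges padded by -Inf
# (max) or by shrinking the window (mean).
shift_mat <- function(m, dr, dc, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- seq_len(h) - dr; cs <- seq_len(w) - dc
  ok_r <- rs >= 1L & rs <= h; ok_c <- cs >= 1L & cs <= w
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

max_filter <- function(m, radius) {
  rowmax <- m
  for (d in seq_len(radius)) {
    rowmax <- pmax(rowmax, shift_mat(m, d, 0, -Inf), shift_mat(m, -d, 0, -Inf))
  }
  out <- rowmax
  for (d in seq_len(radius)) {
    out <- pmax(out, shift_mat(rowmax, 0, d, -Inf),
                shift_mat(rowmax, 0, -d, -Inf))
  }
  out
}

mean_filter <- function(m, radius) {
  acc <- m * 0; cnt <- m * 0
  ones <- matrix(1, nrow(m), ncol(m))
  for (d in -radius:radius) {
    acc <- acc + shift_mat(m, d, 0, 0)
    cnt <- cnt + shift_mat(ones, d, 0, 0)
  }
  row_mean <- acc / cnt
  acc <- m * 0; cnt <- m * 0
  for (d in -radius:radius) {
    acc <- acc + shift_mat(row_mean, 0, d, 0)
    cnt <- cnt + shift_mat(ones, 0, d, 0)
  }
  acc / cnt
}

#' Detect micropattern dot centers in a pre-bleach image
#'
#' Automated stand-in for manually drawn dot masks: the image is
#' smoothed with a small mean filter, local maxima are found within a
#' window set by the pattern pitch, maxima below a relative intensity
#' threshold are rejected, and surviving peaks are refined to
#' intensity-weighted centroids. Detection is deterministic given the
#' image.
#'
#' @param prebleach_image Numeric matrix (pre-bleach frame).
#' @param geom_hint A [pattern_geometry()] supplying the expected pitch
#'   and dot radius in pixels.
#' @param min_height Fraction of the background-to-peak intensity range
#'   a smoothed maximum must reach to count as a dot.
#' @param smooth_radius Mean-filter radius in pixels.
#' @return Data frame with columns `dot`, `row`, `col` (fractional
#'   pixel coordinates); zero rows, with a warning, if no dot is found.
#' @export
detect_dots <- function(prebleach_image, geom_hint,
                        min_height = 0.5, smooth_radius = 2L) {
  stopifnot(is.matrix(prebleach_image), inherits(geom_hint, "pattern_geometry"))
  img <- prebleach_image
  h <- nrow(img); w <- ncol(img)
  sm <- mean_filter(img, smooth_radius)
  bg_px <- geom_hint$background_px
  border <- c(sm[seq_len(bg_px), ], sm[seq(h - bg_px + 1L, h), ],
              sm[, seq_len(bg_px)], sm[, seq(w - bg_px + 1L, w)])
  bg <- stats::median(border)
  thr <- bg + min_height * (max(sm) - bg)
  sep <- max(2L, floor(geom_hint$pitch_px / 2))
  is_peak <- sm == max_filter(sm, sep) & sm > thr
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("no dots detected above threshold")
    return(data.frame(dot = integer(), row = numeric(), col = numeric()))
  }
  ord <- order(sm[is_peak], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  keep <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    if (nrow(keep) == 0L ||
        all((keep[, 1] - p[1])^2 + (keep[, 2] - p[2])^2 >= sep^2)) {
      keep <- rbind(keep, p)
    }
  }
  # refine to intensity-weighted centroid within the dot radius,
  # re-centering the window so pixelation of the peak does not bias it
  r <- ceiling(geom_hint$dot_radius_px) + 1L
  centers <- t(apply(keep, 1L, function(p) {
    ctr <- c(p[1], p[2])
    for (it in 1:3) {
      rr <- max(1L, round(ctr[1]) - r):min(h, round(ctr[1]) + r)
      cc <- max(1L, round(ctr[2]) - r):min(w, round(ctr[2]) + r)
      patch <- img[rr, cc, drop = FALSE] - bg
      # weight only pixels in the upper half of the local range so the
      # uniform in-cell level around the dot does not pull the centroid
      patch[patch < 0.5 * (max(patch) + min(patch))] <- 0
      s <- sum(patch)
      if (s <= 0) break
      ctr <- c(sum(rr * rowSums(patch)) / s, sum(cc * colSums(patch)) / s)
    }
    ctr
  }))
  centers <- centers[order(centers[, 1], centers[, 2]), , drop = FALSE]
  data.frame(dot = seq_len(nrow(centers)),
             row = centers[, 1], col = centers[, 2])
}

#' Build ON/OFF selection masks around dot centers
#'
#' For each dot center, constructs a rectangular ON region inscribed in
#' the dot and a rectangular OFF annulus around it. The ON square is
#' the largest square inscribed in the dot disk; the annulus starts
#' `annulus_gap` pixels outside the ON square and extends to 2/3 of the
#' half-pitch, so the annuli of neighboring dots never reach the
#' neighboring dots themselves. Dots whose annulus would cross the
#' image (or cell) boundary are skipped.
#'
#' @param centers Data frame with `row`, `col` dot centers (pixels), as
#'   returned by [detect_dots()].
#' @param geom A [pattern_geometry()].
#' @param image_dim Integer vector `c(height, width)` of the frames the
#'   masks will be applied to.
#' @param annulus_gap Gap between the ON square and the inner edge of
#'   the OFF annulus, pixels.
#' @param cell_mask Optional logical matrix marking in-cell pixels;
#'   dots whose annulus leaves the mask are skipped.
#' @return A list of `dot_roi` objects, each with fields `dot`, `row`,
#'   `col`, `on_idx` and `off_idx` (linear pixel indices) and a
#'   `contrast` slot filled by [measure_contrast()].
#' @export
build_masks <- function(centers, geom, image_dim, annulus_gap = 2L,
                        cell_mask = NULL) {
  stopifnot(inherits(geom, "pattern_geometry"), length(image_dim) == 2L)
  h <- image_dim[1L]; w <- image_dim[2L]
  on_half <- floor(2 * geom$dot_radius_px / sqrt(2)) %/% 2L
  out_half <- floor(geom$pitch_px / 2 * 2 / 3)
  in_half <- on_half + annulus_gap
  rois <- list()
  skipped <- 0L
  for (i in seq_len(nrow(centers))) {
    r0 <- round(centers$row[i]); c0 <- round(centers$col[i])
    if (r0 - out_half < 1 || r0 + out_half > h ||
        c0 - out_half < 1 || c0 + out_half > w) {
      skipped <- skipped + 1L
      next
    }
    on_rows <- (r0 - on_half):(r0 + on_half)
    on_cols <- (c0 - on_half):(c0 + on_half)
    out_rows <- (r0 - out_half):(r0 + out_half)
    out_cols <- (c0 - out_half):(c0 + out_half)
    grid_on <- expand.grid(row = on_rows, col = on_cols)
    grid_out <- expand.grid(row = out_rows, col = out_cols)
    in_inner <- abs(grid_out$row - r0) <= in_half &
      abs(grid_out$col - c0) <= in_half
    grid_off <- grid_out[!in_inner, ]
    on_idx <- grid_on$row + (grid_on$col - 1L) * h
    off_idx <- grid_off$row + (grid_off$col - 1L) * h
    if (!is.null(cell_mask) && !all(cell_mask[c(on_idx, off_idx)])) {
      skipped <- skipped + 1L
      next
    }
    rois[[length(rois) + 1L]] <- structure(
      list(dot = centers$dot[i], row = r0, col = c0,
           on_idx = as.integer(on_idx), off_idx = as.integer(off_idx),
           contrast = NA_real_),
      class = "dot_roi")
  }
  if (skipped > 0L) {
    message(sprintf("build_masks: skipped %d dot(s) too close to the boundary",
                    skipped))
  }
  rois
}

#' Pre-bleach dot contrast
#'
#' Contrast of a dot is `(F_ON - F_OFF) / F_ON`, computed from the
#' background-corrected mean intensities of the ON and OFF regions on
#' the pre-bleach image.
#'
#' @param f_on Mean background-corrected ON intensity, > 0.
#' @param f_off Mean background-corrected OFF intensity.
#' @return Dimensionless contrast.
#' @examples
#' dot_contrast(1.0, 0.5)  # 0.5
#' @export
dot_contrast <- function(f_on, f_off) {
  if (any(!is.finite(f_on)) || any(f_on <= 0)) {
    stop("F_ON must be finite and > 0", call. = FALSE)
  }
  (f_on - f_off) / f_on
}

#' Measure contrast of dot ROIs on the pre-bleach image
#'
#' Fills the `contrast` slot of each [build_masks()] ROI from the
#' background-corrected mean ON and OFF intensities of the pre-bleach
#' frame.
#'
#' @param rois List of `dot_roi` objects.
#' @param prebleach_image Numeric matrix.
#' @param background_idx Optional linear pixel indices of a dot-free
#'   background region; its mean is subtracted from both ROI means.
#' @return The ROI list with contrasts set.
#' @export
measure_contrast <- function(rois, prebleach_image, background_idx = NULL) {
  bg <- if (is.null(background_idx)) 0 else
    mean(prebleach_image[background_idx])
  lapply(rois, function(roi) {
    f_on <- mean(prebleach_image[roi$on_idx]) - bg
    f_off <- mean(prebleach_image[roi$off_idx]) - bg
    roi$contrast <- dot_contrast(f_on, f_off)
    roi
  })
}

#' Apply the minimum-contrast inclusion filter
#'
#' Only dots whose pre-bleach contrast reaches `min_contrast` are kept
#' for analysis (default 0.4).
#'
#' @param rois List of `dot_roi` objects with contrasts measured.
#' @param min_contrast Inclusion threshold.
#' @return The retained ROIs; a warning is issued if none survive.
#' @export
filter_dots <- function(rois, min_contrast = 0.4) {
  contrasts <- vapply(rois, function(r) r$contrast, numeric(1))
  if (anyNA(contrasts)) {
    stop("ROI contrasts not measured; run measure_contrast() first",
         call. = FALSE)
  }
  keep <- contrasts >= min_contrast
  message(sprintf("filter_dots: %d of %d dots retained (contrast >= %.2g)",
                  sum(keep), length(rois), min_contrast))
  if (!any(keep)) warning("all dots fall below the contrast threshold")
  rois[keep]
}
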