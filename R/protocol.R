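#' FRAP acquisition protocol
#'
#' Frame timing and bleach-pulse description shared by the simulator and
#' the analyzer. The default protocol takes one pre-bleach frame (5 ms
#' exposure), a 500 ms bleach pulse, and 50 post-bleach frames whose
#' time points are evenly spaced on a logarithmic scale starting 6 ms
#' after the end of the pulse. Post-bleach time is counted from the end
#' of the bleach pulse.
#'
#' The total post-bleach observation window defaults to 120 s, a
#' configurable choice on the tens-of-seconds scale where the slow
#' recovery components plateau.
#'
#' @param prebleach_exposure Pre-bleach exposure time, seconds.
#' @param bleach_duration Bleach pulse duration, seconds.
#' @param n_postbleach_frames Number of post-bleach frames.
#' @param first_postbleach_delay Time of the first post-bleach frame
#'   after the end of the pulse, seconds.
#' @param total_duration Time of the last post-bleach frame, seconds.
#' @return An object of class `acquisition_protocol`.
#' @seealso [make_timebase()]
#' @export
acquisition_protocol <- function(prebleach_exposure = 0.005,
                                 bleach_duration = 0.5,
                                 n_postbleach_frames = 50L,
                                 first_postbleach_delay = 0.006,
                                 total_duration = 120) {
  n_postbleach_frames <- as.integer(n_postbleach_frames)
  if (n_postbleach_frames < 2L) {
    stop("need at least 2 post-bleach frames", call. = FALSE)
  }
  if (first_postbleach_delay <= 0) {
    stop("first post-bleach delay must be > 0", call. = FALSE)
  }
  if (total_duration <= first_postbleach_delay) {
    stop("total_duration must exceed the first post-bleach delay",
         call. = FALSE)
  }
  structure(list(prebleach_exposure = prebleach_exposure,
                 bleach_duration = bleach_duration,
                 n_postbleach_frames = n_postbleach_frames,
                 first_postbleach_delay = first_postbleach_delay,
                 total_duration = total_duration),
            class = "acquisition_protocol")
}

#' Logarithmic post-bleach time base
#'
#' Computes the post-bleach frame times of a protocol: `n` points evenly
#' spaced on a logarithmic axis from the first post-bleach delay to the
#' total duration, i.e. a geometric progression. Times are in seconds
#' after the end of the bleach pulse.
#'
#' @param protocol An [acquisition_protocol()].
#' @return Strictly increasing numeric vector of length
#'   `n_postbleach_frames`, starting at `first_postbleach_delay`.
#' @examples
#' t <- make_timebase(acquisition_protocol())
#' head(t)  # starts at 0.006 s
#' @export
make_timebase <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  exp(seq(log(protocol$first_postbleach_delay),
          log(protocol$total_duration),
          length.out = protocol$n_postbleach_frames))
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf(
    "FRAP acquisition protocol: %d post-bleach frames, %.3g ms first delay, %.4g s total,\n  %.0f ms bleach pulse, %.1f ms pre-bleach exposure\n",
    x$n_postbleach_frames, 1000 * x$first_postbleach_delay,
    x$total_duration, 1000 * x$bleach_duration,
    1000 * x$prebleach_exposure))
  invisible(x)
}
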