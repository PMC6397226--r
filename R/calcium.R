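#' Classify a calcium trace as activated
#'
#' A cell counts as activated when its normalized Fura-2 ratio rises
#' strictly more than `threshold` above its value at time zero at any
#' point of the (optionally windowed) trace. Traces are expected
#' normalized to 1 at t = 0; classification is deterministic and
#' scale-invariant after normalization.
#'
#' @param ratio Normalized ratio trace (first element is t = 0).
#' @param threshold Activation threshold on the rise above baseline.
#' @param window Optional number of leading samples to consider (e.g.
#'   the first 300 s of a 1 Hz trace); default the full trace.
#' @return Logical flag.
#' @examples
#' classify_activation(c(1, 1.2, 1.5, 1.1))  # TRUE
#' classify_activation(c(1, 1.1, 1.4))       # FALSE: 1.4 does not exceed 1.4
#' @export
classify_activation <- function(ratio, threshold = 0.4, window = NULL) {
  if (length(ratio) == 0L) stop("empty trace", call. = FALSE)
  if (!is.null(window)) ratio <- ratio[seq_len(min(window, length(ratio)))]
  baseline <- ratio[1L]
  any(ratio - baseline > threshold)
}

#' Percentage of activated cells
#'
#' Applies [classify_activation()] to each trace of a cohort and
#' reports the percentage of activated cells.
#'
#' @param traces Data frame with columns `cell` and `ratio` (as from
#'   [simulate_calcium_traces()]), or a list of numeric traces.
#' @param threshold Activation threshold.
#' @param window Optional classification window (samples).
#' @return List with `percent`, `n_activated`, `n_cells` and the
#'   per-cell logical vector `activated`.
#' @export
percent_activated <- function(traces, threshold = 0.4, window = NULL) {
  if (is.data.frame(traces)) {
    traces <- lapply(split(traces$ratio,
                           factor(traces$cell, levels = unique(traces$cell))),
                     as.numeric)
  }
  if (length(traces) == 0L) stop("no traces supplied", call. = FALSE)
  flags <- vapply(traces, classify_activation, logical(1),
                  threshold = threshold, window = window)
  list(percent = 100 * mean(flags), n_activated = sum(flags),
       n_cells = length(flags), activated = unname(flags))
}
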