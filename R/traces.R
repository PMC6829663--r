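#' Whole-footprint fluorescence trace
#'
#' Container for a cell-footprint intensity time course: raw fluorescence,
#' a scalar or per-sample background, the stimulus window, and (after
#' \code{\link{normalize_trace}}) the F/F0 series normalised to the
#' pre-stimulatory level.
#'
#' @param time sample times, s.
#' @param raw raw intensities, AU.
#' @param background scalar or per-sample background, AU.
#' @param stimulus_window numeric (t_on, t_off), s; may be \code{NULL}.
#' @param F_over_F0 optional pre-computed normalised series.
#' @return object of class \code{granule_trace}.
#' @export
granule_trace <- function(time, raw, background = 0, stimulus_window = NULL,
                          F_over_F0 = NULL) {
  if (length(time) != length(raw))
    stop("time and raw must have equal length", call. = FALSE)
  if (!length(background) %in% c(1L, length(raw)))
    stop("background must be scalar or per-sample", call. = FALSE)
  structure(list(time = time, raw = raw, background = background,
                 stimulus_window = stimulus_window, F_over_F0 = F_over_F0),
            class = "granule_trace")
}

#' Background-correct and F/F0-normalise a trace
#'
#' Subtracts the background and divides by the mean corrected fluorescence
#' over the pre-stimulus baseline window, so the baseline of F/F0 is 1 by
#' construction. Normalising an already-normalised trace (background 0,
#' baseline 1) returns it unchanged.
#'
#' @param trace a \code{\link{granule_trace}}.
#' @param baseline_window numeric (t0, t1), s; defaults to everything
#'   before the stimulus onset.
#' @return the trace with \code{F_over_F0} filled in.
#' @export
normalize_trace <- function(trace, baseline_window = NULL) {
  if (is.null(baseline_window)) {
    if (is.null(trace$stimulus_window))
      stop("give baseline_window or set the stimulus window", call. = FALSE)
    baseline_window <- c(min(trace$time), trace$stimulus_window[1])
  }
  if (!is.null(trace$stimulus_window) &&
      baseline_window[2] > trace$stimulus_window[1])
    stop("baseline window must precede the stimulus", call. = FALSE)
  corr <- trace$raw - trace$background
  in_base <- trace$time >= baseline_window[1] & trace$time <= baseline_window[2]
  if (!any(in_base)) stop("empty baseline window", call. = FALSE)
  f0 <- mean(corr[in_base])
  if (f0 <= 0)
    stop("baseline mean <= 0 after background subtraction", call. = FALSE)
  trace$F_over_F0 <- corr / f0
  trace
}

#' Maximal stimulus response of a normalised trace
#'
#' Maximum of F/F0 - 1 within the stimulus window after a 3-point running
#' median, so single-sample spikes (individual fusion flashes, cosmic-ray
#' pixels) do not dominate the population statistic.
#'
#' @param trace a normalised \code{\link{granule_trace}} with a stimulus
#'   window.
#' @return dimensionless maximal increase over baseline.
#' @export
max_response <- function(trace) {
  if (is.null(trace$F_over_F0)) stop("normalise the trace first", call. = FALSE)
  if (is.null(trace$stimulus_window)) stop("stimulus window not set", call. = FALSE)
  sw <- trace$stimulus_window
  if (sw[1] > max(trace$time) || sw[2] < min(trace$time))
    stop("stimulus window outside trace", call. = FALSE)
  sm <- stats::runmed(trace$F_over_F0, k = 3)
  idx <- trace$time >= sw[1] & trace$time <= sw[2]
  max(sm[idx] - 1)
}

#' Post-stimulus reuptake kinetics
#'
#' Fits a single exponential to the post-stimulus decay of F/F0 and
#' reports the time constant and the fractional recovery at a horizon.
#'
#' @param trace a normalised \code{\link{granule_trace}} with a stimulus
#'   window.
#' @param horizon recovery horizon after stimulus end, s (default 60).
#' @return list(tau_s, fit, fractional_recovery, horizon_s).
#' @export
reuptake_rate <- function(trace, horizon = 60) {
  if (is.null(trace$F_over_F0)) stop("normalise the trace first", call. = FALSE)
  if (is.null(trace$stimulus_window)) stop("stimulus window not set", call. = FALSE)
  t_off <- trace$stimulus_window[2]
  idx <- trace$time >= t_off
  if (sum(idx) < 5L)
    stop("post-stimulus segment has fewer than 5 samples", call. = FALSE)
  y <- trace$F_over_F0[idx]
  tt <- trace$time[idx] - t_off
  fit <- fit_single_exponential(y, tt)   # refuses non-decreasing segments
  peak <- y[1]
  at_h <- fit$A * exp(-horizon / fit$tau) + fit$C
  frac <- if (peak - fit$C > 0) (peak - at_h) / (peak - fit$C) else NA_real_
  list(tau_s = fit$tau, fit = fit, fractional_recovery = frac,
       horizon_s = horizon)
}
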