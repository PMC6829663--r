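#' Detect exocytosis (fusion) events in granule tracks
#'
#' A fusion event is the characteristic abrupt loss of granule-marker
#' fluorescence: the background-corrected track intensity falls below
#' \code{drop_fraction} (default half) of its 5-frame pre-event mean within
#' at most \code{loss_max} frames, and stays lost — no recovery above the
#' threshold within the 5 following frames. Track intensity sequences are
#' extended past the last detection by sampling the movie at the final
#' position, so the post-loss level is measured even though the spot is no
#' longer detectable.
#'
#' @param tracks list of \code{granule_track}s carrying per-frame
#'   intensities.
#' @param movie optional H x W x T array the tracks came from; enables the
#'   post-track intensity sampling and per-frame median background
#'   correction. Without it, track intensities are taken as already
#'   background-corrected.
#' @param drop_fraction fraction of the pre-event mean defining loss.
#' @param loss_max maximum frames for the loss to complete (1 or 2).
#' @param pre_window,post_window frames for the pre/post means.
#' @param min_pre_frames minimum detected frames a track must have before
#'   the drop; guards against isolated spurious detections being scored as
#'   events.
#' @return data.frame(track_id, event_frame, time_s, pre_mean, post_mean,
#'   drop_frames), one row per event.
#' @export
detect_fusion_events <- function(tracks, movie = NULL, drop_fraction = 0.5,
                                 loss_max = 2, pre_window = 5,
                                 post_window = 5, min_pre_frames = 3) {
  n_frames <- if (!is.null(movie)) dim(movie)[3] else
    max(c(1L, vapply(tracks, function(tr) tr$end_frame, 0)))
  frame_bg <- if (!is.null(movie))
    vapply(seq_len(n_frames), function(t) stats::median(movie[, , t]), 0)
  else rep(0, n_frames)

  events <- lapply(tracks, function(tr) {
    if (is.null(tr$intensity)) stop("track has no intensity data", call. = FALSE)
    frames <- tr$frame
    n_det <- length(frames)
    ints <- tr$intensity - frame_bg[frames]
    if (!is.null(movie)) {
      ext <- (tr$end_frame + 1L):min(n_frames, tr$end_frame + post_window)
      if (tr$end_frame < n_frames && length(ext)) {
        h <- dim(movie)[1]; w <- dim(movie)[2]
        r0 <- round(tr$y[length(tr$y)]); c0 <- round(tr$x[length(tr$x)])
        rr <- max(1L, r0 - 1L):min(h, r0 + 1L)
        cc <- max(1L, c0 - 1L):min(w, c0 + 1L)
        samp <- vapply(ext, function(t) mean(movie[rr, cc, t]) - frame_bg[t], 0)
        frames <- c(frames, ext)
        ints <- c(ints, samp)
      }
    }
    n <- length(ints)
    for (i in 3:max(3, n)) {
      if (i > n) break
      if (min(i - 1L, n_det) < min_pre_frames) next   # too little track history
      # reference level from frames well before the candidate drop, and the
      # level immediately before it: an abrupt loss has both near full
      # intensity, a gradual decay has already sagged by the time it
      # crosses half.
      if (i >= 6L) {
        pre_idx <- max(1L, i - 3L - pre_window):(i - 4L)
        before_idx <- (i - 3L):(i - 1L)
      } else {
        pre_idx <- before_idx <- 1:(i - 1L)
      }
      pre <- mean(ints[pre_idx])
      if (!is.finite(pre) || pre <= 0) next
      if (ints[i] >= drop_fraction * pre) next          # not yet lost
      # abrupt loss: at least one of the frames immediately before the
      # drop must still sit near the reference level (max, not mean, so
      # isolated noise dips do not mimic a gradual decay)
      if (max(ints[before_idx]) < 0.8 * pre) next       # loss was gradual
      post_idx <- i:min(n, i + post_window)
      if (length(post_idx) < 3L) next                   # post window incomplete
      if (any(ints[post_idx] >= 0.75 * pre)) next       # reappearance
      post <- mean(ints[i:min(n, i + post_window - 1L)])
      if (post >= drop_fraction * pre) next             # residual signal
      # walk back to the first frame departing from full intensity
      j <- i
      while (j > i - loss_max + 1L && j > 1L && ints[j - 1L] < 0.75 * pre)
        j <- j - 1L
      return(data.frame(track_id = tr$id, event_frame = frames[j],
                        time_s = frames[j] * tr$frame_interval,
                        pre_mean = pre, post_mean = post,
                        drop_frames = i - j + 1L))
    }
    NULL
  })
  out <- do.call(rbind, events)
  if (is.null(out))
    out <- data.frame(track_id = integer(), event_frame = integer(),
                      time_s = numeric(), pre_mean = numeric(),
                      post_mean = numeric(), drop_frames = integer())
  rownames(out) <- NULL
  out
}

#' Cumulative exocytosis over time
#'
#' @param events fusion-event table with a \code{time_s} column (or a bare
#'   numeric vector of event times).
#' @param t_grid time points (s) at which to evaluate the count.
#' @return data.frame(time_s, cumulative): a non-decreasing step function
#'   whose final value is the total number of events.
#' @export
cumulative_exocytosis <- function(events, t_grid) {
  times <- if (is.data.frame(events)) events$time_s else as.numeric(events)
  data.frame(time_s = t_grid,
             cumulative = vapply(t_grid, function(t) sum(times <= t), 0))
}

#' Fit a single-exponential decay
#'
#' Least-squares fit of y(t) = A exp(-t / tau) + C, the standard model for
#' post-fusion fluorescence decay and reuptake kinetics. Starting values
#' come from a log-linear regression on the offset-subtracted data; the fit
#' is then refined by Levenberg-Marquardt nonlinear least squares.
#'
#' @param y numeric response, or a \code{\link{granule_trace}} (its
#'   \code{F_over_F0} if present, else raw).
#' @param time time points (s); defaults to 0, 1, 2, ... or the trace time.
#' @return list(A, tau, C, residual_rms, converged) of class
#'   \code{exp_fit}. Non-convergence of the refinement is flagged via
#'   \code{converged = FALSE} (the log-linear estimate is returned).
#' @export
fit_single_exponential <- function(y, time = NULL) {
  if (inherits(y, "granule_trace")) {
    if (is.null(time)) time <- y$time
    y <- if (!is.null(y$F_over_F0)) y$F_over_F0 else y$raw
  }
  if (is.null(time)) time <- seq_along(y) - 1
  ok <- is.finite(y) & is.finite(time)
  y <- y[ok]; time <- time[ok]
  if (length(y) < 5L)
    stop("need at least 5 samples to fit an exponential", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("constant trace: tau is unidentifiable", call. = FALSE)

  c0 <- min(y) - 0.05 * diff(range(y))
  ll <- stats::lm(log(y - c0) ~ time)
  slope <- stats::coef(ll)[2]
  if (slope >= 0)
    stop("trace has no decreasing trend; single-exponential decay fit refused",
         call. = FALSE)
  tau0 <- as.numeric(-1 / slope)
  a0 <- as.numeric(exp(stats::coef(ll)[1]))
  c0 <- as.numeric(c0)

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-time / tau) + C,
                      start = list(A = a0, tau = tau0, C = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    res <- y - (a0 * exp(-time / tau0) + c0)
    out <- list(A = unname(a0), tau = unname(tau0), C = unname(c0),
                residual_rms = sqrt(mean(res^2)), converged = FALSE)
  } else {
    p <- stats::coef(fit)
    out <- list(A = unname(p["A"]), tau = unname(p["tau"]),
                C = unname(p["C"]),
                residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                converged = TRUE)
  }
  if (out$tau <= 0) stop("fit produced non-positive tau", call. = FALSE)
  class(out) <- "exp_fit"
  out
}
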