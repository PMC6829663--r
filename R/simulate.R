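#' Simulation configuration for synthetic TIRF movies
#'
#' Bundles the optical and camera parameters of the synthetic movie
#' generator. Spots are rendered as 2-D Gaussians (the diffraction-limited
#' point-spread function), photon shot noise is Poisson, read noise is
#' additive Gaussian, and frames are quantized to 16 bits with a saturation
#' clamp, emulating an EMCCD detector.
#'
#' @param image_shape integer (H, W) in pixels.
#' @param n_frames number of frames.
#' @param frame_interval seconds between frames.
#' @param pixel_size nm per pixel (default 100).
#' @param psf_sigma PSF standard deviation in pixels (default 1.3).
#' @param background_level mean background in photons per pixel.
#' @param read_noise_sd Gaussian read noise sd in photons (0 disables).
#' @param spot_amplitude peak amplitude of a rendered spot in photons.
#'   Ignored when \code{snr} is given.
#' @param snr optional peak signal-to-noise ratio; when given,
#'   \code{spot_amplitude} is set to
#'   \code{snr * sqrt(background_level + read_noise_sd^2)}, the peak height
#'   in units of the per-pixel background noise sd.
#' @param shot_noise logical; \code{FALSE} renders noiseless expected-photon
#'   images (useful for geometric tests).
#' @param seed integer seed making the simulation bit-reproducible.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(image_shape = c(128L, 128L), n_frames = 100L,
                       frame_interval = 1, pixel_size = 100,
                       psf_sigma = 1.3, background_level = 100,
                       read_noise_sd = 0, spot_amplitude = 500,
                       snr = NULL, shot_noise = TRUE, seed = NULL) {
  if (length(image_shape) != 2L || any(image_shape < 8))
    stop("image_shape must be (H, W) with both >= 8", call. = FALSE)
  stopifnot_scalar_pos(n_frames, "n_frames")
  stopifnot_scalar_pos(frame_interval, "frame_interval")
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  stopifnot_scalar_pos(psf_sigma, "psf_sigma")
  stopifnot_scalar_pos(background_level, "background_level", strict = FALSE)
  stopifnot_scalar_pos(read_noise_sd, "read_noise_sd", strict = FALSE)
  if (!is.null(snr)) {
    stopifnot_scalar_pos(snr, "snr")
    spot_amplitude <- snr * sqrt(background_level + read_noise_sd^2)
  }
  stopifnot_scalar_pos(spot_amplitude, "spot_amplitude")
  if (spot_amplitude + background_level > 65535)
    stop("spot_amplitude + background_level exceeds the 16-bit range",
         call. = FALSE)
  structure(list(image_shape = as.integer(image_shape),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, pixel_size = pixel_size,
                 psf_sigma = psf_sigma, background_level = background_level,
                 read_noise_sd = read_noise_sd,
                 spot_amplitude = spot_amplitude,
                 shot_noise = isTRUE(shot_noise),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' Granule arrival and residence kinetics for the simulator
#'
#' Describes the generative counterpart of the dwell-time classification:
#' granules arrive in the evanescent field at \code{arrival_rate} per frame
#' and are long-lived ("docked") with probability \code{p_dock}, transient
#' visitors otherwise, or laterally mobile transits with probability
#' \code{p_transit}. Docked and visitor granules jitter around an anchor
#' with per-frame Gaussian displacements of sd \code{confinement_sd};
#' transit granules drift ballistically at \code{transit_speed}.
#'
#' @param arrival_rate mean arrivals per frame (Poisson), used when
#'   \code{n_arrivals} is \code{NULL}.
#' @param p_dock probability that an arriving granule is long-lived.
#' @param p_transit probability that an arrival is a mobile transit
#'   (default 0); visitors make up the remainder.
#' @param dock_residence residence-time sampler for docked granules:
#'   a function \code{function(n)} returning seconds, or a scalar constant.
#'   Default uniform on 45--120 s, comfortably beyond the 40 s survival
#'   horizon.
#' @param visitor_residence sampler for visitor residence, default uniform
#'   on 2--20 s (at or above the 2 s confinement minimum, below 25 s).
#' @param confinement_sd per-frame positional jitter of confined granules,
#'   pixels (default 0.3).
#' @param transit_speed lateral drift of transit granules, pixels/frame.
#' @param n_arrivals optional exact number of granule arrivals; when given,
#'   arrival frames are drawn uniformly over \code{arrival_window}.
#' @param arrival_window integer (first, last) frame for arrivals; defaults
#'   to the whole movie minus a tail long enough to observe 40 s survival.
#' @return an object of class \code{residence_model}.
#' @export
residence_model <- function(arrival_rate = 0.2, p_dock = 0.5,
                            p_transit = 0,
                            dock_residence = function(n) stats::runif(n, 45, 120),
                            visitor_residence = function(n) stats::runif(n, 2, 20),
                            confinement_sd = 0.3, transit_speed = 2,
                            n_arrivals = NULL, arrival_window = NULL) {
  if (p_dock < 0 || p_dock > 1) stop("p_dock must lie in [0, 1]", call. = FALSE)
  if (p_transit < 0 || p_dock + p_transit > 1)
    stop("p_dock + p_transit must lie in [0, 1]", call. = FALSE)
  as_sampler <- function(x, name) {
    if (is.function(x)) return(x)
    stopifnot_scalar_pos(x, name)
    function(n) rep(x, n)
  }
  structure(list(arrival_rate = arrival_rate, p_dock = p_dock,
                 p_transit = p_transit,
                 dock_residence = as_sampler(dock_residence, "dock_residence"),
                 visitor_residence = as_sampler(visitor_residence, "visitor_residence"),
                 confinement_sd = confinement_sd,
                 transit_speed = transit_speed,
                 n_arrivals = n_arrivals, arrival_window = arrival_window),
            class = "residence_model")
}

# Add one Gaussian spot to an expected-photon image, rendered on a local
# patch of radius 4*sigma (covers > 99.99% of the mass).
add_gaussian_spot <- function(img, x, y, amplitude, sigma) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sigma)
  rows <- max(1L, floor(y - r)):min(h, ceiling(y + r))
  cols <- max(1L, floor(x - r)):min(w, ceiling(x + r))
  if (!length(rows) || !length(cols)) return(img)
  gy <- exp(-(rows - y)^2 / (2 * sigma^2))
  gx <- exp(-(cols - x)^2 / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + amplitude * (gy %o% gx)
  img
}

# Poisson shot noise + Gaussian read noise + 16-bit quantization.
apply_camera_noise <- function(expected, shot_noise, read_noise_sd) {
  x <- if (shot_noise) {
    matrix(stats::rpois(length(expected), lambda = expected),
           nrow(expected), ncol(expected))
  } else expected
  if (read_noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(expected), 0, read_noise_sd),
                    nrow(expected), ncol(expected))
  x <- round(pmin(pmax(x, 0), 65535))
  storage.mode(x) <- "integer"
  x
}

new_ground_truth <- function(spots, trajectories, fusion_events = NULL,
                             structure_centers = NULL) {
  if (is.null(fusion_events))
    fusion_events <- data.frame(id = integer(), frame = integer())
  structure(list(spots = spots, trajectories = trajectories,
                 fusion_events = fusion_events,
                 structure_centers = structure_centers),
            class = "ground_truth")
}

# Sample per-granule trajectories; returns a data.frame of per-frame
# positions (id, frame, x, y, ramp) plus the spots summary table.
sample_granule_population <- function(cfg, res) {
  h <- cfg$image_shape[1]; w <- cfg$image_shape[2]
  margin <- ceiling(4 * cfg$psf_sigma) + 2
  win <- res$arrival_window
  if (is.null(win)) {
    tail_frames <- ceiling(45 / cfg$frame_interval)
    win <- c(2L, max(2L, cfg$n_frames - tail_frames))
  }
  if (!is.null(res$n_arrivals)) {
    arrivals <- sort(sample(win[1]:win[2], res$n_arrivals, replace = TRUE))
  } else {
    counts <- stats::rpois(cfg$n_frames, res$arrival_rate)
    counts[seq_len(cfg$n_frames) < win[1] | seq_len(cfg$n_frames) > win[2]] <- 0L
    arrivals <- rep(seq_len(cfg$n_frames), counts)
  }
  n <- length(arrivals)
  if (n == 0L)
    return(list(spots = data.frame(id = integer(), frame_start = integer(),
                                   frame_end = integer(), x0 = numeric(),
                                   y0 = numeric(), kind = character()),
                frames = data.frame(id = integer(), frame = integer(),
                                    x = numeric(), y = numeric(),
                                    ramp = numeric())))
  kind <- sample(c("docked", "visitor", "transit"), n, replace = TRUE,
                 prob = c(res$p_dock, 1 - res$p_dock - res$p_transit,
                          res$p_transit))
  residence <- numeric(n)
  residence[kind == "docked"] <- res$dock_residence(sum(kind == "docked"))
  residence[kind != "docked"] <- res$visitor_residence(sum(kind != "docked"))
  n_res <- pmax(1L, round(residence / cfg$frame_interval))
  x0 <- stats::runif(n, margin, w - margin)
  y0 <- stats::runif(n, margin, h - margin)

  per_frame <- vector("list", n)
  frame_end <- integer(n)
  for (i in seq_len(n)) {
    len <- min(n_res[i], cfg$n_frames - arrivals[i] + 1L)
    frames <- arrivals[i] + seq_len(len) - 1L
    if (kind[i] == "transit") {
      theta <- stats::runif(1, 0, 2 * pi)
      x <- x0[i] + res$transit_speed * cos(theta) * (seq_len(len) - 1)
      y <- y0[i] + res$transit_speed * sin(theta) * (seq_len(len) - 1)
      inside <- x >= 1 & x <= w & y >= 1 & y <= h
      keep <- if (all(inside)) len else max(1L, which(!inside)[1] - 1L)
      x <- x[seq_len(keep)]; y <- y[seq_len(keep)]; frames <- frames[seq_len(keep)]
      len <- keep
    } else {
      x <- x0[i] + stats::rnorm(len, 0, res$confinement_sd)
      y <- y0[i] + stats::rnorm(len, 0, res$confinement_sd)
    }
    ramp <- rep(1, len)
    ramp[1] <- 0.5                      # axial approach: 2-frame intensity ramp
    frame_end[i] <- frames[len]
    per_frame[[i]] <- data.frame(id = i, frame = frames, x = x, y = y,
                                 ramp = ramp)
  }
  spots <- data.frame(id = seq_len(n), frame_start = arrivals,
                      frame_end = frame_end, x0 = x0, y0 = y0, kind = kind,
                      residence_s = residence)
  list(spots = spots, frames = do.call(rbind, per_frame))
}

render_movie <- function(cfg, frames_df, amplitude_col = "ramp") {
  h <- cfg$image_shape[1]; w <- cfg$image_shape[2]
  movie <- array(0L, dim = c(h, w, cfg$n_frames))
  split_f <- if (nrow(frames_df)) split(frames_df, frames_df$frame) else list()
  for (t in seq_len(cfg$n_frames)) {
    img <- matrix(cfg$background_level, h, w)
    fd <- split_f[[as.character(t)]]
    if (!is.null(fd)) {
      for (i in seq_len(nrow(fd))) {
        img <- add_gaussian_spot(img, fd$x[i], fd$y[i],
                                 cfg$spot_amplitude * fd[[amplitude_col]][i],
                                 cfg$psf_sigma)
      }
    }
    movie[, , t] <- apply_camera_noise(img, cfg$shot_noise, cfg$read_noise_sd)
  }
  movie
}

#' Simulate a TIRF granule movie with ground truth
#'
#' Generates a time-lapse of diffraction-limited granule spots with the
#' arrival/residence kinetics of \code{res} atop a noisy background, and
#' records every injected granule (trajectory, residence, kind) for oracle
#' comparison with the detection/tracking/classification pipeline.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param res a \code{\link{residence_model}}.
#' @return list with elements \code{movie} (integer H x W x T array) and
#'   \code{ground_truth} (class \code{ground_truth}).
#' @export
simulate_movie <- function(cfg, res) {
  stopifnot(inherits(cfg, "sim_config"), inherits(res, "residence_model"))
  with_seed(cfg$seed, {
    pop <- sample_granule_population(cfg, res)
    movie <- render_movie(cfg, pop$frames)
    traj <- if (nrow(pop$frames)) split(pop$frames[c("frame", "x", "y")],
                                        pop$frames$id) else list()
    list(movie = movie,
         ground_truth = new_ground_truth(pop$spots, traj))
  })
}

#' Simulate a movie of granule fusion (exocytosis) events
#'
#' Places \code{n_events} docked granules on a well-separated grid; each
#' granule's fluorescence is lost abruptly at its fusion frame, the loss
#' completing within \code{loss_frames} frames with no reappearance,
#' emulating the characteristic signature of full fusion.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param n_events number of fusion events to inject.
#' @param loss_frames frames over which the loss completes (1 or 2).
#' @param min_separation minimum spacing between granules, pixels.
#' @return list(movie, ground_truth); \code{ground_truth$fusion_events} has
#'   exactly \code{n_events} rows (id, frame).
#' @export
simulate_fusion_movie <- function(cfg, n_events, loss_frames = 2,
                                  min_separation = 9) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_events < 0) stop("n_events must be >= 0", call. = FALSE)
  if (!loss_frames %in% c(1, 2))
    stop("loss_frames must be 1 or 2", call. = FALSE)
  h <- cfg$image_shape[1]; w <- cfg$image_shape[2]
  margin <- ceiling(4 * cfg$psf_sigma) + 2
  gx <- seq(margin, w - margin, by = min_separation)
  gy <- seq(margin, h - margin, by = min_separation)
  if (n_events > length(gx) * length(gy))
    stop(sprintf("n_events = %d exceeds the %d placeable granules",
                 n_events, length(gx) * length(gy)), call. = FALSE)
  pre_min <- 10L; post_min <- 8L
  if (cfg$n_frames < pre_min + post_min + 2L)
    stop("n_frames too small to embed fusion events", call. = FALSE)

  with_seed(cfg$seed, {
    if (n_events == 0L) {
      movie <- render_movie(cfg, data.frame(id = integer(), frame = integer(),
                                            x = numeric(), y = numeric(),
                                            ramp = numeric()))
      return(list(movie = movie,
                  ground_truth = new_ground_truth(
                    data.frame(id = integer(), frame_start = integer(),
                               frame_end = integer(), x0 = numeric(),
                               y0 = numeric(), kind = character()),
                    list())))
    }
    sites <- expand.grid(x = gx, y = gy)
    sites <- sites[sample.int(nrow(sites), n_events), , drop = FALSE]
    # jitter sites off the grid so geometry is not degenerate
    sites$x <- sites$x + stats::runif(n_events, -1, 1)
    sites$y <- sites$y + stats::runif(n_events, -1, 1)
    fstart <- sample(2:4, n_events, replace = TRUE)
    fuse_at <- sample((pre_min + 4L):(cfg$n_frames - post_min),
                      n_events, replace = TRUE)

    rows <- vector("list", n_events)
    for (i in seq_len(n_events)) {
      frames <- fstart[i]:(fuse_at[i] + loss_frames - 1L)
      len <- length(frames)
      ramp <- rep(1, len)
      ramp[1] <- 0.5
      if (loss_frames == 2L) ramp[len] <- 0.4  # intermediate frame of the loss
      x <- sites$x[i] + stats::rnorm(len, 0, 0.3)
      y <- sites$y[i] + stats::rnorm(len, 0, 0.3)
      rows[[i]] <- data.frame(id = i, frame = frames, x = x, y = y,
                              ramp = ramp)
    }
    frames_df <- do.call(rbind, rows)
    movie <- render_movie(cfg, frames_df)
    spots <- data.frame(id = seq_len(n_events), frame_start = fstart,
                        frame_end = fuse_at + loss_frames - 1L,
                        x0 = sites$x, y0 = sites$y, kind = "docked")
    traj <- split(frames_df[c("frame", "x", "y")], frames_df$id)
    list(movie = movie,
         ground_truth = new_ground_truth(
           spots, traj,
           fusion_events = data.frame(id = seq_len(n_events),
                                      frame = fuse_at + 1L)))
  })
}

#' Simulate a static field of well-separated spots
#'
#' Renders \code{n_spots} stationary diffraction-limited spots at uniform
#' random positions with a minimum pairwise separation (dart-throwing
#' placement), one rendered image per frame. Used for granule-density and
#' structure-count measurements where arrival kinetics are irrelevant.
#'
#' @param cfg a \code{\link{sim_config}} (its \code{n_frames} images are
#'   rendered; use 1 for a single field).
#' @param n_spots number of spots to place.
#' @param min_separation minimum pairwise distance, pixels.
#' @param max_tries placement attempts before giving up.
#' @return list(movie, ground_truth) as in \code{\link{simulate_movie}}.
#' @export
simulate_spot_field <- function(cfg, n_spots, min_separation = 6,
                                max_tries = 200 * n_spots + 1000) {
  stopifnot(inherits(cfg, "sim_config"))
  h <- cfg$image_shape[1]; w <- cfg$image_shape[2]
  margin <- ceiling(4 * cfg$psf_sigma) + 2
  with_seed(cfg$seed, {
    xs <- numeric(0); ys <- numeric(0); tries <- 0
    while (length(xs) < n_spots && tries < max_tries) {
      tries <- tries + 1
      x <- stats::runif(1, margin, w - margin)
      y <- stats::runif(1, margin, h - margin)
      if (!length(xs) ||
          min((xs - x)^2 + (ys - y)^2) >= min_separation^2) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    if (length(xs) < n_spots)
      stop("could not place the requested spots at this separation",
           call. = FALSE)
    frames_df <- data.frame(
      id = rep(seq_len(n_spots), cfg$n_frames),
      frame = rep(seq_len(cfg$n_frames), each = n_spots),
      x = rep(xs, cfg$n_frames), y = rep(ys, cfg$n_frames), ramp = 1)
    movie <- render_movie(cfg, frames_df)
    spots <- data.frame(id = seq_len(n_spots), frame_start = 1L,
                        frame_end = cfg$n_frames, x0 = xs, y0 = ys,
                        kind = "docked")
    list(movie = movie,
         ground_truth = new_ground_truth(
           spots, split(frames_df[c("frame", "x", "y")], frames_df$id)))
  })
}

#' Simulate two-channel structure-centred crops
#'
#' Generates \code{n_structures} 30 x 30 pixel crop pairs, each centred on a
#' granule-marker structure (channel 1, narrow Gaussian). Channel 2 carries
#' a probe whose above-baseline signal is split between a narrow
#' granule-bound component (fraction \code{bound_fraction}, same width as
#' the marker) and a wide unbound component (sd \code{wide_bg_sigma}),
#' so the colocalization enrichment of the probe is tunable.
#'
#' @param n_structures number of crops (the analysis expects >= 15).
#' @param granule_amplitude peak photons of the channel-1 marker.
#' @param bound_fraction fraction of the probe's above-baseline signal in
#'   the granule-bound component, in [0, 1].
#' @param wide_bg_sigma sd of the wide (unbound) probe component, pixels.
#' @param seed integer seed.
#' @param probe_signal total above-baseline probe photons (integral over
#'   the crop); defaults to the marker's integrated signal.
#' @param baseline photon baseline added to both channels.
#' @param psf_sigma narrow-component sd, pixels.
#' @param shot_noise,read_noise_sd noise model as in \code{\link{sim_config}}.
#' @param crop_size crop side, pixels (the standard analysis uses 30).
#' @return list(channel1, channel2, ground_truth): channels are
#'   crop_size x crop_size x n_structures arrays.
#' @export
simulate_crop_pair <- function(n_structures, granule_amplitude = 400,
                               bound_fraction = 0.5, wide_bg_sigma = 6,
                               seed = NULL, probe_signal = NULL,
                               baseline = 20, psf_sigma = 1.3,
                               shot_noise = TRUE, read_noise_sd = 0,
                               crop_size = 30L) {
  if (bound_fraction < 0 || bound_fraction > 1)
    stop("bound_fraction must lie in [0, 1]", call. = FALSE)
  stopifnot_scalar_pos(n_structures, "n_structures")
  if (is.null(probe_signal))
    probe_signal <- granule_amplitude * 2 * pi * psf_sigma^2
  ctr <- (crop_size + 1) / 2
  narrow_amp <- function(sig) 1 / (2 * pi * sig^2)   # unit-integral Gaussian peak
  with_seed(seed, {
    ch1 <- array(0L, dim = c(crop_size, crop_size, n_structures))
    ch2 <- array(0L, dim = c(crop_size, crop_size, n_structures))
    for (i in seq_len(n_structures)) {
      base1 <- matrix(baseline, crop_size, crop_size)
      base1 <- add_gaussian_spot(base1, ctr, ctr, granule_amplitude, psf_sigma)
      base2 <- matrix(baseline, crop_size, crop_size)
      if (bound_fraction > 0)
        base2 <- add_gaussian_spot(base2, ctr, ctr,
                                   bound_fraction * probe_signal *
                                     narrow_amp(psf_sigma), psf_sigma)
      if (bound_fraction < 1)
        base2 <- add_gaussian_spot(base2, ctr, ctr,
                                   (1 - bound_fraction) * probe_signal *
                                     narrow_amp(wide_bg_sigma), wide_bg_sigma)
      ch1[, , i] <- apply_camera_noise(base1, shot_noise, read_noise_sd)
      ch2[, , i] <- apply_camera_noise(base2, shot_noise, read_noise_sd)
    }
    centers <- data.frame(x = rep(ctr, n_structures),
                          y = rep(ctr, n_structures))
    list(channel1 = ch1, channel2 = ch2,
         ground_truth = new_ground_truth(
           data.frame(id = integer(), frame_start = integer(),
                      frame_end = integer(), x0 = numeric(), y0 = numeric(),
                      kind = character()),
           list(), structure_centers = centers))
  })
}

#' Simulate a stimulus-locked whole-footprint fluorescence trace
#'
#' Emulates a pH-sensitive reporter footprint response: flat baseline, a
#' saturating rise after stimulus onset, and a single-exponential decay
#' (reuptake) after stimulus end.
#'
#' @param baseline pre-stimulus fluorescence, AU (> 0).
#' @param step_time stimulus onset, s.
#' @param step_amplitude asymptotic rise above baseline, AU.
#' @param plateau_time stimulus duration, s.
#' @param decay_tau reuptake time constant, s.
#' @param noise_sd additive Gaussian noise sd, AU.
#' @param seed integer seed.
#' @param rise_tau time constant of the rise, s (default 2).
#' @param dt sampling interval, s.
#' @param total_time trace duration, s; defaults to
#'   \code{step_time + plateau_time + 5 * decay_tau}.
#' @return a \code{\link{granule_trace}} with the stimulus window set.
#' @export
simulate_footprint_trace <- function(baseline, step_time, step_amplitude,
                                     plateau_time, decay_tau, noise_sd = 0,
                                     seed = NULL, rise_tau = 2, dt = 0.5,
                                     total_time = NULL) {
  stopifnot_scalar_pos(baseline, "baseline")
  if (decay_tau <= 0) stop("decay_tau must be positive", call. = FALSE)
  if (is.null(total_time))
    total_time <- step_time + plateau_time + 5 * decay_tau
  tt <- seq(0, total_time, by = dt)
  t_off <- step_time + plateau_time
  f <- rep(baseline, length(tt))
  during <- tt >= step_time & tt < t_off
  f[during] <- baseline +
    step_amplitude * (1 - exp(-(tt[during] - step_time) / rise_tau))
  amp_off <- step_amplitude * (1 - exp(-plateau_time / rise_tau))
  after <- tt >= t_off
  f[after] <- baseline + amp_off * exp(-(tt[after] - t_off) / decay_tau)
  with_seed(seed, {
    if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
    granule_trace(time = tt, raw = f, background = 0,
                  stimulus_window = c(step_time, t_off))
  })
}
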