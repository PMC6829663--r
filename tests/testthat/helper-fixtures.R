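# Shared fixtures: all synthetic, built in code at test time.

# A bare track object without going through detection/linking.
make_track <- function(intensity, x = NULL, y = NULL, id = 1L,
                       start_frame = 1L, frame_interval = 1) {
  n <- length(intensity)
  if (is.null(x)) x <- rep(10, n)
  if (is.null(y)) y <- rep(10, n)
  frames <- start_frame + seq_len(n) - 1L
  structure(list(id = id, frame = frames, x = x, y = y,
                 intensity = intensity, start_frame = frames[1],
                 end_frame = frames[n], frame_interval = frame_interval),
            class = "granule_track")
}

# A line_profile object from raw samples.
make_profile <- function(samples) {
  structure(list(samples = samples, N_All = length(samples),
                 min = min(samples)), class = "line_profile")
}

# Noiseless frame with Gaussian spots at given centres.
render_test_frame <- function(centres, amplitude = 100, background = 10,
                              sigma = 1.3, shape = c(31, 31)) {
  img <- matrix(background, shape[1], shape[2])
  for (i in seq_len(nrow(centres)))
    img <- tirfgranule:::add_gaussian_spot(img, centres[i, 1], centres[i, 2],
                                           amplitude, sigma)
  img
}
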