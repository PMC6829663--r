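test_that("isolated noiseless Gaussian spots are each detected once, at the centre", {
  one <- render_test_frame(cbind(15, 15))
  d <- detect_maxima(one, detection_params(prominence = 10))
  expect_equal(nrow(d), 1L)
  expect_equal(d$x, 15, tolerance = 0.05)
  expect_equal(d$y, 15, tolerance = 0.05)

  two <- render_test_frame(cbind(c(10, 20), c(10, 20)))  # 10 sqrt(2) px apart
  d2 <- detect_maxima(two, detection_params(prominence = 10))
  expect_equal(nrow(d2), 2L)
})

test_that("detection on a dense rendered field has perfect recall and precision", {
  cfg <- sim_config(image_shape = c(160, 160), n_frames = 1, snr = 10,
                    background_level = 100, seed = 21)
  sim <- simulate_spot_field(cfg, 40, min_separation = 6)
  d <- detect_maxima(sim$movie[, , 1])
  gt <- sim$ground_truth$spots
  # match detections to ground truth within 2 px
  hit <- vapply(seq_len(nrow(gt)), function(i)
    any((d$x - gt$x0[i])^2 + (d$y - gt$y0[i])^2 <= 4), TRUE)
  expect_equal(nrow(d), 40L)       # precision 1
  expect_true(all(hit))            # recall 1
})

test_that("detection is invariant to affine intensity rescaling", {
  frame <- render_test_frame(cbind(c(8, 22, 14), c(9, 18, 25)),
                             amplitude = 80, background = 30)
  a <- detect_maxima(frame, detection_params(prominence = 8))
  b <- detect_maxima(frame * 3.5 + 12, detection_params(prominence = 8 * 3.5))
  expect_equal(sort(a$x), sort(b$x))
  expect_equal(sort(a$y), sort(b$y))
  expect_equal(nrow(a), 3L)
})

test_that("granule density is count over footprint area", {
  spots <- data.frame(x = runif(50), y = runif(50))
  expect_equal(granule_density(spots, footprint_area = 625), 0.08)
  expect_equal(granule_density(spots[0, ], footprint_area = 625), 0)
  # area from a mask: 2500 px at 100 nm/px = 25 um^2
  mask <- matrix(FALSE, 100, 100); mask[1:50, 1:50] <- TRUE
  expect_equal(granule_density(spots, mask = mask, pixel_size = 100), 2)
  expect_error(granule_density(spots, footprint_area = 0), "area")
})

test_that("fields rendered at halved density measure half the density", {
  dens <- function(n, s) {
    cfg <- sim_config(image_shape = c(200, 200), n_frames = 1, snr = 10,
                      background_level = 100, seed = s)
    sim <- simulate_spot_field(cfg, n, min_separation = 6)
    nrow(detect_maxima(sim$movie[, , 1])) / (200 * 200 * 0.01)
  }
  hi <- vapply(31:33, function(s) dens(60, s), 0)
  lo <- vapply(34:36, function(s) dens(30, s), 0)
  expect_equal(mean(lo) / mean(hi), 0.5, tolerance = 0.05 / 0.5)
})

test_that("frames with no spots and bad inputs are handled", {
  cfg <- sim_config(image_shape = c(64, 64), n_frames = 3,
                    background_level = 100, seed = 12)
  sim <- simulate_movie(cfg, residence_model(arrival_rate = 0))
  expect_equal(nrow(detect_movie(sim$movie)), 0L)
  expect_error(detect_maxima(matrix(c(1, NA, 2, 3), 2)), "non-finite")
  expect_error(detect_maxima(matrix(1, 5, 5), mask = matrix(TRUE, 4, 4)),
               "shape")
})

test_that("masks restrict detections to the footprint", {
  frame <- render_test_frame(cbind(c(8, 24), c(8, 24)))
  mask <- matrix(FALSE, 31, 31); mask[1:15, 1:15] <- TRUE
  d <- detect_maxima(frame, detection_params(prominence = 10), mask = mask)
  expect_equal(nrow(d), 1L)
  expect_lt(d$x, 15)
})
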