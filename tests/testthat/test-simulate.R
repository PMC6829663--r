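test_that("noiseless rendering puts the brightest pixel at the injected centre", {
  cfg <- sim_config(image_shape = c(41, 41), n_frames = 1, shot_noise = FALSE,
                    background_level = 10, spot_amplitude = 200, seed = 3)
  sim <- simulate_spot_field(cfg, 1)
  gt <- sim$ground_truth$spots
  peak <- which(sim$movie[, , 1] == max(sim$movie[, , 1]), arr.ind = TRUE)
  expect_equal(nrow(gt), 1L)
  expect_equal(peak[1, "row"], round(gt$y0), ignore_attr = TRUE)
  expect_equal(peak[1, "col"], round(gt$x0), ignore_attr = TRUE)
})

test_that("degenerate residence mixtures produce a single granule kind", {
  cfg <- sim_config(image_shape = c(64, 64), n_frames = 60, seed = 4)
  res <- residence_model(n_arrivals = 12, p_dock = 1, dock_residence = 120)
  sim <- simulate_movie(cfg, res)
  expect_true(all(sim$ground_truth$spots$kind == "docked"))
  res0 <- residence_model(n_arrivals = 12, p_dock = 0)
  sim0 <- simulate_movie(cfg, res0)
  expect_true(all(sim0$ground_truth$spots$kind == "visitor"))
})

test_that("fixed seed gives bit-identical movies, crops and traces", {
  cfg <- sim_config(image_shape = c(48, 48), n_frames = 20, seed = 7)
  res <- residence_model(n_arrivals = 8)
  a <- simulate_movie(cfg, res)
  b <- simulate_movie(cfg, res)
  expect_identical(a$movie, b$movie)
  expect_identical(a$ground_truth$spots, b$ground_truth$spots)

  ca <- simulate_crop_pair(20, bound_fraction = 0.4, seed = 9)
  cb <- simulate_crop_pair(20, bound_fraction = 0.4, seed = 9)
  expect_identical(ca$channel1, cb$channel1)
  expect_identical(ca$channel2, cb$channel2)
  expect_equal(dim(ca$channel1)[3], 20L)

  ta <- simulate_footprint_trace(100, 10, 50, 30, 15, noise_sd = 3, seed = 2)
  tb <- simulate_footprint_trace(100, 10, 50, 30, 15, noise_sd = 3, seed = 2)
  expect_identical(ta$raw, tb$raw)
})

test_that("noiseless spot mass matches the Gaussian PSF integral", {
  sigma <- 1.3
  cfg <- sim_config(image_shape = c(41, 41), n_frames = 1, shot_noise = FALSE,
                    background_level = 0, spot_amplitude = 1000, seed = 1)
  sim <- simulate_spot_field(cfg, 1)
  img <- sim$movie[, , 1] * 1.0
  # 99% PSF support: disc of radius 3.03 sigma
  gt <- sim$ground_truth$spots
  rr <- row(img) - gt$y0; cc <- col(img) - gt$x0
  support <- (rr^2 + cc^2) <= (3.03 * sigma)^2
  expect_equal(mean(img[support]),
               0.99 * 1000 * 2 * pi * sigma^2 / sum(support),
               tolerance = 0.02)
})

test_that("Poisson shot noise has variance equal to the mean", {
  cfg <- sim_config(image_shape = c(16, 16), n_frames = 1000,
                    background_level = 100, seed = 5)
  sim <- simulate_movie(cfg, residence_model(arrival_rate = 0))
  m <- apply(sim$movie, c(1, 2), mean)
  v <- apply(sim$movie, c(1, 2), stats::var)
  expect_equal(mean(v / m), 1, tolerance = 0.05)
})

test_that("fusion simulation records exactly the requested events with abrupt loss", {
  cfg <- sim_config(image_shape = c(64, 64), n_frames = 40, snr = 5,
                    background_level = 100, seed = 6)
  sim0 <- simulate_fusion_movie(cfg, 0)
  expect_equal(nrow(sim0$ground_truth$fusion_events), 0L)

  cfg2 <- sim_config(image_shape = c(150, 150), n_frames = 40, snr = 5,
                     background_level = 100, seed = 8)
  sim <- simulate_fusion_movie(cfg2, 12, loss_frames = 2)
  gt <- sim$ground_truth
  expect_equal(nrow(gt$fusion_events), 12L)
  # pre-event intensity >> post-event intensity at every injected site
  for (i in seq_len(12)) {
    r <- round(gt$spots$y0[i]); c <- round(gt$spots$x0[i])
    f <- gt$fusion_events$frame[i]
    pre <- mean(sim$movie[r, c, (f - 5):(f - 1)]) - 100
    post <- mean(sim$movie[r, c, (f + 2):(f + 5)]) - 100
    expect_gt(pre, 3 * max(post, 1))
  }
})

test_that("one-frame loss completes between consecutive frames", {
  cfg <- sim_config(image_shape = c(64, 64), n_frames = 30, shot_noise = FALSE,
                    background_level = 10, spot_amplitude = 100, seed = 9)
  sim <- simulate_fusion_movie(cfg, 2, loss_frames = 1)
  gt <- sim$ground_truth
  for (i in 1:2) {
    r <- round(gt$spots$y0[i]); c <- round(gt$spots$x0[i])
    f <- gt$fusion_events$frame[i]      # first frame with the spot gone
    expect_gt(sim$movie[r, c, f - 1], 50)
    expect_lt(sim$movie[r, c, f], 20)
  }
})

test_that("footprint traces follow the step-plateau-decay model", {
  flat <- simulate_footprint_trace(100, 10, 0, 30, 15, noise_sd = 0)
  expect_true(all(flat$raw == 100))

  # decay_tau chosen so the half-life (tau ln 2) is exactly 10 s, on-grid
  tau <- 10 / log(2)
  tr <- simulate_footprint_trace(100, 10, 80, 120, tau, noise_sd = 0,
                                 rise_tau = 2)
  t_off <- tr$stimulus_window[2]
  at_end <- tr$raw[which.min(abs(tr$time - (t_off - 0.5)))]
  expect_equal(at_end, 180, tolerance = 0.01)
  # exponential identity: halves every tau * ln 2 after stimulus end
  v1 <- tr$raw[which(tr$time == t_off + 10)] - 100
  v2 <- tr$raw[which(tr$time == t_off + 20)] - 100
  expect_equal(v1 / v2, 2, tolerance = 1e-6)
})

test_that("crop pairs split the probe between bound and unbound components", {
  ctr <- 15.5
  # bound_fraction 0: channel2 is exactly baseline + the wide component
  cr0 <- simulate_crop_pair(16, bound_fraction = 0, wide_bg_sigma = 6,
                            shot_noise = FALSE, seed = 1)
  p0 <- make_average_projection(cr0$channel2)
  s_total <- 400 * 2 * pi * 1.3^2           # default probe_signal
  rr <- (row(p0) - ctr)^2 + (col(p0) - ctr)^2
  wide_only <- 20 + s_total / (2 * pi * 36) * exp(-rr / (2 * 36))
  expect_lt(max(abs(p0 - wide_only)), 0.6)  # rounding only, no narrow part
  # bound_fraction 1: channel2 is a scaled channel1 plus baseline
  cr1 <- simulate_crop_pair(16, bound_fraction = 1, shot_noise = FALSE,
                            seed = 2)
  p1 <- make_average_projection(cr1$channel1) - 20
  p2 <- make_average_projection(cr1$channel2) - 20
  ratio <- p2[p1 > 1] / p1[p1 > 1]
  expect_lt(diff(range(ratio)), 0.02 * mean(ratio))
})
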