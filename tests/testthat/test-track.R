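test_that("stationary spots link into single unbroken tracks", {
  spots <- do.call(rbind, lapply(1:30, function(f)
    data.frame(frame = f, x = 10, y = 10, peak_intensity = 100)))
  tr <- link_tracks(spots, docking_params(), frame_interval = 1)
  expect_length(tr, 1L)
  expect_length(tr[[1]]$frame, 30L)

  spots2 <- do.call(rbind, lapply(1:30, function(f)
    data.frame(frame = f, x = c(10, 30), y = c(10, 10),
               peak_intensity = 100)))
  tr2 <- link_tracks(spots2, docking_params(), frame_interval = 1)
  expect_length(tr2, 2L)
  expect_true(all(vapply(tr2, function(t) length(t$frame), 0L) == 30))
  expect_lt(max(vapply(tr2, max_excursion, 0)), 1e-9)
})

test_that("tracking a simulated movie recovers every granule's frame range", {
  cfg <- sim_config(image_shape = c(200, 200), n_frames = 80, snr = 10,
                    background_level = 100, seed = 1)
  res <- residence_model(n_arrivals = 20, p_dock = 0.5,
                         arrival_window = c(2, 40))
  sim <- simulate_movie(cfg, res)
  tracks <- link_tracks(detect_movie(sim$movie), docking_params(),
                        frame_interval = 1)
  gt <- sim$ground_truth$spots
  expect_equal(length(tracks), nrow(gt))
  # match each track to its granule by position and compare frame ranges
  for (t in tracks) {
    mx <- stats::median(t$x); my <- stats::median(t$y)
    j <- which.min((gt$x0 - mx)^2 + (gt$y0 - my)^2)
    expect_lte(abs(t$start_frame - gt$frame_start[j]), 1)
    expect_lte(abs(t$end_frame - gt$frame_end[j]), 1)
  }
})

test_that("dwell time and confinement partition tracks into docked/visitor/transit", {
  set.seed(1)
  p <- docking_params()
  confined_long <- make_track(rep(100, 30), x = rnorm(30, 10, 0.1),
                              y = rnorm(30, 10, 0.1), start_frame = 5L)
  confined_short <- make_track(rep(100, 10), x = rnorm(10, 10, 0.1),
                               y = rnorm(10, 10, 0.1), start_frame = 5L)
  mobile <- make_track(rep(100, 30), x = 10 + (1:30) * 0.5, y = rep(10, 30),
                       start_frame = 5L)
  expect_equal(classify_docking(confined_long, p)$class, "docked")
  expect_equal(classify_docking(confined_short, p)$class, "visitor")
  expect_equal(classify_docking(mobile, p)$class, "transit")
  # exact tie at t_dock classifies as docked
  tie <- make_track(rep(100, 25), x = rep(10, 25), y = rep(10, 25))
  expect_equal(classify_docking(tie, p)$class, "docked")
  # sub-t_min confined contact is not an approach event
  blip <- make_track(rep(100, 1))
  expect_equal(classify_docking(blip, p)$class, "transit")
})

test_that("docking fraction has the right degenerate limits", {
  p <- docking_params()
  long_tracks <- lapply(1:5, function(i)
    make_track(rep(100, 70), x = rep(i * 5, 70), y = rep(10, 70),
               id = i, start_frame = 3L))
  ev <- classify_all(long_tracks, p)
  fr <- docking_fraction(ev, long_tracks, p)
  expect_equal(fr$fraction, 1)

  short_tracks <- lapply(1:5, function(i)
    make_track(rep(100, 10), x = rep(i * 5, 10), y = rep(10, 10),
               id = i, start_frame = 3L))
  ev2 <- classify_all(short_tracks, p)
  fr2 <- docking_fraction(ev2, short_tracks, p)
  expect_equal(fr2$fraction, 0)
  expect_equal(fr2$n_approach, 5L)
  # pre-existing tracks (start at frame 1) are not approaches
  pre <- lapply(1:3, function(i)
    make_track(rep(100, 70), x = rep(i * 5, 70), y = rep(10, 70), id = i))
  fr3 <- suppressWarnings(docking_fraction(classify_all(pre, p), pre, p))
  expect_equal(fr3$n_approach, 0L)
  expect_true(is.na(fr3$fraction))
})

test_that("classification is monotone in t_dock and confine_radius and scale-free", {
  cfg <- sim_config(image_shape = c(160, 160), n_frames = 100, snr = 10,
                    background_level = 100, seed = 17)
  sim <- simulate_movie(cfg, residence_model(n_arrivals = 25))
  tracks <- link_tracks(detect_movie(sim$movie), docking_params(),
                        frame_interval = 1)
  n_docked <- function(t_dock, confine_radius) {
    p <- docking_params(t_dock = t_dock, confine_radius = confine_radius)
    sum(classify_all(tracks, p)$class == "docked")
  }
  docked_by_t <- vapply(c(10, 20, 25, 30, 40), n_docked,
                        0, confine_radius = 1.5)
  expect_true(all(diff(docked_by_t) <= 0))
  docked_by_r <- vapply(c(0.5, 1, 1.5, 2.5), function(r) n_docked(25, r), 0)
  expect_true(all(diff(docked_by_r) >= 0))
  # partition: every track gets exactly one class
  ev <- classify_all(tracks, docking_params())
  expect_equal(nrow(ev), length(tracks))
  expect_true(all(ev$class %in% c("docked", "visitor", "transit")))
  # intensity scaling leaves noiseless classification unchanged
  set.seed(2)
  t0 <- make_track(rep(50, 40), x = rnorm(40, 5, 0.1), y = rnorm(40, 5, 0.1),
                   start_frame = 2L)
  t1 <- t0; t1$intensity <- t0$intensity * 7
  expect_equal(classify_docking(t0, docking_params())$class,
               classify_docking(t1, docking_params())$class)
})

test_that("measured docking fraction is an unbiased estimate of the long-lived share", {
  err <- vapply(1:20, function(s) {
    cfg <- sim_config(image_shape = c(220, 220), n_frames = 150, snr = 10,
                      background_level = 100, seed = 500 + s)
    res <- residence_model(n_arrivals = 25, p_dock = 0.5)
    sim <- simulate_movie(cfg, res)
    tracks <- link_tracks(detect_movie(sim$movie), docking_params(),
                          frame_interval = 1)
    fr <- docking_fraction(classify_all(tracks), tracks)
    fr$fraction - mean(sim$ground_truth$spots$kind == "docked")
  }, 0)
  expect_lt(abs(mean(err)), 0.02)
})
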