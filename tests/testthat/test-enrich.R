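test_that("average projection is the pixel-wise mean and reduces noise as 1/sqrt(n)", {
  crop <- matrix(runif(900), 30, 30)
  stack <- array(rep(crop, 20), c(30, 30, 20))
  expect_equal(make_average_projection(stack), crop)
  expect_warning(make_average_projection(stack[, , 1:5]), "expects")

  set.seed(8)
  noise <- array(rnorm(30 * 30 * 100), c(30, 30, 100))
  proj <- make_average_projection(noise)
  expect_equal(sd(proj) * 10, 1, tolerance = 0.15)
})

test_that("diagonal profiles sample at ~1 px spacing with the documented length", {
  const <- matrix(3.5, 30, 30)
  p <- diagonal_profile(const)
  expect_equal(p$N_All, 42)
  expect_equal(p$samples, rep(3.5, 42))
  expect_equal(p$min, 3.5)

  img <- render_test_frame(cbind(15.5, 15.5), amplitude = 50,
                           background = 5, sigma = 2, shape = c(30, 30))
  pg <- diagonal_profile(img)
  expect_lte(abs(which.max(pg$samples) - (42 + 1) / 2), 1)
  expect_error(diagonal_profile(matrix(0, 20, 30)), "square")
})

test_that("granule width is the FWHM with interpolated crossings", {
  tri <- c(0, 0, seq(1.25, 10, by = 1.25), seq(8.75, 0, by = -1.25), 0, 0)
  gw <- granule_width(make_profile(tri))
  expect_equal(gw$N_gr, 8)     # half-max 5 crossed at samples 6 and 14
  x <- seq_len(201)
  gauss <- exp(-(x - 101)^2 / (2 * 12^2))
  gw2 <- granule_width(make_profile(gauss))
  expect_equal(gw2$N_gr, 2.355 * 12, tolerance = 0.02)
  expect_error(granule_width(make_profile(rep(2, 30))), "flat")
})

test_that("the enrichment statistic matches hand-computed values", {
  # all excess inside the granule region
  prof <- make_profile(c(rep(10, 15), rep(20, 10), rep(10, 15)))
  r <- enrichment_score(prof, c(16, 25), N_gr = 10, rule = "rectangle")
  expect_equal(r$E, 1)
  # all excess outside it
  prof2 <- make_profile(c(rep(10, 3), rep(25, 5), rep(10, 22),
                          rep(10, 10)))
  r2 <- enrichment_score(prof2, c(20, 29), N_gr = 10, rule = "rectangle")
  expect_equal(r2$E, 0)
  # worked rectangle-rule example
  prof3 <- make_profile(c(1, 1, 2, 4, 6, 4, 2, 1))
  r3 <- enrichment_score(prof3, c(4, 6), N_gr = 3, rule = "rectangle")
  expect_equal(r3$AUC_gr, 14)
  expect_equal(r3$AUC_All, 21)
  expect_equal(r3$E, 11 / 13)
  expect_equal(r3$E_null, 3 / 8)
})

test_that("E stays in [0, 1] and is invariant to affine probe rescaling", {
  set.seed(42)
  for (i in 1:200) {
    s <- runif(40, 0, 10) + c(rep(0, 15), runif(1, 0, 20) *
                                exp(-((1:10) - 5)^2 / 4), rep(0, 15))
    prof <- make_profile(s)
    lo <- sample(5:20, 1); hi <- lo + sample(3:15, 1)
    r <- enrichment_score(prof, c(lo, hi))
    if (!r$flagged) {
      expect_gte(r$E, 0); expect_lte(r$E, 1)
      r_scaled <- enrichment_score(make_profile(2.7 * s + 13), c(lo, hi))
      expect_equal(r_scaled$E, r$E, tolerance = 1e-9)
    }
  }
  # exactly uniform probe: flagged, E undefined
  flat <- enrichment_score(make_profile(rep(4, 42)), c(18, 25))
  expect_true(flat$flagged)
  expect_true(is.na(flat$E))
})

test_that("a granule-independent probe converges to the analytic null", {
  marker <- render_test_frame(cbind(15.5, 15.5), amplitude = 400,
                              background = 20, sigma = 1.3,
                              shape = c(30, 30))
  gw <- granule_width(diagonal_profile(marker))
  # linear background: E equals the null exactly (centred granule region)
  lin <- matrix(rep(seq(10, 11, length.out = 30), each = 30), 30, 30)
  r_lin <- enrichment_score(diagonal_profile(lin), gw$region, N_gr = gw$N_gr)
  expect_equal(r_lin$E, r_lin$E_null, tolerance = 1e-9)
  # curved smooth background: E stays within a few percent of the null,
  # independent of the gradient magnitude (E is affine-invariant)
  dev <- vapply(c(2, 0.5, 0.1), function(g) {
    bg <- matrix(10, 30, 30) +
      g * outer(seq(0, 1, length.out = 30), seq(0, 1, length.out = 30))
    r <- enrichment_score(diagonal_profile(bg), gw$region, N_gr = gw$N_gr)
    abs(r$E - r$E_null)
  }, 0)
  expect_true(all(dev < 0.05))
  # exactly uniform background: 0/0 guard flags the result
  unif <- enrichment_score(diagonal_profile(matrix(10, 30, 30)),
                           gw$region, N_gr = gw$N_gr)
  expect_true(unif$flagged)
})

test_that("mean enrichment increases strictly with the bound probe fraction", {
  bf <- c(0, 0.25, 0.5, 0.75, 1)
  mean_e <- vapply(bf, function(b) {
    mean(vapply(1:20, function(s) {
      cr <- simulate_crop_pair(15, bound_fraction = b, seed = 700 + s)
      enrichment_analysis(cr$channel1, cr$channel2)$E
    }, 0))
  }, 0)
  expect_true(all(diff(mean_e) > 0))
})
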