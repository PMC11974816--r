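test_that("noise-free bleed-through estimation is exact to fit tolerance", {
  sim <- simulate_fret_triplet(n_frames = 2, acceptor_present = FALSE,
                               alpha = 0.5, noise_sd = 0, seed = 1,
                               background_level = 0)
  cal <- estimate_bleedthrough(sim$stack, "donor", subtract_bg = FALSE,
                               mask = binary_mask(sim$truth$footprint))
  expect_equal(cal$alpha, 0.5, tolerance = 1e-9)

  # zero bleed-through estimates as ~0
  sim0 <- simulate_fret_triplet(n_frames = 5, acceptor_present = FALSE,
                                alpha = 0, noise_sd = 10, seed = 2,
                                background_level = 100)
  # slope may come out marginally negative and is clamped with a warning
  cal0 <- suppressWarnings(estimate_bleedthrough(sim0$stack, "donor"))
  expect_lt(abs(cal0$alpha), 0.005)
})

test_that("corrected map reproduces the printed-coefficient arithmetic", {
  mask <- binary_mask(matrix(TRUE, 4, 4))
  cal <- fret_calibration(alpha = 0.3072, beta = 0.05228)
  m <- corrected_fret_map(matrix(100, 4, 4), matrix(100, 4, 4),
                          matrix(100, 4, 4), cal, mask)
  expect_equal(unique(as.numeric(m$pixels)), 0.64052)

  # exact-null case: fret_raw = alpha*donor + beta*acceptor -> 0
  d <- matrix(runif(16, 50, 150), 4, 4)
  a <- matrix(runif(16, 50, 150), 4, 4)
  m0 <- corrected_fret_map(0.3072 * d + 0.05228 * a, d, a, cal, mask)
  expect_equal(max(abs(m0$pixels)), 0, tolerance = 1e-12)
  expect_error(corrected_fret_map(d, d[1:2, ], a, cal, mask), "mismatch")
})

test_that("noise-free correction inverts the generator over a grid", {
  mask_sim <- simulate_fret_triplet(seed = 1)
  for (alpha in c(0, 0.25, 0.5)) for (beta in c(0, 0.1, 0.2)) {
    for (E in c(0, 0.4, 0.8)) {
      sim <- simulate_fret_triplet(efficiency_map = E, alpha = alpha,
                                   beta = beta, noise_sd = 0, seed = 1,
                                   background_level = 0)
      mask <- binary_mask(sim$truth$footprint)
      m <- corrected_fret_map(get_frame(sim$stack, 1, "FRET"),
                              get_frame(sim$stack, 1, "mTFP1"),
                              get_frame(sim$stack, 1, "mVenus"),
                              fret_calibration(alpha, beta), mask)
      expect_lt(max(abs(m$pixels[mask$pixels] - E)), 1e-6)
    }
  }
})

test_that("correction is invariant to a common channel gain", {
  sim <- simulate_fret_triplet(efficiency_map = 0.2, noise_sd = 0, seed = 1,
                               background_level = 0)
  mask <- binary_mask(sim$truth$footprint)
  cal <- fret_calibration(0.3072, 0.05228)
  fr <- get_frame(sim$stack, 1, "FRET")
  d <- get_frame(sim$stack, 1, "mTFP1")
  a <- get_frame(sim$stack, 1, "mVenus")
  m1 <- corrected_fret_map(fr, d, a, cal, mask)
  m2 <- corrected_fret_map(fr * 2.5, d * 2.5, a * 2.5, cal, mask)
  expect_equal(m1$pixels, m2$pixels, tolerance = 1e-12)
})

test_that("LP/CB ratio handles planted contrast and bad masks", {
  px <- matrix(0.2, 40, 40)
  px[, 1:10] <- 0.3
  full <- binary_mask(matrix(TRUE, 40, 40))
  lp <- binary_mask(col(px) <= 10)
  cb <- binary_mask(col(px) > 10)
  map <- structure(list(pixels = px, mask = full),
                   class = "FretEfficiencyMap")
  expect_equal(lp_to_cb_fret(map, lp, cb), 1.5)
  # two disjoint patches of the uniform region give exactly 1
  u1 <- binary_mask(col(px) > 10 & col(px) <= 20)
  u2 <- binary_mask(col(px) > 20)
  expect_equal(lp_to_cb_fret(map, u1, u2), 1)
  expect_error(lp_to_cb_fret(map, binary_mask(matrix(FALSE, 40, 40)), cb),
               "empty")
  expect_error(lp_to_cb_fret(map, lp, lp), "overlap")
})

test_that("edge line profile recovers a planted normal gradient", {
  h <- 60; w <- 60
  mask <- binary_mask(matrix(TRUE, h, w), pixel_size_um = 1)
  g <- 0.01
  px <- matrix(rep(g * (seq_len(w) - 1), each = h), h, w)  # slope g per um
  map <- structure(list(pixels = px, mask = mask),
                   class = "FretEfficiencyMap")
  edge <- cbind(seq_len(h), rep(1, h))  # left border as the edge curve
  prof <- edge_line_profile(map, edge, depth_um = 30, bin_um = 2)
  fit <- coef(lm(prof$mean ~ prof$distance_um))
  expect_equal(unname(fit[2]), g, tolerance = 0.05)  # within 5% of slope

  # uniform map -> flat profile
  mapu <- structure(list(pixels = matrix(0.5, h, w), mask = mask),
                    class = "FretEfficiencyMap")
  profu <- edge_line_profile(mapu, edge, depth_um = 20, bin_um = 2)
  expect_true(all(abs(profu$mean - 0.5) < 1e-12))
  expect_error(edge_line_profile(map, edge, depth_um = 0, bin_um = 1), "> 0")
})

test_that("estimator bias stays below 2% of alpha at SNR 20 over seeds", {
  ests <- vapply(1:10, function(s) {
    sim <- simulate_fret_triplet(n_frames = 5, acceptor_present = FALSE,
                                 alpha = 0.3072, noise_sd = 50, seed = s,
                                 background_level = 100)
    estimate_bleedthrough(sim$stack, "donor")$alpha
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.3072), 0.02 * 0.3072)
})
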