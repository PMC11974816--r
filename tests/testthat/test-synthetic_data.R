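test_that("generators are deterministic given a seed", {
  a <- simulate_ratiometric_movie(n_frames = 2, noise_sd = 20, seed = 7)
  b <- simulate_ratiometric_movie(n_frames = 2, noise_sd = 20, seed = 7)
  expect_identical(a$stack$pixels, b$stack$pixels)
  m1 <- simulate_meshwork(n_filaments = 30, seed = 5)
  m2 <- simulate_meshwork(n_filaments = 30, seed = 5)
  expect_identical(m1$image, m2$image)
  t1 <- simulate_tracks(seed = 9)
  t2 <- simulate_tracks(seed = 9)
  expect_identical(t1$detections, t2$detections)
})

test_that("ratiometric generator plants the stated edge/body contrast", {
  sim <- simulate_ratiometric_movie(gradient_peak = 1.5, body_ratio = 1.0,
                                    noise_sd = 0, seed = 1)
  tr <- sim$truth
  d <- lamelloscope:::.distance_to_boundary(tr$footprint)
  band <- tr$footprint & d <= tr$edge_depth_px
  body <- tr$footprint & d > tr$edge_depth_px
  expect_equal(mean(tr$true_ratio_map[band]) / mean(tr$true_ratio_map[body]),
               1.5)
  expect_error(simulate_ratiometric_movie(gradient_peak = 0.9,
                                          body_ratio = 1.0),
               "gradient_peak")
})

test_that("FRET generator obeys its forward model in edge cases", {
  # efficiency 0, beta 0, no noise: FRET channel = alpha x donor exactly
  sim <- simulate_fret_triplet(efficiency_map = 0, alpha = 0.25, beta = 0,
                               noise_sd = 0, seed = 1, background_level = 0)
  d <- get_frame(sim$stack, 1, "mTFP1")
  fr <- get_frame(sim$stack, 1, "FRET")
  expect_equal(fr, 0.25 * d, tolerance = 1e-12)
  # all coefficients zero: FRET identically 0
  sim0 <- simulate_fret_triplet(efficiency_map = 0, alpha = 0, beta = 0,
                                noise_sd = 0, seed = 1, background_level = 0)
  expect_true(all(get_frame(sim0$stack, 1, "FRET") == 0))
  # single-fluorophore stacks carry no energy transfer
  dn <- simulate_fret_triplet(acceptor_present = FALSE, efficiency_map = 0.3,
                              noise_sd = 0, seed = 1, background_level = 0)
  expect_equal(get_frame(dn$stack, 1, "FRET"),
               dn$truth$true_alpha * get_frame(dn$stack, 1, "mTFP1"),
               tolerance = 1e-12)
  expect_error(simulate_fret_triplet(alpha = 1.2), "alpha")
})

test_that("meshwork generator porosity limits and recorded truth", {
  empty <- simulate_meshwork(n_filaments = 0, seed = 1, noise_sd = 0)
  expect_equal(empty$truth$true_porosity, 1.0)
  dense <- simulate_meshwork(shape = c(64, 64), n_filaments = 4000,
                             filament_width_px = 5, seed = 1)
  expect_lt(dense$truth$true_porosity, 0.01)
  sim <- simulate_meshwork(n_filaments = 40, seed = 2)
  expect_equal(sim$truth$true_porosity, mean(!sim$truth$coverage_mask))
})

test_that("edge-movie generator: durations checked, slope and lag planted", {
  expect_error(simulate_edge_movie(
    n_frames = 10,
    phase_plan = data.frame(phase = "protrusion", velocity_um_min = 1,
                            duration_s = 55)), "durations")
  plan <- data.frame(phase = "protrusion", velocity_um_min = 2,
                     duration_s = 600)
  sim <- simulate_edge_movie(n_frames = 60, phase_plan = plan, noise_sd = 0,
                             seed = 1)
  pos <- sim$truth$true_edge_position_um
  expect_equal(unname(coef(lm(pos ~ I(seq_along(pos) / 6)))[2]), 2,
               tolerance = 1e-9)
  expect_equal(sim$truth$true_lag_s, 0)
})

test_that("track generator: persistence-1 walkers move straight at speed", {
  sim <- simulate_tracks(n_cells = 4, n_frames = 15, speed_um_min = 2,
                         persistence = 1, frame_interval_s = 720, seed = 3)
  for (tt in split(sim$truth$true_tracks, sim$truth$true_tracks$true_track)) {
    steps <- sqrt(diff(tt$x_um)^2 + diff(tt$y_um)^2)
    expect_equal(steps / 12, rep(2, length(steps)), tolerance = 1e-9)
    m <- migration_metrics(tt, 720)
    expect_equal(m$di, 1, tolerance = 1e-9)
  }
  expect_error(simulate_tracks(persistence = 2), "persistence")
})

test_that("adhesion generator plants areas inside their class bins", {
  tab <- simulate_adhesion_table(c(8, 8, 8), seed = 4)
  expect_equal(nrow(tab), 24)
  cls <- classify_adhesions(tab$area_um2)
  expect_equal(as.character(cls$class), tab$true_class)
  expect_equal(nrow(simulate_adhesion_table(c(0, 0, 0))), 0)
})
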