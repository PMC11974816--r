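test_that("shading correction inverts the generator's field exactly", {
  sim <- simulate_ratiometric_movie(n_frames = 2, noise_sd = 0,
                                    shading_amplitude = 0.3, seed = 3)
  corr <- shading_correct(sim$stack, sim$truth$shading_field)
  flat <- simulate_ratiometric_movie(n_frames = 2, noise_sd = 0,
                                     shading_amplitude = 0, seed = 3)
  expect_equal(corr$pixels, flat$stack$pixels, tolerance = 1e-10)

  # flat blank leaves the stack unchanged
  same <- shading_correct(sim$stack, matrix(1, 128, 128))
  expect_equal(same$pixels, sim$stack$pixels)
  expect_error(shading_correct(sim$stack, matrix(0, 128, 128)),
               "strictly positive")
})

test_that("registration recovers planted rigid drift within 0.2 px/frame", {
  sim <- simulate_ratiometric_movie(n_frames = 4, noise_sd = 0,
                                    drift_px_per_frame = c(2, -1), seed = 3)
  reg <- register_frames(sim$stack)
  for (t in 2:4) {
    expect_equal(unname(reg$displacements[t, ]), c(2, -1) * (t - 1),
                 tolerance = 0.2 * (t - 1) + 1e-9)
  }
  # no drift: estimates below 0.1 px
  still <- simulate_ratiometric_movie(n_frames = 3, noise_sd = 0, seed = 3)
  reg0 <- register_frames(still$stack)
  expect_lt(max(abs(reg0$displacements)), 0.1)
  # single frame returned unchanged with zero displacement
  one <- simulate_ratiometric_movie(n_frames = 1, seed = 1)
  reg1 <- register_frames(one$stack)
  expect_identical(reg1$stack$pixels, one$stack$pixels)
  expect_equal(as.numeric(reg1$displacements), c(0, 0))
})

test_that("Otsu background subtraction zeroes the background median", {
  set.seed(5)
  img <- matrix(rnorm(64 * 64, 50, 2), 64, 64)
  img[20:40, 20:40] <- rnorm(21 * 21, 500, 5)
  res <- subtract_background(img)
  expect_equal(res$background_level, 50, tolerance = 0.5)
  bg_after <- res$image[res$image < lamelloscope:::.otsu_threshold(res$image)]
  expect_equal(median(bg_after), 0, tolerance = 0.5)
  expect_true(all(res$image >= 0))
  expect_error(subtract_background(matrix(3, 8, 8)), "constant")
})

test_that("cell mask keeps the largest filled component", {
  img <- matrix(0, 64, 64)
  img[5:15, 5:15] <- 100    # small square
  img[25:60, 20:60] <- 100  # large square with a hole
  img[40:45, 35:40] <- 0
  mask <- make_cell_mask(img)
  expect_false(any(mask$pixels[5:15, 5:15]))
  expect_true(all(mask$pixels[25:60, 20:60]))  # hole filled
  expect_error(make_cell_mask(matrix(0, 8, 8)), "constant|foreground")

  sim <- simulate_ratiometric_movie(noise_sd = 0, seed = 2)
  m <- make_cell_mask(get_frame(sim$stack, 1, "reference"))
  inter <- sum(m$pixels & sim$truth$footprint)
  uni <- sum(m$pixels | sim$truth$footprint)
  expect_gte(inter / uni, 0.95)
})

test_that("ratio map flags zero-reference pixels and divides exactly", {
  ref <- matrix(100, 32, 32)
  ref[, 30:32] <- 0
  rep_ <- 2 * ref
  mask <- binary_mask(matrix(TRUE, 32, 32))
  rm <- ratio_map(rep_, ref, mask, denoise_sigma = 0)
  expect_true(all(rm$pixels[, 1:29] == 2))
  expect_true(all(is.na(rm$pixels[, 30:32])))
  expect_error(ratio_map(rep_, ref[1:10, ], mask), "mismatch")
})

test_that("zero-noise full chain inverts the generator pixelwise", {
  sim <- simulate_ratiometric_movie(n_frames = 2, noise_sd = 0, seed = 3,
                                    shading_amplitude = 0.25)
  res <- process_ratiometric_movie(sim$stack,
                                   blank = sim$truth$shading_field,
                                   denoise_sigma = 0, register = FALSE)
  m <- res$maps[[1]]
  inside <- sim$truth$footprint & m$mask$pixels
  expect_lt(max(abs(m$pixels[inside] - sim$truth$true_ratio_map[inside])),
            1e-6)
  expect_equal(res$edge_body$edge_body_ratio, rep(1.5, 2), tolerance = 1e-9)
})

test_that("ratio map is invariant to a common positive gain", {
  sim <- simulate_ratiometric_movie(n_frames = 1, noise_sd = 0, seed = 4)
  rep_ <- get_frame(sim$stack, 1, "reporter") - 20
  ref <- get_frame(sim$stack, 1, "reference") - 20
  mask <- binary_mask(sim$truth$footprint, 0.4)
  r1 <- ratio_map(rep_, ref, mask)
  r2 <- ratio_map(rep_ * 3.7, ref * 3.7, mask)
  expect_equal(r1$pixels, r2$pixels, tolerance = 1e-12)
})

test_that("edge/body ratio of a uniform map is 1 and depth is validated", {
  mask <- binary_mask(square_mask(), 1)
  rm <- structure(list(pixels = ifelse(mask$pixels, 2, NA), mask = mask),
                  class = "RatioMap")
  expect_equal(edge_body_ratio(rm, 5), 1)
  expect_error(edge_body_ratio(rm, 0), "> 0")
  expect_error(edge_body_ratio(rm, 1000), "empty")
})

test_that("noisy chain recovers edge/body contrast within 5%", {
  sim <- simulate_ratiometric_movie(n_frames = 3, noise_sd = 50, seed = 11,
                                    shading_amplitude = 0.2,
                                    drift_px_per_frame = c(1, -1))
  res <- process_ratiometric_movie(sim$stack, blank = sim$truth$shading_field)
  expect_equal(res$edge_body$edge_body_ratio, rep(1.5, 3), tolerance = 0.05)
})
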