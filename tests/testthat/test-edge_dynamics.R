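test_that("kymograph sampling: static image, linearity, width-1 row", {
  px <- array(0, c(2, 1, 20, 40))
  img <- matrix(rep(seq_len(40), each = 20), 20, 40)
  px[1, 1, , ] <- img; px[2, 1, , ] <- img
  st <- channel_stack(px, "c", 0.5, 10)
  kym <- build_kymograph(st, 1, p0 = c(10, 1), p1 = c(10, 40), width_px = 1)
  expect_equal(kym$values[, 1], kym$values[, 2])       # static frames
  expect_equal(kym$values[, 1], as.numeric(img[10, ])) # direct row read

  # linearity in intensity
  st2 <- st; st2$pixels <- st$pixels * 3.5
  kym2 <- build_kymograph(st2, 1, p0 = c(10, 1), p1 = c(10, 40),
                          width_px = 3)
  kym1 <- build_kymograph(st, 1, p0 = c(10, 1), p1 = c(10, 40), width_px = 3)
  expect_equal(kym2$values, 3.5 * kym1$values)
  expect_error(build_kymograph(st, 1, c(10, 1), c(10, 40), width_px = 2),
               "odd")
  expect_error(build_kymograph(st, 1, c(200, 200), c(300, 300)), "outside")
})

test_that("edge tracing follows planted step profiles and trajectories", {
  # step-profile kymograph with edge at row 12
  v <- matrix(10, 30, 8)
  v[1:12, ] <- 100
  kym <- structure(list(values = v, space_step_um = 1, time_step_s = 60),
                   class = "Kymograph")
  tr <- trace_edge(kym)
  expect_equal(tr$position_um, rep(tr$position_um[1], 8))
  expect_true(all(abs(tr$position_um - 11.5) <= 0.5))

  plan <- data.frame(phase = "protrusion", velocity_um_min = 2,
                     duration_s = 600)
  sim <- simulate_edge_movie(n_frames = 60, phase_plan = plan, noise_sd = 0,
                             seed = 1)
  h <- dim(sim$stack$pixels)[3]; w <- dim(sim$stack$pixels)[4]
  k <- build_kymograph(sim$stack, 1, p0 = c(h / 2, 2), p1 = c(h / 2, w - 1))
  t2 <- trace_edge(k)
  truth <- sim$truth$true_edge_position_um - 2 * sim$stack$pixel_size_um
  expect_lte(max(abs(t2$position_um - truth)), 0.5 * sim$stack$pixel_size_um)

  blank <- structure(list(values = matrix(5, 20, 10) +
                            matrix(rnorm(200, 0, 0.1), 20),
                          space_step_um = 1, time_step_s = 1),
                     class = "Kymograph")
  expect_error(trace_edge(blank), ">50%")
})

test_that("spreading speed: linear, two-phase, and retraction sign", {
  tr <- edge_trace(2 * (0:59) / 6, 10)        # 2 um/min over 10 min
  expect_equal(spreading_speed(tr), 2, tolerance = 1e-9)

  # 3 um/min for 2 min then 0.2 um/min for 8 min
  t_min <- (0:59) / 6
  pos <- ifelse(t_min <= 2, 3 * t_min, 6 + 0.2 * (t_min - 2))
  tr2 <- edge_trace(pos, 10)
  expect_equal(spreading_speed(tr2), 3, tolerance = 0.05 * 3)

  tr3 <- edge_trace(20 - 1.5 * t_min, 10)
  expect_lt(spreading_speed(tr3), 0)          # monotone retraction
  expect_error(spreading_speed(edge_trace(1:5, 10)), "short")
})

test_that("phase classification thresholds and short-run merging", {
  tr <- edge_trace(2 * (0:29) / 6, 10)
  expect_true(all(classify_phases(tr, v_stall = 0.5) == "protrusion"))
  tr0 <- edge_trace(rep(1, 30), 10)
  expect_true(all(classify_phases(tr0, v_stall = 0.5) == "stall"))

  # single-frame velocity glitch is merged away
  pos <- 2 * (0:29) / 6
  pos[15] <- pos[15] - 0.4
  trg <- edge_trace(pos, 10)
  expect_true(all(classify_phases(trg, v_stall = 0.5, min_run = 3) ==
                    "protrusion"))

  # planted phase plan recovered away from transitions
  plan <- data.frame(phase = c("protrusion", "stall", "retraction"),
                     velocity_um_min = c(2, 0, -1.5),
                     duration_s = c(240, 180, 180))
  sim <- simulate_edge_movie(n_frames = 60, phase_plan = plan, noise_sd = 0,
                             seed = 2)
  h <- dim(sim$stack$pixels)[3]; w <- dim(sim$stack$pixels)[4]
  tr2 <- trace_edge(build_kymograph(sim$stack, 1, c(h / 2, 2),
                                    c(h / 2, w - 1)))
  ph <- classify_phases(tr2)
  truth <- sim$truth$true_phases
  trans <- which(diff(as.integer(factor(truth))) != 0)
  away <- setdiff(seq_along(truth), c(trans, trans + 1, trans - 1, trans + 2))
  expect_gte(mean(ph[away] == ifelse(truth[away] == "protrusion",
                                     "protrusion",
                                     ifelse(truth[away] == "retraction",
                                            "retraction", "stall"))), 0.95)
})

test_that("protrusion speed averages the largest planted sawtooth events", {
  dtm <- 10 / 60
  vpat <- rep(c(rep(4, 10), rep(-2, 8)), 5)
  pos <- 10 + cumsum(c(0, vpat[-length(vpat)])) * dtm
  tr <- edge_trace(pos, 10)
  expect_equal(protrusion_speed(tr, n_events = 5), 4, tolerance = 0.05 * 4)

  # constant protrusion: one event, n_events = 1 equals the overall slope
  trc <- edge_trace(3 * (0:29) / 6, 10)
  expect_equal(protrusion_speed(trc, n_events = 1), 3, tolerance = 1e-9)
  expect_error(protrusion_speed(edge_trace(rep(2, 30), 10)), "event")
})
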