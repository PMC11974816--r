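test_that("LoG detector finds planted blobs with sub-pixel accuracy", {
  mk_blob <- function(r0, c0, sigma = 9, size = 96) {
    rr <- matrix(seq_len(size), size, size)
    cc <- t(rr)
    100 * exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * sigma^2))
  }
  d <- detect_blobs_log(mk_blob(30, 40), pixel_size_um = 1,
                        diameter_um = 25, quality_threshold = 0.08)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x_um - 39), 1)
  expect_lt(abs(d$y_um - 29), 1)

  # blank image -> nothing
  expect_equal(nrow(detect_blobs_log(matrix(0, 64, 64), 1)), 0)

  # two blobs separated by more than a diameter
  img2 <- mk_blob(25, 25) + mk_blob(70, 70)
  d2 <- detect_blobs_log(img2, 1)
  expect_equal(nrow(d2), 2)
  expect_error(detect_blobs_log(matrix(0, 8, 8), pixel_size_um = 20),
               "diameter")
})

test_that("assignment solver matches brute-force enumeration", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n, n)
    sol <- lamelloscope:::.solve_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), sol)]),
                 brute_force_assignment(cost)$cost, tolerance = 1e-12)
  }
})

test_that("linking recovers planted walkers exactly without dropout", {
  for (s in 1:3) {
    sim <- simulate_tracks(n_cells = 5, n_frames = 20, speed_um_min = 1,
                           persistence = 0.5, seed = s)
    tr <- link_tracks(sim$detections)
    tab <- table(tr$track_id, tr$true_track)
    expect_equal(length(unique(tr$track_id)), 5)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
  # permutation invariance to detection order within frames
  sim <- simulate_tracks(n_cells = 4, n_frames = 10, seed = 4)
  set.seed(1)
  shuf <- sim$detections[sample(nrow(sim$detections)), ]
  t1 <- link_tracks(sim$detections)
  t2 <- link_tracks(shuf)
  p1 <- split(paste(t1$frame, round(t1$x_um, 6)), t1$track_id)
  p2 <- split(paste(t2$frame, round(t2$x_um, 6)), t2$track_id)
  expect_setequal(unname(vapply(p1, paste, collapse = "|", "")),
                  unname(vapply(p2, paste, collapse = "|", "")))
})

test_that("gap closing bridges dropped frames within the limits", {
  sim <- simulate_tracks(n_cells = 1, n_frames = 15, speed_um_min = 1,
                         persistence = 0.8, seed = 2)
  det <- sim$detections
  # one dropped frame: bridged into a single track
  tr <- link_tracks(det[det$frame != 8, ])
  expect_equal(length(unique(tr$track_id)), 1)
  # gap beyond max_frame_gap: split
  tr2 <- link_tracks(det[!det$frame %in% 6:10, ], max_frame_gap = 3)
  expect_equal(length(unique(tr2$track_id)), 2)
  # two detections 60 um apart in consecutive frames are not linked
  far <- data.frame(frame = c(1, 2), x_um = c(0, 60), y_um = 0, quality = 1)
  expect_equal(length(unique(link_tracks(far, max_link_um = 50)$track_id)), 2)
  # empty input
  expect_equal(nrow(link_tracks(far[0, ])), 0)
})

test_that("track filters keep exactly the planted passing mixture", {
  dt_s <- 720  # 12 min frames
  mk <- function(id, n_frames, step) {
    data.frame(track_id = id, frame = seq_len(n_frames),
               x_um = step * (seq_len(n_frames) - 1), y_um = 0)
  }
  # 10 tracks pass (>= 60 min, >= 18 um), 5 fail
  pass <- do.call(rbind, lapply(1:10, function(i) mk(i, 10, 3)))
  fail_short <- do.call(rbind, lapply(11:13, function(i) mk(i, 4, 3)))
  fail_span <- do.call(rbind, lapply(14:15, function(i) mk(i, 10, 1)))
  tracks <- structure(rbind(pass, fail_short, fail_span),
                      class = c("TrackTable", "data.frame"))
  kept <- filter_tracks(tracks, dt_s)
  expect_setequal(unique(kept$track_id), 1:10)
  expect_equal(attr(kept, "n_removed"), 5)
  # 59 min track removed, 120 min / 20 um track kept
  t59 <- structure(mk(1, 5, 10), class = c("TrackTable", "data.frame"))
  expect_equal(nrow(filter_tracks(t59, 708)), 0)  # 4 * 11.8 min = 47.2
  t120 <- structure(mk(1, 11, 2), class = c("TrackTable", "data.frame"))
  expect_equal(unique(filter_tracks(t120, dt_s)$track_id), 1)
})

test_that("migration metrics: DI identities and worked example", {
  straight <- data.frame(frame = 1:5, x_um = (1:5) * 2, y_um = 0)
  expect_equal(migration_metrics(straight, 60)$di, 1)
  loop <- data.frame(frame = 1:5, x_um = c(0, 1, 1, 0, 0),
                     y_um = c(0, 0, 1, 1, 0))
  expect_equal(migration_metrics(loop, 60)$di, 0)
  lshape <- data.frame(frame = 1:3, x_um = c(0, 3, 3), y_um = c(0, 0, 4))
  m <- migration_metrics(lshape, 60)
  expect_equal(m$path_um, 7)
  expect_equal(m$displacement_um, 5)
  expect_equal(m$di, 5 / 7)
  expect_error(migration_metrics(straight[1, ], 60), ">= 2")

  # rotation + translation invariance
  th <- 0.7
  rot <- data.frame(frame = 1:3,
                    x_um = 5 + cos(th) * lshape$x_um - sin(th) * lshape$y_um,
                    y_um = -2 + sin(th) * lshape$x_um + cos(th) * lshape$y_um)
  mr <- migration_metrics(rot, 60)
  expect_equal(mr$di, m$di, tolerance = 1e-12)
  expect_equal(mr$path_um, m$path_um, tolerance = 1e-12)
})

test_that("displacement speed: straight, loop, and generator read-back", {
  tr <- data.frame(frame = c(1, 11), x_um = c(0, 30), y_um = 0)
  expect_equal(displacement_speed(tr, 720), 15)  # 30 um over 2 hr
  loop <- data.frame(frame = 1:5, x_um = c(0, 1, 1, 0, 0),
                     y_um = c(0, 0, 1, 1, 0))
  expect_equal(displacement_speed(loop, 720), 0)
  sim <- simulate_tracks(n_cells = 1, n_frames = 10, speed_um_min = 1.5,
                         persistence = 1, frame_interval_s = 720, seed = 6)
  sp <- displacement_speed(sim$truth$true_tracks, 720)
  expect_equal(sp, 1.5 * 60, tolerance = 1e-9)
})

test_that("TrackMate CSV round trip preserves tracks", {
  sim <- simulate_tracks(n_cells = 3, n_frames = 8, seed = 5)
  tr <- link_tracks(sim$detections)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trackmate_csv(tr, f)
  back <- read_trackmate_csv(f)
  expect_equal(back$x_um, tr$x_um)
  expect_equal(back$track_id, tr$track_id)
  expect_error(read_trackmate_csv(write_table(data.frame(a = 1), f)),
               "TrackMate")
})
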