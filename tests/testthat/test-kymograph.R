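ridge_movie <- function(speed_px = 1, n_frames = 40, nr = 11, nc = 80,
                        start_col = 10, amp = 50, row = 6) {
  arr <- array(0, c(nr, nc, n_frames))
  for (f in seq_len(n_frames))
    arr[, , f] <- dcvtrace:::add_gaussian_spot(
      matrix(0, nr, nc), row, start_col + (f - 1) * speed_px, 1.5, amp)
  dcv_movie(arr, pixel_size = 0.1, frame_interval = 0.1)
}

straight_path <- function(nc = 80, row = 6) {
  axon_path(rbind(c(row, 2), c(row, nc - 1)))
}

test_that("a moving spot makes a diagonal ridge, a static spot a vertical one", {
  mv <- ridge_movie(speed_px = 1)
  ky <- build_kymograph(mv, straight_path())
  peaks <- apply(ky$data, 1, which.max)
  # one straight ridge of slope 1 bin/frame (integer-bin readout wobbles
  # by at most half a bin around the line)
  fit <- lm(peaks ~ seq_along(peaks))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.02)
  expect_lt(max(abs(residuals(fit))), 1)

  static <- ridge_movie(speed_px = 0)
  ky2 <- build_kymograph(static, straight_path())
  expect_equal(var(apply(ky2$data, 1, which.max)), 0)

  empty <- dcv_movie(array(3, c(11, 80, 5)), 0.1, 0.1)
  ky3 <- build_kymograph(empty, straight_path())
  expect_equal(unique(as.vector(ky3$data)), 3)
  expect_error(build_kymograph(mv, straight_path(), position_step = 100),
               "degenerate")
})

test_that("track extraction recovers ridges without identity swaps", {
  mv <- ridge_movie(speed_px = 1)
  trks <- extract_tracks(build_kymograph(mv, straight_path()))
  expect_length(trks, 1)
  expect_length(trks[[1]]$frames, 40)

  # two parallel ridges separated by more than the link radius
  arr <- array(0, c(21, 80, 40))
  for (f in 1:40) {
    img <- matrix(0, 21, 80)
    img <- dcvtrace:::add_gaussian_spot(img, 11, 10 + (f - 1) * 0.5, 1.5, 50)
    img <- dcvtrace:::add_gaussian_spot(img, 11, 50 + (f - 1) * 0.5, 1.5, 50)
    arr[, , f] <- img
  }
  mv2 <- dcv_movie(arr, 0.1, 0.1)
  trks2 <- extract_tracks(build_kymograph(mv2, axon_path(rbind(c(11, 2),
                                                               c(11, 79)))))
  expect_length(trks2, 2)
  seps <- abs(trks2[[1]]$positions_um - trks2[[2]]$positions_um)
  expect_lt(diff(range(seps)), 0.2)   # constant separation = no swap
})

test_that("track metrics follow the arithmetic and direction contracts", {
  const <- kymograph_track(1:50, (0:49) * 0.2, frame_interval = 0.1)
  const <- track_metrics(const)
  expect_equal(const$total_travel_length_um, 9.8)
  expect_equal(const$average_speed_um_s, 2)
  expect_equal(const$direction, "anterograde")

  still <- track_metrics(kymograph_track(1:10, rep(4, 10), 0.1))
  expect_equal(still$total_travel_length_um, 0)
  expect_equal(still$average_speed_um_s, 0)
  expect_equal(still$direction, "stationary")

  wiggle <- track_metrics(kymograph_track(1:5, c(0, 1, 0.4, 1.2, 0.2), 0.1))
  expect_gte(wiggle$total_travel_length_um, abs(0.2 - 0))
  expect_equal(wiggle$total_travel_length_um, 1 + 0.6 + 0.8 + 1)

  # time reversal flips direction but preserves length and speed
  fwd <- track_metrics(kymograph_track(1:20, seq(0, 3.8, 0.2), 0.1))
  rev_tr <- track_metrics(kymograph_track(1:20, rev(seq(0, 3.8, 0.2)), 0.1))
  expect_equal(fwd$total_travel_length_um, rev_tr$total_travel_length_um)
  expect_equal(fwd$average_speed_um_s, rev_tr$average_speed_um_s)
  expect_equal(rev_tr$direction, "retrograde")
  expect_error(track_metrics(kymograph_track(1, 0, 0.1)), ">= 2")
})

test_that("the full transport pipeline recovers counts and lengths", {
  sims <- clean_transport_fixtures(5, seed0 = 300)
  for (sim in sims) {
    trks <- extract_tracks(build_kymograph(sim$movie, sim$path),
                           min_duration_frames = 30)
    expect_length(trks, length(sim$ground_truth$tracks))
    est <- sort(tracks_table(trks)$total_travel_length_um)
    gt <- sort(tracks_table(sim$ground_truth$tracks)$total_travel_length_um)
    expect_lt(max(abs(est - gt) / gt), 0.10)
  }
})

test_that("a slower-transport group is detected as slower", {
  fast <- clean_transport_fixtures(6, seed0 = 400, speed_mean = 1)
  slow <- clean_transport_fixtures(6, seed0 = 500, speed_mean = 0.6,
                                   speed_sd = 0.15)
  speed_of <- function(sims) unlist(lapply(sims, function(s)
    tracks_table(extract_tracks(build_kymograph(s$movie, s$path),
                                min_duration_frames = 30))$average_speed_um_s))
  v_fast <- speed_of(fast)
  v_slow <- speed_of(slow)
  expect_lt(median(v_slow), median(v_fast))
  expect_lt(mann_whitney_u(v_fast, v_slow)$p_value, 0.05)
})
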