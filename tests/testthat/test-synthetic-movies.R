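test_that("zero puncta give a pure-background reporter channel", {
  sched <- protocol_schedule()
  sim <- generate_timelapse_movie(NULL, sched,
                                  noise_model(background_level = 20, seed = 1),
                                  frame_dim = c(16, 16))
  expect_equal(unique(as.vector(sim$reporter$data)), 20)
  expect_null(sim$ground_truth$rois)
})

test_that("planted amplitudes make the release ratio recoverable by construction", {
  sched <- protocol_schedule()
  rois <- data.frame(row = 32, col = 32, a_stim = 2, a_nh4cl = 8)
  sim <- generate_timelapse_movie(rois, sched, noise_model(seed = 1),
                                  frame_dim = c(64, 64))
  gt <- sim$ground_truth$rois
  # window responses saturate below the asymptotic amplitudes, but the
  # ratio of effective peaks stays within a percent of 2/(2+8)
  expect_equal(gt$expected_ratio, gt$peak_stim / (gt$peak_stim + gt$peak_nh4cl))
  expect_lt(abs(gt$expected_ratio - 0.2), 0.01)
  # noiseless measured ratio matches the planted ground truth
  p <- punctum(32, 32, radius = 3)
  m <- peak_metrics(normalize_trace(extract_trace(sim$reporter, p, sched)))
  expect_lt(abs(m$ratio - gt$expected_ratio) / gt$expected_ratio, 0.01)
})

test_that("overlapping puncta are recorded as a warning in ground truth", {
  sched <- protocol_schedule()
  rois <- data.frame(row = c(30, 33), col = c(30, 30),
                     a_stim = 1, a_nh4cl = 5)
  sim <- generate_timelapse_movie(rois, sched, noise_model(seed = 1),
                                  frame_dim = c(64, 64))
  expect_match(sim$ground_truth$warnings, "overlap")
  expect_error(generate_timelapse_movie(
    data.frame(row = 100, col = 5, a_stim = 1, a_nh4cl = 5), sched,
    noise_model(seed = 1), frame_dim = c(64, 64)), "inside the frame")
})

test_that("NH4Cl de-quench dominates the stimulation response in every ROI", {
  # conservation: noiseless reporter intensity during nh4cl >= stimulation
  sched <- protocol_schedule()
  rois <- grid_rois(a_stim = runif_seeded(20, 0.5, 3, seed = 9),
                    a_nh4cl = runif_seeded(20, 4, 10, seed = 10))
  sim <- generate_timelapse_movie(rois, sched, noise_model(seed = 1))
  for (i in seq_len(nrow(rois))) {
    p <- punctum(rois$row[i], rois$col[i], radius = 3)
    tr <- extract_trace(sim$reporter, p, sched)
    expect_gte(max(tr$values[window_frames(sched, "nh4cl")]),
               max(tr$values[window_frames(sched, "stimulation")]))
  }
})

test_that("transport ground truth obeys the kinematic contract", {
  # frozen spot: pause_probability 1 means zero travel
  frozen <- generate_transport_movie(
    transport_spec(n_vesicles = 3, pause_probability = 1),
    n_movie_frames = 30, noise = noise_model(seed = 4))
  lens <- tracks_table(frozen$ground_truth$tracks)$total_travel_length_um
  expect_equal(lens, rep(0, 3))

  # constant 2 px/frame for 50 frames at 0.1 um/px: 49 steps x 0.2 um
  const <- generate_transport_movie(
    transport_spec(n_vesicles = 1, speed_mean = 2, speed_sd = 0,
                   pause_probability = 0, reversal_probability = 0,
                   direction_mix = 1, axon_length_um = 40),
    n_movie_frames = 50, noise = noise_model(seed = 4),
    pixel_size = 0.1, frame_interval = 0.1)
  tt <- tracks_table(const$ground_truth$tracks)
  expect_equal(tt$total_travel_length_um, 9.8, tolerance = 1e-10)
  expect_equal(tt$average_speed_um_s, 2, tolerance = 1e-10)

  # law of large numbers: empirical running speed near the spec mean
  sim <- generate_transport_movie(
    transport_spec(n_vesicles = 100, speed_mean = 1, speed_sd = 0.2,
                   pause_probability = 0.2, reversal_probability = 0.02,
                   axon_length_um = 200),
    n_movie_frames = 100, noise = noise_model(seed = 3))
  steps <- abs(apply(sim$ground_truth$positions_um, 2, diff))
  moving <- sim$ground_truth$moving[-1, ]
  mean_run_speed <- mean(steps[moving] / 0.1)
  expect_lt(abs(mean_run_speed - 1) / 1, 0.05)
})

test_that("movies survive a 16-bit TIFF round trip with calibration", {
  sim <- generate_transport_movie(
    transport_spec(n_vesicles = 2, axon_length_um = 10),
    n_movie_frames = 5, noise = noise_model(background_level = 10, seed = 2))
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(sim$movie, path)
  back <- read_movie_tiff(path)
  expect_equal(back$pixel_size, sim$movie$pixel_size)
  expect_equal(back$frame_interval, sim$movie$frame_interval)
  expect_lt(max(abs(back$data - sim$movie$data)), max(sim$movie$data) / 5e3)
})
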