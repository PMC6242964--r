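make_spot_image <- function(nr = 64, nc = 64, centers, amp = 100, bg = 20,
                            sigma = 2) {
  img <- matrix(bg, nr, nc)
  amp <- rep_len(amp, nrow(centers))
  for (i in seq_len(nrow(centers)))
    img <- dcvtrace:::add_gaussian_spot(img, centers[i, 1], centers[i, 2],
                                        sigma, amp[i])
  img
}

test_that("punctum detection finds planted spots and suppresses neighbours", {
  expect_length(detect_puncta(matrix(5, 32, 32)), 0)
  expect_error(detect_puncta(matrix(numeric(0), 0, 0)), "empty")
  expect_error(detect_puncta(matrix(c(1, NA, 1, 1), 2, 2)), "finite")

  # single bright punctum, noise well below amplitude
  img <- make_spot_image(centers = rbind(c(30, 40)))
  img <- img + withr::with_seed(1, matrix(rnorm(64 * 64, 0, 2), 64, 64))
  cands <- detect_puncta(img)
  expect_length(cands, 1)
  expect_lt(sqrt((cands[[1]]$row - 30)^2 + (cands[[1]]$col - 40)^2), 1.01)

  # two spots closer than min_distance collapse to the brighter one
  img2 <- make_spot_image(centers = rbind(c(30, 30), c(30, 33)),
                          amp = c(100, 60))
  cands2 <- detect_puncta(img2, min_distance = 6)
  expect_length(cands2, 1)
  expect_equal(cands2[[1]]$col, 30, tolerance = 1)
})

test_that("detection is translation-equivariant for whole-pixel shifts", {
  img <- make_spot_image(centers = rbind(c(20, 20), c(40, 45)))
  shifted <- matrix(20, 64, 64)
  shifted[4:64, 6:64] <- img[1:61, 1:59]
  c0 <- detect_puncta(img)
  c1 <- detect_puncta(shifted)
  pos0 <- t(vapply(c0, function(p) c(p$row, p$col), numeric(2)))
  pos1 <- t(vapply(c1, function(p) c(p$row, p$col), numeric(2)))
  shift <- matrix(c(3, 5), nrow(pos0), 2, byrow = TRUE)
  expect_equal(pos1[order(pos1[, 1]), ], pos0[order(pos0[, 1]), ] + shift,
               ignore_attr = TRUE)
})

test_that("the 2-sigma synaptic call follows the local-background rule", {
  img <- matrix(20, 64, 64)
  p <- punctum(32, 32, radius = 3)
  # flat image: signal == background, sd 0 -> not synaptic
  called <- call_synaptic(p, img)
  expect_false(called$is_synaptic)

  # add background texture of known sd and a punctum 3 sigma up
  set.seed(11)
  img_n <- img + matrix(rnorm(64 * 64, 0, 3), 64, 64)
  bright <- img_n
  bright[30:34, 30:34] <- bright[30:34, 30:34] + 3 * 3
  cb <- call_synaptic(punctum(32, 32, radius = 2), bright)
  expect_true(cb$is_synaptic)
  # only 1 sigma up: below the threshold
  dim1 <- img_n
  dim1[30:34, 30:34] <- dim1[30:34, 30:34] + 1 * 3
  expect_false(call_synaptic(punctum(32, 32, radius = 2), dim1)$is_synaptic)

  # the call is scale-invariant
  cb2 <- call_synaptic(punctum(32, 32, radius = 2), bright * 7.3)
  expect_identical(cb2$is_synaptic, cb$is_synaptic)

  # too close to the border: flagged, not called
  edge <- call_synaptic(punctum(2, 2, radius = 3), img_n)
  expect_true(is.na(edge$is_synaptic))
})

test_that("trace extraction averages the ROI mask per frame", {
  arr <- array(7, c(16, 16, 5))
  mv <- dcv_movie(arr, pixel_size = 0.16, frame_interval = 1)
  tr <- extract_trace(mv, punctum(8, 8, radius = 3))
  expect_equal(tr$values, rep(7, 5))

  # ROI fully in background reads the background level
  sched <- protocol_schedule()
  sim <- generate_timelapse_movie(
    data.frame(row = 16, col = 16, a_stim = 2, a_nh4cl = 8), sched,
    noise_model(background_level = 20, seed = 1), frame_dim = c(64, 64))
  far <- extract_trace(sim$reporter, punctum(50, 50, radius = 3), sched)
  expect_equal(mean(far$values), 20, tolerance = 0.01)
})

test_that("synaptic calls on a planted movie hit >= 95% precision and recall", {
  sched <- protocol_schedule()
  rois <- grid_rois(a_stim = 1, a_nh4cl = 6)
  sim <- generate_timelapse_movie(rois, sched, movie_noise(seed = 21))
  det <- detect_synaptic_rois(sim$synapse)
  hit <- vapply(seq_len(nrow(det)), function(i)
    min((rois$row - det$row[i])^2 + (rois$col - det$col[i])^2) <= 1,
    logical(1))
  called <- det[!is.na(det$is_synaptic) & det$is_synaptic, ]
  expect_gte(sum(hit[called$roi_id]) / nrow(called), 0.95)   # precision
  expect_gte(nrow(called) / nrow(rois), 0.95)                # recall

  # flat decoy positions must not be called synaptic
  img <- time_average(sim$synapse)
  decoys <- expand.grid(row = c(17, 27, 37, 47), col = c(18, 32, 45))
  decoy_calls <- vapply(seq_len(nrow(decoys)), function(i)
    isTRUE(call_synaptic(punctum(decoys$row[i], decoys$col[i], radius = 3),
                         img)$is_synaptic), logical(1))
  expect_lte(mean(decoy_calls), 0.05)
})
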