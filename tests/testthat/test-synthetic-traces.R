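sched10 <- single_vesicle_schedule()

test_that("noiseless canonical waveforms satisfy their defining endpoints", {
  fd <- generate_release_trace(
    release_kinetics("full-decay", amplitude = 1, rise_tau = 0.2,
                     decay_tau = 1, onset_frame = 60), sched10)
  expect_lt(abs(fd$values[300]), 1e-6)
  expect_gt(max(fd$values), 0.9)

  dp <- generate_release_trace(
    release_kinetics("decay-plateau", amplitude = 1.5, plateau_level = 0.4,
                     onset_frame = 60), sched10)
  expect_equal(dp$values[300], 0.4 * 1.5)

  # ends in "-decay" return to baseline, ends in "-plateau" stay above
  for (pat in release_patterns()) {
    tr <- generate_release_trace(
      release_kinetics(pat, onset_frame = 60, plateau_duration = 2),
      sched10)
    final <- tr$values[300]
    if (grepl("decay$", pat)) expect_lt(final, 1e-6)
    else expect_gt(final, 0.3)
  }
})

test_that("same seed gives bit-identical traces", {
  spec <- release_kinetics("plateau-decay", onset_frame = 60)
  nz <- noise_model(photon_scale = 50, read_sigma = 0.05, seed = 7)
  t1 <- generate_release_trace(spec, sched10, nz)
  t2 <- generate_release_trace(spec, sched10, nz)
  expect_identical(t1$values, t2$values)
  t3 <- generate_release_trace(spec, sched10, noise_model(read_sigma = 0.05,
                                                          seed = 8))
  expect_false(identical(t1$values, t3$values))
})

test_that("a plateau running past the trace end is rejected", {
  spec <- release_kinetics("plateau-decay", plateau_duration = 40,
                           onset_frame = 60)
  expect_error(generate_release_trace(spec, sched10), "past the end")
  # terminal plateaus are open-ended and fine
  spec2 <- release_kinetics("decay-plateau", plateau_duration = 40,
                            onset_frame = 60)
  expect_silent(generate_release_trace(spec2, sched10))
})

test_that("event population honours proportions, seed, and edge cases", {
  expect_length(generate_event_population(0, c(1, 0, 0, 0, 0))$traces, 0)
  expect_error(generate_event_population(10, c(0.5, 0.4, 0, 0, 0)),
               "sum to 1")
  expect_error(generate_event_population(-1, c(1, 0, 0, 0, 0)), ">= 0")

  all_fd <- generate_event_population(50, c(1, 0, 0, 0, 0),
                                      noise = noise_model(seed = 3))
  expect_true(all(all_fd$labels == "full-decay"))

  props <- c(0.38, 0.36, 0.10, 0.10, 0.06)
  pop <- generate_event_population(1000, props, noise = noise_model(seed = 1))
  counts <- table(factor(pop$labels, levels = release_patterns()))
  # each class count inside its exact binomial 99% interval
  for (k in seq_along(props)) {
    lo <- qbinom(0.005, 1000, props[k])
    hi <- qbinom(0.995, 1000, props[k])
    expect_gte(counts[[k]], lo)
    expect_lte(counts[[k]], hi)
  }
  # determinism of the full population
  pop2 <- generate_event_population(1000, props, noise = noise_model(seed = 1))
  expect_identical(pop$labels, pop2$labels)
  expect_identical(pop$traces[[17]]$values, pop2$traces[[17]]$values)
})

test_that("MES quench returns all post-wash signal to baseline", {
  spec <- release_kinetics("decay-plateau", plateau_level = 0.5,
                           onset_frame = 60)
  nz <- noise_model(read_sigma = 0.03, seed = 2)
  tr <- generate_release_trace(spec, sched10, nz)
  q <- apply_perturbation(tr, "mes_quench", k = 150)
  post <- q$values[150:300]
  expect_lt(max(abs(post)), 5 * 0.03)   # baseline + noise only
  expect_lt(abs(mean(post)), 0.01)
  expect_identical(q$values[1:149], tr$values[1:149])
  expect_error(apply_perturbation(tr, "mes_quench"), "frame k")
  expect_error(apply_perturbation(tr, "warm_wash"), "unknown perturbation")
})

test_that("bafilomycin is a no-op without re-acidification and leaves a
           release-dominated decay constant essentially unchanged", {
  spec <- release_kinetics("full-decay", decay_tau = 1, onset_frame = 60)
  tr <- generate_release_trace(spec, sched10)
  expect_identical(apply_perturbation(tr, "bafilomycin")$values, tr$values)

  spec_re <- release_kinetics("full-decay", decay_tau = 1, onset_frame = 60,
                              reacidification_tau = 100)
  with_re <- generate_release_trace(spec_re, sched10)
  without <- apply_perturbation(with_re, "bafilomycin")
  pk <- which.max(with_re$values)
  tau_re <- fit_single_exponential(with_re$values[pk:(pk + 60)], 0.1,
                                   "decay")$tau
  tau_no <- fit_single_exponential(without$values[pk:(pk + 60)], 0.1,
                                   "decay")$tau
  expect_lt(abs(tau_re - tau_no) / tau_no, 0.02)
})
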