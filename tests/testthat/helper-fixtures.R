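# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed per call site.

# A 5 x 4 grid of punctum positions clear of the image border, so the
# local-background ROIs always fit.
grid_rois <- function(a_stim, a_nh4cl) {
  pos <- expand.grid(row = c(12, 22, 32, 42, 52), col = c(12, 25, 38, 51))
  data.frame(row = pos$row, col = pos$col, a_stim = a_stim,
             a_nh4cl = a_nh4cl)
}

# Default camera noise for movie fixtures: photon noise at 2 e-/unit plus
# 2-unit read noise over a 20-unit background. With a default punctum f0
# of 50 this puts the synapse-channel SNR near 8.
movie_noise <- function(seed, background_level = 20) {
  noise_model(photon_scale = 2, read_sigma = 2,
              background_level = background_level, seed = seed)
}

# Kinetics ranges with unit amplitude, so a read_sigma of 0.05 is exactly
# a noise sd of 0.05 x peak.
unit_amp_ranges <- function() {
  list(amplitude = c(1, 1), rise_tau = c(0.1, 0.4),
       decay_tau = c(0.5, 2.5), plateau_level = c(0.3, 0.6),
       plateau_duration = c(1, 3))
}

# Classify every trace of an event population; returns predicted labels.
classify_population <- function(pop) {
  vapply(seq_along(pop$traces), function(i) {
    evs <- detect_events(pop$traces[[i]])
    if (!length(evs)) return("none")
    ev <- evs[[which.max(vapply(evs, function(e) e$peak_amplitude,
                                numeric(1)))]]
    classify_event(ev)$pattern
  }, character(1))
}

# Generate transport movies and keep only geometrically clean ones
# (vesicles separated by > 1.5 um at all times, no end reflections) until
# `n_movies` fixtures are collected. Selection uses ground-truth geometry
# only, never the tracking output.
clean_transport_fixtures <- function(n_movies, seed0, n_vesicles = 4,
                                     n_frames = 60, axon_length_um = 40,
                                     speed_mean = 1, speed_sd = 0.2) {
  out <- list()
  s <- 0
  while (length(out) < n_movies && s < 10 * n_movies) {
    s <- s + 1
    spec <- transport_spec(n_vesicles = n_vesicles, speed_mean = speed_mean,
                           speed_sd = speed_sd, pause_probability = 0.1,
                           reversal_probability = 0, direction_mix = 1,
                           axon_length_um = axon_length_um)
    noise <- noise_model(photon_scale = 2, read_sigma = 2,
                         background_level = 10, seed = seed0 + s)
    sim <- generate_transport_movie(spec, n_movie_frames = n_frames,
                                    noise = noise)
    pos <- sim$ground_truth$positions_um
    sep_ok <- n_vesicles < 2 ||
      all(apply(pos, 1, function(p) min(diff(sort(p)))) > 1.5)
    refl_ok <- all(pos > 0.2 & pos < axon_length_um - 0.2)
    if (sep_ok && refl_ok) out[[length(out) + 1L]] <- sim
  }
  out
}

# Uniform draws under a local seed (RNG state restored afterwards).
runif_seeded <- function(n, min, max, seed) {
  withr::with_seed(seed, stats::runif(n, min, max))
}

# Independent Mann-Whitney oracle: the exact two-sided p by enumerating
# every assignment of the pooled values into the two groups.
enumerate_mw_p <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  splits <- utils::combn(length(vals), n1)
  u_of <- function(ix) sum(rank(vals)[ix]) - n1 * (n1 + 1) / 2
  u_all <- apply(splits, 2, u_of)
  u_min_all <- pmin(u_all, n1 * (length(vals) - n1) - u_all)
  u_obs <- u_of(seq_len(n1))
  u_min_obs <- min(u_obs, n1 * (length(vals) - n1) - u_obs)
  mean(u_min_all <= u_min_obs)
}

# Independent chi-square oracle: the hand formula sum((O-E)^2/E).
hand_chi_square <- function(counts) {
  e <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  sum((counts - e)^2 / e)
}
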