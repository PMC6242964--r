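---
title: "Quantifying dense-core vesicle release and transport with dcvtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dense-core vesicle release and transport with dcvtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcvtrace)
```

## The measurement problem

Neurotrophins such as BDNF are packaged in dense-core vesicles and released
by activity-dependent exocytosis. The standard optical assay fuses the cargo
to pHluorin, a pH-sensitive GFP that is quenched in the acidic vesicle lumen
and lights up when the fusion pore opens and the lumen equilibrates with the
neutral bath. Three experimental readouts built on this reporter are covered
by this package:

1. **Ensemble release at synapses** (1 Hz time-lapse): presynaptic
   terminals are labelled with an FM dye, the reporter is imaged through a
   baseline window, a field-stimulation window, a rest period, an NH4Cl
   perfusion (which alkalinizes every vesicle and so de-quenches the total
   local reporter content), and a washout. The per-punctum release metric
   is the ratio `I1 / (I1 + I2)`, where `I1` is the peak delta-F/F0 during
   stimulation and `I2` the peak during NH4Cl: the fraction of the local
   reporter pool released by stimulation, insensitive to expression
   differences between puncta.
2. **Single-vesicle fusion events** (TIRF, 10 Hz): individual fusion
   transients are detected in delta-F/F0 traces and classified into five
   kinetic patterns by whether decay starts immediately at the peak and
   whether fluorescence returns to baseline by the end of the recording:
   *full-decay*, *decay-plateau*, *decay-plateau-decay*, *plateau-decay*,
   *plateau-decay-plateau*. Rise and decay time constants come from
   single-exponential fits `a (1 - e^(-t/tau)) + c`.
3. **Axonal transport** (10 Hz): GFP-tagged vesicles moving along an axon
   are projected onto a kymograph (time x position along the axon path);
   tracks extracted from the kymograph yield total travel length
   (sum of absolute per-frame displacements), average speed (travel length
   over duration, pauses included), and direction.

Because raw recordings of this kind are rarely deposited, the package pairs
every analysis stage with a synthetic-data generator that produces movies
and traces with complete ground truth, so the full pipeline can be validated
end to end. All validation claims made below are computed by the test suite
(`tests/testthat/`) and the acceptance script (`scripts/acceptance.R`);
nothing is quoted from elsewhere.

## Conventions

* Coordinates are 1-based `(row, col)` pixels, the natural R matrix
  convention. Movies are `(rows, cols, frames)` arrays with physical
  calibration (`pixel_size` in um/px, `frame_interval` in s).
* Protocol windows are half-open frame intervals `[start, end)`. The
  default release protocol is 20 s baseline, 30 s stimulation, 60 s rest,
  120 s NH4Cl, 30 s washout at 1 Hz; the single-vesicle protocol is 5 s
  baseline and 6 s stimulation at 10 Hz within a 30 s recording.
* delta-F/F0 uses `f0` = mean raw intensity over the baseline window; no
  bleach correction is applied.

## The synthetic-data generator

`generate_release_trace()` builds each fusion transient from piecewise
exponential and constant segments with continuous values at the joins:
an exponential rise `a (1 - e^(-t/tau_rise))` truncated at `3 tau_rise`
(95% of the asymptote), followed by the pattern-specific program — decay
`e^(-t/tau_decay)` toward zero, optionally floored at or interrupted by a
plateau at `plateau_level * a`. The rise is truncated at 3 (not more)
time constants because the final e-folds of an exponential are a near-flat
ramp: carrying them further would build a spurious peak plateau into every
waveform and make the taxonomy itself ill-posed. A terminal plateau is
held to the end of the recording; an interior plateau lasts
`plateau_duration` seconds and must end before the recording does (the
generator raises an error otherwise).

Camera noise is the standard EMCCD approximation: Poisson shot noise at
`photon_scale` electrons per intensity unit plus additive Gaussian read
noise, applied on the raw-intensity scale and mapped back to delta-F/F0.
With the default unit baseline, `read_sigma` is directly the delta-F/F0
noise sd. All generators are pure functions of their parameters and the
seed: the same seed reproduces bit-identical output.

Two pharmacological controls are modelled for completeness.
`apply_perturbation(trace, "mes_quench", k)` removes all de-quenched
signal from frame `k` on (a membrane-impermeant acid wash sees only
surface-exposed reporter), and `"bafilomycin"` disables the
re-acidification loss term. Re-acidification is off by default — its rate
constant is `Inf` — so bafilomycin is a no-op unless a finite
`reacidification_tau` was set; with one set, the decay constant of a
release-dominated trace changes by under 2%, which is why the default
keeps the term off.

Release movies (`generate_timelapse_movie()`) render each synapse as an
isotropic Gaussian punctum (sd 2 px, a diffraction-limited-spot proxy)
whose brightness follows a stimulation-locked transient plus an
NH4Cl-locked rise to the punctum's total-expression amplitude; window
responses rise with fixed time constants (5 s stimulation, 10 s NH4Cl,
20 s decay) so the effective window peaks — and therefore the planted
ratio — are known exactly. The synapse-label channel holds static puncta
at the same positions. Transport movies (`generate_transport_movie()`)
move Gaussian spots along a straight axon by a per-frame Markov process:
pause with `pause_probability`, reverse (resampling the run speed from a
truncated normal) with `reversal_probability`, otherwise advance;
positions reflect at the axon ends. Default frame rates are 1 Hz for
release movies and 10 Hz for single-vesicle and transport recordings.

What the generator does **not** emulate: focal drift, photobleaching,
inhomogeneous background, vesicle docking/undocking in and out of the TIRF
field, and curved or branching axons. Passing tests therefore demonstrate
the correctness of the computations, not robustness to every artefact of
real recordings.

## ROI detection and the 2-sigma synaptic call

Candidate puncta are local maxima of the (optionally smoothed,
sigma = 1 px) time-averaged synapse channel above a robust
`median + 4 mad` background threshold, greedily separated by
`min_distance` (default 4 px). Each candidate receives a circular ROI
(default radius 3 px). The synaptic call places two background ROIs of
the same radius at +/- 2.5 radii along the row axis (falling back to the
column axis, then the diagonals, when the image border or another
candidate is in the way), pools their pixel values, and calls the punctum
synaptic when its mean signal exceeds the background mean by more than
two standard deviations of the background pixel values. The sd is the
pixel spread, not the SEM: "two standard deviations of the local
background" is read as a statement about pixel variability. Candidates
whose background ROIs cannot be placed are flagged (`is_synaptic = NA`)
rather than silently called. The call is scale-invariant, and by default
operates on the time average of the synapse channel (a single frame can
be supplied instead).

## Trace metrics and exponential fits

`peak_metrics()` takes window maxima after a running 3-point median
(disable with `median_filter = FALSE`). The choice was measured, not
assumed: the maximum over tens of noisy frames is biased upward by about
two noise standard deviations, which alone pushed worst-case ratio
recovery past 5% on the validation movie, while the 3-point median — on
transients whose time constants (seconds) dwarf the 1 s frame spacing —
changed noiseless recovery by under 0.1% and cut the worst noisy error to
about 2%. Heavier smoothing *would* bias the peaks and is deliberately
not offered. A negative maximum (no response) is floored at zero and
flagged rather than dropped, and a zero denominator flags the ratio
undefined. Fits use Levenberg-Marquardt on
`a (1 - e^(-t/tau)) + c` with time re-zeroed to the segment start; decays
use the same canonical form with `a < 0`, avoiding a second
parameterization. Initialization is deterministic and scale-aware:
`a0` = signed segment span, `tau0` = duration / 3, `c0` = first segment
value. (`c` is the model's value at `t = 0`, so the first value — not the
last — is the consistent starting point.) `tau` is bounded in
`[frame_interval / 2, 10 x duration]`; hitting a bound clears the
`converged` flag, and flat segments are reported as degenerate with
`a = 0` instead of an arbitrary tau.

## Event detection and the five-pattern classifier

Events are excursions above `baseline mean + 4 sd` lasting at least 3
frames (excursions separated by fewer than 3 frames are merged); each
event then extends forward while the trace stays above baseline + 1 sd,
absorbing any excursions it reaches. The extension matters: noise dips
around the detection threshold would otherwise split one slow decay into
fragments and truncate the segment right where the return-to-baseline
decision is made.

Classification works on a lightly smoothed copy of the segment (running
mean over `plateau_min_frames` = 5 frames, 0.5 s at 10 Hz) and scores
every frame from the first one reaching 95% of the smoothed peak `m` as
decay, plateau, or baseline. Three numeric choices deserve explanation:

* **Slope estimation.** Frame-to-frame differences are far too noisy at
  10 Hz, so slopes are the difference of the forward and backward
  `2 x plateau_min_frames`-frame window *medians* over their centre
  separation. Medians keep a window that mostly covers a plateau from
  being dragged by the steep segments flanking it, which matters for
  short plateaus between fast decays.
* **Noise-aware tolerance.** A frame is "flat" when its slope magnitude is
  below `plateau_slope_tol * m` per second (default 0.05) **plus** three
  standard deviations of the slope estimator, computed from the baseline
  noise sd and the window geometry. With noiseless input the allowance
  vanishes and the criterion is exactly the configured tolerance.
* **Two-scale vetting.** A candidate plateau at or above 85% of `m` is a
  hold at the peak; but the coarse slope estimator changes sign across any
  sharp peak and can linger inside the tolerance band for several frames,
  so peak-level candidates must be confirmed at the finer
  `plateau_min_frames` window before they count. Lower plateaus must sit
  clearly above the baseline criterion (1.5 x `baseline_tol * m`;
  the shallow tail of a slow decay is otherwise indistinguishable from a
  shelf) and, when the data are noisy, must be sustained for twice
  `plateau_min_frames` — slope estimates over half a second cannot
  certify a briefer shelf at 5% noise.

The run sequence plus the return flag (trailing half-second mean below
`baseline_tol * m`, default 0.2) assembles the label; anything with extra
plateaus or an inconsistent return flag is reported as `"other"` rather
than forced into the nearest class. A decay slower than roughly
`-0.5 s / log(0.9)` (about 4.7 s at the defaults) is genuinely
indistinguishable from a brief hold within a 0.5 s test window; the
package documents this resolution limit rather than pretending to beat
it. Misclassifications at 5% noise concentrate, as expected, between
full-decay and decay-plateau-decay, which differ only by a brief interior
shelf.

## Kymographs and tracking

`build_kymograph()` samples the user-supplied axon polyline (ordered
soma -> distal, so increasing position is anterograde) at one position bin
per pixel by default and takes the *maximum* over a 3 px transverse width
(a mean would wash out punctate vesicles). Row peaks above a robust
`median + 4 mad` row background are localized to sub-bin precision by
3-point parabolic interpolation and linked frame-to-frame by greedy
nearest-neighbour assignment (ties: smallest jump, then leftmost), with
jumps capped at 5 bins and up to 2 frames of coasting across missed
detections. Crossing trajectories may swap identities at the crossing;
the track count is preserved and the limitation is documented rather than
patched with a motion model. Speeds include pauses (total travel length
over duration), matching the plain meaning of "average speed"; note that
localization jitter inflates travel length slightly for stationary
vesicles, which is why ground-truth comparisons in the tests use movies
with moving vesicles.

## Statistics

Group comparisons use the two-sided Mann-Whitney U test (exact when both
groups have at most 8 tie-free observations, otherwise the normal
approximation with tie correction and no continuity correction) and
Pearson chi-square tests without continuity correction. Per-class
prevalence comparisons build the 2x2 table `[[k_a, n_a - k_a],
[k_b, n_b - k_b]]`; the uncorrected test is the variant that reproduces
published per-class p-values from reconstructed integer counts
(`reconstruct_counts()` inverts printed percentages against group sizes
and warns when the two are inconsistent). No multiple-testing correction
is applied in reports, matching standard practice for these assays; a
Bonferroni column would be trivial to add downstream.

## Problem sizes and determinism

The validation suite uses 20-punctum release movies (64 x 64 px, 260
frames), 500-event populations for classifier accuracy, and about 100
transport tracks over 25 four-vesicle movies — sizes at which the
binomial/recovery tolerances in the acceptance criteria are comfortably
identified while the whole suite stays quick on a laptop. Every random
quantity flows from an explicit seed; identical seeds give bit-identical
movies, traces, and test statistics.

## A worked example

```{r example, eval = FALSE}
sched <- protocol_schedule()
rois <- data.frame(row = c(20, 40), col = c(20, 44),
                   a_stim = c(1, 2), a_nh4cl = c(6, 8))
sim <- generate_timelapse_movie(
  rois, sched,
  noise_model(photon_scale = 2, read_sigma = 2,
              background_level = 20, seed = 5))
det <- detect_synaptic_rois(sim$synapse)
measure_release(sim$reporter, det, sched)
```

See the README for the printed output of this exact call and the
interpretation of each column.
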