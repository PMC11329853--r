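---
title: "Validating skin-strain sensing against optical motion capture: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating skin-strain sensing against optical motion capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtvalidate)
```

## The problem

Fabric skin-strain sensors ("Motion Tape") are kinesiology tape coated with a
piezoresistive graphene-nanosheet film: when the skin under the tape
stretches or compresses, the film's electrical resistance changes. Worn in a
3 x 2 matrix over the lumbar spine, six such tapes promise low-cost,
out-of-lab monitoring of low back movement. Before the signal can be trusted
it must be validated against the reference standard for spine kinematics —
marker-based optical motion capture recorded simultaneously.

`mtvalidate` implements that concurrent-validity analysis as a tested
pipeline, plus a synthetic-data generator that simulates the whole study
(participants, movement protocol, rigid-segment marker motion, and sensor
physics) so every stage can be exercised and verified end to end without
access to laboratory data.

## The sensor model

The piezoresistive response is the gauge-factor law

> dR / R = K * eps

with `R` the baseline resistance, `K` the gauge factor, and `eps` the skin
strain (tension positive, compression negative). The pipeline's strain proxy
is the fractional resistance change `(r(t) - R0) / R0`, with `K` optionally
divided out; because every trial is normalized to [-1, 1] before
cross-correlation, the analysis is invariant to `K` and to the baseline
value.

The simulator's forward model adds the failure modes seen in practice:

* **noise** — additive Gaussian resistance noise per sample (`noise_sd`,
  default 2 ohms on a 2000 ohm baseline);
* **spikes** — sparse outliers (probability `spike_rate = 0.002` per sample,
  magnitude 20 robust-scale units), the artifact the Hampel filter removes;
* **saturation** — the film's response clips beyond `saturation_strain`
  (default 0.25), the mechanism behind failed high-range trials;
* **fatigue** — the baseline rises by `fatigue_drift_per_trial` (default 1%)
  per completed trial, the slow drift seen late in sessions;
* **rebound** — after a compressed tape is released (true strain crossing
  upward through `-rebound_trigger`), an additive transient
  `rebound_amplitude * exp(-dt / rebound_tau_s)` decays away (defaults 0.02
  strain-equivalent, 0.5 s), reproducing the spurious strain rise seen on
  return from extension.

Raw logs are written the way the acquisition software stores them:
hexadecimal resistance counts (1 count = 0.1 ohm) with ISO 8601 timestamps
under a three-line header. `decode_log()` inverts this exactly; the
count-level round trip is tested to be lossless, and with all failure modes
disabled the decoded strain equals the configured strain to within
quantization (relative error below 1e-9 in the tests).

## The kinematic model

Fourteen-plus markers define three rigid segments: upper lumbar (markers
lateral to L1 plus the L3 spinous marker), lower lumbar (lateral to L4 plus
L5), and pelvis (PSIS, ASIS, posterior pelvis, and iliac crest pairs).
Segment frames are right-handed and orthonormal: origin at the lateral-pair
midpoint, mediolateral axis left-to-right, superoinferior axis orthogonalized
against it, posteroanterior axis their cross product. Relative rotations
(upper vs lower, lower vs pelvis) are decomposed with the **Euler XYZ
sequence**: X about the mediolateral axis (flexion/extension), Y about the
superoinferior axis (axial rotation), Z about the posteroanterior axis
(lateral bending). The canonical branch keeps Y in (-90, 90) degrees and
flags gimbal proximity; decompose-recompose round-trips 10^4 random
rotations below 1e-9 in the acceptance tests.

Segment axis conventions vary across laboratories and the study description
leaves them unspecified; any consistent convention preserves
cross-correlation magnitudes (only signs can flip), so the convention above
is fixed and documented, and the three
convention-negative movements (forward flexion, left lateral bend, right
rotation) form the default flip set applied during normalization.

Since the study reports a single upper/lower lumbar angle per movement, the
pipeline selects the Euler component of the movement's primary plane
(`primary_angle_column()`), recording the choice in its outputs.

## The synthetic study

The generator's defaults are the study conditions:

* 10 participants, 179 Hz motion capture, six tapes per participant;
* the movement protocol: three repetitions to end range per side for lateral
  bending (standing) and seated rotation; three repetitions to ~50% of end
  range for extension; two at ~50% plus one at 100% for forward flexion
  (sub-maximal repetitions protect the sensing element);
* end ranges (not stated in the protocol) default to typical healthy-adult
  total lumbar excursions: 50 deg flexion, 30 deg extension, 25 deg lateral
  bend, 30 deg rotation;
* each repetition is a raised-cosine excursion (3 s) separated by 1 s of
  rest, with 1 s lead-in and tail — smooth (C1), zero at the boundaries, and
  with analytically known peaks, which the protocol-fidelity tests exploit;
* the reference angle splits 50/50 between the two lumbar joints
  (configurable `shares`);
* the sensor stream starts 0.5 s after the mocap stream (`stream_offset_s`),
  so timestamp alignment is exercised nontrivially;
* the sensor sampling rate is not reported anywhere; 50 Hz is a plausible
  rate for the Bluetooth link and deliberately differs from 179 Hz so the
  resampling path is always used.

True skin strain for a sensor is `gain(sensor, movement) * angle(t) /
end_range`. The default gain map (peak 0.15 strain) follows the observed
tension/compression pattern: flexion stretches all tapes, extension
compresses them, lateral bending stretches the contralateral and compresses
the ipsilateral side, rotation stretches both upper tapes and the
ipsilateral middle tape; contralateral-middle and lower tapes during
rotation — cells the study found inconsistent across participants — carry
gain 0.

What the generator does **not** emulate: soft-tissue artifact, participant-
to-participant movement-strategy differences (e.g. bilateral tension during
lateral bending), anthropometric variation, and muscle-engagement strain. A
passing end-to-end test therefore shows the pipeline recovers what the
sensors encode under the stated physics — not that real sensors achieve
those coefficients.

## Quality control

Streams are filtered with a Hampel filter (sliding window, half-width 5
samples, threshold 3 robust SDs, i.e. `1.4826 * MAD`; truncated windows at
the edges). Parameters are conventional since none are reported; filtering
runs on resistance before strain derivation — strain is an affine map of
resistance within a trial, so the choice only fixes the units of the
threshold.

The failed-stream rule removes a stream whose trial-mean resistance lies
more than 10 SDs from the mean resistance across participants for the same
movement and sensor. One subtlety forced an interpretation: with inclusive
population statistics and 10 participants, the largest attainable z-score is
`(n-1)/sqrt(n) ~ 2.85`, which would make a 10 SD rule vacuous. The rule is
therefore applied **leave-one-out**: each stream is compared against the
mean/SD of the other streams in its (movement, sensor) group, so a grossly
failed sensor cannot mask itself by inflating the group SD. Groups of one
warn and flag nothing; zero-SD groups flag nothing.

## Alignment, normalization, correlation

Per trial and sensor: both streams are placed on the mocap clock using the
manifest start timestamps and cropped to their overlap; strain is linearly
interpolated onto the kinematic time base (sensor-to-mocap direction, so no
kinematic bandwidth is discarded); strain is shifted to start at zero
(initial value = mean of the first 0.25 s, noise-robust and configurable)
and scaled by its maximum absolute value; the angle is scaled likewise and
negated for flip-set movements. Identically-zero series are flagged
degenerate and excluded rather than normalized.

The validity statistic is the cross-correlation at **zero phase shift**
under coefficient normalization,

> r0 = sum(x * y) / sqrt(sum(x^2) * sum(y^2))

without demeaning — on zero-shifted, direction-positive series this is the
'coefficient' scaling of the standard cross-correlation toolbox output. A
demeaned (Pearson) variant is computed alongside (`r0_demeaned`). Positive
r0 means the tape was in tension as the kinematic angle grew; negative
means compression. Medians and ranges per (movement, sensor) cell across
participants form the validity table, rendered as a green (tension) /
yellow (compression) heatmap with gray for missing cells; missing trials
(QC-flagged plus degenerate) are counted, never imputed.

## Numerical choices and edge cases

* **Baseline R0**: mean of the first 0.5 s of the trial (the protocol's
  lead-in rest), configurable to first-sample.
* **Marker noise**: `marker_noise_mm` is the RMS 3D displacement per marker
  (per-axis SD `mm/sqrt(3)`), the way mocap residuals are usually quoted.
* **Marker gaps**: zero/blank rows are treated as missing (the export
  convention), filled by per-coordinate cubic splines up to a configurable
  gap length; longer gaps are an error naming the marker and span.
* **Low-pass filtering**: off by default (the study's processing mentions
  none). A 4th-order zero-phase Butterworth is available
  (`compute_lumbar_angles(..., lowpass_hz = 6)`). With the 3-marker segment
  definitions and ~4 cm lever arms, 0.5 mm of broadband marker jitter maps
  to ~0.6-0.8 deg RMS angle error — a geometric bound (sigma/lever), which
  is why the noisy-recovery tests enable the conventional 6 Hz cutoff
  (trunk movement lives below ~1 Hz) and then see ~0.15-0.19 deg RMSE.
* **Degenerate inputs**: zero-energy series yield `NA` coefficients;
  all-missing cells keep `NA` summaries; the left/right marker swap is a
  proper 180-degree rotation and intrinsically undetectable, surfacing as
  sign-flipped X/Z angles downstream.
* **Determinism**: datasets are byte-identical for a fixed configuration and
  seed; the generator saves and restores the caller's RNG state.

## Problem sizes used in the tests

Unit tests run a reduced scenario (2-4 participants, 60 Hz mocap, 25 Hz
sensors, 1.5 s repetitions) chosen to exercise every code path quickly; the
acceptance-style tests run the full study scale (10 participants, 179 Hz,
full protocol, 360 streams) for the end-to-end recovery check, 8
participants per rung of the degradation ladders, 10^4 rotations for the
Euler round trip, and 1000-sample series for the filter and correlation
oracles.

## Known limitations

* The generator's movement profiles are stereotyped raised cosines; real
  movement variability (tempo, strategy, bilateral asymmetry) is absent, so
  between-participant spread in the synthetic validity table is optimistic.
* The QC rule is only as good as its population: with very few participants
  the leave-one-out SD is noisy, and single-stream groups cannot be checked.
* Lag profiles are produced (`xcorr_profile()`) but not used for validity;
  the analysis evaluates zero phase shift only.
* C3D marker files are out of scope; the reader handles the TSV export
  dialect defined here.
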