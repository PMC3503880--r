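---
title: "Detecting covert command-following from sensorimotor rhythms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting covert command-following from sensorimotor rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Patients diagnosed as being in a vegetative state produce no overt motor
response to command. Yet a patient who *attempts* to move a hand when asked
may still generate the electrophysiological signature of that attempt:
event-related desynchronization (ERD) and synchronization (ERS) of the mu
(~7–13 Hz) and beta (~13–30 Hz) sensorimotor rhythms over central scalp.
`smrdetect` implements a bedside assessment of this signature from a minimal
four-electrode EEG montage, at two complementary levels:

1. **Average level** — time–frequency power contrasts of attempted-movement
   trials against rest, tested with cluster-based permutation statistics
   that control the multiple comparisons over (frequency, time) cells.
2. **Single-trial level** — cross-validated Gaussian naïve Bayes
   classification of 1-second sliding-window log bandpower features, with a
   familywise max-statistic randomization test over time-points.

A statistically reliable positive at either level indicates that commands
were followed covertly, i.e. that the patient is aware. Because no bedside
recordings of this kind are publicly deposited, the package includes a
first-class synthetic EEG generator with controllable ERD/ERS ground truth;
every stage of the pipeline is validated against it.

## The task and its simulation

The task is auditory: spoken instructions ("try to move your left hand" /
"right hand" / "relax"), 2 s long, followed by 4–7 s of silence (uniform),
in blocks of 36 trials (12 per instruction) pseudorandomized so that no
more than three consecutive instructions repeat; five blocks give a
180-trial, roughly 20-minute session. `generate_schedule()` reproduces this
structure exactly (rejection sampling per block, run constraint checked
across block boundaries).

`simulate_recording()` renders a schedule as continuous 9-channel EEG
(FC3, FCz, FC4, C3, Cz, C4, CP3, CPz, CP4 at 256 Hz) composed of:

* a **1/f^a background** per channel (default exponent a = 1, 5 µV SD),
  optionally with a per-channel "delta boost" below 4 Hz to emulate the
  pathologically lateralized slow activity often seen after severe injury;
* **band-limited oscillators**: one mu (10 Hz, 4 Hz wide, 2 µV RMS) and one
  high-beta (27.5 Hz, 5 Hz wide, 1.5 µV RMS) source per hemisphere,
  projected with graded weights (FC 1.0, C 0.7, CP 0.3) so the rhythms
  survive the bipolar FC−CP derivation;
* **event-locked ERD/ERS**: each effect is a multiplicative amplitude
  envelope (fractional depth, linear ramps, default 0.25 s) applied to the
  oscillators overlapping its band on trials of its condition. Laterality
  follows the convention that attempted movement of one hand produces an
  *ipsilateral* ERS (inhibition of the contralateral hand representation):
  a left-hand effect with `channel_side = "ipsilateral"` modulates the
  left-hemisphere sources;
* **muscle artifacts**: 0.5–1.5 s bursts of 20–100 Hz noise at 5–10× the
  background SD on a random subset of trials (default rate 0.4, mirroring
  the ~43% trial loss of the reference bedside session), annotated as
  ground truth.

The oscillator amplitudes and signal-to-noise ratios are **documented
modelling assumptions**, not estimates of any patient: no real recordings
are available to fit them. The generator also deliberately omits auditory
evoked potentials to the spoken instructions, volume conduction, and ocular
artifacts; a green test on synthetic data therefore establishes that the
*statistical machinery* behaves as specified (type-I control, parameter
recovery at the stated effect size), not that the pipeline's sensitivity on
real patient EEG equals any published figure.

## Preprocessing

Following the reference protocol, the continuous data are downsampled to
100 Hz and band-pass filtered 1–40 Hz with two-way (forward–backward,
zero-phase) least-squares FIR filters — high-pass first, then low-pass.
Design choices the protocol leaves open:

* The stated order is *downsample, then filter*; the resampler is
  anti-aliased in its own right (windowed-sinc polyphase, 25/64 for
  256→100 Hz), so aliasing is controlled under either order. Both orders
  are available (`filter_before_resample`); they agree to well under 1%
  RMS in epoch cores.
* FIR orders follow the common EEGLAB heuristic (3 × rate/cutoff for the
  high-pass; 3 × rate/(0.25 × cutoff), minimum 15, for the low-pass) with
  15% transition bands, least-squares fit on a dense grid.
* Event onsets are remapped by `round(onset × target/original)`, half away
  from zero, for determinism. Onset samples are 0-based (time =
  onset/rate).

Epochs are 6 s, time-locked to instruction onset, with the time axis
relabeled to instruction *offset* (onset −2.0 s, offset 0.0 s, end just
before +4.0 s; exactly 600 samples at 100 Hz, half-open window).

**Artifact rejection.** The original trials were screened by visual
inspection, which is not reproducible. The automated stand-in rejects a
trial if any channel exceeds 150 µV peak-to-peak or if the robust z-score
of its log-variance (median/MAD across trials, per channel) exceeds 5. The
median/MAD form was chosen over a mean/SD z-score because large artifacts
inflate a non-robust spread estimate enough to mask themselves at realistic
artifact rates. The criterion and its parameters are recorded in the
`RejectionReport`. `match_trial_counts()` then optionally subsamples to
fixed per-condition counts (e.g. the 36/33/34 left/right/rest trials of the
reference analysis) so that datasets are comparable.

Only the bipolar channels C3′ = FC3 − CP3 and C4′ = FC4 − CP4 feed the
statistics; the derivation is label-based and exactly cancels any signal
common to all electrodes (including the reference).

## Average-level statistics

`compute_tfr()` uses a fixed 1 s Hann window sliding in 50 ms steps, 1 Hz
bins (1–40 Hz). **Window labeling** is a documented choice: a naive count
of 1 s windows in a 6 s epoch gives 101 positions, but the reference
analysis prints 100 time-points spanning −1000…+3950 ms. We label each
window by its END time and drop the final window (label +4.0 s), giving
exactly 100 cells from −1.0 to +3.95 s; a cell labeled *t* summarizes
[*t* − 1 s, *t*].

`cluster_permutation_test()` follows the standard nonparametric recipe:
pooled-variance independent-samples t per cell; cells with two-tailed
p < .05 clustered by 4-adjacency (±1 frequency bin, ±1 time cell, no
diagonals — the named toolbox's default) separately by sign, with no
cluster-size limits; cluster statistic = sum of member t-values; null
distribution = maximum absolute cluster sum over 1000 random re-partitions
of the trials into groups of the original sizes; Monte Carlo
p = (1 + #{null ≥ |sum|}) / (1 + n_perm), so p is never zero and the test
is valid by construction. The default cluster threshold is .05/4 = .0125
(two comparisons × two channels). Cells with zero variance across all
trials have no defined t and are excluded with a warning. Each channel is
tested separately; no cross-channel clustering.

`welch_spectrum()` mirrors the clinical-style average spectrum: each 6 s
epoch is split into 8 Hamming-windowed sections of length ⌊N/4.5⌋ (133
samples at 100 Hz) with 50% overlap (hop = ⌊133/2⌋ = 66), periodograms
averaged (256-point FFT, one-sided PSD), averaged across trials, reported
in dB. The section arithmetic follows the published description of the
default sectioning ("eight sections, 50% overlap"); with hop 66 the eighth
section ends at sample 595 of 600.

## Single-trial classification

Features are natural-log bandpower in mu (7–13), low-beta (13–19),
mid-beta (19–25) and high-beta (25–30 Hz) on C3′ and C4′ — 8 features per
time-point, 100 time-points, computed with the *same* STFT convention as
the TFR (band sums over 1 Hz bins; shared band edges go to the lower band,
high-beta keeps 30 Hz). The average-level and single-trial analyses
therefore consume the same quantity at different frequency resolutions,
and the high-beta feature equals the log of the TFR band sum exactly.

At each time-point independently, a two-class Gaussian naïve Bayes
classifier (per class/feature sample mean and unbiased SD, priors from
training frequencies) is evaluated under seeded, *stratified* 10-fold
cross-validation — stratification avoids degenerate folds at ~34 trials
per condition; each trial is tested exactly once; accuracy is the mean of
fold accuracies. The timecourse is smoothed with a 500 ms (11-point)
centered moving average whose window shrinks at the edges (a constant
sequence is unchanged; smoothing cannot leave the raw range).

Numerical guards: SDs are floored at 10⁻⁶ × the pooled within-class SD
(plus machine epsilon) so zero-variance features cannot produce degenerate
densities; prediction runs in the log domain; exact posterior ties go to
the **rest** class — the conservative direction for an awareness claim.
The compiled inner loop (Rcpp) reproduces the R-level
`nb_fit()`/`nb_predict()` semantics exactly and is tested against a
pure-R reference implementation and a closed-form two-Gaussian Bayes
oracle.

`familywise_permutation_test()` shuffles the class labels, re-runs the
entire cross-validated procedure (fresh stratified folds per permutation),
and records the best smoothed accuracy over time-points; with the +1
correction, p(t) = (1 + #{null max ≥ smoothed(t)}) / (1 + n_perm).
Recording the maximum jointly controls the familywise error over the 100
time-points. The default threshold is .05/2 = .025 one-tailed, for the two
comparisons (left vs rest, right vs rest). Both comparisons reuse the same
rest trials — the resulting dependence is reported, not corrected, mirroring
the reference protocol. `band_restricted_classification()` re-runs the
identical pipeline on a band subset (e.g. high-beta only), as used post hoc
when a single band carries the significant ERS.

## Orchestration and reproducibility

`run_pipeline()` drives simulate/load → preprocess → spectral statistics →
classification from a single JSON-serializable config with one master
seed, deterministically split into per-stage seeds; reruns are
byte-identical, and `report.md` can be regenerated from the serialized
stage outputs without recomputation. The `inst/cli/smrassess` script
exposes `simulate`, `preprocess`, `spectral`, `classify`, `assess` and
`report` subcommands; exit codes separate config errors (2) from data
errors (3) — statistical non-significance is a finding, not a failure (0).

File formats: a plain-text CSV fixture dialect (bit-exact round trip) and
16-bit EDF (exact to one quantization step), each with a tab-separated
events sidecar. Configs are JSON. A BrainVision reader is deliberately out
of scope in this build (no offline reader dependency is available, and
nothing in the pipeline produces the format to round-trip against).

## Known limitations

* The simulator states a world; it does not estimate a patient. Absolute
  accuracies on synthetic data (often ~65–75% at depth +1.0 ERS) depend
  entirely on the assumed oscillator SNR and must not be read as expected
  clinical sensitivity.
* The automated artifact rule is a stand-in for expert visual inspection,
  tuned to the simulator's burst model.
* The exact window-count convention (100 vs 101) and the original
  visual-inspection criteria cannot be recovered from the published
  description; both choices here are documented above.
* Type-I error control is verified by simulation at Monte Carlo precision
  (200 datasets, 200 permutations), not analytically.
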