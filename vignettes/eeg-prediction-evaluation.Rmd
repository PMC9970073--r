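---
title: "Methods: EEG prediction overlay and seizure-detection evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG prediction overlay and seizure-detection evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edfviz)
```

This vignette is the package's own account of its methods: what each
stage computes, the assumptions behind it, the tunable parameters and
their defaults, and the choices we made where the design was genuinely
open.

## Scope and data model

`edfviz` operates on a single multi-channel scalp EEG recording at a
time, decoded from a 16-bit EDF or continuous EDF+ (EDF+C) file into
physical units via the format's linear scaling. A recording carries its
header metadata, per-channel sample rates, and a list of time-stamped
text annotations. Time is always expressed in seconds, and every
interval in the package — extraction windows, prediction windows,
seizures, detections — is half-open, `[start, end)`, so abutting
intervals never double-count a sample or a window.

Discontinuous EDF+D files are rejected rather than stitched: the
evaluation protocol below assumes one continuous clock, and clinical
monitoring files are typically continuous. BDF (24-bit) is out of scope.

### De-identification

`anonymize_edf()` replaces the patient field with `"X X X X"`, the
recording field with `"Startdate X X X X X"` and the start date with the
fixed sentinel 01.01.2001. The *time of day* is kept: it is useful when
reviewing (sleep/wake context, alignment with nursing notes) and is not
identifying on its own, whereas the date is. Signal data, signal headers
and annotations are never touched, and every field can be overridden
individually (within EDF's 80-character limits). The sentinel values are
this package's documented choice; sites with their own conventions can
pass overrides.

### Writing and quantisation

Writing emits EDF+C. Samples are quantised to the channel's 16-bit
digital range; values outside the declared physical range are clipped
with a warning rather than erroring, because a handful of railed samples
should not abort an export — the warning reports the count so the user
can widen the range and re-export. Annotation onsets are serialised with
up to three decimals (millisecond resolution, matching clinical
annotation practice); round-trips through write/read therefore preserve
annotations exactly and samples to within one quantisation step.
Header text is coerced to US-ASCII as the format requires.

Predictions stored as EDF channels (`"PRED "` labels) use a `[0, 1]`
physical range, so stored scores are quantised to 1/65535; scores on
that grid round-trip exactly.

## Montages

The shipped presets are the referential 10-20 (19 electrodes), an
extended referential 10-10 superset, and the 18-derivation longitudinal
bipolar chain FP1-F7, F7-T3, T3-T5, T5-O1, FP2-F8, F8-T4, T4-T6, T6-O2,
FP1-F3, F3-C3, C3-P3, P3-O1, FP2-F4, F4-C4, C4-P4, P4-O2, FZ-CZ, CZ-PZ —
the standard "double banana" ordering. The presets live as editable text
files under `inst/extdata/montages/` in the same grammar accepted for
custom montages (`NAME` or `NAME = PLUS - MINUS`), because the exact
10-10 inventory varies between labs.

Electrode-to-channel matching is a normalised token comparison: case is
folded and `"EEG "` prefixes and `"-REF"`/`"-LE"`-style reference
decorations are stripped, so montage entry `C3` matches a channel
labelled `EEG C3-REF`. Ambiguity is an error listing the candidates —
never a silent pick — because a wrong trace in a clinical display is
worse than a hard stop.

Hemisphere colouring follows the 10-20 numbering convention (odd
terminal digit left, even right, `z` midline); bipolar derivations
inherit the hemisphere of their plus electrode. Unclassifiable labels
(e.g. `ECG`) get an `"unknown"` sentinel and a neutral colour rather
than an exception, since auxiliary channels are common.

## Filtering, resampling, features

**Filtering** is a Butterworth of order 4 (the filter family and order
are not dictated by the display problem; a fourth-order zero-phase
Butterworth is the common clinical-viewer choice), applied forward and
backward for zero phase — so the effective magnitude response is the
squared Butterworth response, and a 10 Hz tone inside a 1–30 Hz band
passes essentially unattenuated while a 60 Hz tone under a 30 Hz low-pass
loses more than 99% of its amplitude. Odd-reflection padding at both ends
suppresses edge transients; the output always has the input's length.
Cutoffs at or above Nyquist are validation errors. The library filters
whatever interval it is handed (a GUI's filter-only-the-visible-region
behaviour is a latency trick, not a numerical one).

**Resampling** (e.g. an acquisition at 256 Hz brought to the 200 Hz
analysis rate) reduces the rate ratio to a small rational p/q
(denominator ≤ 1000) and applies windowed-sinc interpolation with an
anti-aliasing cutoff at the lower Nyquist. Two implementation details
matter: the input is replicate-padded at the edges, and each output
phase's filter taps are normalised to unit sum, which makes constant
signals resample *exactly* — a property we test, and which a stock
polyphase routine with zero-padded edges does not have.

**Features.** Variance is the unbiased (n−1) sample variance. Line
length is the sum of absolute first differences. Band power sums a
one-sided periodogram of the mean-removed selection over the canonical
bands delta [1,4), theta [4,8), alpha [8,14), beta [14,30), gamma
[30,45) Hz — half-open edges so adjacent bands never share a bin. We use
a single periodogram rather than Welch averaging because the statistics
pane targets short user-selected intervals where segment averaging would
cost all frequency resolution; the periodogram normalisation satisfies
Parseval (total power = variance of the selection), which the tests
check. Below 90 Hz sampling the gamma band truncates at Nyquist with a
warning. The spectrogram is a Hann-windowed STFT magnitude, default 1 s
segments with 50% overlap — a reasonable clinical default; both
parameters are exposed.

## Predictions

A prediction set is a matrix of window-wise outputs: one row for a
subject-level stream or one row per plotted channel. Binary scores live
in [0, 1] (0 = baseline); multiclass outputs are integer ids with 0 the
baseline class. Alignment requires the number of windows to divide the
number of EEG samples exactly, each window then spanning an equal
integer number of samples; anything else is an alignment error rather
than a silent resample, because a misaligned overlay is actively
misleading.

Smoothing averages `k = 20` consecutive windows by default. We use a
*trailing* (causal) moving average with edge shrinkage: it never uses
future windows, so a smoothed detection can only start at or after the
raw detection — the right behaviour when latency is later measured.
Block (non-overlapping) averaging is available via
`method = "block"`. Thresholding uses `score >= threshold`, so ties
count as detections, threshold 0 is all-positive and only a threshold
above the maximum score is all-negative. In the evaluation path
smoothing always precedes thresholding.

External predictors plug in through a deliberately thin adapter: an R
function or a shell command that emits a numeric matrix, validated
exactly like a loaded file. Deep-learning runtimes are consciously *not*
a dependency; the tests use deterministic toy predictors.

## The evaluation protocol

Calibration scans the unique (smoothed) score values plus 1.0 in
ascending order and returns the smallest threshold whose false-positive
time — positive-classified baseline windows times the window length —
stays within the budget, default 2 minutes per hour of baseline time
(per hour of total time is available behind a flag). The smallest
feasible threshold maximises sensitivity subject to the budget. One
degenerate corner exists: if baseline windows score exactly 1.0 and the
budget cannot absorb them, no threshold in [0, 1] is feasible under the
`>=` rule; the function returns 1.0 with a warning rather than inventing
an out-of-range value, since the mask contract restricts thresholds to
[0, 1].

Window-level AUC-ROC is computed by the midrank formula (equivalent to
the all-pairs Mann–Whitney statistic with ties counting one half — the
tests verify the equivalence against a brute-force pair count and
against `pROC`). AUC-PR is average precision with step interpolation,
avoiding the optimistic linear interpolation of trapezoidal PR areas.

Event-level scoring merges supra-threshold windows into detection
intervals (an optional `merge_gap_sec` closes short gaps). A detection
intersecting any annotated seizure is a true positive; event sensitivity
is detected over total seizures; detections intersecting no seizure
contribute their duration to the false-positive time, reported in
minutes per hour of total recording time. Onset latency is measured from
the annotated onset to the start of the earliest intersecting detection
and clamped at zero — we do not award negative latency to detections
that begin early, since "early" detections are usually the smoothing
tail of preceding false positives rather than genuine anticipation;
missed seizures contribute no latency value. One known quirk of the
intersection definition: a single wall-to-wall detection scores
sensitivity 1 with zero false-positive time; the false-positive *budget*
at calibration time is what rules this regime out in practice.

Per-patient aggregation first averages each metric over a patient's
recordings, then reports the across-patient median, inter-quartile range
and 10th/90th percentiles — the usual box-plot statistics for
heterogeneous epilepsy cohorts, where per-recording pooling would let
long recordings dominate.

## Rendering

Traces are stacked in montage order (top to bottom) with hemisphere
colours, prediction shading in light cyan behind the affected channels
(a subject-level mask shades all channels), an annotation "Notes" row,
and an optional dashed onset marker. The drawing routine returns the
list of shaded spans it actually drew, so tests assert on geometry
instead of decoding pixels.

Scalp maps use exact thin-plate-spline interpolation (radial basis
r²·log r plus an affine term, solved as a dense linear system — cheap at
≤ 128 electrodes) on a 64×64 grid masked to the unit head disk. The
interpolant passes through every electrode value and reproduces constant
inputs exactly, both of which are tested. Electrode coordinates ship as
an editable TSV: ring and midline 10-20 anchors at their standard
angles, interior 10-10 electrodes placed by great-circle interpolation
between anchors, all projected azimuthal-equidistantly (Cz at the
origin, the outer 10-20 ring at radius 1). Users with additional
electrodes append rows to the table.

## The synthetic substrate

`synth_recording()` emulates what the pipeline needs from clinical data
and nothing more: per channel, one sinusoid per canonical band (fixed
representative frequencies 2, 6, 10, 20, 40 Hz; independent random
phases) plus white Gaussian noise, and within seizure intervals an
additional 100 µV, 3 Hz oscillation — a spike-wave-like surrogate that
raises delta power and line length the way electrographic seizures do.
Defaults are 19 channels at 200 Hz with band amplitudes
(20, 10, 15, 5, 2) µV and 5 µV noise, an awake posterior-dominant
pattern at realistic scalp amplitudes. Seizures can be restricted to a
channel subset to exercise channel-wise predictions. Annotations
(`"seizure onset"`/`"seizure offset"`) are inserted at interval bounds,
and everything is deterministic under the spec's seed.

`synth_scores()` emulates a window-wise detector of controllable
quality: `score = clip(indicator + N(0, sd), 0, 1)`, with labels marking
exactly the windows whose half-open span intersects a seizure interval.

What the generator does **not** emulate: 1/f background spectra,
artifacts (EMG, eye blinks, electrode pops), seizure evolution in
frequency/amplitude, inter-channel correlation structure, or
non-stationarity. Passing tests on this substrate therefore demonstrate
the *correctness of the pipeline's arithmetic and contracts*, not
clinical detector performance; real-data metrics depend on properties
the surrogate deliberately lacks.

## Problem sizes and tolerances

The test suite and the acceptance script exercise: two-hour score
streams of one-second windows for calibration and pipeline-recovery
checks (100 noise seeds at σ = 0.1, three seizures of 45–90 s); EDF
round trips of a few seconds × a handful of channels at 128–256 Hz;
periodogram oracles on 2–500 s signals. These sizes give stable
statistics (the null-AUC check at 10 000 windows has standard error
≈ 0.006) while keeping the whole suite in single-digit seconds.
Floating-point equalities use testthat's default tolerance; sample
round-trips are asserted to within one 16-bit quantisation step;
scalp-map exactness at electrodes to 1e-6.

## Known limitations

* EDF+D, BDF and header repair of corrupt files are out of scope.
* The calibration threshold is a single global value per stream;
  per-channel thresholds are not implemented.
* Latency clamping at zero means genuinely anticipatory detectors are
  not rewarded; report raw detection starts if that matters.
* The trailing smoother shrinks its window at the stream start, so the
  first `k − 1` smoothed values have higher variance than the rest.
* Rendering targets static PNG export; there is no interactivity.
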