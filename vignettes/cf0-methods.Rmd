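---
title: "Measuring consonantal F0 perturbation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring consonantal F0 perturbation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cf0)
```

## The measurement problem

Consonants locally disturb the fundamental frequency (F0) of adjacent
vowels — the phenomenon variously called CF0, consonantal perturbation, or
microprosody. The effects ride on top of the utterance's intonation
contour, and their most interesting component is brief: excursions of a
few tens of milliseconds at voice onset. Two methodological hazards make
them easy to destroy or fabricate:

1. **Window-based pitch tracking.** An analysis window of 40–100 ms
   averages away an excursion that lives and dies within 40 ms. The only
   faithful estimate at that time scale is cycle-wise: F0 as the
   reciprocal of each glottal period, from pulse marks.
2. **A missing reference.** "Onset F0 is high" means nothing without
   knowing where the intonation contour would have been. Syllables with
   nasal consonants supply that reference: nasals are voiced throughout,
   impose minimal segmental perturbation, and so trace the underlying
   contour. Every perturbation measure here is a difference from the
   nasal baseline *at the same relative position in normalized time, in
   the same intonation*.

The package implements the full chain — extraction, trimming, smoothing,
time normalization, baselining, measurement — and, because corpora of
marked pulses with hand-labeled boundaries are rarely shareable, a
synthetic corpus generator with known ground truth so that every stage is
validated by parameter recovery.

## Cycle-wise extraction

An F0 track has one sample per consecutive pulse pair,
`f0 = 1/(t[i+1] - t[i])`. The sample is timestamped at the **midpoint** of
its generating pulse pair. The convention is not dictated by the
physics — the cycle has no privileged instant — but the midpoint minimizes
group delay against either edge and makes downstream interpolation
symmetric; it is applied consistently in both the extractor and the
synthetic generator (see below).

**Voice breaks.** A silent interval strictly longer than 33 ms is a voice
break (`detect_voice_breaks()`, threshold configurable). The rationale:
normal F0 does not fall below 30 Hz, so an inter-pulse interval of that
length cannot be a vocal cycle. The comparison is strict — an interval of
exactly 33 ms is not a break. The pseudo-sample spanning a break is
retained in the track (so raw tracks always have `n_pulses - 1` samples)
but flagged and excluded from all interpolation, trimming and smoothing.

**Trimming with edge exemption.** Octave-error-like spikes are removed by
a local rule: a sample deviating from the median of its ±2-sample voiced
neighbourhood by more than 3 semitones is replaced by linear interpolation
of non-spike neighbours, iterated to a fixed point (so `trim()` is
idempotent). The threshold and window are an interpretation of spike
pruning as commonly practised in cycle-based prosody tools; both are
exposed in the configuration, and the implementation is validated by its
invariants (idempotence, count/timestamp preservation, spike restoration
against a running-median oracle) rather than by bit-compatibility with any
external script. Crucially, the vocal cycles **adjacent to a voice break
are exempt** from trimming by default: the sharp F0 spikes at voice onset
and offset are genuine, and trimming them away is precisely the
methodological error the measurement chain is designed to avoid. The
`trimmed_all` and `smoothed` processing variants exist to reproduce that
contrast deliberately.

**Triangular smoothing.** `smooth_triangular()` applies a 70-ms (full
width) triangular kernel in the time domain, renormalized at edges, and
never across a voice break — smoothing across silence would fabricate F0
where there is none. Time-domain weighting was chosen over sample-index
weighting because cycle durations vary; the choice is flagged here for
users comparing against index-domain implementations.

## Normalized time and alignment

Each segment (consonant closure, vowel, context) is resampled at 20
evenly spaced points. The grid is **right-closed**: point *k* of a
segment of duration *d* starting at *s* sits at `s + k*d/20`, so the
segment offset is always a grid point and the segment onset belongs to
the previous segment's last point — consistent with the half-open
`[start, end)` interval convention used throughout. One consequence is
resolved in favour of the missing-data rule: a grid point exactly at a
voicing-onset pulse is treated as unvoiced (strictly before the first
cycle), so a fully voiceless closure yields an all-missing closure block,
while a grid point at a voicing-offset pulse takes the final cycle's
value. F0 at interior points is linear interpolation between flanking
cycles; points spanned by a voice break are missing, never interpolated.

Token ensembles can be aligned four ways (`align_ensemble()`): translated
so the vowel onset, syllable onset, or syllable offset lands at zero, or
mapped segment-by-segment onto the common normalized grid
(`syllable_normalized`). Alignment only ever transforms the time axis;
F0 values are untouched. `mean_contour()` averages time and F0 pointwise
with available-case counts, and can recalibrate a condition's mean times
segment-by-segment (affine per segment) onto the nasal mean, so closures
of different durations align at both syllable edges.
`alignment_variance()` quantifies how well an alignment registers
contours across consonant types; with syllable-synchronized underlying
targets the normalized scheme gives the lowest between-type variance,
which is the package's operational justification for measuring in
normalized time.

## The perturbation measures

Against the matching nasal baseline (`baseline_contour()`, linear
interpolation over the nasal mean's normalized grid):

* **closure duration** — vowel onset minus closure onset, in ms,
  disregarding any voicing during closure; only defined when the target
  closure precedes the target vowel.
* **onset F0** — the first non-missing vowel grid point. The choice of
  grid point over first raw cycle keeps the measure on the same
  normalized axis as the baseline it is differenced against.
* **F0 jump** — onset F0 minus the baseline at the same normalized
  position; the sign is preserved.
* **F0 elbow** — the turning point ending the onset excursion, typically
  a few tens of ms into the vowel. No closed-form detector exists in the
  literature this measure comes from, so the package defines one: a
  continuous two-segment linear model fit by exhaustive least-squares
  search over interior grid breakpoints within a 100-ms window after
  voice onset (covering the typical delay of ~41 ± 22 ms at two SDs),
  accepted when the slopes change sign or the two-line fit reduces the
  single-line residual SS by ≥ 30%, then refined to sub-grid precision by
  intersecting the two arm lines (the grid-optimal node is excluded from
  both arms so it cannot tilt the intersection). Absence of an elbow is a
  valid outcome, not an error. All thresholds are configuration.
* **elbow jump** — the contour value at the first grid point at or after
  the breakpoint, minus the baseline there. Using the *observed* grid
  value rather than the fitted one makes the measure annihilate exactly
  under a self-baseline, a property the test suite enforces.
* **offset F0** — the last non-missing vowel grid point (before a coda
  closure, in CVC).
* **five-point time course** — F0 at vowel voice onset, 1/4, 1/2, 3/4 and
  offset, read off the normalized grid.

**Why per-speaker baselines.** Baselines are keyed by
(speaker, intonation, structure) by default. Differencing each token
against its own speaker's nasal contour removes the between-speaker
register spread (which can exceed 100 Hz) from the jump measures, which
is what makes F0 jump dramatically less variable than raw onset F0. A
pooled baseline (`baseline_by = c("intonation", "structure")`) is
available for designs without per-speaker nasals. Averaging is done in
Hz, not semitones, matching how such contours are conventionally
displayed; a semitone pathway can be had by transforming tracks before
analysis.

## The synthetic corpus

`generate_corpus()` emulates a balanced production study: 8 speakers with
base F0 from 110 to 230 Hz, all 8 consonant types, statements and
questions, 5 repetitions per cell. Per-type parameters are centred on the
scales such studies report: closures of ~100–190 ms (voiceless longer
than voiced), onset jumps of ~2–46 Hz (largest for voiceless fricatives),
sustained post-elbow shifts within about ±10 Hz (raising after voiceless,
lowering after some voiced types), elbow delays of 41 ± 22 ms, and
multiplicative log-normal period jitter with a coefficient of variation
of 0.01 — a typical cycle-to-cycle perturbation magnitude for modal
voice.

The underlying intonation is `base_f0 * (1 + A sin²(πu))` with `u` the
segment-proportional position in the syllable: a rise–fall (A = +0.18)
for statements, a fall–rise (A = −0.12) for questions. Any smooth
rise-fall/fall-rise family satisfying the shape constraints would do;
this one is multiplicative (so doubling the base doubles the contour
exactly), syllable-synchronized in normalized time, and continuous across
the closure — the generator's premise being that voice breaks interrupt
phonation, not the underlying laryngeal movement.

The consonantal excursion is injected additively after voice onset: full
magnitude over the first 5% of the vowel (~9 ms, a brief onset plateau),
then a linear decline reaching the sustained shift exactly at the
specified elbow time, after which the sustained shift persists through
the rest of the token (a slowly decaying laryngeal state rather than a
step). The piecewise-linear shape makes the injected jump and elbow time
*well-defined* ground-truth quantities for recovery testing — an
exponential decay, for instance, has no unambiguous elbow for a two-line
detector to find, and would make "recovered the injected time" an
ill-posed claim. CVC tokens instead carry an anticipatory shift ramping
in over the final quarter of the vowel before the coda; CVCV tokens carry
no anticipatory effect across the syllable boundary.

Two discretization details matter and are deliberate:

* **Midpoint integration.** Pulses are synthesized by time-stepping,
  next pulse at `t + p` with `p = 1/f` evaluated at the cycle *midpoint*
  (two fixed-point refinements). Evaluating at the cycle start instead
  would make every synthesized cycle carry the contour value half a
  period (~3 ms) before the timestamp the extractor assigns it — a
  systematic timing bias that would contaminate elbow recovery while
  having nothing to do with the measurement chain under test.
* **Boundary snapping.** The labeled boundary at a closure onset is
  placed on the last glottal pulse before the silence, as a human
  labeler working from a waveform would place it. The ground-truth table
  records the realized closure duration.

What the generator does *not* emulate: partial voicing during voiced
closures (all non-nasal closures are fully silent), segmental effects on
the vowel other than the injected ones, formant structure or any audio,
creak and other phonation anomalies, declination across the carrier, and
focus-dependent scaling. Passing the recovery tests therefore shows that
the measurement chain is correct and unbiased *under the stated model of
the data*; it does not show that real speech satisfies that model.

## Validation sizes and numerical tolerances

The test suite validates extraction against a reciprocal-of-differences
oracle on 1,000 random pulse trains (exact to 1e-12 relative);
self-baseline annihilation on 100 random tokens (exact); onset-jump
recovery at injected magnitudes {0, 10, 20, 40} Hz with 50 tokens each
(mean within 2 Hz, monotone); elbow-time recovery over 200 tokens with
elbows drawn uniform 20–80 ms (MAE under 5 ms; linear contours yield no
elbow in 100/100 cases); sustained shifts of +8 and −6 Hz recovered
within 1.5 Hz; pooled SD(F0 jump) < SD(onset F0) on a corpus with ≥ 40 Hz
speaker spread; strict smoothing attenuation of brief excursions in
100/100 cases; and the alignment-variance ordering above. These problem
sizes were chosen to estimate each quantity stably while keeping the
default suite fast enough to run on every change.

Degenerate inputs are contracts, not surprises: fewer than two pulses
give an empty track; a fully unvoiced vowel gives missing measures; a
missing elbow leaves the elbow fields jointly absent; a baseline cell
without nasal tokens aborts the analysis with the offending cell named.

## Known limitations

* Binary Praat files are not supported (text dialects only, long and
  short).
* The elbow detector assumes at most one turning point within its search
  window; double perturbations would be summarized by the best single
  breakpoint. On smoothly curved (non-linear) monotone contours the
  30% SS-reduction rule can report a knee; for nasal baselines this is
  inert (their elbow jump is not a defined measure) but users probing
  elbows on arbitrary contours should inspect the fit diagnostics the
  detector returns.
* Mixed-effects inference on the measure tables is intentionally out of
  scope; the pipeline emits tidy tables for whatever modeling tool the
  user prefers.
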