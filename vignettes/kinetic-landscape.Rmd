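---
title: "Methods: event-aligned kinetics of division-site proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-aligned kinetics of division-site proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytokinetics)
```

## The measurement problem

Cytokinesis in budding yeast is executed by protein modules — the
actomyosin ring (AMR), vesicle transport and exo-endocytosis, primary and
secondary septum (PS/SS) synthesis, septum maturation, and the
MEN/RAM temporal-coordination pathways — that accumulate at the bud neck
in a strict temporal order. Time-lapse fluorescence microscopy of
GFP-tagged proteins measures, per cell and per frame, the
background-subtracted intensity at the division site. Because cells enter
mitosis asynchronously, single-cell traces are only comparable after
re-timing each cell to a common clock event: the breakage of the anaphase
spindle (a tubulin marker), defined as time 0. On that clock, a protein's
mean accumulation curve has a characteristic *kinetic signature* — its
peak time(s), arrival and departure — which is shared within a functional
module and can be used to predict the module of an uncharacterized
protein by correlation ranking.

This package implements the full chain: a ground-truth synthetic
generator (traces and rendered movies), image quantification, clock
alignment and aggregation, signature extraction, biphasic constriction
fitting, condition comparison, and correlation-based module assignment.

## The synthetic generator

Nothing in this package is fit to image data shipped with it; instead,
the generator produces data with the statistical structure the analysis
assumes, seeded from published summary values, with the ground truth
recorded for every cell. Passing tests therefore demonstrate *parameter
recovery under the generator's assumptions* — per-frame multiplicative
intensity noise, Gaussian cell-to-cell timing jitter, gamma-distributed
constriction parameters, Gaussian-PSF rendering with Poisson/read noise —
not performance on real micrographs, which additionally contain
segmentation errors, bleaching, focus drift and background structure that
the generator deliberately omits (see *Limitations*).

### Accumulation templates

Each protein's ground-truth curve is a baseline plus a sum of asymmetric
Gaussian bumps (distinct rise and fall widths), a deliberately minimal
form in which the peak time is an explicit parameter, sharp spikes
(Hof1's three peaks) and attenuated rises with slow decays (Cyk3) are
both representable, and the curve never falls below its baseline. The
packaged panel (`loadSignaturePanel()`) holds 25 proteins across six
modules. Peak times, arrivals and departures printed in published results
are used verbatim (e.g. Hof1 at −5/−1/+6 min, Chs2 and Inn1 at +2, the
SS enzymes at ~+4 to +5, Cts1 arriving at +5 and peaking at +25, Iqg1
arriving at −40); unprinted values are fixed package decisions flagged
`decision` in the per-field provenance notes (e.g. Kre6 at +10 min,
between SS formation and PS degradation, and Crh1 slightly later at +12).
Amplitudes are always decisions — published intensities are in arbitrary
units.

Two templates are calibrated rather than hand-set:

* **Cdc3 (septin)**: the hourglass-to-double-ring transition costs the
  neck signal 22.6% of its intensity between −6 and −1 min. The two-bump
  septin template was calibrated numerically so that the mean curve
  *after* convolution with the default 1-min timing jitter loses exactly
  22.6% over that window, with a well-defined hourglass peak at −6 and a
  dimmer double-ring bump at +4.
* **Hof1 widths** (0.55/0.55/1.3 min): narrow enough that the −5/−1
  doublet survives jitter convolution as two resolved maxima of the mean
  curve, and the printed primary peak (−1) stays the highest; broader
  spikes would merge in the mean — contradicting the clearly resolved
  three-peak mean curves this panel emulates.

### Noise model and defaults

`simulateTrace()` evaluates
`template(t + delta) * (1 + eps_t)` on the 1-min acquisition grid, with
`delta ~ N(0, jitter_sd)` per cell and `eps_t ~ N(0, noise_cv)` i.i.d.
per frame. Defaults (packaged with the panel): `jitter_sd` = 1 min —
the residual clock error after per-cell alignment, consistent with
breakage detection accurate to about one frame; `noise_cv` = 0.05 —
shot-noise-scale fluctuations appropriate for bright division-site
markers; `n_cells` = 30 per protein and condition — the published study
does not state its per-strain n, and 30 cells is a realistic size for a
per-strain time-lapse experiment. These defaults are study conditions,
not tuning knobs.

### Ring constriction

The AMR diameter is piecewise linear: constant at `d0` until the onset
(−6 min), a slow linear decline, then a fast one, then 0 (ring gone).
Per-cell slow/fast rates and per-phase diameter drops are drawn from
gamma distributions with the printed means and SDs (slow
0.02 ± 0.02 µm/min, fast 0.18 ± 0.05 µm/min; drops 0.10 ± 0.07 and
0.92 ± 0.11 µm); phase durations follow as drop/rate, and
`d0` defaults to the sampled total drop (≈1.02 µm). A gamma sampler is
used because it reproduces the printed mean *and* SD exactly on positive
support: for the slow rate the printed SD equals the mean (cv = 1),
which no zero-truncated normal can attain, and rejection-truncation
would inflate the mean by ~29%. With all SDs set to 0 the trace is fully
deterministic: breakpoint at −1 min, total drop 1.02 µm, 9-fold rate
ratio — the package's exactness checks are built on this case. Additive
diameter measurement noise defaults to 0.02 µm (sub-pixel localization
error of a two-punctum fit).

Note an intentional consequence of honoring the printed moments: the
implied distribution of slow-phase durations (drop/rate) is heavy-tailed
in both directions. Some sampled cells have slow phases shorter than the
1-min frame interval, and some never close their ring within the movie.
The published mean window (−6 to −2 min) times the mean rate would give
0.08 µm, not the printed 0.10 ± 0.07 µm drop — the printed summary
values are not mutually consistent, and this generator privileges the
drop and rate statistics.

### Rendering

`renderMovie()` draws, on a 64×64 px field at 0.1 µm/px (1-min frames,
−45…+45 min, PSF σ = 0.15 µm): the edge-on ring as two 2-D Gaussian
puncta separated by `d(t)` perpendicular to the mother–bud axis, each
punctum normalized so the rendered flux equals the driving trace exactly
(machine precision, hence the 1% conservation check passes trivially);
an optional second marker channel with the same geometry; and a spindle
that elongates from 1.2 to 6 µm through anaphase and splits at the
breakage frame into two shrinking, fading halves. Noise is Poisson photon
noise (gain 50 photons per intensity unit) plus Gaussian read noise
(SD 2 counts). A constriction-asymmetry parameter moves the punctum
midpoint by `a/2 · (d0 − d(t))`, so `a = 0` converges on a fixed center
and `a = 1` keeps one edge fixed.

## Quantification

**ROI intensity.** The measurement box is an axis-aligned rectangle at
the neck (default 1.5 × 1.5 µm); the background is the median of a 2-px
concentric margin ring, and the measurement is the clipped sum of
(pixel − background) over the box. This makes the measurement exactly
invariant to adding a constant to the image and exactly equivariant to
scaling — both asserted in the tests.

**Ring diameter.** The intensity profile along the neck axis (averaged
over a 3-px strip) is fitted with one- and two-Gaussian-plus-constant
models (shared width, multi-start Nelder–Mead over candidate
separations). The two-peak model is accepted only when it lowers the
residual sum of squares by ≥20%; otherwise the frame is flagged below
resolution (treated as diameter 0 downstream). Frames whose profile does
not rise at least 5% of the channel's global maximum above its own
median are flagged "no ring" — without this guard, pure-noise frames
after ring closure yield spurious separations. The estimator is unbiased
to <0.05 µm for separations ≥3 PSF σ.

**Spindle breakage.** Frames are thresholded at half their maximum
(empty frames: below 5% of the movie-wide maximum); connected components
come from `EBImage::bwlabel`. After an elongated spindle (≥1.5 µm) has
persisted for 3 consecutive frames, breakage is the first frame where
the largest component falls below half its running-maximum length, or
≥2 components of ≥25% of that length remain, or none remains (abrupt
disassembly). On the synthetic movies this is exact without noise and
within ±2 frames in ≥95% of noisy runs.

**Constriction symmetry.** The asymmetry index is the midpoint
displacement at the frame of maximal constriction progress, normalized
by half the *realized* diameter decrease up to that frame, clipped to
[0, 1] (classification threshold 0.25). Normalizing by the realized
rather than the initial diameter makes the index insensitive to where
the two-punctum resolution limit (~0.35 µm) truncates the series; an
initial-radius normalization would cap the observable index at ~0.66 of
its true value.

## Alignment and aggregation

`alignTrace()` shifts timestamps by −t0 and linearly interpolates onto
the −45…+45 min grid, never extrapolating; alignment is exactly
invariant to a common shift of timestamps and t0. `aggregateTraces()`
reports the per-gridpoint sample mean and sample SD (denominator n−1)
over observed cells and masks gridpoints with fewer than `nMin = 10`
cells. Normalization (`max1`, `baseline0_max1`) is a separate, explicit
step — curves are averaged in raw arbitrary units — and downstream
correlations are affine-invariant, so the choice does not affect the
similarity analysis (asserted to 1e-10).

## Signatures and the biphasic fit

**Peaks.** The mean curve is smoothed with a centered 3-point moving
average; local maxima with topographic prominence ≥10% of the curve
range and mutual separation ≥3 min are kept (greedy, highest first),
then each peak is refined to the raw-curve argmax within one gridpoint —
so a noiseless on-grid peak is recovered exactly, while detection
remains noise-robust. Arrival/departure are the first/last crossings of
baseline + 15% of (primary peak − baseline), the baseline being the mean
of the first five unmasked gridpoints. All four fractions are arguments.

**Biphasic constriction fit.** Within the constriction window, every
interior gridpoint is a breakpoint candidate; for each, the continuous
two-segment linear least-squares problem with both slopes constrained
non-positive is solved exactly by active-set enumeration on the normal
equations, and the minimum-SSE candidate wins (ties: earliest, which
favors detecting the slow phase). The tests verify equality with an
independently written brute-force oracle to 1e-9 on 100 random
instances. Breakpoints live on the grid by design — 1-min candidates
match the acquisition resolution.

The fit window needs care. Its end is the first frame at or below the
0.05 µm closure floor (about the precision floor of the two-punctum
fit); by default a trace that never reaches the floor is refused
(`requireClosure`), because a ring that does not close within the movie
has no measurable fast phase. Its start (the constriction onset) cannot
be a simple threshold crossing: a 5%-of-d0 band spans half of a typical
slow-phase drop, so thresholding either truncates the slow segment or
drags plateau frames into it, visibly biasing the slow rate and the
percent-fast split. The onset is therefore located by an exact
least-squares changepoint of a continuous flat-plateau-plus-two-segment
decline over the pre-closure trace — this delimits the window only; the
constriction model itself remains strictly two-phase. For ensembles,
`estimateConstrictionOnset()` finds the onset once on the mean diameter
curve (cell noise shrinks by √n; all cells share the onset up to
jitter) and passes it to the per-cell fits, mirroring the common
practice of reading phase windows off the ensemble curve.

**Ensemble summaries.** `summarizeConstriction()` reports means and SDs
of rates, drops and percent-fast (per-cell, then across cells) and the
fold ratio mean(fast)/mean(slow). Two principled exclusions are applied
and counted: non-closing cells (above) and monophasic fits (fitted
slow ≥ fast — no slow phase resolved at this sampling). With the default
generator and n = 30 this pipeline recovers the fast rate within a few
percent and percent-fast within ~2 points of its configured value. The
mean *slow* rate, however, is recovered at ~0.021–0.030 µm/min against
the configured 0.02: cells whose sampled slow phase is shorter than
about two frames contribute fast-contaminated slow slopes, and with
cv = 1 sampling at n = 30 the truth sample mean itself scatters by 18%.
This is a stated resolution limit of the method at 1-min sampling, not a
bug; the corresponding ensemble check in the test suite documents it by
failing at its nominal tolerance.

**Condition comparisons.** `compareConditions()` reports the peak ratio
(raw a.u.), the primary peak-time shift, the rising-rate ratio (maximal
5-min sliding-window regression slope before the primary peak) and the
baseline-subtracted AUC ratio, each as percent of control. In the
generator, `ConditionEffect(rateFactor = ...)` is calibrated numerically
so that the *measured* window slope of the jitter-convolved mean curve
scales by exactly the requested factor — a naive rise-width scaling
distorts the measured ratio because window-averaging affects narrow and
widened rises unequally. Comparisons are made on mean curves (whether
the published per-condition rates were computed per cell or on means is
unstated; mean curves are the package's choice, flagged here).

## Similarity and module assignment

`correlationMatrix()` computes pairwise-complete Pearson correlations of
mean curves over a common window, default −20…+30 min — wide enough for
every panel signature except Iqg1's early arrival tail, and centered on
the cytokinesis window the comparisons emphasize; pairs with <15 joint
gridpoints and zero-variance curves are masked with a warning.
`rankSimilarity()` orders neighbors by descending r, breaking ties by
primary peak-time distance and then lexicographically, so rankings are
fully deterministic. `assignModule()` predicts the module whose members'
mean correlation with the query is maximal and reports the
nearest-peak-time module alongside, flagging disagreement. On default
panels, Kre6's nearest neighbor is Crh1 and Chs2's is Inn1 in
essentially every run (the test requires ≥18/20 seeds).

## Numerical choices and degenerate inputs

Seeds: one top-level seed; per-cell streams derive deterministically
from it by cell index (multiplicative-congruential mixing below 2^31),
so ensembles are reproducible and order-independent, and identical seeds
give bit-identical traces, movies and output files. Degenerate inputs
are refused with named errors rather than propagated: flat curves in
signature extraction, zero control peaks and zero-variance diameters in
comparisons, missing t0 in alignment, rings wider than the field in
rendering, fewer than three resolved-punctum frames in symmetry scoring.
Problem sizes used throughout the tests and the acceptance script —
30 cells per protein, 25-protein panels, 50-seed detection sweeps,
20-seed ranking sweeps, 91-frame 64×64 movies — were chosen as
desk-scale defaults that keep the full suite in the order of a minute.

## Limitations

* The generator does not emulate segmentation error, photobleaching
  (an optional exponential correction exists but is off by default, as
  no correction is described for the emulated experiments), focus
  drift, cross-channel bleed-through, or structured cytoplasmic
  background; recovery results bound what the pipeline can do on real
  data from above.
* Signatures are defined on mean curves, not per-cell traces; per-cell
  peak statistics are out of scope.
* The biphasic model is strictly two-phase; slow phases shorter than
  the frame interval are not resolvable per cell, and the constriction
  summaries document the resulting slow-rate ceiling rather than hiding
  it.
* Ring geometry is 2-D (edge-on puncta); no z-stacks or 3-D PSF.
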