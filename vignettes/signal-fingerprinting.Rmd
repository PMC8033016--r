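---
title: "Quantifying atrial conduction inhomogeneity from unipolar electrograms"
author: "egmprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying atrial conduction inhomogeneity from unipolar electrograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egmprint)
```

## The problem

Inhomogeneous conduction through the atrial wall predisposes to atrial
fibrillation and leaves a footprint in the morphology of unipolar
electrograms (EGMs) recorded during sinus rhythm: where a wavefront slows,
pivots or blocks, the EGM fragments into multiple deflections and loses
amplitude. `egmprint` turns raw multichannel unipolar recordings from a
regular epicardial electrode array (typically 128 or 192 electrodes, 2.0 mm
spacing, 1 kHz sampling, 5 s of sinus rhythm per site) into a quantified,
per-region *signal fingerprint*: the distribution of EGM types, unipolar
voltages, R/S ratios, fractionation durations and the prevalence of
conduction block. Because clinical mapping recordings of this kind are not
publicly available, the package ships a wavefront/EGM forward simulator
that provides ground truth against which every stage of the pipeline is
validated.

## The pipeline, stage by stage

### Beat segmentation

Beats are located on a reference channel as local maxima above half the
peak amplitude, collapsed within a 150 ms refractory period. Each fiducial
opens an analysis window of −100/+200 ms (clipped at the recording bounds
and at midpoints between fiducials, so windows never overlap). A beat whose
preceding cycle length is shorter than 0.75 of the median cycle length is
rejected as premature and contributes nothing downstream. The window
geometry and the premature-beat fraction are conventions of this package;
they comfortably enclose atrial activation at sinus rates and are exposed
in `AnalysisParams()`.

### Noise estimation

The per-channel noise sigma is the median absolute deviation (scaled by
1.4826) of the samples *outside* all beat windows, so beat amplitude does
not inflate it. If no quiescent samples exist the whole trace is used, with
a warning; a constant trace is an error. Downstream gates apply a floor of
0.01 mV to the estimated sigma — on noise-free synthetic data the quiescent
segments underflow to exactly zero and a literal sigma would make any
numerical ripple "significant".

### Deflection detection and local activation time

The detector operates on a band-limited first derivative: a 5-point
quadratic Savitzky–Golay slope at the sampling rate. Candidate deflections
are local minima of this slope below a noise-scaled threshold
(`slopeGateFactor` = 4.5 times the noise sd propagated through the
derivative filter). Candidates closer than 2 ms merge, keeping the steeper
one — a single downstroke must not be counted twice, and 2 ms is below any
physiological double-potential interval. For each surviving candidate the
R-wave amplitude is the local maximum preceding the downstroke and the
S-wave amplitude the local minimum following it, both relative to the
window baseline (median of the window edges; the baseline convention is
ours — unipolar acquisition chains remove DC) and bounded by midpoints to
neighbouring candidates. A deflection is retained only when its
peak-to-peak amplitude reaches `snrFactor` (2.0) times the noise sigma.
The "twice the signal-to-noise" amplitude criterion is applied to *every*
deflection, not only the LAT-defining one; this is the stricter of the two
possible readings and we flag it as a sensitivity-analysis candidate.

The local activation time (LAT) of an electrode-beat is the time of its
steepest negative slope. At 1 kHz this quantizes LATs to integer
milliseconds, which is also why the simultaneity tolerance below defaults
to 0 ms.

Two gate constants deserve comment. The slope gate at 4.5 noise-sd keeps
the false-deflection rate per 300 ms window near 10^-3 (a 3-sd gate lets
white noise through roughly once per window, which would contaminate the
type proportions); the amplitude gate is fixed at 2 sigma by the
definition of the fingerprint. With a clean 5 mV signal the 4.5-sd slope
gate is exceeded by a factor of more than 20, so detection of genuine
deflections is unaffected up to at least SNR 10.

### Classification and derived features

* 1 deflection → SP (single potential); 2 deflections → SDP if their
  interval is **below** 15 ms, LDP at or **above** 15 ms; ≥ 3 deflections →
  FP. The interval boundary is a parameter (`sdpLdpBoundaryMs`); the
  at-boundary case is deliberately long, following the methods convention
  (`interval ≥ 15 ms` is long) rather than the looser abstract wording.
* Fractionation duration (FD) = time from first to last deflection. It is
  stored for every multi-deflection type (SDP, LDP, FP), not only FP, so
  per-type FD distributions can be reported.
* The R/S ratio of an SP maps relative R- and S-wave amplitude onto
  [−1, 1]: with q = R/S, the ratio is 1 − q for q ≤ 1 and 1/q − 1 for
  q > 1; a potential with no R-wave scores +1, no S-wave −1.
* Peak-to-peak voltage of a potential is the largest R extremum plus the
  largest S magnitude across its deflections (the global excursion over
  the beat window); a potential is low-voltage when this is strictly
  below 1.0 mV.

### Activation maps, far-field exclusion and conduction block

Per accepted beat, LATs populate the electrode grid. Spatially extended
plateaus of identical LATs are the signature of far-field potentials
(a remote wavefront projected onto many electrodes at once), so rook-
connected components of ≥ 4 electrodes with pairwise neighbour LAT
differences ≤ 0 ms are excluded before block detection. The tolerance and
the minimum extent are declared conventions of this package: 0 ms is
meaningful because LATs are integer milliseconds at 1 kHz, and a minimum
area of 4 prevents genuinely near-simultaneous local conduction (two or
three electrodes) from being discarded.

Conduction block is an absolute LAT difference ≥ 12 ms between rook-
adjacent electrodes, both annotated and neither excluded. Adjacency is
4-neighbour because diagonal pairs are √2 farther apart at fixed 2.0 mm
spacing and would correspond to a different effective velocity threshold.
The reported CB percentage is blocked pairs over evaluable pairs — the
only denominator under which the 12 ms pair rule is exact.

### Aggregation

The per-region fingerprint holds medians over pooled electrode-beats
(R/S over SPs only, FD over multi-deflection potentials), type
percentages, the low-voltage percentage, the pooled CB percentage (total
blocked edges over total evaluable pairs of all beats and sites of the
region) and relative frequency distributions with fixed bins: voltage in
0.5 mV bins on [0, 20] mV, R/S in 0.05 bins on [−1, 1], FD in 1 ms bins on
[0, 60] ms, each stacked by type; out-of-range values are clamped into the
edge bins so histogram counts always sum to the population size. The
pooled "entire atrium" entry weights every potential equally rather than
every region equally, matching per-patient medians taken over all EGMs.
Whether per-patient medians should first average per electrode is not
decidable from the reporting conventions we follow; we pool
electrode-beats. Patients are ranked by the pooled LDP+FP percentage
(the fractionation burden).

### Statistics

Spearman correlations (average ranks for ties) carry the conventional
strength categories applied to |rho|: weak < 0.4, moderate 0.4–0.6, strong
> 0.6 — magnitude, because strong *negative* correlations (e.g. voltage
against block) must classify as strong. Regional comparisons use
Kruskal–Wallis plus all pairwise Wilcoxon rank-sum tests at the
Bonferroni-corrected level alpha/C(k,2) (0.05/6 ≈ 0.0083 for four
regions, strict <); exact rank-sum p-values are used when both groups
have n ≤ 10 without ties, the large-sample approximation otherwise. A
Gaussian mode (Shapiro–Wilk-justified ANOVA/t-tests) exists but the
default path is rank-based, since every headline feature is reported as
median [IQR].

## The forward simulator

The simulator provides what patient data cannot: per-electrode ground
truth. It has two layers.

**Activation.** Tissue is an 8-connected lattice at half the electrode
spacing (1 mm), extending 4 mm beyond the array so edge electrodes see
tissue on all sides. The LAT of a node is its geodesic travel time from
the source (Dijkstra; edge weight = distance / conduction velocity). A
*block line* is a linear barrier: lattice edges crossing it incur the
line's delay, so wavefronts either detour around the line's end (a pivot)
or cross it late. Plane waves are seeded on the upstream lattice edge;
focal sources at a single node. On the lattice the travel-time metric is
octile, which is exact along the axes and diagonals and up to ~8% short
elsewhere — immaterial at the 12 ms threshold scale. The default wavefront
direction is 30 degrees off-axis: a perfectly axis-aligned plane wave
activates whole columns at identical integer LATs, which the far-field
exclusion rule would (correctly, but unhelpfully) flag as simultaneous.

**Electrograms.** Every tissue node within 6 mm of an electrode
contributes a Gaussian pulse (width 8 ms) centred on its activation time,
weighted by (1 + d/2 mm)^−3, positive while the front approaches the
electrode (the node activates before the tissue beneath the electrode)
and negative while it recedes. This signed source summation yields the
classic biphasic R–S morphology mid-grid, a solely-S morphology at a
focal origin (nothing ever approaches), R-dominance where a wavefront
leaves the mapped area, and delayed second deflections — double
potentials — on electrodes facing a block line. A symmetric-kernel
summation (each node contributing the same biphasic wavelet) cannot
produce this direction dependence, which is why the signed model was
chosen. The amplitude scale (1.3 mV per source pulse) is calibrated so
interior electrodes show ≈ 5 mV peak-to-peak, the scale of median atrial
unipolar voltages; the truncation radius and decay exponent were chosen
so that fractionation remains spatially specific (electrodes adjacent to
a 20 ms block line are > 3× more fractionated than the rest of the grid)
while a block-free, noise-realistic recording still classifies ≥ 99% SP.
Additive white noise defaults to 0.05 mV (SNR ≈ 100, a clean clinical
channel); all randomness derives from the configuration seed, and
voltages are quantized to float32 so that written bundles round-trip
bit-for-bit.

`generatePatient()` composes one or more sites for each of the four
regions, with a Poisson-distributed number of random block lines per site
(expectation = `blockDensity`) and crossing delays uniform on 12–30 ms,
line lengths 0.6–1.2 of the tissue extent (≥ 1 is a complete line of
block, < 1 leaves a pivot point).

**What the simulator does not emulate.** No reentry or fibrillation, no
endo-epicardial asynchrony, no ionic membrane dynamics, no ventricular
far-field, no electrode contact artefacts. Passing the simulation-based
tests therefore demonstrates that the pipeline recovers the features it
defines from signals whose generating mechanism is known — not that the
thresholds are clinically optimal.

## Problem sizes used in validation

The test-suite uses an 8×8-electrode site (5 beats, 5 s) for end-to-end
checks and a 6×6, 3-beat template for property loops; the simulated
cohort comprises 30 patients × 4 regions × 2 sites at block densities
graded 0–3 lines per site. These sizes keep the full validation suite in
the minutes range while leaving every rule (block threshold, exclusion
extent, SDP/LDP boundary) exercised across its interesting range. At
these sizes the CB–LDP Spearman correlation across the cohort is
reproducibly strong (> 0.6), mirroring the association class reported on
clinical cohorts.

## Numerical conventions and degenerate inputs

* Medians and IQRs interpolate linearly between order statistics (R's
  default quantile type 7), fixed for reproducibility.
* LATs and deflection times are absolute milliseconds from the start of
  the recording; sample i corresponds to (i−1)/fs.
* Ties in candidate merging keep the earlier, steeper deflection; equal
  slopes keep the first.
* An electrode-beat with no retained deflection is a "no potential"
  sentinel: it appears in no type proportion, voltage or LAT statistic.
* Channels flagged bad are excluded end-to-end; their samples may even be
  non-finite without affecting any result.
* Empty regions produce empty fingerprints with counts of zero; a map
  with no evaluable adjacent pair has an undefined (absent) CB
  percentage rather than zero.
* Bundles store voltages as little-endian float32 in millivolts with a
  JSON manifest; writing is deterministic (fixed key order, fixed digit
  formatting), so identical datasets produce byte-identical bundles.

## Known limitations

* The geodesic lattice metric slightly distorts oblique travel times
  (octile anisotropy); conduction-velocity vector fields are out of
  scope.
* The slope-gate and window conventions were designed against the
  simulator's morphology; real recordings with baseline wander beyond
  the 0.5–400 Hz band should enable the optional zero-phase band-pass
  (`applyBandpass`).
* Far-field exclusion keys on exact LAT plateaus; at sampling rates well
  above 1 kHz the tolerance should be raised to the new sample period.
* The statistics layer implements the correlation and regional-comparison
  machinery generically, but no clinical covariate modelling.
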