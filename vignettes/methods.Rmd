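---
title: "Connectivity-driven Kuramoto simulation and EEG complexity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-driven Kuramoto simulation and EEG complexity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kuracomplex)
```

## Overview

`kuracomplex` studies the relationship between EEG functional connectivity
and signal complexity in mild cognitive impairment due to Alzheimer's
disease (MCI-AD). The hypothesis it operationalizes is the network
disconnection model: pathological weakening of cortical coupling should
express itself as a loss of signal complexity. The package chains five
stages:

1. **Alpha-band extraction** from 21-channel resting-state EEG (10-20
   montage, 400 Hz) by Daubechies-wavelet multiresolution decomposition.
2. **Functional connectivity estimation** with the weighted phase lag index
   (WPLI), averaged over subjects into group matrices.
3. **Forward simulation** of a 21-oscillator Kuramoto mean-field model
   coupled through a connectivity matrix, including a **central-region
   lesion** transform (all edges touching T3, C3, Cz, C4, T4 set to 0.1).
4. **Complexity estimation** on real-like and simulated signals with
   Lempel-Ziv complexity (LZC), Higuchi's fractal dimension (HFD) and
   fluctuation-based dispersion entropy (FDispEn), summarized over
   anterior/central/posterior scalp regions.
5. **Group statistics**: Student's t-tests (with Shapiro-Wilk normality
   checks) for subject-level comparisons, Wilcoxon rank-sum tests for
   simulation-run comparisons, Benjamini-Hochberg FDR correction across the
   nine region-by-measure cells of each comparison, and a one-way ANOVA
   between real-like and simulated scores.

Because the clinical recordings that motivated this design are not
redistributable, the package ships a synthetic-data module that emulates
the reported cohort structure (15 controls, 13 patients; group mean
connectivity strengths 0.5575 and 0.4945; patient edges spanning 0.1-0.6),
so that every downstream stage is exercised end to end by the test suite.

## The models

### WPLI

For two band-limited signals the analytic-signal cross-spectrum
$S_{xy}(t) = z_x(t)\,\overline{z_y(t)}$ is formed from the Hilbert
transforms, and

$$\mathrm{WPLI} = \frac{\left|\sum_t |\Im S_{xy}(t)|\,\operatorname{sgn}
\Im S_{xy}(t)\right|}{\sum_t |\Im S_{xy}(t)|}.$$

Weighting the lead/lag signs by the magnitude of the imaginary
cross-spectrum suppresses contributions from near-zero-lag coupling, which
is the signature of volume conduction. Choices worth noting:

* **Instantaneous estimator.** The per-time-point notation is honored with
  the analytic-signal (Hilbert) cross-spectrum rather than a
  Welch-segmented spectral estimate.
* **Numerator absolute value.** Without it the index is sign-indefinite;
  the canonical estimator takes the modulus, keeping values in $[0,1]$.
* **0/0 convention.** Identical (or exactly zero-lag) signals have an
  identically zero imaginary cross-spectrum; the index is defined as 0,
  i.e. "no detectable lagged interaction".
* **Edge trimming.** 5% of samples at each end are discarded before the
  summation to suppress Hilbert edge transients (configurable).

### Kuramoto simulator

The phase dynamics are exactly the printed model,

$$\dot\theta_i = \omega_i + k \sum_j a_{ij} \sin(\theta_j - \theta_i),$$

integrated by forward Euler with step $h = 0.1$ for 15,000 samples, the
first 1,000 discarded, repeated 15 times per group matrix with natural
frequencies redrawn per run from $\mathcal N(10\,\mathrm{Hz},
2\,\mathrm{Hz})$ (clipped at 0.1 Hz) and initial phases uniform on
$[0, 2\pi)$. There is no $1/N$ factor in the default coupling (an option
exists). Synchrony is summarized by the order parameter
$r(t)e^{-i\psi(t)} = N^{-1}\sum_j e^{-i\theta_j(t)}$.

**Time units.** Taken at face value, $f \approx 10$ Hz with $h = 0.1$ s
advances each phase by roughly a full cycle per step: the sampled signal is
aliased. The simulator therefore has two modes:

* `mode = "scaled"` (default) multiplies the angular frequencies by
  `time_unit_scale` (default 0.01), giving ~100 samples per alpha cycle.
  This mode produces well-sampled oscillatory signals and is what the
  synthetic-EEG generator uses (with the scale tied to the sampling rate).
* `mode = "literal"` reproduces the printed arithmetic verbatim
  (`time_unit_scale = 1`). The per-step map is then a near-critical
  circle map: the effective per-step frequency spread (~1.3 rad) and the
  per-step coupling pull (~1 rad at $k=1$ for these matrices) are
  comparable, so coupling strength visibly shapes the irregularity of the
  sampled signal.

This distinction matters for the headline phenomenology. In scaled mode
the default matrices put the network deep in the locked regime
($k\sum_j a_{ij} \approx 10$ versus a frequency spread of ~0.13 rad per
time unit), every channel collapses onto the mean field, and group
differences in complexity vanish. In literal mode the system sits near its
synchronization transition, and the simulated control (mean strength
0.5575), patient (0.4945) and lesioned-control (0.2454) matrices separate:
lower connectivity yields lower Lempel-Ziv complexity, the direction the
disconnection hypothesis predicts. The group-level ensemble simulations in
`run_full_study()` and the directional replication in the test suite
therefore run in literal mode; the acceptance suite checks the ordering
over 10 master seeds.

Euler stability: the sync manifold is attracting at rate
$\lambda \approx k\,\bar a N$ (or $k \bar a$ when normalized), and the
explicit Euler map is stable only while $h\lambda < 2$. Strong-coupling
checks in the tests reduce $h$ accordingly rather than silently relying on
instability artifacts.

**Simulated EEG.** Channel $i$ carries $\sin\theta_i(t)$. The printed
definition sums over all oscillators, which would make the 21 channels
identical and contradict the per-region analyses; the per-channel reading
is used, and the summed signal is available as a diagnostic
(`to_eeg(..., collapse = TRUE)`).

### Lesion model

`induce_lesion()` replaces every edge incident to a chosen channel set
(default: the five central channels) with a constant strength (default
0.1, the smallest non-zero weight of the averaged patient matrix in the
modelled study). On a uniform 0.5 matrix over 21 nodes this lesions
$5 \times 16 + \binom{5}{2} = 90$ of the 210 edges and moves the mean
strength to $(120 \cdot 0.5 + 90 \cdot 0.1)/210 = 0.3286$, an exact anchor
used in the tests. "Edges originating in" the central region is read as
all edges incident to it: the graph is undirected, and an asymmetric
reading would break the symmetry invariant of the matrix type.

### Complexity estimators

* **LZC**: binarize at the median (strictly-greater samples map to 1, so a
  constant signal becomes all-0s), parse with the Lempel-Ziv (1976)
  exhaustive-production scheme in the Kaspar-Schuster scan (the final
  incomplete word counts as one production), and normalize by
  $n/\log_2 n$. The parser is validated against a brute-force
  substring-search implementation of the production definition on every
  binary string up to length 12.
* **HFD**: mean normalized curve lengths $L(k)$ at scales $k = 1..k_{max}$
  and the least-squares slope of $\ln L(k)$ on $\ln(1/k)$. As printed, the
  final formula returns a mean curve length, which is not confined to the
  asserted $[1, 2]$ range of a fractal dimension; the standard Higuchi
  slope is the only self-consistent reading and is what is implemented.
  $k_{max} = 18$ is used for real(-like) EEG and 6 for simulated signals,
  taken as given constants. The estimator is anchored at 1 for straight
  lines and ~2 for white noise.
* **FDispEn**: map amplitudes to $c$ classes (default: normal CDF with the
  signal's own mean and SD, then uniform quantization; a zero-variance
  signal maps to the middle class), embed with dimension $m$ and delay
  $d$, reduce each embedded vector to its $m-1$ successive differences,
  and take the Shannon entropy (natural log) of the pattern distribution;
  $(2c-1)^{m-1}$ patterns are possible, so with the default $m = c = 3$
  the entropy is bounded by $\ln 25 \approx 3.219$. (With $c = 3$ classes
  the extreme difference pairs $(\pm2, \pm2)$ cannot be realized inside a
  single vector, so the bound is not attained by any signal; it remains
  the correct normalization constant.) Unnormalized entropy is the
  default output; normalization is a flag.

All three estimators are invariant under positive affine transforms of the
input, which the tests assert exactly (LZC, FDispEn) or to $10^{-9}$
(HFD).

### Regions

Anterior = {Fp1, Fp2, F7, F3, Fz, F4, F8}, central = {T3, C3, Cz, C4, T4},
posterior = {T5, P3, Pz, P4, T6, O1, O2}. The montage also carries the
anterior temporal electrodes T1 and T2, which belong to none of the three
published clusters; they are tagged `"unassigned"`, contribute to
connectivity estimation and simulation (the model has 21 nodes), but are
excluded from regional complexity means.

## The synthetic-data generator

The generator emulates exactly the statistical structure the analysis
assumes, no more:

* **Group matrices**: i.i.d. uniform edges on the configured range,
  recentered by iterative shift-and-clip (at most 100 iterations) until
  the off-diagonal mean is within $5\times10^{-4}$ of the target. The
  procedure is monotone (preserves edge ranking) and respects the range
  exactly. Control target 0.5575 on $[0.1, 0.95]$ (the control range is
  not reported; the upper bound is a documented choice), patient 0.4945 on
  $[0.1, 0.6]$.
* **Between-subject heterogeneity**: symmetric truncated-Gaussian jitter
  (SD 0.05) of the group matrix per subject, so group statistics see
  realistic between-unit variance.
* **Signals**: the Kuramoto module itself, run on the subject matrix with
  the time unit tied to the sampling rate (about 40 samples per alpha
  cycle at 400 Hz), plus independent per-channel phase noise (SD 0.1 rad
  per step) and additive broadband measurement noise (SD 0.2 against
  unit-amplitude channels). Closing the loop through the simulator makes
  connectivity-estimation recovery testable without inventing a second
  generative model.
* **Generator regime.** The generative runs use $1/N$-normalized coupling
  at `gen_coupling = 0.5`, which keeps the network subcritical (partially
  synchronized). This is deliberate: in the locked regime every pair is
  coherent with the mean field and the estimated WPLI carries no
  edge-specific information, while subcritically the probability of
  transient pairwise locking grows with the edge weight. Recovery of the
  ground-truth edge ranking is assessed on subject-averaged WPLI matrices
  — averaging over subjects (whose natural frequencies are redrawn)
  cancels the frequency-detuning confound that dominates any single
  recording. The tests check a median Spearman correlation above 0.5
  across 20 cohort seeds, and that recovery never improves as measurement
  noise grows.

What the generator does **not** emulate: ocular/muscle artifacts, volume
conduction and field spread, 1/f broadband background, nonstationary
drift, or any non-alpha rhythm. Passing tests therefore demonstrate
internal consistency of the pipeline under the stated generative
assumptions, not performance on clinical recordings.

## Preprocessing choices

At 400 Hz the level-5 wavelet detail spans 6.25-12.5 Hz, the closest
single dyadic band to the 8-13 Hz alpha range; extraction reconstructs
that detail by default (`db10`, computed in-package by spectral
factorization of the Daubechies polynomial). The transform is the
maximal-overlap DWT multiresolution detail, applied in the frequency
domain: it is exactly linear, length-preserving and zero-phase, and
boundaries are handled by whole-signal reflection. Because the alpha band
straddles two dyadic levels, `include_adjacent = TRUE` adds the 12.5-25 Hz
detail, and `method = "fir"` substitutes a zero-phase 8-13 Hz FIR
band-pass for users who prefer a non-dyadic band. Tests verify >= 80%
variance retention for a 10 Hz probe and >= 20 dB attenuation at 2, 20 and
40 Hz. Analyses use the full record by default (no epoching); complexity
is computed on the same band as connectivity for the cohort recordings.

## Statistics

Units of analysis are subjects for real(-like) data and simulation runs
for simulated data (15 per group by default). Regional means are computed
per unit first; each comparison tests its nine region-by-measure cells and
applies Benjamini-Hochberg FDR within those nine cells (the reported
scope; configurable). For subject-level data, Shapiro-Wilk p-values are
recorded per group and cells failing normality are flagged while still
receiving the t-test, mirroring the modelled analysis; a
`strict_normality` switch reroutes flagged cells to the rank-sum test. The
two-group one-way ANOVA satisfies $F = t^2$, which the tests assert to
$10^{-9}$, and the null behavior of the cell tests is calibrated by
simulation (type-I error within $[0.03, 0.07]$ at nominal 0.05 over 1,000
replicates).

## Problem sizes in the shipped tests

The defaults are the study conditions: 5-minute recordings at 400 Hz,
15/13 subjects, 15 runs per ensemble, 15,000-sample simulations. The test
suite exercises the same code paths at reduced sizes chosen for a
single-CPU run: cohort recovery uses 12 subjects x 20 s over 20 seeds, the
null-WPLI check uses the full 5-minute duration (shorter windows cannot
beat-average near-degenerate frequency pairs), the end-to-end study check
uses 4 subjects per group x 4 s x 4 runs, and the directional
phenomenology check runs the full 15-run, 15,000-sample ensembles over 10
master seeds. The acceptance script regenerates its quantities from
scratch at the full simulation defaults.

## Known limitations

* The package replicates the *direction* of the reported group effects on
  synthetic data; it cannot reproduce clinical p-values, since the
  original recordings are not available.
* WPLI on a single short recording is dominated by the frequency-detuning
  draw; edge-level inferences should always use subject- or run-averaged
  matrices.
* The literal-mode simulator is a discrete map, not a faithful ODE
  solution; that is precisely the regime in which the modelled study's
  complexity differentiation arises, and it is labelled as such rather
  than smoothed over.
* The lesion transform is a stylized disconnection model (constant edge
  strength), not a biophysical lesion.
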