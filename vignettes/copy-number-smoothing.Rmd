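---
title: "Kernel-smoothed CNA detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-smoothed CNA detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoothCNA)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical claim that the test
suite or `scripts/acceptance.R` does not itself compute.

## The model

aCGH data are log2 ratios of tumour-versus-diploid hybridization
intensity at probes with known genomic positions. Copy number aberrations
(CNAs) appear as regional shifts of these ratios; tumour heterogeneity
(subclonal events, varying recurrence across samples) attenuates the
shift continuously, which is why this package never discretizes probes
into gain/loss states.

### Smoothing with probe-density correction

All inference happens on a regular grid of *sampling points* (default
spacing 50 kb) rather than at probe positions. The smoothed score at grid
point $x$ is the local-constant (Nadaraya–Watson) kernel regression

$$\mathrm{KC}(x) = \frac{\sum_i k(p_i - x)\, s_i}{\sum_i k(p_i - x)},$$

with $k$ a Gaussian of standard deviation $\sigma = \text{width}/4$,
truncated to exactly zero beyond $|\Delta| > \text{width}$, and the sum
restricted to probes on the same chromosome. Choices embedded here:

* **Kernel shape.** A truncated Gaussian with $\sigma = \text{width}/4$
  makes the user-facing `width` cover about $4\sigma$ (~95% of kernel
  mass), so a 200 kb kernel responds to ~200 kb features; the truncation
  bounds the work per point and makes locality exact (a probe influences
  nothing beyond `width`).
* **Density correction.** Normalizing by the kernel-weighted probe mass is
  the simplest locally weighted regression that corrects unequal probe
  spacing exactly: a constant signal smooths to that constant for *any*
  probe layout. This is a tested invariant, for uniform and log-normal-gap
  spacings alike.
* **Uncovered points.** Where the weight mass falls below $10^{-8}$ (the
  peak single-probe weight is 1), the point lies in a probe desert
  (e.g. a centromere); its KC score is defined as 0 and flagged, avoiding
  0/0. A warning reports when the kernel support is smaller than the
  largest inter-probe gap.
* **Chromosome isolation.** Convolution never crosses a chromosome
  boundary; aberrations do not bleed across chromosomes.

Implementation note: probe positions do not change under permutation, so
the truncated-kernel weights are assembled once as a sparse
points-by-probes matrix and every permutation / sample is a single sparse
matrix-vector product. Cost grows linearly in probes and samples; the
test suite asserts a near-linear empirical timing ratio when probe count
doubles.

## Recurrent mode

Per-probe ratios are summed across samples; the summed signal is split
into a gain channel ($\max(s, 0)$) and a loss channel ($\max(-s, 0)$),
each smoothed separately. Summing rewards both strength and recurrence of
an aberration without requiring it in every sample.

**Null model.** The permutation null shuffles the per-probe *summed*
signal across all probe positions genome-wide (positions fixed, values
permuted), then re-splits and re-smooths. This preserves the marginal
intensity distribution while destroying positional clustering — exactly
the structure the KC score detects. Shuffling the sum rather than each
sample keeps the null comparable across runs and its cost independent of
sample count. Each permutation contributes its genome-wide maximum KC
score per channel.

**Threshold.** The two channels are one testing family: each channel's
threshold is the empirical $1 - \alpha/2$ quantile (type 7) of its own
null maxima. Splitting $\alpha$ keeps thresholds channel-specific — the
gain and loss null distributions differ whenever the data are asymmetric
— while controlling the probability that *any* sampling point in either
channel exceeds its threshold under the null at $\approx \alpha$.
Thresholding each channel at $1-\alpha$ instead would double the
family-wise error (two one-sided tests), which is measurable: the
calibration test in the suite rejects it, and accepts the half-level
split (~0.06–0.08 observed at $\alpha = 0.05$ over 200 null replicates).
Consequently `n_perms` must be at least $2/\alpha$ (40 at the default
$\alpha = 0.05$); requests below that are rejected rather than
extrapolated.

**Regions.** Maximal runs of consecutive grid points above threshold
become regions, extended by half the grid spacing on each side and
clipped to the chromosome; the peak score and point count are recorded.
BED export is 0-based half-open; input positions are 1-based bp.

### Scale space

The analysis is repeated over a strictly increasing series of kernel
widths. Each width gets its own thresholds from the same master seed. For
points inside significant regions the package records a significance
level, $-\log_{10}$ of the empirical p-value of the point's KC score
under that width's null-max distribution (floored at $1/\text{n\_perms}$,
hence bounded by $\log_{10} \text{n\_perms}$); elsewhere the level is 0.
The level feeds the scale-space heatmap; it is a display quantity, not a
per-point test.

"Detected at scale $w$" in the package's own evaluations means the truth
region is recovered by a called region of the right channel with bp
Jaccard ≥ 0.5 at width $w$ — the same criterion used for recovery
elsewhere. Isolated point exceedances are deliberately not counted as
detection of a broad aberration: once many samples are summed, even a
low-amplitude region (half the per-sample noise SD) yields per-point
z-scores of order $0.5\sqrt{n_\text{samples} \cdot m_\text{probes}}$, so
with 20 samples some single point inside a 4 Mb region crosses a
genome-wide-max threshold at almost any width. What distinguishes scales
is whether the *extent* of the region is recovered: the suite shows a
4 Mb gain at half the noise SD is recovered as a region at a 4 Mb width
and never at 100 kb.

## Comparative mode

Each sample's signed ratios (no gain/loss split — direction matters here)
are smoothed individually; all samples share one weight-mass vector. At
each point $i$,

$$\mathrm{SNR}(i) = \frac{\mu^1(i) - \mu^2(i)}{\sigma^{1,2}(i) + f},$$

where $\mu^g(i)$ is the class-$g$ mean of per-sample KC scores,
$\sigma^{1,2}(i)$ the pooled two-class standard deviation (unbiased
within-class variances, $n_1 + n_2 - 2$ df; each class needs ≥ 2
samples), and $f$ the 95th percentile (type-7 quantile) of
$\sigma^{1,2}$ across all points. The denominator is on the SD scale —
$f$ is defined on that scale and must be addable to it — and $f$ keeps
near-zero local variances from inflating the statistic. SNR is invariant
to a common shift or positive rescaling of all profiles and antisymmetric
under label exchange (both tested exactly).

**FDR threshold.** Class labels are permuted preserving group sizes; $f$
is recomputed per permutation so the permuted statistic is exchangeable
with the observed one. For each candidate threshold $t$ (the observed
$|\mathrm{SNR}|$ values),

$$\widehat{\mathrm{FDR}}(t) = \frac{\text{mean}_\pi\, \#\{i : |\mathrm{SNR}_\pi(i)| \ge t\}}{\#\{i : |\mathrm{SNR}_\text{obs}(i)| \ge t\}}$$

clipped to $[0, 1]$ (a plug-in estimator without $\pi_0$ correction; a
$\pi_0$ refinement would only make it less conservative). The reported
threshold is the smallest observed $|\mathrm{SNR}|$ with
$\widehat{\mathrm{FDR}} \le$ target, or $+\infty$ (no calls) if none
qualifies — including the degenerate case where pooled SD and $f$ are
both zero with zero group difference. Control is per sampling point; a
single symmetric threshold on $|\mathrm{SNR}|$ serves both directions,
with `diff_up` / `diff_down` recovered from the sign. Region-level FDR
would need a different null summary and is out of scope.

## The synthetic-data generator

`generate_dataset()` emulates the study conditions every statistical
claim in this package is tested under: probes per chromosome placed
uniformly or with log-normal inter-probe gaps (to exercise the density
correction), i.i.d. Gaussian probe noise, and spiked aberrations with a
log2 `effect` (+0.58 ≈ single-copy gain, −1.0 a strong loss), a
`recurrence` fraction of carriers, and an optional class restriction
(mimicking lineage-specific focal deletions such as immunoglobulin/TCR
VDJ losses, or a class-specific amplicon). Identical seeds give
bit-identical datasets.

What it does *not* emulate: wave/GC artifacts, segmental autocorrelation
of noise, tumour-cell-fraction mixtures, or platform-specific biases.
Passing calibration and recovery tests therefore demonstrates correctness
of the algorithms under clean-noise conditions, not performance on any
particular real platform.

### Study conditions used in the packaged evaluations

Chosen once as representative desk-scale conditions and kept fixed:

* Genome: 2 chromosomes × 50 Mb. Noise SD 0.3 log2 units (typical aCGH).
* FWER calibration: 500 probes/chromosome, 10 samples, 1 Mb kernel,
  100 kb grid, 200 permutations, α = 0.05, 200 replicates; the any-call
  rate must fall in the exact binomial 99% band around 0.05.
* FDR calibration: 5 vs 5 samples, 500 points of unit Gaussian profiles,
  100 permutations, target 0.05, 100 replicates.
* Recurrent recovery: 1 Mb gain, effect 3× noise SD per sample,
  recurrence 0.8, 20 samples, 1 Mb kernel, 50 kb grid.
* Comparative recovery: class-exclusive 1 Mb deletion, effect −1.0,
  10 vs 10 samples, 200 kb kernel, FDR 0.05.
* Scale separation: 4 Mb gain at 0.5× noise SD, 20 samples, widths
  100 kb vs 4 Mb.

Simulation permutation counts (100–200) are smaller than the interactive
defaults (1000 recurrent / 500 comparative), which keeps the full
evaluation around a minute while leaving quantile estimates stable at the
levels used.

## Numerical and interface choices

* Quantiles everywhere are type-7 (R's default linear interpolation).
* Seeds: one master seed; per-permutation (and per-experiment) streams
  are derived deterministically from it, so results are reproducible and
  extending `n_perms` keeps earlier permutations fixed.
* Missing ratios: the default `na_policy = "drop"` removes a probe row
  with any NA, because summation and pooled variances need complete rows;
  `impute_zero` (NA → 0 = diploid) suits sparse platforms. Non-numeric
  garbage always errors.
* Duplicate (chrom, pos) probe rows are averaged — replicate spots are
  common on BAC arrays.
* Region boundaries extend half a grid spacing beyond the outermost
  significant points, clipped to the chromosome; ties at the threshold
  (score exactly equal) are not significant (strict >).
* Plot files are not byte-stable across graphics library versions;
  determinism guarantees (and tests) cover TSV/BED text outputs, plus
  existence of plots.

## Known limitations

* The FWER null assumes exchangeability of summed probe signals, i.e.
  no autocorrelated noise; wavy backgrounds will inflate calls at large
  widths unless removed beforehand.
* Comparative FDR is point-level, not region-level.
* No gene annotation, no per-probe p-values in recurrent mode, and no
  raw-intensity normalization: input must already be normalized log2
  ratios.
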