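# smoothCNA

Kernel-smoothed detection of recurrent and differential DNA copy number
aberrations (CNAs) in multi-sample array-CGH data.

## The problem

Array comparative genomic hybridization (aCGH) measures DNA copy number as
log2 ratios of tumour versus normal diploid hybridization intensity at
probes spread along the genome. Most downstream methods first discretize
each probe into gain / loss / no-change states, which discards signal in
heterogeneous tumour samples where an aberration is carried by only a
subpopulation of cells or a subset of samples. `smoothCNA` works directly
on the continuous log2 ratios:

* **Recurrent (unsupervised) mode** — which regions are gained or lost
  more often / more strongly across a sample set than chance allows?
* **Comparative (supervised) mode** — which regions differ in copy number
  between two user-defined sample classes (e.g. subtype A vs subtype B)?

It is aimed at cancer-genomics analysts working with multi-sample aCGH (or
aCGH-like log-ratio) panels.

## The method

**Smoothing core.** Probe signals are smoothed onto a regular grid of
sampling points by kernel convolution with a Nadaraya–Watson correction
for unequal probe density. At grid point *x*,

    KC(x) = Σ_i k(p_i − x) s_i  /  Σ_i k(p_i − x)

where *s_i* is the probe signal at position *p_i* and *k* is a Gaussian
kernel with σ = width/4, truncated at ±width, restricted to the
chromosome of *x*. The normalization makes a constant signal smooth to
that constant regardless of probe spacing. The kernel *width* selects the
genomic scale: small widths resolve focal (kb–Mb) events, large widths
reveal broad sub-chromosomal trends; repeating the analysis over a series
of widths is the *scale-space* analysis.

**Recurrent mode.** Per-probe log2 ratios are summed across samples, split
into gain (positive part) and loss (negated negative part) channels, and
each channel is smoothed into a KC-score profile. Significance: the summed
signal is permuted across probe positions; each permutation's genome-wide
maximum KC score per channel forms a null distribution, and the channel
threshold is its empirical 1 − α/2 quantile, so the probability that any
point in either channel exceeds its threshold under the null is ≈ α
(family-wise control over the whole analysis). Runs of grid points above
threshold become regions.

**Comparative mode.** Each sample's signed profile is smoothed
individually, and at every sampling point *i* a regularized
signal-to-noise ratio is computed:

    SNR(i) = (μ¹(i) − μ²(i)) / (σ¹²(i) + f)

with class means μ¹, μ², pooled two-class standard deviation σ¹², and
regularization factor *f* = the 95th percentile of the pooled SD across
all points (keeps near-zero variances from dominating). Class labels are
permuted to estimate, for every candidate threshold *t*, the false
discovery rate among points with |SNR| ≥ *t*; the reported threshold is
the smallest |SNR| meeting the user's FDR target. Runs above +thr are
`diff_up` (class 1 higher), below −thr `diff_down`.

A synthetic-data generator with known truth regions (`generate_dataset`,
`score_recovery`) makes the whole pipeline testable end to end.

## Worked example

Simulate 12 samples on a 2-chromosome genome with a recurrent focal gain
(+0.58 ≈ one extra copy, carried by 75% of samples) and a broader, less
recurrent loss, then run the recurrent analysis at a 1 Mb kernel width:

```r
library(smoothCNA)

layout <- genome_layout(c("chr1", "chr2"), c(50e6, 30e6))
sim <- generate_dataset(layout, n_probes_per_chrom = 800, n1 = 12,
  specs = list(
    aberration_spec("chr1", 20e6, 21e6, effect = 0.58, recurrence = 0.75),
    aberration_spec("chr2", 5e6, 9e6, effect = -1.0, recurrence = 0.5)),
  noise_sd = 0.3, seed = 11)

grid <- build_sample_points(layout, spacing = 5e4)
res <- kc_recurrent(sim$pm, grid, kernel_spec(1e6), n_perms = 200,
                    alpha = 0.05, seed = 1)
res
#> Recurrent CNA analysis: kernel width 1e+06 bp, alpha 0.05
#>   thresholds: gain 1.725 / loss 2.088
#>   significant regions: 2
res$regions
#>   chrom start_bp   end_bp channel    score n_points
#> 1  chr1 19850000 21200000    gain 5.342039       27
#> 2  chr2  4950000  9000000    loss 4.097999       81
```

Both spiked events are recovered: the gain channel's peak KC score
(5.34, the summed log2 excess of the carriers) far exceeds its null
threshold (1.73), and the called intervals bracket the true ones.
Checking against the known truth:

```r
score_recovery(res$regions, sim$truth, layout)
#> $jaccard      0.741 0.988   # bp overlap/union per truth region
#> $sensitivity  1             # truth bp covered by calls
#> $specificity  0.9947        # non-truth bp left uncalled
```

`plot_genome_kc(res)` draws the genome-wide profile (gains up, losses
down, dashed threshold lines); `kc_compare()` / `plot_compare()` run the
two-class analysis; `scale_space()` / `plot_scale_space()` sweep kernel
widths. The same analyses are scriptable via the installed CLI
(`inst/cli/smoothcna`): subcommands `recurrent`, `compare`, `scalespace`,
`simulate`; every run writes a JSON run log with all resolved parameters
(including the seed) so outputs are exactly reproducible.

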