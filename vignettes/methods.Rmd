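---
title: "Methods: windowed recombination landscapes and their sequence correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed recombination landscapes and their sequence correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation model

`recmapr` estimates local recombination rate from the Marey map: for a
chromosome with markers ordered by genetic position, each pair of
adjacent markers bounds an interval whose rate is

$$ r = \frac{\Delta\,\mathrm{cM}}{\Delta\,\mathrm{bp} / 10^6}
\quad [\mathrm{cM/Mb}], $$

a finite-difference slope of genetic against physical position. The
genome is tiled into fixed windows (default 100 kb, the scale at which
medium-density maps — roughly 100 kb to 1 Mb marker spacing — carry
signal), and the window rate is the coverage-weighted mean of the
overlapping interval rates,
$r_w = \sum_i o_i r_i \big/ \sum_i o_i$ with $o_i$ the bp overlap.
Windows with no surviving coverage are missing. The assumptions are the
usual Marey-map ones: marker order and anchoring are correct after
screening, and rate is treated as piecewise constant between markers,
so the estimate is a local average whose resolution is set by marker
spacing, not window size.

Three rules guard the estimate:

* **Order-conflict screening.** Within each chromosome (genetic order),
  physical positions must be strictly monotonic — increasing or
  decreasing, since a linkage group may be anchored in reverse
  orientation. The conflicting markers are the complement of a longest
  strictly monotonic subsequence; this is the minimal removal set, an
  objective and reproducible formalization of "screening the map for
  inconsistencies" (the alternative, manual curation, is neither).
  Among equal-length subsequences we prefer keeping markers at smaller
  physical positions, which makes the result deterministic. Both
  intervals flanking a conflicting marker are excluded and **no
  bridging interval** is formed across it: the marker's genetic
  position is unreliable, so any bridge would inherit that
  unreliability.
* **Zero-rate exclusion.** Intervals with exactly zero genetic length
  are discarded *before* window averaging. In real maps these arise
  when missing genotypes make physically close markers appear
  co-segregating; treating them as evidence of zero recombination would
  bias windows downward. A window whose only coverage was zero-rate is
  therefore missing, not 0. (Interval construction itself keeps
  zero-rate intervals, so the exclusion is a landscape-stage policy,
  not a data-loss at ingestion.)
* **Degenerate spans.** Adjacent markers at the same physical position
  give an undefined rate; such intervals are dropped with a warning.

Across maps, each window gets the mean and the sample variance
(denominator $n-1$; the choice matters little at $n = 8$ maps but the
sample form is the unbiased default) of the per-map rates. The mean is
reported from `min_maps` contributing maps (default 1), the variance
from at least 2.

## Coordinates and numerical conventions

Internally everything is 0-based half-open (BED arithmetic); map TSVs
carry 1-based marker positions and are converted on read. Trailing
partial windows are kept and flagged, and all composition features are
normalisable per-bp (`effective_len`) so partial or N-containing
windows remain comparable. Genetic-length bookkeeping is exact to
floating tolerance: on a conflict-free chromosome the interval cM sum
reproduces the map length to 1e-9 (asserted in the tests).

Motif and k-mer occurrences are counted on the forward strand,
overlapping occurrences all counting — plain string-search semantics,
which also preserves the exact count-sum identity (the number of valid
k-mer start positions). An occurrence spanning a window boundary is
credited to the window containing its start, implemented by extending
each window's scan by $k-1$ bases; `N` breaks k-mers and is excluded
from the GC denominator. Reverse complements are deliberately *not*
collapsed: CG and GC, say, are distinct columns, and their ratio is
itself a feature (a methylation indicator).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window_size` | 100 000 | bp | analysis scale matching medium-density maps |
| `min_maps` | 1 (mean), 2 (variance) | maps | variance needs two observations |
| microsatellite `unit_min`–`unit_max` | 1–6 | bp | conventional microsatellite unit range |
| microsatellite `min_length_bp`, `min_copies` | 12, 3 | bp, copies | excludes chance di-/tri-mer runs in random sequence |
| low-complexity `window`, `threshold` | 64, 2 | bp, score | classic DUST frame and cutoff; random sequence scores ≈ 0.008, homopolymers ≈ 31 |
| low-complexity `step` | 32 | bp | half-overlapping frames; dense enough to bound intervals at sub-frame resolution |
| `p_remove` | 0.05 | p-value | stepwise exclusion threshold |
| `n_pcs` | 2 | components | the leading two components carry nearly all k-mer variance (the tables are rank-deficient by construction); more are never hidden — the full spectrum is always written |
| FDR families | k-mers per k; other features together | — | matches the separate reporting of the di-/tri-/tetra-nucleotide screens |

The repeat detectors are deliberately parameterised rather than fixed:
"microsatellite" and "low complexity" have no single canonical
definition, and published annotations come from different tools. Both
can be overridden entirely by supplying precomputed BED intervals.

## Statistical choices

**Correlations** are Pearson by default — consistent with reporting
standardized regression coefficients alongside — with Spearman
available. Pairs are pairwise-complete per feature; constant features
are reported as missing and excluded from their FDR family so they
cannot dilute the Benjamini–Hochberg adjustment. k-mer counts are
converted to per-bp frequencies before correlation and PCA.

**Backward stepwise regression** standardizes response and predictors
(so coefficients are standardized β), drops exactly collinear columns
up front, then repeatedly removes the predictor with the largest
p-value while that p ≥ `p_remove`. Ties remove the later column in the
supplied order, making the elimination path reproducible; the path is
returned as a trace. With `p_remove = 1` the full model is returned,
with `0` the empty model — boundary cases the tests pin down.

**k-mer PCA** decomposes the correlation matrix (columns standardized):
k-mer frequencies live on very different scales (AT-rich vs GC-rich
motifs differ by orders of magnitude in an AT-rich genome), and a
covariance-matrix PCA would simply rank motifs by abundance. Each
component's sign is fixed so its loadings sum positive, resolving the
inherent ± ambiguity of eigenvectors so that PC-vs-rate β signs are
reproducible across runs and backends. The standardized response is
regressed jointly on the leading standardized PC scores.

**Gene features** assign each gene to the window containing its
midpoint — keeping window counts integral and their genome-wide sum
conserved, where overlap-weighting would not. Both mean intron size and
mean exon size are computed (annotation-derived summaries differ in
which they emphasise), with exons taken from the transcript with the
greatest summed exon length.

## What the simulator emulates — and what it does not

`sim_config()` defaults describe the reference scenario used throughout
the tests: 5 chromosomes × 5 Mb, 100 kb windows, a blockwise bimodal
GC landscape (majority of blocks near 0.30 GC, a minority near 0.55,
clamped to [0.1, 0.7] — emulating the strongly bimodal, AT-rich 10–70%
window-GC distribution of the honey bee genome, the archetypal
high-recombination genome this kind of analysis targets), and a linear
rate model

$$ r(w) = \max\{0,\; a + b\,g(w) + \varepsilon_w\},\qquad
a = 5\ \mathrm{cM/Mb},\; b = 30\ \mathrm{cM/Mb\ per\ GC\ unit},\;
\varepsilon_w \sim N(0, 2^2), $$

sampled by four maps of 150 kb mean marker spacing with additive
map-level rate noise of sd 0.5 cM/Mb (clamped at zero — genetic
position must be non-decreasing). These values put the genome-wide mean
rate in the high teens of cM/Mb, the right order for honey bee. Marker
positions follow a Poisson process with anchor markers at chromosome
ends, so with zero noise the map's genetic length equals the rate
integral exactly — an identity the tests assert. Genes are placed
non-overlapping at 30 per Mb with log-normal sizes; microsatellite
tracts (4–12 copies of common 1–4 bp units) are planted at 20 per Mb
and recorded in a truth table.

Bases are sampled i.i.d. within a window given its GC target. That is a
deliberate simplification: it keeps every k-mer expectation an analytic
function of GC, which is what makes the oracle tests sharp. It also
means the simulated composition has a *single* latent factor. In the
resulting di-nucleotide PCA, PC1 is the GC axis, and PC2 — the leading
residual contrast, on which the AT-only motifs load positively —
captures the curvature of the frequency-vs-GC response plus sampling
noise rather than an independent biological factor. The seeded
reference scenario does reproduce the qualitative two-component
structure reported for real genomes (a positive GC-aligned PC1
predictor and a negatively associated AT-loaded PC2), but passing that
check shows the machinery extracts such structure when present — it
does not show that i.i.d. composition is an adequate model of real
dinucleotide correlation. A first-order Markov option with CpG
depletion (`markov_order = 1`) is provided for richer composition
nulls. Likewise absent from the generator: crossover interference,
segregation distortion, genotyping error other than position shuffles,
and any repeat structure beyond the planted tracts.

Order-conflict recovery is exercised by swapping the physical positions
of a configurable fraction of neighbouring markers; each swap is one
inversion, so the minimal-removal screen should flag about one marker
per swap, which the tests check within binomial slack.

## Problem sizes used by the checks

The package's validation runs at sizes chosen to make each property
sharp but cheap: oracle equivalence on 1000 random sequences of 30–80
bp per k; exhaustive conflict-search agreement on 500 random
chromosomes of up to 12 markers (brute force over all removal subsets);
the full reference scenario (25 Mb, 250 windows, 4 maps) for landscape
recovery; 20 replicates of a 2 Mb null genome with permuted responses
for FDR calibration; and two complete pipeline reruns for bitwise
determinism. All are seeded; the seeds are fixed in the tests.

## Known limitations

* Rates are window averages; the method neither interpolates
  (Marey-spline smoothing) nor calls hotspots, and windows beyond the
  terminal markers of a chromosome are missing by construction.
* The conflict screen is order-based only; a marker can be mis-anchored
  yet order-consistent, and such errors pass through.
* Correlations between windows are not modelled: neighbouring windows
  share intervals, so p-values describe per-window association, not
  spatially independent evidence. The FDR calibration check holds
  because the permuted response breaks that dependence with respect to
  the features.
* The stepwise eliminator inherits the usual caveats of stepwise
  selection (post-selection p-values are optimistic); it is provided as
  the field-standard companion to the bivariate screen, not as an
  inference gold standard.
* `read_genes()` assumes a GFF3 with `gene`/`mRNA`/`exon` levels linked
  by `Parent`; exotic annotation layouts need pre-flattening.
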