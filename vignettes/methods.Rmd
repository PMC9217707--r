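---
title: "Permutation DEG testing and regulator-target nomination: methods"
author: "permdeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation DEG testing and regulator-target nomination: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permdeg)
```

## The model and its assumptions

The package analyzes a paired perturbation design: primary cells from a
small number of subjects (three, in the study design this mirrors) are
each subjected to four conditions — regulator overexpression (OE), its
vector control, regulator knockdown (KD), and its siRNA control. For
each gene and subject the two perturbation ratios are

$$\mathrm{OE\_ratio} = \frac{x_{OE} + \varepsilon}{x_{OEctl} + \varepsilon},
\qquad
\mathrm{KD\_ratio} = \frac{x_{KD} + \varepsilon}{x_{KDctl} + \varepsilon},$$

and the per-subject contrast is
$d_s = \log_2 \mathrm{OE\_ratio} - \log_2 \mathrm{KD\_ratio}$. A gene
the regulator induces has $d_s > 0$ in every subject (up under OE, down
under KD); a gene it suppresses has $d_s < 0$. The test statistics are
the paired t across subjects, $T = \bar d / (s_d/\sqrt{n})$, and the
mean contrast $\overline{d}$ reported as the log2 fold change.

Two assumptions matter. First, expression values are treated as
continuous and roughly log-normal — appropriate for FPKM-like RNA-seq
summaries and normalized array intensities, not for raw counts (no
dispersion modeling is attempted; count-based designs belong in DESeq2
or edgeR). Second, with only three subjects a parametric t reference
distribution would be fragile, so inference is purely permutation-based.

### Empirical nulls and the dual p-values

Null distributions for $T$ and $\log_2 FC$ are built by randomly
relabeling samples and recomputing both statistics for every gene, B
times (default 1000). All $B \times G$ null values are pooled into a
single null per statistic: a per-gene null from three subjects is far
too small to resolve tail probabilities, and pooling across genes is
what makes the resulting p-values "adjusted" in the sense of borrowing
strength genome-wide. The price is an exchangeability assumption across
genes (shared null shape), which the log-scale contrast makes
reasonable: $d_s$ is baseline-free, so under the null its distribution
differs across genes only through noise scale.

Empirical p-values are two-sided via absolute values (both induced and
suppressed genes are of interest) with the plus-one correction,
$p = (1 + \#\{|v| \ge |obs|\})/(1 + N)$, which counts the observed
labeling as one permutation and keeps $p > 0$. A gene is a DEG when
both $P_t \le 0.05$ and $P_f \le 0.10$ (inclusive); the dual threshold
requires both statistical stability (T) and effect magnitude (log2FC).
No further multiple-testing correction is layered on top: the pooled
empirical p-values are thresholded directly.

### Permutation scheme

For the paired design the four condition labels are permuted
independently *within each subject*, preserving the subject blocking
that the observed statistic exploits; an `across_samples` scheme
(shuffling all samples jointly) is available behind a flag for
sensitivity analysis. For unpaired case/control designs the group
labels are shuffled across all samples.

The permutation stream is deterministic given the seed, and distinct
relabelings are indexed and sampled *without replacement* while any
remain (mixed-radix indexing over per-subject role permutations; subset
unranking for the unpaired scheme). Consequences worth knowing:

* when `B` equals the number of distinct relabelings, the "Monte-Carlo"
  null is exactly the exhaustive enumeration (the test suite checks this
  against an independent brute-force oracle on a 2-subject design);
* when `B` exceeds it (e.g., B = 1000 on a 3v3 unpaired design with
  only $\binom{6}{3} = 20$ label splits), every distinct relabeling is
  used once and the remainder are drawn with replacement, with a
  warning — duplicates are permitted rather than silently shrinking B;
* spaces larger than $2^{31}$ fall back to independent random draws.

### Degenerate and low-expressed genes

Genes whose contrast $d$ has zero variance across subjects get
$T = 0$ when $d \equiv 0$ and $T = \pm\infty$ otherwise; the latter are
flagged `degenerate`, and their $P_t$ falls back to the log2FC null
(with a warning) rather than reporting an infinite statistic as
maximally significant. The same convention applies inside null
construction so enumeration oracles match as multisets. In practice
degenerate genes arise at the extreme ranks after quantile
normalization, where a gene can receive the identical rank-mean in
every sample. Genes below the pseudocount in *every* design sample are
dropped before testing (logged), since their ratios would be pure
pseudocount artifacts.

The observed statistics and the permuted statistics are computed by the
same floating-point operation sequence, so the identity relabeling
reproduces the observed value bit for bit and ties in the p-value count
resolve consistently. Exact-arithmetic symmetries (e.g., swapping
OE↔control negates every $T$ and leaves p-values unchanged) hold only
up to floating-point resolution of permutation ties at the observed
boundary; the tests document this with an explicit small slack.

## Quantile normalization

`quantile_normalize()` forces every sample onto the distribution of
rank-wise means: sort each column, average across columns at each rank,
map each value back through its column's ranks. It is applied to
linear-scale values before any ratio or log transform. Tied values
within a column all receive the mean of the rank-means over the tied
span — this keeps column sums (hence the grand mean) exactly invariant
and the map idempotent, which the interpolation used by some library
implementations does not guarantee for tie spans longer than two. The
implementation is cross-checked in the tests against
`limma::normalizeQuantiles` on tie-free matrices and against a
brute-force sort-average-map oracle.

## Integration and the direction-consistency rule

DEG sets from the regulator perturbation and from (typically two)
senescence datasets are intersected; `venn_counts()` reports all seven
membership regions. The consistency filter encodes one biological
premise: the regulator itself is *reduced* in the senescent condition.
A gene genuinely driven by the regulator should therefore move opposite
to its regulator-induced direction when the regulator falls: induced
genes down in senescence, suppressed genes up. Candidates must satisfy
this in **every** senescence dataset present; failures are excluded
with a machine-readable reason naming the first offending dataset. The
filter is a direction check only — the subjective between-subject
manual-inspection step of the original workflow is deliberately *not*
automated as a decision; instead `concordance_report()` annotates each
DEG with its per-subject contrast signs so a user can perform that
inspection, without any gene being silently removed.

## qPCR fold changes

`fold_change_ddct()` implements relative quantification:
$\Delta Ct = Ct_{target} - Ct_{reference}$ per sample (reference gene
default 36B4), $\Delta\Delta Ct$ as the difference of group means, fold
change $2^{-\Delta\Delta Ct}$. Group-mean ΔCt (rather than per-pair
differences) is used because treated and control samples are not
paired; per-replicate fold changes against the control mean are also
returned so a standard error can be reported. Amplification efficiency
is fixed at 2 — the method's defining assumption — with no
standard-curve correction.

## The synthetic-data generator

`generate_study()` emulates the statistical structure of the
three-dataset study: a paired 3-subject perturbation experiment and two
unpaired 3v3 senescence datasets. Log2 expression is
`baseline(gene) + subject_effect + condition_effect + N(0, σ)`,
exponentiated to the linear scale. Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 2000 | large enough for stable tail estimates of the pooled null, small enough for second-scale runs |
| `n_subjects` | 3 | the paired design size of the study emulated |
| `effect_size` | 1.0 log2 units | a twofold change, the field's conventional "clear" effect; gives intermediate power at the default noise so power tests are informative rather than saturated |
| `noise_sd` | 0.25 log2 units | within-gene replicate noise typical of expression assays on the log2 scale |
| `subject_sd` | 0.1 | modest donor-to-donor shifts, shared across a subject's four samples — this induces exactly the within-subject correlation the paired statistic exploits |
| baseline | N(5, 2) log2 | spans the dynamic range from near-zero to highly expressed, so pseudocount behavior at low expression is exercised |
| `n_regulator_de` | 200 (10%) | a realistic DE fraction; split evenly induced/suppressed |
| `n_senescence_de` | 300 per dataset | senescence programs are broad; mirrors the larger DEG counts of case/control senescence comparisons |
| shared genes | 5 consistent + 2 inconsistent | the Fig-2-like integration structure: a handful of triple-overlap genes, most but not all direction-consistent |

Planted blocks are disjoint: shared genes are DE in all three datasets
(consistent ones follow the regulator-down rule in both senescence
datasets; inconsistent ones conflict in exactly one, alternating which),
regulator-only and dataset-specific senescence genes fill out the rest.
Ground truth covers every gene.

What the generator does **not** emulate: count-level sampling noise and
mean-variance dependence, library-size or GC artifacts, batch effects,
cross-platform probe/gene mapping noise, and correlated co-regulated
gene modules. Passing tests therefore demonstrate correctness of the
statistical machinery under a clean log-normal world, not robustness to
every artifact of real sequencing or array data.

## Numerical and design choices

* **Pseudocount** ε = 1 expression unit on the linear scale, before
  ratios and logs: bounds ratios for zero-expression genes;
  configurable via `deg_thresholds()`.
* **log2FC definition**: the mean of per-subject log2 ratio contrasts,
  $\overline{d}$ — symmetric in subjects and identical to the quantity
  the paired t tests — rather than the log ratio of subject-mean
  ratios. With three subjects and modest variance the two differ
  little; the symmetric choice keeps $T$ and $\log_2 FC$ estimating the
  same contrast.
* **Unpaired t** uses equal-variance pooling (Student, not Welch),
  matching the classical two-sample method; permutation inference does
  not rely on the variance assumption anyway.
* **Tie-breaks in normalization**: mean of rank-means over the tied
  span (see above).
* **Deterministic ordering** everywhere user-visible: DEG sets,
  intersections and nominations are alphabetical; reports are pure
  functions of (inputs, parameters, seed).
* **Gene identity**: uppercase-trimmed symbols; duplicate rows after
  canonicalization collapse by mean (the common probe-collapse
  convention — how the original microarray probes were summarized is
  not recorded, so this is this package's choice). Missing values are
  rejected, not imputed.
* **Problem sizes in the shipped checks**: the calibration and power
  simulations use 2000 genes with B = 1000 permutations, and the
  enumeration oracle uses a 2-subject, 20-gene instance (576 distinct
  relabelings) — sizes at which every property is sharp yet the whole
  suite runs in seconds.

## Known limitations

* The pooled null assumes cross-gene exchangeability of the null
  statistic; strongly heteroskedastic genes (on the log scale) would
  dilute or sharpen tails. Planted-effect genes do enter the pooled
  null in real analyses, making thresholds slightly conservative.
* With 3 subjects the within-subject permutation group is
  $24^3 = 13{,}824$ relabelings — ample for B = 1000 — but tiny
  unpaired designs (3v3) have only 20 distinct splits, so Pf/Pt
  granularity there comes mostly from pooling across genes.
* Directions are binary (up/down); magnitude consistency across
  datasets is not scored.
* The CLI front-end accepts flags only; there is no config-file layer.
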