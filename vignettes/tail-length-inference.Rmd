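---
title: "Inferring poly(A)-tail-length changes from fractionated RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring poly(A)-tail-length changes from fractionated RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailfrac)
```

## The measurement and its model

Fractionating total RNA by oligo(dT)-capture stringency splits the mRNA pool
into a *short-tail* and a *long-tail* fraction around a cutoff of roughly 50
adenosines. After sequencing both fractions, each gene's relative abundance
in the long versus the short fraction (the l/s ratio) is a monotone proxy
for its poly(A)-tail-length distribution: the longer the tails, the larger
the share of molecules captured at high stringency. Comparing l/s ratios
between genotypes isolates tail-length changes from expression changes,
because an overall abundance shift moves both fractions together.

`tailfrac` models counts per gene with a negative-binomial GLM over the
2 x 2 design of fraction and genotype,

$$\log \mu = \beta_0 + \beta_1\,\text{long} + \beta_2\,\text{mut} +
\beta_3\,\text{long}\times\text{mut} + \log(\text{effective library size}),$$

where $\beta_1$ is the log l/s ratio in the reference genotype, $\beta_2$
the genotype's abundance main effect, and $\beta_3$ the **log ratio of
ratios** — the tail-length-change signal. We report $\beta_3/\ln 2$ as
`log2FC_ratio`; negative values mean shorter tails in the test genotype.
Significance comes from a likelihood-ratio test of $\beta_3 = 0$ against
$\chi^2(1)$, with Benjamini–Hochberg control across genes.

Two assumptions deserve emphasis. First, fraction pairs deriving from the
same starting RNA are treated as independent samples, matching a group-wise
design; the pairing is retained in the metadata only, and a paired model is
future work. Second, the 2 x 2 interaction has no exact-test analogue, so a
GLM + LRT replaces the exact conditional tests familiar from two-group
count analysis. Because of that substitution we treat *calibration* — the
type-I error of the interaction test under a null simulation — as the
quantity to get right, rather than numeric equality with any particular
published gene table.

## What the generator emulates

`simulate_experiment()` reproduces the study design the package targets: two
genotypes x four biological replicates x two fractions (16 libraries), three
spike-in RNAs with defined tails of 30, 75 and 134 A added in equal amounts
to every sample, and a designated subset of genes whose tails shorten in the
mutant.

* **Capture model.** The probability that a molecule with tail length $t$
  elutes in the long fraction is logistic,
  $p(t) = 1/(1+e^{-k(t-c)})$ with cutoff $c = 50$ nt. The source protocol
  only states an approximate 50-nt cutoff, so the steepness is a
  configuration knob; the default $k = 0.15$/nt gives ~95% capture at 70 nt.
* **Within-gene tail distribution.** Gamma with shape 8 (a coefficient of
  variation around 0.35), truncated at 200 nt because tails beyond
  ~150–200 nt are not observed in seedlings; per-gene mean tails are drawn
  uniformly on 30–150 nt. No deadenylation kinetics are published for this
  system, so a steady-state distribution is a modelling choice, and the
  gamma shape is deliberately not exposed as a headline parameter. The mean
  capture probability is integrated by a 201-point trapezoid rule on
  0–200 nt.
* **Genotype effect.** Effect genes have their mutant mean tail shrunk
  multiplicatively, with the shrinkage solved (by `uniroot` on the capture
  odds) so that the implied interaction log2FC equals the configured
  `effect_log2` exactly. The truth table records that odds-ratio quantity —
  not the tail shrinkage — because the pipeline estimates ratios, not
  nucleotide lengths.
* **Counts.** Expected totals are log-normal across genes, split between
  fractions by the capture probability, scaled by per-sample size factors
  drawn log-uniform on [0.7, 1.4] (so TMM has real work to do), and sampled
  negative-binomially with dispersion $\phi = 0.1$ by default (Poisson at
  0). Counts are *absolute-abundance* draws — count $\propto$ amount x
  depth — rather than compositional; per-sample RNA concentrations and
  non-rRNA fractions are emitted such that
  fpkm x concentration x non-rRNA fraction recovers amounts, which is what
  makes the spike-in abundance proxy meaningful.
* **Reproducibility.** One root seed; every gene draws from its own
  deterministic substream (a per-gene seed derived from the root seed and
  the gene index), so changing the number or order of genes never changes
  another gene's counts.
* **Annotations and sequences.** One contig per gene (120 nt upstream, a
  60–300 nt 3' UTR with one or two cleavage sites, 200 nt downstream
  flank), half the genes on the minus strand to exercise strand handling;
  optional planting of a hexamer into the terminal UTR window of effect
  genes; half-lives drawn to hit a target Pearson correlation (default
  −0.21) with the true wild-type mean tail.

What the generator does **not** emulate: read-level artefacts (sequencing
error, mapping bias, rRNA contamination beyond a bookkeeping fraction),
compositional library competition, correlated gene–gene expression, and
batch structure. A green simulation suite therefore demonstrates that the
estimators recover what the model plants, not that real libraries are free
of those artefacts.

## Normalization choices

Genes with 5 or fewer reads in any sample are removed before normalization
(the filter-then-normalize order is a convention choice; the source method
states only the filter rule). Spike-ins are exempt from the filter and are
excluded from the TMM trimmed-mean computation — their fraction allocation
differs from the transcriptome by design, which would distort the trim —
but they are normalized by the resulting factors.

TMM follows the published recipe: reference = sample whose 75th-percentile
count fraction is closest to the mean; M/A values on library-size-scaled
counts excluding zeros; 30%/5% trims on M and A; precision weights from the
delta method; factors rescaled to geometric mean one. All four choices are
exposed as arguments. One practical caveat surfaced by the simulations:
when all planted changes point one way, the effective trim is asymmetric
and a residual compositional bias of a few hundredths of a log2 unit leaks
into every gene's estimate; this is inherent to trimmed-mean normalization
(the edgeR implementation behaves the same on identical data) and shrinks
as the affected fraction falls.

## Dispersion and calibration

Per-gene dispersions are method-of-moments estimates from the squared
residuals of a per-gene Poisson fit (the df correction applies to the
squared-residual term only), floored at zero and shrunk toward a common
dispersion with a prior weight equivalent to 10 residual degrees of
freedom. The common value is the **mean** of the raw estimates: at 12
residual df the raw estimates are strongly right-skewed, so the more
obvious median underestimates a true common $\phi = 0.1$ by roughly 17%,
which in turn inflates the LRT's type-I error beyond its nominal band.
With the mean, the measured type-I error at $p<0.05$ on a 2,000-gene null
simulation ($\phi = 0.1$, mean total 200, four replicates) is ~0.06.

## Statistical power, honestly

With four replicates per genotype and $\phi = 0.1$, the standard deviation
of the interaction estimate is approximately
$\sqrt{\phi + 1/\mu}/\ln 2 \approx 0.47$ log2 units at $\mu \approx 100$
per cell — a planted log2FC of −1 is a ~2$\sigma$ effect. No estimator can
turn that into 80% BH-power (edgeR's own pipeline achieves ~3% on the same
data), and adding depth does not help because $\phi$ dominates. The
package's recovery simulations therefore check that the planted effect is
recovered *unbiasedly* (mean estimate within [−1.15, −0.85]) and report the
measured power as the number it is (a few percent at these conditions).
This is consistent with the biology that motivated the design: detecting
tail-length changes transcriptome-wide is hard, and the original screen
found only on the order of a hundred significant transcripts.

## Group, motif and validation statistics

All rank-based comparisons share one Wilcoxon implementation: exact by
enumeration of rank assignments for 12 or fewer tie-free observations,
otherwise a normal approximation with tie-corrected variance and 0.5
continuity correction. The background of every category/module test is all
*other* tested genes, not all genes. Categories may overlap and are tested
independently; the minimum tested size defaults to 5 (the source is silent;
exposed as an argument). List overlaps use the hypergeometric upper tail,
ranked by overlap count with p as tie-break (the original ranking criterion
is unstated; both are recorded), and a top-q selector keeps
$\lceil q\,m \rceil$ lists — 3% of 600 is exactly 18.

Motif presence in the terminal 100 nt of the 3' UTR (most distal cleavage
site only, one window per gene) is boolean. The published effect-size
phrasing "log2 of mean tail-length changes with vs without" is ill-defined
for signed log fold changes, so two effect sizes are reported: the
difference of group means (primary) and the literal log2 ratio computed on
linearized fold changes (secondary).

For the segregation tables, expected counts are computed unrounded by
default; `table_parity = TRUE` reproduces published p-values that were
calculated from rounded printed expectations (59/119 rather than
59.33/118.67) — recomputation confirms the rounded version is what the
published 1.23501e-16 corresponds to, while the exact weights give 2.1e-16.

## Numerical choices and degenerate inputs

* NB IRLS: at most 50 iterations, relative deviance tolerance 1e-8, linear
  predictor clamped to ±30; non-converged genes are reported with `NA`
  p-values, excluded from the BH denominator, and counted in a warning.
* Internal genome coordinates are 0-based half-open everywhere; GFF3
  converts by −1 on start, BED passes through. Cleavage sites merge by
  union across annotation sources, with the first source authoritative for
  the stop boundary; site collapsing is off by default (`collapse_nt = 0`).
* Distinct cleavage sites within `collapse_nt` keep the more distal site.
* `NA` serializes as `NA` in every TSV; numbers are written with 10
  significant digits, so write-then-read is lossless in practice.
* Ties: sample clustering orders columns lexicographically before
  average-linkage `hclust`, making leaf order deterministic; overlap
  ranking breaks count ties by p-value.
* Constant feature vectors yield `NA` correlations with a warning; empty
  groups, all-zero samples, unpaired fractions, mismatched grids and
  out-of-range p-values raise classed errors (`tailfrac_*_error`).

## Simulation sizes used by the checks

The packaged checks run at sizes chosen to keep the full suite comfortably
reproducible on a single CPU while leaving the statistical conclusions
stable: 2,000 genes for null-calibration runs, 10,000 genes with 500 effect
genes for effect-recovery and the hexamer sweep (500 effect genes in a
small minority keeps trimmed-mean normalization in its validity regime),
500 resampled categories for null uniformity, 200 replicate runs for
planted-category detection, and 5,000 genes for correlation round trips.
The spike-in directionality check uses the full default design with 500
genes, since it concerns only the spike-in rows.

## Known limitations

* Two fractions, two genotypes; no paired or multi-factor designs.
* No absolute tail-length (nucleotide) estimation — only the ratio proxy.
* Dispersion moderation is moment-based with a fixed prior weight, not an
  empirical-Bayes fit; fine for calibration, not tuned for ranking at very
  low counts.
* Trimmed-mean normalization inherits its compositional assumptions; with
  strongly one-sided, widespread changes a small global bias remains.
* The ePAT trace model is a smeared-peak idealization intended for testing
  the trace arithmetic, not an instrument model.
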