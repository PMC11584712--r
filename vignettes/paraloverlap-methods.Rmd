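---
title: "Methods: quantifying target-gene overlap of paralogous transcription factors"
author: "paraloverlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying target-gene overlap of paralogous transcription factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraloverlap)
```

## The scientific question

Paralogous transcription factors that share a DNA-binding motif — the
motivating case is MEIS1 and MEIS2 in human neural stem cells — are commonly
assumed to regulate the same genes. `paraloverlap` asks whether paired
perturbation RNA-seq supports that assumption. The design has six
conditions: each paralog is overexpressed by CRISPR-activation (`TF1-OE`,
`TF2-OE`) and knocked out by CRISPR/Cas9 (`TF1-KO`, `TF2-KO`), and each
CRISPR system has its own non-targeting control (`ctrl-OE`, `ctrl-KO`),
with six replicates per condition.

Three statistical ingredients make up the analysis:

1. a **combined contrast** that adds concordant OE and KO signal while
   cancelling responses to the CRISPR systems themselves;
2. a **constrained bootstrap null** for the overlap (Jaccard index) two
   analyses of the *same* regulator would show, against which the observed
   cross-paralog overlap is tested;
3. **binding-site integration** relating ChIP peaks to the called target
   genes.

## The differential-expression model

Counts are modelled as negative binomial,
$K_{gs} \sim \mathrm{NB}(\mu_{gs},\ \alpha_g)$ with
$\mathrm{Var}(K) = \mu + \alpha\mu^2$ and
$\mu_{gs} = s_s\, q_{g,\mathrm{cond}(s)}$, where $s_s$ is a per-sample size
factor and $q$ a per-condition mean (cell-means coding: one coefficient per
condition, no intercept). The stages are:

* **Count filter.** Genes with fewer than 10 counts summed over all 36
  samples are excluded (inclusive threshold: exactly 10 is kept).
* **Size factors.** Median-of-ratios: per sample, the median over
  all-positive genes of the ratio to the gene's geometric mean. A
  pseudo-reference fallback (counts + 0.5) is available for degenerate
  matrices.
* **Dispersions.** Method-of-moments per gene on normalised counts within
  each condition, pooled across conditions, then shrunk (weight 0.3 by
  default) toward a robustly fitted trend $\alpha(\mu) = a_0 + a_1/\mu$,
  floored at $10^{-8}$. The moment estimator is simple and fast; the trend
  shrinkage stabilises genes whose six-replicate variance estimate is poor.
* **GLM fit.** With cell-means coding and fixed dispersion the NB likelihood
  separates by condition, so each per-gene log-mean solves the 1-D score
  equation $\sum_s (y_s - s_s m)/(1 + \alpha s_s m) = 0$. A Newton iteration
  on $\log m$, vectorised across genes, converges to $10^{-8}$ in a handful
  of steps; this is what makes hundreds of bootstrap re-fits cheap.
  Conditions with all-zero counts get a floored mean (pseudo-count 0.5 over
  the summed size factors) and a near-zero information, i.e. an honestly
  huge variance, rather than a failure.
* **Combined contrast.** For paralog $i$,
  $\widehat{\Delta}_i = (\widehat{OE}_i - \widehat{ctrlOE}) -
  (\widehat{KO}_i - \widehat{ctrlKO})$ in log2 units. Because the covariance
  is diagonal across conditions, $\mathrm{se}^2 = \sum_c c_c^2\,
  \mathrm{Var}(\hat\beta_c)$. A gene that responds only to a CRISPR system
  (identically in targeting and control conditions of that system) has
  expectation zero under this contrast — that is the design's purpose.
  Wald $z = \widehat{\Delta}/\mathrm{se}$ with a two-sided normal reference;
  Benjamini–Hochberg adjustment; DEG thresholds `padj < 0.05` and
  `|log2FC| > 0.58`, both strict, applied to the unshrunken MLE estimate.
  An optional normal-prior posterior-mean shrinkage of the log2FC is
  available (`shrink_lfc = TRUE`) but is deliberately simple; the full
  adaptive-shrinkage machinery used in the original analyses is out of
  scope here, and DEG calling always uses the MLE column.

Where a six-level factor could alternatively be fit as separate per-pair
models, the joint cell-means model with one shared size-factor set is used:
the printed contrast involves four conditions simultaneously, which implies
a joint parameterisation, and pooling all 36 samples improves the dispersion
estimate.

## The bootstrap overlap null

Let $A$ and $B$ be DEG sets; their overlap is the Jaccard index
$J(A,B) = |A \cap B| / |A \cup B|$ (0 when both are empty). The *expected*
overlap under the hypothesis that both paralogs regulate the same genes is
estimated by resampling: within each of the six conditions, replicates are
drawn with replacement, constrained to at least 3 distinct samples per
condition (rejection sampling; rejected draws are counted). The whole DE
chain — size factors, dispersions, GLM, contrast, BH, DEG calling — is rerun
on each of $B$ resamples (default $B = 100$), and all pairwise $J$ values
within one paralog's resamples form the expected-overlap distribution.
Directions are analysed separately (`up`, `down`) and jointly (`all` = union
of up and down per replicate).

Summaries:

* **Basic bootstrap CI** $(2\hat\theta - q_{1-\alpha/2},\,
  2\hat\theta - q_{\alpha/2})$, clipped to $[0,1]$. A within-paralog $J$ has
  no single full-data analogue (it needs two replicates), so the mean of the
  pairwise distribution serves as the reflection centre $\hat\theta$; the
  interval for the *observed* cross-paralog $J$ uses the cross-paralog
  pairwise bootstrap distribution in the same way.
* **One-sample Z test** $z = (\bar J_{\mathrm{within}} - J_{\mathrm{obs}})/
  \mathrm{sd}(J_{\mathrm{within}})$, normal reference, two-sided by default
  (`alternative` is exposed because sidedness is a reporting convention).
* **O/E ratio** $100 \cdot J_{\mathrm{obs}} / \frac{1}{2}(\bar J_1 + \bar
  J_2)$, rendered with one decimal.
* **Fisher exact overlap test** on the 2×2 table over the *tested* universe
  (after the count filter — never the full annotation), reporting the
  conditional-MLE odds ratio with exact CI plus the sample OR for reference.
* **Z-score correlation**: Pearson $r$ (and $r^2$) between the two paralogs'
  per-gene Wald statistics over the shared tested universe, with a
  100-resample percentile bootstrap CI over genes.

Pairwise-$J$ counts grow as $B(B-1)/2$ and are capped at 10,000 by seeded
subsampling. All bootstrap stages take explicit seeds; one pipeline seed
spawns deterministic per-stage child seeds, so identical configurations give
byte-identical reports.

## Off-target filtering

Candidate guide off-target sites (e.g. from an external predictor) are kept
when the CFD score is strictly above 0.1 and the site is exonic or intronic.
A kept gene that is differentially expressed for **both** paralogs cannot be
the off-target of one guide sequence and is labelled
`shared_effect_not_offtarget`; DE for exactly one paralog yields
`possible_guide_specific_offtarget`; otherwise `no_expression_effect`.

## Peak integration

Interval conventions are 0-based half-open on disk (BED/narrowPeak) and
1-based closed in `GRanges` in memory; writers and readers round-trip
losslessly, and `[100,200)` does not overlap `[200,300)`. The reference
point of a peak is its summit when a narrowPeak summit offset is present,
otherwise its midpoint. Distances to a TSS are signed by the gene's strand.

* **Promoter fraction**: share of peaks within ±5 kb (inclusive) of the
  nearest TSS; peaks on chromosomes without any TSS are excluded from the
  denominator and reported.
* **Linking**: every (gene, peak) pair within 1 Mb (inclusive) of the TSS;
  a peak may serve many genes and vice versa. Multi-TSS genes collapse to
  the first listed TSS by default (`collapse = FALSE` keeps all, and
  distances then use the nearest).
* **Active-enhancer filter**: peaks retained on ≥1 bp overlap with histone
  mark intervals (e.g. H3K27ac).
* **Function prediction**: per-gene regulatory potential
  $S_g = \sum_k e^{-(0.5 + 4\Delta_k)}$, $\Delta_k = |d_k|/10^5$ (a peak at
  the TSS contributes $e^{-0.5} \approx 0.607$). One-sided two-sample KS
  tests compare $S$ of upregulated vs. non-DE genes (activating) and
  downregulated vs. non-DE genes (repressive), using all DEGs at
  FDR < 0.05 without a fold-change cutoff to keep power. This
  distance-decay score is a deliberate simplification of rank-product
  binding-and-expression machinery; replicating any specific external tool
  is a non-goal.

## The synthetic-data generator

`simulateCounts()` draws gamma-Poisson counts with the exact structure the
analysis assumes, so every stage is testable without sequencing data:

* per-gene baselines $\mu_g \sim$ log-normal(4, 1.5) (natural-log scale) —
  a realistic span from a few counts to tens of thousands;
* dispersion trend $\alpha(\mu) = 0.05 + 2/\mu$, the common bulk RNA-seq
  shape (moderate biological variability; the study does not report
  within-condition variability, so these are chosen, not fitted);
* size factors log-normal with sd 0.2, renormalised to geometric mean 1;
* 150 and 100 direct targets for TF1/TF2 with `shared_fraction` = 0.15
  (exactly `round(shared_fraction × min(n_targets))` genes are targets of
  both, with the **same signed effect** for both paralogs — shared targets
  are modelled as one regulated program); 30% of targets are downregulated;
  effect sizes $|N(2, 0.5)|$ log2 on the OE side and `-0.5×` that on the KO
  side, reflecting the weaker knockout response;
* stress responders: 10% of genes per CRISPR system with $N(0,1)$ log2
  responses applied identically in targeting and control conditions of that
  system — exactly the structure the combined contrast cancels;
* the TF genes themselves carry log2FC 4.2 / 5.2 under their own OE and
  retain 35% / 47% expression under their own KO, with no cross-regulation.

`simulatePeaks()` lays one TSS per gene on synthetic chromosomes at regular
100 kb spacing (alternating strand), gives 90% of direct targets a peak at a
uniform distance up to 100 kb (random sign) and non-targets background peaks
at rate 0.1. What the generator does **not** emulate: correlated genes,
batch effects, outlier samples, isoform structure, GC/length biases,
realistic TSS clustering, or peak-width/signal distributions. Passing tests
therefore demonstrate correctness of the statistical machinery under the
model's own assumptions, not robustness to everything real data can do.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full method at
desk scale, chosen so each property is measured with useful precision:
simulations use 600–2,000 genes × 36 samples; bootstrap checks use
$B = 30$ with 20 seeded repetitions per scenario; the end-to-end default
preset is 2,000 genes with $B = 100$. Convergence tolerance of the GLM is
$10^{-8}$ (max 100 iterations), information ridge $10^{-8}$, dispersion
floor $10^{-8}$, zero-condition pseudo-count 0.5. Ties in DEG thresholds
are resolved by the strict inequalities stated above.

## Known limitations

* **The bootstrap null is deliberately conservative.** A bootstrap DEG set
  contains, besides the stable targets, a churn of borderline genes: for a
  gene with full-data Wald score $z$, the bootstrap re-estimate is roughly
  $N(z, 1)$, so over the null genes the bootstrap $|z|$ is inflated by about
  $\sqrt2$ and each resample calls extra, largely non-overlapping genes.
  The within-paralog pairwise Jaccard therefore *underestimates* the overlap
  two independent full-power experiments on identical-target paralogs would
  show: in simulations with fully shared targets the observed cross-paralog
  $J$ runs 1.4–1.8× the bootstrap-expected $J$, and the same gap appears
  when an independent reference DE engine drives the bootstrap. The
  consequence is conservatism: a *low* observed/expected ratio understates
  the divergence, it cannot manufacture it. Interpret O/E near or above
  100% cautiously; values far below 100% are the informative regime.
* The moment/trend dispersion estimator with a normal Wald reference is
  mildly anticonservative at six replicates (realised FDR ≈ 0.08–0.10 at
  nominal 0.05 in simulations); the strict fold-change threshold absorbs
  part of this in practice.
* The Z test treats bootstrap pairwise $J$ values as exchangeable draws;
  they are positively dependent (each resample participates in $B-1$
  pairs), so the normal approximation is heuristic — as in the original
  procedure.
* Off-target *prediction* is out of scope; only a provided candidate table
  is filtered.

## A worked miniature

```{r mini, eval = FALSE}
sim <- simulateCounts(simConfig(n_genes = 800, seed = 11))
ov  <- degOverlapAnalysis(sim$counts, B = 30, seed = 11)
renderTable1(ov)
```

The same analysis, file-based and end-to-end, is available through
`runPipeline()` (see the README) and the thin command-line wrapper in
`inst/scripts/paraloverlap.R`.
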