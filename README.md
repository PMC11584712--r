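# paraloverlap

Do two paralogous transcription factors regulate the same target genes?
`paraloverlap` answers this question for paired CRISPR knockout (KO) /
CRISPR-activation (OE) perturbation RNA-seq, the design used to compare
MEIS1 and MEIS2 in human neural stem cells: each paralog is overexpressed
and knocked out, each CRISPR system carries a non-targeting control, six
replicates per condition.

The package is aimed at computational biologists analysing such paired
perturbation designs, and provides:

* a lightweight negative-binomial GLM with the **combined contrast**
  `(OE − ctrl-OE) − (KO − ctrl-KO)`, which adds concordant OE/KO signal and
  cancels stress responses shared between targeting and non-targeting
  guides of the same CRISPR system;
* a **constrained bootstrap null** for gene-set overlap: replicates are
  resampled within every condition (≥ 3 distinct samples each), the whole
  DE analysis is rerun per resample, and the within-paralog pairwise
  Jaccard index `J(A,B) = |A∩B| / |A∪B|` estimates the overlap two analyses
  of the *same* regulator would show — the null for the observed
  cross-paralog overlap (basic bootstrap CIs, one-sample Z tests,
  observed/expected ratios);
* **Fisher exact overlap tests**, Wald **Z-score correlation** with a
  bootstrap CI, and a CRISPR **off-target candidate filter**
  (CFD > 0.1, exonic/intronic, shared-effect exclusion);
* **peak integration**: BED/narrowPeak/TSS readers, ±5 kb promoter
  fraction, 1 Mb peak→gene linking, histone-mark (H3K27ac) filtering, and
  an activating/repressive function test based on the distance-decayed
  regulatory potential `S_g = Σ exp(−(0.5 + 4·|d|/100kb))`;
* a **synthetic-data generator** (NB counts with ground-truth target
  annotations, plus peak/TSS fixtures) so the entire pipeline is testable
  without any sequencing data.

## Worked example

Simulate a paired perturbation experiment with known ground truth, call
target genes for both paralogs, and test the observed overlap against the
bootstrap null:

```r
library(paraloverlap)

sim <- simulateCounts(simConfig(n_genes = 800, seed = 11))
sim$counts
#> ParalogCountSet with 800 genes and 36 samples
#>   conditions: TF1-OE=6, TF1-KO=6, TF2-OE=6, TF2-KO=6, ctrl-OE=6, ctrl-KO=6

callDEGs(runCombinedContrast(sim$counts, "TF1"))
#> DEGSet for TF1: 103 up, 59 down (universe 800, padj < 0.05, |log2FC| > 0.58)
callDEGs(runCombinedContrast(sim$counts, "TF2"))
#> DEGSet for TF2: 68 up, 33 down (universe 800, padj < 0.05, |log2FC| > 0.58)

ov <- degOverlapAnalysis(sim$counts, B = 30, seed = 11)
renderTable1(ov)
#>   direction observed_j   observed_ci expected_j_tf1        ci_tf1    p_tf1
#> 1        Up      0.075 [0.065-0.141]          0.721 [0.617-0.863] 1.22e-30
#> 2      Down      0.082 [0.046-0.124]          0.496 [0.368-0.602] 9.12e-11
#> 3       All      0.096 [0.085-0.191]          0.615 [0.500-0.735] 9.11e-20
#>   expected_j_tf2        ci_tf2    p_tf2 oe_ratio
#> 1          0.626 [0.476-0.765] 1.94e-12    11.2%
#> 2          0.395 [0.255-0.513] 9.32e-06    18.5%
#> 3          0.520 [0.377-0.642] 3.15e-09    16.9%
```

Reading the table: this simulation used mostly distinct target sets
(15% shared), and the analysis says exactly that — two bootstrap analyses
of the *same* paralog overlap at J ≈ 0.5–0.7 (the expected overlap under
shared regulation), the two paralogs' observed sets overlap at only
J ≈ 0.08–0.10, the one-sample Z tests reject the shared-target null, and
the observed/expected ratio is 11–19%.

Classical overlap testing of two called DEG sets against a tested universe
of 19,689 genes (sizes and intersection as in the MEIS1/MEIS2 up-regulated
comparison):

```r
ft <- fisherOverlap(155, 54, 14, 19689)
sprintf("OR = %.1f [%.1f-%.1f], P = %.2g, J = %.3f",
        ft$odds_ratio, ft$or_ci[1], ft$or_ci[2], ft$pvalue, ft$jaccard)
#> "OR = 48.3 [23.7-93.2], P = 4.8e-18, J = 0.072"
```

The file-based pipeline (`counts.tsv` + `samples.csv` in, `report.json`,
`table1.tsv`, `de_*.tsv`, `links.tsv` out) is one call:

```r
runPipeline(defaultRunConfig(seed = 1, outdir = "run"))
```

or, from a shell, via the thin wrapper
`Rscript inst/scripts/paraloverlap.R run --config run/resolved_config.yaml`
(subcommands `simulate`, `de`, `overlap`, `linkpeaks`, `run`,
`render-table1`).

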