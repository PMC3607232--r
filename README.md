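# triMark

Multi-mark ChIP-seq target-gene calling and patient-cohort scoring for
fusion-protein leukemias.

## The problem

Chimeric transcription factors such as MLL-AF4 in t(4;11) acute
lymphoblastic leukemia cannot be immunoprecipitated with a single
antibody. A standard workaround profiles the two halves of the fusion
separately (e.g. MLL-N and AF4-C antibodies) together with a chromatin
mark of productive transcription (H3K79me2), and calls a gene a direct
fusion target only when all lines of evidence coincide: both
fusion-half marks peak in the gene's promoter and the elongation mark
covers its gene body. Target sets derived independently in two cell
lines are then intersected into a consensus set, and that gene set is
scored in patient expression cohorts — subtype comparisons, fold
changes, minimal-residual-disease (MRD) stratification and survival.

triMark implements that full computational chain as reusable,
deterministic, heavily tested functions:

* **Peak calling** — clonal reads collapsed to one per (chrom, position,
  strand), extended to `fraglen` = 170 bp fragments and piled up; a base
  is enriched when its coverage is at least `t` = 15 times the uniform
  background expectation λ = fragments × fraglen / genome size **and**
  the library-size-normalized IP/input ratio is at least `f` = 2 (input
  floored at its own λ); enriched runs are merged into peaks with
  summit, height and fold.
* **Annotation** — strand-aware promoter windows (TSS ± 2 kb) and
  gene-body windows (TSS − 2 kb to TES + 1 kb) from refFlat/BED gene
  models.
* **Target calling** — the AND-rule over promoter marks and body marks,
  symbol-level consensus intersection and full Venn partitions of target
  sets.
* **Cohort analysis** — per-gene expression as the mean over its probe
  sets (log2 scale), gene-set scores as the mean over member genes,
  two-sided Wilcoxon rank-sum comparisons, fold change =
  2^(mean_A − mean_B), MRD dichotomized at 0.01 % (boundary positive),
  Kaplan–Meier curves and two-group log-rank tests.
* **qPCR arithmetic** — ChIP percent-of-input
  (2^(CT_input − CT_IP) × 5.0 %), ΔCT relative expression, and the
  set-max-to-100 / set-control-to-1 normalizations.
* **Synthetic data** — a seeded generator that plants target genes,
  expression shifts, MRD coupling and hazard ratios, so every stage is
  testable end-to-end with no external data.

Built Bioconductor-style: reads, peaks and gene models are `GRanges`;
cohorts are a `SummarizedExperiment` subclass (`CohortExperiment`).

## Worked example

Simulate a study with 10 planted target genes, run the whole chain, and
score the planted set in a matching patient cohort:

```r
library(triMark)

cfg <- syntheticConfig(seed = 11)      # 4 Mb genome, 60 genes, 10 planted
sim <- makeChipseq(cfg)                # MLL-N / AF4-C / H3K79Me2 + input
res <- recoverPlantedTargets(sim = sim)
res$stats
#> $tp: 10   $fp: 0   $fn: 0
#> $precision: 1   $recall: 1   $f1: 1

res$peaks[["H3K79Me2"]][1]
#> GRanges object with 1 range and 3 metadata columns:
#>       seqnames      ranges strand |    summit    height fold_vs_input
#>   [1]     chr1 69747-77620      * |     71197   30.2673       30.2673
```

All 10 planted genes — and no others — pass the triple-mark rule; the
body-mark peak spans the planted gene with a summit height of 30× the
background expectation. Scoring the recovered set in a cohort with a
planted 1.0 log2 shift in the MLLr-like subtype:

```r
co  <- makeCohort(cfg, geneset = plantedSymbols(sim$truth))
compareGroups(co$cohort, "MLLr", "other",
              geneset = plantedSymbols(co$truth))
#>  group_a group_b n_a n_b  mean_a  mean_b u_statistic  p_two_sided fold_change
#>     MLLr   other  20 100 7.89735 6.99232        1902 2.178887e-10    1.872582

survivalByGroup(co$cohort, "os", by = "mrd")[c("chiSquare", "p", "n")]
#> chisq 17.07   p 3.61e-05   n 110
```

The planted two-fold overexpression is recovered (fold 1.87, Wilcoxon
p ≈ 2 × 10⁻¹⁰), and the planted MRD+ hazard ratio of 3 yields a clearly
significant log-rank separation. ChIP-qPCR arithmetic is one call:

```r
chipPercentInput(ctInput = 25.1, ctIp = 22.3)   # 2^2.8 * 5% = 34.8%
```

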