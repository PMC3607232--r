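---
title: "Methods: multi-mark target calling and cohort scoring"
author: "triMark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-mark target calling and cohort scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triMark)
```

# Scope and model

triMark chains five analysis stages: (1) ChIP-seq reads to peaks, (2)
peaks to per-gene mark flags via fixed promoter/body windows, (3) flags
to a target-gene call and cross-sample consensus, (4) target-set scoring
in patient expression cohorts with subtype, MRD and survival
stratification, and (5) the ΔCT qPCR closed forms. A sixth module
generates synthetic inputs with planted ground truth for all of them.
This vignette records the model behind each stage, the tunable
parameters, the numerical conventions, and the decisions taken where
more than one defensible design existed.

# Peak calling

## Background model

Reads are first collapsed to at most one per (chromosome, leftmost
mapped position, strand): reads stacking at exactly the same position
and strand are overwhelmingly PCR ("clonal") duplicates at ChIP-seq
depths. Each surviving read is extended from its 5′ end to a fixed
fragment length (`fraglen`, default 170 bp, the typical sonication
fragment size) and piled into per-base coverage.

The caller's null is a uniform background: with $N$ fragments of length
$L$ on an effective genome of $G$ bases, the expected per-base coverage
is $\lambda = NL/G$. A base is *enriched* iff

* coverage $\ge t\,\lambda$ (height gate, `t`, default 15), and
* when a matched input track is supplied,
  $\dfrac{c_\mathrm{IP}/N_\mathrm{IP}}{\max(c_\mathrm{in},
  \lambda_\mathrm{in})/N_\mathrm{in}} \ge f$ (enrichment gate, `f`,
  default 2).

The per-million style normalization by total fragments makes the ratio
library-size free; flooring the input at its own $\lambda_\mathrm{in}$
prevents division by (near) zero in sparsely covered input regions and
is standard practice. Maximal enriched runs separated by at most
`mergeGap` bases (default `fraglen`) are merged, and runs narrower than
`minWidth` (default 1) are dropped.

This rule deliberately reproduces the *roles* of the classical
`-t / -f / -fraglen` parameterization with a fully transparent statistic
(fold over uniform background), so every call can be verified against a
naive per-base oracle — the package's test suite does exactly that on
random toy genomes. It is an emulation of that caller family, not a
re-implementation of any specific tool; no sliding-window local
background, mappability correction or FDR model is included.

## Numerical conventions

* **Summit.** Within a peak the summit is the first position of maximal
  IP coverage *among gate-passing bases*. Restricting to gate-passing
  bases keeps the peak invariants (height ≥ `t`, fold ≥ `f` at the
  summit) airtight even when `mergeGap` absorbs interstitial bases that
  fail the input gate.
* **Gate scope.** The input gate is applied per base by default
  (`foldScope = "base"`); `"peak"` instead forms candidate peaks on the
  height gate alone and filters them by the summit fold. Whether the
  original analyses gated per base or per peak is not determinable from
  their parameter strings; per-base is the stricter and simpler reading.
* **Duplicate key.** Collapsing keys on the leftmost mapped position
  plus strand. For constant-length reads this coincides with the 5′
  position; the choice only matters for mixed-length inputs.
* **Truncation.** Fragments extending past a chromosome end are
  truncated (with a message); coverage mass is conserved up to the
  truncated bases.

# Annotation windows

Gene models are `GRanges` (1-based, closed — the Bioconductor
convention; BED and refFlat 0-based half-open coordinates are converted
at I/O). For a transcript on the + strand with span $[s, e]$:

* promoter: $[\mathrm{TSS} - u_p,\ \mathrm{TSS} + d_p)$ with
  $u_p = d_p = 2$ kb by default;
* gene body: $[\mathrm{TSS} - u_b,\ \mathrm{TES} + d_b)$ with
  $u_b = 2$ kb, $d_b = 1$ kb.

On the − strand the windows mirror exactly; the TSS of a − transcript is
taken at the half-open boundary so windows are exactly $u + d$ bases on
both strands (the ±1 convention is otherwise arbitrary). Windows are
clamped at position 1. Overlap is any shared base (≥ 1 bp): nothing in
the window definitions justifies a larger minimum.

Multi-transcript genes get one window pair per transcript and a gene is
flagged if *any* transcript's window is hit — the permissive reading of
an annotation that reports gene symbols. Merging overlapping transcripts
first would only make calls stricter; it was not adopted because the
flag is already a simple existence test.

# Target calling and consensus

A `TargetRule` lists the marks required at the promoter and in the gene
body; `is_target` is the conjunction of all flags. The default rule —
MLL-N *and* AF4-C at the promoter *and* H3K79me2 in the body — is the
triple-evidence definition of a fusion-protein target. A single peak
spanning the TSS may satisfy both a promoter and a body flag: the
windows intentionally overlap there and nothing excludes it.

Cross-sample consensus intersects gene *symbols* after uppercasing and
whitespace-stripping. Symbol space is what such target lists are
published in; the normalization is documented as lossy for aliases
(a transcript-accession intersection would behave differently for genes
with renamed symbols). `overlapPartition` produces the full Venn
partition of two or more sets; counts always sum to the union size.

# Cohort analysis

* **Probe averaging.** A gene's expression in a sample is the unweighted
  mean of its probes' log2 values; probes mapping to several genes are
  dropped at construction (ambiguous probes do not "represent" a gene),
  unmapped probes are kept but flagged. Missing values are an error at
  load: post-normalization matrices are complete, and explicit failure
  beats silent imputation.
* **Gene-set score.** The per-sample mean of the member genes'
  expressions — i.e. samples are scored first, then compared, matching
  the units of a per-sample boxplot. The alternative (test each gene,
  summarize p values) answers a different question and is not
  implemented.
* **Wilcoxon.** Two-sided Mann–Whitney with midranks. Exact permutation
  p when the pooled sample is tie-free and ≤ 12 observations; otherwise
  the normal approximation with tie-corrected variance and continuity
  correction (the convention of `stats::wilcox.test`, which backs the
  implementation; the test suite checks it against an independent
  exhaustive-enumeration oracle). Identical constant groups return p = 1
  with a message.
* **Fold change.** $2^{\bar a - \bar b}$ of log2 group means, so
  fold(a,b) · fold(b,a) = 1.
* **MRD.** Dichotomized at 0.01 %, boundary *positive* (a measurement
  "at threshold" demonstrates detectable disease); missing measurements
  are "unknown" and excluded. The threshold is a parameter.
* **Survival.** Kaplan–Meier product-limit and the two-group log-rank
  test, via the survival package behind the module interface, with
  deaths preceding censorings at tied times (the standard product-limit
  convention). The suite pins the closed forms: no-censoring KM equals
  the empirical survival function, and the two-subject single-event
  log-rank gives χ² = 1 exactly.
* No multiple-testing correction is applied by default; comparisons are
  reported with raw two-sided p values. `stats::p.adjust` composes
  trivially downstream if a family of comparisons is run.

# qPCR closed forms

ChIP percent-of-input: $\%=2^{C_T(\mathrm{input})-C_T(\mathrm{IP})}
\times \mathrm{inputFraction} \times 100$, with the input fraction
derived from volumes (50 µl of 1 ml ⇒ 5 %). Relative expression:
$2^{C_T(\mathrm{HK})-C_T(\mathrm{gene})}$. Technical replicate CTs are
averaged on the cycle scale *before* these formulas (averaging linear
quantities instead would weight replicates exponentially). With two
housekeeping genes the single-reference ratios are combined by their
geometric mean — equivalent to using the mean housekeeping CT, and the
natural combiner for ratio-scale quantities; an arithmetic mean would
not be scale-invariant. `normalizeToMax` (highest entry = 100) and
`normalizeToControl` (control = 1) are both invariant to rescaling all
inputs.

# The synthetic generator

The generator emulates the *structure* of the real inputs, not their
full messiness; distributions are its own modelling choices:

* **Genome.** Genes placed left-to-right with inter-gene gaps of
  4.2–6 kb, guaranteeing disjoint promoter windows for distinct genes,
  lengths 2–6 kb on a 100 bp grid, random strands. Defaults: 60 genes on
  a 4 Mb two-chromosome genome, 10 planted targets.
* **Reads.** Uniform background at `backgroundRate` (default 0.01
  fragments/bp, i.e. λ = 1.7 at 170 bp fragments) per mark and for
  input. Planted genes receive extra reads whose fragment centers fall
  uniformly in the central half of the promoter window (promoter marks)
  or across the whole body window (body marks), in numbers that target
  `enrichmentFold` × background coverage (default 40×).
* **Why a 4 Mb genome.** The caller estimates λ from the IP track's own
  fragment total, exactly as on a real genome. If planted windows made
  up a sizeable fraction of the genome, their reads would inflate λ and
  cap the attainable height at genomeSize / Σ(planted window widths)
  regardless of enrichment — a closed-form consequence of the
  definition. The defaults keep planted windows ≈ 2 % of the genome, so
  design heights are ≈ 21× background for body marks and ≈ 30× for
  promoter marks against the t = 15 gate: sensitive but not saturated.
  Depth is parameterized as `backgroundRate`; total fragments per track
  are simply rate × genome size. `plantedRate` decouples the planted
  read budget from the background so a zero-background ("noise-free")
  study still plants reads.
* **Cohort.** Gene baselines ~ Normal(7, 1.5) log2 units (typical
  microarray range); sample-level gene noise sd 1.0; probe offsets sd
  0.3 with probe noise sd 0.25 and 2 probes/gene; a planted `delta`
  (default 1.0 log2 ⇒ two-fold) on the target set in the high subtype
  (20 vs 100 samples, matching a realistically unbalanced cohort). MRD+
  status (prevalence 0.3) adds `mrdShift` (0.5 log2) on the same set,
  independent of subtype; observed MRD percentages are drawn on the
  correct side of the 0.01 % threshold, with 10 % missing.
* **Outcomes.** Exponential survival, baseline hazard 0.1/month and
  hazard ratio 3 for MRD+ (RFS at 1.5× baseline); independent
  exponential censoring calibrated to a 0.2 censoring fraction under the
  null.

Everything is driven by one integer seed (fixed offsets per generator),
so a (config, seed) pair reproduces byte-identical files.

**What passing tests do not show.** The generator has no GC or
mappability bias, no fragment-length distribution, no chromatin
accessibility structure in the input, no probe saturation or batch
effects, and symbol space is clean. Recovery of planted structure
demonstrates the correctness of the chain's logic and calibration of its
statistics — not robustness to artifacts real data may carry.

# Test problem sizes

The suite exercises: the peak caller against an independent naive
per-base oracle on >100 random toy genomes of ≤ 25 kb; planted-target
recovery end-to-end over 25 seeds at the default configuration plus a
noise-free configuration; Wilcoxon against exhaustive permutation
enumeration for all tie-free splits with ≤ 10 pooled observations;
type-I error of the group comparison and of the log-rank test over 500
planted-null simulations each (calibration band 0.05 ± 0.02); and power
at the planted δ = 1, 20-vs-100 design over 200 simulations. These sizes
give stable Monte-Carlo estimates while keeping the default run light.

# Known limitations

* The peak caller is a transparent emulation of the fold-threshold
  family; numbers from specific external callers will differ in detail.
* Symbol-level consensus is lossy under gene-symbol aliasing.
* Windows are fixed promoter/body boxes; distal enhancers are out of
  scope.
* The cohort module assumes pre-normalized complete log2 matrices; no
  normalization, batch correction or Cox regression is provided.
* qPCR arithmetic assumes perfect amplification efficiency (a one-cycle
  difference is exactly two-fold).
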