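---
title: "Screening and validating radiation-induced DNA hypomethylation"
author: "radMethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and validating radiation-induced DNA hypomethylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radMethyl)
```

## The problem and the model

Ionizing radiation (IR) is both a carcinogen and a front-line cancer
therapy, and there is long-standing evidence that it perturbs the DNA
methylation landscape of exposed cells — predominantly toward *loss* of
methylation. radMethyl implements a discovery-and-validation workflow for
identifying genes that become hypomethylated after irradiation of a cancer
cell line, using a genome-scale methylation array read out as beta values
and a panel of qPCR-based follow-up assays.

The central design idea is a *demethylation-controlled screen*. Methylation
loss can arise from many sources (technical drift, culture conditions,
stochastic epialleles). The workflow therefore treats cells exposed to the
DNA-methyltransferase inhibitor 5-aza-2′-deoxycytidine (5-aza-dC) as a
positive control for *bona fide* demethylatable loci: a probe is promoted to
a radiation-hypomethylation candidate only when it loses methylation both
in an irradiated arm (2 Gy or 5 Gy) *and* in the 5-aza-dC arm. Probes that
respond only to radiation, or only to the inhibitor, are reported in the
Venn partition but never promoted.

### Beta values and the two-threshold call

Each CpG probe's methylation is the beta value
$\beta = M / (M + U + \alpha)$, the methylated bead intensity over the
combined intensity, ranging from 0 (unmethylated) to 1 (methylated).
`computeBeta()` defaults to offset $\alpha = 0$; the Illumina-style
stabilising offset (conventionally 100) is available as a parameter for
low-intensity data.

For each treated-vs-mock contrast, per-condition beta is the mean over that
condition's samples, and a probe is called differentially methylated only
when **two criteria pass jointly**:

* $|\Delta\beta| = |\beta_{treated} - \beta_{mock}| \ge \delta_{min}$, with
  $\delta_{min} = 0.2$ by default — this cut-off corresponds to the 99%
  confidence interval of the platform's detection limit, below which a
  difference cannot be distinguished from measurement error; and
* a fold ratio strictly greater than $r_{min} = 1.5$, computed in the
  direction of change: $\beta_{mock} / \max(\beta_{treated}, \epsilon)$ for
  hypomethylation and the mirror image for hypermethylation.

Both thresholds live in `screenConfig()`. The ratio denominator is floored
at $\epsilon = 0.01$ so that a fully demethylated probe
($\beta_{treated} \approx 0$) keeps a finite, large fold rather than
dividing by zero; $\epsilon$ sits below array noise so the floor never
changes a call that noise would not already dominate. The screen is purely
threshold-based by design — no per-probe p-values or multiple-testing
correction are computed, and none should be added: the two thresholds *are*
the decision rule, with the 5-aza-dC intersection acting as the specificity
control that a p-value would otherwise provide.

We read the fold criterion as a ratio test on condition-mean beta values
combined conjunctively with the $|\Delta\beta|$ criterion, and we use
$\ge$ for the delta threshold and strict $>$ for the ratio. With a single
chip per condition, per-probe and condition-mean thresholds coincide; with
replicates we threshold the means.

### Probe reliability filtering

Before calling, `filterReliableProbes()` partitions probes into kept and
excluded sets using three operational rules: (a) any detection p-value
above `detectionPMax` (default 0.01) — the probe's signal is not
distinguishable from background; (b) with at least two mock samples, a
maximum pairwise $|\Delta\beta|$ among mock replicates above
`mockReplicateDeltaMax` (default 0.2) — the control arm itself fluctuates
by a callable effect size, so no treated difference against it is
interpretable; (c) any missing beta. Every exclusion is enumerated with its
reason; probes are never silently dropped. The mock-instability rule
deliberately reuses the calling threshold 0.2: a probe whose control
replicates disagree by more than the smallest effect we would call cannot
support that call.

### Candidate selection and exclusion

`vennPartition()` splits the three hypomethylated probe sets into the seven
exclusive membership patterns; `selectIrCandidates()` promotes the patterns
containing aza together with at least one IR dose. Probes collapse to genes
by the union of their annotated symbols (`collapseToGenes()`); a probe
annotated `TSPY1;TSPY4` supports both genes, and deduplication across the
two IR doses happens at the gene level, so 25 aza∩2 Gy probes and 21
aza∩5 Gy probes with 17 shared can yield 29 distinct genes. We adopt this
union-at-gene-level reading explicitly; it is stated here rather than
assumed silently elsewhere.

`applyExclusionRules()` then flags genes that cannot be assayed
gene-specifically by qPCR: annotated pseudogenes, and genes whose paralog
sequence similarity is at or above `similarityThreshold` (default 94%,
the similarity at which primer specificity breaks down for the TSPY
paralogs in the packaged candidate set). Exclusion gates *validation
eligibility only*: excluded genes remain in every report with their reason,
matching a discovery set of 29 with 26 assayable. In the packaged
29-gene table, the excluded trio is the pseudogene CXADRP2 and the 94%
similar paralogs TSPY1 and TSPY4. One naming note: the candidate list
records the interferon-inducible gene as *IFI16*; an *IFI6* spelling also
circulates for the same list entry, and we standardise on IFI16 throughout.

### Clustering for display

Heatmap ordering uses hierarchical clustering with Pearson-correlation
similarity, i.e. distance $1 - r \in [0, 2]$ on centred values (not the
uncentred cosine variant that some array software also calls "Pearson").
Linkage is average (UPGMA), the conventional choice of that software era;
it is a config option, not a claim about the original software's exact
algorithm, which is not recoverable. Because average linkage is reducible,
merge heights are non-decreasing. Ties are broken by merging the candidate
pair with the lexicographically smallest pair of cluster indices (leaves in
input order, then merged clusters in creation order), which makes the merge
sequence — though not necessarily the cosmetic leaf order under input
permutation — fully deterministic; cluster memberships at any cut height
are permutation-invariant, and the test suite checks this. The
agglomeration is implemented directly (it is a ~40-line loop) so that this
tie-break is guaranteed, and it is cross-checked in the tests against both
a from-scratch re-agglomeration and `stats::hclust(method = "average")` on
tie-free data.

### Validation models

Three standard qPCR quantifications, all at fixed amplification efficiency
2 (perfect doubling; efficiency calibration is out of scope), with
replicate Ct values aggregated by arithmetic mean before any delta:

* **Expression** (`ddctFoldChange()`): the delta-delta-Ct method with GAPDH
  as reference; fold change $= 2^{-\Delta\Delta C_t}$.
* **qMSP** (`qmspRelativeMethylation()`): methylation-specific PCR on
  bisulfite-converted DNA normalized to an Alu repeat —
  $2^{-[(\Delta C_t)_{treated} - (\Delta C_t)_{mock}]}$, so mock = 1 and
  values below 1 mean demethylation.
* **ChIP occupancy** (`chipPercentInput()`): DNMT1 at the promoter
  (TSS ± 1 kb) as percent of input chromatin. The input aliquot's Ct is
  first adjusted by $-\log_2(100 / \text{input\%})$ to a 100% equivalent,
  then occupancy $= 100 \times 2^{C_t^{adj} - C_t^{IP}}$.
  `occupancyDecrease()` reports $100 (1 - treated/mock)$, with increases
  allowed as negative values. The IgG channel is reported alongside DNMT1
  but never subtracted; with no stated background-correction convention,
  showing both channels is the transparent choice.

`scoreConcordance()` calls a retained candidate **validated** when its
expression fold reaches `exprFoldMin` in aza *and in every supporting IR
contrast*. The default `exprFoldMin = 1.5` mirrors the methylation fold
criterion; it is a package default, exposed in the config and echoed in
every report, not a value inherited from a stated expression cutoff. DNMT1
occupancy decrease is *recorded* (`occupancy_down`) but does not gate
validation: a gene can be genuinely hypomethylated and re-expressed without
a detectable DNMT1 occupancy drop at the assayed window, and the synthetic
bundle plants exactly such a gene (IFI16) to keep the rule honest. Genes
with no expression record are reported `unassayed` and never validated.

## The synthetic-data generator

No array accession exists for the motivating experiment, so the package
generates its own inputs with planted, recorded truth
(`generateBetaMatrix()`, `generateCtTables()`,
`generatePaperShapedFixture()`).

What it emulates: bimodal genome-wide beta marginals (a low mode near 0.1
from Beta(2, 18) and a high mode near 0.8 from Beta(16, 4), 60% low);
planted hypomethylation effects applied to treated conditions only, with
planted probes drawn from the high mode (uniform 0.6–0.9) so a −0.4 effect
is callable; additive technical noise on the beta scale (default sd 0.02,
clipped to [0, 1]); planted reliability failures of both kinds; and Ct
tables whose target channels carry the planted gene effects as
$-\log_2(\text{effect})$ cycles around fixed reference channels (GAPDH 20,
Alu 16, input 20; baseline $\Delta C_t$ 6 for expression and 5 for qMSP;
mock DNMT1 occupancy 2% of input with a 1% input fraction and 0.1% IgG
background), with N(0, 0.1) replicate noise in triplicate.

What it does **not** emulate: Infinium I/II chemistry differences, dye
bias, batch structure, intensity-scale (heteroscedastic) error, spatial
artefacts, or biological covariation between neighbouring probes. Noise is
applied on the beta scale as a deliberate simplification. Passing tests on
this generator therefore demonstrate that the *decision rules and
arithmetic* are correct and recover planted truth under realistic effect
and noise magnitudes — not that the pipeline is robust to every artefact of
real array data.

The narrative-shaped bundle plants the full study shape at desk scale: 25
aza∩2 Gy and 21 aza∩5 Gy probes (17 shared) mapping one-to-one onto the 29
packaged candidate genes, a scaled-down aza-only background block (40
probes standing in for the thousands a genome-wide inhibitor arm produces)
plus small IR-only blocks, the 3 exclusion-flagged genes, expression folds
≥ 1.5 in all supporting contrasts for exactly 7 genes (2.5× in aza, 2.0× at
2 Gy, 1.8× at 5 Gy; 1.1× for the other retained genes), qMSP relative
methylation 0.4 for the three genes assayed that way (APBB2, CHGA, CTGF),
and DNMT1 occupancy decreases spanning 21–50% (aza), 50–81% (2 Gy) and
48–81% (5 Gy) across the validated genes. Two samples per condition are
generated: the single-chip-per-condition design of the original platform
is the minimum the readers accept, but two replicates exercise the
mock-instability filter, which needs a pair to compare.

Determinism: one master integer seed; per-table sub-stream seeds are
derived from it by fixed offsets, so regenerating one table never perturbs
another, and an identical seed reproduces every byte.

## Numerical and design choices

* Condition vocabulary is closed ({mock, aza, ir2gy, ir5gy}); unknown
  labels are rejected, not ignored, to prevent silent contrast mismatches.
* Files are tab-delimited UTF-8 with `#` comments; conditions travel in a
  sidecar table so sample identifiers stay clean.
* BED output is 0-based half-open; annotation TSS is 1-based (array-
  manifest convention). A TSS at 10,000 with 1 kb flank yields
  chromStart 8999, chromEnd 10999, clamped at 0; the flank is symmetric
  regardless of strand.
* Missing paralog similarity is `NA` ("not assessed"), never 0, since 0
  would mean "assessed and dissimilar".
* Reliability-filter reasons are reported with precedence detection >
  mock-instability > missing when several apply.
* Degenerate clustering inputs (single item, length-1 profiles) fall back
  to identity order rather than erroring, so a one-probe candidate set
  still renders.
* Report files carry no timestamps; identical config + seed reproduce
  byte-identical output trees.

## Problem sizes

The test suite and the acceptance script run the screen-recovery experiment
at 10,000 probes × 8 samples with 250 planted effects, the end-to-end
narrative bundle at 1,500 probes (600 and smaller in unit tests), and the
qPCR parameter-recovery simulations at 100 seeds per planted value. These
sizes give stable recovery statistics for threshold rules whose error
rates, at the default noise levels, are effectively zero per probe.

## Known limitations

* The screen has no inferential error control; its specificity rests
  entirely on the demethylation-control intersection and the detection-
  limit-derived $\delta_{min}$.
* Gene collapse trusts the annotation's symbol lists; no alias resolution
  against a nomenclature service is attempted.
* The clustering reproduces a similarity measure and a conventional
  linkage, not any specific historical software's exact output.
* Validation arithmetic assumes efficiency-2 amplification and
  mean-aggregated replicates; dropping either assumption requires
  standard-curve data the workflow does not model.
* The synthetic generator's independence assumptions (probe-wise noise,
  fixed reference channels) make recovery easier than on real data; the
  recovery rates the tests demonstrate are upper bounds.
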