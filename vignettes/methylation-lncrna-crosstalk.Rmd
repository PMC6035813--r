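---
title: "Inferring crosstalk between DNA methylation and lncRNA regulation"
author: "lncmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring crosstalk between DNA methylation and lncRNA regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncmeth)
```

## The problem

In paired tumor/adjacent-normal designs (for instance non-small-cell lung
carcinoma tissue pairs profiled on the Illumina 450K methylation array and
by RNA sequencing), two epigenetic signals are measured on the same
patients: per-CpG methylation beta values and lncRNA expression. Both
signals regulate transcription, and genes that are hit by *both* — a
significantly differentially methylated CpG (SDMC) near the gene and a
differentially expressed (DE) lncRNA acting in cis on its promoter — are
candidates for methylation–lncRNA crosstalk and, downstream, for clinical
biomarkers. `lncmeth` implements this inference chain as a pipeline of
five stages plus a synthetic-data generator, so the whole chain is testable
without access to patient-level profiles.

## The model, stage by stage

**Differential methylation.** For probe $j$ with paired beta values
$\beta^{T}_{ij}$ (tumor) and $\beta^{N}_{ij}$ (paratumor) over patients
$i$, the effect estimate is the group-mean difference on the beta scale,
$\Delta\beta_j = \overline{\beta^T_j} - \overline{\beta^N_j}$, and the
test is a two-sided Wilcoxon signed-rank on the per-patient differences
$d_{ij} = \beta^T_{ij} - \beta^N_{ij}$ (a paired t-test is selectable).
Beta values are bounded and typically skewed, which is why the rank test
is the default; working on the beta scale keeps the test and the effect
threshold on the same scale. Zero differences are dropped before ranking
(Wilcoxon's original treatment); the exact null distribution is used
whenever the absolute differences are untied, full sign-flip enumeration
when they are tied at up to 14 pairs, and the normal approximation with
continuity correction beyond that. Probes whose differences are all zero
get $p = 1$: the null holds exactly. P-values are adjusted by
Benjamini–Hochberg step-up, with the number of tests equal to the number
of probes that produced a p-value. A probe is called an SDMC when
$|\Delta\beta_j| \ge 0.25$ **and** adjusted $p \le 0.05$, both bounds
inclusive; $\Delta\beta > 0$ is *hyper*, $< 0$ *hypo*. Missing betas are
handled by per-probe pairwise deletion — a pair with a missing member is
dropped for that probe only — and a probe needs at least two usable pairs
(and two non-missing values per group for $\Delta\beta$) to be scored.

**lncRNA differential expression.** The pipeline consumes a precomputed
candidate table (id, coordinates, length, log2 fold change, adjusted p),
as handed off by any upstream RNA-seq quantification. A candidate is DE
when length $\ge 200$ bp (the lncRNA definition), $|\log_2 FC| \ge 2$ and
adjusted $p \le 0.05$, all inclusive. The fold-change threshold is applied
to the absolute value by default so that strongly down-regulated lncRNAs
are retained — observed fold-change ranges in paired carcinoma data are
strongly two-sided — with `signed = TRUE` available for the one-sided
reading.

**Coordinates.** Everything downstream is interval arithmetic.
Internally all coordinates are 0-based half-open (BED convention);
1-based inputs (the probe manifest) are converted at the reader boundary,
so only one convention exists inside the package. The promoter of a TSS
is the symmetric window TSS $\pm$ 1000 bp, read inclusively on both
flanks (2001 positions, clipped at the chromosome start); strand decides
which end of a gene or lncRNA body is the TSS (`start` on `+`, `end - 1`
on `-`), never the window shape. Strand `"."` is tolerated and treated as
`+` with a warning. Batch overlap queries run through
GenomicRanges/IRanges interval trees; the test suite holds them to exact
agreement with brute-force double loops.

**Annotation.** SDMCs are intersected with SNP, CpG island/shore,
enhancer and DNase-hypersensitivity tracks supplied as BED. Shores are
the field-standard $\pm$ 2 kb island flanks, and the island/shore
category is the merged union of islands and their shores. Categories are
deliberately *not* exclusive — one CpG can be in a shore and an enhancer —
so reported fractions need not sum to one. SNPs are matched by exact
locus containment (point SNPs are width-1 intervals).

**Integration.** Three coordinate joins define crosstalk:
(i) SDMC–lncRNA pairs: every SDMC locus inside a DE lncRNA's promoter or
body, with promoter taking precedence when a locus is in both;
(ii) methylation target genes: genes with an SDMC in promoter or body
(the promoter-plus-body rule mirrors the lncRNA-side convention; a
promoter-only mode is provided);
(iii) lncRNA target genes: genes whose promoter is overlapped by a DE
lncRNA *body* — the literal cis-regulation rule. The crosstalk candidates
are the intersection of (ii) and (iii), and the package attaches an
upper-tail hypergeometric probability $P(X \ge k)$ for the observed
overlap $k$, with the universe defaulting to the number of supplied gene
models — the only defensible default when no external annotation is
loaded.

**Survival.** For each candidate gene, cohort expression is z-scored
with the sample standard deviation ($n-1$; the cBioPortal-style
convention), patients with $|z| \ge 1.96$ (two-sided, inclusive) are
*altered* — high and low outliers pooled into one arm — and altered vs
not-altered survival is compared by Kaplan–Meier product-limit curves and
the two-group log-rank test, $(\sum O - \sum E)^2 / \sum V \sim
\chi^2_1$. Ties between events and censorings at the same time follow
the standard convention (events first). Per-gene p-values are reported
as-is, without multiplicity correction, matching how per-gene log-rank
results are conventionally read in candidate-gene follow-up.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `dbeta_min` | 0.25 | beta difference | SDMC effect threshold |
| `adjp_max` | 0.05 | probability | SDMC FDR threshold |
| `test_method` | wilcoxon | — | paired test (or `ttest`) |
| `min_len` | 200 | bp | lncRNA length definition |
| `min_abs_lfc` | 2.0 | log2 | lncRNA fold-change threshold |
| `lnc_adjp_max` | 0.05 | probability | lncRNA FDR threshold |
| `promoter_flank` | 1000 | bp | promoter half-width around TSS |
| `shore_width` | 2000 | bp | CpG shore width |
| `z_thresh` | 1.96 | z-score | alteration threshold (two-sided 5%) |

All significance bounds are inclusive, so records sitting exactly on a
threshold are called significant; the test suite pins this down with
epsilon-below cases.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults describe a desk-scale paired study: 10,000
probes over 12 tumor/paratumor pairs, 2,500 lncRNA candidates and 1,000
genes on a 10-Mb synthetic genome — roughly a 50-fold shrink of
genome-scale profiling, chosen so a full run takes seconds. The planted
differential fraction (1.3% of probes) echoes the rate of significant
CpGs in paired carcinoma profiling; the planted effect is
$|\Delta\beta| = 0.35$ under per-sample Gaussian noise of sd 0.05,
clipped to $[0,1]$, with the shift direction chosen to stay inside the
unit interval (forced clipping is recorded in the truth table). DE
lncRNAs carry $|\log_2 FC| = 3.5$, comfortably inside fold-change ranges
reported for paired carcinoma tissue; non-DE candidates violate at least
one DE criterion, cycling through short length, weak fold change and
large adjusted p so every filter clause is exercised. Survival cohorts
use exponential times with baseline median 30 months, a hazard ratio of
2.5 for altered patients, uniform censoring solved to hit 20% expected
censoring, and a 5% altered fraction — the value that makes the
tail-sampling construction self-consistent with the $|z| \ge 1.96$ rule.

Two structural guarantees make planted-truth recovery exact rather than
probabilistic: crosstalk genes get their DE lncRNA body placed directly
over the promoter and their planted SDMC within 900 bp of the TSS, and
*all other* lncRNA candidates live on a gene-free second chromosome, so
the lncRNA target set equals the planted crosstalk set by construction.
Each output file draws from its own RNG stream (base seed plus a fixed
offset), so regenerating one file never perturbs the others, and a given
seed reproduces byte-identical bundles.

The generator does **not** attempt the bimodal beta distribution of real
450K data (a clipped Gaussian around a uniform baseline stands in), nor
linkage structure among SNPs, nor realistic gene density or overlapping
transcripts. Passing recovery tests therefore demonstrates that the
pipeline's logic is correct under its stated model — not that the
thresholds are well-calibrated for any particular tissue or platform.

## Numerical choices and degenerate inputs

- Exact signed-rank p-values double the smaller tail and cap at 1, the
  same convention as `wilcox.test`.
- A paired t-test on constant non-zero differences (sd 0) returns p = 0;
  constant zero differences return p = 1. Neither occurs with continuous
  noise; both are pinned by tests.
- `zscore()` refuses cohorts with fewer than two values or zero
  standard deviation, naming the gene.
- Empty overlap sets, all-censored arms and genes with an empty altered
  arm all return well-formed empty/NA results rather than failing, and
  the log-rank test returns p = 1 with a warning when the variance is
  zero.
- Hypergeometric enrichment errors when the stated universe is smaller
  than the union of the target sets.

## Problem sizes used by the test suite

Module tests run on hand-built fixtures of a few rows. Recovery and
calibration checks use the generator defaults above (10,000 probes, 12
pairs) for SDMC sensitivity/FDP, three seeded default-scale bundles for
exact crosstalk recovery, 1,000 null replicates at 100 patients per arm
for log-rank type-I calibration and 100 replicates at 250 per arm for
power — sizes at which a full suite run stays within about half a
minute on one core while keeping Monte-Carlo error well below the
asserted margins.

## Known limitations

- No upstream preprocessing: IDAT parsing, normalization, batch
  correction and RNA-seq quantification are out of scope; the pipeline
  starts from a beta matrix and a lncRNA table.
- The methylation→gene assignment rule (promoter or body) is a
  documented convention, not an inference; promoter-only counts are
  available for comparison.
- Cis-regulation is purely positional (body-over-promoter overlap); no
  expression correlation across patients is computed, and trans effects
  are not modelled.
- Gene Ontology enrichment and plotting are intentionally absent; the
  outputs are tables and a JSON report meant to feed downstream tools.
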