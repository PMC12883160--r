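---
title: "Methods: tissue-specificity, housekeeping stability and structural-variant analytics on a multi-tissue expression atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-specificity, housekeeping stability and structural-variant analytics on a multi-tissue expression atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vescatlas)
```

# Scope

`vescatlas` implements the analytical core of a multi-tissue plant
expression-atlas study combined with structural-variant (SV) analytics:

1. expression ingestion, expressed-gene filtering, log transformation and
   batch adjustment;
2. tissue-specificity (tau) and housekeeping calling;
3. multi-caller SV merging, confidence tiering, transposable-element (TE)
   content classification, genic-overlap enrichment and SV-expression
   association;
4. reconciliation of gene identifiers between two annotation versions;
5. a seeded synthetic-data generator that emulates all pipeline inputs with
   exported ground truth, plus an orchestrator (`run_all()`) that runs every
   stage end-to-end.

This vignette records the statistical models, the default parameters and the
reasoning behind the main design decisions. It is source-only documentation;
the code below is the same API exercised by the test suite.

# Expression model

## Ingestion and filtering

Expression is a genes x samples TPM matrix with sample metadata (`tissue`,
`batch`). A gene is *expressed* in a sample when TPM > 1 (strict); TPM values
at or below 1 are treated as noise. `expressed_gene_mask()` derives three
gene sets: expressed anywhere (in at least one sample), expressed everywhere
(in all samples), and never expressed. The strict inequality means a gene
sitting exactly at TPM = 1 is *not* expressed; the same boundary is used by
the zeroing rule below, so the two filters can never disagree at the
boundary.

## Log transform and batch adjustment

`log_transform()` computes `log2(TPM + eps)` with `eps = 0.01` and records a
`low_flag` matrix marking TPM <= 1 entries. A small positive `eps` keeps
zeros finite while compressing them far below the expressed range; `eps = 0`
is rejected.

`batch_adjust()` (method `tissue_stratified_centering`) removes, per gene,
each batch's mean deviation from its samples' tissue means — the additive
batch effect estimated after stripping tissue structure — and then re-centres
within tissue so per-gene tissue grand means are preserved exactly. The
estimator is a deliberately simple, fully deterministic stand-in for
surrogate-variable-style correction; a `plugin` method accepts an externally
corrected matrix for users who prefer a heavier tool. A batch whose samples
all come from one tissue is confounded with tissue and is skipped with a
warning rather than silently absorbing biology into the correction.

## Tissue profile and scale decisions

`tissue_means()` aggregates per tissue. The default `threshold_log2` scale
operationalises the low-expression rule: values are mapped back to the TPM
scale from the adjusted matrix (`2^v - eps`), TPM <= 1 is set to 0, and
`log2(x + 1)` is averaged per tissue. Tau (below) is computed on this scale.

A substantive decision: the specificity profile is computed from the
*batch-adjusted* matrix, not raw TPM. With additive batch offsets of sd 1 on
the log2 scale, raw-scale means leak batch noise into off-target tissues and
depress tau for genuinely specific genes; the adjusted matrix is also what
the differential tests see, so calls are internally consistent. `raw_tpm`
and `adjusted_log2` scales remain available.

# Tissue-specificity calling

The tau index over N tissue means `x` (all >= 0) is

    tau = sum_i (1 - x_i / max(x)) / (N - 1)

which is 0 for uniform expression, 1 for single-tissue expression, undefined
(NA) when all means are zero, and invariant to positive rescaling.

`call_ts()` combines tau with differential expression. The candidate tissue
is the argmax of the gene's tissue means. The candidate is contrasted
against every other tissue (8 contrasts under the default nine-tissue
design) on per-sample adjusted log2 values with Welch's t-test (an
empirical-Bayes moderated t is available for small designs). A gene passes
DE when in **all** contrasts the signed log2 fold change toward the
candidate is >= 2 and the Benjamini-Hochberg adjusted p-value is <= 0.01; BH
is applied per contrast family across the genes sharing a candidate tissue,
so the multiplicity correction matches the family actually tested. The
final call is the conjunction of DE and tau >= 0.85 (union available).
Tissues with fewer than two samples cannot be candidates and are reported
with a warning.

Defaults (`lfc_min = 2`, `padj_max = 0.01`, `tau_min = 0.85`) are the
study's operating point; all are explicit arguments.

# Housekeeping calling

`call_hk()` candidates are the genes expressed everywhere. A candidate is a
housekeeping gene when (a) its adjusted log2 value strictly exceeds, in
every sample, that sample's median across all genes (a rank-based
"consistently above typical expression" requirement; a single global median
is available), and (b) its stability score — the coefficient of variation of
the adjusted log2 values across samples, computed on the low-expression-
zeroed scale — is at most `cv_max = 0.1` (plain standard deviation
available). Results are sorted most-stable first. Housekeeping and
tissue-specific sets are disjoint by construction of their criteria; the
orchestrator asserts this.

# Structural-variant analytics

## Conventions

All intervals are 0-based half-open internally. Conversions happen only at
I/O: GFF3 and RepeatMasker `.out` are 1-based closed, VCF `POS` is 1-based.
Insertions carry `end == pos` (no reference footprint) and their `length` is
the inserted sequence length; deletions have `end - pos == length`. Calls
shorter than 50 bp are dropped at ingestion.

## Merging and tiering

`merge_svs()` pools three callers — an assembly-based caller (`svim_asm`), a
short-read caller (`manta`) and a long-read caller (`sniffles`) — and
clusters calls sharing chromosome and SV type whose start positions chain
within 1 kb (single linkage). The representative is the assembly caller's
member when present (the merged set is assembly-anchored), otherwise the
longest member; support is the union of member callers.

`classify_tier()`: tier 1 requires support from all three callers; tier 2 is
insertions longer than 500 bp (strict) supported by assembly and long reads
but not tier 1 — short-read callers are insufficiently sensitive for large
insertions, so demanding their agreement would discard true events; tier 3
is everything else. A merged call without assembly support cannot escape
tier 3 and triggers a warning. Tiers 1-2 form the high-confidence set used
downstream.

## TE-content classification

Under random placement, the TE proportion of a length-`l` region is modelled
as approximately Normal, `p_hat ~ N(p, p(1 - p) / l)`, with `p` the
genome-wide background TE proportion. Two tails at `alpha / 2` (total
`alpha = 0.05`) label regions `TE_derived` (upper) or `TE_depleted` (lower);
the rest are `background`. TE-covered bases are counted on the flattened
(union) TE track so overlapping annotations are not double-counted.
TE-derived regions whose dominant family covers more than 80% of the
region's TE bases are `TE_derived_occupancy` (single-element origin);
otherwise `TE_derived_complex`. The occupancy denominator is the region's
TE bases by default — the question asked is "of the TE content, is it one
element?" — with `region_length` available as an alternative.

## Overlap enrichment and gene association

`overlap_enrichment()` flattens the footprint of non-insertion
high-confidence SVs and intersects it at base resolution with the
exon/intron/intergenic partition of the genome (exon takes precedence over
intron for overlapping gene models). Observed base counts are compared with
the genomic proportions by a chi-square goodness-of-fit test (df = 2, where
the closed form `p = exp(-X^2 / 2)` holds).

`link_genes()` associates an SV with a gene when it overlaps the gene span
or the 2-kb strand-aware promoter window (`+`: `[start - 2000, start)`;
`-`: `[end, end + 2000)`), clipped at chromosome ends; insertions count as
1-bp breakpoints. Links are sub-labelled `exon`, `intron`, `promoter`, or
`spanning`. `expression_association()` then compares SV-harboring genes with
all remaining genes by two-sided Wilcoxon rank-sum tests on mean adjusted
expression, tau, and |log2FC| between genotypes, plus a per-region
stratification with BH adjustment.

# Identifier reconciliation

`reconcile()` maps version-A gene ids to version-B ids in three confidence
tiers: `synteny_1to1` (anchor pairs in which both ids occur in exactly one
anchor; genes in several anchors — tandem arrays — are demoted rather than
guessed), then `orthogroup_1to1` (orthogroups with exactly one unmapped gene
of each version), then `orthogroup_best` (minimum evolutionary distance
within the orthogroup, ties broken lexicographically). Genes with no
orthogroup or no finite distance to any candidate remain `unmapped`; every
version-A gene appears exactly once in the output.

# Synthetic data and what it does (not) emulate

`generate_synthetic()` produces every pipeline input from one seed:
a 5 x 2-Mb genome with 2,000 three-exon genes; a background TE landscape
tuned to 30% coverage across 20 families with skewed abundances; planted
occupancy/complex/depleted TE regions under intergenic deletions; three
per-caller VCFs with role-specific sensitivities (assembly 1.0, long-read
0.9, short-read 0.85 falling to 0.1 for insertions > 500 bp) and ±100 bp
breakpoint jitter for the mapping-based callers; a nine-tissue, 6-samples-
per-tissue TPM matrix from three batches (additive per-gene offsets, sd 1)
with 100 planted tissue-specific genes (+4 log2 in one tissue), 100
housekeeping genes (high mean, sd 0.2) and a −1 log2 effect on genes
harboring high-confidence SVs; id-mapping evidence realising all confidence
tiers; and a `truth.json` with every planted fact.

The generator emulates the *statistical shape* of the study inputs — enough
structure for every pipeline branch to be exercised and scored against
truth. It does not emulate sequence content, read alignment, splice
isoform complexity beyond one transcript per gene, or caller-specific error
modes beyond sensitivity and jitter. Problem sizes are the package's own
choice: large enough that planted-signal recovery is a meaningful measure
(binomial noise on 100 planted genes is ±3%), small enough that the full
pipeline runs in well under a minute.

# Worked example

```{r example, eval = FALSE}
report <- run_all(synthetic_config(seed = 101))
print(report)
#> vescatlas run report (seed 101 )
#>   expression: 97 TS (sens 0.950, FDP 0.021), 106 HK (sens 1.000), tissue ARI 1.000
#>   sv: 260 merged (tier1 149, tier2 37, tier3 74); enrichment X2 = 11552.3, p = 0
#>   idmap: 2000 genes, accuracy 1.000
```

# Numerical and engineering notes

- Welch's t is hand-rolled only to pin down degenerate cases (both groups
  constant and equal: p = 1; constant and unequal: p = 0) that `t.test()`
  rejects with an error; it matches `t.test()` to 1e-10 elsewhere.
- The Wilcoxon wrapper uses the exact distribution when both groups are
  <= 12 without ties, the normal approximation with continuity correction
  otherwise — and defines the all-tied case as p = 1.
- BH adjustment, chi-square tests, hierarchical clustering and the adjusted
  Rand index delegate to `stats` and `mclust`.
- Report JSON fields are ordered with C-locale (radix) sorting so output is
  byte-identical across locales.
- All randomness flows from a single integer seed; the same seed yields
  byte-identical generated files.

# Limitations

- The batch model is additive per gene; multiplicative or rank-distorting
  batch effects require the `plugin` adjustment path.
- The TE normal approximation is anti-conservative for very short regions;
  the pipeline only tests regions >= 50 bp and the calibration test pins the
  realized null rate at lengths 500 and 2000.
- Tier rules encode a three-caller design with fixed roles; other caller
  ensembles need their own rule set.
- `orthogroup_best` mapping is not injective: two version-A genes may map to
  the same version-B gene at the lowest confidence tier.
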