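---
title: "devage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{devage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devage)
```

# Scope

`devage` implements the statistical chain of an integrative fetal-brain
study in three mouse strains of differing longevity (A = AKR/J, B =
C57BL/6J, C = the congenic Cav1-null line) sampled on gestational days 12,
15 and 17: splice-junction specificity classification, epigenetic-clock
methylation comparison, SNP–methylation proximity enrichment, and
differential-expression contingency statistics.  Upstream read processing
(QC, trimming, alignment, methylation extraction, DE model fitting) is out
of scope; the package consumes the standard result formats those tools emit
and a synthetic generator stands in for the deposited raw data.

# Splice-junction specificity

## Model

A junction is identified by (chromosome, intron start, intron end, strand),
1-based inclusive, the coordinate frame of the 9-column junction-table
dialect.  After merging tables over the 27-sample design (absent junction →
zero counts), three filters apply, in order:

* **multi-mapped support** — default policy `drop_if_any` removes a junction
  if any sample reports multi-mapped reads.  The filtering rule this
  follows reads literally as dropping such junctions; because that reading
  is aggressive, a `unique_only` policy (ignore multi-mapped counts, keep
  the junction) is offered behind a flag.
* **overhang** — removed when the maximum overhang across all supporting
  samples is below 20 bp.  A junction well-supported in one sample is not
  discarded for a poor overhang elsewhere; whether the original `awk`
  filtering was per sample or per junction is not decidable from the
  description, so the per-junction maximum was chosen and documented here.
* **read support** — removed when unique reads are below 10 in every
  sample.

**S/NS classification.** Cell support is the sum of unique reads over a
(strain, day) cell's replicates (`pooling = "pooled"`); a junction is S iff
exactly one cell reaches the threshold (10) and every other cell is below
it.  One threshold serves both "present" and "absent" because only one
number governs the rule.  Pooling across replicates matches the phrasing
"at a specific time point" (which never mentions replicates); an
`all_replicates` mode (every replicate ≥ threshold) is available.  The
tolerated sub-threshold support elsewhere (1–9 reads) is treated as
absence.

Novelty is exact-coordinate matching against introns derived from the
annotation's exon structure; gene assignment is ≥ 1 bp interval
intersection (the default semantics of interval-intersection tools),
delegated to `GenomicRanges`.

## What the generator emulates

`simulate_junction_tables()` plants, per strain × day cell, junctions whose
pooled support in that cell is forced to the threshold or above and is zero
elsewhere — so planted truth is recoverable exactly, by construction, at
the default `read_depth_mean = 30` (Poisson).  Background junctions appear
in ~95% of samples; decoy classes (overhang < 20 bp everywhere;
multi-mapped support) exist only to exercise the filters.  Real junction
data differ in ways the generator does not model: overdispersed counts,
partially shared junctions between strains, coverage-dependent overhangs.
Passing tests therefore show the bookkeeping and rules are right, not that
the biological totals (130,424 junctions; 378 S variants) would be
reproduced — those require the deposited data.

# Epigenetic-clock methylation

## The β→M transform and the DM test

β-values (methylated-read fractions) are heteroscedastic near 0 and 1;
testing is done on M = log2(β/(1−β)).  Boundary β (0 or 1) is undefined
under the transform: ingest clamps to [ε, 1−ε] with ε = 1e−6, warns, and
records the count.

DM testing is per strain pair — a one-way ANOVA between two groups of
M-values per site, vectorized as the pooled-variance F = t² with
(1, nA+nB−2) df.  The pairwise (rather than single three-group) layout
matches the pairwise Manhattan plots and pairwise DM-set Venn partitions
the analysis reports.  Degenerate sites (zero within-group variance) get
p = 1 when means agree, p = 0 otherwise.  Calls use raw p < 0.05, strict,
with no multiple-testing correction — mirroring the original thresholding
across the 2045-site panel; a Benjamini–Hochberg option exists and is off
by default.

## Clustering comparison

Hierarchical clustering uses Euclidean distance with complete linkage (the
`hclust` default; configurable to average/single — the original linkage is
unstated).  What exactly was clustered for the published dendrogram
comparison (sites, strains, or change profiles) is ambiguous; this package
clusters **sites by their per-site change profile** (difference of group
mean M-values) for each strain pair and compares strain pairs by the
Pearson correlation of cophenetic distance vectors.  The pipeline
subsamples 60 sites (fixed by the run seed) for this comparison to keep
dendrograms readable and the run light.  The published correlation values
(0.96/0.89/0.64/0.66) depend on the real data and on that unstated
clustering choice, so they are structural, not numeric, targets here.

## Generator

`simulate_methylation()` draws per-site baseline M ~ Normal(0, 1.5²),
shifts one randomly chosen strain by `effect_m` at a `dm_fraction` of
sites, adds Normal(0, `noise_sd_m`) sample noise, and back-transforms —
β lands strictly inside (0,1) by construction.  Defaults: 2045 sites,
`dm_fraction = 0.29` (593 planted sites, the magnitude of the reported 594
DM sites), `effect_m = 2`, `noise_sd_m = 0.3`.  The per-site variance of
clock CpGs is not stated in the source study; 0.3 M-units is a free
parameter chosen as a realistic within-strain SD, not an estimate.  The
methylation design is 3 strains × duplicates (d15), so the per-pair test
has (1, 2) df; per-pair power at the defaults is ≈ 0.89, and planted-site
recovery through either affected pair ≈ 0.95 — the property the tests
check.  Under `effect_m = 0` the per-pair type-I error is 0.05 by
construction of the exact F reference.

# SNP–methylation proximity enrichment

Nearest distances are computed per chromosome (binary search on sorted
positions; points on chromosomes without targets are excluded).  Distances
are kept in bp internally; the ten bins are labeled in kb with the first
bin closed [0, 100] bp and subsequent bins half-open (lo, hi], so every
distance ≤ 1000 kb falls in exactly one bin; larger distances fall in no
bin.  **Both directions are binned** — each SNP by its nearest DM and each
DM by its nearest SNP — the only reading consistent with separate SNP and
DM counts per bin; complements are taken within each set's binned universe
so column totals are consistent across bins (the published table's SNP
totals drift between rows, which a consistent partition cannot reproduce;
the statistical step is therefore validated directly on the printed count
rows).

The test is the **one-sided (greater) Fisher exact test** with the
**conditional-MLE odds ratio** (root of the noncentral hypergeometric mean
equation, solved in the log-odds parameter to 1e−12).  The original
methods text mentions both Fisher's exact test and Pearson's chi-square;
the one-sided exact test plus conditional MLE is the unique combination
that reproduces all ten printed OR/p pairs (odds ratios below 1 carry
p > 0.5, impossible two-sided; the printed 1.4418 is the conditional MLE,
not the sample ratio 1.4420).  Two-sided and sample-OR modes are available
behind flags.

`simulate_snp_dm_landscape()` places SNPs uniformly and plants a fraction
of DM sites within `max_pair_distance` of a random SNP (offset uniform,
either side), the rest uniform, on a 100 Mb synthetic chromosome — giving
background nearest distances of tens of kb, so planted sub-kilobase pairs
are the only sub-kilobase mass.  One caveat discovered during validation
and reflected in the tests: with unequal set sizes (303 SNPs vs 1957 DM
sites) the two nearest-distance distributions differ systematically even
with no planting, because each SNP sees the denser DM set; a meaningful
null calibration therefore uses matched densities, and even then "no bin
significant anywhere" is only expected in ~0.95¹⁰ of runs — the tests check
per-bin calibration, not the joint event.

# Differential-expression contingency

Direction per gene: UP if logFC > 0 and FDR < 0.05 (strict), DOWN if
logFC < 0 and FDR < 0.05, else NS; a significant zero logFC is NS with a
warning.  The strain × {UP-P1, DOWN-P1, UP-P2, DOWN-P2} layout is the only
natural table giving the reported df = 3 for two-strain contrasts;
chi-square is Pearson without continuity correction (the R default applies
Yates only to 2×2) and Cramer's V = sqrt(χ²/(n·min(r−1, c−1))).
Expression correlation uses log2(CPM+1) and Pearson (Spearman available);
the original transform is unstated, and log-CPM is the field's standard
choice.  The generator plants exact significant counts per (strain, phase),
early-skewed for the short-lived strains and late-skewed for the long-lived
strain, as fractions of the gene catalog so scaled-down runs keep the same
skew.

# Numerical choices and degenerate inputs

* Round-half-away-from-zero for reported averages (R's `round` is
  banker's rounding).
* `fisher_one_sided` on an all-zero table errors; a zero top-left cell
  returns p = 1 exactly.
* `odds_ratio_cmle` returns 0 / Inf at boundary tables; the root search
  runs on log ψ ∈ [−50, 50] with weights normalized by their maximum to
  avoid overflow.
* Chi-square functions reject zero marginal totals rather than returning
  NaN.
* Duplicate positions in point sets are allowed but flagged; VCF ingest
  deduplicates and logs the count.
* Chromosome names are normalized (leading `chr` stripped) on ingest, since
  VCF and annotation dialects differ.
* All generators take explicit integer seeds through `withr::with_seed`;
  no global RNG state is mutated.

# Problem sizes

The default configuration runs the full chain in well under a minute:
27 junction tables with 200 background + 45 planted junctions, a 2045 × 6
methylation matrix, a 303/1957-point landscape, and 2000-gene DE tables.
Monte-Carlo rates (type-I error, recovery, enrichment-pattern frequency)
use 20 seeds each at 300–400 sites; the unbiasedness check uses 50 seeds at
120 sites.  These sizes were chosen so properties are estimated with
standard errors comfortably inside the asserted bands.

# Known limitations

* The generator's count models (Poisson reads, Normal M-noise, uniform
  point placement) are deliberately minimal; they exercise thresholds and
  statistics, not the full complexity of sequencing data.
* Dataset-dependent totals from the original study (130,424 junctions, 378
  S variants, 594 DM sites, the published cophenetic correlations and DE
  chi-squares) require the deposited raw data and are covered structurally,
  not numerically.
* DE model fitting, GO/pathway enrichment and epigenetic-clock age
  prediction are out of scope by design.
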