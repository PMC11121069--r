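# devage

Integrative analysis of fetal brain development in mouse strains that differ
in longevity — a reusable, tested R implementation of the analysis chain
linking alternative splicing, epigenetic-clock DNA methylation, genetic
variation and differential expression across gestation.

## The scientific problem

Long-lived (C57BL/6J) and short-lived (AKR/J inbred; B6.Cg-*Cav1*-null
congenic) mouse strains differ in how gene regulation unfolds in the fetal
brain between gestational days 12, 15 and 17.  Four analyses probe that
difference:

1. **Developmental-time-specific splice variants.** Multi-sample splice
   junction tables (the 9-column `SJ.out.tab` dialect of two-pass spliced
   alignment) are merged over the 3 strain × 3 day × 3 replicate design,
   filtered (multi-mapped support dropped, overhang < 20 bp dropped,
   junctions with < 10 reads in all samples dropped), and each junction is
   called **S** (specific) when its pooled unique-read support is ≥ 10 in
   exactly one strain × day cell and < 10 in every other cell, else **NS**.
   S/NS calls are cross-tabulated with known/novel status (exact coordinate
   match against annotated introns), splice motifs (GT/AG, CT/AC), gene
   assignment by ≥ 1 bp coordinate intersection, and day contrasts via
   Pearson chi-square.

2. **Epigenetic-clock methylation.** β-values at 2045 clock CpG sites are
   variance-stabilized, M = log2(β/(1−β)), and each site is tested between
   strain pairs by one-way ANOVA (two groups: F = t², df (1, nA+nB−2));
   DM sites are those with raw p < 0.05.  DM sets are partitioned as Venn
   regions, laid out Manhattan-style per chromosome, and clustering
   structure of per-site change profiles is compared between strain pairs by
   the cophenetic correlation of their dendrograms.

3. **SNP–methylation proximity.** For SNP and DM point sets, each point is
   binned by nearest-neighbor distance into ten bins (0–0.1, 0.1–1, 1–5,
   5–10, 10–50, 50–100, 100–200, 200–400, 400–800, 800–1000 kb).  Per bin,
   the 2×2 within/not-within table is tested with a one-sided Fisher exact
   test (hypergeometric tail) and summarized by the **conditional-MLE odds
   ratio** — the maximizer of the noncentral hypergeometric likelihood at
   fixed margins, the estimator R's exact-test toolchain reports (for the
   first bin: 1.4418, versus the sample cross-product ratio 1.4420).

4. **Differential-expression contingency.** UP/DOWN gene counts per strain
   and phase (P1: d12→d15, P2: d15→d17) form strain × category tables tested
   by Pearson chi-square (df = 3) with Cramer's V
   = sqrt(χ²/(n·min(r−1, c−1))) as effect size, plus strain-specific Venn
   partitions and log2(CPM+1) expression correlations between samples.

Because the deposited raw data are not required at desk scale, a
**synthetic-data generator** (first-class, tested) emulates every input with
recorded planted truth: strain×day-exclusive junctions, M-scale strain
shifts at a set fraction of CpG sites, DM sites planted within 1 kb of
SNPs, and phase-skewed DE tables.  Every pipeline stage is validated by
recovering that truth.

## Worked example

The analysis is organised as numbered drivers under `analysis/`
(`Rscript analysis/00_run_all.R` runs the chain; outputs land in
`results/`).  The same computation is available as one call:

```r
library(devage)
report <- run_pipeline(list(seed = 1L, out = "results/pipeline"))
```

With the default configuration (study-scale synthetic inputs, seed 1) the
drivers print:

```
S variants: 45 (NS: 200); recovery vs planted truth: TRUE
DM sites (p < 0.05): A_vs_B 394, A_vs_C 443, B_vs_C 450
significant bins: 0-0.1 kb, 0.1-1 kb (planted enrichment is confined to <= 1 kb)
A vs B: chi2 = 421.2, df = 3, p = 5.67e-91, Cramer's V = 0.501
```

Reading: all 45 planted strain×day-exclusive junctions (5 per cell) survive
the filters and are called S with the correct cell; roughly 2/3 of the 593
planted DM sites are detectable per strain pair (each site shifts one
strain, so two of three pairs carry its signal, on top of a calibrated 5%
false-positive floor); proximity enrichment is significant exactly in the
two sub-kilobase bins where it was planted; and the planted strain-phase
skew in DE counts registers as a strong association (V > 0.2) between a
short- and the long-lived strain, while the two short-lived strains show
V = 0 against each other.

Recomputing the published association statistics from the printed
within/not-within count rows (`analysis/04_snpdm.R`) reproduces, e.g. for
the 0–0.1 kb bin, odds ratio 1.44179 and p 0.03737.

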