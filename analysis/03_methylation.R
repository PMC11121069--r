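#!/usr/bin/env Rscript
# Stage 3: epigenetic-clock methylation comparison between strains.
#
# Transforms the beta matrix to M-values, runs the per-site one-way ANOVA
# for each strain pair, calls DM sites at raw p < 0.05, partitions them
# (Venn), emits the Manhattan-style table, and compares the hierarchical
# clustering of per-site change profiles across strain pairs by cophenetic
# correlation.

library(devage)

fixdir <- "results/fixtures"
design <- sample_design(c("A", "B", "C"), 15, 2)
mat <- read_beta_matrix(file.path(fixdir, "beta_values.csv"), design)

pairs <- list(c("A", "B"), c("A", "C"), c("B", "C"))
results <- lapply(pairs, function(p) dm_anova(mat, p[1], p[2]))
names(results) <- vapply(pairs, paste, "", collapse = "_vs_")

dm_sets <- lapply(results, call_dm, alpha = 0.05)
message(sprintf("DM sites (p < 0.05): %s",
                paste(names(dm_sets), lengths(dm_sets), collapse = ", ")))

venn <- venn_partition(dm_sets)
message(sprintf("shared across all three pairs: %d", venn[["A_vs_B&A_vs_C&B_vs_C"]]))
write_tsv(data.frame(region = names(venn), count = venn), "results/dm_venn.tsv")

manh <- manhattan_table(do.call(rbind, results))
write_tsv(manh, "results/dm_manhattan.tsv")

# cluster a fixed site subsample on each pair's change profile and compare
profiles <- vapply(pairs, function(p) dm_change_profile(mat, p[1], p[2]),
                   numeric(nrow(mat$sites)))
colnames(profiles) <- names(results)
sub <- withr::with_seed(1L, sort(sample.int(nrow(profiles), 60)))
dends <- lapply(colnames(profiles), function(nm)
  hier_cluster(profiles[sub, nm, drop = FALSE]))
names(dends) <- colnames(profiles)
coph <- outer(names(dends), names(dends),
              Vectorize(function(a, b)
                cophenetic_correlation(dends[[a]], dends[[b]])))
dimnames(coph) <- list(names(dends), names(dends))
message("cophenetic correlations of methylation-change clusterings:")
print(round(coph, 3))
write_tsv(as.data.frame(coph), "results/dm_cophenetic.tsv")
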