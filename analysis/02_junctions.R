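#!/usr/bin/env Rscript
# Stage 2: splice-junction merge, filtering and time-specificity calls.
#
# Reads the per-sample junction tables written by 01_simulate.R, merges them
# over the 27-sample design, applies the overhang (>= 20 bp), multi-mapped
# and read-support (>= 10 in at least one sample) filters, classifies each
# surviving junction as specific (S: >= 10 pooled reads in exactly one
# strain x day cell) or non-specific (NS), annotates novelty and genes, and
# contrasts S counts between consecutive days.

library(devage)

fixdir <- "results/fixtures"
design <- read_design(file.path(fixdir, "design.yaml"))
gtf <- file.path(fixdir, "annotation.gtf")

tables <- setNames(
  lapply(design$sample_id, function(sid)
    read_junction_table(file.path(fixdir, "sj", paste0(sid, ".SJ.out.tab")))),
  design$sample_id)
mat <- merge_junctions(tables, design)
message(sprintf("merged: %d junctions across %d samples",
                nrow(mat$junctions), ncol(mat$unique_reads)))

mat <- filter_junctions(mat, min_overhang = 20, min_reads = 10,
                        multimap_policy = "drop_if_any")
message(sprintf("after filters: %d junctions", nrow(mat$junctions)))

calls <- classify_time_specificity(mat, threshold = 10, pooling = "pooled")
novelty <- classify_novelty(mat, gtf)
genes <- assign_genes(mat, gtf)
calls$novelty <- novelty$novelty[match(calls$key, novelty$key)]
calls$gene_ids <- vapply(genes[calls$key], paste, "", collapse = ",")

counts <- specificity_counts(calls)
message(sprintf("S variants: %d (NS: %d); recovery vs planted truth: %s",
                attr(counts, "total_S"), attr(counts, "n_NS"),
                all(sort(calls$key[calls$label == "S"]) ==
                      sort(read_truth(fixdir)$specific_junctions$key))))

# day contrasts of per-strain S counts (d12 vs d15, d15 vs d17)
per_cell <- xtabs(n_S ~ day + strain, counts)
c1 <- day_contrast_chisq(per_cell[c("12", "15"), ])
c2 <- day_contrast_chisq(per_cell[c("15", "17"), ])
message(sprintf("d12 vs d15: chi2 = %.2f (df %d, p = %.3g); d15 vs d17: chi2 = %.2f (df %d, p = %.3g)",
                c1$chi2, c1$df, c1$p, c2$chi2, c2$df, c2$p))

write_tsv(calls, "results/junction_calls.tsv")
write_tsv(counts, "results/junction_specificity_counts.tsv")
write_tsv(motif_summary(calls, mat), "results/junction_motifs.tsv")
write_tsv(data.frame(contrast = c("d12_vs_d15", "d15_vs_d17"),
                     chi2 = c(c1$chi2, c2$chi2), df = c(c1$df, c2$df),
                     p = c(c1$p, c2$p)),
          "results/junction_day_contrasts.tsv")
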