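#!/usr/bin/env Rscript
# Stage 5: contingency statistics on the differential-expression tables.
#
# Counts UP/DOWN genes per strain and developmental phase (P1: d12->d15,
# P2: d15->d17), tests the strain x category association with Pearson
# chi-square (df = 3) and Cramer's V for the short- vs long-lived strain
# contrasts, and partitions strain-specific gene sets as Venn regions.

library(devage)

fixdir <- "results/fixtures"
de_files <- list.files(file.path(fixdir, "de"), full.names = TRUE)
de_tables <- lapply(de_files, function(f) {
  parts <- strsplit(sub("[.]tsv$", "", basename(f)), ".", fixed = TRUE)[[1]]
  read_de_table(f, strain = parts[1], phase = parts[2])
})

pc <- phase_counts(de_tables)
message("DE counts (strain x phase/direction):")
print(pc)
write_tsv(as.data.frame(pc), "results/de_phase_counts.tsv")

for (contrast in list(c("A", "B"), c("C", "B"), c("A", "C"))) {
  st <- chisq_cramers_v(pc[contrast, ])
  message(sprintf("%s vs %s: chi2 = %.1f, df = %d, p = %.3g, Cramer's V = %.3f",
                  contrast[1], contrast[2], st$chi2, st$df, st$p, st$cramers_v))
}

phase <- vapply(de_tables, attr, "", "phase")
strain <- vapply(de_tables, attr, "", "strain")
for (dir in c("UP", "DOWN")) {
  sets <- setNames(lapply(de_tables[phase == "P1"], de_genes, dir),
                   strain[phase == "P1"])
  v <- de_venn(sets)
  message(sprintf("P1 %s-regulated Venn regions: %s", dir,
                  paste(names(v), v, sep = "=", collapse = ", ")))
  write_tsv(data.frame(region = names(v), count = v),
            sprintf("results/de_venn_P1_%s.tsv", tolower(dir)))
}
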