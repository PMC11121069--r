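#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with recorded planted truth.
#
# Emulates the study layout: 27 RNA samples (3 strains x gestational days
# 12/15/17 x 3 replicates) worth of splice-junction tables with 5 planted
# time-specific junctions per cell, a 2045-site epigenetic-clock beta matrix
# (3 strains x duplicates, d15) with a 29% planted DM fraction, a 303-SNP /
# 1957-DM-site landscape with 30% of DM sites planted within 1 kb of a SNP,
# and early/late-skewed differential-expression tables.

library(devage)

seed <- 1L
out <- "results/fixtures"

rna_design <- sample_design(c("A", "B", "C"), c(12, 15, 17), 3)
meth_design <- sample_design(c("A", "B", "C"), 15, 2)
genome <- generate_genome(n_chroms = 2, chrom_len = 2e6, n_genes = 150,
                          seed = seed)
landscape_genome <- generate_genome(n_chroms = 1, chrom_len = 1e8,
                                    n_genes = 0, seed = seed)

sim <- list(
  design = rna_design,
  genome = genome,
  junctions = simulate_junction_tables(rna_design, genome,
                                       n_background_junctions = 200,
                                       n_planted_specific_per_cell = 5,
                                       read_depth_mean = 30, seed = seed),
  methylation = simulate_methylation(meth_design, n_sites = 2045,
                                     dm_fraction = 0.29, effect_m = 2,
                                     noise_sd_m = 0.3, seed = seed),
  landscape = simulate_snp_dm_landscape(landscape_genome, n_snps = 303,
                                        n_dm = 1957, proximal_fraction = 0.3,
                                        max_pair_distance = 1000, seed = seed),
  de = simulate_de_tables(rna_design, n_genes = 2000, seed = seed))

manifest <- write_fixtures(sim, out)

message(sprintf("wrote %d fixture files to %s", nrow(manifest), out))
message(sprintf("planted: %d time-specific junctions, %d DM sites, %d proximal SNP-DM pairs",
                nrow(sim$junctions$truth$specific_junctions),
                nrow(sim$methylation$truth),
                nrow(sim$landscape$truth)))
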