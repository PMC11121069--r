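write_sj <- function(lines) {
  p <- withr::local_tempfile(fileext = ".tab", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("junction table parsing decodes the 9-column dialect and rejects malformed lines", {
  rec <- read_junction_table(write_sj("chr1\t1000\t2000\t1\t1\t1\t25\t0\t30"))
  expect_equal(rec$strand, "+")
  expect_equal(rec$motif_code, 1L)       # GT/AG
  expect_equal(rec$annotated_flag, 1L)
  expect_equal(rec$unique_reads, 25L)
  expect_equal(rec$max_overhang, 30L)
  expect_equal(read_junction_table(write_sj("chr1\t5\t9\t0\t0\t0\t1\t2\t3"))$strand,
               "undefined")
  expect_equal(nrow(read_junction_table(write_sj(character(0)))), 0)
  expect_error(read_junction_table(write_sj("chr1\t1\t2\t1\t1\t1\t5\t0")),
               "line 1.*9 tab-separated")
  expect_error(read_junction_table(
    write_sj(c("chr1\t1\t9\t1\t1\t1\t5\t0\t20", "chr1\t1\t9\t9\t1\t1\t5\t0\t20"))),
    "line 2.*strand")
  expect_error(read_junction_table(write_sj("chr1\tx\t9\t1\t1\t1\t5\t0\t20")),
               "column intron_start")
})

test_that("merging takes the union with zero fill and detects motif conflicts", {
  s1 <- data.frame(chrom = "chr1", intron_start = c(100, 500, 900),
                   intron_end = c(200, 600, 990), strand = "+",
                   motif_code = 1L, annotated_flag = 1L,
                   unique_reads = 10L, multimapped_reads = 0L,
                   max_overhang = 25L, stringsAsFactors = FALSE)
  s2 <- s1[1, ]; s2$intron_start <- 3000; s2$intron_end <- 3100
  s3 <- s1[0, ]
  design <- sample_design(c("A", "B"), 12, 2)
  mat <- merge_junctions(list(A_d12_r1 = s1, A_d12_r2 = s2, B_d12_r1 = s3,
                              B_d12_r2 = s3[0, ]), design)
  expect_equal(nrow(mat$junctions), 4)  # disjoint 3 + 1
  expect_equal(sum(mat$unique_reads[, "A_d12_r1"] > 0), 3)
  expect_equal(sum(mat$unique_reads[, "B_d12_r1"]), 0)
  # one junction present in 1 of 4 samples: 3 zero cells
  expect_equal(sum(mat$unique_reads[junction_key <- paste0("chr1:3000-3100:+"), ] == 0), 3)
  conflict <- s1[1, ]; conflict$motif_code <- 2L
  expect_error(merge_junctions(list(A_d12_r1 = s1, A_d12_r2 = conflict), design),
               "conflict")
  expect_error(merge_junctions(list(Z_d99_r1 = s1), design), "unknown sample")
})

make_matrix <- function(uniq, multi = NULL, over = NULL, design) {
  nJ <- nrow(uniq)
  j <- data.frame(chrom = "chr1", intron_start = seq_len(nJ) * 1000,
                  intron_end = seq_len(nJ) * 1000 + 500, strand = "+",
                  motif_code = 1L, annotated_flag = 1L,
                  stringsAsFactors = FALSE)
  j$key <- paste0(j$chrom, ":", j$intron_start, "-", j$intron_end, ":+")
  dimnames(uniq) <- list(j$key, design$sample_id)
  if (is.null(multi)) multi <- uniq * 0L
  if (is.null(over)) over <- (uniq > 0) * 30L
  dimnames(multi) <- dimnames(over) <- dimnames(uniq)
  structure(list(junctions = j, unique_reads = uniq,
                 multimapped_reads = multi, max_overhang = over,
                 design = design),
            class = "junction_matrix")
}

test_that("filters drop short-overhang, multimapped and low-read junctions", {
  design <- sample_design(c("A", "B"), 12, 1)
  uniq <- rbind(c(9L, 9L),    # < 10 everywhere -> removed
                c(9L, 10L),   # 10 in one sample -> retained
                c(50L, 50L),  # short overhang everywhere -> removed
                c(50L, 0L))   # multimapped support -> policy-dependent
  multi <- rbind(c(0L, 0L), c(0L, 0L), c(0L, 0L), c(5L, 0L))
  over <- rbind(c(30L, 30L), c(30L, 30L), c(19L, 15L), c(30L, 0L))
  mat <- make_matrix(uniq, multi, over, design)
  kept <- filter_junctions(mat)
  expect_equal(nrow(kept$junctions), 1)
  expect_equal(kept$junctions$key, mat$junctions$key[2])
  # retained junction unchanged
  expect_equal(kept$unique_reads[1, ], mat$unique_reads[2, ])
  kept2 <- filter_junctions(mat, multimap_policy = "unique_only")
  expect_setequal(kept2$junctions$key, mat$junctions$key[c(2, 4)])
  expect_true(all(kept2$multimapped_reads == 0))
  # monotonicity: raising thresholds never grows the surviving set
  design3 <- tiny_rna_design()
  genome <- generate_genome(2, 2e6, 150, seed = 21)
  sim <- simulate_junction_tables(design3, genome, 120, 3, 25, seed = 21)
  full <- merge_junctions(sim$tables, design3)
  prev <- Inf
  for (mr in c(0, 5, 10, 40, 200)) {
    nkeep <- nrow(filter_junctions(full, min_reads = mr)$junctions)
    expect_lte(nkeep, prev)
    prev <- nkeep
  }
  prev <- Inf
  for (mo in c(0, 10, 20, 35, 60)) {
    nkeep <- nrow(filter_junctions(full, min_overhang = mo)$junctions)
    expect_lte(nkeep, prev)
    prev <- nkeep
  }
})

test_that("time-specificity calls require single-cell exclusivity", {
  design <- tiny_rna_design()
  # junction 1: pooled 12 in (A,12) only -> S; junction 2: two cells -> NS;
  # junction 3: nowhere -> NS
  uniq <- matrix(0L, 3, 27, dimnames = list(NULL, design$sample_id))
  uniq[1, cell_ids <- design$sample_id[design$strain == "A" & design$day == 12]] <-
    c(5L, 4L, 3L)
  uniq[2, design$sample_id[design$strain == "A" & design$day == 12]] <- 10L
  uniq[2, design$sample_id[design$strain == "B" & design$day == 15]] <- 10L
  mat <- make_matrix(uniq, design = design)
  calls <- classify_time_specificity(mat)
  expect_equal(calls$label, c("S", "NS", "NS"))
  expect_equal(calls$strain[1], "A")
  expect_equal(calls$day[1], 12)
  expect_true(all(is.na(calls$strain[2:3])))
  # partition invariant
  expect_equal(sum(calls$label == "S") + sum(calls$label == "NS"),
               nrow(mat$junctions))
})

test_that("classification agrees with brute-force cell enumeration on random matrices", {
  design <- tiny_rna_design()
  withr::with_seed(42, {
    for (rep in 1:5) {
      nJ <- sample(10:50, 1)
      uniq <- matrix(rpois(nJ * 27, 4), nJ, 27,
                     dimnames = list(NULL, design$sample_id))
      mat <- make_matrix(uniq, design = design)
      calls <- classify_time_specificity(mat)
      oracle <- classify_oracle(mat)
      got <- ifelse(calls$label == "S",
                    paste0("S:", calls$strain, ":", calls$day), "NS")
      expect_equal(got, oracle)
    }
  })
})

test_that("planted S junctions are recovered exactly after the full chain", {
  design <- tiny_rna_design()
  genome <- generate_genome(2, 2e6, 150, seed = 8)
  sim <- simulate_junction_tables(design, genome, 200, 5, 30, seed = 8)
  mat <- filter_junctions(merge_junctions(sim$tables, design))
  calls <- classify_time_specificity(mat)
  s <- calls[calls$label == "S", ]
  truth <- sim$truth$specific_junctions
  expect_equal(nrow(s), nrow(truth))
  m <- merge(s, truth, by = "key")
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$strain.x, m$strain.y)
  expect_equal(m$day.x, m$day.y)
  # decoys never survive the filters
  expect_false(any(sim$truth$decoy_keys %in% mat$junctions$key))
  # zero planting -> zero S calls
  sim0 <- simulate_junction_tables(design, genome, 100, 0, 30, seed = 8)
  mat0 <- filter_junctions(merge_junctions(sim0$tables, design))
  expect_equal(sum(classify_time_specificity(mat0)$label == "S"), 0)
})

test_that("novelty is exact-coordinate matching against the annotation", {
  genome <- generate_genome(1, 1e6, 20, seed = 2)
  ann <- annotated_junctions(genome)
  design <- sample_design("A", 12, 1)
  rec <- data.frame(chrom = ann$chrom[1:3],
                    intron_start = ann$intron_start[1:3] + c(0, 1, 0),
                    intron_end = ann$intron_end[1:3], strand = ann$strand[1:3],
                    motif_code = 1L, annotated_flag = 1L, unique_reads = 20L,
                    multimapped_reads = 0L, max_overhang = 30L,
                    stringsAsFactors = FALSE)
  mat <- merge_junctions(list(A_d12_r1 = rec), design)
  nv <- classify_novelty(mat, genome)
  nv <- nv[match(junction_key(rec$chrom, rec$intron_start, rec$intron_end,
                              rec$strand), nv$key), ]
  expect_equal(nv$novelty, c("known", "novel", "known"))
  # empty annotation: everything novel
  empty <- generate_genome(1, 1e5, 0, seed = 1)
  expect_true(all(classify_novelty(mat, empty)$novelty == "novel"))
  # GTF path is accepted as annotation
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(genome, gtf)
  expect_equal(classify_novelty(mat, gtf), classify_novelty(mat, genome))
})

test_that("gene assignment reports every >=1 bp overlap", {
  genome <- generate_genome(1, 1e6, 5, seed = 3)
  g <- genome$genes[order(genome$genes$start), ]
  design <- sample_design("A", 12, 1)
  rec <- data.frame(
    chrom = g$chrom[1],
    intron_start = c(g$start[1] + 10,            # inside gene 1
                     g$end[1], 1),               # spans gene1->gene2; intergenic
    intron_end = c(g$start[1] + 50, g$start[2], g$start[1] - 10),
    strand = "+", motif_code = 1L, annotated_flag = 0L, unique_reads = 15L,
    multimapped_reads = 0L, max_overhang = 25L, stringsAsFactors = FALSE)
  mat <- merge_junctions(list(A_d12_r1 = rec), design)
  genes <- assign_genes(mat, genome)
  keys <- junction_key(rec$chrom, rec$intron_start, rec$intron_end, rec$strand)
  expect_equal(genes[[keys[1]]], g$gene_id[1])
  expect_setequal(genes[[keys[2]]], g$gene_id[1:2])
  expect_equal(genes[[keys[3]]], character(0))
})

test_that("motif summaries count GT/AG and CT/AC per cell and class", {
  design <- sample_design(c("A", "B"), c(12, 15), 1)
  uniq <- matrix(0L, 4, 4, dimnames = list(NULL, design$sample_id))
  uniq[1, "A_d12_r1"] <- 12L  # S in (A,12)
  uniq[2, "A_d12_r1"] <- 15L  # S in (A,12)
  uniq[3, "A_d12_r1"] <- 11L  # S in (A,12)
  uniq[4, ] <- 10L            # NS, present everywhere
  mat <- make_matrix(uniq, design = design)
  mat$junctions$motif_code <- c(1L, 1L, 2L, 0L)
  calls <- classify_time_specificity(mat)
  ms <- motif_summary(calls, mat)
  a12s <- ms[ms$strain == "A" & ms$day == 12 & ms$label == "S", ]
  expect_equal(a12s$gt_ag, 2)
  expect_equal(a12s$ct_ac, 1)
  expect_equal(a12s$other, 0)
  # motif 0 lands in "other", in every cell the NS junction supports
  expect_true(all(ms$other[ms$label == "NS"] == 1))
  expect_true(all(ms$gt_ag[ms$label == "NS"] == 0))
  # no junctions -> all zeros
  empty <- subset_counts <- motif_summary(calls[0, ], mat)
  expect_true(all(empty[, c("gt_ag", "ct_ac", "other")] == 0))
})

test_that("specificity counts report per-cell totals and 2-decimal fractions", {
  calls <- data.frame(
    key = sprintf("j%d", 1:50),
    label = c(rep("S", 45), rep("NS", 5)),
    strain = c(rep(c("A", "B", "C"), each = 15), rep(NA, 5)),
    day = c(rep(rep(c(12, 15, 17), each = 5), 3), rep(NA, 5)),
    stringsAsFactors = FALSE)
  sc <- specificity_counts(calls)
  expect_equal(attr(sc, "total_S"), 45)
  expect_equal(attr(sc, "n_NS"), 5)
  expect_true(all(sc$n_S == 5))
  expect_true(all(sc$fraction == 0.11))
  # majority-fraction arithmetic at the study scale: 174 of 378 -> 0.46
  study <- data.frame(key = sprintf("j%d", 1:378), label = "S",
                      strain = c(rep("A", 174), rep("B", 204)),
                      day = c(rep(12, 174), rep(15, 204)),
                      stringsAsFactors = FALSE)
  ssc <- specificity_counts(study)
  expect_equal(ssc$fraction[ssc$strain == "A"], 0.46)
  # all NS
  expect_equal(attr(specificity_counts(calls[calls$label == "NS", ]),
                    "total_S"), 0)
})

test_that("day-contrast chi-square matches hand-computed expected counts", {
  expect_equal(day_contrast_chisq(rbind(c(50, 50, 50), c(50, 50, 50)))$chi2, 0)
  expect_equal(day_contrast_chisq(rbind(c(50, 50, 50), c(50, 50, 50)))$p, 1)
  tab <- rbind(c(174, 30, 40), c(20, 25, 30))
  got <- day_contrast_chisq(tab)
  # textbook Pearson formula, written out directly
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$chi2, sum((tab - E)^2 / E))
  expect_equal(got$df, 2)
  expect_error(day_contrast_chisq(matrix(c(5, 5), 2, 1)), "k >= 2")
  expect_error(day_contrast_chisq(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("variants-per-gene average reproduces the printed study arithmetic", {
  v <- variants_per_gene(130424, 21684)
  expect_equal(v$average, 130424 / 21684)
  expect_equal(round(v$average, 2), 6.01)
  expect_equal(v$rounded, 6L)
  expect_equal(variants_per_gene(0, 10)$average, 0)
  expect_equal(variants_per_gene(7, 2)$rounded, 4L)  # half away from zero
  expect_error(variants_per_gene(10, 0), "> 0")
})
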