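#' Simulate per-sample splice-junction tables with planted time-specific
#' junctions
#'
#' Emulates the structure of the study's multi-sample two-pass junction
#' output: background junctions supported across most samples, a set of
#' planted junctions whose read support (pooled over a cell's replicates) is
#' at or above the specificity threshold in exactly one (strain, day) cell
#' and zero elsewhere, and decoy junctions that only exist to exercise the
#' overhang and multi-mapped-read filters.  Unique read counts are Poisson
#' with mean `read_depth_mean`; planted cells are topped up to the pooled
#' threshold so that truth recovery is exact by construction.
#'
#' @param design a [sample_design()].
#' @param genome a [generate_genome()] model; junctions are drawn from its
#'   annotated introns.
#' @param n_background_junctions junctions supported across (most) samples.
#' @param n_planted_specific_per_cell planted strain-and-day-exclusive
#'   junctions per design cell.
#' @param read_depth_mean Poisson mean of per-sample unique read counts.
#' @param seed integer seed.
#' @param novel_fraction fraction of background junctions shifted off the
#'   annotation (novel coordinates, annotated flag 0).
#' @param decoy_fraction size of each decoy class (short-overhang,
#'   multimap-only) relative to `n_background_junctions`.
#' @param specificity_threshold pooled read threshold the planted junctions
#'   are guaranteed to meet (default 10, the classification default).
#' @return list with `tables` (named list, one junction data.frame per
#'   sample in the SJ.out.tab column layout used by [read_junction_table()])
#'   and `truth` (list with `specific_junctions`: data.frame of key, chrom,
#'   coordinates, strain, day; plus decoy keys).
#' @export
simulate_junction_tables <- function(design, genome,
                                     n_background_junctions = 200L,
                                     n_planted_specific_per_cell = 5L,
                                     read_depth_mean = 30,
                                     seed = 1L,
                                     novel_fraction = 0.3,
                                     decoy_fraction = 0.1,
                                     specificity_threshold = 10L) {
  assert_design(design)
  introns <- annotated_junctions(genome)
  cells <- design_cells(design)
  n_planted <- nrow(cells) * n_planted_specific_per_cell
  n_decoy <- round_half_away(decoy_fraction * n_background_junctions)
  need <- n_background_junctions + n_planted + 2L * n_decoy
  if (nrow(introns) < need)
    stopf("not enough gene junction slots: need %d introns, genome has %d",
          need, nrow(introns))

  withr::with_seed(seed, {
    idx <- sample.int(nrow(introns), need)
    take <- function(n) {
      if (n == 0L) return(introns[0L, , drop = FALSE])
      i <- idx[seq_len(n)]; idx <<- idx[-seq_len(n)]; introns[i, , drop = FALSE]
    }
    bg <- take(n_background_junctions)
    pl <- take(n_planted)
    dec_oh <- take(n_decoy)   # short-overhang decoys
    dec_mm <- take(n_decoy)   # multimap-only decoys

    # a fraction of the background is shifted off-annotation: novel junctions
    n_novel <- round_half_away(novel_fraction * nrow(bg))
    novel_i <- if (n_novel > 0) sample.int(nrow(bg), n_novel) else integer(0)
    bg$annotated <- rep(1L, nrow(bg))
    if (length(novel_i)) {
      bg$intron_start[novel_i] <- bg$intron_start[novel_i] + 3L
      bg$annotated[novel_i] <- 0L
    }
    pl$annotated <- rep(1L, nrow(pl))
    dec_oh$annotated <- rep(1L, nrow(dec_oh))
    dec_mm$annotated <- rep(1L, nrow(dec_mm))

    motif_pool <- c(1L, 2L, 0L, 3L, 4L, 5L, 6L)
    motif_prob <- c(0.55, 0.30, 0.05, 0.04, 0.03, 0.02, 0.01)
    all_j <- rbind(bg, pl, dec_oh, dec_mm)
    all_j$motif <- sample(motif_pool, nrow(all_j), replace = TRUE,
                          prob = motif_prob)
    all_j$class <- rep(c("background", "planted", "decoy_overhang",
                         "decoy_multimap"),
                       c(nrow(bg), nrow(pl), nrow(dec_oh), nrow(dec_mm)))
    all_j$key <- junction_key(all_j$chrom, all_j$intron_start,
                              all_j$intron_end, all_j$strand)
    if (anyDuplicated(all_j$key)) stopf("internal: junction keys collide")

    # planted cell assignment: n per cell, in cell order
    pl_rows <- which(all_j$class == "planted")
    cell_of <- cells[rep(seq_len(nrow(cells)),
                         each = n_planted_specific_per_cell), , drop = FALSE]

    samples <- design$sample_id
    nJ <- nrow(all_j); nS <- length(samples)
    uniq <- matrix(0L, nJ, nS, dimnames = list(all_j$key, samples))
    multi <- matrix(0L, nJ, nS, dimnames = list(all_j$key, samples))
    over <- matrix(0L, nJ, nS, dimnames = list(all_j$key, samples))

    bg_rows <- which(all_j$class == "background")
    for (j in bg_rows) {
      present <- runif(nS) < 0.95
      if (!any(present)) present[sample.int(nS, 1L)] <- TRUE
      counts <- rpois(sum(present), read_depth_mean)
      # background must survive the max-over-samples read filter
      if (all(counts < specificity_threshold))
        counts[1L] <- specificity_threshold
      uniq[j, present] <- counts
      over[j, present] <- sample(20:50, sum(present), replace = TRUE)
    }
    for (k in seq_along(pl_rows)) {
      j <- pl_rows[k]
      ids <- cell_samples(design, cell_of$strain[k], cell_of$day[k])
      counts <- rpois(length(ids), read_depth_mean)
      short <- specificity_threshold - sum(counts)
      if (short > 0) counts[1L] <- counts[1L] + short
      uniq[j, ids] <- counts
      over[j, ids] <- sample(20:50, length(ids), replace = TRUE)
    }
    for (j in which(all_j$class == "decoy_overhang")) {
      present <- runif(nS) < 0.8
      if (!any(present)) present[1L] <- TRUE
      counts <- rpois(sum(present), read_depth_mean)
      if (all(counts < specificity_threshold)) counts[1L] <- specificity_threshold
      uniq[j, present] <- counts
      over[j, present] <- sample(1:19, sum(present), replace = TRUE)
    }
    for (j in which(all_j$class == "decoy_multimap")) {
      present <- runif(nS) < 0.8
      if (!any(present)) present[1L] <- TRUE
      uniq[j, present] <- rpois(sum(present), read_depth_mean)
      multi[j, present] <- rpois(sum(present), 5) + 1L
      over[j, present] <- sample(20:50, sum(present), replace = TRUE)
    }
  })

  tables <- setNames(lapply(seq_along(samples), function(s) {
    present <- uniq[, s] > 0L | multi[, s] > 0L
    jj <- all_j[present, , drop = FALSE]
    data.frame(chrom = jj$chrom,
               intron_start = jj$intron_start,
               intron_end = jj$intron_end,
               strand = jj$strand,
               motif_code = jj$motif,
               annotated_flag = jj$annotated,
               unique_reads = uniq[present, s],
               multimapped_reads = multi[present, s],
               max_overhang = over[present, s],
               stringsAsFactors = FALSE, row.names = NULL)
  }), samples)

  truth <- list(
    specific_junctions = data.frame(
      key = all_j$key[pl_rows],
      chrom = all_j$chrom[pl_rows],
      intron_start = all_j$intron_start[pl_rows],
      intron_end = all_j$intron_end[pl_rows],
      strand = all_j$strand[pl_rows],
      strain = cell_of$strain, day = cell_of$day,
      stringsAsFactors = FALSE, row.names = NULL),
    decoy_keys = all_j$key[grepl("^decoy", all_j$class)],
    background_keys = all_j$key[bg_rows])
  list(tables = tables, truth = truth)
}

#' Simulate an epigenetic-clock beta-value matrix with planted strain shifts
#'
#' Site-level methylation is generated on the M scale (the log2 ratio scale
#' on which the downstream ANOVA runs): per-site baseline M drawn once, a
#' planted subset of sites gets one strain's mean shifted by `effect_m`
#' M-units, and sample noise is Normal(0, `noise_sd_m`).  M-values are
#' back-transformed to beta, which lands strictly inside (0, 1) by
#' construction.
#'
#' @param design a [sample_design()]; the study's methylation design is
#'   3 strains x day 15 x 2 replicates.
#' @param n_sites number of clock CpG sites (study panel: 2045).
#' @param dm_fraction fraction of sites planted as differentially methylated.
#' @param effect_m planted shift, in M-units, applied to one strain at each
#'   planted site; `effect_m = 0` plants nothing.
#' @param noise_sd_m per-sample Normal noise SD on the M scale.
#' @param seed integer seed.
#' @return list with `matrix` (a `methylation_matrix`: `sites` data.frame,
#'   `beta` site x sample matrix, `design`) and `truth` (data.frame of
#'   planted `site_id`, `shifted_strain`, `effect_m`).
#' @export
simulate_methylation <- function(design, n_sites = 2045L, dm_fraction = 0.29,
                                 effect_m = 2, noise_sd_m = 0.3, seed = 1L) {
  assert_design(design)
  if (dm_fraction <= 0 || dm_fraction >= 1)
    stopf("dm_fraction must be in (0, 1)")
  if (noise_sd_m <= 0) stopf("noise_sd_m must be > 0")
  strains <- attr(design, "strains")
  samples <- design$sample_id
  withr::with_seed(seed, {
    chrom <- sample(paste0("chr", 1:19), n_sites, replace = TRUE)
    pos <- sample.int(1e8, n_sites, replace = TRUE)
    site_id <- sprintf("%s:%d", chrom, pos)
    while (anyDuplicated(site_id)) {  # vanishingly rare; keep ids unique
      dup <- duplicated(site_id)
      pos[dup] <- sample.int(1e8, sum(dup), replace = TRUE)
      site_id <- sprintf("%s:%d", chrom, pos)
    }
    base_m <- rnorm(n_sites, mean = 0, sd = 1.5)
    n_dm <- if (effect_m == 0) 0L else round_half_away(dm_fraction * n_sites)
    dm_idx <- if (n_dm > 0) sort(sample.int(n_sites, n_dm)) else integer(0)
    shifted <- sample(strains, n_dm, replace = TRUE)
    mu <- matrix(base_m, n_sites, length(strains),
                 dimnames = list(site_id, strains))
    if (n_dm > 0)
      mu[cbind(dm_idx, match(shifted, strains))] <-
        mu[cbind(dm_idx, match(shifted, strains))] + effect_m
    m <- mu[, design$strain, drop = FALSE] +
      matrix(rnorm(n_sites * length(samples), 0, noise_sd_m),
             n_sites, length(samples))
    colnames(m) <- samples
  })
  beta <- m_to_beta(m)
  stopifnot(all(beta > 0 & beta < 1))
  ord <- order(chrom, pos)
  sites <- data.frame(site_id = site_id, chrom = chrom, pos = pos,
                      stringsAsFactors = FALSE)[ord, ]
  rownames(sites) <- NULL
  mat <- methylation_matrix(sites, beta[ord, , drop = FALSE], design)
  truth <- data.frame(site_id = site_id[dm_idx],
                      shifted_strain = shifted,
                      effect_m = rep(effect_m, length(dm_idx)),
                      stringsAsFactors = FALSE)
  list(matrix = mat, truth = truth)
}

#' Simulate SNP and differentially-methylated-site coordinates with planted
#' proximity
#'
#' SNP positions are uniform over the genome.  A `proximal_fraction` of DM
#' sites is planted within `max_pair_distance` bp of a randomly chosen SNP
#' (offset uniform on 1..`max_pair_distance`, either side); the remaining DM
#' sites are uniform.  With `proximal_fraction = 0` the landscape is null and
#' downstream per-bin enrichment odds ratios are ~1.
#'
#' @param genome a `genome_model` (only chromosome lengths are used).
#' @param n_snps,n_dm point counts (study scale: 303-ish SNPs near the clock
#'   panel, 1957 DM sites entering the bin analysis).
#' @param proximal_fraction fraction of DM sites planted near SNPs.
#' @param max_pair_distance planting radius in bp (default 1000, the 1 kb
#'   association radius).
#' @param seed integer seed.
#' @return list with `snp` and `dm` ([genomic_point_set()]s) and `truth`
#'   (data.frame of planted pairs: chrom, snp_pos, dm_pos, distance).
#' @export
simulate_snp_dm_landscape <- function(genome, n_snps = 303L, n_dm = 1957L,
                                      proximal_fraction = 0.3,
                                      max_pair_distance = 1000L, seed = 1L) {
  if (n_snps < 1L || n_dm < 1L) stopf("n_snps and n_dm must be >= 1")
  if (proximal_fraction < 0 || proximal_fraction > 1)
    stopf("proximal_fraction must be in [0, 1]")
  chroms <- genome$chroms
  if (any(chroms$length < 2 * max_pair_distance + 2))
    stopf("capacity error: chromosome shorter than the planting radius")
  withr::with_seed(seed, {
    snp_chr <- chroms$chrom[sample.int(nrow(chroms), n_snps, replace = TRUE)]
    snp_pos <- floor(runif(n_snps, 1, chroms$length[match(snp_chr, chroms$chrom)]))
    n_prox <- round_half_away(proximal_fraction * n_dm)
    prox_chr <- character(0); prox_pos <- numeric(0); truth <- NULL
    if (n_prox > 0) {
      anchor <- sample.int(n_snps, n_prox, replace = TRUE)
      off <- sample(c(-1L, 1L), n_prox, replace = TRUE) *
        sample.int(max_pair_distance, n_prox, replace = TRUE)
      prox_chr <- snp_chr[anchor]
      prox_pos <- pmin(pmax(snp_pos[anchor] + off, 1),
                       chroms$length[match(prox_chr, chroms$chrom)])
      truth <- data.frame(chrom = prox_chr, snp_pos = snp_pos[anchor],
                          dm_pos = prox_pos,
                          distance = abs(prox_pos - snp_pos[anchor]),
                          stringsAsFactors = FALSE)
    }
    n_unif <- n_dm - n_prox
    unif_chr <- chroms$chrom[sample.int(nrow(chroms), n_unif, replace = TRUE)]
    unif_pos <- floor(runif(n_unif, 1,
                            chroms$length[match(unif_chr, chroms$chrom)]))
    dm_chr <- c(prox_chr, unif_chr)
    dm_pos <- c(prox_pos, unif_pos)
  })
  list(snp = genomic_point_set(snp_chr, snp_pos, label = "SNP"),
       dm = genomic_point_set(dm_chr, dm_pos, label = "DM"),
       truth = truth %||% data.frame(chrom = character(), snp_pos = numeric(),
                                     dm_pos = numeric(), distance = numeric(),
                                     stringsAsFactors = FALSE))
}

#' Simulate differential-expression result tables with planted up/down counts
#'
#' Each (strain, phase) table lists every gene with a log-fold-change and an
#' FDR; exactly the planted numbers of genes are significant (FDR < 0.05) in
#' each direction, the rest are null (FDR >= 0.05).
#'
#' @param design a [sample_design()] (strain labels are taken from it).
#' @param n_genes genes per table.
#' @param planted_counts data.frame with columns `strain`, `phase` (`"P1"` /
#'   `"P2"`), `up`, `down`.  Defaults emulate the study's qualitative
#'   pattern: short-lived strains (A, C) skewed toward the early phase (P1),
#'   the long-lived strain (B) toward the late phase (P2).
#' @param seed integer seed.
#' @return list with `tables` (named list `strain.phase` of data.frames
#'   `gene_id`, `logFC`, `FDR`) and `truth` (the planted count table).
#' @export
simulate_de_tables <- function(design, n_genes = 2000L,
                               planted_counts = NULL, seed = 1L) {
  assert_design(design)
  strains <- attr(design, "strains")
  if (is.null(planted_counts)) {
    planted_counts <- expand.grid(strain = strains, phase = c("P1", "P2"),
                                  stringsAsFactors = FALSE)
    # early-skewed for A and C, late-skewed for B; fractions of the catalog
    frac <- function(b_p1, b_p2, o_p1, o_p2)
      round_half_away(n_genes * ifelse(planted_counts$strain == "B",
                                       ifelse(planted_counts$phase == "P1",
                                              b_p1, b_p2),
                                       ifelse(planted_counts$phase == "P1",
                                              o_p1, o_p2)))
    planted_counts$up <- frac(0.060, 0.160, 0.165, 0.055)
    planted_counts$down <- frac(0.050, 0.150, 0.155, 0.045)
  }
  bad <- planted_counts$up + planted_counts$down > n_genes
  if (any(bad)) stopf("planted counts exceed n_genes in %d cell(s)", sum(bad))
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  tables <- list()
  withr::with_seed(seed, {
    for (i in seq_len(nrow(planted_counts))) {
      up <- planted_counts$up[i]; down <- planted_counts$down[i]
      pick <- sample.int(n_genes, up + down)
      lfc <- rnorm(n_genes, 0, 0.3)
      fdr <- runif(n_genes, 0.05, 1)
      lfc[pick[seq_len(up)]] <- abs(rnorm(up, 2, 0.5)) + 0.1
      lfc[pick[up + seq_len(down)]] <- -(abs(rnorm(down, 2, 0.5)) + 0.1)
      fdr[pick] <- runif(up + down, 0, 0.0499)
      nm <- paste(planted_counts$strain[i], planted_counts$phase[i], sep = ".")
      tables[[nm]] <- data.frame(gene_id = genes, logFC = lfc, FDR = fdr,
                                 stringsAsFactors = FALSE)
    }
  })
  list(tables = tables, truth = planted_counts)
}
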