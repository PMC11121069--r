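#' Beta-value / M-value conversion
#'
#' Methylation beta-values (the fraction of methylated reads at a CpG, in
#' (0,1)) are heteroscedastic: variance shrinks toward the 0 and 1
#' boundaries.  Testing is therefore done on the M scale,
#' `M = log2(beta / (1 - beta))`, a strictly increasing bijection from (0,1)
#' to the real line.  `m_to_beta` is the inverse logistic transform.
#'
#' @param beta numeric vector/matrix of beta-values in (0, 1).
#' @param clamp if TRUE, boundary values (<= 0 or >= 1) are clamped to
#'   `[eps, 1 - eps]` with a warning instead of erroring.
#' @param eps clamping epsilon.
#' @return M-values (same shape as the input).
#' @examples
#' beta_to_m(0.5)  # 0
#' beta_to_m(0.8)  # 2
#' @export
beta_to_m <- function(beta, clamp = FALSE, eps = 1e-6) {
  bad <- beta <= 0 | beta >= 1
  if (any(bad, na.rm = TRUE)) {
    if (!clamp)
      stopf("beta-values must lie strictly in (0, 1); %d boundary value(s) (use clamp = TRUE)",
            sum(bad, na.rm = TRUE))
    warnf("clamped %d boundary beta-value(s) to [%g, %g]",
          sum(bad, na.rm = TRUE), eps, 1 - eps)
    beta <- pmin(pmax(beta, eps), 1 - eps)
  }
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @param m numeric vector/matrix of M-values.
#' @export
m_to_beta <- function(m) {
  p <- 2^m
  p / (1 + p)
}

#' Construct a methylation matrix (clock CpG sites x samples)
#'
#' @param sites data.frame with `site_id`, `chrom`, `pos` (1-based).
#' @param beta numeric matrix, rows matching `sites`, columns matching the
#'   design's sample ids; entries strictly in (0, 1).
#' @param design a [sample_design()].
#' @return a `methylation_matrix` (list: `sites`, `beta`, `design`).
#' @export
methylation_matrix <- function(sites, beta, design) {
  assert_design(design)
  if (nrow(sites) != nrow(beta)) stopf("sites and beta row counts differ")
  if (anyDuplicated(sites$site_id)) stopf("one row per site required")
  if (!setequal(colnames(beta), design$sample_id))
    stopf("beta columns must match the design's sample ids")
  if (any(beta <= 0 | beta >= 1))
    stopf("beta entries must lie strictly in (0, 1); clamp on ingest")
  beta <- beta[, design$sample_id, drop = FALSE]
  rownames(beta) <- sites$site_id
  structure(list(sites = sites, beta = beta, design = design),
            class = "methylation_matrix")
}

#' Read a beta-value matrix from CSV/TSV
#'
#' Expected layout: first column the site key `chrom:pos`, remaining columns
#' one per sample id.  Boundary values (<= 0 or >= 1) are clamped to
#' `[eps, 1 - eps]`; the number of clamped entries is recorded in the
#' `"n_clamped"` attribute.
#'
#' @param path CSV or TSV file.
#' @param design a [sample_design()] naming the sample columns.
#' @param eps clamping epsilon for boundary beta-values.
#' @return a [methylation_matrix()].
#' @export
read_beta_matrix <- function(path, design, eps = 1e-6) {
  dt <- data.table::fread(path, data.table = FALSE)
  key <- dt[[1]]
  parts <- strsplit(key, ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stopf("%s: row %d: site key not 'chrom:pos'", path, which(bad)[1])
  beta <- as.matrix(dt[, -1, drop = FALSE])
  missing <- setdiff(design$sample_id, colnames(beta))
  if (length(missing))
    stopf("%s: missing sample column(s): %s", path, paste(missing, collapse = ", "))
  n_clamped <- sum(beta <= 0 | beta >= 1)
  if (n_clamped > 0) {
    warnf("%s: clamped %d boundary beta-value(s)", path, n_clamped)
    beta <- pmin(pmax(beta, eps), 1 - eps)
  }
  sites <- data.frame(site_id = key,
                      chrom = vapply(parts, `[`, "", 1L),
                      pos = as.numeric(vapply(parts, `[`, "", 2L)),
                      stringsAsFactors = FALSE)
  out <- methylation_matrix(sites, beta[, design$sample_id, drop = FALSE],
                            design)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Write a methylation matrix as CSV
#' @param mat a [methylation_matrix()].
#' @param path output CSV.
#' @export
write_beta_matrix <- function(mat, path) {
  df <- data.frame(site = mat$sites$site_id, mat$beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Per-site differential methylation between two strains (one-way ANOVA)
#'
#' For every CpG site, beta-values are transformed to the M scale and a
#' one-way ANOVA between the two strain groups is computed.  With two groups
#' this is the pooled-variance two-sample t-test (F = t^2), with
#' F ~ F(1, nA + nB - 2) under the null; the implementation is vectorized
#' over sites.  Degenerate sites with zero within-group variance get p = 1
#' when the group means are equal, p = 0 otherwise.
#'
#' @param mat a [methylation_matrix()].
#' @param groupA,groupB strain labels to compare.
#' @return data.frame with `site_id`, `chrom`, `pos`, `strain_pair`,
#'   `mean_m_A`, `mean_m_B`, `F_statistic`, `p_value`.
#' @export
dm_anova <- function(mat, groupA, groupB) {
  design <- mat$design
  a_ids <- design$sample_id[design$strain == groupA]
  b_ids <- design$sample_id[design$strain == groupB]
  if (length(a_ids) < 2L || length(b_ids) < 2L)
    stopf("each group needs >= 2 samples (got %d and %d)",
          length(a_ids), length(b_ids))
  m <- beta_to_m(mat$beta)
  ma <- m[, a_ids, drop = FALSE]; mb <- m[, b_ids, drop = FALSE]
  na <- ncol(ma); nb <- ncol(mb)
  mean_a <- rowMeans(ma); mean_b <- rowMeans(mb)
  ss_a <- rowSums((ma - mean_a)^2); ss_b <- rowSums((mb - mean_b)^2)
  ss_within <- ss_a + ss_b
  grand <- (na * mean_a + nb * mean_b) / (na + nb)
  ss_between <- na * (mean_a - grand)^2 + nb * (mean_b - grand)^2
  df2 <- na + nb - 2L
  F_stat <- (ss_between / 1) / (ss_within / df2)
  p <- pf(F_stat, 1, df2, lower.tail = FALSE)
  degen <- ss_within == 0
  if (any(degen)) {
    eq <- degen & ss_between == 0
    F_stat[eq] <- 0; p[eq] <- 1
    F_stat[degen & !eq] <- Inf; p[degen & !eq] <- 0
  }
  data.frame(site_id = mat$sites$site_id, chrom = mat$sites$chrom,
             pos = mat$sites$pos,
             strain_pair = paste(groupA, groupB, sep = "_vs_"),
             mean_m_A = unname(mean_a), mean_m_B = unname(mean_b),
             F_statistic = unname(F_stat), p_value = unname(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call differentially methylated sites at a raw-p threshold
#'
#' Sites with p strictly below `alpha` are called; no multiple-testing
#' correction by default, mirroring the per-site raw-p < 0.05 convention of
#' the analysis this reimplements.  An optional Benjamini-Hochberg mode is
#' available.
#'
#' @param results output of [dm_anova()].
#' @param alpha significance threshold (strict `<`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return character vector of called site ids.
#' @export
call_dm <- function(results, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p <- results$p_value
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  results$site_id[p < alpha]
}

#' Venn partition of 2 or 3 labeled sets
#'
#' @param sets named list of 2 or 3 vectors (treated as sets).
#' @return named integer vector of the 2^k - 1 disjoint region counts;
#'   names are label combinations joined with `&`.  Counts sum to the size
#'   of the union.
#' @examples
#' venn_partition(list(A = 1:3, B = 2:4, C = 3))
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 3L) stopf("venn_partition takes 2 or 3 labeled sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stopf("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- do.call(cbind, lapply(sets, function(s) universe %in% s))
  if (length(universe) == 0L) member <- matrix(logical(0), 0, k)
  regions <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2^k), , drop = FALSE]
  counts <- apply(regions, 1L, function(r)
    sum(apply(member, 1L, function(row) all(row == r))))
  names(counts) <- apply(regions, 1L, function(r)
    paste(names(sets)[as.logical(r)], collapse = "&"))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out[order(nchar(names(out)), names(out))]
}

#' Plot-ready Manhattan table of per-site DM results
#'
#' @param results output of [dm_anova()].
#' @param chrom_order optional character vector giving the chromosome
#'   display order; defaults to the natural sort of observed chromosomes.
#' @param alpha significance threshold for the flag column.
#' @return data.frame sorted by (chromosome order, position) with
#'   `neg_log10_p` and logical `significant`.
#' @export
manhattan_table <- function(results, chrom_order = NULL, alpha = 0.05) {
  chroms <- unique(results$chrom)
  if (is.null(chrom_order)) {
    num <- suppressWarnings(as.numeric(sub("^chr", "", chroms)))
    chrom_order <- chroms[order(is.na(num), num, chroms)]
  }
  out <- results
  out$chrom <- factor(out$chrom, levels = chrom_order)
  out <- out[order(out$chrom, out$pos), ]
  out$chrom <- as.character(out$chrom)
  out$neg_log10_p <- -log10(out$p_value)
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Hierarchical clustering of a profile matrix
#'
#' Thin wrapper over [stats::hclust()] on [stats::dist()]: Euclidean
#' distance with complete linkage by default, configurable to average or
#' single linkage.
#'
#' @param profile numeric entity x feature matrix (>= 2 rows, no NA).
#' @param metric distance metric passed to [stats::dist()].
#' @param linkage `"complete"`, `"average"` or `"single"`.
#' @return an `hclust` object.
#' @export
hier_cluster <- function(profile, metric = "euclidean",
                         linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  profile <- as.matrix(profile)
  if (nrow(profile) < 2L) stopf("need >= 2 entities to cluster")
  if (anyNA(profile)) stopf("missing values are not allowed in the profile")
  hclust(dist(profile, method = metric), method = linkage)
}

#' Cophenetic correlation between two dendrograms
#'
#' The cophenetic distance between two leaves is the merge height at which
#' they first join; two dendrograms over the same leaves are compared by the
#' Pearson correlation of their cophenetic distance vectors (upper triangle,
#' matched leaf order).  It is 1 for a dendrogram against itself and
#' invariant to leaf relabeling and uniform height scaling.
#'
#' @param dendA,dendB `hclust` objects with identical leaf label sets
#'   (>= 3 leaves).
#' @return numeric in [-1, 1].
#' @export
cophenetic_correlation <- function(dendA, dendB) {
  ca <- as.matrix(cophenetic(dendA))
  cb <- as.matrix(cophenetic(dendB))
  if (nrow(ca) < 3L)
    stopf("cophenetic correlation needs >= 3 leaves")
  if (!setequal(rownames(ca), rownames(cb)))
    stopf("dendrograms have different leaf sets")
  cb <- cb[rownames(ca), rownames(ca)]
  ut <- upper.tri(ca)
  cor(ca[ut], cb[ut])
}

#' Per-site methylation change profile between two strains
#'
#' The difference of group mean M-values per site, the profile whose
#' clustering structure is compared across strain pairs.
#'
#' @param mat a [methylation_matrix()].
#' @param groupA,groupB strain labels.
#' @return named numeric vector (site_id -> mean M difference, A - B).
#' @export
dm_change_profile <- function(mat, groupA, groupB) {
  design <- mat$design
  m <- beta_to_m(mat$beta)
  a_ids <- design$sample_id[design$strain == groupA]
  b_ids <- design$sample_id[design$strain == groupB]
  if (!length(a_ids) || !length(b_ids)) stopf("unknown strain label")
  setNames(rowMeans(m[, a_ids, drop = FALSE]) -
             rowMeans(m[, b_ids, drop = FALSE]), mat$sites$site_id)
}
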