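#' Read a differential-expression result table
#'
#' TSV with `gene_id`, `logFC`, `FDR` columns (the edgeR-style output this
#' pipeline consumes).  Direction is derived per gene: UP if logFC > 0 and
#' FDR < 0.05 (strict), DOWN if logFC < 0 and FDR < 0.05, otherwise NS.
#' A zero logFC with significant FDR is NS, with a warning.
#'
#' @param path TSV file.
#' @param strain,phase labels attached to the table (phase `"P1"` is the
#'   early d12->d15 contrast, `"P2"` the late d15->d17 contrast).
#' @param fdr_threshold significance threshold (strict `<`).
#' @return a `de_table`: data.frame `gene_id`, `logFC`, `FDR`, `direction`
#'   with attributes `strain` and `phase`.
#' @export
read_de_table <- function(path, strain, phase, fdr_threshold = 0.05) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  for (f in c("gene_id", "logFC", "FDR"))
    if (!f %in% names(df)) stopf("%s: missing column '%s'", path, f)
  de_table(df, strain, phase, fdr_threshold)
}

#' @rdname read_de_table
#' @param df data.frame with `gene_id`, `logFC`, `FDR`.
#' @export
de_table <- function(df, strain, phase, fdr_threshold = 0.05) {
  if (anyDuplicated(df$gene_id))
    stopf("duplicate gene row: %s", df$gene_id[duplicated(df$gene_id)][1L])
  if (any(df$FDR < 0 | df$FDR > 1)) stopf("FDR must lie in [0, 1]")
  sig <- df$FDR < fdr_threshold
  zero_sig <- sig & df$logFC == 0
  if (any(zero_sig))
    warnf("%d significant gene(s) with logFC = 0 treated as NS", sum(zero_sig))
  df$direction <- ifelse(sig & df$logFC > 0, "UP",
                         ifelse(sig & df$logFC < 0, "DOWN", "NS"))
  structure(df, strain = strain, phase = phase,
            class = c("de_table", "data.frame"))
}

#' Strain x phase/direction DE count table
#'
#' Builds the 2 x 4 (or k x 4) layout whose categories are
#' UP-P1, DOWN-P1, UP-P2, DOWN-P2 per strain — the layout implied by the
#' df = 3 chi-square contrasts between strain pairs.
#'
#' @param tables list of `de_table`s covering both phases for each strain.
#' @return integer matrix, rows = strains, columns = the four categories.
#' @export
phase_counts <- function(tables) {
  strains <- unique(vapply(tables, attr, "", "strain"))
  cats <- c("UP-P1", "DOWN-P1", "UP-P2", "DOWN-P2")
  out <- matrix(0L, length(strains), length(cats),
                dimnames = list(strains, cats))
  seen <- matrix(FALSE, length(strains), 2L,
                 dimnames = list(strains, c("P1", "P2")))
  for (tb in tables) {
    s <- attr(tb, "strain"); ph <- attr(tb, "phase")
    if (!ph %in% c("P1", "P2")) stopf("phase must be 'P1' or 'P2'")
    seen[s, ph] <- TRUE
    out[s, paste0("UP-", ph)] <- sum(tb$direction == "UP")
    out[s, paste0("DOWN-", ph)] <- sum(tb$direction == "DOWN")
  }
  if (!all(seen))
    stopf("missing phase: strain %s lacks %s",
          rownames(seen)[which(!seen, arr.ind = TRUE)[1L, 1L]],
          colnames(seen)[which(!seen, arr.ind = TRUE)[1L, 2L]])
  out
}

#' Pearson chi-square and Cramer's V for an r x c count table
#'
#' Chi-square without continuity correction, df = (r-1)(c-1), and
#' Cramer's V = sqrt(chi2 / (n * min(r - 1, c - 1))), an association
#' effect size in [0, 1] (0 = independence, 1 = complete association).
#'
#' @param tab r x c matrix of non-negative integer counts with no zero
#'   row/column margin.
#' @return list with `chi2`, `df`, `p`, `cramers_v`, `n`.
#' @examples
#' chisq_cramers_v(matrix(c(30, 10, 10, 30), 2))  # chi2 = 20, V = 0.5
#' @export
chisq_cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stopf("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("zero row/column margin")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  v <- sqrt(unname(ct$statistic) / (n * min(nrow(tab) - 1L, ncol(tab) - 1L)))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, cramers_v = v, n = n)
}

#' Venn partition of per-strain DE gene sets
#'
#' Region counts for the three strain-specific gene sets of one direction
#' and phase (e.g. genes downregulated in P1 for strains A, B, C);
#' delegates to [venn_partition()].
#'
#' @param sets named list of 3 gene-id vectors.
#' @return named integer vector of the 7 disjoint region counts.
#' @export
de_venn <- function(sets) {
  if (length(sets) != 3L) stopf("de_venn takes 3 labeled strain sets")
  venn_partition(sets)
}

#' Gene sets of one direction from a DE table
#' @param tb a `de_table`.
#' @param direction `"UP"` or `"DOWN"`.
#' @return character vector of gene ids.
#' @export
de_genes <- function(tb, direction = c("UP", "DOWN")) {
  direction <- match.arg(direction)
  tb$gene_id[tb$direction == direction]
}

#' Between-sample expression correlation for one strain
#'
#' Library-size-normalizes each sample to counts per million, transforms to
#' log2(CPM + 1), and computes the Pearson (or Spearman) correlation for
#' every pair of the strain's samples across the gestational days.
#'
#' @param count_matrix gene x sample matrix of non-negative counts.
#' @param design a [sample_design()].
#' @param strain strain label whose samples are correlated.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return symmetric correlation matrix with unit diagonal, samples ordered
#'   by day then replicate.
#' @export
expression_correlation <- function(count_matrix, design, strain,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_design(design)
  ids <- design$sample_id[design$strain == strain]
  ids <- ids[order(design$day[match(ids, design$sample_id)],
                   design$replicate[match(ids, design$sample_id)])]
  missing <- setdiff(ids, colnames(count_matrix))
  if (length(missing))
    stopf("count matrix lacks sample(s): %s", paste(missing, collapse = ", "))
  cm <- count_matrix[, ids, drop = FALSE]
  lib <- colSums(cm)
  if (any(lib == 0)) stopf("zero library size in sample %s",
                           ids[which(lib == 0)[1L]])
  logcpm <- log2(sweep(cm, 2L, lib, "/") * 1e6 + 1)
  cor(logcpm, method = method)
}
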