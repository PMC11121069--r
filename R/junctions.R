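#' Read a STAR-style splice-junction table
#'
#' The 9-column tab-separated junction dialect: chromosome, intron start,
#' intron end (1-based inclusive), strand code (0 undefined, 1 `+`, 2 `-`),
#' intron motif code (0 non-canonical, 1 GT/AG, 2 CT/AC, 3 GC/AG, 4 CT/GC,
#' 5 AT/AC, 6 GT/AT), annotated flag (0 novel, 1 annotated), unique-read
#' count, multi-mapped-read count, maximum spliced-alignment overhang (bp).
#' Malformed lines are rejected with the file, line and column named.
#'
#' @param path path to a junction table.
#' @return data.frame of junction records with decoded `strand`
#'   (`"undefined"`, `"+"`, `"-"`).
#' @export
read_junction_table <- function(path) {
  lines <- readLines(path)
  cols <- c("chrom", "intron_start", "intron_end", "strand", "motif_code",
            "annotated_flag", "unique_reads", "multimapped_reads",
            "max_overhang")
  empty <- data.frame(chrom = character(), intron_start = numeric(),
                      intron_end = numeric(), strand = character(),
                      motif_code = integer(), annotated_flag = integer(),
                      unique_reads = integer(), multimapped_reads = integer(),
                      max_overhang = integer(), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad))
    stopf("%s: line %d: expected 9 tab-separated columns, found %d",
          path, bad[1], lengths(fields)[bad[1]])
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 2:9, drop = FALSE], 2L, as.numeric))
  if (length(lines) == 1L) num <- matrix(num, nrow = 1L)
  if (anyNA(num)) {
    ij <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stopf("%s: line %d: column %s is not numeric", path, ij[1],
          cols[ij[2] + 1L])
  }
  intcols <- num[, 3:8, drop = FALSE]  # strand..overhang must be integral
  if (any(intcols != floor(intcols)))
    stopf("%s: non-integer value in an integer column", path)
  strand_raw <- num[, 3L]
  if (any(!strand_raw %in% 0:2)) {
    l <- which(!strand_raw %in% 0:2)[1L]
    stopf("%s: line %d: column strand must be 0/1/2", path, l)
  }
  if (any(!num[, 4L] %in% 0:6)) {
    l <- which(!num[, 4L] %in% 0:6)[1L]
    stopf("%s: line %d: column motif_code must be in 0..6", path, l)
  }
  if (any(num[, 1L] > num[, 2L]))
    stopf("%s: line %d: intron_start > intron_end", path,
          which(num[, 1L] > num[, 2L])[1L])
  if (any(!num[, 5L] %in% 0:1)) {
    l <- which(!num[, 5L] %in% 0:1)[1L]
    stopf("%s: line %d: column annotated_flag must be 0/1", path, l)
  }
  if (any(num[, 6:8] < 0))
    stopf("%s: negative read count or overhang", path)
  data.frame(chrom = m[, 1L],
             intron_start = num[, 1L],
             intron_end = num[, 2L],
             strand = c("undefined", "+", "-")[strand_raw + 1L],
             motif_code = as.integer(num[, 4L]),
             annotated_flag = as.integer(num[, 5L]),
             unique_reads = as.integer(num[, 6L]),
             multimapped_reads = as.integer(num[, 7L]),
             max_overhang = as.integer(num[, 8L]),
             stringsAsFactors = FALSE)
}

#' Merge per-sample junction tables into a multi-sample junction matrix
#'
#' Union of junction keys (chrom, intron start, intron end, strand) over all
#' samples; a junction absent from a sample contributes zero counts and zero
#' overhang.  Motif and annotation flags must agree across samples for the
#' same coordinates (a conflict is an error).
#'
#' @param samples named list (sample id -> data.frame from
#'   [read_junction_table()]).
#' @param design a [sample_design()]; every sample id must belong to it.
#' @return a `junction_matrix`: list with `junctions` (key + coordinates +
#'   consensus motif/annotation), matrices `unique_reads`,
#'   `multimapped_reads`, `max_overhang` (junction x sample), and `design`.
#' @export
merge_junctions <- function(samples, design) {
  assert_design(design)
  unknown <- setdiff(names(samples), design$sample_id)
  if (length(unknown))
    stopf("unknown sample id(s): %s", paste(unknown, collapse = ", "))
  recs <- data.table::rbindlist(samples, idcol = "sample_id")
  if (nrow(recs) == 0L) stopf("no junction records supplied")
  recs$key <- junction_key(recs$chrom, recs$intron_start, recs$intron_end,
                           recs$strand)
  jinfo <- unique(as.data.frame(
    recs[, c("key", "chrom", "intron_start", "intron_end", "strand",
             "motif_code", "annotated_flag")]))
  if (anyDuplicated(jinfo$key)) {
    dup <- jinfo$key[duplicated(jinfo$key)][1L]
    stopf("conflicting motif/annotation for junction %s across samples", dup)
  }
  jinfo <- jinfo[order(jinfo$chrom, jinfo$intron_start, jinfo$intron_end), ]
  rownames(jinfo) <- NULL
  ids <- design$sample_id
  mk <- function(field) {
    m <- matrix(0L, nrow(jinfo), length(ids),
                dimnames = list(jinfo$key, ids))
    m[cbind(match(recs$key, jinfo$key), match(recs$sample_id, ids))] <-
      as.integer(recs[[field]])
    m
  }
  structure(list(junctions = jinfo,
                 unique_reads = mk("unique_reads"),
                 multimapped_reads = mk("multimapped_reads"),
                 max_overhang = mk("max_overhang"),
                 design = design),
            class = "junction_matrix")
}

is_junction_matrix <- function(x) inherits(x, "junction_matrix")

subset_junctions <- function(mat, keep) {
  structure(list(junctions = mat$junctions[keep, , drop = FALSE],
                 unique_reads = mat$unique_reads[keep, , drop = FALSE],
                 multimapped_reads = mat$multimapped_reads[keep, , drop = FALSE],
                 max_overhang = mat$max_overhang[keep, , drop = FALSE],
                 design = mat$design),
            class = "junction_matrix")
}

#' Filter a junction matrix on overhang, multi-mapped support and read depth
#'
#' Removes (i) junctions whose maximum overhang is below `min_overhang` in
#' every supporting sample, (ii) junctions with multi-mapped support
#' according to `multimap_policy` (`"drop_if_any"` removes the junction if
#' any sample reports multi-mapped reads; `"unique_only"` keeps it and
#' simply ignores multi-mapped counts), and (iii) junctions whose unique
#' read count is below `min_reads` in all samples.  Retained junctions are
#' unchanged.
#'
#' @param mat a `junction_matrix`.
#' @param min_overhang minimum overhang in bp (default 20).
#' @param min_reads minimum unique reads required in at least one sample
#'   (default 10).
#' @param multimap_policy see above.
#' @return the filtered `junction_matrix`.
#' @export
filter_junctions <- function(mat, min_overhang = 20L, min_reads = 10L,
                             multimap_policy = c("drop_if_any", "unique_only")) {
  multimap_policy <- match.arg(multimap_policy)
  if (min_overhang < 0 || min_reads < 0) stopf("thresholds must be >= 0")
  if (nrow(mat$junctions) == 0L) return(mat)
  best_overhang <- apply(mat$max_overhang, 1L, max)
  keep <- best_overhang >= min_overhang
  if (multimap_policy == "drop_if_any")
    keep <- keep & rowSums(mat$multimapped_reads) == 0L
  keep <- keep & apply(mat$unique_reads, 1L, max) >= min_reads
  out <- subset_junctions(mat, keep)
  if (multimap_policy == "unique_only")
    out$multimapped_reads[] <- 0L
  out
}

#' Classify junctions as developmental-time-specific (S) or non-specific (NS)
#'
#' A junction is S when its read support meets the threshold in exactly one
#' (strain, day) cell and falls below it in every other cell; otherwise NS.
#' Cell support is the sum of unique reads over the cell's replicates
#' (`pooling = "pooled"`, the default) or requires every replicate to meet
#' the threshold individually (`"all_replicates"`).  S and NS calls
#' partition the matrix.
#'
#' @param mat a filtered `junction_matrix`.
#' @param threshold read threshold (default 10), used both for presence and
#'   absence.
#' @param pooling replicate handling, see above.
#' @return data.frame with `key`, `label` (`"S"`/`"NS"`), and for S calls
#'   the exclusive `strain` and `day` (NA for NS).
#' @export
classify_time_specificity <- function(mat, threshold = 10L,
                                      pooling = c("pooled", "all_replicates")) {
  pooling <- match.arg(pooling)
  design <- mat$design
  cells <- design_cells(design)
  nJ <- nrow(mat$junctions)
  meets <- matrix(FALSE, nJ, nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    ids <- cell_samples(design, cells$strain[ci], cells$day[ci])
    sub <- mat$unique_reads[, ids, drop = FALSE]
    meets[, ci] <- if (pooling == "pooled")
      rowSums(sub) >= threshold
    else
      apply(sub, 1L, min) >= threshold
  }
  n_meet <- rowSums(meets)
  is_s <- n_meet == 1L
  which_cell <- ifelse(is_s, max.col(meets, ties.method = "first"), NA_integer_)
  data.frame(key = mat$junctions$key,
             label = ifelse(is_s, "S", "NS"),
             strain = cells$strain[which_cell],
             day = cells$day[which_cell],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify junctions as known or novel against an annotation
#'
#' Known iff (chrom, intron start, intron end) exactly matches a junction
#' derivable from the annotation's exon structure (the gap between
#' consecutive exons of a transcript); otherwise novel.  The annotation is
#' authoritative; the input tables' annotated flag is not consulted.
#'
#' @param mat a `junction_matrix`.
#' @param annotation a `genome_model` or a GTF path.
#' @return data.frame with `key` and `novelty` (`"known"`/`"novel"`).
#' @export
classify_novelty <- function(mat, annotation) {
  genome <- as_genome_model(annotation)
  ann <- annotated_junctions(genome)
  known_keys <- unique(paste0(ann$chrom, ":", ann$intron_start, "-",
                              ann$intron_end))
  j <- mat$junctions
  obs <- paste0(j$chrom, ":", j$intron_start, "-", j$intron_end)
  data.frame(key = j$key,
             novelty = ifelse(obs %in% known_keys, "known", "novel"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign genes to junctions by coordinate intersection
#'
#' A gene is assigned when the junction interval `[intron_start, intron_end]`
#' overlaps the gene interval by at least 1 bp (the default intersect
#' semantics of interval tools); all overlapping genes are reported.
#'
#' @param mat a `junction_matrix`.
#' @param annotation a `genome_model` or a GTF path.
#' @return named list: junction key -> character vector of gene ids
#'   (possibly empty).
#' @export
assign_genes <- function(mat, annotation) {
  genome <- as_genome_model(annotation)
  j <- mat$junctions
  out <- setNames(vector("list", nrow(j)), j$key)
  out[] <- list(character(0))
  if (nrow(j) == 0L || nrow(genome$genes) == 0L) return(out)
  jr <- GenomicRanges::GRanges(j$chrom,
                               IRanges::IRanges(j$intron_start, j$intron_end))
  gr <- GenomicRanges::GRanges(genome$genes$chrom,
                               IRanges::IRanges(genome$genes$start,
                                                genome$genes$end))
  hits <- GenomicRanges::findOverlaps(jr, gr, minoverlap = 1L)
  if (length(hits)) {
    ass <- split(genome$genes$gene_id[S4Vectors::subjectHits(hits)],
                 j$key[S4Vectors::queryHits(hits)])
    out[names(ass)] <- ass
  }
  out
}

#' Junction motif counts per (strain-day, S/NS) cell
#'
#' Tallies the two dominant splice motifs, GT/AG (code 1) and CT/AC
#' (code 2); all other codes fall under `other`.  S junctions count in their
#' exclusive cell; an NS junction counts in every cell whose pooled unique
#' reads meet `threshold`.
#'
#' @param calls output of [classify_time_specificity()].
#' @param mat the `junction_matrix` the calls came from.
#' @param threshold pooled-read presence threshold for NS junctions.
#' @return data.frame with `strain`, `day`, `label`, `gt_ag`, `ct_ac`,
#'   `other`.
#' @export
motif_summary <- function(calls, mat, threshold = 10L) {
  design <- mat$design
  cells <- design_cells(design)
  motif <- setNames(mat$junctions$motif_code, mat$junctions$key)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    ids <- cell_samples(design, cells$strain[ci], cells$day[ci])
    pooled <- rowSums(mat$unique_reads[, ids, drop = FALSE])
    for (lab in c("S", "NS")) {
      keys <- if (lab == "S")
        calls$key[calls$label == "S" & calls$strain == cells$strain[ci] &
                    calls$day == cells$day[ci]]
      else
        calls$key[calls$label == "NS" &
                    calls$key %in% names(pooled)[pooled >= threshold]]
      mm <- motif[keys]
      rows[[length(rows) + 1L]] <- data.frame(
        strain = cells$strain[ci], day = cells$day[ci], label = lab,
        gt_ag = sum(mm == 1L), ct_ac = sum(mm == 2L),
        other = sum(!mm %in% c(1L, 2L)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cell counts of time-specific splice variants
#'
#' @param calls output of [classify_time_specificity()].
#' @return data.frame with `strain`, `day`, `n_S` and `fraction` (of the S
#'   total, rounded to 2 decimals), with attributes `total_S` and `n_NS`.
#' @export
specificity_counts <- function(calls) {
  s <- calls[calls$label == "S", , drop = FALSE]
  if (nrow(s)) {
    agg <- stats::aggregate(list(n_S = s$key), by = list(strain = s$strain,
                                                         day = s$day),
                            FUN = length)
    agg <- agg[order(agg$strain, agg$day), ]
  } else {
    agg <- data.frame(strain = character(), day = numeric(), n_S = integer(),
                      stringsAsFactors = FALSE)
  }
  total <- sum(agg$n_S)
  agg$fraction <- if (total > 0) round(agg$n_S / total, 2) else numeric(nrow(agg))
  rownames(agg) <- NULL
  structure(agg, total_S = total, n_NS = sum(calls$label == "NS"))
}

#' Chi-square contrast of S-variant counts between two days
#'
#' Pearson chi-square without continuity correction on a 2 x k table
#' (2 days x k strains), df = k - 1.
#'
#' @param counts 2 x k matrix of non-negative integer S counts; rows are the
#'   two days compared, columns are strains.
#' @return list with `chi2`, `df`, `p`.
#' @export
day_contrast_chisq <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L || ncol(counts) < 2L)
    stopf("need a 2 x k table with k >= 2 strains")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stopf("zero marginal total")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Average splice variants per gene
#'
#' @param n_junctions total junction count.
#' @param n_genes gene count (> 0).
#' @return list with `average` (float) and `rounded` (nearest integer,
#'   half away from zero).
#' @examples
#' variants_per_gene(130424, 21684)  # average ~6.01, rounded 6
#' @export
variants_per_gene <- function(n_junctions, n_genes) {
  if (n_genes <= 0) stopf("n_genes must be > 0")
  avg <- n_junctions / n_genes
  list(average = avg, rounded = as.integer(round_half_away(avg)))
}

#' Write specificity calls / count tables as TSV
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
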