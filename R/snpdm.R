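#' Construct a genomic point set
#'
#' An ordered set of 1-based point coordinates (SNP positions or DM-site
#' positions) per chromosome.  Positions are sorted within chromosome;
#' duplicates are allowed but counted in the `"n_duplicates"` attribute.
#'
#' @param chrom chromosome names (normalized to the bare dialect).
#' @param pos 1-based positions.
#' @param label set label (e.g. `"SNP"`, `"DM"`).
#' @param ids optional site identifiers.
#' @return a `genomic_point_set`: data.frame `chrom`, `pos` (+ `id`),
#'   sorted, with attributes `label` and `n_duplicates`.
#' @export
genomic_point_set <- function(chrom, pos, label = "points", ids = NULL) {
  if (length(chrom) != length(pos)) stopf("chrom and pos lengths differ")
  if (any(pos < 1)) stopf("positions must be 1-based (>= 1)")
  chrom <- normalize_chrom(chrom)
  ord <- order(chrom, pos)
  df <- data.frame(chrom = chrom[ord], pos = as.numeric(pos[ord]),
                   stringsAsFactors = FALSE)
  if (!is.null(ids)) df$id <- ids[ord]
  ndup <- sum(duplicated(df[, c("chrom", "pos")]))
  structure(df, label = label, n_duplicates = ndup,
            class = c("genomic_point_set", "data.frame"))
}

#' Read SNP positions from a VCF
#'
#' Only CHROM and POS are consumed (the Mouse Genomes Project strain VCFs
#' carry one position per record; multi-allelic records contribute one
#' position).  Duplicate positions are deduplicated with the count recorded
#' in the `"n_duplicates"` attribute.
#'
#' @param vcf_path VCF 4.x file (plain text or gzipped).
#' @return a [genomic_point_set()] labeled `"SNP"`.
#' @export
read_snp_sites <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fx <- v@fix
  if (nrow(fx) == 0L)
    return(genomic_point_set(character(0), numeric(0), label = "SNP"))
  pos <- suppressWarnings(as.numeric(fx[, "POS"]))
  if (anyNA(pos))
    stopf("%s: record %d: missing or non-numeric POS", vcf_path,
          which(is.na(pos))[1L])
  chrom <- normalize_chrom(fx[, "CHROM"])
  dup <- duplicated(paste(chrom, pos))
  ndup <- sum(dup)
  if (ndup > 0) message(sprintf("%s: deduplicated %d position(s)",
                                basename(vcf_path), ndup))
  out <- genomic_point_set(chrom[!dup], pos[!dup], label = "SNP")
  attr(out, "n_duplicates") <- ndup
  out
}

#' Write a minimal VCF of point coordinates
#'
#' Emits a VCF 4.2 with CHROM/POS/ID/REF/ALT columns only (placeholder
#' alleles); INFO is not used by any consumer in this pipeline.
#'
#' @param points a [genomic_point_set()].
#' @param path output path.
#' @export
write_snp_vcf <- function(points, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=devage synthetic landscape",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                  points$chrom, as.integer(points$pos),
                  sprintf("snp%06d", seq_len(nrow(points))), "A", "G")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read DM-site points from a TSV (`chrom`, `pos`) or BED3 file
#'
#' BED input (3 columns, no header, 0-based half-open) is converted to
#' 1-based points using the interval start; TSV input must carry `chrom`
#' and `pos` columns.
#'
#' @param path input file.
#' @param format `"tsv"` or `"bed"`.
#' @return a [genomic_point_set()] labeled `"DM"`.
#' @export
read_dm_sites <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stopf("%s: BED needs >= 3 columns", path)
    return(genomic_point_set(df[[1]], df[[2]] + 1, label = "DM"))
  }
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  for (f in c("chrom", "pos"))
    if (!f %in% names(df)) stopf("%s: missing column '%s'", path, f)
  genomic_point_set(df$chrom, df$pos, label = "DM")
}

#' Nearest-target distance for every query point
#'
#' For each query point, the minimum absolute distance to any target point
#' on the same chromosome (0 when positions coincide); NA when the query's
#' chromosome carries no target (such points are excluded from binning).
#'
#' @param query,target [genomic_point_set()]s.
#' @return numeric vector of distances (bp), aligned with `query` rows.
#' @export
nearest_distance <- function(query, target) {
  if (nrow(query) == 0L) return(numeric(0))
  out <- rep(NA_real_, nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    tp <- target$pos[target$chrom == ch]
    if (length(tp) == 0L) next
    qp <- query$pos[qi]
    # tp is sorted: candidate neighbors are the insertion point and its left
    right <- findInterval(qp, tp) + 1L
    left <- right - 1L
    d_left <- ifelse(left >= 1L, abs(qp - tp[pmax(left, 1L)]), Inf)
    d_right <- ifelse(right <= length(tp), abs(tp[pmin(right, length(tp))] - qp),
                      Inf)
    out[qi] <- pmin(d_left, d_right)
  }
  out
}

#' The ten SNP-DM distance bins
#'
#' Bin labels are in kb: 0-0.1, 0.1-1, 1-5, 5-10, 10-50, 50-100, 100-200,
#' 200-400, 400-800, 800-1000.  Internally edges are kept in bp; the first
#' bin is closed `[0, 100]`, subsequent bins half-open `(lo, hi]`, and
#' distances beyond 1000 kb fall in no bin.
#'
#' @return a `distance_binning`: list with `labels` and bp `edges`.
#' @export
distance_bins <- function() {
  kb <- c(0, 0.1, 1, 5, 10, 50, 100, 200, 400, 800, 1000)
  labels <- paste0(head(kb, -1L), "-", kb[-1L], " kb")
  structure(list(labels = labels, edges = kb * 1000), class = "distance_binning")
}

#' Count distances per bin
#'
#' @param distances numeric vector of non-negative bp distances (NAs, from
#'   queries with no same-chromosome target, are dropped).
#' @param binning a [distance_bins()] object.
#' @return named integer vector of per-bin counts with a `"beyond"` attribute
#'   counting distances above the last edge.
#' @export
bin_distances <- function(distances, binning = distance_bins()) {
  distances <- distances[!is.na(distances)]
  if (any(distances < 0)) stopf("distances must be >= 0")
  b <- cut(distances, breaks = binning$edges, right = TRUE,
           include.lowest = TRUE, labels = binning$labels)
  counts <- table(factor(b, levels = binning$labels))
  out <- setNames(as.integer(counts), binning$labels)
  attr(out, "beyond") <- sum(distances > max(binning$edges))
  out
}

#' Build the 2 x 2 within-bin / not-in-bin contingency table
#'
#' Rows are within-bin vs not-in-bin, columns are SNP vs DM; the complement
#' is taken within the binned universe (points whose nearest distance lies
#' within 1000 kb), so column totals are consistent across bins.
#'
#' @param snp_bins,dm_bins outputs of [bin_distances()] over the same
#'   binning.
#' @param bin bin label (or index).
#' @return 2 x 2 integer matrix `[[snp_in, dm_in], [snp_out, dm_out]]`.
#' @export
build_contingency <- function(snp_bins, dm_bins, bin) {
  if (is.numeric(bin)) bin <- names(snp_bins)[bin]
  if (!bin %in% names(snp_bins)) stopf("unknown bin '%s'", bin)
  snp_in <- snp_bins[[bin]]; dm_in <- dm_bins[[bin]]
  matrix(c(snp_in, dm_in, sum(snp_bins) - snp_in, sum(dm_bins) - dm_in),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("within", "not_within"), c("SNP", "DM")))
}

# hypergeometric parameters of a 2x2 table with margins fixed;
# x11 is the top-left (snp_in) cell
hyper_params <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != floor(tab)))
    stopf("table must hold non-negative integers")
  if (sum(tab) == 0) stopf("all-zero table")
  list(x = tab[1, 1], m = sum(tab[, 1]), n = sum(tab[, 2]),
       k = sum(tab[1, ]))
}

#' One-sided Fisher exact test on a 2 x 2 table
#'
#' Exact p-value for the alternative of greater association in the top-left
#' cell: the sum of hypergeometric probabilities, at fixed margins, of all
#' tables with top-left count at or above the observed one.
#'
#' @param tab 2 x 2 matrix of non-negative integer counts,
#'   `[[snp_in, dm_in], [snp_out, dm_out]]`.
#' @return p-value in [0, 1].
#' @examples
#' fisher_one_sided(matrix(c(38, 170, 277, 1787), 2, byrow = TRUE))
#' @export
fisher_one_sided <- function(tab) {
  hp <- hyper_params(tab)
  hi <- min(hp$m, hp$k)
  if (hp$x == 0) return(1)
  sum(dhyper(seq(hp$x, hi), hp$m, hp$n, hp$k))
}

#' Conditional maximum-likelihood odds ratio of a 2 x 2 table
#'
#' The odds-ratio estimate maximizing the noncentral hypergeometric
#' likelihood of the table with all margins fixed, found by solving the
#' conditional mean equation E_psi[X] = x in the log-odds parameter.  This
#' is the estimator printed by R's exact-test toolchain and differs slightly
#' from the sample cross-product ratio.  Boundary tables give 0 or Inf.
#'
#' @param tab 2 x 2 matrix, as in [fisher_one_sided()].
#' @return non-negative odds ratio (possibly `Inf`).
#' @export
odds_ratio_cmle <- function(tab) {
  hp <- hyper_params(tab)
  lo <- max(0, hp$k - hp$n); hi <- min(hp$m, hp$k)
  if (hp$x <= lo) return(0)
  if (hp$x >= hi) return(Inf)
  supp <- seq(lo, hi)
  logw0 <- lchoose(hp$m, supp) + lchoose(hp$n, hp$k - supp)
  cond_mean <- function(log_psi) {
    lw <- logw0 + supp * log_psi
    w <- exp(lw - max(lw))
    sum(supp * w) / sum(w)
  }
  root <- uniroot(function(lp) cond_mean(lp) - hp$x,
                  lower = -50, upper = 50, tol = 1e-12)
  exp(root$root)
}

# sample (cross-product) odds ratio, offered as an alternative estimator
odds_ratio_sample <- function(tab) {
  tab <- as.matrix(tab)
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' SNP-DM proximity association table over the ten distance bins
#'
#' Both directions are binned: each SNP by its nearest DM site and each DM
#' site by its nearest SNP.  For every bin, the 2 x 2 within/not-within
#' table is built (complement within the 1000 kb universe), the odds ratio
#' estimated, and a Fisher exact p computed.
#'
#' @param snp,dm [genomic_point_set()]s.
#' @param binning a [distance_bins()] object.
#' @param alternative `"greater"` (one-sided, the default used throughout)
#'   or `"two.sided"` (delegated to [stats::fisher.test()]).
#' @param or_estimator `"cmle"` (conditional MLE, default) or `"sample"`
#'   (cross-product ratio).
#' @return data.frame, one row per bin: `bin`, `snp_in`, `dm_in`, `snp_out`,
#'   `dm_out`, `odds_ratio`, `p_value`.
#' @export
association_table <- function(snp, dm, binning = distance_bins(),
                              alternative = c("greater", "two.sided"),
                              or_estimator = c("cmle", "sample")) {
  alternative <- match.arg(alternative)
  or_estimator <- match.arg(or_estimator)
  if (nrow(snp) == 0L || nrow(dm) == 0L) stopf("both point sets must be non-empty")
  snp_bins <- bin_distances(nearest_distance(snp, dm), binning)
  dm_bins <- bin_distances(nearest_distance(dm, snp), binning)
  rows <- lapply(binning$labels, function(b) {
    tab <- build_contingency(snp_bins, dm_bins, b)
    or <- if (or_estimator == "cmle") odds_ratio_cmle(tab)
          else odds_ratio_sample(tab)
    p <- if (alternative == "greater") fisher_one_sided(tab)
         else stats::fisher.test(tab)$p.value
    data.frame(bin = b, snp_in = tab[1, 1], dm_in = tab[1, 2],
               snp_out = tab[2, 1], dm_out = tab[2, 2],
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
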