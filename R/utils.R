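# internal helpers shared across modules

#' @importFrom stats rpois rnorm runif pf setNames cophenetic dist hclust
#'   cor chisq.test uniroot dhyper as.dist
#' @importFrom utils write.table read.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize chromosome names to a common dialect
#'
#' VCF files from the Mouse Genomes Project use bare names (`"1"`), while
#' Ensembl-style GTF and UCSC-style files may use a `"chr"` prefix.  All
#' ingest paths funnel through this mapping so point sets and annotations
#' compare on the same names.
#'
#' @param x character vector of chromosome names.
#' @param style `"bare"` strips a leading `"chr"`; `"chr"` adds one.
#' @return character vector of normalized names.
#' @export
normalize_chrom <- function(x, style = c("bare", "chr")) {
  style <- match.arg(style)
  bare <- sub("^chr", "", as.character(x))
  if (style == "bare") bare else paste0("chr", bare)
}

# junction identity used as a stable row key everywhere
junction_key <- function(chrom, start, end, strand) {
  paste0(chrom, ":", start, "-", end, ":", strand)
}

# round-half-away-from-zero (R's round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# md5 of a file, used in fixture manifests and pipeline provenance
file_checksum <- function(path) unname(tools::md5sum(path))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
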