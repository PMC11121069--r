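#' Generate a synthetic genome model with a non-overlapping gene catalog
#'
#' Stands in for the GRCm39 annotation when exercising the pipeline without
#' the deposited data.  Genes are placed without overlap, each with at least
#' two exons so that every gene contributes at least one splice junction.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len chromosome length in bp (same for all chromosomes).
#' @param n_genes total number of genes to place across chromosomes.
#' @param seed integer seed; the model is byte-identical for a fixed seed.
#' @param exon_range,intron_range integer ranges (bp) sampled for exon and
#'   intron lengths.
#' @param exons_range integer range for the exon count per gene (min 2).
#' @return a `genome_model`: list with `chroms` (chrom, length), `genes`
#'   (gene_id, chrom, strand, start, end) and `exons` (gene_id, chrom, start,
#'   end, exon_number), all 1-based inclusive coordinates.
#' @export
generate_genome <- function(n_chroms = 1L, chrom_len = 1e6, n_genes = 10L,
                            seed = 1L,
                            exon_range = c(100L, 300L),
                            intron_range = c(200L, 2000L),
                            exons_range = c(2L, 5L)) {
  if (n_genes < 0L) stopf("n_genes must be >= 0")
  if (exons_range[1] < 2L) stopf("genes need >= 2 exons to carry a junction")
  chroms <- data.frame(chrom = paste0("chr", seq_len(n_chroms)),
                       length = rep(as.numeric(chrom_len), n_chroms),
                       stringsAsFactors = FALSE)
  genes <- exons <- NULL
  if (n_genes > 0L) {
    withr::with_seed(seed, {
      n_ex <- sample(seq(exons_range[1], exons_range[2]), n_genes, replace = TRUE)
      gene_chrom <- rep_len(seq_len(n_chroms), n_genes)
      glist <- vector("list", n_genes)
      elist <- vector("list", n_genes)
      cursor <- rep(1L, n_chroms)  # next free bp per chromosome
      gap <- 500L
      for (i in seq_len(n_genes)) {
        k <- n_ex[i]
        ex_len <- sample(seq(exon_range[1], exon_range[2]), k, replace = TRUE)
        in_len <- sample(seq(intron_range[1], intron_range[2]), k - 1L,
                         replace = TRUE)
        ci <- gene_chrom[i]
        start <- cursor[ci] + gap
        ex_start <- start + c(0, cumsum(ex_len[-k] + in_len))
        ex_end <- ex_start + ex_len - 1L
        end <- ex_end[k]
        if (end > chrom_len)
          stopf("capacity error: cannot place %d genes on %d chromosome(s) of %g bp",
                n_genes, n_chroms, chrom_len)
        cursor[ci] <- end + 1L
        gid <- sprintf("GENE%04d", i)
        glist[[i]] <- data.frame(gene_id = gid, chrom = chroms$chrom[ci],
                                 strand = sample(c("+", "-"), 1L),
                                 start = start, end = end,
                                 stringsAsFactors = FALSE)
        elist[[i]] <- data.frame(gene_id = gid, chrom = chroms$chrom[ci],
                                 start = ex_start, end = ex_end,
                                 exon_number = seq_len(k),
                                 stringsAsFactors = FALSE)
      }
      genes <- do.call(rbind, glist)
      exons <- do.call(rbind, elist)
    })
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        strand = character(), start = numeric(),
                        end = numeric(), stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        exon_number = integer(), stringsAsFactors = FALSE)
  }
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(chroms = chroms, genes = genes, exons = exons),
            class = "genome_model")
}

is_genome_model <- function(x) inherits(x, "genome_model")

#' Annotated introns of a genome model
#'
#' A junction is the intronic gap between two consecutive exons of a gene
#' (one transcript per gene in the synthetic model): intron start is the base
#' after the upstream exon, intron end the base before the downstream exon,
#' 1-based inclusive.
#'
#' @param genome a `genome_model`.
#' @return data.frame with `gene_id`, `chrom`, `strand`, `intron_start`,
#'   `intron_end`.
#' @export
annotated_junctions <- function(genome) {
  if (!is_genome_model(genome)) stopf("expected a genome_model")
  ex <- genome$exons
  if (nrow(ex) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), intron_start = numeric(),
                      intron_end = numeric(), stringsAsFactors = FALSE))
  ex <- ex[order(ex$gene_id, ex$exon_number), ]
  by_gene <- split(ex, ex$gene_id)
  strand_of <- setNames(genome$genes$strand, genome$genes$gene_id)
  out <- lapply(by_gene, function(g) {
    k <- nrow(g)
    if (k < 2L) return(NULL)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = unname(strand_of[g$gene_id[1]]),
               intron_start = g$end[-k] + 1,
               intron_end = g$start[-1] - 1,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a genome model as GTF
#'
#' The Ensembl-style schema is used: tab-separated, 1-based inclusive, gene /
#' transcript / exon features with `gene_id` (and `transcript_id`) attributes.
#' Reading goes through [rtracklayer::import()] so any conformant GTF (e.g. a
#' subset of the Ensembl mouse annotation) can drive the junction module.
#'
#' @param genome a `genome_model`.
#' @param path GTF file path.
#' @return `write_gtf` returns the path invisibly; `read_gene_annotation`
#'   returns a `genome_model` (chromosome lengths taken as the max feature
#'   end per chromosome when no sequence info is present).
#' @export
write_gtf <- function(genome, path) {
  if (!is_genome_model(genome)) stopf("expected a genome_model")
  g <- genome$genes
  e <- genome$exons
  lines <- character(0)
  if (nrow(g) > 0L) {
    strand_of <- setNames(g$strand, g$gene_id)
    gene_lines <- sprintf(
      "%s\tdevage\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"protein_coding\";",
      g$chrom, g$start, g$end, g$strand, g$gene_id)
    tx_lines <- sprintf(
      "%s\tdevage\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
      g$chrom, g$start, g$end, g$strand, g$gene_id, g$gene_id)
    exon_lines <- sprintf(
      "%s\tdevage\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\"; exon_number \"%d\";",
      e$chrom, e$start, e$end, unname(strand_of[e$gene_id]), e$gene_id,
      e$gene_id, e$exon_number)
    ord <- order(c(g$start, g$start, e$start),
                 c(rep(1L, nrow(g)), rep(2L, nrow(g)), rep(3L, nrow(e))))
    lines <- c(gene_lines, tx_lines, exon_lines)[ord]
  }
  writeLines(c("#!genome synthetic", lines), path)
  invisible(path)
}

#' @rdname write_gtf
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  genes <- df[df$type == "gene", ]
  exons <- df[df$type == "exon", ]
  if (nrow(genes) == 0L && nrow(exons) > 0L) {
    # gene records absent: infer gene span from exons
    sp <- split(exons, exons$gene_id)
    genes <- do.call(rbind, lapply(sp, function(x)
      data.frame(gene_id = x$gene_id[1], seqnames = x$seqnames[1],
                 strand = as.character(x$strand[1]),
                 start = min(x$start), end = max(x$end),
                 stringsAsFactors = FALSE)))
  }
  gene_df <- data.frame(gene_id = genes$gene_id, chrom = genes$seqnames,
                        strand = as.character(genes$strand),
                        start = genes$start, end = genes$end,
                        stringsAsFactors = FALSE)
  gene_df <- gene_df[order(gene_df$chrom, gene_df$start), ]
  exon_df <- data.frame(gene_id = exons$gene_id, chrom = exons$seqnames,
                        start = exons$start, end = exons$end,
                        stringsAsFactors = FALSE)
  exon_df <- exon_df[order(exon_df$gene_id, exon_df$start), ]
  exon_df$exon_number <- stats::ave(exon_df$start, exon_df$gene_id,
                                    FUN = seq_along)
  chroms <- stats::aggregate(end ~ chrom, data = rbind(
    gene_df[, c("chrom", "end")], exon_df[, c("chrom", "end")]), FUN = max)
  names(chroms) <- c("chrom", "length")
  rownames(gene_df) <- rownames(exon_df) <- NULL
  structure(list(chroms = chroms, genes = gene_df, exons = exon_df),
            class = "genome_model")
}

# coerce a genome_model or GTF path to a genome_model
as_genome_model <- function(annotation) {
  if (is_genome_model(annotation)) return(annotation)
  if (is.character(annotation) && length(annotation) == 1L)
    return(read_gene_annotation(annotation))
  stopf("annotation must be a genome_model or a GTF file path")
}
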