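#' Write one junction table in the 9-column dialect
#'
#' Inverse of [read_junction_table()]: strand is re-encoded 0/1/2, fields
#' are tab-separated with no header.
#'
#' @param records junction data.frame (as produced by the simulator or
#'   [read_junction_table()]).
#' @param path output path.
#' @export
write_junction_table <- function(records, path) {
  code <- c("undefined" = 0L, "+" = 1L, "-" = 2L)
  out <- data.frame(records$chrom, records$intron_start, records$intron_end,
                    unname(code[records$strand]), records$motif_code,
                    records$annotated_flag, records$unique_reads,
                    records$multimapped_reads, records$max_overhang)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write simulated pipeline inputs to disk with a checksum manifest
#'
#' Emits every fixture the pipeline readers consume: one junction table per
#' sample (SJ dialect), the annotation GTF, the SNP VCF, the DM-site TSV,
#' the beta-value CSV, per-(strain, phase) DE TSVs, the design YAML, and a
#' `truth.json` with the planted ground truth.  The manifest lists every
#' file with its md5 checksum; a re-run with the same seed reproduces
#' identical checksums.
#'
#' @param outputs list with any of: `design` ([sample_design()]), `genome`
#'   (`genome_model`), `junctions` ([simulate_junction_tables()] output),
#'   `methylation` ([simulate_methylation()] output), `landscape`
#'   ([simulate_snp_dm_landscape()] output), `de`
#'   ([simulate_de_tables()] output).
#' @param directory output directory (created if needed).
#' @return data.frame manifest: `file`, `md5`.
#' @export
write_fixtures <- function(outputs, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stopf("cannot create directory %s", directory)
  files <- character(0)
  emit <- function(rel) {
    p <- file.path(directory, rel)
    files <<- c(files, rel)
    p
  }
  truth <- list()
  if (!is.null(outputs$design))
    write_design(outputs$design, emit("design.yaml"))
  if (!is.null(outputs$genome))
    write_gtf(outputs$genome, emit("annotation.gtf"))
  if (!is.null(outputs$junctions)) {
    dir.create(file.path(directory, "sj"), showWarnings = FALSE)
    for (sid in names(outputs$junctions$tables))
      write_junction_table(outputs$junctions$tables[[sid]],
                           emit(file.path("sj", paste0(sid, ".SJ.out.tab"))))
    truth$specific_junctions <- outputs$junctions$truth$specific_junctions
    truth$decoy_keys <- outputs$junctions$truth$decoy_keys
  }
  if (!is.null(outputs$methylation)) {
    write_beta_matrix(outputs$methylation$matrix, emit("beta_values.csv"))
    truth$dm_sites <- outputs$methylation$truth
  }
  if (!is.null(outputs$landscape)) {
    write_snp_vcf(outputs$landscape$snp, emit("snps.vcf"))
    write_tsv(as.data.frame(outputs$landscape$dm)[, c("chrom", "pos")],
              emit("dm_sites.tsv"))
    truth$proximal_pairs <- outputs$landscape$truth
  }
  if (!is.null(outputs$de)) {
    dir.create(file.path(directory, "de"), showWarnings = FALSE)
    for (nm in names(outputs$de$tables))
      write_tsv(outputs$de$tables[[nm]],
                emit(file.path("de", paste0(nm, ".tsv"))))
    truth$de_counts <- outputs$de$truth
  }
  jsonlite::write_json(truth, file.path(directory, "truth.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  files <- c(files, "truth.json")
  manifest <- data.frame(file = files,
                         md5 = vapply(file.path(directory, files),
                                      file_checksum, ""),
                         stringsAsFactors = FALSE, row.names = NULL)
  write_tsv(manifest, file.path(directory, "manifest.tsv"))
  manifest
}

#' Read planted truth back from a fixture directory
#' @param directory fixture directory written by [write_fixtures()].
#' @return list of truth components (data.frames).
#' @export
read_truth <- function(directory) {
  jsonlite::read_json(file.path(directory, "truth.json"), simplifyVector = TRUE)
}
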