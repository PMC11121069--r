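# end-to-end orchestration over the synthetic fixtures

config_schema <- function() {
  list(
    seed = NULL, out = NULL,
    simulate = list(
      genome = list(n_chroms = NULL, chrom_len = NULL, n_genes = NULL),
      junctions = list(n_background_junctions = NULL,
                       n_planted_specific_per_cell = NULL,
                       read_depth_mean = NULL),
      methylation = list(n_sites = NULL, dm_fraction = NULL, effect_m = NULL,
                         noise_sd_m = NULL),
      landscape = list(chrom_len = NULL, n_snps = NULL, n_dm = NULL,
                       proximal_fraction = NULL, max_pair_distance = NULL),
      de = list(n_genes = NULL)),
    junctions = list(min_reads = NULL, min_overhang = NULL,
                     multimap_policy = NULL, threshold = NULL, pooling = NULL),
    methylation = list(alpha = NULL, linkage = NULL, n_cluster_sites = NULL),
    snpdm = list(alternative = NULL, or_estimator = NULL),
    design = list(rna = list(strains = NULL, days = NULL, replicates = NULL),
                  methylation = list(strains = NULL, days = NULL,
                                     replicates = NULL)))
}

#' Default pipeline configuration
#'
#' The defaults encode the study conditions the synthetic generator
#' emulates: a 3 strain x 3 day x 3 replicate RNA design (27 samples) with
#' 5 planted time-specific junctions per cell, a 3 strain x duplicate
#' methylation design over 2045 clock sites with a 0.29 planted DM
#' fraction, a 303-SNP / 1957-DM landscape with 30% of DM sites planted
#' within 1 kb of SNPs, and early/late-skewed DE tables.
#'
#' @param seed integer seed driving every generator.
#' @param out output directory.
#' @return a nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1L, out = tempfile("devage_run_")) {
  list(
    seed = as.integer(seed), out = out,
    simulate = list(
      genome = list(n_chroms = 2L, chrom_len = 2e6, n_genes = 150L),
      junctions = list(n_background_junctions = 200L,
                       n_planted_specific_per_cell = 5L,
                       read_depth_mean = 30),
      methylation = list(n_sites = 2045L, dm_fraction = 0.29, effect_m = 2,
                         noise_sd_m = 0.3),
      landscape = list(chrom_len = 1e8, n_snps = 303L, n_dm = 1957L,
                       proximal_fraction = 0.3, max_pair_distance = 1000L),
      de = list(n_genes = 2000L)),
    junctions = list(min_reads = 10L, min_overhang = 20L,
                     multimap_policy = "drop_if_any", threshold = 10L,
                     pooling = "pooled"),
    methylation = list(alpha = 0.05, linkage = "complete",
                       n_cluster_sites = 60L),
    snpdm = list(alternative = "greater", or_estimator = "cmle"),
    design = list(
      rna = list(strains = c("A", "B", "C"), days = c(12, 15, 17),
                 replicates = 3L),
      methylation = list(strains = c("A", "B", "C"), days = 15,
                         replicates = 2L)))
}

#' Validate a pipeline configuration
#'
#' Unknown keys at any nesting level are rejected before any stage runs.
#'
#' @param config a configuration list (see [default_config()]).
#' @return the config, invisibly, or an error naming the offending key.
#' @export
validate_config <- function(config) {
  walk <- function(cfg, schema, path) {
    unknown <- setdiff(names(cfg), names(schema))
    if (length(unknown))
      stopf("unknown config key: %s",
            paste0(path, unknown[1L]))
    for (nm in names(cfg))
      if (is.list(schema[[nm]]))
        walk(cfg[[nm]], schema[[nm]], paste0(path, nm, "."))
  }
  walk(config, config_schema(), "")
  if (is.null(config$seed) || is.null(config$out))
    stopf("config needs 'seed' and 'out'")
  invisible(config)
}

# merge user config over defaults, recursively
merge_config <- function(user, base) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]]))
      merge_config(user[[nm]], base[[nm]]) else user[[nm]]
  }
  base
}

#' Run the full synthetic analysis pipeline
#'
#' Stages, in dependency order: simulate (writes fixtures), junctions
#' (read, merge, filter, classify, summarize), methylation (DM ANOVA per
#' strain pair, Venn, Manhattan table, dendrogram comparison), snpdm
#' (nearest distances, bins, association table), decounts (phase counts,
#' chi-square/Cramer's V, Venn partitions).  Every stage re-reads its
#' inputs through the same readers a real run would use, writes its result
#' tables under `config$out`, and records provenance (stage, parameters,
#' input checksums, seed) in `run_manifest.json`.  A stage whose inputs and
#' parameters are unchanged since the recorded run is skipped.
#'
#' @param config configuration list; missing entries are filled from
#'   [default_config()].
#' @return report list with each stage's main tables.
#' @export
run_pipeline <- function(config = list()) {
  config <- merge_config(config, default_config(seed = config$seed %||% 1L,
                                                out = config$out %||%
                                                  tempfile("devage_run_")))
  validate_config(config)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  fixdir <- file.path(out, "fixtures")
  seed <- config$seed
  manifest_path <- file.path(out, "run_manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list()
  report <- list(config = config)

  norm <- function(x) unname(rapply(x, as.character, how = "unlist"))
  stage_fresh <- function(stage, params, inputs, outputs) {
    rec <- manifest[[stage]]
    if (is.null(rec)) return(FALSE)
    ok <- identical(norm(rec$params), norm(params)) &&
      identical(norm(rec$input_checksums),
                unname(vapply(inputs, file_checksum, ""))) &&
      all(file.exists(file.path(out, unlist(rec$outputs))))
    isTRUE(ok)
  }
  record_stage <- function(stage, params, inputs, outputs) {
    manifest[[stage]] <<- list(
      stage = stage, seed = seed,
      params = params,
      input_checksums = as.list(vapply(inputs, file_checksum, "")),
      outputs = outputs)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  ## -- stage: simulate ------------------------------------------------------
  rna_design <- do.call(sample_design, config$design$rna)
  meth_design <- do.call(sample_design, config$design$methylation)
  sim_params <- config$simulate
  genome <- do.call(generate_genome,
                    c(sim_params$genome, list(seed = seed)))
  land_genome <- generate_genome(n_chroms = 1L,
                                 chrom_len = sim_params$landscape$chrom_len,
                                 n_genes = 0L, seed = seed)
  sim <- list(
    design = rna_design,
    genome = genome,
    junctions = do.call(simulate_junction_tables,
                        c(list(design = rna_design, genome = genome,
                               seed = seed), sim_params$junctions)),
    methylation = do.call(simulate_methylation,
                          c(list(design = meth_design, seed = seed),
                            sim_params$methylation)),
    landscape = do.call(simulate_snp_dm_landscape,
                        c(list(genome = land_genome, seed = seed),
                          sim_params$landscape[names(sim_params$landscape) !=
                                                 "chrom_len"])),
    de = do.call(simulate_de_tables,
                 c(list(design = rna_design, seed = seed), sim_params$de)))
  fix_manifest <- write_fixtures(sim, fixdir)
  report$fixtures <- fix_manifest

  ## -- stage: junctions -----------------------------------------------------
  sj_files <- file.path(fixdir, "sj",
                        paste0(rna_design$sample_id, ".SJ.out.tab"))
  jp <- config$junctions
  if (!stage_fresh("junctions", jp, sj_files, "junction_calls.tsv")) {
    tables <- setNames(lapply(sj_files, read_junction_table),
                       rna_design$sample_id)
    mat <- merge_junctions(tables, rna_design)
    mat <- filter_junctions(mat, min_overhang = jp$min_overhang,
                            min_reads = jp$min_reads,
                            multimap_policy = jp$multimap_policy)
    calls <- classify_time_specificity(mat, threshold = jp$threshold,
                                       pooling = jp$pooling)
    novelty <- classify_novelty(mat, file.path(fixdir, "annotation.gtf"))
    genes <- assign_genes(mat, file.path(fixdir, "annotation.gtf"))
    calls$novelty <- novelty$novelty[match(calls$key, novelty$key)]
    calls$gene_ids <- vapply(genes[calls$key], paste, "", collapse = ",")
    write_tsv(calls, file.path(out, "junction_calls.tsv"))
    write_tsv(motif_summary(calls, mat, threshold = jp$threshold),
              file.path(out, "junction_motifs.tsv"))
    counts <- specificity_counts(calls)
    write_tsv(counts, file.path(out, "junction_specificity_counts.tsv"))
    record_stage("junctions", jp, sj_files,
                 c("junction_calls.tsv", "junction_motifs.tsv",
                   "junction_specificity_counts.tsv"))
    report$junctions <- list(matrix = mat, calls = calls, counts = counts)
  } else {
    report$junctions <- list(
      calls = read.table(file.path(out, "junction_calls.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE))
  }

  ## -- stage: methylation ---------------------------------------------------
  mp <- config$methylation
  beta_file <- file.path(fixdir, "beta_values.csv")
  mat <- read_beta_matrix(beta_file, meth_design)
  strains <- attr(meth_design, "strains")
  pairs <- utils::combn(strains, 2L, simplify = FALSE)
  dm_results <- lapply(pairs, function(p) dm_anova(mat, p[1], p[2]))
  names(dm_results) <- vapply(pairs, paste, "", collapse = "_vs_")
  dm_sets <- lapply(dm_results, call_dm, alpha = mp$alpha)
  venn <- venn_partition(dm_sets)
  manh <- manhattan_table(do.call(rbind, dm_results), alpha = mp$alpha)
  write_tsv(manh, file.path(out, "dm_manhattan.tsv"))
  write_tsv(data.frame(region = names(venn), count = venn),
            file.path(out, "dm_venn.tsv"))
  # dendrogram comparison: cluster a fixed subsample of sites on each strain
  # pair's per-site change profile, then correlate cophenetic structure
  profiles <- vapply(pairs, function(p) dm_change_profile(mat, p[1], p[2]),
                     numeric(nrow(mat$sites)))
  colnames(profiles) <- names(dm_results)
  sub <- withr::with_seed(seed,
                          sort(sample.int(nrow(profiles),
                                          min(mp$n_cluster_sites,
                                              nrow(profiles)))))
  dends <- lapply(names(dm_results), function(nm)
    hier_cluster(profiles[sub, nm, drop = FALSE], linkage = mp$linkage))
  names(dends) <- names(dm_results)
  coph <- outer(names(dends), names(dends),
                Vectorize(function(a, b)
                  cophenetic_correlation(dends[[a]], dends[[b]])))
  dimnames(coph) <- list(names(dends), names(dends))
  write_tsv(as.data.frame(coph), file.path(out, "dm_cophenetic.tsv"))
  record_stage("methylation", mp, beta_file,
               c("dm_manhattan.tsv", "dm_venn.tsv", "dm_cophenetic.tsv"))
  report$methylation <- list(results = dm_results, dm_sets = dm_sets,
                             venn = venn, cophenetic = coph)

  ## -- stage: snpdm ---------------------------------------------------------
  sp <- config$snpdm
  snp <- read_snp_sites(file.path(fixdir, "snps.vcf"))
  dm <- read_dm_sites(file.path(fixdir, "dm_sites.tsv"))
  assoc <- association_table(snp, dm, alternative = sp$alternative,
                             or_estimator = sp$or_estimator)
  write_tsv(assoc, file.path(out, "snp_dm_association.tsv"))
  record_stage("snpdm", sp, file.path(fixdir, c("snps.vcf", "dm_sites.tsv")),
               "snp_dm_association.tsv")
  report$snpdm <- assoc

  ## -- stage: decounts ------------------------------------------------------
  de_files <- file.path(fixdir, "de", paste0(names(sim$de$tables), ".tsv"))
  de_tables <- lapply(names(sim$de$tables), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    read_de_table(file.path(fixdir, "de", paste0(nm, ".tsv")),
                  strain = parts[1], phase = parts[2])
  })
  counts <- phase_counts(de_tables)
  stats_ab <- chisq_cramers_v(counts[c("A", "B"), ])
  stats_cb <- chisq_cramers_v(counts[c("C", "B"), ])
  tb_phase <- vapply(de_tables, attr, "", "phase")
  tb_strain <- vapply(de_tables, attr, "", "strain")
  p1 <- de_tables[tb_phase == "P1"]
  venn_up <- de_venn(setNames(lapply(p1, de_genes, "UP"),
                              tb_strain[tb_phase == "P1"]))
  write_tsv(as.data.frame(counts), file.path(out, "de_phase_counts.tsv"))
  jsonlite::write_json(list(A_vs_B = stats_ab, C_vs_B = stats_cb),
                       file.path(out, "de_association.json"),
                       auto_unbox = TRUE, digits = NA)
  record_stage("decounts", list(), de_files,
               c("de_phase_counts.tsv", "de_association.json"))
  report$decounts <- list(counts = counts, A_vs_B = stats_ab,
                          C_vs_B = stats_cb, venn_up_P1 = venn_up)
  report
}
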