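#' Construct a strain x gestational-day x replicate sample design
#'
#' The study layout is a factorial design: strains (AKR/J, C57BL/6J and the
#' congenic Cav1-null line, abbreviated A/B/C), gestational days of fetal
#' brain sampling, and biological replicates per cell.  RNA-seq used
#' 3 strains x 3 days x 3 replicates (27 samples); the methylation assay used
#' the d15 brains only, in duplicates (3 strains x 1 day x 2 replicates).
#'
#' @param strains character vector of unique strain labels.
#' @param days numeric vector of unique gestational days.
#' @param replicates number of replicates per (strain, day) cell.
#' @return a `sample_design`: a data.frame with columns `sample_id`, `strain`,
#'   `day`, `replicate`, one row per sample, plus attributes `strains`,
#'   `days`, `replicates`.
#' @examples
#' d <- sample_design(c("A", "B", "C"), c(12, 15, 17), 3)
#' nrow(d)  # 27
#' @export
sample_design <- function(strains = c("A", "B", "C"),
                          days = c(12, 15, 17),
                          replicates = 3L) {
  if (anyDuplicated(strains)) stopf("strain labels must be unique")
  if (anyDuplicated(days)) stopf("day labels must be unique")
  replicates <- as.integer(replicates)
  if (length(replicates) != 1L || is.na(replicates) || replicates < 1L)
    stopf("replicates_per_cell must be a positive integer")
  grid <- expand.grid(replicate = seq_len(replicates), day = days,
                      strain = strains, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("strain", "day", "replicate")]
  grid$sample_id <- sprintf("%s_d%s_r%d", grid$strain, grid$day, grid$replicate)
  des <- grid[, c("sample_id", "strain", "day", "replicate")]
  rownames(des) <- NULL
  structure(des, strains = strains, days = days, replicates = replicates,
            class = c("sample_design", "data.frame"))
}

is_sample_design <- function(x) inherits(x, "sample_design")

assert_design <- function(design) {
  if (!is_sample_design(design)) stopf("expected a sample_design object")
  if (anyDuplicated(design$sample_id))
    stopf("sample ids must map to exactly one design cell")
  tab <- table(design$strain, design$day)
  if (length(unique(as.vector(tab))) != 1L)
    stopf("design is unbalanced: every (strain, day) cell needs %d samples",
          attr(design, "replicates"))
  invisible(design)
}

# sample ids belonging to one (strain, day) cell
cell_samples <- function(design, strain, day) {
  design$sample_id[design$strain == strain & design$day == day]
}

# all (strain, day) cells as a data.frame
design_cells <- function(design) {
  unique(design[, c("strain", "day")])
}

#' Read / write a sample design as YAML
#'
#' @param path file path.
#' @return `read_design` returns a [sample_design()]; `write_design` returns
#'   the path, invisibly.
#' @export
read_design <- function(path) {
  y <- yaml::read_yaml(path)
  for (f in c("strains", "days", "replicates"))
    if (is.null(y[[f]])) stopf("design file %s: missing field '%s'", path, f)
  sample_design(unlist(y$strains), unlist(y$days), y$replicates)
}

#' @rdname read_design
#' @param design a [sample_design()].
#' @export
write_design <- function(design, path) {
  assert_design(design)
  yaml::write_yaml(list(strains = attr(design, "strains"),
                        days = attr(design, "days"),
                        replicates = attr(design, "replicates")), path)
  invisible(path)
}
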