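# small designs and independent oracles used across the suite

tiny_rna_design <- function() sample_design(c("A", "B", "C"), c(12, 15, 17), 3)
tiny_meth_design <- function() sample_design(c("A", "B", "C"), 15, 2)

# cophenetic matrix by explicit lowest-common-ancestor height lookup:
# walk the merge table and stamp the merge height on every cross pair
coph_lca_oracle <- function(hc) {
  n <- length(hc$labels)
  mat <- matrix(0, n, n, dimnames = list(hc$labels, hc$labels))
  clusters <- vector("list", nrow(hc$merge))
  leaves <- function(j, i) if (j < 0) -j else clusters[[j]]
  for (i in seq_len(nrow(hc$merge))) {
    a <- leaves(hc$merge[i, 1]); b <- leaves(hc$merge[i, 2])
    for (x in a) for (y in b) mat[x, y] <- mat[y, x] <- hc$height[i]
    clusters[[i]] <- c(a, b)
  }
  mat
}

# brute-force S/NS classification: enumerate every cell and count threshold
# hits, without any of the package's matrix bookkeeping
classify_oracle <- function(mat, threshold = 10) {
  design <- mat$design
  cells <- unique(design[, c("strain", "day")])
  vapply(seq_len(nrow(mat$junctions)), function(j) {
    hits <- 0L; hit_cell <- NA_integer_
    for (ci in seq_len(nrow(cells))) {
      ids <- design$sample_id[design$strain == cells$strain[ci] &
                                design$day == cells$day[ci]]
      if (sum(mat$unique_reads[j, ids]) >= threshold) {
        hits <- hits + 1L; hit_cell <- ci
      }
    }
    if (hits == 1L) paste0("S:", cells$strain[hit_cell], ":",
                           cells$day[hit_cell]) else "NS"
  }, "")
}

# exact one-sided p by full enumeration of tables with fixed margins
fisher_oracle <- function(tab) {
  x <- tab[1, 1]; m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  supp <- max(0, k - n):min(m, k)
  w <- choose(m, supp) * choose(n, k - supp)
  sum(w[supp >= x]) / sum(w)
}

# conditional-MLE odds ratio by direct likelihood maximization (optimize),
# independent of the package's mean-equation root finding
cmle_oracle <- function(tab) {
  x <- tab[1, 1]; m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  supp <- max(0, k - n):min(m, k)
  lw0 <- lchoose(m, supp) + lchoose(n, k - supp)
  loglik <- function(lp) {
    lw <- lw0 + supp * lp
    x * lp - (max(lw) + log(sum(exp(lw - max(lw)))))
  }
  exp(stats::optimize(loglik, c(-15, 15), maximum = TRUE,
                      tol = 1e-10)$maximum)
}

# random non-degenerate 2x2 count table
random_table <- function() {
  repeat {
    tab <- matrix(rpois(4, 8), 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0) &&
        tab[1, 1] > max(0, sum(tab[1, ]) - sum(tab[, 2])) &&
        tab[1, 1] < min(sum(tab[, 1]), sum(tab[1, ])))
      return(tab)
  }
}

table1_counts <- function() {
  list(c(38, 170, 277, 1787), c(62, 302, 254, 1655), c(55, 357, 252, 1600),
       c(23, 162, 282, 1795), c(87, 609, 217, 1348), c(27, 177, 276, 1780),
       c(20, 144, 283, 1813), c(4, 20, 299, 1937), c(2, 11, 301, 1946),
       c(1, 5, 302, 1952))
}

as_table <- function(v) matrix(v, 2, byrow = TRUE)
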