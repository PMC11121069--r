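test_that("beta/M transform is the log2 ratio with clamping at the boundary", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  expect_error(beta_to_m(0), "strictly")
  expect_error(beta_to_m(1), "strictly")
  expect_warning(m0 <- beta_to_m(0, clamp = TRUE), "clamped")
  expect_equal(m0, log2(1e-6 / (1 - 1e-6)))
  # antisymmetry and round trip, over a dense grid
  b <- seq(0.001, 0.999, by = 0.001)
  expect_equal(beta_to_m(b), -beta_to_m(1 - b), tolerance = 1e-12)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-12)
  # strictly increasing
  expect_true(all(diff(beta_to_m(b)) > 0))
})

test_that("per-site ANOVA matches hand-computed sums of squares and stats::aov", {
  des <- sample_design(c("A", "B"), 15, 3)
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
              dimnames = list("chr1:100", des$sample_id))
  mat <- methylation_matrix(data.frame(site_id = "chr1:100", chrom = "chr1",
                                       pos = 100), m_to_beta(m), des)
  res <- dm_anova(mat, "A", "B")
  expect_equal(res$F_statistic, 13.5)       # SSB = 13.5, SSW/df = 1
  expect_equal(res$p_value, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(round(res$p_value, 4), 0.0213)
  # cross-check against stats::aov on random data
  withr::with_seed(7, {
    m2 <- matrix(rnorm(12 * 6), 12, 6,
                 dimnames = list(NULL, des$sample_id))
    sites <- data.frame(site_id = sprintf("chr1:%d", 1:12), chrom = "chr1",
                        pos = 1:12)
    rownames(m2) <- sites$site_id
    mat2 <- methylation_matrix(sites, m_to_beta(m2), des)
    res2 <- dm_anova(mat2, "A", "B")
    for (i in c(1, 5, 12)) {
      fit <- stats::aov(m2[i, ] ~ des$strain)
      p_aov <- summary(fit)[[1]][["Pr(>F)"]][1]
      expect_equal(res2$p_value[i], p_aov, tolerance = 1e-10)
    }
  })
  # degenerate convention: identical groups -> p = 1
  mc <- matrix(2, 1, 6, dimnames = list("chr1:1", des$sample_id))
  matc <- methylation_matrix(data.frame(site_id = "chr1:1", chrom = "chr1",
                                        pos = 1), m_to_beta(mc), des)
  resc <- dm_anova(matc, "A", "B")
  expect_equal(resc$p_value, 1)
  expect_equal(resc$F_statistic, 0)
  expect_error(dm_anova(mat, "A", "Z"), ">= 2 samples")
})

test_that("DM calling is strict, monotone in alpha, and calibrated under the null", {
  res <- data.frame(site_id = c("s1", "s2", "s3"),
                    p_value = c(0.05, 0.049, 0.2))
  expect_equal(call_dm(res, 0.05), "s2")   # p = 0.05 exactly is not called
  expect_equal(call_dm(res, 0), character(0))
  # monotone in alpha
  alphas <- c(0.01, 0.05, 0.1, 0.5, 1)
  sizes <- vapply(alphas, function(a) length(call_dm(res, a)), 0L)
  expect_true(all(diff(sizes) >= 0))
  # type-I error under the null generator, averaged over seeds
  des <- tiny_meth_design()
  frac <- vapply(1:20, function(s) {
    sim <- simulate_methylation(des, 300, 0.29, effect_m = 0,
                                noise_sd_m = 0.3, seed = s)
    mean(dm_anova(sim$matrix, "A", "B")$p_value < 0.05)
  }, 0)
  expect_gte(mean(frac), 0.03)
  expect_lte(mean(frac), 0.07)
})

test_that("planted DM sites are recovered with high power at effect 2", {
  des <- tiny_meth_design()
  rec <- vapply(1:20, function(s) {
    sim <- simulate_methylation(des, 300, 0.29, effect_m = 2,
                                noise_sd_m = 0.3, seed = s)
    pairs <- list(c("A", "B"), c("A", "C"), c("B", "C"))
    called <- unique(unlist(lapply(pairs, function(p)
      call_dm(dm_anova(sim$matrix, p[1], p[2])))))
    mean(sim$truth$site_id %in% called)
  }, 0)
  expect_gte(mean(rec), 0.9)
})

test_that("group mean M difference at planted sites is unbiased", {
  des <- tiny_meth_design()
  effs <- vapply(1:50, function(s) {
    sim <- simulate_methylation(des, 120, 0.25, effect_m = 2,
                                noise_sd_m = 0.3, seed = 1000 + s)
    tr <- sim$truth[sim$truth$shifted_strain == "A", ]
    prof <- dm_change_profile(sim$matrix, "A", "B")
    mean(prof[tr$site_id])
  }, 0)
  # Monte-Carlo SE ~ 0.3/sqrt(2*~30*50) ~ 0.01; allow 4 SE
  expect_equal(mean(effs), 2, tolerance = 0.05)
})

test_that("venn partition enumerates disjoint regions summing to the union", {
  v <- venn_partition(list(A = c(1, 2), B = c(2, 3), C = 2))
  expect_equal(unname(v[c("A", "B", "C")]), c(1, 1, 0))
  expect_equal(unname(v["A&B&C"]), 1)
  expect_equal(unname(v[c("A&B", "A&C", "B&C")]), c(0, 0, 0))
  expect_equal(sum(v), 3)  # |union|
  ident <- venn_partition(list(X = 1:5, Y = 1:5))
  expect_equal(unname(ident["X&Y"]), 5)
  expect_equal(sum(ident), 5)
  disj <- venn_partition(list(A = 1:2, B = 3:5, C = 6:9))
  expect_equal(unname(disj[c("A", "B", "C")]), c(2, 3, 4))
  expect_equal(sum(disj), 9)
  # property: counts non-negative and sum to |union| on random sets
  withr::with_seed(11, {
    for (i in 1:10) {
      sets <- list(A = sample(50, 20), B = sample(50, 25), C = sample(50, 5))
      v <- venn_partition(sets)
      expect_true(all(v >= 0))
      expect_equal(sum(v), length(unique(unlist(sets))))
    }
  })
  expect_error(venn_partition(list(1:3)), "2 or 3")
})

test_that("manhattan table sorts by chromosome order and flags p < 0.05", {
  res <- data.frame(site_id = c("a", "b", "c"),
                    chrom = c("chr2", "chr1", "chr1"),
                    pos = c(5, 100, 7), strain_pair = "A_vs_B",
                    p_value = c(0.05, 1, 0.001))
  mt <- manhattan_table(res)
  expect_equal(mt$site_id, c("c", "b", "a"))
  expect_equal(mt$neg_log10_p, -log10(c(0.001, 1, 0.05)))
  expect_equal(mt$significant, c(TRUE, FALSE, FALSE))  # 0.05 strict
  expect_equal(round(mt$neg_log10_p[3], 3), 1.301)
})

test_that("hierarchical clustering honors forced geometry", {
  x <- matrix(c(0, 1, 10), dimnames = list(c("p0", "p1", "p10"), NULL))
  hc <- hier_cluster(x)
  expect_equal(sort(hc$height)[1], 1)  # {0,1} join first at height 1
  first <- hc$merge[1, ]
  expect_setequal(hc$labels[-first], c("p0", "p1"))
  # two entities: single merge at their distance
  hc2 <- hier_cluster(matrix(c(0, 3), dimnames = list(c("u", "v"), NULL)))
  expect_equal(hc2$height, 3)
  # duplicate rows merge at height 0
  hc3 <- hier_cluster(matrix(c(1, 1, 5), dimnames = list(c("a", "b", "c"), NULL)))
  expect_equal(min(hc3$height), 0)
  expect_true(all(diff(hc3$height) >= 0))
  expect_error(hier_cluster(matrix(1)), ">= 2")
  expect_error(hier_cluster(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("cophenetic correlation is exact on oracle matrices and invariant", {
  withr::with_seed(13, {
    x <- matrix(rnorm(10 * 4), 10, dimnames = list(letters[1:10], NULL))
    y <- matrix(rnorm(10 * 4), 10, dimnames = list(letters[1:10], NULL))
    da <- hier_cluster(x); db <- hier_cluster(y)
    # self-correlation is 1
    expect_equal(cophenetic_correlation(da, da), 1)
    # matches brute-force LCA-height cophenetic matrices
    ca <- coph_lca_oracle(da)
    cb <- coph_lca_oracle(db)[rownames(ca), rownames(ca)]
    ut <- upper.tri(ca)
    expect_equal(cophenetic_correlation(da, db), cor(ca[ut], cb[ut]))
    # uniform height scaling leaves the correlation unchanged
    db_scaled <- db; db_scaled$height <- db$height * 7.5
    expect_equal(cophenetic_correlation(da, db_scaled),
                 cophenetic_correlation(da, db))
    # leaf relabeling (consistent permutation of both) leaves it unchanged
    perm <- sample(10)
    xp <- x[perm, , drop = FALSE]
    expect_equal(cophenetic_correlation(hier_cluster(xp), db),
                 cophenetic_correlation(da, db), tolerance = 1e-12)
  })
  d1 <- hier_cluster(matrix(1:3, dimnames = list(c("a", "b", "c"), NULL)))
  d2 <- hier_cluster(matrix(1:3, dimnames = list(c("x", "y", "z"), NULL)))
  expect_error(cophenetic_correlation(d1, d2), "leaf sets")
  two <- hier_cluster(matrix(1:2, dimnames = list(c("a", "b"), NULL)))
  expect_error(cophenetic_correlation(two, two), ">= 3")
})

test_that("beta matrix ingest clamps boundaries and validates the design", {
  des <- tiny_meth_design()
  p <- withr::local_tempfile(fileext = ".csv")
  b <- matrix(runif(4 * 6, 0.2, 0.8), 4, dimnames = list(NULL, des$sample_id))
  b[1, 1] <- 0  # boundary value
  df <- data.frame(site = sprintf("chr1:%d", 1:4), b, check.names = FALSE)
  data.table::fwrite(df, p)
  expect_warning(mat <- read_beta_matrix(p, des), "clamped 1")
  expect_equal(attr(mat, "n_clamped"), 1)
  expect_equal(mat$beta[1, 1], 1e-6)
  expect_true(all(mat$beta > 0 & mat$beta < 1))
})
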