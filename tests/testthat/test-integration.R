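mk_mats <- function(m_rows, t_rows, samples = 6) {
  list(m = matrix(unlist(m_rows), nrow = length(m_rows), byrow = TRUE,
                  dimnames = list(names(m_rows), paste0("s", 1:samples))),
       t = matrix(unlist(t_rows), nrow = length(t_rows), byrow = TRUE,
                  dimnames = list(names(t_rows), paste0("s", 1:samples))))
}

test_that("pair correlations classify by sign with exact limit cases", {
  mats <- mk_mats(list(mirA = c(1, 2, 3, 4, 5, 6),
                       mirB = c(1, 2, 3, 4, 5, 6),
                       mirC = rep(2, 6)),
                  list(gX = c(6, 5, 4, 3, 2, 1),
                       gY = c(1, 2, 3, 4, 5, 6)))
  pairs <- data.frame(mirna_id = c("mirA", "mirB", "mirC"),
                      target_id = c("gX", "gY", "gX"))
  pc <- pair_correlations(mats$m, mats$t, pairs)
  expect_equal(pc$r[1], -1)
  expect_equal(pc$class[1], "negative")
  expect_equal(pc$r[2], 1)
  expect_equal(pc$class[2], "positive")
  # zero-variance member: NA, excluded from counts
  expect_true(is.na(pc$r[3]))
  expect_equal(attr(pc, "n_negative"), 1L)
  expect_equal(attr(pc, "n_positive"), 1L)
})

test_that("pair correlations are affine-invariant and sign-antisymmetric", {
  set.seed(71)
  M <- matrix(rnorm(60, 8, 2), 10, 6,
              dimnames = list(sprintf("mir%02d", 1:10), paste0("s", 1:6)))
  Tm <- matrix(rnorm(60, 8, 2), 10, 6,
               dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:6)))
  pairs <- data.frame(mirna_id = rownames(M), target_id = rownames(Tm))
  pc <- pair_correlations(M, Tm, pairs)
  pc_aff <- pair_correlations(3 * M + 5, 3 * Tm + 5, pairs)
  expect_equal(pc$r, pc_aff$r, tolerance = 1e-12)
  pc_neg <- pair_correlations(-M, Tm, pairs)
  expect_equal(pc_neg$r, -pc$r, tolerance = 1e-12)
  expect_true(all(pc_neg$class == ifelse(pc$class == "negative",
                                         "positive", "negative")))
})

test_that("condition-mean correlations use one point per condition", {
  set.seed(72)
  M <- matrix(rnorm(90), 10, 9,
              dimnames = list(sprintf("mir%02d", 1:10), paste0("s", 1:9)))
  Tm <- matrix(rnorm(90), 10, 9,
               dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:9)))
  pairs <- data.frame(mirna_id = rownames(M), target_id = rownames(Tm))
  cond <- rep(c("DC", "RC", "AC"), each = 3)
  pc <- pair_correlations(M, Tm, pairs, level = "condition_mean",
                          conditions = cond)
  expect_true(all(pc$n == 3))
  i <- 4
  mm <- tapply(M[i, ], cond, mean)[c("DC", "RC", "AC")]
  tt <- tapply(Tm[i, ], cond, mean)[c("DC", "RC", "AC")]
  expect_equal(pc$r[i], unname(cor(mm, tt)))
})

test_that("the diff-vs-other contrast matches the pooled t formula", {
  pairs <- data.frame(mirna_id = sprintf("m%02d", 1:10),
                      target_id = sprintf("g%02d", 1:10),
                      r = c(-0.9, -0.8, -0.85, -0.7, -0.95,
                            -0.2, 0.1, -0.3, 0.2, -0.1),
                      diff_flag = rep(c(TRUE, FALSE), each = 5))
  res <- compare_pair_groups(pairs)
  x <- pairs$r[1:5]; y <- pairs$r[6:10]
  sp <- sqrt((4 * var(x) + 4 * var(y)) / 8)
  t_manual <- (mean(x) - mean(y)) / (sp * sqrt(1 / 5 + 1 / 5))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$df, 8)
  expect_lt(res$mean_diff, res$mean_other)
  # identical r distributions: t = 0, p = 1
  pairs2 <- pairs
  pairs2$r <- rep(c(-0.5, 0, 0.5, 0.2, -0.2), 2)
  res2 <- compare_pair_groups(pairs2)
  expect_equal(res2$t, 0)
  expect_equal(res2$p_value, 1)
})

test_that("region level summaries follow weighted-count arithmetic", {
  g <- gene_models("g1", "Chr01", "+", 10001L, 14000L)
  sites <- make_sites(c(11000, 12000), c(5, 15), c(5, 5))
  lv <- condition_region_levels(list(A = sites), g, "body", "CG")
  expect_equal(unname(lv["g1", "A"]), 20 / 30)
  # promoter region of the same gene has no sites: NA
  lvp <- condition_region_levels(list(A = sites), g, "promoter", "CHH")
  expect_true(is.na(lvp["g1", "A"]))
})

test_that("gene-body integration reports per-condition records and trends", {
  g <- gene_models(paste0("g", 1:6), "Chr01", "+",
                   seq(10001L, 60001L, by = 10000L),
                   seq(12000L, 62000L, by = 10000L))
  lvl <- seq(0.1, 0.6, by = 0.1)
  sites <- lapply(c(A = 1, B = 2), function(i) {
    do.call(rbind, lapply(1:6, function(j)
      make_sites(g$start[j] + c(100, 200), round(20 * lvl[j]),
                 20 - round(20 * lvl[j]))))
  })
  expr <- matrix(rep(lvl * 100, 2), 6,
                 dimnames = list(g$gene_id, c("A", "B")))
  gb <- gene_body_meth_expression(sites, g, expr)
  expect_equal(nrow(gb$records), 12L)
  expect_true(all(gb$spearman$rho > 0.99))
  rec <- gb$records[gb$records$gene_id == "g3" &
                      gb$records$condition == "A", ]
  expect_equal(rec$body_cg_level, 0.3)
})

test_that("three-point coupling correlations match the direct formula", {
  pl <- matrix(c(0.3, 0.2, 0.1, 0.25, 0.25, 0.25, 0.1, 0.3, 0.2), 3,
               byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), c("DC", "RC", "AC")))
  ex <- matrix(c(10, 20, 30, 10, 30, 20, 15, 25, 20), 3, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3"), c("DC", "RC", "AC")))
  res <- dmr_expression_correlation_compare(pl, ex, "g1")
  r1 <- res$records$r[res$records$gene_id == "g1"]
  expect_equal(r1, cor(c(0.3, 0.2, 0.1), c(10, 20, 30)))
  # flat promoter trajectory: correlation undefined, record NA
  expect_true(is.na(res$records$r[res$records$gene_id == "g2"]))
})

test_that("identical coupling distributions give a null U test", {
  set.seed(73)
  pl <- matrix(runif(60, 0.1, 0.4), 20, 3,
               dimnames = list(sprintf("g%02d", 1:20), c("DC", "RC", "AC")))
  ex <- matrix(rnorm(60, 100, 10), 20, 3,
               dimnames = list(sprintf("g%02d", 1:20), c("DC", "RC", "AC")))
  res <- dmr_expression_correlation_compare(pl, ex,
                                            sprintf("g%02d", 1:10))
  expect_gt(res$u_p_value, 0.05)
})

test_that("a degenerate one-cluster run still pairs centroids with CHH", {
  g <- gene_models(paste0("g", 1:5), "Chr01", "+",
                   seq(10001L, 50001L, by = 10000L),
                   seq(12000L, 52000L, by = 10000L))
  dmrs <- data.frame(chrom = "Chr01",
                     start = g$promoter_start[1:4] + 100L,
                     end = g$promoter_start[1:4] + 300L,
                     context = "CHH", stringsAsFactors = FALSE)
  set.seed(74)
  ex <- matrix(rnorm(15, 50, 20), 5,
               dimnames = list(g$gene_id, c("DC", "RC", "AC")))
  pl <- matrix(runif(15, 0.05, 0.3), 5,
               dimnames = list(g$gene_id, c("DC", "RC", "AC")))
  res <- chh_promoter_dmr_clusters(dmrs, g, ex, pl, k = 1, seed = 5)
  expect_true(all(res$records$cluster == 1))
  expect_identical(nrow(res$records), 4L)  # only promoter-DMR genes
  expect_equal(dim(res$chh_trajectories), c(1L, 3L))
})
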