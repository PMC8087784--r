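test_that("size factors reproduce median-of-ratios exactly", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(m, s3 = 2 * m[, 1])
  sf <- size_factors(m2)
  expect_equal(unname(sf["s3"] / sf["s1"]), 2)
  # reference implementation written from the definition
  set.seed(41)
  r <- matrix(rpois(606, 40) + 1, 101,
              dimnames = list(paste0("g", 1:101), paste0("s", 1:6)))
  geo <- exp(rowMeans(log(r)))
  oracle <- apply(r, 2, function(col) median(col / geo))
  expect_lt(max(abs(size_factors(r) - oracle)), 1e-10)
  # independent package cross-check
  expect_lt(max(abs(size_factors(r) -
                      DESeq2::estimateSizeFactorsForMatrix(r))), 1e-10)
  expect_error(size_factors(diag(2) * 5 + 0), "non-zero")
})

test_that("FPKM and TPM follow their definitions and identities", {
  counts <- matrix(c(100, 1e6 - 100), 2,
                   dimnames = list(c("g1", "g2"), "s1"))
  f <- fpkm(counts, lengths = c(1000, 5000))
  expect_equal(unname(f["g1", 1]), 100)  # library 1e6, 1 kb gene
  tp <- tpm(counts, lengths = c(1000, 5000))
  expect_equal(sum(tp[, 1]), 1e6)
  # FPKM / TPM ratio is constant within a sample
  set.seed(43)
  cm <- matrix(rpois(50, 100), 10, 5,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  ln <- sample(500:3000, 10)
  ratio <- fpkm(cm, ln) / tpm(cm, ln)
  expect_lt(max(apply(ratio, 2, function(col) diff(range(col)))), 1e-9)
  expect_error(fpkm(cm * 0, ln), "library")
})

test_that("identical NB groups produce essentially no DEG calls", {
  cfg <- big_gene_config(51, 500, conditions = c("A", "B"), n_reps = 3,
                         de_n = 0, expr_dispersion = 0.1,
                         expr_mean_log_mu = log(200), expr_mean_log_sd = 0,
                         size_factor_sd = 0)
  genes <- simulate_gene_models(cfg)
  sim <- simulate_expression(cfg, genes)
  res <- deg_test(sim$expr)
  expect_lte(sum(res$status != "ns"), 1)
})

test_that("true 8-fold changes are recovered with high power", {
  cfg <- big_gene_config(52, 500, conditions = c("A", "B"), n_reps = 3,
                         de_n = 100, de_fc = 8, de_condition = "B",
                         expr_dispersion = 0.1,
                         expr_mean_log_mu = log(200), expr_mean_log_sd = 0,
                         size_factor_sd = 0)
  genes <- simulate_gene_models(cfg)
  sim <- simulate_expression(cfg, genes)
  res <- deg_test(sim$expr)
  de_ids <- sim$truth$de$gene_id
  hit <- res$status[res$feature_id %in% de_ids] != "ns"
  expect_gte(mean(hit), 0.8)
  # direction agrees with the configured truth
  up_ids <- sim$truth$de$gene_id[sim$truth$de$direction == "up"]
  expect_true(all(res$status[res$feature_id %in% up_ids &
                               res$status != "ns"] == "up"))
})

test_that("the fold-change threshold boundary is inclusive by default", {
  m <- matrix(c(rep(100L, 3), rep(403L, 3)), 1, byrow = TRUE,
              dimnames = list("g1", paste0("s", 1:6)))
  m <- rbind(m, g2 = rep(100L, 6))
  cond <- rep(c("A", "B"), each = 3)
  res <- deg_test(m, cond, sf = setNames(rep(1, 6), colnames(m)))
  # (403 + 1) / (100 + 1) = 4 exactly at the threshold
  expect_equal(2 ^ res$log2_fc[res$feature_id == "g1"], 4)
  expect_equal(res$status[res$feature_id == "g1"], "up")
  strict <- deg_test(m, cond, strict_fc = TRUE,
                     sf = setNames(rep(1, 6), colnames(m)))
  expect_equal(strict$status[strict$feature_id == "g1"], "ns")
})

test_that("miRNA tests are label-antisymmetric and null-calibrated", {
  set.seed(53)
  m <- matrix(rnbinom(600 * 6, mu = 150, size = 10), 600, 6,
              dimnames = list(sprintf("mir%03d", 1:600), paste0("s", 1:6)))
  cond <- rep(c("A", "B"), each = 3)
  r_ab <- de_mirna(m, cond, "A", "B")
  expect_lte(sum(r_ab$status != "ns"), 1)
  r_ba <- de_mirna(m, cond, "B", "A")
  expect_equal(r_ab$log2_fc, -r_ba$log2_fc, tolerance = 1e-12)
})

test_that("k-means recovers planted archetypes deterministically", {
  set.seed(57)
  arch <- rbind(c(-1, 0, 1), c(1, 0, -1), c(1, 1, 1) * 0.0 + c(-1, 2, -1),
                c(2, -1, -1))
  truth <- rep(1:4, each = 50)
  mat <- arch[truth, ] * 3 + matrix(rnorm(600, 0, 0.3), 200, 3)
  rownames(mat) <- sprintf("f%03d", 1:200)
  km <- kmeans_patterns(mat, k = 4, seed = 99)
  # best label matching: majority label per planted archetype
  agree <- sum(vapply(1:4, function(tc) {
    max(table(km$assignment$cluster[truth == tc]))
  }, numeric(1))) / 200
  expect_gte(agree, 0.95)
  km2 <- kmeans_patterns(mat, k = 4, seed = 99)
  expect_identical(km$assignment, km2$assignment)
  # k = 1 degenerates to a single all-inclusive cluster
  km1 <- kmeans_patterns(mat, k = 1, seed = 1)
  expect_true(all(km1$assignment$cluster == 1))
  z <- t(scale(t(mat)))
  expect_equal(unname(km1$centers[1, ]), unname(colMeans(z)),
               tolerance = 1e-10)
  expect_error(kmeans_patterns(mat[1:3, ], k = 4), "exceeds")
})

test_that("read-length filtering keeps the inclusive 18-30 nt window", {
  ld <- length_distribution(c(17L, 18L, 30L, 31L))
  expect_equal(sum(ld$count), 2L)
  expect_equal(ld$count[ld$length %in% c(18L, 30L)], c(1L, 1L))
  expect_equal(attr(ld, "n_removed"), 2L)
  set.seed(61)
  ld2 <- length_distribution(sample(15:33, 5000, TRUE,
                                    prob = dnorm(15:33, 24, 2)))
  expect_equal(sum(ld2$proportion), 1)
  expect_identical(attr(ld2, "mode_nt"), 24L)
})
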