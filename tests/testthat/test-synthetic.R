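test_that("the methylome generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 3, conditions = c("A", "B"), n_reps = 2,
                    n_chroms = 2, chrom_length = 50000L,
                    n_sites = 6000L, dmr_n = 5L, dmr_width = 600L)
  m1 <- simulate_methylome(cfg)
  m2 <- simulate_methylome(cfg)
  expect_identical(m1$samples, m2$samples)
  expect_identical(m1$truth$spikes, m2$truth$spikes)
})

test_that("zero methylation and perfect conversion give zero counts", {
  cfg <- sim_config(seed = 1, conditions = "A", n_reps = 1,
                    n_sites = 1000L, mu = c(CG = 0, CHG = 0, CHH = 0),
                    conversion_failure = 0)
  m <- simulate_methylome(cfg)
  expect_true(all(m$samples[[1]]$count_meth == 0L))
})

test_that("weighted global levels recover the configured context means", {
  mu <- c(CG = 0.20, CHG = 0.125, CHH = 0.06)
  cfg <- sim_config(seed = 5, conditions = "A", n_reps = 1,
                    n_chroms = 2, chrom_length = 1000000L,
                    n_sites = 50000L, mu = mu, coverage_mean = 20,
                    conversion_failure = 0.005)
  m <- simulate_methylome(cfg)
  gl <- global_levels(m$samples[[1]])
  for (ctx in c("CG", "CHG", "CHH"))
    expect_lt(abs(gl$weighted[gl$context == ctx] - mu[[ctx]]), 0.01)
})

test_that("every spiked DMR covers at least 3 sites of its context", {
  cfg <- sim_config(seed = 9, conditions = c("A", "B"), n_reps = 1,
                    n_sites = 20000L, chrom_length = 150000L,
                    dmr_n = 40L, dmr_sites = 5L, dmr_width = 400L,
                    dmr_delta = 0.3, dmr_context = "CHH")
  m <- simulate_methylome(cfg)
  sp <- m$truth$spikes
  expect_identical(nrow(sp), 40L)
  expect_true(all(sp$n_sites >= 3L))
  expect_true(all(sp$start >= 1 & sp$end <= cfg$chrom_length))
  # spiked sites really are shifted in the affected condition only
  expect_true(all(sp$delta_B == 0.3) && all(sp$delta_A == 0))
})

test_that("configured deltas outside [0,1] are rejected at validation", {
  expect_error(sim_config(dmr_n = 5, dmr_delta = 0.9,
                          mu = c(CG = 0.2, CHG = 0.1, CHH = 0.05),
                          dmr_context = "CG"),
               "outside")
  expect_error(sim_config(conversion_failure = 1), "conversion_failure")
})

test_that("expression fold changes match the configured truth", {
  cfg <- big_gene_config(13, 400, conditions = c("A", "B"), n_reps = 3,
                         de_n = 200, de_fc = 8, de_condition = "B",
                         expr_mean_log_mu = log(200), expr_mean_log_sd = 0,
                         expr_dispersion = 0.1, size_factor_sd = 0)
  genes <- simulate_gene_models(cfg)
  sim <- simulate_expression(cfg, genes)
  expect_gte(nrow(genes), 300)
  counts <- sim$expr$counts
  cond <- as.character(sim$expr$conditions)
  mA <- rowMeans(counts[, cond == "A", drop = FALSE])
  mB <- rowMeans(counts[, cond == "B", drop = FALSE])
  de <- sim$truth$de
  up <- de$gene_id[de$direction == "up"]
  dn <- de$gene_id[de$direction == "down"]
  # ratio of condition means over many genes concentrates at the truth
  expect_lt(abs(median(mB[up] / mA[up]) - 8), 1.2)
  expect_lt(abs(median(mB[dn] / mA[dn]) - 1 / 8), 0.05)
  null_ids <- setdiff(rownames(counts), de$gene_id)
  expect_lt(abs(median(mB[null_ids] / mA[null_ids]) - 1), 0.2)
})

test_that("a unit fold-change spec produces an empty DE truth table", {
  cfg <- sim_config(seed = 2, conditions = c("A", "B"), de_n = 20,
                    de_fc = 1, n_genes = 30)
  genes <- simulate_gene_models(cfg)
  sim <- simulate_expression(cfg, genes)
  expect_identical(nrow(sim$truth$de), 0L)
})

test_that("miRNA pair coupling signs are recovered from the data", {
  cfg <- big_gene_config(21, 400, conditions = c("A", "B", "C"), n_reps = 3,
                         n_pairs = 500, pair_frac_diff = 0,
                         pair_frac_negative = 0.6,
                         pair_coupling = 1.2, pair_noise_sd = 0.3)
  genes <- simulate_gene_models(cfg)
  es <- simulate_expression(cfg, genes)
  mr <- simulate_mirna_pairs(cfg, es$expr)
  truth <- mr$truth$pairs
  # configured 60/40 split within binomial error of the configuration
  expect_lt(abs(mean(truth$sign == -1) - 0.6),
            3 * sqrt(0.6 * 0.4 / nrow(truth)))
  pc <- pair_correlations(log2(mr$mirna$counts + 1),
                          log2(es$expr$counts + 1), mr$pairs)
  agree <- mean(pc$class == truth$class, na.rm = TRUE)
  expect_gt(agree, 0.85)
})

test_that("strong negative coupling drives pair correlations toward -1", {
  cfg <- big_gene_config(22, 300, conditions = c("A", "B", "C"), n_reps = 3,
                         n_pairs = 60, pair_frac_diff = 0,
                         pair_frac_negative = 1,
                         pair_coupling = 2, pair_noise_sd = 0.01)
  genes <- simulate_gene_models(cfg)
  es <- simulate_expression(cfg, genes)
  mr <- simulate_mirna_pairs(cfg, es$expr)
  pc <- pair_correlations(log2(mr$mirna$counts + 1),
                          log2(es$expr$counts + 1), mr$pairs)
  expect_lt(median(pc$r, na.rm = TRUE), -0.8)
  expect_gt(mean(pc$class == "negative", na.rm = TRUE), 0.9)
})

test_that("simulated read lengths peak at the configured modal length", {
  cfg <- sim_config(seed = 4, read_length_mode = 24L, n_reads = 30000L)
  rl <- simulate_read_lengths(cfg)
  expect_true(any(rl < 18) && any(rl > 30))  # filter has work to do
  ld <- length_distribution(rl)
  expect_identical(attr(ld, "mode_nt"), 24L)
})

test_that("pairs referencing unknown targets are rejected", {
  cfg <- sim_config(seed = 2, conditions = c("A", "B"), n_genes = 30,
                    n_pairs = 10)
  genes <- simulate_gene_models(cfg)
  es <- simulate_expression(cfg, genes)
  mr <- simulate_mirna_pairs(cfg, es$expr)
  bad <- mr$pairs
  bad$target_id[1] <- "nonexistent_gene"
  expect_error(pair_correlations(log2(mr$mirna$counts + 1),
                                 log2(es$expr$counts + 1), bad),
               "unknown target")
})
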