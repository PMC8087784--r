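test_that("Fisher exact p-values match enumeration and fisher.test", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10),
               fisher_enum_oracle(10, 0, 0, 10))
  set.seed(19)
  for (i in 1:300) {
    tot <- sample(4:30, 1)
    a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
    c <- sample(0:(tot - a - b), 1); d <- tot - a - b - c
    p_impl <- fisher_exact_2x2(a, b, c, d)
    expect_lt(abs(p_impl - fisher_enum_oracle(a, b, c, d)), 1e-10)
  }
  # independent cross-check against the stock scalar implementation
  for (i in 1:50) {
    m <- matrix(rpois(4, 8), 2)
    expect_equal(fisher_exact_2x2(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 stats::fisher.test(m)$p.value, tolerance = 1e-8)
  }
  # degenerate margins: p = 1 by convention
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1)
  expect_equal(fisher_exact_2x2(0, 5, 0, 5), 1)
})

test_that("site tests pool replicates and flag differential sites", {
  # pooling check: replicates 3/7 and 2/8 pool to 5/15
  a1 <- make_sites(c(100, 200), c(3, 0), c(7, 20))
  a2 <- make_sites(c(100, 200), c(2, 0), c(8, 20))
  b1 <- make_sites(c(100, 200), c(3, 20), c(7, 0))
  b2 <- make_sites(c(100, 200), c(2, 20), c(8, 0))
  sd <- site_diff_tests(list(a1, a2), list(b1, b2))
  s100 <- sd[sd$pos == 100, ]
  expect_equal(s100$meth_a, 5L)
  expect_equal(s100$unmeth_a, 15L)
  # identical pooled counts: delta 0, p 1, not differential
  expect_equal(s100$delta, 0)
  expect_equal(s100$p_value, 1)
  expect_false(s100$differential)
  # 0/40 vs 40/40: delta 1, p from enumeration, differential
  s200 <- sd[sd$pos == 200, ]
  expect_equal(s200$delta, 1)
  expect_equal(s200$p_value, fisher_enum_oracle(0, 40, 40, 0))
  expect_true(s200$differential)
})

test_that("DMR construction honors gap, site-count and coverage rules", {
  mk <- function(pos, meth_frac_b, cov = 30L) {
    a <- lapply(1:2, function(r) make_sites(pos, 0L, cov))
    b <- lapply(1:2, function(r)
      make_sites(pos, as.integer(round(cov * meth_frac_b)),
                 cov - as.integer(round(cov * meth_frac_b))))
    site_diff_tests(a, b)
  }
  # 5 differential sites within 150 bp: exactly one DMR spanning them
  sd5 <- mk(c(100, 130, 160, 200, 250), 0.8)
  d <- call_dmrs(sd5)
  expect_identical(nrow(d), 1L)
  expect_equal(d$start, 100L)
  expect_equal(d$end, 250L)
  expect_equal(d$n_diff_sites, 5L)
  expect_equal(d$direction, "hyper")
  # only 2 differential sites: below min_sites, no DMR
  expect_identical(nrow(call_dmrs(mk(c(100, 150), 0.8))), 0L)
  # a gap above max_gap splits the run
  d2 <- call_dmrs(mk(c(100, 150, 200, 900, 950, 1000), 0.8))
  expect_identical(nrow(d2), 2L)
  # mean member coverage below threshold is rejected
  expect_identical(nrow(call_dmrs(mk(c(100, 150, 200), 0.9, cov = 4L))), 0L)
  # empty input gives an empty result
  expect_identical(nrow(call_dmrs(mk(c(100, 200), 0))), 0L)
})

test_that("swapping condition labels swaps hyper and hypo exactly", {
  set.seed(23)
  pos <- sort(sample.int(5000, 60))
  cm_a <- rbinom(60, 30, 0.2)
  cm_b <- rbinom(60, 30, ifelse(seq_along(pos) %% 2, 0.2, 0.7))
  a <- list(make_sites(pos, cm_a, 30L - cm_a))
  b <- list(make_sites(pos, cm_b, 30L - cm_b))
  d_ab <- call_dmrs(site_diff_tests(a, b))
  d_ba <- call_dmrs(site_diff_tests(b, a))
  expect_equal(nrow(d_ab), nrow(d_ba))
  if (nrow(d_ab)) {
    expect_equal(d_ab$mean_delta, -d_ba$mean_delta)
    expect_equal(d_ab$direction,
                 ifelse(d_ba$direction == "hyper", "hypo", "hyper"))
    expect_true(all(d_ab$mean_delta[d_ab$direction == "hyper"] > 0))
  }
})

test_that("DMR annotation follows the promoter-first priority rules", {
  g <- gene_models(c("gA", "gB"), "Chr01", "+", c(10001L, 30001L),
                   c(14000L, 34000L), first_exon_end = c(10500L, 30500L))
  dm <- function(start, end)
    structure(data.frame(chrom = "Chr01", start = start, end = end,
                         context = "CG", n_diff_sites = 3L,
                         mean_cov_a = 20, mean_cov_b = 20,
                         p_value = 0.01, mean_delta = 0.3,
                         direction = "hyper", stringsAsFactors = FALSE),
              class = c("dmr_set", "data.frame"))
  # fully inside the promoter
  a1 <- annotate_dmrs(dm(9000L, 9500L), g)
  expect_equal(a1$annotation, "promoter")
  expect_equal(a1$gene_id, "gA")
  # straddling the promoter / first-exon boundary: promoter wins
  a2 <- annotate_dmrs(dm(9900L, 10200L), g)
  expect_equal(a2$annotation, "promoter")
  # inside the body but past the first exon
  a3 <- annotate_dmrs(dm(12000L, 12400L), g)
  expect_equal(a3$annotation, "gene_body")
  expect_equal(a3$gene_id, "gA")
  # first exon beats gene body
  a4 <- annotate_dmrs(dm(10400L, 10450L), g)
  expect_equal(a4$annotation, "first_exon")
  # no gene within 2 kb: intergenic with no gene
  a5 <- annotate_dmrs(dm(20000L, 20100L), g)
  expect_equal(a5$annotation, "intergenic")
  expect_true(is.na(a5$gene_id))
})

test_that("overlapping gene assignment prefers the larger overlap", {
  # gB's promoter (18001..20000) overlaps gA's body (10001..19000)
  g <- gene_models(c("gA", "gB"), "Chr01", "+", c(10001L, 20001L),
                   c(19000L, 24000L))
  a <- annotate_dmrs(structure(
    data.frame(chrom = "Chr01", start = 18200L, end = 18700L,
               context = "CG", n_diff_sites = 3L, mean_cov_a = 20,
               mean_cov_b = 20, p_value = 0.01, mean_delta = 0.3,
               direction = "hyper", stringsAsFactors = FALSE),
    class = c("dmr_set", "data.frame")), g)
  expect_equal(a$annotation, "promoter")  # promoter outranks body
  expect_equal(a$gene_id, "gB")
})

test_that("set-overlap cardinalities obey inclusion-exclusion", {
  ov <- dmr_gene_set_overlaps(list(s1 = c("a", "b"), s2 = c("b", "c"),
                                   s3 = "b"))
  expect_equal(ov$n_intersection[ov$combination == "s1&s2&s3"], 1L)
  expect_equal(ov$n_exclusive[ov$combination == "s1&s2&s3"], 1L)
  ov2 <- dmr_gene_set_overlaps(list(x = "a", y = "b"))
  expect_true(all(ov2$n_exclusive[grepl("&", ov2$combination)] == 0))
  set.seed(31)
  sets <- lapply(1:3, function(i) sample(letters, sample(5:20, 1)))
  names(sets) <- c("A", "B", "C")
  ov3 <- venn_overlap(sets)
  expect_equal(sum(ov3$n_exclusive), length(unique(unlist(sets))))
})

test_that("gene-body-only selection matches hand enumeration", {
  g <- gene_models(paste0("g", 1:3), "Chr01", "+",
                   c(10001L, 30001L, 50001L), c(14000L, 34000L, 54000L))
  # g1: body mC in both conditions -> selected
  # g2: body mC plus one promoter mC in condition B -> excluded
  # g3: body mC in condition A only -> excluded
  calls_a <- make_calls(c(11000, 31000, 51000), TRUE)
  calls_b <- make_calls(c(11500, 31500, 29500, 51500),
                        c(TRUE, TRUE, TRUE, FALSE))
  sel <- select_gene_body_only_genes(list(A = calls_a, B = calls_b), g)
  expect_identical(sel, "g1")
})
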