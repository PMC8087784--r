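# promoter-CHH archetype trajectories: four expression patterns across
# the stage order (flat-high, down, up, strongly up), the down/up ones
# coupled to a decreasing promoter CHH methylation trajectory
chh_archetypes <- function(config) {
  n <- length(config$conditions)
  t <- seq(0, 1, length.out = n)
  fc <- config$chh_expr_fc
  d <- config$chh_delta
  list(
    list(label = "flat_high", expr = rep(2, n), chh = rep(d, n)),
    list(label = "down",      expr = fc ^ (1 - t), chh = d * (1 - t)),
    list(label = "up",        expr = fc ^ t, chh = d * (1 - t)),
    list(label = "up_strong", expr = (1.5 * fc) ^ t, chh = 0.8 * d * (1 - t)))
}

#' Simulate a complete multi-omic study with ground truth
#'
#' Wires the three generators together under one configuration and one
#' seed: gene models; a methylome with background spiked DMRs, per-gene
#' body-CG elevation, and promoter CHH spikes following four
#' stage-trajectory archetypes; an expression matrix whose means are
#' coupled to body-CG levels and to the promoter-CHH archetypes; and
#' miRNA/target pairs coupled to target expression.
#'
#' @param config a [sim_config()], e.g. [study_preset()].
#' @return list of class `sim_study`: `config`, `genes`, `meth`,
#'   `expr`, `mirna`, `chh_genes` (archetype assignment table).
#' @export
simulate_study <- function(config) {
  genes <- simulate_gene_models(config)

  chh_tab <- NULL
  extra <- NULL
  cond_mult <- NULL
  if (config$n_chh_genes > 0L) {
    set.seed(derive_seed(config$seed, "spikes"))
    ok <- !is.na(genes$promoter_start)
    pick <- sample(which(ok), min(config$n_chh_genes, sum(ok)))
    arch <- chh_archetypes(config)
    ai <- rep(seq_along(arch), length.out = length(pick))
    chh_tab <- data.frame(gene_id = genes$gene_id[pick],
                          archetype = vapply(arch[ai], `[[`, "", "label"),
                          stringsAsFactors = FALSE)
    extra <- data.frame(chrom = genes$chrom[pick],
                        start = genes$promoter_start[pick],
                        end = genes$promoter_end[pick],
                        context = "CHH", stringsAsFactors = FALSE)
    cond_mult <- matrix(1, nrow(genes), length(config$conditions),
                        dimnames = list(genes$gene_id, config$conditions))
    for (j in seq_along(pick)) {
      a <- arch[[ai[j]]]
      for (ci in seq_along(config$conditions)) {
        extra[j, paste0("delta_", config$conditions[ci])] <- a$chh[ci]
        cond_mult[pick[j], ci] <- a$expr[ci]
      }
    }
    extra$gene_id <- genes$gene_id[pick]
  }

  meth <- simulate_methylome(config, genes = genes, extra_spikes = extra)
  expr_sim <- simulate_expression(config, genes,
                                  body_levels = meth$truth$body_levels,
                                  cond_multipliers = cond_mult,
                                  de_exclude = chh_tab$gene_id)
  mirna_sim <- NULL
  if (config$n_pairs > 0L)
    mirna_sim <- simulate_mirna_pairs(config, expr_sim$expr,
                                      de_genes = expr_sim$truth$de$gene_id)
  out <- list(config = config, genes = genes, meth = meth,
              expr = expr_sim, mirna = mirna_sim, chh_genes = chh_tab)
  class(out) <- "sim_study"
  out
}

genes_with_promoter_chh_dmr <- function(dmrs, genes) {
  chh <- dmrs[dmrs$context == "CHH", , drop = FALSE]
  if (!nrow(chh)) return(character())
  prom <- genes[!is.na(genes$promoter_start), , drop = FALSE]
  pg <- regions_gr(prom$chrom, prom$promoter_start, prom$promoter_end)
  dg <- regions_gr(chh$chrom, chh$start, chh$end)
  hits <- GenomicRanges::findOverlaps(dg, pg, ignore.strand = TRUE)
  unique(prom$gene_id[pg$idx[S4Vectors::subjectHits(hits)]])
}

#' Run the full analysis pipeline on a simulated (or assembled) study
#'
#' Executes every analysis layer in order: per-condition replicate
#' pooling, binomial site calling, global/windowed/metagene methylation
#' statistics, expression-quartile profiles, pairwise per-site Fisher
#' tests and DMR calling with gene annotation and set overlaps,
#' pairwise DEG and DE-miRNA tests with Venn overlaps and k-means
#' patterning, miRNA/target correlations with the differential-vs-other
#' contrast, and the three methylation-expression integration analyses.
#' Deterministic given the study's seed.
#'
#' @param sim a `sim_study` from [simulate_study()].
#' @param deg_fc,deg_fdr DEG thresholds (defaults 4 and 0.01).
#' @param mirna_l2fc,mirna_fdr DE-miRNA thresholds (defaults 2, 0.01).
#' @param dmr_args list of overrides for [call_dmrs()].
#' @return a nested list of class `study_results`; see the vignette for
#'   a tour of its components.
#' @export
run_study <- function(sim, deg_fc = 4, deg_fdr = 0.01, mirna_l2fc = 2,
                      mirna_fdr = 0.01, dmr_args = list()) {
  cfg <- sim$config
  conds <- cfg$conditions
  conv <- 1 - cfg$conversion_failure
  chrom_lengths <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                   sprintf("Chr%02d", seq_len(cfg$n_chroms)))
  reps_of <- function(cd) sim$meth$samples[grep(paste0("^", cd, "_"),
                                                names(sim$meth$samples))]
  pooled <- lapply(stats::setNames(conds, conds),
                   function(cd) pool_replicates(reps_of(cd)))
  calls <- lapply(pooled, call_sites, conversion_rate = conv)

  globals <- lapply(pooled, global_levels)
  props <- lapply(calls, mc_proportions)
  density <- lapply(pooled, window_density, chrom_lengths = chrom_lengths)
  metagene <- lapply(pooled, metagene_profile, genes = sim$genes)

  fpkm_mat <- fpkm(sim$expr$expr)
  cond_of <- as.character(sim$expr$expr$conditions)
  mean_fpkm <- vapply(conds, function(cd)
    rowMeans(fpkm_mat[, cond_of == cd, drop = FALSE]),
    numeric(nrow(fpkm_mat)))
  last <- conds[length(conds)]
  quartiles <- quartile_profiles(pooled[[last]], sim$genes,
                                 mean_fpkm[, last])

  cmb <- utils::combn(conds, 2)
  cmp_names <- paste0(cmb[1, ], "vs", cmb[2, ])
  comparisons <- list()
  for (i in seq_len(ncol(cmb))) {
    a <- cmb[1, i]; b <- cmb[2, i]
    sd <- site_diff_tests(reps_of(a), reps_of(b))
    dmrs <- do.call(call_dmrs, c(list(sd), dmr_args))
    dmrs <- annotate_dmrs(dmrs, sim$genes)
    deg <- deg_test(sim$expr$expr, cond_a = a, cond_b = b,
                    min_fc = deg_fc, max_fdr = deg_fdr)
    dem <- if (!is.null(sim$mirna))
      de_mirna(sim$mirna$mirna, cond_a = a, cond_b = b,
               min_l2fc = mirna_l2fc, max_fdr = mirna_fdr)
    comparisons[[cmp_names[i]]] <-
      list(a = a, b = b, site_diffs = sd, dmrs = dmrs, deg = deg,
           de_mirna = dem)
  }

  dmr_gene_sets <- lapply(stats::setNames(METH_CONTEXTS, METH_CONTEXTS),
                          function(ctx) {
    lapply(comparisons, function(cp) {
      d <- cp$dmrs
      unique(d$gene_id[d$context == ctx & !is.na(d$gene_id)])
    })
  })
  dmr_overlaps <- lapply(dmr_gene_sets, dmr_gene_set_overlaps)
  deg_sets <- lapply(comparisons, function(cp)
    cp$deg$feature_id[cp$deg$status != "ns"])
  deg_overlaps <- venn_overlap(deg_sets)
  all_degs <- unique(unlist(deg_sets))
  deg_clusters <- if (length(all_degs) >= 4)
    kmeans_patterns(mean_fpkm[all_degs, , drop = FALSE], k = 4,
                    seed = cfg$seed)

  mirna_block <- NULL
  if (!is.null(sim$mirna)) {
    de_mirna_union <- unique(unlist(lapply(comparisons, function(cp)
      cp$de_mirna$feature_id[cp$de_mirna$status != "ns"])))
    mirna_log <- log2(tpm(sim$mirna$mirna) + 1)
    target_log <- log2(fpkm_mat + 1)
    pc <- pair_correlations(mirna_log, target_log, sim$mirna$pairs,
                            de_mirnas = de_mirna_union)
    mirna_block <- list(de_mirna_union = de_mirna_union,
                        pair_corr = pc,
                        group_contrast = compare_pair_groups(pc),
                        length_dist =
                          length_distribution(sim$mirna$read_lengths))
  }

  prom_chh <- condition_region_levels(pooled, sim$genes, "promoter", "CHH")
  body_cg <- condition_region_levels(pooled, sim$genes, "body", "CG")
  body_only <- select_gene_body_only_genes(calls, sim$genes)
  gb_ids <- if (length(body_only) >= 5) body_only else NULL
  if (is.null(gb_ids))
    ml_log("run_study: fewer than 5 gene-body-only genes; ",
           "body-methylation/expression trend computed over all genes")
  gene_body <- gene_body_meth_expression(pooled, sim$genes, mean_fpkm,
                                         gene_ids = gb_ids)
  all_dmrs <- do.call(rbind, lapply(comparisons, function(cp)
    cp$dmrs[, setdiff(names(cp$dmrs), c("annotation", "gene_id"))]))
  chh_dmr_genes <- genes_with_promoter_chh_dmr(all_dmrs, sim$genes)
  chh_clusters <- NULL
  if (length(chh_dmr_genes) >= 4)
    chh_clusters <- chh_promoter_dmr_clusters(all_dmrs, sim$genes,
                                              mean_fpkm, prom_chh, k = 4,
                                              seed = cfg$seed)
  dmr_corr <- if (length(chh_dmr_genes) >= 2)
    dmr_expression_correlation_compare(prom_chh, mean_fpkm, chh_dmr_genes)

  out <- list(pooled_sites = pooled, calls = calls, globals = globals,
              mc_proportions = props, density = density,
              metagene = metagene, quartiles = quartiles,
              mean_fpkm = mean_fpkm, comparisons = comparisons,
              dmr_gene_sets = dmr_gene_sets, dmr_overlaps = dmr_overlaps,
              deg_overlaps = deg_overlaps, deg_clusters = deg_clusters,
              mirna = mirna_block, promoter_chh = prom_chh,
              body_cg = body_cg, gene_body_only = body_only,
              gene_body = gene_body, chh_dmr_genes = chh_dmr_genes,
              chh_clusters = chh_clusters, dmr_corr = dmr_corr)
  class(out) <- "study_results"
  out
}

#' Write the main pipeline outputs as deterministic TSV/BED files
#'
#' Serializes the text artifacts of a [run_study()] result (global
#' levels, methylcytosine proportions, density tracks, metagene
#' profiles, DMR and DEG tables, pair correlations, integration
#' records) so two runs with the same seed can be compared
#' byte-for-byte.
#'
#' @param res `study_results`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_study_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wt <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }
  for (cd in names(res$globals)) {
    wt(res$globals[[cd]], paste0("global_levels_", cd, ".tsv"))
    wt(res$mc_proportions[[cd]], paste0("mc_proportions_", cd, ".tsv"))
    wt(as.data.frame(res$metagene[[cd]]), paste0("metagene_", cd, ".tsv"))
    path <- file.path(dir, paste0("density_", cd, ".bed"))
    write_bed_track(res$density[[cd]], path)
    files <- c(files, path)
  }
  for (nm in names(res$comparisons)) {
    cp <- res$comparisons[[nm]]
    wt(cp$dmrs, paste0("dmrs_", nm, ".tsv"))
    wt(cp$deg, paste0("deg_", nm, ".tsv"))
    if (!is.null(cp$de_mirna)) wt(cp$de_mirna, paste0("de_mirna_", nm,
                                                      ".tsv"))
  }
  for (ctx in names(res$dmr_overlaps))
    wt(res$dmr_overlaps[[ctx]], paste0("dmr_overlaps_", ctx, ".tsv"))
  wt(res$deg_overlaps, "deg_overlaps.tsv")
  if (!is.null(res$mirna)) {
    wt(as.data.frame(res$mirna$pair_corr), "pair_correlations.tsv")
    wt(res$mirna$length_dist, "length_distribution.tsv")
  }
  wt(res$gene_body$records, "gene_body_integration.tsv")
  if (!is.null(res$chh_clusters))
    wt(res$chh_clusters$records, "chh_dmr_clusters.tsv")
  invisible(files)
}
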