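#' Simulation configuration
#'
#' One validated object fixes every knob of the synthetic study:
#' genome geometry, per-condition per-context methylation means, the
#' beta heterogeneity of site levels, the coverage model, bisulfite
#' conversion failure, spiked DMRs, the expression model with
#' differential genes, and miRNA/target coupling. A single `seed`
#' determines the entire output; per-stage sub-seeds are derived from it
#' deterministically so partial re-runs stay reproducible.
#'
#' @param seed integer master seed.
#' @param conditions condition labels, in stage order.
#' @param n_reps biological replicates per condition.
#' @param n_chroms,chrom_length genome geometry (bp).
#' @param n_sites total cytosines simulated genome-wide.
#' @param context_weights site-placement weights for CG/CHG/CHH
#'   (CHH-plurality by default, as in plant genomes).
#' @param mu mean methylation level: either a named vector
#'   (CG, CHG, CHH), recycled over conditions, or a conditions x contexts
#'   matrix. Values in \[0, 1\].
#' @param beta_precision precision (a+b) of the Beta distribution of
#'   per-site true levels around the condition mean; larger = less
#'   site-to-site heterogeneity.
#' @param coverage_mean,coverage_dispersion negative-binomial coverage
#'   model per site per sample (dispersion = 1/size).
#' @param conversion_failure epsilon, the probability an unmethylated
#'   cytosine escapes conversion and reads as methylated; equals the
#'   null rate of the site-calling binomial test.
#' @param dmr_n,dmr_sites,dmr_width,dmr_delta,dmr_context,dmr_condition
#'   spiked DMR spec: number of spikes, sites per spike, maximum span
#'   (bp), level shift, context, and the condition carrying the shift
#'   (default: last condition). `dmr_delta` may be negative.
#' @param n_genes,gene_length_range,first_exon_frac gene model geometry.
#' @param body_cg_mu_boost per-gene mean increment of CG methylation in
#'   gene bodies (drawn per gene in \[0, 2x boost\]); produces the
#'   body-methylation peak and, with `body_coupling`, the
#'   body-CG/expression trend.
#' @param expr_mean_log_mu,expr_mean_log_sd,expr_dispersion log-normal
#'   baseline mean and NB dispersion of gene counts.
#' @param size_factor_sd log-normal sd of per-sample library size factors.
#' @param de_n,de_fc,de_condition differential expression spec: number
#'   of DE genes, fold change (applied up for half, down for half) in
#'   `de_condition`.
#' @param body_coupling strength of the monotone link from a gene's
#'   simulated body-CG level to its expected expression (log-scale slope
#'   per sd of body level; 0 disables).
#' @param n_pairs,pair_frac_diff,pair_frac_negative,pair_frac_negative_diff
#'   miRNA/target pair spec: pair count, fraction of pairs whose miRNA
#'   is built differentially expressed (tracking a DE target), and the
#'   negative-coupling fractions for ordinary and differential pairs.
#' @param pair_coupling,pair_noise_sd,pair_coupling_diff,pair_noise_sd_diff
#'   log2-scale coupling slopes and Gaussian noise sds for ordinary and
#'   differential pairs.
#' @param mirna_mean_log_mu,mirna_mean_log_sd miRNA baseline abundance
#'   (log2 scale).
#' @param n_chh_genes,chh_delta,chh_expr_fc promoter-CHH integration
#'   spec: number of genes receiving a promoter CHH spike with a
#'   per-stage trajectory, the maximum CHH increment, and the expression
#'   fold change of the coupled archetypes.
#' @param read_length_mode,n_reads small-RNA read-length model (modal
#'   length in nt and simulated read count).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       conditions = c("DC", "RC", "AC"),
                       n_reps = 3L,
                       n_chroms = 2L,
                       chrom_length = 200000L,
                       n_sites = 20000L,
                       context_weights = c(CG = 0.2, CHG = 0.2, CHH = 0.6),
                       mu = c(CG = 0.20, CHG = 0.125, CHH = 0.06),
                       beta_precision = 40,
                       coverage_mean = 20,
                       coverage_dispersion = 0.3,
                       conversion_failure = 0.005,
                       dmr_n = 0L, dmr_sites = 5L, dmr_width = 300L,
                       dmr_delta = 0.4, dmr_context = "CG",
                       dmr_condition = NULL,
                       n_genes = 200L,
                       gene_length_range = c(1200L, 4000L),
                       first_exon_frac = 0.15,
                       body_cg_mu_boost = 0,
                       expr_mean_log_mu = log(150),
                       expr_mean_log_sd = 1,
                       expr_dispersion = 0.1,
                       size_factor_sd = 0.1,
                       de_n = 0L, de_fc = 8, de_condition = NULL,
                       body_coupling = 0,
                       n_pairs = 0L,
                       pair_frac_diff = 0.3,
                       pair_frac_negative = 0.6,
                       pair_frac_negative_diff = 0.85,
                       pair_coupling = 0.6, pair_noise_sd = 0.5,
                       pair_coupling_diff = 1.0, pair_noise_sd_diff = 0.15,
                       mirna_mean_log_mu = log2(200),
                       mirna_mean_log_sd = 1,
                       n_chh_genes = 0L, chh_delta = 0.25, chh_expr_fc = 6,
                       read_length_mode = 24L, n_reads = 50000L) {
  conditions <- as.character(conditions)
  if (!length(conditions)) stop2("need at least one condition")
  if (n_reps < 1L) stop2("n_reps must be >= 1")
  cw <- context_weights[METH_CONTEXTS]
  if (any(is.na(cw)) || any(cw < 0) || sum(cw) <= 0)
    stop2("context_weights must be non-negative and named CG/CHG/CHH")
  cw <- cw / sum(cw)
  if (is.matrix(mu)) {
    if (!all(METH_CONTEXTS %in% colnames(mu)))
      stop2("mu matrix needs CG/CHG/CHH columns")
    if (nrow(mu) != length(conditions))
      stop2("mu matrix needs one row per condition")
    mu <- mu[, METH_CONTEXTS, drop = FALSE]
    rownames(mu) <- conditions
  } else {
    if (!all(METH_CONTEXTS %in% names(mu)))
      stop2("mu must be named CG/CHG/CHH")
    mu <- matrix(rep(mu[METH_CONTEXTS], each = length(conditions)),
                 nrow = length(conditions),
                 dimnames = list(conditions, METH_CONTEXTS))
  }
  if (any(mu < 0 | mu > 1)) stop2("mu values must lie in [0, 1]")
  if (conversion_failure < 0 || conversion_failure >= 1)
    stop2("conversion_failure must lie in [0, 1)")
  if (beta_precision <= 0) stop2("beta_precision must be > 0")
  if (coverage_dispersion <= 0 || expr_dispersion <= 0)
    stop2("dispersions must be > 0")
  dmr_condition <- dmr_condition %||% conditions[length(conditions)]
  de_condition <- de_condition %||% conditions[length(conditions)]
  if (!dmr_condition %in% conditions || !de_condition %in% conditions)
    stop2("dmr_condition/de_condition must be one of the conditions")
  if (dmr_n > 0L) {
    assert_contexts(dmr_context, "dmr_context")
    shifted <- mu[dmr_condition, dmr_context] + dmr_delta
    if (any(shifted < 0 | shifted > 1))
      stop2("dmr_delta pushes the methylation level outside [0, 1]")
    if (dmr_sites < 3L) stop2("dmr_sites must be >= 3")
  }
  if (n_chh_genes > 0L) {
    lift <- max(mu[, "CHH"]) + chh_delta
    if (lift > 1 || chh_delta < 0)
      stop2("chh_delta must be >= 0 and keep levels <= 1")
  }
  cfg <- list(seed = as.integer(seed), conditions = conditions,
              n_reps = as.integer(n_reps), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_sites = as.integer(n_sites), context_weights = cw, mu = mu,
              beta_precision = beta_precision, coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              conversion_failure = conversion_failure,
              dmr_n = as.integer(dmr_n), dmr_sites = as.integer(dmr_sites),
              dmr_width = as.integer(dmr_width), dmr_delta = dmr_delta,
              dmr_context = dmr_context, dmr_condition = dmr_condition,
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              first_exon_frac = first_exon_frac,
              body_cg_mu_boost = body_cg_mu_boost,
              expr_mean_log_mu = expr_mean_log_mu,
              expr_mean_log_sd = expr_mean_log_sd,
              expr_dispersion = expr_dispersion,
              size_factor_sd = size_factor_sd,
              de_n = as.integer(de_n), de_fc = de_fc,
              de_condition = de_condition, body_coupling = body_coupling,
              n_pairs = as.integer(n_pairs), pair_frac_diff = pair_frac_diff,
              pair_frac_negative = pair_frac_negative,
              pair_frac_negative_diff = pair_frac_negative_diff,
              pair_coupling = pair_coupling, pair_noise_sd = pair_noise_sd,
              pair_coupling_diff = pair_coupling_diff,
              pair_noise_sd_diff = pair_noise_sd_diff,
              mirna_mean_log_mu = mirna_mean_log_mu,
              mirna_mean_log_sd = mirna_mean_log_sd,
              n_chh_genes = as.integer(n_chh_genes), chh_delta = chh_delta,
              chh_expr_fc = chh_expr_fc,
              read_length_mode = as.integer(read_length_mode),
              n_reads = as.integer(n_reads))
  class(cfg) <- "sim_config"
  cfg
}

#' Study-like simulation preset
#'
#' Fixes the generator at the study conditions this package emulates:
#' three seasonal cambium stages (dormant, reactivating, active) with
#' three biological replicates each; mean methylation levels per context
#' near the reported genome-wide ranges (CG about 20 percent, CHG about
#' 12.5 percent, CHH about 6 percent, with CG/CHG slightly higher and
#' CHH slightly lower in the active stage); CHH-plurality cytosine
#' composition; coverage around 20x with 99.5 percent bisulfite
#' conversion; spiked DMRs dominated by the CHH context; 40 DE genes at
#' 8-fold change; body-CG coupled expression; and a 60/40
#' negative/positive miRNA-target coupling split with differential pairs
#' built more strongly negative.
#'
#' @param seed master seed.
#' @param ... overrides passed to [sim_config()].
#' @return `sim_config`.
#' @export
study_preset <- function(seed = 1L, ...) {
  mu <- rbind(DC = c(CG = 0.197, CHG = 0.122, CHH = 0.063),
              RC = c(CG = 0.200, CHG = 0.124, CHH = 0.062),
              AC = c(CG = 0.208, CHG = 0.127, CHH = 0.058))
  defaults <- list(seed = seed, conditions = c("DC", "RC", "AC"),
                   n_reps = 3L, n_chroms = 2L, chrom_length = 1100000L,
                   n_sites = 60000L, mu = mu,
                   dmr_n = 30L, dmr_sites = 5L, dmr_width = 400L,
                   dmr_delta = 0.35, dmr_context = "CHH",
                   n_genes = 250L, body_cg_mu_boost = 0.15,
                   de_n = 40L, de_fc = 8, body_coupling = 0.6,
                   n_pairs = 150L, pair_frac_diff = 0.3,
                   pair_frac_negative = 0.5,
                   pair_frac_negative_diff = 0.85,
                   n_chh_genes = 48L, chh_delta = 0.25, chh_expr_fc = 6)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(sim_config, defaults)
}

sample_names <- function(config) {
  as.vector(t(outer(config$conditions, seq_len(config$n_reps), paste,
                    sep = "_")))
}

sample_conditions <- function(config) {
  rep(config$conditions, each = config$n_reps)
}
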