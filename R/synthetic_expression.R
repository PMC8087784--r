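#' Simulate an RNA-Seq count matrix with ground truth
#'
#' Gene counts are negative-binomial with a log-normal baseline mean,
#' per-sample library size factors, per-gene condition fold changes for
#' the configured differential genes (half up, half down in
#' `de_condition`), and an optional monotone coupling of expression to
#' the gene's simulated body-CG methylation level (log-scale slope
#' `body_coupling` per standard deviation of body level, per condition).
#'
#' @param config a [sim_config()].
#' @param genes `gene_models` (supplies feature ids and lengths).
#' @param body_levels optional genes x conditions matrix of true body-CG
#'   levels (from [simulate_methylome()] truth) enabling the coupling.
#' @param cond_multipliers optional genes x conditions matrix of extra
#'   mean multipliers (used by [simulate_study()] for promoter-CHH
#'   coupled archetypes).
#' @param de_exclude gene ids kept out of the DE sampling pool (e.g.
#'   genes already made differential through `cond_multipliers`).
#' @return list with `expr` (an [expr_set()]), and `truth` (DE table,
#'   size factors, per-gene per-condition expected means).
#' @export
simulate_expression <- function(config, genes, body_levels = NULL,
                                cond_multipliers = NULL,
                                de_exclude = character()) {
  set.seed(derive_seed(config$seed, "expression"))
  ng <- nrow(genes)
  conds <- config$conditions
  base <- stats::rlnorm(ng, config$expr_mean_log_mu, config$expr_mean_log_sd)
  fc <- matrix(1, ng, length(conds), dimnames = list(genes$gene_id, conds))

  de <- NULL
  if (config$de_n > 0L) {
    if (config$de_fc < 1) stop2("de_fc must be >= 1")
    pool <- which(!genes$gene_id %in% de_exclude)
    idx <- sample(pool, min(config$de_n, length(pool)))
    dir <- rep(c(1, -1), length.out = length(idx))
    fc[cbind(idx, match(config$de_condition, conds))] <- config$de_fc ^ dir
    de <- data.frame(gene_id = genes$gene_id[idx],
                     condition = config$de_condition,
                     fold_change = config$de_fc ^ dir,
                     direction = ifelse(dir > 0, "up", "down"),
                     stringsAsFactors = FALSE)
  }
  if (!is.null(de) && config$de_fc == 1) de <- de[0, ]

  if (!is.null(body_levels) && config$body_coupling != 0) {
    bl <- body_levels[genes$gene_id, conds, drop = FALSE]
    for (cd in conds) {
      z <- as.numeric(scale(bl[, cd]))
      z[is.na(z)] <- 0
      fc[, cd] <- fc[, cd] * exp(config$body_coupling * z)
    }
  }
  if (!is.null(cond_multipliers))
    fc <- fc * cond_multipliers[genes$gene_id, conds, drop = FALSE]

  sam <- sample_names(config)
  sf <- stats::rlnorm(length(sam), 0, config$size_factor_sd)
  names(sf) <- sam
  mu_mat <- base * fc  # genes x conditions expected means at sf = 1

  counts <- matrix(0, ng, length(sam), dimnames = list(genes$gene_id, sam))
  cond_of <- sample_conditions(config)
  for (j in seq_along(sam)) {
    mu <- mu_mat[, cond_of[j]] * sf[j]
    counts[, j] <- stats::rnbinom(ng, mu = mu,
                                  size = 1 / config$expr_dispersion)
  }
  expr <- expr_set(counts, lengths = genes$length, conditions = cond_of)
  ml_log("simulate_expression: ", ng, " genes x ", length(sam), " samples, ",
         if (is.null(de)) 0 else nrow(de), " DE genes")
  list(expr = expr,
       truth = list(de = de, size_factors = sf, expected_means = mu_mat))
}

#' Simulate miRNA abundances coupled to target genes
#'
#' Each pair links one simulated miRNA to one target gene. The miRNA's
#' log2 abundance tracks the standardized log2 expression of its target
#' with a configured sign and coupling slope plus Gaussian noise;
#' "differential" pairs target differentially expressed genes with a
#' stronger (and more often negative) coupling, so their miRNAs are
#' themselves differentially expressed - the regulatory signature the
#' integration layer is built to detect. Counts are Poisson draws around
#' the log-linear mean. Small-RNA read lengths are drawn with the
#' configured modal length (default 24 nt) over a range that extends
#' past the 18-30 nt filter so the length filter is exercised.
#'
#' @param config a [sim_config()].
#' @param expr target [expr_set()] (genes x samples).
#' @param de_genes optional character vector of truly differential gene
#'   ids used to host differential pairs.
#' @return list with `mirna` ([expr_set()]), `pairs` (mirna_id,
#'   target_id), `read_lengths` (integer vector) and `truth` (per-pair
#'   sign, coupling class, diff flag; modal read length).
#' @export
simulate_mirna_pairs <- function(config, expr, de_genes = NULL) {
  if (config$n_pairs < 1L) stop2("config$n_pairs must be >= 1")
  set.seed(derive_seed(config$seed, "mirna"))
  gene_ids <- rownames(expr$counts)
  if (!is.null(de_genes)) de_genes <- intersect(de_genes, gene_ids)
  np <- config$n_pairs
  n_diff <- if (length(de_genes)) round(np * config$pair_frac_diff) else 0L
  n_other <- np - n_diff
  other_pool <- setdiff(gene_ids, de_genes)
  targets <- c(if (n_diff) sample(de_genes, n_diff, replace =
                                    n_diff > length(de_genes)),
               sample(other_pool, n_other, replace =
                        n_other > length(other_pool)))
  is_diff <- rep(c(TRUE, FALSE), c(n_diff, n_other))
  sign <- ifelse(stats::runif(np) < ifelse(is_diff,
                                           config$pair_frac_negative_diff,
                                           config$pair_frac_negative),
                 -1, 1)
  coupling <- ifelse(is_diff, config$pair_coupling_diff, config$pair_coupling)
  noise_sd <- ifelse(is_diff, config$pair_noise_sd_diff, config$pair_noise_sd)

  tgt_log <- log2(expr$counts[targets, , drop = FALSE] + 1)
  z <- t(scale(t(tgt_log)))
  z[is.na(z)] <- 0
  base <- stats::rnorm(np, config$mirna_mean_log_mu, config$mirna_mean_log_sd)
  ns <- ncol(expr$counts)
  logmean <- base + sign * coupling * z +
    matrix(stats::rnorm(np * ns, 0, noise_sd), np, ns)
  counts <- matrix(stats::rpois(np * ns, lambda = 2 ^ logmean), np, ns)
  mirna_ids <- sprintf("mir%04d", seq_len(np))
  dimnames(counts) <- list(mirna_ids, colnames(expr$counts))

  pairs <- data.frame(mirna_id = mirna_ids, target_id = targets,
                      stringsAsFactors = FALSE)
  read_lengths <- simulate_read_lengths(config)
  ml_log("simulate_mirna_pairs: ", np, " pairs (", n_diff, " differential)")
  list(mirna = expr_set(counts, conditions = as.character(expr$conditions)),
       pairs = pairs,
       read_lengths = read_lengths,
       truth = list(pairs = cbind(pairs,
                                  sign = sign,
                                  class = ifelse(sign < 0, "negative",
                                                 "positive"),
                                  diff = is_diff),
                    mode_nt = config$read_length_mode))
}

#' Simulate small-RNA read lengths
#'
#' Unimodal integer length distribution over 15-33 nt peaking at the
#' configured modal length, deliberately spilling outside the 18-30 nt
#' window so that [length_distribution()]'s filter has work to do.
#'
#' @param config a [sim_config()].
#' @param n number of reads (default `config$n_reads`).
#' @return integer vector of read lengths (nt).
#' @export
simulate_read_lengths <- function(config, n = config$n_reads) {
  set.seed(derive_seed(config$seed, "lengths"))
  support <- 15:33
  w <- stats::dnorm(support, config$read_length_mode, 2.0)
  sample(support, n, replace = TRUE, prob = w)
}
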