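#' Pearson correlations of miRNA/target pairs
#'
#' Correlates each miRNA's expression with its predicted target's
#' across matched samples, classifies pairs by the sign of r and flags
#' pairs involving differentially expressed miRNAs (default mode) or
#' targets. Correlations default to replicate-level points (all
#' samples); `level = "condition_mean"` first averages per condition.
#'
#' @param mirna_mat,target_mat expression matrices (features x samples)
#'   with identical sample columns; log-scale or normalized values are
#'   the caller's choice.
#' @param pairs data.frame with `mirna_id`, `target_id`.
#' @param level "replicate" or "condition_mean".
#' @param conditions per-sample condition labels (needed for
#'   condition_mean).
#' @param de_mirnas,de_targets character vectors of differential
#'   feature ids.
#' @param diff_mode which member must be differential for the pair to
#'   be flagged: "mirna" (default), "target", "either", "both".
#' @return data.frame of class `pair_correlations`: `mirna_id`,
#'   `target_id`, `r`, `p_value`, `n`, `class` (negative/positive),
#'   `diff_flag`. Pairs with a zero-variance member get `NA` r and are
#'   excluded from the sign counts stored in the `n_negative` /
#'   `n_positive` attributes.
#' @export
pair_correlations <- function(mirna_mat, target_mat, pairs,
                              level = c("replicate", "condition_mean"),
                              conditions = NULL, de_mirnas = character(),
                              de_targets = character(),
                              diff_mode = c("mirna", "target", "either",
                                            "both")) {
  level <- match.arg(level)
  diff_mode <- match.arg(diff_mode)
  if (!identical(colnames(mirna_mat), colnames(target_mat)))
    stop2("miRNA and target matrices must share sample columns")
  missing_t <- setdiff(pairs$target_id, rownames(target_mat))
  if (length(missing_t))
    stop2("pair references unknown target: ", missing_t[1])
  missing_m <- setdiff(pairs$mirna_id, rownames(mirna_mat))
  if (length(missing_m))
    stop2("pair references unknown miRNA: ", missing_m[1])
  M <- mirna_mat
  Tm <- target_mat
  if (level == "condition_mean") {
    if (is.null(conditions)) stop2("condition_mean level needs conditions")
    agg <- function(m) {
      do.call(cbind, lapply(unique(conditions), function(cd)
        rowMeans(m[, conditions == cd, drop = FALSE])))
    }
    M <- agg(M)
    Tm <- agg(Tm)
  }
  if (ncol(M) < 3) stop2("need at least 3 points per correlation")
  x <- M[pairs$mirna_id, , drop = FALSE]
  y <- Tm[pairs$target_id, , drop = FALSE]
  n <- ncol(M)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    if (stats::sd(x[i, ]) == 0 || stats::sd(y[i, ]) == 0) return(NA_real_)
    stats::cor(x[i, ], y[i, ])
  }, numeric(1))
  # t-transform p-value for the Pearson correlation
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diff_flag <- switch(diff_mode,
                      mirna = pairs$mirna_id %in% de_mirnas,
                      target = pairs$target_id %in% de_targets,
                      either = pairs$mirna_id %in% de_mirnas |
                        pairs$target_id %in% de_targets,
                      both = pairs$mirna_id %in% de_mirnas &
                        pairs$target_id %in% de_targets)
  out <- data.frame(mirna_id = pairs$mirna_id, target_id = pairs$target_id,
                    r = r, p_value = p, n = n,
                    class = ifelse(is.na(r), NA_character_,
                                   ifelse(r < 0, "negative", "positive")),
                    diff_flag = diff_flag, stringsAsFactors = FALSE)
  excl <- sum(is.na(r))
  if (excl) ml_log("pair_correlations: ", excl,
                   " pair(s) with zero variance excluded from sign counts")
  attr(out, "n_negative") <- sum(out$class == "negative", na.rm = TRUE)
  attr(out, "n_positive") <- sum(out$class == "positive", na.rm = TRUE)
  class(out) <- c("pair_correlations", "data.frame")
  out
}

#' Contrast correlations of differential vs. other pairs
#'
#' Two-sample Student's t-test (pooled variance) on the Pearson r values
#' of pairs flagged differential against the remaining pairs - the
#' comparison behind "differentially expressed miRNA/target pairs show
#' stronger negative correlations".
#'
#' @param pairs `pair_correlations` output.
#' @return list: `t`, `df`, `p_value`, `mean_diff`, `mean_other`,
#'   `n_diff`, `n_other`.
#' @export
compare_pair_groups <- function(pairs) {
  ok <- !is.na(pairs$r)
  rd <- pairs$r[ok & pairs$diff_flag]
  ro <- pairs$r[ok & !pairs$diff_flag]
  if (length(rd) < 2 || length(ro) < 2)
    stop2("both pair groups need at least 2 correlations")
  tt <- stats::t.test(rd, ro, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(rd), mean_other = mean(ro),
       n_diff = length(rd), n_other = length(ro))
}

#' Per-gene per-condition weighted region methylation levels
#'
#' Weighted methylation level of one region type (gene body, promoter
#' or downstream) for one context, per gene and condition.
#'
#' @param sites_by_condition named list of cytosine site tables (one
#'   per condition; replicate-pooled counts are the intended input).
#' @param genes `gene_models`.
#' @param region "body", "promoter" or "downstream".
#' @param context methylation context.
#' @return genes x conditions matrix of levels (`NA` where no covered
#'   site).
#' @export
condition_region_levels <- function(sites_by_condition, genes,
                                    region = c("body", "promoter",
                                               "downstream"),
                                    context = "CG") {
  region <- match.arg(region)
  reg <- switch(region,
                body = data.frame(region_id = genes$gene_id,
                                  chrom = genes$chrom, start = genes$start,
                                  end = genes$end),
                promoter = data.frame(region_id = genes$gene_id,
                                      chrom = genes$chrom,
                                      start = genes$promoter_start,
                                      end = genes$promoter_end),
                downstream = data.frame(region_id = genes$gene_id,
                                        chrom = genes$chrom,
                                        start = genes$downstream_start,
                                        end = genes$downstream_end))
  reg <- reg[!is.na(reg$start) & !is.na(reg$end), , drop = FALSE]
  out <- matrix(NA_real_, nrow(genes), length(sites_by_condition),
                dimnames = list(genes$gene_id, names(sites_by_condition)))
  for (cd in names(sites_by_condition)) {
    lv <- region_levels(sites_by_condition[[cd]], reg, context)
    out[names(lv), cd] <- lv
  }
  out
}

#' Gene-body methylation versus expression
#'
#' For a selected gene set (typically the gene-body-only methylated
#' genes from [select_gene_body_only_genes()]), pairs each gene's
#' weighted body-CG level with its mean expression per condition and
#' summarizes the across-gene association with Spearman correlations
#' (per condition and pooled).
#'
#' @param sites_by_condition named list of per-condition pooled site
#'   tables.
#' @param genes `gene_models`.
#' @param expression genes x conditions matrix of mean expression
#'   (e.g. mean FPKM per condition).
#' @param gene_ids optional restriction (default: all genes with data).
#' @return list: `records` (gene_id, condition, body_cg_level,
#'   expression), `spearman` (per-condition rho and pooled rho),
#'   `n_excluded` genes without covered body sites.
#' @export
gene_body_meth_expression <- function(sites_by_condition, genes, expression,
                                      gene_ids = NULL) {
  bl <- condition_region_levels(sites_by_condition, genes, "body", "CG")
  ids <- gene_ids %||% rownames(bl)
  ids <- intersect(ids, rownames(expression))
  bl <- bl[ids, , drop = FALSE]
  ex <- expression[ids, colnames(bl), drop = FALSE]
  covered <- rowSums(is.na(bl)) == 0
  if (any(!covered))
    ml_log("gene_body_meth_expression: excluding ", sum(!covered),
           " gene(s) without covered body CG sites")
  bl <- bl[covered, , drop = FALSE]
  ex <- ex[covered, , drop = FALSE]
  if (!nrow(bl)) stop2("no genes with covered body sites")
  records <- do.call(rbind, lapply(colnames(bl), function(cd)
    data.frame(gene_id = rownames(bl), condition = cd,
               body_cg_level = bl[, cd], expression = ex[, cd],
               stringsAsFactors = FALSE)))
  rownames(records) <- NULL
  rho <- vapply(colnames(bl), function(cd)
    stats::cor(bl[, cd], ex[, cd], method = "spearman"), numeric(1))
  pooled <- stats::cor(as.vector(bl), as.vector(ex), method = "spearman")
  list(records = records,
       spearman = data.frame(condition = c(colnames(bl), "pooled"),
                             rho = c(rho, pooled), stringsAsFactors = FALSE),
       n_excluded = sum(!covered))
}

#' Expression clusters of genes with promoter CHH DMRs
#'
#' Restricts to genes whose promoter overlaps at least one CHH DMR,
#' clusters their standardized per-stage expression with the shared
#' k-means engine, and pairs each cluster's expression centroid with the
#' cluster's mean promoter-CHH level trajectory - the joint display
#' behind the promoter-hypomethylation/up-regulation motif.
#'
#' @param dmrs `dmr_set` (annotated or not), typically pooled over all
#'   pairwise comparisons.
#' @param genes `gene_models`.
#' @param expression genes x conditions matrix of mean expression.
#' @param promoter_levels genes x conditions matrix of promoter CHH
#'   levels (from [condition_region_levels()]).
#' @param k,seed clustering parameters.
#' @return list of class `chh_dmr_clusters`: `records` (gene, cluster,
#'   per-condition expression and CHH level), `expr_centers` (k x
#'   conditions standardized expression centroids), `chh_trajectories`
#'   (k x conditions mean promoter CHH levels),
#'   `centroid_correlations` (per-cluster Pearson r between the
#'   expression centroid and the CHH trajectory).
#' @export
chh_promoter_dmr_clusters <- function(dmrs, genes, expression,
                                      promoter_levels, k = 4L, seed = 1L) {
  chh <- dmrs[dmrs$context == "CHH", , drop = FALSE]
  prom <- data.frame(region_id = genes$gene_id, chrom = genes$chrom,
                     start = genes$promoter_start, end = genes$promoter_end)
  prom <- prom[!is.na(prom$start), , drop = FALSE]
  eligible <- character()
  if (nrow(chh)) {
    pg <- regions_gr(prom$chrom, prom$start, prom$end)
    dg <- regions_gr(chh$chrom, chh$start, chh$end)
    hits <- GenomicRanges::findOverlaps(dg, pg, ignore.strand = TRUE)
    eligible <- unique(prom$region_id[pg$idx[S4Vectors::subjectHits(hits)]])
  }
  eligible <- intersect(eligible, rownames(expression))
  if (length(eligible) < k)
    stop2("fewer than k genes carry a promoter CHH DMR")
  ex <- expression[eligible, , drop = FALSE]
  km <- kmeans_patterns(ex, k = k, seed = seed)
  cl <- stats::setNames(km$assignment$cluster, km$assignment$feature_id)
  used <- names(cl)
  pl <- promoter_levels[used, colnames(ex), drop = FALSE]
  chh_traj <- t(vapply(seq_len(k), function(ki)
    colMeans(pl[cl == ki, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(pl))))
  rownames(chh_traj) <- seq_len(k)
  cc <- vapply(seq_len(k), function(ki) {
    if (all(is.finite(chh_traj[ki, ])) && stats::sd(chh_traj[ki, ]) > 0)
      stats::cor(km$centers[ki, ], chh_traj[ki, ])
    else NA_real_
  }, numeric(1))
  records <- data.frame(gene_id = used, cluster = unname(cl),
                        stringsAsFactors = FALSE)
  for (cd in colnames(ex)) {
    records[[paste0("expr_", cd)]] <- ex[used, cd]
    records[[paste0("chh_", cd)]] <- pl[used, cd]
  }
  rownames(records) <- NULL
  out <- list(records = records, expr_centers = km$centers,
              chh_trajectories = chh_traj, centroid_correlations = cc,
              sizes = km$sizes)
  class(out) <- "chh_dmr_clusters"
  out
}

#' Compare methylation-expression coupling in DMR vs. non-DMR genes
#'
#' Per gene, the Pearson correlation across stages between promoter CHH
#' level and expression; the distributions of |r| for genes with and
#' without a promoter CHH DMR are compared by a two-sided Mann-Whitney
#' U test alongside the group medians.
#'
#' @param promoter_levels genes x conditions matrix of promoter CHH
#'   levels.
#' @param expression genes x conditions matrix of mean expression.
#' @param dmr_gene_ids genes carrying a promoter CHH DMR.
#' @return list: `records` (gene_id, r, abs_r, group), `median_dmr`,
#'   `median_other`, `u_p_value`.
#' @export
dmr_expression_correlation_compare <- function(promoter_levels, expression,
                                               dmr_gene_ids) {
  ids <- intersect(rownames(promoter_levels), rownames(expression))
  if (ncol(promoter_levels) < 3) stop2("need at least 3 stages")
  r <- vapply(ids, function(g) {
    x <- promoter_levels[g, ]
    y <- expression[g, colnames(promoter_levels)]
    if (any(is.na(x)) || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  grp <- ifelse(ids %in% dmr_gene_ids, "dmr", "other")
  ok <- !is.na(r)
  if (!any(grp[ok] == "dmr") || !any(grp[ok] == "other"))
    stop2("both gene groups must be non-empty")
  ad <- abs(r)[ok & grp == "dmr"]
  ao <- abs(r)[ok & grp == "other"]
  wt <- stats::wilcox.test(ad, ao, exact = FALSE)
  list(records = data.frame(gene_id = ids, r = unname(r),
                            abs_r = unname(abs(r)), group = grp,
                            stringsAsFactors = FALSE),
       median_dmr = stats::median(ad), median_other = stats::median(ao),
       u_p_value = wt$p.value)
}
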