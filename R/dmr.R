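#' Two-sided Fisher's exact test for 2x2 tables (vectorized)
#'
#' Exact conditional test on the table \[\[a, b\], \[c, d\]\] using the
#' minimum-likelihood rule: the two-sided p-value is the sum of all
#' hypergeometric probabilities, over tables with the observed margins,
#' not exceeding the probability of the observed table (with a 1 + 1e-7
#' relative tolerance, as in standard implementations). Degenerate
#' margins give p = 1 by convention. Implemented directly on the
#' hypergeometric mass so that genome-scale per-site scans are feasible.
#'
#' @param a,b,c,d non-negative integer cell counts (vectorized).
#' @return numeric vector of two-sided p-values.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop2("cell counts must be non-negative")
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  m1 <- a + b   # row 1 margin
  m2 <- c + d   # row 2 margin
  k <- a + c    # column 1 margin
  vapply(seq_len(n), function(i) {
    if (m1[i] == 0 || m2[i] == 0 || k[i] == 0 || k[i] == m1[i] + m2[i])
      return(1)
    lo <- max(0L, k[i] - m2[i])
    hi <- min(k[i], m1[i])
    probs <- stats::dhyper(lo:hi, m1[i], m2[i], k[i])
    pobs <- probs[a[i] - lo + 1L]
    min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Pool replicate cytosine tables by summing read counts
#'
#' Merges per-replicate evidence site-wise ("data from each sample were
#' merged"): counts are summed over replicates sharing a site key
#' (chrom, pos, strand, context). All replicates must share one site
#' universe.
#'
#' @param samples list of cytosine site tables.
#' @return a single `cx_sites` table with summed counts.
#' @export
pool_replicates <- function(samples) {
  stopifnot(length(samples) >= 1)
  acc <- as.data.frame(samples[[1]])[, c("chrom", "pos", "strand",
                                         "context", "count_meth",
                                         "count_unmeth")]
  key <- paste(acc$chrom, acc$pos, acc$strand, acc$context)
  cm <- acc$count_meth
  cu <- acc$count_unmeth
  for (s in samples[-1]) {
    s <- as.data.frame(s)
    idx <- match(paste(s$chrom, s$pos, s$strand, s$context), key)
    if (any(is.na(idx)))
      stop2("replicates do not share a common site universe")
    cm[idx] <- cm[idx] + s$count_meth
    cu[idx] <- cu[idx] + s$count_unmeth
  }
  acc$count_meth <- cm
  acc$count_unmeth <- cu
  as_cx_sites(acc)
}

#' Per-site differential methylation tests between two conditions
#'
#' Replicate read counts are pooled per condition (summed), then each
#' site shared by both conditions is tested with the two-sided Fisher
#' exact test on the pooled methylated/unmethylated x condition table.
#' A site is flagged differential when p < `p_threshold` AND the level
#' difference |delta| >= `min_delta` (delta = level_B - level_A; set
#' `min_delta = 0` for the literal p-only rule).
#'
#' @param samples_a,samples_b lists of cytosine site tables (replicates
#'   of condition A and B).
#' @param context optional context filter ("CG", "CHG" or "CHH").
#' @param p_threshold,min_delta differential-site thresholds.
#' @return data.frame of class `site_diffs`: site key columns, pooled
#'   counts per condition, `level_a`, `level_b`, `delta`, `p_value`,
#'   `differential`. Sites with zero pooled coverage in either condition
#'   are skipped (count logged).
#' @export
site_diff_tests <- function(samples_a, samples_b, context = NULL,
                            p_threshold = 0.05, min_delta = 0.1) {
  pa <- pool_replicates(samples_a)
  pb <- pool_replicates(samples_b)
  if (!is.null(context)) {
    assert_contexts(context, "context filter")
    pa <- pa[pa$context %in% context, , drop = FALSE]
    pb <- pb[pb$context %in% context, , drop = FALSE]
  }
  ka <- paste(pa$chrom, pa$pos, pa$strand, pa$context)
  kb <- paste(pb$chrom, pb$pos, pb$strand, pb$context)
  m <- match(ka, kb)
  shared <- !is.na(m)
  df <- pa[shared, , drop = FALSE]
  names(df)[names(df) == "count_meth"] <- "meth_a"
  names(df)[names(df) == "count_unmeth"] <- "unmeth_a"
  df$meth_b <- pb$count_meth[m[shared]]
  df$unmeth_b <- pb$count_unmeth[m[shared]]
  cov_a <- df$meth_a + df$unmeth_a
  cov_b <- df$meth_b + df$unmeth_b
  skipped <- sum(cov_a == 0 | cov_b == 0) + sum(!shared)
  if (skipped) ml_log("site_diff_tests: skipped ", skipped,
                      " sites absent or uncovered in one condition")
  keep <- cov_a > 0 & cov_b > 0
  df <- df[keep, , drop = FALSE]
  df$level_a <- df$meth_a / (df$meth_a + df$unmeth_a)
  df$level_b <- df$meth_b / (df$meth_b + df$unmeth_b)
  df$delta <- df$level_b - df$level_a
  df$p_value <- fisher_exact_2x2(df$meth_a, df$unmeth_a,
                                 df$meth_b, df$unmeth_b)
  df$differential <- df$p_value < p_threshold & abs(df$delta) >= min_delta
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("site_diffs", "data.frame")
  df
}

#' Call differentially methylated regions
#'
#' Candidate regions are maximal runs of same-context differential
#' sites (from [site_diff_tests()]) on one chromosome whose consecutive
#' positions are at most `max_gap` bp apart, trimmed to their
#' differential endpoints. A candidate is kept as a DMR when it has at
#' least `min_sites` differential sites, the mean coverage of its member
#' sites is at least `min_cov` in both conditions, and the two-sided
#' Fisher test on the region-pooled counts gives p < `alpha`. Direction
#' is `hyper` when the mean level difference (B minus A) is positive.
#'
#' @param site_diffs output of [site_diff_tests()].
#' @param max_gap maximum intra-region gap between differential sites.
#' @param min_sites minimum differential sites per DMR.
#' @param min_cov minimum mean member-site coverage per condition.
#' @param alpha region-level Fisher p threshold.
#' @return data.frame of class `dmr_set`: `chrom`, `start`, `end`,
#'   `context`, `n_diff_sites`, `mean_cov_a`, `mean_cov_b`, `p_value`,
#'   `mean_delta`, `direction`.
#' @export
call_dmrs <- function(site_diffs, max_gap = 200L, min_sites = 3L,
                      min_cov = 10, alpha = 0.05) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      n_diff_sites = integer(), mean_cov_a = numeric(),
                      mean_cov_b = numeric(), p_value = numeric(),
                      mean_delta = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  ds <- site_diffs[site_diffs$differential, , drop = FALSE]
  if (!nrow(ds)) {
    class(empty) <- c("dmr_set", "data.frame")
    return(empty)
  }
  out <- list()
  for (grp in split(ds, paste(ds$chrom, ds$context))) {
    grp <- grp[order(grp$pos), , drop = FALSE]
    run <- cumsum(c(1L, diff(grp$pos) > max_gap))
    for (r in split(grp, run)) {
      if (nrow(r) < min_sites) next
      mca <- mean(r$meth_a + r$unmeth_a)
      mcb <- mean(r$meth_b + r$unmeth_b)
      if (mca < min_cov || mcb < min_cov) next
      p <- fisher_exact_2x2(sum(r$meth_a), sum(r$unmeth_a),
                            sum(r$meth_b), sum(r$unmeth_b))
      if (p >= alpha) next
      md <- mean(r$delta)
      out[[length(out) + 1L]] <- data.frame(
        chrom = r$chrom[1], start = min(r$pos), end = max(r$pos),
        context = r$context[1], n_diff_sites = nrow(r),
        mean_cov_a = mca, mean_cov_b = mcb, p_value = p, mean_delta = md,
        direction = if (md > 0) "hyper" else "hypo",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    class(empty) <- c("dmr_set", "data.frame")
    return(empty)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  ml_log("call_dmrs: ", nrow(res), " DMRs")
  class(res) <- c("dmr_set", "data.frame")
  res
}

#' Annotate DMRs against gene models
#'
#' Each DMR is assigned to one genomic category with priority
#' promoter > first exon > gene body > intergenic: the highest-priority
#' region type it overlaps anywhere decides the category, and the gene
#' owning the matched region becomes the associated gene. When several
#' genes' regions of the winning type overlap the DMR, the larger
#' overlap wins; exact ties go to the gene with the nearer TSS.
#'
#' @param dmrs `dmr_set` from [call_dmrs()].
#' @param genes `gene_models`.
#' @return the input with `annotation` (promoter/first_exon/gene_body/
#'   intergenic) and `gene_id` (NA for intergenic) columns added.
#' @export
annotate_dmrs <- function(dmrs, genes) {
  dmrs$annotation <- "intergenic"
  dmrs$gene_id <- NA_character_
  if (!nrow(dmrs) || !nrow(genes)) return(dmrs)
  dgr <- regions_gr(dmrs$chrom, dmrs$start, dmrs$end)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  region_defs <- list(
    promoter = cbind(genes$promoter_start, genes$promoter_end),
    first_exon = cbind(genes$fe_start, genes$fe_end),
    gene_body = cbind(genes$start, genes$end))
  unassigned <- rep(TRUE, nrow(dmrs))
  for (type in names(region_defs)) {
    if (!any(unassigned)) break
    reg <- region_defs[[type]]
    ggr <- regions_gr(genes$chrom, reg[, 1], reg[, 2])
    hits <- GenomicRanges::findOverlaps(dgr, ggr, ignore.strand = TRUE)
    if (!length(hits)) next
    di <- dgr$idx[S4Vectors::queryHits(hits)]
    gi <- ggr$idx[S4Vectors::subjectHits(hits)]
    ok <- unassigned[di]
    di <- di[ok]; gi <- gi[ok]
    if (!length(di)) next
    ov <- pmin(dmrs$end[di], reg[gi, 2]) - pmax(dmrs$start[di], reg[gi, 1]) + 1
    mid <- (dmrs$start[di] + dmrs$end[di]) / 2
    tssd <- abs(mid - tss[gi])
    ord <- order(di, -ov, tssd, genes$gene_id[gi])
    first <- !duplicated(di[ord])
    sel_d <- di[ord][first]
    sel_g <- gi[ord][first]
    n_multi <- sum(table(di) > 1)
    if (n_multi) ml_log("annotate_dmrs: ", n_multi, " ", type,
                        " DMR(s) overlapped multiple genes; ",
                        "assigned by larger overlap / nearer TSS")
    dmrs$annotation[sel_d] <- type
    dmrs$gene_id[sel_d] <- genes$gene_id[sel_g]
    unassigned[sel_d] <- FALSE
  }
  dmrs
}

#' Intersection-region cardinalities of gene sets
#'
#' Computes, for every non-empty combination of the input sets, both the
#' size of the full intersection and the size of the exclusive region
#' (elements in exactly those sets) - the numbers a Venn diagram
#' displays. Exclusive region sizes sum to the union size.
#'
#' @param sets named list of character vectors (e.g. DMR-associated
#'   gene sets per pairwise comparison).
#' @return data.frame `combination`, `n_intersection`, `n_exclusive`.
#' @export
dmr_gene_set_overlaps <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- matrix(FALSE, length(universe), length(sets),
                   dimnames = list(NULL, names(sets)))
  for (j in seq_along(sets)) member[, j] <- universe %in% sets[[j]]
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  names(combos) <- names(sets)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    inset <- unlist(combos[i, ])
    inter <- if (length(universe))
      rowSums(member[, inset, drop = FALSE]) == sum(inset) else logical(0)
    excl <- inter & (if (any(!inset) && length(universe))
      rowSums(member[, !inset, drop = FALSE]) == 0 else TRUE)
    data.frame(combination = paste(names(sets)[inset], collapse = "&"),
               n_intersection = sum(inter), n_exclusive = sum(excl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Genes methylated only in the gene body
#'
#' Selects genes that, in every condition, carry at least one FDR-called
#' methylcytosine in the gene body and none in the promoter or
#' downstream 2 kb regions.
#'
#' @param calls_by_condition named list of `meth_calls` (one per
#'   condition; replicate-merged calls are the intended input).
#' @param genes `gene_models`.
#' @return character vector of gene ids.
#' @export
select_gene_body_only_genes <- function(calls_by_condition, genes) {
  count_mc <- function(calls, start, end) {
    m <- calls[calls$is_methylated, , drop = FALSE]
    reg <- regions_gr(genes$chrom, start, end)
    n <- integer(nrow(genes))
    if (!nrow(m)) return(n)
    hits <- GenomicRanges::findOverlaps(sites_gr(m), reg,
                                        ignore.strand = TRUE)
    tab <- tabulate(reg$idx[S4Vectors::subjectHits(hits)],
                    nbins = nrow(genes))
    tab
  }
  ok <- rep(TRUE, nrow(genes))
  for (calls in calls_by_condition) {
    body <- count_mc(calls, genes$start, genes$end)
    prom <- count_mc(calls, genes$promoter_start, genes$promoter_end)
    down <- count_mc(calls, genes$downstream_start, genes$downstream_end)
    ok <- ok & body >= 1L & prom == 0L & down == 0L
  }
  genes$gene_id[ok]
}
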