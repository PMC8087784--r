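#' Median-of-ratios size factors
#'
#' Per-sample normalization factor: the median, over genes expressed in
#' every sample, of the ratio of the gene's count in that sample to its
#' across-sample geometric mean (the DESeq normalization).
#'
#' @param counts count matrix or [expr_set()].
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "expr_set")) counts$counts else as.matrix(counts)
  loggeo <- rowMeans(log(m))
  use <- is.finite(loggeo)
  if (!any(use))
    stop2("no gene has non-zero counts in every sample; ",
          "cannot compute median-of-ratios size factors")
  sf <- apply(m[use, , drop = FALSE], 2,
              function(col) exp(stats::median(log(col) - loggeo[use])))
  if (any(!is.finite(sf) | sf <= 0)) stop2("degenerate size factor")
  sf
}

#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' count * 1e9 / (length * library size).
#'
#' @param counts count matrix or [expr_set()] (with lengths).
#' @param lengths feature lengths in bp (taken from the expr_set if
#'   omitted).
#' @return matrix of FPKM values.
#' @export
fpkm <- function(counts, lengths = NULL) {
  if (inherits(counts, "expr_set")) {
    lengths <- lengths %||% counts$lengths
    counts <- counts$counts
  }
  if (is.null(lengths)) stop2("FPKM needs feature lengths")
  if (any(lengths <= 0)) stop2("lengths must be > 0")
  lib <- colSums(counts)
  if (any(lib == 0)) stop2("zero library size")
  sweep(counts / lengths, 2, lib, "/") * 1e9
}

#' TPM normalization
#'
#' Transcripts per million; with unit lengths (the miRNA convention)
#' this is plain counts-per-million. Columns sum to 1e6 exactly.
#'
#' @param counts count matrix or [expr_set()].
#' @param lengths feature lengths (default 1 for every feature).
#' @return matrix of TPM values.
#' @export
tpm <- function(counts, lengths = NULL) {
  if (inherits(counts, "expr_set")) {
    lengths <- lengths %||% counts$lengths
    counts <- counts$counts
  }
  if (is.null(lengths)) lengths <- rep(1, nrow(counts))
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop2("zero library size")
  sweep(rate, 2, tot, "/") * 1e6
}

# conditioned NB exact test on rounded normalized condition sums
# (DESeq-style): given kA + kB, p = sum of P(a, kS - a) <= P(kA, kB),
# with the sum's NB dispersion alpha / n per condition.
nb_exact_p <- function(kA, kB, nA, nB, alpha) {
  kS <- kA + kB
  if (kS == 0) return(1)
  mu_hat <- kS / (nA + nB)
  muA <- nA * mu_hat
  muB <- nB * mu_hat
  szA <- nA / alpha
  szB <- nB / alpha
  # enumerate over the region carrying essentially all conditional mass
  lo <- max(0, min(stats::qnbinom(1e-14, mu = muA, size = szA),
                   kS - stats::qnbinom(1 - 1e-14, mu = muB, size = szB)))
  hi <- min(kS, max(stats::qnbinom(1 - 1e-14, mu = muA, size = szA),
                    kS - stats::qnbinom(1e-14, mu = muB, size = szB)))
  a <- lo:hi
  p <- stats::dnbinom(a, mu = muA, size = szA) *
    stats::dnbinom(kS - a, mu = muB, size = szB)
  pobs <- stats::dnbinom(kA, mu = muA, size = szA) *
    stats::dnbinom(kB, mu = muB, size = szB)
  tot <- sum(p)
  if (tot == 0) return(1)
  min(1, sum(p[p <= pobs * (1 + 1e-7)]) / tot)
}

#' Negative-binomial exact test for differential expression
#'
#' DESeq-style pipeline implemented from first principles: library
#' normalization by median-of-ratios (or supplied factors), per-gene
#' method-of-moments NB dispersion pooled across the two conditions
#' (floored at 1e-8), an exact conditional test on the rounded
#' normalized condition sums, Benjamini-Hochberg correction, and a
#' joint fold-change/FDR status call. Fold change is the ratio of
#' normalized condition means with a pseudo-count of 1; the
#' fold-change rule is inclusive (>=) unless `strict_fc`.
#'
#' @param counts count matrix or [expr_set()] restricted to two
#'   conditions, or a full set with `conditions` naming the pair to
#'   compare.
#' @param conditions factor/character per sample (taken from the
#'   expr_set if omitted).
#' @param cond_a,cond_b the two condition labels to compare (defaults:
#'   first two levels). Fold changes are B relative to A.
#' @param min_fc fold-change threshold (linear scale, default 4).
#' @param max_fdr FDR threshold (default 0.01).
#' @param strict_fc require strictly greater fold change.
#' @param fdr_inclusive use q <= max_fdr instead of q < max_fdr.
#' @param sf optional named size factors; default median-of-ratios on
#'   the two-condition submatrix.
#' @return data.frame of class `deg_results`: `feature_id`,
#'   `base_mean_a`, `base_mean_b`, `log2_fc`, `p_value`, `q_value`,
#'   `status` (up/down/ns), plus the dispersion used.
#' @export
deg_test <- function(counts, conditions = NULL, cond_a = NULL, cond_b = NULL,
                     min_fc = 4, max_fdr = 0.01, strict_fc = FALSE,
                     fdr_inclusive = FALSE, sf = NULL) {
  if (inherits(counts, "expr_set")) {
    conditions <- conditions %||% as.character(counts$conditions)
    counts <- counts$counts
  }
  if (is.null(conditions)) stop2("conditions are required")
  conditions <- as.character(conditions)
  lv <- unique(conditions)
  cond_a <- cond_a %||% lv[1]
  cond_b <- cond_b %||% lv[2]
  sel <- conditions %in% c(cond_a, cond_b)
  m <- counts[, sel, drop = FALSE]
  cond <- conditions[sel]
  nA <- sum(cond == cond_a)
  nB <- sum(cond == cond_b)
  if (nA < 1 || nB < 1) stop2("both conditions need at least one sample")
  sf <- sf %||% size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  A <- norm[, cond == cond_a, drop = FALSE]
  B <- norm[, cond == cond_b, drop = FALSE]
  mA <- rowMeans(A)
  mB <- rowMeans(B)
  base_mean <- rowMeans(norm)

  if (nA < 2 || nB < 2) {
    warning("a condition has < 2 replicates; using a common dispersion ",
            "estimate across all genes", call. = FALSE)
    v <- apply(norm, 1, stats::var)
    mu <- base_mean
    alpha_common <- stats::median(pmax((v - mu) / mu^2, 1e-8), na.rm = TRUE)
    disp <- rep(alpha_common, nrow(m))
  } else {
    vA <- apply(A, 1, stats::var)
    vB <- apply(B, 1, stats::var)
    pooled_var <- (vA * (nA - 1) + vB * (nB - 1)) / (nA + nB - 2)
    mu <- (mA + mB) / 2
    disp <- pmax((pooled_var - mu) / mu^2, 1e-8)
    disp[!is.finite(disp)] <- 1e-8
  }

  kA <- round(rowSums(A))
  kB <- round(rowSums(B))
  p <- vapply(seq_len(nrow(m)), function(i)
    nb_exact_p(kA[i], kB[i], nA, nB, disp[i]), numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  fc <- (mB + 1) / (mA + 1)
  l2fc <- log2(fc)
  fc_pass <- if (strict_fc) pmax(fc, 1 / fc) > min_fc
  else pmax(fc, 1 / fc) >= min_fc
  q_pass <- if (fdr_inclusive) q <= max_fdr else q < max_fdr
  status <- ifelse(fc_pass & q_pass, ifelse(l2fc > 0, "up", "down"), "ns")
  out <- data.frame(feature_id = rownames(m), base_mean_a = mA,
                    base_mean_b = mB, log2_fc = l2fc, p_value = p,
                    q_value = q, dispersion = disp, status = status,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "comparison") <- c(a = cond_a, b = cond_b)
  class(out) <- c("deg_results", "data.frame")
  out
}

#' Differential miRNA test
#'
#' Same NB exact-test engine as [deg_test()] with the small-RNA
#' thresholds (|log2 fold change| >= 2, FDR <= 0.01, both inclusive)
#' and library-size normalization in the TPM spirit (unit lengths),
#' since median-of-ratios geometric means are unstable on sparse miRNA
#' matrices.
#'
#' @inheritParams deg_test
#' @param min_l2fc absolute log2 fold-change threshold (default 2).
#' @return `deg_results` data.frame.
#' @export
de_mirna <- function(counts, conditions = NULL, cond_a = NULL, cond_b = NULL,
                     min_l2fc = 2, max_fdr = 0.01) {
  if (inherits(counts, "expr_set")) {
    conditions <- conditions %||% as.character(counts$conditions)
    counts <- counts$counts
  }
  conditions <- as.character(conditions)
  lv <- unique(conditions)
  cond_a <- cond_a %||% lv[1]
  cond_b <- cond_b %||% lv[2]
  sel <- conditions %in% c(cond_a, cond_b)
  lib <- colSums(counts[, sel, drop = FALSE])
  sf <- lib / exp(mean(log(lib)))
  deg_test(counts[, sel, drop = FALSE], conditions[sel], cond_a, cond_b,
           min_fc = 2 ^ min_l2fc, max_fdr = max_fdr, strict_fc = FALSE,
           fdr_inclusive = TRUE, sf = sf)
}

#' K-means clustering of standardized expression patterns
#'
#' Rows are z-score standardized (zero-variance rows are excluded with a
#' message), then clustered with `stats::kmeans` under a fixed seed with
#' multiple random restarts, keeping the restart with the lowest total
#' within-cluster sum of squares. Cluster labels are renumbered by
#' descending size so output is deterministic and comparable across
#' runs.
#'
#' @param mat features x samples (or features x conditions) numeric
#'   matrix, e.g. standardized FPKM input.
#' @param k number of clusters.
#' @param seed RNG seed for the restarts.
#' @param nstart random restarts (default 50).
#' @return list of class `pattern_clusters`: `assignment` (feature_id,
#'   cluster), `centers` (k x columns, on the standardized scale),
#'   `sizes`, `tot_withinss`, `excluded` (zero-variance feature ids).
#' @export
kmeans_patterns <- function(mat, k = 4L, seed = 1L, nstart = 50L) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- seq_len(nrow(mat))
  sds <- apply(mat, 1, stats::sd)
  excluded <- rownames(mat)[is.na(sds) | sds == 0]
  if (length(excluded))
    ml_log("kmeans_patterns: excluding ", length(excluded),
           " zero-variance feature(s)")
  z <- mat[!(rownames(mat) %in% excluded), , drop = FALSE]
  z <- t(scale(t(z)))
  if (k > nrow(z)) stop2("k exceeds the number of clusterable features")
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100L)
  ord <- order(-km$size, seq_len(k))
  relabel <- match(seq_len(k), ord)
  cl <- relabel[km$cluster]
  centers <- km$centers[ord, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  out <- list(assignment = data.frame(feature_id = rownames(z),
                                      cluster = cl,
                                      stringsAsFactors = FALSE),
              centers = centers, sizes = as.integer(km$size[ord]),
              tot_withinss = km$tot.withinss, excluded = excluded)
  class(out) <- "pattern_clusters"
  out
}

#' Small-RNA read-length distribution
#'
#' Applies the standard small-RNA length filter (reads shorter than
#' `min_len` or longer than `max_len` nt removed, bounds inclusive) and
#' tabulates the surviving lengths.
#'
#' @param read_lengths integer vector of read lengths (nt).
#' @param min_len,max_len inclusive bounds (defaults 18 and 30).
#' @return data.frame `length`, `count`, `proportion` over the full
#'   18-30 grid, with attributes `mode_nt` (modal length) and
#'   `n_removed`.
#' @export
length_distribution <- function(read_lengths, min_len = 18L, max_len = 30L) {
  keep <- read_lengths >= min_len & read_lengths <= max_len
  kept <- read_lengths[keep]
  grid <- min_len:max_len
  counts <- tabulate(factor(kept, levels = grid), nbins = length(grid))
  out <- data.frame(length = grid, count = counts,
                    proportion = if (sum(counts)) counts / sum(counts)
                    else rep(NA_real_, length(grid)))
  attr(out, "mode_nt") <- if (sum(counts)) grid[which.max(counts)]
  else NA_integer_
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Venn-region cardinalities of DEG sets
#'
#' Identical contract to [dmr_gene_set_overlaps()] (shared
#' implementation), applied to differential-gene id sets per pairwise
#' comparison.
#'
#' @param sets named list of character vectors.
#' @return data.frame `combination`, `n_intersection`, `n_exclusive`.
#' @export
venn_overlap <- function(sets) dmr_gene_set_overlaps(sets)
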