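# site -> metagene bin assignment with fractional-overlap weighting
#
# Each site (1 bp) is mapped to a position along the canonical gene axis:
# `n_flank_bins` fixed-width upstream bins covering 2 kb before the TSS,
# `n_body_bins` length-scaled body bins, and `n_flank_bins` downstream
# bins past the TES. Minus-strand genes are reflected. A body base pair
# whose fractional footprint straddles a bin boundary (genes shorter
# than n_body_bins bp, or any length not a bin multiple) is split across
# the straddled bins in proportion to overlap, so short genes are
# weighted, not dropped.
assign_metagene_bins <- function(sites, genes, n_flank_bins, n_body_bins,
                                 flank) {
  df <- as.data.frame(sites)
  df$coverage <- df$count_meth + df$count_unmeth
  df <- df[df$coverage > 0, , drop = FALSE]
  if (!nrow(df) || !nrow(genes))
    return(data.frame(bin = integer(), context = character(),
                      count_meth = numeric(), coverage = numeric(),
                      weight = numeric()))
  ext <- regions_gr(genes$chrom, genes$start - flank, genes$end + flank)
  hits <- GenomicRanges::findOverlaps(sites_gr(df), ext,
                                      ignore.strand = TRUE)
  si <- S4Vectors::queryHits(hits)
  gi <- ext$idx[S4Vectors::subjectHits(hits)]
  if (!length(si))
    return(data.frame(bin = integer(), context = character(),
                      count_meth = numeric(), coverage = numeric(),
                      weight = numeric()))
  pos <- df$pos[si]
  gs <- genes$start[gi]; ge <- genes$end[gi]
  plus <- genes$strand[gi] == "+"
  L <- ge - gs + 1
  nf <- n_flank_bins; nb <- n_body_bins
  w <- flank / nf

  up <- ifelse(plus, pos < gs, pos > ge)
  down <- ifelse(plus, pos > ge, pos < gs)
  body <- !up & !down
  d_up <- ifelse(plus, gs - pos, pos - ge)
  d_dn <- ifelse(plus, pos - ge, gs - pos)
  o <- ifelse(plus, pos - gs, ge - pos)

  bin <- integer(length(si))
  bin[up] <- nf - ceiling(d_up[up] / w) + 1L
  bin[down] <- nf + nb + ceiling(d_dn[down] / w)

  # body: fractional footprint [o, o+1) / L mapped to nb bins
  a <- o * nb / L
  b <- (o + 1) * nb / L
  lo <- floor(a)
  hi <- pmin(floor(b - 1e-9), nb - 1)
  single <- body & (lo == hi)
  bin[single] <- nf + lo[single] + 1L

  out <- data.frame(bin = bin, context = df$context[si],
                    count_meth = df$count_meth[si],
                    coverage = df$coverage[si],
                    weight = 1, stringsAsFactors = FALSE)[!body | single, ]

  straddle <- which(body & lo != hi)
  if (length(straddle)) {
    extra <- lapply(straddle, function(j) {
      bins <- lo[j]:hi[j]
      ww <- pmin(b[j], bins + 1) - pmax(a[j], bins)
      ww <- ww / sum(ww)
      data.frame(bin = nf + bins + 1L, context = df$context[si[j]],
                 count_meth = df$count_meth[si[j]],
                 coverage = df$coverage[si[j]], weight = ww,
                 stringsAsFactors = FALSE)
    })
    out <- rbind(out, do.call(rbind, extra))
  }
  out
}

#' Metagene methylation profile
#'
#' Average methylation along length-normalized gene bodies plus fixed
#' 2 kb flanks, per context, aggregated over all genes (strand-aware;
#' minus-strand genes are reflected so bin 1 is always the far upstream
#' end). Two estimators: `weighted` (the fraction method - pooled
#' methylated reads over pooled coverage per bin) and `site_mean` (mean
#' of per-site levels per bin). Levels are computed from raw counts, not
#' only FDR-called sites.
#'
#' @param sites cytosine site table.
#' @param genes `gene_models`.
#' @param n_flank_bins bins per 2 kb flank (default 20, i.e. 100 bp).
#' @param n_body_bins length-scaled body bins (default 40).
#' @param estimator "weighted" or "site_mean".
#' @param flank flank width in bp.
#' @return data.frame of class `metagene_profile`: `context`, `region`
#'   (upstream/body/downstream), `bin` (1-based along the full axis),
#'   `level`, `n_eff` (summed site weight). Bins with no sites are `NA`.
#' @export
metagene_profile <- function(sites, genes, n_flank_bins = 20L,
                             n_body_bins = 40L,
                             estimator = c("weighted", "site_mean"),
                             flank = 2000L) {
  estimator <- match.arg(estimator)
  asg <- assign_metagene_bins(sites, genes, n_flank_bins, n_body_bins, flank)
  total <- 2L * n_flank_bins + n_body_bins
  grid <- expand.grid(bin = seq_len(total), context = METH_CONTEXTS,
                      stringsAsFactors = FALSE)
  grid$region <- ifelse(grid$bin <= n_flank_bins, "upstream",
                        ifelse(grid$bin <= n_flank_bins + n_body_bins,
                               "body", "downstream"))
  grid$level <- NA_real_
  grid$n_eff <- 0
  if (nrow(asg)) {
    key <- paste(asg$context, asg$bin)
    num <- if (estimator == "weighted")
      tapply(asg$weight * asg$count_meth, key, sum)
    else
      tapply(asg$weight * asg$count_meth / asg$coverage, key, sum)
    den <- if (estimator == "weighted")
      tapply(asg$weight * asg$coverage, key, sum)
    else
      tapply(asg$weight, key, sum)
    wsum <- tapply(asg$weight, key, sum)
    gkey <- paste(grid$context, grid$bin)
    m <- match(gkey, names(num))
    grid$level <- as.numeric(num[m] / den[m])
    grid$n_eff <- ifelse(is.na(m), 0, as.numeric(wsum[m]))
  }
  out <- grid[, c("context", "region", "bin", "level", "n_eff")]
  attr(out, "estimator") <- estimator
  attr(out, "n_flank_bins") <- n_flank_bins
  attr(out, "n_body_bins") <- n_body_bins
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Metagene profiles by expression quartile
#'
#' Genes are ranked by expression (mean FPKM of one condition is the
#' intended input), split into four groups - quartile 1 holds the most
#' highly expressed genes - and a metagene profile is computed per
#' group. Ties and the rank order are broken by gene id so membership
#' is stable under permutation of the input.
#'
#' @param sites cytosine site table.
#' @param genes `gene_models`.
#' @param expression named numeric vector of per-gene expression.
#' @param ... passed to [metagene_profile()].
#' @return list with `profiles` (list Q1..Q4 of `metagene_profile`) and
#'   `membership` (gene_id, expression, quartile).
#' @export
quartile_profiles <- function(sites, genes, expression, ...) {
  expr <- expression[genes$gene_id]
  keep <- !is.na(expr)
  if (sum(keep) < 4L) stop2("need at least 4 genes with expression values")
  g <- genes[keep, , drop = FALSE]
  expr <- expr[keep]
  ord <- order(-expr, g$gene_id)
  n <- length(ord)
  sizes <- rep(n %/% 4L, 4L) + c(rep(1L, n %% 4L), rep(0L, 4L - n %% 4L))
  quart <- integer(n)
  quart[ord] <- rep(1:4, sizes)
  profiles <- lapply(1:4, function(q)
    metagene_profile(sites, g[quart == q, , drop = FALSE], ...))
  names(profiles) <- paste0("Q", 1:4)
  list(profiles = profiles,
       membership = data.frame(gene_id = g$gene_id, expression = unname(expr),
                               quartile = quart, stringsAsFactors = FALSE))
}
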