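#' Call methylated cytosines with a binomial test
#'
#' For every site passing the coverage filter (coverage depth above 4,
#' i.e. at least 5 reads), tests the observed methylated read count
#' against the bisulfite non-conversion null: under a fully unmethylated
#' cytosine, reads appear methylated at rate p0 = 1 - conversion_rate.
#' The one-sided (greater) binomial tail probability is corrected across
#' all tested sites by Benjamini-Hochberg; sites with q below `alpha`
#' are called methylated. One-sided because conversion failure can only
#' inflate the methylation signal.
#'
#' @param sites cytosine site table (`cx_sites` or compatible
#'   data.frame).
#' @param conversion_rate bisulfite conversion rate in (0, 1].
#' @param min_coverage minimum reads for a site to be tested (default 5,
#'   the strict reading of a "coverage depth > 4" filter).
#' @param alpha FDR level for the methylation call.
#' @return data.frame of class `meth_calls`: the tested sites plus
#'   `coverage`, `level`, `p_value`, `q_value`, `is_methylated`.
#'   Zero-coverage and low-coverage sites are excluded.
#' @export
call_sites <- function(sites, conversion_rate, min_coverage = 5L,
                       alpha = 0.05) {
  if (conversion_rate <= 0 || conversion_rate > 1)
    stop2("conversion_rate must lie in (0, 1]")
  df <- as.data.frame(sites)
  df$coverage <- df$count_meth + df$count_unmeth
  n_in <- nrow(df)
  df <- df[df$coverage >= min_coverage, , drop = FALSE]
  ml_log("call_sites: ", nrow(df), "/", n_in, " sites pass coverage >= ",
         min_coverage)
  p0 <- 1 - conversion_rate
  if (!nrow(df)) {
    df$level <- df$p_value <- df$q_value <- numeric(0)
    df$is_methylated <- logical(0)
    class(df) <- c("meth_calls", "data.frame")
    return(df)
  }
  if (p0 == 0) {
    if (any(df$count_meth > 0))
      warning("conversion_rate = 1 with methylated reads observed; ",
              "p-values set to 0 by convention", call. = FALSE)
    p <- ifelse(df$count_meth > 0, 0, 1)
  } else {
    # P(X >= count_meth | n = coverage, p0); count_meth = 0 gives p = 1
    p <- stats::pbinom(df$count_meth - 1L, df$coverage, p0,
                       lower.tail = FALSE)
  }
  df$level <- df$count_meth / df$coverage
  df$p_value <- p
  df$q_value <- stats::p.adjust(p, method = "BH")
  df$is_methylated <- df$q_value < alpha
  rownames(df) <- NULL
  class(df) <- c("meth_calls", "data.frame")
  df
}

#' Genome-wide methylation level per context, two estimators
#'
#' The weighted ("fraction") estimator is total methylated reads over
#' total coverage; the site-mean estimator averages per-site levels.
#' They diverge when coverage correlates with level, which is why both
#' are reported.
#'
#' @param sites cytosine site table or `meth_calls`.
#' @return data.frame with one row per context: `context`, `weighted`,
#'   `site_mean`, `n_sites`, `total_coverage`. Contexts with no covered
#'   site get `NA` levels.
#' @export
global_levels <- function(sites) {
  if (!nrow(as.data.frame(sites))) stop2("no sites supplied")
  df <- as.data.frame(sites)
  df$coverage <- df$count_meth + df$count_unmeth
  df <- df[df$coverage > 0, , drop = FALSE]
  out <- data.frame(context = METH_CONTEXTS, weighted = NA_real_,
                    site_mean = NA_real_, n_sites = 0L,
                    total_coverage = 0, stringsAsFactors = FALSE)
  for (i in seq_along(METH_CONTEXTS)) {
    s <- df[df$context == METH_CONTEXTS[i], , drop = FALSE]
    if (!nrow(s)) next
    out$weighted[i] <- sum(s$count_meth) / sum(s$coverage)
    out$site_mean[i] <- mean(s$count_meth / s$coverage)
    out$n_sites[i] <- nrow(s)
    out$total_coverage[i] <- sum(s$coverage)
  }
  out
}

#' Context proportions of methylated cytosines
#'
#' Fractions of FDR-called methylcytosines falling in each context
#' (the quantity behind "relative percentage of methylated cytosines").
#'
#' @param calls `meth_calls` from [call_sites()].
#' @return data.frame `context`, `n`, `proportion` (sums to 1); zero
#'   rows if no site is called methylated.
#' @export
mc_proportions <- function(calls) {
  m <- calls[calls$is_methylated, , drop = FALSE]
  if (!nrow(m))
    return(data.frame(context = character(), n = integer(),
                      proportion = numeric(), stringsAsFactors = FALSE))
  tab <- table(factor(m$context, levels = METH_CONTEXTS))
  data.frame(context = METH_CONTEXTS, n = as.integer(tab),
             proportion = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE)
}

#' Methylation density in fixed windows
#'
#' Tiles each chromosome with non-overlapping windows (default 100 kb)
#' and reports the weighted methylation level per window per context.
#' Windows with no covered site of a context are `NA`, not zero.
#'
#' @param sites cytosine site table.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param window window size in bp.
#' @return data.frame of class `density_track`: `chrom`, `start`, `end`
#'   (1-based inclusive), `context`, `level`, `n_sites`.
#' @export
window_density <- function(sites, chrom_lengths, window = 100000L) {
  df <- as.data.frame(sites)
  df$coverage <- df$count_meth + df$count_unmeth
  out <- list()
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    starts <- seq(1L, len, by = window)
    ends <- pmin(starts + window - 1L, len)
    s <- df[df$chrom == chrom & df$coverage > 0, , drop = FALSE]
    win <- findInterval(s$pos, starts)
    for (ctx in METH_CONTEXTS) {
      sel <- s$context == ctx
      cm <- tapply(s$count_meth[sel], win[sel], sum)
      cv <- tapply(s$coverage[sel], win[sel], sum)
      nn <- tapply(rep(1L, sum(sel)), win[sel], sum)
      lv <- rep(NA_real_, length(starts))
      ns <- rep(0L, length(starts))
      if (length(cm)) {
        ii <- as.integer(names(cm))
        lv[ii] <- as.numeric(cm) / as.numeric(cv)
        ns[ii] <- as.integer(nn)
      }
      out[[paste(chrom, ctx)]] <- data.frame(
        chrom = chrom, start = starts, end = ends, context = ctx,
        level = lv, n_sites = ns, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("density_track", "data.frame")
  res
}
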