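#' Simulate gene models
#'
#' Places non-overlapping genes with random strands along the simulated
#' chromosomes, leaving flank room for 2 kb promoter/downstream regions.
#' First exons take a configured fraction of the gene length at the
#' 5' end.
#'
#' @param config a [sim_config()].
#' @return `gene_models` data.frame.
#' @export
simulate_gene_models <- function(config) {
  set.seed(derive_seed(config$seed, "genes"))
  per_chrom <- diff(round(seq(0, config$n_genes, length.out =
                                config$n_chroms + 1)))
  rows <- list()
  gi <- 0L
  for (ci in seq_len(config$n_chroms)) {
    chrom <- sprintf("Chr%02d", ci)
    pos <- 3000L
    placed <- 0L
    while (placed < per_chrom[ci]) {
      len <- sample(config$gene_length_range[1]:config$gene_length_range[2], 1)
      gap <- sample(4500:8000, 1)
      start <- pos + gap
      end <- start + len - 1L
      if (end > config$chrom_length - 3000L) break
      gi <- gi + 1L
      placed <- placed + 1L
      strand <- sample(c("+", "-"), 1)
      fe_len <- max(100L, round(len * config$first_exon_frac))
      rows[[gi]] <- data.frame(
        gene_id = sprintf("gene%04d", gi), chrom = chrom, strand = strand,
        start = start, end = end,
        fe_start = if (strand == "+") start else end - fe_len + 1L,
        fe_end = if (strand == "+") start + fe_len - 1L else end,
        stringsAsFactors = FALSE)
      pos <- end
    }
  }
  if (!length(rows)) stop2("chromosomes too short to place any gene")
  df <- do.call(rbind, rows)
  new_gene_models(df, chrom_lengths =
                    stats::setNames(rep(config$chrom_length, config$n_chroms),
                                    sprintf("Chr%02d",
                                            seq_len(config$n_chroms))))
}

# choose non-overlapping runs of `k` consecutive same-context sites whose
# span does not exceed `width`; returns spike intervals with one delta
# column per condition
build_default_spikes <- function(config, site_df) {
  if (config$dmr_n == 0L) return(NULL)
  k <- config$dmr_sites
  cand <- list()
  for (chrom in unique(site_df$chrom)) {
    p <- site_df$pos[site_df$chrom == chrom &
                       site_df$context == config$dmr_context]
    p <- sort(p)
    if (length(p) < k) next
    span <- p[seq_len(length(p) - k + 1) + k - 1] - p[seq_len(length(p) - k + 1)]
    ok <- which(span <= config$dmr_width)
    if (length(ok))
      cand[[chrom]] <- data.frame(chrom = chrom, start = p[ok],
                                  end = p[ok + k - 1])
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) < config$dmr_n)
    stop2("not enough dense ", config$dmr_context,
          " site runs to place ", config$dmr_n, " spiked DMRs; ",
          "increase n_sites or dmr_width")
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  chosen <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, ]
    clash <- chosen$chrom == r$chrom &
      chosen$start <= r$end + 1000L & chosen$end >= r$start - 1000L
    if (!any(clash)) chosen <- rbind(chosen, r)
    if (nrow(chosen) == config$dmr_n) break
  }
  if (nrow(chosen) < config$dmr_n)
    stop2("could not place ", config$dmr_n, " non-overlapping spiked DMRs")
  chosen <- chosen[order(chosen$chrom, chosen$start), , drop = FALSE]
  rownames(chosen) <- NULL
  chosen$context <- config$dmr_context
  for (cond in config$conditions)
    chosen[[paste0("delta_", cond)]] <-
      if (cond == config$dmr_condition) config$dmr_delta else 0
  chosen
}

#' Simulate a multi-sample bisulfite methylome with ground truth
#'
#' Site positions, contexts and strands are shared across all samples.
#' Each site carries a latent methylation propensity drawn from a Beta
#' distribution around its condition's context mean; the Beta draw is
#' comonotone across conditions (one shared uniform per site, mapped
#' through each condition's quantile function), so conditions with equal
#' configured means have *identical* true levels and all observed
#' differences under the null come from binomial read sampling - the
#' null the downstream Fisher tests assume. Spiked DMRs shift the mean
#' of their member sites in selected conditions. Observed methylated
#' counts are Binomial(coverage, level + (1 - level) * eps) where eps is
#' the conversion-failure rate and coverage is negative-binomial.
#'
#' @param config a [sim_config()].
#' @param genes optional `gene_models`; enables the per-gene body-CG
#'   boost and per-gene true body levels in the truth table.
#' @param spikes optional spike table overriding the default
#'   (`chrom`, `start`, `end`, `context`, one `delta_<condition>` column
#'   per condition); the default places `dmr_n` runs of `dmr_sites`
#'   consecutive `dmr_context` sites shifted by `dmr_delta` in
#'   `dmr_condition`.
#' @param extra_spikes optional additional spike rows (same columns as
#'   `spikes`) applied on top of the default spikes, e.g. promoter CHH
#'   trajectories; extra spikes overlapping fewer than 3 sites of their
#'   context are dropped with a message instead of failing.
#' @return list with `samples` (named list of `cx_sites`, one per
#'   sample, names like `DC_1`), `truth` (spike intervals, per-gene true
#'   body-CG levels, per-site true levels) and `config`.
#' @export
simulate_methylome <- function(config, genes = NULL, spikes = NULL,
                               extra_spikes = NULL) {
  set.seed(derive_seed(config$seed, "methylome"))
  n_chrom_sites <- diff(round(seq(0, config$n_sites,
                                  length.out = config$n_chroms + 1)))
  site_df <- do.call(rbind, lapply(seq_len(config$n_chroms), function(ci) {
    data.frame(chrom = sprintf("Chr%02d", ci),
               pos = sort(sample.int(config$chrom_length, n_chrom_sites[ci])),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(site_df)
  site_df$strand <- sample(c("+", "-"), n, replace = TRUE)
  site_df$context <- sample(METH_CONTEXTS, n, replace = TRUE,
                            prob = config$context_weights)
  h <- function(m) sample(c("A", "C", "T"), m, replace = TRUE)
  site_df$trinucleotide <- ifelse(
    site_df$context == "CG", paste0("CG", sample(c("A", "C", "G", "T"), n,
                                                 replace = TRUE)),
    ifelse(site_df$context == "CHG", paste0("C", h(n), "G"),
           paste0("C", h(n), h(n))))

  conds <- config$conditions
  means <- sapply(conds, function(cd) config$mu[cd, site_df$context])
  means <- matrix(means, nrow = n, dimnames = list(NULL, conds))

  # per-gene body CG elevation (gene-body methylation signal)
  body_boost <- NULL
  if (!is.null(genes) && config$body_cg_mu_boost > 0) {
    body_boost <- stats::runif(nrow(genes), 0, 2 * config$body_cg_mu_boost)
    names(body_boost) <- genes$gene_id
    gr <- regions_gr(genes$chrom, genes$start, genes$end)
    hits <- GenomicRanges::findOverlaps(sites_gr(site_df), gr,
                                        ignore.strand = TRUE)
    sel <- S4Vectors::queryHits(hits)[site_df$context[
      S4Vectors::queryHits(hits)] == "CG"]
    gsel <- gr$idx[S4Vectors::subjectHits(hits)][site_df$context[
      S4Vectors::queryHits(hits)] == "CG"]
    means[sel, ] <- pmin(means[sel, , drop = FALSE] + body_boost[gsel], 0.99)
  }

  if (is.null(spikes)) spikes <- build_default_spikes(config, site_df)
  if (!is.null(spikes)) spikes$origin <- "background"
  if (!is.null(extra_spikes)) {
    extra_spikes$origin <- "extra"
    common <- union(names(spikes) %||% names(extra_spikes),
                    names(extra_spikes))
    for (cc in common) {
      if (!is.null(spikes) && is.null(spikes[[cc]])) spikes[[cc]] <- NA
      if (is.null(extra_spikes[[cc]])) extra_spikes[[cc]] <- NA
    }
    spikes <- if (is.null(spikes)) extra_spikes else
      rbind(spikes[common], extra_spikes[common])
  }
  if (!is.null(spikes)) {
    count_spike_sites <- function(sp) {
      sgr <- regions_gr(sp$chrom, sp$start, sp$end)
      hits <- GenomicRanges::findOverlaps(sites_gr(site_df), sgr,
                                          ignore.strand = TRUE)
      qh <- S4Vectors::queryHits(hits)
      sh <- sgr$idx[S4Vectors::subjectHits(hits)]
      match_ctx <- site_df$context[qh] == sp$context[sh]
      list(qh = qh[match_ctx], sh = sh[match_ctx],
           n = tabulate(sh[match_ctx], nbins = nrow(sp)))
    }
    ov <- count_spike_sites(spikes)
    spikes$n_sites <- ov$n
    if (any(spikes$n_sites < 3L & spikes$origin == "background"))
      stop2("a spiked DMR overlaps fewer than 3 sites of its context")
    thin <- spikes$n_sites < 3L
    if (any(thin)) {
      ml_log("simulate_methylome: dropping ", sum(thin),
             " extra spike(s) with < 3 sites of their context")
      spikes <- spikes[!thin, , drop = FALSE]
      rownames(spikes) <- NULL
      ov <- count_spike_sites(spikes)
    }
    for (cd in conds) {
      d <- spikes[[paste0("delta_", cd)]][ov$sh]
      d[is.na(d)] <- 0
      means[ov$qh, cd] <- pmin(pmax(means[ov$qh, cd] + d, 0), 1)
    }
  }

  # comonotone Beta levels across conditions
  u <- stats::runif(n)
  prec <- config$beta_precision
  levels <- sapply(conds, function(cd) {
    m <- means[, cd]
    lv <- numeric(n)
    inner <- m > 0 & m < 1
    lv[inner] <- stats::qbeta(u[inner], m[inner] * prec,
                              (1 - m[inner]) * prec)
    lv[m <= 0] <- 0
    lv[m >= 1] <- 1
    lv
  })
  levels <- matrix(levels, nrow = n, dimnames = list(NULL, conds))

  eps <- config$conversion_failure
  samples <- list()
  for (cd in conds) {
    p_obs <- levels[, cd] + (1 - levels[, cd]) * eps
    for (r in seq_len(config$n_reps)) {
      cov <- stats::rnbinom(n, mu = config$coverage_mean,
                            size = 1 / config$coverage_dispersion)
      cm <- stats::rbinom(n, cov, p_obs)
      df <- site_df
      df$count_meth <- cm
      df$count_unmeth <- cov - cm
      df <- df[, c("chrom", "pos", "strand", "count_meth", "count_unmeth",
                   "context", "trinucleotide")]
      samples[[paste0(cd, "_", r)]] <- as_cx_sites(df, paste0(cd, "_", r))
    }
  }

  body_levels <- NULL
  if (!is.null(genes)) {
    gr <- regions_gr(genes$chrom, genes$start, genes$end)
    hits <- GenomicRanges::findOverlaps(sites_gr(site_df), gr,
                                        ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    gh <- gr$idx[S4Vectors::subjectHits(hits)]
    iscg <- site_df$context[qh] == "CG"
    qh <- qh[iscg]; gh <- gh[iscg]
    body_levels <- matrix(NA_real_, nrow(genes), length(conds),
                          dimnames = list(genes$gene_id, conds))
    for (cd in conds) {
      mns <- tapply(levels[qh, cd], gh, mean)
      body_levels[as.integer(names(mns)), cd] <- as.numeric(mns)
    }
  }

  ml_log("simulate_methylome: ", n, " sites x ", length(samples), " samples",
         if (!is.null(spikes)) paste0(", ", nrow(spikes), " spiked DMRs"))
  list(samples = samples,
       truth = list(spikes = spikes, body_levels = body_levels,
                    true_levels = levels, site_means = means,
                    body_boost = body_boost),
       sites = site_df,
       config = config)
}
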