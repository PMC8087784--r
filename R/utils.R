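# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
ml_log <- function(..., verbose = getOption("methylink.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[methylink] ", ...)
  invisible(NULL)
}

stop2 <- function(...) stop(..., call. = FALSE)

METH_CONTEXTS <- c("CG", "CHG", "CHH")

assert_contexts <- function(x, where = "input") {
  bad <- setdiff(unique(x), METH_CONTEXTS)
  if (length(bad))
    stop2("unknown methylation context token(s) in ", where, ": ",
          paste(bad, collapse = ", "))
  invisible(TRUE)
}

# deterministic per-stage sub-seed from one global seed; stays < 2^31
derive_seed <- function(seed, stage) {
  offs <- c(genes = 11L, methylome = 23L, expression = 37L, mirna = 53L,
            lengths = 71L, spikes = 89L)
  off <- offs[[stage]] %||% 97L
  (as.integer(seed) %% 1000000L) * 1009L + off
}

# sites data.frame -> GRanges (1-based, width 1)
sites_gr <- function(sites) {
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(sites$pos, width = 1L),
                         strand = sites$strand)
}

regions_gr <- function(chrom, start, end) {
  keep <- !is.na(start) & !is.na(end) & end >= start
  gr <- GenomicRanges::GRanges(chrom[keep],
                               IRanges::IRanges(start[keep], end[keep]))
  gr$idx <- which(keep)
  gr
}

#' Weighted methylation level of arbitrary regions
#'
#' Sum of methylated read counts over total coverage of all sites of one
#' context falling inside each region (the "fraction" estimator applied
#' region-wise). Used for gene-body and promoter level summaries.
#'
#' @param sites data.frame of cytosine sites (chrom, pos, count_meth,
#'   count_unmeth, context).
#' @param regions data.frame with columns `region_id`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param context one of "CG", "CHG", "CHH".
#' @return named numeric vector of weighted levels per region_id; `NA` for
#'   regions with no covered site of the context.
#' @export
region_levels <- function(sites, regions, context) {
  stopifnot(context %in% METH_CONTEXTS)
  s <- sites[sites$context == context &
               (sites$count_meth + sites$count_unmeth) > 0L, , drop = FALSE]
  out <- stats::setNames(rep(NA_real_, nrow(regions)), regions$region_id)
  if (!nrow(s) || !nrow(regions)) return(out)
  rg <- regions_gr(regions$chrom, regions$start, regions$end)
  hits <- GenomicRanges::findOverlaps(sites_gr(s), rg, ignore.strand = TRUE)
  if (!length(hits)) return(out)
  ridx <- rg$idx[S4Vectors::subjectHits(hits)]
  sidx <- S4Vectors::queryHits(hits)
  cm <- tapply(s$count_meth[sidx], ridx, sum)
  cv <- tapply(s$count_meth[sidx] + s$count_unmeth[sidx], ridx, sum)
  out[as.integer(names(cm))] <- as.numeric(cm) / as.numeric(cv)
  stats::setNames(out, regions$region_id)
}
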