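#' Read a Bismark-style cytosine report
#'
#' Parses the 7-column per-cytosine CX report dialect emitted by
#' Bismark's methylation extractor: chromosome, 1-based position, strand,
#' methylated read count, unmethylated read count, context (CG/CHG/CHH)
#' and trinucleotide.
#'
#' @param path path to a tab-separated CX report (no header).
#' @param sample_id optional sample label stored as the `sample_id`
#'   attribute of the result.
#' @return data.frame of class `cx_sites` with columns `chrom`, `pos`,
#'   `strand`, `count_meth`, `count_unmeth`, `context`, `trinucleotide`;
#'   input order preserved.
#' @export
read_cx_report <- function(path, sample_id = NULL) {
  cols <- c("chrom", "pos", "strand", "count_meth", "count_unmeth",
            "context", "trinucleotide")
  if (!file.exists(path)) stop2("no such file: ", path)
  if (file.size(path) == 0L) {
    df <- as.data.frame(stats::setNames(
      list(character(), integer(), character(), integer(), integer(),
           character(), character()), cols))
    return(as_cx_sites(df, sample_id))
  }
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                      comment.char = "", col.names = cols,
                      colClasses = c("character", "character", "character",
                                     "character", "character", "character",
                                     "character")),
    error = function(e) stop2("malformed CX report ", path, ": ",
                              conditionMessage(e)))
  num <- function(field) {
    v <- suppressWarnings(as.integer(raw[[field]]))
    bad <- which(is.na(v) | v < 0L)
    if (length(bad))
      stop2("parse error in ", path, " at line ", bad[1],
            ": bad ", field, " value '", raw[[field]][bad[1]], "'")
    v
  }
  df <- data.frame(chrom = raw$chrom, pos = num("pos"), strand = raw$strand,
                   count_meth = num("count_meth"),
                   count_unmeth = num("count_unmeth"),
                   context = raw$context, trinucleotide = raw$trinucleotide,
                   stringsAsFactors = FALSE)
  badctx <- which(!df$context %in% METH_CONTEXTS)
  if (length(badctx))
    stop2("parse error in ", path, " at line ", badctx[1],
          ": unknown context token '", df$context[badctx[1]], "'")
  bads <- which(!df$strand %in% c("+", "-"))
  if (length(bads))
    stop2("parse error in ", path, " at line ", bads[1],
          ": bad strand '", df$strand[bads[1]], "'")
  if (any(df$pos < 1L)) stop2("positions must be >= 1 in ", path)
  ml_log("read_cx_report: ", nrow(df), " sites from ", basename(path))
  as_cx_sites(df, sample_id)
}

as_cx_sites <- function(df, sample_id = NULL) {
  class(df) <- c("cx_sites", "data.frame")
  attr(df, "sample_id") <- sample_id
  df
}

#' Write a cytosine report
#'
#' Inverse of [read_cx_report()]; emits the canonical 7-column
#' tab-separated form so that write-then-read is the identity.
#'
#' @param sites cytosine site table.
#' @param path output path.
#' @export
write_cx_report <- function(sites, path) {
  cols <- c("chrom", "pos", "strand", "count_meth", "count_unmeth",
            "context", "trinucleotide")
  utils::write.table(as.data.frame(sites)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge the two strands of each CpG
#'
#' CX reports are per-strand. Merging the symmetric CpG's plus and minus
#' strand evidence is an analysis choice, not a format fact, so it is an
#' explicit opt-in: counts of a minus-strand CG at position p+1 are added
#' to the plus-strand CG at p.
#'
#' @param sites cytosine site table.
#' @return `cx_sites` with CG sites strand-merged onto the plus strand;
#'   CHG/CHH sites untouched.
#' @export
merge_cpg_strands <- function(sites) {
  cg <- sites$context == "CG"
  other <- sites[!cg, , drop = FALSE]
  g <- sites[cg, , drop = FALSE]
  if (!nrow(g)) return(sites)
  # anchor = position of the plus-strand C of the dyad
  anchor <- ifelse(g$strand == "+", g$pos, g$pos - 1L)
  key <- paste(g$chrom, anchor)
  cm <- tapply(g$count_meth, key, sum)
  cu <- tapply(g$count_unmeth, key, sum)
  first <- !duplicated(key)
  m <- g[first, , drop = FALSE]
  m$pos <- anchor[first]
  m$strand <- "+"
  k <- paste(m$chrom, m$pos)
  m$count_meth <- as.integer(cm[k])
  m$count_unmeth <- as.integer(cu[k])
  out <- rbind(m, other)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  as_cx_sites(out, attr(sites, "sample_id"))
}

# ---- gene models -----------------------------------------------------------

#' Construct gene models from vectors
#'
#' Programmatic constructor using the same inner-boundary first-exon
#' semantics as the TSV dialect of [read_gene_models()].
#'
#' @param gene_id,chrom,strand,start,end gene coordinates (1-based
#'   inclusive).
#' @param first_exon_end inner boundary of the first exon (default: a
#'   200 bp first exon at the 5' end).
#' @param promoter_width,downstream_width,chrom_lengths see
#'   [read_gene_models()].
#' @return `gene_models` data.frame with derived promoter/downstream
#'   regions.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end,
                        first_exon_end = NULL, promoter_width = 2000L,
                        downstream_width = 2000L, chrom_lengths = NULL) {
  plus <- strand == "+"
  if (is.null(first_exon_end))
    first_exon_end <- ifelse(plus, pmin(start + 199L, end),
                             pmax(end - 199L, start))
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   start = as.integer(start), end = as.integer(end),
                   fe_start = as.integer(ifelse(plus, start, first_exon_end)),
                   fe_end = as.integer(ifelse(plus, first_exon_end, end)),
                   stringsAsFactors = FALSE)
  new_gene_models(df, promoter_width, downstream_width, chrom_lengths)
}

new_gene_models <- function(df, promoter_width = 2000L,
                            downstream_width = 2000L, chrom_lengths = NULL) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end",
                  "fe_start", "fe_end") %in% names(df)))
  if (anyDuplicated(df$gene_id))
    stop2("duplicated gene_id: ", df$gene_id[duplicated(df$gene_id)][1])
  bad <- which(df$end < df$start)
  if (length(bad))
    stop2("gene ", df$gene_id[bad[1]], " has end < start")
  plus <- df$strand == "+"
  df$promoter_start <- ifelse(plus, df$start - promoter_width, df$end + 1L)
  df$promoter_end   <- ifelse(plus, df$start - 1L, df$end + promoter_width)
  df$downstream_start <- ifelse(plus, df$end + 1L, df$start - downstream_width)
  df$downstream_end   <- ifelse(plus, df$end + downstream_width, df$start - 1L)
  # clip flanks at chromosome bounds; a flank fully off-chromosome becomes NA
  df$promoter_start <- pmax(df$promoter_start, 1L)
  df$downstream_start <- pmax(df$downstream_start, 1L)
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[df$chrom])
    df$promoter_end <- pmin(df$promoter_end, lim)
    df$downstream_end <- pmin(df$downstream_end, lim)
  }
  for (pre in c("promoter", "downstream")) {
    s <- df[[paste0(pre, "_start")]]; e <- df[[paste0(pre, "_end")]]
    empty <- e < s
    df[[paste0(pre, "_start")]][empty] <- NA_integer_
    df[[paste0(pre, "_end")]][empty] <- NA_integer_
  }
  df$length <- df$end - df$start + 1L
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  attr(df, "chrom_lengths") <- chrom_lengths
  df
}

#' Read gene models from GFF3 or a 6-column TSV
#'
#' Two dialects are accepted. GFF3 files (by extension `.gff`/`.gff3`)
#' are parsed with rtracklayer; `gene` features define the body and the
#' strand-aware first `exon` per gene defines the first-exon interval.
#' The TSV dialect has a header `gene_id chrom strand start end
#' first_exon_end`; for plus-strand genes the first exon is
#' `[start, first_exon_end]`, for minus-strand genes
#' `[first_exon_end, end]` (the column always holds the inner boundary).
#' Strand-aware 2 kb promoter and downstream regions are derived,
#' clipped at chromosome ends.
#'
#' @param path input file.
#' @param promoter_width,downstream_width flank widths in bp.
#' @param chrom_lengths optional named vector used to clip flanks.
#' @return data.frame of class `gene_models`.
#' @export
read_gene_models <- function(path, promoter_width = 2000L,
                             downstream_width = 2000L, chrom_lengths = NULL) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    df <- parse_gff3_genes(path)
  } else {
    raw <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "start", "end", "first_exon_end")
    if (!all(need %in% names(raw)))
      stop2("gene TSV must have columns: ", paste(need, collapse = ", "))
    bad <- which(raw$first_exon_end < raw$start | raw$first_exon_end > raw$end)
    if (length(bad))
      stop2("gene ", raw$gene_id[bad[1]],
            ": first_exon_end outside [start, end]")
    plus <- raw$strand == "+"
    df <- data.frame(gene_id = raw$gene_id, chrom = raw$chrom,
                     strand = raw$strand,
                     start = as.integer(raw$start), end = as.integer(raw$end),
                     fe_start = as.integer(ifelse(plus, raw$start,
                                                  raw$first_exon_end)),
                     fe_end = as.integer(ifelse(plus, raw$first_exon_end,
                                                raw$end)),
                     stringsAsFactors = FALSE)
  }
  ml_log("read_gene_models: ", nrow(df), " genes from ", basename(path))
  new_gene_models(df, promoter_width, downstream_width, chrom_lengths)
}

parse_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path)
  genes <- gr[tolower(as.character(gr$type)) == "gene"]
  if (!length(genes)) stop2("no gene features in ", path)
  exons <- gr[tolower(as.character(gr$type)) == "exon"]
  gid <- as.character(genes$ID)
  parent <- if (length(exons)) as.character(unlist(exons$Parent)) else character()
  df <- data.frame(gene_id = gid,
                   chrom = as.character(GenomicRanges::seqnames(genes)),
                   strand = as.character(GenomicRanges::strand(genes)),
                   start = GenomicRanges::start(genes),
                   end = GenomicRanges::end(genes),
                   fe_start = NA_integer_, fe_end = NA_integer_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    ex <- exons[parent == df$gene_id[i]]
    if (!length(ex)) {
      warning("gene ", df$gene_id[i],
              " has no exons; first exon set to gene start + 1", call. = FALSE)
      if (df$strand[i] == "+") {
        df$fe_start[i] <- df$start[i]; df$fe_end[i] <- df$start[i] + 1L
      } else {
        df$fe_start[i] <- df$end[i] - 1L; df$fe_end[i] <- df$end[i]
      }
      next
    }
    first <- if (df$strand[i] == "+")
      ex[which.min(GenomicRanges::start(ex))]
    else ex[which.max(GenomicRanges::end(ex))]
    df$fe_start[i] <- GenomicRanges::start(first)
    df$fe_end[i] <- GenomicRanges::end(first)
  }
  df
}

#' Write gene models as TSV (inner-boundary dialect)
#' @param genes gene_models data.frame.
#' @param path output path.
#' @export
write_gene_models_tsv <- function(genes, path) {
  plus <- genes$strand == "+"
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand, start = genes$start,
                    end = genes$end,
                    first_exon_end = ifelse(plus, genes$fe_end,
                                            genes$fe_start))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene models as GFF3 (gene + first-exon features)
#' @param genes gene_models data.frame.
#' @param path output path.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  hdr <- "##gff-version 3"
  gene_ln <- sprintf("%s\tmethylink\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id)
  exon_ln <- sprintf("%s\tmethylink\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                     genes$chrom, genes$fe_start, genes$fe_end, genes$strand,
                     genes$gene_id)
  writeLines(c(hdr, as.vector(rbind(gene_ln, exon_ln))), path)
  invisible(path)
}

# ---- count matrices --------------------------------------------------------

#' Construct an expression set
#'
#' Light-weight container for a features-by-samples count matrix with
#' optional feature lengths and a sample-to-condition mapping.
#'
#' @param counts integer matrix, rownames = feature ids.
#' @param lengths optional numeric vector of feature lengths (bp).
#' @param conditions optional factor/character of length ncol(counts).
#' @return list of class `expr_set` with elements `counts`, `lengths`,
#'   `conditions`; all-zero features are kept and flagged in the
#'   `all_zero` attribute.
#' @export
expr_set <- function(counts, lengths = NULL, conditions = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop2("counts must have feature rownames")
  if (anyDuplicated(rownames(counts)))
    stop2("duplicated feature id: ",
          rownames(counts)[duplicated(rownames(counts))][1])
  if (any(is.na(counts)) || any(counts < 0))
    stop2("counts must be non-negative numbers")
  storage.mode(counts) <- "double"
  if (!is.null(lengths)) {
    lengths <- as.numeric(lengths)
    if (length(lengths) != nrow(counts))
      stop2("lengths must match the number of features")
    if (any(lengths <= 0)) stop2("feature lengths must be > 0")
    names(lengths) <- rownames(counts)
  }
  if (!is.null(conditions)) {
    if (length(conditions) != ncol(counts))
      stop2("conditions must match the number of samples")
    conditions <- factor(conditions, levels = unique(as.character(conditions)))
    names(conditions) <- colnames(counts)
  }
  out <- list(counts = counts, lengths = lengths, conditions = conditions)
  attr(out, "all_zero") <- rowSums(counts) == 0
  class(out) <- "expr_set"
  out
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$counts), "features x", ncol(x$counts), "samples\n")
  if (!is.null(x$conditions))
    cat("conditions:", paste(levels(x$conditions), collapse = ", "), "\n")
  invisible(x)
}

#' Read a count matrix TSV
#'
#' First column `feature_id`, optional `length` column, remaining columns
#' per-sample integer counts.
#'
#' @param path TSV path.
#' @param conditions optional named vector mapping sample name ->
#'   condition label.
#' @return an [expr_set()].
#' @export
read_count_matrix <- function(path, conditions = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (names(raw)[1] != "feature_id")
    stop2("first column must be feature_id")
  lengths <- NULL
  if ("length" %in% names(raw)) {
    lengths <- raw$length
    raw$length <- NULL
  }
  ids <- raw$feature_id
  raw$feature_id <- NULL
  m <- as.matrix(raw)
  if (!is.numeric(m)) stop2("non-numeric count in ", path)
  if (any(m < 0)) stop2("negative count in ", path)
  if (any(m != round(m))) stop2("non-integer count in ", path)
  rownames(m) <- ids
  cond <- if (!is.null(conditions)) unname(conditions[colnames(m)]) else NULL
  ml_log("read_count_matrix: ", nrow(m), " features x ", ncol(m),
         " samples from ", basename(path))
  expr_set(m, lengths = lengths, conditions = cond)
}

#' Write a count matrix TSV
#' @param x expr_set or matrix.
#' @param path output path.
#' @export
write_count_matrix <- function(x, path) {
  m <- if (inherits(x, "expr_set")) x$counts else as.matrix(x)
  df <- data.frame(feature_id = rownames(m), check.names = FALSE)
  if (inherits(x, "expr_set") && !is.null(x$lengths))
    df$length <- unname(x$lengths)
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA->target pair table (TSV with mirna_id, target_id)
#' @param path TSV path.
#' @return data.frame with columns mirna_id, target_id.
#' @export
read_pair_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "target_id") %in% names(df)))
    stop2("pair table needs mirna_id and target_id columns")
  df
}

#' Read a study configuration (YAML)
#'
#' Keys: `samples` (sample -> condition), `conversion_rates`
#' (sample -> rate), `thresholds`, `seed`. Conversion rates at or below
#' 0.9 are flagged with a warning (typical bisulfite libraries convert
#' more than 99 percent of unmethylated cytosines).
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$conversion_rates)) {
    cr <- unlist(cfg$conversion_rates)
    if (any(cr <= 0 | cr > 1)) stop2("conversion rates must be in (0, 1]")
    if (any(cr <= 0.9))
      warning("conversion rate <= 0.9 for sample(s): ",
              paste(names(cr)[cr <= 0.9], collapse = ", "), call. = FALSE)
  }
  cfg
}

#' Write a 0-based half-open BED-like track
#'
#' Internal coordinates are 1-based inclusive; this writer performs the
#' conversion expected by BED consumers (start - 1, end unchanged).
#'
#' @param df data.frame with chrom, start, end plus any score columns.
#' @param path output path.
#' @param extra_cols character vector of additional columns to emit.
#' @export
write_bed_track <- function(df, path, extra_cols = setdiff(names(df),
                                                           c("chrom", "start",
                                                             "end"))) {
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end)
  for (cc in extra_cols) out[[cc]] <- df[[cc]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
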