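# small programmatic fixtures shared across test files

options(methylink.verbose = FALSE)

make_sites <- function(pos, count_meth, count_unmeth, chrom = "Chr01",
                       strand = "+", context = "CG", trinucleotide = "CGA") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             count_meth = as.integer(count_meth),
             count_unmeth = as.integer(count_unmeth),
             context = context, trinucleotide = trinucleotide,
             stringsAsFactors = FALSE)
}

# calls-like table for functions that only need positions + the call flag
make_calls <- function(pos, is_methylated, chrom = "Chr01",
                       context = "CG") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = "+",
             context = context, is_methylated = is_methylated,
             stringsAsFactors = FALSE)
}

# two-sided Fisher p by explicit enumeration over all tables with the
# observed margins, probabilities from binomial coefficients
# (independent of the package's dhyper-based implementation)
fisher_enum_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || k == m1 + m2) return(1)
  as <- max(0, k - m2):min(k, m1)
  pr <- choose(m1, as) * choose(m2, k - as) / choose(m1 + m2, k)
  pobs <- pr[as == a]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# reference BH step-up written from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# geometry roomy enough to place `n` genes
big_gene_config <- function(seed, n_genes, ...) {
  sim_config(seed = seed, n_chroms = 6L, chrom_length = 1000000L,
             n_genes = n_genes, ...)
}
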