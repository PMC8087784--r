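---
title: "Methods: models, parameters and design choices in methylink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in methylink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylink)
options(methylink.verbose = FALSE)
```

# What the package models

methylink implements the analysis layer of a three-condition multi-omic
design: whole-genome bisulfite methylomes, RNA-Seq expression and
small-RNA profiles measured in the same tissue across developmental
stages — the motivating system is the seasonal vascular cambium of a
woody plant, sampled dormant (DC), reactivating (RC) and active (AC)
with three biological replicates each. The pipeline answers four
questions: where is the genome methylated (per CG/CHG/CHH context),
where does methylation differ between stages (DMRs), which genes and
miRNAs change expression, and how the three layers co-vary
(miRNA–target correlations, gene-body methylation vs. expression,
promoter CHH methylation vs. expression).

Every statistical component is validated against a synthetic-data
module that generates all inputs with machine-readable ground truth, so
calibration and power are measured properties, not assumptions.

# Methylation site calling

A cytosine covered by $n$ reads of which $k$ support methylation is
tested against the bisulfite conversion null: if the true methylation
level is zero, a read still appears methylated when conversion fails,
with probability $p_0 = 1 - \text{conversion rate}$. The p-value is the
one-sided binomial tail $P(X \ge k \mid n, p_0)$; one-sided because
conversion failure can only inflate the signal upward, never deflate
it. p-values are corrected across all tested sites by
Benjamini–Hochberg and a site is called methylated at $q < 0.05$.

Two conventions are fixed deliberately:

* **Coverage filter.** "Coverage depth above 4" is read strictly:
  tested sites have at least 5 reads (`min_coverage = 5`).
* **Strand handling.** CX reports are per-strand, and the two strands
  of a symmetric CpG are *not* merged by default; `merge_cpg_strands()`
  exposes merging as an explicit analysis choice, since either
  behaviour is defensible and the choice affects CG site counts.

Degenerate input is handled by convention: a perfect conversion rate
($p_0 = 0$) with observed methylated reads yields $p = 0$ with a
warning; zero-coverage sites are excluded before testing.

# Level estimators, density tracks and metagene profiles

Two estimators of a region's methylation level are computed everywhere:

* **weighted** (the "fraction" estimator, the default): summed
  methylated reads over summed coverage;
* **site-mean**: the unweighted mean of per-site levels.

They diverge exactly when coverage correlates with level (a 1/1 site
plus a 0/99 site gives 0.01 weighted but 0.5 site-mean), which is why
both are reported. Profiles and density tracks are computed from *raw
counts of all covered sites*, not only FDR-called sites — levels are a
property of the data, while the FDR-called set feeds the
methylcytosine context proportions. Both choices can be inverted by
passing call-filtered tables.

Density tracks tile each chromosome with non-overlapping 100-kb
windows; a window without covered sites of a context is missing, not
zero. Metagene profiles map every site to one of 20 fixed 100-bp bins
per 2-kb flank plus 40 length-scaled gene-body bins, strand-aware
(minus-strand genes are reflected). A body base pair whose fractional
footprint straddles a bin boundary is split across bins in proportion
to overlap, so genes shorter than the bin count still contribute with
conserved total weight rather than being dropped. Expression-quartile
profiles rank genes (quartile 1 = highest expression) with ties and
order broken by gene id, making membership invariant to input
permutation.

# DMR detection

The original study states only the acceptance criteria for DMRs —
coverage depth ≥ 10, at least three differentially methylated sites,
Fisher's exact test p < 0.05 — and the criteria sentence applies them
to "differentially methylated sites", leaving the regionization
under-specified. methylink therefore implements both layers explicitly
and documents the construction as its own design:

1. **Per-site layer.** Replicate counts are pooled per condition
   (summed), matching an analysis in which merged sample data feed the
   tests; each shared site gets a two-sided Fisher exact test on the
   pooled 2×2 table plus the level difference
   $\Delta = \text{level}_B - \text{level}_A$. A site is *differential*
   when $p < 0.05$ **and** $|\Delta| \ge 0.1$. The effect-size guard
   exists because at deep pooled coverage the exact test flags
   biologically negligible differences; `min_delta = 0` restores the
   literal p-only rule.
2. **Region layer.** Candidate regions are maximal runs of same-context
   differential sites with inter-site gaps ≤ 200 bp, trimmed to their
   differential endpoints — the gap-linking construction used by common
   bisulfite DMR callers, fully parameterized (`max_gap`). A candidate
   is a DMR when it has ≥ 3 differential sites, the *mean* coverage of
   its member sites is ≥ 10 in both conditions (a per-site minimum
   would interact redundantly with the ≥ 5-read site filter), and the
   Fisher test on region-pooled counts gives p < 0.05.

Direction is `hyper` when the mean $\Delta$ is positive, i.e. "A vs B"
reads as *B relative to A*; swapping the condition arguments swaps
hyper and hypo exactly, which is tested. Pooling replicates before
testing means the Fisher null assumes no extra-binomial variation
between replicates of a condition; the generator reproduces exactly
this null (see below), and on real data with strong replicate
heterogeneity the calls will be anti-conservative — a known limitation
shared with all pooled Fisher DMR callers.

The two-sided Fisher p-value uses the minimum-likelihood rule (sum of
hypergeometric probabilities not exceeding the observed table's, with
the customary $1 + 10^{-7}$ relative tolerance). It is implemented
directly on the hypergeometric mass so genome-scale per-site scans are
feasible; the implementation is checked exhaustively against a
binomial-coefficient enumeration oracle for every table with total
≤ 60, and spot-checked against `stats::fisher.test`.

DMR annotation assigns one category per DMR with priority
promoter > first exon > gene body > intergenic, taking the owning gene
of the matched region; among several genes of the winning type the
larger overlap wins and exact ties go to the nearer TSS. Promoters and
downstream regions are strand-aware 2-kb flanks clipped at chromosome
ends.

# Differential expression

The DEG/DE-miRNA engine is a from-first-principles negative-binomial
exact-test pipeline in the style of the classic NB exact tests:

* **Normalization.** Median-of-ratios size factors (the median over
  everywhere-expressed genes of the count over its geometric mean);
  miRNA matrices use library-size factors instead because sparse miRNA
  matrices rarely have features expressed everywhere, and
  counts-per-million is the field's small-RNA convention.
* **Dispersion.** Per-gene method-of-moments estimate pooled across the
  two conditions, $\alpha = (\hat v - \hat\mu)/\hat\mu^2$, floored at
  $10^{-8}$; with fewer than two replicates in a condition a common
  (median) dispersion across genes is used, with a warning.
* **Test.** Conditioned exact test on the rounded normalized condition
  sums $k_A + k_B$: under the null both sums are NB with shared
  per-sample mean and dispersion $\alpha/n$, and the p-value sums the
  probabilities of all splits no more likely than the observed one.
  The enumeration is restricted to the support region carrying all but
  $\sim 10^{-14}$ of the conditional mass, so large counts stay cheap.
* **Calling.** BH correction, then a joint rule: fold change computed
  as $(\bar\mu_B + 1)/(\bar\mu_A + 1)$ (the pseudo-count prevents
  infinite fold changes for zero-count genes) with an inclusive
  threshold (≥ 4-fold for genes; methods-style "≥" wins over the
  results-style ">", and `strict_fc` restores the strict reading), and
  FDR < 0.01 for genes / ≤ 0.01 for miRNAs with |log2 FC| ≥ 2. The
  three-condition design is analysed as the three pairwise contrasts;
  an omnibus test is deliberately out of scope.

Numerical identity with any specific DESeq release is a non-goal; the
contract is calibration and power, which the acceptance checks measure
on ground-truth simulations (≤ 1 false DEG in 500 null genes; ≥ 80%
recovery of 8-fold changes at mean 200, dispersion 0.1, n = 3).

K-means expression patterning standardizes rows to z-scores (constant
rows are excluded with a message), runs Hartigan–Wong k-means with 50
random restarts under a fixed seed keeping the best objective, and
renumbers cluster labels by descending size so outputs are
deterministic and comparable without claiming semantic cluster
identity.

# Integration layer

* **miRNA–target correlations** default to replicate-level points (all
  nine samples) because that is the better-powered choice and the
  condition-mean alternative (three points) is exposed as an option.
  Pairs are classified by the sign of Pearson r; zero-variance members
  give an undefined r and are excluded from the sign counts. The
  "differential pair" flag defaults to *miRNA differentially
  expressed*, with target/either/both modes available, since the
  original wording does not fix which member must be differential.
* The **differential-vs-other contrast** is a pooled-variance Student's
  t-test on the r values, reported with group means.
* **Gene-body methylation vs. expression** pairs the weighted body-CG
  level with mean expression per condition and summarizes across genes
  with Spearman correlations (rank-based, since FPKM is heavily
  right-skewed). The gene set defaults to the gene-body-only methylated
  genes where at least five exist; under genome-wide methylation
  regimes that set is often empty and the trend is computed over all
  genes with covered bodies, which the log records.
* **Promoter-CHH integration** restricts to genes whose promoter
  overlaps a CHH DMR, clusters standardized per-stage expression with
  the shared k-means engine (k = 4), and pairs each cluster's
  expression centroid with its mean promoter-CHH trajectory plus their
  Pearson correlation — the analysis behind the display, rather than a
  re-creation of a heatmap. The DMR-vs-other coupling comparison uses
  per-gene |r| across stages and a two-sided Mann–Whitney U test:
  |r| is bounded and non-normal, so a rank test is the defensible
  default where no test was named.

# The synthetic-data module

The generator emulates the statistical structure the analysis assumes,
not the sequence biology:

* **Sites.** Positions are uniform per chromosome; contexts are
  assigned by weighted sampling (default CG/CHG/CHH = 0.2/0.2/0.6,
  giving CHH the plurality as in plant genomes) rather than simulated
  sequence, because only context labels feed the downstream math.
* **Levels.** Each site has a latent level drawn from a Beta
  distribution around its condition's context mean (precision 40 by
  default). The Beta draw is *comonotone* across conditions: one
  uniform per site mapped through each condition's quantile function.
  Conditions with equal means therefore have identical true levels, so
  all between-condition variation under the null is binomial read
  sampling — exactly the null of the pooled Fisher tests, which makes
  the calibration checks meaningful. Spiked DMRs shift the mean of
  runs of real sites (guaranteeing ≥ 3 sites of the right context per
  spike); promoter-CHH spikes carry per-stage trajectories.
* **Reads.** Coverage is negative-binomial (mean 20, dispersion 0.3 by
  default); conversion failure adds false methylation:
  $P(\text{read methylated}) = \ell + (1-\ell)\varepsilon$ with
  $\varepsilon = 0.005$, so $\varepsilon$ *is* the binomial null rate
  $p_0$.
* **Expression.** NB counts with log-normal baselines, per-sample
  size factors, configured fold changes for DE genes (half up, half
  down), an optional log-linear coupling to the gene's body-CG level,
  and four promoter-CHH archetypes (flat-high, down, up, strongly up)
  whose expression multipliers and promoter trajectories produce the
  up-regulation/hypomethylation motif. Archetype genes are excluded
  from the random-DE pool so the two differential mechanisms do not
  collide.
* **miRNAs.** Each pair's miRNA tracks its target's standardized log2
  expression with a configured sign, slope and Gaussian noise;
  "differential" pairs target truly-DE genes with stronger and more
  often negative coupling, so differential miRNAs and the stronger
  negative correlation of differential pairs both *emerge* from the
  coupling rather than being stamped on. Read lengths are drawn
  unimodally around 24 nt over 15–33 nt so the 18–30-nt filter is
  exercised.

Default parameter values in `study_preset()` are fixed at the
study conditions this package emulates: three stages × three
replicates; context means near the reported genome-wide ranges (CG
≈ 20%, CHG ≈ 12.5%, CHH ≈ 6%, with CG/CHG slightly higher and CHH
slightly lower in the active stage); 99.5% conversion; ~20× coverage.
The preset genome is 2 chromosomes × 1.1 Mb with 60,000 cytosines and
~250 genes — small enough that the complete pipeline runs in seconds,
large enough that every per-test check retains power (each promoter
holds ~30 CHH sites, each gene body several CG sites, and 100-spike
recovery runs use 20,000 sites at 30× coverage).

What the generator does **not** emulate — and hence what green checks
do not certify on real data: sequence-determined context spacing and
CpG islands, transposable-element structure, mapping and conversion
biases that vary along the genome, replicate-level biological
overdispersion of methylation (see the DMR caveat above), batch
effects, and isoform-level expression. The generator is a calibration
instrument, not a genome simulator.

# Numerical and coordinate conventions

* Internal coordinates are 1-based inclusive, the GenomicRanges
  convention used by every interval operation here; CX and GFF3
  readers/writers keep their native 1-based forms and the BED-track
  writer converts to 0-based half-open on output.
* One master seed drives everything; per-stage sub-seeds are derived
  deterministically so partial re-runs reproduce. The full pipeline is
  byte-reproducible, which an acceptance check verifies by hashing all
  written outputs across two runs.
* Fisher and binomial p-values match enumeration oracles to well below
  $10^{-10}$ (exhaustively for all 2×2 tables with total ≤ 60 and all
  binomial n ≤ 50); BH is `stats::p.adjust`, cross-checked against a
  step-up reference implementation.
* Ties: quartile membership and k-means labels are made deterministic
  as described; DMR annotation ties go to the nearer TSS and are
  logged.

# Known limitations

Pooled-Fisher DMR calling ignores replicate dispersion; the
windowing/gap parameters are a declared substitute for whichever
regionization the original tooling used, not a reconstruction of it;
the NB exact test rounds normalized sums to integers; FPKM/TPM inherit
their usual compositional caveats; and the integration layer reports
associations across stages and genes, never causal direction.
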