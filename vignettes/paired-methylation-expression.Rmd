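---
title: "Paired differential methylation and expression analysis with medipdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired differential methylation and expression analysis with medipdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdiff)
```

## The analysis

medipdiff implements a paired case/control analysis for two read-count
assays measured on the same subjects: MeDIP-seq, where read density over a
genomic region is a proxy for DNA methylation, and mRNA-seq, where per-gene
read counts measure expression. The design is strictly pairwise — each case
sample is compared only against its matched control — and pair-level calls
are then aggregated.

### Differentially methylated regions

For a pair, the two samples' peak calls are merged into their base-union;
each merged region is a *candidate DMR*. With region read counts
$x_1, x_2$ and library sizes $N_1, N_2$ (uniquely mapped reads), each
candidate is tested with the Pearson chi-square statistic (1 df, no
continuity correction) on the table

$$\begin{pmatrix} x_1 & N_1 - x_1 \\ x_2 & N_2 - x_2 \end{pmatrix},$$

the standard contingency construction for read enrichment against
library-size margins. P-values are FDR-adjusted across all candidates of
the pair (Benjamini–Hochberg by default). The fold change is the ratio of
normalised rates $r = (x_1/N_1)/(x_2/N_2)$, folded to $\max(r, 1/r)$. A
candidate is a *true DMR* when $p \le 0.01$, $q \le 0.01$ and fold $> 2$
(strict). Trend is *uptrend* when the case rate is higher, *downtrend* when
the control rate is higher.

Genes are then classified per element — promoter, 5'-UTR, CDS, intron,
3'-UTR — from the trend of overlapping true DMRs: an element overlapping
only uptrend DMRs is *hyper*-methylated, only downtrend *hypo*, both
*mixed*, none *unmethylated*.

### Differentially expressed genes

Expression is quantified as RPKM,
$10^9 \cdot x / (N \cdot L)$ for count $x$, library size $N$ and gene
length $L$ bp. Per pair, each gene with a nonzero count in at least one
sample is tested with the Audic–Claverie exact conditional test: given the
count $x$ in the first library, the null distribution of the second
library's count $y$ is

$$P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}},$$

with two-sided $p = \min(1,\, 2\min(P(Y \le y), P(Y \ge y)))$. This
distribution is a negative binomial with size $x + 1$ and success
probability $N_1/(N_1+N_2)$; the implementation evaluates the tails through
that identity, which is numerically stable at any count, and the test suite
checks it against direct log-space tail summation. A 2×2 chi-square variant
is available via `test = "chisq"`.

P-values are adjusted within each pair with the Benjamini–Yekutieli (2001)
step-up procedure (valid under arbitrary dependence, harmonic-sum factor
$c(m)$), and a gene is called up or down when FDR $\le 0.001$ and its RPKM
ratio exceeds 2 in either direction. Calls are aggregated across pairs; the
default reporting filter keeps genes called in $\ge 5$ of the pairs, and
both the any-direction and direction-consistent counts are emitted because
the aggregation rule's direction requirement is genuinely open — we default
to any-direction and report `n_consistent` alongside. DEG patterns (the
gene × pair matrix of +1/−1/0 calls) are clustered hierarchically under
Euclidean distance with average linkage; the merge table and leaf order are
exported for heatmap rendering.

### Enrichment and integration

Term enrichment of a gene set against a universe uses the hypergeometric
upper tail $P(X \ge k)$ with Bonferroni correction; the multiplier $m$ is
the number of terms tested (terms with at least one selected member) within
the term's category, and is reported in the output so the correction is
auditable. GO-style categories use corrected $p \le 0.01$, pathway terms
$\le 0.05$. The DEG universe defaults to genes expressed in at least one
sample; the DMG universe to all annotated genes — the background the
original analysis used is not recoverable, so both are explicit,
configurable choices.

The methylation–expression integration joins, per pair and element, each
gene's methylation status with its $\log_2$ RPKM ratio (case/control), and
tabulates the ratio distribution per (element, status) stratum in unit
bins over $[-10, 10]$ with edge clamping. Genes with zero RPKM on either
side have no finite ratio; they are excluded from the distributions but
counted, so totals are conserved. "Unmethylated" means *overlaps no true
DMR*; mixed genes are reported separately and excluded from the three-way
comparison, which mirrors a three-stratum display.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `promoter_len` | 2000 bp | upstream window defining the promoter element; the element set itself never fixes an extent, so this is exposed |
| `p_max` (DMR) | 0.01 | applied to both raw p and FDR-adjusted q |
| `fold_min` (DMR, DEG) | 2 | strict `>` on the normalised ratio |
| `fdr_method` (DMR) | BH | BY available |
| `fdr_max` (DEG) | 0.001 | Benjamini–Yekutieli within pair |
| `k_min` | 5 | minimum pairs for aggregated DEG reporting |
| `alpha_go`, `alpha_kegg` | 0.01, 0.05 | significance on Bonferroni-corrected p |
| `pseudocount` | 0.5 | added to both counts only when one is zero, for fold/ratio computation — never for the test itself |

Two rules are ambiguous in the underlying method description and are
resolved as defaults with the alternative kept available: the 2-fold DMR
rule is applied to library-size-normalised counts (raw-count ratios are not
comparable across libraries), and the "$p \le 0.01$" condition is required
of both the raw and the adjusted p.

## The synthetic data generator

The study whose design this pipeline implements deposited no raw data, so
the generator is a first-class module producing complete, truth-labelled
inputs with the structure the analysis assumes:

- 10 case/control pairs; 49 bp single-end reads; per-pair peak scaffolds
  covering 5% of the genome (the study's reported peak coverage was close
  to this value) — all configurable.
- Planted DMRs: a chosen number of scaffold peaks per pair receive a fold-
  $f$ difference in expected normalised counts, split symmetrically
  ($\sqrt f$ up, $\sqrt f$ down) around the base mean, with a configurable
  uptrend fraction.
- Planted DEGs: log-normal baseline abundances; planted genes' case-side
  rate is multiplied/divided by $2^{\mathrm{lfc}}$ in their affected pairs.
- Counts are negative binomial (dispersion 0.1) by default, reflecting
  biological overdispersion; a Poisson option exists for clean type-I-error
  calibration, and the statistical validation runs use it because the
  chi-square and Audic–Claverie tests are exact/asymptotic under Poisson
  sampling — under NB counts both are anticonservative, which is a known
  property of these tests, not an implementation artifact.
- Library sizes are drawn log-uniformly within 2× of each other per pair to
  exercise the normalisation paths.
- Term collections: random memberships; planted terms sample their members
  with elevated weight on a designated gene set.

Everything is a pure function of the configuration (including its seed):
re-running `run_all()` with the same config reproduces every output file
byte-for-byte.

What the generator does *not* emulate: mappability and GC bias, fragment-
size effects, peak-boundary uncertainty (both samples of a pair share one
peak scaffold), read-level sequencing errors, correlated genes, and
realistic chromosome sizes. Passing recovery tests therefore demonstrate
that the statistical machinery is correct under its own model assumptions,
not that the thresholds are well calibrated for real patient data.

## Numerical and degenerate-input choices

- Coordinates are held in `GRanges` (1-based, closed) — the convention of
  the container library every interval operation runs on. BED is converted
  from 0-based half-open at the I/O boundary; GTF ingested as-is. Intervals
  that touch as half-open intervals (`[a,b)`,`[b,c)`) are adjacent in the
  closed convention and are merged, preserving union-of-covered-bases
  semantics for candidate DMRs.
- Overlap is strand-blind everywhere (MeDIP reads and peaks are
  unstranded); element derivation is strand-aware.
- Candidates with zero reads in both samples are flagged untestable: stat
  0, p 1, never a true DMR, trend `none`.
- Genes with zero counts in both samples of a pair are excluded from
  testing and from the FDR denominator $m$.
- The hypergeometric and negative-binomial tails are computed by `phyper` /
  `pnbinom` in preference to explicit summation; both are validated against
  enumeration/summation oracles in the tests.
- Cytosines lacking two downstream bases, or whose context window contains
  N, are left unclassified; CpG/CHG/CHH labels are mutually exclusive per
  (position, strand).
- Average-linkage merge order under exact distance ties is ambiguous;
  `hclust`'s deterministic behaviour is used, and the clustering oracle
  comparison is run on continuous data where ties have probability zero.

## Problem sizes used in validation

The packaged validation suite runs at desk scale, chosen so that each
statistical property is measured with adequate replication: 2000 candidate
regions × 20 seeds for type-I error; 100 planted 4-fold DMRs among 1900
nulls (mean count 100) for recovery; 2000 genes with 50 planted 8-fold DEGs
(mean count 200) per pair across 10 pairs; enrichment over a 2000-gene
universe with 20 replicates; 500 records per stratum for the integration
null. End-to-end runs use one or two chromosomes of 120–500 kb.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_chroms = 1, chrom_len = 150000,
                  n_genes = 15, n_pairs = 3, dmr_count = 8)
manifest <- run_all(cfg, "pipeline_out")
head(read_tsv_with_header("pipeline_out/results/dmr_summary.tsv"))
```

## Known limitations

- Alignment and peak calling are out of scope: aligned read intervals and
  peak calls are inputs (the generator produces them directly).
- The exact identity of the historical DEG test is not recoverable from the
  method description it cites; the Audic–Claverie test is the standard
  two-library digital expression test of that era and is the default, with
  a chi-square fallback. Output headers name the test used.
- Group-level (non-paired) DMR models, smoothing-based DMR callers and
  term-graph propagation are deliberately not implemented.
- Results-level counts from the original patient cohort are not
  reproducible (data never deposited) and are not targets of this package;
  the validation is property-based on planted truth.
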