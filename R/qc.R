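# MeDIP-seq read filtering and the descriptive distribution statistics
# computed from aligned reads and peak calls.

#' Read a FASTQ file with qualities
#'
#' Phred+33 encoding is assumed.
#'
#' @param path FASTQ path.
#' @return A `QualityScaledDNAStringSet`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own internal metadata columns here
  suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path,
                                              quality.scoring = "phred"))
}

#' Filter sequencing reads on undetermined-base and quality rules
#'
#' A read is removed iff its fraction of undetermined (N) bases exceeds
#' `max_n_frac`, or the fraction of bases with Phred quality `Q <= low_q`
#' exceeds `max_lowq_frac`. Q is the standard Phred score,
#' Q = -10 log10(error rate). Defaults implement the rules "more than 10%
#' bases undetermined" and "more than 50% bases with Q <= 20".
#'
#' @param reads A `QualityScaledDNAStringSet` (see [read_fastq()]).
#' @param max_n_frac Maximum tolerated N fraction (strict `>` removes).
#' @param low_q Quality threshold; bases with `Q <= low_q` count as low
#'   quality.
#' @param max_lowq_frac Maximum tolerated low-quality base fraction (strict
#'   `>` removes).
#' @return List with `kept` (the retained reads), `report` (data.frame with
#'   counts of reads removed by each rule; a read violating both rules counts
#'   under both, `removed_total` counts it once) and `removed_ids`.
#' @export
filter_reads <- function(reads, max_n_frac = 0.10, low_q = 20L,
                         max_lowq_frac = 0.50) {
  stopifnot(is(reads, "QualityScaledDNAStringSet"))
  w <- width(reads)
  qw <- width(Biostrings::quality(reads))
  if (any(w != qw)) {
    stop("sequence/quality length mismatch for read(s): ",
         paste(head(names(reads)[w != qw], 5), collapse = ", "))
  }
  n_frac <- as.vector(Biostrings::letterFrequency(reads, "N")) / w
  qs <- as(Biostrings::quality(reads), "IntegerList")
  lowq_frac <- sum(qs <= low_q) / w
  bad_n <- n_frac > max_n_frac
  bad_q <- lowq_frac > max_lowq_frac
  removed <- bad_n | bad_q
  list(
    kept = reads[!removed],
    report = data.frame(
      n_input = length(reads),
      removed_n_rule = sum(bad_n),
      removed_quality_rule = sum(bad_q),
      removed_total = sum(removed),
      kept = sum(!removed)
    ),
    removed_ids = names(reads)[removed]
  )
}

#' Classify cytosine contexts (CpG / CHG / CHH) across a genome
#'
#' Every cytosine on either strand is labelled by its downstream dinucleotide
#' context: CpG when followed by G, CHG when the pattern is C-H-G, CHH when
#' C-H-H (H is A, C or T). Minus-strand contexts are read on the reverse
#' complement. Cytosines within two bases of the downstream chromosome end,
#' or whose context window contains N, are left unclassified.
#'
#' @param genome A named `DNAStringSet` (one entry per chromosome).
#' @return `data.table` with columns `chrom`, `pos` (1-based position of the
#'   C on the plus-strand coordinate system), `strand`, `context`.
#' @export
classify_contexts <- function(genome) {
  stopifnot(is(genome, "DNAStringSet"))
  one_strand <- function(chars) {
    n <- length(chars)
    if (n < 2L) return(data.table(pos = integer(0), context = character(0)))
    is_c <- chars == "C"
    nxt1 <- c(chars[-1L], "N")
    nxt2 <- c(chars[-(1:2)], "N", "N")
    h1 <- nxt1 %in% c("A", "C", "T")
    h2 <- nxt2 %in% c("A", "C", "T")
    in_window <- seq_len(n) <= n - 2L   # need 2 downstream bases
    cpg <- is_c & nxt1 == "G" & in_window
    chg <- is_c & h1 & nxt2 == "G" & in_window
    chh <- is_c & h1 & h2 & in_window
    data.table(
      pos = c(which(cpg), which(chg), which(chh)),
      context = rep(c("CpG", "CHG", "CHH"),
                    c(sum(cpg), sum(chg), sum(chh)))
    )
  }
  out <- lapply(names(genome), function(chrom) {
    s <- toupper(as.character(genome[[chrom]]))
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(chars)
    plus <- one_strand(chars)
    if (nrow(plus)) plus[, `:=`(chrom = chrom, strand = "+")]
    rc <- strsplit(as.character(
      Biostrings::reverseComplement(genome[[chrom]])), "", fixed = TRUE)[[1]]
    minus <- one_strand(toupper(rc))
    if (nrow(minus)) {
      minus[, pos := n - pos + 1L]   # map back to plus-strand coordinates
      minus[, `:=`(chrom = chrom, strand = "-")]
    }
    rbindlist(list(plus, minus), fill = TRUE)
  })
  res <- rbindlist(out)
  if (nrow(res) == 0L) {
    return(data.table(chrom = character(0), pos = integer(0),
                      strand = character(0), context = character(0)))
  }
  setorder(res, chrom, pos, strand)
  res[, c("chrom", "pos", "strand", "context"), with = FALSE]
}

#' Genome coverage as a function of sequencing depth
#'
#' @param reads `GRanges` of aligned read intervals.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return data.frame with `depth`, `frac_eq` (fraction of the genome at
#'   exactly that depth) and `frac_ge` (at or above it), for depth 1..max.
#'   The `frac_ge` column is non-increasing, and `frac_eq` plus the uncovered
#'   fraction sums to 1.
#' @export
coverage_by_depth <- function(reads, chrom_sizes) {
  genome_len <- sum(as.numeric(chrom_sizes))
  if (length(reads) == 0L) {
    return(data.frame(depth = integer(0), frac_eq = numeric(0),
                      frac_ge = numeric(0)))
  }
  seqlevels(reads) <- names(chrom_sizes)
  seqlengths(reads) <- chrom_sizes[seqlevels(reads)]
  cov <- GenomicRanges::coverage(reads)
  counts <- integer(0)
  for (chrom in names(cov)) {
    rv <- runValue(cov[[chrom]])
    rl <- runLength(cov[[chrom]])
    keep <- rv > 0
    if (!any(keep)) next
    tab <- tapply(rl[keep], rv[keep], sum)
    d <- as.integer(names(tab))
    m <- max(max(d), length(counts))
    counts <- c(counts, integer(m - length(counts)))
    counts[d] <- counts[d] + as.integer(tab)
  }
  if (length(counts) == 0L) {
    return(data.frame(depth = integer(0), frac_eq = numeric(0),
                      frac_ge = numeric(0)))
  }
  frac_eq <- counts / genome_len
  data.frame(depth = seq_along(counts), frac_eq = frac_eq,
             frac_ge = rev(cumsum(rev(frac_eq))))
}

#' CpG-site positions as a GRanges
#'
#' Extracts the plus-strand CpG dinucleotide positions (one site per CpG)
#' from a context table.
#'
#' @param contexts Output of [classify_contexts()].
#' @return `GRanges` of 1 bp sites at the C of each plus-strand CpG.
#' @export
cpg_sites <- function(contexts) {
  cg <- contexts[contexts$context == "CpG" & contexts$strand == "+", ]
  GRanges(cg$chrom, IRanges(cg$pos, cg$pos))
}

#' Distribution of items over CpG-density bins
#'
#' Each item's density is the number of CpG sites it overlaps scaled to
#' CpGs per 100 bp, then binned.
#'
#' @param items `GRanges` (reads, peaks, or fixed windows).
#' @param sites `GRanges` of CpG sites (see [cpg_sites()]).
#' @param breaks Bin edges in CpGs per 100 bp; the last bin is open-ended.
#' @return data.frame with `bin_lo`, `bin_hi`, `count`; counts sum to
#'   `length(items)`.
#' @export
density_binned_distribution <- function(items, sites,
                                        breaks = c(0, 1, 2, 3, 4, 5, 7.5,
                                                   10, 15, 20)) {
  dens <- countOverlaps(items, sites, ignore.strand = TRUE) * 100 /
    width(items)
  edges <- c(breaks, Inf)
  idx <- findInterval(dens, edges, rightmost.closed = FALSE)
  idx[idx == 0L] <- 1L   # clamp anything below the first edge
  data.frame(
    bin_lo = edges[seq_along(breaks)],
    bin_hi = edges[-1][seq_along(breaks)],
    count = tabulate(idx, nbins = length(breaks))
  )
}

#' Item counts and base coverage per gene element class
#'
#' For each annotation class (CpG island, promoter, 5'-UTR, CDS, intron,
#' 3'-UTR, each repeat class, intergenic) reports how many items overlap the
#' class by at least one base and how many class bases are covered by at
#' least one item. An item spanning several classes counts once in each.
#' Intergenic is the genome minus gene spans and promoters.
#'
#' @param items `GRanges` of reads or peaks.
#' @param bundle An annotation bundle (see [simulate_genome()] for the
#'   structure: `genes`, `exons`, `elements`, `cpg_islands`, `repeats`,
#'   `chrom_sizes`).
#' @return data.frame with `class`, `n_items`, `covered_bp`, `class_bp`.
#' @export
element_distribution <- function(items, bundle) {
  cls <- list(cpg_island = bundle$cpg_islands)
  el <- bundle$elements
  for (e in c("promoter", "utr5", "cds", "intron", "utr3")) {
    cls[[e]] <- el[mcols(el)$element_type == e]
  }
  if (length(bundle$repeats)) {
    rep_cls <- mcols(bundle$repeats)$repeat_class
    if (is.null(rep_cls)) rep_cls <- rep("repeat", length(bundle$repeats))
    for (rc in unique(rep_cls)) {
      cls[[paste0("repeat_", rc)]] <- bundle$repeats[rep_cls == rc]
    }
  }
  genic <- GRanges(bundle$genes$chrom,
                   IRanges(bundle$genes$tx_start, bundle$genes$tx_end))
  occupied <- merge_intervals(c(genic, granges(el[mcols(el)$element_type ==
                                                    "promoter"])))
  seqlevels(occupied) <- names(bundle$chrom_sizes)
  seqlengths(occupied) <- bundle$chrom_sizes
  cls$intergenic <- gaps(occupied)
  cls$intergenic <- cls$intergenic[strand(cls$intergenic) == "*"]

  items_u <- merge_intervals(items)
  rows <- lapply(names(cls), function(name) {
    cg <- merge_intervals(cls[[name]])
    data.frame(
      class = name,
      n_items = sum(countOverlaps(items, cg, ignore.strand = TRUE) > 0),
      covered_bp = sum(width(GenomicRanges::intersect(
        items_u, cg, ignore.strand = TRUE))),
      class_bp = sum(width(cg))
    )
  })
  do.call(rbind, rows)
}

#' Average item density around anchor regions
#'
#' Anchor bodies are scaled to `n_bins` bins; fixed-width flanks of
#' `flank` bp on each side are split into `n_flank_bins` bins. Minus-strand
#' anchors are reversed so upstream always reads left. The profile is the
#' per-base item coverage averaged within each bin, then averaged over
#' anchors. Anchors whose flanks extend past a chromosome end are dropped.
#'
#' @param items `GRanges` of reads.
#' @param anchors `GRanges` of CpG islands or gene bodies (strand respected).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param flank Flank width in bp.
#' @param n_bins Number of body bins.
#' @param n_flank_bins Number of bins per flank.
#' @return data.frame with `bin` (1..total), `zone` (upstream/body/
#'   downstream) and `mean_density`.
#' @export
metagene_profile <- function(items, anchors, chrom_sizes, flank = 1000L,
                             n_bins = 20L, n_flank_bins = 10L) {
  total_bins <- n_flank_bins * 2L + n_bins
  zone <- rep(c("upstream", "body", "downstream"),
              c(n_flank_bins, n_bins, n_flank_bins))
  out <- data.frame(bin = seq_len(total_bins), zone = zone,
                    mean_density = 0)
  keep <- start(anchors) - flank >= 1 &
    end(anchors) + flank <= chrom_sizes[as.character(seqnames(anchors))]
  anchors <- anchors[keep]
  if (length(anchors) == 0L) return(out)
  cov <- GenomicRanges::coverage(items)
  bin_means <- function(v, k) {
    # split a numeric vector into k contiguous chunks, mean of each
    idx <- ceiling(seq_along(v) / (length(v) / k))
    as.numeric(tapply(v, idx, mean))
  }
  acc <- matrix(0, nrow = length(anchors), ncol = total_bins)
  for (i in seq_along(anchors)) {
    a <- anchors[i]
    chrom <- as.character(seqnames(a))
    chrom_cov <- if (chrom %in% names(cov)) cov[[chrom]] else
      Rle(0L, chrom_sizes[[chrom]])
    if (length(chrom_cov) < end(a) + flank) {
      chrom_cov <- c(chrom_cov,
                     Rle(0L, end(a) + flank - length(chrom_cov)))
    }
    up <- as.numeric(chrom_cov[(start(a) - flank):(start(a) - 1L)])
    body <- as.numeric(chrom_cov[start(a):end(a)])
    down <- as.numeric(chrom_cov[(end(a) + 1L):(end(a) + flank)])
    prof <- c(bin_means(up, n_flank_bins), bin_means(body, n_bins),
              bin_means(down, n_flank_bins))
    if (as.character(strand(a)) == "-") prof <- rev(prof)
    acc[i, ] <- prof
  }
  out$mean_density <- colMeans(acc)
  out
}

#' Peak length histogram
#'
#' @param peaks `GRanges` of peaks.
#' @param bin_width Histogram bin width in bp.
#' @return data.frame with `bin_lo`, `bin_hi`, `count`; empty input yields an
#'   empty histogram. Counts sum to the number of peaks.
#' @export
peak_length_distribution <- function(peaks, bin_width = 100L) {
  if (length(peaks) == 0L) {
    return(data.frame(bin_lo = integer(0), bin_hi = integer(0),
                      count = integer(0)))
  }
  w <- width(peaks)
  idx <- w %/% bin_width
  lo <- min(idx):max(idx)
  data.frame(bin_lo = lo * bin_width,
             bin_hi = (lo + 1L) * bin_width,
             count = tabulate(idx - min(idx) + 1L, nbins = length(lo)))
}
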