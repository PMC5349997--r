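# Deterministic truth-labelled data generator. It emulates the study design
# the pipeline expects: 10 case/control pairs, 49 bp single-end MeDIP-seq
# reads concentrated in peak regions covering ~5% of the genome, planted
# up/downtrend DMRs with known fold, gene-count matrices with planted DEGs,
# and term collections with planted enrichment.

#' Simulation configuration
#'
#' All tunables for the synthetic generator, with defaults mirroring the
#' study design: 10 sample pairs, 49 bp reads, peaks covering 5% of the
#' genome, negative-binomial count noise.
#'
#' @param seed Integer RNG seed; the whole simulation is a pure function of
#'   the configuration including this seed.
#' @param n_chroms,chrom_len Number and length (bp) of toy chromosomes.
#' @param n_genes Number of gene models.
#' @param max_exons Maximum exons per gene.
#' @param n_islands CpG islands per chromosome.
#' @param n_repeats Repeat intervals per chromosome.
#' @param n_pairs Case/control sample pairs (default 10).
#' @param read_len Read length in bp (default 49).
#' @param peak_fraction Fraction of the genome covered by peaks (default
#'   0.05).
#' @param peak_width_range Peak width range in bp.
#' @param peak_mean_count Mean read count per peak region at the reference
#'   library size.
#' @param dmr_count Planted DMRs per pair.
#' @param dmr_fold Normalised count fold at planted DMRs (default 4).
#' @param dmr_uptrend_frac Fraction of planted DMRs that are uptrend
#'   (default 0.5).
#' @param lib_size Reference library size (uniquely mapped reads); actual
#'   sizes are drawn log-uniformly within 2x of each other per pair.
#' @param noise `"nb"` (negative binomial, default) or `"poisson"`.
#' @param dispersion NB dispersion (default 0.1; variance = mu + disp*mu^2).
#' @param expr_mean_count Mean gene read count at the reference library size.
#' @param expr_sdlog Log-normal spread of baseline gene abundances.
#' @param deg_count Planted DEGs.
#' @param deg_log2_fold Planted DEG effect (default 3, i.e. 8-fold).
#' @param deg_pairs_affected Pairs in which each planted DEG is perturbed
#'   (default all).
#' @param n_terms Terms in the simulated collection.
#' @param term_size_range Term size range (genes).
#' @param planted_terms Number of terms planted as enriched.
#' @param term_enrich_ratio Sampling-weight ratio favouring selected genes in
#'   planted terms (1 = no planted enrichment).
#' @param promoter_len Promoter length used for element derivation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_len = 500000L,
                       n_genes = 100L, max_exons = 5L,
                       n_islands = 15L, n_repeats = 40L,
                       n_pairs = 10L, read_len = 49L,
                       peak_fraction = 0.05,
                       peak_width_range = c(300L, 900L),
                       peak_mean_count = 100,
                       dmr_count = 20L, dmr_fold = 4,
                       dmr_uptrend_frac = 0.5,
                       lib_size = 1e6,
                       noise = c("nb", "poisson"), dispersion = 0.1,
                       expr_mean_count = 200, expr_sdlog = 1,
                       deg_count = 10L, deg_log2_fold = 3,
                       deg_pairs_affected = NULL,
                       n_terms = 50L, term_size_range = c(10L, 30L),
                       planted_terms = 2L, term_enrich_ratio = 20,
                       promoter_len = 2000L) {
  cfg <- list(seed = as.integer(seed), n_chroms = n_chroms,
              chrom_len = chrom_len, n_genes = n_genes,
              max_exons = max_exons, n_islands = n_islands,
              n_repeats = n_repeats, n_pairs = n_pairs,
              read_len = read_len, peak_fraction = peak_fraction,
              peak_width_range = peak_width_range,
              peak_mean_count = peak_mean_count, dmr_count = dmr_count,
              dmr_fold = dmr_fold, dmr_uptrend_frac = dmr_uptrend_frac,
              lib_size = lib_size, noise = match.arg(noise),
              dispersion = dispersion, expr_mean_count = expr_mean_count,
              expr_sdlog = expr_sdlog, deg_count = deg_count,
              deg_log2_fold = deg_log2_fold,
              deg_pairs_affected = deg_pairs_affected, n_terms = n_terms,
              term_size_range = term_size_range,
              planted_terms = planted_terms,
              term_enrich_ratio = term_enrich_ratio,
              promoter_len = promoter_len)
  stopifnot(cfg$peak_fraction > 0, cfg$peak_fraction < 1,
            cfg$read_len > 0, cfg$n_pairs > 0, cfg$lib_size > 0)
  class(cfg) <- "sim_config"
  cfg
}

.draw_counts <- function(mu, noise, dispersion) {
  if (noise == "poisson") rpois(length(mu), mu) else
    rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate a toy genome with annotation
#'
#' Random sequence with CpG islands of elevated C+G content, non-overlapping
#' gene models with valid exon/CDS structure (about 10% non-coding), and
#' labelled repeat intervals. Genes are placed in regularly spaced slots so
#' promoters and intergenic space always exist.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (`DNAStringSet`) and `bundle`, an annotation
#'   bundle: `genes`, `exons`, `elements`, `cpg_islands`, `repeats`,
#'   `chrom_sizes`, `promoter_len`.
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_sizes <- setNames(rep(as.integer(cfg$chrom_len), cfg$n_chroms),
                          chroms)
  bg_p <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)
  isl_p <- c(A = 0.15, C = 0.35, G = 0.35, T = 0.15)

  seqs <- list()
  islands <- list()
  for (chrom in chroms) {
    s <- sample(names(bg_p), cfg$chrom_len, replace = TRUE, prob = bg_p)
    # islands: fixed slots, random offset and width
    slot_w <- cfg$chrom_len %/% cfg$n_islands
    isl_start <- (seq_len(cfg$n_islands) - 1L) * slot_w +
      sample.int(slot_w %/% 2L, cfg$n_islands, replace = TRUE)
    isl_len <- sample(500:1500, cfg$n_islands, replace = TRUE)
    isl_end <- pmin(isl_start + isl_len - 1L, cfg$chrom_len)
    for (i in seq_len(cfg$n_islands)) {
      idx <- isl_start[i]:isl_end[i]
      s[idx] <- sample(names(isl_p), length(idx), replace = TRUE,
                       prob = isl_p)
    }
    seqs[[chrom]] <- paste(s, collapse = "")
    islands[[chrom]] <- GRanges(chrom, IRanges(isl_start, isl_end))
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chroms
  cpg_islands <- unlist(GRangesList(islands), use.names = FALSE)

  # gene models in regularly spaced slots, leaving promoter/intergenic room
  genes_per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  slot_w <- cfg$chrom_len %/% genes_per_chrom
  margin <- cfg$promoter_len + 500L
  gene_rows <- list()
  exon_rows <- list()
  gi <- 0L
  for (chrom in chroms) {
    for (k in seq_len(genes_per_chrom)) {
      gi <- gi + 1L
      if (gi > cfg$n_genes) break
      gene_id <- sprintf("gene%04d", gi)
      slot_lo <- (k - 1L) * slot_w + margin
      slot_hi <- k * slot_w - margin
      max_len <- min(slot_hi - slot_lo, 6000L)
      tx_len <- sample(2000:max(2001L, max_len), 1L)
      tx_start <- slot_lo + sample.int(max(1L, slot_hi - slot_lo - tx_len),
                                       1L)
      tx_end <- tx_start + tx_len - 1L
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample.int(cfg$max_exons, 1L)
      # alternate exon/intron widths that sum to tx_len
      cuts <- sort(sample(seq(tx_start + 100L, tx_end - 100L, by = 50L),
                          2L * (n_ex - 1L)))
      ex_start <- c(tx_start, cuts[seq_len(n_ex - 1L) * 2L])
      ex_end <- c(cuts[seq_len(n_ex - 1L) * 2L - 1L], tx_end)
      if (n_ex == 1L) { ex_start <- tx_start; ex_end <- tx_end }
      coding <- runif(1) > 0.1
      if (coding) {
        cds_start <- tx_start + sample.int(tx_len %/% 4L, 1L)
        cds_end <- tx_end - sample.int(tx_len %/% 4L, 1L)
      } else {
        cds_start <- NA_integer_
        cds_end <- NA_integer_
      }
      gene_rows[[gi]] <- data.table(
        gene_id = gene_id, chrom = chrom, strand = strand,
        tx_start = tx_start, tx_end = tx_end,
        cds_start = cds_start, cds_end = cds_end)
      exon_rows[[gi]] <- data.table(gene_id = gene_id, chrom = chrom,
                                    strand = strand, start = ex_start,
                                    end = ex_end)
    }
  }
  genes <- as.data.frame(rbindlist(gene_rows))
  ex <- rbindlist(exon_rows)
  exons <- GRanges(ex$chrom, IRanges(ex$start, ex$end), strand = ex$strand)
  mcols(exons)$gene_id <- ex$gene_id

  # labelled repeats, uniform placement
  rep_classes <- c("SINE", "LINE", "LTR", "Simple_repeat")
  reps <- list()
  for (chrom in chroms) {
    w <- sample(100:600, cfg$n_repeats, replace = TRUE)
    st <- sample.int(cfg$chrom_len - max(w), cfg$n_repeats)
    g <- GRanges(chrom, IRanges(st, st + w - 1L))
    mcols(g)$repeat_class <- sample(rep_classes, cfg$n_repeats,
                                    replace = TRUE)
    reps[[chrom]] <- g
  }
  repeats <- unlist(GRangesList(reps), use.names = FALSE)

  elements <- derive_elements_all(genes, exons,
                                  promoter_len = cfg$promoter_len,
                                  chrom_sizes = chrom_sizes)
  bundle <- list(genes = genes, exons = exons, elements = elements,
                 cpg_islands = cpg_islands, repeats = repeats,
                 chrom_sizes = chrom_sizes,
                 promoter_len = cfg$promoter_len)
  class(bundle) <- "annotation_bundle"
  list(genome = genome, bundle = bundle)
}

#' Simulate paired region counts with planted differential regions
#'
#' The count-level core shared by the methylome simulator and the
#' statistical validation runs: for `n` candidate regions, paired counts are
#' drawn from the configured noise model with equal normalised rates except
#' at planted regions, where the case/control expected rates differ by
#' `fold` (split symmetrically: case rate x sqrt(fold), control rate /
#' sqrt(fold) for uptrend; mirrored for downtrend).
#'
#' @param n Number of candidate regions.
#' @param mean_count Expected count at the reference library size.
#' @param planted_idx Integer indices of planted regions (may be empty).
#' @param fold Planted fold (> 1).
#' @param trend Character vector (length of `planted_idx`) of
#'   `"uptrend"`/`"downtrend"`.
#' @param lib_case,lib_control Library sizes.
#' @param lib_ref Reference library size that `mean_count` refers to.
#' @param noise,dispersion Noise model (see [sim_config()]).
#' @return data.frame with `count_case`, `count_control`, `is_planted`,
#'   `trend` (planted trend or `NA`).
#' @export
simulate_pair_counts <- function(n, mean_count, planted_idx = integer(0),
                                 fold = 4, trend = NULL,
                                 lib_case = 1e6, lib_control = 1e6,
                                 lib_ref = 1e6, noise = "poisson",
                                 dispersion = 0.1) {
  mu_case <- rep(mean_count, n)
  mu_control <- rep(mean_count, n)
  if (length(planted_idx)) {
    if (is.null(trend)) trend <- rep("uptrend", length(planted_idx))
    up <- trend == "uptrend"
    mu_case[planted_idx[up]] <- mean_count * sqrt(fold)
    mu_control[planted_idx[up]] <- mean_count / sqrt(fold)
    mu_case[planted_idx[!up]] <- mean_count / sqrt(fold)
    mu_control[planted_idx[!up]] <- mean_count * sqrt(fold)
  }
  cc <- .draw_counts(mu_case * lib_case / lib_ref, noise, dispersion)
  cn <- .draw_counts(mu_control * lib_control / lib_ref, noise, dispersion)
  out <- data.frame(count_case = cc, count_control = cn,
                    is_planted = FALSE, trend = NA_character_)
  if (length(planted_idx)) {
    out$is_planted[planted_idx] <- TRUE
    out$trend[planted_idx] <- trend
  }
  out
}

.draw_pair_libs <- function(lib_size) {
  # log-uniform within 2x of each other
  exp(log(lib_size) + runif(2, -log(2) / 2, log(2) / 2))
}

#' Simulate MeDIP-seq peak sets and reads for all pairs
#'
#' Per pair, a shared peak scaffold covering about `peak_fraction` of the
#' genome is laid out in disjoint slots; planted DMRs get a `dmr_fold`
#' difference in expected normalised counts with the configured trend mix;
#' per-region counts follow the noise model scaled by each sample's library
#' size; reads of `read_len` bp are placed uniformly within their region.
#'
#' @param cfg A [sim_config()].
#' @param bundle Annotation bundle from [simulate_genome()] (only
#'   `chrom_sizes` is used).
#' @return List with per-pair entries (named `pair01`, ...), each holding
#'   `case`/`control` lists (`sample_id`, `peaks`, `reads`, `library_size`),
#'   plus `truth`: data.frame of planted DMRs (pair_id, chrom, start, end,
#'   trend, fold) and `pairs`: the pair manifest.
#' @export
simulate_methylome <- function(cfg, bundle) {
  set.seed(cfg$seed + 1L)
  chrom_sizes <- bundle$chrom_sizes
  genome_len <- sum(as.numeric(chrom_sizes))
  mean_w <- mean(cfg$peak_width_range)
  n_peaks <- max(1L, round(cfg$peak_fraction * genome_len / mean_w))
  slot_w <- max(cfg$peak_width_range) + 200L

  pairs <- data.frame(
    pair_id = sprintf("pair%02d", seq_len(cfg$n_pairs)),
    case_id = sprintf("case%02d", seq_len(cfg$n_pairs)),
    control_id = sprintf("ctrl%02d", seq_len(cfg$n_pairs))
  )
  out <- list()
  truth <- list()
  for (i in seq_len(cfg$n_pairs)) {
    pid <- pairs$pair_id[i]
    # disjoint peak scaffold: pick slots genome-wide, offset inside slot
    slots_per_chrom <- floor(chrom_sizes / slot_w)
    slot_tab <- data.table(
      chrom = rep(names(chrom_sizes), slots_per_chrom),
      slot = unlist(lapply(slots_per_chrom, seq_len)))
    pick <- slot_tab[sort(sample.int(nrow(slot_tab),
                                     min(n_peaks, nrow(slot_tab)))), ]
    w <- sample(cfg$peak_width_range[1]:cfg$peak_width_range[2],
                nrow(pick), replace = TRUE)
    off <- sample.int(200L, nrow(pick), replace = TRUE)
    st <- (pick$slot - 1L) * slot_w + off
    peaks <- GRanges(pick$chrom, IRanges(st, st + w - 1L))

    n_dmr <- min(cfg$dmr_count, length(peaks))
    planted_idx <- sort(sample.int(length(peaks), n_dmr))
    n_up <- round(n_dmr * cfg$dmr_uptrend_frac)
    trend <- sample(rep(c("uptrend", "downtrend"),
                        c(n_up, n_dmr - n_up)))
    libs <- .draw_pair_libs(cfg$lib_size)
    counts <- simulate_pair_counts(
      length(peaks), cfg$peak_mean_count, planted_idx, cfg$dmr_fold,
      trend, lib_case = libs[1], lib_control = libs[2],
      lib_ref = cfg$lib_size, noise = cfg$noise,
      dispersion = cfg$dispersion)

    place_reads <- function(n_per_region) {
      idx <- rep(seq_along(peaks), n_per_region)
      max_off <- pmax(width(peaks)[idx] - cfg$read_len, 0L)
      starts <- start(peaks)[idx] + floor(runif(length(idx)) * (max_off + 1))
      GRanges(seqnames(peaks)[idx],
              IRanges(starts, width = cfg$read_len))
    }
    out[[pid]] <- list(
      case = list(sample_id = pairs$case_id[i], peaks = peaks,
                  reads = place_reads(counts$count_case),
                  library_size = libs[1]),
      control = list(sample_id = pairs$control_id[i], peaks = peaks,
                     reads = place_reads(counts$count_control),
                     library_size = libs[2])
    )
    if (n_dmr > 0L) {
      truth[[pid]] <- data.table(
        pair_id = pid,
        chrom = as.character(seqnames(peaks))[planted_idx],
        start = start(peaks)[planted_idx],
        end = end(peaks)[planted_idx],
        trend = trend, fold = cfg$dmr_fold)
    }
  }
  list(samples = out,
       truth = as.data.frame(rbindlist(truth)),
       pairs = pairs)
}

#' Simulate a gene-count matrix with planted DEGs
#'
#' Baseline gene abundances are log-normal; planted DEGs have the case-side
#' expected rate multiplied (up) or divided (down) by `2^deg_log2_fold` in
#' their affected pairs; counts follow the configured noise model scaled by
#' per-sample library sizes.
#'
#' @param cfg A [sim_config()].
#' @param gene_ids Character vector of gene ids.
#' @param gene_lengths Optional named lengths (bp); drawn uniform 500-5000
#'   when missing.
#' @return List with `counts` (genes x samples integer matrix),
#'   `gene_lengths`, `lib_sizes` (named, actual simulated totals are the
#'   reference sizes used for scaling), `pairs` and `truth` (gene_id,
#'   direction, log2_fold, pairs).
#' @export
simulate_expression <- function(cfg, gene_ids, gene_lengths = NULL) {
  set.seed(cfg$seed + 2L)
  n <- length(gene_ids)
  if (is.null(gene_lengths)) {
    gene_lengths <- setNames(sample(500:5000, n, replace = TRUE), gene_ids)
  }
  pairs <- data.frame(
    pair_id = sprintf("pair%02d", seq_len(cfg$n_pairs)),
    case_id = sprintf("case%02d", seq_len(cfg$n_pairs)),
    control_id = sprintf("ctrl%02d", seq_len(cfg$n_pairs))
  )
  mu <- rlnorm(n, meanlog = log(cfg$expr_mean_count) -
                 cfg$expr_sdlog^2 / 2, sdlog = cfg$expr_sdlog)
  names(mu) <- gene_ids
  n_deg <- min(cfg$deg_count, n)
  deg_idx <- sort(sample.int(n, n_deg))
  direction <- sample(c("up", "down"), n_deg, replace = TRUE)
  affected <- cfg$deg_pairs_affected
  if (is.null(affected)) affected <- pairs$pair_id
  eff <- 2^cfg$deg_log2_fold

  samples <- c(rbind(pairs$case_id, pairs$control_id))
  counts <- matrix(0L, n, length(samples),
                   dimnames = list(gene_ids, samples))
  lib_sizes <- numeric(length(samples))
  names(lib_sizes) <- samples
  for (i in seq_len(cfg$n_pairs)) {
    libs <- .draw_pair_libs(cfg$lib_size)
    mu_case <- mu
    mu_control <- mu
    if (pairs$pair_id[i] %in% affected && n_deg > 0L) {
      up <- direction == "up"
      mu_case[deg_idx[up]] <- mu[deg_idx[up]] * sqrt(eff)
      mu_control[deg_idx[up]] <- mu[deg_idx[up]] / sqrt(eff)
      mu_case[deg_idx[!up]] <- mu[deg_idx[!up]] / sqrt(eff)
      mu_control[deg_idx[!up]] <- mu[deg_idx[!up]] * sqrt(eff)
    }
    counts[, pairs$case_id[i]] <-
      .draw_counts(mu_case * libs[1] / cfg$lib_size, cfg$noise,
                   cfg$dispersion)
    counts[, pairs$control_id[i]] <-
      .draw_counts(mu_control * libs[2] / cfg$lib_size, cfg$noise,
                   cfg$dispersion)
    lib_sizes[pairs$case_id[i]] <- libs[1]
    lib_sizes[pairs$control_id[i]] <- libs[2]
  }
  truth <- if (n_deg > 0L) {
    data.frame(gene_id = gene_ids[deg_idx], direction = direction,
               log2_fold = cfg$deg_log2_fold,
               pairs = paste(affected, collapse = ";"))
  } else {
    data.frame(gene_id = character(0), direction = character(0),
               log2_fold = numeric(0), pairs = character(0))
  }
  list(counts = counts, gene_lengths = gene_lengths,
       lib_sizes = lib_sizes, pairs = pairs, truth = truth)
}

#' Simulate a term collection with planted enrichment
#'
#' Random term memberships over the gene set; the first `planted_terms`
#' terms draw their members with sampling weight `term_enrich_ratio` on the
#' `selected` genes, so they are genuinely enriched for that set. A ratio of
#' 1 plants nothing.
#'
#' @param cfg A [sim_config()].
#' @param genes Character vector of all gene ids (the universe).
#' @param selected Character vector of genes the planted terms oversample.
#' @return List with `terms` (data.frame term_id, category, gene_id,
#'   term_name) and `truth` (planted term ids; empty when
#'   `term_enrich_ratio == 1` or `selected` is empty).
#' @export
simulate_terms <- function(cfg, genes, selected = character(0)) {
  set.seed(cfg$seed + 3L)
  n_planted <- if (cfg$term_enrich_ratio > 1 && length(selected))
    min(cfg$planted_terms, cfg$n_terms) else 0L
  cats <- sample(c("C", "F", "P", "pathway"), cfg$n_terms, replace = TRUE)
  rows <- list()
  for (t in seq_len(cfg$n_terms)) {
    size <- sample(cfg$term_size_range[1]:cfg$term_size_range[2], 1L)
    size <- min(size, length(genes))
    w <- rep(1, length(genes))
    if (t <= n_planted) {
      w[genes %in% selected] <- cfg$term_enrich_ratio
    }
    members <- sample(genes, size, prob = w)
    rows[[t]] <- data.table(
      term_id = sprintf("TERM:%04d", t), category = cats[t],
      gene_id = members, term_name = sprintf("simulated term %d", t))
  }
  list(terms = as.data.frame(rbindlist(rows)),
       truth = if (n_planted > 0L) sprintf("TERM:%04d", seq_len(n_planted))
               else character(0))
}
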