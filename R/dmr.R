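# Candidate DMR construction and testing for one case/control sample pair,
# plus per-element hyper/hypo gene classification.

#' Build candidate DMRs for a sample pair
#'
#' The peak calls of the two samples are merged into their base-union; each
#' merged region is a candidate differentially methylated region. The number
#' of reads from each sample overlapping each candidate by at least one base
#' is recorded together with the library sizes.
#'
#' @param case_peaks,control_peaks `GRanges` of MACS-style peak calls.
#' @param case_reads,control_reads `GRanges` of aligned read intervals.
#' @param lib_case,lib_control Total uniquely mapped read counts for the two
#'   samples (must be positive).
#' @return data.frame with `chrom`, `start`, `end` (1-based closed), `width`,
#'   `count_case`, `count_control`, `lib_case`, `lib_control`. Candidate
#'   regions are disjoint. Empty peak sets yield an empty frame with a
#'   warning.
#' @export
build_candidates <- function(case_peaks, control_peaks, case_reads,
                             control_reads, lib_case, lib_control) {
  stopifnot(lib_case > 0, lib_control > 0)
  regions <- merge_intervals(c(granges(case_peaks), granges(control_peaks)))
  if (length(regions) == 0L) {
    warning("no peaks in either sample; no candidate DMRs")
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), width = integer(0),
                      count_case = integer(0), count_control = integer(0),
                      lib_case = numeric(0), lib_control = numeric(0)))
  }
  data.frame(
    chrom = as.character(seqnames(regions)),
    start = start(regions),
    end = end(regions),
    width = width(regions),
    count_case = countOverlaps(regions, case_reads, ignore.strand = TRUE),
    count_control = countOverlaps(regions, control_reads,
                                  ignore.strand = TRUE),
    lib_case = lib_case,
    lib_control = lib_control
  )
}

#' Pearson chi-square test of a region count against library margins
#'
#' Tests each candidate's 2x2 contingency table
#' `[[count_case, lib_case - count_case], [count_control, lib_control -
#' count_control]]` with the Pearson chi-square statistic on 1 degree of
#' freedom and no continuity correction; the p-value is the upper tail of the
#' chi-square distribution. Vectorised over candidates.
#'
#' @param count_case,count_control Region read counts.
#' @param lib_case,lib_control Library sizes (recycled).
#' @return List with numeric vectors `stat` and `p_value`. Regions with zero
#'   counts in both samples get stat 0 and p 1.
#' @export
chi_square_test <- function(count_case, count_control, lib_case,
                            lib_control) {
  a <- as.numeric(count_case)
  b <- as.numeric(lib_case) - a
  c_ <- as.numeric(count_control)
  d <- as.numeric(lib_control) - c_
  n <- a + b + c_ + d
  stat <- n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  stat[a + c_ == 0] <- 0   # untestable: no reads in either sample
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  list(stat = stat, p_value = p)
}

#' Test candidate DMRs and call true DMRs
#'
#' Each candidate is chi-square tested, FDR-adjusted across all candidates of
#' the pair, and filtered on fold change. The fold is the ratio of
#' library-size-normalised read rates, folded to be >= 1; when one count is
#' zero a pseudocount is added to both counts (for the fold only, never for
#' the test). A candidate is a true DMR iff `p <= p_max`, `q <= p_max` and
#' `fold > fold_min`. Trend is `uptrend` when the case (epileptic) sample has
#' the higher normalised rate and `downtrend` when the control sample does.
#'
#' @param candidates data.frame from [build_candidates()].
#' @param p_max Significance threshold applied to both raw and adjusted p
#'   (default 0.01).
#' @param fold_min Fold threshold, strict `>` (default 2).
#' @param fdr_method `p.adjust` method for the q-value (default `"BH"`;
#'   `"BY"` available).
#' @param pseudocount Added to both counts when either is zero, for the fold
#'   computation only (default 0.5).
#' @return The input frame with columns `chi2_stat`, `p_value`, `q_value`,
#'   `fold`, `trend` (`uptrend`/`downtrend`/`none`), `is_true_dmr` appended.
#' @export
call_true_dmrs <- function(candidates, p_max = 0.01, fold_min = 2.0,
                           fdr_method = c("BH", "BY"), pseudocount = 0.5) {
  fdr_method <- match.arg(fdr_method)
  out <- candidates
  ct <- chi_square_test(out$count_case, out$count_control,
                        out$lib_case, out$lib_control)
  out$chi2_stat <- ct$stat
  out$p_value <- ct$p_value
  out$q_value <- p.adjust(out$p_value, method = fdr_method)

  cc <- as.numeric(out$count_case)
  cn <- as.numeric(out$count_control)
  zero <- cc == 0 | cn == 0
  cc[zero] <- cc[zero] + pseudocount
  cn[zero] <- cn[zero] + pseudocount
  r <- (cc / out$lib_case) / (cn / out$lib_control)
  out$fold <- pmax(r, 1 / r)
  out$trend <- ifelse(r > 1, "uptrend", ifelse(r < 1, "downtrend", "none"))
  untestable <- out$count_case + out$count_control == 0
  out$trend[untestable] <- "none"
  out$is_true_dmr <- !untestable &
    out$p_value <= p_max & out$q_value <= p_max & out$fold > fold_min
  out
}

#' GRanges view of a DMR result table
#'
#' @param dmrs Output of [call_true_dmrs()].
#' @param true_only Keep only true DMRs (default `TRUE`).
#' @return `GRanges` with `trend` and the test statistics as metadata.
#' @export
dmrs_as_granges <- function(dmrs, true_only = TRUE) {
  if (true_only) dmrs <- dmrs[dmrs$is_true_dmr, , drop = FALSE]
  gr <- GRanges(dmrs$chrom, IRanges(dmrs$start, dmrs$end))
  mcols(gr) <- dmrs[, intersect(c("count_case", "count_control", "chi2_stat",
                                  "p_value", "q_value", "fold", "trend",
                                  "is_true_dmr"), names(dmrs)),
                    drop = FALSE]
  gr
}

#' Classify genes per element from overlapping DMR trends
#'
#' For each (gene, element class) pair: `hyper` if the element overlaps only
#' uptrend true DMRs, `hypo` if only downtrend, `mixed` if both, and
#' `unmethylated` if it overlaps none. The supporting DMR indices are listed.
#'
#' @param dmrs Output of [call_true_dmrs()] (only rows with
#'   `is_true_dmr == TRUE` are used).
#' @param elements `GRanges` of gene elements with `gene_id` and `element`
#'   metadata (see [derive_elements_all()]).
#' @return data.frame with `gene_id`, `element`, `status`, `n_up`, `n_down`,
#'   `dmr_ids` (comma-separated row indices into the true-DMR subset's
#'   original `dmrs` rows). Every (gene, element) present in `elements`
#'   appears exactly once.
#' @export
classify_dmgs <- function(dmrs, elements) {
  true_idx <- which(dmrs$is_true_dmr)
  row_key <- paste(mcols(elements)$gene_id, mcols(elements)$element_type, sep = "\r")
  base <- data.table(gene_id = mcols(elements)$gene_id,
                     element = mcols(elements)$element_type, row_key = row_key)
  base <- unique(base, by = "row_key")
  if (length(true_idx)) {
    dgr <- GRanges(dmrs$chrom[true_idx],
                   IRanges(dmrs$start[true_idx], dmrs$end[true_idx]))
    trend <- dmrs$trend[true_idx]
    hits <- findOverlaps(elements, dgr, ignore.strand = TRUE)
    hit_dt <- data.table(row_key = row_key[queryHits(hits)],
                         dmr = true_idx[subjectHits(hits)],
                         trend = trend[subjectHits(hits)])
    agg <- hit_dt[, list(n_up = sum(trend == "uptrend"),
                         n_down = sum(trend == "downtrend"),
                         dmr_ids = paste(sort(unique(dmr)), collapse = ",")),
                  by = "row_key"]
    res <- merge(base, agg, by = "row_key", all.x = TRUE)
  } else {
    res <- base
    res$n_up <- NA_integer_
    res$n_down <- NA_integer_
    res$dmr_ids <- NA_character_
  }
  res[is.na(res$n_up), `:=`(n_up = 0L, n_down = 0L, dmr_ids = "")]
  res$status <- ifelse(res$n_up > 0 & res$n_down > 0, "mixed",
                ifelse(res$n_up > 0, "hyper",
                ifelse(res$n_down > 0, "hypo", "unmethylated")))
  setorder(res, gene_id, element)
  as.data.frame(res[, c("gene_id", "element", "status", "n_up", "n_down",
                        "dmr_ids"), with = FALSE])
}

#' Summaries of true DMRs across pairs
#'
#' @param dmr_list Named list (by pair id) of [call_true_dmrs()] outputs.
#' @param dmg_list Optional named list (same pairs) of [classify_dmgs()]
#'   outputs, used for the per-chromosome DMG presence matrix.
#' @param elements Optional `GRanges` of elements (needed to locate DMGs on
#'   chromosomes when `dmg_list` is given).
#' @return List with `per_pair` (pair_id, n_candidates, n_true_dmrs,
#'   covered_bp, n_uptrend, n_downtrend) and, when DMGs are supplied,
#'   `dmg_by_chrom` (pairs x chromosomes count of distinct methylated genes).
#' @export
summarize_dmrs <- function(dmr_list, dmg_list = NULL, elements = NULL) {
  per_pair <- rbindlist(lapply(names(dmr_list), function(pid) {
    d <- dmr_list[[pid]]
    t <- d[d$is_true_dmr, , drop = FALSE]
    data.table(pair_id = pid,
               n_candidates = nrow(d),
               n_true_dmrs = nrow(t),
               covered_bp = sum(as.numeric(t$end - t$start + 1L)),
               n_uptrend = sum(t$trend == "uptrend"),
               n_downtrend = sum(t$trend == "downtrend"))
  }))
  out <- list(per_pair = as.data.frame(per_pair))
  if (!is.null(dmg_list) && !is.null(elements)) {
    gene_chrom <- tapply(as.character(seqnames(elements)),
                         mcols(elements)$gene_id, function(x) x[1])
    chroms <- sort(unique(unname(gene_chrom)))
    mat <- matrix(0L, nrow = length(dmg_list), ncol = length(chroms),
                  dimnames = list(names(dmg_list), chroms))
    for (pid in names(dmg_list)) {
      dmg <- dmg_list[[pid]]
      meth <- unique(dmg$gene_id[dmg$status != "unmethylated"])
      if (length(meth)) {
        tab <- table(gene_chrom[meth])
        mat[pid, names(tab)] <- as.integer(tab)
      }
    }
    out$dmg_by_chrom <- mat
  }
  out
}
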