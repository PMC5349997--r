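# Integration of per-element methylation status with per-pair expression
# change: the distribution of log2 RPKM ratios stratified by hyper / hypo /
# unmethylated status in each gene element.

#' Join methylation status with expression change per (gene, pair, element)
#'
#' For every gene element classified in a pair, attaches that pair's log2
#' RPKM ratio (case/control). Genes with zero RPKM on either side carry no
#' finite ratio; they are kept with `log2_rpkm_ratio = NA` and flagged
#' `excluded`, so ratio distributions can omit them while conserving totals.
#'
#' @param dmg_list Named list (by pair id) of [classify_dmgs()] outputs.
#' @param deg_results Output of [call_pairwise_degs()] covering the same
#'   pairs.
#' @return data.frame with `gene_id`, `pair_id`, `element`, `meth_status`,
#'   `log2_rpkm_ratio`, `excluded`.
#' @export
integrate_meth_expr <- function(dmg_list, deg_results) {
  expr <- as.data.table(deg_results)[
    , c("gene_id", "pair_id", "rpkm_case", "rpkm_control"), with = FALSE]
  out <- rbindlist(lapply(names(dmg_list), function(pid) {
    dmg <- as.data.table(dmg_list[[pid]])
    e <- expr[expr$pair_id == pid, ]
    m <- merge(dmg[, c("gene_id", "element", "status"), with = FALSE],
               e[, c("gene_id", "rpkm_case", "rpkm_control"), with = FALSE],
               by = "gene_id")
    m$pair_id <- pid
    m
  }))
  if (nrow(out) == 0L) {
    return(data.frame(gene_id = character(0), pair_id = character(0),
                      element = character(0), meth_status = character(0),
                      log2_rpkm_ratio = numeric(0), excluded = logical(0)))
  }
  out$excluded <- out$rpkm_case <= 0 | out$rpkm_control <= 0
  out$log2_rpkm_ratio <- ifelse(out$excluded, NA_real_,
                                log2(out$rpkm_case / out$rpkm_control))
  setorder(out, pair_id, gene_id, element)
  data.table::setnames(out, "status", "meth_status")
  as.data.frame(out[, c("gene_id", "pair_id", "element", "meth_status",
                        "log2_rpkm_ratio", "excluded"), with = FALSE])
}

#' Binned distribution of log2 RPKM ratios per element and status
#'
#' Ratios are binned in `bin_width` steps over `range`; values outside the
#' range clamp to the edge bins. Fractions are per (element, status) stratum
#' and sum to 1 within every non-empty stratum. Records without a finite
#' ratio are excluded (their count is reported in the `n_excluded`
#' attribute).
#'
#' @param records Output of [integrate_meth_expr()].
#' @param bin_width Bin width in log2 units (default 1).
#' @param range Two-element numeric range (default c(-10, 10)).
#' @return data.frame with `element`, `meth_status`, `bin_lo`, `bin_hi`,
#'   `count`, `fraction`.
#' @export
ratio_distribution <- function(records, bin_width = 1.0,
                               range = c(-10, 10)) {
  edges <- seq(range[1], range[2], by = bin_width)
  n_bins <- length(edges) - 1L
  dt <- as.data.table(records)
  excluded <- dt[dt$excluded | !is.finite(dt$log2_rpkm_ratio), ]
  dt <- dt[!dt$excluded & is.finite(dt$log2_rpkm_ratio), ]
  strata <- unique(as.data.table(records)[, c("element", "meth_status"),
                                          with = FALSE])
  grid <- strata[rep(seq_len(nrow(strata)), each = n_bins), ]
  grid$bin_lo <- rep(edges[-length(edges)], nrow(strata))
  grid$bin_hi <- rep(edges[-1], nrow(strata))
  if (nrow(dt)) {
    idx <- findInterval(dt$log2_rpkm_ratio, edges, rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1L), n_bins)   # clamp out-of-range to edge bins
    dt$bin <- idx
    cnt <- dt[, list(count = .N), by = c("element", "meth_status", "bin")]
    cnt$bin_lo <- edges[cnt$bin]
    grid <- merge(grid, cnt[, c("element", "meth_status", "bin_lo", "count"),
                            with = FALSE],
                  by = c("element", "meth_status", "bin_lo"), all.x = TRUE)
  } else {
    grid$count <- NA_integer_
  }
  grid$count[is.na(grid$count)] <- 0L
  grid[, total := sum(count), by = c("element", "meth_status")]
  grid$fraction <- ifelse(grid$total > 0, grid$count / grid$total, NA_real_)
  setorder(grid, element, meth_status, bin_lo)
  out <- as.data.frame(grid[, c("element", "meth_status", "bin_lo", "bin_hi",
                                "count", "fraction"), with = FALSE])
  attr(out, "n_excluded") <- nrow(excluded)
  out
}
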