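# RPKM, the Audic-Claverie exact count test, Benjamini-Yekutieli FDR,
# per-pair DEG calling, cross-pair aggregation and expression-pattern
# clustering.

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = 1e9 * count / (library_size * gene_length_bp)`.
#'
#' @param count Read count(s).
#' @param gene_length_bp Gene model length(s) in bp.
#' @param library_size Reads uniquely mapped to genes in the sample.
#' @return Numeric RPKM value(s).
#' @export
rpkm <- function(count, gene_length_bp, library_size) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (any(gene_length_bp <= 0)) stop("gene_length_bp must be positive")
  1e9 * count / (library_size * gene_length_bp)
}

#' Audic-Claverie exact test for two-library count comparison
#'
#' Conditional on the count `x` observed in the first library, the null
#' distribution of the count `y` in the second library is
#' `P(y | x) = (N2/N1)^y * (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`,
#' which is the negative binomial with size `x + 1` and success probability
#' `N1/(N1+N2)`; tails are evaluated through that identity in a numerically
#' stable way. The two-sided p-value is `min(1, 2*min(P(Y<=y), P(Y>=y)))`.
#' Vectorised.
#'
#' @param x Count in the first (case) library.
#' @param y Count in the second (control) library.
#' @param n1,n2 Library sizes (positive).
#' @return Two-sided p-value(s) in (0, 1].
#' @export
ac_test <- function(x, y, n1, n2) {
  stopifnot(all(x >= 0), all(y >= 0), all(n1 > 0), all(n2 > 0))
  prob <- n1 / (n1 + n2)
  lower <- stats::pnbinom(y, size = x + 1, prob = prob)
  upper <- ifelse(y == 0, 1,
                  stats::pnbinom(y - 1, size = x + 1, prob = prob,
                                 lower.tail = FALSE))
  pmin(1, 2 * pmin(lower, upper))
}

#' Benjamini-Yekutieli (2001) FDR adjustment
#'
#' Step-up adjustment with the harmonic-sum inflation factor
#' `c(m) = sum(1/i, i = 1..m)`, valid under arbitrary dependence:
#' `adj_(i) = min_{j >= i} min(1, m c(m) p_(j) / j)` on the sorted p-values,
#' mapped back to input order.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
by_fdr <- function(p) {
  p.adjust(p, method = "BY")
}

#' Call differentially expressed genes per sample pair
#'
#' For each pair, every gene with a nonzero count in at least one of the two
#' samples is tested with the exact count test (or a 2x2 chi-square via
#' `test`); p-values are BY-adjusted within the pair (m = genes tested in
#' that pair); a gene is called when `fdr <= fdr_max` and its RPKM ratio
#' (case/control) exceeds `fold_min` in either direction (strict `>`), with
#' direction from the ratio. Zero-RPKM sides use a count pseudocount for the
#' ratio only.
#'
#' @param counts Integer matrix, genes x samples.
#' @param gene_lengths Named numeric vector of gene lengths (bp).
#' @param lib_sizes Named numeric vector of per-sample library sizes; by
#'   default the column sums of `counts`.
#' @param pairs data.frame with `pair_id`, `case_id`, `control_id` (sample
#'   column names).
#' @param fdr_max BY-FDR threshold (default 0.001).
#' @param fold_min Fold threshold, strict `>` (default 2).
#' @param test `"exact"` (Audic-Claverie, default) or `"chisq"` (2x2
#'   chi-square against library margins).
#' @param pseudocount Count pseudocount used only when a count is zero, for
#'   the RPKM ratio (default 0.5).
#' @return data.frame with one row per tested (gene, pair): `gene_id`,
#'   `pair_id`, `count_case`, `count_control`, `rpkm_case`, `rpkm_control`,
#'   `log2_ratio`, `p_value`, `fdr`, `call` (`up`/`down`/`none`).
#' @export
call_pairwise_degs <- function(counts, gene_lengths, lib_sizes = NULL,
                               pairs, fdr_max = 0.001, fold_min = 2.0,
                               test = c("exact", "chisq"),
                               pseudocount = 0.5) {
  test <- match.arg(test)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  stopifnot(all(rownames(counts) %in% names(gene_lengths)),
            all(c(pairs$case_id, pairs$control_id) %in% colnames(counts)))
  len <- gene_lengths[rownames(counts)]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    case <- pairs$case_id[i]
    ctrl <- pairs$control_id[i]
    x <- counts[, case]
    y <- counts[, ctrl]
    testable <- x + y > 0
    x <- x[testable]; y <- y[testable]; l <- len[testable]
    n1 <- lib_sizes[[case]]; n2 <- lib_sizes[[ctrl]]
    p <- if (test == "exact") ac_test(x, y, n1, n2) else
      chi_square_test(x, y, n1, n2)$p_value
    fdr <- by_fdr(p)
    rc <- rpkm(x, l, n1)
    rk <- rpkm(y, l, n2)
    xx <- ifelse(x == 0, x + pseudocount, x)
    yy <- ifelse(y == 0, y + pseudocount, y)
    ratio <- (xx / n1) / (yy / n2)
    pass <- fdr <= fdr_max & pmax(ratio, 1 / ratio) > fold_min
    data.frame(
      gene_id = rownames(counts)[testable],
      pair_id = pairs$pair_id[i],
      count_case = x, count_control = y,
      rpkm_case = rc, rpkm_control = rk,
      log2_ratio = log2(ratio),
      p_value = p, fdr = fdr,
      call = ifelse(!pass, "none", ifelse(ratio > 1, "up", "down")),
      row.names = NULL
    )
  })
  do.call(rbind, res)
}

#' Aggregate per-pair DEG calls across pairs
#'
#' @param results Output of [call_pairwise_degs()] over all pairs.
#' @param k_min Minimum number of pairs in which a gene must be called
#'   (either direction) to be retained (default 5).
#' @return List with `table` (data.frame: `gene_id`, `n_pairs_called`,
#'   `n_up`, `n_down`, `n_consistent` = max(n_up, n_down), filtered to
#'   `n_pairs_called >= k_min`) and `ternary` (genes x pairs matrix of +1
#'   up / -1 down / 0 none over ALL genes ever called).
#' @export
aggregate_across_pairs <- function(results, k_min = 5L) {
  dt <- as.data.table(results)
  called <- dt[dt$call != "none", ]
  pair_ids <- sort(unique(dt$pair_id))
  if (nrow(called) == 0L) {
    return(list(table = data.frame(gene_id = character(0),
                                   n_pairs_called = integer(0),
                                   n_up = integer(0), n_down = integer(0),
                                   n_consistent = integer(0)),
                ternary = matrix(0L, 0, length(pair_ids),
                                 dimnames = list(NULL, pair_ids))))
  }
  agg <- called[, list(n_pairs_called = .N,
                       n_up = sum(call == "up"),
                       n_down = sum(call == "down")),
                by = "gene_id"]
  agg$n_consistent <- pmax(agg$n_up, agg$n_down)
  setorder(agg, -n_pairs_called, gene_id)
  genes <- agg$gene_id
  tern <- matrix(0L, length(genes), length(pair_ids),
                 dimnames = list(genes, pair_ids))
  tern[cbind(match(called$gene_id, genes),
             match(called$pair_id, pair_ids))] <-
    ifelse(called$call == "up", 1L, -1L)
  tab <- as.data.frame(agg[agg$n_pairs_called >= k_min, ])
  list(table = tab, ternary = tern)
}

#' Annotate aggregated DEGs against a reference gene list
#'
#' Exact, case-sensitive identifier matching against an externally supplied
#' gene list (for example a disease-gene catalogue).
#'
#' @param aggregated The `table` element of [aggregate_across_pairs()].
#' @param reference Character vector of reference gene ids.
#' @return The input with a logical `in_reference` column; attribute
#'   `n_in_reference` carries the overlap size.
#' @export
intersect_gene_list <- function(aggregated, reference) {
  out <- aggregated
  out$in_reference <- out$gene_id %in% reference
  attr(out, "n_in_reference") <- sum(out$in_reference)
  out
}

#' Hierarchically cluster DEG expression patterns
#'
#' Agglomerative clustering of the gene rows of the ternary call matrix under
#' Euclidean distance (average linkage by default), for heatmap rendering.
#'
#' @param ternary Numeric matrix, genes x pairs (+1/-1/0).
#' @param linkage Linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return List with `merge`, `height`, `order` (leaf order), `labels`,
#'   `linkage`, `metric`, and the underlying `hclust` object.
#' @export
cluster_degs <- function(ternary, linkage = "average") {
  stopifnot(nrow(ternary) >= 2L)
  hc <- hclust(dist(ternary, method = "euclidean"), method = linkage)
  list(merge = hc$merge, height = hc$height, order = hc$order,
       labels = rownames(ternary), linkage = linkage,
       metric = "euclidean", hclust = hc)
}
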