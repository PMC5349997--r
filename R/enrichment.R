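# Hypergeometric term enrichment with Bonferroni correction, applied to DMG
# and DEG sets against GO-style and KEGG-style term collections.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X hypergeometric: drawing `n` genes from a universe of
#' `N` of which `K` belong to the term.
#'
#' @param k Selected genes in the term.
#' @param K Universe genes in the term.
#' @param n Selected genes in the universe.
#' @param N Universe size.
#' @return Upper-tail probability; `k = 0` gives 1.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(k < 0) || any(k > K) || any(k > n) || any(K > N) || any(n > N)) {
    stop("inconsistent hypergeometric arguments (need k <= K, k <= n, ",
         "K <= N, n <= N)")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term enrichment of a selected gene set
#'
#' One hypergeometric upper-tail test per term with at least one selected
#' member; Bonferroni correction with multiplier m = number of terms tested
#' within the term's category. GO categories (C/F/P) use `alpha_go` on the
#' corrected p, pathway terms use `alpha_kegg`. Selected genes outside the
#' universe are dropped (their count is reported).
#'
#' @param selected Character vector of selected gene ids.
#' @param terms data.frame with `term_id`, `category` (one of C, F, P,
#'   pathway), `gene_id`, optionally `term_name` (see [read_terms()]).
#' @param universe Character vector of background gene ids.
#' @param alpha_go Significance threshold for GO categories (default 0.01).
#' @param alpha_kegg Threshold for pathway terms (default 0.05).
#' @return data.frame sorted by `p_corrected` with `term_id`, `category`,
#'   `k`, `K`, `n`, `N`, `p`, `m`, `p_corrected`, `significant`; attribute
#'   `n_dropped` = selected genes outside the universe.
#' @export
enrich <- function(selected, terms, universe, alpha_go = 0.01,
                   alpha_kegg = 0.05) {
  universe <- unique(universe)
  selected <- unique(selected)
  dropped <- setdiff(selected, universe)
  if (length(dropped)) {
    message(length(dropped), " selected gene(s) outside the universe dropped")
  }
  selected <- intersect(selected, universe)
  dt <- unique(as.data.table(terms)[, c("term_id", "category", "gene_id"),
                                    with = FALSE])
  dt <- dt[dt$gene_id %in% universe, ]
  N <- length(universe)
  n <- length(selected)
  stats <- dt[, list(K = length(unique(gene_id)),
                     k = sum(unique(gene_id) %in% selected),
                     category = category[1]),
              by = "term_id"]
  stats <- stats[stats$k >= 1L, ]
  if (nrow(stats) == 0L) {
    out <- data.frame(term_id = character(0), category = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), m = integer(0),
                      p_corrected = numeric(0), significant = logical(0))
    attr(out, "n_dropped") <- length(dropped)
    return(out)
  }
  stats$n <- n
  stats$N <- N
  stats$p <- hypergeom_upper_tail(stats$k, stats$K, n, N)
  stats[, m := .N, by = "category"]
  stats$p_corrected <- pmin(1, stats$m * stats$p)
  alpha <- ifelse(stats$category == "pathway", alpha_kegg, alpha_go)
  stats$significant <- stats$p_corrected <= alpha
  setorder(stats, p_corrected, term_id)
  out <- as.data.frame(stats[, c("term_id", "category", "k", "K", "n", "N",
                                 "p", "m", "p_corrected", "significant"),
                             with = FALSE])
  attr(out, "n_dropped") <- length(dropped)
  out
}
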