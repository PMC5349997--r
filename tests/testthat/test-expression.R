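# RPKM, the exact count test, BY adjustment, DEG calling, aggregation and
# clustering.

test_that("rpkm implements 1e9 * count / (lib * length) and its scalings", {
  expect_equal(rpkm(1000, 2000, 1e7), 50)
  expect_equal(rpkm(0, 2000, 1e7), 0)
  # joint count/library rescaling leaves RPKM unchanged
  expect_equal(rpkm(2000, 2000, 2e7), rpkm(1000, 2000, 1e7))
  # linear in counts
  expect_equal(rpkm(c(1, 2, 4), 1000, 1e6), c(1, 2, 4))
  expect_error(rpkm(10, 1000, 0), "library_size")
})

test_that("exact count test matches direct tail summation", {
  # symmetric case: p capped at 1
  expect_equal(ac_test(7, 7, 1e6, 1e6), 1)
  expect_equal(ac_test(0, 0, 1e6, 1e6), 1)
  for (case in list(c(5, 25, 1e6, 1e6), c(0, 12, 1e6, 1e6),
                    c(40, 10, 2e6, 1e6), c(100, 180, 1e6, 1e6))) {
    got <- ac_test(case[1], case[2], case[3], case[4])
    want <- oracle_ac_test(case[1], case[2], case[3], case[4])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("BY adjustment matches the step-up formula with harmonic factor", {
  expect_equal(by_fdr(0.005), 0.005)
  # m = 3, c(3) = 1 + 1/2 + 1/3; all three adjust to 0.03 * 5.5 / 3 etc.
  got <- by_fdr(c(0.01, 0.02, 0.03))
  expect_equal(got, rep(0.055, 3), tolerance = 1e-12)
  set.seed(51)
  for (rep in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_equal(by_fdr(p), oracle_by_adjust(p), tolerance = 1e-12)
    # monotone non-decreasing in raw p
    o <- order(p)
    expect_true(all(diff(by_fdr(p)[o]) >= -1e-15))
    # BY dominates BH pointwise
    expect_true(all(by_fdr(p) >= p.adjust(p, "BH") - 1e-15))
  }
})

make_pair_counts <- function(n_genes, planted_idx, eff, mean_count = 200,
                             lib = 1e6) {
  mu <- rep(mean_count, n_genes)
  mu_case <- mu
  mu_ctrl <- mu
  mu_case[planted_idx] <- mu[planted_idx] * sqrt(eff)
  mu_ctrl[planted_idx] <- mu[planted_idx] / sqrt(eff)
  counts <- cbind(case01 = rpois(n_genes, mu_case),
                  ctrl01 = rpois(n_genes, mu_ctrl))
  rownames(counts) <- sprintf("g%04d", seq_len(n_genes))
  counts
}

test_that("pairwise DEG calls recover a planted 8-fold gene, with direction", {
  set.seed(52)
  counts <- make_pair_counts(2000, planted_idx = 1, eff = 8)
  lens <- setNames(rep(1000, 2000), rownames(counts))
  pairs <- data.frame(pair_id = "p1", case_id = "case01",
                      control_id = "ctrl01")
  res <- call_pairwise_degs(counts, lens, c(case01 = 1e6, ctrl01 = 1e6),
                            pairs)
  expect_equal(res$call[res$gene_id == "g0001"], "up")

  # identical counts and libraries: never called
  flat <- counts
  flat[, 2] <- flat[, 1]
  res_flat <- call_pairwise_degs(flat, lens, c(case01 = 1e6, ctrl01 = 1e6),
                                 pairs)
  expect_true(all(res_flat$call == "none"))

  # antisymmetry: swapping case and control flips the direction
  pairs_sw <- data.frame(pair_id = "p1", case_id = "ctrl01",
                         control_id = "case01")
  res_sw <- call_pairwise_degs(counts, lens, c(case01 = 1e6, ctrl01 = 1e6),
                               pairs_sw)
  expect_equal(res_sw$call[res_sw$gene_id == "g0001"], "down")
  # every gene called in both orientations flips its direction; the exact
  # conditional test is not perfectly swap-symmetric in p, so only the
  # direction is asserted
  merged <- merge(res[res$call != "none", ], res_sw[res_sw$call != "none", ],
                  by = "gene_id")
  if (nrow(merged)) {
    expect_true(all((merged$call.x == "up") == (merged$call.y == "down")))
  }
  expect_equal(merged$log2_ratio.x, -merged$log2_ratio.y, tolerance = 1e-12)
})

test_that("genes silent in both samples are excluded from testing and m", {
  counts <- cbind(case01 = c(10L, 0L, 5L), ctrl01 = c(12L, 0L, 7L))
  rownames(counts) <- c("a", "b", "c")
  lens <- c(a = 1000, b = 1000, c = 1000)
  pairs <- data.frame(pair_id = "p1", case_id = "case01",
                      control_id = "ctrl01")
  res <- call_pairwise_degs(counts, lens, c(case01 = 100, ctrl01 = 100),
                            pairs)
  expect_equal(sort(res$gene_id), c("a", "c"))
})

test_that("aggregation counts calls per gene and applies the k_min filter", {
  res <- data.frame(
    gene_id = c(rep("gA", 10), rep("gB", 10)),
    pair_id = rep(sprintf("p%02d", 1:10), 2),
    call = c(rep("up", 6), "down", rep("none", 3),
             rep("none", 9), "up")
  )
  agg <- aggregate_across_pairs(res, k_min = 5)
  expect_equal(agg$table$gene_id, "gA")
  expect_equal(agg$table$n_pairs_called, 7)
  expect_equal(agg$table$n_up, 6)
  expect_equal(agg$table$n_down, 1)
  expect_equal(agg$table$n_consistent, 6)
  # ternary matrix covers every called gene
  expect_equal(sort(rownames(agg$ternary)), c("gA", "gB"))
  expect_equal(unname(agg$ternary["gA", "p07"]), -1)
  expect_equal(unname(agg$ternary["gB", "p10"]), 1)
  expect_equal(sum(abs(agg$ternary)), 8)
  # a gene never called is excluded for any k_min >= 1
  expect_false("gC" %in% rownames(agg$ternary))
})

test_that("reference gene-list intersection is exact and case-sensitive", {
  agg <- data.frame(gene_id = c("SCN1A", "scn1a", "GABRA1"))
  out <- intersect_gene_list(agg, c("SCN1A", "KCNQ2"))
  expect_equal(out$in_reference, c(TRUE, FALSE, FALSE))
  expect_equal(attr(out, "n_in_reference"), 1)
  out0 <- intersect_gene_list(agg, character(0))
  expect_equal(attr(out0, "n_in_reference"), 0)
})

test_that("clustering merges identical rows at height zero", {
  m <- rbind(a = c(1, 1, 0), b = c(1, 1, 0), c = c(-1, -1, 0))
  cl <- cluster_degs(m)
  expect_equal(cl$height[1], 0)
  expect_equal(cl$metric, "euclidean")
  expect_setequal(cl$labels[cl$order], c("a", "b", "c"))
})

test_that("average-linkage merge heights match a brute-force agglomerator", {
  set.seed(53)
  for (rep in 1:3) {
    # continuous rows: distance ties (under which UPGMA merge order is
    # ambiguous) have probability zero
    m <- matrix(runif(20 * 5), 20, 5)
    rownames(m) <- sprintf("g%02d", 1:20)
    cl <- cluster_degs(m)
    expect_equal(cl$height, oracle_average_linkage_heights(m),
                 tolerance = 1e-10)
    expect_true(all(diff(cl$height) >= -1e-12))  # monotone heights
  }
  # ternary rows still cluster deterministically
  m3 <- matrix(sample(c(-1, 0, 1), 20 * 5, replace = TRUE), 20, 5)
  rownames(m3) <- sprintf("g%02d", 1:20)
  expect_identical(cluster_degs(m3)$merge, cluster_degs(m3)$merge)
})
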