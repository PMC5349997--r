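# Candidate DMR construction, chi-square testing, true-DMR calling and
# per-element gene classification.

test_that("candidate regions are the union of the pair's peaks", {
  case <- GRanges("chr1", IRanges(101, 300))
  ctrl <- GRanges("chr1", IRanges(251, 400))
  reads <- GRanges("chr1", IRanges(c(110, 120, 390), width = 49))
  cand <- build_candidates(case, ctrl, reads, reads[1:2], 1e6, 1e6)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$start, cand$end), c(101, 400))
  expect_equal(cand$count_case, 3)
  expect_equal(cand$count_control, 2)

  case2 <- GRanges("chr1", IRanges(c(1, 501), c(100, 600)))
  cand2 <- build_candidates(case2, GRanges(), reads[0], reads[0], 1e6, 1e6)
  expect_equal(nrow(cand2), 2)

  expect_warning(build_candidates(GRanges(), GRanges(), reads, reads,
                                  1e6, 1e6), "no peaks")
})

test_that("candidate base-union matches the per-base oracle", {
  set.seed(41)
  for (rep in 1:5) {
    case <- random_granges(40, 20000)
    ctrl <- random_granges(40, 20000)
    cand <- build_candidates(case, ctrl, GRanges(), GRanges(), 1e6, 1e6)
    oracle <- mask_to_intervals(oracle_union_mask(c(case, ctrl), 20000))
    expect_equal(cand$start, oracle$start)
    expect_equal(cand$end, oracle$end)
  }
})

test_that("chi-square statistic agrees with stats::chisq.test", {
  res <- chi_square_test(100, 20, 1e6, 1e6)
  ref <- chisq.test(matrix(c(100, 1e6 - 100, 20, 1e6 - 20), 2,
                           byrow = TRUE), correct = FALSE)
  expect_equal(res$stat, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$stat, 53.3, tolerance = 0.01)

  # equal counts and libraries: no signal
  null <- chi_square_test(50, 50, 1e6, 1e6)
  expect_equal(null$stat, 0)
  expect_equal(null$p_value, 1)

  # swapping the rows leaves the statistic unchanged
  sw <- chi_square_test(20, 100, 1e6, 1e6)
  expect_equal(sw$stat, res$stat)
  expect_equal(sw$p_value, res$p_value)

  # both zero counts: flagged untestable
  z <- chi_square_test(0, 0, 1e6, 1e6)
  expect_equal(z$stat, 0)
  expect_equal(z$p_value, 1)
})

test_that("true-DMR calling enforces p, q and fold thresholds jointly", {
  cand <- data.frame(
    chrom = "chr1", start = c(1, 1001, 2001), end = c(500, 1500, 2500),
    width = 500,
    count_case = c(100, 30, 0), count_control = c(20, 20, 0),
    lib_case = 1e6, lib_control = 1e6
  )
  res <- call_true_dmrs(cand)
  expect_equal(res$fold[1], 5)
  expect_equal(res$trend[1], "uptrend")
  expect_true(res$is_true_dmr[1])
  # fold 1.5 fails the fold filter regardless of p
  expect_equal(res$fold[2], 1.5)
  expect_false(res$is_true_dmr[2])
  # zero-zero candidates are never true DMRs
  expect_false(res$is_true_dmr[3])
  expect_equal(res$trend[3], "none")
})

test_that("fold is swap-invariant with trend flipped; p is swap-invariant", {
  cand <- data.frame(chrom = "chr1", start = 1, end = 500, width = 500,
                     count_case = 120, count_control = 25,
                     lib_case = 2e6, lib_control = 1e6)
  swapped <- cand
  swapped$count_case <- cand$count_control
  swapped$count_control <- cand$count_case
  swapped$lib_case <- cand$lib_control
  swapped$lib_control <- cand$lib_case
  a <- call_true_dmrs(cand)
  b <- call_true_dmrs(swapped)
  expect_equal(a$fold, b$fold)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$trend, "uptrend")
  expect_equal(b$trend, "downtrend")
})

test_that("null candidates give a calibrated raw-p exceedance near 0.01", {
  set.seed(42)
  counts <- simulate_pair_counts(2000, mean_count = 100,
                                 noise = "poisson")
  cand <- data.frame(chrom = "chr1",
                     start = seq(1, by = 1000, length.out = 2000),
                     end = seq(500, by = 1000, length.out = 2000),
                     width = 500,
                     count_case = counts$count_case,
                     count_control = counts$count_control,
                     lib_case = 1e6, lib_control = 1e6)
  res <- call_true_dmrs(cand)
  frac <- mean(res$p_value <= 0.01)
  expect_gt(frac, 0.003)
  expect_lt(frac, 0.025)
  expect_equal(sum(res$is_true_dmr), 0)   # BH at 0.01 kills pure noise
})

test_that("gene elements are classified hyper/hypo/mixed by DMR trends", {
  elements <- GRanges("chr1", IRanges(c(1001, 2001, 3001),
                                      c(1500, 2500, 3500)))
  mcols(elements)$gene_id <- c("g1", "g1", "g2")
  mcols(elements)$element_type <- c("cds", "intron", "cds")
  dmrs <- data.frame(
    chrom = "chr1", start = c(1100, 2100, 2200), end = c(1200, 2150, 2300),
    trend = c("uptrend", "uptrend", "downtrend"),
    is_true_dmr = TRUE
  )
  dmg <- classify_dmgs(dmrs, elements)
  expect_equal(dmg$status[dmg$gene_id == "g1" & dmg$element == "cds"],
               "hyper")
  expect_equal(dmg$status[dmg$gene_id == "g1" & dmg$element == "intron"],
               "mixed")
  expect_equal(dmg$status[dmg$gene_id == "g2" & dmg$element == "cds"],
               "unmethylated")
})

test_that("classification equals a brute-force overlap recount", {
  set.seed(43)
  for (rep in 1:5) {
    n_el <- 60
    elements <- random_granges(n_el, 50000)
    mcols(elements)$gene_id <- sample(sprintf("g%02d", 1:20), n_el,
                                      replace = TRUE)
    mcols(elements)$element_type <- sample(c("promoter", "cds", "intron"),
                                           n_el, replace = TRUE)
    dgr <- random_granges(30, 50000)
    dmrs <- data.frame(chrom = "chrT", start = start(dgr), end = end(dgr),
                       trend = sample(c("uptrend", "downtrend"), 30,
                                      replace = TRUE),
                       is_true_dmr = sample(c(TRUE, FALSE), 30,
                                            replace = TRUE))
    dmg <- classify_dmgs(dmrs, elements)
    # brute force per (gene, element)
    for (i in sample(nrow(dmg), 10)) {
      sel <- mcols(elements)$gene_id == dmg$gene_id[i] &
        mcols(elements)$element_type == dmg$element[i]
      el_sel <- elements[sel]
      tr <- dmrs[dmrs$is_true_dmr, ]
      ov <- vapply(seq_len(nrow(tr)), function(j)
        any(start(el_sel) <= tr$end[j] & end(el_sel) >= tr$start[j]),
        logical(1))
      n_up <- sum(ov & tr$trend == "uptrend")
      n_down <- sum(ov & tr$trend == "downtrend")
      want <- if (n_up > 0 && n_down > 0) "mixed" else
        if (n_up > 0) "hyper" else if (n_down > 0) "hypo" else
          "unmethylated"
      expect_equal(dmg$status[i], want)
    }
    # permutation invariance in input order
    perm <- sample(nrow(dmrs))
    dmg2 <- classify_dmgs(dmrs[perm, ], elements)
    expect_equal(dmg$status[order(dmg$gene_id, dmg$element)],
                 dmg2$status[order(dmg2$gene_id, dmg2$element)])
  }
})

test_that("summaries recount true DMRs, covered bp and trends", {
  d1 <- data.frame(chrom = "chr1", start = c(1, 1001), end = c(100, 1100),
                   trend = c("uptrend", "downtrend"),
                   is_true_dmr = c(TRUE, FALSE))
  s <- summarize_dmrs(list(pairA = d1))
  expect_equal(s$per_pair$n_true_dmrs, 1)
  expect_equal(s$per_pair$covered_bp, 100)
  expect_equal(s$per_pair$n_uptrend, 1)

  d0 <- d1[0, ]
  s0 <- summarize_dmrs(list(pairA = d0))
  expect_equal(s0$per_pair$n_true_dmrs, 0)
  expect_equal(s0$per_pair$covered_bp, 0)
})
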