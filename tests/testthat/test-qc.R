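# Read filtering, cytosine contexts and the distribution statistics.

test_that("filter_reads applies the N and low-quality rules verbatim", {
  seqs <- c(
    paste0(strrep("A", 43), strrep("N", 6)),   # 6/49 N -> removed
    strrep("A", 49),                           # 25/49 at Q20 -> removed
    paste0(strrep("A", 45), strrep("N", 4))    # 4 N, 24 low-Q -> kept
  )
  quals <- list(
    rep(30L, 49),
    c(rep(20L, 25), rep(30L, 24)),
    c(rep(20L, 24), rep(30L, 25))
  )
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(path, c("r1", "r2", "r3"), seqs, quals)
  reads <- read_fastq(path)
  res <- filter_reads(reads)
  expect_equal(sort(res$removed_ids), c("r1", "r2"))
  expect_equal(names(res$kept), "r3")
  expect_equal(res$report$removed_n_rule, 1)
  expect_equal(res$report$removed_quality_rule, 1)
})

test_that("filter_reads keeps the same id set under stream shuffling", {
  set.seed(31)
  n <- 200
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T", "N"), 49, replace = TRUE,
                prob = c(0.23, 0.23, 0.23, 0.23, 0.08))
    paste(s, collapse = "")
  }, character(1))
  quals <- lapply(seq_len(n), function(i)
    sample(10:40, 49, replace = TRUE))
  path <- withr::local_tempfile(fileext = ".fastq")
  ids <- sprintf("r%03d", seq_len(n))
  write_fastq(path, ids, seqs, quals)
  res1 <- filter_reads(read_fastq(path))
  perm <- sample(n)
  write_fastq(path, ids[perm], seqs[perm], quals[perm])
  res2 <- filter_reads(read_fastq(path))
  expect_setequal(names(res1$kept), names(res2$kept))
})

test_that("context classification handles the canonical small cases", {
  g <- Biostrings::DNAStringSet(c(chrA = "ACGT"))
  ctx <- classify_contexts(g)
  cpg_plus <- ctx[ctx$strand == "+" & ctx$context == "CpG", ]
  expect_equal(cpg_plus$pos, 2)       # the C of the CpG
  cpg_minus <- ctx[ctx$strand == "-" & ctx$context == "CpG", ]
  expect_equal(cpg_minus$pos, 3)      # the G, a C on the reverse strand

  g2 <- Biostrings::DNAStringSet(c(chrA = "CATAA"))
  ctx2 <- classify_contexts(g2)
  plus <- ctx2[ctx2$strand == "+", ]
  expect_true(any(plus$pos == 1 & plus$context == "CHH"))
})

test_that("context labels match the exhaustive triplet oracle", {
  set.seed(32)
  for (rep in 1:3) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 5000, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    got <- classify_contexts(Biostrings::DNAStringSet(c(chrA = s)))
    want <- oracle_contexts(s)
    got_key <- sort(paste(got$pos, got$strand, got$context))
    want_key <- sort(paste(want$pos, want$strand, want$context))
    expect_equal(got_key, want_key)
  }
})

test_that("context labels are mutually exclusive per position and strand", {
  set.seed(33)
  s <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
             collapse = "")
  ctx <- classify_contexts(Biostrings::DNAStringSet(c(chrA = s)))
  expect_equal(anyDuplicated(paste(ctx$pos, ctx$strand)), 0)
})

test_that("coverage_by_depth counts per-base depth fractions", {
  reads <- GRanges("chrA", IRanges(c(1, 6), c(10, 15)))
  prof <- coverage_by_depth(reads, c(chrA = 20))
  expect_equal(prof$frac_ge[1], 0.75)
  expect_equal(prof$frac_ge[2], 0.25)
  expect_equal(nrow(coverage_by_depth(GRanges(), c(chrA = 20))), 0)
})

test_that("depth fractions match the per-base oracle and conserve mass", {
  set.seed(34)
  reads <- random_granges(200, 10000, max_width = 100)
  prof <- coverage_by_depth(reads, c(chrT = 10000))
  depth <- oracle_depth_counts(reads, 10000)
  for (d in prof$depth) {
    expect_equal(prof$frac_eq[d], mean(depth == d))
    expect_equal(prof$frac_ge[d], mean(depth >= d))
  }
  expect_equal(sum(prof$frac_eq) + mean(depth == 0), 1, tolerance = 1e-12)
  expect_true(all(diff(prof$frac_ge) <= 0))
})

test_that("CpG density uses sites per 100 bp and conserves item totals", {
  sites <- GRanges("chrA", IRanges(c(10, 20, 30, 40, 50), width = 1))
  peak <- GRanges("chrA", IRanges(1, 100))
  h <- density_binned_distribution(peak, sites)
  expect_equal(sum(h$count), 1)
  expect_equal(h$count[h$bin_lo == 5], 1)   # density exactly 5 per 100 bp

  empty_peak <- GRanges("chrA", IRanges(200, 299))
  h0 <- density_binned_distribution(empty_peak, sites)
  expect_equal(h0$count[1], 1)              # density 0 in the lowest bin

  set.seed(35)
  peaks <- random_granges(300, 50000)
  sites2 <- GRanges("chrT", IRanges(sample.int(50000, 2000), width = 1))
  h2 <- density_binned_distribution(peaks, sites2)
  expect_equal(sum(h2$count), length(peaks))
})

test_that("element_distribution counts items per class with multi-class", {
  bundle <- simulate_genome(sim_config(seed = 36, n_chroms = 1,
                                       chrom_len = 100000, n_genes = 8,
                                       n_islands = 4, n_repeats = 10))$bundle
  el <- bundle$elements
  cds <- el[mcols(el)$element_type == "cds"][1]
  intron <- el[mcols(el)$element_type == "intron"]
  intron <- intron[seqnames(intron) == seqnames(cds) &
                     start(intron) == end(cds) + 1][1]
  if (length(intron) == 1) {
    junction <- GRanges(seqnames(cds), IRanges(end(cds) - 10,
                                               end(cds) + 10))
    tab <- element_distribution(junction, bundle)
    expect_equal(tab$n_items[tab$class == "cds"], 1)
    expect_equal(tab$n_items[tab$class == "intron"], 1)
  }
  # an item placed in intergenic space counts only there
  inter_tab <- element_distribution(GRanges("chr1", IRanges(1, 50)), bundle)
  expect_equal(inter_tab$n_items[inter_tab$class == "intergenic"], 1)
  expect_equal(sum(inter_tab$n_items[inter_tab$class %in%
                                       c("promoter", "cds", "intron",
                                         "utr5", "utr3")]), 0)
})

test_that("per-class base coverage matches the per-base class-mask oracle", {
  set.seed(37)
  cfg <- sim_config(seed = 37, n_chroms = 1, chrom_len = 100000,
                    n_genes = 8, n_islands = 4, n_repeats = 10)
  bundle <- simulate_genome(cfg)$bundle
  items <- random_granges(100, 100000, chrom = "chr1")
  tab <- element_distribution(items, bundle)
  item_mask <- oracle_union_mask(items, 100000)
  el <- bundle$elements
  for (class in c("promoter", "cds", "intron", "utr5", "utr3")) {
    cg <- el[mcols(el)$element_type == class]
    class_mask <- oracle_union_mask(cg, 100000)
    expect_equal(tab$covered_bp[tab$class == class],
                 sum(item_mask & class_mask))
  }
})

test_that("metagene profile is flat under uniform depth and zero without reads", {
  anchors <- GRanges("chrA", IRanges(5001, 6000), strand = "+")
  reads <- GRanges("chrA", IRanges(3001, 8000))   # depth 1 everywhere nearby
  prof <- metagene_profile(reads, anchors, c(chrA = 20000), flank = 1000,
                           n_bins = 10, n_flank_bins = 5)
  expect_equal(prof$mean_density, rep(1, 20))
  prof0 <- metagene_profile(GRanges(), anchors, c(chrA = 20000))
  expect_equal(prof0$mean_density, rep(0, nrow(prof0)))
})

test_that("minus-strand anchors are reversed in the metagene profile", {
  anchors_plus <- GRanges("chrA", IRanges(5001, 6000), strand = "+")
  anchors_minus <- GRanges("chrA", IRanges(5001, 6000), strand = "-")
  reads <- GRanges("chrA", IRanges(4001, 5000))  # upstream of plus anchor
  p_plus <- metagene_profile(reads, anchors_plus, c(chrA = 20000))
  p_minus <- metagene_profile(reads, anchors_minus, c(chrA = 20000))
  expect_equal(p_plus$mean_density, rev(p_minus$mean_density))
})

test_that("peak length histogram bins by width and conserves totals", {
  peaks <- GRanges("chrA", IRanges(c(1, 101, 201), width = c(100, 100, 300)))
  h <- peak_length_distribution(peaks, bin_width = 100)
  expect_equal(h$count[h$bin_lo == 100], 2)
  expect_equal(h$count[h$bin_lo == 300], 1)
  expect_equal(sum(h$count), 3)
  expect_equal(nrow(peak_length_distribution(GRanges())), 0)
})
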