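# Independent brute-force oracles used to validate the fast implementations.
# All work per base / per pair / by direct summation and never share code
# with the functions they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

# random intervals on a single toy chromosome
random_granges <- function(n, chrom_len, chrom = "chrT",
                           max_width = 500L) {
  w <- sample.int(max_width, n, replace = TRUE)
  st <- sample.int(chrom_len - max_width, n, replace = TRUE)
  GRanges(chrom, IRanges(st, st + w - 1L))
}

# per-base boolean-array union of intervals on one chromosome
oracle_union_mask <- function(gr, chrom_len) {
  mask <- logical(chrom_len)
  for (i in seq_along(gr)) mask[start(gr)[i]:end(gr)[i]] <- TRUE
  mask
}

mask_to_intervals <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# quadratic all-pairs overlap scan
oracle_overlapping_subjects <- function(query, subject) {
  hits <- logical(length(subject))
  for (i in seq_along(query)) {
    hits <- hits | (start(subject) <= end(query)[i] &
                      end(subject) >= start(query)[i] &
                      as.character(seqnames(subject)) ==
                        as.character(seqnames(query))[i])
  }
  which(hits)
}

# per-base depth counting
oracle_depth_counts <- function(gr, chrom_len) {
  depth <- integer(chrom_len)
  for (i in seq_along(gr)) {
    idx <- start(gr)[i]:end(gr)[i]
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

# exhaustive triplet scan of both strands of one sequence string
oracle_contexts <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(toupper(s), "")[[1]]
  n <- length(chars)
  res <- list()
  classify <- function(tri) {
    if (tri[1] != "C") return(NA_character_)
    h <- c("A", "C", "T")
    if (tri[2] == "G") return("CpG")
    if (tri[2] %in% h && tri[3] == "G") return("CHG")
    if (tri[2] %in% h && tri[3] %in% h) return("CHH")
    NA_character_
  }
  for (i in seq_len(max(0, n - 2))) {
    ctx <- classify(chars[i:(i + 2)])
    if (!is.na(ctx)) res[[length(res) + 1]] <-
        data.frame(pos = i, strand = "+", context = ctx)
  }
  for (i in seq_len(n)) {
    if (i < 3) next
    tri <- comp[chars[c(i, i - 1, i - 2)]]
    ctx <- classify(unname(tri))
    if (!is.na(ctx)) res[[length(res) + 1]] <-
        data.frame(pos = i, strand = "-", context = ctx)
  }
  do.call(rbind, res)
}

# direct evaluation of the Benjamini-Yekutieli step-up adjustment
oracle_by_adjust <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj_sorted <- pmin(1, m * cm * p[o] / seq_len(m))
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# exhaustive subset enumeration of the hypergeometric upper tail
oracle_hyper_upper <- function(k, K, n, N) {
  subsets <- utils::combn(N, n)
  term <- seq_len(K)
  mean(apply(subsets, 2, function(s) sum(s %in% term) >= k))
}

# direct log-space tail summation of the conditional count-test distribution
oracle_ac_test <- function(x, y, n1, n2) {
  r <- n2 / n1
  logp <- function(yy) {
    yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) - lgamma(yy + 1) -
      (x + yy + 1) * log1p(r)
  }
  ys <- 0:max(2000, 20 * (x + y + 1))
  p_all <- exp(logp(ys))
  lower <- sum(p_all[ys <= y])
  upper <- sum(p_all[ys >= y])
  min(1, 2 * min(lower, upper))
}

# naive quadratic average-linkage agglomeration; returns merge heights
oracle_average_linkage_heights <- function(mat) {
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# write a FASTQ file from sequences and integer qualities (Phred+33)
write_fastq <- function(path, ids, seqs, quals) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(c(paste0("@", ids[i]), seqs[i], "+",
                 intToUtf8(quals[[i]] + 33L)), con)
  }
  invisible(path)
}
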