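# File readers and writers. BED is 0-based half-open on disk and converted to
# the internal 1-based closed GRanges convention on ingest; GTF is already
# 1-based closed and is taken as-is.

.stop_line <- function(file, line_no, msg) {
  stop(sprintf("%s: line %d: %s", file, line_no, msg), call. = FALSE)
}

#' Read a BED file (BED3/BED6) into a GRanges
#'
#' @param path BED file path.
#' @param chrom_sizes Optional named vector of chromosome lengths to attach as
#'   `seqlengths`.
#' @return `GRanges`; BED columns 4-6 become `name`, `score` and strand when
#'   present. Malformed lines raise an error naming the file and line number.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = list(character = 1))
  if (nrow(dt) == 0L) {
    gr <- GRanges()
  } else {
    if (ncol(dt) < 3L) .stop_line(path, 1L, "fewer than 3 BED columns")
    starts <- suppressWarnings(as.integer(dt[[2]]))
    ends <- suppressWarnings(as.integer(dt[[3]]))
    bad <- which(is.na(starts) | is.na(ends) | starts < 0 | ends <= starts |
                   is.na(dt[[1]]) | dt[[1]] == "")
    if (length(bad)) .stop_line(path, bad[1], "malformed BED record")
    strand <- if (ncol(dt) >= 6L) {
      s <- as.character(dt[[6]])
      s[!s %in% c("+", "-")] <- "*"
      s
    } else "*"
    gr <- GRanges(dt[[1]], IRanges(starts + 1L, ends), strand = strand)
    if (ncol(dt) >= 4L) mcols(gr)$name <- as.character(dt[[4]])
    if (ncol(dt) >= 5L) mcols(gr)$score <- suppressWarnings(as.numeric(dt[[5]]))
  }
  if (!is.null(chrom_sizes)) {
    seqlevels(gr) <- union(seqlevels(gr), names(chrom_sizes))
    seqlengths(gr) <- chrom_sizes[seqlevels(gr)]
  }
  gr
}

#' Write a GRanges to a BED file
#'
#' Coordinates are converted back to 0-based half-open. `name` and `score`
#' metadata columns, when present, populate BED columns 4-6 (strand written as
#' `.` for `*`).
#'
#' @param gr `GRanges` to write.
#' @param path Output path.
#' @return Invisibly the path.
#' @export
write_bed <- function(gr, path) {
  dt <- data.table(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr)
  )
  has_name <- "name" %in% names(mcols(gr))
  has_score <- "score" %in% names(mcols(gr))
  str <- as.character(strand(gr))
  if (has_name || has_score || any(str != "*")) {
    dt$name <- if (has_name) mcols(gr)$name else "."
    dt$score <- if (has_score) mcols(gr)$score else 0
    str[str == "*"] <- "."
    dt$strand <- str
  }
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene models from GTF or BED12
#'
#' GTF ingest collects `exon` and `CDS` features per `gene_id`; BED12 ingest
#' expands block definitions into exons and takes `thickStart`/`thickEnd` as
#' the CDS span. One model per `gene_id` is assumed.
#'
#' @param path GTF or BED12 path.
#' @param format `"gtf"` or `"bed12"`; guessed from the file extension by
#'   default.
#' @return List with `genes` (data.frame: gene_id, chrom, strand, tx_start,
#'   tx_end, cds_start, cds_end; 1-based closed, NA CDS for non-coding) and
#'   `exons` (`GRanges` with `gene_id`).
#' @export
read_gene_models <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  }
  if (format == "gtf") .read_gene_models_gtf(path) else
    .read_gene_models_bed12(path)
}

.read_gene_models_gtf <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              colClasses = list(character = c(1, 2, 3, 6, 7, 8, 9)))
  if (ncol(dt) < 9L) .stop_line(path, 1L, "fewer than 9 GTF columns")
  starts <- suppressWarnings(as.integer(dt[[4]]))
  ends <- suppressWarnings(as.integer(dt[[5]]))
  bad <- which(is.na(starts) | is.na(ends) | starts < 1 | ends < starts)
  if (length(bad)) .stop_line(path, bad[1], "malformed GTF coordinates")
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", dt[[9]])
  no_gid <- which(!grepl('gene_id "', dt[[9]], fixed = TRUE))
  if (length(no_gid)) .stop_line(path, no_gid[1], "missing gene_id attribute")
  feat <- dt[[3]]
  keep <- feat %in% c("exon", "CDS")
  tab <- data.table(chrom = dt[[1]][keep], start = starts[keep],
                    end = ends[keep], strand = dt[[7]][keep],
                    feature = feat[keep], gene_id = gid[keep])
  .assemble_gene_models(tab)
}

.assemble_gene_models <- function(tab) {
  ex <- tab[tab$feature == "exon", ]
  cds <- tab[tab$feature == "CDS", ]
  genes <- ex[, list(chrom = chrom[1], strand = strand[1],
                     tx_start = min(start), tx_end = max(end)),
              by = "gene_id"]
  if (nrow(cds)) {
    cds_span <- cds[, list(cds_start = min(start), cds_end = max(end)),
                    by = "gene_id"]
    genes <- merge(genes, cds_span, by = "gene_id", all.x = TRUE)
  } else {
    genes$cds_start <- NA_integer_
    genes$cds_end <- NA_integer_
  }
  setorder(genes, chrom, tx_start, gene_id)
  exons <- GRanges(ex$chrom, IRanges(ex$start, ex$end), strand = ex$strand)
  mcols(exons)$gene_id <- ex$gene_id
  exons <- sort(exons, ignore.strand = TRUE)
  list(genes = as.data.frame(genes), exons = exons)
}

.read_gene_models_bed12 <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              colClasses = list(character = c(1, 4, 6, 11, 12)))
  if (ncol(dt) < 12L) .stop_line(path, 1L, "fewer than 12 BED12 columns")
  rows <- lapply(seq_len(nrow(dt)), function(i) {
    chrom_start <- as.integer(dt[[2]][i])
    sizes <- as.integer(strsplit(sub(",$", "", dt[[11]][i]), ",")[[1]])
    offs <- as.integer(strsplit(sub(",$", "", dt[[12]][i]), ",")[[1]])
    if (length(sizes) != as.integer(dt[[10]][i]) ||
        length(offs) != length(sizes)) {
      .stop_line(path, i, "blockSizes/blockStarts disagree with blockCount")
    }
    ex_start <- chrom_start + offs + 1L     # to 1-based
    ex_end <- chrom_start + offs + sizes
    thick_start <- as.integer(dt[[7]][i])
    thick_end <- as.integer(dt[[8]][i])
    coding <- thick_end > thick_start
    data.table(
      gene_id = dt[[4]][i], chrom = dt[[1]][i], strand = dt[[6]][i],
      tx_start = chrom_start + 1L, tx_end = as.integer(dt[[3]][i]),
      cds_start = if (coding) thick_start + 1L else NA_integer_,
      cds_end = if (coding) thick_end else NA_integer_,
      ex_start = list(ex_start), ex_end = list(ex_end)
    )
  })
  tab <- rbindlist(rows)
  genes <- as.data.frame(tab[, c("gene_id", "chrom", "strand", "tx_start",
                                 "tx_end", "cds_start", "cds_end")])
  exons <- GRanges(
    rep(tab$chrom, lengths(tab$ex_start)),
    IRanges(unlist(tab$ex_start), unlist(tab$ex_end)),
    strand = rep(tab$strand, lengths(tab$ex_start))
  )
  mcols(exons)$gene_id <- rep(tab$gene_id, lengths(tab$ex_start))
  list(genes = genes, exons = sort(exons, ignore.strand = TRUE))
}

#' Write gene models as BED12
#'
#' @param models List with `genes` and `exons` as returned by
#'   [read_gene_models()].
#' @param path Output path.
#' @export
write_gene_models_bed12 <- function(models, path) {
  genes <- models$genes
  ex_by <- split(models$exons, mcols(models$exons)$gene_id)
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- sort(ex_by[[as.character(g$gene_id)]], ignore.strand = TRUE)
    offs <- start(ex) - g$tx_start
    sizes <- width(ex)
    coding <- !is.na(g$cds_start)
    paste(g$chrom, g$tx_start - 1L, g$tx_end, g$gene_id, 0, g$strand,
          if (coding) g$cds_start - 1L else g$tx_start - 1L,
          if (coding) g$cds_end else g$tx_start - 1L,
          "0", length(ex),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(offs, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path TSV with chromosome name and length.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              colClasses = list(character = 1))
  if (ncol(dt) < 2L) .stop_line(path, 1L, "expected 2 columns")
  len <- suppressWarnings(as.integer(dt[[2]]))
  bad <- which(is.na(len) | len <= 0)
  if (length(bad)) .stop_line(path, bad[1], "invalid chromosome length")
  setNames(len, dt[[1]])
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return A `DNAStringSet` named by chromosome.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}


.fread_tsv <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "# ")]
  fread(text = paste(lines, collapse = "\n"), sep = "\t", header = TRUE,
        ...)
}

#' Read a gene-count table
#'
#' @param path TSV with columns `gene_id`, `length`, then one column of read
#'   counts per sample.
#' @return List with `counts` (integer matrix, genes x samples),
#'   `gene_lengths` (named vector, bp) and `samples`.
#' @export
read_counts <- function(path) {
  dt <- .fread_tsv(path)
  if (!all(c("gene_id", "length") %in% names(dt))) {
    stop(path, ": expected columns gene_id and length")
  }
  samples <- setdiff(names(dt), c("gene_id", "length"))
  counts <- as.matrix(dt[, samples, with = FALSE])
  rownames(counts) <- dt$gene_id
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop(path, ": negative counts")
  list(counts = counts,
       gene_lengths = setNames(as.numeric(dt$length), dt$gene_id),
       samples = samples)
}

#' Read a case/control pair manifest
#'
#' @param path TSV with columns `pair_id`, `case_id`, `control_id`.
#' @return data.frame of pairs.
#' @export
read_pairs <- function(path) {
  dt <- .fread_tsv(path, colClasses = "character")
  need <- c("pair_id", "case_id", "control_id")
  if (!all(need %in% names(dt))) {
    stop(path, ": expected columns ", paste(need, collapse = ", "))
  }
  as.data.frame(dt[, need, with = FALSE])
}

#' Read a gene-to-term mapping
#'
#' @param path Flat TSV with columns `term_id`, `category` (C/F/P/pathway),
#'   `gene_id`, and optionally `term_name`.
#' @return data.frame of memberships.
#' @export
read_terms <- function(path) {
  dt <- .fread_tsv(path, colClasses = "character")
  need <- c("term_id", "category", "gene_id")
  if (!all(need %in% names(dt))) {
    stop(path, ": expected columns ", paste(need, collapse = ", "))
  }
  as.data.frame(dt)
}
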