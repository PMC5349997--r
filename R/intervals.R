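#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits Rle runValue runLength
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<- seqlevels seqlevels<-
#' @importFrom methods is as
#' @importFrom data.table data.table fread fwrite rbindlist setorder as.data.table :=
#' @importFrom stats pchisq p.adjust phyper rnorm runif rpois rnbinom rlnorm
#'   hclust dist setNames ks.test
#' @importFrom utils head tail
NULL

# Coordinates are held in GRanges (1-based, closed) throughout; BED files are
# converted from 0-based half-open on ingest and back on export.

#' Merge genomic intervals into their union
#'
#' Collapses a set of intervals into the minimal sorted set of disjoint
#' intervals covering the same bases. Book-ended intervals (one ending where
#' the next begins) are merged, matching the union-of-covered-bases semantics
#' used when paired peak sets are merged into candidate DMRs. Strand is
#' ignored.
#'
#' @param gr A `GRanges` object.
#' @return A `GRanges` of disjoint, sorted intervals with `*` strand.
#' @export
merge_intervals <- function(gr) {
  stopifnot(is(gr, "GRanges"))
  if (length(gr) == 0L) return(GRanges(seqlengths = seqlengths(gr)))
  GenomicRanges::reduce(gr, ignore.strand = TRUE)
}

#' Find subject intervals overlapping a query
#'
#' Returns the subject intervals sharing at least one base with any query
#' interval. Overlap is strand-blind: MeDIP-seq reads and peaks carry no
#' meaningful strand.
#'
#' @param query,subject `GRanges` objects.
#' @return The subset of `subject` overlapping `query` by >= 1 bp.
#' @export
overlap_query <- function(query, subject) {
  stopifnot(is(query, "GRanges"), is(subject, "GRanges"))
  hits <- findOverlaps(query, subject, ignore.strand = TRUE)
  subject[sort(unique(subjectHits(hits)))]
}

#' Derive promoter/UTR/CDS/intron elements for one gene model
#'
#' Splits a gene model into the five element classes used throughout the
#' methylation analysis: promoter (fixed-length window immediately upstream of
#' the strand-aware TSS, clipped to chromosome bounds), 5'-UTR (exonic
#' sequence between the transcript start and the CDS start, strand-aware),
#' CDS, 3'-UTR, and introns (gaps between consecutive exons). For non-coding
#' genes (no CDS) the UTR/CDS classes are empty while promoter and introns are
#' still produced.
#'
#' @param gene One-row data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `cds_start`, `cds_end` (1-based closed; `NA` CDS
#'   bounds mark a non-coding gene).
#' @param exons `GRanges` of the gene's exons (sorted, disjoint, within the
#'   transcript span).
#' @param promoter_len Promoter length in bp upstream of the TSS (default
#'   2000).
#' @param chrom_sizes Named integer vector of chromosome lengths, used to clip
#'   the promoter. Optional; if missing no upper clipping is applied.
#' @return `GRanges` with metadata columns `gene_id` and `element` (one of
#'   `promoter`, `utr5`, `cds`, `intron`, `utr3`).
#' @export
derive_elements <- function(gene, exons, promoter_len = 2000L,
                            chrom_sizes = NULL) {
  stopifnot(nrow(gene) == 1L, is(exons, "GRanges"))
  chrom <- as.character(gene$chrom)
  strand <- as.character(gene$strand)
  tx_start <- gene$tx_start
  tx_end <- gene$tx_end
  coding <- !is.na(gene$cds_start) && !is.na(gene$cds_end) &&
    gene$cds_end >= gene$cds_start

  out <- list()
  # promoter: strand-aware upstream window, clipped to [1, chrom length]
  if (strand == "-") {
    p_start <- tx_end + 1L
    p_end <- tx_end + promoter_len
  } else {
    p_start <- tx_start - promoter_len
    p_end <- tx_start - 1L
  }
  p_start <- max(p_start, 1L)
  if (!is.null(chrom_sizes) && chrom %in% names(chrom_sizes)) {
    p_end <- min(p_end, unname(chrom_sizes[[chrom]]))
  }
  if (p_end >= p_start) {
    out$promoter <- GRanges(chrom, IRanges(p_start, p_end), strand = strand)
  }

  ex <- sort(GenomicRanges::reduce(exons, ignore.strand = TRUE))
  # introns: gaps between consecutive exons
  if (length(ex) > 1L) {
    gap_start <- end(ex)[-length(ex)] + 1L
    gap_end <- start(ex)[-1L] - 1L
    keep <- gap_end >= gap_start
    if (any(keep)) {
      out$intron <- GRanges(chrom, IRanges(gap_start[keep], gap_end[keep]),
                            strand = strand)
    }
  }

  if (coding) {
    cds_span <- GRanges(chrom, IRanges(gene$cds_start, gene$cds_end))
    left_span <- if (gene$cds_start > tx_start) {
      GRanges(chrom, IRanges(tx_start, gene$cds_start - 1L))
    } else GRanges()
    right_span <- if (gene$cds_end < tx_end) {
      GRanges(chrom, IRanges(gene$cds_end + 1L, tx_end))
    } else GRanges()
    cds <- GenomicRanges::intersect(ex, cds_span, ignore.strand = TRUE)
    left <- GenomicRanges::intersect(ex, left_span, ignore.strand = TRUE)
    right <- GenomicRanges::intersect(ex, right_span, ignore.strand = TRUE)
    if (length(cds)) out$cds <- `strand<-`(cds, value = strand)
    if (strand == "-") {
      if (length(right)) out$utr5 <- `strand<-`(right, value = strand)
      if (length(left)) out$utr3 <- `strand<-`(left, value = strand)
    } else {
      if (length(left)) out$utr5 <- `strand<-`(left, value = strand)
      if (length(right)) out$utr3 <- `strand<-`(right, value = strand)
    }
  }

  classes <- names(out)
  if (length(out) == 0L) {
    res <- GRanges()
    mcols(res)$gene_id <- character(0)
    mcols(res)$element_type <- character(0)
    return(res)
  }
  res <- unlist(GRangesList(lapply(out, function(g) {
    mcols(g) <- NULL
    g
  })), use.names = FALSE)
  mcols(res)$gene_id <- rep(as.character(gene$gene_id), length(res))
  mcols(res)$element_type <- rep(classes, vapply(out, length, 1L))
  res
}

#' Derive elements for every gene in an annotation
#'
#' @param genes data.frame of gene models (see [derive_elements()]).
#' @param exons `GRanges` of exons with a `gene_id` metadata column.
#' @inheritParams derive_elements
#' @return Combined `GRanges` with `gene_id` and `element` metadata columns.
#' @export
derive_elements_all <- function(genes, exons, promoter_len = 2000L,
                                chrom_sizes = NULL) {
  ex_by_gene <- split(exons, mcols(exons)$gene_id)
  parts <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- as.character(genes$gene_id[i])
    derive_elements(genes[i, , drop = FALSE], ex_by_gene[[gid]],
                    promoter_len = promoter_len, chrom_sizes = chrom_sizes)
  })
  out <- suppressWarnings(do.call(c, parts))
  if (!is.null(chrom_sizes)) {
    seqlevels(out) <- names(chrom_sizes)
  }
  out
}

#' Validate a gene-model table and its exons
#'
#' Checks the structural invariants assumed downstream: exons sorted and
#' disjoint within each gene, CDS nested in the transcript span, exons inside
#' the transcript span.
#'
#' @param genes Gene-model data.frame.
#' @param exons `GRanges` of exons with `gene_id`.
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_gene_models <- function(genes, exons) {
  stopifnot(all(genes$tx_start <= genes$tx_end))
  coding <- !is.na(genes$cds_start)
  if (any(coding)) {
    ok <- genes$tx_start[coding] <= genes$cds_start[coding] &
      genes$cds_start[coding] <= genes$cds_end[coding] &
      genes$cds_end[coding] <= genes$tx_end[coding]
    if (!all(ok)) {
      stop("CDS not nested within transcript span for gene(s): ",
           paste(genes$gene_id[coding][!ok], collapse = ", "))
    }
  }
  ex_by <- split(exons, mcols(exons)$gene_id)
  for (gid in names(ex_by)) {
    g <- genes[genes$gene_id == gid, ]
    ex <- sort(ex_by[[gid]], ignore.strand = TRUE)
    if (length(ex) > 1L &&
        any(start(ex)[-1L] <= end(ex)[-length(ex)])) {
      stop("overlapping exons in gene ", gid)
    }
    if (min(start(ex)) < g$tx_start || max(end(ex)) > g$tx_end) {
      stop("exon outside transcript span in gene ", gid)
    }
  }
  invisible(TRUE)
}
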