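# End-to-end orchestration: simulate -> qc -> dmr -> dmg -> deg -> enrich ->
# methexpr, with every output written as headered TSV/BED/FASTA and a
# checksum manifest.

#' Write a TSV with a commented parameter header
#'
#' Output tables carry the thresholds and parameters that produced them as
#' `# key=value` comment lines, so every file is self-describing.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param params Named list echoed into the header.
#' @return Invisibly the path.
#' @export
write_tsv_with_header <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params)) {
    writeLines(sprintf("# %s=%s", k, paste(params[[k]], collapse = ",")),
               con)
  }
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a TSV written by [write_tsv_with_header()]
#'
#' @param path File path.
#' @return data.frame (header comments skipped).
#' @export
read_tsv_with_header <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "# ")]
  as.data.frame(fread(text = paste(lines, collapse = "\n"), sep = "\t",
                      header = TRUE))
}

.thresholds <- function(cfg) {
  list(dmr_p_max = 0.01, dmr_fold_min = 2, dmr_fdr_method = "BH",
       deg_fdr_max = 0.001, deg_fold_min = 2, deg_k_min = 5,
       alpha_go = 0.01, alpha_kegg = 0.05,
       promoter_len = cfg$promoter_len, seed = cfg$seed)
}

#' Run the full pipeline on simulated data
#'
#' Executes simulate, qc, dmr, dmg, deg, enrich and methexpr in dependency
#' order, writing all outputs under `outdir` and a manifest with MD5
#' checksums. The run is a pure function of the configuration: re-running
#' with the same config yields byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created; existing files overwritten).
#' @param quiet Suppress progress messages.
#' @return Invisibly the manifest data.frame (`stage`, `file`, `md5`), also
#'   written to `manifest.tsv`. All analysis thresholds are echoed into
#'   every output header.
#' @export
run_all <- function(cfg = sim_config(), outdir, quiet = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  th <- .thresholds(cfg)
  say <- function(stage, ...) {
    if (!quiet) message("[", stage, "] ", ...)
  }
  for (d in c("", "fasta", "beds", "counts", "terms", "truth", "results")) {
    dir.create(file.path(outdir, d), showWarnings = FALSE, recursive = TRUE)
  }
  files <- list()
  reg <- function(stage, path) {
    files[[length(files) + 1L]] <<- data.frame(stage = stage, file = path)
    path
  }

  ## stage: simulate -------------------------------------------------------
  say("simulate", "genome, methylome, expression, terms (seed ", cfg$seed,
      ")")
  gen <- simulate_genome(cfg)
  bundle <- gen$bundle
  Biostrings::writeXStringSet(gen$genome,
                              reg("simulate",
                                  file.path(outdir, "fasta", "genome.fa")))
  fwrite(data.table(chrom = names(bundle$chrom_sizes),
                    len = bundle$chrom_sizes),
         reg("simulate", file.path(outdir, "fasta", "chrom.sizes")),
         sep = "\t", col.names = FALSE)
  write_gene_models_bed12(list(genes = bundle$genes, exons = bundle$exons),
                          reg("simulate",
                              file.path(outdir, "beds", "genes.bed12")))
  write_bed(bundle$cpg_islands,
            reg("simulate", file.path(outdir, "beds", "cpg_islands.bed")))
  rep_bed <- granges(bundle$repeats)
  mcols(rep_bed)$name <- mcols(bundle$repeats)$repeat_class
  write_bed(rep_bed, reg("simulate",
                         file.path(outdir, "beds", "repeats.bed")))

  meth <- simulate_methylome(cfg, bundle)
  lib_rows <- list()
  for (pid in names(meth$samples)) {
    for (side in c("case", "control")) {
      s <- meth$samples[[pid]][[side]]
      write_bed(s$peaks,
                reg("simulate", file.path(outdir, "beds",
                                          paste0(s$sample_id,
                                                 ".peaks.bed"))))
      write_bed(s$reads,
                reg("simulate", file.path(outdir, "beds",
                                          paste0(s$sample_id,
                                                 ".reads.bed"))))
      lib_rows[[s$sample_id]] <- data.frame(sample_id = s$sample_id,
                                            library_size = s$library_size)
    }
  }
  write_tsv_with_header(do.call(rbind, unname(lib_rows)),
                        reg("simulate",
                            file.path(outdir, "counts", "lib_sizes.tsv")),
                        th)
  write_tsv_with_header(meth$pairs,
                        reg("simulate", file.path(outdir, "pairs.tsv")), th)
  write_tsv_with_header(meth$truth,
                        reg("simulate",
                            file.path(outdir, "truth", "dmrs.tsv")), th)

  expr <- simulate_expression(cfg, bundle$genes$gene_id)
  counts_df <- data.frame(gene_id = rownames(expr$counts),
                          length = expr$gene_lengths[rownames(expr$counts)],
                          expr$counts, check.names = FALSE)
  write_tsv_with_header(counts_df,
                        reg("simulate",
                            file.path(outdir, "counts", "gene_counts.tsv")),
                        th)
  write_tsv_with_header(expr$truth,
                        reg("simulate",
                            file.path(outdir, "truth", "degs.tsv")), th)

  trm <- simulate_terms(cfg, bundle$genes$gene_id,
                        selected = expr$truth$gene_id)
  write_tsv_with_header(trm$terms,
                        reg("simulate",
                            file.path(outdir, "terms", "terms.tsv")), th)
  write_tsv_with_header(data.frame(term_id = trm$truth),
                        reg("simulate",
                            file.path(outdir, "truth", "terms.tsv")), th)

  ## stage: qc -------------------------------------------------------------
  say("qc", "read/peak distribution statistics")
  contexts <- classify_contexts(gen$genome)
  sites <- cpg_sites(contexts)
  ctx_tab <- as.data.frame(table(context = contexts$context))
  names(ctx_tab) <- c("context", "n_sites")
  write_tsv_with_header(ctx_tab,
                        reg("qc", file.path(outdir, "results",
                                            "qc_context_sites.tsv")), th)
  s1 <- meth$samples[[1]]$case
  write_tsv_with_header(coverage_by_depth(s1$reads, bundle$chrom_sizes),
                        reg("qc", file.path(outdir, "results",
                                            "qc_depth_profile.tsv")), th)
  write_tsv_with_header(density_binned_distribution(s1$peaks, sites),
                        reg("qc", file.path(outdir, "results",
                                            "qc_peak_cpg_density.tsv")), th)
  write_tsv_with_header(element_distribution(s1$reads, bundle),
                        reg("qc", file.path(outdir, "results",
                                            "qc_read_elements.tsv")), th)
  write_tsv_with_header(element_distribution(s1$peaks, bundle),
                        reg("qc", file.path(outdir, "results",
                                            "qc_peak_elements.tsv")), th)
  write_tsv_with_header(peak_length_distribution(s1$peaks),
                        reg("qc", file.path(outdir, "results",
                                            "qc_peak_lengths.tsv")), th)
  write_tsv_with_header(
    metagene_profile(s1$reads, bundle$cpg_islands, bundle$chrom_sizes),
    reg("qc", file.path(outdir, "results", "qc_cpg_island_profile.tsv")),
    th)

  ## stage: dmr + dmg ------------------------------------------------------
  say("dmr", "candidate construction and testing for ", cfg$n_pairs,
      " pairs")
  dmr_list <- list()
  dmg_list <- list()
  for (pid in names(meth$samples)) {
    p <- meth$samples[[pid]]
    cand <- build_candidates(p$case$peaks, p$control$peaks,
                             p$case$reads, p$control$reads,
                             p$case$library_size, p$control$library_size)
    dmrs <- call_true_dmrs(cand, p_max = th$dmr_p_max,
                           fold_min = th$dmr_fold_min,
                           fdr_method = th$dmr_fdr_method)
    dmr_list[[pid]] <- dmrs
    write_tsv_with_header(dmrs,
                          reg("dmr", file.path(outdir, "results",
                                               paste0("dmr_", pid,
                                                      ".tsv"))), th)
    tr <- dmrs_as_granges(dmrs)
    if (length(tr)) {
      bed <- granges(tr)
      mcols(bed)$name <- mcols(tr)$trend
      write_bed(bed, reg("dmr", file.path(outdir, "results",
                                          paste0("dmr_true_", pid,
                                                 ".bed"))))
    }
    dmg_list[[pid]] <- classify_dmgs(dmrs, bundle$elements)
    write_tsv_with_header(dmg_list[[pid]],
                          reg("dmg", file.path(outdir, "results",
                                               paste0("dmg_", pid,
                                                      ".tsv"))), th)
  }
  summ <- summarize_dmrs(dmr_list, dmg_list, bundle$elements)
  write_tsv_with_header(summ$per_pair,
                        reg("dmr", file.path(outdir, "results",
                                             "dmr_summary.tsv")), th)
  write_tsv_with_header(
    data.frame(pair_id = rownames(summ$dmg_by_chrom), summ$dmg_by_chrom,
               check.names = FALSE),
    reg("dmg", file.path(outdir, "results", "dmg_by_chrom.tsv")), th)

  ## stage: deg ------------------------------------------------------------
  say("deg", "pairwise exact tests and aggregation")
  deg <- call_pairwise_degs(expr$counts, expr$gene_lengths,
                            expr$lib_sizes, expr$pairs,
                            fdr_max = th$deg_fdr_max,
                            fold_min = th$deg_fold_min)
  write_tsv_with_header(deg, reg("deg", file.path(outdir, "results",
                                                  "deg_pairwise.tsv")), th)
  agg <- aggregate_across_pairs(deg, k_min = th$deg_k_min)
  write_tsv_with_header(agg$table,
                        reg("deg", file.path(outdir, "results",
                                             "deg_aggregated.tsv")), th)
  write_tsv_with_header(
    data.frame(gene_id = rownames(agg$ternary), agg$ternary,
               check.names = FALSE),
    reg("deg", file.path(outdir, "results", "deg_ternary.tsv")), th)
  if (nrow(agg$ternary) >= 2L) {
    cl <- cluster_degs(agg$ternary)
    write_tsv_with_header(
      data.frame(merge_i = cl$merge[, 1], merge_j = cl$merge[, 2],
                 height = cl$height),
      reg("deg", file.path(outdir, "results", "deg_linkage.tsv")), th)
    write_tsv_with_header(
      data.frame(leaf = cl$order, gene_id = cl$labels[cl$order]),
      reg("deg", file.path(outdir, "results", "deg_leaf_order.tsv")), th)
  }

  ## stage: enrich ---------------------------------------------------------
  say("enrich", "hypergeometric term enrichment")
  universe <- rownames(expr$counts)[rowSums(expr$counts) > 0]
  deg_genes <- unique(deg$gene_id[deg$call != "none"])
  enr <- enrich(deg_genes, trm$terms, universe,
                alpha_go = th$alpha_go, alpha_kegg = th$alpha_kegg)
  write_tsv_with_header(enr, reg("enrich",
                                 file.path(outdir, "results",
                                           "enrich_deg.tsv")), th)
  dmg_all <- unique(unlist(lapply(dmg_list, function(d)
    d$gene_id[d$status != "unmethylated"])))
  enr_dmg <- enrich(dmg_all, trm$terms, bundle$genes$gene_id,
                    alpha_go = th$alpha_go, alpha_kegg = th$alpha_kegg)
  write_tsv_with_header(enr_dmg,
                        reg("enrich", file.path(outdir, "results",
                                                "enrich_dmg.tsv")), th)

  ## stage: methexpr -------------------------------------------------------
  say("methexpr", "methylation-expression integration")
  rec <- integrate_meth_expr(dmg_list, deg)
  dist <- ratio_distribution(rec)
  write_tsv_with_header(dist,
                        reg("methexpr",
                            file.path(outdir, "results",
                                      "methexpr_distribution.tsv")), th)

  ## manifest --------------------------------------------------------------
  manifest <- do.call(rbind, files)
  manifest$file <- vapply(manifest$file, function(f)
    sub(paste0("^", outdir, "/?"), "", f), character(1))
  manifest$md5 <- unname(tools::md5sum(file.path(outdir, manifest$file)))
  fwrite(manifest, file.path(outdir, "manifest.tsv"), sep = "\t")
  say("done", nrow(manifest), " files written to ", outdir)
  invisible(manifest)
}
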