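#' Run the full downstream analysis over one or more samples
#'
#' Orchestrates filter -> stats -> density -> effects -> clusters/PAV for
#' every sample in the configuration and writes all artifacts into the
#' output directory: per-sample kept VCFs, SNP/InDel summary TSVs, region
#' BEDs, a shared-region BED, effect-call TSVs, large-effect gene tables, a
#' cluster TSV, a PAV TSV, and a machine-readable JSON manifest of the
#' headline numbers. Re-running with the same inputs and config reproduces
#' the same artifacts.
#'
#' @param cfg configuration list (or path to a YAML file with the same
#'   structure): `samples` is a named list with per-sample `vcf` and
#'   optionally `bedgraph` paths; `gff`, `fasta` and optionally `domains`,
#'   `unique_genes_bed` point at the shared inputs; `outdir` names the
#'   output directory; optional `filter` (arguments for [filter_config()]),
#'   `window_bp`, `flank_bp`, `cluster` (`max_span_bp`, `min_genes`),
#'   `pav_threshold`.
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  stopifnot(!is.null(cfg$samples), !is.null(cfg$outdir))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  fcfg <- do.call(filter_config, cfg$filter %||% list())
  window_bp <- cfg$window_bp %||% 100000L
  flank_bp <- cfg$flank_bp %||% 2000L
  pav_threshold <- cfg$pav_threshold %||% 1.0
  genome <- read_genome(cfg$fasta)
  genes <- if (!is.null(cfg$gff)) read_gff(cfg$gff, domains = cfg$domains) else list()
  lens <- genome_lengths(genome)

  out <- function(...) file.path(cfg$outdir, paste0(...))
  manifest <- list(samples = list())
  calls_per_sample <- list()
  kept_per_sample <- list()
  coverages <- list()

  for (s in names(cfg$samples)) {
    sc <- cfg$samples[[s]]
    raw <- read_vcf(sc$vcf, sample = sc$sample %||% NULL)
    rep <- apply_all_filters(raw, fcfg)
    kept <- rep$kept
    kept_per_sample[[s]] <- kept
    write_vcf(kept, out(s, ".kept.vcf"), sample = s)
    utils::write.table(rep$counts, out(s, ".filter_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    snps <- kept[is_snp(kept), , drop = FALSE]
    indels <- kept[is_indel(kept), , drop = FALSE]
    ss <- snp_summary(snps)
    is_ <- indel_summary(indels, genes)
    utils::write.table(ss$per_chromosome, out(s, ".snp_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    track <- window_counts(kept, lens, window_bp)
    calls <- call_regions(track)
    calls_per_sample[[s]] <- calls
    write_region_bed(calls[, c("chrom", "start", "end", "label")],
                     out(s, ".regions.bed"))

    eff <- classify_effects(kept, genes, genome, flank_bp)
    utils::write.table(eff, out(s, ".effects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    leg <- large_effect_genes(eff)
    utils::write.table(leg$counts, out(s, ".large_effect_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    cov <- NULL
    if (!is.null(sc$bedgraph) && !is.null(cfg$unique_genes_bed)) {
      uniq <- read_region_bed(cfg$unique_genes_bed)
      names(uniq)[names(uniq) == "label"] <- "gene_id"
      trackd <- read_bedgraph(sc$bedgraph)
      cov <- data.frame(gene_id = uniq$gene_id,
                        covered_fraction = vapply(seq_len(nrow(uniq)), function(i)
                          gene_coverage(trackd, list(chrom = uniq$chrom[i],
                                                     start = uniq$start[i],
                                                     end = uniq$end[i])), 0))
      coverages[[s]] <- cov
    }

    manifest$samples[[s]] <- list(
      n_raw = nrow(raw),
      filter_removed = stats::setNames(as.list(rep$counts$removed), rep$counts$stage),
      n_kept = nrow(kept),
      n_snps = ss$n_snps, titv = ss$titv_ratio, het_pct = ss$het_pct,
      n_indels = is_$n_total, n_ins = is_$n_ins, n_del = is_$n_del,
      indel_cds_pct = is_$pct_cds,
      n_rich = sum(calls$label == "rich"), n_poor = sum(calls$label == "poor"),
      n_large_effect = sum(eff$is_large_effect),
      n_large_effect_genes = length(leg$gene_ids))
  }

  if (length(calls_per_sample) >= 1L) {
    shared <- shared_regions(calls_per_sample, "rich")
    shared_bed <- shared[, c("chrom", "start", "end")]
    shared_bed$label <- rep("rich", nrow(shared_bed))
    write_region_bed(shared_bed, out("shared_rich.bed"))
    manifest$shared_rich_regions <- nrow(shared)
  }

  nbs <- Filter(function(g) g$is_nbs_lrr, genes)
  clusters <- detect_clusters(nbs, cfg$cluster$max_span_bp %||% 200000L,
                              cfg$cluster$min_genes %||% 4L)
  cl_out <- clusters[, c("chrom", "start", "end", "span", "n_genes")]
  cl_out$gene_ids <- vapply(clusters$gene_ids, paste, "", collapse = ",")
  utils::write.table(cl_out, out("clusters.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest$n_clusters <- nrow(clusters)

  if (length(coverages)) {
    pav <- call_presence(coverages, pav_threshold)
    pav_tab <- do.call(rbind, lapply(names(pav$calls), function(s)
      cbind(sample = s, pav$calls[[s]])))
    utils::write.table(pav_tab, out("pav.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$pav <- list(n_present = as.list(pav$n_present),
                         n_shared = length(pav$shared))
  }

  if (length(kept_per_sample) >= 2L)
    manifest$site_sharing <- compare_samples(kept_per_sample)$counts

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Cross-sample variant-site sharing
#'
#' Intersects variant sets across samples using exact
#' `(chrom, pos, ref, alt)` site identity (no fuzzy InDel matching):
#' reports pairwise and all-way shared-site counts.
#'
#' @param variant_sets named list of [variants()] data.frames.
#' @return list with `counts` (named list of pairwise `a&b` and `all`
#'   intersection counts) and `shared_all` (keys shared by every sample).
#' @export
compare_samples <- function(variant_sets) {
  stopifnot(length(variant_sets) >= 2L)
  keys <- lapply(variant_sets, function(v)
    unique(paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")))
  counts <- list()
  ns <- names(keys)
  for (i in seq_along(ns)) for (j in seq_along(ns)) {
    if (i < j)
      counts[[paste0(ns[i], "&", ns[j])]] <-
        length(intersect(keys[[i]], keys[[j]]))
  }
  shared <- Reduce(intersect, keys)
  counts[["all"]] <- length(shared)
  list(counts = counts, shared_all = sort(shared))
}
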