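#' Detect gene clusters among candidate genes
#'
#' Finds maximal runs of consecutive candidate genes (consecutive within
#' the supplied candidate list, per chromosome) whose span - first gene
#' start to last gene end, inclusive - is below `max_span_bp` and which
#' contain at least `min_genes` genes. Defaults implement the classical
#' resistance-gene cluster rule: more than three genes in less than 200 kb.
#' Overlapping possibilities are resolved greedily, leftmost-first, so the
#' reported clusters are disjoint.
#'
#' @param candidate_genes list of [gene_model()] objects (the candidate set,
#'   e.g. NBS-LRR genes), any order.
#' @param max_span_bp strict upper bound on the cluster span (default
#'   200,000).
#' @param min_genes minimum number of genes per cluster (default 4).
#' @return data.frame with one row per cluster: `chrom`, `start`, `end`,
#'   `span`, `n_genes` and a list-column `gene_ids`.
#' @export
detect_clusters <- function(candidate_genes, max_span_bp = 200000L, min_genes = 4L) {
  tab <- genes_table(candidate_genes)
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  out <- list()
  for (ch in unique(tab$chrom)) {
    g <- tab[tab$chrom == ch, , drop = FALSE]
    i <- 1L
    while (i <= nrow(g)) {
      j <- i
      hi <- g$end[i]
      while (j + 1L <= nrow(g) &&
             max(hi, g$end[j + 1L]) - g$start[i] + 1L < max_span_bp) {
        j <- j + 1L
        hi <- max(hi, g$end[j])
      }
      if (j - i + 1L >= min_genes) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = g$start[i], end = hi,
          span = hi - g$start[i] + 1L, n_genes = j - i + 1L,
          stringsAsFactors = FALSE)
        out[[length(out)]]$gene_ids <- list(g$gene_id[i:j])
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(out) == 0L) {
    res <- data.frame(chrom = character(), start = integer(), end = integer(),
                      span = integer(), n_genes = integer(), stringsAsFactors = FALSE)
    res$gene_ids <- list()
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of a gene covered by reads
#'
#' Computes the fraction of bases in `[gene$start, gene$end]` whose read
#' depth is at least `min_depth`, from a bedGraph-derived depth track.
#' Positions absent from the track count as depth 0.
#'
#' @param track a `depth_track` from [read_bedgraph()] (0-based half-open
#'   runs per chromosome).
#' @param gene a [gene_model()] or a list with `chrom`, `start`, `end`.
#' @param min_depth minimum depth for a base to count as covered.
#' @return covered fraction in `[0, 1]`, rounded to 4 decimals.
#' @export
gene_coverage <- function(track, gene, min_depth = 1) {
  runs <- track[[gene$chrom]]
  if (is.null(runs)) stopf("depth track has no chromosome %s", gene$chrom)
  g0 <- gene$start - 1L   # 0-based half-open gene interval [g0, g1)
  g1 <- gene$end
  ok <- runs$depth >= min_depth
  covered <- sum(pmax(0L, pmin(runs$end[ok], g1) - pmax(runs$start[ok], g0)))
  round_half_up(covered / (g1 - g0), 4)
}

#' Presence/absence calls from gene coverage
#'
#' A gene is called present in a sample when its covered fraction reaches
#' `threshold`; the default 1.0 implements the strict rule that only genes
#' fully covered by sequencing reads count as present. With several
#' samples, the shared set is the genes present in every sample.
#'
#' @param coverages either a data.frame with columns `gene_id`,
#'   `covered_fraction` (one sample) or a named list of such data.frames
#'   (one per sample, same gene universe).
#' @param threshold presence threshold on the covered fraction.
#' @return list with `calls` (per-sample data.frames gaining a logical
#'   `present` column), `n_present` (named counts) and `shared` (gene ids
#'   present in all samples).
#' @export
call_presence <- function(coverages, threshold = 1.0) {
  if (is.data.frame(coverages)) coverages <- list(sample = coverages)
  universe <- sort(unique(unlist(lapply(coverages, `[[`, "gene_id"))))
  for (s in names(coverages)) {
    ids <- sort(coverages[[s]]$gene_id)
    if (!identical(ids, universe))
      stopf("sample '%s' does not cover the shared gene universe", s)
  }
  calls <- lapply(coverages, function(x) {
    x$present <- x$covered_fraction >= threshold
    x
  })
  present_sets <- lapply(calls, function(x) x$gene_id[x$present])
  list(calls = calls,
       n_present = vapply(present_sets, length, 0L),
       shared = sort(Reduce(intersect, present_sets)))
}
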