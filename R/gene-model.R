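#' Construct a gene model
#'
#' A protein-coding gene with its genomic span, ordered CDS segments and
#' optional protein-domain intervals. All coordinates are 1-based inclusive
#' genomic positions; CDS segments are stored in ascending genomic order and
#' read in translation order (ascending on `+`, descending on `-`).
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive genomic span of the gene.
#' @param cds_segments two-column matrix or data.frame of CDS `start`,`end`
#'   pairs (1-based inclusive, non-overlapping, within `[start, end]`).
#' @param domains optional data.frame with columns `family`, `aa_start`,
#'   `aa_end` of protein-domain intervals (1-based amino-acid positions).
#' @param is_nbs_lrr logical; whether the gene is an NBS-LRR candidate.
#' @param incomplete logical; `TRUE` when the CDS length is not a multiple
#'   of three (model kept but excluded from codon-level classification).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end, cds_segments,
                       domains = NULL, is_nbs_lrr = FALSE, incomplete = FALSE) {
  stopifnot(strand %in% c("+", "-"))
  cds <- as.matrix(as.data.frame(cds_segments)[, 1:2])
  storage.mode(cds) <- "integer"
  colnames(cds) <- c("start", "end")
  cds <- cds[order(cds[, 1L]), , drop = FALSE]
  if (nrow(cds) == 0L) stopf("gene %s has no CDS segments", gene_id)
  if (any(cds[, 1L] > cds[, 2L])) stopf("gene %s: CDS segment with start > end", gene_id)
  if (nrow(cds) > 1L && any(cds[-1L, 1L] <= cds[-nrow(cds), 2L]))
    stopf("gene %s: overlapping CDS segments", gene_id)
  if (cds[1L, 1L] < start || cds[nrow(cds), 2L] > end)
    stopf("gene %s: CDS outside gene span", gene_id)
  len <- sum(cds[, 2L] - cds[, 1L] + 1L)
  if (len %% 3L != 0L && !incomplete) {
    warnf("gene %s: CDS length %d is not a multiple of 3; model flagged incomplete",
          gene_id, len)
    incomplete <- TRUE
  }
  if (!is.null(domains)) {
    domains <- as.data.frame(domains, stringsAsFactors = FALSE)
    stopifnot(all(c("family", "aa_start", "aa_end") %in% names(domains)))
    if (nrow(domains) && any(domains$aa_start < 1L | domains$aa_start > domains$aa_end))
      stopf("gene %s: invalid domain interval", gene_id)
  }
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand, start = as.integer(start), end = as.integer(end),
                 cds_segments = cds, domains = domains,
                 is_nbs_lrr = isTRUE(is_nbs_lrr), incomplete = isTRUE(incomplete)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) %d CDS segment(s), CDS %d bp%s%s\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand,
              nrow(x$cds_segments), cds_length(x),
              if (x$is_nbs_lrr) ", NBS-LRR" else "",
              if (x$incomplete) ", incomplete" else ""))
  invisible(x)
}

#' Total CDS length of a gene model in bp
#' @param gene a [gene_model()].
#' @return integer CDS length.
#' @export
cds_length <- function(gene) {
  sum(gene$cds_segments[, 2L] - gene$cds_segments[, 1L] + 1L)
}

# Protein length in amino acids, excluding the stop codon.
protein_length <- function(gene) cds_length(gene) %/% 3L - 1L

# CDS segments in translation order (ascending on +, descending on -).
cds_translation_order <- function(gene) {
  cds <- gene$cds_segments
  if (gene$strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
  cds
}

# 1-based offset of a genomic position within the translated CDS, or NA when
# the position is not coding.
cds_offset <- function(gene, pos) {
  cds <- gene$cds_segments
  k <- which(pos >= cds[, 1L] & pos <= cds[, 2L])
  if (length(k) != 1L) return(NA_integer_)
  asc <- if (k > 1L) sum(cds[seq_len(k - 1L), 2L] - cds[seq_len(k - 1L), 1L] + 1L) else 0L
  asc <- unname(asc + (pos - cds[k, 1L] + 1L))
  if (gene$strand == "+") asc else cds_length(gene) - asc + 1L
}

#' Summarise a list of gene models as a table
#'
#' @param genes list of [gene_model()] objects.
#' @return data.frame with one row per gene (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `cds_length`, `is_nbs_lrr`, `incomplete`).
#' @export
genes_table <- function(genes) {
  if (length(genes) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      cds_length = integer(), is_nbs_lrr = logical(),
                      incomplete = logical(), stringsAsFactors = FALSE))
  data.frame(gene_id = vapply(genes, `[[`, "", "gene_id"),
             chrom = vapply(genes, `[[`, "", "chrom"),
             strand = vapply(genes, `[[`, "", "strand"),
             start = vapply(genes, `[[`, 0L, "start"),
             end = vapply(genes, `[[`, 0L, "end"),
             cds_length = vapply(genes, cds_length, 0L),
             is_nbs_lrr = vapply(genes, `[[`, FALSE, "is_nbs_lrr"),
             incomplete = vapply(genes, `[[`, FALSE, "incomplete"),
             stringsAsFactors = FALSE)
}
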