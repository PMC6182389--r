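#' Read gene models from a GFF3 file
#'
#' Parses a GFF3 gene/mRNA/CDS hierarchy (via \pkg{rtracklayer}) into a list
#' of [gene_model()] objects, taking the mRNA with the longest total CDS as
#' the representative transcript per gene. Protein-domain intervals can be
#' supplied through a sidecar TSV (see [read_domains()]); a gene is flagged
#' NBS-LRR when any of its domain families is in `nbs_families`.
#'
#' @param path path to a GFF3 file.
#' @param domains optional path to a domain sidecar TSV, or a data.frame with
#'   columns `gene_id`, `family`, `aa_start`, `aa_end`.
#' @param nbs_families domain families marking a gene as NBS-LRR candidate.
#' @return named list of [gene_model()] objects, ordered by `(chrom, start)`.
#' @export
read_gff <- function(path, domains = NULL, nbs_families = "NB-ARC") {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  parent <- md$Parent
  parent1 <- vapply(seq_along(gr), function(i) {
    p <- parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[1L])
  }, "")

  gene_idx <- which(type == "gene")
  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  cds_idx <- which(type == "CDS")
  if (length(cds_idx) && any(is.na(parent1[cds_idx])))
    stopf("GFF3 %s: CDS feature without a Parent", path)

  if (is.character(domains)) domains <- read_domains(domains)

  genes <- list()
  for (gi in gene_idx) {
    gid <- ids[gi]
    mr <- mrna_idx[parent1[mrna_idx] == gid]
    # CDS grouped by transcript; tolerate CDS attached directly to the gene
    cds_by_tx <- list()
    if (length(mr)) {
      for (mi in mr) {
        ci <- cds_idx[parent1[cds_idx] == ids[mi]]
        if (length(ci)) cds_by_tx[[ids[mi]]] <- ci
      }
    }
    ci_direct <- cds_idx[parent1[cds_idx] == gid]
    if (length(ci_direct)) cds_by_tx[[gid]] <- ci_direct
    if (length(cds_by_tx) == 0L) next
    lens <- vapply(cds_by_tx, function(ci) sum(GenomicRanges::width(gr[ci])), 0L)
    ci <- cds_by_tx[[which.max(lens)]]
    seg <- cbind(start = GenomicRanges::start(gr[ci]), end = GenomicRanges::end(gr[ci]))
    dom <- NULL
    nbs <- FALSE
    if (!is.null(domains)) {
      dom <- domains[domains$gene_id == gid, c("family", "aa_start", "aa_end"), drop = FALSE]
      if (nrow(dom) == 0L) dom <- NULL else nbs <- any(dom$family %in% nbs_families)
    }
    genes[[gid]] <- gene_model(
      gene_id = gid, chrom = as.character(GenomicRanges::seqnames(gr[gi])),
      strand = as.character(GenomicRanges::strand(gr[gi])),
      start = GenomicRanges::start(gr[gi]), end = GenomicRanges::end(gr[gi]),
      cds_segments = seg, domains = dom, is_nbs_lrr = nbs)
  }
  tab <- genes_table(genes)
  genes[order(tab$chrom, tab$start)]
}

#' Write gene models as GFF3
#'
#' Emits a gene/mRNA/CDS hierarchy (one mRNA per gene) that [read_gff()]
#' reads back identically; used by the synthetic-data generator.
#'
#' @param genes list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    mrna <- paste0(g$gene_id, ".1")
    lines <- c(lines,
      paste(g$chrom, "wildvar", "gene", g$start, g$end, ".", g$strand, ".",
            paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$chrom, "wildvar", "mRNA", g$start, g$end, ".", g$strand, ".",
            paste0("ID=", mrna, ";Parent=", g$gene_id), sep = "\t"))
    cds <- g$cds_segments
    # GFF3 phase of each CDS segment, in translation order
    ord <- if (g$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    phase <- integer(nrow(cds))
    off <- 0L
    for (k in ord) {
      phase[k] <- (3L - off %% 3L) %% 3L
      off <- off + cds[k, 2L] - cds[k, 1L] + 1L
    }
    for (k in seq_len(nrow(cds))) {
      lines <- c(lines,
        paste(g$chrom, "wildvar", "CDS", cds[k, 1L], cds[k, 2L], ".", g$strand,
              phase[k], paste0("ID=", mrna, ".cds;Parent=", mrna), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-domain sidecar table
#'
#' @param path TSV with columns `gene_id`, `family`, `aa_start`, `aa_end`
#'   (1-based inclusive amino-acid positions).
#' @return data.frame of domain intervals.
#' @export
read_domains <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("gene_id", "family", "aa_start", "aa_end") %in% names(d)))
  d$aa_start <- as.integer(d$aa_start)
  d$aa_end <- as.integer(d$aa_end)
  d
}

#' Write a protein-domain sidecar table
#' @param genes list of [gene_model()] objects (only genes with domains are
#'   written) or a data.frame as returned by [read_domains()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domains <- function(genes, path) {
  if (is.data.frame(genes)) {
    d <- genes
  } else {
    rows <- lapply(genes, function(g) {
      if (is.null(g$domains) || nrow(g$domains) == 0L) return(NULL)
      cbind(gene_id = g$gene_id, g$domains[, c("family", "aa_start", "aa_end")])
    })
    d <- do.call(rbind, rows)
    if (is.null(d)) d <- data.frame(gene_id = character(), family = character(),
                                    aa_start = integer(), aa_end = integer())
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
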