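#' Classify a base substitution as transition or transversion
#'
#' Transitions exchange the two purines (A/G) or the two pyrimidines (C/T);
#' the eight remaining ordered substitutions are transversions.
#'
#' @param ref,alt single bases in `A`, `C`, `G`, `T` (vectorised).
#' @return character vector of `"Ti"` or `"Tv"`.
#' @examples
#' classify_substitution("C", "T")  # Ti
#' classify_substitution("G", "C")  # Tv
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") & ref != alt
  if (!all(ok)) stopf("substitutions must be two distinct bases in A/C/G/T")
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  unname(ifelse(purine[ref] == purine[alt], "Ti", "Tv"))
}

#' Transition/transversion ratio from counts
#'
#' @param n_ti,n_tv transition and transversion counts.
#' @param digits decimals for half-up rounding (`NULL` for the raw ratio).
#' @return the ratio, or `NA` when `n_tv` is zero.
#' @export
titv_ratio <- function(n_ti, n_tv, digits = 2) {
  if (n_tv == 0) return(NA_real_)
  r <- n_ti / n_tv
  if (is.null(digits)) r else round_half_up(r, digits)
}

#' Heterozygosity percentage from counts
#'
#' @param n_het,n_hom heterozygous and homozygous site counts.
#' @param digits decimals for half-up rounding (`NULL` for the raw value).
#' @return `100 * n_het / (n_het + n_hom)`, or `NA` for empty input.
#' @export
het_percentage <- function(n_het, n_hom, digits = 2) {
  if (n_het + n_hom == 0) return(NA_real_)
  p <- 100 * n_het / (n_het + n_hom)
  if (is.null(digits)) p else round_half_up(p, digits)
}

snp_block <- function(s) {
  ti <- classify_substitution(s$ref, s$alt)
  n_ti <- sum(ti == "Ti"); n_tv <- sum(ti == "Tv")
  n_het <- sum(s$zygosity == "het"); n_hom <- sum(s$zygosity == "hom")
  list(n_snps = nrow(s), n_ti = n_ti, n_tv = n_tv,
       titv_ratio = titv_ratio(n_ti, n_tv),
       n_het = n_het, n_hom = n_hom,
       het_pct = het_percentage(n_het, n_hom))
}

#' Summarise a SNP set
#'
#' Counts transitions/transversions and zygosity classes genome-wide and per
#' chromosome; ratios are computed in exact integer arithmetic and rounded
#' half-up to two decimals.
#'
#' @param snps SNP-only [variants()] data.frame.
#' @return object of class `snp_summary`: the genome-wide fields `n_snps`,
#'   `n_ti`, `n_tv`, `titv_ratio`, `n_het`, `n_hom`, `het_pct`, plus a
#'   `per_chromosome` data.frame with the same columns.
#' @export
snp_summary <- function(snps) {
  if (nrow(snps) && !all(is_snp(snps))) stopf("snp_summary expects SNPs only")
  if (nrow(snps) == 0L) {
    g <- list(n_snps = 0L, n_ti = 0L, n_tv = 0L, titv_ratio = NA_real_,
              n_het = 0L, n_hom = 0L, het_pct = NA_real_)
    per <- data.frame(chrom = character(), n_snps = integer(), n_ti = integer(),
                      n_tv = integer(), titv_ratio = numeric(), n_het = integer(),
                      n_hom = integer(), het_pct = numeric())
  } else {
    g <- snp_block(snps)
    per <- do.call(rbind, lapply(split(snps, snps$chrom), function(s)
      as.data.frame(snp_block(s))))
    per <- cbind(chrom = rownames(per), per)
    rownames(per) <- NULL
  }
  structure(c(g, list(per_chromosome = per)), class = "snp_summary")
}

#' @export
print.snp_summary <- function(x, ...) {
  cat(sprintf("<snp_summary> %d SNPs  Ti %d  Tv %d  Ti/Tv %s  Het %d  Hom %d  Het%% %s\n",
              x$n_snps, x$n_ti, x$n_tv, format(x$titv_ratio), x$n_het, x$n_hom,
              format(x$het_pct)))
  invisible(x)
}

# TRUE for each indel whose affected span intersects any CDS segment.
indel_in_cds <- function(indels, genes) {
  if (nrow(indels) == 0L) return(logical())
  hit <- rep(FALSE, nrow(indels))
  spans <- affected_span(indels)
  tab <- genes_table(genes)
  for (ch in unique(spans$chrom)) {
    gi <- which(tab$chrom == ch)
    if (length(gi) == 0L) next
    cds <- do.call(rbind, lapply(genes[gi], `[[`, "cds_segments"))
    ii <- which(spans$chrom == ch)
    q <- IRanges::IRanges(spans$start[ii], spans$end[ii])
    s <- IRanges::IRanges(cds[, 1L], cds[, 2L])
    hit[ii] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' Summarise an InDel set
#'
#' Counts insertions and deletions genome-wide and in coding sequence
#' (membership: the InDel's affected reference span intersects any CDS
#' segment), and tabulates the signed length spectrum
#' (`nchar(alt) - nchar(ref)`).
#'
#' @param indels InDel-only [variants()] data.frame.
#' @param genes list of [gene_model()] objects (may be empty; then no InDel
#'   is counted as coding).
#' @return object of class `indel_summary` with counts (`n_ins`, `n_del`,
#'   `n_total`, `n_cds`, `n_cds_ins`, `n_cds_del`), percentages (`pct_cds`,
#'   `pct_single_nt`, `pct_1_9bp`, `pct_triple_nt_genome`,
#'   `pct_triple_nt_cds`) and the signed `length_histogram`.
#' @export
indel_summary <- function(indels, genes = list()) {
  if (nrow(indels) && !all(is_indel(indels))) stopf("indel_summary expects InDels only")
  len <- indel_signed_length(indels)
  in_cds <- if (nrow(indels)) indel_in_cds(indels, genes) else logical()
  n_total <- nrow(indels)
  pct <- function(num, den) if (den == 0) NA_real_ else round_half_up(100 * num / den, 2)
  hist <- table(len)
  structure(list(
    n_ins = sum(len > 0L), n_del = sum(len < 0L), n_total = n_total,
    n_cds = sum(in_cds),
    n_cds_ins = sum(in_cds & len > 0L), n_cds_del = sum(in_cds & len < 0L),
    pct_cds = pct(sum(in_cds), n_total),
    pct_single_nt = pct(sum(abs(len) == 1L), n_total),
    pct_1_9bp = pct(sum(abs(len) >= 1L & abs(len) <= 9L), n_total),
    pct_triple_nt_genome = pct(sum(abs(len) == 3L), n_total),
    pct_triple_nt_cds = pct(sum(abs(len) == 3L & in_cds), sum(in_cds)),
    length_histogram = hist), class = "indel_summary")
}

#' @export
print.indel_summary <- function(x, ...) {
  cat(sprintf("<indel_summary> %d InDels (%d ins, %d del)  CDS %d (%s%%)  1bp %s%%  1-9bp %s%%  3bp-in-CDS %s%%\n",
              x$n_total, x$n_ins, x$n_del, x$n_cds, format(x$pct_cds),
              format(x$pct_single_nt), format(x$pct_1_9bp),
              format(x$pct_triple_nt_cds)))
  invisible(x)
}

#' Assign variants to genomic region categories
#'
#' Each variant position maps to exactly one of `GENIC` (inside a gene
#' span), `UPSTREAM` (within `flank_bp` of a gene's 5' end, strand-aware),
#' `DOWNSTREAM` (within `flank_bp` of a 3' end) or `INTERGENIC`. Precedence
#' on overlap: GENIC > UPSTREAM > DOWNSTREAM.
#'
#' @param v a [variants()] data.frame (or any data.frame with `chrom`,
#'   `pos`).
#' @param genes list of [gene_model()] objects.
#' @param flank_bp flank length in bp (default 2000).
#' @return character vector of categories, one per row of `v`.
#' @export
assign_region <- function(v, genes, flank_bp = 2000L) {
  n <- nrow(v)
  out <- rep("INTERGENIC", n)
  if (n == 0L || length(genes) == 0L) return(out)
  tab <- genes_table(genes)
  up_start <- ifelse(tab$strand == "+", tab$start - flank_bp, tab$end + 1L)
  up_end <- ifelse(tab$strand == "+", tab$start - 1L, tab$end + flank_bp)
  dn_start <- ifelse(tab$strand == "+", tab$end + 1L, tab$start - flank_bp)
  dn_end <- ifelse(tab$strand == "+", tab$end + flank_bp, tab$start - 1L)
  for (ch in unique(v$chrom)) {
    vi <- which(v$chrom == ch)
    gi <- which(tab$chrom == ch)
    if (length(gi) == 0L) next
    q <- IRanges::IRanges(v$pos[vi], v$pos[vi])
    olap <- function(s, e) {
      s <- pmax(1L, s)
      keep <- e >= s
      IRanges::overlapsAny(q, IRanges::IRanges(s[keep], e[keep]))
    }
    genic <- olap(tab$start[gi], tab$end[gi])
    up <- olap(up_start[gi], up_end[gi])
    dn <- olap(dn_start[gi], dn_end[gi])
    out[vi][dn] <- "DOWNSTREAM"
    out[vi][up] <- "UPSTREAM"
    out[vi][genic] <- "GENIC"
  }
  out
}
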