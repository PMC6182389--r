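#' Categories defining a large-effect variant
#'
#' Variants hitting the initiation or termination codon, a splice site, or
#' shifting the reading frame are classed as large-effect: they compromise
#' the integrity of the encoded product.
#'
#' @export
LARGE_EFFECT_CATEGORIES <- c("START_LOST", "NON_SYNONYMOUS_START",
                             "STOP_GAINED", "STOP_LOST",
                             "SPLICE_SITE_REGION", "SPLICE_SITE_ACCEPTOR",
                             "SPLICE_SITE_DONOR", "FRAME_SHIFT")

comp_base <- function(x) chartr("ACGT", "TGCA", x)

# Coding sequence of a gene in translation order (reverse complement on -).
gene_cds_seq <- function(gene, genome) {
  chr <- genome[[gene$chrom]]
  segs <- gene$cds_segments
  asc <- paste0(vapply(seq_len(nrow(segs)), function(k)
    as.character(Biostrings::subseq(chr, segs[k, 1L], segs[k, 2L])), ""),
    collapse = "")
  if (gene$strand == "+") asc
  else as.character(Biostrings::reverseComplement(Biostrings::DNAString(asc)))
}

# Genomic splice windows of a gene: the first/last two intronic bases of
# each intron (donor/acceptor in transcription orientation) plus intronic
# bases `region_intron[1]..region_intron[2]` from each junction.
splice_windows <- function(gene, intron_core = 2L, region_intron = c(3L, 8L)) {
  segs <- gene$cds_segments
  out <- data.frame(start = integer(), end = integer(), category = character(),
                    stringsAsFactors = FALSE)
  n <- nrow(segs)
  if (n < 2L) return(out)
  clip <- function(s, e, lo, hi) c(max(s, lo), min(e, hi))
  for (k in seq_len(n - 1L)) {
    lo <- segs[k, 2L] + 1L; hi <- segs[k + 1L, 1L] - 1L
    if (hi < lo) next
    left_core <- clip(lo, lo + intron_core - 1L, lo, hi)
    right_core <- clip(hi - intron_core + 1L, hi, lo, hi)
    if (gene$strand == "+") {
      donor <- left_core; acceptor <- right_core
    } else {
      donor <- right_core; acceptor <- left_core
    }
    reg1 <- clip(lo + region_intron[1L] - 1L, lo + region_intron[2L] - 1L, lo, hi)
    reg2 <- clip(hi - region_intron[2L] + 1L, hi - region_intron[1L] + 1L, lo, hi)
    out <- rbind(out,
      data.frame(start = c(donor[1L], acceptor[1L], reg1[1L], reg2[1L]),
                 end = c(donor[2L], acceptor[2L], reg1[2L], reg2[2L]),
                 category = c("SPLICE_SITE_DONOR", "SPLICE_SITE_ACCEPTOR",
                              "SPLICE_SITE_REGION", "SPLICE_SITE_REGION"),
                 stringsAsFactors = FALSE))
  }
  out[out$end >= out$start, , drop = FALSE]
}

classify_cds_snp <- function(gene, cds, pos, ref, alt,
                             alt_start_codons = c("ATG", "CTG", "TTG")) {
  k <- cds_offset(gene, pos)
  refc <- if (gene$strand == "+") ref else comp_base(ref)
  altc <- if (gene$strand == "+") alt else comp_base(alt)
  if (substr(cds, k, k) != refc)
    stopf("reference allele mismatch at %s:%d (VCF says %s, genome CDS has %s)",
          gene$chrom, pos, ref,
          if (gene$strand == "+") substr(cds, k, k) else comp_base(substr(cds, k, k)))
  ci <- (k - 1L) %/% 3L + 1L
  cstart <- (ci - 1L) * 3L + 1L
  cod <- substr(cds, cstart, cstart + 2L)
  ncod <- cod
  substr(ncod, k - cstart + 1L, k - cstart + 1L) <- altc
  old_aa <- Biostrings::GENETIC_CODE[[cod]]
  new_aa <- Biostrings::GENETIC_CODE[[ncod]]
  n_codons <- nchar(cds) %/% 3L
  category <-
    if (ci == 1L) {
      if (ncod %in% alt_start_codons) "NON_SYNONYMOUS_START" else "START_LOST"
    } else if (ci == n_codons) {
      if (new_aa == "*") "SYNONYMOUS" else "STOP_LOST"
    } else if (new_aa == old_aa) {
      "SYNONYMOUS"
    } else if (new_aa == "*") {
      "STOP_GAINED"
    } else {
      "NON_SYNONYMOUS"
    }
  list(category = category, aa_pos = ci)
}

#' Classify one variant against one gene model
#'
#' Codon- and splice-aware effect classification. CDS SNPs are classified
#' by mutating their codon and translating with the standard nuclear code
#' (strand-aware): a new stop is `STOP_GAINED`, a lost terminal stop
#' `STOP_LOST`; a change in the initiation codon is `START_LOST` unless the
#' new codon is an alternative start (`CTG`/`TTG`), then
#' `NON_SYNONYMOUS_START`; otherwise `SYNONYMOUS`/`NON_SYNONYMOUS`. CDS
#' InDels are `FRAME_SHIFT` when their length is not a multiple of three,
#' else `CODON_INDEL`. Intronic variants within two bases of a junction are
#' splice donor/acceptor (transcription orientation), within intronic bases
#' 3-8 `SPLICE_SITE_REGION`, else `INTRON`. Genic positions outside the CDS
#' span are `UTR`; positions outside the gene fall back to
#' `UPSTREAM`/`DOWNSTREAM`/`INTERGENIC` relative to this gene. An InDel
#' overlapping several classes takes the most severe
#' (splice > frameshift > codon).
#'
#' @param variant one-row [variants()] data.frame.
#' @param gene a complete [gene_model()].
#' @param genome a [Biostrings::DNAStringSet] with the gene's chromosome.
#' @param flank_bp up/downstream flank width (default 2000).
#' @return one-row data.frame: variant columns plus `gene_id`, `category`,
#'   `is_large_effect` and `aa_pos` (codon index for coding SNPs, else NA).
#' @examples
#' g <- Biostrings::DNAStringSet(c(Chr1 = paste0(
#'   "AAAA", "ATGGAATGGTAA", "AAAA")))
#' gm <- gene_model("g1", "Chr1", "+", 1, 20, cbind(5, 16))
#' v <- variants("Chr1", 13L, "G", "A", "hom", 40L)
#' classify_effect(v, gm, g)$category  # TGG -> TGA: STOP_GAINED
#' @export
classify_effect <- function(variant, gene, genome, flank_bp = 2000L) {
  stopifnot(nrow(variant) == 1L)
  row <- variant[, c("chrom", "pos", "ref", "alt", "vclass", "zygosity", "depth")]
  finish <- function(category, aa_pos = NA_integer_) {
    row$gene_id <- gene$gene_id
    row$category <- category
    row$is_large_effect <- category %in% LARGE_EFFECT_CATEGORIES
    row$aa_pos <- aa_pos
    rownames(row) <- NULL
    row
  }
  pos <- variant$pos
  span_end <- pos + nchar(variant$ref) - 1L
  if (variant$chrom != gene$chrom) return(finish("INTERGENIC"))
  if (span_end < gene$start || pos > gene$end) {
    up <- if (gene$strand == "+") c(gene$start - flank_bp, gene$start - 1L)
          else c(gene$end + 1L, gene$end + flank_bp)
    dn <- if (gene$strand == "+") c(gene$end + 1L, gene$end + flank_bp)
          else c(gene$start - flank_bp, gene$start - 1L)
    if (pos >= up[1L] && pos <= up[2L]) return(finish("UPSTREAM"))
    if (pos >= dn[1L] && pos <= dn[2L]) return(finish("DOWNSTREAM"))
    return(finish("INTERGENIC"))
  }
  segs <- gene$cds_segments
  cds_lo <- segs[1L, 1L]; cds_hi <- segs[nrow(segs), 2L]
  sw <- splice_windows(gene)
  overlaps <- function(tab) {
    hit <- tab[pos <= tab$end & span_end >= tab$start, , drop = FALSE]
    nrow(hit) > 0L
  }
  if (variant$vclass == "SNP") {
    if (!is.na(cds_offset(gene, pos))) {
      if (gene$incomplete)
        stopf("gene %s is incomplete (CDS not a multiple of 3); cannot classify coding SNP",
              gene$gene_id)
      r <- classify_cds_snp(gene, gene_cds_seq(gene, genome), pos,
                            variant$ref, variant$alt)
      return(finish(r$category, r$aa_pos))
    }
    if (pos >= cds_lo && pos <= cds_hi) {
      hit <- sw[pos >= sw$start & pos <= sw$end, , drop = FALSE]
      if (nrow(hit)) {
        sev <- c("SPLICE_SITE_DONOR", "SPLICE_SITE_ACCEPTOR", "SPLICE_SITE_REGION")
        return(finish(sev[min(match(hit$category, sev))]))
      }
      return(finish("INTRON"))
    }
    return(finish("UTR"))
  }
  # InDel: most severe overlapping class
  for (cat in c("SPLICE_SITE_DONOR", "SPLICE_SITE_ACCEPTOR", "SPLICE_SITE_REGION")) {
    if (overlaps(sw[sw$category == cat, , drop = FALSE])) return(finish(cat))
  }
  cds_tab <- data.frame(start = segs[, 1L], end = segs[, 2L])
  if (overlaps(cds_tab)) {
    shift <- abs(indel_signed_length(variant)) %% 3L != 0L
    aa <- cds_offset(gene, pos)
    aa_pos <- if (is.na(aa)) NA_integer_ else (aa - 1L) %/% 3L + 1L
    return(finish(if (shift) "FRAME_SHIFT" else "CODON_INDEL", aa_pos))
  }
  if (pos >= cds_lo && span_end <= cds_hi) return(finish("INTRON"))
  finish("UTR")
}

#' Classify all variants against a gene set
#'
#' Matches each variant to every gene whose span (extended by `flank_bp`)
#' contains its anchor position and classifies each (variant, gene) pair
#' with [classify_effect()]; variants matching no gene get a single
#' `INTERGENIC` row with `gene_id = NA`.
#'
#' @param v a [variants()] data.frame.
#' @param genes list of [gene_model()] objects.
#' @param genome a [Biostrings::DNAStringSet].
#' @param flank_bp flank width in bp.
#' @return data.frame of effect calls, one row per (variant, gene) pair.
#' @export
classify_effects <- function(v, genes, genome, flank_bp = 2000L) {
  tab <- genes_table(genes)
  rows <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    gi <- which(tab$chrom == v$chrom[i] &
                  v$pos[i] >= tab$start - flank_bp &
                  v$pos[i] <= tab$end + flank_bp)
    if (length(gi) == 0L) {
      row <- v[i, c("chrom", "pos", "ref", "alt", "vclass", "zygosity", "depth")]
      row$gene_id <- NA_character_
      row$category <- "INTERGENIC"
      row$is_large_effect <- FALSE
      row$aa_pos <- NA_integer_
      rows[[i]] <- row
    } else {
      rows[[i]] <- do.call(rbind, lapply(genes[gi], function(g)
        classify_effect(v[i, , drop = FALSE], g, genome, flank_bp)))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), vclass = character(),
                      zygosity = character(), depth = integer(),
                      gene_id = character(), category = character(),
                      is_large_effect = logical(), aa_pos = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genes carrying large-effect variants
#'
#' @param effects an effect-call data.frame from [classify_effects()].
#' @return list with `gene_ids` (genes having at least one large-effect
#'   call) and `counts` (per-gene large-effect SNP and InDel counts).
#' @export
large_effect_genes <- function(effects) {
  le <- effects[effects$is_large_effect & !is.na(effects$gene_id), , drop = FALSE]
  if (nrow(le) == 0L)
    return(list(gene_ids = character(),
                counts = data.frame(gene_id = character(), n_snp = integer(),
                                    n_indel = integer(), stringsAsFactors = FALSE)))
  counts <- do.call(rbind, lapply(split(le, le$gene_id), function(x)
    data.frame(gene_id = x$gene_id[1L],
               n_snp = sum(x$vclass == "SNP"),
               n_indel = sum(x$vclass != "SNP"), stringsAsFactors = FALSE)))
  counts <- counts[order(counts$gene_id), , drop = FALSE]
  rownames(counts) <- NULL
  list(gene_ids = counts$gene_id, counts = counts)
}

#' Non-synonymous/synonymous SNP ratios per protein domain family
#'
#' Counts `NON_SYNONYMOUS` and `SYNONYMOUS` coding SNP calls whose protein
#' position (`aa_pos`) lies in a domain interval of each family, across all
#' genes, and reports the Ns/Sy ratio per family.
#'
#' @param effects an effect-call data.frame from [classify_effects()].
#' @param genes list of [gene_model()] objects carrying `domains`.
#' @return data.frame `family`, `n_nonsynonymous`, `n_synonymous`, `ratio`
#'   (half-up to 2 decimals; `NA` when the family has no synonymous SNPs).
#' @export
ns_sy_by_domain <- function(effects, genes) {
  gmap <- stats::setNames(genes, vapply(genes, `[[`, "", "gene_id"))
  eff <- effects[effects$category %in% c("NON_SYNONYMOUS", "SYNONYMOUS") &
                   !is.na(effects$gene_id) & !is.na(effects$aa_pos), , drop = FALSE]
  acc <- list()
  for (i in seq_len(nrow(eff))) {
    g <- gmap[[eff$gene_id[i]]]
    if (is.null(g) || is.null(g$domains) || nrow(g$domains) == 0L) next
    d <- g$domains
    fams <- unique(d$family[eff$aa_pos[i] >= d$aa_start & eff$aa_pos[i] <= d$aa_end])
    for (f in fams) {
      cur <- acc[[f]] %||% c(ns = 0L, sy = 0L)
      if (eff$category[i] == "NON_SYNONYMOUS") cur["ns"] <- cur["ns"] + 1L
      else cur["sy"] <- cur["sy"] + 1L
      acc[[f]] <- cur
    }
  }
  if (length(acc) == 0L)
    return(data.frame(family = character(), n_nonsynonymous = integer(),
                      n_synonymous = integer(), ratio = numeric(),
                      stringsAsFactors = FALSE))
  out <- data.frame(family = names(acc),
                    n_nonsynonymous = vapply(acc, `[[`, 0L, "ns"),
                    n_synonymous = vapply(acc, `[[`, 0L, "sy"),
                    stringsAsFactors = FALSE)
  out$ratio <- ifelse(out$n_synonymous == 0L, NA_real_,
                      round_half_up(out$n_nonsynonymous / out$n_synonymous, 2))
  out <- out[order(out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes overlapping a set of genomic intervals
#'
#' Annotates arbitrary intervals (e.g. structural-variant or copy-number
#' calls) with the gene identifiers whose spans they intersect.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param genes list of [gene_model()] objects.
#' @return `intervals` with a list-column `gene_ids`.
#' @export
overlap_genes <- function(intervals, genes) {
  tab <- genes_table(genes)
  intervals$gene_ids <- lapply(seq_len(nrow(intervals)), function(i) {
    gi <- tab$chrom == intervals$chrom[i] &
      tab$start <= intervals$end[i] & tab$end >= intervals$start[i]
    tab$gene_id[gi]
  })
  intervals
}
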