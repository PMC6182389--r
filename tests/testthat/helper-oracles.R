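# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# --- filter oracles (quadratic, all pairs) ---------------------------------

oracle_depth_keep <- function(v, min_depth, max_depth) {
  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v))) keep[i] <- v$depth[i] >= min_depth && v$depth[i] <= max_depth
  keep
}

oracle_cluster_keep <- function(v, window_bp) {
  n <- nrow(v)
  if (n == 0L) return(logical())
  same <- outer(v$chrom, v$chrom, "==")
  close <- abs(outer(v$pos, v$pos, "-")) <= window_bp - 1L
  diag(close) <- FALSE
  rowSums(same & close) == 0L
}

oracle_near_indel_keep <- function(snps, indels, dist) {
  keep <- rep(TRUE, nrow(snps))
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(indels))) {
      if (snps$chrom[i] != indels$chrom[j]) next
      s <- indels$pos[j]
      e <- indels$pos[j] + nchar(indels$ref[j]) - 1L
      d <- max(0L, s - snps$pos[i], snps$pos[i] - e)
      if (d <= dist) { keep[i] <- FALSE; break }
    }
  }
  keep
}

# --- region-assignment oracle ----------------------------------------------

oracle_assign_region <- function(v, genes, flank_bp = 2000L) {
  out <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    cat_i <- "INTERGENIC"
    up <- dn <- FALSE
    for (g in genes) {
      if (g$chrom != v$chrom[i]) next
      p <- v$pos[i]
      if (p >= g$start && p <= g$end) { cat_i <- "GENIC"; break }
      five <- if (g$strand == "+") g$start else g$end
      three <- if (g$strand == "+") g$end else g$start
      if (g$strand == "+") {
        if (p >= five - flank_bp && p < five) up <- TRUE
        if (p > three && p <= three + flank_bp) dn <- TRUE
      } else {
        if (p > five && p <= five + flank_bp) up <- TRUE
        if (p >= three - flank_bp && p < three) dn <- TRUE
      }
    }
    if (cat_i != "GENIC") cat_i <- if (up) "UPSTREAM" else if (dn) "DOWNSTREAM" else "INTERGENIC"
    out[i] <- cat_i
  }
  out
}

# --- quantile oracle (manual type-7 interpolation) -------------------------

oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, 0)
}

# --- effect-classification oracle (full-CDS re-translation) ----------------

# Rebuilds the whole CDS from the (mutated) chromosome sequence, translates
# both with Biostrings, and derives the category from the differing codon.
oracle_cds_snp_category <- function(gene, genome, pos, ref, alt,
                                    alt_starts = c("ATG", "CTG", "TTG")) {
  chr <- as.character(genome[[gene$chrom]])
  stopifnot(substr(chr, pos, pos) == ref)
  mut <- chr
  substr(mut, pos, pos) <- alt
  build_cds <- function(seqstr) {
    segs <- gene$cds_segments
    s <- paste0(vapply(seq_len(nrow(segs)), function(k)
      substr(seqstr, segs[k, 1L], segs[k, 2L]), ""), collapse = "")
    if (gene$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  ref_cds <- build_cds(chr)
  alt_cds <- build_cds(mut)
  diff_at <- which(strsplit(ref_cds, "")[[1L]] != strsplit(alt_cds, "")[[1L]])
  stopifnot(length(diff_at) == 1L)
  ci <- (diff_at - 1L) %/% 3L + 1L
  n_codons <- nchar(ref_cds) %/% 3L
  tr <- function(s) as.character(Biostrings::translate(Biostrings::DNAString(s),
                                                       no.init.codon = TRUE))
  if (ci == 1L) {
    if (substr(alt_cds, 1L, 3L) %in% alt_starts) "NON_SYNONYMOUS_START" else "START_LOST"
  } else if (ci == n_codons) {
    last <- substr(alt_cds, nchar(alt_cds) - 2L, nchar(alt_cds))
    if (tr(last) == "*") "SYNONYMOUS" else "STOP_LOST"
  } else {
    pa <- tr(ref_cds); pb <- tr(alt_cds)
    aa_a <- substr(pa, ci, ci); aa_b <- substr(pb, ci, ci)
    if (aa_a == aa_b) "SYNONYMOUS"
    else if (aa_b == "*") "STOP_GAINED"
    else "NON_SYNONYMOUS"
  }
}

# --- cluster oracle (exhaustive window enumeration) ------------------------

oracle_clusters <- function(genes, max_span_bp, min_genes) {
  tab <- genes_table(genes)
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  res <- list()
  for (ch in unique(tab$chrom)) {
    g <- tab[tab$chrom == ch, , drop = FALSE]
    valid <- list()
    for (i in seq_len(nrow(g))) for (j in i:nrow(g)) {
      span <- max(g$end[i:j]) - g$start[i] + 1L
      if (span < max_span_bp && j - i + 1L >= min_genes)
        valid[[length(valid) + 1L]] <- c(i, j)
    }
    i_min <- 1L
    repeat {
      cand <- Filter(function(w) w[1L] >= i_min, valid)
      if (length(cand) == 0L) break
      starts <- vapply(cand, `[`, 0, 1L)
      i0 <- min(starts)
      j0 <- max(vapply(cand[starts == i0], `[`, 0, 2L))
      res[[length(res) + 1L]] <- list(chrom = ch, gene_ids = g$gene_id[i0:j0])
      i_min <- j0 + 1L
    }
  }
  res
}

# --- fixture builders ------------------------------------------------------

write_test_vcf <- function(records, path, sample = "S1") {
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample, sep = "\t"),
               records), path)
  path
}

random_variants <- function(n, chroms = c("Chr01", "Chr02"), max_pos = 100000L,
                            snp_frac = 0.8) {
  pos_pool <- lapply(chroms, function(ch) sample.int(max_pos, n))
  chrom <- sample(chroms, n, replace = TRUE)
  pos <- integer(n)
  for (ci in seq_along(chroms)) {
    idx <- which(chrom == chroms[ci])
    pos[idx] <- pos_pool[[ci]][seq_along(idx)]
  }
  snp <- runif(n) < snp_frac
  ref <- ifelse(snp, "A", strrep("A", sample(2:6, n, replace = TRUE)))
  alt <- ifelse(snp, "G", "A")
  variants(chrom, pos, ref, alt,
           sample(c("het", "hom"), n, replace = TRUE),
           sample(0:150, n, replace = TRUE))
}

# A hand-built single-gene fixture: + or - strand, two exons, known CDS.
# CDS (translation order): ATG AAA TGG GAA CCC TAA  (M K W E P *)
toy_gene <- function(strand = "+") {
  cds <- "ATGAAATGGGAACCCTAA"
  pad <- strrep("T", 50)
  ex1 <- substr(cds, 1, 9)    # first 3 codons
  ex2 <- substr(cds, 10, 18)  # last 3 codons
  intron <- strrep("C", 20)
  if (strand == "+") {
    chrom_seq <- paste0(pad, ex1, intron, ex2, pad)
  } else {
    rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    chrom_seq <- paste0(pad, rc(ex2), intron, rc(ex1), pad)
  }
  genome <- Biostrings::DNAStringSet(c(Chr01 = chrom_seq))
  gene <- gene_model("toy", "Chr01", strand, 41L, 108L,
                     cbind(c(51L, 80L), c(59L, 88L)))
  list(gene = gene, genome = genome, cds = cds)
}
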