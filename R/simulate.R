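# Deterministic synthetic-data generator: reference genome, gene models,
# per-sample variant sets and depth tracks, each with recorded ground truth.
# Every generator draws from its own RNG stream derived from the master seed
# and a label, so adding one output never perturbs the others.

#' Simulate a reference genome
#'
#' @param lengths named integer vector of chromosome lengths.
#' @param gc target GC content in `[0, 1]` (default 0.435, typical for a
#'   rice nuclear genome).
#' @param seed master seed; the same seed reproduces the sequence exactly.
#' @return a [Biostrings::DNAStringSet].
#' @export
simulate_genome <- function(lengths = c(Chr01 = 1000000L, Chr02 = 1000000L),
                            gc = 0.435, seed = 1L) {
  stopifnot(gc >= 0, gc <= 1, all(lengths >= 1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(seed, "genome"))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lengths, function(L)
    paste0(sample(names(p), L, replace = TRUE, prob = p), collapse = ""), "")
  Biostrings::DNAStringSet(stats::setNames(seqs, names(lengths)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# One random coding sequence of n_codons codons (incl. start and stop):
# ATG + non-stop codons + stop, so translation has no internal stops.
random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- names(Biostrings::GENETIC_CODE)
  nonstop <- setdiff(all_codons, stops)
  paste0(c("ATG", sample(nonstop, n_codons - 2L, replace = TRUE),
           sample(stops, 1L)), collapse = "")
}

place_gene <- function(gene_id, chrom, strand, gstart, cds, n_exons, utr = 100L) {
  L <- nchar(cds)
  # split CDS into n_exons chunks of >= 30 bp
  if (n_exons > 1L) {
    repeat {
      cuts <- sort(sample(seq(30L, L - 30L), n_exons - 1L))
      sizes <- diff(c(0L, cuts, L))
      if (all(sizes >= 30L)) break
    }
  } else sizes <- L
  introns <- if (n_exons > 1L) sample(100:400, n_exons - 1L, replace = TRUE) else integer()
  # ascending genomic exon i carries CDS chunk i on +, chunk n-i+1 on -,
  # so the genomic slot sizes follow the reversed chunk sizes on -
  layout_sizes <- if (strand == "+") sizes else rev(sizes)
  ex_start <- integer(n_exons); ex_end <- integer(n_exons)
  cur <- gstart + utr
  for (k in seq_len(n_exons)) {
    ex_start[k] <- cur
    ex_end[k] <- cur + layout_sizes[k] - 1L
    cur <- ex_end[k] + if (k < n_exons) introns[k] else 0L
  }
  # genomic sequence of each exon: chunk k in transcription order; on the
  # minus strand ascending exon i carries revcomp(chunk_{n-i+1})
  chunks <- character(n_exons)
  off <- 0L
  for (k in seq_len(n_exons)) {
    chunks[k] <- substr(cds, off + 1L, off + sizes[k])
    off <- off + sizes[k]
  }
  genomic <- if (strand == "+") chunks else
    rev(vapply(chunks, function(s)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))), ""))
  list(gene = gene_model(gene_id, chrom, strand, gstart, ex_end[n_exons] + utr,
                         cbind(ex_start, ex_end)),
       exon_seqs = genomic)
}

#' Simulate gene models embedded in a genome
#'
#' Places non-overlapping protein-coding genes (1-3 exons, ATG start, stop
#' codon, no internal stops) along the genome, writing their exon sequences
#' into the reference so codon-level classification is consistent with the
#' FASTA. A subset of genes are NBS-LRR candidates carrying NB-ARC and
#' LRR_1 domain intervals; clusters of candidates can be planted inside a
#' stated span.
#'
#' @param genome a [Biostrings::DNAStringSet] (modified copy returned).
#' @param n_genes number of background genes.
#' @param n_nbs how many of them carry NB-ARC/LRR_1 domains.
#' @param clusters optional list of planted clusters, each a list with
#'   `chrom`, `start`, `n` (genes) and `span` (bp); planted genes are
#'   NBS-LRR candidates.
#' @param min_gap,max_gap intergenic gap range between background genes.
#' @param seed master seed.
#' @return list with `genes` (list of [gene_model()]), `genome` (modified
#'   [Biostrings::DNAStringSet]) and `truth` (planted-cluster record).
#' @export
simulate_genes <- function(genome, n_genes = 20L, n_nbs = 8L, clusters = NULL,
                           min_gap = 4000L, max_gap = 12000L, seed = 1L) {
  stopifnot(n_nbs <= n_genes)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(seed, "genes"))
  lens <- genome_lengths(genome)
  chroms <- names(lens)
  seqs <- as.character(genome)
  genes <- list()
  gid <- 0L
  emit <- function(chrom, gstart, is_nbs) {
    gid <<- gid + 1L
    id <- sprintf("g%03d", gid)
    n_codons <- sample(60:160, 1L)
    pg <- place_gene(id, chrom, sample(c("+", "-"), 1L), gstart,
                     random_cds(n_codons), sample(1:3, 1L))
    g <- pg$gene
    if (g$end > lens[[chrom]]) return(NULL)
    cds <- g$cds_segments
    for (k in seq_len(nrow(cds)))
      substr(seqs[[chrom]], cds[k, 1L], cds[k, 2L]) <<- pg$exon_seqs[k]
    if (is_nbs) {
      pl <- protein_length(g)
      nb_end <- min(pl - 10L, max(40L, pl %/% 2L))
      g$domains <- data.frame(
        family = c("NB-ARC", "LRR_1"),
        aa_start = c(10L, nb_end + 5L),
        aa_end = c(nb_end, pl), stringsAsFactors = FALSE)
      g$is_nbs_lrr <- TRUE
    }
    genes[[id]] <<- g
    g
  }
  # planted clusters first so they claim their spans
  planted <- list()
  reserved <- lapply(chroms, function(ch) cbind(start = integer(), end = integer()))
  names(reserved) <- chroms
  for (cl in clusters %||% list()) {
    if (cl$start + cl$span - 1L > lens[[cl$chrom]])
      stopf("planted cluster exceeds chromosome %s", cl$chrom)
    slot <- cl$span %/% cl$n
    ids <- character(cl$n)
    for (j in seq_len(cl$n)) {
      g <- emit(cl$chrom, cl$start + (j - 1L) * slot, is_nbs = TRUE)
      if (is.null(g) || g$end > cl$start + cl$span - 1L)
        stopf("cannot fit %d genes into a %d bp span on %s", cl$n, cl$span, cl$chrom)
      ids[j] <- g$gene_id
    }
    planted[[length(planted) + 1L]] <- list(chrom = cl$chrom, start = cl$start,
                                            span = cl$span, gene_ids = ids)
    reserved[[cl$chrom]] <- rbind(reserved[[cl$chrom]],
                                  c(cl$start - max_gap, cl$start + cl$span + max_gap))
  }
  # background genes round-robin across chromosomes, skipping reserved spans
  nbs_flags <- sample(rep(c(TRUE, FALSE), c(n_nbs, n_genes - n_nbs)))
  cursors <- stats::setNames(rep(1L, length(chroms)), chroms)
  placed <- 0L
  tries <- 0L
  while (placed < n_genes && tries < n_genes * 50L) {
    tries <- tries + 1L
    ch <- chroms[(placed %% length(chroms)) + 1L]
    gstart <- cursors[[ch]] + sample(min_gap:max_gap, 1L)
    res <- reserved[[ch]]
    clash <- any(gstart >= res[, 1L] & gstart <= res[, 2L])
    if (clash) {
      cursors[[ch]] <- max(res[gstart >= res[, 1L] & gstart <= res[, 2L], 2L])
      next
    }
    g <- emit(ch, gstart, nbs_flags[placed + 1L])
    if (is.null(g)) {
      cursors[[ch]] <- lens[[ch]]  # chromosome full
      if (all(vapply(chroms, function(c2) cursors[[c2]] >= lens[[c2]] - 3000L, TRUE)))
        stopf("cannot pack %d genes into the genome", n_genes)
      next
    }
    cursors[[ch]] <- g$end
    placed <- placed + 1L
  }
  if (placed < n_genes) stopf("cannot pack %d genes into the genome", n_genes)
  tab <- genes_table(genes)
  genes <- genes[order(tab$chrom, tab$start)]
  list(genes = genes,
       genome = Biostrings::DNAStringSet(seqs),
       truth = list(seed = seed, n_genes = n_genes, n_nbs = n_nbs,
                    planted_clusters = planted))
}

# Truncated-geometric-plus-uniform InDel length law reproducing the field's
# marginals: P(1) = single_frac; lengths 2..9 share short_frac with
# geometric decay; lengths 10..30 share the remainder uniformly.
draw_indel_lengths <- function(n, single_frac = 0.46, short_frac = 0.45,
                               short_decay = 0.7, max_len = 30L) {
  comp <- sample(c(1L, 2L, 3L), n, replace = TRUE,
                 prob = c(single_frac, short_frac, 1 - single_frac - short_frac))
  out <- integer(n)
  out[comp == 1L] <- 1L
  k <- 2:9
  out[comp == 2L] <- sample(k, sum(comp == 2L), replace = TRUE,
                            prob = short_decay^(k - 2))
  out[comp == 3L] <- sample(10:max_len, sum(comp == 3L), replace = TRUE)
  out
}

ti_partner <- c(A = "G", G = "A", C = "T", T = "C")
tv_partners <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))

#' Simulate a per-sample variant set with planted truth
#'
#' Draws SNPs and InDels over the genome with controllable marginals:
#' transition/transversion ratio (`titv`), heterozygous fraction
#' (`het_frac`), InDel length spectrum, CDS triple-nucleotide InDel
#' fraction (`cds_triple_frac`), and planted variation-rich/-poor windows
#' whose background intensity is multiplied by `rich_multiplier` /
#' `poor_multiplier`. Read depths are Poisson with mean `mean_depth`.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param genes list of [gene_model()] objects (hosts for CDS InDels).
#' @param n_snps,n_indels variant counts to draw.
#' @param titv target transition/transversion ratio (transitions drawn with
#'   probability `titv / (1 + titv)`).
#' @param het_frac Bernoulli probability of a heterozygous genotype.
#' @param cds_triple_frac probability that a CDS InDel has length exactly 3.
#' @param cds_indel_frac fraction of InDels placed inside CDS segments.
#' @param del_frac fraction of InDels that are deletions.
#' @param rich_tiles,poor_tiles optional data.frames (`chrom`, `start`) of
#'   planted window starts aligned to the `window_bp` grid.
#' @param rich_multiplier,poor_multiplier intensity multipliers for planted
#'   windows.
#' @param window_bp window grid used for planting (default 100,000).
#' @param mean_depth mean read depth.
#' @param seed master seed.
#' @return list with `variants` (a [variants()] data.frame) and `truth`
#'   (all configured parameters and planted window sets).
#' @export
simulate_variants <- function(genome, genes = list(), n_snps = 10000L,
                              n_indels = 2000L, titv = 2.53,
                              het_frac = 0.1135, cds_triple_frac = 0.4274,
                              cds_indel_frac = 0.058, del_frac = 0.519,
                              rich_tiles = NULL, poor_tiles = NULL,
                              rich_multiplier = 10, poor_multiplier = 0.05,
                              window_bp = 100000L, mean_depth = 44,
                              seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(seed, "variants"))
  lens <- genome_lengths(genome)
  seqs <- as.character(genome)

  tiles <- do.call(rbind, lapply(names(lens), function(ch) {
    n_tiles <- ceiling(lens[[ch]] / window_bp)
    start <- (seq_len(n_tiles) - 1L) * as.integer(window_bp) + 1L
    data.frame(chrom = ch, start = start,
               end = pmin(start + as.integer(window_bp) - 1L, lens[[ch]]),
               stringsAsFactors = FALSE)
  }))
  tiles$mult <- 1
  mark <- function(tab, mult) {
    if (is.null(tab)) return()
    for (i in seq_len(nrow(tab))) {
      j <- which(tiles$chrom == tab$chrom[i] & tiles$start == tab$start[i])
      if (length(j) != 1L)
        stopf("planted window %s:%d is not on the %d bp grid inside the genome",
              tab$chrom[i], tab$start[i], window_bp)
      tiles$mult[j] <<- mult
    }
  }
  mark(rich_tiles, rich_multiplier)
  mark(poor_tiles, poor_multiplier)
  w <- tiles$mult * (tiles$end - tiles$start + 1L) / window_bp

  sample_positions <- function(n) {
    cnt <- stats::rmultinom(1L, n, prob = w)[, 1L]
    pos <- integer(0); chrom <- character(0)
    for (j in which(cnt > 0L)) {
      size <- tiles$end[j] - tiles$start[j] + 1L
      k <- min(cnt[j], size)
      pos <- c(pos, tiles$start[j] - 1L + sample.int(size, k))
      chrom <- c(chrom, rep(tiles$chrom[j], k))
    }
    list(chrom = chrom, pos = pos)
  }

  base_at <- function(chrom, pos) {
    vapply(seq_along(pos), function(i) substr(seqs[[chrom[i]]], pos[i], pos[i]), "")
  }
  seg_at <- function(chrom, pos, len) {
    vapply(seq_along(pos), function(i)
      substr(seqs[[chrom[i]]], pos[i], pos[i] + len[i] - 1L), "")
  }

  # SNPs
  sp <- sample_positions(n_snps)
  ref <- base_at(sp$chrom, sp$pos)
  is_ti <- stats::runif(length(ref)) < titv / (1 + titv)
  alt <- character(length(ref))
  alt[is_ti] <- ti_partner[ref[is_ti]]
  alt[!is_ti] <- vapply(ref[!is_ti], function(b) sample(tv_partners[[b]], 1L), "")

  # InDels: CDS-hosted subset plus genome-wide background
  n_cds <- round(n_indels * cds_indel_frac)
  n_bg <- n_indels - n_cds
  bg <- sample_positions(n_bg)
  bg_len <- draw_indel_lengths(n_bg)
  cds_pool <- do.call(rbind, lapply(genes, function(g) {
    s <- g$cds_segments
    data.frame(chrom = g$chrom, start = s[, 1L], end = s[, 2L],
               stringsAsFactors = FALSE)
  }))
  if (n_cds > 0L && (is.null(cds_pool) || nrow(cds_pool) == 0L))
    stopf("cds_indel_frac > 0 but no genes supplied")
  cds_len <- integer(0); cds_chrom <- character(0); cds_pos <- integer(0)
  if (n_cds > 0L) {
    triple <- stats::runif(n_cds) < cds_triple_frac
    cds_len <- integer(n_cds)
    cds_len[triple] <- 3L
    nt <- sum(!triple)
    if (nt > 0L) {
      draw <- draw_indel_lengths(nt * 2L + 10L)
      cds_len[!triple] <- draw[draw != 3L][seq_len(nt)]
    }
    seg_w <- cds_pool$end - cds_pool$start + 1L
    for (i in seq_len(n_cds)) {
      ok <- which(seg_w >= cds_len[i] + 1L)
      j <- ok[sample.int(length(ok), 1L)]
      cds_chrom[i] <- cds_pool$chrom[j]
      cds_pos[i] <- cds_pool$start[j] - 1L +
        sample.int(seg_w[j] - cds_len[i], 1L)
    }
  }
  ichrom <- c(bg$chrom, cds_chrom)
  ipos <- c(bg$pos, cds_pos)
  ilen <- c(bg_len, cds_len)
  # keep spans inside the chromosome
  fit <- ipos + ilen <= lens[ichrom]
  ichrom <- ichrom[fit]; ipos <- ipos[fit]; ilen <- ilen[fit]
  is_del <- stats::runif(length(ipos)) < del_frac
  iref <- ialt <- character(length(ipos))
  anchor <- base_at(ichrom, ipos)
  del <- which(is_del)
  iref[del] <- seg_at(ichrom[del], ipos[del], ilen[del] + 1L)
  ialt[del] <- anchor[del]
  ins <- which(!is_del)
  iref[ins] <- anchor[ins]
  ialt[ins] <- paste0(anchor[ins], vapply(ilen[ins], function(L)
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), ""))

  chrom <- c(sp$chrom, ichrom)
  pos <- c(sp$pos, ipos)
  ref <- c(ref, iref)
  alt <- c(alt, ialt)
  n <- length(pos)
  zyg <- ifelse(stats::runif(n) < het_frac, "het", "hom")
  depth <- stats::rpois(n, mean_depth)
  # drop duplicate sites so every (chrom, pos) is a single call
  key <- paste(chrom, pos)
  keep <- !duplicated(key)
  v <- variants(chrom[keep], pos[keep], ref[keep], alt[keep], zyg[keep], depth[keep])

  truth <- list(seed = seed, n_snps = n_snps, n_indels = n_indels,
                titv = titv, het_frac = het_frac,
                cds_triple_frac = cds_triple_frac,
                cds_indel_frac = cds_indel_frac, del_frac = del_frac,
                window_bp = as.integer(window_bp),
                rich_tiles = rich_tiles, poor_tiles = poor_tiles,
                rich_multiplier = rich_multiplier,
                poor_multiplier = poor_multiplier, mean_depth = mean_depth)
  list(variants = v, truth = truth)
}

#' Simulate per-sample depth tracks with planted absent genes
#'
#' Builds a constant-depth track over each chromosome, zeroing coverage
#' across the full span of every planted absent gene, so presence/absence
#' calling at any positive threshold recovers the planted sets exactly.
#'
#' @param genome a [Biostrings::DNAStringSet] or named length vector.
#' @param unique_genes data.frame (`gene_id`, `chrom`, `start`, `end`) of
#'   the pan-genome unique genes, or a list of [gene_model()] objects.
#' @param absent_sets named list: sample name -> character vector of absent
#'   gene ids (must be a subset of `unique_genes`).
#' @param base_depth depth outside absent genes.
#' @param seed master seed (recorded in the truth; the track is
#'   deterministic).
#' @return list with `tracks` (named list of `depth_track`) and `truth`.
#' @export
simulate_depth <- function(genome, unique_genes, absent_sets,
                           base_depth = 30, seed = 1L) {
  if (!is.data.frame(unique_genes)) unique_genes <- genes_table(unique_genes)
  lens <- genome_lengths(genome)
  unknown <- setdiff(unlist(absent_sets), unique_genes$gene_id)
  if (length(unknown))
    stopf("absent gene(s) not in the unique-gene set: %s",
          paste(unknown, collapse = ", "))
  tracks <- lapply(absent_sets, function(absent) {
    track <- lapply(names(lens), function(ch) {
      g <- unique_genes[unique_genes$chrom == ch &
                          unique_genes$gene_id %in% absent, , drop = FALSE]
      g <- g[order(g$start), , drop = FALSE]
      runs <- data.frame(start = integer(), end = integer(), depth = numeric())
      cur <- 0L
      for (i in seq_len(nrow(g))) {
        s0 <- g$start[i] - 1L; e0 <- g$end[i]
        if (s0 > cur) runs <- rbind(runs, data.frame(start = cur, end = s0,
                                                     depth = base_depth))
        runs <- rbind(runs, data.frame(start = s0, end = e0, depth = 0))
        cur <- e0
      }
      if (cur < lens[[ch]])
        runs <- rbind(runs, data.frame(start = cur, end = lens[[ch]],
                                       depth = base_depth))
      runs
    })
    names(track) <- names(lens)
    structure(track, class = "depth_track")
  })
  list(tracks = tracks,
       truth = list(seed = seed, base_depth = base_depth,
                    absent_sets = absent_sets))
}
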