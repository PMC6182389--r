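# toy_gene: CDS "ATG AAA TGG GAA CCC TAA" (M K W E P *) on two exons,
# genomic 51..59 (cds 1..9) and 80..88 (cds 10..18), intron 60..79.

test_that("codon-level SNP classification on a hand-built gene", {
  fx <- toy_gene("+")
  cls <- function(pos, ref, alt)
    classify_effect(variants("Chr01", pos, ref, alt, "hom", 50L),
                    fx$gene, fx$genome)$category
  expect_equal(cls(59L, "G", "A"), "STOP_GAINED")     # TGG -> TGA
  expect_equal(cls(82L, "A", "G"), "SYNONYMOUS")      # GAA -> GAG, both Glu
  expect_equal(cls(81L, "A", "T"), "NON_SYNONYMOUS")  # GAA -> GTA
  le <- classify_effect(variants("Chr01", 59L, "G", "A", "hom", 50L),
                        fx$gene, fx$genome)
  expect_true(le$is_large_effect)
  expect_equal(le$aa_pos, 3L)
})

test_that("start and stop codon edge cases", {
  fx <- toy_gene("+")
  cls <- function(pos, ref, alt)
    classify_effect(variants("Chr01", pos, ref, alt, "hom", 50L),
                    fx$gene, fx$genome)$category
  # ATG -> CTG / TTG are alternative starts; ATG -> AGG loses the start
  expect_equal(cls(51L, "A", "C"), "NON_SYNONYMOUS_START")
  expect_equal(cls(51L, "A", "T"), "NON_SYNONYMOUS_START")
  expect_equal(cls(52L, "T", "G"), "START_LOST")
  # stop codon TAA -> TAG stays a stop; TAA -> CAA is lost
  expect_equal(cls(88L, "A", "G"), "SYNONYMOUS")
  expect_equal(cls(86L, "T", "C"), "STOP_LOST")
})

test_that("InDel frame logic, splice-site geometry, flanks", {
  fx <- toy_gene("+")
  cls <- function(pos, ref, alt) {
    r <- classify_effect(variants("Chr01", pos, ref, alt, "hom", 50L),
                         fx$gene, fx$genome)
    list(cat = r$category, le = r$is_large_effect)
  }
  # 2-bp deletion inside CDS shifts the frame; 3-bp deletion does not
  expect_equal(cls(53L, "GAA", "G"), list(cat = "FRAME_SHIFT", le = TRUE))
  expect_equal(cls(53L, "GAAA", "G"), list(cat = "CODON_INDEL", le = FALSE))
  # intron 60..79: donor = 60..61, acceptor = 78..79 on +, region 3..8 in
  expect_equal(cls(60L, "C", "A")$cat, "SPLICE_SITE_DONOR")
  expect_equal(cls(61L, "C", "A")$cat, "SPLICE_SITE_DONOR")
  expect_equal(cls(79L, "C", "A")$cat, "SPLICE_SITE_ACCEPTOR")
  expect_equal(cls(64L, "C", "A")$cat, "SPLICE_SITE_REGION")
  expect_equal(cls(70L, "C", "A")$cat, "INTRON")
  # a deletion reaching into the donor window is splice, not frameshift
  expect_equal(cls(58L, "GGCC", "G")$cat, "SPLICE_SITE_DONOR")
  expect_true(cls(58L, "GGCC", "G")$le)
  # flanks and UTR
  expect_equal(cls(45L, "T", "A")$cat, "UTR")
  expect_equal(cls(30L, "T", "A")$cat, "UPSTREAM")
  expect_equal(cls(120L, "T", "A")$cat, "DOWNSTREAM")
})

test_that("minus-strand translation order and donor orientation", {
  fx <- toy_gene("-")
  # translation starts at the highest genomic exon base
  expect_equal(cds_offset(fx$gene, 88L), 1L)
  expect_equal(cds_offset(fx$gene, 51L), 18L)
  expect_equal(as.character(Biostrings::subseq(fx$genome[["Chr01"]], 88L, 88L)),
               "T")  # complement of the leading A of ATG
  # on -, the donor side of the intron is its high end
  expect_equal(classify_effect(variants("Chr01", 79L, "C", "A", "hom", 50L),
                               fx$gene, fx$genome)$category,
               "SPLICE_SITE_DONOR")
  expect_equal(classify_effect(variants("Chr01", 60L, "C", "A", "hom", 50L),
                               fx$gene, fx$genome)$category,
               "SPLICE_SITE_ACCEPTOR")
})

test_that("strand symmetry: reverse-complementing the locus preserves categories", {
  fwd <- toy_gene("+")
  L <- length(fwd$genome[["Chr01"]])
  genome_rc <- Biostrings::DNAStringSet(c(Chr01 = as.character(
    Biostrings::reverseComplement(fwd$genome[["Chr01"]]))))
  mirror <- function(a, b) c(L - b + 1L, L - a + 1L)
  segs <- fwd$gene$cds_segments
  gene_rc <- gene_model("toy_rc", "Chr01", "-",
                        L - fwd$gene$end + 1L, L - fwd$gene$start + 1L,
                        rbind(mirror(segs[2, 1], segs[2, 2]),
                              mirror(segs[1, 1], segs[1, 2])))
  rc_base <- function(b) chartr("ACGT", "TGCA", b)
  withr::local_seed(41)
  for (i in 1:25) {
    seg <- segs[sample(1:2, 1), ]
    pos <- sample(seg[1]:seg[2], 1)
    ref <- as.character(Biostrings::subseq(fwd$genome[["Chr01"]], pos, pos))
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    cat_f <- classify_effect(variants("Chr01", pos, ref, alt, "hom", 50L),
                             fwd$gene, fwd$genome)$category
    cat_r <- classify_effect(variants("Chr01", L - pos + 1L, rc_base(ref),
                                      rc_base(alt), "hom", 50L),
                             gene_rc, genome_rc)$category
    expect_equal(cat_r, cat_f)
  }
})

test_that("random CDS SNPs match the full re-translation oracle", {
  g <- simulate_genome(c(Chr01 = 150000L), seed = 44)
  sg <- simulate_genes(g, n_genes = 5L, n_nbs = 0L, seed = 44)
  withr::local_seed(44)
  for (i in seq_len(120L)) {
    gene <- sg$genes[[sample(length(sg$genes), 1L)]]
    seg <- gene$cds_segments[sample(nrow(gene$cds_segments), 1L), ]
    pos <- sample(seg[1]:seg[2], 1L)
    ref <- as.character(Biostrings::subseq(sg$genome[[gene$chrom]], pos, pos))
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    got <- classify_effect(variants(gene$chrom, pos, ref, alt, "hom", 50L),
                           gene, sg$genome)
    want <- oracle_cds_snp_category(gene, sg$genome, pos, ref, alt)
    expect_equal(got$category, want)
    expect_equal(got$is_large_effect, want %in% LARGE_EFFECT_CATEGORIES)
  }
})

test_that("reference mismatches are reported with their position", {
  fx <- toy_gene("+")
  base55 <- as.character(Biostrings::subseq(fx$genome[["Chr01"]], 55L, 55L))
  wrong <- setdiff(c("A", "C", "G", "T"), base55)
  expect_error(classify_effect(variants("Chr01", 55L, wrong[1], wrong[2], "hom", 50L),
                               fx$gene, fx$genome), "mismatch")
})

test_that("large-effect gene aggregation groups per gene", {
  eff <- data.frame(
    chrom = "Chr1", pos = 1:4, ref = "A", alt = c("G", "G", "G", "AT"),
    vclass = c("SNP", "SNP", "SNP", "INS"), zygosity = "hom", depth = 50L,
    gene_id = c("A", "A", "A", "B"),
    category = c("STOP_GAINED", "SYNONYMOUS", "NON_SYNONYMOUS", "CODON_INDEL"),
    is_large_effect = c(TRUE, FALSE, FALSE, FALSE),
    aa_pos = NA_integer_, stringsAsFactors = FALSE)
  le <- large_effect_genes(eff)
  expect_equal(le$gene_ids, "A")
  expect_equal(le$counts$n_snp, 1L)
  expect_equal(large_effect_genes(eff[0, ])$gene_ids, character())
  # random tables match a plain group-by
  withr::local_seed(45)
  eff2 <- eff[sample(1:4, 50, replace = TRUE), ]
  eff2$gene_id <- sample(c("A", "B", "C"), 50, replace = TRUE)
  le2 <- large_effect_genes(eff2)
  want <- sort(unique(eff2$gene_id[eff2$is_large_effect]))
  expect_equal(le2$gene_ids, want)
  for (g in want)
    expect_equal(le2$counts$n_snp[le2$counts$gene_id == g] +
                   le2$counts$n_indel[le2$counts$gene_id == g],
                 sum(eff2$gene_id == g & eff2$is_large_effect))
})

test_that("Ns/Sy ratios per domain family count protein positions in intervals", {
  gene <- toy_gene("+")$gene
  gene$domains <- data.frame(family = "NB-ARC", aa_start = 2L, aa_end = 4L)
  mk_eff <- function(aa, cat)
    data.frame(chrom = "Chr01", pos = 1L, ref = "A", alt = "G", vclass = "SNP",
               zygosity = "hom", depth = 50L, gene_id = "toy", category = cat,
               is_large_effect = FALSE, aa_pos = aa, stringsAsFactors = FALSE)
  eff <- rbind(mk_eff(2L, "NON_SYNONYMOUS"), mk_eff(3L, "NON_SYNONYMOUS"),
               mk_eff(4L, "SYNONYMOUS"), mk_eff(5L, "SYNONYMOUS"))
  r <- ns_sy_by_domain(eff, list(gene))
  expect_equal(r$n_nonsynonymous, 2L)
  expect_equal(r$n_synonymous, 1L)  # aa 5 lies outside the interval
  expect_equal(r$ratio, 2)
  r2 <- ns_sy_by_domain(eff[1:2, ], list(gene))
  expect_true(is.na(r2$ratio))
})

test_that("interval-to-gene overlap matches the quadratic oracle", {
  withr::local_seed(46)
  genes <- lapply(1:20, function(i) {
    s <- sample.int(500000L, 1)
    gene_model(paste0("g", i), sample(c("Chr01", "Chr02"), 1), "+",
               s, s + 4000L, cbind(s, s + 2999L))
  })
  iv <- data.frame(chrom = sample(c("Chr01", "Chr02"), 100, replace = TRUE),
                   start = sample.int(500000L, 100))
  iv$end <- iv$start + sample.int(20000L, 100)
  got <- overlap_genes(iv, genes)
  for (i in seq_len(nrow(iv))) {
    want <- vapply(genes, function(g)
      g$chrom == iv$chrom[i] && g$start <= iv$end[i] && g$end >= iv$start[i], TRUE)
    expect_equal(sort(got$gene_ids[[i]]),
                 sort(vapply(genes[want], `[[`, "", "gene_id")))
  }
})
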