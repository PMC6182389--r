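test_that("genome generation is deterministic with controlled GC", {
  g1 <- simulate_genome(c(Chr01 = 1000000L), gc = 0.435, seed = 61)
  g2 <- simulate_genome(c(Chr01 = 1000000L), gc = 0.435, seed = 61)
  expect_identical(as.character(g1), as.character(g2))
  expect_false(identical(as.character(g1),
                         as.character(simulate_genome(c(Chr01 = 1000000L),
                                                      gc = 0.435, seed = 62))))
  freq <- Biostrings::alphabetFrequency(g1[[1]])
  gc_obs <- sum(freq[c("G", "C")]) / sum(freq[c("A", "C", "G", "T")])
  expect_true(abs(gc_obs - 0.435) < 0.01)
  all_gc <- simulate_genome(c(Chr01 = 1000L), gc = 1, seed = 61)
  expect_equal(sum(Biostrings::alphabetFrequency(all_gc[[1]])[c("A", "T")]), 0L)
})

test_that("generated gene models are valid coding genes", {
  g <- simulate_genome(c(Chr01 = 200000L, Chr02 = 200000L), seed = 63)
  sg <- simulate_genes(g, n_genes = 12L, n_nbs = 5L, seed = 63)
  expect_length(sg$genes, 12L)
  expect_equal(sum(vapply(sg$genes, `[[`, FALSE, "is_nbs_lrr")), 5L)
  for (gene in sg$genes) {
    expect_equal(cds_length(gene) %% 3L, 0L)
    cds <- wildvar:::gene_cds_seq(gene, sg$genome)
    expect_equal(substr(cds, 1L, 3L), "ATG")
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    # single terminal stop, no internal stops
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("*", substr(prot, 1L, nchar(prot) - 1L), fixed = TRUE))
  }
  # NBS candidates carry NB-ARC and LRR_1 intervals within the protein
  nbs <- Filter(function(x) x$is_nbs_lrr, sg$genes)
  for (gene in nbs) {
    expect_setequal(gene$domains$family, c("NB-ARC", "LRR_1"))
    expect_true(all(gene$domains$aa_end <= wildvar:::protein_length(gene)))
  }
})

test_that("planted gene clusters are recovered by detect_clusters", {
  g <- simulate_genome(c(Chr01 = 600000L, Chr02 = 600000L), seed = 64)
  sg <- simulate_genes(g, n_genes = 6L, n_nbs = 0L,
                       clusters = list(list(chrom = "Chr01", start = 200001L,
                                            n = 5L, span = 150000L)),
                       seed = 64)
  nbs <- Filter(function(x) x$is_nbs_lrr, sg$genes)
  cl <- detect_clusters(nbs)
  expect_equal(nrow(cl), 1L)
  expect_setequal(cl$gene_ids[[1]], sg$truth$planted_clusters[[1]]$gene_ids)
  # n_genes = 0 with no clusters is an empty model set
  expect_length(simulate_genes(g, n_genes = 0L, n_nbs = 0L, seed = 64)$genes, 0L)
})

test_that("variant generation is deterministic and respects degenerate settings", {
  g <- simulate_genome(c(Chr01 = 400000L), seed = 65)
  a <- simulate_variants(g, n_snps = 2000L, n_indels = 400L,
                         cds_indel_frac = 0, seed = 65)
  b <- simulate_variants(g, n_snps = 2000L, n_indels = 400L,
                         cds_indel_frac = 0, seed = 65)
  expect_identical(a$variants, b$variants)
  hom_only <- simulate_variants(g, n_snps = 500L, n_indels = 0L, het_frac = 0,
                                cds_indel_frac = 0, seed = 65)
  expect_true(all(hom_only$variants$zygosity == "hom"))
  # VCF alleles agree with the reference genome
  chr <- as.character(g[[1]])
  v <- a$variants
  refs <- vapply(seq_len(nrow(v)), function(i)
    substr(chr, v$pos[i], v$pos[i] + nchar(v$ref[i]) - 1L), "")
  expect_equal(refs, v$ref)
})

test_that("configured marginals are recovered within three standard errors", {
  g <- simulate_genome(c(Chr01 = 1000000L, Chr02 = 1000000L), seed = 66)
  sg <- simulate_genes(g, n_genes = 16L, n_nbs = 0L, seed = 66)
  sv <- simulate_variants(sg$genome, sg$genes, n_snps = 20000L, n_indels = 5000L,
                          seed = 66)
  v <- sv$variants
  snps <- v[v$vclass == "SNP", ]
  ss <- snp_summary(snps)
  # Ti/Tv by the delta method on the transition share
  p <- sv$truth$titv / (1 + sv$truth$titv)
  se_r <- sqrt(p * (1 - p) / nrow(snps)) / (1 - p)^2
  expect_lt(abs(ss$n_ti / ss$n_tv - sv$truth$titv), 3 * se_r)
  # het fraction
  se_h <- sqrt(sv$truth$het_frac * (1 - sv$truth$het_frac) / nrow(snps))
  expect_lt(abs(ss$n_het / nrow(snps) - sv$truth$het_frac), 3 * se_h)
  # CDS triple-nucleotide fraction among CDS InDels
  is_ <- indel_summary(v[v$vclass != "SNP", ], sg$genes)
  f <- sv$truth$cds_triple_frac
  se_t <- sqrt(f * (1 - f) / is_$n_cds)
  expect_gt(is_$n_cds, 100L)
  expect_lt(abs(is_$pct_triple_nt_cds / 100 - f), 3 * se_t)
  # InDel length law: single-nucleotide and 1-9 bp shares near the field's
  len <- abs(nchar(v$alt) - nchar(v$ref))[v$vclass != "SNP"]
  expect_lt(abs(mean(len == 1) - 0.46), 0.05)
  expect_lt(abs(mean(len <= 9) - 0.91), 0.05)
})

test_that("depth simulation zeroes planted absent genes only", {
  genome <- c(Chr01 = 50000L)
  ug <- data.frame(gene_id = c("u1", "u2", "u3"), chrom = "Chr01",
                   start = c(1000L, 20000L, 40000L))
  ug$end <- ug$start + 2000L
  sd <- simulate_depth(genome, ug, list(s1 = "u3", s2 = character()),
                       base_depth = 0)
  # base_depth 0 makes every gene absent regardless of planting
  covs <- vapply(seq_len(nrow(ug)), function(i)
    gene_coverage(sd$tracks$s1, list(chrom = "Chr01", start = ug$start[i],
                                     end = ug$end[i])), 0)
  expect_equal(covs, c(0, 0, 0))
  sd2 <- simulate_depth(genome, ug, list(s1 = "u3"), base_depth = 25)
  covs2 <- vapply(seq_len(nrow(ug)), function(i)
    gene_coverage(sd2$tracks$s1, list(chrom = "Chr01", start = ug$start[i],
                                      end = ug$end[i])), 0)
  expect_equal(covs2, c(1, 1, 0))
  expect_error(simulate_depth(genome, ug, list(s1 = "nope")), "nope")
})
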