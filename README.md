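# wildvar

Downstream analysis of small genetic variants from high-depth plant
re-sequencing panels — the kind of study that re-sequences a wild rice
accession and its derived inbred lines against the Nipponbare reference
and asks where the genomes differ, how strongly, and which resistance
genes are hit.

`wildvar` takes per-sample variant calls (VCF), gene models (GFF3), a
reference genome (FASTA) and read-depth tracks (bedGraph), and computes:

* **Variant filtering** — the positional cluster filters (≥ 2 SNPs in a
  5-bp span, SNPs ≤ 5 bp from an InDel, ≥ 2 InDels in a 10-bp span) and
  the 11–100× depth window, as an exact partition with a per-stage report.
* **Summary statistics** — transition/transversion ratio
  (Ti/Tv = n(A↔G, C↔T) / n(other)), heterozygosity percentage
  100·Het/(Het+Hom), insertion/deletion counts with signed length spectra
  and CDS membership, and genomic-region assignment
  (GENIC / UPSTREAM 2 kb / DOWNSTREAM 2 kb / INTERGENIC).
* **Density scan** — variant counts in consecutive 100-kb windows, the
  boxplot five-number summary (type-7 quartiles), and variation-rich/-poor
  region calls as Tukey-fence outliers (count > Q3 + 1.5·IQR rich,
  < Q1 − 1.5·IQR poor), plus cross-sample shared-region intersection.
* **Effect annotation** — codon- and splice-aware classification of
  variants against gene models (standard genetic code, strand-aware), with
  the large-effect predicate over the eight categories START_LOST,
  NON_SYNONYMOUS_START, STOP_GAINED, STOP_LOST, SPLICE_SITE_REGION,
  SPLICE_SITE_ACCEPTOR, SPLICE_SITE_DONOR, FRAME_SHIFT; per-gene
  large-effect tables and non-synonymous/synonymous ratios per protein
  domain family.
* **Gene clusters and PAV** — resistance-gene cluster detection
  (≥ 4 candidate genes spanning < 200 kb) and coverage-based
  presence/absence calls over pan-genome unique genes (present when fully
  covered by reads, threshold configurable).
* **Synthetic data** — a deterministic generator for genomes, valid coding
  gene models, multi-sample variant sets (controllable Ti/Tv, zygosity,
  InDel length law, planted rich/poor windows) and depth tracks with
  planted absent genes, each with a recorded truth object.

`run_pipeline()` orchestrates all stages over a multi-sample configuration
and writes TSV/BED/VCF artifacts plus a JSON manifest.

## Worked example

Simulate a two-chromosome dataset with a planted variation-rich window and
a planted gene cluster, then run the main stages:

```r
library(wildvar)

genome <- simulate_genome(c(Chr01 = 500000L, Chr02 = 500000L), seed = 20)
sim <- simulate_genes(genome, n_genes = 10, n_nbs = 0,
                      clusters = list(list(chrom = "Chr01", start = 150001L,
                                           n = 4L, span = 120000L)),
                      seed = 20)
calls <- simulate_variants(sim$genome, sim$genes, n_snps = 8000, n_indels = 1500,
                           rich_tiles = data.frame(chrom = "Chr02", start = 200001L),
                           seed = 20)

rep <- apply_all_filters(calls$variants)
rep
#> <filter_report>
#>            stage removed
#> 1    snp_cluster    1365
#> 2 snp_near_indel     294
#> 3  indel_cluster     121
#> 4          depth       0
#> kept: 6341 SNP, 649 INS, 702 DEL

kept <- rep$kept
snp_summary(kept[kept$vclass == "SNP", ])
#> <snp_summary> 6341 SNPs  Ti 4543  Tv 1798  Ti/Tv 2.53  Het 703  Hom 5638  Het% 11.09

indel_summary(kept[kept$vclass != "SNP", ], sim$genes)
#> <indel_summary> 1351 InDels (649 ins, 702 del)  CDS 60 (4.44%)  1bp 43.45%  1-9bp 91.12%  3bp-in-CDS 38.33%

call_regions(window_counts(kept, genome_lengths(sim$genome)))
#>   chrom  start    end label count          name
#> 1 Chr02 200001 300000  rich  3313 Chr02:0.2-0.3

detect_clusters(Filter(function(g) g$is_nbs_lrr, sim$genes))[, 1:5]
#>   chrom  start    end  span n_genes
#> 1 Chr01 150001 240546 90546       4
```

Reading the output: the cluster filters removed 1,780 calls before the
depth window (which removed none here because simulated depths are
Poisson(44)); the kept SNPs recover the generator's configured Ti/Tv of
2.53 and ~11% heterozygosity; the one window called `rich` is exactly the
planted one (3,313 variants against a ~900-variant background, far above
the upper Tukey fence); and the planted 4-gene cluster is found spanning
91 kb.

On real data, replace the simulated objects with `read_vcf()`,
`read_gff()`, `read_genome()` and `read_bedgraph()`, or drive everything
from a config list with `run_pipeline()`.

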