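---
title: "Methods: downstream variant analysis in wildvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream variant analysis in wildvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildvar)
```

# Scope and model

`wildvar` implements the downstream half of a plant re-sequencing analysis:
it starts from per-sample small-variant calls (VCF), gene models (GFF3), a
reference genome (FASTA) and per-base depth tracks (bedGraph), and produces
the summary statistics, region calls, effect annotations, gene-cluster and
presence/absence results that such studies report. Alignment and raw variant
calling are out of scope; the package assumes calls have already been made
against a reference.

All internal coordinates are 1-based inclusive (the VCF/GFF convention);
conversion to BED's 0-based half-open convention happens only at the I/O
boundary, and composing the two conversions is the identity. InDel positions
anchor at the VCF record position as given; no re-normalisation or
left-alignment is performed, because none is specified for the upstream
calls and re-anchoring would silently change filter distances.

# Variant filters

Four filters are applied to each sample's call set
(`apply_all_filters()`), with thresholds collected in `filter_config()`:

* **SNP clusters** — two or more SNPs inside a 5-bp span are all discarded.
  A span of 5 consecutive bases holds positions $p \dots p+4$, so two SNPs
  conflict when their positions differ by at most 4 bp. Removal is
  symmetric: every member of a conflicting pair or run goes, since a
  clustered call gives no reason to trust either member.
* **SNPs near InDels** — a SNP within 5 bp of an InDel is discarded. The
  distance is measured to the InDel's *affected reference span*
  (`pos .. pos + nchar(ref) - 1`), not just its anchor, because the whole
  disturbed region is alignment-suspect. InDels are never removed by this
  filter.
* **InDel clusters** — two or more InDels whose anchors share a 10-bp span
  (difference at most 9 bp) are all discarded.
* **Depth window** — surviving SNPs/InDels must have read depth in
  [11, 100] inclusive; the analogous window for structural-variant calls
  starts at 21.

The positional filters run on the raw set and the depth filter on the
survivors, so that a depth-failing variant still disqualifies its
neighbours; `depth_first = TRUE` swaps the order for sensitivity analyses.
Each filter is idempotent, partitions its input exactly, and is insensitive
to input order; the test suite verifies all three properties and checks
every filter against a quadratic all-pairs oracle on random instances.

# Summary statistics

`classify_substitution()` labels the two purine–purine and
pyrimidine–pyrimidine exchanges as transitions (Ti) and the remaining eight
ordered substitutions as transversions (Tv). `snp_summary()` reports Ti/Tv
and zygosity counts genome-wide and per chromosome; heterozygosity uses
SNPs only, on the argument that SNPs are dense enough for SNP zygosity to
represent genome zygosity. `indel_summary()` reports insertion/deletion
counts, the signed length spectrum (`nchar(alt) - nchar(ref)`), and CDS
membership (the affected span intersects any CDS segment). Ratios and
percentages are computed in exact integer arithmetic and rounded half away
from zero to two decimals (`round_half_up()`), so printed values match what
hand division of the integer counts gives; base R's round-half-to-even
would differ on boundary cases.

`assign_region()` maps every position to exactly one of GENIC, UPSTREAM
(within 2 kb of a 5' end, strand-aware), DOWNSTREAM (2 kb, 3' end) or
INTERGENIC. Precedence on overlap is GENIC > UPSTREAM > DOWNSTREAM, the
usual annotator convention; both the flank width and the precedence are
arguments.

# Density scan and region calling

`window_counts()` tiles each chromosome into consecutive 100-kb windows
from position 1; a trailing window shorter than 100 kb is kept but flagged
partial and excluded from all statistics, since its count is not comparable
to full windows. `five_number()` computes the boxplot five-number summary
of the per-window counts, with quartiles by linear interpolation between
order statistics (`stats::quantile()` type 7). The convention is pinned
deliberately: quartile definitions differ across software, and the outlier
fences move with them.

`call_regions()` labels windows as variation-rich when the count exceeds
the upper Tukey fence $Q_3 + 1.5\,\mathrm{IQR}$ and variation-poor below
$Q_1 - 1.5\,\mathrm{IQR}$, the standard boxplot-outlier rule; the
multiplier is an argument. Fences are computed over all complete windows
pooled genome-wide, because the downstream quantities of interest are
genome-level rich/poor totals per sample; `scope = "chromosome"` computes
per-chromosome fences instead. With a constant count the IQR is zero and
nothing is called. `shared_regions()` intersects the window keys across
samples and refuses to compare call sets made on different window grids.

One consequence of fence-based calling worth stating: on a homogeneous
(Poisson-like) background, a fraction of a percent of ordinary windows
fall outside the fences by chance. Planted-truth recovery is therefore
exact only when planted densities sit far outside the fences and the
background is well-behaved; on real data the calls near the fence are the
ones to treat with caution.

# Effect classification

`classify_effect()` assigns one category per (variant, gene) pair.

For a CDS SNP the affected codon is rebuilt from the reference (reverse
complement on the minus strand), mutated, and translated with the standard
nuclear code. A new internal stop is `STOP_GAINED`; a change in the final
codon that destroys the stop is `STOP_LOST` (a stop-to-stop change is
synonymous). A change in codon 1 is `START_LOST` unless the new codon is
an alternative initiation codon (`CTG`/`TTG`, configurable), in which case
it is `NON_SYNONYMOUS_START`; this reading is declared rather than
inherited, since annotator semantics for the start-codon categories have
varied across versions. Otherwise the call is `SYNONYMOUS` or
`NON_SYNONYMOUS`.

CDS InDels are `FRAME_SHIFT` when their length is not a multiple of three
and `CODON_INDEL` otherwise; only the frameshift is a large-effect call.
Splice geometry follows the common annotator convention: the first and
last two intronic bases of each intron are donor and acceptor sites (in
transcription orientation), intronic bases 3–8 from either junction are
`SPLICE_SITE_REGION`, deeper intronic positions are `INTRON`. An InDel
overlapping several classes takes the most severe:
splice > frameshift > codon. Genic positions outside the CDS span are
`UTR`; positions outside the gene fall back to the flank categories.

The **large-effect** predicate is exactly the eight categories
`r paste(LARGE_EFFECT_CATEGORIES, collapse = ", ")`: variants compromising
initiation, termination, splicing or reading frame.
`large_effect_genes()` aggregates them per gene, and `ns_sy_by_domain()`
counts non-synonymous and synonymous coding SNPs whose protein position
(`ceil(cds_offset / 3)`) falls inside each protein-domain family's
intervals, reporting the Ns/Sy ratio per family (undefined when a family
has no synonymous SNPs).

The classifier is tested against an independent oracle that re-translates
the entire CDS before and after the variant, and against a mirror test
that reverse-complements the whole locus and expects identical categories.

# Gene clusters and presence/absence

`detect_clusters()` implements the classical resistance-gene cluster rule:
at least four candidate genes ("more than three") spanning less than
200 kb, where the span runs from the first gene's start to the last gene's
end inclusive. Candidacy is restricted to the supplied list (e.g. NBS-LRR
genes flagged by an NB-ARC domain); consecutiveness is within that list.
Overlapping possibilities are resolved greedily leftmost-first, producing
disjoint clusters, which matches how disjoint cluster counts are reported
in practice. Both thresholds are arguments.

`gene_coverage()` computes the exact fraction of gene bases at depth at
least `min_depth` from a bedGraph track (positions absent from the track
count as zero), rounded to 4 decimals. `call_presence()` marks a gene
present when its covered fraction reaches the threshold; the default 1.0
is the strict "fully covered" rule. The threshold is exposed because a
strict 100% is brittle under real sequencing noise — a single uncovered
base flips the call — so real-data analyses may prefer 0.95–0.99.

# Synthetic data generator

The generator exists so that every stage can be tested against recorded
truth without downloads. Its defaults are the study conditions the package
targets, fixed once:

| parameter | default | meaning |
|---|---|---|
| `gc` | 0.435 | genome GC content (rice-like) |
| `titv` | 2.53 | target transition/transversion ratio |
| `het_frac` | 0.1135 | heterozygous genotype probability |
| `cds_triple_frac` | 0.4274 | P(length = 3) for CDS InDels |
| `cds_indel_frac` | 0.058 | fraction of InDels placed in CDS |
| `del_frac` | 0.519 | deletion share of InDels |
| `mean_depth` | 44 | Poisson mean read depth |

Transitions are drawn with probability $r/(1+r)$ for target ratio $r$. The
genome-wide InDel length law is a three-part mixture — $P(1)=0.46$;
lengths 2–9 share 0.45 with geometric decay; lengths 10–30 share 0.09
uniformly — chosen to reproduce the two marginals such data show
(about 46% single-nucleotide and about 91% within 1–9 bp). CDS InDels are
length 3 with probability `cds_triple_frac` exactly (the alternative draw
is conditioned on length ≠ 3, so the configured value is the expectation).

Gene models are packed non-overlapping, each a 1–3-exon coding gene with
an ATG start, a single terminal stop and no internal stops; the exon
sequences are written into the returned genome so codon-level
classification agrees with the FASTA. NBS-LRR candidates carry NB-ARC and
LRR_1 intervals; clusters of candidates can be planted inside a stated
span. Variant placement within a window is uniform, with planted rich/poor
windows multiplying the background intensity (defaults 10 and 0.05);
clustering violations for filter tests are planted explicitly in fixtures
rather than emergent. Depth tracks are constant at `base_depth` with
planted absent genes zeroed across their span.

Every generator draws from its own RNG stream derived from the master seed
and a fixed label, so regenerating one output never perturbs another, and
identical seeds give identical outputs.

What the generator does *not* emulate — mapping bias, depth waves,
alignment artefacts around repeats, error-driven false calls, linkage
structure — bounds what passing tests show: they demonstrate that the
algorithms compute what they claim on data matching their assumptions, not
that the upstream calls on real data are correct.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
statistical checks are sharp while the whole suite stays fast: filter
oracle equivalence on twenty 1,000-variant instances; region recovery on a
2 × 5 Mb genome (100 windows, about 20,000 variants, planted windows at
10× and 0.05× background); classifier equivalence on 500 random coding
variants; parameter recovery at 100,000 variants, where three standard
errors correspond to about ±0.05 on Ti/Tv, ±0.003 on the heterozygous
fraction and ±0.04 on the CDS-triple fraction. Genome-scale totals from
the original study (millions of sites per accession) require the raw
sequencing data and are not recomputable here; printed count tables are
instead used as inputs to the ratio computations.

Ties and degenerate inputs are handled explicitly: zero transversions or
zero synonymous SNPs yield `NA` ratios rather than errors; an empty
variant set produces zero-count summaries; constant window counts produce
no region calls; quartiles need at least one complete window.

# Known limitations

* Multi-allelic records are split per alternate allele carried by the
  sample's genotype; alleles present in the file but absent from the
  genotype are not emitted for that sample.
* Effect classification requires complete gene models (CDS length a
  multiple of three); incomplete models are flagged at parse time and
  refuse codon-level calls rather than guessing a frame.
* One representative transcript per gene (longest CDS); isoform-specific
  effects are out of scope.
* The boxplot-outlier region caller has no false-discovery control; it is
  a descriptive scan, not a segmentation method.
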