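#' Construct a variant table
#'
#' The central small-variant container: one row per called variant for one
#' sample, in reference coordinates. Positions are 1-based; for InDels `pos`
#' anchors at the VCF record position (left-aligned as given, no
#' re-normalisation). The variant class is derived from the alleles:
#' SNP when both alleles are single differing bases, INS when the alternate
#' is longer than the reference, DEL when shorter.
#'
#' @param chrom character chromosome names.
#' @param pos integer 1-based positions of the first affected base.
#' @param ref reference allele strings.
#' @param alt alternate allele strings.
#' @param zygosity `"het"` (heterozygous) or `"hom"` (homozygous for the
#'   alternate allele).
#' @param depth non-negative integer read depths.
#' @return a `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `zygosity`, `depth`, `vclass`, sorted by `(chrom, pos)`.
#' @examples
#' variants("Chr01", c(100L, 200L), c("A", "AT"), c("G", "A"),
#'          c("hom", "het"), c(40L, 30L))
#' @export
variants <- function(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), zygosity = character(),
                     depth = integer()) {
  n <- length(pos)
  stopifnot(length(chrom) %in% c(1L, n), length(ref) %in% c(1L, n),
            length(alt) %in% c(1L, n),
            length(zygosity) %in% c(0L, 1L, n), length(depth) %in% c(0L, 1L, n))
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  if (length(zygosity) == 0L) zygosity <- rep("hom", n)
  if (length(depth) == 0L) depth <- rep(0L, n)
  zygosity <- rep_len(as.character(zygosity), n)
  depth <- rep_len(as.integer(depth), n)
  if (n > 0 && any(pos < 1L)) stopf("variant positions must be >= 1")
  if (n > 0 && any(depth < 0L)) stopf("variant depths must be >= 0")
  bad <- setdiff(unique(zygosity), c("het", "hom"))
  if (length(bad)) stopf("unknown zygosity value(s): %s", paste(bad, collapse = ", "))
  v <- data.frame(chrom = rep_len(as.character(chrom), n),
                  pos = as.integer(pos),
                  ref = toupper(ref),
                  alt = toupper(alt),
                  zygosity = zygosity,
                  depth = depth,
                  stringsAsFactors = FALSE)
  v$vclass <- variant_class(v$ref, v$alt)
  v <- v[order(v$chrom, v$pos, v$ref, v$alt), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Classify alleles as SNP, insertion or deletion
#'
#' @param ref,alt allele strings.
#' @return character vector of `"SNP"`, `"INS"` or `"DEL"`.
#' @export
variant_class <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  out <- character(length(lr))
  out[lr == 1L & la == 1L] <- "SNP"
  out[la > lr] <- "INS"
  out[la < lr] <- "DEL"
  if (any(out == "")) {
    i <- which(out == "")[1L]
    stopf("cannot classify alleles ref=%s alt=%s (equal-length MNPs are not supported)",
          ref[i], alt[i])
  }
  same <- out == "SNP" & ref == alt
  if (any(same)) stopf("SNP with identical ref and alt allele at index %d", which(same)[1L])
  out
}

# Affected reference span of each variant, 1-based inclusive:
# pos .. pos + nchar(ref) - 1 (an insertion touches only its anchor base).
affected_span <- function(v) {
  data.frame(chrom = v$chrom, start = v$pos,
             end = v$pos + nchar(v$ref) - 1L, stringsAsFactors = FALSE)
}

# Signed InDel length: nchar(alt) - nchar(ref); > 0 insertion, < 0 deletion.
indel_signed_length <- function(v) nchar(v$alt) - nchar(v$ref)

is_snp <- function(v) v$vclass == "SNP"
is_indel <- function(v) v$vclass %in% c("INS", "DEL")

assert_sorted <- function(v) {
  if (nrow(v) > 1L) {
    o <- order(v$chrom, v$pos)
    if (!identical(o, seq_len(nrow(v)))) stopf("variants must be sorted by (chrom, pos)")
  }
  invisible(v)
}
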