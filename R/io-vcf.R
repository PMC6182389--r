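#' Read one sample's variants from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and extracts the variants carried by
#' one sample as a [variants()] table. Multi-allelic records are split into
#' one row per alternate allele the sample's genotype actually carries; a
#' genotype homozygous for one alternate allele (`1/1`) yields a single
#' homozygous row, while any genotype mixing alleles (`0/1`, `1/2`) yields
#' heterozygous rows. Depth is taken from the per-sample `DP` FORMAT field,
#' falling back to the `INFO` `DP` field, then 0.
#'
#' @param path path to an uncompressed or gzipped VCF file.
#' @param sample sample name as in the VCF header; defaults to the first
#'   sample when the file has exactly one.
#' @return a [variants()] data.frame sorted by `(chrom, pos)`.
#' @export
read_vcf <- function(path, sample = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) return(variants())
  samples <- colnames(vcf@gt)[-1L]
  if (is.null(sample)) {
    if (length(samples) != 1L)
      stopf("VCF has %d samples; specify one of: %s", length(samples),
            paste(samples, collapse = ", "))
    sample <- samples[1L]
  }
  if (!sample %in% samples) stopf("sample '%s' not present in VCF %s", sample, path)
  gt <- vcfR::extract.gt(vcf, element = "GT")[, sample]
  if (all(is.na(gt))) stopf("no GT field for sample '%s' in %s", sample, path)
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)[, sample])
  info_dp <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "DP")))
  if (length(info_dp) == 0L) info_dp <- rep(NA_real_, n)
  depth <- ifelse(is.na(dp), info_dp, dp)
  depth[is.na(depth)] <- 0

  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- gt[i]
    if (is.na(g)) next
    al <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1L]]))
    if (any(is.na(al)))
      stopf("malformed genotype '%s' for sample '%s' at record %d", g, sample, i)
    carried <- unique(al[al > 0L])
    if (length(carried) == 0L) next
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    if (max(carried) > length(alts))
      stopf("genotype allele index %d exceeds ALT count at record %d", max(carried), i)
    zyg <- ifelse(vapply(carried, function(a) length(al) > 1L && all(al == a), FALSE),
                  "hom", "het")
    out[[i]] <- data.frame(chrom = unname(fix[i, "CHROM"]),
                           pos = as.integer(fix[i, "POS"]),
                           ref = unname(fix[i, "REF"]), alt = alts[carried],
                           zygosity = zyg, depth = as.integer(depth[i]),
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(variants())
  variants(out$chrom, out$pos, out$ref, out$alt, out$zygosity, out$depth)
}

#' Write a variant table as a single-sample VCF
#'
#' Emits a minimal valid VCF 4.2 file with `GT:DP` genotypes reconstructed
#' from the zygosity and depth columns (`hom` becomes `1/1`, `het` `0/1`).
#' Rows are written sorted; split multi-allelic rows stay split, so a
#' write/read round trip is the identity on the variant table.
#'
#' @param v a [variants()] data.frame.
#' @param path output path.
#' @param sample sample name for the header column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(v, path, sample = "SAMPLE") {
  v <- v[order(v$chrom, v$pos, v$ref, v$alt), , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=wildvar",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", sample, sep = "\t"))
  body <- if (nrow(v)) {
    gt <- ifelse(v$zygosity == "hom", "1/1", "0/1")
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT:DP",
          paste0(gt, ":", v$depth), sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
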