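#' Variant filter configuration
#'
#' Thresholds for the positional and depth filters applied to per-sample
#' variant calls before any downstream statistics:
#' two or more SNPs inside a `snp_window_bp` span are discarded, SNPs within
#' `snp_indel_dist_bp` of an InDel's affected reference span are discarded,
#' two or more InDels inside an `indel_window_bp` span are discarded, and
#' surviving variants must have read depth in `[min_depth, max_depth]`.
#'
#' @param snp_window_bp SNP cluster window span in bp (default 5; two SNPs
#'   conflict when both fit inside it, i.e. positions differ by at most
#'   `snp_window_bp - 1`).
#' @param snp_indel_dist_bp maximum SNP-to-InDel distance considered "near".
#' @param indel_window_bp InDel cluster window span in bp (default 10).
#' @param min_depth,max_depth inclusive depth window for SNPs/InDels.
#' @param sv_min_depth lower depth bound used for structural variants when
#'   the same filter is applied to SV calls.
#' @param depth_first apply the depth filter before (rather than after) the
#'   positional filters in [apply_all_filters()].
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(snp_window_bp = 5L, snp_indel_dist_bp = 5L,
                          indel_window_bp = 10L, min_depth = 11L,
                          max_depth = 100L, sv_min_depth = 21L,
                          depth_first = FALSE) {
  stopifnot(snp_window_bp >= 1L, snp_indel_dist_bp >= 1L, indel_window_bp >= 1L,
            min_depth >= 0L, min_depth <= max_depth, sv_min_depth >= 0L)
  structure(list(snp_window_bp = as.integer(snp_window_bp),
                 snp_indel_dist_bp = as.integer(snp_indel_dist_bp),
                 indel_window_bp = as.integer(indel_window_bp),
                 min_depth = as.integer(min_depth),
                 max_depth = as.integer(max_depth),
                 sv_min_depth = as.integer(sv_min_depth),
                 depth_first = isTRUE(depth_first)),
            class = "filter_config")
}

partition <- function(v, keep) list(kept = v[keep, , drop = FALSE],
                                    removed = v[!keep, , drop = FALSE])

#' Depth-window filter
#'
#' Keeps variants whose read depth lies in `[min_depth, max_depth]`
#' (inclusive on both ends).
#'
#' @param v a [variants()] data.frame.
#' @param cfg a [filter_config()].
#' @return list with elements `kept` and `removed`, an exact partition of
#'   the input.
#' @export
filter_depth <- function(v, cfg = filter_config()) {
  partition(v, v$depth >= cfg$min_depth & v$depth <= cfg$max_depth)
}

# Symmetric cluster removal: a variant goes when any other variant of the
# same set on the same chromosome is within max_gap bases of its anchor.
cluster_hit <- function(v, max_gap) {
  n <- nrow(v)
  if (n < 2L) return(rep(FALSE, n))
  same_prev <- c(FALSE, v$chrom[-1L] == v$chrom[-n] & v$pos[-1L] - v$pos[-n] <= max_gap)
  same_next <- c(same_prev[-1L], FALSE)
  same_prev | same_next
}

#' SNP cluster filter
#'
#' Removes every SNP that shares a `snp_window_bp`-bp span with another SNP
#' on the same chromosome (both members of a conflicting pair are removed).
#' With the default 5-bp span two SNPs conflict when their positions differ
#' by 4 bp or less.
#'
#' @inheritParams filter_depth
#' @return list with `kept` and `removed` partitions.
#' @export
filter_snp_clusters <- function(v, cfg = filter_config()) {
  if (nrow(v) && !all(is_snp(v))) stopf("filter_snp_clusters expects SNPs only")
  assert_sorted(v)
  partition(v, !cluster_hit(v, cfg$snp_window_bp - 1L))
}

#' InDel cluster filter
#'
#' Removes every InDel whose anchor shares an `indel_window_bp`-bp span with
#' another InDel's anchor on the same chromosome (symmetric removal).
#'
#' @inheritParams filter_depth
#' @return list with `kept` and `removed` partitions.
#' @export
filter_indel_clusters <- function(v, cfg = filter_config()) {
  if (nrow(v) && !all(is_indel(v))) stopf("filter_indel_clusters expects InDels only")
  assert_sorted(v)
  partition(v, !cluster_hit(v, cfg$indel_window_bp - 1L))
}

#' Filter SNPs near InDels
#'
#' Removes SNPs whose position is within `snp_indel_dist_bp` bases of any
#' InDel's affected reference span (`pos .. pos + nchar(ref) - 1`); InDels
#' are never removed by this filter.
#'
#' @param snps SNP-only [variants()] data.frame.
#' @param indels InDel-only [variants()] data.frame.
#' @param cfg a [filter_config()].
#' @return list with `kept` and `removed` partitions of `snps`.
#' @export
filter_snps_near_indels <- function(snps, indels, cfg = filter_config()) {
  if (nrow(snps) == 0L || nrow(indels) == 0L) return(partition(snps, rep(TRUE, nrow(snps))))
  if (!all(is_snp(snps))) stopf("filter_snps_near_indels expects SNPs in `snps`")
  if (!all(is_indel(indels))) stopf("filter_snps_near_indels expects InDels in `indels`")
  hit <- rep(FALSE, nrow(snps))
  spans <- affected_span(indels)
  for (ch in unique(snps$chrom)) {
    si <- which(snps$chrom == ch)
    sp <- spans[spans$chrom == ch, , drop = FALSE]
    if (nrow(sp) == 0L) next
    q <- IRanges::IRanges(snps$pos[si], snps$pos[si])
    s <- IRanges::IRanges(sp$start - cfg$snp_indel_dist_bp,
                          sp$end + cfg$snp_indel_dist_bp)
    hit[si] <- IRanges::overlapsAny(q, s)
  }
  partition(snps, !hit)
}

#' Apply the full filter pipeline
#'
#' Runs the three positional filters on the raw variant set, then the depth
#' filter on the survivors (order configurable via `depth_first`): SNP
#' clusters, then SNPs near InDels (measured against all raw InDels), then
#' InDel clusters, then depth.
#'
#' @param v a mixed, sorted [variants()] data.frame.
#' @param cfg a [filter_config()].
#' @return list of class `filter_report` with elements `kept` (surviving
#'   variants), `removed` (named list per stage) and `counts` (data.frame of
#'   per-stage removal counts and survivors per variant class).
#' @export
apply_all_filters <- function(v, cfg = filter_config()) {
  v <- v[order(v$chrom, v$pos, v$ref, v$alt), , drop = FALSE]
  stage <- list()
  run_positional <- function(snps, indels) {
    f1 <- filter_snp_clusters(snps, cfg)
    stage[["snp_cluster"]] <<- f1$removed
    f2 <- filter_snps_near_indels(f1$kept, indels, cfg)
    stage[["snp_near_indel"]] <<- f2$removed
    f3 <- filter_indel_clusters(indels, cfg)
    stage[["indel_cluster"]] <<- f3$removed
    rbind(f2$kept, f3$kept)
  }
  if (cfg$depth_first) {
    fd <- filter_depth(v, cfg)
    stage[["depth"]] <- fd$removed
    kept <- run_positional(fd$kept[is_snp(fd$kept), , drop = FALSE],
                           fd$kept[is_indel(fd$kept), , drop = FALSE])
  } else {
    kept <- run_positional(v[is_snp(v), , drop = FALSE],
                           v[is_indel(v), , drop = FALSE])
    fd <- filter_depth(kept, cfg)
    stage[["depth"]] <- fd$removed
    kept <- fd$kept
  }
  kept <- kept[order(kept$chrom, kept$pos, kept$ref, kept$alt), , drop = FALSE]
  rownames(kept) <- NULL
  counts <- data.frame(stage = names(stage),
                       removed = vapply(stage, nrow, 0L),
                       row.names = NULL, stringsAsFactors = FALSE)
  survivors <- table(factor(kept$vclass, levels = c("SNP", "INS", "DEL")))
  structure(list(kept = kept, removed = stage, counts = counts,
                 survivors = as.list(survivors), config = cfg),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print(x$counts)
  cat(sprintf("kept: %d SNP, %d INS, %d DEL\n",
              x$survivors$SNP, x$survivors$INS, x$survivors$DEL))
  invisible(x)
}
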