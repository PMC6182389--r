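#' Count variants in consecutive fixed-width windows
#'
#' Tiles every chromosome into consecutive `window_bp` windows starting at
#' position 1 (tile k spans `[(k-1)*window_bp + 1, k*window_bp]`) and counts
#' the variants falling in each tile. A trailing tile shorter than
#' `window_bp` is recorded but flagged `partial`, and is excluded from the
#' boxplot statistics downstream.
#'
#' @param v a sorted [variants()] data.frame.
#' @param chromosome_lengths named vector of chromosome lengths (or a
#'   [Biostrings::DNAStringSet]); must cover every chromosome present in `v`.
#' @param window_bp window width in bp (default 100,000).
#' @return object of class `density_track`: list with `window_bp` and a
#'   `windows` data.frame (`chrom`, `start`, `end`, `count`, `partial`).
#' @export
window_counts <- function(v, chromosome_lengths, window_bp = 100000L) {
  lens <- genome_lengths(chromosome_lengths)
  missing <- setdiff(unique(v$chrom), names(lens))
  if (length(missing))
    stopf("variants on chromosome(s) with unknown length: %s",
          paste(missing, collapse = ", "))
  windows <- do.call(rbind, lapply(names(lens), function(ch) {
    L <- lens[[ch]]
    n_tiles <- ceiling(L / window_bp)
    start <- (seq_len(n_tiles) - 1L) * as.integer(window_bp) + 1L
    end <- pmin(start + as.integer(window_bp) - 1L, L)
    pos <- v$pos[v$chrom == ch]
    if (length(pos) && max(pos) > L)
      stopf("variant at %s:%d beyond chromosome length %d", ch, max(pos), L)
    cnt <- tabulate((pos - 1L) %/% window_bp + 1L, nbins = n_tiles)
    data.frame(chrom = ch, start = start, end = end, count = cnt,
               partial = end - start + 1L < window_bp, stringsAsFactors = FALSE)
  }))
  structure(list(window_bp = as.integer(window_bp), windows = windows,
                 chromosome_lengths = lens), class = "density_track")
}

#' Five-number summary of window densities
#'
#' Minimum, lower quartile, median, upper quartile and maximum of the
#' per-window variant counts, over complete windows only. Quartiles use
#' linear interpolation between order statistics
#' ([stats::quantile()] type 7), the convention pinned for reproducibility.
#'
#' @param track a `density_track` from [window_counts()].
#' @return named list `min`, `q1`, `median`, `q3`, `max`.
#' @export
five_number <- function(track) {
  x <- track$windows$count[!track$windows$partial]
  if (length(x) == 0L) stopf("no complete windows: five-number summary undefined")
  q <- stats::quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  list(min = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L], max = q[5L])
}

#' Call variation-rich and variation-poor windows
#'
#' Flags boxplot outliers of the window-density distribution: with
#' `IQR = q3 - q1`, a complete window is `rich` when its count exceeds
#' `q3 + k * IQR` and `poor` when it falls below `q1 - k * IQR`
#' (Tukey fences, `k = 1.5`). Fences are computed over all complete windows
#' pooled genome-wide by default; `scope = "chromosome"` computes them per
#' chromosome. Partial windows are never called.
#'
#' @param track a `density_track` from [window_counts()].
#' @param k fence multiplier (default 1.5).
#' @param scope `"genome"` or `"chromosome"`.
#' @return data.frame of calls: `chrom`, `start`, `end`, `label`
#'   (`rich`/`poor`), `count` and a human-readable `name`
#'   (`Chr:start-end` in Mb).
#' @export
call_regions <- function(track, k = 1.5, scope = c("genome", "chromosome")) {
  scope <- match.arg(scope)
  w <- track$windows
  out <- w[0, c("chrom", "start", "end", "count")]
  out$label <- character()
  groups <- if (scope == "genome") list(seq_len(nrow(w))) else
    split(seq_len(nrow(w)), w$chrom)
  for (idx in groups) {
    complete <- idx[!w$partial[idx]]
    if (length(complete) == 0L) next
    x <- w$count[complete]
    q <- stats::quantile(x, probs = c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2L] - q[1L]
    upper <- q[2L] + k * iqr
    lower <- q[1L] - k * iqr
    rich <- complete[w$count[complete] > upper]
    poor <- complete[w$count[complete] < lower]
    if (length(rich) + length(poor) == 0L) next
    add <- w[c(rich, poor), c("chrom", "start", "end", "count")]
    add$label <- rep(c("rich", "poor"), c(length(rich), length(poor)))
    out <- rbind(out, add)
  }
  out <- out[order(out$chrom, out$start), c("chrom", "start", "end", "label", "count")]
  out$name <- region_name(out$chrom, out$start, out$end)
  rownames(out) <- NULL
  out
}

#' Format region names in Mb
#'
#' Renders `Chr01:12500001-12600000` as `"Chr01:12.5-12.6"`.
#'
#' @param chrom,start,end region coordinates (1-based inclusive).
#' @return character vector of names.
#' @export
region_name <- function(chrom, start, end) {
  sprintf("%s:%.1f-%.1f", chrom, (start - 1) / 1e6, end / 1e6)
}

#' Regions sharing a label across all samples
#'
#' Intersects region-call tables from several samples scanned on the same
#' window grid: returns the windows carrying `label` in every sample.
#'
#' @param calls_per_sample named list of [call_regions()] data.frames.
#' @param label `"rich"` or `"poor"`.
#' @return data.frame `chrom`, `start`, `end`, `name` of shared windows.
#' @export
shared_regions <- function(calls_per_sample, label = c("rich", "poor")) {
  label <- match.arg(label)
  stopifnot(length(calls_per_sample) >= 1L)
  keys <- lapply(calls_per_sample, function(calls) {
    calls <- calls[calls$label == label, , drop = FALSE]
    widths <- sort(unique(calls$end - calls$start + 1L))
    list(key = paste(calls$chrom, calls$start, calls$end, sep = ":"), widths = widths)
  })
  widths <- unique(unlist(lapply(keys, `[[`, "widths")))
  if (length(widths) > 1L)
    stopf("region-call sets use different window grids (widths: %s)",
          paste(widths, collapse = ", "))
  shared <- Reduce(intersect, lapply(keys, `[[`, "key"))
  if (length(shared) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(shared, ":", fixed = TRUE))
  out <- data.frame(chrom = parts[, 1L], start = as.integer(parts[, 2L]),
                    end = as.integer(parts[, 3L]), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- region_name(out$chrom, out$start, out$end)
  rownames(out) <- NULL
  out
}
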