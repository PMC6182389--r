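#' Read a reference genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that strips FASTA
#' description text after the first whitespace so sequence names match the
#' chromosome names used in VCF/GFF files.
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Chromosome lengths of a genome
#' @param genome a [Biostrings::DNAStringSet] or a named numeric vector.
#' @return named integer vector of chromosome lengths.
#' @export
genome_lengths <- function(genome) {
  if (is.numeric(genome)) return(stats::setNames(as.integer(genome), names(genome)))
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Read a per-base depth track from a bedGraph file
#'
#' @param path bedGraph file (`chrom  start  end  depth`, 0-based half-open).
#' @return a `depth_track`: named list (one element per chromosome) of
#'   data.frames with 0-based half-open columns `start`, `end` and `depth`,
#'   sorted and non-overlapping.
#' @export
read_bedgraph <- function(path) {
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         col.names = c("chrom", "start", "end", "depth"),
                         colClasses = c("character", "integer", "integer", "numeric"))
  track <- lapply(split(d[, c("start", "end", "depth")], d$chrom), function(x) {
    x <- x[order(x$start), , drop = FALSE]
    if (nrow(x) > 1L && any(x$start[-1L] < x$end[-nrow(x)]))
      stopf("bedGraph %s has overlapping runs", path)
    rownames(x) <- NULL
    x
  })
  structure(track, class = "depth_track")
}

#' Write a depth track as bedGraph
#' @param track a `depth_track` as returned by [read_bedgraph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  rows <- unlist(lapply(names(track), function(ch) {
    x <- track[[ch]]
    if (nrow(x) == 0L) return(character())
    paste(ch, x$start, x$end, x$depth, sep = "\t")
  }))
  writeLines(rows %||% character(), path)
  invisible(path)
}

#' Write labelled genomic regions as a BED4 file
#'
#' Converts 1-based inclusive intervals to BED's 0-based half-open
#' convention, sorts, and writes four columns. An empty region set produces
#' a file holding only the header comment.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(regions, path) {
  lines <- "#chrom\tstart\tend\tlabel"
  if (nrow(regions)) {
    regions <- regions[order(regions$chrom, regions$start, regions$end), , drop = FALSE]
    lines <- c(lines, paste(regions$chrom, to_bed_start(regions$start),
                            to_bed_end(regions$end), regions$label, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read labelled regions from a BED4 file
#'
#' Inverse of [write_region_bed()]: BED coordinates are converted back to
#' 1-based inclusive intervals.
#'
#' @param path BED4 file.
#' @return data.frame with columns `chrom`, `start`, `end`, `label`.
#' @export
read_region_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      label = character(), stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(chrom = parts[, 1L],
             start = from_bed_start(as.integer(parts[, 2L])),
             end = from_bed_end(as.integer(parts[, 3L])),
             label = parts[, 4L], stringsAsFactors = FALSE)
}
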