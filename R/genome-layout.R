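#' Genome layout: chromosomes, centromeres, telomere margins, bin size
#'
#' A `GenomeLayout` records the coordinate system every other object in the
#' package works against: chromosome names and lengths, centromere positions,
#' the distance from each chromosome end that is treated as telomeric, and the
#' Hi-C bin size (5 kb by default). All coordinates are 0-based half-open.
#'
#' @param chrom_names character vector of chromosome identifiers.
#' @param chrom_lengths integer vector of chromosome lengths in bp.
#' @param centromere_pos integer vector of centromere positions in bp
#'   (0-based), one per chromosome.
#' @param telomere_margin bp from each chromosome end treated as telomeric.
#' @param bin_size Hi-C bin size in bp.
#' @return An object of class `GenomeLayout`.
#' @export
genome_layout <- function(chrom_names, chrom_lengths, centromere_pos,
                          telomere_margin = 20000L, bin_size = 5000L) {
  if (length(chrom_names) != length(chrom_lengths) ||
      length(chrom_names) != length(centromere_pos))
    stop("chrom_names, chrom_lengths and centromere_pos must have equal length")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (any(centromere_pos < 0 | centromere_pos >= chrom_lengths))
    stop("centromere positions must lie within [0, length)")
  if (telomere_margin < 0) stop("telomere_margin must be >= 0")
  if (bin_size <= 0) stop("bin_size must be > 0")
  structure(
    list(chrom_names = as.character(chrom_names),
         chrom_lengths = as.integer(chrom_lengths),
         centromere_pos = as.integer(centromere_pos),
         telomere_margin = as.integer(telomere_margin),
         bin_size = as.integer(bin_size)),
    class = "GenomeLayout")
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat(sprintf("GenomeLayout: %d chromosomes, %s bp total, bin size %d bp\n",
              length(x$chrom_names),
              format(sum(as.numeric(x$chrom_lengths)), big.mark = ","),
              x$bin_size))
  invisible(x)
}

#' Genome-wide bin table for a layout
#'
#' Tiles each chromosome with `bin_size` bins (last bin truncated at the
#' chromosome end) and returns the genome-wide bin table used to index
#' contact matrices and bead coordinates.
#'
#' @param layout a `GenomeLayout`.
#' @return data.frame with columns `bin` (1-based genome-wide index),
#'   `chrom`, `start`, `end` (0-based half-open).
#' @export
layout_bins <- function(layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  pieces <- lapply(seq_along(layout$chrom_names), function(ci) {
    len <- layout$chrom_lengths[ci]
    starts <- seq(0L, len - 1L, by = layout$bin_size)
    data.frame(chrom = layout$chrom_names[ci],
               start = starts,
               end = pmin(starts + layout$bin_size, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- cbind(bin = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Map a genomic window to genome-wide bin indices
#'
#' @param layout a `GenomeLayout`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open window; clipped to the chromosome with a
#'   warning when out of bounds.
#' @return integer vector of genome-wide bin indices overlapping the window.
#' @export
bins_in_window <- function(layout, chrom, start, end) {
  bins <- layout_bins(layout)
  ci <- match(chrom, layout$chrom_names)
  if (is.na(ci)) stop("unknown chromosome: ", chrom)
  len <- layout$chrom_lengths[ci]
  if (start < 0 || end > len) {
    warning(sprintf("window [%d,%d) clipped to chromosome %s bounds", start, end, chrom))
    start <- max(0L, start); end <- min(len, end)
  }
  which(bins$chrom == chrom & bins$start < end & bins$end > start)
}

#' Telomeric bin indices of a layout
#'
#' Bins whose interval overlaps the first or last `telomere_margin` bp of a
#' chromosome. Used for relative telomere distance metrics.
#'
#' @param layout a `GenomeLayout`.
#' @return integer vector of genome-wide bin indices.
#' @export
telomere_bins <- function(layout) {
  bins <- layout_bins(layout)
  idx <- integer(0)
  for (ci in seq_along(layout$chrom_names)) {
    len <- layout$chrom_lengths[ci]
    m <- max(1L, min(layout$telomere_margin, len))
    cb <- bins[bins$chrom == layout$chrom_names[ci], ]
    idx <- c(idx, cb$bin[cb$start < m | cb$end > len - m])
  }
  unique(idx)
}
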