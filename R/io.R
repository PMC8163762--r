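#' Construct a contact matrix object
#'
#' @param counts symmetric non-negative numeric matrix over genome-wide bins.
#' @param layout the `GenomeLayout` the bins tile.
#' @param masked integer vector of bin indices excluded from analysis.
#' @return object of class `ContactMatrix` with elements `counts`, `bins`,
#'   `masked`, `layout`.
#' @export
contact_matrix <- function(counts, layout, masked = integer(0)) {
  bins <- layout_bins(layout)
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(bins) || ncol(counts) != nrow(bins))
    stop(sprintf("counts must be %d x %d for this layout", nrow(bins), nrow(bins)))
  if (any(counts < 0)) stop("negative contact counts")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(counts)))
    stop("counts must be symmetric")
  dimnames(counts) <- NULL
  structure(list(counts = counts, bins = bins,
                 masked = sort(unique(as.integer(masked))), layout = layout),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %d bins, %s total counts, %d masked bins\n",
              nrow(x$counts), format(sum(x$counts), big.mark = ","),
              length(x$masked)))
  invisible(x)
}

#' Read a binned Hi-C contact matrix
#'
#' Accepts either sparse COO text (three whitespace-separated columns:
#' `bin_i bin_j count`, 0-based bin indices) or a dense square TSV. Duplicate
#' `(i,j)`/`(j,i)` records are summed and the result symmetrized. An empty
#' file yields the all-zero matrix for the layout.
#'
#' @param path file path.
#' @param layout a `GenomeLayout`; bin indexing must be consistent with it.
#' @return a `ContactMatrix`.
#' @export
read_contact_matrix <- function(path, layout) {
  bins <- layout_bins(layout)
  n <- nrow(bins)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  counts <- matrix(0, n, n)
  if (length(lines)) {
    fields <- strsplit(trimws(lines), "\\s+")
    ncol1 <- length(fields[[1]])
    if (ncol1 == 3) {
      rec <- matrix(as.numeric(unlist(fields)), ncol = 3, byrow = TRUE)
      if (any(is.na(rec))) stop("malformed COO record")
      i <- rec[, 1]; j <- rec[, 2]; v <- rec[, 3]
      if (any(i != floor(i) | j != floor(j))) stop("bin indices must be integers")
      if (any(i < 0 | j < 0 | i >= n | j >= n))
        stop("bin index out of range for layout with ", n, " bins")
      if (any(v < 0)) stop("negative contact count")
      for (k in seq_along(v)) {
        counts[i[k] + 1, j[k] + 1] <- counts[i[k] + 1, j[k] + 1] + v[k]
      }
      counts <- counts + t(counts)
      diag(counts) <- diag(counts) / 2
    } else if (ncol1 == n) {
      rec <- matrix(as.numeric(unlist(fields)), ncol = n, byrow = TRUE)
      if (nrow(rec) != n) stop("dense matrix must be square and match the layout")
      if (any(is.na(rec))) stop("malformed dense matrix")
      if (any(rec < 0)) stop("negative contact count")
      counts <- (rec + t(rec)) / 2
    } else {
      stop("expected 3-column COO text or a dense ", n, "-column matrix")
    }
  }
  contact_matrix(counts, layout)
}

#' Write a contact matrix as COO text
#'
#' Upper-triangle non-zero entries, 0-based bin indices.
#'
#' @param cm a `ContactMatrix`.
#' @param path output file.
#' @export
write_contact_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "ContactMatrix"))
  ut <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts != 0, arr.ind = TRUE)
  writeLines(sprintf("%d %d %.10g", ut[, 1] - 1L, ut[, 2] - 1L,
                     cm$counts[ut]), path)
  invisible(path)
}

#' Construct a per-bp coverage track
#'
#' @param chrom chromosome name.
#' @param values numeric vector of non-negative per-bp signal.
#' @param start 0-based start of the covered region.
#' @return object of class `CoverageTrack`.
#' @export
coverage_track <- function(chrom, values, start = 0L) {
  if (any(values < 0)) stop("coverage values must be >= 0")
  structure(list(chrom = chrom, start = as.integer(start),
                 values = as.numeric(values)),
            class = "CoverageTrack")
}

#' Read a bedGraph coverage track
#'
#' Expands 0-based half-open bedGraph intervals for one chromosome to a per-bp
#' vector; uncovered gaps are filled with zero. Overlapping intervals or
#' intervals with `end <= start` are format errors.
#'
#' @param path bedGraph file.
#' @param chrom chromosome to extract.
#' @param region_len length of the returned track in bp; defaults to the
#'   maximum interval end seen on `chrom`.
#' @return a `CoverageTrack` starting at position 0.
#' @export
read_coverage <- function(path, chrom, region_len = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines)) {
    if (is.null(region_len)) stop("empty bedGraph and no region_len given")
    return(coverage_track(chrom, numeric(region_len)))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(fields) < 4)) stop("bedGraph records need 4 fields")
  rec <- data.frame(chrom = vapply(fields, `[`, "", 1),
                    start = as.integer(vapply(fields, `[`, "", 2)),
                    end = as.integer(vapply(fields, `[`, "", 3)),
                    value = as.numeric(vapply(fields, `[`, "", 4)),
                    stringsAsFactors = FALSE)
  rec <- rec[rec$chrom == chrom, ]
  if (nrow(rec)) {
    if (any(rec$end <= rec$start)) stop("bedGraph interval with end <= start")
    rec <- rec[order(rec$start), ]
    if (nrow(rec) > 1 && any(rec$start[-1] < rec$end[-nrow(rec)]))
      stop("overlapping bedGraph intervals")
    if (any(rec$value < 0)) stop("negative coverage value")
  }
  if (is.null(region_len)) region_len <- if (nrow(rec)) max(rec$end) else 0L
  values <- numeric(region_len)
  for (k in seq_len(nrow(rec))) {
    lo <- rec$start[k] + 1L; hi <- min(rec$end[k], region_len)
    if (lo <= hi) values[lo:hi] <- rec$value[k]
  }
  coverage_track(chrom, values)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are merged into intervals; zero runs are skipped.
#'
#' @param track a `CoverageTrack`.
#' @param path output file.
#' @export
write_coverage <- function(track, path) {
  stopifnot(inherits(track, "CoverageTrack"))
  v <- track$values
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  writeLines(sprintf("%s\t%d\t%d\t%.10g", track$chrom,
                     track$start + starts[keep], track$start + ends[keep],
                     r$values[keep]), path)
  invisible(path)
}

#' Write a structure ensemble as a multi-model PDB-like file
#'
#' One MODEL per structure, one pseudo-atom (CA) per bead, one chain per
#' chromosome. Coordinates are multiplied by `scale_nm_per_unit` and written
#' with three decimals; [read_structures()] round-trips them bit-exactly at
#' that precision.
#'
#' @param structures list of beads-by-3 coordinate matrices.
#' @param path output file.
#' @param layout a `GenomeLayout`; its bins define chain assignment. `NULL`
#'   writes a single chain.
#' @param scale_nm_per_unit multiplicative scale applied on write.
#' @export
write_structures <- function(structures, path, layout = NULL,
                             scale_nm_per_unit = 1) {
  if (inherits(structures, "StructureEnsemble")) structures <- structures$members
  if (is.matrix(structures)) structures <- list(structures)
  if (!length(structures)) stop("no structures to write")
  chains <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(structures)) {
    X <- structures[[m]] * scale_nm_per_unit
    if (any(!is.finite(X))) stop("refusing to write non-finite coordinates")
    if (is.null(chains)) {
      chains <- if (is.null(layout)) rep("A", nrow(X)) else {
        bins <- layout_bins(layout)
        LETTERS[(match(bins$chrom, layout$chrom_names) - 1L) %% 26 + 1L]
      }
    }
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- seq_len(nrow(X))
    writeLines(sprintf(
      "ATOM  %5d  CA  BED %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      serial %% 100000, chains, (serial - 1L) %% 10000,
      X[, 1], X[, 2], X[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read structures written by [write_structures()]
#'
#' @param path PDB-like multi-model file.
#' @param scale_nm_per_unit scale divided out on read (pass the value used on
#'   write to recover model units).
#' @return list of beads-by-3 coordinate matrices.
#' @export
read_structures <- function(path, scale_nm_per_unit = 1) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, "MODEL")) cur <- character(0)
    else if (startsWith(ln, "ATOM")) cur <- c(cur, ln)
    else if (startsWith(ln, "ENDMDL")) {
      X <- matrix(c(as.numeric(substr(cur, 31, 38)),
                    as.numeric(substr(cur, 39, 46)),
                    as.numeric(substr(cur, 47, 54))), ncol = 3)
      out[[length(out) + 1]] <- X / scale_nm_per_unit
      cur <- NULL
    }
  }
  if (!length(out)) stop("no MODEL records found in ", path)
  out
}
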