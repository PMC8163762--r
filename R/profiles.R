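## Aggregate profiles around genomic anchors: anchored averages, gene-body
## binning (137 bins by default), dyad-centered methylation profiles, and
## promoter-methylation-stratified nucleosome-free-region statistics.

#' Anchor set for profile computation
#'
#' @param anchors data.frame with `chrom`, `pos` (0-based), `strand`.
#' @param kind one of `"TSS"`, `"TTS"`, `"dyad"`, `"custom"`.
#' @return data.frame of class `AnchorSet`.
#' @export
anchor_set <- function(anchors, kind = "custom") {
  stopifnot(all(c("chrom", "pos") %in% names(anchors)))
  if (is.null(anchors$strand)) anchors$strand <- "+"
  if (!all(anchors$strand %in% c("+", "-"))) stop("strand must be + or -")
  attr(anchors, "kind") <- kind
  class(anchors) <- c("AnchorSet", "data.frame")
  anchors
}

#' Mean signal profile around a set of anchors
#'
#' Averages a per-bp signal over windows of `+/- flank` bp centered on each
#' anchor; minus-strand anchors are reversed when `strand_aware`. Windows
#' extending beyond the track contribute only their in-bounds offsets.
#'
#' @param signal a `CoverageTrack` or named list of tracks keyed by
#'   chromosome.
#' @param anchors an `AnchorSet` (or plain data.frame with `chrom`, `pos`,
#'   `strand`).
#' @param flank bp on each side of the anchor.
#' @param strand_aware reverse windows of minus-strand anchors.
#' @return data.frame of class `ProfileResult`: `offset`, `mean`, `n`.
#' @export
anchored_profile <- function(signal, anchors, flank = 850L,
                             strand_aware = TRUE) {
  if (!nrow(anchors)) stop("empty anchor set")
  tracks <- if (inherits(signal, "CoverageTrack"))
    stats::setNames(list(signal), signal$chrom) else signal
  width <- 2L * flank + 1L
  acc <- numeric(width)
  n <- integer(width)
  for (a in seq_len(nrow(anchors))) {
    tr <- tracks[[anchors$chrom[a]]]
    if (is.null(tr)) next
    pos <- anchors$pos[a] - tr$start
    lo <- pos - flank; hi <- pos + flank
    idx <- lo:hi + 1L
    ok <- idx >= 1L & idx <= length(tr$values)
    vals <- rep(NA_real_, width)
    vals[ok] <- tr$values[idx[ok]]
    if (strand_aware && anchors$strand[a] == "-") vals <- rev(vals)
    hit <- !is.na(vals)
    acc[hit] <- acc[hit] + vals[hit]
    n <- n + hit
  }
  out <- data.frame(offset = -flank:flank,
                    mean = ifelse(n > 0, acc / pmax(n, 1), NA_real_), n = n)
  class(out) <- c("ProfileResult", "data.frame")
  out
}

#' Length-normalized gene-body profile
#'
#' Rescales each gene to `n_bins` bins by length-proportional index mapping
#' (bp `k` of a gene of length `L` goes to bin `floor(k * n_bins / L)`), so
#' genes shorter than `n_bins` spread single bp over multiple bins; bin means
#' are averaged over genes, minus-strand genes reversed.
#'
#' @param signal a `CoverageTrack` or named list of tracks by chromosome.
#' @param genes data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`.
#' @param n_bins number of bins (default 137).
#' @return data.frame: `bin` (1-based), `mean`, `n` (genes contributing).
#' @export
gene_body_profile <- function(signal, genes, n_bins = 137L) {
  if (!nrow(genes)) stop("empty gene set")
  tracks <- if (inherits(signal, "CoverageTrack"))
    stats::setNames(list(signal), signal$chrom) else signal
  acc <- numeric(n_bins); n <- integer(n_bins)
  for (gi in seq_len(nrow(genes))) {
    tr <- tracks[[genes$chrom[gi]]]
    if (is.null(tr)) next
    lo <- genes$start[gi] - tr$start; hi <- genes$end[gi] - tr$start
    if (lo < 0 || hi > length(tr$values)) next
    vals <- tr$values[(lo + 1L):hi]
    L <- length(vals)
    if (genes$strand[gi] == "-") vals <- rev(vals)
    if (L >= n_bins) {
      bin <- floor((seq_len(L) - 1) * n_bins / L) + 1L
      bm <- tapply(vals, bin, mean)
      acc <- acc + as.numeric(bm)
      n <- n + 1L
    } else {
      # short gene: linear index mapping, bins may share bp
      bin_of <- floor((seq_len(n_bins) - 1) * L / n_bins) + 1L
      acc <- acc + vals[bin_of]
      n <- n + 1L
    }
  }
  data.frame(bin = seq_len(n_bins), mean = acc / pmax(n, 1), n = n)
}

#' CpG methylation profiles around nucleosome dyads
#'
#' For each offset in `-flank..flank` relative to a dyad, reports the fraction
#' of covered CpG sites whose methylation level (`n_meth / depth`) exceeds
#' `min_prob`, and the mean level, separately per call class (well-positioned
#' vs fuzzy) and optionally per strand (conventionally with `flank = 75`).
#'
#' @param sites data.frame (`chrom`, `pos`, `strand`, `n_meth`, `n_unmeth`).
#' @param calls data.frame (`chrom`, `pos`, `call_class`) of dyad calls.
#' @param flank bp on each side of the dyad (150 by default).
#' @param per_strand split profiles by CpG strand.
#' @param min_prob methylation-probability threshold for the fraction channel.
#' @return data.frame: `call_class`, (`strand`,) `offset`, `frac_above`,
#'   `mean_level`, `n_sites`.
#' @export
dyad_methylation_profile <- function(sites, calls, flank = 150L,
                                     per_strand = FALSE, min_prob = 0.01) {
  depth <- sites$n_meth + sites$n_unmeth
  lev <- ifelse(depth > 0, sites$n_meth / depth, NA_real_)
  out <- list()
  for (cls in unique(calls$call_class)) {
    cc <- calls[calls$call_class == cls, , drop = FALSE]
    if (!nrow(cc)) { warning("no calls of class ", cls); next }
    strata <- if (per_strand) c("+", "-") else "*"
    for (st in strata) {
      ss <- if (st == "*") sites else sites[sites$strand == st, , drop = FALSE]
      sl <- if (st == "*") lev else lev[sites$strand == st]
      site_key <- paste(ss$chrom, ss$pos)
      offs <- -flank:flank
      # calls x offsets lookup of site levels
      want <- paste(rep(cc$chrom, times = length(offs)),
                    rep(cc$pos, times = length(offs)) +
                      rep(offs, each = nrow(cc)))
      m <- match(want, site_key)
      lvm <- matrix(sl[m], nrow = nrow(cc))
      rows <- lapply(seq_along(offs), function(oi) {
        lv <- lvm[, oi]; lv <- lv[!is.na(lv)]
        data.frame(call_class = cls, strand = st, offset = offs[oi],
                   frac_above = if (length(lv)) mean(lv > min_prob) else 0,
                   mean_level = if (length(lv)) mean(lv) else NA_real_,
                   n_sites = length(lv))
      })
      out[[paste(cls, st)]] <- do.call(rbind, rows)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Promoter-methylation-stratified NFR widths
#'
#' Genes are stratified by mean promoter methylation (window `TSS +/-
#' promoter_flank`) into top/bottom deciles and the 45-55% band by default.
#' Per gene, the -1/+1 nucleosomes are the nearest calls upstream/downstream
#' of the TSS (strand-aware); the nucleosome-free-region width is the distance
#' between their proximal edges (dyad distance minus 147). Genes lacking a
#' flanking call are excluded and counted.
#'
#' @param calls data.frame (`chrom`, `pos`, `call_class`) of dyad calls.
#' @param sites CpG site table as in [dyad_methylation_profile()].
#' @param genes data.frame (`chrom`, `start`, `end`, `strand`); the TSS is
#'   `start` on plus and `end - 1` on minus strand.
#' @param strata named list of quantile bands over promoter methylation, each
#'   `c(lo, hi)` in [0, 1].
#' @param promoter_flank bp around the TSS for stratification.
#' @return list: `per_gene` (data.frame gene, tss, meth, nfr_width, stratum),
#'   `per_stratum` (data.frame stratum, mean_width, n), `n_excluded`.
#' @export
promoter_stratified_nfr <- function(calls, sites, genes,
                                    strata = list(top10 = c(0.9, 1),
                                                  mid = c(0.45, 0.55),
                                                  bottom10 = c(0, 0.1)),
                                    promoter_flank = 850L) {
  tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  depth <- sites$n_meth + sites$n_unmeth
  lev <- ifelse(depth > 0, sites$n_meth / depth, NA_real_)
  meth <- vapply(seq_len(nrow(genes)), function(gi) {
    w <- sites$chrom == genes$chrom[gi] &
      sites$pos >= tss[gi] - promoter_flank &
      sites$pos <= tss[gi] + promoter_flank
    mean(lev[w], na.rm = TRUE)
  }, 0)
  nfr <- rep(NA_real_, nrow(genes))
  for (gi in seq_len(nrow(genes))) {
    cc <- calls[calls$chrom == genes$chrom[gi], , drop = FALSE]
    up <- cc$pos[cc$pos < tss[gi]]
    dn <- cc$pos[cc$pos >= tss[gi]]
    if (!length(up) || !length(dn)) next
    nfr[gi] <- (min(dn) - max(up)) - 147
  }
  n_excluded <- sum(is.na(nfr))
  rk <- rank(meth, ties.method = "average") / length(meth)
  stratum <- rep(NA_character_, nrow(genes))
  for (nm in names(strata)) {
    b <- strata[[nm]]
    stratum[rk > b[1] & rk <= b[2] |
              (b[1] == 0 & rk >= 0 & rk <= b[2])] <- nm
  }
  per_gene <- data.frame(gene = seq_len(nrow(genes)), tss = tss, meth = meth,
                         nfr_width = nfr, stratum = stratum)
  ok <- !is.na(nfr) & !is.na(stratum)
  per_stratum <- if (any(ok))
    aggregate(nfr_width ~ stratum, per_gene[ok, ], mean) else NULL
  if (!is.null(per_stratum)) {
    cnt <- aggregate(nfr_width ~ stratum, per_gene[ok, ], length)
    per_stratum$n <- cnt$nfr_width
    names(per_stratum)[2] <- "mean_width"
  }
  list(per_gene = per_gene, per_stratum = per_stratum,
       n_excluded = n_excluded)
}

#' Filter a CpG site table by the standard call criteria
#'
#' Flags sites passing the call filter (depth above `min_reads` and level
#' above `min_level`) and drops sites above the coverage cap (`max_depth`,
#' default 500x), which are typically collapsed repeats.
#'
#' @param sites CpG site table.
#' @param min_reads,min_level call-filter thresholds.
#' @param max_depth coverage cap; sites above it are removed.
#' @return the filtered table with a logical `called` column.
#' @export
apply_site_filters <- function(sites, min_reads = 10L, min_level = 0.1,
                               max_depth = 500L) {
  depth <- sites$n_meth + sites$n_unmeth
  sites <- sites[depth <= max_depth, , drop = FALSE]
  depth <- sites$n_meth + sites$n_unmeth
  lev <- ifelse(depth > 0, sites$n_meth / depth, 0)
  sites$called <- depth > min_reads & lev > min_level
  sites
}
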