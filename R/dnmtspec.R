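## Sequence-context (6-mer) effects on CpG methylation.
##
## With the motif as the only categorical predictor of per-site
## methylated/unmethylated counts, the logistic-regression MLE per motif is
## the empirical log-odds of its pooled counts. A Jeffreys pseudocount of 0.5
## on both counts keeps effects finite at 0/all-methylated motifs, and the
## delta method gives the standard error sqrt(1/(n1+0.5) + 1/(n0+0.5)).

#' Extract +/-2 bp CpG contexts from a sequence
#'
#' Returns the 6-mer consisting of two bases upstream, the CG, and two bases
#' downstream of each CpG. Sites within 2 bp of a sequence end or whose
#' context contains N are dropped (reported via the `dropped` attribute).
#'
#' @param sequence a single string over ACGTN.
#' @param cpg_positions 0-based positions of the C of each CpG.
#' @return character vector of 6-mers named by position, with attribute
#'   `dropped` (positions excluded and why).
#' @export
extract_contexts <- function(sequence, cpg_positions) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  bad <- which(substr(rep(sequence, length(cpg_positions)),
                      cpg_positions + 1, cpg_positions + 2) != "CG")
  if (length(bad))
    stop("position ", cpg_positions[bad[1]], " is not the C of a CpG")
  out <- character(0)
  dropped <- character(0)
  for (pos in cpg_positions) {
    if (pos < 2 || pos + 3 >= L) {
      dropped <- c(dropped, sprintf("%d: insufficient flank", pos))
      next
    }
    ctx <- substr(sequence, pos - 1, pos + 4)  # 1-based: (pos-2 .. pos+3) 0-based
    if (grepl("N", ctx, fixed = TRUE)) {
      dropped <- c(dropped, sprintf("%d: N in context", pos))
      next
    }
    out <- c(out, stats::setNames(ctx, pos))
  }
  if (length(dropped))
    message(length(dropped), " CpG site(s) dropped: ",
            paste(dropped, collapse = "; "))
  attr(out, "dropped") <- dropped
  out
}

#' Fit per-motif methylation effects from a site count table
#'
#' Sites with fewer than `min_reads` mapped reads are excluded; remaining
#' counts are pooled per motif and the effect is the Jeffreys-smoothed
#' log-odds `log((n_meth + 0.5) / (n_unmeth + 0.5))` with delta-method
#' standard error. Significance follows the centered two-standard-deviation
#' rule of [significant_motifs()].
#'
#' @param sites data.frame with `motif`, `n_meth`, `n_unmeth` per CpG site.
#' @param min_reads minimum mapped reads per site (default 10).
#' @param vs_zero flag significance against zero instead of the across-motif
#'   mean effect.
#' @return data.frame (`motif`, `effect`, `se`, `n_meth`, `n_unmeth`,
#'   `significant`), class `MotifEffectTable`.
#' @export
fit_motif_effects <- function(sites, min_reads = 10L, vs_zero = FALSE) {
  if (any(nchar(sites$motif) != 6 | substr(sites$motif, 3, 4) != "CG"))
    stop("all motifs must be 6-mers with a central CG")
  depth <- sites$n_meth + sites$n_unmeth
  sites <- sites[depth >= min_reads, , drop = FALSE]
  if (!nrow(sites)) stop("no sites left after the min_reads filter")
  n1 <- tapply(sites$n_meth, sites$motif, sum)
  n0 <- tapply(sites$n_unmeth, sites$motif, sum)
  tab <- data.frame(motif = names(n1),
                    effect = log((n1 + 0.5) / (n0 + 0.5)),
                    se = sqrt(1 / (n1 + 0.5) + 1 / (n0 + 0.5)),
                    n_meth = as.numeric(n1), n_unmeth = as.numeric(n0),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab$significant <- .flag_significant(tab, vs_zero)
  class(tab) <- c("MotifEffectTable", "data.frame")
  tab
}

# significant = deviates from the center by more than two per-motif standard
# errors AND more than two across-motif standard deviations; the second
# condition keeps high-depth tables (tiny se) from flagging every motif
.flag_significant <- function(table, vs_zero = FALSE) {
  center <- if (vs_zero) 0 else mean(table$effect)
  dev <- abs(table$effect - center)
  spread <- if (nrow(table) > 1) sd(table$effect) else 0
  dev > 2 * table$se & dev > 2 * spread
}

#' Motifs with a significant methylation effect
#'
#' Flags motifs whose effect deviates from the across-motif mean (or from
#' zero with `vs_zero = TRUE`) by more than two per-motif standard errors and
#' more than two across-motif standard deviations of the effects. The second
#' condition makes the flag an outlier criterion: at high coverage every
#' standard error shrinks toward zero, and a pure 2-se rule would flag ~5% of
#' null motifs by chance.
#'
#' @param table a `MotifEffectTable`.
#' @param vs_zero compare against zero rather than the mean effect.
#' @return the flagged subset of `table`.
#' @export
significant_motifs <- function(table, vs_zero = FALSE) {
  table[.flag_significant(table, vs_zero), , drop = FALSE]
}

#' Correlation of motif effects between two samples
#'
#' Pearson correlation of per-motif effects over motifs present in both
#' tables, by default weighted by inverse summed variance so noisy motifs
#' count less.
#'
#' @param tableA,tableB `MotifEffectTable`s.
#' @param weighted inverse-variance weighting (default) or plain Pearson.
#' @return the correlation coefficient (scalar).
#' @export
compare_effects <- function(tableA, tableB, weighted = TRUE) {
  shared <- intersect(tableA$motif, tableB$motif)
  if (length(shared) < 3) stop("need at least 3 shared motifs")
  a <- tableA$effect[match(shared, tableA$motif)]
  b <- tableB$effect[match(shared, tableB$motif)]
  if (!weighted) return(stats::cor(a, b))
  va <- tableA$se[match(shared, tableA$motif)]^2
  vb <- tableB$se[match(shared, tableB$motif)]^2
  w <- 1 / (va + vb)
  w <- w / sum(w)
  ma <- sum(w * a); mb <- sum(w * b)
  sum(w * (a - ma) * (b - mb)) /
    sqrt(sum(w * (a - ma)^2) * sum(w * (b - mb)^2))
}

#' Reverse complement of ACGTN strings
#'
#' @param x character vector of sequences.
#' @return reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}
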