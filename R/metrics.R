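#' Radius of gyration
#'
#' Root-mean-square distance of points from their centroid.
#'
#' @param X points-by-3 coordinate matrix.
#' @return scalar Rg.
#' @export
radius_of_gyration <- function(X) {
  ctr <- colMeans(X)
  sqrt(mean(rowSums((X - matrix(ctr, nrow(X), 3, byrow = TRUE))^2)))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Rotates and translates `P` onto `Q` minimizing RMSD, with the usual
#' determinant correction so no reflection is introduced.
#'
#' @param P,Q points-by-3 matrices with matched rows.
#' @return the transformed copy of `P`.
#' @export
superpose <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- P - matrix(cp, nrow(P), 3, byrow = TRUE)
  Q0 <- Q - matrix(cq, nrow(Q), 3, byrow = TRUE)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  P0 %*% t(R) + matrix(cq, nrow(P), 3, byrow = TRUE)
}

#' Structural metrics of a 3D chromosome ensemble
#'
#' Computes, over ensemble members: the radius of gyration of the beads
#' within +/- `centromere_window` of each centromere (mean and standard error
#' over members); per-bead flexibility as the RMSD of bead positions after
#' optimal superposition of each member onto the ensemble mean shape; all
#' pairwise telomere-bead distances divided by their grand mean (so the
#' relative distances average exactly 1); and mean +/- SE distances for named
#' locus pairs.
#'
#' @param ensemble a `StructureEnsemble`, or a list of coordinate matrices
#'   (then `bead_ids` and `layout` are required).
#' @param layout a `GenomeLayout`.
#' @param bead_ids genome-wide bin indices of the ensemble beads.
#' @param centromere_window bp on each side of the centromere (default 1e5).
#' @param loci optional named list of locus pairs, each
#'   `list(c(chrom, pos), c(chrom, pos))`.
#' @return list: `rg_centromere` (data.frame chrom, mean, se, n_beads),
#'   `flexibility` (data.frame chrom, bead, rmsd), `chrom_flexibility`
#'   (per-chromosome mean RMSD), `telomere_rel_dist` (vector),
#'   `locus_distances` (data.frame, if `loci` given).
#' @export
structure_metrics <- function(ensemble, layout = NULL, bead_ids = NULL,
                              centromere_window = 1e5, loci = NULL) {
  if (inherits(ensemble, "StructureEnsemble")) {
    members <- ensemble$members
    if (is.null(bead_ids)) bead_ids <- ensemble$restraints$bead_ids
    if (is.null(layout)) layout <- ensemble$restraints$layout
  } else members <- ensemble
  stopifnot(!is.null(layout), !is.null(bead_ids))
  bins <- layout_bins(layout)
  nm <- length(members)
  loc <- function(g) match(g, bead_ids)

  # Rg around centromeres
  rg_rows <- list()
  for (ci in seq_along(layout$chrom_names)) {
    ch <- layout$chrom_names[ci]
    win <- suppressWarnings(bins_in_window(
      layout, ch, max(0, layout$centromere_pos[ci] - centromere_window),
      min(layout$chrom_lengths[ci], layout$centromere_pos[ci] + centromere_window)))
    li <- loc(intersect(win, bead_ids))
    li <- li[!is.na(li)]
    if (length(li) < 2) next
    rgs <- vapply(members, function(X) radius_of_gyration(X[li, , drop = FALSE]), 0)
    rg_rows[[ch]] <- data.frame(chrom = ch, rg_mean = mean(rgs),
                                rg_se = sd(rgs) / sqrt(nm), n_beads = length(li))
  }
  rg_centromere <- do.call(rbind, rg_rows)
  rownames(rg_centromere) <- NULL

  # per-bead flexibility: superpose members onto the ensemble mean shape
  flex_rows <- list()
  for (ch in unique(bins$chrom[bead_ids])) {
    li <- which(bins$chrom[bead_ids] == ch)
    if (length(li) < 3) next
    sub <- lapply(members, function(X) X[li, , drop = FALSE])
    ref <- sub[[1]]
    for (iter in 1:2) {
      aligned <- lapply(sub, superpose, Q = ref)
      ref <- Reduce(`+`, aligned) / nm
    }
    dev2 <- Reduce(`+`, lapply(aligned, function(A) rowSums((A - ref)^2))) / nm
    flex_rows[[ch]] <- data.frame(chrom = ch, bead = bead_ids[li],
                                  rmsd = sqrt(dev2))
  }
  flexibility <- do.call(rbind, flex_rows)
  rownames(flexibility) <- NULL
  chrom_flex <- if (!is.null(flexibility))
    aggregate(rmsd ~ chrom, flexibility, mean) else NULL

  # relative telomere distances
  tel <- loc(intersect(telomere_bins(layout), bead_ids))
  tel <- tel[!is.na(tel)]
  telomere_rel <- NULL
  if (length(tel) >= 2) {
    dd <- unlist(lapply(members, function(X) {
      D <- as.matrix(dist(X[tel, , drop = FALSE]))
      D[upper.tri(D)]
    }))
    telomere_rel <- dd / mean(dd)
  }

  locus_distances <- NULL
  if (!is.null(loci)) {
    rows <- lapply(names(loci), function(nmX) {
      pr <- loci[[nmX]]
      b1 <- bins_in_window(layout, pr[[1]][1], as.numeric(pr[[1]][2]),
                           as.numeric(pr[[1]][2]) + 1)
      b2 <- bins_in_window(layout, pr[[2]][1], as.numeric(pr[[2]][2]),
                           as.numeric(pr[[2]][2]) + 1)
      l1 <- loc(b1); l2 <- loc(b2)
      if (is.na(l1) || is.na(l2)) return(NULL)
      d <- vapply(members, function(X) sqrt(sum((X[l1, ] - X[l2, ])^2)), 0)
      data.frame(pair = nmX, mean = mean(d), se = sd(d) / sqrt(nm))
    })
    locus_distances <- do.call(rbind, rows)
  }

  list(rg_centromere = rg_centromere, flexibility = flexibility,
       chrom_flexibility = chrom_flex, telomere_rel_dist = telomere_rel,
       locus_distances = locus_distances)
}
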