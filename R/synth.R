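#' Mixture specification for simulated per-read methylation
#'
#' Defines the ground-truth binomial mixture a simulated long-read library is
#' drawn from: component weights, per-component methylation rates, and the law
#' for the number of CpG sites assayed per read.
#'
#' @param weights component weights, summing to 1.
#' @param rates per-component methylation probabilities in [0, 1].
#' @param sites_min,sites_max bounds of the per-read CpG count law.
#' @param sites_law `"uniform"` (discrete uniform on `sites_min:sites_max`) or
#'   `"fixed"` (`sites_min` sites for every read).
#' @return object of class `MixtureSpec`, components sorted by rate.
#' @export
mixture_spec <- function(weights, rates, sites_min = 20L, sites_max = 100L,
                         sites_law = c("uniform", "fixed")) {
  sites_law <- match.arg(sites_law)
  if (!length(weights) || length(weights) != length(rates))
    stop("weights and rates must be non-empty and of equal length")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  o <- order(rates)
  structure(list(weights = weights[o], rates = rates[o],
                 sites_min = as.integer(sites_min),
                 sites_max = as.integer(sites_max),
                 sites_law = sites_law),
            class = "MixtureSpec")
}

#' Simulate ground-truth 3D chromosome structures
#'
#' Generates self-avoiding bead chains per chromosome inside a spherical
#' nucleus, with centromeres biased toward a common pole (a Rabl-like
#' arrangement) and optional local compaction that shortens bond lengths.
#' Used as the known truth behind simulated Hi-C maps.
#'
#' @param layout a `GenomeLayout`; one bead per bin.
#' @param n_structures number of independent structures.
#' @param rabl_strength in [0, 1]: 0 leaves chromosomes where the random walk
#'   put them; 1 moves every centromere bead exactly to the nuclear pole.
#' @param compaction_map optional data.frame (`chrom`, `start`, `end`,
#'   `factor`) shortening bond lengths inside each region by `factor`
#'   (factor 2 halves the local bond length). Factors must be > 0.
#' @param bond_length target consecutive-bead distance in model units.
#' @param seed RNG seed.
#' @return object of class `TruthStructureSet`: list with `members` (list of
#'   beads-by-3 matrices), `layout`, and the generating parameters.
#' @export
simulate_structures <- function(layout, n_structures = 1L, rabl_strength = 0.8,
                                compaction_map = NULL, bond_length = 1,
                                seed = 1L) {
  stopifnot(inherits(layout, "GenomeLayout"), n_structures >= 1)
  if (rabl_strength < 0 || rabl_strength > 1)
    stop("rabl_strength must lie in [0, 1]")
  bins <- layout_bins(layout)
  n <- nrow(bins)
  # per-bond compaction factor, assigned by the bin the bond starts in
  factor_of_bin <- rep(1, n)
  if (!is.null(compaction_map)) {
    if (any(compaction_map$factor <= 0)) stop("compaction factor must be > 0")
    for (k in seq_len(nrow(compaction_map))) {
      hit <- bins$chrom == compaction_map$chrom[k] &
        bins$start < compaction_map$end[k] & bins$end > compaction_map$start[k]
      factor_of_bin[hit] <- compaction_map$factor[k]
    }
  }
  nucleus_r <- bond_length * max(4, n^(1/3) * 2)
  pole <- c(0, 0, nucleus_r * 0.9)
  set.seed(seed)
  members <- vector("list", n_structures)
  for (s in seq_len(n_structures)) {
    X <- matrix(NA_real_, n, 3)
    for (ci in seq_along(layout$chrom_names)) {
      idx <- which(bins$chrom == layout$chrom_names[ci])
      nb <- length(idx)
      # random start well inside the nucleus
      repeat {
        p0 <- runif(3, -1, 1) * nucleus_r * 0.5
        if (sum(p0^2) < (nucleus_r * 0.5)^2) break
      }
      chain <- matrix(NA_real_, nb, 3)
      chain[1, ] <- p0
      for (b in 2:nb) {
        blen <- bond_length / factor_of_bin[idx[b - 1]]
        ok <- FALSE
        for (try in 1:50) {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          cand <- chain[b - 1, ] + blen * u
          if (sum(cand^2) > nucleus_r^2) next
          if (b > 2) {
            d2 <- rowSums((chain[1:(b - 2), , drop = FALSE] -
                             matrix(cand, b - 2, 3, byrow = TRUE))^2)
            if (min(d2) < (0.7 * blen)^2) next
          }
          ok <- TRUE; break
        }
        if (!ok) cand <- chain[b - 1, ] + blen * u  # accept last proposal
        chain[b, ] <- cand
      }
      # rigid shift of the whole chromosome toward the pole
      cen_bin <- which(bins$chrom == layout$chrom_names[ci] &
                         bins$start <= layout$centromere_pos[ci] &
                         bins$end > layout$centromere_pos[ci])
      cen_local <- match(cen_bin, idx)
      shift <- rabl_strength * (pole - chain[cen_local, ])
      X[idx, ] <- chain + matrix(shift, nb, 3, byrow = TRUE)
    }
    members[[s]] <- X
  }
  structure(list(members = members, layout = layout,
                 params = list(rabl_strength = rabl_strength,
                               bond_length = bond_length,
                               nucleus_r = nucleus_r, pole = pole,
                               seed = seed)),
            class = "TruthStructureSet")
}

#' Convert ground-truth structures to a simulated Hi-C contact matrix
#'
#' Applies the contact-to-distance power law in reverse: the expected contact
#' frequency of a bead pair is proportional to the mean over structures of
#' `(gamma / d_ij)^(1/alpha)`, scaled so the total expectation equals `depth`;
#' observed counts are Poisson samples. The diagonal is excluded. Coincident
#' beads are capped at the bond length with a warning.
#'
#' @param truth a `TruthStructureSet`.
#' @param gamma,alpha power-law scale and exponent (> 0).
#' @param depth expected total count.
#' @param seed RNG seed.
#' @param bias optional per-bin multiplicative bias vector (exercises
#'   iterative correction downstream); total expectation is rescaled back to
#'   `depth`.
#' @return a `ContactMatrix`.
#' @export
structures_to_contacts <- function(truth, gamma, alpha, depth, seed = 1L,
                                   bias = NULL) {
  stopifnot(inherits(truth, "TruthStructureSet"))
  if (gamma <= 0 || alpha <= 0 || depth <= 0)
    stop("gamma, alpha and depth must be > 0")
  n <- nrow(truth$members[[1]])
  bl <- truth$params$bond_length
  f <- matrix(0, n, n)
  warned <- FALSE
  for (X in truth$members) {
    D <- as.matrix(dist(X))
    if (any(D[upper.tri(D)] < 1e-9)) warned <- TRUE
    D <- pmax(D, bl)
    f <- f + (gamma / D)^(1 / alpha)
  }
  if (warned) warning("coincident beads: distance capped at bond length")
  f <- f / length(truth$members)
  diag(f) <- 0
  if (!is.null(bias)) {
    stopifnot(length(bias) == n, all(bias > 0))
    f <- f * outer(bias, bias)
  }
  lam <- f * (depth / sum(f[upper.tri(f)]))
  set.seed(seed)
  ut <- upper.tri(lam)
  counts <- matrix(0, n, n)
  counts[ut] <- rpois(sum(ut), lam[ut])
  counts <- counts + t(counts)
  contact_matrix(counts, truth$layout)
}

#' Simulate a per-read CpG methylation table
#'
#' Each read draws a mixture component by weight, a CpG count from the
#' configured law, and a methylated count from the component's binomial rate.
#' The hidden component label is kept as an attribute for recovery tests.
#'
#' @param n_reads number of reads (>= 1).
#' @param spec a `MixtureSpec`.
#' @param seed RNG seed.
#' @return data.frame (`read_id`, `n_sites`, `n_meth`) with attribute
#'   `truth_component` (integer labels into `spec`'s sorted components).
#' @export
simulate_reads <- function(n_reads, spec, seed = 1L) {
  stopifnot(inherits(spec, "MixtureSpec"), n_reads >= 1)
  set.seed(seed)
  comp <- sample.int(length(spec$weights), n_reads, replace = TRUE,
                     prob = spec$weights)
  n_sites <- if (spec$sites_law == "fixed") rep(spec$sites_min, n_reads)
             else sample(spec$sites_min:spec$sites_max, n_reads, replace = TRUE)
  n_meth <- rbinom(n_reads, n_sites, spec$rates[comp])
  out <- data.frame(read_id = sprintf("read_%06d", seq_len(n_reads)),
                    n_sites = n_sites, n_meth = n_meth,
                    stringsAsFactors = FALSE)
  attr(out, "truth_component") <- comp
  out
}

#' Simulate a per-site CpG count table with sequence context
#'
#' Sites draw a 6-mer context uniformly from the supplied set; methylated
#' counts follow a binomial with success probability `plogis(effect)` of the
#' site's motif. Ground-truth effects are retained as an attribute.
#'
#' @param motif_effects named numeric vector: 6-mer motif (central CG) to
#'   log-odds of methylation.
#' @param n_sites number of CpG sites.
#' @param depth read depth per site: a single integer or a function of `n`.
#' @param seed RNG seed.
#' @return data.frame (`chrom`, `pos`, `strand`, `motif`, `n_meth`,
#'   `n_unmeth`) with attribute `truth_effects`.
#' @export
simulate_site_table <- function(motif_effects, n_sites, depth = 50L,
                                seed = 1L) {
  motifs <- names(motif_effects)
  if (is.null(motifs) || any(nchar(motifs) != 6) ||
      any(substr(motifs, 3, 4) != "CG"))
    stop("every motif must be a 6-mer with a central CG")
  set.seed(seed)
  m <- sample(motifs, n_sites, replace = TRUE)
  d <- if (is.function(depth)) depth(n_sites) else rep(as.integer(depth), n_sites)
  p <- stats::plogis(motif_effects[m])
  n_meth <- rbinom(n_sites, d, p)
  out <- data.frame(chrom = "chrS", pos = seq_len(n_sites) * 10L, strand = "+",
                    motif = m, n_meth = n_meth, n_unmeth = d - n_meth,
                    stringsAsFactors = FALSE)
  attr(out, "truth_effects") <- motif_effects
  out
}

#' Simulate an MNase-seq coverage track from planted nucleosome dyads
#'
#' Fragment centers are normal around each dyad (spread `fuzz_sd`, dyad chosen
#' by occupancy weight); coverage is the pileup of center-trimmed fragments
#' (50 bp by default, matching the trimmed-fragment convention).
#'
#' @param dyads data.frame (`pos`, `fuzz_sd`, `occupancy`), positions 0-based
#'   within the region.
#' @param region_len region length in bp.
#' @param depth number of fragments; 0 yields an all-zero track.
#' @param frag_len trimmed fragment length in bp.
#' @param seed RNG seed.
#' @return a `CoverageTrack` with attribute `truth_dyads`.
#' @export
simulate_mnase <- function(dyads, region_len, depth = 1e5, frag_len = 50L,
                           seed = 1L) {
  stopifnot(all(dyads$pos >= 0), all(dyads$pos < region_len))
  values <- numeric(region_len)
  if (depth > 0) {
    set.seed(seed)
    k <- sample.int(nrow(dyads), depth, replace = TRUE, prob = dyads$occupancy)
    centers <- round(rnorm(depth, dyads$pos[k], dyads$fuzz_sd[k]))
    lo <- pmax(0L, centers - floor((frag_len - 1) / 2))
    hi <- pmin(region_len - 1L, centers + ceiling((frag_len - 1) / 2))
    keep <- lo <= hi & hi >= 0 & lo < region_len
    # difference-array accumulation of interval pileup
    diffs <- numeric(region_len + 1L)
    tab_lo <- tabulate(lo[keep] + 1L, nbins = region_len)
    tab_hi <- tabulate(hi[keep] + 2L, nbins = region_len + 1L)
    diffs[seq_len(region_len)] <- tab_lo
    diffs <- diffs - tab_hi
    values <- cumsum(diffs[seq_len(region_len)])
  }
  out <- coverage_track("chrS", values)
  attr(out, "truth_dyads") <- dyads
  out
}
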