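## Restraint-based 3D chromosome modeling from Hi-C contact matrices.
##
## Pipeline: iterative correction (ICE) -> power-law conversion of contact
## frequencies to equilibrium distances (d = gamma / f^alpha, applied to
## pairs above twice the median trans count) -> harmonic restraint system
## (flat-welled parabola with one-bead-radius tolerance, connectivity five
## orders of magnitude stiffer, excluded volume, long-range repulsion) ->
## annealed sampling -> greedy ensemble selection by restraint violations.

#' Iterative correction (ICE) of a contact matrix
#'
#' Removes multiplicative per-bin biases by repeatedly dividing by the outer
#' product of row marginals until unmasked per-bin coverage is uniform within
#' `tol`. The total count is preserved. Unmasked all-zero rows are auto-masked
#' with a warning.
#'
#' @param cm a `ContactMatrix`.
#' @param max_iter iteration cap.
#' @param tol maximum allowed relative deviation of row sums from their mean.
#' @return a balanced `ContactMatrix` (masked set possibly grown).
#' @export
ice_balance <- function(cm, max_iter = 200L, tol = 1e-6) {
  stopifnot(inherits(cm, "ContactMatrix"))
  M <- cm$counts
  masked <- cm$masked
  active <- setdiff(seq_len(nrow(M)), masked)
  zero <- active[rowSums(M[active, , drop = FALSE]) == 0]
  if (length(zero)) {
    warning(length(zero), " all-zero unmasked bin(s) auto-masked")
    masked <- sort(union(masked, zero))
    active <- setdiff(active, zero)
  }
  if (!length(active)) stop("no active bins to balance")
  A <- M[active, active, drop = FALSE]
  total <- sum(A)
  for (it in seq_len(max_iter)) {
    s <- rowSums(A)
    b <- s / mean(s)
    if (max(abs(b - 1)) < tol) break
    A <- A / outer(b, b)
  }
  A <- A * (total / sum(A))
  out <- matrix(0, nrow(M), ncol(M))
  out[active, active] <- A
  contact_matrix(out, cm$layout, masked)
}

#' Convert contact frequencies to equilibrium distances
#'
#' Implements the inverse power law `d_ij = gamma / f_ij^alpha`. Interacting
#' pairs are those with frequency above twice the median of all trans
#' (inter-chromosomal) counts; remaining pairs are recorded for repulsive
#' restraints. With a single chromosome (no trans bins) the cutoff falls back
#' to a quantile of the positive cis counts, with a warning.
#'
#' @param cm a (balanced) `ContactMatrix`.
#' @param gamma length scale of the structure (model units).
#' @param alpha power-law exponent.
#' @param cis_quantile fallback cutoff quantile for single-chromosome input.
#' @return object of class `DistanceModel`: `gamma`, `alpha`, `cutoff`,
#'   `pairs` (data.frame `i`, `j`, `f`, `r0` over interacting pairs,
#'   genome-wide bin indices), `layout`, `masked`, `counts`.
#' @export
contacts_to_distances <- function(cm, gamma, alpha, cis_quantile = 0.75) {
  stopifnot(inherits(cm, "ContactMatrix"))
  if (gamma <= 0 || alpha <= 0) stop("gamma and alpha must be > 0")
  bins <- cm$bins
  n <- nrow(bins)
  active <- setdiff(seq_len(n), cm$masked)
  chrom_of <- bins$chrom
  ut <- which(upper.tri(cm$counts), arr.ind = TRUE)
  keep <- ut[, 1] %in% active & ut[, 2] %in% active
  ut <- ut[keep, , drop = FALSE]
  f <- cm$counts[ut]
  is_trans <- chrom_of[ut[, 1]] != chrom_of[ut[, 2]]
  if (any(is_trans)) {
    cutoff <- 2 * median(f[is_trans])
  } else {
    warning("no trans bins: cutoff falls back to the cis ",
            cis_quantile, " quantile")
    cutoff <- quantile(f[f > 0], cis_quantile, names = FALSE)
  }
  sel <- f > cutoff
  pairs <- data.frame(i = ut[sel, 1], j = ut[sel, 2], f = f[sel],
                      r0 = gamma / f[sel]^alpha)
  structure(list(gamma = gamma, alpha = alpha, cutoff = cutoff,
                 pairs = pairs, layout = cm$layout, masked = cm$masked,
                 counts = cm$counts),
            class = "DistanceModel")
}

#' Build the restraint system for a set of beads
#'
#' Constructs, over the requested beads (all unmasked bins of one chromosome,
#' or genome-wide): connectivity restraints between consecutive beads with a
#' force constant 1e5 times the interaction constant (gaps over masked bins
#' get proportionally longer equilibrium distances); flat-welled interaction
#' restraints (half-width one bead radius) for interacting pairs; one
#' repulsive restraint per non-interacting pair, active below the maximum
#' interaction equilibrium distance; and Lennard-Jones-style excluded volume
#' between all bead pairs with equilibrium distance one bead radius.
#'
#' @param dm a `DistanceModel`.
#' @param chrom chromosome to model, or `NULL` for the whole genome.
#' @param k_interaction interaction force constant (arbitrary units).
#' @param r_bead bead radius / flat-well half-width; default half the median
#'   consecutive-bead equilibrium distance.
#' @return object of class `RestraintSet`: data.frame `pairs`
#'   (`i`, `j` local bead indices, `r0`, `k`, `kind`), plus `r_bead`,
#'   `bead_ids` (genome-wide bin indices), `n_beads`, `k_interaction`,
#'   `eps_lj`.
#' @export
build_restraints <- function(dm, chrom = NULL, k_interaction = 1,
                             r_bead = NULL) {
  stopifnot(inherits(dm, "DistanceModel"))
  bins <- layout_bins(dm$layout)
  beads <- setdiff(seq_len(nrow(bins)), dm$masked)
  if (!is.null(chrom)) beads <- beads[bins$chrom[beads] == chrom]
  if (length(beads) < 2) stop("fewer than 2 beads to model")
  nb <- length(beads)
  loc <- function(g) match(g, beads)
  P <- dm$pairs[dm$pairs$i %in% beads & dm$pairs$j %in% beads, , drop = FALSE]
  # consecutive beads within a chromosome, bridging masked gaps
  same_chr <- bins$chrom[beads[-nb]] == bins$chrom[beads[-1]]
  ci <- which(same_chr)
  gap <- (bins$start[beads[ci + 1]] - bins$start[beads[ci]]) /
    dm$layout$bin_size
  pk <- paste(P$i, P$j)
  conn_key <- paste(beads[ci], beads[ci + 1])
  conn_r0 <- dm$pairs$r0[match(conn_key, pk)]
  med_conn <- median(conn_r0, na.rm = TRUE)
  if (!is.finite(med_conn)) med_conn <- median(P$r0)
  conn_r0[is.na(conn_r0)] <- med_conn
  conn_r0 <- conn_r0 * gap
  if (is.null(r_bead)) r_bead <- med_conn / 2
  conn <- data.frame(i = ci, j = ci + 1L, r0 = conn_r0,
                     k = k_interaction * 1e5, kind = "connectivity")
  # interaction restraints for non-consecutive interacting pairs
  inter_sel <- !(pk %in% conn_key)
  inter <- data.frame(i = loc(P$i[inter_sel]), j = loc(P$j[inter_sel]),
                      r0 = P$r0[inter_sel],
                      k = rep(k_interaction, sum(inter_sel)),
                      kind = rep("interaction", sum(inter_sel)))
  r0_max <- if (nrow(P)) max(P$r0) else med_conn * 2
  # all remaining pairs: repulsive beyond r0_max
  all_ut <- which(upper.tri(matrix(0, nb, nb)), arr.ind = TRUE)
  restrained <- paste(all_ut[, 1], all_ut[, 2]) %in%
    c(paste(conn$i, conn$j), paste(inter$i, inter$j))
  rep_pairs <- all_ut[!restrained, , drop = FALSE]
  repl <- data.frame(i = rep_pairs[, 1], j = rep_pairs[, 2],
                     r0 = rep(r0_max, nrow(rep_pairs)),
                     k = rep(k_interaction, nrow(rep_pairs)),
                     kind = rep("repulsive", nrow(rep_pairs)))
  # excluded volume between every pair
  ev <- data.frame(i = all_ut[, 1], j = all_ut[, 2], r0 = r_bead,
                   k = k_interaction, kind = "excluded_volume")
  pairs <- rbind(conn, inter, repl, ev)
  rownames(pairs) <- NULL
  # full-matrix distance estimates over these beads (initialization only;
  # restraints above are the model)
  fsub <- dm$counts[beads, beads]
  d_full <- dm$gamma / pmax(fsub, 1e-12)^dm$alpha
  d_full[fsub <= 0] <- NA
  diag(d_full) <- 0
  structure(list(pairs = pairs, r_bead = r_bead, bead_ids = beads,
                 d_full = d_full,
                 n_beads = nb, k_interaction = k_interaction,
                 eps_lj = 0.1 * k_interaction * r_bead^2,
                 layout = dm$layout, gamma = dm$gamma, alpha = dm$alpha),
            class = "RestraintSet")
}

# per-pair energies and dE/dr, vectorized over the restraint table
.pair_energy <- function(r, rs) {
  p <- rs$pairs
  e <- numeric(nrow(p)); de <- numeric(nrow(p))
  fw <- p$kind %in% c("connectivity", "interaction")
  if (any(fw)) {
    lo <- p$r0[fw] - rs$r_bead
    hi <- p$r0[fw] + rs$r_bead
    rr <- r[fw]
    dev <- ifelse(rr < lo, rr - lo, ifelse(rr > hi, rr - hi, 0))
    e[fw] <- p$k[fw] * dev^2
    de[fw] <- 2 * p$k[fw] * dev
  }
  rp <- p$kind == "repulsive"
  if (any(rp)) {
    dev <- pmin(r[rp] - p$r0[rp], 0)
    e[rp] <- p$k[rp] * dev^2
    de[rp] <- 2 * p$k[rp] * dev
  }
  ev <- p$kind == "excluded_volume"
  if (any(ev)) {
    rm <- p$r0[ev]
    rr <- pmax(r[ev], 0.3 * rm)    # hard floor against overflow
    x <- (rm / rr)^6
    inside <- r[ev] < rm
    e[ev] <- ifelse(inside, rs$eps_lj * (x^2 - 2 * x + 1), 0)
    de[ev] <- ifelse(inside, rs$eps_lj * 12 * (x - x^2) / rr, 0)
  }
  list(e = e, de = de)
}

#' Total restraint energy with per-kind breakdown
#'
#' Flat-welled parabola `k (r - r')^2` for connectivity and interaction
#' restraints (`r'` equals `r0 - r_bead` below the well, `r` inside
#' `r0 +/- r_bead`, `r0 + r_bead` above), one-sided quadratic repulsion below
#' the maximum equilibrium distance for non-interacting pairs, and a purely
#' repulsive truncated-shifted Lennard-Jones excluded volume with minimum at
#' one bead radius.
#'
#' @param coords beads-by-3 coordinate matrix.
#' @param restraints a `RestraintSet`.
#' @return list with `total` and `by_kind`.
#' @export
restraint_energy <- function(coords, restraints) {
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  p <- restraints$pairs
  d <- coords[p$i, , drop = FALSE] - coords[p$j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  pe <- .pair_energy(r, restraints)
  list(total = sum(pe$e),
       by_kind = tapply(pe$e, p$kind, sum))
}

#' Analytic gradient of the restraint energy
#'
#' @param coords beads-by-3 coordinate matrix.
#' @param restraints a `RestraintSet`.
#' @return beads-by-3 gradient matrix.
#' @export
restraint_gradient <- function(coords, restraints) {
  p <- restraints$pairs
  d <- coords[p$i, , drop = FALSE] - coords[p$j, , drop = FALSE]
  r <- pmax(sqrt(rowSums(d^2)), 1e-12)
  pe <- .pair_energy(r, restraints)
  gv <- d * (pe$de / r)
  n <- nrow(coords)
  acc <- function(v, idx) {
    out <- numeric(n)
    t <- rowsum(v, idx)
    out[as.integer(rownames(t))] <- t
    out
  }
  G <- matrix(0, n, 3)
  for (col in 1:3)
    G[, col] <- acc(gv[, col], p$i) - acc(gv[, col], p$j)
  G
}

#' Distance-geometry initialization from a restraint set
#'
#' Converts every observed contact frequency over the modeled beads to a
#' distance estimate (falling back to the connectivity + interaction restraint
#' graph), completes missing entries by shortest paths, and embeds the result
#' in 3D by classical multidimensional scaling — the standard starting point
#' for restraint-based structure calculation. Only the restraints, not these
#' estimates, enter the energy.
#'
#' @param restraints a `RestraintSet`.
#' @return beads-by-3 coordinate matrix.
#' @export
distance_geometry_init <- function(restraints) {
  nb <- restraints$n_beads
  if (!is.null(restraints$d_full)) {
    D <- restraints$d_full
    D[is.na(D)] <- Inf
  } else {
    p <- restraints$pairs[restraints$pairs$kind %in%
                            c("connectivity", "interaction"), ]
    D <- matrix(Inf, nb, nb); diag(D) <- 0
    D[cbind(p$i, p$j)] <- p$r0
    D[cbind(p$j, p$i)] <- p$r0
  }
  for (k in seq_len(nb))   # Floyd-Warshall, vectorized over (i, j)
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  if (any(!is.finite(D))) D[!is.finite(D)] <- max(D[is.finite(D)]) * 2
  X <- cmdscale(D, k = min(3L, nb - 1L))
  if (ncol(X) < 3) X <- cbind(X, matrix(0, nb, 3 - ncol(X)))
  X
}

#' Sample candidate structures by annealed descent
#'
#' Per replica: initialize from a distance-geometry embedding, an extended
#' conformation, or a random localization, then alternate normalized
#' steepest-descent steps (backtracking line search) with Metropolis-accepted
#' random bead perturbations under a geometric temperature schedule. Snapshots
#' are collected along the way; deterministic under `seed`.
#'
#' @param restraints a `RestraintSet`.
#' @param n_replicas number of independent replicas.
#' @param init_mode `"mixed"` (cycles mds/extended/random), `"mds"`,
#'   `"extended"`, or `"random"`.
#' @param n_steps descent steps per replica.
#' @param snapshot_stride keep a snapshot every this many steps (the final and
#'   best-energy conformations are always kept).
#' @param perturb_every Metropolis perturbation interval.
#' @param seed RNG seed.
#' @return list of class `CandidateSet`: `structures` (list of coordinate
#'   matrices), `energy` (per candidate), `replica` (origin), `restraints`.
#' @export
sample_structures <- function(restraints, n_replicas = 10L,
                              init_mode = c("mixed", "mds", "extended",
                                            "random"),
                              n_steps = 400L, snapshot_stride = 200L,
                              perturb_every = 10L, seed = 1L) {
  init_mode <- match.arg(init_mode)
  stopifnot(n_replicas >= 1)
  rb <- restraints$r_bead
  nb <- restraints$n_beads
  conn <- restraints$pairs[restraints$pairs$kind == "connectivity", ]
  spacing <- if (nrow(conn)) median(conn$r0) else 2 * rb
  set.seed(seed)
  X_dg <- distance_geometry_init(restraints)
  structures <- list(); energies <- numeric(0); replica <- integer(0)
  for (rep_i in seq_len(n_replicas)) {
    mode <- if (init_mode == "mixed") {
      c("mds", "extended", "random")[(rep_i - 1L) %% 3L + 1L]
    } else init_mode
    X <- if (mode == "mds") {
      X_dg + matrix(rnorm(nb * 3, 0, rb), nb, 3)
    } else if (mode == "extended") {
      cbind(seq_len(nb) * spacing, 0, 0) + matrix(rnorm(nb * 3, 0, 0.1 * rb),
                                                  nb, 3)
    } else {
      R <- spacing * nb^(1/3) * 1.5
      matrix(runif(nb * 3, -R, R), nb, 3)
    }
    E <- restraint_energy(X, restraints)$total
    E0 <- E
    T0 <- max(E0 / max(1, nrow(restraints$pairs)), 1e-8)
    Tend <- T0 * 1e-4
    s <- rb
    best <- list(X = X, E = E)
    dropped <- FALSE
    for (t in seq_len(n_steps)) {
      G <- restraint_gradient(X, restraints)
      gmax <- max(sqrt(rowSums(G^2)))
      if (!is.finite(gmax) || gmax == 0) gmax <- 1
      ok <- FALSE
      for (try in 1:8) {
        Xn <- X - (s / gmax) * G
        En <- tryCatch(restraint_energy(Xn, restraints)$total,
                       error = function(e) Inf)
        if (is.finite(En) && En <= E) { ok <- TRUE; break }
        s <- s * 0.5
      }
      if (ok) { X <- Xn; E <- En; s <- min(s * 1.3, 5 * rb) }
      else if (s < 1e-6 * rb) s <- 0.5 * rb
      if (t %% perturb_every == 0) {
        Temp <- T0 * (Tend / T0)^(t / n_steps)
        sel <- sample.int(nb, max(1L, round(0.1 * nb)))
        Y <- X
        Y[sel, ] <- Y[sel, ] + matrix(rnorm(length(sel) * 3, 0, rb), length(sel), 3)
        Ey <- tryCatch(restraint_energy(Y, restraints)$total,
                       error = function(e) Inf)
        if (is.finite(Ey) &&
            (Ey < E || runif(1) < exp(-(Ey - E) / Temp))) {
          X <- Y; E <- Ey
        }
      }
      if (E < best$E) best <- list(X = X, E = E)
      if (t %% snapshot_stride == 0 && t < n_steps) {
        structures[[length(structures) + 1]] <- X
        energies <- c(energies, E)
        replica <- c(replica, rep_i)
      }
      if (!is.finite(E)) { dropped <- TRUE; break }
    }
    if (dropped) { warning("replica ", rep_i, " dropped (diverging energy)"); next }
    structures[[length(structures) + 1]] <- best$X
    energies <- c(energies, best$E)
    replica <- c(replica, rep_i)
  }
  if (!length(structures)) stop("all replicas diverged")
  structure(list(structures = structures, energy = energies,
                 replica = replica, restraints = restraints),
            class = "CandidateSet")
}

# logical matrix: candidate x interaction-restraint satisfaction
.satisfaction <- function(structures, restraints) {
  p <- restraints$pairs
  ii <- p$kind == "interaction"
  pi <- p[ii, , drop = FALSE]
  t(vapply(structures, function(X) {
    r <- sqrt(rowSums((X[pi$i, , drop = FALSE] - X[pi$j, , drop = FALSE])^2))
    r >= pi$r0 - restraints$r_bead & r <= pi$r0 + restraints$r_bead
  }, logical(nrow(pi))))
}

#' Greedy ensemble selection by restraint violations
#'
#' Implements the selection rule: candidates with more interaction-restraint
#' violations than the population mean are discarded; the candidate with the
#' fewest violations seeds the ensemble; then, considering only restraints not
#' yet satisfied by any selected member, the candidate satisfying the most of
#' them is added, iterating until no candidate satisfies a new restraint.
#' Ties are broken by lower total energy, then input order. A violation is an
#' interaction restraint whose realized distance falls outside
#' `r0 +/- r_bead`.
#'
#' @param candidates a `CandidateSet` (or list of coordinate matrices, in
#'   which case `restraints` is required).
#' @param restraints a `RestraintSet`; defaults to the one in `candidates`.
#' @return object of class `StructureEnsemble`: `members`, `member_ids`
#'   (indices into the candidate list), `violations` (per member),
#'   `selection_order`, `satisfied_union` (logical per interaction restraint),
#'   `restraints`.
#' @export
select_ensemble <- function(candidates, restraints = NULL) {
  if (inherits(candidates, "CandidateSet")) {
    if (is.null(restraints)) restraints <- candidates$restraints
    energy <- candidates$energy
    structures <- candidates$structures
  } else {
    structures <- candidates
    if (is.null(restraints)) stop("restraints required with a plain list")
    energy <- vapply(structures, function(X)
      restraint_energy(X, restraints)$total, 0)
  }
  if (!length(structures)) stop("no candidates")
  S <- .satisfaction(structures, restraints)
  n_restr <- ncol(S)
  viol <- n_restr - rowSums(S)
  keep <- which(viol <= mean(viol))
  pick_best <- function(pool, score) {
    # maximal score, ties by lower energy then input order
    o <- order(-score, energy[pool], pool)
    pool[o[1]]
  }
  first <- pick_best(keep, -viol[keep])
  selected <- first
  pool <- setdiff(keep, first)
  unsat <- if (n_restr) !S[first, ] else logical(0)
  while (length(pool) && any(unsat)) {
    gains <- rowSums(S[pool, unsat, drop = FALSE])
    if (max(gains) == 0) break
    nxt <- pick_best(pool, gains)
    selected <- c(selected, nxt)
    unsat <- unsat & !S[nxt, ]
    pool <- setdiff(pool, nxt)
  }
  structure(list(members = structures[selected], member_ids = selected,
                 violations = viol[selected], selection_order = selected,
                 satisfied_union = if (n_restr) !unsat else logical(0),
                 energy = energy[selected],
                 restraints = restraints),
            class = "StructureEnsemble")
}

#' @export
print.StructureEnsemble <- function(x, ...) {
  cat(sprintf(
    "StructureEnsemble: %d members, %d/%d interaction restraints satisfied\n",
    length(x$members), sum(x$satisfied_union), length(x$satisfied_union)))
  invisible(x)
}

#' Modeled contact map from an ensemble
#'
#' Hard mode (default): entry (i, j) is the fraction of ensemble members in
#' which beads i and j lie within `contact_radius`. Soft mode: the mean over
#' members of `(gamma / d_ij)^(1/alpha)`, the power-law expectation.
#'
#' @param ensemble a `StructureEnsemble` (or list of coordinate matrices).
#' @param contact_radius contact threshold; default `3 * r_bead`.
#' @param mode `"hard"` or `"soft"`.
#' @param gamma,alpha power-law parameters for soft mode; default from the
#'   ensemble's restraint set.
#' @return beads-by-beads matrix of contact fractions (hard) or expected
#'   frequencies (soft).
#' @export
ensemble_contact_map <- function(ensemble, contact_radius = NULL,
                                 mode = c("hard", "soft"),
                                 gamma = NULL, alpha = NULL) {
  mode <- match.arg(mode)
  members <- if (inherits(ensemble, "StructureEnsemble")) ensemble$members
             else ensemble
  rs <- if (inherits(ensemble, "StructureEnsemble")) ensemble$restraints else NULL
  if (is.null(contact_radius)) {
    if (is.null(rs)) stop("contact_radius required without a restraint set")
    contact_radius <- 3 * rs$r_bead
  }
  if (mode == "soft") {
    if (is.null(gamma)) gamma <- rs$gamma
    if (is.null(alpha)) alpha <- rs$alpha
  }
  n <- nrow(members[[1]])
  acc <- matrix(0, n, n)
  for (X in members) {
    D <- as.matrix(dist(X))
    acc <- acc + if (mode == "hard") (D <= contact_radius) * 1
    else { diag(D) <- Inf; (gamma / pmax(D, 1e-9))^(1 / alpha) }
  }
  out <- acc / length(members)
  diag(out) <- 0
  out
}

#' Fit the power-law exponent alpha
#'
#' For each grid value, runs a reduced-budget model (restraints, annealed
#' sampling, greedy ensemble selection). The default objective,
#' `method = "violation"`, picks the exponent whose converted equilibrium
#' distances are most geometrically realizable: the fraction of interaction
#' restraints violated by the ensemble mean distances, minimized over the
#' grid. Because a smaller exponent always yields a more easily embeddable
#' distance set (powers below 1 of a metric remain near-metric, powers above 1
#' break triangle inequalities), the rule returns the LARGEST exponent whose
#' violation fraction lies within `margin` of the grid minimum.
#' `method = "map_pearson"` instead maximizes the Pearson correlation between
#' the modeled contact map ([ensemble_contact_map()]) and
#' `log(1 + observed counts)`; on the log scale that statistic is nearly
#' invariant to the exponent (log distances are linear in log frequencies for
#' every alpha), so it discriminates poorly and is kept only for comparison.
#'
#' @param cm a balanced `ContactMatrix`.
#' @param gamma power-law scale.
#' @param alpha_grid candidate exponents in (0, 3].
#' @param budget list with `n_replicas` and `n_steps` for the reduced runs.
#' @param seed RNG seed.
#' @param chrom chromosome to model (default: each chromosome in turn, scores
#'   pooled).
#' @param method `"violation"` or `"map_pearson"`.
#' @param map_mode contact-map mode for `method = "map_pearson"`.
#' @param margin violation-fraction tolerance for the largest-feasible rule.
#' @return list: `alpha` (best), `scores` (data.frame with `alpha`,
#'   `violation_fraction`, `correlation`).
#' @export
fit_alpha <- function(cm, gamma, alpha_grid = c(0.5, 1, 1.5, 2),
                      budget = list(n_replicas = 4L, n_steps = 500L),
                      seed = 1L, chrom = NULL,
                      method = c("violation", "map_pearson"),
                      map_mode = "hard", margin = 0.08) {
  method <- match.arg(method)
  if (any(alpha_grid <= 0 | alpha_grid > 3)) stop("alpha_grid must lie in (0, 3]")
  bins <- cm$bins
  chroms <- if (is.null(chrom)) unique(bins$chrom) else chrom
  viol <- numeric(length(alpha_grid))
  corr <- numeric(length(alpha_grid))
  for (ai in seq_along(alpha_grid)) {
    a <- alpha_grid[ai]
    dm <- suppressWarnings(contacts_to_distances(cm, gamma, a))
    mod <- c(); obs <- c(); nv <- 0; nr <- 0
    for (ch in chroms) {
      rs <- build_restraints(dm, chrom = ch)
      cand <- sample_structures(rs, n_replicas = budget$n_replicas,
                                n_steps = budget$n_steps,
                                snapshot_stride = budget$n_steps,
                                init_mode = "mds", seed = seed + 7L * ai)
      ens <- select_ensemble(cand)
      p <- rs$pairs[rs$pairs$kind == "interaction", ]
      if (nrow(p)) {
        dmod <- rowMeans(vapply(ens$members, function(X)
          sqrt(rowSums((X[p$i, , drop = FALSE] - X[p$j, , drop = FALSE])^2)),
          numeric(nrow(p))))
        nv <- nv + sum(abs(dmod - p$r0) > rs$r_bead)
        nr <- nr + nrow(p)
      }
      map <- ensemble_contact_map(ens, mode = map_mode)
      ids <- rs$bead_ids
      ut <- upper.tri(map)
      mod <- c(mod, map[ut])
      obs <- c(obs, log1p(cm$counts[ids, ids][ut]))
    }
    viol[ai] <- if (nr) nv / nr else NA_real_
    corr[ai] <- if (sd(mod) == 0 || sd(obs) == 0) NA_real_ else cor(mod, obs)
  }
  scores <- data.frame(alpha = alpha_grid, violation_fraction = viol,
                       correlation = corr)
  if (method == "violation") {
    if (all(is.na(viol))) stop("no interaction restraints at any alpha")
    best <- max(alpha_grid[viol <= min(viol, na.rm = TRUE) + margin])
  } else {
    if (all(is.na(corr))) stop("all correlations undefined (constant maps)")
    best <- alpha_grid[which.max(corr)]
  }
  list(alpha = best, scores = scores)
}

#' Full restraint-based modeling pipeline for a contact matrix
#'
#' Chains iterative correction, contact-to-distance conversion, restraint
#' construction, annealed sampling and greedy ensemble selection, by default
#' independently per chromosome.
#'
#' @param cm a raw `ContactMatrix`.
#' @param gamma power-law scale; `NULL` scales the structure so the converted
#'   median consecutive-bead distance is 1 model unit.
#' @param alpha power-law exponent, or `"auto"` to call [fit_alpha()] first.
#' @param chroms chromosomes to model (default all).
#' @param n_replicas,n_steps,init_mode sampling budget per chromosome.
#' @param seed RNG seed.
#' @param balance run [ice_balance()] first (disable only if `cm` is already
#'   balanced).
#' @return list of class `HicModel`: `balanced`, `distmodel`, `alpha`,
#'   `gamma`, per-chromosome `restraints` and `ensembles`, and `metrics` from
#'   [structure_metrics()] computed over the pooled per-chromosome ensembles.
#' @export
hic_model <- function(cm, gamma = NULL, alpha = 1, chroms = NULL,
                      n_replicas = 10L, n_steps = 1000L, init_mode = "mds",
                      seed = 1L, balance = TRUE) {
  bal <- if (balance) ice_balance(cm) else cm
  if (is.null(gamma)) {
    # provisional conversion at gamma = 1 to find the consecutive-bead scale
    dm0 <- suppressWarnings(contacts_to_distances(bal, 1, 1))
    cons <- dm0$pairs[dm0$pairs$j - dm0$pairs$i == 1, "r0"]
    gamma <- if (length(cons)) 1 / median(cons) else 1
  }
  if (identical(alpha, "auto")) {
    alpha <- fit_alpha(bal, gamma, seed = seed, chrom = chroms)$alpha
  }
  dm <- suppressWarnings(contacts_to_distances(bal, gamma, alpha))
  if (is.null(chroms)) chroms <- unique(cm$bins$chrom)
  restraints <- list(); ensembles <- list()
  for (ch in chroms) {
    rs <- build_restraints(dm, chrom = ch)
    cand <- sample_structures(rs, n_replicas = n_replicas, n_steps = n_steps,
                              snapshot_stride = n_steps, init_mode = init_mode,
                              seed = seed + match(ch, chroms))
    ensembles[[ch]] <- select_ensemble(cand)
    restraints[[ch]] <- rs
  }
  structure(list(balanced = bal, distmodel = dm, alpha = alpha, gamma = gamma,
                 restraints = restraints, ensembles = ensembles,
                 layout = cm$layout),
            class = "HicModel")
}
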