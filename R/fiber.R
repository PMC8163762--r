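## Nucleosome-resolution chromatin fibers from MNase-seq coverage.
##
## Coverage is deconvolved into Gaussian nucleosome components (matching
## pursuit + joint nonnegative refinement), components are combined into
## sterically compatible nucleosome families, and each family is built as a
## 3D fiber with rigid nucleosomes (147 bp left-handed superhelix) and
## flexible linkers at base-pair resolution, sampled by Metropolis Monte
## Carlo over helical parameters (rise, slide, shift, twist, roll, tilt).

#' Deconvolve an MNase coverage track into nucleosome components
#'
#' Greedy matching pursuit with a composite kernel: each nucleosome
#' contributes a Gaussian positional spread (`sigma`) convolved with the
#' center-trimmed fragment footprint (`frag_len` bp box), which is exactly the
#' expected pileup of trimmed fragments around a dyad. The best single kernel
#' (nonnegative amplitude, spread within `sigma_bounds`) is fit to the
#' residual and subtracted, stopping when the residual peak drops below
#' `min_weight` times the global maximum; amplitudes are then refined jointly
#' by nonnegative least squares. Scores: `height_score` is the refined
#' amplitude normalized by the track maximum; `width_score` is
#' `1 - clamp((sigma - sigma_ref) / sigma_range, 0, 1)`. Calls with width
#' score > 0.6 and height score > 0.4 are classed well-positioned, else fuzzy.
#'
#' @param track a `CoverageTrack`.
#' @param sigma_bounds allowed positional spread in bp.
#' @param min_weight stopping fraction of the global coverage maximum.
#' @param max_components cap on extracted components.
#' @param sigma_ref,sigma_range width-score normalization constants.
#' @param frag_len trimmed-fragment length of the coverage convention.
#' @return data.frame (`mu`, `sigma`, `weight`, `height_score`,
#'   `width_score`, `call_class`), sorted by `mu`; zero rows for an all-zero
#'   track.
#' @export
deconvolve_coverage <- function(track, sigma_bounds = c(10, 60),
                                min_weight = 0.2, max_components = 30L,
                                sigma_ref = 10, sigma_range = 50,
                                frag_len = 50L) {
  stopifnot(inherits(track, "CoverageTrack"))
  v <- track$values
  L <- length(v)
  empty <- data.frame(mu = numeric(0), sigma = numeric(0), weight = numeric(0),
                      height_score = numeric(0), width_score = numeric(0),
                      call_class = character(0), stringsAsFactors = FALSE)
  if (!any(v > 0)) return(empty)
  gmax <- max(v)
  sig_grid <- seq(sigma_bounds[1], sigma_bounds[2], by = 5)
  x <- seq_len(L)
  # unit-peak pileup kernel at offset t: Gaussian spread x fragment box
  kernel_of <- function(t, sg) {
    k <- pnorm(t + frag_len / 2, 0, sg) - pnorm(t - frag_len / 2, 0, sg)
    k / (pnorm(frag_len / 2, 0, sg) - pnorm(-frag_len / 2, 0, sg))
  }
  res <- v
  mus <- numeric(0); sigs <- numeric(0)
  while (max(res) >= min_weight * gmax && length(mus) < max_components) {
    best <- NULL
    for (sg in sig_grid) {
      half <- min(ceiling(4 * sg + frag_len), (L - 1) %/% 2)
      kern <- kernel_of(-half:half, sg)
      num <- as.numeric(stats::filter(res, kern, sides = 2))
      num[is.na(num)] <- 0
      gg <- sum(kern^2)
      a <- pmax(num / gg, 0)
      red <- a * num  # a^2 * gg = a * num
      k <- which.max(red)
      if (is.null(best) || red[k] > best$red)
        best <- list(mu = k, sigma = sg, a = a[k], red = red[k])
    }
    if (best$a <= 0) break
    res <- res - best$a * kernel_of(x - best$mu, best$sigma)
    mus <- c(mus, best$mu); sigs <- c(sigs, best$sigma)
  }
  if (!length(mus)) return(empty)
  # joint nonnegative refinement of amplitudes
  G <- vapply(seq_along(mus), function(k)
    kernel_of(x - mus[k], sigs[k]), numeric(L))
  a <- pracma::lsqnonneg(G, v)$x
  keep <- a > 1e-8 * gmax
  mus <- mus[keep]; sigs <- sigs[keep]; a <- a[keep]
  if (!length(mus)) return(empty)
  mass <- a * colSums(G)[keep]
  width <- 1 - pmin(pmax((sigs - sigma_ref) / sigma_range, 0), 1)
  height <- a / gmax
  out <- data.frame(mu = mus - 1, sigma = sigs, weight = mass / sum(mass),
                    height_score = height, width_score = width,
                    call_class = ifelse(width > 0.6 & height > 0.4,
                                        "well_positioned", "fuzzy"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mu), ]
  rownames(out) <- NULL
  out
}

#' Enumerate nucleosome families compatible with a set of calls
#'
#' A family is a maximal subset of nucleosome placements whose adjacent dyads
#' are at least `147 - max_overlap` bp apart. Fuzzy components branch into
#' alternative placements at `mu` and `mu +/- sigma`. Family weight is
#' proportional to the product of member occupancies, normalized over the
#' returned families; at most `max_families` are kept by weight.
#'
#' @param components data.frame from [deconvolve_coverage()].
#' @param region_len region length in bp (placements outside are dropped).
#' @param max_overlap maximum allowed overlap of adjacent 147 bp footprints.
#' @param max_families cap on returned families.
#' @return list of class `NucleosomeFamilySet`; each family is a list with
#'   `dyads`, `occupancy`, `weight`. A single empty family if nothing can be
#'   placed.
#' @export
enumerate_families <- function(components, region_len, max_overlap = 80L,
                               max_families = 16L) {
  min_space <- 147L - max_overlap
  if (!nrow(components)) {
    fam <- list(list(dyads = numeric(0), occupancy = numeric(0), weight = 1))
    class(fam) <- "NucleosomeFamilySet"
    return(fam)
  }
  components <- components[order(components$mu), , drop = FALSE]
  opts <- lapply(seq_len(nrow(components)), function(k) {
    mu <- components$mu[k]
    pos <- if (components$call_class[k] == "fuzzy")
      c(mu, mu - components$sigma[k], mu + components$sigma[k]) else mu
    pos <- round(pos[pos >= 0 & pos < region_len])
    unique(pos)
  })
  wts <- components$weight
  results <- list()
  nodes <- 0L
  dfs <- function(k, dyads, occ, skipped) {
    nodes <<- nodes + 1L
    if (nodes > 2e5) return()
    if (k > length(opts)) {
      # maximality: no skipped component fits anywhere in the chosen set
      for (s in skipped) {
        for (p in opts[[s]]) {
          if (!length(dyads) || all(abs(dyads - p) >= min_space)) return()
        }
      }
      results[[length(results) + 1]] <<- list(dyads = dyads, occupancy = occ)
      return()
    }
    placed <- FALSE
    for (p in opts[[k]]) {
      if (!length(dyads) || all(abs(dyads - p) >= min_space)) {
        placed <- TRUE
        dfs(k + 1L, c(dyads, p), c(occ, wts[k]), skipped)
      }
    }
    dfs(k + 1L, dyads, occ, c(skipped, k))
  }
  dfs(1L, numeric(0), numeric(0), integer(0))
  if (!length(results)) {
    fam <- list(list(dyads = numeric(0), occupancy = numeric(0), weight = 1))
    class(fam) <- "NucleosomeFamilySet"
    return(fam)
  }
  key <- vapply(results, function(f) paste(sort(f$dyads), collapse = ","), "")
  results <- results[!duplicated(key)]
  raw_w <- vapply(results, function(f)
    if (length(f$occupancy)) prod(f$occupancy) else 1e-12, 0)
  o <- order(-raw_w)
  results <- results[o[seq_len(min(length(o), max_families))]]
  raw_w <- raw_w[o[seq_len(min(length(o), max_families))]]
  for (k in seq_along(results)) {
    results[[k]]$dyads <- sort(results[[k]]$dyads)
    results[[k]]$occupancy <- results[[k]]$occupancy[order(results[[k]]$dyads)]
    results[[k]]$weight <- raw_w[k] / sum(raw_w)
  }
  class(results) <- "NucleosomeFamilySet"
  results
}

#' Default fiber geometry and elastic parameters
#'
#' Equilibrium helical parameters and per-parameter stiffnesses follow an
#' average B-DNA parameterization (rise 3.4 A, twist 34.3 deg, other steps 0;
#' stiffness in kT per squared unit). The nucleosome is a rigid left-handed
#' superhelix of 147 bp (radius 41.8 A, pitch 25.9 A, 1.65 turns). One charge
#' site per 5 bp feeds the Debye-Huckel term (screening length 8 A at
#' ~150 mM monovalent salt).
#'
#' @param ... overrides for any listed element.
#' @return list of geometry and potential parameters.
#' @export
fiber_geometry <- function(...) {
  g <- list(
    rise_eq = 3.4, twist_eq = 34.3,
    eq = c(shift = 0, slide = 0, rise = 3.4, tilt = 0, roll = 0, twist = 34.3),
    stiff = c(shift = 4, slide = 4, rise = 25, tilt = 0.06, roll = 0.05,
              twist = 0.05),
    nuc_radius = 41.8, nuc_pitch = 25.9, nuc_turns = 1.65, nuc_bp = 147L,
    charge_stride = 5L, dh_amplitude = 1, dh_lambda = 8,
    ev_radius = 20, ev_k = 0.05, nuc_ev_radius = 55,
    hard_overlap = 6
  )
  ov <- list(...)
  g[names(ov)] <- ov
  g
}

.rot_z <- function(th) {
  c <- cos(th); s <- sin(th)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}
.rot_y <- function(th) {
  c <- cos(th); s <- sin(th)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
.rot_x <- function(th) {
  c <- cos(th); s <- sin(th)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

# rotation taking unit vector a to unit vector b (Rodrigues)
.rot_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # pick any axis orthogonal to a
    ax <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * a) * a; v <- v / sqrt(sum(v^2))
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + cth)
}

# step transform from 6 helical parameters (angles in degrees)
.step_transform <- function(par) {
  d2r <- pi / 180
  R <- .rot_z(par["twist"] * d2r) %*% .rot_y(par["roll"] * d2r) %*%
    .rot_x(par["tilt"] * d2r)
  list(R = R, t = c(par["shift"], par["slide"], par["rise"]))
}

# local coordinates of the 147 wrapped bp (left-handed superhelix) plus
# entry/exit tangents
.nucleosome_local <- function(g) {
  k <- 0:(g$nuc_bp - 1)
  phi <- -2 * pi * g$nuc_turns * k / (g$nuc_bp - 1)
  P <- cbind(g$nuc_radius * cos(phi), g$nuc_radius * sin(phi),
             g$nuc_pitch * phi / (2 * pi))
  tangent <- function(i1, i2) {
    t <- P[i2, ] - P[i1, ]; t / sqrt(sum(t^2))
  }
  list(P = P, t_in = tangent(1, 2), t_out = tangent(g$nuc_bp - 1, g$nuc_bp))
}

#' Build an ideal 3D chromatin fiber for a nucleosome family
#'
#' Places rigid 147 bp nucleosomes at the family dyads and initializes every
#' linker base-pair step at the equilibrium helical parameters, yielding a
#' continuous bp-resolution 3D path. An empty family gives straight B-DNA.
#'
#' @param family a family from [enumerate_families()] (list with `dyads`), or
#'   a numeric vector of dyads.
#' @param region_len region length in bp.
#' @param geometry from [fiber_geometry()].
#' @param seed unused unless `jitter_sd > 0`.
#' @param jitter_sd optional Gaussian jitter (in parameter units) applied to
#'   the initial linker parameters.
#' @return object of class `FiberConformation`: `positions` (L x 3),
#'   `is_nuc` (logical L), `params` ((L-1) x 6 helical parameters, NA inside
#'   nucleosomes), `dyads`, `geometry`.
#' @export
build_fiber <- function(family, region_len, geometry = fiber_geometry(),
                        seed = 1L, jitter_sd = 0) {
  dyads <- if (is.list(family)) family$dyads else family
  dyads <- sort(dyads)
  half <- (geometry$nuc_bp - 1) / 2
  if (length(dyads)) {
    if (dyads[1] - half < 0 || dyads[length(dyads)] + half > region_len - 1)
      stop("nucleosome footprint outside the region")
    if (length(dyads) > 1 && any(diff(dyads) < geometry$nuc_bp - 100))
      stop("family footprint conflicts exceed tolerance")
  }
  L <- as.integer(region_len)
  is_nuc <- logical(L)
  for (d in dyads) is_nuc[(d - half):(d + half) + 1L] <- TRUE
  params <- matrix(NA_real_, max(L - 1, 0), 6,
                   dimnames = list(NULL, names(geometry$eq)))
  # flexible steps have both ends outside wrapped DNA; boundary steps are rigid
  linker_step <- !(is_nuc[-L] | is_nuc[-1])
  params[linker_step, ] <- matrix(geometry$eq, sum(linker_step), 6,
                                  byrow = TRUE)
  if (jitter_sd > 0) {
    set.seed(seed)
    params[linker_step, ] <- params[linker_step, ] +
      matrix(rnorm(sum(linker_step) * 6, 0, jitter_sd), sum(linker_step), 6)
  }
  fib <- structure(list(positions = NULL, is_nuc = is_nuc, params = params,
                        dyads = dyads, geometry = geometry),
                   class = "FiberConformation")
  fib$positions <- fiber_path(fib)
  fib
}

#' Derived 3D path of a fiber conformation
#'
#' Walks the base-pair frames: linker steps apply their helical-parameter
#' transform; wrapped stretches are placed rigidly from the nucleosome
#' superhelix geometry, attached at the entry tangent.
#'
#' @param fiber a `FiberConformation`.
#' @return L x 3 matrix of bp positions.
#' @export
fiber_path <- function(fiber) {
  g <- fiber$geometry
  L <- length(fiber$is_nuc)
  nl <- .nucleosome_local(g)
  X <- matrix(0, L, 3)
  R <- diag(3)
  o <- c(0, 0, 0)
  X[1, ] <- o
  i <- 1L
  dyads <- fiber$dyads
  half <- (g$nuc_bp - 1) / 2
  starts <- if (length(dyads)) dyads - half + 1L else integer(0)  # 1-based bp
  while (i < L) {
    if ((i + 1L) %in% starts) {
      # place the wrapped block rigidly, entry tangent along current local z
      gz <- R[, 3]
      M <- .rot_between(nl$t_in, gz)
      block <- sweep(nl$P, 2, nl$P[1, ]) %*% t(M)
      # connect entry bp at one equilibrium rise from the current bp
      entry <- o + g$rise_eq * gz
      idx <- (i + 1L):(i + g$nuc_bp)
      X[idx, ] <- block + matrix(entry, g$nuc_bp, 3, byrow = TRUE)
      o <- X[i + g$nuc_bp, ]
      tz <- as.vector(M %*% nl$t_out)
      R <- .rot_between(gz, tz) %*% R
      R[, 3] <- tz  # guard against drift
      i <- i + g$nuc_bp
    } else if (is.na(fiber$params[i, 1])) {
      # rigid boundary step out of a nucleosome: equilibrium rise, no bend
      o <- o + g$rise_eq * R[, 3]
      X[i + 1L, ] <- o
      i <- i + 1L
    } else {
      st <- .step_transform(fiber$params[i, ])
      o <- o + as.vector(R %*% st$t)
      R <- R %*% st$R
      X[i + 1L, ] <- o
      i <- i + 1L
    }
  }
  X
}

# elastic energy of linker steps (kT)
.fiber_elastic <- function(params, g) {
  ok <- !is.na(params[, 1])
  if (!any(ok)) return(0)
  dev <- sweep(params[ok, , drop = FALSE], 2, g$eq)
  sum(sweep(dev^2, 2, g$stiff, `*`)) / 2
}

# nonbonded energy (Debye-Huckel + excluded volume) over charge sites and
# nucleosome centers; returns list(total, hard_overlaps)
.fiber_nonbonded <- function(X, fiber, g) {
  sites <- seq(1, nrow(X), by = g$charge_stride)
  P <- X[sites, , drop = FALSE]
  D <- as.matrix(dist(P))
  near <- abs(outer(sites, sites, `-`)) <= 2 * g$charge_stride
  D[near] <- Inf
  ut <- upper.tri(D)
  d <- D[ut]
  dh <- sum(g$dh_amplitude * exp(-d / g$dh_lambda) / pmax(d, 1))
  evd <- pmin(d - g$ev_radius, 0)
  ev <- sum(g$ev_k * evd^2)
  hard <- sum(d < g$hard_overlap)
  if (length(fiber$dyads) > 1) {
    half <- (g$nuc_bp - 1) / 2
    centers <- t(vapply(fiber$dyads, function(dd)
      colMeans(X[(dd - half):(dd + half) + 1L, , drop = FALSE]), numeric(3)))
    Dn <- as.matrix(dist(centers))
    dn <- Dn[upper.tri(Dn)]
    evn <- pmin(dn - 2 * g$nuc_ev_radius, 0)
    ev <- ev + sum(g$ev_k * evn^2)
    hard <- hard + sum(dn < g$nuc_ev_radius)
  }
  list(total = dh + ev, hard = hard)
}

#' Total energy of a fiber conformation
#'
#' Elastic (pseudo-harmonic helical-parameter deviations) plus, unless
#' disabled, Debye-Huckel electrostatics and excluded-volume repulsion over
#' charge sites and nucleosome centers.
#'
#' @param fiber a `FiberConformation`.
#' @param nonbonded include the Debye-Huckel / excluded-volume terms.
#' @return list with `total`, `elastic`, `nonbonded`, `hard_overlaps`.
#' @export
fiber_energy <- function(fiber, nonbonded = TRUE) {
  g <- fiber$geometry
  el <- .fiber_elastic(fiber$params, g)
  if (!nonbonded)
    return(list(total = el, elastic = el, nonbonded = 0, hard_overlaps = 0L))
  nb <- .fiber_nonbonded(fiber$positions, fiber, g)
  list(total = el + nb$total, elastic = el, nonbonded = nb$total,
       hard_overlaps = nb$hard)
}

.metropolis_accept <- function(dE, temperature, u) {
  dE <= 0 || (temperature > 0 && u < exp(-dE / temperature))
}

#' Metropolis sampling over a discrete state space
#'
#' Minimal Metropolis chain with symmetric uniform proposals over the given
#' state energies; shares its acceptance rule with [mc_sample_fiber()]. Used
#' for detailed-balance checks against analytic Boltzmann ratios.
#'
#' @param energies numeric vector of state energies (kT).
#' @param n_steps chain length.
#' @param temperature in kT.
#' @param seed RNG seed.
#' @return integer vector of visited states.
#' @export
metropolis_states <- function(energies, n_steps, temperature = 1, seed = 1L) {
  set.seed(seed)
  K <- length(energies)
  out <- integer(n_steps)
  s <- 1L
  props <- sample.int(K, n_steps, replace = TRUE)
  us <- runif(n_steps)
  for (t in seq_len(n_steps)) {
    p <- props[t]
    if (.metropolis_accept(energies[p] - energies[s], temperature, us[t]))
      s <- p
    out[t] <- s
  }
  out
}

#' Monte Carlo sampling of a chromatin fiber
#'
#' Metropolis moves perturb single linker-bp helical parameters (Gaussian
#' steps); the path is rebuilt for the nonbonded terms. Moves creating hard
#' overlaps are rejected outright. If acceptance drops below 1% over a
#' 500-move window, step sizes are halved with a warning. At zero temperature
#' only energy-decreasing moves are accepted, so an equilibrium start stays
#' put.
#'
#' @param fiber a `FiberConformation` from [build_fiber()].
#' @param n_steps number of Monte Carlo moves (>= 1).
#' @param temperature in kT.
#' @param seed RNG seed.
#' @param nonbonded include Debye-Huckel / excluded-volume terms (turn off
#'   for pure elastic sampling of naked DNA).
#' @param snapshot_stride keep a snapshot every this many moves.
#' @param step_scale multiplier on the default per-parameter step sizes.
#' @return list of class `FiberEnsemble`: `snapshots` (list of
#'   `FiberConformation`), `acceptance`, `energy` (trace at snapshots),
#'   `energy_drift` (max |incremental - recomputed| energy at checkpoints),
#'   `fiber` (final state).
#' @export
mc_sample_fiber <- function(fiber, n_steps, temperature = 1, seed = 1L,
                            nonbonded = TRUE, snapshot_stride = NULL,
                            step_scale = 1) {
  stopifnot(n_steps >= 1)
  g <- fiber$geometry
  if (is.null(snapshot_stride)) snapshot_stride <- max(1L, n_steps %/% 50L)
  linker_steps <- which(!is.na(fiber$params[, 1]))
  if (!length(linker_steps)) stop("fiber has no flexible linker steps")
  # step sizes ~ thermal scale of each parameter
  sds <- step_scale * sqrt(pmax(temperature, 1e-3) / g$stiff)
  set.seed(seed)
  E <- fiber_energy(fiber, nonbonded = nonbonded)
  e_el <- E$elastic; e_nb <- E$nonbonded
  acc <- 0L; win_acc <- 0L
  snapshots <- list(); etrace <- numeric(0)
  drift <- 0
  for (t in seq_len(n_steps)) {
    k <- sample(linker_steps, 1L)
    pidx <- sample.int(6, 1L)
    old <- fiber$params[k, pidx]
    new <- old + rnorm(1, 0, sds[pidx])
    d_el <- 0.5 * g$stiff[pidx] *
      ((new - g$eq[pidx])^2 - (old - g$eq[pidx])^2)
    cand <- fiber
    cand$params[k, pidx] <- new
    if (nonbonded) {
      cand$positions <- fiber_path(cand)
      nb <- .fiber_nonbonded(cand$positions, cand, g)
      if (nb$hard > 0) { d_nb <- Inf } else d_nb <- nb$total - e_nb
    } else d_nb <- 0
    if (.metropolis_accept(d_el + d_nb, temperature, runif(1))) {
      fiber <- cand
      e_el <- e_el + d_el
      if (nonbonded) e_nb <- e_nb + d_nb
      acc <- acc + 1L; win_acc <- win_acc + 1L
    }
    if (t %% 500 == 0) {
      if (win_acc < 5) {
        sds <- sds / 2
        warning("acceptance below 1%; step sizes halved")
      }
      win_acc <- 0L
    }
    if (t %% 1000 == 0) {
      Efull <- fiber_energy(fiber, nonbonded = nonbonded)
      drift <- max(drift, abs(Efull$total - (e_el + e_nb)))
      e_el <- Efull$elastic; e_nb <- Efull$nonbonded
    }
    if (t %% snapshot_stride == 0) {
      if (!nonbonded) fiber$positions <- fiber_path(fiber)
      snapshots[[length(snapshots) + 1]] <- fiber
      etrace <- c(etrace, e_el + e_nb)
    }
  }
  if (!nonbonded) fiber$positions <- fiber_path(fiber)
  structure(list(snapshots = snapshots, acceptance = acc / n_steps,
                 energy = etrace, energy_drift = drift, fiber = fiber),
            class = "FiberEnsemble")
}

#' Metrics over fiber ensembles
#'
#' Per family (and pooled): radius of gyration of the bp path, and the 3D
#' distances between nucleosome N and N+x centers for x in 1..5, with their
#' dispersion (SD) across conformations.
#'
#' @param ensembles named list: one `FiberEnsemble` (or list of
#'   `FiberConformation`) per family.
#' @return list with `rg` (data.frame family, mean, sd) and `nn_dist`
#'   (data.frame family, x, mean, sd, n).
#' @export
fiber_metrics <- function(ensembles) {
  if (inherits(ensembles, "FiberEnsemble") ||
      inherits(ensembles, "FiberConformation"))
    ensembles <- list(family1 = ensembles)
  rg_rows <- list(); nn_rows <- list()
  for (nm in names(ensembles)) {
    e <- ensembles[[nm]]
    confs <- if (inherits(e, "FiberEnsemble")) e$snapshots
             else if (inherits(e, "FiberConformation")) list(e) else e
    rgs <- vapply(confs, function(f) radius_of_gyration(f$positions), 0)
    rg_rows[[nm]] <- data.frame(family = nm, rg_mean = mean(rgs),
                                rg_sd = sd(rgs))
    g <- confs[[1]]$geometry
    half <- (g$nuc_bp - 1) / 2
    nd <- length(confs[[1]]$dyads)
    if (nd >= 2) {
      for (x in 1:min(5, nd - 1)) {
        dd <- unlist(lapply(confs, function(f) {
          centers <- t(vapply(f$dyads, function(d)
            colMeans(f$positions[(d - half):(d + half) + 1L, , drop = FALSE]),
            numeric(3)))
          sqrt(rowSums((centers[1:(nd - x), , drop = FALSE] -
                          centers[(1 + x):nd, , drop = FALSE])^2))
        }))
        nn_rows[[paste(nm, x)]] <- data.frame(family = nm, x = x,
                                              mean = mean(dd), sd = sd(dd),
                                              n = length(dd))
      }
    }
  }
  list(rg = do.call(rbind, rg_rows), nn_dist = do.call(rbind, nn_rows))
}

#' Expected coverage of nucleosome families and goodness of fit
#'
#' The expected coverage of a dyad is the pileup probability of center-trimmed
#' fragments whose centers are normal around the dyad; families contribute
#' their weighted sum. Goodness of fit is the Pearson correlation with the
#' input track (NaN for an empty family set).
#'
#' @param families a `NucleosomeFamilySet`.
#' @param region_len region length in bp.
#' @param fragment_model list with `frag_len` and `fuzz_sd`.
#' @param track optional `CoverageTrack` to score against.
#' @return list: `track` (a `CoverageTrack`), `correlation`.
#' @export
reconstruct_coverage <- function(families, region_len,
                                 fragment_model = list(frag_len = 50L,
                                                       fuzz_sd = 10),
                                 track = NULL) {
  fl <- fragment_model$frag_len
  f1 <- floor((fl - 1) / 2); f2 <- ceiling((fl - 1) / 2)
  x <- 0:(region_len - 1)
  values <- numeric(region_len)
  for (fam in families) {
    if (!length(fam$dyads)) next
    fv <- numeric(region_len)
    for (k in seq_along(fam$dyads)) {
      fv <- fv + fam$occupancy[k] *
        (pnorm(x + f2 + 0.5, fam$dyads[k], fragment_model$fuzz_sd) -
           pnorm(x - f1 - 0.5, fam$dyads[k], fragment_model$fuzz_sd))
    }
    values <- values + fam$weight * fv
  }
  correlation <- NA_real_
  if (!is.null(track)) {
    if (sd(values) > 0 && sd(track$values) > 0)
      correlation <- cor(values, track$values)
    else correlation <- NaN
  }
  list(track = coverage_track("chrS", values), correlation = correlation)
}

#' Greedy selection of nucleosome families by coverage fit
#'
#' Starting from the empty set, repeatedly adds the family that most improves
#' the Pearson correlation between the weighted reconstructed coverage and the
#' observed track; stops when no family improves the fit or `max_keep` is
#' reached. The kept set's correlation is therefore at least that of any
#' single discarded family.
#'
#' @param families a `NucleosomeFamilySet`.
#' @param track observed `CoverageTrack`.
#' @param fragment_model as in [reconstruct_coverage()].
#' @param max_keep cap on selected families.
#' @return list: `families` (selected, weights renormalized), `correlation`.
#' @export
select_families <- function(families, track,
                            fragment_model = list(frag_len = 50L,
                                                  fuzz_sd = 10),
                            max_keep = 8L) {
  region_len <- length(track$values)
  selected <- integer(0)
  best_cor <- -Inf
  repeat {
    gain <- rep(NA_real_, length(families))
    for (k in setdiff(seq_along(families), selected)) {
      sub <- families[c(selected, k)]
      w <- vapply(sub, `[[`, 0, "weight")
      for (q in seq_along(sub)) sub[[q]]$weight <- w[q] / sum(w)
      class(sub) <- "NucleosomeFamilySet"
      gain[k] <- reconstruct_coverage(sub, region_len, fragment_model,
                                      track)$correlation
    }
    if (all(is.na(gain)) || max(gain, na.rm = TRUE) <= best_cor + 1e-12) break
    selected <- c(selected, which.max(gain))
    best_cor <- max(gain, na.rm = TRUE)
    if (length(selected) >= max_keep) break
  }
  out <- families[selected]
  w <- vapply(out, `[[`, 0, "weight")
  for (q in seq_along(out)) out[[q]]$weight <- w[q] / sum(w)
  class(out) <- "NucleosomeFamilySet"
  list(families = out, correlation = best_cor)
}
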