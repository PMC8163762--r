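make_dm <- function(lay = toy_layout(), gamma = 1, alpha = 1, seed = 61,
                    depth = 5e5) {
  ts <- simulate_structures(lay, 1, rabl_strength = 0.3, seed = seed)
  cm <- structures_to_contacts(ts, gamma, alpha, depth = depth,
                               seed = seed + 1)
  contacts_to_distances(ice_balance(cm), gamma, alpha)
}

test_that("ICE balancing equalizes coverage and matches a long oracle loop", {
  lay <- toy_layout()
  # already-balanced matrix (constant row sums) is a fixed point
  n <- nrow(layout_bins(lay))
  M <- matrix(1, n, n); diag(M) <- 0
  cm <- contact_matrix(M, lay)
  bal <- ice_balance(cm)
  expect_equal(bal$counts, cm$counts, tolerance = 1e-8)

  # toy with one heavy bin vs an independent 1000-iteration loop
  M3 <- matrix(c(0, 10, 2,
                 10, 0, 1,
                 2, 1, 0), 3, 3, byrow = TRUE)
  A <- M3
  for (it in 1:1000) {
    b <- rowSums(A) / mean(rowSums(A))
    A <- A / outer(b, b)
  }
  A <- A * sum(M3) / sum(A)
  lay3 <- genome_layout("c1", 15000, 1000, 1000, 5000)
  bal3 <- ice_balance(contact_matrix(M3, lay3))
  expect_equal(bal3$counts, A, tolerance = 1e-5)
  rs <- rowSums(bal3$counts)
  expect_lt(max(abs(rs - mean(rs))) / mean(rs), 1e-5)

  # all-zero row auto-masked
  M0 <- M; M0[5, ] <- 0; M0[, 5] <- 0
  expect_warning(b0 <- ice_balance(contact_matrix(M0, lay)), "auto-masked")
  expect_true(5 %in% b0$masked)
})

test_that("balanced matrices have equal unmasked row sums within tolerance", {
  lay <- toy_layout()
  ts <- simulate_structures(lay, 1, seed = 71)
  cm <- structures_to_contacts(ts, 1, 1, depth = 3e5, seed = 72)
  bal <- ice_balance(cm, tol = 1e-8)
  rs <- rowSums(bal$counts)
  rs <- rs[setdiff(seq_along(rs), bal$masked)]
  expect_lt(max(abs(rs - mean(rs))) / mean(rs), 1e-6)
})

test_that("the contact-to-distance conversion applies the inverse power law", {
  # gamma = 100, alpha = 1, f = 4 -> r0 = 25; alpha = 0.5, f = 16, gamma = 8
  # -> r0 = 2 (hand substitution)
  expect_equal(100 / 4^1, 25)
  lay <- toy_layout()
  n <- nrow(layout_bins(lay))
  set.seed(73)
  M <- matrix(rpois(n * n, 20), n, n); M <- M + t(M); diag(M) <- 0
  cm <- contact_matrix(M, lay)
  dm <- contacts_to_distances(cm, gamma = 100, alpha = 1)
  k <- which(dm$pairs$f == dm$pairs$f[1])[1]
  expect_equal(dm$pairs$r0[k], 100 / dm$pairs$f[k])
  dm2 <- contacts_to_distances(cm, gamma = 8, alpha = 0.5)
  expect_equal(dm2$pairs$r0, 8 / dm2$pairs$f^0.5)

  # cutoff = 2 x median trans: constructed counts with trans {0,1,2,3,10}
  lay2 <- genome_layout(c("a", "b"), c(25000, 5000), c(1000, 1000),
                        1000, 5000)
  M2 <- matrix(0, 6, 6)
  M2[1:5, 6] <- c(0, 1, 2, 3, 10)  # trans column
  cis <- cbind(c(1, 1, 2, 2, 3), c(2, 3, 3, 4, 5))
  M2[cis] <- c(5, 3, 8, 6, 7)
  M2 <- M2 + t(M2)
  dm3 <- contacts_to_distances(contact_matrix(M2, lay2), 1, 1)
  expect_equal(dm3$cutoff, 4)  # median(0,1,2,3,10) = 2, doubled
  expect_true(all(dm3$pairs$f > 4))
  expect_false(any(dm3$pairs$f == 3))

  # single chromosome: cis-quantile fallback with warning
  lay1 <- genome_layout("c1", 30000, 1000, 1000, 5000)
  M1 <- M[1:6, 1:6]
  expect_warning(contacts_to_distances(contact_matrix(M1, lay1), 1, 1),
                 "quantile")
})

test_that("restraint sets follow the construction rules", {
  # 3 beads, interacting pair (1,3) only
  lay <- genome_layout("c1", 15000, 1000, 1000, 5000)
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[2, 1] <- 10; M[2, 3] <- M[3, 2] <- 10
  M[1, 3] <- M[3, 1] <- 20
  dm <- suppressWarnings(contacts_to_distances(contact_matrix(M, lay), 1, 1,
                                               cis_quantile = 0.4))
  # one interacting non-consecutive pair (beads 1 and 3)
  expect_equal(nrow(dm$pairs), 1)
  rs <- build_restraints(dm)
  kinds <- table(rs$pairs$kind)
  expect_equal(unname(kinds["connectivity"]), 2)
  expect_equal(unname(kinds["interaction"]), 1)
  expect_equal(unname(kinds["excluded_volume"]), 3)
  # connectivity k is exactly 1e5 x interaction k
  expect_equal(unique(rs$pairs$k[rs$pairs$kind == "connectivity"]),
               1e5 * rs$k_interaction)

  # with an empty interacting set beyond consecutive pairs, the remaining
  # pairs become repulsive at the maximum equilibrium distance
  M2 <- matrix(0, 3, 3)
  M2[1, 2] <- M2[2, 1] <- 20; M2[2, 3] <- M2[3, 2] <- 18
  M2[1, 3] <- M2[3, 1] <- 5
  dm2 <- suppressWarnings(contacts_to_distances(contact_matrix(M2, lay), 1, 1,
                                                cis_quantile = 0.4))
  rs2 <- build_restraints(dm2)
  expect_equal(sum(rs2$pairs$kind == "interaction"), 0)
  expect_equal(rs2$pairs$r0[rs2$pairs$kind == "repulsive"],
               max(dm2$pairs$r0))

  dm_big <- make_dm()
  rs_big <- build_restraints(dm_big, chrom = "chrI")
  expect_equal(unique(rs_big$pairs$k[rs_big$pairs$kind == "connectivity"]),
               1e5)
  expect_equal(nrow(rs_big$pairs[rs_big$pairs$kind == "excluded_volume", ]),
               choose(rs_big$n_beads, 2))
})

test_that("flat-welled energies follow the three-branch definition", {
  lay <- genome_layout("c1", 10000, 1000, 1000, 5000)
  rs <- list(pairs = data.frame(i = 1L, j = 2L, r0 = 5, k = 1,
                                kind = "interaction"),
             r_bead = 1, n_beads = 2L, k_interaction = 1, eps_lj = 0.1)
  class(rs) <- "RestraintSet"
  e_at <- function(r) restraint_energy(
    matrix(c(0, 0, 0, r, 0, 0), 2, 3, byrow = TRUE), rs)$total
  expect_equal(e_at(5), 0)            # inside the well
  expect_equal(e_at(5.5), 0)          # still inside r0 +/- r_bead
  expect_equal(e_at(7), 1)            # (r - (r0 + r_bead))^2 = 1
  expect_equal(e_at(4), 0)            # well edge
  expect_equal(e_at(2), 4)            # (r - (r0 - r_bead))^2 = 4
  expect_error(e_at(NaN), "non-finite")
})

test_that("analytic gradients match finite differences", {
  dm <- make_dm()
  rs <- build_restraints(dm, chrom = "chrII", k_interaction = 1)
  # scale the system so interaction terms dominate the numeric comparison
  set.seed(75)
  X <- matrix(rnorm(rs$n_beads * 3, 0, 20 * rs$r_bead), rs$n_beads, 3)
  G <- restraint_gradient(X, rs)
  h <- 1e-7 * rs$r_bead * 100
  idx <- cbind(sample(rs$n_beads, 12, TRUE), sample(3, 12, TRUE))
  for (k in seq_len(nrow(idx))) {
    Xp <- X; Xp[idx[k, 1], idx[k, 2]] <- Xp[idx[k, 1], idx[k, 2]] + h
    Xm <- X; Xm[idx[k, 1], idx[k, 2]] <- Xm[idx[k, 1], idx[k, 2]] - h
    fd <- (restraint_energy(Xp, rs)$total -
             restraint_energy(Xm, rs)$total) / (2 * h)
    denom <- max(1, abs(fd))
    expect_lt(abs(G[idx[k, 1], idx[k, 2]] - fd) / denom, 1e-5)
  }
})

test_that("energy is invariant under rigid motions", {
  dm <- make_dm()
  rs <- build_restraints(dm, chrom = "chrI")
  X <- rand_coords(rs$n_beads, seed = 76, scale = 10 * rs$r_bead)
  R <- random_rotation(77)
  Xr <- X %*% t(R) + matrix(c(3, -2, 7), rs$n_beads, 3, byrow = TRUE)
  expect_equal(restraint_energy(Xr, rs)$total,
               restraint_energy(X, rs)$total, tolerance = 1e-8)
})

test_that("two restrained beads settle into the flat well", {
  rs <- list(pairs = data.frame(i = 1L, j = 2L, r0 = 1, k = 1e5,
                                kind = "connectivity"),
             r_bead = 0.2, n_beads = 2L, k_interaction = 1, eps_lj = 0.004)
  class(rs) <- "RestraintSet"
  cand <- sample_structures(rs, n_replicas = 2, n_steps = 200,
                            init_mode = "random", seed = 78)
  d_final <- vapply(cand$structures, function(X)
    sqrt(sum((X[1, ] - X[2, ])^2)), 0)
  expect_true(all(d_final >= 0.8 - 1e-6 & d_final <= 1.2 + 1e-6))
})

test_that("a planted structure is reconstructed from its exact distances", {
  set.seed(79)
  # 10-bead self-avoiding-ish chain
  Xt <- matrix(0, 10, 3)
  for (b in 2:10) {
    u <- rnorm(3); Xt[b, ] <- Xt[b - 1, ] + u / sqrt(sum(u^2))
  }
  D <- as.matrix(dist(Xt))
  ut <- which(upper.tri(D), arr.ind = TRUE)
  cons <- ut[, 2] - ut[, 1] == 1
  pairs <- data.frame(i = ut[, 1], j = ut[, 2], r0 = D[ut],
                      k = ifelse(cons, 1e5, 1),
                      kind = ifelse(cons, "connectivity", "interaction"))
  rs <- list(pairs = pairs, r_bead = 0.15, n_beads = 10L,
             k_interaction = 1, eps_lj = 0.1 * 0.15^2)
  class(rs) <- "RestraintSet"
  cand <- sample_structures(rs, n_replicas = 4, n_steps = 500,
                            init_mode = "mixed", seed = 80)
  best <- cand$structures[[which.min(cand$energy)]]
  # distances cannot fix chirality: compare against the better enantiomer
  mirror <- best; mirror[, 1] <- -mirror[, 1]
  rmsd <- min(sqrt(mean(rowSums((superpose(best, Xt) - Xt)^2))),
              sqrt(mean(rowSums((superpose(mirror, Xt) - Xt)^2))))
  expect_lt(rmsd, rs$r_bead)

  expect_identical(
    sample_structures(rs, n_replicas = 2, n_steps = 50, seed = 5)$structures,
    sample_structures(rs, n_replicas = 2, n_steps = 50, seed = 5)$structures)
})

test_that("greedy ensemble selection reproduces the worked example", {
  # S1 satisfies {R1,R2,R3}, S2 {R3,R4}, S3 {R4}: violations (1,2,3),
  # mean 2 -> S3 discarded; S1 picked; S2 fulfills the remaining {R4}
  S <- rbind(c(TRUE, TRUE, TRUE, FALSE),
             c(FALSE, FALSE, TRUE, TRUE),
             c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(brute_force_selection(S, energy = c(1, 1, 1)), c(1, 2))

  # all candidates satisfy everything -> ensemble of one (first by tie-break)
  S_all <- matrix(TRUE, 4, 5)
  expect_equal(brute_force_selection(S_all, energy = rep(0, 4)), 1)
})

test_that("greedy selection matches the brute-force oracle on random instances", {
  # random geometric instances exercised through the real code path
  lay <- genome_layout("c1", 40000, 1000, 1000, 5000)
  set.seed(81)
  for (rep in 1:40) {
    n_cand <- sample(2:8, 1)
    n_beads <- sample(4:7, 1)
    n_restr <- sample(3:20, 1)
    pr <- t(replicate(n_restr, sample(n_beads, 2)))
    pairs <- data.frame(i = pmin(pr[, 1], pr[, 2]),
                        j = pmax(pr[, 1], pr[, 2]),
                        r0 = runif(n_restr, 0.5, 2), k = 1,
                        kind = "interaction")
    rs <- list(pairs = pairs, r_bead = 0.3, n_beads = n_beads,
               k_interaction = 1, eps_lj = 0)
    class(rs) <- "RestraintSet"
    cands <- lapply(seq_len(n_cand), function(k)
      matrix(rnorm(n_beads * 3), n_beads, 3))
    ens <- select_ensemble(cands, rs)
    S <- epichrom:::.satisfaction(cands, rs)
    energy <- vapply(cands, function(X) restraint_energy(X, rs)$total, 0)
    expect_equal(ens$member_ids, brute_force_selection(S, energy))
  }
})

test_that("ensemble contact maps count member fractions", {
  members <- list(
    matrix(c(0, 0, 0, 1, 0, 0, 5, 0, 0), 3, 3, byrow = TRUE),
    matrix(c(0, 0, 0, 1, 0, 0, 1.5, 0, 0), 3, 3, byrow = TRUE),
    matrix(c(0, 0, 0, 3, 0, 0, 9, 0, 0), 3, 3, byrow = TRUE),
    matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3, byrow = TRUE))
  map <- ensemble_contact_map(members, contact_radius = 2)
  expect_equal(map[1, 2], 0.75)   # pair within radius in 3 of 4 members
  expect_equal(map[1, 3], 0.5)    # d = 1.5 and 2 are within radius 2
  expect_equal(map[2, 3], 0.5)    # d = 0.5 and 1
  single <- ensemble_contact_map(members[1], contact_radius = 2)
  expect_equal(single[1, 2], 1.0)
  expect_equal(single[1, 3], 0.0)
})

test_that("alpha grid search satisfies its argmax contract", {
  lay <- genome_layout("chrA", 150e3, 50e3)
  ts <- simulate_structures(lay, 1, rabl_strength = 0, seed = 82)
  cm <- structures_to_contacts(ts, 1, 1, depth = 4e5, seed = 83)
  bal <- suppressWarnings(ice_balance(cm))
  one <- suppressWarnings(
    fit_alpha(bal, 1, alpha_grid = 1.2,
              budget = list(n_replicas = 2, n_steps = 120), seed = 84))
  expect_equal(one$alpha, 1.2)

  fa <- suppressWarnings(
    fit_alpha(bal, 1, alpha_grid = c(0.8, 1.6),
              budget = list(n_replicas = 2, n_steps = 120), seed = 85))
  # the returned alpha is feasible-optimal under the package rule
  vf <- fa$scores$violation_fraction
  expect_equal(fa$alpha, max(fa$scores$alpha[vf <= min(vf) + 0.08]))
  expect_error(fit_alpha(bal, 1, alpha_grid = c(-1, 1)), "0, 3")
})

test_that("round-trip modeling recovers truth distance ranks up to the ICE ceiling", {
  lay <- four_chrom_layout()
  ts <- simulate_structures(lay, 1, rabl_strength = 0.5, seed = 86)
  cm <- structures_to_contacts(ts, 1, 1, depth = 1e6, seed = 87)
  bal <- ice_balance(cm)
  dm <- contacts_to_distances(bal, 1, 1)
  Xt <- ts$members[[1]]
  rs <- build_restraints(dm, chrom = "chr1")
  cand <- sample_structures(rs, n_replicas = 6, n_steps = 600,
                            snapshot_stride = 600, init_mode = "mds",
                            seed = 88)
  ens <- select_ensemble(cand)
  p <- rs$pairs[rs$pairs$kind == "interaction", ]
  ids <- rs$bead_ids
  dtruth <- sqrt(rowSums((Xt[ids[p$i], ] - Xt[ids[p$j], ])^2))
  dmod <- rowMeans(vapply(ens$members, function(X)
    sqrt(rowSums((X[p$i, , drop = FALSE] - X[p$j, , drop = FALSE])^2)),
    numeric(nrow(p))))
  ceiling_sp <- cor(dtruth, p$r0, method = "spearman")
  model_sp <- cor(dtruth, dmod, method = "spearman")
  expect_gt(model_sp, 0.5)
  expect_gt(model_sp, ceiling_sp - 0.15)
})
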