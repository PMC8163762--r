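test_that("coverage deconvolution recovers planted nucleosomes", {
  dy <- data.frame(pos = 500, fuzz_sd = 5, occupancy = 1)
  tr <- simulate_mnase(dy, 1000, depth = 1e5, seed = 101)
  comp <- deconvolve_coverage(tr)
  expect_equal(nrow(comp), 1)
  expect_lte(abs(comp$mu - 500), 2)
  expect_equal(comp$call_class, "well_positioned")

  expect_equal(nrow(deconvolve_coverage(coverage_track("c", numeric(800)))), 0)
})

test_that("two dyads resolve and fuzz controls the class", {
  dy2 <- data.frame(pos = c(400, 600), fuzz_sd = c(4, 4),
                    occupancy = c(1, 1))
  tr2 <- simulate_mnase(dy2, 1000, depth = 1e5, seed = 102)
  comp2 <- deconvolve_coverage(tr2)
  expect_equal(nrow(comp2), 2)
  expect_true(all(abs(sort(comp2$mu) - c(400, 600)) <= 5))
  expect_true(all(comp2$call_class == "well_positioned"))

  dyf <- data.frame(pos = 500, fuzz_sd = 50, occupancy = 1)
  trf <- simulate_mnase(dyf, 1000, depth = 1e5, seed = 103)
  compf <- deconvolve_coverage(trf)
  expect_equal(compf$call_class[which.max(compf$weight)], "fuzzy")
})

test_that("well/fuzzy classification recovers planted labels at depth 1e5", {
  dy <- data.frame(pos = c(300, 500, 700, 900, 1100),
                   fuzz_sd = c(4, 45, 5, 50, 6),
                   occupancy = c(1, 1, 1, 1, 1))
  tr <- simulate_mnase(dy, 1400, depth = 1e5, seed = 104)
  comp <- deconvolve_coverage(tr)
  truth_class <- ifelse(dy$fuzz_sd <= 10, "well_positioned", "fuzzy")
  hits <- 0
  for (k in seq_len(nrow(dy))) {
    j <- which.min(abs(comp$mu - dy$pos[k]))
    hits <- hits + (abs(comp$mu[j] - dy$pos[k]) <= 25 &&
                      comp$call_class[j] == truth_class[k])
  }
  expect_gte(hits / nrow(dy), 0.9)
})

test_that("family enumeration respects the steric spacing rule", {
  comp2 <- data.frame(mu = c(300, 500), sigma = c(15, 15),
                      weight = c(0.5, 0.5), height_score = 1, width_score = 0.8,
                      call_class = "well_positioned")
  fams <- enumerate_families(comp2, 1000)
  expect_length(fams, 1)
  expect_equal(fams[[1]]$dyads, c(300, 500))

  # 147 - 80 = 67 bp required: 50 bp apart conflicts -> two singleton families
  conf <- data.frame(mu = c(300, 350), sigma = c(15, 15),
                     weight = c(0.6, 0.4), height_score = 1, width_score = 0.8,
                     call_class = "well_positioned")
  fams2 <- enumerate_families(conf, 1000)
  expect_length(fams2, 2)
  expect_true(all(lengths(lapply(fams2, `[[`, "dyads")) == 1))
  expect_equal(sum(vapply(fams2, `[[`, 0, "weight")), 1)

  three <- data.frame(mu = c(200, 400, 600), sigma = 15, weight = 1 / 3,
                      height_score = 1, width_score = 0.8,
                      call_class = "well_positioned")
  fams3 <- enumerate_families(three, 1000)
  expect_length(fams3, 1)
  expect_equal(fams3[[1]]$weight, 1)

  fams0 <- enumerate_families(comp2[0, ], 1000)
  expect_length(fams0, 1)
  expect_length(fams0[[1]]$dyads, 0)
})

test_that("naked DNA builds a straight path at equilibrium", {
  g <- fiber_geometry()
  fib <- build_fiber(list(dyads = numeric(0)), 500)
  expect_equal(nrow(fib$positions), 500)
  ee <- sqrt(sum((fib$positions[500, ] - fib$positions[1, ])^2))
  expect_equal(ee, 499 * g$rise_eq, tolerance = 1e-8)
  expect_equal(fiber_energy(fib, nonbonded = FALSE)$total, 0)
})

test_that("wrapped and linker bp exactly tile the region", {
  fib <- build_fiber(list(dyads = 250), 500)
  expect_equal(nrow(fib$positions), 500)
  expect_equal(sum(fib$is_nuc), 147)
  expect_equal(sum(!fib$is_nuc), 500 - 147)
  # consecutive bp stay at plausible B-DNA distances through the wrap
  steps <- sqrt(rowSums(diff(fib$positions)^2))
  expect_true(all(steps > 0.5 & steps < 15))
  expect_error(build_fiber(list(dyads = 20), 500), "footprint")

  fib2 <- build_fiber(list(dyads = c(150, 350)), 600, jitter_sd = 0.01,
                      seed = 7)
  fib3 <- build_fiber(list(dyads = c(150, 350)), 600, jitter_sd = 0.01,
                      seed = 7)
  expect_identical(fib2$positions, fib3$positions)
})

test_that("zero-temperature sampling stays at the elastic equilibrium", {
  fib <- build_fiber(list(dyads = numeric(0)), 300)
  # every move is rejected at T = 0, so the low-acceptance warning fires
  expect_warning(
    out <- mc_sample_fiber(fib, n_steps = 500, temperature = 0, seed = 11,
                           nonbonded = FALSE),
    "acceptance")
  expect_equal(fiber_energy(out$fiber, nonbonded = FALSE)$total, 0)
  expect_equal(out$acceptance, 0)
})

test_that("naked-linker twist satisfies equipartition at finite temperature", {
  g <- fiber_geometry()
  fib <- build_fiber(list(dyads = numeric(0)), 200)
  out <- mc_sample_fiber(fib, n_steps = 40000, temperature = 1, seed = 12,
                         nonbonded = FALSE, snapshot_stride = 400)
  tw <- unlist(lapply(out$snapshots, function(f) f$params[, "twist"]))
  expect_lt(abs(mean(tw) - g$eq["twist"]), 1)
  # variance close to kT / k_twist
  expect_equal(var(tw), 1 / g$stiff[["twist"]], tolerance = 0.2)
  expect_gt(out$acceptance, 0.1)
})

test_that("incremental energies agree with full recomputation", {
  fib <- build_fiber(list(dyads = 250), 500)
  out <- mc_sample_fiber(fib, n_steps = 2500, temperature = 1, seed = 13,
                         nonbonded = TRUE, snapshot_stride = 500)
  expect_lt(out$energy_drift, 1e-6)
})

test_that("discrete Metropolis occupancies match the Boltzmann ratio", {
  # two states with energy gap 1 kT: P1/P0 = exp(-1)
  states <- metropolis_states(c(0, 1), n_steps = 1e5, temperature = 1,
                              seed = 14)
  ratio <- mean(states == 2) / mean(states == 1)
  expect_equal(ratio, exp(-1), tolerance = 0.05)
})

test_that("fiber metrics: rod Rg and neighbor distance tables", {
  fib <- build_fiber(list(dyads = numeric(0)), 2000)
  met <- fiber_metrics(list(naked = list(fib)))
  L <- 1999 * fiber_geometry()$rise_eq
  expect_equal(met$rg$rg_mean, L / sqrt(12), tolerance = 0.01)
  expect_null(met$nn_dist)

  fib1 <- build_fiber(list(dyads = 250), 500)
  met1 <- fiber_metrics(list(one = list(fib1)))
  expect_null(met1$nn_dist)

  fib4 <- build_fiber(list(dyads = c(100, 280, 460, 640)), 800)
  met4 <- fiber_metrics(list(four = list(fib4)))
  expect_setequal(met4$nn_dist$x, 1:3)
  expect_true(all(met4$nn_dist$mean > 0))
})

test_that("fuzzier families sample more dispersed neighbor distances", {
  mkfam <- function(d) list(dyads = d, occupancy = rep(1, length(d)),
                            weight = 1)
  well <- build_fiber(mkfam(c(150, 330, 510)), 700)
  sw <- mc_sample_fiber(well, n_steps = 3000, temperature = 1, seed = 15,
                        snapshot_stride = 150)
  # a fuzzy family: same nucleosomes but alternative placements sampled by
  # rebuilding with shifted dyads (position uncertainty -> wider spacing mix)
  shifts <- list(c(150, 330, 510), c(120, 330, 540), c(180, 330, 480))
  snaps_fuzzy <- list()
  for (k in seq_along(shifts)) {
    fz <- build_fiber(mkfam(shifts[[k]]), 700)
    sf <- mc_sample_fiber(fz, n_steps = 1000, temperature = 1,
                          seed = 20 + k, snapshot_stride = 150)
    snaps_fuzzy <- c(snaps_fuzzy, sf$snapshots)
  }
  mw <- fiber_metrics(list(w = sw$snapshots))
  mf <- fiber_metrics(list(f = snaps_fuzzy))
  sd_w <- mw$nn_dist$sd[mw$nn_dist$x == 2]
  sd_f <- mf$nn_dist$sd[mf$nn_dist$x == 2]
  expect_gt(sd_f, sd_w)
})

test_that("reconstructed coverage scores families against the track", {
  dy <- data.frame(pos = c(300, 500), fuzz_sd = c(8, 8), occupancy = c(1, 1))
  tr <- simulate_mnase(dy, 900, depth = 1e5, seed = 31)
  truth_fam <- list(list(dyads = c(300, 500), occupancy = c(1, 1),
                         weight = 1))
  class(truth_fam) <- "NucleosomeFamilySet"
  rec <- reconstruct_coverage(truth_fam, 900,
                              list(frag_len = 50, fuzz_sd = 8), tr)
  expect_gt(rec$correlation, 0.95)

  empty <- list(list(dyads = numeric(0), occupancy = numeric(0), weight = 1))
  class(empty) <- "NucleosomeFamilySet"
  rec0 <- reconstruct_coverage(empty, 900, list(frag_len = 50, fuzz_sd = 8),
                               tr)
  expect_true(is.nan(rec0$correlation) || is.na(rec0$correlation))
  expect_equal(sum(rec0$track$values), 0)

  tr_scaled <- coverage_track(tr$chrom, tr$values * 7.3)
  rec_s <- reconstruct_coverage(truth_fam, 900,
                                list(frag_len = 50, fuzz_sd = 8), tr_scaled)
  expect_equal(rec_s$correlation, rec$correlation, tolerance = 1e-12)
})

test_that("greedy family selection dominates any discarded single family", {
  dy <- data.frame(pos = c(250, 430, 610), fuzz_sd = 8, occupancy = 1)
  tr <- simulate_mnase(dy, 900, depth = 5e4, seed = 41)
  comp <- deconvolve_coverage(tr)
  fams <- enumerate_families(comp, 900)
  sel <- select_families(fams, tr, list(frag_len = 50, fuzz_sd = 8))
  singles <- vapply(seq_along(fams), function(k) {
    f1 <- fams[k]
    f1[[1]]$weight <- 1
    class(f1) <- "NucleosomeFamilySet"
    reconstruct_coverage(f1, 900, list(frag_len = 50, fuzz_sd = 8),
                         tr)$correlation
  }, 0)
  expect_gte(sel$correlation, max(singles) - 1e-9)
})
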