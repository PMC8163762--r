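# Shared fixtures: small layouts and an independent brute-force
# implementation of the greedy ensemble-selection rules, used as the oracle
# against select_ensemble().

toy_layout <- function() {
  genome_layout(c("chrI", "chrII"), c(60000L, 40000L), c(20000L, 15000L),
                telomere_margin = 5000L, bin_size = 5000L)
}

four_chrom_layout <- function() {
  genome_layout(paste0("chr", 1:4), c(150e3, 250e3, 325e3, 400e3),
                c(50e3, 120e3, 160e3, 200e3))
}

# Plain re-statement of the published selection rules over explicit sets.
# satisfied: logical candidates x restraints matrix; energy breaks ties,
# then input order.
brute_force_selection <- function(satisfied, energy) {
  n_cand <- nrow(satisfied)
  viol <- ncol(satisfied) - rowSums(satisfied)
  keep <- which(viol <= mean(viol))
  best_of <- function(pool, score) {
    cand <- pool[score == max(score)]
    cand <- cand[energy[cand] == min(energy[cand])]
    min(cand)
  }
  sel <- best_of(keep, -viol[keep])
  chosen <- sel
  pool <- setdiff(keep, sel)
  unmet <- which(!satisfied[sel, ])
  repeat {
    if (!length(pool) || !length(unmet)) break
    gains <- sapply(pool, function(cc) sum(satisfied[cc, unmet]))
    if (max(gains) == 0) break
    nxt <- best_of(pool, gains)
    chosen <- c(chosen, nxt)
    unmet <- setdiff(unmet, which(satisfied[nxt, ]))
    pool <- setdiff(pool, nxt)
  }
  chosen
}

# random coordinates with a fixed seed, n beads
rand_coords <- function(n, seed = 1, scale = 1) {
  set.seed(seed)
  matrix(rnorm(n * 3, 0, scale), n, 3)
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
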