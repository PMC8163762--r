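## Binomial mixture modeling of per-read methylation counts.
##
## A long read assaying n CpG sites with m methylated calls is modeled as
##   m | component c  ~  Binomial(n, p_c),   P(component c) = w_c.
## EM runs on (n, m) profiles collapsed to unique rows with multiplicities,
## so the cost per iteration is O(#profiles x C) regardless of library size.

.collapse_reads <- function(reads) {
  if (!nrow(reads)) stop("empty read table")
  if (any(reads$n_meth < 0 | reads$n_meth > reads$n_sites | reads$n_sites < 1))
    stop("invalid read counts: need 0 <= n_meth <= n_sites, n_sites >= 1")
  key <- paste(reads$n_sites, reads$n_meth)
  u <- !duplicated(key)
  idx <- match(key, key[u])
  n <- reads$n_sites[u]; m <- reads$n_meth[u]
  list(n = n, m = m, lch = lchoose(n, m), nm = n - m,
       wt = as.vector(table(factor(idx, levels = seq_len(sum(u))))),
       map = idx)
}

# log w_c + log P(m | n, p_c) over profiles x components; rates clipped
.log_post_mat <- function(cd, w, p, eps = 1e-6) {
  pc <- pmin(pmax(p, eps), 1 - eps)
  cd$lch + outer(cd$m, log(pc)) + outer(cd$nm, log1p(-pc)) +
    rep(log(pmax(w, 1e-300)), each = length(cd$n))
}

.logsumexp_rows <- function(L) {
  mx <- L[, 1]
  for (cc in seq_len(ncol(L))[-1]) mx <- pmax(mx, L[, cc])
  mx + log(rowSums(exp(L - mx)))
}

# one EM run from a given start; data are collapsed profiles
.em_run <- function(cd, w, p, tol, max_iter) {
  m <- cd$m; n <- cd$n; wt <- cd$wt
  N <- sum(wt)
  ll_old <- -Inf
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    L <- .log_post_mat(cd, w, p)
    lse <- .logsumexp_rows(L)
    ll <- sum(wt * lse)
    R <- exp(L - lse)
    w_new <- colSums(wt * R) / N
    num <- colSums(wt * R * m)
    den <- colSums(wt * R * n)
    p_new <- ifelse(den > 0, num / den, p)
    if (ll < ll_old - 1e-8)
      stop(sprintf("EM log-likelihood decreased (%.10g -> %.10g)", ll_old, ll))
    done <- is.finite(ll_old) && (ll - ll_old) < tol * (abs(ll) + 1)
    w <- w_new; p <- p_new
    if (done) { converged <- TRUE; break }
    if (it >= max_iter) break
    ll_old <- ll
  }
  # final E-step at the reported parameters with a negligible clip, so
  # boundary-converged rates score their exact likelihood
  L <- .log_post_mat(cd, w, p, eps = 1e-12)
  lse <- .logsumexp_rows(L)
  list(w = w, p = p, loglik = sum(wt * lse), resp = exp(L - lse),
       n_iter = it, converged = converged)
}

#' Fit a binomial mixture to per-read methylation counts by EM
#'
#' Maximizes the mixture likelihood over component weights and methylation
#' rates with multiple random restarts. `C = 1` uses the closed-form pooled
#' rate. Rates are clipped to `[1e-6, 1 - 1e-6]` inside E-steps for numerical
#' stability; reported rates are the raw M-step values, so boundary components
#' converge to exactly 0 or 1. Components are returned sorted by rate.
#'
#' @param reads data.frame with `n_sites` and `n_meth` per read.
#' @param C number of components.
#' @param n_restarts random EM restarts (best log-likelihood kept).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per restart.
#' @param seed RNG seed for restart initialization.
#' @param min_sites reads with fewer assayed CpGs are dropped (near-
#'   uninformative reads destabilize small-rate components); set 1 to keep all.
#' @return object of class `MixtureFit`: `C`, `w`, `p`, `loglik`, `n_iter`,
#'   `converged`, `responsibilities` (per retained read), `n_reads`,
#'   `kept` (logical index of retained rows).
#' @export
fit_mixture <- function(reads, C = 3L, n_restarts = 20L, tol = 1e-10,
                        max_iter = 500L, seed = 1L, min_sites = 5L) {
  if (!nrow(reads)) stop("empty read table")
  kept <- reads$n_sites >= min_sites
  reads <- reads[kept, , drop = FALSE]
  if (!nrow(reads)) stop("no reads left after the n_sites filter")
  cd <- .collapse_reads(reads)
  if (C > length(cd$n))
    warning("more components than distinct (n_sites, n_meth) profiles; ",
            "the fit is degenerate")
  pooled <- sum(cd$wt * cd$m) / sum(cd$wt * cd$n)
  if (C == 1) {
    ll <- sum(cd$wt * dbinom(cd$m, cd$n, min(max(pooled, 1e-12), 1 - 1e-12),
                             log = TRUE))
    if (pooled %in% c(0, 1)) # exact boundary: likelihood is exactly 1 per read
      ll <- sum(cd$wt * dbinom(cd$m, cd$n, pooled, log = TRUE))
    fit <- list(w = 1, p = pooled, loglik = ll,
                resp = matrix(1, length(cd$n), 1), n_iter = 0L,
                converged = TRUE)
  } else {
    set.seed(seed)
    qs <- quantile(cd$m / cd$n, probs = seq(0.1, 0.9, length.out = C),
                   names = FALSE)
    # deterministic start at the pooled-rate stationary point: guarantees the
    # fit is never worse than the nested one-component model
    best <- .em_run(cd, rep(1 / C, C), rep(pooled, C), tol, max_iter)
    for (r in seq_len(n_restarts)) {
      p0 <- pmin(pmax(qs + rnorm(C, 0, 0.05 * r / n_restarts + 1e-3), 0), 1)
      w0 <- rexp(C); w0 <- w0 / sum(w0)   # Dirichlet(1)
      run <- .em_run(cd, w0, p0, tol, max_iter)
      if (run$loglik > best$loglik) best <- run
    }
    fit <- best
  }
  o <- order(fit$p)
  structure(list(C = as.integer(C), w = unname(fit$w[o]), p = unname(fit$p[o]),
                 loglik = fit$loglik, n_iter = fit$n_iter,
                 converged = fit$converged,
                 responsibilities = fit$resp[cd$map, o, drop = FALSE],
                 n_reads = nrow(reads), kept = kept),
            class = "MixtureFit")
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat(sprintf("MixtureFit: C=%d, loglik=%.4f (%s in %d iterations)\n",
              x$C, x$loglik, if (x$converged) "converged" else "not converged",
              x$n_iter))
  cat("  weights:", paste(sprintf("%.4f", x$w), collapse = " "), "\n")
  cat("  rates:  ", paste(sprintf("%.4f", x$p), collapse = " "), "\n")
  invisible(x)
}

#' Likelihood-ratio test of read-population homogeneity
#'
#' Tests a homogeneous read population (one binomial rate) against a `C_alt`-
#' component mixture with the statistic `Lambda = 2 (loglik_alt - loglik_null)`.
#' Because the null lies on the boundary of the mixture parameter space, the
#' default reference distribution is a parametric bootstrap: datasets are
#' simulated from the null fit (same per-read site counts), both models are
#' refit, and the p-value is the empirical tail probability
#' `(1 + #{Lambda* >= Lambda}) / (n_boot + 1)`. `method = "chi2"` uses the
#' nominal `2 (C_alt - 1)` degrees of freedom instead.
#'
#' @param reads data.frame with `n_sites` and `n_meth`.
#' @param C_alt alternative number of components (>= 2).
#' @param method `"bootstrap"` or `"chi2"`.
#' @param n_boot bootstrap replicates (>= 19).
#' @param seed RNG seed.
#' @param n_restarts restarts for the observed-data alternative fit.
#' @param boot_restarts restarts used inside bootstrap refits.
#' @param boot_max_iter EM iteration cap inside bootstrap refits (the
#'   near-null likelihood ridge converges sublinearly; a moderate cap keeps
#'   the statistic's distribution intact at a fraction of the cost).
#' @param min_sites per-read CpG floor, as in [fit_mixture()].
#' @return object of class `LRTResult`: `statistic`, `df_nominal`, `p_value`,
#'   `method`, `n_boot`, plus both fits.
#' @export
lrt_homogeneity <- function(reads, C_alt = 3L,
                            method = c("bootstrap", "chi2"), n_boot = 199L,
                            seed = 1L, n_restarts = 20L, boot_restarts = 2L,
                            boot_max_iter = 30L, min_sites = 5L) {
  method <- match.arg(method)
  if (C_alt < 2) stop("C_alt must be >= 2")
  if (method == "bootstrap" && n_boot < 19)
    stop("n_boot must be >= 19 for a usable bootstrap p-value")
  fit0 <- fit_mixture(reads, C = 1L, seed = seed, min_sites = min_sites)
  fit1 <- fit_mixture(reads, C = C_alt, n_restarts = n_restarts, seed = seed,
                      min_sites = min_sites)
  lambda <- 2 * (fit1$loglik - fit0$loglik)
  if (lambda < -1e-6)
    stop("negative LRT statistic beyond tolerance; alternative fit failed")
  lambda <- max(lambda, 0)
  df <- 2L * (C_alt - 1L)
  kept <- reads[reads$n_sites >= min_sites, , drop = FALSE]
  if (method == "chi2") {
    p <- pchisq(lambda, df = df, lower.tail = FALSE)
  } else {
    # the observed statistic and every bootstrap statistic are computed by
    # the identical capped procedure, so the ranks are exchangeable under
    # the null and the p-value is calibrated by construction
    lam_fn <- function(cd_x) {
      pooled_x <- sum(cd_x$wt * cd_x$m) / sum(cd_x$wt * cd_x$n)
      px <- min(max(pooled_x, 1e-12), 1 - 1e-12)
      ll0 <- sum(cd_x$wt * (cd_x$lch + cd_x$m * log(px) +
                              cd_x$nm * log1p(-px)))
      best <- .em_run(cd_x, rep(1 / C_alt, C_alt), rep(pooled_x, C_alt),
                      1e-7, boot_max_iter)
      qs <- quantile(rep(cd_x$m / cd_x$n, pmin(cd_x$wt, 5)),
                     probs = seq(0.1, 0.9, length.out = C_alt),
                     names = FALSE)
      for (r in seq_len(boot_restarts)) {
        p0r <- pmin(pmax(qs + rnorm(C_alt, 0, 0.02 * r), 0), 1)
        w0r <- rexp(C_alt); w0r <- w0r / sum(w0r)
        run <- .em_run(cd_x, w0r, p0r, 1e-7, boot_max_iter)
        if (run$loglik > best$loglik) best <- run
      }
      max(0, 2 * (best$loglik - ll0))
    }
    # bootstrap datasets are drawn on the collapsed-profile scale: for each
    # unique site count n the methylated counts are multinomial over 0..n
    # with binomial(n, p-hat) cell probabilities
    nn <- table(kept$n_sites)
    nvals <- as.integer(names(nn))
    p0 <- min(max(fit0$p, 1e-12), 1 - 1e-12)
    cells <- lapply(nvals, function(nv) {
      mm <- 0:nv
      list(n = rep(nv, nv + 1L), m = mm, nm = nv - mm,
           lch = lchoose(nv, mm), prob = dbinom(mm, nv, p0))
    })
    set.seed(seed + 1L)
    lambda_obs <- lam_fn(.collapse_reads(kept))
    cell_n <- unlist(lapply(cells, `[[`, "n"))
    cell_m <- unlist(lapply(cells, `[[`, "m"))
    cell_nm <- unlist(lapply(cells, `[[`, "nm"))
    cell_lch <- unlist(lapply(cells, `[[`, "lch"))
    lam_boot <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      wt <- unlist(lapply(seq_along(nvals), function(k)
        as.vector(rmultinom(1, nn[[k]], cells[[k]]$prob))))
      keep_cells <- wt > 0
      cd_b <- list(n = cell_n[keep_cells], m = cell_m[keep_cells],
                   nm = cell_nm[keep_cells], lch = cell_lch[keep_cells],
                   wt = wt[keep_cells])
      lam_boot[b] <- lam_fn(cd_b)
    }
    p <- (1 + sum(lam_boot >= lambda_obs)) / (n_boot + 1)
    lambda <- lambda_obs
  }
  structure(list(statistic = lambda, df_nominal = df, p_value = p,
                 method = method,
                 n_boot = if (method == "bootstrap") as.integer(n_boot) else 0L,
                 fit_null = fit0, fit_alt = fit1),
            class = "LRTResult")
}

#' @export
print.LRTResult <- function(x, ...) {
  cat(sprintf("LRT homogeneity test: Lambda = %.4f, p = %.4g (%s%s)\n",
              x$statistic, x$p_value, x$method,
              if (x$method == "bootstrap") sprintf(", B=%d", x$n_boot) else
                sprintf(", df=%d", x$df_nominal)))
  invisible(x)
}

#' Classify reads by posterior component membership
#'
#' @param fit a `MixtureFit`.
#' @return list with `labels` (per retained read, argmax responsibility,
#'   components indexed in ascending-rate order) and `occupancy` (mean
#'   responsibility per component).
#' @export
classify_reads <- function(fit) {
  stopifnot(inherits(fit, "MixtureFit"))
  R <- fit$responsibilities
  list(labels = max.col(R, ties.method = "first"),
       occupancy = colMeans(R))
}
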