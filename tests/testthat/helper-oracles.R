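# Independent oracles used across the suites. These deliberately re-derive
# quantities with naive enumeration so they stay independent of the package
# implementation they check.

# Topological overlap by explicit triple loop.
tom_brute_force <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      u <- setdiff(seq_len(n), c(i, j))
      l_ij <- sum(a[i, u] * a[u, j])
      k_i <- sum(a[i, -i])
      k_j <- sum(a[j, -j])
      tom[i, j] <- (l_ij + a[i, j]) / (min(k_i, k_j) + 1 - a[i, j])
    }
  }
  tom
}

# Two-sample log-rank by explicit risk-set enumeration at each death time.
logrank_brute_force <- function(times, events, groups) {
  g <- as.integer(factor(groups)) # 1/2
  dt <- sort(unique(times[events == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in dt) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Log partial likelihood for a single binary covariate, no ties.
cox_loglik_1cov <- function(beta, times, events, x) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]; x <- x[ord]
  ll <- 0
  for (i in seq_along(times)) {
    if (events[i] == 1) {
      risk <- times >= times[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

# Adjusted Rand index between two labelings.
rand_index_adj <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# Small expression tibble from a plain matrix.
toy_expr <- function(m, probes = sprintf("P%03d", seq_len(nrow(m))),
                     samples = sprintf("S%03d", seq_len(ncol(m)))) {
  dimnames(m) <- list(probes, samples)
  tibble::as_tibble(m, .name_repair = "minimal") |>
    dplyr::mutate(probe_id = probes, .before = 1)
}

block_expr <- function(n_per_block = 50, n_samples = 60, r = 0.9, seed = 1) {
  # two latent-factor blocks, independent of each other
  withr::with_seed(seed, {
    lam <- sqrt(r)
    m <- do.call(rbind, lapply(1:2, function(b) {
      f <- rnorm(n_samples)
      lam * matrix(f, n_per_block, n_samples, byrow = TRUE) +
        sqrt(1 - lam^2) * matrix(rnorm(n_per_block * n_samples),
                                 n_per_block, n_samples)
    }))
    toy_expr(m)
  })
}
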