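# Shared fixtures and independent oracles used across the suite.

# small cohort with two anxiety labels of two strains each (the minimum the
# permutation machinery accepts)
small_cohort <- function(seed = 11, n_structures = 8, n_per_cell = 3,
                         ...) {
  generate_cohort(cohort_config(
    n_strains = 4, n_per_cell = n_per_cell, n_structures = n_structures,
    anxiety_groups = c(strain01 = "increased", strain02 = "increased",
                       strain03 = "decreased", strain04 = "decreased"),
    seed = seed, ...))
}

# a quick low-precision BHM spec for structural unit tests (convergence is
# not asserted on fits this small)
tiny_bhm_spec <- function(seed = 7) {
  bhm_spec(chains = 2, draws = 150, warmup = 300, adapt = 100, thin = 2,
           seed = seed)
}

# hand-built posterior_draws object with known values, for formula tests
fake_posterior <- function(bstr, bint, dstr, dint, sig_e,
                           structures, strains, reference = strains[1]) {
  nd <- length(sig_e)
  K <- length(strains); S <- length(structures)
  structure(list(
    draws = list(mu = numeric(nd), bsex = numeric(nd),
                 bstr = bstr, bint = bint, dstr = dstr, dint = dint,
                 dsex = matrix(0, nd, S),
                 sig_a = rep(0.1, nd), sig_e = sig_e,
                 Sigma = array(diag(1 + 2 * (K - 1)),
                               c(nd, 1 + 2 * (K - 1), 1 + 2 * (K - 1)))),
    chain = rep(1L, nd), strains = strains, structures = structures,
    reference = reference,
    diagnostics = data.frame(parameter = "none", rhat = 1, ess = nd),
    converged = TRUE,
    spec = bhm_spec(seed = 1)),
    class = "posterior_draws")
}

# hand-built phenotype_posterior from a named list of draws x structure
# matrices
fake_phenotype <- function(beta, reference = names(beta)[1]) {
  structure(list(beta = beta,
                 mean = lapply(beta, colMeans),
                 cov = lapply(beta, stats::cov),
                 strains = names(beta),
                 structures = colnames(beta[[1]]),
                 reference = reference),
            class = "phenotype_posterior")
}

# --- independent oracles -------------------------------------------------

# extra-sum-of-squares F from explicit projection matrices
oracle_partial_f <- function(y, X_full, X_red) {
  proj <- function(X) X %*% solve(crossprod(X), t(X))
  rss <- function(P) sum(((diag(nrow(P)) - P) %*% y)^2)
  r_f <- rss(proj(X_full)); r_r <- rss(proj(X_red))
  df1 <- qr(X_full)$rank - qr(X_red)$rank
  df2 <- length(y) - qr(X_full)$rank
  F <- ((r_r - r_f) / df1) / (r_f / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# Hellinger distance by trapezoidal integration of sqrt(p * q), 1-D
oracle_hellinger_1d <- function(m1, v1, m2, v2, n_grid = 20001) {
  lo <- min(m1 - 10 * sqrt(v1), m2 - 10 * sqrt(v2))
  hi <- max(m1 + 10 * sqrt(v1), m2 + 10 * sqrt(v2))
  x <- seq(lo, hi, length.out = n_grid)
  f <- sqrt(stats::dnorm(x, m1, sqrt(v1)) * stats::dnorm(x, m2, sqrt(v2)))
  bc <- sum((f[-1] + f[-n_grid]) / 2 * diff(x))
  sqrt(max(0, 1 - bc))
}

# Hellinger distance by grid integration, 2-D
oracle_hellinger_2d <- function(m1, C1, m2, C2, n_grid = 401) {
  dmvn <- function(X, m, C) {
    Ci <- solve(C)
    d <- sweep(X, 2, m)
    q <- rowSums((d %*% Ci) * d)
    exp(-q / 2) / (2 * pi * sqrt(det(C)))
  }
  sd_max <- sqrt(max(diag(C1), diag(C2)))
  lo <- pmin(m1, m2) - 8 * sd_max
  hi <- pmax(m1, m2) + 8 * sd_max
  g1 <- seq(lo[1], hi[1], length.out = n_grid)
  g2 <- seq(lo[2], hi[2], length.out = n_grid)
  X <- as.matrix(expand.grid(g1, g2))
  f <- sqrt(dmvn(X, m1, C1) * dmvn(X, m2, C2))
  bc <- sum(f) * diff(g1[1:2]) * diff(g2[1:2])
  sqrt(max(0, 1 - bc))
}

# exhaustive BH step-up definition: q_i = min_{j: p_(j) >= p_(i)} min(1, m p_(j) / j)
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  vapply(seq_len(m), function(i) {
    ri <- which(ord == i)  # rank position of p[i]
    cand <- vapply(ri:m, function(j) min(1, m * p[ord[j]] / j), numeric(1))
    min(cand)
  }, numeric(1))
}

# exact upper-tail hypergeometric by combinatorial enumeration
oracle_hypergeom <- function(overlap, K, N, n) {
  js <- overlap:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Rand index between two partitions
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
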