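#' Specify the Bayesian hierarchical model of standardised volumes
#'
#' The model for the standardised volume of animal `i`, structure `s` is
#'
#' \deqn{y_{is} = \mu + a_i + (\beta^{sex} + b^{sex}_s) x_i +
#'   (\beta^{strain}_{k(i)} + b^{strain}_{k(i),s}) +
#'   (\beta^{int}_{k(i)} + b^{int}_{k(i),s}) x_i + \varepsilon_{is}}
#'
#' with `x_i` an indicator for the non-reference sex, global coefficients
#' shared across structures, structure-specific deviations `b` drawn jointly
#' (per structure) from a multivariate normal with estimated scales and
#' correlation across coefficient types, a single per-animal intercept `a_i`
#' (a brain-size-like nuisance shared across that animal's structures), and
#' Gaussian residuals. The wild-type reference strain has all strain and
#' interaction terms fixed to zero, so strain coefficients are directly the
#' deviation from wild-type.
#'
#' Priors: Normal(0, `prior_global_sd`) on global coefficients, half-Normal
#' (0, `prior_scale_sd`) on the animal-intercept and residual SDs, and a
#' Wishart prior on the precision of the structure-deviation vector with
#' `P + 1 + corr_concentration` degrees of freedom (identity scale), where
#' `P` is the deviation dimension; larger `corr_concentration` concentrates
#' the implied correlations nearer zero.
#'
#' @param reference_sex baseline sex level (default `"F"`; male effects then
#'   include the interaction terms).
#' @param prior_global_sd,prior_scale_sd prior SDs (standardised-volume
#'   units), both positive.
#' @param corr_concentration extra Wishart degrees of freedom controlling the
#'   correlation prior's concentration (default 2).
#' @param chains,draws,warmup,adapt MCMC layout: independent chains, retained
#'   draws per chain, burn-in iterations, and adaptation iterations.
#' @param thin keep every `thin`-th iteration (`draws * thin` iterations are
#'   run per chain). The conjugate Gibbs updates of this model are strongly
#'   autocorrelated, so undiluted chains waste draws; the default keeps the
#'   retained sample compact while meeting the effective-sample-size gate.
#' @param rhat_max,ess_min convergence gate: maximum split R-hat and minimum
#'   effective sample size over all reported scalar quantities.
#' @param seed integer seed; chain RNGs are derived from it.
#' @return list of class `bhm_spec`.
#' @export
bhm_spec <- function(reference_sex = "F",
                     prior_global_sd = 1, prior_scale_sd = 1,
                     corr_concentration = 2,
                     chains = 4, draws = 500, warmup = 1000, adapt = 200,
                     thin = 15, rhat_max = 1.05, ess_min = 100, seed = 1L) {
  stopifnot(chains >= 1, draws >= 1, warmup >= 0, adapt >= 10, thin >= 1,
            prior_global_sd > 0, prior_scale_sd > 0, corr_concentration >= 0,
            rhat_max > 1, ess_min > 0)
  structure(list(reference_sex = reference_sex,
                 prior_global_sd = prior_global_sd,
                 prior_scale_sd = prior_scale_sd,
                 corr_concentration = corr_concentration,
                 chains = as.integer(chains), draws = as.integer(draws),
                 warmup = as.integer(warmup), adapt = as.integer(adapt),
                 thin = as.integer(thin),
                 rhat_max = rhat_max, ess_min = ess_min,
                 seed = as.integer(seed)),
            class = "bhm_spec")
}

# Centred parameterisation: per-structure total coefficients v[s,] are drawn
# around the global coefficient vector, and animal intercepts around the
# global mean. With informative per-structure data this mixes much better
# than the equivalent zero-centred deviation form (same posterior).
bhm_model_string <- "
model {
  for (i in 1:n) {
    a[i] ~ dnorm(mu, tau_a)
    for (s in 1:S) {
      y[i,s] ~ dnorm(a[i] + v[s,1] * x[i]
                     + tstr[k[i],s] + tint[k[i],s] * x[i], tau_e)
    }
  }
  for (s in 1:S) {
    v[s,1:P] ~ dmnorm(gvec, Omega)
    tstr[1,s] <- 0
    tint[1,s] <- 0
    for (m in 2:K) {
      tstr[m,s] <- v[s,m]
      tint[m,s] <- v[s,K - 1 + m]
    }
  }
  gvec[1] <- bsex
  for (m in 2:K) {
    gvec[m] <- bstr[m]
    gvec[K - 1 + m] <- bint[m]
  }
  Omega ~ dwish(Rmat, wish_df)
  Sigma <- inverse(Omega)
  mu ~ dnorm(0, prec_g)
  bsex ~ dnorm(0, prec_g)
  bstr[1] <- 0
  bint[1] <- 0
  for (m in 2:K) {
    bstr[m] ~ dnorm(0, prec_g)
    bint[m] ~ dnorm(0, prec_g)
  }
  sig_a ~ dnorm(0, prec_s) T(0,)
  tau_a <- pow(sig_a, -2)
  sig_e ~ dnorm(0, prec_s) T(0,)
  tau_e <- pow(sig_e, -2)
}"

# split coda variable names like "dstr[3,12]" into arrays
coda_to_array <- function(mat, var, dims) {
  pat <- paste0("^", var, "\\[")
  cols <- grep(pat, colnames(mat))
  if (length(cols) == 0) {
    cols <- which(colnames(mat) == var)
    return(mat[, cols])
  }
  idx <- sub(paste0("^", var, "\\[(.*)\\]$"), "\\1", colnames(mat)[cols])
  idx <- do.call(rbind, lapply(strsplit(idx, ","), as.integer))
  arr <- array(NA_real_, dim = c(nrow(mat), dims))
  for (j in seq_along(cols)) {
    pos <- cbind(seq_len(nrow(mat)),
                 matrix(idx[j, ], nrow(mat), ncol(idx), byrow = TRUE))
    arr[pos] <- mat[, cols[j]]
  }
  arr
}

# Split R-hat (Gelman-Rubin with halved chains) for a draws x chains matrix.
split_rhat <- function(x) {
  half <- floor(nrow(x) / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(nrow(x) - half + 1):nrow(x), , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  mu_j <- colMeans(sub); var_j <- apply(sub, 2, stats::var)
  B <- nn * stats::var(mu_j); W <- mean(var_j)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Fit the Bayesian hierarchical model
#'
#' Samples the posterior of the model in [bhm_spec()] by Gibbs sampling
#' (JAGS backend via \pkg{rjags}), computes split R-hat and effective sample
#' size for every scalar quantity, and attaches a convergence flag. A
#' non-converged fit is returned with `converged = FALSE` and a warning —
#' never silently — so callers (and the pipeline) can refuse to proceed.
#'
#' @param sv a standardised [volume_table()] (see [standardise_volumes()]).
#' @param spec a [bhm_spec()].
#' @param quiet suppress sampler progress output.
#' @return list of class `posterior_draws`: `draws` (named list of arrays
#'   whose first dimension indexes retained draws across all chains —
#'   `mu`, `bsex`, `dsex` (structure), `bstr`, `bint` (strain),
#'   `dstr`, `dint` (strain x structure), `sig_a`, `sig_e`,
#'   `Sigma` (deviation covariance)), `chain` (chain index per draw),
#'   `strains` (reference first), `structures`, `reference`,
#'   `diagnostics` (per-quantity R-hat and ESS), `converged`, `spec`.
#' @export
fit_bhm <- function(sv, spec = bhm_spec(), quiet = TRUE) {
  stopifnot(inherits(sv, "volume_table"))
  if (!isTRUE(attr(sv, "standardised")))
    stop("fit_bhm expects standardised volumes; see standardise_volumes()")
  ref <- wildtype_strain(sv)
  strains <- c(ref, sort(setdiff(unique(sv$strain), ref)))
  if (length(strains) < 2) stop("need at least two strains")
  structures <- structure_names(sv)
  if (length(structures) < 2) stop("need at least two structures")
  if (length(unique(sv$sex)) < 2) stop("both sexes required")
  y <- volume_matrix(sv)
  K <- length(strains); S <- length(structures)
  P <- 1L + 2L * (K - 1L)
  dat <- list(y = y,
              x = as.numeric(sv$sex != spec$reference_sex),
              k = match(sv$strain, strains),
              n = nrow(y), S = S, K = K, P = P,
              Rmat = diag(P),
              wish_df = P + 1 + spec$corr_concentration,
              prec_g = spec$prior_global_sd^-2,
              prec_s = spec$prior_scale_sd^-2)
  inits <- lapply(seq_len(spec$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = substream_seed(spec$seed, 100 + ch))
  })
  model <- rjags::jags.model(textConnection(bhm_model_string), data = dat,
                             n.chains = spec$chains, n.adapt = spec$adapt,
                             inits = inits, quiet = quiet)
  if (spec$warmup > 0)
    stats::update(model, spec$warmup, progress.bar = "none")
  monitors <- c("mu", "bsex", "v", "bstr", "bint",
                "sig_a", "sig_e", "Sigma")
  samp <- rjags::coda.samples(model, monitors,
                              n.iter = spec$draws * spec$thin,
                              thin = spec$thin, progress.bar = "none")

  full <- do.call(rbind, lapply(samp, as.matrix))
  chain <- rep(seq_len(spec$chains), each = spec$draws)
  v <- coda_to_array(full, "v", c(S, P))        # draws x structure x coef
  draws <- list(
    mu = coda_to_array(full, "mu", NULL),
    bsex = coda_to_array(full, "bsex", NULL),
    bstr = coda_to_array(full, "bstr", K),
    bint = coda_to_array(full, "bint", K),
    sig_a = coda_to_array(full, "sig_a", NULL),
    sig_e = coda_to_array(full, "sig_e", NULL),
    Sigma = coda_to_array(full, "Sigma", c(P, P)))
  # deviations of the structure-specific totals from the global coefficients
  nd <- nrow(full)
  draws$dsex <- v[, , 1] - draws$bsex
  draws$dstr <- array(0, c(nd, K, S))
  draws$dint <- array(0, c(nd, K, S))
  for (m in 2:K) {
    draws$dstr[, m, ] <- v[, , m] - draws$bstr[, m]
    draws$dint[, m, ] <- v[, , K - 1 + m] - draws$bint[, m]
  }

  # diagnostics over every non-constant scalar
  keep <- apply(full, 2, function(col) stats::sd(col) > 0)
  diag_rhat <- vapply(which(keep), function(j) {
    split_rhat(matrix(full[, j], ncol = spec$chains))
  }, numeric(1))
  diag_ess <- vapply(which(keep), function(j) {
    as.numeric(coda::effectiveSize(full[, j]))
  }, numeric(1))
  diagnostics <- data.frame(parameter = colnames(full)[keep],
                            rhat = diag_rhat, ess = diag_ess,
                            stringsAsFactors = FALSE)
  converged <- all(diagnostics$rhat <= spec$rhat_max) &&
    all(diagnostics$ess >= spec$ess_min)
  if (!converged)
    warning("BHM did not meet convergence thresholds (max R-hat = ",
            round(max(diagnostics$rhat), 3), ", min ESS = ",
            round(min(diagnostics$ess), 1), ")")
  structure(list(draws = draws, chain = chain, strains = strains,
                 structures = structures, reference = ref,
                 diagnostics = diagnostics, converged = converged,
                 spec = spec),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf(
    "posterior_draws: %d draws (%d chains), %d strains, %d structures\n",
    length(x$draws$mu), max(x$chain), length(x$strains),
    length(x$structures)))
  cat(sprintf("  converged: %s (max R-hat %.3f, min ESS %.0f)\n",
              x$converged, max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  invisible(x)
}

#' Posterior effect-size (d) draws per structure, strain and sex
#'
#' For each posterior draw, the effect size of strain `k` in structure `s`
#' is the expected standardised volume difference from the wild-type
#' reference (same sex, same structure) divided by that draw's residual SD:
#' for the reference sex `d = (beta_k + b_ks) / sigma_eps`; for the other sex
#' the interaction terms are added. With `denominator = "unit"` the raw
#' coefficient difference is returned instead.
#'
#' @param pd a [fit_bhm()] result.
#' @param denominator `"residual"` (default) or `"unit"`.
#' @return list of class `effect_size_distribution` with `d`, an array
#'   `draws x structure x strain x sex` (dimnames set; sexes `F`, `M`), and
#'   `reference`.
#' @export
effect_size_draws <- function(pd, denominator = c("residual", "unit")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(pd, "posterior_draws"))
  nd <- length(pd$draws$mu)
  K <- length(pd$strains); S <- length(pd$structures)
  total_ref <- array(0, c(nd, S, K))  # effect in reference sex
  total_alt <- array(0, c(nd, S, K))  # effect in the other sex
  for (m in seq_len(K)) {
    eff <- pd$draws$bstr[, m] + pd$draws$dstr[, m, ]       # nd x S
    inter <- pd$draws$bint[, m] + pd$draws$dint[, m, ]
    total_ref[, , m] <- eff
    total_alt[, , m] <- eff + inter
  }
  if (denominator == "residual") {
    total_ref <- total_ref / pd$draws$sig_e
    total_alt <- total_alt / pd$draws$sig_e
  }
  ref_sex <- pd$spec$reference_sex
  sexes <- c(ref_sex, setdiff(c("F", "M"), ref_sex))
  d <- array(NA_real_, c(nd, S, K, 2),
             dimnames = list(NULL, pd$structures, pd$strains, sexes))
  d[, , , 1] <- total_ref
  d[, , , 2] <- total_alt
  d <- d[, , , c("F", "M"), drop = FALSE]
  structure(list(d = d, reference = pd$reference,
                 denominator = denominator),
            class = "effect_size_distribution")
}

#' Probability of a large effect size
#'
#' Empirical posterior probability that the effect-size magnitude exceeds a
#' threshold (by convention 1, the boundary drawn on effect-size posteriors).
#'
#' @param esd an [effect_size_draws()] result.
#' @param threshold positive effect-size magnitude boundary.
#' @return data frame `structure, strain, sex, p_large`.
#' @export
prob_large_effect <- function(esd, threshold = 1) {
  stopifnot(inherits(esd, "effect_size_distribution"), threshold >= 0)
  tab <- apply(abs(esd$d) > threshold, c(2, 3, 4), mean)
  out <- as.data.frame.table(tab, stringsAsFactors = FALSE)
  names(out) <- c("structure", "strain", "sex", "p_large")
  out
}

#' Rank structures by susceptibility to strain effects
#'
#' Summarises the effect-size posterior per structure: the median over
#' mutant strains and sexes of the posterior median absolute effect size
#' (`med_abs_d`), and the maximum posterior probability of a large effect
#' (`max_p_large`). Rows are ranked by `med_abs_d` descending, ties broken
#' by structure name, which makes ROI selection deterministic.
#'
#' @param esd an [effect_size_draws()] result.
#' @param threshold magnitude boundary for `max_p_large`.
#' @return data frame `structure, med_abs_d, max_p_large, rank`.
#' @export
structure_susceptibility <- function(esd, threshold = 1) {
  stopifnot(inherits(esd, "effect_size_distribution"))
  mutants <- setdiff(dimnames(esd$d)[[3]], esd$reference)
  dm <- esd$d[, , mutants, , drop = FALSE]
  med_d <- apply(abs(dm), c(2, 3, 4), stats::median)  # structure x strain x sex
  med_abs <- apply(med_d, 1, stats::median)
  p_lrg <- apply(abs(dm) > threshold, c(2, 3, 4), mean)
  max_p <- apply(p_lrg, 1, max)
  out <- data.frame(structure = names(med_abs), med_abs_d = unname(med_abs),
                    max_p_large = unname(max_p), stringsAsFactors = FALSE)
  out <- out[order(-out$med_abs_d, out$structure), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
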