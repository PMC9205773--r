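#' Hellinger distance between two multivariate Gaussians
#'
#' Closed form: with Bhattacharyya coefficient
#' \deqn{BC = \frac{\det(C_1)^{1/4}\det(C_2)^{1/4}}{\det(\bar C)^{1/2}}
#'   \exp\{-\tfrac18 (m_1-m_2)^\top \bar C^{-1} (m_1-m_2)\}, \quad
#'   \bar C = (C_1+C_2)/2,}
#' the distance is `H = sqrt(1 - BC)`, bounded in `[0, 1]`. Scalars are
#' accepted for the one-dimensional case. Determinants are computed on the
#' log scale so high-dimensional inputs do not underflow.
#'
#' @param m1,m2 mean vectors.
#' @param C1,C2 covariance matrices (positive definite; a small diagonal
#'   `jitter` is added before inversion).
#' @param jitter diagonal regularisation.
#' @return Hellinger distance in `[0, 1]`.
#' @export
hellinger_gaussian <- function(m1, C1, m2, C2, jitter = 1e-8) {
  m1 <- as.numeric(m1); m2 <- as.numeric(m2)
  C1 <- as.matrix(C1); C2 <- as.matrix(C2)
  p <- length(m1)
  stopifnot(length(m2) == p, all(dim(C1) == p), all(dim(C2) == p))
  C1 <- C1 + diag(jitter, p); C2 <- C2 + diag(jitter, p)
  Cbar <- (C1 + C2) / 2
  ld1 <- determinant(C1, logarithm = TRUE)$modulus
  ld2 <- determinant(C2, logarithm = TRUE)$modulus
  ldb <- determinant(Cbar, logarithm = TRUE)$modulus
  diff <- m1 - m2
  quad <- drop(crossprod(diff, solve(Cbar, diff)))
  log_bc <- 0.25 * ld1 + 0.25 * ld2 - 0.5 * ldb - quad / 8
  sqrt(max(0, 1 - exp(as.numeric(log_bc))))
}

# log Bhattacharyya coefficient of two 1-D Gaussians (vectorised)
log_bc_1d <- function(m1, v1, m2, v2) {
  0.25 * log(v1) + 0.25 * log(v2) - 0.5 * log((v1 + v2) / 2) -
    (m1 - m2)^2 / (4 * (v1 + v2))
}

#' Strain endophenotype posteriors from BHM draws
#'
#' The neuroanatomy endophenotype of a strain is its vector of
#' structure-wise volume coefficients referenced to wild-type (the wild-type
#' vector is identically zero). By default female and male effects are
#' averaged per draw; per-sex endophenotypes are available via `sex_mode`.
#' For each strain the raw draws are kept along with a Gaussian summary
#' (mean vector and covariance across draws) used by the closed-form
#' Hellinger machinery.
#'
#' @param pd a [fit_bhm()] result.
#' @param sex_mode `"average"` (default), `"F"`, or `"M"`.
#' @param min_draws fewer draws than this is an error unless `force = TRUE`
#'   (moment estimates become unstable).
#' @param force bypass the draw-count check.
#' @return list of class `phenotype_posterior`: `beta` (named list of
#'   draws x structure matrices per strain), `mean`, `cov`, `strains`,
#'   `structures`, `reference`.
#' @export
phenotype_posterior <- function(pd, sex_mode = c("average", "F", "M"),
                                min_draws = 100, force = FALSE) {
  sex_mode <- match.arg(sex_mode)
  stopifnot(inherits(pd, "posterior_draws"))
  esd <- effect_size_draws(pd, denominator = "unit")
  nd <- dim(esd$d)[1]
  if (nd < min_draws && !force)
    stop("only ", nd, " draws; moment summaries need >= ", min_draws,
         " (use force = TRUE to override)")
  beta <- lapply(pd$strains, function(k) {
    bF <- esd$d[, , k, "F"]
    bM <- esd$d[, , k, "M"]
    switch(sex_mode, average = (bF + bM) / 2, F = bF, M = bM)
  })
  names(beta) <- pd$strains
  structure(list(beta = beta,
                 mean = lapply(beta, colMeans),
                 cov = lapply(beta, stats::cov),
                 strains = pd$strains, structures = pd$structures,
                 reference = pd$reference),
            class = "phenotype_posterior")
}

#' Pairwise Hellinger distances between strain endophenotypes
#'
#' Three Gaussian approximations of the posterior over the structure-effect
#' vector are supported. `"joint-diagonal"` (default) treats structures as
#' independent: the per-structure one-dimensional Bhattacharyya coefficients
#' are multiplied and `H = sqrt(1 - prod(BC_s))` — the joint formula under
#' diagonal covariances, which is stable for many structures and finite
#' draws. `"mean-marginal"` reports the mean over structures of the
#' one-dimensional Hellinger distances. `"full-covariance"` applies the
#' joint closed form with a shrinkage-regularised covariance
#' (`(1 - shrink) * C + shrink * mean(diag(C)) * I`).
#'
#' @param pp a [phenotype_posterior()].
#' @param mode distance mode, see above.
#' @param shrink shrinkage weight for full-covariance mode.
#' @return symmetric zero-diagonal matrix of class `hellinger_matrix` with
#'   entries in `[0, 1]` and attribute `mode`.
#' @export
hellinger_matrix <- function(pp,
                             mode = c("joint-diagonal", "mean-marginal",
                                      "full-covariance"),
                             shrink = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(pp, "phenotype_posterior"))
  strains <- pp$strains
  nk <- length(strains)
  if (nk < 2) stop("need at least two strains")
  H <- matrix(0, nk, nk, dimnames = list(strains, strains))
  mu <- pp$mean
  va <- lapply(pp$cov, diag)
  for (i in seq_len(nk - 1)) for (j in (i + 1):nk) {
    h <- switch(mode,
      "joint-diagonal" = {
        lbc <- sum(log_bc_1d(mu[[i]], va[[i]], mu[[j]], va[[j]]))
        sqrt(max(0, 1 - exp(lbc)))
      },
      "mean-marginal" = {
        lbc <- log_bc_1d(mu[[i]], va[[i]], mu[[j]], va[[j]])
        mean(sqrt(pmax(0, 1 - exp(lbc))))
      },
      "full-covariance" = {
        shr <- function(C) {
          (1 - shrink) * C + shrink * mean(diag(C)) * diag(nrow(C))
        }
        hellinger_gaussian(mu[[i]], shr(pp$cov[[i]]),
                           mu[[j]], shr(pp$cov[[j]]))
      })
    H[i, j] <- H[j, i] <- h
  }
  structure(H, class = c("hellinger_matrix", "matrix"), mode = mode)
}

#' Strain-similarity network from a Hellinger matrix
#'
#' Builds the complete weighted graph on strains with edge weight `1 - H`
#' (greater weight = more similar endophenotype). Optionally prunes to the
#' heaviest fraction of edges for display, keeping `ceiling(E * keep_top)`
#' edges with ties broken by lexicographic strain pair.
#'
#' @param H a [hellinger_matrix()].
#' @param keep_top fraction of edges to keep (`NULL` keeps all).
#' @return an \pkg{igraph} undirected weighted graph; the edge list is also
#'   attached as attribute `edges` (`strain_a, strain_b, weight`).
#' @export
similarity_network <- function(H, keep_top = NULL) {
  stopifnot(inherits(H, "hellinger_matrix"))
  strains <- rownames(H)
  pairs <- utils::combn(strains, 2)
  edges <- data.frame(strain_a = pairs[1, ], strain_b = pairs[2, ],
                      weight = H[t(pairs)] * -1 + 1,
                      stringsAsFactors = FALSE)
  if (!is.null(keep_top)) {
    stopifnot(keep_top > 0, keep_top <= 1)
    keep_n <- ceiling(nrow(edges) * keep_top)
    ord <- order(-edges$weight, edges$strain_a, edges$strain_b)
    edges <- edges[sort(ord[seq_len(keep_n)]), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = strains)
  attr(g, "edges") <- edges
  g
}
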