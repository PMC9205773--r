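#' Anxiety-phenotype annotations
#'
#' A strain-to-anxiety-label table. Labels are `increased`, `decreased` or
#' `unchanged`; strains whose label is assumed rather than literature-backed
#' carry `assumed = TRUE` so analyses can be repeated without them.
#'
#' @param strain character vector of strain names.
#' @param anxiety labels, one per strain.
#' @param assumed logical, default all `FALSE`.
#' @param source free-text provenance per strain.
#' @return data frame of class `anxiety_annotation`.
#' @export
anxiety_annotation <- function(strain, anxiety, assumed = FALSE,
                               source = NA_character_) {
  stopifnot(length(anxiety) == length(strain))
  if (!all(anxiety %in% c("increased", "decreased", "unchanged")))
    stop("anxiety labels must be increased/decreased/unchanged")
  if (anyDuplicated(strain)) stop("duplicated strain")
  out <- data.frame(strain = as.character(strain),
                    anxiety = as.character(anxiety),
                    assumed = rep_len(assumed, length(strain)),
                    source = rep_len(source, length(strain)),
                    stringsAsFactors = FALSE)
  class(out) <- c("anxiety_annotation", "data.frame")
  out
}

#' @rdname anxiety_annotation
#' @param path CSV with columns `strain,anxiety,assumed,source`.
#' @export
read_anxiety_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  anxiety_annotation(df$strain, df$anxiety,
                     assumed = if ("assumed" %in% names(df)) as.logical(df$assumed) else FALSE,
                     source = if ("source" %in% names(df)) df$source else NA_character_)
}

# mean between-label minus mean within-label distance for a label vector
between_minus_within <- function(H, labels) {
  same <- outer(labels, labels, "==")
  ut <- upper.tri(H)
  mean(H[ut & !same]) - mean(H[ut & same])
}

# all distinct arrangements of a label multiset (used by the exhaustive mode)
label_arrangements <- function(labels, cap = 1e5) {
  n <- length(labels)
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(out) >= cap) stop("too many arrangements to enumerate")
    if (length(remaining) == 0) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (l in unique(remaining)) {
      rec(c(prefix, l), remaining[-match(l, remaining)])
    }
  }
  rec(character(0), sort(labels))
  out
}

#' Permutation test: do strains with the same anxiety label have closer
#' endophenotypes?
#'
#' The observed statistic is `Delta = mean(H between-label pairs) -
#' mean(H within-label pairs)`; a positive value means same-label strains are
#' more similar. The null distribution is built by permuting the anxiety
#' labels over strains (label counts preserved), and the one-sided p-value
#' uses the add-one correction `p = (1 + #(Delta_perm >= Delta_obs)) /
#' (1 + n_iter)`, so p is never zero and ties count against rejection.
#' Because label counts are preserved, the within-pair set is non-empty for
#' every permutation whenever it is non-empty for the observed labels.
#'
#' @param H a [hellinger_matrix()] (or any symmetric distance matrix with
#'   strain dimnames).
#' @param annotation an [anxiety_annotation()] covering the strains of `H`
#'   (wild-type, which has no anxiety annotation, is dropped automatically).
#' @param n_iter Monte-Carlo permutations (ignored when `exhaustive`).
#' @param seed integer seed.
#' @param exclude_assumed drop strains flagged `assumed` before testing.
#' @param exhaustive enumerate every distinct label arrangement instead of
#'   sampling (exact p-value; feasible for small strain counts).
#' @return list of class `permutation_result`: `delta_obs`, `null`
#'   (permuted statistics), `p`, `n_iterations`, `statistic`
#'   (`"between-minus-within"`), `strains`, `labels`, `seed`, `exhaustive`.
#' @export
anxiety_permutation_test <- function(H, annotation, n_iter = 1e5, seed = 1L,
                                     exclude_assumed = FALSE,
                                     exhaustive = FALSE) {
  ann <- annotation
  if (exclude_assumed) ann <- ann[!ann$assumed, , drop = FALSE]
  strains <- intersect(rownames(H), ann$strain)
  if (length(strains) < 3) stop("need at least three annotated strains")
  labels <- ann$anxiety[match(strains, ann$strain)]
  if (length(unique(labels)) < 2 || sum(table(labels) >= 2) < 2)
    stop("need >= 2 anxiety labels with >= 2 strains each")
  Hs <- H[strains, strains]
  delta_obs <- between_minus_within(Hs, labels)
  if (exhaustive) {
    arrangements <- label_arrangements(labels)
    null <- vapply(arrangements, function(l) between_minus_within(Hs, l),
                   numeric(1))
    p <- mean(null >= delta_obs - 1e-12)
    n_iter <- length(null)
  } else {
    set.seed(seed)
    null <- vapply(seq_len(n_iter), function(i) {
      between_minus_within(Hs, sample(labels))
    }, numeric(1))
    p <- (1 + sum(null >= delta_obs - 1e-12)) / (1 + n_iter)
  }
  structure(list(delta_obs = delta_obs, null = null, p = p,
                 n_iterations = n_iter,
                 statistic = "between-minus-within",
                 strains = strains, labels = labels,
                 seed = seed, exhaustive = exhaustive),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation test (%s, %s): Delta_obs = %.4f, p = %.4g (%d iterations)\n",
    x$statistic, if (x$exhaustive) "exhaustive" else "Monte-Carlo",
    x$delta_obs, x$p, x$n_iterations))
  invisible(x)
}

#' Bootstrap stability of similarity-network edges
#'
#' Robustness variant of the network analysis: posterior draws are resampled
#' with replacement, the Hellinger matrix recomputed, and for every strain
#' pair the frequency with which its edge ranks in the heaviest `keep_top`
#' fraction is reported.
#'
#' @param pp a [phenotype_posterior()].
#' @param n_boot bootstrap replicates.
#' @param keep_top edge fraction defining "present".
#' @param mode passed to [hellinger_matrix()].
#' @param seed integer seed.
#' @return data frame `strain_a, strain_b, stability` (frequency in `[0,1]`).
#' @export
network_edge_stability <- function(pp, n_boot = 100, keep_top = 0.5,
                                   mode = "joint-diagonal", seed = 1L) {
  stopifnot(inherits(pp, "phenotype_posterior"), n_boot >= 1)
  set.seed(seed)
  nd <- nrow(pp$beta[[1]])
  pairs <- utils::combn(pp$strains, 2)
  counts <- numeric(ncol(pairs))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nd, nd, replace = TRUE)
    bpp <- pp
    bpp$beta <- lapply(pp$beta, function(m) m[idx, , drop = FALSE])
    bpp$mean <- lapply(bpp$beta, colMeans)
    bpp$cov <- lapply(bpp$beta, stats::cov)
    Hb <- hellinger_matrix(bpp, mode = mode)
    eb <- attr(similarity_network(Hb, keep_top = keep_top), "edges")
    key <- paste(eb$strain_a, eb$strain_b)
    counts <- counts + (paste(pairs[1, ], pairs[2, ]) %in% key)
  }
  data.frame(strain_a = pairs[1, ], strain_b = pairs[2, ],
             stability = counts / n_boot, stringsAsFactors = FALSE)
}

#' Eta-squared of a one-way grouping
#'
#' `SS_between / SS_total`: the proportion of total variance in `values`
#' explained by `labels`. Invariant to shifting and scaling of the values.
#'
#' @param values numeric vector.
#' @param labels grouping vector (>= 2 groups).
#' @return eta-squared in `[0, 1]`.
#' @export
eta_squared <- function(values, labels) {
  stopifnot(length(values) == length(labels), length(values) >= 2)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least two groups")
  ss_total <- sum((values - mean(values))^2)
  if (ss_total == 0) stop("zero total variance")
  gm <- tapply(values, labels, mean)
  gn <- tapply(values, labels, length)
  ss_between <- sum(gn * (gm - mean(values))^2)
  ss_between / ss_total
}

#' Posterior eta-squared distribution of the anxiety grouping per structure
#'
#' For every posterior draw and every structure, the strain coefficients
#' (mutants only; wild-type carries no anxiety annotation) are grouped by
#' anxiety label and the one-way eta-squared is computed, giving a posterior
#' distribution of the anxiety effect size per structure. Bands use the
#' conventional medium (0.06) and large (0.14) eta-squared thresholds.
#'
#' @param pp a [phenotype_posterior()].
#' @param annotation an [anxiety_annotation()].
#' @param medium,large eta-squared band thresholds.
#' @return list of class `eta_squared_distribution`: `draws`
#'   (draws x structure matrix), `summary` (data frame `structure,
#'   eta2_median, eta2_low95, eta2_high95, p_medium, p_large`).
#' @export
eta_squared_draws <- function(pp, annotation, medium = 0.06, large = 0.14) {
  stopifnot(inherits(pp, "phenotype_posterior"))
  strains <- intersect(setdiff(pp$strains, pp$reference), annotation$strain)
  if (length(strains) < 3) stop("need at least three annotated strains")
  labels <- annotation$anxiety[match(strains, annotation$strain)]
  if (length(unique(labels)) < 2) stop("need at least two anxiety labels")
  nd <- nrow(pp$beta[[1]])
  S <- length(pp$structures)
  bet <- array(unlist(pp$beta[strains], use.names = FALSE),
               c(nd, S, length(strains)))
  lab_f <- factor(labels)
  Gmat <- stats::model.matrix(~ lab_f - 1)          # strains x groups
  gn <- colSums(Gmat)
  e2 <- matrix(NA_real_, nd, S, dimnames = list(NULL, pp$structures))
  for (s in seq_len(S)) {
    v <- bet[, s, ]                                  # nd x strains
    grand <- rowMeans(v)
    gmeans <- (v %*% Gmat) / rep(gn, each = nd)
    ssb <- rowSums(sweep(gmeans, 1, grand)^2 %*% diag(gn))
    sst <- rowSums((v - grand)^2)
    # identical values across strains mean no anxiety effect, not missing
    e2[, s] <- ifelse(sst > 0, ssb / sst, 0)
  }
  qs <- apply(e2, 2, stats::quantile, probs = c(0.5, 0.025, 0.975),
              na.rm = TRUE)
  summary <- data.frame(structure = pp$structures,
                        eta2_median = qs[1, ], eta2_low95 = qs[2, ],
                        eta2_high95 = qs[3, ],
                        p_medium = colMeans(e2 >= medium, na.rm = TRUE),
                        p_large = colMeans(e2 >= large, na.rm = TRUE),
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(draws = e2, summary = summary, labels = labels,
                 strains = strains),
            class = "eta_squared_distribution")
}
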