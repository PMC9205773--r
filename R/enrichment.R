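#' Select the region of interest from a susceptibility ranking
#'
#' The ROI is the set of structures most affected across strains: either the
#' top `k` by the [structure_susceptibility()] ranking (default, k = 25 in a
#' full-scale analysis) or, with `threshold`, every structure whose median
#' absolute effect size exceeds it. Ties are already broken by structure
#' name in the ranking, so selection is deterministic.
#'
#' @param susceptibility a [structure_susceptibility()] table.
#' @param k number of structures to keep.
#' @param threshold if non-`NULL`, select by `med_abs_d > threshold` instead
#'   of top-k.
#' @return list of class `roi_definition`: `structures` (ordered), `statistic`
#'   (named selection statistic), `k`.
#' @export
select_roi <- function(susceptibility, k = 25, threshold = NULL) {
  stopifnot(is.data.frame(susceptibility),
            all(c("structure", "med_abs_d") %in% names(susceptibility)))
  tab <- susceptibility[order(-susceptibility$med_abs_d,
                              susceptibility$structure), ]
  if (is.null(threshold)) {
    if (k > nrow(tab)) stop("k exceeds the number of structures")
    sel <- tab[seq_len(k), ]
  } else {
    sel <- tab[tab$med_abs_d > threshold, ]
    if (nrow(sel) == 0) stop("no structure exceeds the threshold")
  }
  structure(list(structures = sel$structure,
                 statistic = stats::setNames(sel$med_abs_d, sel$structure),
                 k = nrow(sel)),
            class = "roi_definition")
}

#' Preferential-expression fold change
#'
#' For each gene, fold change is its unweighted mean expression over the ROI
#' structures divided by its unweighted mean over all structures of the
#' brain (the whole-brain mean includes the ROI). Genes whose whole-brain
#' mean is zero are dropped with a warning. Ranks are dense, 1 = highest
#' fold change, ties broken by gene id.
#'
#' @param em gene-by-structure expression matrix (non-negative, gene ids as
#'   row names).
#' @param roi a [select_roi()] result or character vector of structures.
#' @return data frame of class `fold_change_table`: `gene, fc, rank`,
#'   ordered by rank.
#' @export
fold_change <- function(em, roi) {
  if (inherits(roi, "roi_definition")) roi <- roi$structures
  stopifnot(length(roi) >= 1, all(roi %in% colnames(em)), all(em >= 0))
  brain_mean <- rowMeans(em)
  keep <- brain_mean > 0
  if (!all(keep)) {
    warning(sum(!keep), " gene(s) with zero whole-brain expression dropped")
    em <- em[keep, , drop = FALSE]
    brain_mean <- brain_mean[keep]
  }
  fc <- rowMeans(em[, roi, drop = FALSE]) / brain_mean
  out <- data.frame(gene = rownames(em), fc = unname(fc),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fc, out$gene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Top-n preferentially expressed genes
#'
#' The enrichment target set: the `n` genes with the highest fold change
#' (ties by gene id). `target_set_sweep()` returns the sets for several
#' sizes at once for robustness reporting; with strict ranks the sets are
#' nested.
#'
#' @param fc a [fold_change()] table.
#' @param n target-set size.
#' @return character vector of gene ids.
#' @export
target_set <- function(fc, n = 4000) {
  stopifnot(inherits(fc, "fold_change_table"))
  if (n > nrow(fc)) stop("n exceeds the number of ranked genes")
  fc$gene[seq_len(n)]
}

#' @rdname target_set
#' @param sizes target-set sizes to sweep.
#' @export
target_set_sweep <- function(fc, sizes = c(3000, 4000, 5000)) {
  stats::setNames(lapply(sizes, function(n) target_set(fc, n)),
                  as.character(sizes))
}

#' Hypergeometric gene-set enrichment
#'
#' For each term, tests whether its overlap with the target set exceeds
#' chance given the background: the upper-tail hypergeometric probability
#' of an overlap at least as large as observed, with Benjamini-Hochberg
#' FDR across terms. Terms are intersected with the background first; the
#' target must be a subset of the background.
#'
#' @param target character vector of target gene ids.
#' @param sets named list of term gene vectors (e.g. from [read_gmt()]).
#' @param background character vector of background gene ids.
#' @param min_term_size terms smaller than this (after background
#'   intersection) are skipped.
#' @return data frame of class `enrichment_result`: `term, term_size,
#'   overlap, expected, fold_enrichment, p, q`, ordered by p.
#' @export
hypergeom_enrich <- function(target, sets, background, min_term_size = 1) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background")
  target <- unique(target)
  if (!all(target %in% background)) stop("target must be within background")
  N <- length(background); n <- length(target)
  rows <- lapply(names(sets), function(term) {
    tg <- intersect(unique(sets[[term]]), background)
    K <- length(tg)
    if (K < min_term_size) return(NULL)
    ov <- length(intersect(tg, target))
    expected <- n * K / N
    p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, term_size = K, overlap = ov,
               expected = expected,
               fold_enrichment = if (expected > 0) ov / expected else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable terms")
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Kolmogorov-Smirnov comparison of term fold changes
#'
#' Two-sided two-sample KS test between the fold-change values of a term's
#' genes and those of all genes (default, the term genes included, matching
#' a term-versus-genome comparison) or of the complement. The p-value is
#' asymptotic.
#'
#' @param fc a [fold_change()] table.
#' @param term_genes character vector of gene ids.
#' @param against `"all"` (default) or `"complement"`.
#' @return list with `D`, `p`, `n_term`, `n_ref`.
#' @export
ks_compare <- function(fc, term_genes, against = c("all", "complement")) {
  against <- match.arg(against)
  stopifnot(inherits(fc, "fold_change_table"))
  in_term <- fc$gene %in% term_genes
  x <- fc$fc[in_term]
  y <- if (against == "all") fc$fc else fc$fc[!in_term]
  if (length(x) < 2 || length(y) < 2) stop("degenerate samples")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_term = length(x), n_ref = length(y))
}
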