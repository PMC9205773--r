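#' Read and write GMT gene-set files
#'
#' One record per line: `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @return [read_gmt()] returns a named list of character vectors with a
#'   `description` attribute per element; [write_gmt()] returns `path`
#'   invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT record: ", substr(ln, 1, 40))
    genes <- parts[-(1:2)]
    attr(genes, "description") <- parts[2]
    sets[[parts[1]]] <- genes
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors of gene ids.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Developmental archetype shapes evaluated at ages in postnatal days
# (embryonic timepoints get negative ages). Four canonical trajectories:
# an early postnatal peak (~P4), a mid peak (~P14), expression rising from
# ~P14, and expression rising only towards ~P56.
trajectory_archetypes <- function(age_days) {
  cbind(early_peak = exp(-((age_days - 4) / 5)^2),
        mid_peak   = exp(-((age_days - 14) / 7)^2),
        rise_mid   = stats::plogis((age_days - 14) / 4),
        rise_late  = stats::plogis((age_days - 45) / 5))
}

# "E13.5" -> -7.5 (days to birth at ~E21), "P14" -> 14
timepoint_age <- function(labels) {
  num <- as.numeric(sub("^[EP]", "", labels))
  ifelse(grepl("^E", labels), num - 21, num)
}

#' Generate a synthetic spatial and developmental expression atlas
#'
#' Emulates the inputs of a preferential-expression enrichment analysis: a
#' gene-by-structure expression matrix in which the genes of designated
#' "enriched" terms receive a multiplicative boost inside a region of
#' interest, a gene-by-timepoint developmental matrix whose trajectories are
#' noisy mixtures of exactly four archetype shapes, and a GMT gene-set
#' collection containing the enriched term(s) plus random background terms.
#'
#' @param n_genes number of genes.
#' @param structures character vector of structure (region) names.
#' @param roi_structures subset of `structures` where enrichment is planted.
#' @param enriched_term_genes named list of gene-id vectors (term -> genes);
#'   gene ids are `gene00001, ...`. May be empty.
#' @param boost multiplicative expression boost of enriched-term genes inside
#'   `roi_structures` (1 = no enrichment).
#' @param timepoints developmental timepoint labels, ordered; must include
#'   P4, P14, P28, P56 and at least one embryonic (E*) point.
#' @param n_background_sets,background_set_size random gene sets added to the
#'   GMT collection.
#' @param noise_sd SD of Gaussian noise added to the standardised archetype
#'   trajectories.
#' @param seed integer seed.
#' @return list of class `expression_atlas`: `expression` (gene x structure
#'   matrix), `development` (gene x timepoint matrix), `gene_sets` (GMT-style
#'   list), `archetype` (true archetype label per gene), `genes`.
#' @export
generate_expression_atlas <- function(n_genes, structures, roi_structures,
                                      enriched_term_genes = list(),
                                      boost = 1,
                                      timepoints = c("E13.5", "P4", "P14",
                                                     "P28", "P56"),
                                      n_background_sets = 10,
                                      background_set_size = 100,
                                      noise_sd = 0.3, seed = 1L) {
  stopifnot(n_genes >= 1, length(structures) >= 1, boost > 0)
  if (length(roi_structures) == 0) stop("empty ROI")
  if (!all(roi_structures %in% structures))
    stop("roi_structures must be a subset of structures")
  if (!all(c("P4", "P14", "P28", "P56") %in% timepoints) ||
      !any(grepl("^E", timepoints)))
    stop("timepoints must include P4, P14, P28, P56 and an embryonic point")
  genes <- sprintf("gene%05d", seq_len(n_genes))
  for (term in names(enriched_term_genes))
    if (!all(enriched_term_genes[[term]] %in% genes))
      stop("term '", term, "' contains unknown gene ids")

  set.seed(substream_seed(seed, 11))
  # baseline log-normal expression, gene-specific level, structure wobble
  level <- stats::rlnorm(n_genes, meanlog = 2, sdlog = 0.5)
  expr <- matrix(stats::rlnorm(n_genes * length(structures),
                               meanlog = 0, sdlog = 0.4),
                 n_genes, length(structures),
                 dimnames = list(genes, structures)) * level
  for (term in names(enriched_term_genes)) {
    idx <- match(enriched_term_genes[[term]], genes)
    expr[idx, roi_structures] <- expr[idx, roi_structures] * boost
  }

  set.seed(substream_seed(seed, 12))
  ages <- timepoint_age(timepoints)
  shapes <- trajectory_archetypes(ages)          # time x 4
  shapes <- scale(shapes)                        # standardised archetypes
  archetype <- sample(colnames(shapes), n_genes, replace = TRUE)
  dev <- t(shapes[, archetype, drop = FALSE]) +
    matrix(stats::rnorm(n_genes * length(timepoints), 0, noise_sd),
           n_genes, length(timepoints))
  dev <- dev - min(dev)                          # expression is non-negative
  dimnames(dev) <- list(genes, timepoints)

  set.seed(substream_seed(seed, 13))
  sets <- enriched_term_genes
  for (b in seq_len(n_background_sets)) {
    nm <- sprintf("background_set_%02d", b)
    sets[[nm]] <- sample(genes, min(background_set_size, n_genes))
  }
  structure(list(expression = expr, development = dev, gene_sets = sets,
                 archetype = stats::setNames(archetype, genes), genes = genes),
            class = "expression_atlas")
}
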