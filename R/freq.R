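#' Partial F-test for the effect of strain on one structure
#'
#' Fits the full linear model `volume ~ sex + strain + sex:strain` and
#' compares it against a reduced model by an extra-sum-of-squares F-test.
#' By default the reduced model is `volume ~ sex`, so the test assesses all
#' strain-involving terms (main effect and interaction) jointly — one "effect
#' of strain" statistic per structure. With `strain_terms = "main"` only the
#' strain main effect is tested (reduced model `volume ~ sex + sex:strain` is
#' not estimable, so the comparison is `sex + strain` vs `sex`).
#'
#' @param y numeric vector of volumes (raw or standardised) for one structure.
#' @param strain,sex factors (or character vectors) per subject.
#' @param strain_terms `"all"` (default) tests strain and sex:strain jointly;
#'   `"main"` tests the strain main effect only.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
strain_f_test <- function(y, strain, sex, strain_terms = c("all", "main")) {
  strain_terms <- match.arg(strain_terms)
  d <- data.frame(y = y, strain = factor(strain), sex = factor(sex))
  if (nlevels(d$strain) < 2) stop("need at least two strains")
  if (any(table(d$strain, d$sex) == 0))
    stop("empty strain-by-sex cell: design is rank deficient")
  full <- if (strain_terms == "all") stats::lm(y ~ sex * strain, data = d)
          else stats::lm(y ~ sex + strain, data = d)
  red <- stats::lm(y ~ sex, data = d)
  av <- stats::anova(red, full)
  list(F = av$F[2], df1 = av$Df[2], df2 = av$Res.Df[2],
       p = av$`Pr(>F)`[2])
}

#' Per-sex mutant-versus-wild-type t statistics for one structure
#'
#' Estimates, from the single full interaction model
#' `volume ~ sex * strain` (shared residual variance across all cells), the
#' mean difference of each mutant strain from the wild-type reference within
#' each sex, its standard error, t statistic and two-sided p-value. The sign
#' is positive when the mutant is larger.
#'
#' @inheritParams strain_f_test
#' @param reference wild-type strain label, present in both sexes.
#' @return data frame with columns `strain`, `sex`, `estimate`, `se`, `t`,
#'   `df`, `p`.
#' @export
mutant_t_stats <- function(y, strain, sex, reference) {
  strain <- as.character(strain); sex <- as.character(sex)
  if (!reference %in% strain) stop("reference strain absent")
  if (length(unique(sex[strain == reference])) < 2)
    stop("reference strain must be present in both sexes")
  d <- data.frame(y = y,
                  strain = stats::relevel(factor(strain), ref = reference),
                  sex = factor(sex, levels = c("F", "M")))
  if (any(table(d$strain, d$sex) == 0))
    stop("empty strain-by-sex cell: design is rank deficient")
  fit <- stats::lm(y ~ sex * strain, data = d)
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  df <- fit$df.residual
  mutants <- setdiff(levels(d$strain), reference)
  rows <- lapply(mutants, function(m) {
    main <- paste0("strain", m)
    inter <- paste0("sexM:strain", m)
    out <- lapply(c(F = 0, M = 1), function(male) {
      cvec <- stats::setNames(numeric(length(beta)), names(beta))
      cvec[main] <- 1
      if (male) cvec[inter] <- 1
      est <- sum(cvec * beta)
      se <- sqrt(drop(t(cvec) %*% V %*% cvec))
      data.frame(strain = m, sex = if (male) "M" else "F",
                 estimate = est, se = se, t = est / se, df = df,
                 p = 2 * stats::pt(-abs(est / se), df),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper around
#' [stats::p.adjust()] with input validation.
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NA` is an error.
#' @return vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p)) stop("NA p-values")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Structure-wise frequentist analysis of a volume table
#'
#' Runs [strain_f_test()] and [mutant_t_stats()] for every structure and
#' attaches FDR q-values. The FDR families are: one family across structures
#' for the F-tests, and one family across all structure-by-strain-by-sex
#' contrasts for the t-tests (the most conservative plausible grouping; set
#' `t_family = "per_structure"` to adjust within structure instead).
#' Significance flags mark q below 5% and below 0.01%, the two display
#' thresholds conventionally used for such maps.
#'
#' @param vt a [volume_table()] (raw or standardised).
#' @param strain_terms passed to [strain_f_test()].
#' @param t_family `"global"` or `"per_structure"` FDR family for contrasts.
#' @return list of class `freq_result` with data frames `f_tests`
#'   (`structure,F,df1,df2,p,q`) and `t_tests`
#'   (`structure,strain,sex,estimate,se,t,p,q,sig_fdr5,sig_fdr01pct`).
#' @export
freq_analysis <- function(vt, strain_terms = "all",
                          t_family = c("global", "per_structure")) {
  t_family <- match.arg(t_family)
  stopifnot(inherits(vt, "volume_table"))
  ref <- wildtype_strain(vt)
  vm <- volume_matrix(vt)
  fs <- lapply(colnames(vm), function(s) {
    r <- strain_f_test(vm[, s], vt$strain, vt$sex, strain_terms = strain_terms)
    data.frame(structure = s, F = r$F, df1 = r$df1, df2 = r$df2, p = r$p,
               stringsAsFactors = FALSE)
  })
  f_tests <- do.call(rbind, fs)
  f_tests$q <- bh_fdr(f_tests$p)
  ts <- lapply(colnames(vm), function(s) {
    r <- mutant_t_stats(vm[, s], vt$strain, vt$sex, reference = ref)
    cbind(structure = s, r)
  })
  t_tests <- do.call(rbind, ts)
  if (t_family == "global") {
    t_tests$q <- bh_fdr(t_tests$p)
  } else {
    t_tests$q <- stats::ave(t_tests$p, t_tests$structure, FUN = bh_fdr)
  }
  t_tests$sig_fdr5 <- t_tests$q < 0.05
  t_tests$sig_fdr01pct <- t_tests$q < 1e-4
  rownames(t_tests) <- NULL
  structure(list(f_tests = f_tests, t_tests = t_tests, reference = ref),
            class = "freq_result")
}

#' Monte-Carlo power of a two-group volume comparison
#'
#' Simulates a wild-type and a mutant group of `n_per_cell` animals each,
#' with volumes normally distributed around a unit base volume with relative
#' SD `cv` and the mutant mean shifted by `effect_pct` percent, and reports
#' the fraction of simulations in which a two-sample t-test rejects at level
#' `alpha`. This is the design-stage computation behind choosing a sample
#' size to detect a given percentage volume change.
#'
#' @param effect_pct percentage volume change in the mutant group
#'   (e.g. 4 for a 4% larger structure); must exceed -100.
#' @param alpha type-I error level.
#' @param n_per_cell animals per group.
#' @param cv coefficient of variation of volumes within a group.
#' @param n_sims number of simulated experiments (>= 100).
#' @param seed integer seed.
#' @return list of class `power_estimate`: `power`, `mc_se`
#'   (`sqrt(p(1-p)/n_sims)`), plus the inputs.
#' @export
power_simulation <- function(effect_pct, alpha = 0.05, n_per_cell = 15,
                             cv = 0.05, n_sims = 1000, seed = 1L) {
  stopifnot(effect_pct > -100, cv > 0, n_sims >= 100, n_per_cell >= 2)
  set.seed(seed)
  rej <- vapply(seq_len(n_sims), function(i) {
    wt <- stats::rnorm(n_per_cell, 1, cv)
    mut <- stats::rnorm(n_per_cell, 1 + effect_pct / 100, cv)
    stats::t.test(mut, wt)$p.value < alpha
  }, logical(1))
  power <- mean(rej)
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / n_sims),
                 effect_pct = effect_pct, alpha = alpha,
                 n_per_cell = n_per_cell, cv = cv, n_sims = n_sims,
                 seed = seed),
            class = "power_estimate")
}
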