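# one small fit shared across blocks (structural checks; precision tests
# live in the acceptance suite)
shared_fit <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      coh <- small_cohort(seed = 21, n_structures = 6, n_per_cell = 4)
      sv <- standardise_volumes(coh$volumes)
      val <<- list(cohort = coh,
                   pd = suppressWarnings(fit_bhm(sv, tiny_bhm_spec())))
    }
    val
  }
})

test_that("fit_bhm returns a complete, internally consistent posterior", {
  f <- shared_fit()
  pd <- f$pd
  expect_s3_class(pd, "posterior_draws")
  nd <- 2 * 150
  expect_length(pd$draws$mu, nd)
  expect_equal(dim(pd$draws$dstr), c(nd, 5, 6))   # strains x structures
  expect_true(all(pd$draws$sig_e > 0))
  expect_true(all(pd$draws$sig_a > 0))
  expect_identical(pd$strains[1], "WT")
  # reference strain carries no effect
  expect_true(all(pd$draws$dstr[, 1, ] == 0))
  expect_true(all(pd$draws$bstr[, 1] == 0))
  # diagnostics table covers the monitored scalars
  expect_true(all(c("rhat", "ess") %in% names(pd$diagnostics)))
  expect_true(all(is.finite(pd$diagnostics$rhat)))
})

test_that("fit_bhm refuses unstandardised input and degenerate designs", {
  coh <- small_cohort(seed = 22)
  expect_error(fit_bhm(coh$volumes, tiny_bhm_spec()), "standardised")
})

test_that("seeded fits are reproducible", {
  coh <- small_cohort(seed = 23, n_structures = 4, n_per_cell = 3)
  sv <- standardise_volumes(coh$volumes)
  spec <- bhm_spec(chains = 1, draws = 50, warmup = 100, adapt = 100,
                   thin = 1, seed = 42)
  p1 <- suppressWarnings(fit_bhm(sv, spec))
  p2 <- suppressWarnings(fit_bhm(sv, spec))
  expect_identical(p1$draws$bstr, p2$draws$bstr)
  expect_identical(p1$draws$sig_e, p2$draws$sig_e)
})

test_that("effect-size draws apply the d formula exactly", {
  # two strains (ref + one mutant), two structures, two draws with known values
  pd <- fake_posterior(
    bstr = cbind(0, c(0.8, 0.6)), bint = cbind(0, c(0.4, 0.2)),
    dstr = array(c(rep(0, 4), 0, 0, 0.1, -0.1), c(2, 2, 2)),
    dint = array(0, c(2, 2, 2)),
    sig_e = c(1, 2), structures = c("sA", "sB"), strains = c("WT", "mut"))
  esd <- effect_size_draws(pd)
  # draw 1: strain effect 0.8 (+dev 0), interaction 0.4, sigma 1
  expect_equal(esd$d[1, "sA", "mut", "F"], 0.8)
  expect_equal(esd$d[1, "sA", "mut", "M"], 1.2)
  # draw 2: (0.6 + 0.1)/2 female, (0.6 + 0.1 + 0.2)/2 male on structure B...
  expect_equal(esd$d[2, "sB", "mut", "F"], (0.6 - 0.1) / 2)
  expect_equal(esd$d[2, "sB", "mut", "M"], (0.6 - 0.1 + 0.2) / 2)
  # reference strain identically zero
  expect_true(all(esd$d[, , "WT", ] == 0))
  # unit denominator skips the sigma division
  esd_u <- effect_size_draws(pd, denominator = "unit")
  expect_equal(esd_u$d[2, "sB", "mut", "F"], 0.6 - 0.1)
})

test_that("prob_large_effect counts draws and is monotone in the threshold", {
  pd <- fake_posterior(
    bstr = cbind(0, c(-2, 0, 2, 0.5)), bint = cbind(0, rep(0, 4)),
    dstr = array(0, c(4, 2, 1)), dint = array(0, c(4, 2, 1)),
    sig_e = rep(1, 4), structures = "sA", strains = c("WT", "mut"))
  esd <- effect_size_draws(pd)
  tab <- prob_large_effect(esd, threshold = 1)
  expect_equal(tab$p_large[tab$strain == "mut" & tab$sex == "F"], 0.5)
  expect_equal(tab$p_large[tab$strain == "WT" & tab$sex == "F"], 0)
  t0 <- prob_large_effect(esd, 0.4)$p_large
  t1 <- prob_large_effect(esd, 1)$p_large
  t2 <- prob_large_effect(esd, 3)$p_large
  expect_true(all(t1 <= t0) && all(t2 <= t1))
  # tight posteriors have essentially no mass past 1
  pdn <- fake_posterior(
    bstr = cbind(0, rnorm(500, 0, 0.1)), bint = cbind(0, rep(0, 500)),
    dstr = array(0, c(500, 2, 1)), dint = array(0, c(500, 2, 1)),
    sig_e = rep(1, 500), structures = "sA", strains = c("WT", "mut"))
  p <- prob_large_effect(effect_size_draws(pdn))$p_large
  expect_true(all(p < 0.001))
})

test_that("structure susceptibility ranks by median |d| with deterministic ties", {
  nd <- 200
  set.seed(4)
  dstr <- array(0, c(nd, 2, 2))
  dstr[, 2, 1] <- rnorm(nd, 0, 0.05)      # structure quiet: tiny effects
  dstr[, 2, 2] <- rnorm(nd, 2, 0.05)      # structure loud: large effects
  pd <- fake_posterior(bstr = cbind(0, rep(0, nd)), bint = cbind(0, rep(0, nd)),
                       dstr = dstr, dint = array(0, c(nd, 2, 2)),
                       sig_e = rep(1, nd), structures = c("quiet", "loud"),
                       strains = c("WT", "mut"))
  esd <- effect_size_draws(pd)
  susc <- structure_susceptibility(esd)
  expect_equal(susc$structure[1], "loud")
  expect_equal(susc$rank, 1:2)
  # matches a brute-force recomputation from the raw draws
  brute <- median(apply(abs(esd$d[, "loud", "mut", , drop = FALSE]), c(2, 3, 4),
                        median))
  expect_equal(susc$med_abs_d[1], brute)
})

test_that("phenotype posterior averages sexes and zeroes the reference", {
  f <- shared_fit()
  pp <- phenotype_posterior(f$pd, min_draws = 10)
  expect_true(all(pp$beta$WT == 0))
  esd <- effect_size_draws(f$pd, denominator = "unit")
  manual <- (esd$d[, , "strain01", "F"] + esd$d[, , "strain01", "M"]) / 2
  expect_equal(pp$beta$strain01, manual)
  expect_error(phenotype_posterior(f$pd, min_draws = 1e6), "draws")
})
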