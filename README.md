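# phenoscape

Neuroanatomical endophenotype analysis for cohorts of mutant mouse strains.

Structural imaging of many genetically engineered lines — for example, mice
each lacking a different immune-system component — produces a
subject-by-structure table of brain volumes whose strain effects are
individually noisy and collectively heterogeneous. `phenoscape` implements
the statistical chain that extracts pattern from that heterogeneity, for
researchers analysing multi-strain morphometry studies:

- **Per-structure frequentist tests** — the linear model
  `volume ~ sex + strain + sex:strain` with a partial F-test of all
  strain-involving terms, per-strain/per-sex contrasts against pooled
  wild-type, Benjamini–Hochberg FDR, and a power simulator for the
  percentage-volume-change design question.
- **A Bayesian hierarchical model** of Z-scored volumes,

  y<sub>is</sub> = μ + a<sub>i</sub> + (β<sup>sex</sup> + b<sup>sex</sup><sub>s</sub>)x<sub>i</sub> + (β<sup>strain</sup><sub>k</sub> + b<sup>strain</sup><sub>ks</sub>) + (β<sup>int</sup><sub>k</sub> + b<sup>int</sup><sub>ks</sub>)x<sub>i</sub> + ε<sub>is</sub>,

  with a per-animal intercept shared across structures and jointly
  multivariate-normal structure-specific deviations, sampled by Gibbs (JAGS)
  with a built-in convergence gate (split R-hat ≤ 1.05, ESS ≥ 100). The
  posterior yields effect-size (*d*) distributions per structure, strain and
  sex, the probability of |*d*| > 1, and a susceptibility ranking of
  structures.
- **Endophenotype clustering** — closed-form Gaussian Hellinger distances
  between strains' posterior effect-vector distributions, a similarity
  network, a label-permutation test of whether strains sharing an anxiety
  phenotype have closer neuroanatomy (with an exact enumeration mode), and
  posterior η² distributions of the anxiety grouping per structure.
- **Expression enrichment** — ROI selection from the susceptibility ranking,
  preferential-expression fold change (ROI mean over whole-brain mean),
  top-n target sets, hypergeometric gene-set enrichment with FDR, KS
  comparison, and k-means clustering of developmental trajectories with a
  log-curvature elbow rule.
- **A seeded synthetic-data generator** for cohorts, anatomies, expression
  atlases and gene sets with known ground truth, so the whole chain can be
  calibrated and verified without access to restricted imaging data.

See `vignettes/immune-neuroanatomy-methods.Rmd` for the model details,
numerical choices and limitations.

## Worked example

```r
library(phenoscape)

# 1. a synthetic nine-strain cohort (3 anxiety labels x 3 strains)
cohort <- generate_cohort(cohort_config(n_strains = 9, seed = 42))
regions <- sapply(cohort$tree$children, `[[`, "name")
volumes <- aggregate_to_regions(cohort$volumes, cohort$tree, regions)
sv <- standardise_volumes(volumes)
sv
#> volume_table: 160 subjects x 10 structures (standardised)
#>   strains: strain01, ..., strain09, WT (wild-type: WT)

# 2. per-structure frequentist tests
freq <- freq_analysis(sv)
head(freq$f_tests, 3)
#>   structure         F df1 df2            p            q
#> 1  region01  1.229072  18 140 2.462152e-01 2.462152e-01
#> 2  region02  4.745373  18 140 4.020851e-08 6.701418e-08
#> 3  region03 10.612522  18 140 2.165489e-18 7.218297e-18

# 3. Bayesian hierarchical model and effect sizes
fit <- fit_bhm(sv, bhm_spec(chains = 2, draws = 500, warmup = 2000,
                            thin = 20, seed = 1))
fit
#> posterior_draws: 1000 draws (2 chains), 10 strains, 10 structures
#>   converged: TRUE (max R-hat 1.017, min ESS 141)
esd <- effect_size_draws(fit)
head(structure_susceptibility(esd), 3)
#>   structure med_abs_d max_p_large rank
#> 1  region03 0.8662604       0.990    1
#> 2  region06 0.8297047       0.991    2
#> 3  region04 0.7366148       0.988    3

# 4. endophenotype distances and the anxiety permutation test
pheno <- phenotype_posterior(fit)
H <- hellinger_matrix(pheno)
ann <- anxiety_annotation(cohort$annotation$strain, cohort$annotation$anxiety)
anxiety_permutation_test(H, ann, n_iter = 1e4, seed = 2)
#> permutation test (between-minus-within, Monte-Carlo):
#>   Delta_obs = 0.0650, p = 0.0038 (10000 iterations)
head(eta_squared_draws(pheno, ann)$summary[, 1:4], 3)
#>   structure eta2_median eta2_low95 eta2_high95
#> 1  region01   0.7051408  0.2847762   0.9283822
#> 2  region02   0.4952915  0.2120780   0.7665556
#> 3  region03   0.9335529  0.8334274   0.9822746
```

Reading the output: region03 is both the most strain-susceptible structure
(median posterior |d| ≈ 0.87, with ~99% posterior probability of a large
effect in at least one strain-sex cell) and the one whose strain effects
separate most cleanly by anxiety label (posterior median η² ≈ 0.93). The
permutation p of 0.0038 says that strains annotated with the same anxiety
phenotype have systematically closer endophenotypes than relabelled nulls —
the cohort was generated with within-label effect correlation 0.9, which is
exactly the signal this test should find. F-tests in step 2 flag the same
structures from the frequentist side; region01, generated with weak effects
at this seed, is correctly left unflagged (q ≈ 0.25).

`run_pipeline(pipeline_config(...), out_dir)` chains all stages (simulate →
aggregate → standardise → frequentist → BHM → distances/permutation/η² →
ROI → enrichment → trajectory clustering) and writes tidy CSV/JSON outputs
plus a manifest with per-stage timings and file checksums. A thin
command-line wrapper over these functions is installed at
`inst/scripts/phenoscape` (`phenoscape simulate|run-all --seed N --out DIR
[--config FILE]`).

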