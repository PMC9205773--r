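---
title: "Methods: linking mutant-mouse neuroanatomy to anxiety phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking mutant-mouse neuroanatomy to anxiety phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cohorts of genetically engineered mouse strains — here, lines each lacking a
different component of the immune system — show heterogeneous changes in
regional brain volume. `phenoscape` implements the statistical chain that
turns a subject-by-structure volume table into interpretable structure: which
structures are affected (per-structure tests and posterior effect sizes),
whether strains sharing a behavioural phenotype share a neuroanatomical
endophenotype (Hellinger distances and a label-permutation test), and whether
the most-affected regions preferentially express biologically coherent gene
sets (fold-change scoring with hypergeometric enrichment and developmental
trajectory clustering).

Because the imaging data such studies rest on are typically restricted, the
package ships a seeded synthetic-data generator that emulates the study
design, so every stage can be exercised, calibrated and power-checked, and
parameter recovery can be verified against known ground truth.

## Frequentist per-structure analysis

For each structure, the volume is fit by the linear model
`volume ~ sex + strain + sex:strain`. The "effect of strain" is a partial
F-test of all strain-involving terms jointly against the reduced model
`volume ~ sex` (a flag restricts this to the strain main effect). Per-strain,
per-sex contrasts against the pooled wild-type group come from the same full
model, so they share one residual-variance estimate across cells; this gives
them more degrees of freedom than per-sex refits would. Benjamini–Hochberg
FDR is applied in two families — across structures for the F-tests, and
across all structure-by-strain-by-sex contrasts for the t-tests. This is the
most conservative plausible family definition; a per-structure family is
available by argument. Output tables carry flags at q < 0.05 and q < 1e-4,
the two display thresholds conventionally used for such maps.

`power_simulation()` reproduces the design-stage sample-size reasoning: two
groups of `n_per_cell` animals with a configurable coefficient of variation,
one shifted by a percentage volume change, tested by a two-sample t-test.

## The Bayesian hierarchical model

Volumes are Z-scored per structure (sample SD, `n − 1` denominator, pooled
over all animals; group structure enters only through the model). The default
is to standardise after reducing left/right leaf structures to bilateral
regions via the anatomical hierarchy; a flag allows standardising before
reduction, since the order is a genuinely open choice.

The model for the standardised volume of animal $i$, structure $s$ is

$$y_{is} = \mu + a_i + (\beta^{sex} + b^{sex}_s)x_i +
(\beta^{strain}_{k(i)} + b^{strain}_{k(i),s}) +
(\beta^{int}_{k(i)} + b^{int}_{k(i),s})x_i + \varepsilon_{is}$$

with $x_i$ indicating the non-reference sex (reference: female),
$a_i \sim N(\mu, \sigma_a^2)$ a single per-animal intercept shared across all
structures (a brain-size-like nuisance — the only reading of an
"individual-specific intercept" that is coherent in a multi-structure model),
and $\varepsilon_{is} \sim N(0, \sigma_\varepsilon^2)$. The wild-type
reference strain has all strain and interaction terms fixed at zero, so
strain coefficients are directly deviations from wild-type. The
structure-specific deviation vector of each structure (one sex slot, strain
and interaction slots for every mutant) is jointly multivariate normal with
estimated scales and correlations across coefficient types; correlations are
estimated within structure across coefficient slots, which is the default
resolution of the ambiguity about what the correlation structure spans.

**Priors.** Normal(0, 1) on global coefficients; half-Normal(0, 1) on
$\sigma_a$ and $\sigma_\varepsilon$; a Wishart prior on the precision of the
deviation vector with identity scale and $P + 1 + c$ degrees of freedom,
where $P$ is the deviation dimension and the concentration $c$ (default 2)
plays the role of an LKJ-style concentration: larger $c$ pulls the implied
correlations towards zero. All prior scales are arguments of `bhm_spec()`.

**Sampling and convergence.** The model is sampled by Gibbs updates (JAGS).
Two numerical choices matter. First, the model is *centred*: the
structure-specific totals are drawn around the global coefficients, and the
animal intercepts around the global mean. The mathematically equivalent
zero-centred deviation form mixes pathologically for the global coefficients
(split R-hat above 1.2 in our checks), because global terms and deviation
means trade off along a soft likelihood mode. Second, chains are thinned
(default: keep every 15th iteration, 4 chains × 500 retained draws, warmup
1000): the conjugate updates are strongly autocorrelated, and undiluted
chains of this length fail the package's own convergence contract. That
contract — split R-hat ≤ 1.05 and effective sample size ≥ 100 for every
monitored scalar — is computed on every fit; a failing fit is returned with
`converged = FALSE` and a warning, and the pipeline refuses to continue
unless explicitly told to.

**Effect sizes.** Per draw, the effect size of strain $k$ in structure $s$
and sex $x$ is the expected standardised volume difference from wild-type
divided by that draw's $\sigma_\varepsilon$, so $d$ is expressed in
within-group SD units. The source text never defines $d$'s denominator; the
raw-coefficient alternative (`denominator = "unit"`) is kept available.
`prob_large_effect()` integrates the posterior mass outside $\pm 1$, and
`structure_susceptibility()` ranks structures by the median (over mutant
strains and sexes) of the posterior median $|d|$, ties broken by structure
name so ROI selection is reproducible.

## Endophenotype comparison and the anxiety grouping

A strain's endophenotype is its vector of structure coefficients referenced
to wild-type. Females and males are averaged per draw by default — the source
text does not state sex handling here, and averaging is the symmetric choice;
per-sex modes exist. Pairwise dissimilarity uses the Hellinger distance
between Gaussian approximations of the posterior. The default mode
(`joint-diagonal`) multiplies per-structure one-dimensional Bhattacharyya
coefficients, i.e. the joint Gaussian formula under diagonal covariance: with
~10–95 structures and a few thousand draws, a full covariance estimate is
unstable, so the full-covariance mode applies shrinkage towards a scaled
identity (weight 0.1) plus a 1e-8 diagonal jitter. A mean-marginal mode
(mean of per-structure distances) is also provided. The wild-type posterior
is a point mass at zero, so its distance to any strain with a proper
posterior is ~1; wild-type is excluded from the anxiety analyses, which only
ever see annotated mutant strains.

The permutation test asks whether strains sharing an anxiety label are
closer: $\Delta$ = mean between-label distance − mean within-label distance,
with the null built by relabelling strains (label counts preserved) and the
one-sided add-one-corrected p-value $(1 + \#\{\Delta_{perm} \ge
\Delta_{obs}\})/(1 + n_{iter})$, ties counting against rejection. Because
label counts are preserved, the within-pair set is never empty when it is
non-empty for the observed labels. An exhaustive mode enumerates all
distinct label arrangements for exact p-values on small strain sets.

**Granularity.** The statistic depends on labels only through the partition
they induce. Six strains in three pairs admit just 15 distinct partitions,
so the smallest attainable p-value is 1/15 ≈ 0.067 — no data can reject at
α = 0.05 at that size. Group-label inference at conventional levels needs
roughly nine or more strains (nine strains in three triples give 280
partitions; eleven strains with a 4/4/3 split, the emulated full design,
give 5775). The package's calibration and power studies therefore run at
nine and eleven strains; the scaled-down six-strain default remains
appropriate for every other stage.

Per structure, the anxiety effect size is the posterior η² distribution:
for each draw, the one-way η² (SS between / SS total) of the mutant strain
coefficients grouped by anxiety label, with conventional medium (0.06) and
large (0.14) bands. Draws where all strain coefficients coincide contribute
η² = 0 (no group effect) rather than a missing value.

## Expression enrichment over the most-affected regions

The ROI is the top-k structures (k = 25 at full scale) of the susceptibility
ranking; a threshold rule (`med_abs_d > 1`) is provided because the source
describes the selection both ways and the two coincided there. Per gene,
preferential expression is the unweighted mean over ROI structures divided by
the unweighted mean over *all* structures — the whole-brain mean includes the
ROI, the literal reading of "relative to the brain". The target set is the
top-n genes by fold change (n = 4000 at full scale; a sweep over
3000/4000/5000 supports robustness reporting). Term enrichment is the
upper-tail hypergeometric probability of the observed overlap, BH-corrected
across terms; distributional shift is a two-sided two-sample KS test of term
genes against all genes (against the complement by flag).

Developmental trajectories are Z-scored per gene (raw mode by flag), then
clustered by k-means (10 restarts) over k = 2..8. The elbow picks the
interior k with maximum curvature of log within-cluster SS — the point where
the *relative* decrease flattens most sharply. Working on the log scale makes
the rule invariant to overall SS magnitude; a chord-distance rule fails when
the first drops dwarf the true elbow, and no endpoint of the scanned range
can ever be selected, so the range must bracket the expected k from below.
Cluster representatives are the members nearest their centroid, ties broken
by gene id.

## The synthetic cohort generator

`generate_cohort()` emulates the study design: mutant strains plus one
pooled wild-type group, balanced male/female cells, and per-structure volumes
driven by a latent standardised predictor
$\eta = \text{strain} + \text{sex}\cdot x + \text{interaction}\cdot x +
a_i + \varepsilon$ in residual-SD units. Strain effect vectors are drawn from
a block-correlated multivariate normal: correlation `within_group_corr`
(default 0.9) for strains sharing an anxiety label, zero across labels — the
premise that behaviourally similar strains have similar neuroanatomy, which
the downstream clustering is meant to detect. Volumes are
$base_s \exp(cv\,\eta)$ by default, keeping them positive and roughly
log-normal; an additive form $base_s(1 + cv\,\eta)$ exists so that the latent
predictor can be recovered *exactly* (`cohort_latent_table()`), which is the
pathway used for parameter-recovery studies: data on that scale follow the
hierarchical model exactly and posterior estimates are directly comparable to
the stored ground truth.

Default dimensions are scaled down for speed — 6 strains, 20 leaf structures
(10 bilateral regions), 8 mice per strain-by-sex cell — against the emulated
full design of 11 strains, ~15 per cell and 336 leaves reducing to 95
regions, which remains available by configuration. Effect scales default to
1 residual-SD for strain effects (large effects, matching a regime where
several structures exceed $|d| = 1$), 0.5 for sex, 0.2 for interactions, 0.3
for animal intercepts; the per-structure coefficient of variation defaults to
0.05 with base volumes log-spaced over 0.5–20 mm³. These are placeholders for
quantities the source does not report and are all configuration-exposed.
Separate RNG substreams drive effects, intercepts and noise, so enlarging the
cohort does not perturb the true effect vectors. What the generator does
*not* emulate: registration/segmentation error, allometric scaling,
left–right asymmetry structure, non-Gaussian residuals, or unbalanced cells —
so green tests here demonstrate correctness of the statistical machinery
under its own assumptions, not robustness to real-data pathologies.

The expression-atlas generator plants a configurable multiplicative boost of
designated term genes inside an ROI on a log-normal baseline, and builds
developmental trajectories as noisy copies of exactly four archetypes (an
early postnatal peak near P4, a mid peak near P14, a rise from P14, and a
late rise towards P56) over timepoints that must include one embryonic point
and P4/P14/P28/P56.

## Problem sizes and what the checks compute

The test-suite and the acceptance script (`scripts/acceptance.R`) recompute,
from scratch at fixed seeds: BHM parameter recovery (6 strains × 2 sexes ×
8 per cell × 20 structures on the model-scale pathway; RMSE and 95% CI
coverage over the 120 sex-averaged strain-by-structure effects); frequentist
agreement with a projection-matrix least-squares oracle (100 random small
designs) and the type-I rate over 2000 null structures; closed-form Gaussian
Hellinger against numerical integration of $\sqrt{pq}$ (including the 1-D
worked values $H^2 = 1 - e^{-1/8}$ and $1 - \sqrt{4/5}$); Monte-Carlo versus
exhaustive permutation p-values, the type-I rate over 200 exchangeable-label
replicates at nine strains, and rejection power over ten simulated cohorts
at nine strains; exact η²/hypergeometric/BH values; elbow and membership
recovery of the four trajectory archetypes; and an end-to-end eleven-strain
run in which genes planted in the truly most-affected structures must come
out enriched and the anxiety permutation test must reject. At these sizes
the whole suite runs in well under half an hour on one CPU.

One check is known to sit at the edge of what the design can deliver: with
8 animals per cell and strain effects as large as the residual SD, the
posterior RMSE of a sex-averaged strain-by-structure effect is ~0.25–0.27
SD-units across seeds — the sampling-noise floor of a 16-vs-16 contrast
after shrinkage — so a 0.25 RMSE bound is met or missed by hair's breadth
depending on the seed, while CI coverage sits comfortably near 0.95.

## Known limitations

- A single residual SD is shared across structures. After Z-scoring data in
  which strain effects contribute a large, structure-varying share of the
  variance, the true residual scale differs across structures; the shared
  $\sigma_\varepsilon$ then misstates per-structure uncertainty. This is a
  property of the model as specified, visible in the generator's
  multiplicative pathway at large effect scales.
- The Wishart prior couples deviation scales and correlations; with few
  structures the cross-strain correlations that the generator plants are
  only partially recovered, costing some pooling efficiency.
- The permutation test's resolution is bounded by the number of distinct
  label partitions (see above).
- Hellinger distances rest on Gaussian approximations of the posterior;
  heavy-tailed or multimodal posteriors would need the bootstrap variant
  (`network_edge_stability()`) or more draws.
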