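---
title: "Tripartite microbe-brain-phenotype networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tripartite microbe-brain-phenotype networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripnet)
library(dplyr)
```

`tripnet` integrates three subject-level data blocks — gut genus relative
abundances, regional centrality of a functional brain network, and GI
sensorimotor phenotypes — into group-specific association networks and a
between-group difference network. This vignette explains the statistical
model, the choices behind every tunable parameter, what the synthetic cohort
generator does and does not emulate, and the numerical details a user or
reviewer would want to audit.

## The association model

All inference is pairwise and rank-based. For a variable pair $(x, y)$
within one group of $n$ subjects, the package computes an *adjusted Spearman
correlation*: both variables are converted to average ranks, each rank
vector is residualised by least squares against the covariate design
$(1, \text{age}, \text{sex})$, and the Pearson correlation $r$ of the
residuals is taken. With an intercept-only design this is exactly Spearman's
$\rho_s$. The within-group p-value uses
$t = r\sqrt{n - 2 - k}\,/\sqrt{1 - r^2}$ with $k$ adjusted covariates.
Rank-basedness buys invariance to any strictly increasing transform of any
single variable — important because abundances are compositional fractions,
centralities live on arbitrary scales, and several phenotypes (AUC measures)
are strongly right-skewed. The cost is attenuation: a latent (Pearson)
correlation $\rho$ maps to a population Spearman value
$\rho_s = \tfrac{6}{\pi}\arcsin(\rho/2)$ under a Gaussian copula
(`pearson_to_spearman()`), about 4% smaller at moderate $\rho$.

Groups are contrasted with the Fisher r-to-z difference test,

$$ z = \frac{\operatorname{atanh}(r_{\mathrm{IBS}}) - \operatorname{atanh}(r_{\mathrm{HC}})}
          {\sqrt{1/(n_{\mathrm{IBS}}-3) + 1/(n_{\mathrm{HC}}-3)}}, $$

oriented so positive $z$ means the IBS correlation exceeds the HC one. Edges
with two-sided $p < \alpha$ form the difference network; edges significant
within a group form that group's network. The default $\alpha = 0.05$ is
deliberately uncorrected: the design is hypothesis-generating, and the
companion sensitivity analysis (below) makes the implied effect-size floor
explicit. Benjamini-Hochberg correction is available through
`build_network(p_adjust = "BH")` for reuse in confirmatory settings.

### Calibration and the variance convention

The classic $1/(n-3)$ variance in the $z$ denominator ignores two things:
the degrees of freedom consumed by residualising on $k$ covariates, and the
extra dispersion of the Fisher transform of a rank correlation. At the
default group sizes (21 and 65) this matters: simulating null cohorts
(~5,600 independent edges) the classic test rejects at about 6.3% rather
than 5%. `correlate_all(var_adjust = "df_penalty")` switches the variance to
$1/(n-3-k)$, which restores the empirical rate to ~5.1%, inside the 99%
binomial interval. The classic convention remains the default because it is
the test the publication-style analysis performs; the calibrated option is
one argument away, and the acceptance suite pins down both behaviours.

`analytic_difference_power()` is the closed-form companion used by the power
tests: it attenuates the latent correlations to the Spearman scale, models
the true sampling variance of each group's transformed correlation as
$1.06/(n-3-k)$ (the Fieller-David inflation for Spearman's $z$, plus the
covariate degrees of freedom), and keeps the classic scaling in the test
statistic, mirroring the pipeline exactly. Against 4,000-replicate
simulations at $\Delta\rho \in \{0.3, 0.5, 0.7\}$ this approximation is
accurate to about half a percentage point.

## Brain graph construction and centrality

Per-subject connectivity matrices (symmetric, entries in $[-1, 1]$, unit
diagonal) become weighted undirected graphs by zeroing negative weights and
the diagonal (`build_functional_network()`). Negative functional couplings
are discarded rather than modelled — the standard choice for weighted
connectome metrics, which are defined for non-negative weights. Three
regional centralities are computed on the whole graph and then restricted to
the regions of interest:

* **Degree strength** `S`: row sums of the weight matrix.
* **Betweenness** `B`: weighted shortest-path betweenness with edge length
  $1/w$ (stronger coupling = shorter path), fractional counting over tied
  shortest paths, reported as raw unordered-pair counts. A $-\log(w)$ length
  (multiplicative path strength) is available via `distance = "neglog"`;
  because downstream inference is rank-based, any monotone normalisation of
  betweenness leaves every correlation unchanged, so the raw count default
  simply eases oracle testing. Normalised counts
  ($\times\,2/((n-1)(n-2))$) are an option.
* **Eigenvector** `E`: principal eigenvector of the non-negative weight
  matrix, computed by power iteration on the shifted matrix $W + I$ (the
  shift makes the dominant eigenvalue strictly largest in magnitude, so the
  iteration cannot oscillate on bipartite components), normalised to unit
  Euclidean norm with the largest-magnitude entry positive. On disconnected
  graphs this is the principal eigenvector of the full matrix, i.e. mass
  concentrates on the dominant component. Convergence tolerance 1e-14 on
  the iterate, far inside the 1e-8 oracle tolerance used in tests. An
  all-zero graph is an error, not a silent zero vector.

Features are labelled `X_Y_Z` (metric, laterality `L`/`R`, region
abbreviation from `roi_table()` — putamen `Pu`, caudate `CaN`, accumbens
`NAcc`, thalamus `Tha`, postcentral gyrus `PosCG`, and so on). Matrix region
labels are expected as `<abbr>_L` / `<abbr>_R`, or a bare abbreviation for
midline structures.

## Genus selection and missingness

The microbe block is restricted to a fixed panel (`genus_panel()`): nine
genera of the families Ruminococcaceae and Lachnospiraceae, chosen a priori
for their role in host serotonin modulation. A genus is excluded when its
fraction of missing values is *strictly greater than* 0.80 in either group;
exactly 80% is retained. "Missing" means recorded as 0 or absent, the
natural semantics for amplicon genus tables where 0 encodes non-detection;
`missing = "na_only"` switches to literal-NA semantics. Abundances are used
as provided — relative to the whole community — and are *not* renormalised
after panel selection, because the scientific quantity is the genus's share
of the full community, not of the panel; ranks downstream make the point
largely moot. No CLR or other compositional transform is applied, again
because rank-based inference absorbs monotone transforms.

## Cohort statistics

`cohort_report()` reproduces the usual case-control summary: per variable,
group means, SDs, n, and the pooled-variance Student t (HC minus IBS, so a
larger IBS mean gives negative t). The pooled rather than Welch form is the
default because it is what published summary tables of this kind report, and
it is recomputable from printed (M, SD, n) triplets; Welch is available via
`welch = TRUE`. Severity classification uses the validated IBS-SSS cut-offs
with 175–300 read as inclusive (so 300 is moderate, 301 severe).

`min_detectable_r(n)` inverts the power function of the two-sided
correlation test: the smallest $r$ detectable with 80% power at
$\alpha = 0.05$. Two methods are implemented because the published
sensitivity numbers depend on unstated software settings: `"fisher-z"`
(default) uses the Fisher-transform normal approximation with the
second-order mean correction $r/(2(n-1))$ — Monte Carlo checks show this
matches the exact test's power to better than 0.6% even at $n = 21$ — and
`"noncentral-t"` uses a noncentral-t model with
$\lambda = r\sqrt{n}/\sqrt{1-r^2}$, which reproduces the values common
power-analysis software reports.
At the study sizes these give 0.339/0.333 ($n = 65$) and 0.570/0.542
($n = 21$): the HC group is powered only for large effects, which is why
single-study subnetwork differences are hypotheses, not conclusions.

## The synthetic cohort generator

`simulate_cohort()` exists because the raw study data are not distributable:
it generates cohorts with the statistical structure the analysis assumes,
plus planted ground truth for calibration and power experiments.

The generator is a Gaussian copula: per group, latent standard normals with
a target correlation matrix (identity except for planted edges) are mapped
through strictly monotone marginal transforms. Monotonicity is the key
design constraint — it makes every planted latent correlation land on the
rank scale as exactly $\tfrac{6}{\pi}\arcsin(\rho/2)$, so ground truth is
analytically known. Concretely:

* **Abundances**: genus $g$ gets $a_g = c_g \cdot
  \operatorname{logistic}(\mu + \sigma z_g)$ with fixed capacities $c_g$
  (geometric series summing to 0.45; the remainder stands for all
  unmodelled genera), $\mu = -1$, $\sigma = 1.5$. Values below the
  detection limit (1e-4) are recorded as 0, and an additional per-group
  non-detection probability (default 0.10 per genus) creates
  missing-at-random zeros. A normalising "closure" step was deliberately
  avoided: dividing by the realised total would couple every abundance to
  every latent variable and distort planted rank correlations.
* **Phenotypes**: normal with the published group means and SDs; a
  `skew_phenotypes` option swaps in moment-matched lognormals (the AUC
  measures are strongly right-skewed — the study's true marginals are
  unknown, and no claim is made either way; ranks make the analysis
  indifferent).
* **Brain features**: lognormal-positive transforms of their latents.
* **Covariates**: age truncated-normal on [18, 65] with the published group
  means/SDs; sex Bernoulli with the published female proportions (16/21 HC,
  46/65 IBS), independent of all planted structure.

Defaults are the study conditions: 21 HC, 65 IBS, nine panel genera, the
nine-variable phenotype battery, 36 brain features (three metrics × both
hemispheres × six somatosensory/basal-ganglia regions). An infeasible
planted structure (non-positive-definite target matrix) is an error naming
the offending edges — silently projecting to the nearest PSD matrix would
change the planted effect sizes.

`simulate_connectivity_stack()` generates per-subject matrices for the
connectome stage: a fixed template (drawn once per seed) perturbed by
symmetric noise on the Fisher-z scale and mapped back through tanh, with
optional couplings that shift all edges of one region by
$0.25\cdot\text{strength}\cdot u_s$ for a subject latent $u_s$, so that
region's centralities track the latent across subjects.

**What passing tests show — and what they do not.** The generator
reproduces the features the *statistics* depend on: group sizes, rank-scale
correlation structure, compositional zeros, covariate distributions. It does
not emulate sequencing depth, taxonomic misassignment, the spatial
covariance of real connectomes, batch effects, or genus-genus ecological
interactions beyond what is planted. Green calibration and recovery tests
therefore validate the *inferential machinery* at the study's sample sizes;
they say nothing about whether any particular biological association is
real.

## Numerical choices and degenerate inputs

* Ties rank as averages everywhere; a variable constant within a group
  (e.g. a genus entirely non-detected) yields an undefined correlation and
  the edge is skipped and logged (`attr(edges, "skipped")`), never silently
  zeroed. $|r| = 1$ likewise skips the edge (infinite Fisher transform).
* Pairwise-complete deletion per edge per group; each edge records its
  per-group $n$. A pair needs $n \ge k + 4$ complete cases to be computed.
  When a block has no missing values the implementation residualises all
  columns once per group and forms one cross-product matrix; with NAs it
  falls back to per-pair computation. Both paths are tested against each
  other and against the normal-equations oracle.
* A covariate constant within a group (e.g. all-female small samples) is
  dropped from the design with a warning rather than crashing the QR solve.
* Connectivity validation: symmetry to 1e-8, $|w| \le 1$, unique labels,
  errors name the first offending cell.
* Severity boundaries, the 0.80 missingness threshold, and $p < \alpha$
  thresholds are all strict/inclusive exactly as documented, with boundary
  tests.
* Determinism: simulation is byte-reproducible from `seed` (RNG state is
  restored afterwards); `run_pipeline()` writes a manifest with a config
  hash and stage counts, and identical inputs give byte-identical outputs.

## Subnetworks: induced versus incident

`extract_subnetwork(net, focus)` keeps the focus and its first neighbours
with the *induced* edge set (all edges among selected nodes) by default.
Note the consequence: a genus → brain → phenotype "indirect" path ends at a
second-order node, so it can only appear under `mode = "incident"` (all
edges touching a selected node), which is also what published subnetwork
figures of this kind display. `classify_associations()` therefore accepts
any network; use the full difference network or an incident-mode subnetwork
when enumerating indirect effects.

## Problem sizes used by the test suite

The suite favours many small deterministic checks plus a few targeted
simulations: oracle equivalence on 200+ random graphs of up to 7 nodes and
500+ random partial-correlation datasets; null calibration on three
simulated cohorts contributing ~2,800 edges; planted-edge recovery on 2,000
replicates per effect size at the study's 21/65 split; sensitivity-analysis
power on 20,000 simulated samples per group size. These sizes give
Monte-Carlo standard errors comfortably inside the tolerances asserted
(±2–3 percentage points) while keeping the default run short.

## Known limitations

* Associations are correlational and cross-sectional; "indirect" is a
  topological label, not a mediation claim.
* The classic difference test's mild anticonservatism at small $n$ is
  documented and quantified rather than hidden; use `df_penalty` when
  nominal size matters.
* The dominant-component convention for eigenvector centrality on
  disconnected graphs assigns near-zero values off the dominant component;
  comparisons of `E` features across subjects implicitly assume similar
  component structure, which holds for dense functional connectomes.
* The generator's planted structure is sparse and pairwise; it does not
  model dense correlated backgrounds, so recovery rates reported here are
  best-case for isolated effects.
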