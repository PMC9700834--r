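---
title: "Methods: Bayesian spatio-temporal CAR disease mapping with stcarmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian spatio-temporal CAR disease mapping with stcarmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`stcarmap` maps small-area disease risk from repeated cross-sectional survey
rounds. The outcome in zone $i$ and period $k$ is a count $O_{ik}$ of affected
children among $n_{ik}$ examined, modelled as

$$O_{ik} \sim \mathrm{Poisson}(\mu_{ik}), \qquad
\log \mu_{ik} = \log E_{ik} + \alpha + u_i + v_i + \beta_1 t_k +
\mathbf{x}_{ik}'\boldsymbol\beta .$$

The expected count $E_{ik}$ comes from internal direct standardization:
$E_{ik} = n_{ik}\,\bar r$ with $\bar r = \sum O / \sum n$ the pooled rate, so
$\sum E = \sum O$ and the crude relative risk $O_{ik}/E_{ik}$ (the SMR)
averages to 1 with weights $E$. We pool the reference rate over periods by
default so that a real secular trend remains visible in the risks; a
per-period option exists for users who want each round standardized to
itself.

The convolution ("BYM") random-effect pair separates spatial signal from
noise:

* $u$ is spatially structured, with an intrinsic CAR (ICAR) prior on the
  queen-contiguity graph: each $u_i$ is conditionally normal around the mean
  of its neighbours with conditional variance $1/(\tau_u m_i)$. The joint
  kernel is the pairwise-difference form
  $\tfrac{n-c}{2}\log\tau_u - \tfrac{\tau_u}{2}\sum_{i\sim j}(u_i-u_j)^2$,
  improper with rank deficiency equal to the number of connected components
  $c$.
* $v$ is unstructured, iid $\mathrm{Normal}(0, 1/\tau_v)$.

The ICAR prior is invariant to a constant shift of $u$, so the model carries
an explicit intercept $\alpha$ and the sampler re-centres $u$ to sum to zero
after every sweep, transferring the mean into $\alpha$ — the standard
identifiability fix. Zones with no neighbours (islands) have no ICAR full
conditional; they receive an exchangeable $\mathrm{Normal}(0, 1/\tau_u)$
prior, are counted out of the rank term, and are reported loudly when a fit
starts.

Covariates enter as zone-level quartile indicators. For each of three
variables — the proportion of mothers with any education, with
richer/richest household wealth, and with any anemia — zones are cut at the
empirical 25/50/75 percentiles into categories 1–4, with category 1 the
reference (high education, high socio-economic status, *low* maternal
anemia). Quartiles 2–4 of each variable give nine indicator columns. By
default quartiles are computed within each survey period (the subscript on
$\mathbf{x}_{ik}$ is taken seriously; zone covariate mixes do change between
survey rounds); a pooled-over-periods switch is provided because either
reading of the design is defensible. Ties at a cut share the lower quartile,
deterministically.

### Priors

Fixed effects get flat $\mathrm{Normal}(0, V_\beta)$ priors with
$V_\beta = 10^6$; both precisions get $\mathrm{Gamma}(0.5, 0.0005)$ — the
conventional weakly-informative disease-mapping choices. All are
config-overridable. Time is coded $t_k = k \in \{1, 2, 3\}$; a centring
option exists but the plain coding is the default.

## Estimation

The sampler is adaptive random-walk Metropolis-within-Gibbs, written in
C++ for speed:

1. each $u_i$ in turn against its Poisson likelihood × ICAR full
   conditional, then the re-centring step;
2. each $v_i$ likewise;
3. $\alpha$, $\beta_1$ and each $\beta_j$ by random-walk Metropolis against
   the full likelihood (indicator covariates make these updates cheap);
4. exact conjugate Gibbs draws
   $\tau_u \sim \mathrm{Gamma}(a + \tfrac{n-c}{2}, b + \tfrac{1}{2}\sum_{i\sim j}(u_i-u_j)^2)$
   and $\tau_v \sim \mathrm{Gamma}(a + \tfrac{n}{2}, b + \tfrac{1}{2}\sum v_i^2)$.

Proposal scales adapt toward a 0.35 acceptance rate in windows of 100 sweeps
during burn-in only, then freeze, so the retained chain has a fixed,
detailed-balanced kernel. Classic WinBUGS-era software uses
derivative-based or slice updates for these log-concave conditionals; the
target posterior is identical, and a unit test checks the sampler against
1-D numerical quadrature on an intercept-only model, where the posterior is
available essentially exactly.

Chain 1 starts at the null state (zeros, unit precisions); further chains
start over-dispersed. The default desk-scale run is 2 chains × (5,000
burn-in + 20,000 sweeps, thinned by 10). A fidelity preset matching common
practice for production disease-mapping runs — 100,000 burn-in, 1,000,000
sweeps, thin 10 — is a matter of raising the config numbers; nothing is
hard-coded.

### Convergence and model comparison

`diagnostics_report()` computes, per scalar parameter, the classic
(non-rank-normalized) Gelman–Rubin statistic
$\hat R = \sqrt{(\tfrac{n-1}{n}W + B/n)/W}$, lag autocorrelations, and the
batch-means Monte Carlo error (20 batches) with the conventional "MC error
< 5% of posterior SD" flag. Model comparison uses DIC with the classic
plug-in at posterior means of the natural-scale parameters:
$pD = \bar D - D(\bar\theta)$, $\mathrm{DIC} = \bar D + pD$.
`overdispersion_check()` reports the variance/mean ratio of the counts that
motivates the Poisson likelihood.

## Outputs

`risk_surface()` reports, per zone-period: the crude RR; the smoothed RR
$\exp(\alpha + u_i + v_i + \beta_1 t_k + \mathbf{x}_{ik}'\boldsymbol\beta)$
summarised by its posterior median (robust under the lognormal skew; the
mean is emitted alongside since mapping conventions differ) with a 2.5–97.5
percentile credible interval; the exceedance probability
$P(\mathrm{RR}_{ik} > 1 \mid y)$ as the fraction of stored draws above the
threshold; and two map classifications — RR bands $<0.85$ / $0.85$–$1.1$ /
$>1.1$ and probability bands $[0,0.25]$, $(0.25,0.5]$, $(0.5,0.8]$,
$(0.8,1]$ with closed upper bounds. The RR class bounds as printed in the
source literature are self-inconsistent ("$<0.85$" alongside "0.8–1.1"); we
resolve the middle band as $0.85$–$1.1$.

Coefficient tables (`fixed_effect_table()`) report posterior mean, SD and
95% CrI on the log scale, and an RR column computed from the per-draw
exponentials (median and percentiles) rather than $\exp(\text{posterior
mean})$ — the principled choice, since the exponential of a mean is not the
mean (or median) of an exponential unless the posterior is symmetric and
tight. `rr_from_coef()` provides the plain $\exp(\cdot)$ convention, rounded
to two decimals, for comparison with published tables.

## The synthetic-data generator

Restricted survey microdata cannot ship with a package, so
`simulate_dataset()` generates everything the pipeline consumes from the
model's own generative process with known parameters:

* an 8×9 lattice of unit-square zones (72 zones, close to the 74
  administrative zones of the motivating application), whose queen graph is
  known analytically;
* three survey periods with ~85 children per zone-period
  (≈18,400 records, mirroring the ~18,900 of the application);
* zone covariate proportions drawn around a per-zone anchor with a small
  per-period drift — survey rounds several years apart do not show frozen
  covariate maps, and the drift also keeps the covariate field from being
  perfectly confounded with the time-constant spatial field;
* $u$ drawn exactly from the sum-to-zero ICAR distribution by spectral
  decomposition of the graph Laplacian (covariance
  $\sigma_u^2 (D-W)^+$ on the constraint subspace), $v$ iid normal;
* counts $O_{ik} \sim \mathrm{Poisson}(E_{ik} e^{\eta_{ik}})$ with
  $E_{ik} = n_{ik} \times 0.55$ (the baseline anemia rate), true
  $\alpha = -0.1$, $\beta_1 = 0.02$ and nine quartile effects of magnitude
  0.05–0.2 on the log scale;
* individual records consistent with the counts, severity split among
  severe/moderate/mild at the pooled application proportions, and
  record-level covariates drawn independently given the zone proportions.

Parameter validity is checked on the fixed-effect part of the rate (random
effects at their central value); realised Poisson draws exceeding $n_{ik}$
in extreme random-effect tails are capped at $n_{ik}$ (a child count cannot
exceed the children examined) and counted in the truth manifest — at the
default settings this touches a handful of cells per dataset at most.

What the generator does *not* emulate, deliberately: multi-stage cluster
sampling, survey weights, household structure, and any cross-variable
dependence beyond the zone proportions. Passing recovery tests therefore
demonstrate correctness of the estimation machinery under the model's own
assumptions — not robustness to design effects present in real survey data.

`table1_fixture()` is a separate, purely descriptive fixture: 18,939
synthetic records whose per-period one-way margins reproduce a published
descriptive table exactly, with a product-of-margins joint distribution. Two
cells of the published maternal-anemia margins are inconsistent with the
survey sizes (one period sums to one more than $n$, another 104 short); the
fixture keeps every printed count, carries the shortfall as missing values,
and trims the single overflow record from the largest category.

## Design and numerical choices

* **Recovery fits use the generator's covariate quartiles** (computed from
  the true zone proportions through the same quartile code path), not
  quartiles re-estimated from the finite records. Re-estimation is supported
  and exercised end-to-end in the pipeline tests; for calibration studies it
  would add quartile-misclassification noise that is a property of the
  survey size, not of the estimator under test.
* **Contiguity predicate**: minimum boundary distance (vertex-to-segment,
  both directions) ≤ `tol`, default 0 (exact touch). Polygons of a valid
  tessellation never cross without touching, which is the one configuration
  this predicate does not see. `tol` exists for dirty real-world shapefiles.
* **Degenerate inputs**: zero-area polygons warn but are processed;
  zone-periods with no records get $O = n = 0$, a warning, and are skipped
  by the likelihood; an all-equal covariate vector puts every zone in
  quartile 1 with a warning; a non-finite posterior at the initial state is
  an immediate, named error.
* **Problem sizes in the test-suite**: the calibration study runs 20
  replicates of the 72-zone design at the default desk-scale chain lengths,
  giving 180 coverage events and a 99% binomial acceptance band of roughly
  0.91–0.99 around the nominal 0.95; the DIC comparison runs 50 replicate
  pairs at shorter chain lengths (DIC differences of ~30 units are far
  larger than their Monte Carlo noise). These sizes make the whole suite
  run in a couple of minutes while keeping each check statistically sharp.

## Known limitations

* Order-1 queen contiguity only; no order-2, rook, distance-band or
  row-standardized weights.
* No proper-CAR/Leroux mixing parameter, no space–time interaction random
  effect, no overdispersion term (the motivating data showed none).
* DIC magnitudes depend on the data; only the *direction* of the
  null-vs-covariate comparison is a generative invariant, and that is what
  the tests assert.
* The Gelman–Rubin statistic is the classic form; rank-normalized variants
  are out of scope.

## A worked run

```{r, eval = FALSE}
library(stcarmap)

res <- run_pipeline(pipeline_config(
  out_dir = "demo_run", seed = 1,
  simulate = list(rows = 8, cols = 9),
  sampler = list(n_chains = 2, n_burnin = 5000, n_iter = 20000, thin = 10)))

res$dic
head(res$fixed_effects)
head(res$surface)
```

The output directory then holds every stage artifact (geometry, adjacency,
counts, expected counts, samples, convergence report, risk surface as CSV
and GeoJSON) plus a manifest with content hashes; re-running the same config
reproduces identical files.
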