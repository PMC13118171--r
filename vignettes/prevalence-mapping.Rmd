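---
title: "Prevalence mapping from stratified household surveys: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prevalence mapping from stratified household surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevmapr)
```

# The problem

In many low- and middle-income countries, stratified two-stage household
surveys (DHS-style designs) are the primary source of information on binary
health indicators: the country is stratified into urban and rural strata
within each first-level administrative area (admin-1), clusters (census
enumeration areas) are sampled within strata by probability proportional to
size with households as the size variable, and a fixed number of individuals
is interviewed per cluster. Design weights are inverse inclusion
probabilities, with urban strata typically over-sampled. The analytic task is
small area estimation: prevalence estimates, with honest uncertainty, for
admin-1 areas (where the survey is powered) and admin-2 areas (where data are
sparse — often a handful of clusters per area).

prevmapr implements a staged workflow: (1) data and design diagnostics,
(2) three model classes — direct design-based estimation, area-level
(Fay-Herriot) smoothing, and cluster-level beta-binomial models, (3)
evaluation screens comparing the models, and (4) posterior summaries
(exceedance probabilities, comparison tables). A synthetic survey generator
with known truth makes every stage testable without restricted microdata.

# Direct estimation

For area $i$ with sampled individuals $S_i$, the design-weighted (Hájek
ratio) estimator is
$$\hat p_i^w = \sum_{j \in S_i} w_j y_j \Big/ \sum_{j \in S_i} w_j .$$
Its design variance uses stratified, with-replacement-PSU Taylor
linearization restricted to the area's strata and clusters: with cluster
residual totals $z_c = \sum_{j\in c} w_j (y_j - \hat p)/\hat N$,
$$\widehat{\mathrm{var}} = \sum_h \frac{n_h}{n_h - 1} \sum_{c \in h}
 (z_c - \bar z_h)^2 .$$

Numerical choices:

* **Lonely PSUs.** A stratum contributing a single cluster to an area enters
  as its squared deviation from the area-wide mean of cluster residuals
  (factor 1), with a warning — the "adjust" convention. This keeps sparse
  admin-2 areas estimable instead of failing hard.
* **Single-cluster areas.** When an area has exactly one cluster, clustering
  cannot be estimated at all; we fall back to an individual-level
  with-replacement approximation. Such areas are flagged degenerate only if
  the prevalence is 0/1 or the variance sits below the floor. This makes the
  phantom-cluster rescue (below) effective even for areas that previously had
  no clusters.
* **Degeneracy floor.** Variances below $10^{-12}$ are treated as zero:
  0/1 prevalences give exactly-zero variances, and other sparse
  configurations give unusably small ones.
* **Interval scale.** 95% intervals are built on the logit scale
  ($\hat\theta_i^w \pm z\sqrt{\hat V_i}$, with
  $\hat\theta_i^w = \mathrm{logit}(\hat p_i^w)$ and the delta-method variance
  $\hat V_i = \widehat{\mathrm{var}}/[\hat p(1-\hat p)]^2$) and
  back-transformed, so they respect $[0,1]$.
* **CV.** Reported as $\sqrt{\widehat{\mathrm{var}}}/\hat p$, the standard
  coefficient of variation.

The variance estimator assumes with-replacement PSU sampling with negligible
sampling fractions; finite-population corrections are out of scope. The test
suite validates it against the empirical sampling variance under exactly
those conditions (many PSUs per stratum, small sampling fractions, no
between-cluster spatial structure that systematic selection would implicitly
stratify on); under systematic PPS with geographically ordered frames it is
mildly conservative, as in real designs.

# Area-level smoothing (Fay-Herriot)

The sampling model takes the logit-scale direct estimates at face value,
$\hat\theta_i^w \mid \theta_i \sim N(\theta_i, \hat V_i)$, and the linking
model is $\theta_i = \alpha + x_i^T\beta + u_i$. The random effect $u$ is IID
normal or, by default, the BYM2 reparameterization
$$u = \sigma\left(\sqrt{1-\phi}\, e_{\mathrm{iid}} +
  \sqrt{\phi}\, e_{\mathrm{icar}}\right),$$
where $e_{\mathrm{icar}}$ follows an intrinsic CAR on the area adjacency
graph, scaled so the geometric mean of its constrained marginal variances is
1. $\sigma$ is then the interpretable total standard deviation and $\phi$ the
spatial proportion of variance.

* **Adjacency.** Queen contiguity (shared boundary point) from polygons, or
  an edge list. The ICAR is constrained to sum to zero per connected
  component and scaled per component. Islands carry a pure unstructured
  effect with the full standard deviation $\sigma$ (their structured marginal
  variance slot is set to 1 by convention).
* **Priors.** Penalised-complexity priors: $P(\sigma > 1) = 0.01$ (an
  exponential with rate $-\log(0.01)$ on $\sigma$) and $P(\phi > 0.5) = 2/3$
  for the spatial proportion. The $\phi$ prior has no closed form; it is
  tabulated on a 513-point grid from the distance
  $d(\phi) = \sqrt{2\,\mathrm{KLD}(\phi)}$ to the base model $\phi = 0$
  (computed from the eigenvalues of the scaled structured covariance), with
  density $\propto e^{-\lambda d(\phi)} d'(\phi)$ and $\lambda$ calibrated by
  root finding. A tail statement placing 2/3 of the mass *above* 0.5 requires
  a negative $\lambda$ — the base measure's upper tail is below 1/2 for any
  graph, since KLD is convex in $\phi$ and zero at 0 — so the calibration
  machinery admits negative rates, yielding an exponentially *tilted*
  distance prior that favours the spatial model. We adopt this as the
  package's convention because the probability statement itself, not the sign
  of the rate, is the quantity an analyst specifies. Fixed effects get vague
  $N(0, 31.6^2)$ priors.
* **Inference.** A self-contained Gibbs/Metropolis sampler: conjugate
  Gaussian updates for $(\alpha, \beta)$ and $u$, and adaptive random-walk
  Metropolis for $(\log\sigma, \mathrm{logit}\,\phi)$ on the marginal
  likelihood with $u$ integrated out. Defaults: 4000 kept draws after 2000
  burn-in, seed-reproducible. Correctness is validated against conjugate
  closed forms (collapsed hyperpriors), the design-consistency limit
  ($\hat V_i \to 0$ pins the posterior at the direct estimate), and
  parameter-recovery simulations, rather than against any particular
  approximate fitter.
* **Degenerate areas** contribute no likelihood term and are predicted from
  the linking model.
* **Phantom clusters.** Admin-2 areas whose design variance is missing or
  below the floor are rescued before model fitting by appending one synthetic
  cluster with prevalence equal to the parent admin-1 direct estimate and
  weight-sum equal to the mean cluster weight-sum in that admin-1. Since only
  the weight-sum and prevalence are dictated by the rule, the phantom is
  realized as $n = \mathrm{round}(\bar n_c)$ individuals with
  $Y = \mathrm{round}(n \hat p_{a})$ successes, placed in the admin-1's modal
  stratum and flagged by provenance. Phantoms feed the Fay-Herriot inputs
  only; reported direct estimates are computed before augmentation.

# Cluster-level models

Cluster counts get a beta-binomial likelihood,
$Y_c \mid p_c \sim \mathrm{BetaBinomial}(n_c, p_c, d)$, parameterized by the
mean $p_c$ and the intra-cluster correlation $d \in (0,1)$ (shapes
$a = p(1-d)/d$, $b = (1-p)(1-d)/d$; $d = 0$ recovers the binomial). Five
linear predictors are supported:

| variant | logit($p_c$) |
|---|---|
| unstratified | $\alpha + x_c^T\beta + u_{i[c]}$ |
| nested unstratified | $\alpha_{a[c]} + x_c^T\beta + u_{i[c]}$ |
| stratified non-nested | $\alpha + \gamma 1_{c\,\mathrm{rural}} + x_c^T\beta + u_{i[c]}$ |
| stratified nested | $\alpha_{a[c]} + \gamma 1_{c\,\mathrm{rural}} + x_c^T\beta + u_{i[c]}$ |
| nested with interaction | $\alpha_{a[c]} + \gamma_{a[c]} 1_{c\,\mathrm{rural}} + x_c^T\beta + u_{i[c]}$ |

Admin-1 intercepts $\alpha_a$ and interaction slopes $\gamma_a$ are fixed
effects with vague normal priors (sd 31.6). The stratified-nested variant is
the workhorse: it accounts for the urban/rural sampling stratification
(essential whenever prevalence is associated with urbanicity and urban
clusters are over-sampled) and reduces cross-admin-1 shrinkage.

* **Prior for $d$.** No standard convention exists for the overdispersion's
  prior; we use an exponential truncated to $(0,1)$, calibrated by
  $P(d > 0.5) = 0.1$ by default and exposed as a sensitivity switch
  (`d_prob_half`).
* **Inference.** Adaptive Metropolis-within-Gibbs in compiled code:
  single-site updates for fixed effects and the BYM2 components
  ($e_{\mathrm{iid}}, e_{\mathrm{icar}}$ per area), random-walk updates on
  transformed scales for $\sigma$, $\phi$ and $d$. The ICAR sum-to-zero
  constraint is imposed softly (component sums get a tight zero-mean normal
  penalty), which keeps single-site updates O(neighbourhood) while pinning
  the unidentified level. Defaults: 2000 kept draws after 1000 burn-in.
* **Uniform-on-$p$ option.** For the no-random-effect intercept-only model,
  `p_prior = "uniform"` places a standard-logistic prior on $\alpha$, i.e. a
  uniform prior on the prevalence scale — used by the conjugate
  Beta-posterior validation.
* **WAIC** compares variants from per-draw per-cluster log-likelihoods.

# Aggregation with urban fractions

Stratified fits produce urban- and rural-specific surfaces; area prevalences
are their mix, e.g. for the nested variant
$$\theta_i = (1-q_i)\,\mathrm{expit}(\alpha_{a[i]} + \gamma + x_i^T\beta + u_i)
           + q_i\,\mathrm{expit}(\alpha_{a[i]} + x_i^T\beta + u_i),$$
with $q_i$ the urban fraction of the *target* population in area $i$. Because
cluster listings are never public, $q_i$ is reconstructed from gridded
population: per admin-1 area, pixels of the frame-year (T0) raster are sorted
by population density and the urban set is the smallest prefix whose
population share first reaches the reported urban fraction (exact matching is
impossible on a discrete grid; the achieved fraction and gap are recorded,
ties break by pixel index, and an unattainable target clamps to all-urban
with a warning). The partition is frozen at T0 and applied to the survey-year
target-population raster to compute $q_i$ and the within-area pixel weights
$q'$. With cluster/pixel-level covariates, aggregation sums over pixels
standing in for the unknown population clusters:
$\theta_i = \sum_{\mathrm{pix} \in i} q'_{\mathrm{pix}}\,
\mathrm{expit}(\alpha_a + \gamma 1_{\mathrm{pix\,rural}} +
x_{\mathrm{pix}}^T\beta + u_i)$.

Aggregation applies expit to the linear predictor directly: the
overdispersion $d$ is a within-cluster nuisance, not part of the latent
prevalence. Rasters are plain gridded arrays with an affine origin/step
header (a small text format is provided); no geospatial raster stack is
required.

# Evaluation

* **Over-smoothing screen.** The posterior of
  $v = \frac{1}{M-1}\sum_i (\theta_i - \bar\theta)^2$ for a fine-level model
  is compared with the same statistic for a coarse-level model whose draws
  are populated verbatim to the fine areas. A fine model with materially
  *less* between-area variation than its coarse counterpart is over-smoothed.
* **Comparison tables** align models on shared areas and report correlations,
  shrinkage slopes (regression of one model's points on another's; slopes
  below 1 indicate attenuation toward the grand mean), and counts of
  points falling outside the other model's interval. Degenerate direct
  estimates stay in the table, flagged.
* **CV screen.** Default release threshold 16.7% (the common
  official-statistics rule that estimates below it can be used without
  restriction), configurable.
* **Exceedance probabilities** are per-area fractions of draws above a policy
  threshold.
* Point estimates: posterior means and medians are both emitted; plots and
  tables default to the mean.

# The synthetic generator

`generate_frame()` + `draw_survey()` emulate the target design at desk scale:
47 admin-1 areas containing 300 admin-2 areas on a snake-ordered lattice
(so admin-1 blocks are contiguous), urban/rural strata within admin-1 with
two purely urban admin-1 areas (92 strata), 40 EAs per admin-2 area with
log-normal household counts and Poisson eligible counts, truth drawn from the
nested stratified model ($\alpha_a \sim N(0.9, 0.35^2)$, $\gamma = -0.45$,
$\sigma = 0.3$, $\phi = 0.5$, $d = 0.15$ — prevalences around 0.55–0.75, a
rural deficit, and moderate spatial structure), systematic PPS cluster
sampling with household sizes, 36 clusters per admin-1 (about 1700 in total,
median 5–6 clusters per admin-2 area), a take of 25 individuals per cluster,
2x urban over-sampling, and inverse-inclusion-probability weights with
optional nonresponse inflation. Covariate surfaces, when requested, are
smooth low-order spatial polynomials plus noise.

What it deliberately does **not** emulate: household rosters, GPS jitter
(the assignment module has its own geometric fixtures), non-ignorable
nonresponse, frame undercoverage, and certainty PSUs. Passing recovery tests
on this generator demonstrates internal consistency of the estimators under
the stated design, not robustness to those real-data features.

Sizes used by the test suite are chosen for desk-scale reproducibility:
parameter-recovery runs use 20 replicates of the full 47/300 design with 2000
kept draws, and the design-based unbiasedness check uses 1000 replicate
surveys.

# Known limitations and open choices

* GPS mis-assignment correction: the snap-to-nearest-polygon-within-recorded-
  admin-1 rule is a documented stand-in for survey-specific correction
  procedures.
* The Fay-Herriot sampler uses dense linear algebra — comfortable to a few
  hundred areas, not thousands.
* Phantom clusters affect only the smoothing-model inputs; whether they
  should also back-fill reported direct estimates is left to the analyst.
* Replicate-weight variances, finite-population corrections, generalized
  variance functions, and classification-model urban reconstruction are out
  of scope.
* With all-island graphs, $\phi$ is unidentified and the model falls back to
  a pure unstructured effect.
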