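---
title: "Methods: spatial point-pattern analysis of Janzen-Connell effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial point-pattern analysis of Janzen-Connell effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jcpattern)
```

## The scientific problem

In fully mapped forest census plots, several mechanisms leave fingerprints in
the spatial arrangement of stems: Janzen-Connell (J-C) effects (reduced
offspring survival near conspecific adults and at high conspecific density),
dispersal limitation (recruits concentrate near parents), self-thinning
(competition for space as stems grow), and habitat association (species track
topography). `jcpattern` implements a three-part point-pattern protocol that
weighs these mechanisms against each other for every common species of a
census:

1. **Habitat association** — a Berman covariate test of each life-stage
   pattern against quadrat-level topographic covariates, under a null model
   of stochastic pattern reconstruction.
2. **Aggregation by life stage** — the K2-function of each stage under CSR
   envelopes, plus counts of stage-to-stage declines in aggregation.
3. **Adult-offspring association** — the bivariate pair-correlation function
   g12 of offspring around adults under a heterogeneous Poisson null that
   factors out habitat-driven density variation.

Stems are classified into saplings, juveniles and adults from dbh, with size
classes specific to the growth form (canopy 1-5/5-10/>=10 cm, under-story
1-2.5/2.5-5/>=5, shrub 1-1.5/1.5-2/>=2). The published class limits do not
state boundary ownership; we use lower-closed, upper-open intervals so every
dbh maps to exactly one stage. Species enter the analysis when they have at
least 40 individuals in every stage.

## Second-order summary statistics

All ring-based estimators share one edge correction: the **exact analytic
area** of the annulus `[max(0, r - w/2), r + w/2)` intersected with the
rectangular window, computed as the difference of two disk-rectangle
intersection areas (each assembled from four quarter-disk-rectangle terms in
closed form). Compared with grid-approximated ring areas this removes a
discretisation parameter and is testable against Monte-Carlo integration; the
test suite checks agreement with a 10^6-sample oracle to 0.5%.

The pair-correlation estimator is the O-ring form

$$\hat g(r) = \frac{\sum_i \#\{j \ne i : d_{ij} \in \mathrm{ring}(r)\}}
{\sum_i |\mathrm{ring}(x_i, r) \cap W|} \Big/ \hat\lambda,
\qquad \hat\lambda = n / |W|,$$

with the bivariate version normalised by the intensity of the second pattern.
We use `n/|W|` rather than `(n-1)/|W|`; at the analysis floor of 40 points
per pattern the bias is below 2.5% and the relative-density interpretation
stays simple. Distance bins are half-open, matching the interval convention
used everywhere else.

The default analysis grid is 1 m resolution with a 3 m ring width over
0-50 m (the first ring is the disk `[0, 1.5)`). The K-function cumulates
contiguous rings of width equal to the grid step, centred at `r - step/2`, so
that `K(r)` counts distances below `r`; `L(r) = sqrt(K/pi)` equals `r` under
CSR. The nearest-neighbour distributions `D^k` (k = 1, 2 by default; the
protocol names "nearest neighbor distribution functions" in the plural
without fixing k) and the spherical contact distribution `Hs` are empirical
fractions without edge correction — they are only ever compared between
patterns in the same window, where the boundary bias is shared. `Hs` uses a
deterministic square test lattice (1 m spacing by default) rather than random
test points, for reproducibility.

### The K2-function

`K2(r) = (g(r + dr) - g(r - dr)) / (2 dr)` is the finite-difference
derivative of the pair-correlation function (dr = 1 m by default, matching
the 1 m grid; the ring width for the underlying g is 3 m as in the bivariate
analysis — the protocol leaves both unstated for this analysis). Large-scale
intensity gradients move `g` up and down smoothly; `K2` responds to the
*rate of change* of neighbourhood density and is therefore robust to such
heterogeneity. Under CSR envelopes, `K2` **below** the lower envelope flags
aggregation (neighbourhood density decaying quickly away from points) and
above the upper envelope regularity.

## Null models

All null generators condition on the observed point count, so envelopes
compare like-for-like sample sizes.

* **CSR** — n uniform points (binomial process).
* **Heterogeneous Poisson (HP)** — rejection sampling from an Epanechnikov
  kernel intensity estimate
  `e_R(d) = (2 / (pi R^2)) (1 - d^2 / R^2)` with bandwidth R = 30 m, the
  scale within which distance-dependent interactions are expected. Each
  point's kernel is renormalised by its mass inside the window, so the
  surface integrates to n. The raster uses 2 m cells with bilinear
  interpolation during sampling. A bounded-displacement variant (uniform
  relocation within 30 m disks) is provided under the same interface.
* **Pattern reconstruction** — generates replicates that share the observed
  pattern's summary statistics while being independent of any covariate.
  Starting from CSR, one uniformly chosen point at a time is proposed a
  uniform new location; the move is accepted iff the energy
  $E = \sum_s w_s \sum_r (\hat S_{s,\mathrm{rec}}(r) - \hat S_{s,\mathrm{obs}}(r))^2 / \mathrm{norm}_s$
  does not increase (improvement-only, zero-temperature annealing — the
  cited reconstruction literature shows this converges well and it removes
  the cooling-schedule hyperparameter). The energy statistics are g on
  1-50 m (1 m rings), L on 1-50 m, Hs on 1-30 m, and D1/D2 on 1-30 m, with
  equal weights; each term is normalised by the variance of the observed
  curve over its grid so statistics on different scales contribute
  comparably (a variance below 1e-12 falls back to 1 to keep the energy
  finite for degenerate curves). The default budget is `200 n` proposals
  with a stall limit of 5000 consecutive rejections. For desk-scale runs the
  Hs test lattice defaults to 2 m spacing inside the reconstruction (the
  stand-alone `spherical_contact()` keeps 1 m); the lattice spacing is a
  documented, configurable trade-off between Hs resolution and per-step
  cost. The implementation maintains all statistics incrementally (pair
  distance matrix, ring count histograms, per-lattice-point nearest
  providers), so a step costs O(n + lattice) rather than O(n^2 + lattice n).

## Inference machinery

* **Envelopes** — pointwise bounds from the 5th-lowest and 5th-highest of
  199 simulations (a nominal two-sided 5% pointwise test). Only strictly
  exceeding a bound counts as outside, so an observed curve tied with a
  simulation stays inside.
* **GoF rank test** — guards against multiple testing across distances:
  `u_i` is the summed squared deviation of curve i from the mean of all
  other curves over a distance interval, and
  `p = (#{u_sim >= u_obs} + 1) / (n_sims + 1)` (ties counted as >=,
  conservative). The interval is 1-25 m for the K2 analysis (where
  small-scale effects are of interest) and 0-50 m for the bivariate
  analysis. The rank formula is exact for any number of simulations >= 2,
  which the unit tests exercise with a hand-built 3-simulation example.
* **Berman test** — `Z1 = (S_obs - mu) / sigma` where `S_obs` is the mean
  covariate value at the points and mu, sigma come from the null replicates;
  two-sided p from the standard normal. Significance uses |Z1| > 1.96. The
  protocol does not state how many reconstruction replicates feed mu and
  sigma; we default to `n_sims` (199), configurable.
* **Association classification** — a conjunction rule: positive requires GoF
  p < 0.05 *and* at least one distance above the upper envelope in 0-50 m;
  negative requires GoF p < 0.05 and a distance below the lower envelope in
  0-10 m; when both trigger, the direction with more exceedance distances
  wins, ties going to positive. The published protocol uses both criteria
  together without stating precedence, so the tie-break is this package's
  documented choice, and result tables carry the raw envelope and GoF flags
  so the rule can be re-audited. No multiple-testing correction is applied
  across species or covariates, mirroring the original per-test reporting.
* **Peak distances** of positive associations are the argmax of g12 over
  0-50 m (smallest r on ties) with the cumulative categories <1, >=1, >=3,
  >=5 m.

## Topographic covariates

Quadrat (20 x 20 m) covariates follow the forest-dynamics-plot conventions:
mean elevation is the mean of the four corner elevations; slope is the mean
angular slope (degrees) of the four triangular planes spanned by the corners
taken three at a time; convexity is the focal quadrat's mean elevation minus
the mean of its neighbours' mean elevations. Edge quadrats use their
available (3 or 5) neighbours — simpler than the focal-minus-corner-mean
edge rule used by some plot software, and configurable in principle since the
convention is not fixed by the protocol. Covariate lookup at tree locations
uses half-open quadrat boundaries with the plot's upper edge clamped to the
last quadrat, so every stem that passes window validation has a covariate.

## The synthetic forest generator

No accession exists for the motivating 24-ha census, so the package ships a
generator that produces stem tables with the statistical structure the
analyses assume, giving every pipeline stage ground-truthed inputs:

* deterministic ridge-valley topography (sinusoid plus Gaussian hills)
  sampled at 20 m corners;
* adults drawn from a log-linear habitat intensity
  `exp(sum beta_k v_k)` on standardised quadrat covariates, optionally
  Thomas-clustered, conditioned on an exact count;
* offspring cohorts (saplings and juveniles independently, from the same
  adults — simpler than aging one cohort and sufficient for testing the
  detectors) by Poisson reproduction and isotropic Gaussian dispersal
  (sd `sigma_d`, default 5 m), reflected into the window;
* switchable mortality: J-C distance thinning with survival
  `p(d) = d^2 / (d^2 + d_jc^2)` (a smooth monotone curve with a single
  interpretable scale — survival 1/2 at `d = d_jc`), density thinning
  `exp(-c k)` on the neighbour count within a radius, and hard-core
  self-thinning by iterative random removal below distance h.

The default community has 10 species with 60-300 adults each in the
600 x 400 m window, mirroring the >= 40-per-stage selection floor. The
generator emulates habitat filtering, dispersal limitation and the mortality
mechanisms; it does **not** emulate interspecific interactions, temporal
demography, or observation error, so passing mechanism-recovery tests shows
the detectors respond to the intended spatial signatures, not that real
censuses are this simple.

## Verification and problem sizes

The test suite checks every estimator against an independent oracle (closed
forms under CSR, numeric integration and Monte-Carlo sampling for geometry,
direct enumeration for rank tests) and the pipeline against planted
mechanisms: dispersal-limitation scenarios must classify adult-offspring
associations positive, strong J-C thinning must remove small-scale
positives, planted elevation effects must be recovered by the Berman
pipeline, and self-thinned adults must be flagged aggregated less often than
the juveniles they were thinned from. Calibration checks verify the 5%
pointwise envelope error rate, uniform GoF p-values and standard-normal Z1
under matched nulls. These checks run at desk scale — windows of 200-300 m,
patterns of 80-300 points, 39-199 simulations, 20 replicates per scenario,
and 2000 replicates for the envelope error rate — sizes chosen so the whole
suite completes in minutes while leaving the Monte-Carlo error of each check
well inside its decision band.

## Known limitations

* Estimator dialect: ring areas are exact rather than grid-approximated, so
  results match grid-based plot software in kind, not digit-for-digit.
* `D^k` and `Hs` carry boundary bias that cancels only in same-window
  comparisons, which is how the package uses them.
* Reconstruction quality depends on the proposal budget; the energy trace is
  returned so convergence can be inspected.
* The heterogeneous Poisson null conditions on n and uses a fixed 30 m
  bandwidth; parametric intensity models fitted to covariates are
  deliberately out of scope.
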