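# jcpattern

Spatial point-pattern analysis of Janzen-Connell effects in fully mapped
forest census plots.

In species-rich forests, several mechanisms shape where trees stand:
Janzen-Connell (J-C) effects (offspring die near conspecific adults and at
high conspecific density), dispersal limitation, self-thinning through
competition for space, and habitat association with topography. `jcpattern`
implements a three-part protocol that weighs these mechanisms per species in
a rectangular census plot, for ecologists working with stem tables
(species, x, y, dbh, growth form) and a quadrat-corner elevation grid:

1. **Habitat association** — the Berman test compares the mean covariate
   value at the stems of each life stage, `S_obs`, with its distribution
   under a null model of stochastic pattern reconstruction (replicates that
   keep the observed clustering but are independent of the covariate):
   `Z1 = (S_obs - mu) / sigma ~ N(0, 1)`.
2. **Aggregation by life stage** — the K2-function
   `K2(r) = (g(r + dr) - g(r - dr)) / (2 dr)`, the finite-difference
   derivative of the pair-correlation function `g(r)`, detects aggregation
   (K2 below CSR envelopes) robustly under habitat-driven heterogeneity;
   per-species stage comparisons count declines in aggregation from sapling
   to juvenile to adult.
3. **Adult-offspring association** — the bivariate pair-correlation
   `g12(r)` of offspring around adults is tested against a heterogeneous
   Poisson null built from an Epanechnikov kernel estimate (bandwidth
   30 m) of the offspring intensity, which factors out large-scale habitat
   effects; positives/negatives are classified by simulation envelopes
   (5th extremes of 199 simulations) together with a goodness-of-fit rank
   test, and peak association distances are tabulated.

All ring statistics use an exact analytic circle-rectangle edge correction.
Because the motivating 24-ha census is not publicly deposited, the package
includes a synthetic forest generator (habitat filtering, Thomas-clustered
adults, Gaussian dispersal, switchable J-C / density / hard-core thinning)
so every analysis can be exercised against ground truth.

## Worked example

A small synthetic community (two species in a 200 x 200 m window, habitat
filtering plus dispersal-limited recruitment, no J-C thinning) ships in
`inst/extdata/`. The full pipeline runs from the shell:

```sh
Rscript inst/scripts/jcpattern.R all \
  --stems inst/extdata/synthetic_stems.csv \
  --dem inst/extdata/synthetic_elevation.csv \
  --config config.yaml --out results/ --seed 5
```

with `config.yaml` reducing the simulation effort for a quick demo:

```yaml
window: [200, 200]
n_sims: 39
recon: {max_steps: 1500, hs_spacing: 5, stall_limit: 800}
```

The log reports:

```
read 794 stems, 2 species pass the selection floor
analysis1: 18 Berman tests, 50.0% species consistently associated
analysis2: 6 species-stage K2 tests
analysis3: 6 bivariate tests, 5 positive
```

and `results/analysis3_table.csv` begins:

```
species,pair,n1,n2,gof_p,classification,peak_r,peak_category,...
sp02,adult_juvenile,80,125,0.025,positive,0,<1 m,...
sp02,adult_sapling,80,270,0.025,positive,0,<1 m,...
```

Read: for species `sp02`, juveniles are significantly positively associated
with adults (GoF p = 0.025 at 39 simulations) with the neighbourhood
density peaking below 1 m — exactly the dispersal-limitation signature the
generator planted. `analysis2_table.csv` shows the same species' saplings
aggregated at 32 of 49 distances under CSR envelopes, and
`analysis1_*.csv` carries the per-stage Berman `Z1` values recovering the
planted elevation preferences.

The same computations are available programmatically:

```r
library(jcpattern)
w <- rect_window(0, 0, 200, 200)
stems <- read_stem_table("inst/extdata/synthetic_stems.csv", w)
cfg <- analysis_config(n_sims = 39,
                       recon = recon_config(max_steps = 1500, hs_spacing = 5))
a3 <- analysis3_association(stems, w, cfg)
a3$table
```

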