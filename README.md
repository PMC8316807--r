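# domstyle

Dominance style — the strictness with which a dominance hierarchy is
enforced, from *despotic* to *tolerant* — shapes how group-living primates
interact, and plausibly how much and how they vocalize. `domstyle` is an R
package for the complete two-level analysis of that question, aimed at
behavioral ecologists and comparative researchers working with multi-site
observational data:

* **Individual level.** From raw tables of directed aggression bouts it
  computes dominance ranks (modified David's scores on decided bouts) and
  three tolerance measures over rank-restricted dyads — aggression symmetry
  (directional inconsistency index, DII = proportion of dyadic bouts in the
  less frequent direction), counteraggression %, and aggression-intensity
  (contact) % — each in a "given" (toward subordinates) and "received"
  (from dominants) version, plus feeding-proximity tolerance from scans.
  Vocal rates come from focal observations via a 30-s bout-chaining rule
  with a 2-h inclusion minimum. The individual-level model is a Bayesian
  Gaussian mixed model on log10 vocal rate,

      y_i = x_i' β + u_species + u_group(species) + ε_i,

  fitted by a conjugate Gibbs sampler with diffuse normal priors on β and
  inverse-Wishart (V = 1, ν = 0.002) priors on the variances, reporting
  posterior means, 95% credible intervals, pMCMC and a variance partition.
* **Species level.** The three measures are aggregated
  individual → group → species, z-scored across species (intensity negated
  so everything points toward tolerance) and averaged into a composite
  dominance-style index. Repertoire sizes (total calls and the
  hierarchy-related subset) are modelled by phylogenetic generalized least
  squares with Pagel's λ fixed (default 1),
  β̂ = (X'C⁻¹X)⁻¹X'C⁻¹y, on a time-calibrated tree — including grafting of
  taxa missing from the reference phylogeny at a known divergence time.
* **Synthetic studies.** A generator (`simulate_study()`) produces complete
  datasets — bouts, scans, sessions, vocal events, repertoires, Yule
  phylogeny — from known ground truth, so every estimator is testable by
  parameter recovery.

See the methods vignette (`vignettes/dominance-style-methods.Rmd`) for the
models, priors, numerical choices and limitations.

## Worked example

```r
library(domstyle)

study <- simulate_study(sim_config(seed = 7))
study
#> Synthetic study: 16 species, 41 groups, 431 individuals
#>   17628 aggression bouts, 38616 scans, 16816 vocal events; seed 7

run <- run_study(study, pipeline_config(seed = 7))
summary(run$individual$given)
#> Bayesian Gaussian mixed model (Gibbs sampler)
#>   log_rate ~ given_dii + given_counter + given_intensity + group_size
#>   n = 360 individuals, 41 groups, 16 species; 1000 retained draws
#>             term post_mean ci_lower ci_upper pMCMC
#>      (Intercept)   0.11716 -0.30454  0.52189 0.570
#>        given_dii   0.21718 -0.10923  0.51623 0.188
#>    given_counter  -0.00115 -0.00496  0.00221 0.574
#>  given_intensity  -0.00104 -0.00455  0.00239 0.542
#>       group_size   0.01572 -0.01450  0.04751 0.360
#>
#> Posterior mean variance components:
#> species   group   resid
#>  0.0304  0.0497  0.0624
#>
#> Variance partition (proportions):
#>   fixed species   group   resid
#>   0.016   0.210   0.343   0.431

run$species$hierarchy
#> Phylogenetic GLS (Pagel's lambda fixed at 1)
#>   log_hierarchy ~ composite + group_size
#>   n = 16 species, residual df = 13, sigma2 = 0.002017
#>         term    beta     se     t       p
#>  (Intercept)  0.9051 0.2293  3.95 0.00167
#>    composite -0.0980 0.0367 -2.67 0.01920
#>   group_size -0.0193 0.0173 -1.12 0.28427
```

Reading the output: the `given_dii` posterior mean (0.217) is the change in
log10 vocal bouts/hour per unit of given aggression symmetry — positive, so
individuals that tolerate more upward aggression from subordinates vocalize
more (the generating truth is 0.42 on the *expected* DII; fitting the
measured, noisy DII attenuates the estimate, as it would in a real study).
The species-level `composite` slope (−0.098, p = 0.019) says more despotic
species (lower index) carry more hierarchy-related calls. The variance
partition attributes 21% and 34% of response variance to species and group.
`run_study(..., out_dir = "results")` additionally writes every
intermediate table (ranks, profiles, rates, composite index, coefficient
tables, exclusion log) as CSV, and `report("results")` assembles a summary
from those files alone.

A thin command-line wrapper over the same functions is installed at
`inst/cli/domstyle.R` (subcommands `simulate`, `validate`, `run-all`,
`report`).

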