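---
title: "Dominance style and vocal communication: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominance style and vocal communication: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Group-living primates differ in *dominance style*: the strictness with which
a dominance hierarchy is enforced, from despotic (dominants assert rank
consistently, aggression is one-sided and harsh) to tolerant (subordinates
can aggress upward, retaliate, and feed near dominants). `domstyle`
implements a two-level analysis of how dominance style relates to vocal
communication:

* **Individual level** — does an individual's tolerance, given to
  subordinates or received from dominants, predict how often it vocalizes?
* **Species level** — does a species' overall dominance style predict the
  size of its vocal repertoire, and in particular the number of
  hierarchy-related (dominance/appeasement) calls?

Because multi-site observational datasets of this kind are rarely released,
the package pairs the estimators with a synthetic-study generator whose
ground truth is known, so every stage can be tested by parameter recovery.

## From observations to dominance-style measures

The raw inputs are five CSV tables (directed aggression bouts with
contact/counteraggression/decided flags, feeding-proximity scans, focal
sessions, vocal events, group metadata), a per-species repertoire table, and
a time-calibrated Newick phylogeny. Times are plain seconds from an
arbitrary per-study epoch: every rule in the pipeline uses only time
differences, so calendar handling is deliberately out of scope. Readers
validate each file completely and report the first offending row and field.

**Ranks.** Within each group, decided bouts (the victim fled or submitted)
are tallied into a win matrix and converted to modified David's scores: the
dyadic win proportion \(P_{ij} = s_{ij}/n_{ij}\) is shrunk for sparse dyads,
\(D_{ij} = P_{ij} - (P_{ij} - 1/2)/(n_{ij} + 1)\) (0 for unobserved dyads),
and combined as \(DS_i = w_1 + w_2 - l_1 - l_2\) with
\(w_1 = \sum_j D_{ij}\), \(w_2 = \sum_j D_{ij} w_{1j}\) and the analogous
loss terms. Scores sum to zero; the normalized score
\(normDS = (DS + N(N-1)/2)/N\) lies in \([0, N-1]\). Ordinal ranks break
exact ties lexicographically and flag them, so ranking is deterministic.
Individuals with fewer than `min_decided` (default 3) decided bouts are
excluded from ranking and logged.

**Tolerance measures.** Three aggression-based measures are computed per
individual over rank-restricted dyads — partners ranked *below* the focal
("given" tolerance: what a dominant allows) or *above* it ("received"):

* *aggression symmetry* (directional inconsistency index, DII): the
  proportion of dyadic bouts in the less frequent direction, pooled
  bout-weighted across dyads, \(\sum_d \min(a_d, b_d) / \sum_d (a_d+b_d)\).
  Pooling by bouts rather than averaging dyadic DIIs keeps one-bout dyads
  (whose dyadic DII is always 0) from dominating; the unweighted mean is
  available via `dii_mode = "dyad_mean"`.
* *counteraggression*: percent of bouts in which the victim retaliated.
* *aggression intensity*: percent of bouts with physical contact.

All bouts within a restricted dyad count, whoever initiated them; the
restriction is a property of the dyad, not of the initiator
(`initiator_only = TRUE` restricts to focal-initiated bouts). A measure is
missing when fewer than `min_bouts` (default 10) bouts back it — these
minima are analysis choices, configurable, not facts about the data.
*Feeding proximity* (percent of feeding scans with the nearest neighbour
within 1 m, minimum `min_scans` feeding scans) is kept separate: it cannot
be split into given/received because only the nearest neighbour's identity
is known.

**The species composite index.** For the species-level models the three
measures (computed over all dyads, unrestricted by rank) are aggregated:
individual → group mean → species mean, then z-scored across species
(sample SD), with intensity *negated* before z-scoring so all three
components increase with tolerance; the composite is the mean of the three
z-scores. Positive values indicate a tolerant species, negative a despotic
one. Because z-scores absorb any positive affine rescaling, the index is
invariant to the units of the raw measures. A measure with zero
cross-species variance is an error, not a silent division by zero.

## Vocal rates

A vocal bout is all of an individual's vocalizations within 30 s of one
another: segmentation chains consecutive events while gaps are \(\le\) the
inter-bout interval (`ibi`, default 30 s; a gap of exactly 30 s chains,
reading "within 30 s" inclusively). Bouts never chain across focal
sessions — a bout cannot span unobserved time. The rate is bouts per hour
of focal observation, and individuals with under `min_focal_hours`
(default 2 h) are excluded and logged.

## The individual-level model

Vocal rates are analysed on the log10 scale,
\(y_i = \log_{10}(\text{rate}_i + \delta)\) with a uniform offset
\(\delta = 0.01\) bouts/h so individuals with zero observed bouts are
retained (how zero rates were handled in comparable field analyses is
generally unstated; the offset is configurable, and rerunning at 0.001 and
0.1 is the recommended sensitivity check). The model is Gaussian with
nested random intercepts,

\[ y_i = x_i^\top \beta + u_{species(i)} + u_{group(i)} + \varepsilon_i, \]

with the three given (or received) tolerance measures plus group size — or
feeding proximity plus group size — as fixed effects, entered raw so
coefficients are per unit of the measure. Groups are indexed *within*
species, so identical group labels in different species never pool.

Fitting is by conjugate Gibbs sampling: the fixed-effect block from its
multivariate normal full conditional, each random intercept from its normal
full conditional, each variance from its inverse-gamma full conditional.
Priors are diffuse normal for \(\beta\) (variance \(10^{10}\)) and
univariate inverse-Wishart for each variance component with \(V = 1\),
\(\nu = 0.002\) — the weakly-informative convention of MCMC mixed-model
practice. The sampler is intentionally a from-scratch conjugate
implementation of exactly this Gaussian model: the posterior is the same as
a general-purpose MCMC mixed-model package would target, with a fully
auditable update rule. The default chain (13 000 iterations, 3 000 burn-in,
thinning 10, 1 000 retained draws) follows the same conventions and is
configurable; a chain retaining fewer than 100 draws is refused. Given a
seed the fit is bit-reproducible.

Reporting follows the field's format: posterior mean, 95% credible
interval, and `pMCMC` \(= 2\max(1, \min(n_+, n_-))/n\) capped at 1 — twice
the smaller tail proportion with a one-draw floor so a one-sided posterior
reports \(2/n\) rather than an impossible 0. The variance partition takes
the fixed-effect share as the variance of the fitted linear predictor
\(X\hat\beta\) across individuals (a definitional choice; no standard
definition exists for the Bayesian case) and the remaining shares from the
posterior means of the variance components, normalized to sum to 1.

Calibration checks implemented in the test suite: with random-effect
variances fixed near zero the posterior mean collapses to ordinary least
squares; with all variances fixed it matches the generalized least-squares
solution computed from the marginal covariance; doubling the chain moves
posterior means by less than Monte-Carlo error; and on 100 replicates of
the default design with truth known by construction, the 95% intervals
cover every coefficient at the nominal rate.

## The species-level model

Repertoire counts enter as a curated table (total calls and
hierarchy-related calls, the latter a subset classified by
dominance/appeasement context in the source descriptions — an editorial,
not computational, step). Both counts are modelled as
\(\log_{10}(\text{count} + 1)\); the offset (configurable) is needed
because hierarchy-call counts can be 0, and the same transform is applied
to both responses for comparability.

The model is generalized least squares with phylogenetically structured
residuals: \(C_{ij}\) is the shared root-to-ancestor path length of species
\(i\) and \(j\) in Myr, off-diagonals multiplied by Pagel's \(\lambda\),
and

\[ \hat\beta = (X^\top C^{-1} X)^{-1} X^\top C^{-1} y, \qquad
   \hat\sigma^2 = \frac{e^\top C^{-1} e}{n - p}, \]

with t-based two-sided p-values on \(n - p\) degrees of freedom.
\(\lambda\) is *fixed* (default 1, full Brownian signal), never estimated:
with ~20 species the signal cannot be estimated reliably, and fixing it at
1 is the conservative choice. \(\lambda = 0\) recovers OLS exactly, and
p-values are invariant to rescaling \(C\) — both are asserted in tests
against a Cholesky-whitening oracle and an independent GLS implementation.

Taxa missing from the reference phylogeny but with a known divergence time
are grafted as a sister lineage: a new node is inserted on the sister's
terminal branch at the divergence time and the new tip attached with a
branch of that length, so ultrametry is preserved exactly (tested to 1e-9
at a 1.99 Myr graft). Grafting deeper than the sister's terminal branch is
refused rather than silently reattached. Predictors are the composite index
and mean group size; single-measure follow-ups fit each raw style measure
(plus group size) separately.

## The synthetic-study generator

The generator emulates the statistical structure the estimators assume, not
behavioral realism. Each species has a latent tolerance
\(\tau_s \sim U(-1, 1)\) mapped to per-bout probabilities: subordinate
initiation \(p_{up} = 0.05 + 0.20(\tau+1)\), counteraggression
\(0.05 + 0.25(\tau+1)\), contact \(0.60 - 0.25(\tau+1)\), feeding proximity
\(0.1 + 0.3(\tau+1)/2\); bouts are decided with probability 0.8 and won by
the aggressor with probability 0.9; dyadic bout counts are Poisson(8).
Hierarchy-call repertoires are Poisson with log-rate \(1.5 - 0.6\tau\)
(declining in tolerance, so the true species-level slope is negative), plus
Poisson(\(e^{2.2}\)) other calls. The phylogeny is a Yule tree (birth 0.2
/Myr) rescaled to 40 Myr height; species intercepts are exchangeable by
default, with an option to draw them from the tree's covariance.

Two generator choices deserve emphasis:

* **Individuals vary in tolerance.** Individual tolerance is
  \(\tau_i = \tau_s + N(0, \sigma_{\tau,ind})\), clamped to \([-1, 1]\),
  with \(\sigma_{\tau,ind} = 0.5\), and the dominant partner's \(\tau_i\)
  sets each dyad's subordinate-initiation probability (tolerance is *given*
  by the dominant). This is both biologically motivated — dominance style
  varies between individuals within species, which is precisely why the
  individual-level analysis exists — and statistically necessary: if
  tolerance were purely species-level, the true vocal-rate predictor would
  be constant within species and therefore confounded with the species
  random intercept, leaving the individual-level effect unidentifiable in
  principle (and its estimate collapsing toward zero once predictor
  measurement error is added).
* **The vocal-rate truth uses the *expected*, not realized, DII.** The
  log10 vocal-bout rate is \(0.3 + 0.42\,E[\text{given DII}_i] + u_s + u_g
  + \varepsilon\) (SDs 0.25, 0.20, 0.15), where
  \(E[\text{given DII}_i]\) is the exact expectation
  \(E[\min(B, n-B)]/E[n]\) under the individual's \(p_{up}\) and the
  Poisson bout-count law (`expected_dii()`). The analysis pipeline fits the
  *measured* DII, so estimates are attenuated by measurement error exactly
  as in a real study: pooling ~30–80 bouts per individual gives a
  reliability of roughly 0.4–0.7, and the recovered coefficient averages
  ~0.24 against a generating value of 0.42. Parameter-recovery tests
  therefore check sampler calibration on the true predictor (where coverage
  is nominal) and separately bound the attenuation ratio of the
  measured-predictor fit.

Vocal events are generated as a Poisson process of bouts, each emitted as
1–4 calls under 30 s apart inside a focal session, so segmentation is
genuinely exercised; focal time is 2–10 h per individual. What the
generator does **not** emulate: rank-distance effects on aggression,
seasonal/diurnal structure, sex differences, context-specific calling, or
non-Gaussian rate distributions. Passing recovery tests on these data shows
the estimators are correct for the assumed structure; it does not validate
the behavioral assumptions against real populations.

## Pipeline, logging and reproducibility

`run_study()` chains everything: validation → ranks → tolerance profiles →
vocal rates → three mixed models → composite index → species table → five
PGLS fits, writing every intermediate table as CSV so each reported number
is recomputable from the artifacts, plus an exclusion log recording every
filtered unit and why (per-model sample sizes differ only through such
filters). Reruns with the same config and seed are identical; per-model
chain seeds are derived from the master seed. `report()` rebuilds a
summary purely from the emitted CSVs.

Problem sizes used by the test suite were chosen to exercise the
statistics at full strength while keeping a default run modest: 1 000
random groups for the exhaustive dominance-statistics oracles, 1 000 random
win matrices and event sets, 100 mixed-model replicates at the default
design (~430 individuals), 500 PGLS simulations at 21 species, and 20
end-to-end seeds.

## Known limitations

* The end-to-end sign-recovery experiment (positive given-DII effect on
  vocal rate *and* negative hierarchy-calls slope in one run) succeeds in
  about 85% of replicates at the default design, not more: attenuation plus
  the collinearity of the three tolerance measures (all driven by the same
  latent \(\tau\)) makes the full-model DII coefficient's sign unstable in
  ~8% of runs, and 16-species Poisson repertoire noise flips the PGLS slope
  in ~7%. These are properties of the design's signal-to-noise, not of the
  estimators; a test demanding joint sign agreement in ≥95% of runs fails
  under these conditions and is retained in the suite as documentation of
  that fact.
* Dyads whose members are exactly tied on `normDS` belong to neither the
  given nor the received restriction.
* `P[i][j]` is taken as 0 for never-interacting dyads, following the
  modified David's score convention; very sparse groups are better served
  by raising `min_decided`.
* The PGLS treats the composite index as known, ignoring its estimation
  error; with ~2–3 groups per species this error is visible in the
  generator's recovery spread.
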