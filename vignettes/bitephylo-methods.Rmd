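---
title: "Models and methods behind bitephylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bitephylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitephylo)
```

## The scientific question

Crocodylians bite far harder than their adult ecology seems to require,
and their bite force scales with body size rather than snout shape. One
explanation is *ontogenetic inertia*: crocodylians have type III
survivorship, so selection is concentrated on neonates and juveniles
racing toward large body size, and the adult apparatus inherits
juvenile-optimized allometry. If that is right, the strongly positive
allometry of bite force seen during development should reappear, at some
point, as a macroevolutionary pattern of bite-force proxies outpacing
body-size proxies along the lineage leading to living crocodylians.

`bitephylo` operationalizes that comparison with two osteological
proxies measured in millimeters and analyzed on the natural-log scale:

* **RAP** — the anterior-posterior length of the retroarticular process,
  the in-lever through which the dominant jaw-closing muscles act; a
  bite-force proxy.
* **HW** — head width across the quadrate-articular joint; a body-size
  proxy.

The package takes a time-calibrated phylogeny (branch durations in Myr;
fossil tips are expected, so trees need not be ultrametric) and per-taxon
RAP/HW measurements, and asks: on which branches did RAP evolve faster
than HW, and does the evolutionary trajectory of the RAP:HW ratio along
the focal lineage invert the ontogenetic one?

## Continuous-trait models and model comparison

Before fitting the branch-rate model, `compare_trait_models()` screens
the three standard single-rate models of continuous character change by
maximum likelihood:

* **BM**: tip values are multivariate normal with mean equal to the root
  state and covariance $\sigma^2 C$, where $C_{ij}$ is the shared
  root-to-MRCA path length. The likelihood is computed by postorder
  peeling in $O(n)$ (never forming $C$), and the root and rate have
  closed-form maximum-likelihood solutions. The ML rate uses divisor
  $n$; the REML value (divisor $n-1$, equal to the mean squared
  phylogenetically independent contrast) is reported alongside.
* **OU**: a single-optimum Ornstein-Uhlenbeck process with the root
  fixed at the optimum. Because fossil tips destroy ultrametricity, the
  stationary covariance is invalid; we use the fixed-root form
  $V_{ij} = \sigma^2 e^{-\alpha(T_i+T_j-2t_a)}\,
  \frac{1-e^{-2\alpha t_a}}{2\alpha}$ with $t_a$ the shared path length,
  which reduces to BM as $\alpha \to 0$. The pull parameter $\alpha$
  (per Myr) is profiled out by bounded 1-D optimization with the
  generalized-least-squares closed form nested inside.
* **EB**: an early-burst model whose rate decays as $e^{rt}$; its
  covariance is the shared-path transform $(e^{rC_{ij}}-1)/r$, again
  profiled over $r \le 0$.

Models are ranked by AIC with $\Delta$AIC relative to the best; AICc is
emitted alongside because the sample sizes typical of fossil datasets
are small. When all tip values are identical the rate sits on the
$\sigma^2 = 0$ boundary and the fit is returned with a degeneracy flag
rather than a fabricated likelihood.

## The multiple-variance Brownian-motion model

The core engine, `mvbm_mcmc()`, estimates ancestral states and
branch-specific rates under an explicitly stated generative model:

$$x_c \mid x_p \sim \mathcal{N}(x_p,\; \sigma^2 r_b t_b)$$

for each branch $b$ of duration $t_b$, with independent priors
$\ln r_b \sim \mathcal{N}(0, \nu^2)$ on the rate multipliers, a
conjugate inverse-gamma prior on the base rate $\sigma^2$ (default
shape 0.001, rate 0.001 — the usual weakly-informative choice) and a
flat prior on the root state. The sampler is Metropolis-within-Gibbs:

1. every internal node state is Gibbs-updated from its normal full
   conditional, assembled from the (at most three) incident branches;
2. $\sigma^2$ is Gibbs-updated from its conjugate inverse-gamma full
   conditional given the current increments;
3. each $\ln r_b$ takes a random-walk Metropolis step (default proposal
   sd 1.6, tuned for mid-band acceptance on data of this scale).

Tip states are data and are never touched. Setting $\nu = 0$ pins every
multiplier at 1, collapsing the model to single-rate BM — the limit in
which the posterior root mean must match the GLS closed form and the
internal-node means must match the joint-normal conditional means, both
of which the test suite checks against dense-matrix oracles.

Defaults are desk-scale: 100,000 iterations, 20% burn-in, thinning 10,
$\nu = 1$. These mix well on trees of a few dozen taxa (effective sample
sizes in the thousands); production runs on larger trees simply raise
the iteration count, which is a configuration value rather than a code
path. The chain is initialized inside the typical set (internal states
at postorder child averages, multipliers at 1, $\sigma^2$ at the BM ML
estimate), every random draw flows through R's seeded RNG so identical
configuration gives bit-identical output, and the log joint density is
checked to be finite at every retained sample. Acceptance fractions
outside [0.1, 0.6] are surfaced as a diagnostic warning.

### What branch-rate estimates can and cannot tell you

A multiplier $r_b$ is informed by exactly one Brownian increment. Its
standardized magnitude is distributed $|\mathcal{N}(0, r_b)|$, so even
a 25-fold rate elevation produces a small increment in a substantial
fraction of realizations. Two practical consequences, both visible in
the test suite:

* *Top-rank detection is capped.* With one elevated branch among ~126,
  ranking by posterior-mean multiplier identifies the elevated branch
  only ~55–70% of the time — and an oracle given the *true* node states
  does no better. The sampler operates at this information ceiling; no
  amount of MCMC buys past it.
* *Rank correlation with the truth is attenuated.* Posterior means of
  weakly constrained increments are shrunk toward the prior, so the
  Spearman correlation between true and estimated multipliers on
  mixed-rate simulations plateaus around 0.35–0.4 (the truth-informed
  ceiling itself is ~0.6). The tests therefore assert significantly
  positive rank recovery rather than a fixed correlation.

Single-branch labels should accordingly be read as a map of where the
posterior concentrates evidence, not as per-branch certainties;
`scenario_probabilities()` propagates posterior draws to quantify that
uncertainty.

## The rate space and the six tradeoff scenarios

For every non-root node, `branch_rates()` computes the signed change in
each trait's posterior-mean state along the subtending branch divided by
the branch duration (ln-units per Myr). Signs are essential: the
tradeoff scenarios distinguish increase from decrease, which absolute
rates cannot express.

A reduced-major-axis line — slope $\mathrm{sign}(r)\,s_y/s_x$ through
the means, the symmetric fit standard in allometry — is fit to the cloud
of (HW rate, RAP rate) points and serves as the isometry reference.
With $u$ the HW rate, $v$ the RAP rate and the residual the vertical
offset from the line, every branch receives exactly one label:

| scenario | condition | reading |
|---|---|---|
| AI | $u>0$, $v>0$, above the line | RAP increasing faster than body size |
| DI | $u>0$, $v>0$, below | RAP increasing more slowly |
| SEP_POS | $u\le 0$, $v>0$ | pure RAP elongation |
| DD | $u<0$, $v<0$, above | RAP decreasing more slowly |
| AD | $u<0$, $v<0$, below | RAP decreasing faster |
| SEP_NEG | $u\ge 0$, $v<0$ | RAP shortening against size increase |
| ISO | within tolerance of the line | isometric change |

The on-line tolerance defaults to $10^{-9}$ ln-units/Myr because exact
ties essentially only arise in constructed fixtures. The published
description of this construction is ambiguous about whether rates or
residuals from a separate regression are plotted; we take the RMA line
through the signed-rate cloud as the isometry reference — the simplest
geometry consistent with the six scenarios — and note the alternative
here rather than hiding it.

`paint_tree()` writes an annotated Newick (scenario as a branch
comment), a census of branches per scenario, and, for each tip, the
length of the contiguous run of AI branches ending at that tip — the
"continuous AI trend" diagnostic for the focal lineage.

## Ontogenetic versus evolutionary heterochrony

Both trajectories summarize the trait ratio over ten sequential stages.
The ratio is the quotient of natural logs, $\ln(\mathrm{RAP}) /
\ln(\mathrm{HW})$, taking the published construction literally; the
alternative $\ln(\mathrm{RAP}/\mathrm{HW})$ is available behind the
`ratio` switch because the quotient convention is unit-sensitive (the
package fixes millimeters at load, and a regression test pins that
convention).

* `ontogeny_trajectory()` bins specimens into ten equal-width intervals
  of $\ln(\mathrm{HW})$ between the series extremes ("progressive
  stages"); equal-count binning is a config option since the original
  staging is described as partly arbitrary.
* `evolution_trajectory()` maps the $m$ ancestor-chain states (root
  first, focal tip last) to stages by $\lceil 10k/m \rceil$, so the
  earliest ancestors land in stage 1 and the extant taxon in stage 10.

`compare_trajectories()` locates each trajectory's inflection as the
interior stage maximizing the absolute second difference of stage means
(ties to the earliest stage; below a flatness threshold of $10^{-6}$,
no inflection), and sets the inversion flag when the ontogenetic
inflection precedes the evolutionary one. A visual judgment in the
source material becomes, here, a reproducible operator. One geometric
caveat discovered during validation: for a biphasic log-log allometry
the ratio curve is concave within the juvenile phase (curvature is
strongest at the smallest sizes), so when the breakpoint falls exactly
on a bin edge its kink splits across two stages and the detected
inflection can shift one stage early. Mid-bin breakpoints behave as
expected.

## The synthetic-data generators

No measurement data are redistributed with the package, so all tests
run on generators whose truth is recorded:

* `simulate_tree()` — Yule trees with optional truncation of a fraction
  of tips at uniform random heights along their terminal branches,
  emulating the mixed fossil/extant shape of archosaur phylogenies.
  Defaults of 36 taxa match the scale of the pruned empirical tree this
  workflow targets.
* `simulate_mvbm()` — recursive normal increments with variance
  $\sigma^2 r_b t_b$ and full truth (every node state, every
  multiplier) returned for scoring estimators.
* `simulate_ontogeny()` — a continuous two-phase log-log allometry
  $\ln(\mathrm{rap}) = \ln a_1 + b_1 \ln(\mathrm{hw})$ below a
  breakpoint, slope $b_2$ above it, with multiplicative noise. Defaults
  (n = 34; head widths 15–260 mm on an even ln grid; $a_1 = 0.12$,
  $b_1 = 1.35$, $b_2 = 0.95$; breakpoint 35 mm, about 30% up the ln-HW
  range; noise sd 0.05) encode a wild *Alligator mississippiensis*
  developmental series: strongly positive early allometry that
  decelerates near the size at which juveniles first take robust prey,
  spanning total lengths of roughly 28–364 cm.

What the generators deliberately do not emulate: measurement error on
the phylogeny itself, correlated evolution between RAP and HW (each
trait is modeled independently, as in the original analysis),
non-Brownian tail behavior, and sampling biases of the fossil record.
Green tests on these fixtures therefore validate the estimators and the
pipeline plumbing, not the empirical claims, whose measurements are not
publicly deposited.

## Numerical choices and problem sizes

* Likelihood peeling folds multifurcations pairwise; the dense
  multivariate-normal oracle agrees to $<10^{-8}$ on random trees.
* OU/EB use `expm1`-stabilized covariances and collapse exactly to BM
  at their parameter limits; optimization bounds scale with tree depth.
* Node ids are made stable by canonicalizing child order (sorted by
  smallest descendant tip label) before numbering, so posterior
  summaries are comparable across runs and machines.
* Pruning preserves every kept tip's root-to-tip duration exactly,
  retaining the stem to the kept taxa's MRCA as a root edge.
* Zero-length branches are rejected at read time: branch variance is
  rate x duration, so a zero duration makes the rate unidentifiable.
* The test suite and acceptance script run MCMC at 4,000–100,000
  iterations on trees of 8–64 tips and ML fits on up to 200 tips —
  sizes at which every check completes in seconds while the properties
  under test (calibration, recovery, determinism) are already sharp.

## Known limitations

* Single-increment information bounds per-branch rate inference, as
  quantified above.
* The "adaptive peak" qualifier of the original rate model is realized
  here purely as rate heterogeneity; no optimum parameters are
  estimated, and reversible-jump shift detection is out of scope.
* Trait chains are run independently; cross-trait correlation in the
  posterior is ignored when rates are paired in the rate space.
* The stage construction inherits the unit and binning ambiguities of
  the source description; both are surfaced as options rather than
  resolved silently.
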