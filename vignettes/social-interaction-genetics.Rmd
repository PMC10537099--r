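---
title: "Simulating and genetically analysing directional social interactions"
author: "socialsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and genetically analysing directional social interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialsim)
```

## The problem

Harmful social behaviours in group-housed livestock — feather pecking in
laying hens, tail biting in pigs — are heritable, directed, and pairwise:
one animal performs the behaviour, another receives it. Sensor and computer
vision systems are beginning to deliver longitudinal logs of who did what to
whom. `socialsim` provides a complete in-silico test bed for breeding on such
data: it simulates directed interaction records over a pedigree with known
genetic architecture, fits the genetic analysis model to the simulated
records, and evaluates how accurately breeding values can be estimated under
various recording designs.

## The latent-trait model

Each animal $i$ carries two latent traits on the logit scale: a performer
tendency $P_{\alpha,i}$ and a recipient tendency $P_{\beta,i}$,

$$P_{\alpha,i} = \mu_\alpha + A_{\alpha,i} + Ep_{\alpha,i}, \qquad
  P_{\beta,i} = \mu_\beta + A_{\beta,i} + Ep_{\beta,i},$$

with breeding values $A$ and permanent environmental effects $Ep$ and *no*
residual on the latent scale. When $i$ and $j$ are within sensing range
(an *encounter*), $i$ performs towards $j$ with probability

$$p_{ij} = \mathrm{logistic}(P_{\alpha,i} + P_{\beta,j}),$$

and a Bernoulli draw decides whether the directed interaction happens. The
Bernoulli sampling plays the role of the residual: the model is equivalent
to a threshold model with a logistic residual of variance $\pi^2/3$ (the
link variance), so the underlying-scale heritability of the performer trait
is

$$h^2_u = \frac{\sigma^2_{A_\alpha}}
  {\sigma^2_{A_\alpha}+\sigma^2_{A_\beta}+\sigma^2_{Ep_\alpha}+
   \sigma^2_{Ep_\beta}+\pi^2/3}.$$

Base-generation breeding values are bivariate normal with genetic
correlation $r_A$ between the two traits; offspring receive the parent
average plus a Mendelian sampling deviation with half the base covariance.
Base parents carry breeding values but never behave; only the offspring
generation is simulated in pens.

```{r}
gp <- geneticParams(varAAlpha = 0.170)  # strongest published setting
underlyingH2(gp)
extremeInteractionProbability(gp, 2)    # a top-ranking performer
```

The means default to $\mu_\alpha=\mu_\beta=\mathrm{logit}(0.01)/2 \approx
-2.2976$ (stored at full precision; displays often round it to $-2.3$), so
the median pair interacts with probability 1% per encounter.

## The movement model

Animals move in square pens at a fixed density of one animal per square
metre, driven by three motivations (eat, walk, rest). Per time step the
motivation vector changes by the column of

```{r}
defaultDelta()
```

that corresponds to the behaviour currently expressed. A behaviour starts
when its motivation reaches the threshold $T = 100$ and stops when the
motivation falls to zero; eating has priority over resting, walking has the
lowest priority, and an animal with nothing above threshold rests. Eating
sends the animal to the nearest free feeder (feeders sit on two opposite pen
sides at a 5:1 animal:feeder ratio); walking moves 1 m per step in a random
heading that reflects off walls.

Numerical choices worth knowing:

* **Step duration = 1 s.** With the default matrix, eating motivation rises
  at 0.025 per step, so the inter-meal interval is $\approx T/0.025 = 4000$
  steps plus the $\approx100$-step meal and the walk to the feeder —
  roughly 70 minutes, matching observed feeding cycles, and 1 m/step is then
  a plausible 1 m/s walking speed. Walk and rest bouts alternate on a
  10–20 s rhythm and split the non-eating time evenly.
* **Approaching or queueing at a feeder is classified as eating** in the
  time budget, and changes no motivations; this keeps the meal bounded at
  $T/|\Delta_{EE}| = 100$ s. The realized time budget puts a few percent of
  time on eating.
* **Sensing range = 1 m by default.** The published experiments do not state
  this radius. Because every experiment stops on an interaction-count
  target, the sensing range mainly rescales how much wall-clock time a pen
  needs to accumulate its records; the genetic analysis sees the same
  pair-count structure. It is configurable in `movementConfig()`.
* Encounters are counted once per pair per time step, so a pair dwelling
  next to each other for $k$ steps contributes $k$ potential interactions,
  and both ordered directions are sampled independently at every encounter
  (an animal can perform and receive in the same step).

```{r}
mu <- qlogis(0.01) / 2
sim <- simulatePen(rep(mu, 50), rep(mu, 50), nSteps = 9000, seed = 1,
  logRecords = FALSE)
mealIntervalMean(sim, minutes = TRUE)
timeBudget(sim)
```

Movement is identical across animals: no genetic variation in activity, no
dominance hierarchy, no social transmission of behaviour. These are real
phenomena in livestock; a passing test suite here therefore demonstrates
recovery of the simulated architecture, not robustness to behavioural
dynamics the generator does not emulate (overdispersion from dependent
records being the most important omission).

## Random-number streams

Genetics, movement and interaction sampling draw from independent seeded
streams (the interaction Bernoulli draws use a dedicated xorshift generator
inside the simulation loop). Changing a movement parameter therefore never
perturbs the sampled breeding values or the pen composition, which makes
scenario variants directly comparable replicate by replicate. Given a root
seed, the whole pipeline is deterministic.

## Calibrating the latent variances

Observed-scale heritabilities of behavioural counts reported in the
literature are 0.05–0.2. To place the latent-scale inputs on that scale, a
test data set is simulated in which every animal accumulates ~2500
encounters (~25 interactions), the per-animal performed counts are analysed
with a pedigree animal model $n_i = \mu + A_i + \varepsilon_i$ by REML, and
the latent variance input (all four components equal, $r_A = 0$ during
calibration) is root-found until $\hat h^2_o = \hat\sigma^2_A /
(\hat\sigma^2_A + \hat\sigma^2_\varepsilon)$ hits the target
(`calibrateVariance()`). The published calibrated inputs are kept as presets:

```{r}
h2oPresets
```

One caveat: the mapping from a latent variance input to an observed-scale
count heritability runs through the movement model, because variation in
per-animal encounter numbers dilutes the genetic signal in the counts. The
movement model implemented here gives every animal near-identical exposure
(encounter totals vary by only a few percent between animals), so a given
latent input maps to a *higher* count heritability — i.e. more informative
records — than it would under a movement process with strong encounter
heterogeneity. The presets above are retained as published reference
values; when the realized count heritability matters for a study design,
recalibrate with `calibrateVariance()` against the movement configuration
actually used. The EBV-accuracy levels reported by the test suite sit
slightly above the published ones for exactly this reason, while parameter
recovery is unaffected.

The REML fit itself (`fitAnimalModelReml()`) profiles the restricted
likelihood on the eigenbasis of the relationship submatrix of the recorded
animals, reducing the problem to a one-dimensional search over the
heritability with a closed-form residual variance — fast, and immune to the
convergence tuning a general mixed-model fitter would need.

## The genetic analysis model

The analysis aggregates the event log into ordered pair counts: $y_{ij}$
interactions out of $N_{ij}$ encounters (aggregation is exact for a
Bernoulli model with a time-constant $p_{ij}$). Pairs that never met are
omitted. The binomial logit GLMM is

$$\mathrm{logit}(p_{ij}) = \mu + \mathrm{Pen}_k + A_{\alpha,i} + A_{\beta,j}
  + Ep_{\alpha,i} + Ep_{\beta,j},$$

with $\mathrm{var}[\mathbf a_\alpha; \mathbf a_\beta] = G_0 \otimes
\mathbf A$ ($G_0$ the 2×2 genetic covariance matrix, $\mathbf A$ the
numerator relationship matrix) and iid permanent environmental effects per
trait. Pen effects are fixed with reference-level coding.

Estimation is penalized quasi-likelihood with the binomial dispersion fixed
at 1 (the generator produces exactly binomial data): iterate a working
linearized model; at each round the variance components maximize the
restricted likelihood of that working model, evaluated through one sparse
Cholesky factorization of the Henderson mixed-model equations per candidate,
and the equations' solutions give fixed effects and EBVs — including EBVs of
the record-free base parents through the pedigree. Implementation details
that matter:

* $\mathbf A^{-1}$ is built directly from the pedigree by Henderson's rules
  (exact for the non-inbred two-generation design) and stays sparse.
* The mixed-model equations are eliminated pen block by pen block: the
  effects of one pen's animals form a near-dense clique through the pair
  design, while pens are coupled only through the parents. This ordering
  keeps the Cholesky fill-in small and makes a default-scenario fit (198,000
  pair rows, ~9000 equations) take well under a minute.
* Variance parameters are optimized on an unconstrained scale (log variances,
  atanh correlation), so $G_0$ stays positive semi-definite by construction;
  a guard keeps it invertible as $|r_A| \to 1$.
* Convergence: relative tolerance $10^{-6}$ in the variance optimizer, outer
  rounds until the variance parameters move less than $10^{-4}$; starting
  values are half the strongest preset unless supplied.
* PQL has a known small-sample bias for sparse binomial data. That bias is
  part of what the parameter-recovery experiments measure; the test suite
  checks that the default scenario recovers the simulated truth within
  Monte-Carlo error, and the fitted solutions are verified against a dense
  Laplace-likelihood oracle on small instances.

## Evaluating breeding values

The selection target is the total breeding value $A_\alpha + A_\beta$:
animals with a low total initiate and attract fewer harmful interactions.
`accuracyAndBias()` reports the correlation between true and estimated
totals and the regression of true on estimated (slopes below 1 flag
overestimation). `selectionIndexBound()` gives the theoretical ceiling for
an index of the animal's own limiting repeated-record phenotype ($A + Ep$)
plus its full-sib and half-sib family means: with 4 full sibs, 15 half sibs
and equal $Ep$ and $A$ variance the ceiling is 0.77, rising to
$\sqrt{2/3} \approx 0.82$ with unlimited sibs — accuracy cannot reach 1
because own records never separate $A$ from $Ep$.

```{r}
selectionIndexBound(4, 15, 1)
selectionIndexBound(Inf, Inf, 1)
```

## Scenario orchestration

`scenarioConfig()` defaults to the published default scenario: 2000
offspring from 100 sires × 4 dams × 5 offspring, housed in 20 pens of 100
(1 animal/m²), simulated until every pen logged 10,000 interactions (~100
per animal, ~10⁶ encounters per pen at the 1% median rate).
`runScenario()` replicates the simulate→fit→evaluate pipeline (published
analyses used 20–25 replicates; the replicate count is a parameter);
`varyPens()` refits on the first $k$ pens to emulate phenotyping fewer
individuals, and `varyRecords()` refits chronological prefixes of the
interaction stream via in-run snapshots of the pair counts. Prefixes are
chronological per pen, and fit failures on very small subsets are flagged
and excluded rather than fatal.

```{r, eval = FALSE}
cfg <- scenarioConfig(nReplicates = 5, seed = 101)
res <- runScenario(cfg)
res$summary
```

## Problem sizes used by the test suite

The bundled tests run the full default scenario (20 pens of 100, 10,000
interactions per pen) for five replicates at the strongest genetic setting,
plus a sparse-records variant (~10 interactions per animal) with the
count-LMM comparison; the remaining tests use pens of 10–100 animals and
pedigrees of 20–500 animals. These sizes were chosen so the whole suite
doubles as a demonstration that a desk machine can reproduce the headline
experiment; full grids over all heritabilities, correlations and 20–25
replicates scale linearly from there.

## Known limitations

* Two generations, non-inbred: the pedigree rules for $\mathbf A^{-1}$ are
  exact here but would need inbreeding terms for deeper pedigrees.
* Dispersion is fixed at 1; real interaction streams are likely
  overdispersed (hierarchy, social transmission), which would require a
  temporal environmental term the model deliberately omits.
* The LMM/GLMM accuracy comparison shares one data set; the published
  comparison at equal record numbers is reproduced, but the two models are
  not otherwise expected to agree.
* Movement parameters shape encounter rates only; genetic variation in
  movement, collision avoidance and hierarchy-dependent behaviour are out
  of scope.
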