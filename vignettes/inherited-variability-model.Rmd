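---
title: "Social interaction coefficients and inherited variability: model and methods"
author: "igevar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Social interaction coefficients and inherited variability: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igevar)
```

## The model and its assumptions

`igevar` simulates pairs of individuals whose growth rates are coupled
through a heritable interaction coefficient. For focal individual $i$ with
group mate $j$,

$$P_{t,i} - P_{t-1,i} = \mu_{GR} + A_{GR,i} + E_{p,GR,i} + E_{t,GR,i}
  + b_{ij}\,(P_{t-1,j} - P_{t-1,i}),$$

$$b_{ij} = \bar b + A_{D,i} + E_{D,i} + A_{I,j} + E_{I,j}.$$

The assumptions built into the implementation:

* **Pairs only.** Groups have exactly two members; the effector trait is
  the within-pair weight difference at the previous time point.
* **Absolute growth.** The mean increment $\mu_{GR}$ does not scale with
  current weight. Relative (multiplicative) growth would amplify
  divergence under competition; it is deliberately out of scope.
* **Synchronous update.** Both members' increments at time $t$ use the
  weights at $t-1$. This is what makes the pair difference follow the
  linear recursion $d_t = c\,d_{t-1} + \delta$ with
  $c = 1 - b_{ij} - b_{ji}$, on which the closed-form oracle rests. An
  asynchronous (sequential) update would break this algebra and was
  rejected.
* **`b` frozen per pairing.** $E_D$ and $E_I$ are permanent individual
  effects drawn at birth; $b_{ij}$ and $b_{ji}$ are computed once when a
  pair is formed and held constant over the trajectory (the coefficient
  model has no time index).
* **No floor on weight.** Under extreme competition simulated weights can
  go negative; the simulator warns but does not truncate, because any
  floor would distort the variance algebra that the oracle checks.
* **Independent effects.** The six lifetime effects are mutually
  independent; in particular the correlations between $A_{D}$, $A_{I}$ and
  $A_{GR}$ are zero, so selection responses in weight and in the
  interaction coefficients are genetically uncoupled.

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `mu_gr` | mean growth per step | 10 | g |
| `var_a_gr` | additive variance, growth | 1 | g² |
| `var_ep_gr` | permanent env. variance, growth | 0.4 | g² |
| `var_et_gr` | temporary env. variance, growth (redrawn each step) | 0.6 | g² |
| `b_bar` | average interaction coefficient | −0.08 … 0.08 | g⁻¹ |
| `var_ad`, `var_ai`, `var_ed`, `var_ei` | direct/indirect genetic and env. variances of `b` | 0.225·10⁻³ each | — |
| `start_weight_mean` | weight at time 0 | 10 | g |
| `start_weight_sd` | SD of weight at time 0 | √2 | g |
| `n_time_points` | growth increments | 10 | — |

The five canonical scenarios differ only in `b_bar`
(−0.08, −0.05, 0, 0.05, 0.08: strong/moderate competition, neutral,
moderate/strong cooperation). The single-step phenotypic variance computed
excluding `b` is $\sigma^2_{P_{GR}} = 1 + 0.4 + 0.6 = 2$ g²;
`start_weight_sd` defaults to the matching $\sqrt2$ g so that "an initial
difference of 2 SD" is the same yardstick at time 0 as for one growth
step.

**Time points.** "Ten time points" is read as ten growth increments after
the initial weight (stored weights $P_0 \dots P_{10}$): starting weight
and per-step growth share the same 10 g scale, which reads most naturally
as increments between stored points. The alternative reading (nine
increments) is a one-line configuration change via `n_time_points`.

**Family design.** Each generation is a hierarchical half-sib design. The
default is 100 sires × 40 dams × 2 offspring = 8000 individuals in 4000
pairs (80 offspring per sire). This size was chosen so that, over 100
replicates, (i) the replicate-to-replicate spread of the mean within-group
variance is of the order of a few percent of its value, and (ii) per-sire
offspring-variance estimates rest on enough offspring that their
correlation with the sire's breeding values is dominated by signal rather
than by sampling noise of the variance estimates. With small sire families
(e.g. 20 offspring) that correlation is attenuated by roughly half. The
design is fully configurable (`n_sires`, `n_dams_per_sire`,
`n_offspring_per_dam`).

**Grouping.** Default policy `non_sib` forbids full and half sibs as group
mates, so that a sire's effect on his offspring's groups (via $A_D$) stays
separate from his effect on the group mates of his offspring (via $A_I$).
Random pairing is available, and is used inside selection experiments
where sib encounters are part of the breeding-program reality.

## Variance conventions

All headline statistics use population (i.e. $n$) denominators:

* within-group variance of a pair contributes $(P_i - P_j)^2/4$,
* between-group variance is the variance of pair means,
* phenotypic = between + within holds *exactly*, and
* for independent group mates the within-group variance is half the
  phenotypic variance — the baseline against which competition
  ($\rho < 0$, within > half) and cooperation ($\rho > 0$, within < half)
  are read.

The group-mate correlation $\rho = (\sigma^2_b - \sigma^2_w)/(\sigma^2_b +
\sigma^2_w)$ is then algebraically the intraclass correlation of the
pairs. Sample ($n-1$) versions of every statistic are available via
`method = "sample"`; the per-sire offspring variances in
`sire_variability_correlations()` use the ordinary sample variance, where
the denominator choice is immaterial to a correlation.

At `b_bar = 0` the within-group variance sits very slightly *above* half
of the phenotypic variance and $\rho$ slightly below zero: variation of
`b` around zero is not symmetric in its effect, because divergence under a
negative pair sum outweighs convergence under a positive one (the
difference multiplier enters convexly). This is a property of the model,
not an estimator bias.

## The analytic oracle

Conditioning on $(b_{ij}, b_{ji})$ and unrolling
$d_t = c\,d_{t-1} + \delta_{perm} + \delta_{temp,t}$:

$$E(d_T) = c^T d_0, \qquad
V(d_T) = \Big(\sum_{k=0}^{T-1} c^k\Big)^2 \sigma^2_{perm}
 + \sum_{k=0}^{T-1} c^{2k}\, \sigma^2_{temp} + c^{2T} V(d_0),$$

with $\sigma^2_{perm} = 2(1-r)\sigma^2_{A_{GR}} + 2\sigma^2_{E_p}$ for
mates of relatedness $r$ and $\sigma^2_{temp} = 2\sigma^2_{E_t}$.
Marginalising over the distribution of `b` is left to Monte Carlo; the
closed form deliberately conditions, which is what makes it an independent
check of the simulator rather than a restatement of it. The geometric sums
are evaluated in closed form with an explicit branch at $c = 1$. The test
suite asserts exact agreement of $E(d_T)$ with the deterministic simulator
on a grid of over 100 coefficient/initial-difference/horizon combinations,
and agreement of $V(d_T)$ with Monte-Carlo variances within three standard
errors.

```{r oracle}
p <- sim_params(scenario = 1)
pair_difference_law_from_params(-0.08, -0.08, p, d0 = 2)
```

## Selection experiments

`run_selection_experiment()` iterates simulate → select → mate for
`n_generations`, tracking mean weight, within-group variance, realised
mean `b`, and the three mean breeding values. Choices that the procedure
leaves open and how they are resolved:

* **Sexes** are assigned randomly 1:1 at birth; selected males become
  sires and selected females dams. This keeps a single selected
  proportion (default 11 %) meaningful without sex-specific truncation.
* **Mating**: every selected dam is used once, each mated to a uniformly
  drawn selected sire (sires may serve several dams, as in mass spawning);
  offspring counts are split as evenly as possible across dams to restore
  the fixed population size. Fecundity is unconstrained.
* **Group schemes select whole groups**; the number of groups is rounded
  to nearest, so the realised selected fraction can differ slightly from
  the nominal one.

One dynamic deserves note. The first round of selection produces a one-off
drop in the between-family genetic variance (gametic-phase
disequilibrium), visible as a dip of the within-group variance between the
base generation and generation ~2 under every scheme. The recurrent
directional responses — the trends the three schemes are compared on —
establish themselves after this transient. For group selection on the
mean, whose variance response is small, the test suite therefore assesses
the variance trend over generations 1–10 (and its magnitude relative to
mass selection), while all other responses are assessed on the full
trajectory.

## Estimating the average `b`

From time-series pair records $y_{t,i} = P_{t+1,i} - P_{t,i}$ regressed on
$\Delta_{t,ij} = P_{t,j} - P_{t,i}$, `estimate_fixed_b()` fits a single
intercept and slope by OLS. Two caveats are deliberately surfaced in the
output rather than corrected:

* **Naive standard errors.** Records repeat within individuals and
  groups; no dependence correction is applied.
* **Confounding by permanent effects.** $A_{GR}+E_p$ of the focal enters
  $y$ directly and enters $\Delta$ cumulatively with opposite sign, so
  with permanent growth effects present the pooled slope is pulled well
  below the true average `b` (about $-0.07$ at `b_bar = 0` under the
  default variances — larger than the coefficient itself). The estimator
  is exact on data from the fixed-`b` regression model (temporary noise
  only), which is the regime under which parameter recovery is tested; on
  full-model data it should be read as a descriptive, not unbiased,
  summary. Separating the permanent effects requires the mixed-model
  (random-regression) machinery, which is out of scope here.

## Numerical and reproducibility choices

* All randomness flows from one integer master seed;
  `replicate_seed(seed, r, stream)` derives an order-independent seed per
  replicate and experiment arm, so partial runs and reordered replicates
  reproduce exactly. Derived seeds stay below $2^{31}$.
* Ties in truncation selection are broken by individual id.
* Non-sib matching repairs a uniform random matching by bounded
  re-shuffling of conflicting pairs (plus randomly drawn companions, so
  repair cannot stall); it fails loudly after a bounded number of rounds.
* Degenerate inputs error early: odd cohort sizes, groups of size ≠ 2,
  zero-variance correlations, constant covariates in the regression,
  non-finite effects or weights.

## Problem sizes in the test suite

The suite runs the full family design (4000 pairs) with 40 replicates per
scenario for the scenario-level checks, 100 replicates per scheme for mass
and variance group selection, and 200 for mean group selection (whose
variance trend is the smallest contrast tested); Monte-Carlo oracle checks
use 20 000 pairs. These sizes were chosen so that each assertion's
Monte-Carlo error is small against the tolerance it is tested at. The
acceptance script uses 100 replicates per scenario, matching the canonical
study design.

## What the generator does and does not emulate

The simulator produces idealised breeding-program data: discrete
generations, balanced families, exactly two group mates, no mortality, no
measurement error, normal effects with known variances, and no
environmental trends. Passing tests therefore show that the *model's*
mechanisms behave as derived — competition inflating variability, group
selection recovering indirect effects — not that real populations will
show effects of this size. In real data, group sizes vary, growth is
closer to multiplicative, variances are estimated rather than known, and
the non-genetic structure (tanks, pens, batches) adds variance components
the model omits. Inbreeding accumulates under 10 generations of selection
at 11 %, but the Mendelian-sampling variance is kept at half the base
additive variance (no inbreeding accounting), so late-generation genetic
variances are mildly optimistic.

## Known limitations

* Pairs only; larger groups would need the matrix extension of the
  difference recursion.
* No feedback-explicit interaction model; `b` acts on the lagged
  difference, so there is no simultaneity to resolve.
* No REML/MCMC machinery for the genetic variance components of `b`; the
  OLS estimator addresses only the population average.
* Inherited variability is *emergent* here: there is no explicit breeding
  value for environmental variance, so the package cannot represent
  variability genetics that is unrelated to social interaction.
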