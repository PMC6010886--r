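---
title: "Comparing diversification rates among phylogenies: model, simulators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing diversification rates among phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratecomp)
```

## The model

`ratecomp` asks whether two or more time-calibrated phylogenies accumulated
lineages under the same speciation rate $\lambda$ and extinction rate $\mu$.
Each tree is reduced to its sufficient statistic under a constant-rate
birth–death process: the sampled tip count $N$ and the internal node ages
$t_1 \ge t_2 \ge \dots \ge t_{N-1}$, measured backward from the present
($t_1$ is the crown age). With a known sampling fraction $\rho$ — the
probability that an extant species made it into the tree, assumed missing at
random — the log-likelihood of one tree, conditioned on its crown age and on
both crown lineages leaving sampled descendants, is

$$\log L \;=\; \log\!\big((N-1)!\big) + 2\log p_1(t_1) - 2\log\!\big(1-p_0(t_1)\big)
  + \sum_{j=2}^{N-1}\big[\log\lambda + \log p_1(t_j)\big],$$

with

$$p_0(t) = 1-\frac{\rho(\lambda-\mu)}{\rho\lambda+(\lambda(1-\rho)-\mu)e^{-(\lambda-\mu)t}},
\qquad
p_1(t) = \frac{\rho(\lambda-\mu)^2 e^{-(\lambda-\mu)t}}
             {\big[\rho\lambda+(\lambda(1-\rho)-\mu)e^{-(\lambda-\mu)t}\big]^2}.$$

$p_0(t)$ is the probability that a lineage alive at age $t$ leaves no
sampled descendant; $p_1(t)$ that it leaves exactly one. Independence across
trees makes the joint log-likelihood a sum, so multi-tree hypotheses are
just equality constraints on the per-tree rates: the `equal` null (2
parameters), the `free` alternative ($2m$), the intermediate
`free-speciation` / `free-extinction` models ($m+1$), the pure-birth
`yule-equal` / `yule-free` pair, and a `grouped` model for a-priori tree
classes ($2g$). Nested pairs are compared by the likelihood-ratio statistic
$2\Delta\log L$ against $\chi^2$ with df equal to the parameter-count
difference ($2m-2$, $m-1$, $2g-2$).

Assumptions worth keeping in mind: rates are constant within a tree over
time and across lineages; the trees are correctly time-calibrated,
ultrametric, binary, and conditionally independent; $\rho$ is known, not
estimated; missing taxa are missing at random. Violations (rate
heterogeneity through time, density dependence, clumped missing taxa,
systematically compressed deep branches) can masquerade as rate differences
between trees.

## Numerical design

**Stability.** All probability terms are computed on the log scale.
$\log(1-p_0)$ uses the algebraic form
$\log\rho + \log|\lambda-\mu| - \log|\text{denominator}|$, never the
subtraction $1-p_0$, which cancels catastrophically as $p_0 \to 1$ (large
$\mu t$). The factorial term uses `lgamma`, so thousands of tips do not
overflow. At the ridge $\lambda = \mu$ the closed forms are $0/0$; when
$|\lambda-\mu| < 10^{-9}\max(\lambda, 1)$ the analytic limits
$p_0 = 1-\rho/(1+\rho\lambda t)$ and $p_1 = \rho/(1+\rho\lambda t)^2$ take
over, so the optimizer can cross the ridge. The limit branch was verified
against 50-digit arbitrary-precision evaluations of the full formulas at
$|\lambda-\mu| = 10^{-12}$ (frozen in the test suite — double precision
cannot evaluate the full formulas accurately there).

**Optimization.** Rates are optimized on the log scale, which enforces
positivity without constrained solvers. Models whose rate classes separate
(`equal`, `free`, `grouped`, the Yule family) are fitted blockwise: each
block is a 2-parameter Nelder–Mead search (relative tolerance $10^{-8}$,
default 5 restarts jittered by $e^{U(-1,1)}$) plus an explicit $\mu = 0$
boundary profile, because the extinction MLE frequently sits on that
boundary and a log-scale search can only approach it asymptotically.
`free-speciation` and `free-extinction` share exactly one rate, so they are
fitted by profile likelihood: a golden-section search over the shared rate
(grid-bracketed, with the $\mu=0$ boundary evaluated explicitly) whose
inner problems are independent 1-D solves per tree. This exploits the
model structure exactly rather than approximately, and it is why no
high-dimensional joint search is ever needed. Alternative models are
warm-started from the fitted null and always evaluate the null's solution
as a candidate, so $\log L_\text{alt} \ge \log L_\text{null}$ holds
structurally; residual negative $2\Delta\log L$ within $10^{-4}$ is clamped
to zero, anything larger is reported as an optimization failure rather than
silently truncated. Starting values use the pure-birth growth heuristic
$\lambda_0 = \max(\ln(\bar N/2)/\bar T,\,10^{-6})$, $\mu_0 = \lambda_0/4$.

**Degenerate inputs.** Polytomies are a hard error (resolving them with
zero-length branches would create zero node ages and silently change the
$(N-1)!$ and per-node $\lambda p_1$ accounting); zero-length terminal
branches are fine, zero internal node ages are not. Ties among positive
node ages are allowed — the likelihood is order-independent given the set.
Ultrametricity is checked to a relative tolerance of $10^{-6}$ of tree
depth by default, which absorbs the rounding noise of empirical
chronograms. $\mu > \lambda$ is permitted in evaluation (the formulas
remain valid) but is rarely optimal. `lrt()` checks nesting structurally
from the model constraint maps, not from parameter counts alone.

## What the simulators emulate

`simulate_crown_bd()` is a forward Gillespie simulation started from the
two crown lineages and run for a fixed duration $T$: waiting times are
exponential at total rate $n(\lambda+\mu)$, events are births with
probability $\lambda/(\lambda+\mu)$, and the affected lineage is uniform
among those alive. Extinct lineages are pruned and, for $\rho < 1$, tips
are dropped independently with probability $1-\rho$. A replicate is
accepted only if both crown lineages keep at least one sampled descendant —
so the reconstructed crown age equals $T$ exactly, matching the likelihood's
conditioning — and the extant count reaches `min_tips` (default 5, the
small-tree rejection rule of the power studies; set 2 to disable). This
crown-start design is deliberate: simulating from a single stem lineage
makes the reconstructed crown age random (and the conditional tree sizes
smaller at the same nominal rates), which mismatches a likelihood that
conditions on the crown age. Rejection-rate comparisons between the two
conventions are not interchangeable: at the same nominal rates,
crown-conditioned data contain systematically more information, so power
figures quoted for one convention will overstate or understate the other.

`simulate_yule_NT()` conditions a pure-birth tree jointly on $N$ and $T$:
given those, the non-crown node ages are i.i.d. with CDF
$(1-e^{-\lambda t})/(1-e^{-\lambda T})$ on $(0,T)$ (inverted analytically),
and the topology grows by splitting a uniformly chosen extant lineage at
each age. The exact joint conditioning is implemented only for $\mu = 0$;
for $\mu > 0$ a tip-count match is obtained by rejection
(`n_target`), which is also how the `depth-rates-N` bootstrap conditioning
handles birth–death nulls. Both simulators were validated against each
other distributionally (inverse-CDF draws vs rejection sampling).

What the generator does *not* emulate about real data: phylogenetic
estimation error, non-random taxon sampling, time-varying or
lineage-varying rates, and coalescent-vs-speciation time offsets. Passing
simulation tests therefore demonstrates internal statistical correctness of
the method under its own model, not robustness to those empirical
complications.

## Hypothesis testing choices

The $\chi^2$ reference is the default. Because $\hat\mu$ often sits on the
$\mu = 0$ boundary, a parametric bootstrap (`bootstrap_pvalue()`) is
provided: the null model is refitted, replicate tree sets are simulated
under the null MLEs, and the observed statistic is ranked with the add-one
estimator $(1 + \#\{\text{boot} \ge \text{obs}\})/(n_\text{boot}+1)$, which
never returns 0. Whether bootstrap replicates should match only each
observed tree's crown age and the fitted rates (`depth-rates`) or
additionally its tip count (`depth-rates-N`) is genuinely unsettled; both
are implemented, with `depth-rates` the default since the likelihood itself
is not conditioned on $N$. The binomial check used in the simulation
summaries is one-sided (greater): the question asked of a type-I-error
estimate is whether it *exceeds* the nominal 0.05.

## The simulation studies

The `run_*()` experiments reproduce the method's operating characteristics:
a null grid over expected richnesses $E(N) \in \{20, 50, 100, 200, 500\}$
at extinction fraction $0.25$ and depth $T = 100$ (rates solved by
`rates_from_EN()`, which inverts $E(N) = 2e^{(\lambda-\mu)T}$); an
unequal-depth null ($T_1 = 100$, $T_2 = 141.14$, shared rates
$\lambda = 0.052$, $\mu = 0.013$); power sweeps in speciation
($\lambda_2 \in \{0.045, \dots, 0.075\}$ against $\lambda_1 = 0.052$),
extinction, and both; a multi-tree design (one fast tree, $n - 1$ slow
ones); and small conditioned Yule pairs ($\lambda$ 0.04 vs 0.08, equal $N$
and matched depths). Two unstated constants had to be chosen: the shared
$\lambda$ of the extinction sweep is 0.075, the smallest round value from
the study's own rate set for which every richness target up to 1000 keeps
$\mu \ge 0$; and the crossing extinction fractions of the "both" sweep
interpolate linearly, $\{0.35, 0.30, 0.25, 0.20, 0.15\}$ against its
reverse. The `min_tips = 5` rejection rule is stated only for the power
studies; it is applied to the null grids too, for consistency, and recorded
in each experiment's metadata.

Every experiment derives one RNG stream per replicate from its base seed,
so runs are bit-reproducible and any single replicate can be regenerated in
isolation. Summaries always carry Monte-Carlo standard errors.

**Problem sizes.** The shipped test suite runs the null studies at their
reference scale (500 replicates per condition, where a rejection-rate
estimate carries a Monte-Carlo standard error of about 0.01) and the power
studies at desk scale — 150 replicates per power-sweep condition, 200 per
multi-tree design, 500 small-Yule pairs — sizes chosen so Monte-Carlo
standard errors (0.01–0.04 on a rejection rate) stay well inside the
replication bands being checked. `scripts/acceptance.R` uses 500 replicates
(200 for the multi-tree design) throughout.

## Known limitations

* Constant rates only; no time-varying, diversity-dependent, or
  trait-dependent extensions, and no stem-age or survival-only
  conditionings of the likelihood.
* $\rho$ must be known; it is never estimated, and clumped (phylogenetically
  autocorrelated) missingness violates the sampling model in ways the
  method cannot detect.
* Extinction estimates inherit the well-known upward boundary bias at
  $\mu = 0$ and the general difficulty of separating $\mu$ from $\lambda$
  in reconstructed trees; expect wide scatter in $\hat\mu$ on small trees.
* The exact $(N, T)$ joint conditioning is pure-birth only; birth–death
  tip-count conditioning falls back to rejection sampling and can be slow
  or fail (with a clear error) when the requested $N$ is improbable.
* Power figures depend on the simulator's conditioning convention (crown
  vs stem start); comparisons with numbers generated under another
  convention must account for that.
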