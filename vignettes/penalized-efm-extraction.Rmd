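---
title: "Frequency-penalized LP extraction of elementary flux modes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-penalized LP extraction of elementary flux modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxpen)
```

## The model

A metabolism is represented by its stoichiometric matrix $S$ (rows =
metabolites, columns = reactions). A flux vector $v$ describes rates at
which the reactions run; at steady state every internal metabolite is
produced and consumed at equal rates,

$$S\,v = 0, \qquad v_r \ge 0 \;\; \forall r,$$

where nonnegativity encodes the thermodynamic direction of each reaction.
Reversible reactions are first *de-doubled* — split into a forward and a
negated backward column — so that the sign constraint becomes plain
nonnegativity on the split network (`split_reversible()`).

A **pathway** (flux mode) is a nonzero, nonnegative steady-state flux
vector, identified with its *support* (the set of reactions with nonzero
flux). An **elementary flux mode** (EFM) is a pathway whose support
strictly contains no other pathway's support; EFMs are the canonical
generators of the flux cone, and any pathway is a nonnegative combination
of them.

## Extraction by repeated linear programming

`solve_iteration()` solves, per iteration,

$$\min \textstyle\sum_i w_i v_i \quad \text{s.t.} \quad S v = 0,\; v \ge 0,\;
  v_j \ge c \;\; \forall j \in \text{seed},$$

where the *seed* is a small random set of reactions forced to carry flux.
Without the seed the optimum is the useless all-zero vector; with it, the
minimization drives all unforced flux to zero and the optimal vertex is a
support-minimal — typically elementary — pathway through the seeded
reactions. Because the feasible set is a cone, the floor $c$ only fixes the
scale; the default $c = 1$ is arbitrary and harmless. Positive seeds cannot
express contradictions of the form "produce a metabolite nothing may
consume *and* forbid its consumers", so infeasibility arises only when a
seeded reaction (combination) is structurally blocked; infeasible seeds are
discarded and redrawn rather than counted.

The repeated-LP extractor (`run_extraction()`) draws a fresh uniform
$k$-reaction seed per iteration ($k = 4$ by default, the protocol used for
all reference experiments here) and collects solutions until `N_target`
feasible ones exist. A deterministic solver maps every (seed, weights) pair
to the same vertex, so the run is a pure function of the RNG seed — which
is what makes experiments bit-reproducible.

## Penalization

Deterministic solvers fall into the same vertices again and again: a few
structurally favoured reactions dominate the solution set while others
never appear. The remedy implemented here biases the objective away from
overused reactions. With $O_i$ the number of collected solutions containing
reaction $i$ and $F_i = O_i/N$ its running frequency, the objective weights
are

$$w_i = 1 + p\,F_i,$$

with a single tunable *penalization* $p \ge 0$ (dimensionless; default 0 =
classic unweighted extraction; the reference experiments use
$p \in \{2, 5, 20\}$). Weights stay in $[1, 1+p]$: frequent reactions
become expensive but are never forbidden — unlike negative seeds, raising a
weight can never cause infeasibility. Three weighting modes are exposed:

* `dynamic` (default): weights recomputed from the running $F$ before each
  iteration — the self-adjusting reading of the procedure;
* `static`: weights fixed from a supplied frequency vector, e.g. a prior
  unpenalized experiment — the two-experiment reading;
* `off`: unit weights, exactly equivalent to `p = 0` (asserted by test).

Both readings are defensible from the protocol description the method
comes from; we default to `dynamic` because it needs no reference run and
converges to the same qualitative behaviour, and we keep `static` because
penalizing against a converged profile gives a cleaner A/B comparison
design when one wants it.

## Comparing experiments

Whether penalization *changed* an experiment is judged on the frequency
vectors of two runs, aligned by reaction (`compare_frequency_tables()`):

* **Wilcoxon signed-rank** (`wilcoxon_signed_rank()`), two-sided, zero
  differences excluded. For up to 25 nonzero pairs the exact null is
  computed by convolution over midranks — unlike the textbook exact test
  this remains valid under tied differences, which frequency vectors
  (multiples of $1/N$) produce constantly; beyond that a tie-corrected
  normal approximation is used. High p-values mean the two runs are
  statistically alike.
* **Chi-bar-squared** (`chi_bar_squared()`),
  $\bar\chi^2 = \sum_{F_i > 0} (F'_i - F_i)^2 / F_i$. Reaction frequencies
  are structurally dependent (coupled reactions move together), so this
  statistic is *not* referred to a $\chi^2$ distribution: it is reported as
  a raw divergence, larger meaning more different. Reactions the reference
  run never used are skipped and counted, so representativeness gaps stay
  visible instead of becoming infinities.

A caution that our own experiments bear out: the signed-rank test assumes
independent pairs, and coupled reaction modules violate that assumption in
the same way the chi-square does. On the strongly coupled core *E. coli*
network, two *identically configured* unpenalized runs are declared
significantly different in a majority of trials at 5000 iterations —
spurious significance caused purely by the inflated variance of the rank
sum under positive inter-pair correlation. The chi-bar divergence, used as
an ordinal measure, is robust in the same experiments: its median over
trials increases strictly with $p$ at every problem size we run. Treat
Wilcoxon p-values on frequency vectors as descriptive, not inferential, on
networks with strong coupling.

## Elementarity and the brute-force oracle

A support $T$ is elementary iff the steady-state space restricted to its
columns is a single ray, i.e. $\operatorname{rank} S_{\cdot T} = |T| - 1$
(`is_elementary()`; SVD rank with a relative tolerance of $10^{-9}$, exact
in practice for the small integer stoichiometries of the fixtures). The
test depends on the support only, hence is invariant to flux rescaling,
and it refuses supports that admit no pathway, where the question is
undefined.

For networks of at most 15 split reactions, `brute_force_efms()`
enumerates every subset in increasing size, keeps those that admit a
pathway with exactly that support (a feasibility LP with $v \ge 1$ on the
subset and $v = 0$ off it), and prunes supersets of accepted supports. It
shares no logic with the rank test or with the extraction path — the
enumeration is the ground truth the others are checked against. Splitting
a reversible reaction always introduces the futile *two-cycle*
$\{fwd, bwd\}$, a genuine steady-state ray with no biological meaning;
`deduplicate(..., drop_two_cycles = TRUE)` removes such supports from
diversity counts while the raw output retains them.

## The simplex core

The per-iteration LP is solved by a dense two-phase simplex written for
this package (`src/simplex.cpp`). Three numerical choices matter:

* **Bland's smallest-index pivoting** in both phases. The flux cone makes
  every basic feasible solution degenerate, so an anti-cycling rule is a
  correctness requirement, and Bland's rule also makes vertex selection
  deterministic — identical inputs give identical supports.
* **Row equilibration**: each constraint row is scaled to unit max-norm
  before solving. Genome-scale matrices mix coefficients across four
  orders of magnitude (biomass stoichiometries), which otherwise lets
  roundoff masquerade as negative reduced costs.
* **A tolerance ladder**: the pivot tolerance starts at
  `solver_feas_tol` ($10^{-9}$) and is loosened deterministically
  ($\times 100$, $\times 10^4$) if the instance stalls, before reporting a
  retriable failure. Seed bounds enter by the substitution
  $u = v - c\,\mathbf{1}_{\text{seed}}$, keeping the program in equality
  standard form.

The solver was validated against an independent interior-point/simplex
implementation on randomized instances (feasibility status and optimal
objective agreed on all of them) and against hand-solved cases; those
expected values are frozen in the unit tests.

Supports are read off at a *relative* threshold,
$v_i > 10^{-6} \max_j v_j$, because the solution scale is arbitrary (the
cone again); an absolute threshold would make support membership depend on
the seed floor $c$.

## Synthetic fixtures and what they do (not) show

* `make_chain(L)` — a linear pathway with one EFM; the degenerate
  reference where every run must return the same support and all
  frequencies converge to 1.
* `make_parallel(b)` — source, $b$ exchangeable branches, sink; exactly
  $b$ EFMs. The canonical diversity testbed: with single-reaction seeds an
  unpenalized deterministic solver may keep choosing the same branch,
  penalization must spread solutions across all $b$.
* `make_random(m, n, density, reversible_fraction, rng_seed)` — integer
  coefficients in $\{-2,-1,1,2\}$ placed uniformly, rejection-resampled
  until a nontrivial pathway exists. Integer stoichiometry keeps rank
  checks exact; rejection is necessary because sparse random matrices
  often admit only $v = 0$. The reference fixture used across the tests is
  `make_random(8, 20, 0.3, 0.2, rng_seed = 1)`: about 2.4 metabolites per
  reaction and a 20% reversible share, chosen once to mirror the sparsity
  and reversibility ballpark of curated models at toy scale.

What uniform random fixtures do *not* emulate is the hub-dominated usage
profile of real metabolisms — a few universally used reactions and a long
tail of rare ones. Two consequences, measured and documented here rather
than hidden: with $k$-reaction seeds on $n$ split reactions every
frequency is floored near $k/n$ (on 20 reactions the floor is high, on 141
it is negligible), and the sign-count asymmetry that makes a signed-rank
test sensitive to penalization (many rare reactions each gaining a little,
few hubs losing a lot) is largely absent at $n = 20$. Passing diversity
tests on fixtures therefore demonstrates correctness of the machinery, not
effect sizes on real networks; the chi-bar ladder on the core *E. coli*
model is the realistic-scale check.

## Reference problem sizes

The package's own reference experiments, used by the acceptance script and
the protocol-scale tests, are: Wilcoxon comparisons on the 20-reaction
fixture at 5000 iterations per run; the chi-bar penalization ladder
($p = 2, 5, 20$ against $p = 0$) on the core *E. coli* model at 2000
iterations per run; both as medians over 10 independently seeded trials.
Representativeness is measured on `make_parallel(5)` with $k = 1$,
$N = 200$, over 20 RNG seeds. These sizes are the package's choices for a
single-workstation protocol; the qualitative directions they probe are
already stable there (the chi-bar ladder is monotone in every trial, not
just in the median).

## Degenerate inputs and edge rules

* The all-zero flux vector is never a pathway; `is_pathway()` excludes it
  explicitly.
* Seeds may contain both split directions of one reversible reaction —
  feasible (the two-cycle) but vacuous; `no_two_cycle_seeds = TRUE`
  redraws such seeds.
* Repeated identical solutions increment occurrences: $F_i = O_i/N$ is
  per-iteration, which is what keeps it in $[0,1]$.
* Infeasible seeds do not advance $N$; a run of 1000 consecutive
  infeasible seeds (configurable) aborts with partial results and a
  `drought` status instead of spinning forever.
* All-zero frequency differences give a Wilcoxon p of exactly 1;
  comparing a table with itself gives $\bar\chi^2 = 0$ exactly.

## Known limitations

* No enumeration completeness: repeated LP extraction samples the EFM set,
  it does not enumerate it, and no coverage guarantee exists beyond the
  empirical representativeness measurements.
* The brute-force oracle is exponential and hard-capped at 15 split
  reactions.
* Reversibility is taken from the sign of the lower flux bound; bound
  magnitudes are ignored throughout, so models whose biology lives in
  finite bounds (uptake limits) are analysed only up to cone structure.
  De-doubled reaction counts consequently depend on the bound conventions
  of the model distribution in use.
* Wilcoxon p-values on coupled networks are miscalibrated (see above);
  they are reported because they are the field's convention, with the
  chi-bar divergence as the robust companion.
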