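---
title: "Stochastic community assembly: model, analytics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic community assembly: model, analytics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commassembly)
```

## The model and its assumptions

`commassembly` models the assembly of an initially empty community from a
fixed external species pool. Species $i$ carries three traits: a division
rate $r_i$, a dispersal (arrival-and-establishment) rate $c_i$, and an
optional death rate $d_i$ (zero in the core model). Community size
$N = \sum_i n_i$ is bounded by a carrying capacity $K$; both division and
dispersal are logistically saturated by $(1 - N/K)$, so the per-capita
division rate of species $i$ is $r_i (1 - N/K)$ and dispersers establish
at rate $c_i (1 - N/K)$. The model assumes:

* a *fixed* pool — community feedback on the pool is ignored;
* *neutral competition for space* — no facilitation, inhibition or other
  interspecific interaction beyond the shared saturation term;
* *identical habitats* — replicate communities differ only through the
  randomness of event timing and ordering.

Saturated dispersal reflects density-dependent invasion resistance: an
arriving propagule establishes less easily in a nearly full community.
Setting `saturated_dispersal = FALSE` on the model removes the factor from
dispersal propensities (dispersal is still forced off at $N = K$ so
assembly terminates); this changes event *timing* but, as the tests
confirm, not the final-composition distribution in any regime far from
the boundary cases, because final compositions are governed by the
recruit-identity kernel below.

## Exact analytics

In the death-free model every event increases $N$ by one, so assembly is a
sequence of $K$ recruitments. The recruit is species A with probability

$$\alpha(N_A, N) = \frac{r_A N_A + c_A}{r_A N_A + c_A + r_B (N - N_A) + c_B},$$

in which the saturation factor cancels — $\alpha$, and hence every result
built on it, is insensitive to the form of density dependence (logistic,
Gompertz, Richards). Iterating the associated master equation from
$P(0,0) = 1$ gives the abundance fluctuation distribution (AFD)
$P(N_A, N)$: the distribution of one species' abundance *across replicate
communities*, to be distinguished from the within-community species
abundance distribution. `afd_exact()` performs this forward recursion with
a rolling $O(N)$-memory update.

At the two boundaries the recursion telescopes into products with
Pochhammer (rising-factorial) closed forms, e.g.

$$P(0, N) = \frac{c_B}{c_A + c_B}\,
\frac{(1 + c_B/r_B)_{N-1}}{(1 + (c_A + c_B)/r_B)_{N-1}},$$

implemented in `prob_all_B()` / `prob_all_A()`, from which
`prob_cooccurrence()` returns $P_\mathrm{cooc} = 1 - P(0,K) - P(K,K)$.

When both division rates are equal (the neutral case) $\alpha$ is linear
in $N_A$, which closes the moment hierarchy: `neutral_moments()`
propagates the first four raw moments through an $O(N)$ recursion, and
the mean is *exactly* $N c_A / (c_A + c_B)$ at every $N$ — the same value
in the low- and high-dispersal limits. From the moments, Sarle's
bimodality coefficient $\mathrm{BC} = (\gamma^2 + 1)/\kappa$ (skewness
$\gamma$, **non-excess** kurtosis $\kappa$; this convention is fixed
package-wide) has closed forms: `bc_symmetric()` for equal dispersal
rates, including the finite-$N$ expression and its large-$N$ limit
$(2c + 3r)/(3(2c + r))$, and `bc_asymmetric()` for unequal dispersal
rates at large $N$.

Three limit distributions complete the picture: a Bernoulli-like two-point
AFD as $c \to 0$ (each community monodominant, species chosen with
probability $c_i/\sum_j c_j$, `monodominance_probs()`), the flat AFD
$P(N_A, N) = 1/(N+1)$ when all four rates coincide
(`afd_uniform_solution()`), and $\mathrm{Binomial}(N, c_A/(c_A+c_B))$ as
$c \to \infty$ (`afd_binomial_limit()`, multi-species version
`multinomial_limit()`).

The dispersal timescale $T_c = 1/c$ and the logistic growth timescale
$T_r = \sum_{N=1}^{K-1} 1/[r(1-N/K)N] \approx 2\ln(K)/r$ meet at the
limiting dispersal rate $c_\mathrm{lim} = r/(2 \ln K)$ (`timescales()`,
`c_lim()`), which separates division-driven from dispersal-driven
assembly; the co-occurrence curve passes $1/2$ in its neighbourhood.

### A note on the flat-AFD constant

For the all-rates-equal case the recruit kernel is
$\alpha = (N_A + 1)/(N + 2)$, and direct substitution (or a two-step hand
recursion at $N = 2$) shows the flat solution has constant $1/(N+1)$ over
the $N + 1$ compositions $N_A = 0, \dots, N$ — this is what
`afd_uniform_solution()` returns, and what the DP oracle confirms.

## Simulation design

Two simulation paths are provided, both with compiled cores:

* **Full Gillespie** (`assemble_one()`, `assemble_with_death()`):
  exponential waiting times over all division/dispersal/death
  propensities. Required when death rates are positive, when dispersal is
  unsaturated, or when event-time trajectories are wanted.
* **Embedded jump chain** (`assemble_ensemble()`, the default
  `fast_path`): death-free final compositions only. Each of the $K$
  recruits is drawn directly from $\alpha$, which is
  distribution-identical to Gillespie for final compositions at $O(K)$
  cost — ensembles of $10^3$ replicates at $K = 10^5$ take about a
  second. The fast path refuses models with death (events no longer
  monotone in $N$) and models with unsaturated dispersal (the saturation
  factor then fails to cancel from the recruit probability).

**Random numbers.** One master seed initialises R's global RNG and
replicates are drawn sequentially from that single stream, making every
ensemble bit-for-bit reproducible from `(model, n_replicates,
master_seed)`. Per-replicate counter-based streams (which would add
order-independence under parallel execution) were considered and dropped:
the package runs single-threaded, and the reproducibility contract the
tests assert is the sequential one.

**Death and stopping.** With $0 < d < r$ (the only supported death
regime; $d \ge r$ is rejected at construction) the community no longer
absorbs at $K$ but fluctuates around the logistic equilibrium
$K(1 - d/r)$. Because the process then has no natural endpoint, the
stopping rule is explicit (`stopping_rule()`): `"equilibrium"` stops at
the first passage of $N$ to $\lceil K(1 - \max_i d_i/r_i)\rceil$ (the
default), `"fixed_time"` at a stated horizon. Extinction at the stopping
time is reported as a zero row, never resampled; relative-abundance
metrics exclude such rows and report the count.

## Empirical metrics

`regime_metrics()` summarises a replicate-by-species table (simulated or
read from delimited text) by the bimodality coefficient, per-species mean
relative abundance, monodominance fractions, co-occurrence fraction
(richness $\ge 2$; presence means count $\ge 1$, matching the integer
state space) and mean pairwise dissimilarity. Design choices:

* **Population moments by default.** `bimodality_coefficient()` uses
  divide-by-$n$ moments so empirical values converge to the analytic
  coefficients; the finite-sample-corrected Sarle variant is an explicit
  opt-in (`bias_corrected = TRUE`) because there is no single canonical
  choice for small cohorts.
* **Bray–Curtis dissimilarity** (via `vegan::vegdist()`) on relative
  abundances is used as the between-community metric. It is a
  representative choice of β-diversity metric, not a canonical one;
  any abundance-based dissimilarity would show the same regime contrast
  (≈ 0.5 under dispersal limitation, small under high dispersal). Exact
  all-pairs computation is used up to 2000 replicates, a uniform random
  pair subsample above.
* **Regime labels** use BC thresholds around the uniform value $5/9$ with
  a band of $\pm 0.05$: above the band is called low-dispersal (bimodal),
  below high-dispersal (unimodal), inside intermediate.
* The dispersal-ratio estimator $\hat\rho = m/(1 - m)$ from the mean
  relative abundance $m$ is exact in the two extreme regimes and a good
  approximation elsewhere in the neutral model.

## What the generator emulates — and what it does not

Simulated ensembles play the role of replicated colonisation experiments:
many identical, independent habitats filled from one pool, with
demographic stochasticity as the only source of variation. The canonical
scenarios (`scenario_preset()`) mirror this design: neutral symmetric
pools at dispersal rates 0.5, 1 and 2; a two-fold dispersal advantage; a
5% division advantage ($s = 0.05$); and replicated 59-host cohorts at
four dispersal conditions, neutral versus a 1.5-fold dispersal advantage.
Real data differ in ways the model deliberately omits: measurement noise
and detection limits, pool composition drift, host-to-host environmental
variation, interspecific interactions, and label artefacts in
fluorescence-based strain counting. Passing tests therefore demonstrate
internal consistency of model, analytics and simulator — not that any
particular real system satisfies the model's assumptions.

## Numerical choices

* Pochhammer ratios are computed as differences of `lgamma` values and
  exponentiated once; direct products overflow near $K = 10^5$.
* `afd_exact()` is capped at $N \le 5000$ by default (override via
  `cap`): the DP costs $O(N^2)$ while every large-$K$ quantity of
  interest has an $O(N)$ or $O(1)$ form.
* $1 - P_0 - P_K$ is clipped into $[0,1]$ to absorb $10^{-16}$-scale
  negative residue.
* Probabilities from the DP and the closed forms agree to $10^{-12}$
  *absolute*; over a thousand multiply-add steps the DP accumulates
  rounding of order $10^{-13}$, so comparisons in the tests are on the
  absolute scale natural for probabilities.
* Empirical-vs-exact distribution comparisons use total variation on a
  20-bin aggregation of the support: per-atom TV over $K + 1$ support
  points carries an $O(\sqrt{K/n})$ sampling bias that would swamp any
  real discrepancy at feasible ensemble sizes.
* Kurtosis is everywhere non-excess ($\kappa \ge 1$, with equality for a
  symmetric two-point distribution), so BC lands in $[1/3, 1]$ across the
  regimes.

## Problem sizes

The test-suite and preset defaults use $K = 10^3$ ensembles of $10^3$
replicates (and $10^4$ where convergence of empirical BC is checked),
which the analytics show to be deep inside the same three regimes as
$K = 10^5$: the large-$N$ BC is within $10^{-3}$ of its limit by
$N = 10^4$, and regime boundaries scale only logarithmically through
$c_\mathrm{lim} = r/(2\ln K)$. The presets accept `paper_scale = TRUE` to
restore $K = 10^5$ (cohort preset $2 \times 10^5$), which the embedded
chain handles in seconds. Closed-form curves (`run_analytic()`) are always
evaluated at $K = 10^5$ — they are $O(1)$.

## Known limitations

* Non-neutral exact answers come only from the DP ($N \le$ cap); the
  non-neutral master equation has no closed-form solution, and published
  approximations for that case are not implemented.
* The probability that at least two of $S > 2$ species co-occur is
  available only by simulation; the closed form is two-species.
* The death model supports $d \ll r$; comparable death and division rates
  are a qualitatively different (decline-to-extinction or diffusion-
  dominated) regime and are rejected rather than guessed at.
* The dispersal-ratio estimator assumes neutrality; with $s \ne 0$ its
  bias grows in the intermediate regime where selection is visible.
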