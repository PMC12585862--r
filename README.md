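# commassembly

Stochastic assembly of microbial communities: simulation and exact
analytics for abundance fluctuation distributions.

## The problem

When many initially sterile habitats — germ-free host guts, fresh
environmental patches, replicate microcosms — are colonised from the same
microbial pool, the resulting communities can differ wildly in composition
even though every habitat saw identical conditions. `commassembly`
implements a minimal stochastic model of this process for ecologists and
modellers who want quantitative predictions for that variation: which
species co-occur within a community (richness, an α-diversity property)
and how much replicate communities differ from each other (dissimilarity,
a β-diversity property).

## The model

A community assembles from an empty state by two kinds of events. Species
*i* (abundance *n<sub>i</sub>*, community size *N* = Σ *n<sub>i</sub>*,
carrying capacity *K*) gains individuals by

* **dispersal** from the pool at rate *c<sub>i</sub>* (1 − *N*/*K*), and
* **division** at rate *r<sub>i</sub>* (1 − *N*/*K*) *n<sub>i</sub>*,

until *N* = *K* (an optional per-capita death rate *d<sub>i</sub>* ≪
*r<sub>i</sub>* is supported, in which case the community settles near
*K*(1 − *d*/*r*)). Because every death-free event adds one individual, the
identity of each successive recruit is species A with probability

α(*N<sub>A</sub>*, *N*) = (*r<sub>A</sub>N<sub>A</sub>* + *c<sub>A</sub>*) /
(*r<sub>A</sub>N<sub>A</sub>* + *c<sub>A</sub>* + *r<sub>B</sub>*(*N* − *N<sub>A</sub>*) + *c<sub>B</sub>*),

independent of the form of density dependence. Iterating α gives the exact
**abundance fluctuation distribution** (AFD) *P*(*N<sub>A</sub>*, *N*) —
the distribution of one species' abundance across replicate communities —
and Pochhammer closed forms for the monodominance probabilities
*P*(0, *K*), *P*(*K*, *K*) and the co-occurrence probability
*P*<sub>cooc</sub> = 1 − *P*(0, *K*) − *P*(*K*, *K*).

The ratio of the dispersal timescale *T<sub>c</sub>* = 1/*c* to the
logistic growth timescale *T<sub>r</sub>* ≈ 2 ln(*K*)/*r* sets three
assembly regimes, summarised by Sarle's bimodality coefficient
BC = (γ² + 1)/κ of the AFD:

| regime | dispersal | AFD | BC |
|---|---|---|---|
| low-dispersal | *c* ≪ *c*<sub>lim</sub> | bimodal (Bernoulli-like) | → 1 |
| intermediate | *c* = *r* | uniform | 5/9 |
| high-dispersal | *c* ≫ *r* | unimodal (binomial) | → 1/3 |

with *c*<sub>lim</sub> = *r* / (2 ln *K*). The mean relative abundance of
a species equals *c<sub>A</sub>*/(*c<sub>A</sub>* + *c<sub>B</sub>*) in
both extreme regimes, which lets a dispersal-rate ratio be read off
replicate data as ρ̂ = m/(1 − m).

## Worked example

Two neutrally dividing species, species A dispersing twice as fast
(*c<sub>A</sub>* = 2, *c<sub>B</sub>* = 1, *r* = 1, *K* = 1000):

```r
library(commassembly)
m   <- two_species_pool(r_A = 1, r_B = 1, c_A = 2, c_B = 1, K = 1000)
ens <- assemble_ensemble(m, n_replicates = 1000, master_seed = 42)
regime_metrics(ens)
#> <regime_metrics> 1000 replicates (0 excluded)
#>   BC = 0.5470  ->  intermediate regime (5/9 = uniform threshold)
#>   mean relative abundance: A = 0.667, B = 0.333
#>   co-occurrence fraction = 0.999, mean Bray-Curtis = 0.266
bc_asymmetric(1, 2, 1)                      # analytic large-N BC
#> [1] 0.55
prob_cooccurrence(1000, m)                  # exact co-occurrence probability
#> [1] 0.998002
dispersal_ratio_estimate(ens)               # recovers c_A / c_B = 2
#> [1] 2.002597
```

The empirical BC (0.547) sits at the analytic value 0.55 — mean dispersal
(*c<sub>A</sub>* + *c<sub>B</sub>*)/2 = 1.5 is close to *r*, so the AFD is
near-uniform — and the mean relative abundance 0.667 matches
*c<sub>A</sub>*/(*c<sub>A</sub>* + *c<sub>B</sub>*) = 2/3, from which the
dispersal ratio 2 is recovered.

A command-line front end wraps the same functions
(`exec/commassembly simulate|analytic|metrics|scenario`) with YAML
scenario configs, tab-delimited tables and JSON metric summaries; the
`scenario` subcommand ships the canonical presets (`fig2`, `fig3`, `fig4`,
`fig6`).

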