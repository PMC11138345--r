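# breedalloc

Optimized progeny allocation for small genomic-selection breeding schemes.

## The problem

A recurrent selection program with a fixed budget must decide, every
generation, how many progenies to raise from each mating pair. Equal
allocation is the usual default; `breedalloc` instead treats the allocation
rule as a tunable policy and optimizes it, by forward simulation, for the
genetic gain at the end of the scheme. The setting is a small program —
a parent panel of a few hundred genotypes, a few generations, e.g. breeding
of neglected and underutilized species — where every seedling counts.

## The method

Each generation: the top *N*<sub>sel</sub> genotypes by **weighted breeding
value** (WBV, rare favorable alleles up-weighted by *p*<sup>−1/2</sup>) are
selected; all pairwise crosses including selfings form
*N*<sub>pair</sub> = *N*<sub>sel</sub>(*N*<sub>sel</sub>+1)/2 mating pairs;
the progeny budget *N*<sub>pop</sub> is divided by a softmax over weighted
pair features:

> **b** = ⌊ *N*<sub>pop</sub> · softmax(Ω h(τ)) ⌋  (+ largest-fraction remainder)

where the rows of Ω describe each pair by any subset of

* **BV** — mean parental breeding value (= expected progeny value),
* **WBV** — mean parental weighted breeding value,
* **GVP** — the expected genetic variance of the progeny of that cross,
  computed from parental phase and recombination fractions:
  v = ¼(αᵀC⁽ᴹ⁾α + αᵀC⁽ᴾ⁾α), a usefulness-type criterion,

and h(τ) ∈ [0,2] per feature and generation. With h = 0 the rule reduces
exactly to equal allocation. Progeny genomes are simulated by meiosis along
a linkage map (Kosambi map function). The weight schedule h(0..T−1) is
fitted with **StoSOO**, a budgeted stochastic tree-search optimizer, against
the mean final gain over replicate simulations. Everything is reproducible
from a single seed.

## A worked example

```r
library(breedalloc)

world <- sim_world(n_chromosomes = 2, markers_per_chromosome = 50,
                   n_haplotypes = 200, n_founders = 200, n_panel = 30,
                   qtl_per_chromosome = 5, seed = 7)
cfg <- scheme_config(n_pop = 60, n_sel = 8,
                     feature_set = c("BV", "WBV", "GVP"))
fit <- optimize_allocation(world, cfg, budget = 300, n_rep = 20, seed = 7)
summary(fit, n_schemes = 500)
```

```
Optimized progeny-allocation weight schedule
  features: BV, WBV, GVP | generations: 4 | 300 evaluations x 20 sims
  expected final gain at optimum: 1.2509
        BV   WBV GVP
tau0 0.333 0.333   1
tau1 1.000 0.333   1
tau2 1.000 1.000   1
tau3 1.000 1.000   1

Evaluation over 500 paired schemes:
  mean final gain optimized: 1.2272 | equal allocation: 1.1701
  improvement over equal allocation: 4.88%
```

The fitted object holds the T × Q weight schedule (`coef(fit)`, entries in
[0, 2]): here the optimizer allocates gently in the first generation and
pulls increasingly hard on the parental means later, while retaining the
progeny-variance feature throughout. The summary re-simulates the scheme
500 times with the fitted softmax policy and with equal allocation under
paired random streams: the optimized allocation improves the mean final
gain of the top-5 genotypes by about 5% in four generations on this small
world. `plot(fit)` draws the optimizer's convergence;
`simulate(fit, nsim)` returns per-replicate trajectories; and
`run_scheme(..., keep_tables = TRUE)` exports per-generation crossing
tables (`write_crossing_table()`) listing each pair's progeny count,
expected WBV and softmax probability — the artifact a breeder would take to
the crossing block.

The methods vignette (`vignettes/allocation-optimization.Rmd`) documents
the model, the founder-genome generator, the StoSOO internals and the
package's design choices.

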