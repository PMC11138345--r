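---
title: "Optimizing progeny allocation in genomic-selection breeding schemes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing progeny allocation in genomic-selection breeding schemes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a recurrent genomic-selection program a breeder repeatedly selects
parents, crosses them, and raises a fixed number of progenies. Selection and
pairing are well studied; how to *divide the progeny budget among the mating
pairs* is usually left to a rule of thumb (equal allocation, or a few extra
seedlings for the most promising crosses). Yet the division matters: pouring
the budget into the best pairs raises short-term gain but erodes the genetic
variance that later cycles feed on, while spreading it evenly wastes
opportunities. This package treats the allocation rule itself as the object
to optimize, for small programs — e.g. neglected and underutilized species —
where the budget is a few hundred plants and only a handful of generations
are affordable.

`breedalloc` simulates the whole scheme forward in time and tunes a
parameterized allocation policy against the simulated outcome. The fitted
object is returned by `optimize_allocation()`, the package's model-fitting
front end.

## The scheme

One cycle at generation $t$ (defaults in parentheses, see
`scheme_config()`):

1. **Selection.** The $N_{sel}$ (15) genotypes with the highest weighted
   breeding value are kept as parent candidates.
2. **Pairing.** All unordered pairs including selfings form the crossing
   block: $N_{pair} = N_{sel}(N_{sel}+1)/2$ (120) pairs.
3. **Allocation.** The progeny budget $N_{pop}$ (250) is divided among the
   pairs (below).
4. **Meiosis.** Each progeny receives one gamete from each parent,
   simulated as a walk along the linkage map with Kosambi recombination
   fractions between adjacent markers.

The cycle repeats to generation $T$ (4). Outcomes are summarized by
$u_{top}(t)$, the mean true genotypic value of the best $N_{top}$ (5)
genotypes, and the final gain $g(T) = u_{top}(T) - u_{top}(0)$.

All marker effects are treated as known (heritability 1, selection acts on
true values): the package isolates the allocation question from the
prediction question, so its results are upper bounds with respect to
prediction accuracy.

## Selection criteria and pair features

With dosage $w_m \in \{-1, 0, 1\}$ and additive effect $\alpha_m$ at QTL
$m$:

* **BV** (breeding value, equal to the true genotypic value here):
  $u^{BV} = \sum_m w_m \alpha_m$.
* **WBV** (weighted breeding value):
  $u^{WBV} = \sum_m w_m \alpha_m \, p_m^{-1/2}$, where $p_m$ is the
  frequency of the *favorable* allele (the allele whose addition increases
  the trait). Rare favorable alleles are up-weighted, which protects
  diversity; selection (step 1) always uses WBV. When a favorable allele is
  absent its term is dropped — it is constant across individuals and cannot
  affect a ranking, and this avoids $p^{-1/2}$ at zero. Reading $p_m$ as
  the frequency of the counted allele instead is a plausible alternative
  convention; the favorable-allele reading follows the weighted-selection
  literature and is what the package implements.
* **GVP** (expected genetic variance of progeny of a cross): for parents
  with phased haplotypes $x^{(1)}, x^{(2)}$,
  $$v = \tfrac14\left(\alpha^\top C^{(M)} \alpha +
                       \alpha^\top C^{(P)} \alpha\right),\qquad
    C_{m_1 m_2} = (x^{(1)}_{m_1}-x^{(2)}_{m_1})
                  (x^{(1)}_{m_2}-x^{(2)}_{m_2})\,\lambda_{m_1 m_2},$$
  with linkage factor $\lambda = 1-2r$. Diagonal entries are 1 at
  heterozygous and 0 at homozygous loci; off-diagonal entries are
  $+\lambda$ for loci heterozygous in coupling phase and $-\lambda$ in
  repulsion. GVP is a usefulness-type criterion: a cross of two
  complementary heterozygous parents can have modest mean but large
  variance, i.e. a real chance of transgressive progeny.

**A consistency point on $r$.** The meiosis simulator switches the source
haplotype between *adjacent* markers with the Kosambi fraction of their
distance. Under that Markov walk, the realized recombination fraction
between non-adjacent loci is the chain composition of the adjacent-interval
fractions ($\lambda$ is multiplicative along the chain), *not* the Kosambi
function of the total distance — map functions with interference are not
closed under composition. `gvp_kernel()` therefore composes
$\lambda_{m_1m_2}$ along the marker chain, which makes the closed form agree
with brute-force meiosis simulation to Monte-Carlo accuracy (the test suite
checks 2% relative error with 200,000 simulated progenies per cross; the
observed agreement is a few tenths of a percent). Using Kosambi of the
total distance instead produces errors of several percent for loosely
linked pairs.

## The allocation policy

For each pair $n$ the features in `feature_set` (any subset of BV, WBV,
GVP; BV and WBV enter as the mean of the two parents, GVP as the cross
variance) form a row of the matrix $\Omega$. Given a per-generation weight
vector $h(\tau) \in [0,2]^Q$, the progeny counts are

$$b = \left\lfloor N_{pop} \cdot
      \mathrm{softmax}(\Omega h)\right\rfloor ,$$

with the flooring deficit (at most $N_{pair}-1$ progenies) handed one each
to the pairs with the largest fractional parts, ties resolved by the higher
expected pair WBV and then pair order. Two details are deliberate:

* **Feature standardization.** $\Omega$'s columns are z-scored across pairs
  by default. BV, WBV and GVP live on incommensurate scales; with $h$
  confined to $[0,2]$ an unstandardized column with the widest numeric
  range would dominate the softmax regardless of its weight. Raw columns
  remain available (`standardize_features = FALSE`).
* **The $h = 0$ limit.** With zero weights the softmax is uniform and the
  remainder rule reduces to: every pair gets
  $\lfloor N_{pop}/N_{pair}\rfloor$, the leftover goes to the pairs with
  the highest expected WBV — exactly `allocate_equal()`. The equivalence is
  bit-exact by construction (shared remainder code path) and is asserted
  over randomized instances in the tests. With the defaults this is the
  familiar "3 progenies for the 10 best pairs, 2 for the other 110".

## Fitting the weight schedule: StoSOO

The expected final gain as a function of the flattened schedule
$h \in [0,2]^{T \times Q}$ is a noisy black box: each evaluation averages
$g(T)$ over `n_rep` forward simulations. `stosoo_maximize()` implements
StoSOO (stochastic simultaneous optimistic optimization): the domain is
recursively trisected along its longest side, each cell is summarized by
repeated noisy evaluations of its center, and cells are explored by upper
confidence bounds per depth level. The search starts at the domain center —
the all-ones schedule. Hyper-parameters default to the standard analysis
values ($k = \max(1, \lfloor n/\ln^3 n\rfloor)$ samples per node,
$\delta = 1/\sqrt n$, depth cap $\lfloor\sqrt{n/k}\rfloor$) and are
exposed as arguments; the recommendation is the deepest node, breaking ties
by evaluation count and then empirical mean. Children of a split start
unevaluated — the middle child keeps its parent's center but is sampled
afresh, since carrying a parent's (possibly noise-favored) mean down an
expansion chain would let a lucky cell cascade to depth on stale
statistics. Tie-breaks (longest side, then lowest coordinate index) are
deterministic, and each objective evaluation consumes a child RNG stream
derived from the master seed and an evaluation counter, so fits are exactly
reproducible.

`reevaluate_trace()` re-scores the incumbent schedule at chosen evaluation
steps with an independent objective, giving an honest convergence curve
(the optimizer's own incumbent means are biased upward by selection).

## The simulated world

`sim_world()` builds the study system end to end:

* **Founder haplotypes with LD.** Haplotypes are recombination mosaics of a
  small ancestral set: each of `n_ancestors` (40) ancestral haplotypes
  carries 1-alleles at Beta(0.4, 0.4)-distributed frequencies, and each of
  the `n_haplotypes` (4,000) founder haplotypes switches ancestor along the
  map with probability $1-(1-r)^g$ per interval ($g$ = 10 generations since
  the bottleneck). Nearby loci share ancestry — LD decays with map
  distance — and the Beta spectrum supplies rare minor alleles. This
  generator reproduces the two properties the downstream method consumes
  (polymorphism with an excess of rare alleles, and distance-decaying LD);
  it does not model mutation age, gene conversion, demography, or
  population structure, so tests passing on it say nothing about, e.g.,
  admixed panels. `read_haplotypes()` imports any external 0/1 haplotype
  CSV instead.
* **Locus panel.** Per chromosome, 500 of the simulated loci with minor
  allele frequency ≥ 0.01 (computed on the haplotype pool, since filtering
  precedes founder sampling) are kept at random.
* **Pre-breeding material.** 2,000 diploid founders are drawn as random
  haplotype pairs and randomly mated for one generation.
* **Parent panel.** k-medoids (PAM, Euclidean distance on dosage; the
  `cluster` package) picks 250 medoids as a diversity-representative panel
  — actual genotypes, not averages.
* **Trait.** 2 QTLs per chromosome, effects i.i.d.
  $N(0, 1/M_{QTL})$, so the trait-variance scale is QTL-count invariant.

Chromosome map length defaults to 1,000 cM — long, but consistent with the
dense-recombination founder regime the defaults emulate — and is a plain
parameter (`length_cM`) since the realized post-filter map length is the
quantity that matters downstream.

## Experiments and scale

`run_comparison()` evaluates named strategies (BV, WBV, TBV, BVGVP,
WBVGVP, TBVGVP — see `strategy_features()` — and the EQ baseline) with
*paired seeds*: replicate $i$ shares its random stream across strategies,
so strategy contrasts are not diluted by between-replicate noise. Whether
paired or independent streams are "correct" is a design choice; pairing
was chosen for variance reduction and only affects the precision, not the
definition, of the contrasts. `improvement_table()` reports
$100\,(\bar g_S - \bar g_{EQ})/\bar g_{EQ}$ per trait replicate,
summarized as min/mean/max.

The full-scale protocol (10 chromosomes × 500 loci, panel 250, 20,000
StoSOO evaluations × 50 simulations, 10,000 evaluation schemes, ten trait
replicates) and a desk-scale run are the same code path; only
configuration differs (`run_config(preset = "tiny")`). The package's test
suite and acceptance script use the desk scale: a 2-chromosome × 50-locus
genome, panel 30, 8 selected parents, 60 progenies, $T = 4$, 5 QTLs per
chromosome, optimizations of 150–300 evaluations averaging 10–20
simulations, and 200–500 evaluation schemes. The tiny trait keeps 10 QTLs
(rather than the full-scale rate of 2 per chromosome) so the gain ceiling
$\sum_m |\alpha_m|$ is rarely reached within four generations; with fewer
QTLs the ceiling saturates and all strategies collapse onto it, leaving
nothing to compare. At this scale the qualitative results — optimized
allocation beats equal allocation; GVP-bearing feature sets hold more
mid-scheme genetic variance — reproduce; the full-scale magnitudes
(improvement rates near 7–12%) require the full protocol.

## Numerical and degenerate-input choices

* Softmax scores are computed with max subtraction; non-finite features or
  scores raise errors rather than propagate.
* A zero-variance feature column standardizes to zeros (no information, no
  influence), not NaN.
* Selection ties break by population order; allocation-remainder ties by
  expected pair WBV then pair order — every path is deterministic given the
  seed.
* Clones of a fully inbred genotype yield zero gain and zero variance
  (nothing segregates); selfing a *heterozygote* does segregate, which is
  easy to forget when constructing degenerate cases.
* `expected_gvp()` of any fully homozygous parent pair is exactly 0; the
  quadratic form is positive semidefinite, and tiny negative values from
  floating-point roundoff are clamped at 0.

## Limitations

* True marker effects throughout: no genomic-prediction model, no
  estimation error, heritability 1.
* Additive QTL effects only; no dominance or epistasis, no mutation after
  the founder stage, strictly diploid, discrete generations.
* No inbred-line development or fixation phase; no mating constraints
  (selfings are always allowed).
* The optimized schedule is specific to the panel, trait architecture and
  scheme dimensions it was fitted on; transferring it to a different panel
  is an extrapolation the package does not validate.

## A minimal session

```{r, eval = FALSE}
library(breedalloc)

world <- sim_world(n_chromosomes = 2, markers_per_chromosome = 50,
                   n_haplotypes = 200, n_founders = 200, n_panel = 30,
                   qtl_per_chromosome = 5, seed = 7)
cfg <- scheme_config(n_pop = 60, n_sel = 8,
                     feature_set = c("BV", "WBV", "GVP"))
fit <- optimize_allocation(world, cfg, budget = 300, n_rep = 20, seed = 7)
coef(fit)          # fitted T x Q weight schedule in [0, 2]
summary(fit)       # paired comparison against equal allocation
plot(fit)          # incumbent mean gain per objective evaluation
```
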