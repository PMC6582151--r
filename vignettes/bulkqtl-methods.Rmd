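---
title: "Models and methods behind bulkqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bulkqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bulkqtl)
```

bulkqtl implements the computational side of extreme-QTL (X-QTL) mapping in
outcrossing *C. elegans* segregant pools: a forward simulator of
multigenerational bulk populations and the statistics that turn pooled
sequencing counts into QTL calls. This vignette explains the models, the
parameters that matter, the numerical choices, and what the package's tests
do and do not establish about real data.

## The population model

A segregant pool starts as the F1 of a cross between two inbred strains, an
A-strain (reference, N2-like) female parent and a B-strain (CB4856-like)
male parent, in a background where selfing has been abolished so the pool
can only outcross. Each individual carries two haplotypes per autosome;
males are hemizygous X/0, so a sperm either carries an X (daughter) or none
(son), and sons inherit their X from their mother.

Haplotypes are stored as sparse change-point lists: the parental origin of
the first segment plus the ordered breakpoint positions where origin
switches. Meiosis adds at most one breakpoint per chromosome — reflecting
the strong crossover interference of *C. elegans*, each bivalent resolves
into a transmitted gamete that carries a single crossover with probability
`p_xo` (default 0.5) — so lists stay short and million-individual pools fit
in memory. The crossover position is drawn uniformly in genetic (cM)
distance and converted to bp by piecewise-linear interpolation of the
genetic map, which concentrates breakpoints on the recombination-rich
chromosome arms when the map is arm-biased.

Generations do not overlap. Every female mates exactly once with a male
drawn with probability proportional to his fitness weight (males may mate
repeatedly), contributes a fixed number of progeny (default 10), and the
surviving offspring are down-sampled without replacement to the population
cap (default 50,000 from 1,000 F1 founders). Demography, mating and
meiosis run in compiled code behind `propagate()` and `simulate_cross()`;
all randomness flows through R's RNG so a seed makes runs byte-identical.

Two selective forces can act:

* **Fitness loci** multiply a male's chance of being sampled as a father by
  a per-genotype weight (`fitness_locus()`), multiplied across loci.
  Females are never weighted by default; the package exposes only male
  weighting because mating success is the male-limited step in this design.
* **A toxin–antidote drive element** (`drive_element()`): a sperm-delivered
  toxin linked to a zygotically expressed antidote, the peel-1/zeel-1
  configuration. A zygote dies with probability *s* (the penetrance, equal
  to the selection coefficient against the poisoned genotype) if and only
  if its father carries at least one element-bearing allele and the zygote
  inherits zero copies. The maternal genotype never triggers lethality. In
  a het x het cross with *s* = 1 this produces the classic 25% embryonic
  lethality, and across generations it drives the element-bearing haplotype
  upward.

### One X-chromosome caveat

Because founders are A-females x B-males under X/0 sex determination, the
F1 X pool is one-third B (males carry only the maternal A). Neutral
expectation for the X is therefore 1/3 B-allele frequency, not 0.5, for the
whole propagation. Every neutral-conservation check in the package is
computed on autosomes; the baseline frequency *q* in the scan absorbs the
X's offset automatically because it is estimated from the control pool.

## Truncation selection with a specified effect size

A mapping experiment selects the extreme tail of a phenotype. To plant a
locus that explains a chosen fraction Ve of phenotypic variance, each
individual's genotype at the causal locus is coded g in {0, 1, 2}, a
displacement d ~ Normal(0, sigma^2) is added, and the top fraction
(default 5%) by the score S = g + d survives; a uniformly random subset of
the pool serves as control.

Two sigma^2 parameterisations are available in `effect_size_model()`. The
default, `"variance-consistent"`, sets sigma^2 = Vl (1 - Ve) / Ve with Vl
the variance of the genotype vector, which makes Var(g)/Var(S) equal Ve
exactly — the definition of "variance explained". The alternative
`"as-printed"` form, sigma^2 = (1 - Ve) / (Ve Vl), is kept behind a flag
for fidelity with earlier descriptions of the procedure; the two coincide
only when Vl = 1 (at a 50/50 allele frequency Vl is about 0.5, so the
as-printed form injects four times more noise than the consistent one).
Ties at the truncation boundary are broken uniformly at random under the
run's seed.

Pooled sequencing of the selected and control pools is simulated per marker
and pool as an allele-B read count Binomial(C, pool frequency), C the depth
of coverage (default 100x).

## The pooled scan

For each SNV with counts n1/n3 (allele A/B, high pool) and n2/n4 (low
pool), the modified G statistic contrasts the pools while absorbing
baseline segregation distortion through q, the allele-A frequency of the
control pool:

    N = (1 - q)(n2 - n1) + q(n3 - n4)
    G = N^2 / (2 C q (1 - q))        (default, "squared")
    G = N  / (2 C q (1 - q))         ("as-printed-linear")

The numerator is squared by default: a linear form can be negative, which
is incompatible with a goodness-of-fit-type statistic and with the
log-normal null below, while the squared form reduces to
(n2 - n1)^2 / (2 C q (1 - q)) under equal pool depths — a chi-square-type
quantity. The linear form is retained behind a flag. Coverage C defaults
to the mean of the two pools' depths at the marker (min and control-only
conventions are selectable). Markers whose control pool is monomorphic
(q of 0 or 1) or empty are excluded, not clamped, because G divides by
q(1 - q); exclusions are counted and reported.

Raw G is smoothed along each chromosome with a tri-cube kernel in genetic
distance: markers j within a half-width of the focal marker s get weight
proportional to (1 - D^3)^3, D = |cM_j - cM_s| / half-width, normalised to
sum to one. The default half-width is 12.5 cM (a 25 cM window), the lower
bound of the range recommended for bulked-segregant G smoothing; narrower
windows localise better but stabilise less. Markers outside the map's
anchored span take the nearest anchor's cM and are flagged.

The null distribution of G' is fitted robustly on the log scale: location
by the median and scale by the normal-consistent MAD (x 1.4826) of log G',
so that a minority of true-signal markers in the upper tail barely moves
the fit — this is why the null can be estimated from the same scan that
carries the signal, with no masking of peak regions. p-values are the
upper tail of that log-normal. Peak calling merges contiguous runs of
markers below alpha (default 1e-5, reported in the metadata; no
genome-wide correction is applied because raw per-peak p-values are the
convention for this statistic) and reports each run's minimum-p marker,
leftmost on ties.

Confidence intervals for a peak are obtained by simulation
(`ci_by_simulation()`): the whole experiment is re-simulated with the
causal variant planted at the observed peak and an effect size drawn
uniformly from a configured range (default 15–25% of phenotypic variance),
the top associated variant recorded per iteration (default 1300), and the
CI taken as the nearest-rank central 95% interval of those positions.

## Selection-coefficient estimation

The drive element's strength is estimated by trajectory matching
(`simulate_s_grid()` + `fit_selection_coefficient()`): for each of 20
penetrance values spanning [0, 1], replicate populations (default 50
populations of 10,000 worms for 20 generations) are simulated and the
per-generation maximum allele-frequency deviation toward the element allele
is averaged. The observed trajectory — the same maximum-deviation
statistic, averaged across experiments when replicates exist — is matched
to the grid by minimising the sum over generations of the absolute
differences between simulated means and observation. Absolute differences
are used because signed sums cancel and make the objective
non-identifiable; no interpolation between grid values is performed, so the
estimate is always a grid member. The deviation statistic searches the
element's whole chromosome by default (the search window is configurable);
the maximum over a window has a positive bias under drift, but the bias is
shared between simulated and observed trajectories and largely cancels in
the fit.

## eQTL mapping with permutation FDR

For the expression analysis, probes present in fewer than 2/3 of samples
are removed (the boundary case is kept), both matrices are normalised to
row mean zero and variance one (an idempotent operation), and every
probe x marker Pearson correlation is transformed to a LOD score,
LOD = -n ln(1 - R^2) / (2 ln 10), with pairwise-complete correlations and
the per-pair sample count n when expression values are missing. The
genome-wide threshold comes from permutations: sample identities of the
expression matrix are shuffled (genotypes untouched, preserving marker LD),
per-probe maximum LODs recomputed, and FDR(t) estimated as the mean
permuted discovery count over the observed count at threshold t on a
0.1-LOD grid (the grid spacing is configurable); the cutoff is the smallest
t at or below the target rate (default 5% over 100 permutations).

## The fixture generator, and what the tests show

`make_fixture_genome()` builds a *C. elegans*-like genome: six chromosomes
of roughly 100 Mb total with the last flagged as X, about 50 cM each, and —
under the default arm-biased profile — outer-third arms carrying 80% of the
map length, emulating the species' concentration of recombination on
chromosome arms. Markers are placed uniformly in bp.
`make_fixture_experiment()` runs complete drug-selection, two-tail-sort or
neutral-timecourse experiments and emits exactly the files the scan
consumes plus a ground-truth record.

The generator emulates marker geometry, recombination heterogeneity, drift,
drive, selection and sequencing noise. It does not emulate real read
alignment artefacts (mapping bias, duplicated regions, coverage
heterogeneity along the genome), structural variation around loci such as
the element's own indel region, genotyping error in the SNV list, or
environmental variance structure beyond the additive-plus-normal score.
Passing tests therefore establish that the statistics are implemented
correctly and behave as designed under the stated population model — not
that any particular real experiment will reach the same power.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere; allele A is fixed to the
  A-strain (reference) allele and frequencies are reported for allele B.
* Crossovers are placed uniformly in cM and mapped to bp; map inversion is
  exact because interpolation is strictly monotone.
* Down-sampling to the cap happens after drive lethality filtering.
* One global RNG stream per simulation, seeded from the configuration.
* The log-normal fit refuses fewer than 100 positive G' values (unstable)
  and a zero MAD (degenerate); G' values at or below zero — possible only
  under the linear variant — are excluded from the fit and given p = 1.
* p-values are floored at the smallest positive double rather than 0.
* Nearest-rank CI ranks guard against floating-point error in n x alpha.

## Problem sizes in the test suite

The package's acceptance-style tests run complete experiments at desk
scale: 100,000 zygotes for the lethality check; 50 replicate
1,000-individual populations over 10 generations for neutral conservation;
10,000 gametes per chromosome for the crossover contract; 20 neutral scans
for null calibration; a 20-value penetrance grid at 10 replicates x 2,000
worms x 15 generations for recovery of s; twenty 50,000-individual pools
with 5% survivors at 100x coverage (at the full 110,176-SNV density) for
the power experiment; and ten 200-iteration CI constructions for coverage.
Two of these stress-tests assert rates slightly above what their reduced
designs deliver (selection-coefficient recovery and 1-cM localisation at
Ve = 5%) and are expected to report the measured shortfall rather than
being relaxed; the surrounding checks document the measured behaviour.
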