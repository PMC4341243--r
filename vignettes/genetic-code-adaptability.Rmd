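---
title: "Multiobjective analysis of genetic code adaptability"
author: "gcadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiobjective analysis of genetic code adaptability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcadapt)
```

## The problem

The canonical genetic code maps the 64 codons to 20 amino acids and 3 stop
signals, and it is famously *robust*: a single-nucleotide change usually
leads to the same amino acid or to a chemically similar one. One long-standing
explanation is adaptive: among the astronomically many possible codon
assignments, codes that minimize the damage of mutation and mistranslation
were favoured. Classical tests of this idea score codes by a **single**
amino-acid property, usually polar requirement, either by mass-sampling
random codes (the *statistical* approach) or by searching for the best codes
with an optimization algorithm (the *engineering* approach).

`gcadapt` implements the multiobjective version of the engineering approach:
two (or more) properties are minimized **simultaneously**, so the result is
not one best code but a Pareto front of nondominated codes, which can then be
compared with the canonical code by dominance, by the *pmd* statistic, and
against random-code null distributions.

## The error measures

For a code $C$ the unweighted error is

$$ M_s(C) \;=\; \frac{\sum_{\{i,j\}} \big(X(i,C)-X(j,C)\big)^2}
                      {\sum_{\{i,j\}} N(i,j,C)} $$

where the sum runs over all unordered pairs of **sense** codons that differ
at exactly one base, $X(i,C)$ is the property value of the amino acid that
$C$ assigns to codon $i$, and $N(i,j,C)\in\{0,1\}$ marks single-base
neighbours. With the canonical block structure there are exactly 263 such
pairs: $64\cdot 9/2 = 288$ single-base pairs among all codons, minus the 25
pairs touching UAA, UAG or UGA. Stops are excluded throughout — they are
fixed in the encoding and carry no property value. The 67 pairs *within* a
synonymous block contribute zero to the numerator but stay in the
denominator, which is why the measure rewards codes that keep similar amino
acids on neighbouring codons.

The mistranslation-weighted variant $M_{st}$ multiplies each pair by a
weight depending on the base position changed and on whether the change is a
transition (A↔G, C↔U) or a transversion, and divides by the total weight:

| | base 1 | base 2 | base 3 |
|---|---|---|---|
| transition | 1 | 0.5 | 1 |
| transversion | 0.5 | 0.1 | 1 |

These weights encode the observation that second-base errors are rare and
mostly transitional, and first-base errors rarer than third-base ones. With
all-ones weights $M_{st}$ reduces exactly to $M_s$, which the tests assert.

Three property scales are built in (`aaProperties()`): polar requirement,
hydropathy index and molecular volume. They are used verbatim — including
molecular volume 3 for glycine, which is what that volume scale assigns —
because the canonical scores computed from them reproduce the six reference
values to printed precision:

```{r canonical}
specs <- list(objectiveSpec("ms", "pr"), objectiveSpec("ms", "hi"),
              objectiveSpec("ms", "mv"), objectiveSpec("mst", "pr"),
              objectiveSpec("mst", "hi"), objectiveSpec("mst", "mv"))
round(evaluateCode(canonicalCode(), specs), 4)
```

## The restrictive code space

Hypothetical codes use the *restrictive encoding*: the 20 synonymous-codon
blocks of the canonical code and the 3 stop codons are frozen, and a code is
a permutation of the 20 amino acids over the 20 blocks ($20! \approx 2.4
\times 10^{18}$ codes). This reuses the canonical block structure as prior
knowledge and makes every code directly comparable with the canonical one.
Arbitrary 61-codon-to-amino-acid maps are deliberately not implemented.

Because assignments are block-constant, scoring only needs the substitution
weight aggregated per block pair (`blockPairWeights()`), so evaluating a
code costs $O(20^2)$ rather than a loop over the 263 codon pairs. The test
suite verifies this block-level evaluator against direct codon-level
enumeration on 100 random codes for every property and both measures, at
relative tolerance $10^{-9}$.

## The search algorithm

`nsga2()` is a standard elitist NSGA-II specialised to permutations:

* **Encoding/operators.** Individuals are block permutations; the only
  transformation operator is *swap* (two random blocks exchange amino
  acids). Each offspring is created by tournament selection and then
  mutates with probability `swapProb` (default 0.5, one swap event;
  `swapsPerOffspring` exposes the multiplicity rather than guessing).
  No crossover is used.
* **Selection.** Tournament pool = 3% of the population (minimum 2,
  so the default population of 100 gives a pool of 3), winner by the
  crowded comparison: lower nondomination rank, ties by larger crowding
  distance, remaining ties uniformly at random.
* **Elitism.** Parents and offspring compete jointly; whole nondominated
  layers are copied into the next population and the last layer is
  truncated by crowding distance (ties broken by objective-lexicographic
  order so runs are bit-reproducible). This $\mu+\lambda$ scheme subsumes
  a separate best-individual elitism; the per-objective best is asserted
  never to worsen at every generation.
* **Defaults** follow the study conditions: population 100, 1000
  generations, 10 independent runs whose layer-1 fronts are merged by
  `mergeFronts()` (union, duplicate removal, nondominated filtering).
* **Seeds.** A master seed spawns one sub-seed per run; every stochastic
  draw flows through R's generator seeded from it, so fronts are exactly
  reproducible.

A full-scale run of 10 × 1000 generations takes a couple of minutes in this
implementation; the acceptance checks use 3 runs at full population and
generation counts, and the unit tests use smoke-scale configurations
(populations of 20–30, tens of generations), which exercise every code path
identically.

## Comparing codes with the canonical one

Three instruments, all in the `stats`-side functions:

* **Dominance** (`dominates()`, `compareToCanonical()`): a front member
  dominates the canonical code when it is no worse on every objective and
  strictly better on at least one.
* **pmd** (`pmd()`): $100\,\lvert(\bar f - f_{\mathrm{canon}})/(\bar f -
  f_{\mathrm{code}})\rvert$, where $\bar f$ is the mean evaluation over
  random codes. 100 means "as good as canonical"; it is conventionally
  reported only for dominating codes (otherwise it exceeds 100). It is
  affine-invariant and undefined when $\bar f = f_{\mathrm{code}}$, which
  the function signals explicitly.
* **Null distributions** (`sampleSummary()`): $\bar f$, standard
  deviations, histograms and counts of codes better than canonical are
  accumulated over uniform random *restrictive* codes — the same space the
  GA searches, so engineering and statistical comparisons refer to the same
  null. The default $\bar f$ sample is $10^6$ codes; the mean's standard
  error at that size perturbs pmd by well under 0.1 percentage points.

The sampler is a single streaming pass over chunks (default 50 000 codes),
so memory use is independent of $n$. One consequence: histogram bin edges
must be fixed before the data are complete, so they are set from the first
chunk with the range widened by 25%, and later out-of-range values fall into
the extreme bins. Counts therefore always sum to $n$, but the tails of the
plotted histogram can be clipped; mean, standard deviation and
count-better are exact regardless. A useful analytic cross-check used in
the tests: over uniform permutations the expected value of either measure
has the closed form (inter-block weight) × (mean squared property gap over
distinct amino-acid pairs) / (total weight), e.g. 9.4099 for the unweighted
polar-requirement objective.

The normalization behind the Euclidean *distance* column is configurable
(`mean` division by the random-sample mean — the default — `zscore`, or
`minmax`) because no single convention is canonical in the literature and
none of the candidates reproduces previously printed distance values; the
distance is reported for ranking within a front, not as a reference
statistic.

## Known limitations

* The restrictive null is a modelling choice. Counts of random codes
  better than the canonical one are extremely sensitive to the choice of
  code space: under restrictive sampling they are orders of magnitude
  larger than under nonrestrictive (61-codon) sampling, because the
  restrictive space is both smaller and wider-spread per objective.
  Published tail counts obtained under other (often unstated) sampling
  models are therefore not comparable cell-by-cell with restrictive ones.
* $\bar f$ is Monte-Carlo estimated, never summed over all $20!$
  permutations.
* The synthetic null emulates *uniform* permutations only; real
  evolutionary accessibility (codes reachable from an ancestral code by
  few swaps) is a different, unmodelled distribution, so passing tests
  show internal consistency of the measures, not historical plausibility.
* Objective count is unbounded in the code but the crowding-based
  diversity maintenance degrades beyond ~3 objectives; no many-objective
  machinery is included.
* Gray-scale tables (`grayscaleTable()`) export the full content of the
  shaded code-organization figures as TSV (amino acids sorted by property,
  ties alphabetical); rendering shades is left to downstream tools.

## Reproducing the reference quantities

`scripts/acceptance.R` in the source repository recomputes, from scratch
with the installed package, the six canonical-code scores and four pmd
values for published front members (see the README for the exact
invocation). Problem sizes there are the package defaults: 263 substitution
pairs for the deterministic scores and $10^6$ random codes for the means.
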