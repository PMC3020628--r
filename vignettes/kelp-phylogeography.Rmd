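---
title: "Haplotype phylogeography along a linear coast: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype phylogeography along a linear coast: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelpcoast)
```

## The scientific problem

Rocky-shore organisms with limited effective dispersal — southern
bull-kelp (*Durvillaea antarctica*) on the Chilean coast is the motivating
system — are sampled at a series of localities strung along an
essentially one-dimensional coastline. Three questions recur in such
studies:

1. **Population structure.** How many haplotypes are there, how divergent
   are they, and do they fall into deeply separated clades (for example a
   postglacially recolonised, genetically homogeneous region versus a
   refugial region with high structure)?
2. **Isolation by distance (IBD).** Does genetic distance between
   localities increase with along-coast distance?
3. **Habitat discontinuity.** Are genetic disjunctions between *adjacent*
   localities predicted by the length of uninhabitable habitat (long sandy
   beaches) separating them, over and above mere distance?

`kelpcoast` implements this analysis chain end to end, from aligned
sequences to a fitted disjunction regression, plus a synthetic-coast
generator so that every stage can be exercised and validated without
field data.

## Distances on the raw count scale

The per-pair kernel is the **raw pairwise difference**: the number of
positions at which two aligned sequences both carry unambiguous bases
(A/C/G/T) and differ. Positions holding a gap or an IUPAC ambiguity code
in either sequence are excluded everywhere — haplotype collapsing is by
exact string identity, but variable-site counting and all distances use
only unambiguous sites. This is the conservative convention for clean
Sanger-quality haplotypes; it slightly undercounts divergence if
ambiguities hide real differences.

Between two localities $a$ and $b$ with $n_a$ and $n_b$ sampled
individuals, **Nei's raw average pairwise difference** is

$$D_{ab} \;=\; \frac{1}{n_a n_b} \sum_{i \in a}\sum_{j \in b} d(i, j),$$

with $d$ the raw difference count. $D$ is deliberately **not** divided by
sequence length and not corrected for multiple hits: the disjunction
classification below uses the threshold $D \ge 1$ ("on average at least
one fixed difference between random individuals of the two localities"),
which is only meaningful on the count scale. The uncorrected
*p*-distance ($d$ divided by the number of comparable sites) is reported
for describing clade divergences as percentages; percentages are rounded
half-up to one decimal.

Within-locality diversity $\pi$ averages $d$ over distinct unordered
sample pairs ($n(n-1)/2$ pairs; a single-sample locality has $\pi = 0$),
and the package exposes the simple $\pi$-based fixation index

$$F_{ST} = \frac{\pi_{between} - \tfrac12(\pi_a + \pi_b)}{\pi_{between}},$$

clamped to $[0, 1]$ and flagged undefined when $\pi_{between} = 0$. Two
localities fixed for different haplotypes give $F_{ST} = 1$ regardless of
how divergent the haplotypes are — which is precisely why pairwise
$F_{ST}$ is a poor input for distance-based IBD tests on datasets with
many fixed localities, and why the Mantel stage uses $D$ instead. No
linearised $F_{ST}/(1-F_{ST})$ transform is provided for the same reason.

## The Mantel isolation-by-distance test

`mantel_test()` correlates the strict upper triangles of the genetic-$D$
matrix and the coastal-distance matrix (Pearson $r$), and assesses it by
jointly permuting rows and columns of the genetic matrix while holding
the geographic matrix fixed. The test is one-tailed (upper), matching the
directional IBD hypothesis, with the standard unbiased convention that
counts the observed statistic among the permutations:

$$p = \frac{1 + \#\{r_{perm} \ge r_{obs}\}}{1 + n_{perm}}.$$

Permutations are drawn uniformly from the full permutation group
(including, very occasionally, the identity); the tests verify that the
sampled $p$ converges to the exhaustive-enumeration value on $4 \times 4$
matrices and that the test attains its nominal 5% size over 1000 null
simulations. The seed is a mandatory part of a pipeline configuration,
and the RNG state is restored afterwards, so any reported $p$ is
reproducible bit-for-bit.

Coastal distance is taken from a user-supplied table of cumulative
along-coast positions (km). For the published Chilean design shipped with
the package (`chile_localities()`), positions are approximated by
cumulative great-circle distances between consecutive localities; on this
nearly straight coast that is a serviceable stand-in for true along-coast
distance, but users with measured coastal distances should supply them.

## Statistical-parsimony networks and the connection limit

Following the statistical-parsimony (TCS) framework, two haplotypes are
joined in a network only when the number of mutational steps between them
is small enough that a minimal connection is credible at a stated
confidence (conventionally 95%, or 90% for a more permissive network).
The package operationalizes the parsimony probability with a
finite-sites Jukes–Cantor calculation:

* per-site substitution counts are Poisson with mean $\lambda$;
* $\lambda$ is calibrated so the expected proportion of differing sites
  equals the observed $q = j/m$ for a pair differing at $j$ of $m$ sites,
  i.e. $q = \tfrac34\left(1 - e^{-4\lambda/3}\right)$;
* a connection is *parsimonious* when every differing site changed
  exactly once and every identical site never changed, giving
  $$P(j, m) = \left(\frac{\lambda e^{-\lambda}}{q}\right)^{j}
              \left(\frac{e^{-\lambda}}{1 - q}\right)^{m - j}.$$

`connection_limit(m, c)` returns the largest $j$ with $P(j, m) \ge c$.
For a 629 bp fragment this gives 11 steps at 90% and 7 at 95% confidence
— comfortably bracketing the regime the Chilean data require (pairs
within the central clade, at most ~8 steps, connect at 90%; the
Patagonian haplotype, at 28+ steps from everything else, does not). An
independently coded implementation of the same probability model
(root-finding instead of the closed form) serves as the oracle in the
test suite across $m \in \{100, \dots, 1000\}$ and $c \in \{0.90,
0.95\}$.

Network assembly is a deliberate simplification of the full TCS
machinery: haplotype pairs are considered in order of increasing raw
distance (ties: higher combined frequency, then lexicographic IDs); a
pair within the limit that spans two components is connected through
$d - 1$ unlabeled hypothetical intermediates; a pair whose endpoints are
already connected by a path of exactly $d$ steps is recorded as an
ambiguous (equal-length alternative) link rather than closing the loop.
Component membership — the only network property the downstream analysis
uses — depends only on pairwise distances versus the limit, so it is
unaffected by the simplification; the tests verify component partitions
against an exhaustive transitive-closure oracle. Hypothetical node
sequences are not imputed, and no forced (non-supported) connection
between components is ever emitted.

## Genetic disjunction and the Firth regression

Adjacent locality pairs (consecutive in coastal order, within a
configurable region) are classified **disjunct** when $D \ge 1.0$
(inclusive). Haplotype sharing is computed independently from the count
matrix as a consistency check: a disjunct pair that shares haplotypes is
flagged, not silently reclassified.

The disjunction model is logistic:

$$\text{logit}\, P(\text{disjunct}) = \beta_0 +
  \beta_1 \cdot \text{max beach length (km)} +
  \beta_2 \cdot \text{coastal distance (km)}.$$

With ~15 binary observations and a strong predictor, ordinary maximum
likelihood readily diverges under complete separation, so the package
fits the **Firth-penalized** likelihood
$\ell^*(\beta) = \ell(\beta) + \tfrac12 \log\det I(\beta)$ (Jeffreys
prior), which always yields finite estimates. Numerics: modified-score
Newton iterations using the hat-diagonal form of the penalized score,
convergence when every score component falls below `tol = 1e-8`, at most
`max_iter = 50` iterations, with step-halving whenever a step would
decrease $\ell^*$. P-values are penalized likelihood-ratio tests — the
model is refit with the coefficient pinned at zero, the penalty still
evaluated on the full design — rather than Wald tests, matching the
default of the reference implementations of this estimator and behaving
far better under near-separation. The test suite checks the maximizer
against a dense grid search of $\ell^*$ on a fixed 8-observation fixture
(agreement to $10^{-4}$), exact coefficient rescaling under unit changes,
convergence to the unpenalized MLE on large separation-free data, and
null calibration of the p-values.

`disjunction_analysis()` fits the model twice when an exclusion list is
given (e.g. a pair whose beach barrier is bridged by a coastal island
acting as a stepping stone), reporting both fits plus the per-pair table
($D$, beach length, coastal distance, disjunction flag).

## The synthetic coast: what it emulates, and what it does not

`generate_dataset()` is a forward haplotype-pool model, not a coalescent
simulator. The analyses consume only haplotype frequencies and pairwise
distances, so the generator plants exactly the three signals the
pipeline must recover, each controllable and with closed-form
expectations:

* **A monomorphic southern clade.** All southern samples are identical
  copies of a southern ancestor that differs from the northern ancestor
  by $\text{Binomial}(L, 0.05)$ substitutions (~31.5 steps at $L = 629$,
  i.e. ~5% divergence) — emulating postglacial recolonisation by a
  single widespread haplotype.
* **An IBD gradient in the north.** Locality haplotypes follow a
  stepping-stone walk: crossing each inter-locality boundary, one new
  mutation enters the pool with probability 0.5, capped at 8 steps in
  total (so within-clade divergence stays near the ~1.3% the motivating
  system shows). Expected pool distance therefore grows with coastal
  separation.
* **Beach barriers.** Beach lengths between adjacent northern localities
  are drawn from a mixture — short $U(0, 15)$ km with probability 0.7,
  long $U(25, 70)$ km with probability 0.3 — and any beach over 20 km is
  a barrier: the downstream locality jumps 3 fixed mutations and receives
  no migrant carryover, so cross-barrier pools are disjoint and
  cross-barrier $D \ge 3$ deterministically (every planted barrier is
  classified disjunct at the $D \ge 1$ threshold).

Choices the generator makes where the emulated design is silent, fixed
once: the 3-step barrier jump (the smallest value that keeps barrier
pairs unambiguously past the threshold even with within-pool variation);
a per-sample probability 0.3 of carrying the *previous* locality's
haplotype across a non-barrier boundary (neighbours share haplotypes, so
expected adjacent $D \le 1$ off barriers); a per-sample private-mutation
probability 0.1 (realistic haplotype richness, ~20+ haplotypes per
dataset); transition:transversion weight 9:1; localities spaced
$90 \pm 15$ km (uniform jitter — without it, coastal distance would be a
constant regressor and the two-predictor design singular; the jittered
minimum of 75 km still exceeds the longest possible beach, preserving
the beach-within-distance constraint).

Mutations are always placed at previously untouched sites, so distances
along the walk are additive and there is no homoplasy. Real data differ
in exactly these respects: recurrent and back-mutation, non-equilibrium
frequency spectra from drift and expansion, migration beyond nearest
neighbours, and measurement artefacts are all absent. Passing recovery
tests therefore demonstrates that the pipeline detects the signals it
targets when they are present as planted, not that the generator is a
demographic model of any real coast.

Determinism: given a seed, generation is reproducible to the byte across
runs (file-level identity is part of the test suite). All seeded
operations restore the caller's RNG state.

## Problem sizes and test design

The shipped validation uses deliberately modest problem sizes, chosen as
the smallest that make each property sharp: exhaustive Mantel
enumeration on $4 \times 4$ matrices (24 permutations); type-I
calibration over 1000 null simulations of 8 localities with 199
permutations each; Firth oracle agreement on 8 observations; connection
limits over $m$ up to 1000 bp; and full-pipeline recovery over 200
seeded synthetic coasts (21 localities × 8 samples of 629 bp each),
checking clade splitting, IBD rejection at $\alpha = 0.05$, the sign of
the beach coefficient, and barrier disjunction. The desk-scale published
quantities (the 1.4% two-haplotype chloroplast divergence from 12 sites
over 886 bp; 164 individuals over 24 localities; 15 adjacent pairs among
the 16 beach-survey localities, 14 after excluding the island-bridged
pair) are recomputed from the shipped design table.

## Known limitations

* The parsimony probability is this package's operationalization of the
  statistical-parsimony idea; limits can differ by a step or two from
  other implementations of the framework. Only component membership, not
  the exact limit, feeds the scientific conclusions.
* `nei_average_pairwise_D` treats each locality sample as the
  population; no rarefaction or unequal-sampling correction is applied.
* The Mantel test assumes exchangeability of localities under the null;
  spatial autocorrelation structure beyond the tested distance
  relationship is not modelled.
* The disjunction regression fits exactly one model form (no
  interactions, no model selection), by design.
* Model-corrected distances (K2P, TrN, ...), AMOVA and phylogeny
  estimation are out of scope; use dedicated phylogenetics tooling for
  those questions.
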