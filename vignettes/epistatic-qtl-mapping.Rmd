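---
title: "Epistatic QTL mapping in an F2 line cross: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epistatic QTL mapping in an F2 line cross: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiqtl)
```

# The problem

An F2 intercross between two divergent lines (here labelled E and W, after
the Erhualian and White Duroc pig lines that motivate the design) segregates
for line-origin alleles at every position of the genome. QTL mapping in such
a cross regresses a phenotype on the *expected* line-origin genotype at each
map position — Haley–Knott regression — and asks where the regression is
stronger than chance. `epiqtl` implements the complete workflow for this
design with epistasis as a first-class citizen: two-locus genome scans with
permutation-derived thresholds, a model-simplification procedure, and a
decomposition of each interaction into background-conditional additive and
dominance effects.

# Line-origin probabilities

## Map arithmetic

Linkage maps estimated with interference-aware map functions (Kosambi) are
converted to Haldane distances interval by interval
(`kosambi_to_haldane()`), because the transition model of the hidden Markov
chain assumes no interference. The Haldane map function
`haldane_recombination()` converts a distance $d$ (cM) to a recombination
fraction $r = \tfrac12(1 - e^{-2d/100})$.

## The hidden Markov model

The hidden state at a position is the *ordered* pair of line origins of the
maternally and paternally inherited haplotypes, four states in all. The two
haplotypes recombine independently, the maternal one at female-map rates and
the paternal one at male-map rates, which is why the state is kept ordered
internally: pooling EW/WE too early would force a common transition rate.
The chains are coupled only through the emissions, because a marker
genotype is an unordered allele pair.

Emissions are computed from the phased F1 parents. `phase_f1()` assigns
each F1 allele to its E-line or W-line founder where the founder allele
sets determine the assignment uniquely. Where both phasings are consistent
(the founders share the relevant alleles) the marker is left unresolved and
the emission probability averages over the consistent phase configurations
— an exact marginalisation rather than discarding the marker. Missing
genotypes emit 1 in every state. An observation compatible with no state
raises a Mendelian-inconsistency error naming the individual and
chromosome. No genotyping-error term is modelled: the emission model is
exact given the declared genotypes.

Forward–backward is run with per-step scaling on the sorted union of the
1 cM grid (anchored at 0, through the last marker rounded up) and the
marker positions; female/male coordinates for grid points are interpolated
linearly within the marker frame. Posteriors are collapsed to
$p(EE), p(EW), p(WW)$ and converted to the regression variables
$A = p(WW) - p(EE) \in [-1, 1]$ and $D = p(EW) \in [0, 1]$.

The test suite checks the forward–backward output against an independent
exhaustive-enumeration oracle on chromosomes of up to five markers (maximum
absolute difference below $10^{-8}$), and checks that fully informative
markers yield 0/1 posteriors equal to the simulated truth.

# Phenotype adjustment

Growth traits are interval gains between weighings (birth weight for age
0). Inclusion filters remove animals measured outside the per-trait age
and interval-length windows, animals that died before the endpoint,
animals whose weight declined during the experiment (the final
post-starvation weight is exempt), and — for traits after day 46 — females
of the first two batches, which were fed differently.

The base model is a REML mixed model (via lme4) of the trait on the
retained explanatory variables with the (rearing) mother as a random
effect. Fixed terms are tested with a Wald F whose denominator is the
estimated residual variance; because the appropriate denominator degrees of
freedom in a mixed model are unclear, $d \times F$ is referred to a
$\chi^2_d$ distribution, assuming large denominator df. Backward selection
removes the least significant term at $p \ge 0.05$, refits, and repeats;
ties drop the later-declared term. The maternal effect is tested by a REML
likelihood-ratio test against a fixed-effects-only fit whose REML
log-likelihood is computed in closed form on the same scale as lme4's
criterion. The default null is $\chi^2_1$, the conservative choice; the
50:50 boundary mixture is available as an option.

The *adjusted phenotype* is the conditional residual: observed minus fixed
effects minus predicted maternal effects. The maternal effect must be
removed here because the scan models contain no mother term. The base
model's residual variance is the standardisation denominator for all
reported effects.

Age-at-move is coarsened by `coarsen_move_age()`: 6-day bins, merging of
adjacent bins whose estimates differ by less than one pooled standard
error (the merge tolerance is configurable; no established value exists),
then a boundary search over ±6 days maximising the explained sum of
squares.

# Genome scans

## Single locus

At every grid position the adjusted phenotype is regressed on $A$ and $D$
(plus the $A$/$D$ of already-detected loci when conditioning), and the
2-df joint F ratio is recorded. The genomewide threshold is the 95th
percentile of the per-permutation maximum F over 1000 row permutations of
the phenotype against the whole grid. Per chromosome, the supra-threshold
peak is a putative QTL; its span is the contiguous supra-threshold stretch
around it, with sub-threshold gaps of at most 10 cM (configurable; chosen
below the mean marker spacing of the motivating design) merged in. The
forward search conditions on all current putative QTL, rescans with the
same threshold, freezes called peaks, and allows a second peak on an
occupied chromosome only outside the existing span.

## Two locus

The 9-parameter model at a pair of positions adds the four interaction
variables $I_{AA} = A_1A_2, I_{AD} = A_1D_2, I_{DA} = D_1A_2,
I_{DD} = D_1D_2$. Significance is judged on the residual sum of squares
(SSE). Two permutation thresholds are used:

* **SSE_genome** — the 5% quantile of the per-permutation *minimum* SSE
  over all eligible pairs. The per-permutation minimisation is an
  exhaustive search on the scan lattice (default 5 cM; 1 cM by setting
  `step = 1`). Eligible pairs are all between-chromosome pairs plus
  same-chromosome pairs at least 20 cM apart.
* **SSE_specific** — per putative QTL: the QTL's $A, D$ columns stay
  fixed, the partner's rows are permuted jointly and the interaction
  columns rebuilt from the permuted partner, the minimum SSE over partner
  positions is taken, and the 5% quantile of the minima is the threshold.
  This corrects the test for the detected locus's marginal effect, and is
  applied to every pair with a position inside that QTL's span (the
  lowest applicable threshold when spans overlap). A locus-specific
  threshold is only used where it is stricter than SSE_genome. The
  partner minimisation is genomewide rather than per chromosome.

Retained pairs form clusters under 8-neighbour connectivity on the pair
lattice within each chromosome-pair panel; the pair with the largest heat
value (governing threshold minus SSE) is the cluster's candidate. Because
the governing threshold changes discontinuously at a span boundary, a
fragment of a region can survive just outside the boundary after the pairs
inside were removed; such a cluster is discarded when the adjoining
initial-map region across the boundary contains a pair with lower absolute
SSE (the edge-effect rule). Finally, each candidate's interaction set is
tested: a 4-df F test at $p < 0.05$, or any single interaction coefficient
at $p < 0.0125$ (= 0.05/4, a fixed constant of the workflow).

# Model simplification and reporting

Putative QTL and putative epistatic pairs are combined into one REML model
of the *raw* phenotype: covariates, maternal random effect, $(a, d)$ per
locus, and the four interaction coefficients per pair. A pair locus within
20 cM of a putative QTL (or inside its span) replaces that QTL at the
epistatic position. Non-significant pairs are removed worst-first with a
refit after every removal; a removed pair's matched QTL survives as an
independent locus, its position re-chosen by REML log-likelihood if the
two candidates differ (ties keep the epistatic position; later-added pairs
are removed first on tied p-values). Surviving pair-loci within 20 cM of
each other in different pairs are merged the same way. Pairs are then
tested on every *other* trait (pointwise, i.e. without genomewide
correction; individually and, when several pass, jointly), and flagged
additions are labelled pointwise-significant. Remaining independent loci
must pass a joint F at $p < 0.05$ or a coefficient t test at $p < 0.025$.
Across traits, loci within 30 cM are reported as the same QTL by
single-linkage chaining.

Locus-term inference in the mixed model reuses the $\chi^2$ approximation
of $d\times F$, with per-coefficient tests using the large-df normal
approximation — one testing machinery throughout.

## Variance explained

The penalised residual sum of squares (PSS) of an LMM at the REML solution
is the residual sum of squares plus the squared, scaled random-effect
deviations (lme4's penalised weighted RSS). The percentage residual
variance explained by a term set is $100\,(PSS_{without} -
PSS_{with})/PSS_{base}$.

## Background-conditional effects

From the fitted pair coefficients, the nine genotypic values are, e.g.,
$G_{WWWW} = a_1' + a_2' + i_{aa}$, relative to the mean of the
double-homozygote classes. The additive and dominance effect of each locus
is then computed *separately for each genotype at the partner locus*, in
the single-locus way: $a_1(X) = (G_{WWX} - G_{EEX})/2$, which reduces to
linear combinations such as $a_1(WW) = a_1' + i_{aa}$. Standard errors are
$\sqrt{c^\top V c}$ with $V$ the coefficient covariance of the REML fit.
The 12 effects of a pair are Holm-corrected at family level 0.05; effects
at $p < 0.025$ before correction are flagged nominally significant and
never promoted. When two pairs share a locus, the shared locus's effects
are indexed by the genotype *pair* at both partners (9 combinations),
giving 18 + 6 + 6 = 30 effects tested together at level 0.1 — the level is
raised because terms from two pairs, each with significant epistasis, are
assessed as one family. All reported effects are standardised by the base
model's residual standard deviation. Under linkage equilibrium the
$(\tfrac14, \tfrac12, \tfrac14)$-weighted mean of a locus's conditional
effects equals its population single-locus coefficients; the suite checks
this identity both algebraically and on simulation.

The independent effects model refits the independent-scan QTL set without
interactions, for comparing effect estimates with and without epistasis.

# The synthetic-data generator

`simulate_cross()` builds founders homozygous for line-labelled
chromosomes, F1s from founder matings, and F2 litters from F1 matings.
Gametes receive Poisson crossovers on the sex-specific map (no
interference), so realised recombination matches the Haldane function by
construction. Marker alleles come from line-specific pools; with
probability `shared_prob` (default 0.3) an allele copy is drawn from a
pool common to both lines, producing the partially informative,
microsatellite-like markers the HMM must handle, and genotypes go missing
independently at `missing_rate` (default 5%). Phenotypes are generated
from the same F∞ model the analysis fits: genetic values from the true
line origins, a Gaussian maternal effect per dam, sex/batch effects, and
Gaussian residuals. `simulate_records()` additionally builds the
weight-at-age records (interval gains accumulate into weights, measurement
ages drawn inside the per-trait windows, optional mortality), so the
filtering and trait-derivation code paths run on realistic inputs.

What the generator does *not* emulate: genotyping error, segregation
distortion, selection or non-random mortality with respect to genotype,
unbalanced fostering, and latent growth-curve structure (growth is
simulated directly as interval gains, the object the analysis works on).
Passing tests therefore validate the inferential machinery under the
model's own assumptions, not robustness to violations of them.

Two presets are provided. `mini` — 2 chromosomes × 100 cM, 8 markers
each, 400 F2 — is the unit of repeated simulation; its reference
architecture (`mini_architecture()`) places an additive locus
($a = 0.4\,\sigma$) on chromosome 1 at 30 cM that interacts
($i_{aa} = 0.5\,\sigma$) with a purely epistatic partner on chromosome 2
at 70 cM. This mirrors the configuration F2 studies most often report —
one pair member detectable on its own, the other visible only through the
interaction — and it exercises the locus-specific threshold machinery,
which exists precisely to detect partners of loci with marginal effects.
`paper_scale` — 18 autosomes, ~2 800 sex-averaged cM, 178 markers, 1 750
genotyped F2 from 17 + 2 founders — matches the scale of a large pig F2
resource population and is used for the maternal-variance and
trait-correlation checks (maternal share configured at 19% of phenotypic
variance).

# Numerical choices and problem sizes

* Forward–backward uses per-step scaling; posteriors are normalised to
  $10^{-9}$.
* Permutation thresholds use the empirical type-7 quantile; all
  permutation work flows from the caller's RNG state, so a single seed
  reproduces every threshold bit for bit.
* Rank-deficient designs: the base model refuses aliased fixed designs by
  name; the two-locus fit drops aliased interaction columns and records
  them; the full model canonicalises bookkeeping duplicates (two loci on
  one grid cell are one locus) before fitting.
* Degenerate inputs: a perfect (zero-SSE) two-locus fit reports a joint
  interaction p of 1 when the main effects already fit perfectly and 0
  when the interactions are required.
* The routine validation sizes are chosen to keep the full suite within a
  desktop coffee break: calibration uses 200 null replicates at 200
  permutations on the mini genome; recovery uses 50 replicates of the full
  pipeline; the acceptance script scales these to 100 and 30.

# Known limitations

* The X chromosome and interference models are out of scope (the
  motivating design uses 18 autosomes and Haldane distances).
* The per-permutation pair-minimisation is exhaustive on a lattice rather
  than a stochastic search; at 1 cM resolution on a large genome this is
  the slowest step and the 5 cM default trades resolution for speed.
* Three-locus structures are handled exactly for one shared locus between
  two pairs; deeper sharing is not implemented.
* Localisation of a purely epistatic partner at mini-study power
  ($n = 400$, $i_{aa} = 0.5\,\sigma$) is noisy: the pair is detected in
  most replicates but its partner coordinate can fall outside 20 cM in a
  substantial minority, a power limit of the design rather than of the
  implementation.
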