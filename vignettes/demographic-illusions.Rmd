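---
title: "Demographic illusions in constant-size bacterial populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic illusions in constant-size bacterial populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

Coalescent demographic inference — skyline plots, site-frequency-spectrum
(SFS) neutrality tests such as Tajima's *D* — reads variation in the
coalescence rate of a genealogy as variation in effective population size.
That reading is only valid under the standard neutral model: no selection, no
recombination beyond what the model accommodates, random sampling. Bacterial
data violate all three assumptions routinely. `coalbias` provides a forward
simulator and the full downstream analysis chain so that each violation can
be switched on alone, in a population whose size is *known to be constant*,
and its imprint on the inferred demography measured.

Everything the package reports about "what selection/conversion/sampling does"
is recomputed by the test suite and the `analysis/` scripts; this vignette
explains the model, the estimators, and the design decisions.

## The forward model

The simulator (`run_simulation()`, compiled core in `src/wf_engine.cpp`)
evolves a haploid Wright–Fisher population of constant size *N* over a single
linear locus of *L* finite sites. Per generation, in order:

1. **Mutation.** The number of events is Poisson(*N·L·u*), with
   *u = θ/(2N)* per site per generation. Each event hits a uniform
   (individual, site) pair and replaces the current nucleotide by one of the
   other three uniformly (JC69). Events are applied sequentially, so two
   events on the same cell in one generation simply compose.
2. **Gene conversion** (if enabled). Initiations are Poisson(*N·L·ρ*) with
   *ρ = (ρ/μ)·u*; each picks a recipient cell, a donor uniform among the
   other *N* − 1 individuals, and a geometric tract length (mean 542 nt by
   default), clipped at the locus end. Donor alleles overwrite recipient
   alleles inside the tract — copying only, never creating alleles. There are
   no crossovers.
3. **Selection and reproduction.** Each child picks a parent multinomially
   with probability proportional to fitness. Fitness is multiplicative
   across sites, a factor (1 + *s*) per carried derived allele. New derived
   alleles draw *s* from a three-point mass: deleterious (*s*~del~ < 0),
   neutral, or adaptive (*s*~adv~ > 0) with configurable probabilities;
   back-mutation to a column's ancestral allele is neutral by definition.

The population starts monomorphic (uniform random nucleotides) and runs for a
burn-in of 10 *N* generations by default. The whole-population TMRCA is of
order 2 *N* generations, so 10 *N* leaves the residual disequilibrium of the
deepest branches at the e^−5^ level; the choice is configurable
(`burnin_gens`).

Only polymorphic sites are materialised: the state is a monomorphic
background sequence plus one column per segregating site carrying every
individual's allele, the pre-mutation (ancestral) allele and the per-allele
selection coefficients. Columns fold back into the background on fixation or
loss; a fixed selected allele is a constant fitness factor and is rebased
away. Log-fitness is tracked incrementally through every mutation,
conversion and inheritance event, and `population_fitness()` recomputes it
from scratch — the test suite holds the two equal to 10^−8^.

Key parameter defaults (all in `scenario_preset()`):

| parameter | default | meaning |
|---|---|---|
| *N* | 1000 | haploid population size |
| *L* | 20000 nt | locus length |
| θ | 0.02 /site | 2 *N u*; so *u* = 10^−5^ per site per generation |
| *n* | 100 | sample size |
| class probs | (0.449, 0.528, 0.022) | deleterious/neutral/adaptive, from the ratio of the E. coli genomic deleterious (2×10^−4^) and adaptive (10^−5^) rates to the total genomic mutation rate (8.9×10^−11^ × 5×10^6^) |
| *s* (weak) | ±5/*N* | *N·s* = ±5 |
| *s* (strong) | ±0.5 | see below |
| ρ/μ | 1 (or 10) | conversion initiations per mutation |
| tract mean | 542 nt | geometric |

**The strong-selection cap.** For E. coli, *N~e~·s* is of order 10^6^;
rescaling to a simulated *N* of 1000 would require *s* > 1, which is
meaningless for a per-generation relative fitness increment. We cap |*s*| at
0.5 and treat the strong-selection scenario as "any regime with
2 *N s* ≫ 1"; its quantitative outputs (e.g. the segregating fraction) are
order-of-magnitude statements, not point predictions, because the diversity
left standing between recurrent sweeps depends on the (unknowable) literal
*s* used by any particular rescaling.

## What the statistics measure

`unfolded_sfs()` counts ξ~i~, the sites where exactly *i* of *n* sequences
carry the derived allele, polarised by the *true* ancestral sequence the
simulator records. Finite-sites JC69 produces some sites with three or more
alleles; these are excluded from the SFS and from *S* and counted separately
(`n_multiallelic`), as are sample-fixed derived sites. `tajimas_d()` is the
standard Tajima (1989) statistic over the biallelic segregating sites, with
π computed from the spectrum; it is undefined (NA, excluded from averages)
when *S* = 0. The transformed SFS, *i·ξ~i~* normalised to sum 1, has flat
expectation 1/(*n* − 1) under neutrality because E[ξ~i~] = θ/*i* — departures
from flatness are the visual signature every scenario is judged against.

A consequence of finite sites worth stating: the closed form
E[*S*] = θ·L·a~n~ (≈ 10.35% of sites at the defaults) is an infinite-sites
result. At θ = 0.02 per site, repeat mutation converts roughly 1% of the
locus into multiallelic or re-hit sites, so the *biallelic* segregating
fraction sits slightly below the closed form (around 9–9.5%). We verified
this against an independent coalescent simulator with a finite-sites JC69
mutation model during development; the package's own tests therefore check
the neutral fraction against a band around the ~10% figure rather than a
pure 3-SE interval around 10.35%.

## Misorientation: model, estimator, correction

With real data the ancestral state comes from an outgroup, which matches the
true ancestor only with probability *q*. A misoriented biallelic site has its
frequency class reflected, giving the mixing model
ξ~k~^obs^ = *q* ξ~k~ + (1 − *q*) ξ~n−k~. Sites where the outgroup matches
*neither* allele cannot be polarised at all; under JC69 a misoriented
outgroup lands on neither allele with probability 2/3, so the unpolarisable
fraction among segregating sites is x = P(U|S) = 2(1 − *q*)/3, and
*q̂* = 1 − 3x/2 (`estimate_q()`, mode `jc_consistent`). A second mode,
`paper_literal`, implements the rule *q̂* = x/2 that circulates in the
source literature; it is retained for comparability but is inconsistent with
the mixing model itself (it cannot produce *q* near 1 for small x), which is
why it is not the default. Similarly `correct_sfs()` defaults to the exact
algebraic inverse of the mixing model,
ξ~k~ = (*q* ξ~k~^obs^ − (1 − *q*) ξ~n−k~^obs^)/(2*q* − 1), and keeps the
printed variant (which omits the factor *q* on the first term) as
`paper_literal`. The tests verify that mixing followed by the exact inverse
is the identity for any spectrum and *q* ∈ (0.5, 1], and that the
JC-consistent estimator recovers *q* on simulated outgroups across a grid.

## Biased sampling

The full final population (all *N* individuals) is clustered with PAM
(k-medoids; BUILD + best-improvement SWAP, re-implemented and cross-checked
against `cluster::pam`) on the pairwise p-distance matrix. Three schemes then
draw the sample of *n*:

- **uniform** — one individual per cluster, *k* = *n*;
- **clustered** — all *n* from a single cluster (*k* = 10), chosen uniformly
  among clusters with ≥ *n* members (an error, reported to the caller, if
  none qualifies);
- **mixed** — *n* − 9 from a focal cluster plus one from each of the
  remaining nine (*k* = 10).

PAM clusters need not be monophyletic; that is deliberate — the procedure
mimics the imprecise typing methods used to pick strains for sequencing.

## Genealogies and skylines

Trees are UPGMA (average linkage on JC69-corrected distances, ultrametric by
construction; `stats::hclust` behind `upgma_tree()`). Sorted node heights
give the coalescent intervals. The classic skyline estimates
N~e~·u = t~k~·k(k−1)/2 per interval; the generalized skyline pools
consecutive intervals (from the present backwards) until each composite
spans at least ε of time, a terminal short composite being merged inward,
and gives each composite the maximum-likelihood estimate
(1/c)·Σ C(k~i~,2)·t~i~. The AIC, 2K − 2 lnL with one parameter per
composite, selects ε over a grid of 0 plus 20 log-spaced values from
depth/1000 to the tree depth; ties go to the smaller ε. Zero-length
intervals (identical sequences, frequent under clustered sampling) make the
classic skyline degenerate; ε-pooling absorbs them, which is why the
amplitude statistic (max/min N~e~·u across segments) is always taken from
the AIC-selected skyline.

Our pooling rule and likelihood follow the piecewise-constant coalescent
MLE as stated above; `ape`'s `skyline()` implements the same classic
estimator (the tests assert exact agreement there) but its generalized
variant differs in bookkeeping details, so it is used as a cross-check only
for ε = 0.

Two calibration facts anchor the estimator (both tested): on constant-size
Kingman trees the fully pooled skyline recovers the simulated N~e~·u within
Monte-Carlo error, and the AIC selects fewer segments than the classic
skyline in the vast majority of replicates — with constant truth, pooling
wins. A corollary worth knowing: because AIC pooling is aggressive, skylines
from *random* samples of a constant population typically collapse to a
single segment (amplitude exactly 1), so the sampling-bias signal appears as
amplitudes > 1 under uniform and clustered sampling against a baseline of 1,
and the comparisons are made with paired one-sided Wilcoxon tests. Bayesian
skyline implementations smooth far less, so the very large amplitude ratios
they report under the same biases (orders of magnitude) translate here into
direction and significance, not magnitude.

## What the generator does and does not emulate

The simulator reproduces: constant-size haploid drift, finite-sites JC69
mutation, point-mass selection with multiplicative fitness, intra-population
gene conversion with geometric tracts, and exact knowledge of ancestral
states. It does not emulate: crossover recombination, demographic change of
any kind (constancy is the point), population structure or migration,
horizontal transfer from outside the population, rate heterogeneity along
the locus, or sequencing error. Passing tests therefore demonstrate that the
*analysis chain* behaves as claimed on data whose generating process is
fully known — not that real bacterial datasets are free of additional
complications (structure, HGT, error) that the model omits.

## Numerical and design notes

- **Replicate seeds.** A scenario's master seed expands into per-replicate
  seeds (`sample.int(2^31 - 1)` under `set.seed(master)`), so any replicate
  reruns in isolation; all randomness, including inside the compiled engine,
  flows from R's global RNG.
- **Event order** within a generation is mutation → conversion →
  reproduction; with per-generation rates of order 10^−5^ per site the order
  is immaterial to distributions, but it is fixed and documented for
  reproducibility.
- **Collisions** (two mutation events on one cell in one generation) are
  resolved by sequential application; the second event mutates the product
  of the first.
- **Desk scales.** The analysis scripts default to N = 300, L = 2000,
  20–25 replicates — large enough that every qualitative effect in the study
  reproduces, small enough to run in minutes; the acceptance-grade runs in
  the test suite and `scripts/acceptance.R` use the full N = 1000,
  L = 20000, n = 100 with 8–20 replicates per scenario.
- **Ties.** PAM assigns equidistant points to the lowest-index medoid;
  UPGMA tie handling is `hclust`'s deterministic rule; AIC ties go to the
  smallest ε.
- **Degenerate inputs.** S = 0 makes the transformed SFS and Tajima's D
  undefined (error and NA respectively, never silently 0); q ≤ 0.5 makes the
  misorientation mixing non-invertible (error); skylines with a zero
  estimate report an undefined amplitude rather than Inf.

## Known limitations

- The strong-selection scenario's segregating fraction is sensitive to the
  |s| cap (see above); treat it as an order of magnitude.
- The generalized-skyline amplitude is a conservative distortion detector:
  AIC pooling absorbs mild distortion (clustered-sampling amplitudes are
  only a few-fold above 1 here, versus the larger ratios a Bayesian skyline
  reports).
- Gene conversion from a uniformly chosen donor lets a lineage jump onto
  the other member of a tracked pair, adding an extra pair-coalescence rate
  of order 2·ρ·(mean tract)/N. At the default 1× rate this shaves well under
  1% off E[S] (invisible against genealogical noise); at 10× it is a ~10%
  dip at full scale, and proportionally more if a desk-scale miniature keeps
  the 542-nt tract against a short locus. The analysis scripts scale the
  tract with the locus for this reason.
- p-distances underestimate divergence beyond ~0.1 substitutions/site;
  JC69 correction is available (`distance_matrix(..., "JC69")`) and is the
  default for tree building but not for the PAM clustering, where only the
  ranking of distances matters.
- The simulator is single-locus and haploid by design — the natural encoding
  for bacterial populations; no diploid re-encoding is offered.
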