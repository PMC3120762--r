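---
title: "Phylogeographic model selection and coalescent dating with demeflow"
author: "demeflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeographic model selection and coalescent dating with demeflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demeflow)
```

## Scope

`demeflow` implements a statistical-phylogeography workflow for shallow
intraspecific haplotype data sampled from a small number of geographic
demes, of the kind produced by range-wide surveys of a single mitochondrial
and a single nuclear locus. The workflow has four analysis layers:

1. **Haplotype statistics and networks** — collapsing an alignment to a
   haplotype table, Nei's haplotype diversity, per-site nucleotide
   diversity, singleton / parsimony-informative site classification, and
   statistical-parsimony networks with a 95% connection limit.
2. **Colonization-scenario inference** — encoding explicit colonization
   hypotheses over three demes as constrained migration matrices of the
   structured coalescent, estimating each scenario's maximum-likelihood
   parameters by Markov chain Monte Carlo over genealogies, and ranking the
   scenarios by AIC.
3. **Coalescent skyline dating** — Bayesian reconstruction of the effective
   population-size trajectory under a strict molecular clock, expansion
   onset summaries in years, and Bayes-factor comparison against a
   constant-size model.
4. **Synthetic data** — a structured-coalescent simulator with finite-sites
   mutation that generates datasets with the statistical shape the analysis
   layers assume, so every stage can be tested without access to field
   data.

## Conventions and units

All coalescent-layer quantities use the migrate-style scaling:

* $\theta_i = x N_i \mu$ per site, with inheritance scalar $x = 1$ for a
  haploid maternally inherited locus and $x = 4$ for a nuclear autosomal
  one. Within deme $i$ any pair of lineages coalesces at rate $2/\theta_i$.
* Time is measured in expected substitutions per site, so node times of a
  genealogy are directly branch lengths for the substitution model.
* Migration is parameterised backward in time: $M_{ij}$ is the rate at
  which a lineage currently in deme $i$ relocates to deme $j$ when traced
  into the past. A forward-time colonization edge $X{>}Y$ therefore frees
  the backward rate $Y{\to}X$; this convention is used consistently by the
  simulator, the likelihood and the scenario encoder.

A colonization hypothesis over three demes fixes all backward rates to zero
except those implied by its forward edges. Taking each deme in turn as the
origin, with either simultaneous or sequential colonization of the other
two demes, yields nine constrained hypotheses with $k = 5$ free parameters
each (three sizes, two rates), plus the unconstrained full model with
$k = 9$.

## The synthetic-data generator

`simulateGenealogy()` runs the backward structured coalescent exactly:
exponential waiting times between events, competing coalescence and
migration, and (optionally) a two-epoch demographic history in which every
deme's size ramps linearly from an ancestral value $\rho\,\theta_i$ at the
expansion onset to $\theta_i$ at the present. Time-varying coalescence
rates are simulated by thinning, which is exact for any bounded rate
function. `mutateOnGenealogy()` places substitutions by a continuous-time
Markov process (JC, HKY or GTR, optionally with discrete-gamma rate classes
and invariant sites, normalised to one expected substitution per site per
unit time).

The default generating conditions are chosen once to match the statistical
shape of shallow western-Mediterranean range-expansion data: three demes
F/S/A; a ~600 bp maternally inherited locus with 138 sequences split
34/52/52 (the origin and first-colonised demes sampled more densely than
the small terminal population, which shows the lowest diversity); a ~220 bp
nuclear locus typed for 38 diploid individuals emitted as 76 phased allele
copies; $\theta = 0.01$ per site per deme; a recent ten-fold expansion with
onset $3.424\times10^{-4}$ substitutions per site (8,000 years at the
default clock); and backward rate 300 on each colonization route
($\theta M = 3$, several effective migrants per scaled generation). The
rate value deserves a note, because it controls whether the colonization
*order* is identifiable at all. When routes are weak
($\theta M \lesssim 0.3$), a colonised deme coalesces down to a single
lineage before that lineage takes the onward jump, so a two-jump sequential
history and a one-jump independent history from the same origin explain the
data almost equally well — the origin is recovered, the order is not.
Identifiability of the order requires immigrant lineages to arrive while
the source deme is still carrying several lineages, i.e. migration fast
relative to within-deme coalescence ($\theta M \gtrsim 1$). The default
$\theta M = 3$ sits firmly in that regime while the demes remain
distinguishable. The shape-emulation preset (`presetConfig()`) is
calibrated separately to the stated empirical summaries (about 13–18
haplotypes and 15–30 segregating sites among 138 sequences) with
$\theta = 0.005$ and route rate 150. With the recent expansion included,
the simulated data show the features the method relies on: shallow
diversity, haplotype sharing along the colonization chain, and derived
demes whose lineages nest within the source deme's diversity.

What the generator deliberately does **not** emulate: recombination,
selection, more than one locus per run, unphased genotypes, colonization
*pulses* (rates are constant through time; a founder event is represented
by the expansion, not by a migration burst), and population structure
within demes. Passing recovery tests on these data therefore demonstrate
that the inference machinery works under its own model assumptions with
study-sized samples — not that any empirical dataset of this shape will
yield a decisive answer.

## Haplotype statistics and networks

Haplotypes are exact sequence classes after upper-casing; IUPAC ambiguity
codes are rejected (phasing is out of scope), and alignment columns with
non-ACGT symbols are excluded from distances and site statistics, with the
excluded columns recorded on the table. Diversity statistics are Nei's
unbiased $h = \frac{n}{n-1}(1 - \sum p_i^2)$ and per-site $\pi$ (mean
pairwise Hamming distance over retained columns). Both are reported because
published per-region "haplotype diversities" for nuclear loci are sometimes
two orders of magnitude below the mitochondrial values and evidently on the
per-site scale; providing both statistics avoids the ambiguity. A variable
column is parsimony-informative when at least two bases each occur in at
least two sequences; otherwise each variant present in exactly one sequence
counts as a singleton mutation.

The connection limit is the largest step count $j$ whose probability of a
parsimonious connection is at least the confidence level. We model that
probability as the chance that $j$ mutations hit $j$ distinct sites of an
$L$-site sequence, $\prod_{i=0}^{j-1}(1 - i/L)$: any repeated hit —
parallel or back mutation included — shortens the observable path and
breaks parsimony. This closed form is deliberately simple; it agrees with a
Monte-Carlo simulation of the same process (the acceptance reference), and
gives a limit of 8 steps for a 604 bp locus at 95%. Published
statistical-parsimony software uses a related but more elaborate estimator;
networks built at either limit differ only for haplotype pairs beyond ~8
differences, which do not occur in data this shallow.

Networks connect haplotype pairs level by level in order of increasing
Hamming distance; a pair is joined (through inferred intermediates when
more than one step apart) only if its members are still in separate
components at the start of its distance level, so all equal-length
alternative connections between two components are retained and loops can
arise. Candidate edges within a level are processed in a deterministic
order (summed haplotype frequency decreasing, then lexicographic id).

## Migration inference

The likelihood of an alignment under a scenario is the probability of the
data integrated over genealogies-with-migration-histories of the structured
coalescent. `estimateLoglik()` provides the direct Monte-Carlo form of this
integral — genealogies simulated from the coalescent prior, Felsenstein
likelihood averaged over draws — which is exact in expectation and is
validated against numeric quadrature for two-sequence data, but is far too
variable for scenario comparison at realistic sample sizes.

`fitScenario()` / `fitAllScenarios()` therefore use a sampling scheme in
the spirit of the classic ML migration-rate estimators:

* **Kernel.** A Metropolis–Hastings chain over genealogies with explicit
  migration paths. The tree move detaches a random lineage and re-grows it
  from the conditional structured coalescent at driving parameter values,
  so its Hastings ratio is the data-likelihood ratio alone. Because that
  move re-finds attachment points by prior chance, it mixes migration
  histories slowly; each iteration therefore adds a batch of cheap
  refresh moves that leave the tree (and hence the likelihood) untouched: a
  redraw of one lineage's deme path from the endpoint-conditioned migration
  process, and a flip of one coalescence node's deme with bridged adjacent
  paths. The refresh moves only need the prior-density ratio, for which the
  chain keeps each state's sufficient statistics (per-deme coalescence
  counts, pair-time and lineage-time integrals, migration counts).
* **Parameter estimation.** Retained sufficient statistics allow the
  genealogy density to be evaluated at any parameter values, so the
  likelihood *ratio* to the driving values has a simple importance-sampling
  estimate; it is maximised over the scenario's free parameters (log scale,
  Nelder–Mead, a ±log 50 trust region around the driving values), and the
  procedure can be re-centred for several driving rounds.
* **Comparable log-likelihoods.** Absolute log-likelihoods are estimated by
  stepping-stone sampling from the coalescent prior to the posterior along
  a Beta(0.3, 1)-spaced power ladder. Warm-started ladders of affordable
  length retain an annealing bias, so cross-scenario comparisons do not use
  two absolute estimates: the full model is anchored once per dataset, and
  each constrained scenario's difference to it is estimated along a short
  parameter-path bridge (free parameters interpolated log-linearly, vanishing
  rates decayed exponentially before dropping to zero), where each rung
  samples an ordinary posterior and contributes a telescoping ratio. The
  annealing distance between two fitted models is far smaller than from the
  prior, and the absolute anchor cancels from the ranking entirely.
* **Semantics of `-Inf`.** A constrained scenario's likelihood is reported
  as `-Inf` when, at the end of the bridge, every retained genealogy still
  requires a migration event on a route the scenario forbids. This is the
  correct limit of the likelihood when the data cannot be explained through
  the allowed routes, but it can also arise for a merely ill-fitting
  scenario when the chain cannot rearrange the genealogy within its budget;
  either way the scenario is ranked last, which is the decision-relevant
  property.

Estimated log-likelihood *values* are tied to this estimator and its
budgets; they are not comparable to the output of other programs, and AIC
differences — not levels — carry the information. The default substitution
model for this layer is HKY with empirical base frequencies, which is
adequate at intraspecific divergence; GTR+$\Gamma_4$+I remains available.

## Model selection

`aic()` is $2k - 2\ln L$ and `rankModels()` sorts scenarios by it. The
unconstrained full model takes part in fitting and appears in the table,
but is excluded from the best-versus-runner-up gap among the colonization
hypotheses: the decisive quantity is the AIC difference between the best
and second-best *constrained* models, which is also how the published
decision values for this design are defined (the full model would otherwise
sit between them and mask the comparison).

## Coalescent skyline dating

The demographic model is a piecewise-linear effective-size trajectory with
change points: sizes $N_0$ (present) through $N_K$ (ancestral), change
times uniform on (0, root height) given their count, the count $K$ carrying
a truncated Poisson(2) prior on $\{0,\dots,4\}$ (the mean reflects an
expectation of two expansion events), and sizes bounded in $[10^4,
10^{12}]$ individuals. One calendar year is treated as one generation. Two
size-prior shapes are available. The default is log-uniform on the bounds;
a flat (uniform) option is provided. The log-uniform default was chosen
because it is the scale-invariant reference prior and because it makes an
exact property hold: the sampler's internal state is parameterised in
substitution units (node times in substitutions per site, sizes as
$\nu = N r$ for clock rate $r$), in which the posterior depends on $r$ only
through the size-bound indicators; with slack bounds, re-running with rate
$r/2$ and the same seed reproduces the identical internal chain, so every
time summary in years scales exactly by two. With a uniform size prior (or
when the bounds bind) the law holds only approximately.

The MCMC combines node-height slides, whole-tree scaling, narrow exchange,
size random walks, change-time slides, reversible-jump birth/death of
change points (size proposals relative to the current trajectory within a
log window, so the jump acceptance stays scale-free), and a joint
"up-down" scaling of heights, sizes and change times that decorrelates the
overall time scale from the sizes. The chain starts from a UPGMA tree whose
zero-height merges (identical haplotypes) are spread over the recent half of
the tree — a start state with all-instant coalescences lies in a degenerate
small-size mode that the sampler escapes only slowly. The substitution
model is GTR with empirical base frequencies, four gamma categories and
invariant sites; its nuisance parameters are plugged in by a quick ML fit
(empirical Bayes) via `phangorn` when available, with fixed fallback values
otherwise.

**Expansion onset** is operationalised as the most recent change-point time
among posterior trajectories whose modern size exceeds the ancestral size
at least two-fold, summarised by the median and central 95% interval in
years before present. Samples without a two-fold expansion contribute no
onset; if fewer than three samples qualify the summary is reported as
missing rather than fabricated.

**Marginal likelihoods** are estimated by stepping-stone sampling along a
16-rung Beta(0.3, 1) power ladder by default. For the skyline model the
change-point count is marginalised explicitly: one fixed-dimension ladder
per count $K \in \{0,\dots,4\}$, combined with the truncated-Poisson
weights. Fixed-dimension ladders anneal far more reliably than
reversible-jump ones — a mixture bound guarantees the skyline marginal can
never fall more than $\log 1/P(K{=}0) \approx 1.95$ below the constant-size
marginal, which makes strongly negative reversible-jump estimates
immediately recognisable as annealing artefacts. The reversible-jump moves
are kept for posterior summaries, where trans-dimensional mixing matters
less than marginal-likelihood accuracy. A trapezoidal
thermodynamic-integration estimate over the same rungs is returned as a
cross-check.

## Numerical choices

* Alignment columns are compressed to site patterns before any likelihood
  work; at intraspecific diversity this shrinks a 600-column alignment to a
  few dozen patterns.
* The pruning kernel runs in compiled code with per-node rescaling of
  partial likelihoods and flush-to-zero arithmetic: posterior trees carry
  many near-zero branches whose partials otherwise drift into subnormal
  range, which is dramatically slow on common hardware.
* Transition matrices come from the symmetrised eigendecomposition of the
  normalised rate matrix; rows are clipped to non-negative values and
  renormalised.
* The growth simulator uses thinning with the terminal (smallest) size as
  the global rate bound, which is exact.
* Ties in network construction are broken deterministically; all stochastic
  stages are seeded, and dataset generation is byte-reproducible from its
  configuration.

## Test and experiment sizes

The test suite and the acceptance script run every stage end to end at
reduced, documented budgets chosen as the package's own default experiment
sizes: scenario recovery uses 20 replicate datasets of 20 sequences per
deme and 600 bp fitted with single-round driving and a 6-rung bridge;
skyline coverage uses 20 replicates of 60 sequences and 604 bp with
6,000-iteration chains. Final analyses of real data should raise the
budgets (several driving rounds, longer ladders, 10× longer skyline chains)
and check the reported diagnostics (acceptance rates, importance effective
sample sizes, trace ESS) rather than rely on these defaults.

## Known limitations

* Scenario discrimination from a single shallow locus is intrinsically
  weak. Under the generating conditions above, the origin deme is usually
  recovered decisively, but sequential versus simultaneous colonization
  from the same origin can remain within a few log-likelihood units —
  comparable to the Monte-Carlo error of affordable budgets — so individual
  replicates can rank a same-origin rival first.
* The reported Monte-Carlo standard errors of stepping-stone estimates omit
  the annealing component; treat them as lower bounds.
* The skyline layer fits a single locus; the onset posterior for very
  recent expansions leans on the change-time prior when the data carry few
  recent coalescences.
* The migration layer's fitted rate and size values inherit the trust
  region of the optimizer; rates at the trust boundary indicate the moment
  starting values were far off and warrant a re-run with more driving
  rounds.
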