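---
title: "Composite-likelihood demographic inference and admixture modeling with sfskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite-likelihood demographic inference and admixture modeling with sfskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sfskit)
```

## The problem

Given diploid genotype panels from several populations, we want to (i)
infer the demographic history — population divergence times, effective
sizes, bottlenecks and continuous gene flow — that best explains the
multidimensional joint site frequency spectrum (SFS), and (ii) quantify
admixture between populations with allele-frequency (f-) statistics and
qpAdm-style mixture models.  The package is built around the history of
Sino-Tibetan-speaking populations of the eastern Tibetan Plateau margin
(Han Chinese, highland and lowland Tibetan, Yi and Mosuo groups), whose
divergence structure it ships as a library of competing scenarios, but
every component takes arbitrary models and panels.

Because the genotype data such studies rest on are access-controlled,
`sfskit` treats synthetic data as a first-class citizen: a built-in
structured-coalescent simulator generates genotype panels under any model
in the library, a drift simulator generates allele-frequency panels with
known admixture proportions, and every analysis can therefore be exercised
as a parameter-recovery experiment in which the generating truth is known
and recorded in a ledger.

## The joint SFS and its filters

The unfolded joint SFS over k populations counts, for every combination of
derived-allele counts, the number of sites showing that combination.  It
requires knowing the ancestral allele at every site and complete genotypes,
so sites are filtered before tallying, removing any site that is

1. missing in at least one sample;
2. out of Hardy-Weinberg equilibrium (exact test, p < 1e-4) in at least
   one population;
3. inside a CpG-island mask;
4. inside a coding-sequence mask;
5. lacking ancestral-state information.

The HWE exact test is evaluated within each population by default (an
out-of-equilibrium signal in a single admixed or inbred group should not
be diluted by pooling); a pooled mode is available via
`per_population = FALSE`.  Masks are BED interval sets (half-open,
0-based) because annotation sources differ between studies; the simulator
marks its output so that clean synthetic panels pass all five filters with
zero removals, which the tests assert.

Counts at one corner of the SFS (all populations ancestral) are not part
of the polymorphic array; they are carried separately as the monomorphic
count, which the composite likelihood uses during its early cycles.  The
other corner (all derived) stays addressable, matching the layout of
multidimensional `.obs` interchange files.

## The composite likelihood

For an observed SFS with cell counts $m_i$ and model-predicted per-site
probabilities $p_i$, the composite log-likelihood is

$$\log_{10} CL = \sum_i m_i \log_{10} \hat p_i ,$$

treating sites as independent.  Entries with counts of five or fewer are
pooled into a single residual cell before estimation — sparsely observed
cells are exactly the ones whose Monte-Carlo probabilities are worst
estimated, so pooling both regularizes the likelihood and guards against
overfitting.  The monomorphic cell is included for the first
`n_cycles_with_monomorphic` optimization cycles (anchoring the overall
mutation yield) and dropped afterwards, with probabilities renormalized
over the polymorphic support.

Expected probabilities come from Monte-Carlo coalescent simulation: a
cell's probability is the mutation rate times the mean genealogical branch
length subtending that derived-count configuration.  Zero or near-zero
estimates are floored at `1/(10 * n_sims)` *on the polymorphic-conditional
scale*.  The scale matters: per-site cell probabilities are tiny (of order
$\mu \times$ branch length), and flooring them directly at the resolution
of the simulation would inflate most of the spectrum; the floor is
therefore interpreted as the smallest resolvable conditional probability
and rescaled by the total polymorphic mass when absolute probabilities are
in use.

## The fitting protocol

`ecm_optimize()` implements expectation conditional maximization: each
replicate run starts from a random point of the search space (log-uniform
for times and sizes) and repeatedly cycles through the free parameters,
maximizing the composite likelihood in one dimension at a time with a
Brent search whose interval is clipped to the topological order
constraints (a child split cannot become older than its parent).  All
evaluations within one cycle share a simulation seed (common random
numbers), which removes most of the Monte-Carlo noise from *comparisons*
along the 1-D search.

Because the surface is re-simulated each cycle, an ECM trajectory is
stochastic and its final position is not its best: each replicate
evaluates its position at the end of every cycle under one fixed
tracking seed and keeps the best point visited (the same reason
production SFS fitters report the best likelihood reached across
optimization iterations rather than the terminal iterate).

Monte-Carlo noise still matters across cycles, so the protocol never
trusts a single trajectory: many replicates are run, and the
maximum-likelihood replicate is designated by re-computing every
replicate's final likelihood with a single shared seed and many more
simulations (`n_sims_select`, default 17x the per-evaluation count — the
same ratio production-scale fits use when they re-evaluate their best runs
with 1e7 simulations after optimizing with 6e5; the shipped recovery
configurations raise it to 1e6 so that designation noise, about +/-7
log10 units there, sits well below the typical separation between
candidate replicate optima).  The designated run's
likelihood is then *re-estimated* 100 times with independent expected
spectra (`reestimate_likelihood()`), characterizing the Monte-Carlo spread
of the likelihood at the optimum.

Model selection (`select_model()`) is deliberately conservative and does
not use information criteria: a model is decisive best only if (i) its ML
run's terminal likelihood is the highest and (ii) its mean re-estimated
likelihood exceeds every alternative's by strictly more than 50 log10
units.  Anything less reports "no decisive model" with the failing
comparisons.

Parameter uncertainty comes from a nonparametric block bootstrap:
1 Mb genomic blocks are resampled with replacement (keeping the total
block count), the SFS is rebuilt, a reduced fit (20 replicate runs) is
performed per bootstrap, and 95% intervals are the nearest-rank 2.5th and
97.5th percentiles of the 100 bootstrap ML estimates — with 100 values,
the 3rd and 98th order statistics.  `rescale_parameters()` applies the
standard correction for a mismatch between observed and expected SNP
counts (sizes and times multiply by the ratio, migration rates divide).

## The coalescent engine

Expected spectra and synthetic genotypes come from a single-locus
structured coalescent written in C++: populations with piecewise-constant
diploid sizes, divergence events that move lineages into an ancestral
deme, bottlenecks as paired size changes, continuous backward migration
and admixture pulses.  Sites are independent (no intra-locus
recombination), matching the independence assumption of the composite
likelihood; genotype simulation partitions the requested sequence length
into 500 bp loci, one genealogy each, with Poisson mutation counts.  The
engine was validated against the analytic neutral SFS (singletons :
doubletons : tripletons = 1 : 1/2 : 1/3) and the Watterson expectation
for segregating sites, both enforced in the test suite.

## The scenario library and its defaults

Six scenarios encode competing hypotheses about Sino-Tibetan population
history in two tiers (four-population base models; six-population extended
models).  Published point estimates anchor the generating truth: the
Han/Tibeto-Burman split at ~9.9 kya, Tibetan vs non-Tibetan Tibeto-Burman
at ~4.2 kya, Muli vs highland Tibetan at ~3.4 kya, Yi vs Mosuo at ~2.2
kya, Dujiangyan vs Lhasa Tibetan at ~1.2 kya, with 29 years per
generation and a mutation rate of 1.25e-8 per site per generation.

Quantities the study system does not print get documented defaults, chosen
once: deep ancestral branches at N_e 10,000; a bottleneck of N_e 1,000
lasting 10 generations immediately preceding the basal Tibeto-Burman
split; symmetric continuous migration at 1e-4 per generation on
within-clade contact edges; a Northern/Southern Han split at 6.0 kya; Han
lineages at N_e 20,000 and Tibeto-Burman lineages at N_e 5,000.  The
asymmetric sizes reflect the study system's own demography — these
Tibeto-Burman groups are repeatedly described as maintaining small
effective sizes with bottlenecks, while Han populations expanded — and
they matter for study design: with all sizes at 10,000 the recent
within-clade splits accumulate so little drift that a desk-scale SFS
cannot resolve them (a power analysis during design showed the composite
likelihood separating truth from a two-fold-different alternative by only
~10 log10 units; with the small Tibeto-Burman sizes and five diploids per
population the separation is ~75-100 units).

## Recovery experiments and their design

`make_sfs_study_fixture()` generates the recovery substrate at three
scales: `mini` (~1e4 polymorphic sites, for smoke tests), `desk` (~2e5,
the scale at which the package's accuracy claims are made) and `paper`
(~2.7e6).  Sample sizes are 5 diploids per Tibeto-Burman population and 4
per Han population in the six-population panel (58 haploid genomes; the
power analysis above) and 4 diploids per population in the four-population
panel.  Recovery fits free the split times and fix the remaining
(nuisance) parameters at their generating values; the experiment measures
how well the protocol recovers times, not whether every nuisance dimension
is identifiable at reduced settings.  Reduced fitting settings are used
throughout: 1e4 simulations per evaluation, 20 ECM cycles, and 10
replicate runs.  Only the first 4 cycles include the monomorphic cell:
monomorphic-aware cycles primarily calibrate absolute population sizes,
which the recovery design holds fixed, and the Monte-Carlo noise of the
monomorphic term (hundreds of log10 units per evaluation at desk scale,
because ~1e8 monomorphic sites multiply the error in the expected tree
length) would otherwise dominate the early search for split times; a few
monomorphic cycles are kept so the overall SNP yield still anchors the
deepest split.

What the synthetic data do *not* emulate: sequencing error, missing data
patterns, array ascertainment, phasing artifacts, pseudo-haploid calling
of ancient samples, recombination within loci, and selection.  Passing
recovery tests therefore demonstrates correctness of the estimation
machinery under the model's own assumptions — not robustness to the many
ways real data violate them.

## f-statistics and qpAdm

`f3(A, B; C)` is the mean of $(c-a)(c-b)$ with an optional finite-sample
heterozygosity correction for the target; `f4(A, B; C, D)` the mean of
$(a-b)(c-d)$; Hudson's FST is the ratio of genome-wide averages of its
corrected numerator and denominator.  All standard errors are weighted
delete-one-block jackknives (block weight = usable sites), verified in the
tests against closed forms (two equal blocks give SE $=|x-y|/2$) and
brute-force recomputation.  Hudson's estimator was chosen over
Weir-Cockerham because it composes naturally with the f2-based machinery;
both are frequency-based and the choice is documented rather than load-
bearing.

`qpwave_rank()` forms the f4 matrix $X_{ij} = f4(l_i, l_1; r_j, r_1)$ and
tests its rank by minimizing the quadratic form under the block-jackknife
covariance of $vec(X)$ (alternating weighted least squares for the
low-rank factor), with $(|L|-1-r)(|R|-1-r)$ degrees of freedom.
`qpadm()` exploits the linearity of f4 in the target's frequencies: if the
target is a mixture $T = \sum_i w_i S_i$, then every outgroup contrast
satisfies $f4(T, r_1; r_j, r_1) = \sum_i w_i\, f4(S_i, r_1; r_j, r_1)$.
Weights (summing to one) solve this system by generalized least squares
under the jackknife covariance of the residuals, iterated a few times from
equal weights; weight standard errors come from delete-one-block
re-estimation, and nested models (dropping each source) are assessed by
the same rank machinery.  The covariance is ridge-stabilized at 1e-12 of
its trace, which matters only when blocks are few.  Feasibility (all
weights in [0,1]) is reported as a flag, never hard-filtered — the raw
values stay visible.

The admixture fixture (`make_qpadm_fixture()`) places the seven canonical
outgroups (Mbuti, GanjDareh_N, Villabruna_HG, Mixe, Papuan, Onge, Atayal)
on a continental drift scaffold in which they are *differentially* related
to the three source lineages (northern millet-farmer, coastal southern,
western steppe) — a design requirement, since outgroups symmetric to all
sources carry no weight information.  The target mixes the sources'
pre-drift ancestors (so each sampled source carries private drift, as real
proxy populations do) and then drifts on its own.  Ancient sources are
emulated as extra-drifted populations with small sampled allele counts;
pseudo-haploid sampling and damage are out of scope.  Default mixing
proportions follow the published admixture models for the region: a
three-way model with the majority (northern) source at 80.7% and the
remainder split between coastal-southern and western-steppe sources in
the ratio of their published lower bounds, and a two-way model with the
northern source at 85.7%.

## Numerical choices and degenerate inputs

* Times are generations backward from the present, real-valued; config
  files may specify kya, converted with the model's generation time.
* The ECM cycles parameters in their configuration order, which the
  shipped scenarios arrange deep-to-shallow: a nested split time is
  constrained below its parent's current value, so maximizing the deeper
  times first releases the bound before the nested ones are searched.
  Shallow-first cycling can trap a mid-level split under a
  not-yet-updated parent.
* Brent searches use a relative tolerance of ~1.2% of the (log-scaled)
  interval; tighter tolerances only chase Monte-Carlo noise at reduced
  simulation counts.
* Replicates whose likelihood becomes non-finite are marked failed and
  excluded from ML designation; a fit errors only if every replicate
  fails.  Bootstrap CIs error when fewer than 80% of bootstraps survive.
* A one-block dataset yields degenerate bootstraps: every replicate equals
  the original and the CI has zero width (tested).
* Percentiles are nearest-rank order statistics, stated explicitly because
  with exactly 100 bootstrap values the convention is visible in the
  result.
* The Lehmer/MINSTD stream used for block resampling and ECM starts is
  deliberately independent of R's global RNG so that package randomness
  never perturbs — and is never perturbed by — user code; the
  frequency-panel simulator seeds R's RNG locally and restores the
  previous state on exit.

## Known limitations

* The composite likelihood ignores linkage; standard errors from it would
  be anticonservative, which is why all interval estimates go through
  block resampling.
* At reduced simulation counts the likelihood surface is noisy; the
  replicate-plus-precise-designation protocol compensates, but single
  replicates should never be trusted (this mirrors the production
  protocol's 100-replicate design).
* Split-time estimates at modest simulation counts tend to sit somewhat
  below the generating value (typically 5-15% in the recovery
  experiments).  Deeper splits spread expected mass across many rare
  cells whose Monte-Carlo probabilities are noisier, and the concavity of
  the log penalizes that noise asymmetrically, tilting the stochastic
  surface toward shallower times.  More simulations per evaluation shrink
  the effect; the production regime (6e5 per evaluation, 1e7 for final
  likelihoods) makes it small, and the recovery targets' acceptance
  bands absorb what remains at reduced settings.
* Monte-Carlo expected spectra make no use of analytic SFS results; for
  single-population constant-size models the analytic spectrum exists and
  is used in the tests as an oracle, not as an implementation shortcut.
* qpAdm weight estimates inherit the usual caveats: attenuation from
  noisy source frequencies at small sample sizes, and sensitivity to
  outgroup choice; the fixture's scaffold makes the default outgroups
  informative by construction.
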