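---
title: "The sdturnover model: assumptions, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sdturnover model: assumptions, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdturnover)
```

## The model and its assumptions

`sdturnover` tracks a two-sex, infinite, randomly mating population with
discrete non-overlapping generations. The state is not a genotype table
but a pair of haplotype ("gamete") frequency vectors: the egg pool
(maternally transmitted copies of the next generation) and the sperm pool
(paternally transmitted copies). This parent-of-origin bookkeeping is
essential: the ancestral system has the Y confined to paternal copies of
males, and turnover is diagnosed on origin-specific frequencies.

The genome has seven biallelic loci on four independently assorting
linkage groups. Three groups (XY, I^A, II^W) pair a sex-determination
locus with a sexually antagonistic locus at a within-group recombination
fraction; the fourth carries the single epistasis partner locus EPI. The
gamete space is therefore the 2^7 = 128 binary vectors, encoded as
integers 0–127 with a fixed bit order (XY.SD, XY.SA, IA.SD, IA.SA,
IIW.SD, IIW.SA, EPI; least-significant bit first) so that indices in
trajectory and sweep files are stable across runs and machines.

One generation applies, in order:

1. **Random mating**: zygote frequencies are the outer product of the
   egg and sperm pools.
2. **Sex assignment**: a dominant W makes a female; otherwise Y or A
   makes a male; otherwise female. W/W is representable but never arises
   in valid dynamics, because W carriers are female and the sperm pool
   purges any W in one generation.
3. **Viability selection within each sex**: zygotes are weighted by the
   product of per-SA-locus factors (1, `1 + h*s`, `1 + s` for 0/1/2
   focal copies, sex-specific `h` and `s`), males additionally by
   `1 + sigma * epsilon`. The binary `sigma` encodes the epistasis type
   (dominance, overdominance, coadaptation) read off the copy numbers at
   EPI and its partner SA locus. Epistasis is strictly male-limited; no
   female hook exists.
4. **Gametogenesis**: within each two-locus group, parental haplotypes
   receive mass `(1-r)/2` and recombinants `r/2`; the EPI locus
   segregates 1/2–1/2; groups multiply independently. The new egg pool is
   the fitness-weighted mixture over females, the new sperm pool the same
   over males, each renormalised to sum 1 — so each sex contributes half
   of the gene pool regardless of the post-selection sex ratio. The
   recursion nowhere samples: identical inputs give bitwise identical
   trajectories.

## Parameters that matter

* `s_Y`, `s_new` — homozygous SA effect magnitudes of the locus linked to
  the ancestral (SA^Y) and novel (SA^A or SA^W) SD locus, with
  `sM = -sF` enforced. Sweeps sample both uniformly on (0, 0.05):
  weak-to-moderate antagonism, the regime where linked SA selection can
  tip turnovers either way.
* `epsilon` — male-fitness benefit of an epistatic match, same (0, 0.05)
  range.
* `hM = 0.6, hF = 0.4` — the focal SA allele is partially dominant in the
  sex it benefits (mirrored for the female-beneficial SA^W). This
  beneficial-dominance asymmetry creates the net advantage that maintains
  SA polymorphism at intermediate frequency.
* `r_XY = r_A = r_W = 0.01` — tight SD–SA linkage, required for the
  linked-SA turnover mechanism to act; all three are configurable, and
  0.01 is a deliberate default choice of this implementation rather than
  a published value.
* Initial frequencies — active SA and EPI focal alleles start at 0.25 in
  both pools at linkage equilibrium; the ancestral zygotes are 50% Y/+
  males (Y paternal) and 50% +/+ females. The inert SA locus of the
  non-participating linkage group starts absent with `s = 0`, so no
  unreported selection is injected.
* Run lengths — the reference profile (`profile = "full"`) is a
  10,000-generation burn-in
  (letting SA/EPI frequencies relax to an approximate equilibrium, not an
  analytically solved one) within a 200,000-generation horizon, with the
  novel SD allele introduced at 1e-4 after burn-in. The `desk` profile
  (2,000 / 20,000) is the reduced problem size used by the examples, the
  test suite and the acceptance script; it resolves the same outcome
  boundaries at the sampled effect sizes, and spot checks against the
  full profile agree.

## Outcome classification

A run is classified by the frequency of the novel SD allele on the
parent-of-origin copies through which it functions: A among the
paternally inherited copies of males (Y→A), W among the maternally
inherited copies of females (Y→W). With this within-sex read, complete
turnover gives exactly 1 (a pool-wide read would plateau at 0.5 for W);
both read modes are exposed via `outcome_read` because the alternative is
defensible, but the within-sex read is the default for precisely this
reason. The rounded read (`>= 0.5`, ties counted as turnover — an
arbitrary, documented choice never observed to bind) is the outcome bit.
Classification happens at the simulator level rather than by rounding
inside a downstream model fit; the two are equivalent and this avoids
fitting pathologies when final frequencies sit at 1e-300.

## Numerical policy

Pools are renormalised every generation; entries within 1e-15 below zero
are clipped to 0; no other smoothing is applied. The per-generation
mass-conservation drift is monitored and stays at rounding level. The
engine restricts all tables to the *segregating support*: the product set
of alleles that can ever be present in a scenario (32 of the 128 gamete
types in a standard transition). A product set is closed under
segregation and recombination, so the restriction is exact — verified in
the tests against the dense 128-type computation — and makes the
recursion roughly 16x cheaper. The generation loop itself is compiled
(Rcpp); everything else, including all table construction, is R. An
optional early-termination rule (L-infinity change below 1e-13 for 100
consecutive generations) exists but is disabled by default to mirror the
fixed-horizon design.

Deterministic sanity properties are enforced in the test suite: exact
neutrality conservation from product-form initial states, a zygote sex
ratio of exactly 1/2 in the ancestral system, absence of Y from the egg
pool, and two closed-form linkage-disequilibrium laws. On the latter: the
classic within-group decay `D(t+1) = (1-r) D(t)` presumes a locus pair
transmitted identically through both sexes, which in this model is only
realised when sex determination is decoupled from the group — the test
fixes A and lets the maternally segregating W drive sex, making the XY
pair effectively autosomal. For a group whose own SD allele segregates,
sex-linked transmission makes the decay law inapplicable, and with the SD
allele absent it is trivial; the general engine behaviour is instead
pinned by brute-force one-generation enumeration oracles, with selection.

## Sweeps and reproducibility

A sweep cell fixes (transition, epistasis type, partner) and samples
`s_Y`, `s_new`, `epsilon` independently and uniformly per replicate. Each
replicate's RNG seed is derived from the master seed by a fixed affine
counter scheme modulo the Mersenne prime 2^31 - 1, so any replicate can
be reproduced in isolation and the table is independent of execution
order. Replicate failures are recorded per-row and do not abort the
sweep. Uniform draws are rejection-sampled onto the open interval, and a
degenerate range pins the coefficient (used for the `epsilon = 0`
validation set, where all three epistasis types must — and do — produce
identical dynamics).

## Boundary estimation

The scientific object is the location of the 0.5-probability contour of
turnover in the (`s_Y`, `s_new`) plane per epsilon slice, not any
particular smoother basis. The default estimator is local-linear kernel
regression of the binary outcome with a Gaussian product kernel
(bandwidth 1.5x Scott's rule per dimension, floored at one grid cell);
local-linear fitting removes the boundary bias of plain kernel averaging,
and with a fixed bandwidth the fit is invariant to duplicating records.
A penalized-spline logistic alternative (`method = "gam"`) is provided
for cross-checking. Contour vertices within one bandwidth of the
evaluation-range edge are flagged `edge = TRUE`: there the smoother
extrapolates from one-sided data and the boundary is not reliably
identified, so accuracy statements apply to the supported vertices. On
synthetic monotone step-rule labels with 5% label noise at 1,000 samples,
the supported contour stays within two cells of a 51-point grid of the
true threshold. When epsilon is sampled continuously rather than run at
a few discrete levels, the kernel smoother treats epsilon as a third
kernel dimension and evaluates the surface at the requested slices.

## What the stochastic oracle does and does not show

The test suite contains an independent individual-based Wright–Fisher
simulator (multinomial resampling of zygotes and of both gamete pools at
N = 100,000) built from its own reference implementations of the sex,
fitness and segregation rules. Its trajectories track the deterministic
recursion within a three-standard-error random-walk envelope that
accumulates the per-generation binomial sampling variance
`2 p (1 - p) / N` along the deterministic path. Passing this check shows
the recursion is the correct infinite-population limit of the stated
rules; it does not show that drift, mutation, non-random mating, selfing
or demographic structure — all absent from the model — are negligible in
any real population. Similarly, the synthetic step-rule labels used to
validate the boundary estimator emulate a monotone invasion boundary with
classification noise, not the curvature or class imbalance a particular
empirical sweep may produce.

## Known limitations

* The model is deterministic; establishment probabilities of a rare novel
  SD allele (a fundamentally stochastic quantity at frequency 1e-4) are
  outside its scope.
* Only the four canonical transition scenarios are supported: Y→A and
  Y→W with the epistasis partner on the ancestral or the novel pair. No
  W→Y reversals, no simultaneous invasion of A and W, at most two alleles
  per locus, one EPI locus.
* Coadaptation epistasis treats Y-linked loci as diploid; a hemizygous
  variant could behave differently and is not implemented.
* Desk-scale boundary maps are coarse (tens of grid runs); the full
  1,000-replicate-per-cell design is a matter of compute budget, not of
  code paths.
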