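---
title: "Methods: demography, reproductive values and the eusociality threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demography, reproductive values and the eusociality threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eusocia)
```

# The model

`eusocia` models a partially bivoltine insect population: overwintered
foundresses produce a spring brood; survivors (probability `S_f`)
produce a second, summer brood whose output grows linearly with the
number of helper daughters recruited from the spring brood.  Two life
cycles are implemented:

* **FH (female hibernation)** — only mated females overwinter.  Seven
  classes: (1) foundresses, (2) their stored sperm, (3) non-helping
  spring daughters, (4) helper daughters, (5) surviving foundresses,
  (6) their sperm, (7) spring males.  Spring males mate with spring
  daughters and, surviving with probability `S_m`, compete again in the
  autumn mating pool.
* **LD (larval diapause)** — both sexes overwinter.  Eight classes;
  summer males are split into surviving overwintered males and
  spring-born sons, because the two have different mating prospects.

Three female traits evolve: the brood sex ratios `z1` (spring) and `z2`
(summer), and the helping tendency `h` of spring daughters.  All are
probabilities.

## Demography

`stable_classes()` builds the two seasonal transition matrices and the
annual block matrix `D`, scaling winter survival by `alpha` so that the
dominant eigenvalue is exactly 1 (each spring female is replaced by one
spring female a year later).  The stable class distribution `u`
(normalised to `u1 = 1`) has a closed form from forward cohort
bookkeeping; with `check = TRUE` it is verified against the dominant
eigenvector of `D` to a relative 1e-8 and `|lambda - 1| < 1e-10`.
Sperm classes receive no reproduction credit in `D` (offspring are
counted through mothers only, to avoid double counting).

Mean mates per male are head-count ratios: `Q1` for the autumn (FH) or
spring (LD) pool and `Q2` for the summer pool.  The **male generation
overlap** is defined operationally as the paternity share of the
earlier male brood in the later mating pool,

$$O_m^{FH} = \frac{S_m u_7}{S_m u_7 + z_2 F_A}, \qquad
  O_m^{LD} = \frac{S_m u_2}{S_m u_2 + F_1 z_1 u_1},$$

with `F_A` the total autumn offspring per spring female.  `O_m` is 0
when earlier-brood males never survive (`S_m = 0`) or are never
produced, and tends to 1 when they monopolise the later pool.  We use
the same demographic definition for both ploidies.  For LD, `O_f` is
the analogous maternity share of surviving spring females in the summer
brood; for FH both broods share one autumn pool and `O_f = 0`.

## Helper effect

A surviving foundress with `n = h (1 - z_1) F_1` expected helpers has
summer fecundity `F5 = F_1 (1 + b n)`: each helper adds `b F_1`
offspring.  At the moment a daughter decides to stay, her expected
contribution per maternal baseline offspring is conditional on her
mother surviving, `B = S_f b`.  All thresholds are reported on the `B`
scale, which makes them invariant to the choice of the fecundity
baseline (`F_1`) in `F5`.

## Gene flow, reproductive values and relatedness

`gene_flow_matrix()` re-routes every demographic inflow to the classes
whose genes it carries: survivors credit themselves 100%; under
haplodiploidy a mother gets 100% credit for sons while mother and
father get 50% each for daughters; under diploidy both parents get 50%
for offspring of either sex.  Male and sperm columns carry the mean
mates per male, so each class's parental credits sum exactly to its
inflow (`A u = u`; asserted in the tests).  Class reproductive values
`v` are the dominant left eigenvector of `A`, normalised so a
summer-born daughter has value 1 (`v_f2 = 1`).  Brood-level values
follow: e.g. for FH a summer-born son is worth `Q1 * alpha * v2` (his
expected matings, times winter survival of the inseminated female,
times the value of stored sperm).

Relatedness coefficients use the matching gene-contribution
("life-for-life") scale: a coefficient is the share of the recipient's
genome contributed by or identical to the focal female's, so
coefficients toward haploid recipients are twice the diploid-normalised
regression values.  Haplodiploid: daughter 1/2, son 1, sister
`1/4 + p/2`, brother 1/2; diploid: daughter = son = 1/2, sister =
brother = `(1 + p)/4 * 2`, i.e. 1/2 for full siblings.  Here `p` is the
probability that the siblings a helper rears share her father: 1 under
lifetime monogamy, `1/m_e` under polyandry with lifetime sperm storage,
0 under serial monogamy (the two broods have different fathers).  This
convention is pinned down jointly by two requirements — maternal
sex-ratio control must give unbiased equilibria whenever male
generations do not overlap, for both ploidies, and the threshold limits
below must come out at their known values — and it is the convention
under which the familiar no-overlap ratios `v_m2/v_f2 = 1/2`
(haplodiploid) and 1 (diploid) appear at even sex ratios.

## Selection and equilibria

Mutant inclusive fitness is the relatedness- and reproductive-value-
weighted offspring account of a focal female carrying the mutant trait
in a resident population, with all resident-dependent quantities (mate
counts, class frequencies, reproductive values) held at their resident
values.  `selection_gradient()` differentiates it by central finite
differences (step 1e-6, one-sided at trait boundaries); because the
fitness expressions are linear in each mutant trait the finite
difference is exact up to floating-point noise, and internal closed
forms are kept as a cross-check.  The summer sex ratio is expressed by
two classes (class-3 breeders and class-5 foundresses); their gradients
are combined with plain normalised class-frequency weights.  Whether
those weights should also carry reproductive-value factors is not
decidable from the weighting rule alone; we use plain frequencies and
note that the equilibrium position is invariant to the choice, because
both class gradients share the sign factor
`r_son v_m2 - r_dau v_f2`.

`sex_ratio_equilibrium()` solves both gradients to zero by nested
bracketing (`uniroot`, tolerance 1e-10), returning boundary values 0/1
when a gradient points outward across the whole interior.
`eusociality_threshold()` bisects `B` over `[1e-3, 10]` (tolerance
1e-6) on the sign of the helping gradient at `h = 0`, with sex ratios
at their helper-free equilibrium (`fixed_sex_ratios`) or re-equilibrated
at an incipient helping level `h = 1e-4` for every candidate `B`
(`coevolved_sex_ratios`), which captures the first-order feedback of
helping on sex-ratio selection.

Two useful closed forms emerge from the machinery and anchor the test
suite: for haplodiploid FH populations the fixed-ratio threshold equals
`2 m_e / (m_e + 2 (1 - z2*))`, which is 1 at no overlap (`z2* = 1/2`),
`2/3` at full overlap (`z2* -> 0`, monogamy) and 2 under extreme
polyandry; for diploids it is `2 m_e / (m_e + 1)` independently of male
survival (1, 4/3, 3/2, -> 2 for `m_e` = 1, 2, 3, infinity).  Serial
monogamy halves both sibling coefficients relative to the offspring
coefficients and therefore gives exactly 2 for any demography.

Because the threshold is naturally a function of the overlap, the
`om` argument substitutes a prescribed paternity share for the
demographically computed one throughout the mate-count and gene-flow
bookkeeping.  This is a continuous-limit evaluation device: overlap
values arbitrarily close to 1 are not reachable by any finite parameter
combination at equilibrium sex ratios, but the limit of the threshold
as `O_m -> 1` is well defined and equals the value cited above.

## Boundary traits

Class frequencies at trait boundaries can vanish (no spring males at
`z1 = 0`; no independent-breeding daughters at `h = 1`), making mate
counts 0/0.  All selection-side computations therefore clamp resident
traits inward by 1e-9 and evaluate boundary classes as limits from
strictly positive frequency, so gradients — and hence equilibria pinned
at boundaries — remain defined.  The exported demographic functions
honour exact inputs (a helper-free population really has a zero helper
class) and flag truly unmated states.

## Adaptive dynamics

`integrate_coevolution()` integrates `dx/dt = K dW/dx` with deSolve
(`lsoda`, `rtol = atol = 1e-8`), recomputing the resident state at
every evaluation.  Boundary handling is a projected gradient made
continuous: an outward gradient is ramped to zero across a 1e-6
boundary layer, so pinned traits stay pinned (a trait leaves the
boundary only when its gradient points inward) without introducing
discontinuities that defeat the step control.  The helping gradient is
masked until `h_release_time`, mirroring the simulator's delayed
helping-locus mutation.  The rate constant defaults to `K = 3e-4`:
time units are arbitrary in the rate law, and this value makes the
sex-ratio equilibration phase span a few thousand time units, so
deterministic trajectories are commensurate with individual-based runs
on a shared axis — the same criterion the adaptive-dynamics literature
uses to set `K`.  Halving the tolerances changes the endpoints of a
full coevolutionary run by less than 1e-6 per trait (tested).

## The individual-based simulator

`run_simulation()` is the stochastic counterpart: `N` nests per spring,
three loci with continuous allelic values in `[0, 1]` expressed in
codominance, haploid males under haplodiploidy, mutation with
probability `mu = 0.01` per allele per transmission and normal step
s.d. `sigma = 0.01`, clipped to `[0, 1]`.  Defaults are the study
conditions: `N = 5000`, 25,000 years, helping-locus mutation from year
10,000.  Choices on which the analytic model is silent, each taken as
the minimal standard assumption:

* offspring numbers are Poisson with the deterministic fecundity as
  mean (the analytic model constrains only means);
* each female samples mates uniformly with replacement from the current
  male pool; males mate without limit (matching the head-count `Q`
  bookkeeping).  Polyandrous females take `ceiling(m_e)` distinct
  males with equal shares (one share adjusted so the squared shares sum
  to `1/m_e`); serially monogamous foundresses take a fresh single mate
  for the summer brood;
* females facing an empty mate pool stay unmated and do not reproduce
  (the analytic model has no unmated-reproduction pathway);
* winter density dependence samples exactly `N` mated females uniformly
  without replacement (all survive if fewer exist); in the LD cycle
  overwintering sons are thinned by the same survival fraction (a
  common winter scale for both sexes).

The simulator emulates the analytic model's demography and genetics,
not field data: generations are discrete and seasonal, there is no
spatial or nest-level environmental variation, no inbreeding, no
queen–worker conflict, and fitness effects of helping are strictly
linear.  Agreement between simulator and analytic predictions therefore
validates the inclusive-fitness calculation, not the model's realism.

A practical property of the simulator worth knowing: the speed of the
selection response scales with the mutational variance input, roughly
`N * mu * sigma^2` per year.  At the default `N = 5000` the full
coevolutionary transition completes within a few thousand years after
helping is released; at `N = 500` the same transition takes on the
order of ten thousand years.  Scaled-down runs must therefore scale the
horizon up, not down, if they are expected to reach the evolutionary
endpoint.

## Numerical choices and test problem sizes

Eigenproblems use base `eigen()` on the 7x7/8x8 matrices, selecting the
eigenvalue nearest 1 (the annual map has a paired eigenvalue at -1 from
the two-season structure); an imaginary part above 1e-12 is an error.
The tests verify: `lambda = 1` to 1e-10 and closed-form vs eigenvector
class frequencies to 1e-8 across 100 random configurations per suite;
reproductive values against an independent allele-descent oracle
(expected gene-pool shares of a marked cohort propagated season by
season for 10^4 years) to within 2% for all four life-cycle x ploidy
combinations; simulated sex-ratio means against analytic equilibria
within 0.03 using 800-nest, 7,000-year helper-free runs; and the full
deterministic transition at the trajectory-figure parameters.  These
problem sizes are the package's own choices for routine testing;
larger runs only tighten the stochastic comparisons.

## Known limitations

Thresholds require `S_f > 0` (with no maternal survival there is no
brood to help) and serial monogamy is defined only for the FH cycle.
The model has no worker reproduction, no conflict over the summer sex
ratio, no inbreeding correction to relatedness, and no perennial
colonies; the overlap measure `O_m` is demographic, so closed-form
threshold curves parameterised directly by `O_m` should be read through
the `om` evaluation device described above.
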