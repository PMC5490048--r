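# eusocia

Inclusive-fitness demography of the evolutionary transition to
eusociality in partially bivoltine insects.

## The scientific problem

Many solitary bees and wasps are *partially bivoltine*: an overwintered
foundress produces a spring brood, and — if she survives — a summer
brood, with two mating episodes per season.  Several traits of the
Hymenoptera have been proposed as preadaptations that make the leap to
eusociality (a sterile worker caste) more likely: haplodiploid genetics,
maternal control of brood sex ratios, lifetime monogamy, and life cycles
in which male generations overlap.  `eusocia` implements a unified
class-structured model in which all of these can be switched on and off,
and asks: how efficient must a daughter be at rearing her siblings
(relative to rearing her own offspring) before natural selection favours
her staying at the nest?

Three female traits coevolve:

* `z1` — proportion of sons in the spring brood,
* `z2` — proportion of sons in the summer brood,
* `h`  — probability that a spring daughter stays as a helper.

Each helper raises her mother's summer output linearly; on the scale
used throughout, a helper adds `B = S_f * b` sibling equivalents per
maternal offspring, conditional on the mother surviving (probability
`S_f`).  The **eusociality threshold** `B_min` is the smallest `B` at
which the selection gradient on helping turns positive.

## The model

The annual cycle is a matrix population model over 7 (female
hibernation, FH) or 8 (larval diapause, LD) classes, with winter
survival scaled by a factor `alpha` so the annual matrix `D` has
dominant eigenvalue 1.  A gene-flow matrix `A` with the same block
structure assigns each newborn or survivor to the classes whose genes it
carries (haplodiploid: mothers get 100% credit for sons, each parent 50%
for daughters; diploid: 50%/50% for both sexes).  The dominant left
eigenvector of `A` gives class reproductive values `v`; the dominant
right eigenvector of `D` gives stable class frequencies `u`.  Selection
gradients are reproductive-value-weighted derivatives of mutant
inclusive fitness,

    dW/dx at x = x*,   x in {z1, z2, h},

and trait dynamics follow the adaptive-dynamics rate law `dx/dt = K
dW/dx`.  A key demographic summary is the male generation overlap `O_m`
— the paternity share that the earlier male brood captures in the later
mating pool.  A matching stochastic individual-based simulator (three
continuous-allele loci, codominant expression, mutation, random mating,
density-dependent overwintering) provides an independent check of the
analytic predictions.

## Worked example

Threshold analysis for a haplodiploid, female-hibernation, lifetime
monogamous population with `F1 = F3 = 2`, `S_f = 0.9`, `S_m = 0.6`:

```r
library(eusocia)
cfg <- model_config("FH", "haplodiploid", "monogamy",
                    F1 = 2, F3 = 2, S_f = 0.9, S_m = 0.6, b = 1.5)

sex_ratio_equilibrium(cfg, h_fixed = 0)[c("z1", "z2")]
#> $z1
#> [1] 0.7799558
#> $z2
#> [1] 0.2910915

th <- eusociality_threshold(cfg)
th$B_min
#> [1] 0.8271924
th$O_m
#> [1] 0.5453844
```

Before helping evolves, selection drives the spring brood male-biased
(`z1* = 0.78`) and the summer brood female-biased (`z2* = 0.29`),
because spring males can also sire the summer brood (`O_m = 0.55` at
those ratios).  A helper then rears mostly sisters (relatedness 3/4)
whose reproductive value exceeds that of her own mixed-sex offspring, so
helping pays already at `B_min = 0.83 < 1` — helpers need *less* than
full nursing efficiency.  Setting `S_m = 0` (no male overlap) moves the
threshold to exactly 1; diploid genetics give 1 regardless of `S_m`;
serial monogamy gives 2; extreme polyandry gives 2.

The full coevolutionary run at the reference coevolution parameters
(`F1 = F3 = 5`, `b = 1.5`) reproduces the evolutionary transition:

```r
cfg5 <- model_config("FH", "haplodiploid", "monogamy",
                     F1 = 5, F3 = 5, S_f = 0.9, S_m = 0.6, b = 1.5)
traj <- integrate_coevolution(cfg5, trait_state(0.5, 0.5, 0))
detect_equilibrium(traj)
#> <trait_state> z1 = 0, z2 = 0.5, h = 1
```

All spring offspring become unmated female workers (`z1 = 0`, `h = 1`),
the summer brood returns to an even sex ratio, and the life cycle has
become effectively univoltine with a worker brood before a reproductive
brood.

A command-line interface wraps these functions; see
`inst/cli/eusocia.R` (`eusocia threshold --config scenario.yaml`,
`eusocia sweep ...`, `eusocia simulate ...`).

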