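# litterkin

Genetic mating-system analysis for shark litters — microsatellite parentage
from mother–embryo genotypes.

## The problem

In viviparous elasmobranchs, mating is almost never observed: the genetic
route to the mating system is to genotype pregnant females and their litters
at polymorphic microsatellite loci. Because the mother's genotype is known,
her contribution can be subtracted from each embryo, leaving the paternally
derived alleles. A single father contributes at most two alleles per locus
per litter, so **three or more paternal alleles at any locus demonstrate
multiple paternity (polyandry)**. `litterkin` implements that whole analysis
chain for a two-species study design (two closely related smooth-hound
sharks whose morphological identification is unreliable, telling them apart
with a panel of diagnostic loci first), plus the simulation machinery needed
to validate every stage without access to raw genotypes.

Its stages:

1. **Species / hybrid diagnosis** from a 6-locus diagnostic panel (two loci
   fixed between species, three non-overlapping, one partially overlapping).
   F1 hybrids are heterozygous for one allele of each species at the fixed
   loci.
2. **Population-genetic summaries** per locus on reference adults:
   number of alleles Na, observed heterozygosity Ho, Nei's unbiased expected
   heterozygosity He = (2n/(2n−1))(1 − Σᵢ pᵢ²), Monte-Carlo exact
   Hardy–Weinberg tests (conditional on allele counts) and genotypic
   linkage-disequilibrium permutation tests (G statistic), with Bonferroni
   flags.
3. **Minimum-sire reconstruction** per litter by exhaustive Mendelian
   search: the smallest number k of father genotypes that explains all
   embryos at all loci, with all (fathers, assignment) solutions enumerated
   and ranked by HWE-prior × transmission likelihood — GERUD-style, with a
   known mother.
4. **Mendelian segregation checks** for monandrous litters (per-locus 1:1
   χ² combined by Fisher's method, −2Σln pᵢ ~ χ²₂ₘ) and **exact
   binomial/multinomial skew tests** for polyandrous ones.
5. **Detection power (PrDM)**: Monte-Carlo probability that a litter of a
   given size, under a given sire-number/skew scenario and locus panel,
   would reveal polyandry at all — the same ≥3-paternal-allele criterion the
   empirical pipeline uses.
6. **Bayesian multiple-mating frequency (FMM)**: with per-litter detection
   power dᵢ, the likelihood of the observed detection pattern is
   `∏ detected f·dᵢ × ∏ undetected (1 − f·dᵢ)`; a grid posterior over
   f ∈ [0,1] (uniform prior by default) gives the most likely population
   frequency of multiple mating and a central 95% interval.
7. **Fecundity ANCOVA** (litter size ~ female length + mating system,
   Type-II F tests) and species-level summaries (polyandry %, mean/max
   sires, top-sire share of assigned embryos).

## Worked example

```r
library(litterkin)

cfg <- sim_config(seed = 7, n_litters = c(A = 10, B = 8), f = 0.5)
st  <- simulate_study(cfg)              # two-species study, truth sidecar
rep <- run_pipeline(st$table, seed = 42, power_reps = 2000)
rep
#> study report: 581 individuals
#> calls: A=244, B=337
#> species A: 10 litters, 5 polyandrous (50%), fmm mode 0.53
#> species B: 8 litters, 4 polyandrous (50%), fmm mode 0.55
```

The study was simulated with a true multiple-mating frequency of 0.5; the
pipeline flags 5/10 and 4/8 litters and the power-corrected posterior modes
(0.53, 0.55) sit next to the direct counts. Per-litter detail:

```r
rep$litters$A$report[, c("mother_id", "n_embryos", "polyandrous", "k", "skew", "p_skew")]
#>    mother_id n_embryos polyandrous k skew    p_skew
#> 1       Am01        12       FALSE 1   12        NA
#> 4       Am04        15        TRUE 2  9:6 0.6072388
#> 5       Am05        11        TRUE 2  8:3 0.2265625
#> ...
```

`k` is the reconstructed minimum number of sires, `skew` the embryo split
among them in the most likely solution (assigned embryos only), `p_skew`
the exact test against equal paternal contributions. The power table for
the same panel (percent detection across litter sizes):

```r
round(rep$power$A)
#>                           6  10  13  17
#> 2 males (50:50)          92  98  99 100
#> 2 males (66.7:33.3)      85  96  98  99
#> 3 males (33.3:33.3:33.3) 97 100 100 100
#> 3 males (57:28.5:14.5)   93  99 100 100
```

A published 32-litter reference summary ships with the package
(`reference_study()`); `summarize_species()` on it reproduces the headline
numbers (47% / 54% polyandry, mean 2.1 / 2.0 sires, top sire fathering
~70% of assigned embryos in skewed litters).

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("scripts","litterkin.R",package="litterkin"))') \
    simulate --config cfg.json --out-dir sim/
# ... pipeline --genotypes sim/genotypes.tsv --seed 4 --out-dir run/
```

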