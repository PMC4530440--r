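---
title: "Methods: microsatellite parentage analysis for shark litters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsatellite parentage analysis for shark litters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litterkin)
```

This vignette documents the models, conventions and numerical choices behind
`litterkin`, in the spirit of a methods section: what is assumed, which knobs
matter, what the synthetic-data generator does and does not emulate, and
where the design was genuinely open.

## Data model

A study is a rectangular genotype table: individuals (mothers, embryos,
reference adults) × paired integer allele columns per microsatellite locus,
in binned base-pair units. Alleles are assumed **pre-binned**; fragment-size
binning is upstream of this package. `0` encodes a missing allele and any
half-missing pair is treated as wholly missing; missing genotypes are
skipped, never imputed. Loci that do not amplify in one species are simply
missing for all its members and drop out of that species' computations —
they are not treated as null alleles.

## Species diagnosis

Each diagnostic locus votes `A`, `B`, `mixed`, or is uninformative. A locus
with between-species allelic overlap votes only through its species-specific
alleles: any overlap allele in a genotype silences the locus, so a genotype
like 224/229 at the overlapping locus never votes, while 229/229 (the allele
private to species A) does. Alleles unseen in the panel also silence a locus
— within-species variation unknown to the panel must not produce confident
calls.

An individual is called pure when all informative votes agree. The **hybrid
call deliberately requires mixed genotypes at both fixed loci** and no pure
vote at any fixed/non-overlapping locus. Fixed loci are the only ones immune
to rare-allele surprises (one low-variation diagnostic locus in the
motivating data revealed a new rare allele when the sample grew), so this
rule minimizes false hybrid calls at the cost of calling partially genotyped
F1s `ambiguous`. An individual whose only genotyped diagnostic locus is the
overlapping one is `ambiguous`. An external species hint (standing in for an
mtDNA assay, which in an F1 reflects only the maternal species) is never
allowed to override the nuclear call; conflicts are reported.

## Population-genetic summaries

Per locus: Na, Ho, and Nei's unbiased expected heterozygosity
$H_e = \frac{2n}{2n-1}\left(1 - \sum_i p_i^2\right)$. The Hardy–Weinberg
test is a **Monte-Carlo exact test**: the statistic is the conditional
probability of the genotype table given the allele counts (Levene), the null
is sampled by re-pairing the observed allele multiset, and the p-value uses
the add-one convention $(1 + \#\{P^* \le P_{obs}\})/(R+1)$. The linkage test
permutes one locus' genotypes across individuals and uses the G statistic on
the two-locus genotype table — genotypic level, because gametic phase is
unknown. A cited workflow would use a Markov-chain method with
dememorization/batch parameters; a plain Monte-Carlo sampler targets the
identical null distribution with a simpler convergence story, so that is
what ships (default 10,000 replicates, explicit seed).

## Paternal-allele deduction

With mother $m_1/m_2$ known, each embryo–locus falls into one of four cases:
exactly one embryo allele can be maternal (the other is a **determined
paternal allele**); the embryo is homozygous for a maternal allele (paternal
allele determined, possibly equal to a maternal allele); the embryo equals a
heterozygous mother (paternal allele **ambiguous** between $m_1, m_2$); or
no embryo allele can be maternal (incompatible; two or more such loci flag
the embryo `maternal_mismatch` and exclude it, one is treated as a local
dropout). Because all embryos share one mother, every ambiguous candidate
set *is* the mother's pair — the minimum paternal-allele count is therefore
exactly the number of distinct determined alleles, plus one if ambiguity
exists and no determined allele is maternal. **Polyandry is flagged at ≥ 3
minimally-resolved paternal alleles at ≥ 1 locus** — the conservative
resolution prevents false polyandry from mother-sharing heterozygotes.

## Minimum-sire reconstruction

`min_sires()` finds the smallest $k$ (default cap 4; the motivating data
never needed more than 3) for which embryos can be partitioned among $k$
father genotypes Mendel-consistent at every locus. The search is a
depth-first enumeration of set partitions (fathers canonically numbered by
first use), most-constrained embryos first; a father is infeasible as soon
as its accumulated determined alleles at any locus exceed two, or leave no
room to cover an ambiguous member. Every embryo is treated as distinct, so
each labeled partition is enumerated exactly once — assignments that differ
only in which of two equally compatible fathers an ambiguous embryo joins
are distinct solutions, as in the field's standard reporting.

Father genotypes at each locus are restricted to the litter's paternal
candidate alleles; an unconstrained second allele is completed with the most
frequent population allele (a wildcard that maximizes the HWE prior without
affecting $k$). A solution's score is
$\prod_{\text{fathers},\ \ell} \Pr_{HWE}(g) \times \prod_{\text{embryos},\ \ell} \Pr(\text{transmission})$,
normalized over the full enumerated set; alleles absent from the reference
frequency table get the small-sample fallback $1/(2n+2)$. Ties are broken
deterministically (sort order of genotypes). Caps (`max_solutions`,
`expand_cap`, `max_nodes`) bound pathological litters and set a `truncated`
flag; the normalizing constant is exact whenever no cap fires. Embryos whose
assignment differs among equally-best solutions are reported **unassigned**
and excluded from the skew denominators — which is why a reported skew can
sum to fewer than the litter size.

Monandrous litters get a per-locus $\chi^2$ (1 df) test of paternal-allele
counts against 1:1 at loci where the reconstructed father is heterozygous,
combined by Fisher's method ($-2\sum\ln p_i$, $\chi^2_{2m}$). For skewed
paternity no canonical test is named in the motivating literature, so the
package uses an **exact two-sided binomial** (minimum-likelihood ordering)
for two sires and an **exact multinomial** against equal contributions for
three or more (full enumeration to $n = 30$, Monte Carlo beyond); test
identity is recorded in the result.

## Detection power and the mating-frequency posterior

`prdm()` draws parents from HWE at the panel frequencies, simulates embryos
under the scenario's sire count and skew, and asks whether the pipeline's
own polyandry flag would fire. Using the same ≥3-allele criterion for power
and for the empirical flags keeps the two mutually consistent; a
cross-locus single-father-exclusion criterion could add a few points of
power and is deliberately not used. Monte-Carlo error is reported as
$\sqrt{p(1-p)/R}$; a panel with no locus beyond two alleles has exactly
zero power and is warned about.

Per-litter power $d_i$ conditions on the observed mother genotype and
litter size, with the alternative fixed at two sires of equal success (the
modal observed pattern; configurable). The population multiple-mating
frequency $f$ then has likelihood $f d_i$ per detected and $1 - f d_i$ per
undetected litter; the posterior is evaluated on a grid (step 0.001) under
a uniform prior, making the mode the maximum-likelihood estimate, with a
**central** (equal-tailed, not HPD) 95% interval — the interval convention
of the original closed-source estimator is unspecified, so the simplest one
is used and named.

## Fecundity and summaries

The fecundity model is `litter_size ~ female_length + mating_system` with
Type-II (drop-one) F tests. Published F statistics for this model carry
internally inconsistent degrees-of-freedom subscripts, so no numeric
reproduction of those values is claimed — only the qualitative pattern
(size matters, mating system does not) is exercised, on data constructed to
have it. Species summaries report the polyandry fraction, mean and maximum
sire counts over polyandrous litters, and the top sire's share **of
assigned embryos** — with total-litter denominators the shipped reference
table does not reproduce its published ~69/70 ± 19/17% shares, with
assigned-embryo denominators it does (to 0.6 of a percentage point; the
published species-A mean appears to round per-litter shares first).

## Synthetic data: the stated world

`sim_config()` defaults encode the emulated study: reference samples of
136/117 adults; 19/13 litters; female total length uniform on 1210–1630 mm
(species A) and 1100–1410 mm (species B); litter size increasing linearly
with length across the species' observed ranges (3–18 and 9–35) with
Gaussian jitter (SD 2 embryos, a design choice) — so the fecundity ANCOVA
is exercisable; multiple-mating frequency 0.5 (between the two published
direct counts); polyandrous litters get 2 sires with probability 0.9 and 3
with 0.1 (15 of 16 published polyandrous litters had 2), equal expected
success by default. The polymorphic panels reproduce the published allele
counts and unbiased heterozygosities per locus exactly, through a geometric
allele-frequency profile $p_i \propto r^i$ solved to the implied gene
diversity; the full published frequency spectra are not public, so the
profile shape is a design choice and allele sizes are invented. Diagnostic
within-species frequencies use the published genotype lists with modest
made-up frequencies for the slightly variable loci.

Genotyping is error-free by default (re-genotyping in the motivating study
found no discrepancies); an optional per-allele mis-scoring rate exists for
robustness exercises. The generator does not model demography, mutation,
null alleles, sperm storage across seasons, or linkage — a green test
therefore establishes correctness of the inference machinery under the
stated world, not robustness to scoring artefacts.

With these defaults the simulated panels reproduce the published power-table
structure closely (e.g. ~46% detection for two equal sires at litter size 3
on the species-A panel, rising above 95% from nine embryos), which the
acceptance suite checks as ordering properties within Monte-Carlo error
rather than as cell values.

## Reproducibility and budgets

All randomness flows from explicit seeds; the pipeline splits one root seed
per stage and logs it. The acceptance suite scales simulations to desk
budgets: oracle equivalence on 220 exhaustively enumerated small litters,
soundness on 1,000 simulated litters with early-exit reconstruction,
power-structure checks at 10,000 replicates, and frequency recovery over
102 replicate studies of 100 litters with per-litter power at 300
replicates. The recovery bands (mode within ±0.10, ≥90% interval coverage)
are the stated world's own properties, not tuned values.

## Known limitations

- No candidate-father databases, sibship-only reconstruction, or
  mutation/null-allele-aware likelihoods.
- Backcross/F2 hybrid classes are out of scope; the diagnosis separates
  pure species from F1-like patterns only.
- Solution probabilities are relative to the enumerated solution set; when
  an enumeration cap fires the reported probabilities cover less than the
  full mass (flagged).
- The exact-test p-values are Monte-Carlo estimates with the add-one
  convention; they are conservative at small replicate counts.
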