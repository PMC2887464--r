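---
title: "Tetrasomic segregation analysis with double reduction and gametophytic selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tetrasomic segregation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetraseg)
```

## The problem

A recessive allele that kills the gametophyte never appears in
homozygous sporophytes, so its dominance and dosage cannot be read off a
diploid segregation ratio. Tetraploid genetics restores the signal: a
tetraploid parent produces *diploid* gametes, so a gametophytically
recessive allele is sheltered in heterozygous (`Aa`) gametes and only
fully mutant (`aa`) gametes die. The parent's allele dosage, the
allele's dominance mode in the gametophyte, and the rate of double
reduction then jointly determine three observable quantities: the
fraction of infertile ovules, the marker segregation ratio among
progeny, and the fraction of phenotypically abnormal female
gametophytes. `tetraseg` turns each candidate (dosage, mode) pair into
exact expected ratios and ranks the candidates by Pearson χ² against the
observed counts.

## Gamete-class frequencies

For a tetraploid parent with mutant dosage $d$ and double-reduction
coefficient $\alpha$, the package uses the closed form

$$
f(aa) = \alpha\frac{d}{4} + (1-\alpha)\frac{\binom{d}{2}}{6},\qquad
f(Aa) = (1-\alpha)\frac{d(4-d)}{6},\qquad
f(AA) = \alpha\frac{4-d}{4} + (1-\alpha)\frac{\binom{4-d}{2}}{6}.
$$

The two terms are the two meiotic routes. With probability $\alpha$ the
gamete receives both sister-chromatid copies of one randomly chosen
parental chromosome — double reduction, possible when quadrivalents form
and the locus recombines away from its centromere — so the gamete is
homozygous for that chromosome's allele. Otherwise two distinct
chromosomes are sampled, the classical chromosomal-segregation
hypergeometric. The source analysis this package reconstructs never
printed this formula, only its numerical consequences; the decomposition
above was adopted because it reproduces every printed seed-set and
progeny expectation exactly (see the tests), and it is validated against
two independent enumeration oracles:

```{r oracle}
all(gamete_frequencies(2, alpha = 0)$freq ==
      enumerate_gametes(2, "chromosomal")$freq)
all(gamete_frequencies(2, alpha = frac(1, 7))$freq ==
      enumerate_gametes(2, "random_chromatid")$freq)
```

The chromosomal oracle enumerates the $\binom{4}{2} = 6$ chromosome
pairs; the random-chromatid oracle enumerates all $\binom{8}{2} = 28$
chromatid pairs, among which the 4 sister pairs *are* the
double-reduction gametes, giving $\alpha = 4/28 = 1/7$. The default
$\alpha = 1/6$ is the theoretical maximum for a locus unlinked to its
centromere, appropriate here because the locus under study lies ~45 cM
from its centromere; $\alpha = 0$ is available for expectations computed
without double reduction. Values outside $[0, 1/6]$ are rejected, as are
ploidies other than 2 and 4.

## Exact arithmetic

All frequencies are carried as exact rationals (a small vctrs record
class, `frac()`), so distribution-sum and oracle-equivalence invariants
are asserted as equalities rather than tolerances, and expected counts
reach the χ² statistic unrounded. This matters numerically: testing the
observed 171:507 seed set against the rounded duplex-recessive
expectation 151:527 gives χ² ≈ 3.41, while the unrounded 150.67:527.33
gives the published 3.53. Floating point appears only in reported
columns (`prob`, `category_a`, statistics). Arbitrary doubles entering
model parameters (e.g. root-finding iterates in transmission-efficiency
estimation) are snapped to their nearest small rational by
continued-fraction expansion.

## Gametophytic selection

Selection is sex-specific and mode-dependent:

* **Female.** Affected gamete classes abort. The aborted fraction *is*
  the expected infertile-ovule fraction (pollen is treated as
  non-limiting, so seed set reflects female abortion only), and the
  surviving classes, renormalised, form the maternal side of progeny.
* **Male.** Pollen competes, so affected classes fertilise at a relative
  transmission efficiency (TE) rather than disappearing; the default
  weight 0.1 is the empirical estimate for the allele that motivated the
  package, measured from reciprocal-cross progeny ratios
  (`estimate_te()`) and from triplex:duplex recovery among selfed
  triplex progeny (`estimate_te_from_triplex_ratio()`).
* Under a **recessive** model the affected set is the fully mutant class
  only; under a **dominant** model it is every mutant-carrying class.

A progeny individual is marker-sensitive iff it inherits zero mutant
alleles from both sides, so the expected sensitive fraction is the
product of the two selected class-0 shares; the same number must (and
does, exactly) fall out of the full offspring-dosage convolution
`offspring_dosage_distribution()`, which also shows that no quadruplex
mutant offspring can arise under the recessive model — their maternal
gamete would have to be an aborting `aa`.

The male weight of the fully mutant class is genuinely uncertain in one
published row (a 208:0 progeny test whose printed χ² of 1.71 sits
between the 0.1-weight reconstruction, 1.55, and the full-abortion
reconstruction, 1.73), so `selection_model()` exposes per-class weights
(`male_weights = c(1, 1, 0)` models full pollen abortion); the package
asserts only non-rejection for that row and takes no position on which
reconstruction was intended.

## Assays and the candidate grid

```{r table}
fits <- fit_all_models(published_observed("tetraploid_a"))
segregation_report(fits)
```

Ranking is by the worse of the two statistics, ties by their sum; a
model is accepted when both fall below the df = 1 critical value at the
threshold (default p = 0.05, configurable). The duplex-recessive model
is the unique acceptable candidate here, and the χ² separation to the
alternatives is two to three orders of magnitude — which is why model
recovery from simulated data at these sample sizes is essentially
perfect.

One published cell is knowingly not reproduced: the simplex-recessive
progeny expectation was printed as 295:57, which no selection/TE
combination in this model family yields (the natural model gives
≈240:112). The report annotates that row as unresolved rather than
tuning parameters toward it. Relatedly, the published triplex
confirmation seed-set row prints 293:247 against an observed total of
541; the model's unrounded 293.04:247.96 rounds to 293:248, and its χ²
matches the published 1.89, so the discrepancy is a one-unit rounding
slip in the original table, not a model difference.

The female-gametophyte assay is scored in cleared ovules *before*
abortion removes the doomed gametophytes, so its expectation uses the
pre-selection frequency of the fully mutant class: 13/24 ≈ 54% of
female gametophytes of a triplex parent are expected to proliferate, and
a diploid heterozygote's haploid gametes give 50%.

```{r fg}
expected_fg_phenotypes(genetic_model(3, "recessive"), 162)
```

## The forward simulator

`simulate_selfing()` draws, per ovule, a female gamete class
(multinomial from the exact frequencies); aborting classes become
infertile ovules. Genotyped progeny pair a viable female gamete with a
TE-weighted male gamete; female-gametophyte scoring draws from the
pre-selection distribution. The generator's defaults are the published
experiment's sample sizes (678 ovules, 352 genotyped progeny, 162 scored
gametophytes), and a fixed seed reproduces output exactly (R's
Mersenne-Twister). What it emulates is the sampling noise of those
assays under the model's own assumptions; what it does not emulate —
post-fertilisation seed abortion, aneuploidy, unreduced-gamete triploid
formation, pollen limitation, scoring error — bounds what a passing
recovery test says about real data: it demonstrates statistical
separability of the candidates at these sample sizes, not robustness to
model misspecification.

`simulate_model_recovery()` wraps this into a parameter-recovery
harness. Five hundred replicates per truth run in under a second because
the replicate loop precomputes the exact expectations once and then
works in plain numeric arithmetic:

```{r recovery}
simulate_model_recovery(genetic_model(2, "recessive"),
                           n_replicates = 100, seed = 1)
```

## Numerical and design notes

* Display ratios round half-up; machine-readable columns keep full
  precision. χ² always consumes unrounded expectations; zero *observed*
  cells are allowed, zero *expected* cells are an error, and observed
  and expected totals must agree.
* No Yates continuity correction: the published statistics match the
  uncorrected Pearson form.
* `estimate_te_from_triplex_ratio()` inverts the offspring-dosage
  convolution by bisection on the male class-2 weight; the mapping is
  monotone, unattainable ratios clamp to the boundary with a warning,
  and at $\alpha = 1/6$ the closed-form inverse
  $w = 100r / (13(10 - r))$ is used as an independent oracle in the
  tests.
* Progeny totals are taken from the observed data, never re-derived from
  seed counts; the two assays are treated as independent samples.
* Problem sizes in the test suite (10^6-draw convergence checks, 500
  replicate recovery runs, 10^5-progeny TE round-trips) were chosen so
  the whole suite runs in well under a minute while keeping Monte-Carlo
  assertions at 3 standard errors.

## Limitations

Ploidy is limited to 2 and 4; α is a free scalar, not derived from
centromere distance; multi-category (>2) goodness of fit,
likelihood-based model selection, and linked-locus double reduction are
out of scope. The candidate grid assumes a single biallelic locus with
fully penetrant gametophytic action.
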