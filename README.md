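# tetraseg

Segregation analysis for selfed autotetraploids carrying a
gametophytically lethal allele.

When a mutant allele kills or handicaps the gametophyte (the haploid —
or, in a tetraploid, diploid — gamete-producing generation of plants),
progeny ratios and seed set are distorted away from Mendelian
expectations, and in an autotetraploid the distortion depends on three
things at once: the parent's mutant-allele dosage (simplex, duplex,
triplex...), the dominance mode of the allele in the gametophyte, and
double reduction, the polyploid-specific meiotic event that lets a
heterozygote produce homozygous gametes. `tetraseg` computes the exact
expected ratios for all of these model combinations and selects the
best-fitting model for observed counts by Pearson χ² goodness of fit. It
was built around the classic tetraploid genetic analysis of an
*Arabidopsis* *RETINOBLASTOMA RELATED* insertion allele, whose printed
segregation table it reproduces, and generalises to any two-category
tetrasomic segregation assay.

## The model

A tetraploid parent with `d` mutant alleles (0 ≤ d ≤ 4) produces diploid
gametes in three classes by mutant dosage: `AA`, `Aa`, `aa`. With double
reduction coefficient α (0 ≤ α ≤ 1/6, the maximum for a locus unlinked
to its centromere), the gamete-class frequencies are

    f(aa) = α·d/4 + (1−α)·C(d,2)/6
    f(Aa) = (1−α)·d(4−d)/6
    f(AA) = α·(4−d)/4 + (1−α)·C(4−d,2)/6

— a mixture of the double-reduction route (a random chromosome carried
twice, probability of `aa` = d/4) and classical chromosomal segregation
(two distinct chromosomes, hypergeometric). α = 0 is chromosomal
segregation, α = 1/7 random-chromatid segregation; both are verified
against exhaustive enumeration oracles with exact rational arithmetic.

Gametophytic selection is sex-specific. Affected female gametophyte
classes abort, which sterilises their ovules (the seed-set assay) and
removes them from the maternal side of progeny; affected pollen classes
transmit at a relative transmission efficiency TE (default 0.1) because
pollen is in excess. Under a recessive model only `aa` gametes are
affected; under a dominant model every mutant-carrying class is. From
these two selected pools the package derives expected infertile:developing
ovule ratios, resistant:sensitive progeny ratios (resistance marking
inheritance of at least one insertion allele), proliferating:normal
female-gametophyte phenotype ratios, and the full offspring dosage
distribution. All frequencies are exact fractions; χ² statistics are
computed on unrounded expected counts.

## Worked example

```r
library(tetraseg)

# gametes of a duplex (2 mutant alleles) parent at maximal double reduction
gamete_frequencies(2, alpha = frac(1, 6))
#> # A tibble: 3 × 4
#>   class label   freq   prob
#>   <int> <chr> <frac>  <dbl>
#> 1     0 AA       2/9  0.222
#> 2     1 Aa       5/9  0.556
#> 3     2 aa       2/9  0.222

# fit all six candidate models to the bundled observed counts:
# 171:507 infertile:developing ovules, 327:25 resistant:sensitive progeny
fits <- fit_all_models(published_observed("tetraploid_a"))
glance(fits)
#> # A tibble: 1 × 7
#>   best_model        chisq_seed chisq_progeny accepted n_candidates n_accepted threshold
#>   <chr>                  <dbl>         <dbl> <lgl>           <int>      <int>     <dbl>
#> 1 Duplex, recessive       3.53         0.335 TRUE                6          1      0.05
```

The duplex-recessive model (expected 151:527 seed set, χ² = 3.53;
expected 324:28 progeny, χ² = 0.34) is the only candidate with both
statistics below the df = 1 critical value 3.84 at p = 0.05: the plant
is duplex for a recessive gametophytic-lethal allele. Every other
candidate fails at least one assay with χ² between ~90 and ~8500.
`segregation_report(fits)` renders the full grid; `autoplot(fits)`
plots it. A triplex parent is expected to show proliferating female
gametophytes in 13/24 ≈ 54% of ovules
(`expected_fg_phenotypes(genetic_model(3, "recessive"), 162)`), and a
forward simulator (`simulate_selfing()`, `simulate_model_recovery()`)
checks that the six models are recoverable from data at these sample
sizes.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/tetraseg.R expect --genotype duplex --mode recessive --assay seed_set --n 678
# 151:527
Rscript inst/cli/tetraseg.R report
```

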