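#' Expected two-category counts for a segregation assay
#'
#' Derives the expected split of `n` scored units between the two
#' categories of one of the three assays used to genotype a selfing
#' parent:
#'
#' * `seed_set` — infertile ovules vs developing seeds. Infertility is
#'   modelled purely as abortion of the affected female gametophyte
#'   classes; pollen is in excess and never limits seed number.
#' * `progeny` — marker-resistant vs marker-sensitive seedlings, where
#'   resistance marks inheritance of at least one mutant (insertion)
#'   allele. A seedling is sensitive iff both its gametes carried zero
#'   mutant alleles, so the sensitive fraction is the product of the
#'   viable-female and selected-male class-0 shares.
#' * `fg_phenotype` — proliferating vs normal female gametophytes scored
#'   in cleared ovules. Scoring happens before abortion removes the
#'   doomed gametophytes, so the proliferating fraction is the
#'   pre-selection frequency of the fully mutant female class.
#'
#' Expected counts are computed from exact class frequencies and reported
#' unrounded; `display_a`/`display_b` carry the half-up-rounded integers
#' used for ratio presentation. Chi-square tests must consume the
#' unrounded values.
#'
#' @param model a [genetic_model()].
#' @param n total number of scored units (ovules, seedlings or
#'   gametophytes); must be positive.
#' @param assay one of `"seed_set"`, `"progeny"`, `"fg_phenotype"`.
#' @return A one-row tibble: `assay`, `n`, `frac_a` (exact category-A
#'   fraction), `category_a`, `category_b` (unrounded expected counts,
#'   summing to `n`), `display_a`, `display_b`, and `ratio` (display
#'   string, e.g. `"151:527"`). Category A is the mutant-revealing
#'   category: infertile, resistant, or proliferating.
#' @examples
#' m <- genetic_model(2, "recessive")
#' expected_counts(m, 678, "seed_set")   # 151:527
#' expected_counts(m, 352, "progeny")    # 324:28
#' expected_counts(genetic_model(3, "recessive"), 162, "fg_phenotype")
#' @export
expected_counts <- function(model, n,
                            assay = c("seed_set", "progeny", "fg_phenotype")) {
  assay <- rlang::arg_match(assay)
  switch(assay,
    seed_set = expected_seed_set(model, n),
    progeny = expected_progeny(model, n),
    fg_phenotype = expected_fg_phenotypes(model, n)
  )
}

check_n <- function(n) {
  if (length(n) != 1 || !is.finite(n) || n <= 0 || n != trunc(n)) {
    rlang::abort("`n` must be a single positive integer.")
  }
}

build_expected <- function(assay, n, frac_a) {
  a <- as.numeric(frac_a) * n
  b <- n - a
  da <- round_half_up(a)
  tibble::tibble(
    assay = assay, n = n, frac_a = frac_a,
    category_a = a, category_b = b,
    display_a = da, display_b = n - da,
    ratio = paste0(da, ":", n - da)
  )
}

# round-half-up for ratio display (R's round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

#' @rdname expected_counts
#' @export
expected_seed_set <- function(model, n) {
  check_n(n)
  g <- gamete_frequencies(model$dosage, model$alpha, model$ploidy)
  fem <- apply_female_selection_or_all(g, model$selection)
  build_expected("seed_set", n, fem$abort_fraction)
}

# female selection that tolerates the all-abort degenerate case for
# assays that only need the abort fraction
apply_female_selection_or_all <- function(g, selection) {
  aborting <- g$class %in% selection$female_abort
  abort_fraction <- sum(g$freq[aborting])
  if (as.numeric(abort_fraction) == 1) {
    list(viable = g[0, , drop = FALSE], abort_fraction = abort_fraction)
  } else {
    apply_female_selection(g, selection)
  }
}

#' @rdname expected_counts
#' @export
expected_progeny <- function(model, n) {
  check_n(n)
  s <- sensitive_fraction(model)
  build_expected("progeny", n, frac(1) - s)
}

# probability a progeny individual inherits zero mutant alleles
sensitive_fraction <- function(model) {
  g <- gamete_frequencies(model$dosage, model$alpha, model$ploidy)
  fem <- apply_female_selection(g, model$selection)
  male <- apply_male_selection(g, model$selection)
  class_share <- function(tab, k) {
    hit <- tab$class == k
    if (!any(hit)) frac(0) else sum(tab$freq[hit])
  }
  class_share(fem$viable, 0) * class_share(male, 0)
}

#' @rdname expected_counts
#' @export
expected_fg_phenotypes <- function(model, n) {
  check_n(n)
  g <- gamete_frequencies(model$dosage, model$alpha, model$ploidy)
  full <- model$ploidy / 2
  proliferating <- sum(g$freq[g$class == full])
  build_expected("fg_phenotype", n, proliferating)
}

#' Offspring mutant-dosage distribution of a selfing parent
#'
#' Convolves the viable female gamete-class distribution with the
#' TE-selected male distribution to give the exact distribution of mutant
#' dosage among progeny. Under a recessive model with female abortion of
#' fully mutant gametes, the maximal offspring dosage class has frequency
#' exactly zero (no quadruplex mutants from a selfed tetraploid).
#'
#' @param model a [genetic_model()].
#' @return A tibble with `dosage` (0 .. ploidy), `freq` (exact [frac()])
#'   and `prob`; frequencies sum to exactly 1.
#' @examples
#' offspring_dosage_distribution(genetic_model(2, "recessive"))
#' @export
offspring_dosage_distribution <- function(model) {
  g <- gamete_frequencies(model$dosage, model$alpha, model$ploidy)
  fem <- apply_female_selection(g, model$selection)$viable
  male <- apply_male_selection(g, model$selection)
  dmax <- model$ploidy
  freq <- vctrs::vec_rep(frac(0), dmax + 1)
  for (i in seq_len(nrow(fem))) {
    for (j in seq_len(nrow(male))) {
      k <- fem$class[i] + male$class[j]
      freq[[k + 1]] <- freq[[k + 1]] + fem$freq[[i]] * male$freq[[j]]
    }
  }
  tibble::tibble(dosage = 0:dmax, freq = freq, prob = as.numeric(freq))
}

#' Joint probability of independent rare transmission events
#'
#' Probability that a progeny individual both inherits the mutant allele
#' through pollen (transmission efficiency `te_male`) and arises from a
#' gametic genome-duplication (triploid) event of frequency
#' `triploid_fraction`; the two are treated as independent, so the result
#' is the plain product. Used to argue why mutant triploid offspring of a
#' diploid heterozygote are too rare to recover (0.1 x 0.06 = 0.006).
#'
#' @param te_male male transmission efficiency in \[0, 1\].
#' @param triploid_fraction triploid frequency among transmitted mutant
#'   progeny, in \[0, 1\].
#' @return The product, a plain numeric probability.
#' @examples
#' triploid_recovery_probability(0.1, 0.06)  # 0.006
#' @export
triploid_recovery_probability <- function(te_male, triploid_fraction) {
  for (v in c(te_male, triploid_fraction)) {
    if (!is.finite(v) || v < 0 || v > 1) {
      rlang::abort("Both arguments must lie in [0, 1].")
    }
  }
  te_male * triploid_fraction
}
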