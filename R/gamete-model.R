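#' Gamete-class frequencies under tetrasomic inheritance
#'
#' Computes the exact distribution of gamete classes produced by a selfed
#' parent carrying `dosage` copies of a mutant allele `a`. A tetraploid
#' parent produces diploid gametes in three classes by mutant dosage
#' (0 = `AA`, 1 = `Aa`, 2 = `aa`); a diploid parent produces haploid
#' gametes (0 = `A`, 1 = `a`).
#'
#' For a tetraploid the model combines two routes: with probability
#' `alpha` (the double-reduction coefficient) the gamete receives both
#' sister-chromatid copies of one randomly chosen parental chromosome, so
#' it is homozygous `aa` with probability `d/4` and `AA` with probability
#' `(4-d)/4`; with probability `1 - alpha` two distinct chromosomes are
#' sampled (chromosomal segregation), giving the classical hypergeometric
#' frequencies `C(d,2)/6`, `d(4-d)/6`, `C(4-d,2)/6`. `alpha` is at most
#' 1/6, the maximum for a locus unlinked to its centromere; `alpha = 1/7`
#' corresponds to random-chromatid segregation and `alpha = 0` to pure
#' chromosomal segregation.
#'
#' @param dosage integer, number of mutant alleles carried by the parent
#'   (0 to `ploidy`). For a tetraploid: 0 nulliplex, 1 simplex, 2 duplex,
#'   3 triplex, 4 quadruplex.
#' @param alpha double-reduction coefficient in \[0, 1/6\]; a number or a
#'   [frac()]. Must be 0 for diploid parents.
#' @param ploidy 2 or 4.
#' @return A tibble with one row per gamete class: `class` (mutant dosage
#'   of the gamete), `label` (`"AA"`, `"Aa"`, `"aa"` or `"A"`, `"a"`),
#'   `freq` (exact [frac()]) and `prob` (numeric value of `freq`).
#' @examples
#' gamete_frequencies(2, alpha = 0)       # classical 1:4:1
#' gamete_frequencies(3, alpha = 1 / 6)   # aa = 13/24, about 54%
#' gamete_frequencies(1, ploidy = 2)      # haploid 1:1
#' @seealso [enumerate_gametes()] for the brute-force oracle,
#'   [apply_female_selection()] and [apply_male_selection()] for
#'   gametophytic selection.
#' @export
gamete_frequencies <- function(dosage, alpha = frac(1, 6), ploidy = 4) {
  check_ploidy(ploidy)
  check_dosage(dosage, ploidy)
  alpha <- check_alpha(alpha, ploidy)
  d <- dosage
  if (ploidy == 4) {
    f_aa <- alpha * frac(d, 4) + (frac(1) - alpha) * frac(choose2(d), 6)
    f_Aa <- (frac(1) - alpha) * frac(d * (4 - d), 6)
    f_AA <- alpha * frac(4 - d, 4) + (frac(1) - alpha) * frac(choose2(4 - d), 6)
    freq <- vctrs::vec_c(f_AA, f_Aa, f_aa)
    tibble::tibble(
      class = 0:2,
      label = c("AA", "Aa", "aa"),
      freq = freq,
      prob = as.numeric(freq)
    )
  } else {
    f_a <- frac(d, 2)
    freq <- vctrs::vec_c(frac(1) - f_a, f_a)
    tibble::tibble(
      class = 0:1,
      label = c("A", "a"),
      freq = freq,
      prob = as.numeric(freq)
    )
  }
}

choose2 <- function(n) if (n < 2) 0 else n * (n - 1) / 2

check_ploidy <- function(ploidy) {
  if (!ploidy %in% c(2, 4)) {
    rlang::abort("`ploidy` must be 2 or 4; higher ploidies are not supported.")
  }
}

check_dosage <- function(dosage, ploidy) {
  if (length(dosage) != 1 || dosage != trunc(dosage) ||
      dosage < 0 || dosage > ploidy) {
    rlang::abort(sprintf("`dosage` must be an integer in 0..%d.", ploidy))
  }
}

check_alpha <- function(alpha, ploidy = 4) {
  alpha <- as_frac(alpha)
  if (length(alpha) != 1) rlang::abort("`alpha` must be a single value.")
  a <- as.numeric(alpha)
  if (a < 0 || a > 1 / 6) {
    rlang::abort("`alpha` must lie in [0, 1/6] (maximum for an unlinked locus).")
  }
  if (ploidy == 2 && a != 0) {
    rlang::abort("Double reduction is undefined for diploids: `alpha` must be 0 when `ploidy = 2`.")
  }
  alpha
}

#' Brute-force gamete enumeration oracle
#'
#' Enumerates every equally likely gamete of a tetraploid parent under one
#' of two classical segregation regimes, as an independent check on the
#' closed form in [gamete_frequencies()]. Under `"chromosomal"`
#' segregation all `C(4,2) = 6` unordered chromosome pairs are gametes
#' (equals the closed form at `alpha = 0`); under `"random_chromatid"`
#' segregation all `C(8,2) = 28` unordered pairs of the 8 chromatids are
#' gametes, the 4 sister pairs being exactly the double-reduction
#' outcomes (equals the closed form at `alpha = 4/28 = 1/7`).
#'
#' @param dosage mutant-allele dosage of the tetraploid parent, 0 to 4.
#' @param regime `"chromosomal"` or `"random_chromatid"`.
#' @return A tibble in the same shape as [gamete_frequencies()].
#' @examples
#' enumerate_gametes(2, "random_chromatid")  # 3/14, 8/14, 3/14
#' @export
enumerate_gametes <- function(dosage, regime = c("chromosomal", "random_chromatid")) {
  regime <- rlang::arg_match(regime)
  check_dosage(dosage, 4)
  # chromosomes: `dosage` mutant (1) and the rest wild type (0)
  chrom <- c(rep(1, dosage), rep(0, 4 - dosage))
  if (regime == "chromosomal") {
    pairs <- utils::combn(4, 2)
    counts <- chrom[pairs[1, ]] + chrom[pairs[2, ]]
  } else {
    # two identical chromatids per chromosome; a sister pair in one
    # gamete is a double-reduction event and stays in the sample space
    chromatid_allele <- rep(chrom, each = 2)
    pairs <- utils::combn(8, 2)
    counts <- chromatid_allele[pairs[1, ]] + chromatid_allele[pairs[2, ]]
  }
  total <- length(counts)
  freq <- frac(vapply(0:2, function(k) sum(counts == k), double(1)), total)
  tibble::tibble(
    class = 0:2,
    label = c("AA", "Aa", "aa"),
    freq = freq,
    prob = as.numeric(freq)
  )
}

#' Sex-specific gametophytic selection model
#'
#' Describes how gametophytic lethality of a mutant allele distorts the
#' two gamete pools of a selfing parent. On the female side, affected
#' gamete classes abort outright (frequency weight 0), which both
#' sterilises the corresponding ovules and removes those classes from the
#' maternal contribution to progeny. On the male side, pollen is in
#' excess, so selection acts as a relative transmission efficiency (TE):
#' affected classes fertilise at weight `male_te` relative to 1 for
#' unaffected ones.
#'
#' Under the `"recessive"` mode only fully mutant gametes (class `aa`
#' from a tetraploid, `a` from a diploid) are affected; under
#' `"dominant"` every mutant-carrying class is.
#'
#' @param mode `"recessive"` or `"dominant"`.
#' @param male_te relative transmission weight of affected classes
#'   through pollen, in \[0, 1\]. The field estimate for the allele
#'   studied here is 0.1.
#' @param male_weights optional full override: numeric vector of per-class
#'   weights (length 3 for tetraploid gametes, classes 0..2), each in
#'   \[0, 1\]. Overrides the `mode`/`male_te` defaults, e.g. to model full
#'   abortion (`weight 0`) of homozygous-mutant pollen.
#' @param ploidy parental ploidy, 2 or 4.
#' @return An object of class `seg_selection`: list with `mode`,
#'   `female_abort` (aborting female classes), `male_weights` (a
#'   [frac()] vector aligned with `classes`) and `ploidy`.
#' @examples
#' selection_model("recessive")
#' selection_model("dominant", male_te = 0.1)
#' selection_model("recessive", male_weights = c(1, 1, 0))  # aborting pollen
#' @export
selection_model <- function(mode = c("recessive", "dominant"), male_te = 0.1,
                            male_weights = NULL, ploidy = 4) {
  mode <- rlang::arg_match(mode)
  check_ploidy(ploidy)
  classes <- 0:(ploidy / 2)
  full <- max(classes)
  affected <- if (mode == "recessive") full else classes[classes > 0]
  te <- as_frac(male_te, strict = FALSE)
  if (as.numeric(te) < 0 || as.numeric(te) > 1) {
    rlang::abort("`male_te` must lie in [0, 1].")
  }
  if (is.null(male_weights)) {
    w <- vctrs::vec_rep(frac(1), length(classes))
    w[classes %in% affected] <- te
  } else {
    if (length(male_weights) != length(classes)) {
      rlang::abort(sprintf("`male_weights` must have length %d (classes %s).",
                           length(classes), paste(classes, collapse = ", ")))
    }
    w <- as_frac(male_weights, strict = FALSE)
    if (any(as.numeric(w) < 0) || any(as.numeric(w) > 1)) {
      rlang::abort("All `male_weights` must lie in [0, 1].")
    }
  }
  structure(
    list(mode = mode, female_abort = affected, male_weights = w,
         classes = classes, ploidy = ploidy),
    class = "seg_selection"
  )
}

#' @export
print.seg_selection <- function(x, ...) {
  cat("<seg_selection> mode:", x$mode, "(ploidy", paste0(x$ploidy, ")"), "\n")
  cat("  female aborting classes:", paste(x$female_abort, collapse = ", "), "\n")
  cat("  male transmission weights:",
      paste(x$classes, format(x$male_weights), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Female gametophytic selection
#'
#' Splits a gamete-class distribution into the fraction that aborts (the
#' expected infertile-ovule fraction) and the renormalised distribution of
#' surviving female gametes.
#'
#' @param freqs a gamete-class tibble from [gamete_frequencies()].
#' @param selection a [selection_model()].
#' @return A list of class `seg_female_selection`: `viable`, a tibble of
#'   the surviving classes with `freq` renormalised to sum to one, and
#'   `abort_fraction`, an exact [frac()].
#' @examples
#' g <- gamete_frequencies(2, alpha = 1 / 6)
#' apply_female_selection(g, selection_model("recessive"))
#' @export
apply_female_selection <- function(freqs, selection) {
  check_dist(freqs)
  aborting <- freqs$class %in% selection$female_abort
  abort_fraction <- sum(freqs$freq[aborting])
  surviving <- sum(freqs$freq) - abort_fraction
  if (as.numeric(surviving) == 0) {
    rlang::abort("Degenerate female pool: every gamete class aborts.")
  }
  viable <- freqs[!aborting, , drop = FALSE]
  viable$freq <- viable$freq / surviving
  viable$prob <- as.numeric(viable$freq)
  structure(
    list(viable = tibble::as_tibble(viable), abort_fraction = abort_fraction),
    class = "seg_female_selection"
  )
}

#' @export
print.seg_female_selection <- function(x, ...) {
  cat("<seg_female_selection> abort fraction:", format(x$abort_fraction),
      sprintf("(%.4f)\n", as.numeric(x$abort_fraction)))
  print(x$viable)
  invisible(x)
}

#' Male gametophytic selection
#'
#' Reweights a gamete-class distribution by per-class male transmission
#' efficiencies and renormalises, giving the distribution of the pollen
#' classes that actually fertilise.
#'
#' @inheritParams apply_female_selection
#' @return A gamete-class tibble with selected, renormalised `freq`.
#' @examples
#' g <- gamete_frequencies(2, alpha = 1 / 6)
#' apply_male_selection(g, selection_model("recessive"))
#' @export
apply_male_selection <- function(freqs, selection) {
  check_dist(freqs)
  w <- selection$male_weights[match(freqs$class, selection$classes)]
  weighted <- freqs$freq * w
  total <- sum(weighted)
  if (as.numeric(total) == 0) {
    rlang::abort("Degenerate male pool: all weighted frequencies are zero.")
  }
  out <- freqs
  out$freq <- weighted / total
  out$prob <- as.numeric(out$freq)
  out
}

check_dist <- function(freqs) {
  if (!is.data.frame(freqs) || !all(c("class", "freq") %in% names(freqs))) {
    rlang::abort("Expected a gamete-class tibble with `class` and `freq` columns.")
  }
  if (!is_frac(freqs$freq)) {
    rlang::abort("`freq` must be an exact `frac` vector.")
  }
  if (any(as.numeric(freqs$freq) < 0) || sum(freqs$freq) != frac(1)) {
    rlang::abort("Gamete-class frequencies must be non-negative and sum to exactly 1.")
  }
  invisible(freqs)
}
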