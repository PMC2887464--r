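#' Forward simulation of a selfing experiment
#'
#' Simulates the three assays scored on a selfed parent under a candidate
#' genetic model, with exactly the statistical structure the inference
#' functions assume:
#'
#' 1. each of `n_ovules` ovules draws a female gamete class from the
#'    parent's gamete-class distribution; aborting classes become
#'    infertile ovules, the rest develop (pollen is unlimited);
#' 2. each of `n_genotyped` progeny pairs a viable female gamete with a
#'    male gamete drawn from the TE-selected pollen distribution; the
#'    individual is marker-resistant iff its summed mutant dosage is at
#'    least 1;
#' 3. each of `n_fg_scored` female gametophytes is drawn from the
#'    pre-selection distribution (cleared-ovule scoring sees doomed
#'    gametophytes too) and labelled proliferating iff fully mutant.
#'
#' All draws are multinomial; a fixed `seed` gives identical output on
#' every run and platform (R's default Mersenne-Twister generator).
#'
#' @param model a [genetic_model()]; the truth to simulate from.
#' @param n_ovules,n_genotyped,n_fg_scored per-assay sample sizes
#'   (non-negative; an assay with size 0 yields a zero row).
#' @param seed integer seed for reproducibility, or `NULL` to use the
#'   current RNG state.
#' @return A list of class `seg_simulation`: `counts`, a tibble in the
#'   observed-counts schema (`group_label`, `assay`, `category_a`,
#'   `category_b`) with one row per assay; and `offspring_dosages`, a
#'   tibble of realised progeny dosage counts.
#' @examples
#' sim <- simulate_selfing(genetic_model(2, "recessive"),
#'                         n_ovules = 678, n_genotyped = 352,
#'                         n_fg_scored = 162, seed = 1)
#' sim$counts
#' @export
simulate_selfing <- function(model, n_ovules = 678, n_genotyped = 352,
                             n_fg_scored = 162, seed = NULL) {
  for (n in c(n_ovules, n_genotyped, n_fg_scored)) {
    if (!is.finite(n) || n < 0 || n != trunc(n)) {
      rlang::abort("Sample sizes must be non-negative integers.")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  k <- selfing_kernel(model)
  draws <- selfing_draws(k, n_ovules, n_genotyped, n_fg_scored)
  infertile <- draws$infertile
  dosage_counts <- draws$dosage_counts
  sensitive <- dosage_counts[1]
  resistant <- n_genotyped - sensitive
  proliferating <- draws$proliferating
  dmax <- model$ploidy

  counts <- tibble::tibble(
    group_label = model$label,
    assay = c("seed_set", "progeny", "fg_phenotype"),
    category_a = as.numeric(c(infertile, resistant, proliferating)),
    category_b = as.numeric(c(n_ovules - infertile, sensitive,
                              n_fg_scored - proliferating))
  )
  structure(
    list(counts = counts,
         offspring_dosages = tibble::tibble(dosage = 0:dmax,
                                            count = as.integer(dosage_counts))),
    class = "seg_simulation"
  )
}

# plain-numeric view of a model's selfing process, computed once so the
# replicate loop never touches exact-fraction arithmetic
selfing_kernel <- function(model) {
  g <- gamete_frequencies(model$dosage, model$alpha, model$ploidy)
  fem <- apply_female_selection(g, model$selection)
  male <- apply_male_selection(g, model$selection)
  full <- model$ploidy / 2
  list(
    p_abort = as.numeric(fem$abort_fraction),
    fem_classes = fem$viable$class, fem_probs = fem$viable$prob,
    male_classes = male$class, male_probs = male$prob,
    p_prolif = sum(g$prob[g$class == full]),
    dmax = model$ploidy
  )
}

selfing_draws <- function(k, n_ovules, n_genotyped, n_fg_scored) {
  infertile <- if (n_ovules > 0) stats::rbinom(1, n_ovules, k$p_abort) else 0L
  dosage_counts <- rep(0L, k$dmax + 1)
  if (n_genotyped > 0) {
    fem_draw <- stats::rmultinom(1, n_genotyped, k$fem_probs)[, 1]
    for (i in seq_along(fem_draw)) {
      if (fem_draw[i] == 0) next
      male_draw <- stats::rmultinom(1, fem_draw[i], k$male_probs)[, 1]
      for (j in seq_along(male_draw)) {
        d <- k$fem_classes[i] + k$male_classes[j]
        dosage_counts[d + 1] <- dosage_counts[d + 1] + male_draw[j]
      }
    }
  }
  proliferating <- if (n_fg_scored > 0) stats::rbinom(1, n_fg_scored, k$p_prolif) else 0L
  list(infertile = infertile, dosage_counts = dosage_counts,
       proliferating = proliferating)
}

#' @export
print.seg_simulation <- function(x, ...) {
  cat("<seg_simulation>\n")
  print(x$counts)
  invisible(x)
}

#' Model-recovery rate under simulated truth
#'
#' Repeatedly simulates seed-set and progeny counts at chosen sample
#' sizes from a truth model, runs [fit_all_models()] over the candidate
#' set, and reports how often the truth comes out best-fitting. Used to
#' check that the six candidate models are statistically separable at the
#' experiment's actual sample sizes.
#'
#' @param truth the [genetic_model()] to simulate from; its `label` must
#'   appear among `candidates`.
#' @param n_replicates number of simulated experiments.
#' @param seed integer seed.
#' @param n_ovules,n_genotyped per-replicate sample sizes (defaults are
#'   the published experiment's).
#' @param candidates candidate list for [fit_all_models()].
#' @param threshold significance level passed through.
#' @return The recovery rate (fraction of replicates whose best-fitting
#'   model is the truth), with attribute `selections`: a tibble counting
#'   which model won each replicate.
#' @examples
#' simulate_model_recovery(genetic_model(2, "recessive"),
#'                            n_replicates = 20, seed = 1)
#' @export
simulate_model_recovery <- function(truth, n_replicates, seed = NULL,
                                       n_ovules = 678, n_genotyped = 352,
                                       candidates = candidate_models(),
                                       threshold = 0.05) {
  if (n_replicates < 1) rlang::abort("`n_replicates` must be at least 1.")
  labels <- purrr::map_chr(candidates, "label")
  if (!truth$label %in% labels) {
    rlang::abort("`truth` must be among the candidate models (matched by label).")
  }
  if (!is.null(seed)) set.seed(seed)
  kern <- selfing_kernel(truth)
  # per-candidate expected counts are fixed by the sample sizes
  exp_seed <- t(vapply(candidates, function(m) {
    e <- expected_seed_set(m, n_ovules)
    c(e$category_a, e$category_b)
  }, double(2)))
  exp_prog <- t(vapply(candidates, function(m) {
    e <- expected_progeny(m, n_genotyped)
    c(e$category_a, e$category_b)
  }, double(2)))
  if (any(exp_seed <= 0) || any(exp_prog <= 0)) {
    rlang::abort("A candidate model has a zero expected count at these sample sizes.")
  }
  chisq2 <- function(obs, expct) {
    (obs[1] - expct[, 1])^2 / expct[, 1] + (obs[2] - expct[, 2])^2 / expct[, 2]
  }
  winners <- character(n_replicates)
  for (r in seq_len(n_replicates)) {
    draws <- selfing_draws(kern, n_ovules, n_genotyped, 0)
    sensitive <- draws$dosage_counts[1]
    cs <- chisq2(c(draws$infertile, n_ovules - draws$infertile), exp_seed)
    cp <- chisq2(c(n_genotyped - sensitive, sensitive), exp_prog)
    # same ranking rule as fit_all_models: worst assay, ties by sum
    winners[r] <- labels[order(pmax(cs, cp), cs + cp)][1]
  }
  rate <- mean(winners == truth$label)
  attr(rate, "selections") <- dplyr::count(tibble::tibble(label = winners),
                                           .data$label, sort = TRUE)
  rate
}
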