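#' Pearson chi-square goodness of fit for a two-category assay
#'
#' Tests observed two-category counts against the expected split from a
#' candidate genetic model. The statistic is the uncorrected Pearson form
#' on the two categories (df = 1), computed on unrounded expected counts
#' — no Yates continuity correction, matching the convention of classical
#' segregation analysis. Zero observed cells are legitimate (e.g. a
#' progeny test with no sensitive seedlings); zero expected cells are an
#' error.
#'
#' @param observed integer vector `c(category_a, category_b)` of observed
#'   counts, or a one-row tibble with `category_a`/`category_b` columns
#'   (the [read_observed_counts()] schema).
#' @param expected a one-row expected-counts tibble from
#'   [expected_counts()], or a numeric vector `c(category_a, category_b)`
#'   of unrounded expected counts.
#' @param threshold significance level for the rejection decision.
#' @param model optionally, the [genetic_model()] the expectation came
#'   from, carried through for reporting.
#' @return An object of class `seg_fit`: list with `statistic`, `df`
#'   (always 1), `p_value`, `rejected`, `threshold`, `observed`,
#'   `expected`, `assay` and `label`. Use [generics::tidy()] for a
#'   one-row tibble.
#' @examples
#' m <- genetic_model(2, "recessive")
#' chisq_gof(c(171, 507), expected_seed_set(m, 678))   # statistic 3.53
#' chisq_gof(c(327, 25), expected_progeny(m, 352))     # statistic 0.34
#' @export
chisq_gof <- function(observed, expected, threshold = 0.05, model = NULL) {
  obs <- as_count_pair(observed)
  if (is.data.frame(expected)) {
    exp_counts <- c(expected$category_a, expected$category_b)
    assay <- expected$assay
    n_exp <- expected$n
  } else {
    exp_counts <- as.numeric(expected)
    assay <- NA_character_
    n_exp <- sum(exp_counts)
  }
  if (length(exp_counts) != 2 || any(!is.finite(exp_counts))) {
    rlang::abort("`expected` must provide two finite expected counts.")
  }
  if (any(exp_counts <= 0)) {
    rlang::abort("Zero (or negative) expected count: chi-square is undefined.")
  }
  if (sum(obs) != n_exp) {
    rlang::abort(sprintf(
      "Observed total (%d) does not match expected total (%g).",
      sum(obs), n_exp))
  }
  stat <- sum((obs - exp_counts)^2 / exp_counts)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(
    list(statistic = stat, df = 1L, p_value = p,
         rejected = p < threshold, threshold = threshold,
         observed = obs, expected = exp_counts, assay = assay,
         label = if (is.null(model)) NA_character_ else model$label),
    class = "seg_fit"
  )
}

as_count_pair <- function(observed) {
  if (is.data.frame(observed)) {
    if (nrow(observed) != 1 ||
        !all(c("category_a", "category_b") %in% names(observed))) {
      rlang::abort("`observed` tibble must be one row with `category_a` and `category_b`.")
    }
    observed <- c(observed$category_a, observed$category_b)
  }
  obs <- as.numeric(observed)
  if (length(obs) != 2 || any(!is.finite(obs)) || any(obs < 0) ||
      any(obs != trunc(obs)) || sum(obs) == 0) {
    rlang::abort("`observed` must be two non-negative integer counts with a positive total.")
  }
  obs
}

#' @export
print.seg_fit <- function(x, ...) {
  cat("<seg_fit>", if (!is.na(x$label)) x$label else "", "\n")
  cat(sprintf("  assay: %s  observed %d:%d  expected %.2f:%.2f\n",
              x$assay, x$observed[1], x$observed[2],
              x$expected[1], x$expected[2]))
  cat(sprintf("  X-squared = %.4g, df = %d, p = %.4g (%s at p = %g)\n",
              x$statistic, x$df, x$p_value,
              if (x$rejected) "rejected" else "not rejected", x$threshold))
  invisible(x)
}

#' Fit and rank candidate models on seed-set and progeny data
#'
#' Scores every candidate model against the observed seed-set and progeny
#' counts by two Pearson chi-square tests, then ranks models by the worse
#' (larger) of the two statistics, breaking ties by their sum. A model is
#' `accepted` when both statistics fall below the critical value at the
#' threshold (3.84 at p = 0.05, df = 1); the best-fitting model is the
#' top-ranked one.
#'
#' @param observed a tibble of observed counts with columns `assay`,
#'   `category_a`, `category_b` containing (at least) one `seed_set` row
#'   and one `progeny` row — see [read_observed_counts()] and
#'   [published_observed()].
#' @param candidates a list of [genetic_model()] objects; default the
#'   standard six-model set.
#' @param threshold significance level.
#' @return A tibble of class `seg_fit_tbl`, one row per candidate, ranked
#'   best first: `label`, `dosage`, `mode`, `alpha`, expected/observed
#'   ratios, `chisq_seed`, `chisq_progeny`, `p_seed`, `p_progeny`,
#'   `max_chisq`, `accepted`, `best`. [generics::glance()] returns the
#'   best row.
#' @examples
#' fits <- fit_all_models(published_observed("tetraploid_a"))
#' dplyr::filter(fits, accepted)
#' @export
fit_all_models <- function(observed, candidates = candidate_models(),
                           threshold = 0.05) {
  if (length(candidates) < 1) {
    rlang::abort("`candidates` must contain at least one genetic model.")
  }
  obs_seed <- pick_assay(observed, "seed_set")
  obs_prog <- pick_assay(observed, "progeny")
  n_seed <- obs_seed$category_a + obs_seed$category_b
  n_prog <- obs_prog$category_a + obs_prog$category_b
  rows <- purrr::map(candidates, function(m) {
    es <- expected_seed_set(m, n_seed)
    ep <- expected_progeny(m, n_prog)
    fs <- chisq_gof(obs_seed, es, threshold, model = m)
    fp <- chisq_gof(obs_prog, ep, threshold, model = m)
    tibble::tibble(
      label = m$label, dosage = m$dosage, mode = m$selection$mode,
      alpha = as.numeric(m$alpha),
      expected_seed = es$ratio,
      observed_seed = paste0(obs_seed$category_a, ":", obs_seed$category_b),
      chisq_seed = fs$statistic, p_seed = fs$p_value,
      expected_progeny = ep$ratio,
      observed_progeny = paste0(obs_prog$category_a, ":", obs_prog$category_b),
      chisq_progeny = fp$statistic, p_progeny = fp$p_value,
      max_chisq = max(fs$statistic, fp$statistic),
      sum_chisq = fs$statistic + fp$statistic,
      accepted = !fs$rejected && !fp$rejected
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), max_chisq, sum_chisq)
  out$best <- seq_len(nrow(out)) == 1
  attr(out, "threshold") <- threshold
  class(out) <- c("seg_fit_tbl", class(out))
  out
}

pick_assay <- function(observed, assay) {
  if (!is.data.frame(observed) ||
      !all(c("assay", "category_a", "category_b") %in% names(observed))) {
    rlang::abort("`observed` must have columns `assay`, `category_a`, `category_b`.")
  }
  row <- observed[observed$assay == assay, , drop = FALSE]
  if (nrow(row) != 1) {
    rlang::abort(sprintf("`observed` must contain exactly one `%s` row.", assay))
  }
  as_count_pair(row[, c("category_a", "category_b")])
  row[, c("category_a", "category_b")]
}

#' Transmission efficiency from a progeny ratio
#'
#' Transmission efficiency (TE) of a mutant allele through one sex is
#' estimated as the ratio of mutant to wild-type plants among the progeny
#' of a cross in which Mendelian expectation is 1:1.
#'
#' @param mutant_count number of mutant progeny.
#' @param wildtype_count number of wild-type progeny; must be positive.
#' @return The TE estimate, `mutant_count / wildtype_count`.
#' @examples
#' estimate_te(0, 50)   # no transmission
#' estimate_te(5, 50)   # 0.1
#' @export
estimate_te <- function(mutant_count, wildtype_count) {
  if (wildtype_count <= 0) {
    rlang::abort("`wildtype_count` must be positive.")
  }
  if (mutant_count < 0) {
    rlang::abort("`mutant_count` must be non-negative.")
  }
  mutant_count / wildtype_count
}

#' Male transmission weight from the triplex:duplex offspring ratio
#'
#' In the selfed progeny of a triplex parent under the recessive model,
#' triplex offspring can only arise when a homozygous-mutant pollen class
#' fertilises (female fully mutant gametes abort), so the observed
#' triplex:duplex ratio pins down the relative transmission weight `w` of
#' homozygous-mutant pollen. The function inverts
#' [offspring_dosage_distribution()] numerically, solving for the `w`
#' whose predicted dosage-3 : dosage-2 ratio matches the observed one.
#'
#' @param observed_triplex triplex (dosage 3) offspring count.
#' @param observed_duplex duplex (dosage 2) offspring count; positive.
#' @param alpha double-reduction coefficient of the model.
#' @return The estimated weight in \[0, 1\]. If the observed ratio lies
#'   outside the attainable range the boundary value is returned with a
#'   warning and attribute `boundary = TRUE`.
#' @examples
#' estimate_te_from_triplex_ratio(13, 101, alpha = 1 / 6)  # about 0.1
#' @export
estimate_te_from_triplex_ratio <- function(observed_triplex, observed_duplex,
                                           alpha = frac(1, 6)) {
  if (observed_duplex <= 0) rlang::abort("`observed_duplex` must be positive.")
  if (observed_triplex < 0) rlang::abort("`observed_triplex` must be non-negative.")
  if (observed_triplex == 0) return(0)
  target <- observed_triplex / observed_duplex
  ratio_at <- function(w) {
    m <- genetic_model(3, "recessive", alpha = alpha,
                       male_weights = c(1, 1, w))
    d <- offspring_dosage_distribution(m)
    d$prob[d$dosage == 3] / d$prob[d$dosage == 2]
  }
  upper <- ratio_at(1)
  if (target >= upper) {
    rlang::warn(sprintf(
      "Observed ratio %.4g exceeds the maximum attainable %.4g; returning w = 1.",
      target, upper))
    return(structure(1, boundary = TRUE))
  }
  stats::uniroot(function(w) ratio_at(w) - target, c(0, 1),
                 tol = 1e-10)$root
}
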