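#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single chi-square fit
#'
#' @param x a `seg_fit` from [chisq_gof()].
#' @param ... unused.
#' @return A one-row tibble with the model label, assay, observed and
#'   expected counts, statistic, df, p-value and rejection decision.
#' @export
tidy.seg_fit <- function(x, ...) {
  tibble::tibble(
    label = x$label, assay = x$assay,
    observed_a = x$observed[1], observed_b = x$observed[2],
    expected_a = x$expected[1], expected_b = x$expected[2],
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    rejected = x$rejected
  )
}

#' @rdname tidy.seg_fit
#' @export
glance.seg_fit <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 rejected = x$rejected, threshold = x$threshold)
}

#' Tidy a fitted model table
#'
#' `tidy()` pivots a [fit_all_models()] result to one row per model and
#' assay; `glance()` summarises the model selection: the best-fitting
#' model, its statistics, and how many candidates were accepted.
#'
#' @param x a `seg_fit_tbl` from [fit_all_models()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.seg_fit_tbl <- function(x, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("label", "dosage", "mode", "alpha",
                             "chisq_seed", "p_seed",
                             "chisq_progeny", "p_progeny")],
    cols = c("chisq_seed", "p_seed", "chisq_progeny", "p_progeny"),
    names_to = c(".value", "assay"),
    names_pattern = "(chisq|p)_(seed|progeny)"
  )
  long$assay <- ifelse(long$assay == "seed", "seed_set", "progeny")
  dplyr::rename(long, statistic = "chisq", p_value = "p")
}

#' @rdname tidy.seg_fit_tbl
#' @export
glance.seg_fit_tbl <- function(x, ...) {
  best <- x[x$best, , drop = FALSE]
  tibble::tibble(
    best_model = best$label,
    chisq_seed = best$chisq_seed,
    chisq_progeny = best$chisq_progeny,
    accepted = best$accepted,
    n_candidates = nrow(x),
    n_accepted = sum(x$accepted),
    threshold = attr(x, "threshold") %||% 0.05
  )
}
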