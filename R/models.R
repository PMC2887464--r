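#' Candidate genetic model
#'
#' Bundles a parent genotype (ploidy and mutant-allele dosage), a
#' dominance mode with its gametophytic selection rules, and a
#' double-reduction coefficient into one testable model of segregation.
#'
#' @param dosage mutant-allele dosage of the selfed parent.
#' @param mode `"recessive"` or `"dominant"` gametophytic action.
#' @param alpha double-reduction coefficient, default the unlinked-locus
#'   maximum 1/6; set 0 for a model without double reduction.
#' @param ploidy 2 or 4.
#' @param male_te,male_weights passed to [selection_model()].
#' @param label display label; defaults to e.g. `"Duplex, recessive"`.
#' @return An object of class `seg_model`.
#' @examples
#' genetic_model(2, "recessive")
#' genetic_model(1, "recessive", alpha = 0)
#' @export
genetic_model <- function(dosage, mode = c("recessive", "dominant"),
                          alpha = frac(1, 6), ploidy = 4, male_te = 0.1,
                          male_weights = NULL, label = NULL) {
  mode <- rlang::arg_match(mode)
  check_ploidy(ploidy)
  check_dosage(dosage, ploidy)
  alpha <- check_alpha(alpha, ploidy)
  selection <- selection_model(mode, male_te = male_te,
                               male_weights = male_weights, ploidy = ploidy)
  if (is.null(label)) {
    label <- if (ploidy == 4) {
      paste0(dosage_name(dosage), ", ", mode)
    } else {
      paste0("Diploid d=", dosage, ", ", mode)
    }
  }
  structure(
    list(dosage = dosage, ploidy = ploidy, alpha = alpha,
         selection = selection, label = label),
    class = "seg_model"
  )
}

dosage_name <- function(d) {
  c("Nulliplex", "Simplex", "Duplex", "Triplex", "Quadruplex")[d + 1]
}

#' @export
print.seg_model <- function(x, ...) {
  cat("<seg_model>", x$label, "\n")
  cat("  ploidy:", x$ploidy, " dosage:", x$dosage,
      " alpha:", format(x$alpha), "\n")
  print(x$selection)
  invisible(x)
}

#' The standard six-model candidate set
#'
#' The candidate models tested against a tetraploid segregation data set:
#' simplex, duplex and triplex parental dosages, each under recessive and
#' dominant gametophytic action of the mutant allele.
#'
#' @inheritParams genetic_model
#' @return A list of six [genetic_model()] objects, named by label.
#' @examples
#' names(candidate_models())
#' @export
candidate_models <- function(alpha = frac(1, 6), male_te = 0.1) {
  grid <- tidyr::expand_grid(dosage = 1:3, mode = c("recessive", "dominant"))
  models <- purrr::pmap(grid, function(dosage, mode) {
    genetic_model(dosage, mode, alpha = alpha, male_te = male_te)
  })
  rlang::set_names(models, purrr::map_chr(models, "label"))
}
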