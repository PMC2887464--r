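#' Segregation-analysis report
#'
#' Formats a [fit_all_models()] result as a publication-style grid (rows
#' = candidate models; expected vs observed ratios and chi-square for
#' each assay), as a tibble, tab-separated text, or aligned plain text.
#' Machine-readable columns carry full precision; ratios are rounded
#' half-up for display only. The report body is deterministic given its
#' inputs; a `# tetraseg` header line carries run metadata when
#' `header = TRUE`.
#'
#' A `note` column flags known caveats: the simplex-recessive progeny
#' expectation reconstructed here differs from the originally published
#' value for that row (295:57), which no selection/transmission
#' combination in this model family reproduces; the row is annotated
#' rather than adjusted.
#'
#' @param fits a `seg_fit_tbl` from [fit_all_models()].
#' @param format `"tibble"`, `"tsv"` or `"text"`.
#' @param path optional output file for `"tsv"`/`"text"`; when `NULL` the
#'   formatted lines are returned invisibly and printed.
#' @param header include the metadata header line (ignored for
#'   `"tibble"`).
#' @return The report in the requested format.
#' @examples
#' segregation_report(fit_all_models(published_observed("tetraploid_a")))
#' @export
segregation_report <- function(fits, format = c("tibble", "tsv", "text"),
                               path = NULL, header = TRUE) {
  format <- rlang::arg_match(format)
  if (!inherits(fits, "seg_fit_tbl")) {
    rlang::abort("`fits` must come from fit_all_models().")
  }
  tab <- tibble::as_tibble(fits)[, c(
    "label", "expected_seed", "observed_seed", "chisq_seed",
    "expected_progeny", "observed_progeny", "chisq_progeny",
    "accepted", "best"
  )]
  tab$note <- ifelse(
    grepl("^Simplex, recessive$", fits$label),
    "progeny expectation differs from the originally published 295:57 (unresolved)",
    ""
  )
  if (format == "tibble") {
    return(tab)
  }
  num <- function(x) sprintf("%.2f", x)
  body <- tab
  body$chisq_seed <- num(body$chisq_seed)
  body$chisq_progeny <- num(body$chisq_progeny)
  lines <- character(0)
  if (header) {
    lines <- sprintf("# tetraseg %s segregation report",
                     as.character(utils::packageVersion("tetraseg")))
  }
  if (format == "tsv") {
    lines <- c(lines, paste(names(body), collapse = "\t"),
               apply(body, 1, paste, collapse = "\t"))
  } else {
    mat <- rbind(names(body), as.matrix(body))
    widths <- apply(nchar(mat), 2, max)
    pad <- function(row) paste(mapply(formatC, row, width = widths,
                                      flag = "-"), collapse = "  ")
    lines <- c(lines, apply(mat, 1, pad))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(path))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
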