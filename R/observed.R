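#' Published observed counts for the tetraploid segregation analysis
#'
#' The observed two-category counts scored on the selfed tetraploid
#' mutant plants, bundled as the package's reference fixture (from
#' `inst/extdata/observed_counts.csv`):
#'
#' * `tetraploid_a` — the phenotypic group tested against all six
#'   candidate models: 171 infertile : 507 developing ovules (n = 678)
#'   and 327 resistant : 25 sensitive seedlings (n = 352).
#' * `simplex_b` — the confirmation group fitted as simplex-recessive:
#'   16:250 seed set (n = 266) and 321:86 progeny (n = 407; the progeny
#'   expectation for this group is conventionally computed without double
#'   reduction).
#' * `triplex_b` — the confirmation group fitted as triplex-recessive:
#'   309:232 seed set (n = 541) and 208:0 progeny.
#'
#' Female-gametophyte phenotype scoring published only class totals
#' (194 ovules for the diploid heterozygote, 162 for the triplex
#' tetraploid), so no `fg_phenotype` rows are bundled; use
#' [expected_fg_phenotypes()] with those totals directly.
#'
#' @param group optionally, a single `group_label` to filter to.
#' @return A tibble with columns `group_label`, `assay`, `category_a`,
#'   `category_b`.
#' @examples
#' published_observed()
#' published_observed("tetraploid_a")
#' @export
published_observed <- function(group = NULL) {
  path <- system.file("extdata", "observed_counts.csv", package = "tetraseg",
                      mustWork = TRUE)
  obs <- read_observed_counts(path)
  if (!is.null(group)) {
    if (!group %in% obs$group_label) {
      rlang::abort(sprintf("Unknown group label '%s'.", group))
    }
    obs <- obs[obs$group_label == group, , drop = FALSE]
  }
  obs
}

#' Read and write observed-count tables
#'
#' The package's on-disk schema for observed counts is a plain CSV with
#' columns `assay` (one of `seed_set`, `progeny`, `fg_phenotype`),
#' `category_a`, `category_b` (non-negative integers; category A is
#' infertile / resistant / proliferating) and `group_label`. The ratio
#' separator in count columns may be written with ASCII `:`; the Unicode
#' ratio sign is accepted on input and normalised. Malformed rows are
#' reported with their line number.
#'
#' @param path file path.
#' @return `read_observed_counts()`: a validated tibble;
#'   `write_observed_counts()`: `path`, invisibly.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_observed_counts(published_observed(), p)
#' identical(read_observed_counts(p), published_observed())
#' @export
read_observed_counts <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  required <- c("assay", "category_a", "category_b", "group_label")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Missing column(s) in ", path, ": ",
                        paste(missing_cols, collapse = ", ")))
  }
  assays <- c("seed_set", "progeny", "fg_phenotype")
  parse_count <- function(x) {
    x <- trimws(gsub("∶", ":", x))
    suppressWarnings(as.numeric(x))
  }
  out <- tibble::tibble(
    group_label = raw$group_label,
    assay = raw$assay,
    category_a = parse_count(raw$category_a),
    category_b = parse_count(raw$category_b)
  )
  for (i in seq_len(nrow(out))) {
    line <- i + 1  # header is line 1
    if (!out$assay[i] %in% assays) {
      rlang::abort(sprintf("Line %d of %s: unknown assay '%s'.",
                           line, path, out$assay[i]))
    }
    counts <- c(out$category_a[i], out$category_b[i])
    ok <- !any(is.na(counts)) && all(counts >= 0) && all(counts == trunc(counts))
    if (!ok) {
      rlang::abort(sprintf(
        "Line %d of %s: counts must be non-negative integers.", line, path))
    }
  }
  out
}

#' @param counts a tibble in the observed-counts schema.
#' @rdname read_observed_counts
#' @export
write_observed_counts <- function(counts, path) {
  required <- c("group_label", "assay", "category_a", "category_b")
  if (!all(required %in% names(counts))) {
    rlang::abort(paste("`counts` must have columns",
                       paste(required, collapse = ", ")))
  }
  # labels may contain commas (e.g. "Duplex, recessive"), so keep quoting
  utils::write.csv(counts[, required], path, row.names = FALSE)
  invisible(path)
}
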