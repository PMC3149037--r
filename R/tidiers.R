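#' Tidy an association scan
#'
#' @param x a `cnv_assoc` object.
#' @param ... unused.
#' @return the per-locus results tibble.
#' @export
tidy.cnv_assoc <- function(x, ...) {
  x$results
}

#' One-row summary of an association scan
#'
#' @param x a `cnv_assoc` object.
#' @param ... unused.
#' @return one-row tibble: loci tested, permutations, cohort sizes, and the
#'   minimum nominal and genome-wide empirical p.
#' @export
glance.cnv_assoc <- function(x, ...) {
  tibble::tibble(
    n_loci = nrow(x$results),
    n_perm = x$B,
    exhaustive = x$exhaustive,
    mode = x$mode,
    n_cases = x$n_cases,
    n_controls = x$n_controls,
    min_p_nominal = suppressWarnings(min(x$results$p_nominal)),
    min_p_genomewide = suppressWarnings(min(x$results$p_genomewide))
  )
}

#' Tidy a mosaic scan
#'
#' @param x a `mosaic_scan` tibble.
#' @param ... unused.
#' @return the per-arm tibble without list columns.
#' @export
tidy.mosaic_scan <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a mosaic scan
#'
#' @param x a `mosaic_scan` tibble.
#' @param ... unused.
#' @return one-row tibble of arm counts by outcome.
#' @export
glance.mosaic_scan <- function(x, ...) {
  tibble::tibble(
    n_arms = nrow(x),
    n_flagged = sum(x$outlier, na.rm = TRUE),
    n_excluded = sum(x$excluded, na.rm = TRUE),
    n_samples_excluded = dplyr::n_distinct(x$sample_id[x$excluded])
  )
}
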