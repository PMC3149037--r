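#' qPCR dosage classification
#'
#' Each sample's DNA quantity is compared to the mean quantity of the run's
#' controls; replicate proportions are averaged before classification.
#' Proportions strictly below 0.80 flag a possible deletion, strictly above
#' 1.20 a possible duplication.
#'
#' @param sample_quantity numeric vector of replicate quantities for one
#'   sample (strictly positive).
#' @param control_quantities numeric vector of control quantities shared by
#'   all replicates, or a list with one control vector per replicate.
#' @param low,high classification thresholds (exclusive).
#' @return one-row tibble with `proportion`, `assay`, `verdict`.
#' @export
qpcr_classify <- function(sample_quantity, control_quantities,
                          low = 0.80, high = 1.20) {
  assert_that(all(sample_quantity > 0), "non-positive DNA quantity")
  if (is.list(control_quantities)) {
    assert_that(length(control_quantities) == length(sample_quantity),
                "one control set per replicate required")
    ctrl_mean <- vapply(control_quantities, mean, numeric(1))
  } else {
    ctrl_mean <- rep(mean(control_quantities), length(sample_quantity))
  }
  assert_that(all(ctrl_mean > 0), "control mean must be positive")
  prop <- mean(sample_quantity / ctrl_mean)
  verdict <- if (prop < low) "deletion" else if (prop > high) "duplication"
    else "normal"
  tibble::tibble(assay = "qpcr", proportion = prop, verdict = verdict)
}

#' MLPA peak-ratio classification
#'
#' Relative peak ratios between 0.8 and 1.2 (inclusive) are normal; below,
#' a deletion; above, a duplication.
#'
#' @param peak_ratio numeric ratio(s), strictly positive (vectorised).
#' @param low,high inclusive bounds of the normal range.
#' @return tibble with one row per ratio (`assay`, `proportion`, `verdict`).
#' @export
mlpa_classify <- function(peak_ratio, low = 0.8, high = 1.2) {
  assert_that(all(peak_ratio > 0), "peak ratio must be positive")
  verdict <- dplyr::case_when(
    peak_ratio < low ~ "deletion",
    peak_ratio > high ~ "duplication",
    TRUE ~ "normal"
  )
  tibble::tibble(assay = "mlpa", proportion = peak_ratio, verdict = verdict)
}

#' Gel band sizing and repeat-count arithmetic
#'
#' Assigns a PCR product length by linear interpolation between the two
#' nearest ladder bands flanking the band's pixel position, then converts to
#' a tandem-repeat count as `(size_bp - flank_bp) / unit_len`.
#'
#' @param band_pixel pixel coordinate of the band centre.
#' @param ladder data frame with columns `pixel` and `bp`; the band must lie
#'   within the ladder's pixel range.
#' @param flank_bp base pairs between the primers and the repeated sequence.
#' @param unit_len repeat unit length in bp (default 32).
#' @return one-row tibble with `size_bp`, `n_repeats`, `n_repeats_rounded`.
#' @export
gel_size_and_repeats <- function(band_pixel, ladder, flank_bp,
                                 unit_len = 32) {
  ladder <- ladder[order(ladder$pixel), , drop = FALSE]
  assert_that(band_pixel >= min(ladder$pixel) &&
                band_pixel <= max(ladder$pixel),
              "band lies outside the ladder range")
  size <- approx(ladder$pixel, ladder$bp, xout = band_pixel)$y
  n_rep <- (size - flank_bp) / unit_len
  tibble::tibble(size_bp = size, n_repeats = n_rep,
                 n_repeats_rounded = round(n_rep))
}

#' Decompose a tandem-repeat sequence into unit variants
#'
#' Tiles the sequence into consecutive blocks of `unit_len` from the first
#' base, clusters blocks by exact sequence, and reports the distinct unit
#' variants (in order of first appearance) with their counts, the positions
#' within the unit at which variants differ, and any trailing partial unit
#' (reported, not counted).
#'
#' @param sequence character scalar (e.g. the VNTR region sequence).
#' @param unit_len repeat unit length (default 32).
#' @return list with `units` tibble (`variant`, `count`), `n_units`,
#'   `variable_positions` (integer vector), `partial` (string, possibly
#'   empty).
#' @export
repeat_decompose <- function(sequence, unit_len = 32) {
  assert_that(is.character(sequence) && length(sequence) == 1,
              "sequence must be a single string")
  n <- nchar(sequence)
  assert_that(n >= unit_len, "sequence shorter than one repeat unit")
  k <- n %/% unit_len
  starts <- (seq_len(k) - 1) * unit_len + 1
  blocks <- substring(sequence, starts, starts + unit_len - 1)
  partial <- if (n %% unit_len > 0) substring(sequence, k * unit_len + 1, n)
    else ""
  variants <- unique(blocks)
  counts <- vapply(variants, function(v) sum(blocks == v), integer(1))
  var_pos <- integer(0)
  if (length(variants) > 1) {
    mat <- do.call(rbind, strsplit(variants, ""))
    var_pos <- which(apply(mat, 2, function(col) length(unique(col)) > 1))
  }
  list(units = tibble::tibble(variant = variants, count = unname(counts)),
       n_units = k, variable_positions = var_pos, partial = partial)
}

#' Two-sample Student's t-test on summed allele sizes
#'
#' Equal-variance two-sided Student's t comparing summed allele sizes
#' between two call groups (e.g. deletion calls vs duplication calls); the
#' null result is the signature of a repeat polymorphism unlinked to the
#' calls.
#'
#' @param group_a_sizes,group_b_sizes numeric vectors (each n >= 2).
#' @return one-row tibble with `t`, `df`, `p_value`, group means.
#' @export
summed_allele_test <- function(group_a_sizes, group_b_sizes) {
  assert_that(length(group_a_sizes) >= 2 && length(group_b_sizes) >= 2,
              "each group needs n >= 2")
  if (sd(group_a_sizes) == 0 && sd(group_b_sizes) == 0) {
    same <- mean(group_a_sizes) == mean(group_b_sizes)
    return(tibble::tibble(t = if (same) 0 else Inf,
                          df = length(group_a_sizes) + length(group_b_sizes) - 2,
                          p_value = if (same) 1 else 0,
                          mean_a = mean(group_a_sizes),
                          mean_b = mean(group_b_sizes)))
  }
  ht <- t.test(group_a_sizes, group_b_sizes, var.equal = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value,
                 mean_a = mean(group_a_sizes), mean_b = mean(group_b_sizes))
}
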