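#' Flag markers inside unstable regions
#'
#' Markers overlapping any supplied region (telomeres, centromeres,
#' immunoglobulin loci, ...) are flagged `unstable_region` and excluded from
#' all downstream calling. Regions are 1-based inclusive, as returned by
#' [read_genes_bed()]. An empty region table is a no-op.
#'
#' @param marker_map marker map tibble.
#' @param regions tibble with `chrom`, `start`, `end`.
#' @return the marker map with the `unstable_region` flag updated.
#' @export
exclude_unstable <- function(marker_map, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(marker_map)
  flag <- rep(FALSE, nrow(marker_map))
  for (j in seq_len(nrow(regions))) {
    flag <- flag | (marker_map$chrom == regions$chrom[j] &
                      marker_map$pos >= regions$start[j] &
                      marker_map$pos <= regions$end[j])
  }
  marker_map$unstable_region <- marker_map$unstable_region | flag
  marker_map
}

# logistic ML fit of sex ~ v1 + v2; returns the two per-coefficient
# likelihood-ratio p-values (deviance drop against the model without the
# coefficient). LRT rather than Wald: near-separated fits -- exactly the
# markers this screen must catch -- drive Wald standard errors to infinity
# (Hauck-Donner) while the deviance difference stays well behaved.
# Perfect separation (deviance ~ 0) returns the sentinel 0, treated as
# below any threshold. Degenerate predictors return p = 1.
logit_two_var_p <- function(v1, v2, y) {
  ok <- is.finite(v1) & is.finite(v2)
  v1 <- v1[ok]; v2 <- v2[ok]; y <- y[ok]
  if (length(y) < 4 || (sd(v1) == 0 && sd(v2) == 0)) return(c(1, 1))
  dev_of <- function(X) {
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = binomial())),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged && anyNA(fit$coefficients)) return(NA_real_)
    fit$deviance
  }
  dev_full <- dev_of(cbind(1, v1, v2))
  if (is.na(dev_full)) return(c(1, 1))
  if (dev_full < 1e-6) return(c(0, 0))  # perfect separation
  d1 <- dev_of(cbind(1, v2))
  d2 <- dev_of(cbind(1, v1))
  p <- stats::pchisq(c(d1, d2) - dev_full, df = 1, lower.tail = FALSE)
  p[is.na(p)] <- 1
  pmax(pmin(p, 1), 0)
}

#' Per-marker sex-prediction p-values
#'
#' Fits up to three two-predictor logistic regressions of sex on
#' (X, Y), (R, Theta) and (BAF, LRR), where R = X + Y and
#' Theta = (2/pi) atan2(Y, X), and returns the per-coefficient two-sided
#' Wald p-values (six when raw intensities are available, two otherwise).
#' A marker that hybridizes to a sex chromosome separates the sexes in at
#' least one of these planes, driving a p-value below the genome-wide
#' threshold; perfect separation returns a 0 sentinel.
#'
#' @param x,y raw intensities (may be `NULL`).
#' @param baf,lrr signal vectors.
#' @param sex character vector, `"male"`/`"female"`; both sexes required.
#' @return named numeric vector of p-values.
#' @export
sex_model_pvalues <- function(x, y, baf, lrr, sex) {
  assert_that(length(unique(sex[!is.na(sex)])) == 2,
              "both sexes required to fit sex-prediction models")
  ybin <- as.integer(sex == "male")
  assert_that(min(table(ybin)) >= 10,
              "need >= 10 samples of each sex")
  out <- c()
  if (!is.null(x) && !is.null(y)) {
    p_xy <- logit_two_var_p(x, y, ybin)
    r <- x + y
    theta <- (2 / pi) * atan2(y, x)
    p_rt <- logit_two_var_p(r, theta, ybin)
    out <- c(p_x = p_xy[1], p_y = p_xy[2], p_r = p_rt[1], p_theta = p_rt[2])
  }
  p_bl <- logit_two_var_p(baf, lrr, ybin)
  c(out, p_baf = p_bl[1], p_lrr = p_bl[2])
}

#' Scan a panel for sex-cross-hybridizing markers
#'
#' Runs [sex_model_pvalues()] at every non-unstable marker and removes those
#' whose minimum p-value falls below the Bonferroni-style genome-wide
#' threshold 0.05 / (n_markers x n_variables), recomputed from the panel at
#' hand (6 variables with raw X/Y available, 2 otherwise). With 370,404
#' markers and 6 variables this reproduces the canonical 2.2e-8 cut.
#'
#' @param panel an `intensity_panel` with sample sex labels.
#' @param threshold removal threshold; `NULL` (default) recomputes
#'   0.05 / (n_markers x n_variables).
#' @return tibble with per-model p-values, `min_p` and `removed` per marker.
#' @export
gender_linked_scan <- function(panel, threshold = NULL) {
  map <- panel$markers
  idx <- which(!map$unstable_region)
  has_xy <- !is.null(panel$x) && !is.null(panel$y)
  n_var <- if (has_xy) 6L else 2L
  if (!has_xy) {
    inform("raw X/Y absent: only the (BAF, LRR) model runs; threshold uses 2 variables")
  }
  if (is.null(threshold)) threshold <- 0.05 / (length(idx) * n_var)
  sex <- panel$samples$sex
  ybin <- as.integer(sex == "male")
  assert_that(length(unique(ybin)) == 2 && min(table(ybin)) >= 10,
              "need >= 10 samples of each sex")
  pm <- matrix(NA_real_, length(idx), n_var)
  colnames(pm) <- if (has_xy) {
    c("p_x", "p_y", "p_r", "p_theta", "p_baf", "p_lrr")
  } else {
    c("p_baf", "p_lrr")
  }
  for (k in seq_along(idx)) {
    m <- idx[k]
    if (has_xy) {
      xv <- panel$x[, m]; yv <- panel$y[, m]
      pm[k, 1:2] <- logit_two_var_p(xv, yv, ybin)
      pm[k, 3:4] <- logit_two_var_p(xv + yv, (2 / pi) * atan2(yv, xv), ybin)
      pm[k, 5:6] <- logit_two_var_p(panel$baf[, m], panel$lrr[, m], ybin)
    } else {
      pm[k, ] <- logit_two_var_p(panel$baf[, m], panel$lrr[, m], ybin)
    }
  }
  out <- dplyr::bind_cols(tibble::tibble(marker_id = map$marker_id[idx]),
                          tibble::as_tibble(pm))
  out$min_p <- apply(pm, 1, min)
  out$removed <- out$min_p < threshold
  attr(out, "threshold") <- threshold
  attr(out, "n_variables") <- n_var
  out
}

#' Apply marker exclusions
#'
#' Removes unstable-region and gender-linked markers from the map; the final
#' map is what CNV calling should see.
#'
#' @param marker_map marker map tibble.
#' @param gender_results result of [gender_linked_scan()] (may be `NULL`).
#' @return filtered marker map with `gender_linked` flags set.
#' @export
apply_marker_exclusions <- function(marker_map, gender_results = NULL) {
  if (!is.null(gender_results)) {
    removed_ids <- gender_results$marker_id[gender_results$removed]
    marker_map$gender_linked <- marker_map$marker_id %in% removed_ids
  }
  out <- marker_map %>%
    dplyr::filter(!.data$unstable_region, !.data$gender_linked)
  assert_that(nrow(out) > 0, "all markers excluded; downstream refuses empty map")
  out
}

#' Marker exclusion accounting
#'
#' One-row tibble of initial/unstable/gender-linked/final marker counts and
#' exclusion percentages.
#'
#' @param marker_map the pre-exclusion marker map (flags set).
#' @param gender_results result of [gender_linked_scan()] (may be `NULL`).
#' @return one-row tibble.
#' @export
marker_accounting <- function(marker_map, gender_results = NULL) {
  n0 <- nrow(marker_map)
  n_unstable <- sum(marker_map$unstable_region)
  removed_ids <- if (is.null(gender_results)) character(0) else
    gender_results$marker_id[gender_results$removed]
  n_gender <- sum(marker_map$marker_id %in% removed_ids &
                    !marker_map$unstable_region)
  tibble::tibble(
    initial = n0,
    unstable = n_unstable,
    gender_linked = n_gender,
    final = n0 - n_unstable - n_gender,
    pct_unstable = 100 * n_unstable / n0,
    pct_gender_linked = 100 * n_gender / n0
  )
}
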