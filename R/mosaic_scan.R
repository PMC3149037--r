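#' Mid-band BAF statistics for one chromosomal arm
#'
#' A germline deletion shows B-allele frequencies only near 0 and 1; a
#' mosaic event moves heterozygote BAF off 0.5 into split bands, inflating
#' the dispersion of the mid-band values. This computes the screening
#' statistics over BAF values strictly inside (0.15, 0.85).
#'
#' @param baf numeric BAF vector for one sample-arm.
#' @param min_mid minimum number of mid-band values for defined statistics.
#' @return one-row tibble with `n_mid`, `baf_sd`, `baf_iqr`.
#' @export
arm_baf_stats <- function(baf, min_mid = 30) {
  mid <- baf[!is.na(baf) & baf > 0.15 & baf < 0.85]
  if (length(mid) < min_mid) {
    return(tibble::tibble(n_mid = length(mid), baf_sd = NA_real_,
                          baf_iqr = NA_real_))
  }
  tibble::tibble(n_mid = length(mid), baf_sd = sd(mid),
                 baf_iqr = unname(diff(quantile(mid, c(0.25, 0.75)))))
}

#' Flag outlier arms by robust z-score
#'
#' An arm is flagged when the robust z-score (median/MAD scaling across all
#' sample-arms) of either its mid-band BAF standard deviation or its IQR
#' exceeds `z_threshold`. A degenerate MAD falls back to `mad_floor`.
#'
#' @param stats tibble with `baf_sd`, `baf_iqr` (from [mosaic_scan()]).
#' @param z_threshold robust z cut (default 6).
#' @param mad_floor lower bound on the MAD scale.
#' @return logical vector of flags (NA statistics are never flagged).
#' @export
flag_outlier_arms <- function(stats, z_threshold = 6, mad_floor = 0.005) {
  ok <- !is.na(stats$baf_sd)
  assert_that(sum(ok) >= 50, "need >= 50 arm records for robust scaling")
  rz <- function(x) {
    m <- median(x, na.rm = TRUE)
    s <- max(mad(x, na.rm = TRUE), mad_floor)
    (x - m) / s
  }
  flag <- rz(stats$baf_sd) > z_threshold | rz(stats$baf_iqr) > z_threshold
  flag & ok
}

#' Estimate mosaic direction and cell fraction from band geometry
#'
#' Splits the mid-band BAF values at 0.5 and measures the band separation
#' `d = mean(upper) - mean(lower)`. For a mosaic loss the heterozygote bands
#' sit at (1-f)/(2-f) and 1/(2-f), so f = 2d/(1+d); for a gain the bands are
#' 1/(2+f) and (1+f)/(2+f), so f = 2d/(1-d). Direction is taken from the
#' arm's mean LRR (loss when negative).
#'
#' @param baf BAF values for the arm.
#' @param mean_lrr the arm's mean LRR.
#' @param min_mid minimum mid-band count.
#' @return one-row tibble with `direction`, `d`, `est_fraction` (NA when the
#'   mid-band is one-sided or too sparse).
#' @export
estimate_mosaic_fraction <- function(baf, mean_lrr, min_mid = 30) {
  mid <- baf[!is.na(baf) & baf > 0.15 & baf < 0.85]
  lower <- mid[mid < 0.5]
  upper <- mid[mid > 0.5]
  if (length(mid) >= min_mid && length(lower) == 0 && length(upper) == 0) {
    # every mid-band value sits exactly on 0.5: coincident bands, d = 0
    lower <- upper <- 0.5
  }
  if (length(mid) < min_mid || length(lower) == 0 || length(upper) == 0) {
    return(tibble::tibble(direction = NA_character_, d = NA_real_,
                          est_fraction = NA_real_))
  }
  d <- mean(upper) - mean(lower)
  direction <- if (mean_lrr < 0) "loss" else "gain"
  f <- if (direction == "loss") 2 * d / (1 + d) else 2 * d / (1 - d)
  tibble::tibble(direction = direction, d = d,
                 est_fraction = clamp(f, 0, 1))
}

# count distinct band-shift segments along an arm: runs of heterozygote
# markers whose displacement from 0.5 exceeds `shift_cut`, smoothed over
# windows of `window` mid-band markers
count_shift_segments <- function(baf, shift_cut = 0.1, window = 15,
                                 run_frac = 0.6) {
  mid_idx <- which(!is.na(baf) & baf > 0.15 & baf < 0.85)
  if (length(mid_idx) < 2 * window) return(0L)
  shifted <- abs(baf[mid_idx] - 0.5) > shift_cut
  k <- length(shifted) - window + 1
  roll <- vapply(seq_len(k), function(i)
    mean(shifted[i:(i + window - 1)]), numeric(1))
  # a new segment opens only after a confidently unshifted stretch of at
  # least one window; ambiguous windows neither extend nor separate
  cold_cut <- 0.2
  seg <- 0L
  cold_count <- window
  for (i in seq_len(k)) {
    if (roll[i] > run_frac) {
      if (cold_count >= window) seg <- seg + 1L
      cold_count <- 0L
    } else if (roll[i] < cold_cut) {
      cold_count <- cold_count + 1L
    }
  }
  seg
}

#' Scan a panel for whole-chromosomal-arm mosaicism
#'
#' Computes [arm_baf_stats()] for every sample-arm, flags outliers
#' ([flag_outlier_arms()]), estimates direction and cell fraction for the
#' flagged arms ([estimate_mosaic_fraction()]), classifies them and applies
#' the exclusion policy against an optional callset
#' ([classify_mosaic_arms()]).
#'
#' @param panel an `intensity_panel`.
#' @param callset optional callset tibble used to classify flagged arms.
#' @param z_threshold,mad_floor see [flag_outlier_arms()].
#' @param min_mid minimum mid-band values per arm.
#' @param coverage_frac arm-coverage fraction above which a flagged arm
#'   counts as "mosaic called as CNV" and is excluded.
#' @param lrr_sd_cut per-arm LRR sd above which a flagged arm is "noisy".
#' @param faint_cut estimated fraction below which a flagged arm is "faint".
#' @return tibble of per-arm records (class `mosaic_scan`).
#' @export
mosaic_scan <- function(panel, callset = NULL, z_threshold = 6,
                        mad_floor = 0.005, min_mid = 30,
                        coverage_frac = 0.5, lrr_sd_cut = 0.35,
                        faint_cut = 0.15) {
  map <- panel$markers
  # allelic statistics use SNP-class markers only; monomorphic copy-number
  # probes carry no genotype signal in BAF
  arms <- map %>%
    dplyr::mutate(.idx = dplyr::row_number()) %>%
    dplyr::filter(.data$probe_class == "snp") %>%
    dplyr::group_by(.data$chrom, .data$arm) %>%
    dplyr::summarise(idx = list(.data$.idx),
                     arm_start = min(.data$pos), arm_end = max(.data$pos),
                     .groups = "drop")
  recs <- purrr::map(seq_len(nrow(panel$samples)), function(i) {
    sid <- panel$samples$sample_id[i]
    purrr::map(seq_len(nrow(arms)), function(a) {
      idx <- arms$idx[[a]]
      baf <- panel$baf[i, idx]
      lrr <- panel$lrr[i, idx]
      st <- arm_baf_stats(baf, min_mid)
      dplyr::bind_cols(
        tibble::tibble(sample_id = sid, chrom = arms$chrom[a],
                       arm = arms$arm[a], arm_start = arms$arm_start[a],
                       arm_end = arms$arm_end[a],
                       mean_lrr = mean(lrr, na.rm = TRUE),
                       lrr_sd = sd(lrr, na.rm = TRUE),
                       n_shift_segments = count_shift_segments(baf)),
        st)
    }) %>% dplyr::bind_rows()
  })
  stats <- dplyr::bind_rows(recs)
  stats$outlier <- flag_outlier_arms(stats, z_threshold, mad_floor)
  est <- purrr::map(seq_len(nrow(stats)), function(r) {
    if (!stats$outlier[r]) {
      return(tibble::tibble(direction = NA_character_, d = NA_real_,
                            est_fraction = NA_real_))
    }
    i <- match(stats$sample_id[r], panel$samples$sample_id)
    a <- which(arms$chrom == stats$chrom[r] & arms$arm == stats$arm[r])
    estimate_mosaic_fraction(panel$baf[i, arms$idx[[a]]], stats$mean_lrr[r],
                             min_mid)
  }) %>% dplyr::bind_rows()
  stats <- dplyr::bind_cols(stats, est)
  out <- classify_mosaic_arms(stats, callset, coverage_frac, lrr_sd_cut,
                              faint_cut)
  class(out) <- c("mosaic_scan", class(out))
  out
}

#' Classify flagged arms and apply the exclusion policy
#'
#' Flagged arms overlapped over `coverage_frac` of their span by CNV calls
#' are classified `mosaic_called_cnv` and excluded (their calls must be
#' dropped downstream, see [mask_excluded_arms()]); arms with two or more
#' distinct band-shift segments are `multi_event` and excluded; noisy arms
#' (high LRR sd) are `noisy`; faint band splitting is `faint`; remaining
#' flagged arms are `mosaic_uncalled` and retained. Unflagged arms are
#' `normal`; arms with too few mid-band values are `unknown`.
#'
#' @param stats per-arm tibble from [mosaic_scan()].
#' @param callset optional callset tibble.
#' @param coverage_frac,lrr_sd_cut,faint_cut see [mosaic_scan()].
#' @return `stats` with `arm_class` and `excluded` columns.
#' @export
classify_mosaic_arms <- function(stats, callset = NULL, coverage_frac = 0.5,
                                 lrr_sd_cut = 0.35, faint_cut = 0.15) {
  cov <- rep(0, nrow(stats))
  if (!is.null(callset) && nrow(callset) > 0) {
    for (r in which(stats$outlier)) {
      cs <- callset[callset$sample_id == stats$sample_id[r] &
                      callset$chrom == stats$chrom[r], , drop = FALSE]
      if (nrow(cs) == 0) next
      ov <- interval_overlap(cs$start, cs$end,
                             stats$arm_start[r], stats$arm_end[r])
      cov[r] <- sum(ov) / (stats$arm_end[r] - stats$arm_start[r] + 1)
    }
  }
  cls <- rep("normal", nrow(stats))
  cls[is.na(stats$baf_sd)] <- "unknown"
  fl <- which(stats$outlier)
  for (r in fl) {
    cls[r] <- if (stats$lrr_sd[r] > lrr_sd_cut) {
      "noisy"
    } else if (is.na(stats$est_fraction[r])) {
      "unknown"
    } else if (stats$n_shift_segments[r] >= 2) {
      "multi_event"
    } else if (cov[r] >= coverage_frac) {
      "mosaic_called_cnv"
    } else if (stats$est_fraction[r] < faint_cut) {
      "faint"
    } else {
      "mosaic_uncalled"
    }
  }
  stats$call_coverage <- cov
  stats$arm_class <- cls
  stats$excluded <- cls %in% c("mosaic_called_cnv", "multi_event")
  stats
}

#' Drop CNV calls on excluded mosaic arms
#'
#' Removes every call that overlaps a sample-arm excluded by the mosaic
#' screen, so excluded arms contribute nothing to filtering or association.
#'
#' @param callset callset tibble.
#' @param mosaic_stats result of [mosaic_scan()].
#' @return filtered callset.
#' @export
mask_excluded_arms <- function(callset, mosaic_stats) {
  ex <- mosaic_stats[mosaic_stats$excluded, , drop = FALSE]
  if (nrow(ex) == 0 || nrow(callset) == 0) return(callset)
  drop <- rep(FALSE, nrow(callset))
  for (r in seq_len(nrow(ex))) {
    drop <- drop | (callset$sample_id == ex$sample_id[r] &
                      callset$chrom == ex$chrom[r] &
                      interval_overlap(callset$start, callset$end,
                                       ex$arm_start[r], ex$arm_end[r]) > 0)
  }
  callset[!drop, , drop = FALSE]
}

#' Excluded mosaic arms as an association mask
#'
#' @param mosaic_stats result of [mosaic_scan()].
#' @return tibble (sample_id, chrom, arm_start, arm_end) of excluded arms.
#' @export
excluded_arms <- function(mosaic_stats) {
  mosaic_stats %>%
    dplyr::filter(.data$excluded) %>%
    dplyr::select("sample_id", "chrom", "arm", "arm_start", "arm_end")
}
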