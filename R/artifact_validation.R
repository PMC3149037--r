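#' Low-MAF loss-of-heterozygosity diagnostic for a deletion candidate
#'
#' A run of SNPs whose minor alleles all ride one rare haplotype produces
#' long homozygous stretches (BAF only near 0/1) in non-carriers of the
#' haplotype -- a pattern a BAF-aware caller can misread as a deletion. The
#' diagnostic selects the low-MAF, tight-LD SNP panel inside the region,
#' estimates the frequency of the all-minor-allele haplotype separately in
#' call carriers and non-carriers with a two-class EM on unphased
#' genotypes, and flags the locus when carriers show a haplotype frequency
#' of (essentially) zero and no heterozygotes while the rest of the sample
#' carries the haplotype at an appreciable frequency.
#'
#' @param genotypes samples x markers integer matrix of B-allele counts
#'   (dimnames required), e.g. `panel$genotypes`.
#' @param marker_map marker map tibble.
#' @param region list with `chrom`, `start`, `end` (1-based inclusive).
#' @param carrier_ids sample ids with a deletion call over the region.
#' @param maf_cut minor-allele-frequency ceiling for panel SNPs.
#' @param r2_cut composite (genotype-correlation) r-squared floor for the
#'   tight-LD panel.
#' @param freq_floor minimum non-carrier haplotype frequency for a flag.
#' @return object of class `loh_diagnostic` (list): `snp_ids`,
#'   `hap_freq_carriers`, `hap_freq_noncarriers`, per-group het rates,
#'   `flag`, and `defined` (FALSE when no qualifying panel exists).
#' @export
loh_check <- function(genotypes, marker_map, region, carrier_ids,
                      maf_cut = 0.05, r2_cut = 0.75, freq_floor = 0.01) {
  region <- as.list(region)
  in_region <- marker_map$chrom == region$chrom &
    marker_map$pos >= region$start & marker_map$pos <= region$end &
    marker_map$probe_class == "snp"
  ids <- marker_map$marker_id[in_region]
  ids <- intersect(ids, colnames(genotypes))
  g <- genotypes[, ids, drop = FALSE]
  keep <- colSums(!is.na(g)) > 0
  g <- g[, keep, drop = FALSE]
  undefined <- function(reason) {
    structure(list(snp_ids = character(0), hap_freq_carriers = NA_real_,
                   hap_freq_noncarriers = NA_real_,
                   het_rate_carriers = NA_real_,
                   het_rate_noncarriers = NA_real_,
                   flag = FALSE, defined = FALSE, reason = reason),
              class = "loh_diagnostic")
  }
  if (ncol(g) < 3) return(undefined("fewer than 3 genotyped SNPs in region"))
  # orient to minor allele and select low-MAF SNPs
  freq <- colMeans(g, na.rm = TRUE) / 2
  flip <- freq > 0.5
  g[, flip] <- 2L - g[, flip]
  maf <- pmin(freq, 1 - freq)
  g <- g[, maf < maf_cut & maf > 0, drop = FALSE]
  if (ncol(g) < 3) return(undefined("fewer than 3 low-MAF SNPs"))
  # tight-LD panel: keep SNPs whose mean pairwise r^2 with the other
  # candidates clears the cut (composite r^2 from genotype correlation)
  r2 <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))^2
  diag(r2) <- NA
  mean_r2 <- rowMeans(r2, na.rm = TRUE)
  g <- g[, !is.na(mean_r2) & mean_r2 > r2_cut, drop = FALSE]
  if (ncol(g) < 3) return(undefined("no tight-LD panel at the r2 cut"))

  is_carrier <- rownames(g) %in% carrier_ids
  q_carr <- loh_em_hap_freq(g[is_carrier, , drop = FALSE])
  q_non <- loh_em_hap_freq(g[!is_carrier, , drop = FALSE])
  het_carr <- mean(g[is_carrier, ] == 1L, na.rm = TRUE)
  het_non <- mean(g[!is_carrier, ] == 1L, na.rm = TRUE)
  flag <- isTRUE(q_carr < 0.005) && isTRUE(q_non > freq_floor) &&
    isTRUE(het_carr == 0 | is.nan(het_carr))
  structure(list(snp_ids = colnames(g),
                 hap_freq_carriers = q_carr,
                 hap_freq_noncarriers = q_non,
                 het_rate_carriers = het_carr,
                 het_rate_noncarriers = het_non,
                 flag = flag, defined = TRUE, reason = NA_character_),
            class = "loh_diagnostic")
}

# two-haplotype-class EM on unphased minor-allele counts: each haplotype is
# either H (minor allele at every panel SNP) with frequency q, or "other"
# (major alleles). A sample carries nH in {0,1,2} copies of H; genotypes
# match nH at every SNP up to a small error rate.
loh_em_hap_freq <- function(g, error_rate = 0.01, max_iter = 100,
                            tol = 1e-8) {
  n <- nrow(g)
  if (n == 0) return(NA_real_)
  k <- ncol(g)
  loglik_nh <- function(nh) {
    rowSums(log(ifelse(g == nh, 1 - error_rate, error_rate / 2)), na.rm = TRUE)
  }
  ll <- cbind(loglik_nh(0L), loglik_nh(1L), loglik_nh(2L))
  q <- 0.05
  for (it in seq_len(max_iter)) {
    prior <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    lp <- sweep(ll, 2, log(pmax(prior, 1e-300)), `+`)
    lp <- lp - apply(lp, 1, max)
    post <- exp(lp)
    post <- post / rowSums(post)
    q_new <- sum(post %*% c(0, 1, 2)) / (2 * n)
    if (abs(q_new - q) < tol) {
      q <- q_new
      break
    }
    q <- q_new
  }
  q
}

#' @export
print.loh_diagnostic <- function(x, ...) {
  cat("<loh_diagnostic>",
      if (!x$defined) paste0(" undefined (", x$reason, ")\n") else sprintf(
        " %d panel SNPs; hap freq carriers %.3f vs non-carriers %.3f; flag = %s\n",
        length(x$snp_ids), x$hap_freq_carriers, x$hap_freq_noncarriers,
        x$flag))
  invisible(x)
}

#' VNTR / DNA-source diagnostic for a candidate locus
#'
#' Checks whether calls at a monomorphic probe group behave like a tandem
#' repeat confounded with DNA source rather than a genuine CNV: (i) an
#' exact test of call-carrier status against DNA source; (ii) a re-call of
#' the chromosome with the probe group masked, measuring the fraction of
#' region calls that vanish; (iii) when truth repeat counts are supplied,
#' the regression slope of probe-mean LRR on summed repeat count.
#'
#' @param panel an `intensity_panel`.
#' @param callset callset tibble from [call_cnvs()] on this panel.
#' @param probe_ids marker ids of the probe group (non-empty).
#' @param params the [hmm_params()] used for `callset` (for the re-call).
#' @param repeats optional tibble (`sample_id`, `summed_repeats`).
#' @param alpha flag threshold on the source-association p-value.
#' @return object of class `vntr_diagnostic` (list): `probe_ids`,
#'   `source_assoc_p`, `recall_delta`, `lrr_repeat_slope`,
#'   `lrr_repeat_p`, `flag`.
#' @export
vntr_check <- function(panel, callset, probe_ids, params = hmm_params(),
                       repeats = NULL, alpha = 0.01) {
  assert_that(length(probe_ids) > 0, "VNTR probe group is empty")
  map <- panel$markers
  idx <- match(probe_ids, map$marker_id)
  assert_that(!anyNA(idx), "probe_ids absent from marker map")
  chrom <- unique(map$chrom[idx])
  assert_that(length(chrom) == 1, "probe group must sit on one chromosome")
  lo <- min(map$pos[idx]); hi <- max(map$pos[idx])

  region_calls <- callset[callset$chrom == chrom &
                            interval_overlap(callset$start, callset$end,
                                             lo, hi) > 0, , drop = FALSE]
  carrier <- panel$samples$sample_id %in% region_calls$sample_id

  source_p <- NA_real_
  if (length(unique(panel$samples$dna_source)) > 1) {
    tab <- table(carrier, panel$samples$dna_source)
    if (all(dim(tab) == c(2, 2))) {
      source_p <- fisher.test(tab)$p.value
    } else {
      source_p <- 1
    }
  } else {
    inform("single-source cohort: source association undefined")
  }

  # re-call the chromosome with the probe group masked
  masked <- panel
  keep <- !(map$marker_id %in% probe_ids)
  on_chrom <- map$chrom == chrom
  sub <- function(m) if (is.null(m)) NULL else m[, keep & on_chrom, drop = FALSE]
  masked$markers <- map[keep & on_chrom, , drop = FALSE]
  masked$lrr <- sub(panel$lrr)
  masked$baf <- sub(panel$baf)
  masked$x <- sub(panel$x); masked$y <- sub(panel$y)
  masked$genotypes <- sub(panel$genotypes)
  recalls <- call_cnvs(masked, params)
  after <- recalls[recalls$chrom == chrom &
                     interval_overlap(recalls$start, recalls$end,
                                      lo, hi) > 0, , drop = FALSE]
  recall_delta <- if (nrow(region_calls) == 0) 0 else
    1 - nrow(after) / nrow(region_calls)

  slope <- slope_p <- NA_real_
  if (!is.null(repeats)) {
    mean_lrr <- rowMeans(panel$lrr[, idx, drop = FALSE])
    d <- dplyr::left_join(tibble::tibble(sample_id = panel$samples$sample_id,
                                         mean_lrr = mean_lrr),
                          repeats, by = "sample_id")
    fit <- stats::lm(mean_lrr ~ summed_repeats, data = d)
    cf <- summary(fit)$coefficients
    slope <- cf["summed_repeats", "Estimate"]
    slope_p <- cf["summed_repeats", "Pr(>|t|)"]
  }
  structure(list(probe_ids = probe_ids, source_assoc_p = source_p,
                 recall_delta = recall_delta,
                 n_region_calls = nrow(region_calls),
                 n_region_calls_masked = nrow(after),
                 lrr_repeat_slope = slope, lrr_repeat_p = slope_p,
                 flag = isTRUE(source_p < alpha)),
            class = "vntr_diagnostic")
}

#' @export
print.vntr_diagnostic <- function(x, ...) {
  cat("<vntr_diagnostic> ", length(x$probe_ids), " probes; source p = ",
      format(x$source_assoc_p, digits = 3), "; recall delta = ",
      format(x$recall_delta, digits = 3), "; flag = ", x$flag, "\n", sep = "")
  invisible(x)
}
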