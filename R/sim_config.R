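#' Simulation configuration
#'
#' Builds the configuration object consumed by [build_marker_map()] and
#' [simulate_cohort()]. Defaults describe a desk-scale cohort with the signal
#' structure of an Illumina-style genotyping array: per-sample LRR noise,
#' Hardy-Weinberg genotypes with marker-specific B-allele frequencies,
#' intensity-only copy-number probes carrying the monomorphic PFB sentinel
#' (value 2), implanted germline CNVs, mosaic chromosomal arms, and the three
#' optional artifact structures (sex-cross-hybridizing markers, a VNTR probe
#' group whose signal tracks repeat length and DNA source, and a low-MAF
#' tight-LD SNP block that mimics loss of heterozygosity).
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param n_markers markers per chromosome (recycled over chromosomes).
#' @param centromere_frac position of the p/q boundary as a fraction of the
#'   chromosome length.
#' @param cnv_probe_frac fraction of markers that are intensity-only
#'   copy-number probes (PFB sentinel 2).
#' @param unstable_end_markers markers at each arm end flagged as unstable
#'   (telomere/centromere windows).
#' @param n_cases,n_controls cohort sizes. In the default design every case
#'   has DNA from whole blood and every control from a lymphoblast cell line,
#'   the confounded layout the artifact diagnostics are built to expose.
#' @param lrr_sd per-sample LRR noise standard deviation.
#' @param lrr_sd_cell_line extra LRR sd for cell-line samples (additive;
#'   default 0 = no global source effect).
#' @param baf_sd BAF cluster standard deviation around genotype means.
#' @param lrr_means LRR emission means for copy numbers 0..4.
#' @param n_cnvs_per_sample expected germline CNV count per sample (Poisson).
#' @param cnv_size_markers integer range of CNV sizes in markers.
#' @param cn_probs probabilities of copy numbers 0, 1, 3, 4 for a drawn CNV.
#' @param n_mosaic_arms total number of mosaic sample-arms implanted.
#' @param mosaic_fraction_range range of mosaic cell fractions.
#' @param mosaic_gain_prob probability a mosaic event is a gain.
#' @param implant_cnvs optional tibble (sample_id, chrom, start, end, cn) of
#'   CNVs to implant deterministically, in addition to random draws.
#' @param implant_mosaics optional tibble (sample_id, chrom, arm, direction,
#'   fraction) of mosaic arms to implant deterministically.
#' @param with_xy synthesize raw X/Y intensities (needed by the X/Y and
#'   R/Theta sex-prediction models).
#' @param gender_linked list(n_b, n_c, n_d): number of markers overwritten
#'   with each sex-cross-hybridization pattern. Pattern B: complete
#'   co-hybridization (females heterozygous-like, males homozygous-like);
#'   pattern C: monomorphic probe separating sexes in raw intensity with
#'   equal mean LRR; pattern D: polymorphic probe with sex-separated
#'   clusters in BAF/LRR space.
#' @param vntr list(enabled, n_probes, slope, source_shift, ref_repeats,
#'   repeat_range, probe_noise_sd): monomorphic probe group tagging a VNTR.
#'   Per-sample LRR at these probes is
#'   `slope * (summed_repeats - 2*ref_repeats)/(2*ref_repeats) +
#'   source_shift * [cell line] + noise`; allele repeat counts are drawn
#'   uniformly from `repeat_range`, independent of phenotype.
#' @param loh list(enabled, k, hap_freq, assumed_pfb, source_lrr_shift):
#'   block of `k` SNPs whose minor alleles ride a single haplotype of
#'   frequency `hap_freq`; the marker map reports `assumed_pfb` for these
#'   SNPs (the default-frequency placeholder a manifest assigns to SNPs
#'   absent from its reference panel, which makes homozygous runs look like
#'   deletions to a BAF-aware caller). `source_lrr_shift` is a mild LRR
#'   depression applied to blood-derived samples over the block, emulating
#'   the source-linked intensity dip such loci show.
#' @param seed integer master seed; fixes the full output bit-for-bit.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(chrom_lengths = c(`1` = 25e6, `2` = 25e6),
                       n_markers = 1500,
                       centromere_frac = 0.4,
                       cnv_probe_frac = 0.06,
                       unstable_end_markers = 2,
                       n_cases = 100,
                       n_controls = 100,
                       lrr_sd = 0.15,
                       lrr_sd_cell_line = 0,
                       baf_sd = 0.03,
                       lrr_means = c(-3.5, -0.66, 0, 0.40, 0.68),
                       n_cnvs_per_sample = 0,
                       cnv_size_markers = c(10, 50),
                       cn_probs = c(`0` = 0.05, `1` = 0.55, `3` = 0.35, `4` = 0.05),
                       n_mosaic_arms = 0,
                       mosaic_fraction_range = c(0.2, 0.8),
                       mosaic_gain_prob = 0.3,
                       implant_cnvs = NULL,
                       implant_mosaics = NULL,
                       with_xy = FALSE,
                       gender_linked = list(n_b = 0, n_c = 0, n_d = 0),
                       vntr = list(enabled = FALSE, n_probes = 6, slope = 2.5,
                                   source_shift = 0.5, ref_repeats = 28,
                                   repeat_range = c(20, 36),
                                   probe_noise_sd = 0.1),
                       loh = list(enabled = FALSE, k = 9, hap_freq = 0.041,
                                  assumed_pfb = 0.5, source_lrr_shift = -0.42),
                       seed = 1L) {
  assert_that(length(chrom_lengths) >= 1 && all(chrom_lengths > 0),
              "chrom_lengths must be positive")
  assert_that(!is.null(names(chrom_lengths)) && !anyDuplicated(names(chrom_lengths)),
              "chrom_lengths must have unique names")
  n_markers <- rep_len(as.integer(n_markers), length(chrom_lengths))
  assert_that(all(n_markers > 0), "zero markers on a declared chromosome")
  assert_that(all(n_markers <= chrom_lengths),
              "more markers than base pairs on a chromosome")
  assert_that(n_cases >= 0 && n_controls >= 0, "cohort sizes must be >= 0")
  assert_that(length(lrr_means) == 5 && all(diff(lrr_means) > 0),
              "lrr_means must be 5 strictly increasing values for CN 0..4")
  assert_that(baf_sd > 0 && lrr_sd > 0, "noise sds must be positive")
  assert_that(centromere_frac > 0 && centromere_frac < 1,
              "centromere_frac must lie in (0,1)")
  assert_that(abs(sum(cn_probs) - 1) < 1e-8, "cn_probs must sum to 1")

  gl_default <- list(n_b = 0, n_c = 0, n_d = 0)
  gender_linked <- utils::modifyList(gl_default, gender_linked)
  vntr_default <- list(enabled = FALSE, n_probes = 6, slope = 2.5,
                       source_shift = 0.5, ref_repeats = 28,
                       repeat_range = c(20, 36), probe_noise_sd = 0.1)
  vntr <- utils::modifyList(vntr_default, vntr)
  loh_default <- list(enabled = FALSE, k = 9, hap_freq = 0.041,
                      assumed_pfb = 0.5, source_lrr_shift = -0.42)
  loh <- utils::modifyList(loh_default, loh)
  assert_that(loh$hap_freq >= 0 && loh$hap_freq <= 1,
              "loh hap_freq must lie in [0,1]")

  structure(list(
    chrom_lengths = chrom_lengths, n_markers = n_markers,
    centromere_frac = centromere_frac, cnv_probe_frac = cnv_probe_frac,
    unstable_end_markers = as.integer(unstable_end_markers),
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    lrr_sd = lrr_sd, lrr_sd_cell_line = lrr_sd_cell_line, baf_sd = baf_sd,
    lrr_means = lrr_means, n_cnvs_per_sample = n_cnvs_per_sample,
    cnv_size_markers = as.integer(cnv_size_markers), cn_probs = cn_probs,
    n_mosaic_arms = as.integer(n_mosaic_arms),
    mosaic_fraction_range = mosaic_fraction_range,
    mosaic_gain_prob = mosaic_gain_prob,
    implant_cnvs = implant_cnvs, implant_mosaics = implant_mosaics,
    with_xy = isTRUE(with_xy), gender_linked = gender_linked,
    vntr = vntr, loh = loh, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  chromosomes:", length(x$chrom_lengths),
      " markers:", sum(x$n_markers), "\n")
  cat("  cohort:", x$n_cases, "cases /", x$n_controls, "controls\n")
  cat("  noise: lrr_sd", x$lrr_sd, " baf_sd", x$baf_sd, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
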