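#' Build a synthetic marker map
#'
#' Draws an ordered array manifest from a [sim_config()]: strictly increasing
#' positions per chromosome, p/q arm assignment at the configured centromere
#' fraction, a configured share of intensity-only copy-number probes (PFB
#' sentinel 2), SNP population B-allele frequencies, and unstable-region
#' flags at the arm ends.
#'
#' @param config a [sim_config()] object.
#' @return tibble with columns `marker_id`, `chrom`, `arm`, `pos`,
#'   `probe_class`, `pfb`, `unstable_region`, `gender_linked`.
#' @export
build_marker_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 1L), {
    maps <- purrr::map2(names(config$chrom_lengths),
                        seq_along(config$chrom_lengths), function(chr, i) {
      len <- config$chrom_lengths[[i]]
      n <- config$n_markers[[i]]
      pos <- sort(sample.int(len, n, replace = FALSE))
      centro <- round(len * config$centromere_frac)
      arm <- ifelse(pos <= centro, "p", "q")
      is_cnv <- runif(n) < config$cnv_probe_frac
      pfb <- ifelse(is_cnv, 2, round(runif(n, 0.05, 0.95), 4))
      tibble::tibble(
        marker_id = sprintf("chr%s_m%05d", chr, seq_len(n)),
        chrom = chr, arm = arm, pos = pos,
        probe_class = ifelse(is_cnv, "cnv_probe", "snp"),
        pfb = pfb, unstable_region = FALSE, gender_linked = FALSE
      )
    })
    map <- dplyr::bind_rows(maps)
    k <- config$unstable_end_markers
    if (k > 0) {
      map <- map %>%
        dplyr::group_by(.data$chrom, .data$arm) %>%
        dplyr::mutate(unstable_region = dplyr::row_number() <= k |
                        dplyr::row_number() > dplyr::n() - k) %>%
        dplyr::ungroup()
    }
    map
  })
}

# polar intensity synthesis: R = X + Y on a unit expected scale encodes
# LRR, Theta = (2/pi) atan2(Y, X) encodes the allelic ratio
synth_xy <- function(lrr, baf, theta_sd = 0.01) {
  r <- 2^lrr
  theta <- clamp(baf + rnorm(length(baf), 0, theta_sd), 0, 1)
  a <- tan(theta * pi / 2)
  x <- r / (1 + a)
  x[theta >= 1 - 1e-9] <- 0
  y <- r - x
  list(x = x, y = y)
}

new_intensity_panel <- function(markers, samples, lrr, baf,
                                x = NULL, y = NULL, genotypes = NULL) {
  stopifnot(nrow(lrr) == nrow(samples), ncol(lrr) == nrow(markers),
            all(dim(baf) == dim(lrr)))
  dn <- list(samples$sample_id, markers$marker_id)
  dimnames(lrr) <- dn
  dimnames(baf) <- dn
  if (!is.null(x)) dimnames(x) <- dn
  if (!is.null(y)) dimnames(y) <- dn
  if (!is.null(genotypes)) dimnames(genotypes) <- dn
  structure(list(markers = markers, samples = samples, lrr = lrr, baf = baf,
                 x = x, y = y, genotypes = genotypes),
            class = "intensity_panel")
}

#' @export
print.intensity_panel <- function(x, ...) {
  cat("<intensity_panel> ", nrow(x$samples), " samples x ",
      nrow(x$markers), " markers\n", sep = "")
  cat("  chromosomes:", paste(unique(x$markers$chrom), collapse = ", "), "\n")
  cat("  assays: lrr, baf",
      if (!is.null(x$x)) ", x, y" else "",
      if (!is.null(x$genotypes)) ", genotypes" else "", "\n", sep = "")
  invisible(x)
}

# sample table construction; sexes drawn from the master stream so the
# per-sample emission streams stay independent of cohort composition
make_sample_table <- function(config) {
  n <- config$n_cases + config$n_controls
  ids <- sprintf("S%04d", seq_len(n))
  pheno <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  tibble::tibble(
    sample_id = ids,
    sex = with_seed(child_seed(config$seed, 2L),
                    sample(c("male", "female"), n, replace = TRUE)),
    phenotype = pheno,
    dna_source = ifelse(pheno == "case", "blood", "cell_line"),
    study = ifelse(pheno == "case", "discovery", "reference")
  )
}

# random germline CNV truth draws plus validated implants
draw_truth_cnvs <- function(marker_map, samples, config) {
  by_chrom <- split(marker_map$pos, marker_map$chrom)
  chroms <- names(by_chrom)
  n_by_chrom <- vapply(by_chrom, length, integer(1))
  rand <- purrr::map(seq_len(nrow(samples)), function(i) {
    sid <- samples$sample_id[i]
    with_seed(child_seed(config$seed, 100L + i), {
      k <- rpois(1, config$n_cnvs_per_sample)
      if (k == 0) return(NULL)
      out <- vector("list", k)
      taken <- list()
      for (j in seq_len(k)) {
        for (try in 1:20) {
          chr <- sample(chroms, 1, prob = n_by_chrom)
          pos <- by_chrom[[chr]]
          size <- sample(seq(config$cnv_size_markers[1],
                             config$cnv_size_markers[2]), 1)
          if (size > length(pos)) next
          s <- sample(length(pos) - size + 1, 1)
          iv <- c(pos[s], pos[s + size - 1])
          clash <- any(vapply(taken, function(t)
            t[[1]] == chr && interval_overlap(iv[1], iv[2], t[[2]], t[[3]]) > 0,
            logical(1)))
          if (!clash) {
            taken[[length(taken) + 1]] <- list(chr, iv[1], iv[2])
            cn <- as.integer(sample(names(config$cn_probs), 1,
                                    prob = config$cn_probs))
            out[[j]] <- tibble::tibble(sample_id = sid, chrom = chr,
                                       start = iv[1], end = iv[2], cn = cn)
            break
          }
        }
      }
      dplyr::bind_rows(out)
    })
  })
  empty_cnvs <- tibble::tibble(sample_id = character(), chrom = character(),
                               start = double(), end = double(),
                               cn = integer())
  truth <- dplyr::bind_rows(empty_cnvs, rand)
  if (!is.null(config$implant_cnvs)) {
    imp <- tibble::as_tibble(config$implant_cnvs)
    assert_that(all(imp$sample_id %in% samples$sample_id),
                "implant_cnvs references unknown sample")
    assert_that(all(imp$cn %in% c(0L, 1L, 3L, 4L)),
                "implant_cnvs cn must be in {0,1,3,4}")
    covered <- purrr::pmap_lgl(imp, function(chrom, start, end, ...) {
      any(marker_map$chrom == chrom & marker_map$pos >= start &
            marker_map$pos <= end)
    })
    assert_that(all(covered), "implanted CNV interval covers no marker")
    truth <- dplyr::bind_rows(truth, imp)
  }
  if (nrow(truth) > 1) {
    # reject overlapping truth CNVs within one sample
    ov <- truth %>%
      dplyr::group_by(.data$sample_id, .data$chrom) %>%
      dplyr::arrange(.data$start, .by_group = TRUE) %>%
      dplyr::summarise(bad = any(dplyr::lead(.data$start) <= .data$end,
                                 na.rm = TRUE), .groups = "drop")
    assert_that(!any(ov$bad), "overlapping truth CNVs in one sample")
  }
  truth
}

draw_truth_mosaics <- function(marker_map, samples, config) {
  arms <- marker_map %>% dplyr::distinct(.data$chrom, .data$arm)
  rand <- NULL
  if (config$n_mosaic_arms > 0) {
    rand <- with_seed(child_seed(config$seed, 3L), {
      pick_s <- sample(samples$sample_id, config$n_mosaic_arms, replace = TRUE)
      pick_a <- arms[sample(nrow(arms), config$n_mosaic_arms, replace = TRUE), ]
      tibble::tibble(
        sample_id = pick_s, chrom = pick_a$chrom, arm = pick_a$arm,
        direction = ifelse(runif(config$n_mosaic_arms) < config$mosaic_gain_prob,
                           "gain", "loss"),
        fraction = runif(config$n_mosaic_arms,
                         config$mosaic_fraction_range[1],
                         config$mosaic_fraction_range[2])
      ) %>% dplyr::distinct(.data$sample_id, .data$chrom, .data$arm,
                            .keep_all = TRUE)
    })
  }
  empty <- tibble::tibble(sample_id = character(), chrom = character(),
                          arm = character(), direction = character(),
                          fraction = double())
  out <- dplyr::bind_rows(empty, rand, config$implant_mosaics)
  if (nrow(out) > 0) {
    assert_that(all(out$fraction > 0 & out$fraction <= 1),
                "mosaic fractions must lie in (0,1]")
  }
  out
}

#' Simulate a case-control intensity cohort
#'
#' Generates per-sample LRR/BAF (optionally raw X/Y) tracks over a marker
#' map, together with the sample table and a ground-truth annotation. The
#' emission model: at a diploid SNP the genotype is Binomial(2, pfb), BAF is
#' centred at 0, 0.5 or 1 with the configured cluster sd (clipped to [0,1])
#' and LRR is Normal(0, lrr_sd); inside a germline CNV of copy number c, LRR
#' is centred at the configured state mean and BAF at b/c for
#' b ~ Binomial(c, pfb) (uniform BAF at c = 0); on a mosaic arm with cell
#' fraction f, LRR is the linear mixture f * mu_c and heterozygote BAF moves
#' to the bands (1-f)/(2-f) and 1/(2-f) for a loss, 1/(2+f) and (1+f)/(2+f)
#' for a gain. Artifact structures from the config are injected via
#' [inject_artifacts()].
#'
#' @param marker_map from [build_marker_map()].
#' @param config the same [sim_config()].
#' @return list with `panel` (an `intensity_panel`), `samples` (tibble) and
#'   `truth` (list of tibbles: `germline_cnvs`, `mosaic_arms`,
#'   `gender_linked_markers`, `vntr`, `loh`).
#' @export
simulate_cohort <- function(marker_map, config) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(nrow(marker_map) > 0, "empty marker map")
  samples <- make_sample_table(config)
  n_s <- nrow(samples)
  n_m <- nrow(marker_map)
  truth_cnv <- draw_truth_cnvs(marker_map, samples, config)
  truth_mos <- draw_truth_mosaics(marker_map, samples, config)

  lrr <- matrix(0, n_s, n_m)
  baf <- matrix(0, n_s, n_m)
  geno <- matrix(NA_integer_, n_s, n_m)
  is_snp <- marker_map$probe_class == "snp"
  pfb <- marker_map$pfb
  mu <- config$lrr_means

  for (i in seq_len(n_s)) {
    sid <- samples$sample_id[i]
    sd_i <- config$lrr_sd +
      if (samples$dna_source[i] == "cell_line") config$lrr_sd_cell_line else 0
    with_seed(child_seed(config$seed, 1000L + i), {
      g <- integer(n_m)
      g[is_snp] <- rbinom(sum(is_snp), 2L, pfb[is_snp])
      b <- numeric(n_m)
      b[is_snp] <- g[is_snp] / 2
      b[!is_snp] <- runif(sum(!is_snp))
      l <- rnorm(n_m, 0, sd_i)
      bn <- ifelse(is_snp, rnorm(n_m, 0, config$baf_sd), 0)
      gi <- g
      gi[!is_snp] <- NA_integer_

      tc <- truth_cnv[truth_cnv$sample_id == sid, , drop = FALSE]
      if (nrow(tc) > 0) {
        for (j in seq_len(nrow(tc))) {
          idx <- which(marker_map$chrom == tc$chrom[j] &
                         marker_map$pos >= tc$start[j] &
                         marker_map$pos <= tc$end[j])
          cn <- tc$cn[j]
          l[idx] <- rnorm(length(idx), mu[cn + 1], sd_i)
          sidx <- idx[is_snp[idx]]
          if (cn == 0) {
            b[idx] <- runif(length(idx))
            bn[idx] <- 0
            gi[idx] <- NA_integer_
          } else if (length(sidx) > 0) {
            bc <- rbinom(length(sidx), cn, pfb[sidx])
            b[sidx] <- bc / cn
            gi[sidx] <- NA_integer_
          }
        }
      }

      tm <- truth_mos[truth_mos$sample_id == sid, , drop = FALSE]
      if (nrow(tm) > 0) {
        for (j in seq_len(nrow(tm))) {
          idx <- which(marker_map$chrom == tm$chrom[j] &
                         marker_map$arm == tm$arm[j])
          f <- tm$fraction[j]
          target_cn <- if (tm$direction[j] == "loss") 1L else 3L
          l[idx] <- rnorm(length(idx), f * mu[target_cn + 1], sd_i)
          het <- idx[is_snp[idx] & g[idx] == 1L]
          if (length(het) > 0) {
            lower_first <- runif(length(het)) < 0.5
            bands <- if (tm$direction[j] == "loss") {
              c((1 - f) / (2 - f), 1 / (2 - f))
            } else {
              c(1 / (2 + f), (1 + f) / (2 + f))
            }
            b[het] <- ifelse(lower_first, bands[1], bands[2])
          }
        }
      }
      lrr[i, ] <- l
      baf[i, ] <- clamp(b + bn, 0, 1)
      geno[i, ] <- gi
    })
  }

  x <- y <- NULL
  if (config$with_xy) {
    xy <- synth_xy(lrr, baf)
    x <- xy$x
    y <- xy$y
  }

  panel <- new_intensity_panel(marker_map, samples, lrr, baf, x, y, geno)
  truth <- list(germline_cnvs = truth_cnv, mosaic_arms = truth_mos,
                gender_linked_markers = tibble::tibble(marker_id = character(),
                                                       pattern = character()),
                vntr = NULL, loh = NULL)
  res <- inject_artifacts(panel, truth, config)
  list(panel = res$panel, samples = samples, truth = res$truth)
}

#' Inject artifact structures into a simulated panel
#'
#' Overwrites designated markers with the three artifact mechanisms:
#' sex-cross-hybridizing markers (patterns B, C, D), a monomorphic VNTR
#' probe group whose LRR depends on summed repeat length and DNA source, and
#' a low-MAF tight-LD SNP block producing LOH-like BAF with a mis-specified
#' manifest PFB. Called by [simulate_cohort()] when the config enables any
#' artifact; exported so panels can be re-injected under different settings.
#'
#' @param panel an `intensity_panel` (must carry sample sex labels).
#' @param truth truth list as produced by [simulate_cohort()].
#' @param config a [sim_config()].
#' @return list(panel, truth) with the injected structures recorded in truth.
#' @export
inject_artifacts <- function(panel, truth, config) {
  map <- panel$markers
  samples <- panel$samples
  n_s <- nrow(samples)
  gl <- config$gender_linked
  n_gl <- gl$n_b + gl$n_c + gl$n_d

  if (n_gl > 0) {
    with_seed(child_seed(config$seed, 4L), {
      snp_idx <- which(map$probe_class == "snp" & !map$unstable_region)
      cnv_idx <- which(map$probe_class == "cnv_probe" & !map$unstable_region)
      assert_that(length(snp_idx) >= gl$n_b + gl$n_d && length(cnv_idx) >= gl$n_c,
                  "not enough markers to host gender-linked artifacts")
      picks_b <- sample(snp_idx, gl$n_b)
      picks_d <- sample(setdiff(snp_idx, picks_b), gl$n_d)
      picks_c <- sample(cnv_idx, gl$n_c)
      male <- samples$sex == "male"

      for (m in picks_b) {
        # complete co-hybridization: females heterozygous-like, males
        # homozygous-like with the single-copy intensity drop of a
        # hemizygous X target
        panel$baf[!male, m] <- clamp(rnorm(sum(!male), 0.5, config$baf_sd), 0, 1)
        hom_b <- runif(sum(male)) < 0.5
        panel$baf[male, m] <- clamp(ifelse(hom_b, 1, 0) +
                                      rnorm(sum(male), 0, config$baf_sd), 0, 1)
        panel$lrr[male, m] <- panel$lrr[male, m] - 0.5
      }
      for (m in picks_d) {
        # partial hybridization: genotype clusters shifted/compressed by sex
        g <- rbinom(n_s, 2L, map$pfb[m])
        bafd <- ifelse(male, 0.18 + 0.64 * g / 2, g / 2)
        panel$baf[, m] <- clamp(bafd + rnorm(n_s, 0, config$baf_sd), 0, 1)
        panel$lrr[, m] <- panel$lrr[, m] + ifelse(male, 0.35, 0)
      }
      for (m in picks_c) {
        # monomorphic probe separating sexes in raw intensity, equal LRR
        if (!is.null(panel$x)) {
          r <- 2^panel$lrr[, m]
          th <- ifelse(male, 0.15, 0.85) + rnorm(n_s, 0, 0.03)
          a <- tan(clamp(th, 0, 1) * pi / 2)
          panel$x[, m] <- r / (1 + a)
          panel$y[, m] <- r - panel$x[, m]
        }
        panel$baf[, m] <- clamp(ifelse(male, 0.15, 0.85) +
                                  rnorm(n_s, 0, 0.03), 0, 1)
      }
      # re-derive raw intensities for overwritten polymorphic markers
      if (!is.null(panel$x)) {
        for (m in c(picks_b, picks_d)) {
          xy <- synth_xy(panel$lrr[, m], panel$baf[, m])
          panel$x[, m] <- xy$x
          panel$y[, m] <- xy$y
        }
      }
      truth$gender_linked_markers <- tibble::tibble(
        marker_id = map$marker_id[c(picks_b, picks_c, picks_d)],
        pattern = rep(c("B", "C", "D"), c(gl$n_b, gl$n_c, gl$n_d))
      )
    })
  }

  if (isTRUE(config$vntr$enabled)) {
    v <- config$vntr
    assert_that(v$n_probes >= 1, "VNTR artifact requested but probe set empty")
    with_seed(child_seed(config$seed, 5L), {
      # a nested probe set targets one physical locus: convert a contiguous
      # run of markers mid-chromosome into monomorphic copy-number probes
      chr1 <- map$chrom == map$chrom[1]
      cand <- which(chr1 &
                      !(map$marker_id %in% truth$gender_linked_markers$marker_id))
      assert_that(length(cand) >= v$n_probes,
                  "VNTR artifact requested but probe set empty")
      start <- cand[max(1, floor(length(cand) / 3))]
      probes <- start + seq_len(v$n_probes) - 1
      probes <- probes[probes <= nrow(map)]
      panel$markers$probe_class[probes] <- "cnv_probe"
      panel$markers$pfb[probes] <- 2
      if (!is.null(panel$genotypes)) panel$genotypes[, probes] <- NA_integer_
      a1 <- sample(seq(v$repeat_range[1], v$repeat_range[2]), n_s, replace = TRUE)
      a2 <- sample(seq(v$repeat_range[1], v$repeat_range[2]), n_s, replace = TRUE)
      summed <- a1 + a2
      shift <- ifelse(samples$dna_source == "cell_line", v$source_shift, 0)
      base <- v$slope * (summed - 2 * v$ref_repeats) / (2 * v$ref_repeats) + shift
      for (m in probes) {
        panel$lrr[, m] <- base + rnorm(n_s, 0, v$probe_noise_sd)
        panel$baf[, m] <- runif(n_s)
      }
      truth$vntr <- list(
        probe_ids = map$marker_id[probes],
        repeats = tibble::tibble(sample_id = samples$sample_id,
                                 allele1 = a1, allele2 = a2,
                                 summed_repeats = summed)
      )
    })
  }

  if (isTRUE(config$loh$enabled)) {
    lo <- config$loh
    vntr_ids <- if (is.null(truth$vntr)) character(0) else truth$vntr$probe_ids
    snp_idx <- which(panel$markers$probe_class == "snp" &
                       !(map$marker_id %in% truth$gender_linked_markers$marker_id) &
                       !(map$marker_id %in% vntr_ids))
    assert_that(length(snp_idx) >= lo$k, "LOH artifact requested but SNP set empty")
    with_seed(child_seed(config$seed, 6L), {
      # contiguous run of k SNPs, placed mid-chromosome where available
      runs <- snp_idx[which(diff(snp_idx, lag = lo$k - 1) == lo$k - 1)]
      start <- if (length(runs) > 0) runs[ceiling(length(runs) / 2)] else NA
      block <- if (!is.na(start)) start + seq_len(lo$k) - 1 else
        sort(sample(snp_idx, lo$k))
      # the haplotype count is pinned at its expectation so the block's
      # sample allele frequency equals the configured rare-haplotype
      # frequency (the scenario's defining condition) for every seed
      tot <- 2L * n_s
      n_minor <- round(tot * lo$hap_freq)
      carriers_chr <- sample(tot, n_minor)
      minor_count <- tabulate(ceiling(carriers_chr / 2), nbins = n_s)
      shift <- ifelse(samples$dna_source == "blood", lo$source_lrr_shift, 0)
      for (m in block) {
        panel$baf[, m] <- clamp(minor_count / 2 +
                                  rnorm(n_s, 0, config$baf_sd), 0, 1)
        panel$lrr[, m] <- panel$lrr[, m] + shift
        panel$genotypes[, m] <- as.integer(minor_count)
        panel$markers$pfb[m] <- lo$assumed_pfb
      }
      truth$loh <- list(marker_ids = map$marker_id[block],
                        hap_freq = lo$hap_freq,
                        carriers = tibble::tibble(
                          sample_id = samples$sample_id,
                          n_minor_haplotypes = minor_count))
    })
  }

  list(panel = panel, truth = truth)
}
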