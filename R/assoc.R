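#' Carrier-status contingency table at a locus
#'
#' A sample is a carrier iff at least one retained call overlaps the locus.
#' Samples carrying two or more distinct calls at the locus (putative
#' compound heterozygotes) are dropped from both margins when
#' `exclude_compound_hets` is on. Samples whose mosaic-excluded arm covers
#' the locus are dropped from the margins for this locus.
#'
#' @param callset filtered callset tibble.
#' @param samples sample tibble with `sample_id`, `phenotype`.
#' @param locus list or one-row data frame with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param exclude_compound_hets drop samples with >= 2 distinct calls at the
#'   locus.
#' @param masked_arms optional tibble from [excluded_arms()].
#' @param known_chroms optional character vector of valid chromosomes; a
#'   locus on a chromosome outside it is rejected.
#' @return one-row tibble (`a`, `b`, `c`, `d`, `n_dropped_compound`):
#'   case carriers / case non-carriers / control carriers / control
#'   non-carriers.
#' @export
carrier_status <- function(callset, samples, locus,
                           exclude_compound_hets = TRUE,
                           masked_arms = NULL, known_chroms = NULL) {
  locus <- as.list(locus)
  if (!is.null(known_chroms)) {
    assert_that(locus$chrom %in% known_chroms,
                paste0("locus on unknown chromosome: ", locus$chrom))
  }
  ov <- callset[callset$chrom == locus$chrom &
                  interval_overlap(callset$start, callset$end,
                                   locus$start, locus$end) > 0, , drop = FALSE]
  counts <- table(factor(ov$sample_id, levels = samples$sample_id))
  drop_comp <- names(counts)[counts >= 2 & exclude_compound_hets]
  drop_mask <- character(0)
  if (!is.null(masked_arms) && nrow(masked_arms) > 0) {
    m <- masked_arms[masked_arms$chrom == locus$chrom &
                       interval_overlap(masked_arms$arm_start,
                                        masked_arms$arm_end,
                                        locus$start, locus$end) > 0, ,
                     drop = FALSE]
    drop_mask <- unique(m$sample_id)
  }
  keep <- !(samples$sample_id %in% c(drop_comp, drop_mask))
  carrier <- samples$sample_id %in% ov$sample_id & keep
  case <- samples$phenotype == "case"
  tibble::tibble(
    a = sum(carrier & case & keep),
    b = sum(!carrier & case & keep),
    c = sum(carrier & !case & keep),
    d = sum(!carrier & !case & keep),
    n_dropped_compound = length(drop_comp)
  )
}

#' One-sided Fisher p-value and odds ratio for a 2x2 carrier table
#'
#' `fisher_one_sided()` returns the hypergeometric tail probability
#' P(X >= a | margins) -- the one-sided exact test in the direction of case
#' excess. `odds_ratio()` returns (a d)/(b c), with an `Inf` sentinel on a
#' zero denominator and `NaN` for the all-zero table.
#'
#' @param a,b,c,d case carriers, case non-carriers, control carriers,
#'   control non-carriers.
#' @return numeric scalar (vectorised over table entries).
#' @export
fisher_one_sided <- function(a, b, c, d) {
  # X ~ Hypergeometric(total carriers a+c among a+b draws from a+b+c+d)
  p <- phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  ifelse(a + b + c + d == 0, 1, pmin(p, 1))
}

#' @rdname fisher_one_sided
#' @export
odds_ratio <- function(a, b, c, d) {
  ifelse(b * c == 0,
         ifelse(a * d == 0, NaN, Inf),
         (a * d) / (b * c))
}

# carrier sample-index sets per marker locus, collapsed over adjacent
# markers with identical carrier sets; returns a tibble of distinct loci
scan_loci <- function(callset, samples, marker_map,
                      mode = c("position", "window"), half_width = 2e5) {
  mode <- match.arg(mode)
  hw <- if (mode == "window") half_width else 0
  n_s <- nrow(samples)
  sidx <- seq_len(n_s)
  names(sidx) <- samples$sample_id
  loci <- NULL
  for (ch in unique(marker_map$chrom)) {
    pos <- marker_map$pos[marker_map$chrom == ch]
    m <- length(pos)
    cov <- matrix(FALSE, n_s, m)
    cs <- callset[callset$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(cs))) {
      i <- sidx[[cs$sample_id[j]]]
      hit <- pos >= cs$start[j] - hw & pos <= cs$end[j] + hw
      cov[i, hit] <- TRUE
    }
    key <- apply(cov, 2, function(col) paste(which(col), collapse = ","))
    grp <- cumsum(c(TRUE, key[-1] != key[-m]))
    for (g in unique(grp)) {
      cols <- which(grp == g)
      carriers <- which(cov[, cols[1]])
      loci[[length(loci) + 1]] <- tibble::tibble(
        chrom = ch, start = pos[cols[1]], end = pos[cols[length(cols)]],
        n_markers = length(cols), carriers = list(carriers))
    }
  }
  dplyr::bind_rows(loci)
}

#' Genome-wide carrier-based CNV association scan
#'
#' Tests, at every marker position (or 400 kb-style window centred on every
#' marker), whether carriers of an overlapping CNV are enriched in cases,
#' by a one-sided Fisher exact test. Adjacent loci with identical carrier
#' sets are collapsed into one record spanning their markers.
#'
#' @param callset filtered callset tibble (mosaic-excluded arms already
#'   masked via [mask_excluded_arms()]).
#' @param samples sample tibble.
#' @param marker_map marker map tibble.
#' @param mode `"position"` (carrier = call covering the marker) or
#'   `"window"` (carrier = call overlapping the window
#'   `pos +/- half_width`).
#' @param half_width window half-width in bp (default 200 kb).
#' @return tibble of collapsed loci with carrier counts, odds ratio and
#'   one-sided nominal p.
#' @export
cnv_scan <- function(callset, samples, marker_map,
                     mode = c("position", "window"), half_width = 2e5) {
  mode <- match.arg(mode)
  loci <- scan_loci(callset, samples, marker_map, mode, half_width)
  case <- samples$phenotype == "case"
  n_case <- sum(case)
  n_ctrl <- sum(!case)
  a <- purrr::map_int(loci$carriers, function(cr) sum(case[cr]))
  k <- purrr::map_int(loci$carriers, length)
  cvec <- k - a
  loci %>%
    dplyr::mutate(a = a, b = n_case - a, c = cvec, d = n_ctrl - cvec,
                  odds_ratio = odds_ratio(.data$a, .data$b, .data$c, .data$d),
                  p_nominal = fisher_one_sided(.data$a, .data$b,
                                               .data$c, .data$d),
                  mode = mode)
}

#' Empirical genome-wide p-values by max-statistic permutation
#'
#' Permutes affection status (preserving case/control totals), re-tests all
#' loci per permutation, and records the genome-wide minimum nominal p. The
#' empirical genome-wide p of a locus is
#' `(1 + #permutations with min p <= observed p) / (B + 1)`; the pointwise
#' empirical p uses the locus's own permutation distribution. With
#' `exhaustive = TRUE` every distinct case-label assignment is enumerated
#' and the empirical p is an exact proportion.
#'
#' @param callset,samples,marker_map,mode,half_width as in [cnv_scan()].
#' @param B number of permutations.
#' @param seed integer seed for the permutation stream.
#' @param exhaustive enumerate all case assignments (feasible only for tiny
#'   cohorts).
#' @return object of class `cnv_assoc`: list with `results` tibble
#'   (nominal, pointwise and genome-wide empirical p per locus), `B`,
#'   `mode`, `n_cases`, `n_controls`.
#' @export
maxt_permutation <- function(callset, samples, marker_map,
                             mode = c("position", "window"),
                             half_width = 2e5, B = 1000, seed = 1,
                             exhaustive = FALSE) {
  mode <- match.arg(mode)
  assert_that(B >= 1 || exhaustive, "B must be >= 1")
  obs <- cnv_scan(callset, samples, marker_map, mode, half_width)
  case <- samples$phenotype == "case"
  n <- length(case)
  n_case <- sum(case)
  if (nrow(obs) == 0) {
    return(structure(list(results = dplyr::mutate(dplyr::select(obs, -"carriers"),
                                                  p_pointwise = double(0),
                                                  p_genomewide = double(0)),
                          B = B, mode = mode, exhaustive = exhaustive,
                          n_cases = n_case, n_controls = n - n_case),
                     class = "cnv_assoc"))
  }
  k <- purrr::map_int(obs$carriers, length)
  # carrier indicator matrix keeps each permutation a single matrix product
  cmat <- matrix(0L, nrow(obs), n)
  for (i in seq_len(nrow(obs))) cmat[i, obs$carriers[[i]]] <- 1L
  perm_p <- function(z) {
    a <- as.vector(cmat %*% z)
    fisher_one_sided(a, n_case - a, k - a, n - n_case - (k - a))
  }
  if (exhaustive) {
    combos <- utils::combn(n, n_case)
    B_eff <- ncol(combos)
    pm <- matrix(NA_real_, B_eff, nrow(obs))
    for (j in seq_len(B_eff)) {
      z <- integer(n)
      z[combos[, j]] <- 1L
      pm[j, ] <- perm_p(z)
    }
    minp <- apply(pm, 1, min)
    p_gw <- purrr::map_dbl(seq_len(nrow(obs)), function(i)
      mean(minp <= obs$p_nominal[i]))
    p_point <- purrr::map_dbl(seq_len(nrow(obs)), function(i)
      mean(pm[, i] <= obs$p_nominal[i]))
    B_used <- B_eff
  } else {
    if (B < 19) {
      warn(sprintf("smallest attainable empirical p is 1/(B+1) = %.3g",
                   1 / (B + 1)))
    }
    pm <- matrix(NA_real_, B, nrow(obs))
    with_seed(seed, {
      for (j in seq_len(B)) {
        z <- integer(n)
        z[sample.int(n, n_case)] <- 1L
        pm[j, ] <- perm_p(z)
      }
    })
    minp <- apply(pm, 1, min)
    p_gw <- purrr::map_dbl(seq_len(nrow(obs)), function(i)
      (1 + sum(minp <= obs$p_nominal[i])) / (B + 1))
    p_point <- purrr::map_dbl(seq_len(nrow(obs)), function(i)
      (1 + sum(pm[, i] <= obs$p_nominal[i])) / (B + 1))
    B_used <- B
  }
  res <- obs %>%
    dplyr::mutate(p_pointwise = p_point, p_genomewide = p_gw) %>%
    dplyr::select(-"carriers")
  structure(list(results = res, B = B_used, mode = mode,
                 exhaustive = exhaustive,
                 n_cases = n_case, n_controls = n - n_case),
            class = "cnv_assoc")
}

#' @export
print.cnv_assoc <- function(x, ...) {
  cat("<cnv_assoc> ", nrow(x$results), " loci; mode = ", x$mode,
      "; B = ", x$B, if (x$exhaustive) " (exhaustive)", "\n", sep = "")
  cat("  cohort: ", x$n_cases, " cases / ", x$n_controls, " controls\n",
      sep = "")
  top <- dplyr::arrange(x$results, .data$p_genomewide) %>% utils::head(3)
  print(top)
  invisible(x)
}

#' Study-wide significance annotation
#'
#' Flags loci whose empirical genome-wide p falls strictly below the
#' Bonferroni threshold `0.05 / n_approaches` across the analysis
#' approaches run (e.g. 4 approaches give 0.0125).
#'
#' @param results a `cnv_assoc` object or its results tibble.
#' @param n_approaches number of analysis approaches.
#' @return the results tibble with `study_wide_threshold` and
#'   `study_wide_significant` columns.
#' @export
study_wide_correction <- function(results, n_approaches = 4) {
  assert_that(n_approaches >= 1, "need >= 1 approach")
  if (inherits(results, "cnv_assoc")) results <- results$results
  thr <- 0.05 / n_approaches
  results %>%
    dplyr::mutate(study_wide_threshold = thr,
                  study_wide_significant = .data$p_genomewide < thr)
}

#' Candidate-locus replication test
#'
#' Carrier-based one-sided Fisher test at a single gene interval, with
#' compound-heterozygote exclusion on: the replication design for a
#' known susceptibility locus.
#'
#' @param callset filtered callset tibble (gene-centric CNV definition:
#'   pass calls overlapping the gene).
#' @param samples sample tibble.
#' @param gene_interval list/one-row data frame with `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param masked_arms optional tibble from [excluded_arms()].
#' @return one-row tibble with the contingency table, odds ratio and
#'   one-sided p.
#' @export
replicate_locus <- function(callset, samples, gene_interval,
                            masked_arms = NULL) {
  tab <- carrier_status(callset, samples, gene_interval,
                        exclude_compound_hets = TRUE,
                        masked_arms = masked_arms)
  tab %>%
    dplyr::mutate(odds_ratio = odds_ratio(.data$a, .data$b, .data$c, .data$d),
                  p_one_sided = fisher_one_sided(.data$a, .data$b,
                                                 .data$c, .data$d))
}
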