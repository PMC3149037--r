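#' HMM caller parameters
#'
#' Parameters of the five-state (copy number 0-4) hidden Markov model over
#' LRR/BAF tracks. The `strict` preset uses a low leave-state rate and the
#' confidence/size gate (confidence >= 10, >= 5 markers); the `lenient`
#' preset raises the leave-state rate and lowers the confidence gate, which
#' yields more and longer calls on the same data -- the knob used to study
#' caller discordance.
#'
#' @param preset `"strict"` or `"lenient"`.
#' @param lrr_means LRR emission means for CN 0..4 (strictly increasing).
#' @param lrr_sd,baf_sd emission standard deviations.
#' @param transition_bp distance scale D of the transition model; the total
#'   leave-state probability over a gap of d bp is
#'   `lambda_max * (1 - exp(-d/D))`, split equally among the other states.
#' @param lambda_max maximal leave-state probability (in (0, 0.5)).
#' @param min_markers,min_confidence call gate: minimum marker count and
#'   minimum confidence (summed per-marker log-likelihood ratio of the
#'   called state over the diploid state).
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(preset = c("strict", "lenient"),
                       lrr_means = c(-3.5, -0.66, 0, 0.40, 0.68),
                       lrr_sd = 0.2, baf_sd = 0.03,
                       transition_bp = 1e5,
                       lambda_max = NULL,
                       min_markers = 5L,
                       min_confidence = NULL) {
  preset <- match.arg(preset)
  lambda_max <- lambda_max %||% switch(preset, strict = 1e-3, lenient = 1e-2)
  min_confidence <- min_confidence %||% switch(preset, strict = 10, lenient = 3)
  assert_that(length(lrr_means) == 5 && all(diff(lrr_means) > 0),
              "lrr_means must be strictly increasing in copy number")
  assert_that(lambda_max > 0 && lambda_max < 0.5,
              "lambda_max must lie in (0, 0.5)")
  assert_that(transition_bp > 0, "transition_bp must be positive")
  structure(list(states = 0:4, lrr_means = lrr_means, lrr_sd = lrr_sd,
                 baf_sd = baf_sd, transition_bp = transition_bp,
                 lambda_max = lambda_max, min_markers = as.integer(min_markers),
                 min_confidence = min_confidence, preset = preset),
            class = "hmm_params")
}

#' Per-marker emission log-likelihood
#'
#' `log[ Normal(lrr; mu_state, lrr_sd) * BafMix(baf; state, pfb) ]` where the
#' BAF term is a Binomial(state, pfb)-weighted mixture of boundary-censored
#' Normals centred at b/state (b = 0..state), Uniform(0,1) at state 0, and
#' absent (LRR only) for monomorphic probes carrying the PFB sentinel 2.
#'
#' @param lrr,baf,pfb numeric vectors of equal length.
#' @param state copy-number state in 0..4.
#' @param params an [hmm_params()] object.
#' @return numeric vector of log-likelihoods.
#' @export
emission_loglik <- function(lrr, baf, pfb, state, params = hmm_params()) {
  stopifnot(state %in% 0:4)
  n <- length(lrr)
  ll_lrr <- dnorm(lrr, params$lrr_means[state + 1], params$lrr_sd, log = TRUE)
  ll_baf <- numeric(n)
  poly <- which(pfb != 2)
  if (state > 0 && length(poly) > 0) {
    eps <- 1e-6
    sdb <- params$baf_sd
    lik <- numeric(length(poly))
    bafp <- baf[poly]
    pfbp <- pfb[poly]
    lo <- bafp <= eps
    hi <- bafp >= 1 - eps
    for (b in 0:state) {
      w <- dbinom(b, state, pfbp)
      m <- b / state
      comp <- dnorm(bafp, m, sdb)
      comp[lo] <- pnorm(0, m, sdb)
      comp[hi] <- pnorm(1, m, sdb, lower.tail = FALSE)
      lik <- lik + w * comp
    }
    ll_baf[poly] <- log(pmax(lik, 1e-300))
  }
  # state 0: BAF ~ Uniform(0,1), log-density 0
  ll_lrr + ll_baf
}

# n x 5 emission log-likelihood matrix
emission_matrix <- function(lrr, baf, pfb, params) {
  vapply(0:4, function(s) emission_loglik(lrr, baf, pfb, s, params),
         numeric(length(lrr)))
}

#' Viterbi segmentation of one sample track
#'
#' Decodes the copy-number path of one sample along one chromosome with
#' distance-dependent transitions and emits confidence-scored CNV calls:
#' maximal runs of non-diploid state become calls; confidence is the summed
#' per-marker emission log-likelihood ratio of the called state over the
#' diploid state; calls failing the marker-count or confidence gate are
#' discarded.
#'
#' @param lrr,baf,pfb,pos equal-length vectors for one sample-chromosome,
#'   positions sorted increasing; excluded markers must already be dropped.
#' @param chrom chromosome label for the emitted calls.
#' @param sample_id sample label.
#' @param params an [hmm_params()] object.
#' @return callset tibble (possibly empty).
#' @export
viterbi_segment <- function(lrr, baf, pfb, pos, chrom = "1",
                            sample_id = "S", params = hmm_params()) {
  ok <- is.finite(lrr) & is.finite(baf)
  lrr <- lrr[ok]; baf <- baf[ok]; pfb <- pfb[ok]; pos <- pos[ok]
  n <- length(lrr)
  empty <- tibble::tibble(sample_id = character(), chrom = character(),
                          start = integer(), end = integer(), cn = integer(),
                          n_markers = integer(), length_bp = integer(),
                          confidence = numeric())
  if (n == 0) return(empty)
  emis <- emission_matrix(lrr, baf, pfb, params)
  if (n == 1) {
    path <- which.max(emis[1, ]) - 1L
  } else {
    d <- diff(pos)
    lam <- params$lambda_max * (1 - exp(-d / params$transition_bp))
    ldiag <- log1p(-lam)
    loff <- log(lam / 4)
    ptr <- matrix(0L, 5, n)
    prev <- log(c(2.5e-4, 2.5e-4, 0.999, 2.5e-4, 2.5e-4)) + emis[1, ]
    for (t in 2:n) {
      ord <- order(prev, decreasing = TRUE)
      m1i <- ord[1]; m2i <- ord[2]
      stay <- prev + ldiag[t - 1]
      off_val <- prev[m1i] + loff[t - 1]
      off_val2 <- prev[m2i] + loff[t - 1]
      cur <- numeric(5)
      for (s in 1:5) {
        ov <- if (s == m1i) off_val2 else off_val
        oi <- if (s == m1i) m2i else m1i
        if (stay[s] >= ov) {
          cur[s] <- stay[s]
          ptr[s, t] <- s
        } else {
          cur[s] <- ov
          ptr[s, t] <- oi
        }
      }
      prev <- cur + emis[t, ]
    }
    path <- integer(n)
    path[n] <- which.max(prev)
    if (n > 1) for (t in n:2) path[t - 1] <- ptr[path[t], t]
    path <- path - 1L
  }

  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values != 2L)
  if (length(keep) == 0) return(empty)
  calls <- purrr::map(keep, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    st <- r$values[k]
    conf <- sum(emis[i0:i1, st + 1] - emis[i0:i1, 3])
    tibble::tibble(sample_id = sample_id, chrom = chrom,
                   start = pos[i0], end = pos[i1], cn = st,
                   n_markers = i1 - i0 + 1L,
                   length_bp = pos[i1] - pos[i0] + 1L,
                   confidence = conf)
  }) %>% dplyr::bind_rows()
  calls <- calls[calls$n_markers >= params$min_markers &
                   calls$confidence >= params$min_confidence, , drop = FALSE]
  calls
}

#' Call CNVs across a panel
#'
#' Runs [viterbi_segment()] over every sample and chromosome of a panel.
#' Markers flagged `unstable_region` or `gender_linked` in the panel's map
#' are dropped before decoding. Optionally re-estimates each sample's LRR sd
#' (median absolute deviation over its whole track) and drops samples above
#' a noise cut.
#'
#' @param panel an `intensity_panel`.
#' @param params an [hmm_params()] object.
#' @param sample_qc drop samples whose estimated LRR sd exceeds
#'   `sample_sd_cut`.
#' @param sample_sd_cut LRR sd cut for sample exclusion.
#' @return callset tibble, sorted by sample, chromosome, start.
#' @export
call_cnvs <- function(panel, params = hmm_params(), sample_qc = FALSE,
                      sample_sd_cut = 0.35) {
  map <- panel$markers
  use <- !(map$unstable_region | map$gender_linked)
  keep_samples <- seq_len(nrow(panel$samples))
  if (sample_qc) {
    sds <- apply(panel$lrr[, use, drop = FALSE], 1, mad, na.rm = TRUE)
    keep_samples <- which(sds <= sample_sd_cut)
  }
  chroms <- unique(map$chrom)
  out <- purrr::map(keep_samples, function(i) {
    purrr::map(chroms, function(ch) {
      idx <- which(use & map$chrom == ch)
      if (length(idx) == 0) return(NULL)
      viterbi_segment(panel$lrr[i, idx], panel$baf[i, idx],
                      map$pfb[idx], map$pos[idx], chrom = ch,
                      sample_id = panel$samples$sample_id[i], params = params)
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  if (nrow(out) == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          start = integer(), end = integer(), cn = integer(),
                          n_markers = integer(), length_bp = integer(),
                          confidence = numeric()))
  }
  dplyr::arrange(out, .data$sample_id, .data$chrom, .data$start)
}

#' Compare two callsets
#'
#' Matches calls by sample, chromosome, CNV direction and reciprocal
#' overlap, and summarises per-sample counts and mean lengths -- the tool
#' for strict-vs-lenient (or with/without marker exclusion) comparisons.
#'
#' @param a,b callset tibbles over the same sample universe.
#' @param sample_ids the shared sample universe; defaults to the union of
#'   samples appearing in either callset.
#' @param reciprocal minimum reciprocal overlap fraction for a match.
#' @return list with `per_sample` tibble, overall matched fractions, and
#'   `gained` / `lost` call tibbles (in `b` only / in `a` only).
#' @export
compare_callsets <- function(a, b, sample_ids = NULL, reciprocal = 0.5) {
  if (is.null(sample_ids)) {
    if (nrow(a) > 0 && nrow(b) > 0) {
      assert_that(length(intersect(a$sample_id, b$sample_id)) > 0,
                  "callsets cover disjoint samples")
    }
    sample_ids <- union(a$sample_id, b$sample_id)
  }
  match_one <- function(q, ref) {
    if (nrow(q) == 0) return(logical(0))
    vapply(seq_len(nrow(q)), function(i) {
      cand <- ref[ref$sample_id == q$sample_id[i] &
                    ref$chrom == q$chrom[i] &
                    sign(ref$cn - 2) == sign(q$cn[i] - 2), , drop = FALSE]
      if (nrow(cand) == 0) return(FALSE)
      ov <- interval_overlap(cand$start, cand$end, q$start[i], q$end[i])
      any(ov / (q$end[i] - q$start[i] + 1) >= reciprocal &
            ov / (cand$end - cand$start + 1) >= reciprocal)
    }, logical(1))
  }
  ma <- match_one(a, b)
  mb <- match_one(b, a)
  per_sample <- purrr::map(sample_ids, function(s) {
    ai <- a[a$sample_id == s, , drop = FALSE]
    bi <- b[b$sample_id == s, , drop = FALSE]
    tibble::tibble(sample_id = s, n_a = nrow(ai), n_b = nrow(bi),
                   mean_len_a = mean(ai$length_bp),
                   mean_len_b = mean(bi$length_bp))
  }) %>% dplyr::bind_rows()
  list(per_sample = per_sample,
       matched_frac_a = if (nrow(a) > 0) mean(ma) else NA_real_,
       matched_frac_b = if (nrow(b) > 0) mean(mb) else NA_real_,
       lost = a[!ma, , drop = FALSE],
       gained = b[!mb, , drop = FALSE])
}
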