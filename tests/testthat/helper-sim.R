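# shared fixtures, built once per test run
.fx <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fx, inherits = FALSE)) {
    assign(key, force(expr), envir = .fx)
  }
  get(key, envir = .fx)
}

# small null cohort: one chromosome, no CNVs, no artifacts
fx_null <- function() {
  fixture("null", {
    cfg <- sim_config(chrom_lengths = c(`1` = 12e6), n_markers = 600,
                      n_cases = 20, n_controls = 20, seed = 101)
    map <- build_marker_map(cfg)
    c(simulate_cohort(map, cfg), list(map = map, cfg = cfg))
  })
}

# cohort with implanted germline CNVs of every copy number
fx_cnv <- function() {
  fixture("cnv", {
    imp <- tibble::tibble(
      sample_id = c("S0001", "S0002", "S0003", "S0004", "S0005"),
      chrom = "1",
      start = c(2e6, 5e6, 8e6, 11e6, 14e6),
      end = c(3e6, 6e6, 9e6, 12e6, 14.4e6),
      cn = c(1L, 3L, 0L, 4L, 1L)
    )
    cfg <- sim_config(chrom_lengths = c(`1` = 20e6), n_markers = 1000,
                      n_cases = 15, n_controls = 15, implant_cnvs = imp,
                      seed = 102)
    map <- build_marker_map(cfg)
    c(simulate_cohort(map, cfg), list(map = map, cfg = cfg, implants = imp))
  })
}

# markers covered by an interval of a marker map
markers_in <- function(map, chrom, start, end) {
  which(map$chrom == chrom & map$pos >= start & map$pos <= end)
}

# 50% reciprocal-overlap recall/precision of a callset against truth
match_calls_truth <- function(calls, truth, reciprocal = 0.5) {
  match_in <- function(q, ref) {
    if (nrow(q) == 0) return(logical(0))
    vapply(seq_len(nrow(q)), function(i) {
      cand <- ref[ref$sample_id == q$sample_id[i] &
                    ref$chrom == q$chrom[i] &
                    sign(ref$cn - 2) == sign(q$cn[i] - 2), , drop = FALSE]
      if (nrow(cand) == 0) return(FALSE)
      ov <- pmax(0, pmin(cand$end, q$end[i]) - pmax(cand$start, q$start[i]) + 1)
      any(ov / (q$end[i] - q$start[i] + 1) >= reciprocal &
            ov / (cand$end - cand$start + 1) >= reciprocal)
    }, logical(1))
  }
  list(recall = mean(match_in(truth, calls)),
       precision = mean(match_in(calls, truth)))
}
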