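# brute-force hypergeometric tail: P(X >= a) enumerated directly
oracle_fisher <- function(a, b, c, d) {
  K <- a + c
  n1 <- a + b
  N <- a + b + c + d
  if (N == 0) return(1)
  xs <- max(0, K + n1 - N):min(K, n1)
  probs <- choose(K, xs) * choose(N - K, n1 - xs) / choose(N, n1)
  sum(probs[xs >= a])
}

test_that("one-sided Fisher p equals exhaustive hypergeometric enumeration", {
  set.seed(11)
  for (rep in 1:200) {
    a <- sample(0:12, 1); b <- sample(0:18, 1)
    c <- sample(0:12, 1); d <- sample(0:18, 1)
    if (a + b + c + d == 0) next
    expect_equal(fisher_one_sided(a, b, c, d), oracle_fisher(a, b, c, d),
                 tolerance = 1e-12)
    # and the standard exact-test implementation agrees
    ft <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                      alternative = "greater")$p.value
    expect_equal(fisher_one_sided(a, b, c, d), ft, tolerance = 1e-9)
  }
})

test_that("odds ratio carries the documented sentinels", {
  expect_equal(odds_ratio(10, 386, 8, 848), 10 * 848 / (386 * 8))
  expect_equal(odds_ratio(3, 7, 0, 10), Inf)
  expect_true(is.nan(odds_ratio(0, 10, 0, 10)))
  # symmetric table: OR 1, p at least one half
  expect_equal(odds_ratio(4, 6, 4, 6), 1)
  expect_gte(fisher_one_sided(4, 6, 4, 6), 0.5)
})

samples6 <- tibble::tibble(
  sample_id = sprintf("S%d", 1:6), sex = "female",
  phenotype = rep(c("case", "control"), each = 3),
  dna_source = "blood", study = "x")

map6 <- tibble::tibble(marker_id = sprintf("m%d", 1:20), chrom = "1",
                       arm = "p", pos = 1:20 * 1000L, probe_class = "snp",
                       pfb = 0.5, unstable_region = FALSE,
                       gender_linked = FALSE)

call6 <- function(ids, start = 5000L, end = 9000L) {
  tibble::tibble(sample_id = ids, chrom = "1", start = start, end = end,
                 cn = 1L, n_markers = 5L, length_bp = end - start + 1L,
                 confidence = 30)
}

test_that("carrier status honours compound-het and mosaic-arm exclusions", {
  samples <- samples6
  locus <- list(chrom = "1", start = 4000, end = 10000)
  empty <- carrier_status(call6(character(0)), samples, locus)
  expect_equal(unlist(empty[c("a", "b", "c", "d")]),
               c(a = 0, b = 3, c = 0, d = 3))
  # sample S1 with two disjoint calls at the locus: dropped when exclusion on
  two <- dplyr::bind_rows(call6("S1", 4000L, 5000L), call6("S1", 8000L, 9000L))
  on <- carrier_status(two, samples, locus, exclude_compound_hets = TRUE)
  expect_equal(on$a + on$b, 2)
  expect_equal(on$n_dropped_compound, 1)
  off <- carrier_status(two, samples, locus, exclude_compound_hets = FALSE)
  expect_equal(off$a, 1)
  expect_equal(off$a + off$b, 3)
  # masked arm drops the sample from the margins at overlapping loci
  arms <- tibble::tibble(sample_id = "S4", chrom = "1", arm = "p",
                         arm_start = 1L, arm_end = 20000L)
  masked <- carrier_status(call6("S2"), samples, locus, masked_arms = arms)
  expect_equal(masked$c + masked$d, 2)
  expect_error(carrier_status(call6("S2"), samples,
                              list(chrom = "7", start = 1, end = 10),
                              known_chroms = "1"),
               "unknown chromosome")
})

test_that("the position scan matches direct enumeration on a small instance", {
  calls <- call6(c("S1", "S2", "S3"))
  scan <- cnv_scan(calls, samples6, map6, mode = "position")
  hit <- scan[scan$a == 3, ]
  expect_equal(nrow(hit), 1)  # identical carrier sets collapse to one locus
  expect_equal(hit$p_nominal, oracle_fisher(3, 0, 0, 3))
  expect_equal(hit$start, 5000L)
  expect_equal(hit$end, 9000L)
  # window mode with zero half-width reduces to the position scan
  w0 <- cnv_scan(calls, samples6, map6, mode = "window", half_width = 0)
  expect_equal(scan[setdiff(names(scan), "mode")],
               w0[setdiff(names(w0), "mode")])
  # empty callset: everything p = 1
  none <- cnv_scan(call6(character(0)), samples6, map6, mode = "position")
  expect_true(all(none$p_nominal == 1))
})

test_that("exhaustive max-T permutation equals a brute-force oracle", {
  calls <- dplyr::bind_rows(call6(c("S1", "S2", "S3")),
                            call6(c("S2", "S5"), 15000L, 19000L))
  res <- maxt_permutation(calls, samples6, map6, mode = "position",
                          exhaustive = TRUE)
  expect_equal(res$B, choose(6, 3))
  # independent enumeration of all 20 case assignments
  scan0 <- cnv_scan(calls, samples6, map6, mode = "position")
  carriers <- list(c(1, 2, 3), c(2, 5))
  combos <- combn(6, 3)
  minp <- apply(combos, 2, function(cs) {
    min(vapply(carriers, function(cr) {
      a <- length(intersect(cr, cs))
      oracle_fisher(a, 3 - a, length(cr) - a, 3 - (length(cr) - a))
    }, numeric(1)))
  })
  for (g in which(scan0$n_markers == 5)) {
    # tolerance guards the floating tie between choose- and phyper-arithmetic
    expect_equal(res$results$p_genomewide[g],
                 mean(minp <= scan0$p_nominal[g] + 1e-9))
  }
  # sampled permutations: empirical p bounded below by 1/(B+1)
  res2 <- maxt_permutation(calls, samples6, map6, mode = "position",
                           B = 99, seed = 5)
  expect_true(all(res2$results$p_genomewide >= 1 / 100))
  res2b <- maxt_permutation(calls, samples6, map6, mode = "position",
                            B = 99, seed = 5)
  expect_identical(res2$results, res2b$results)
})

test_that("study-wide correction applies a strict Bonferroni threshold", {
  res <- tibble::tibble(p_genomewide = c(0.001, 0.0125, 0.02, 1))
  ann4 <- study_wide_correction(res, n_approaches = 4)
  expect_equal(unique(ann4$study_wide_threshold), 0.0125)
  expect_equal(ann4$study_wide_significant, c(TRUE, FALSE, FALSE, FALSE))
  ann1 <- study_wide_correction(res, n_approaches = 1)
  expect_equal(unique(ann1$study_wide_threshold), 0.05)
  expect_equal(ann1$study_wide_significant, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("locus replication handles degenerate carrier patterns", {
  gene <- list(chrom = "1", start = 4000, end = 10000)
  none <- replicate_locus(call6(character(0)), samples6, gene)
  expect_equal(none$p_one_sided, 1)
  expect_true(is.nan(none$odds_ratio))
  all_cases <- replicate_locus(call6(c("S1", "S2", "S3")), samples6, gene)
  expect_equal(all_cases$odds_ratio, Inf)
  expect_equal(all_cases$p_one_sided, oracle_fisher(3, 0, 0, 3))
})

test_that("tidy and glance expose the association results", {
  calls <- call6(c("S1", "S2"))
  res <- maxt_permutation(calls, samples6, map6, mode = "position",
                          B = 50, seed = 3)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("p_nominal", "p_genomewide") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_loci, nrow(td))
  expect_equal(gl$n_cases, 3)
})
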