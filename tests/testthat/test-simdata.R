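test_that("marker map conserves counts, ordering and unstable flags", {
  cfg <- sim_config(chrom_lengths = c(`1` = 5e6), n_markers = 100,
                    unstable_end_markers = 2, seed = 1)
  map <- build_marker_map(cfg)
  expect_equal(nrow(map), 100)
  expect_true(all(diff(map$pos) > 0))
  # 2 markers at each end of each of the 2 arms
  expect_equal(sum(map$unstable_region), 4 * 2)
  expect_true(all(map$pfb == 2 | (map$pfb >= 0 & map$pfb <= 1)))
  expect_setequal(unique(map$arm), c("p", "q"))
})

test_that("same seed gives byte-identical maps and panels", {
  cfg <- sim_config(chrom_lengths = c(`1` = 5e6), n_markers = 200,
                    n_cases = 5, n_controls = 5, n_cnvs_per_sample = 1,
                    seed = 33)
  m1 <- build_marker_map(cfg)
  m2 <- build_marker_map(cfg)
  expect_identical(m1, m2)
  s1 <- simulate_cohort(m1, cfg)
  s2 <- simulate_cohort(m2, cfg)
  expect_identical(s1$panel$lrr, s2$panel$lrr)
  expect_identical(s1$panel$baf, s2$panel$baf)
  expect_identical(s1$truth$germline_cnvs, s2$truth$germline_cnvs)
})

test_that("degenerate configs are rejected", {
  expect_error(sim_config(chrom_lengths = c(`1` = 1e6), n_markers = 0),
               "zero markers")
  expect_error(sim_config(chrom_lengths = c(`1` = 1e6), n_markers = 100,
                          lrr_means = c(0, 1, 2, 3)), "strictly increasing")
  cfg <- sim_config(chrom_lengths = c(`1` = 5e6), n_markers = 100,
                    implant_cnvs = tibble::tibble(
                      sample_id = "S0001", chrom = "1",
                      start = 1, end = 2, cn = 1L),
                    n_cases = 2, n_controls = 2, seed = 1)
  map <- build_marker_map(cfg)
  expect_error(simulate_cohort(map, cfg), "covers no marker")
  cfg2 <- sim_config(chrom_lengths = c(`1` = 5e6), n_markers = 100,
                     implant_cnvs = tibble::tibble(
                       sample_id = "S0001", chrom = "1",
                       start = c(1e6, 1.5e6), end = c(2e6, 2.5e6),
                       cn = c(1L, 3L)),
                     n_cases = 2, n_controls = 2, seed = 1)
  map2 <- build_marker_map(cfg2)
  expect_error(simulate_cohort(map2, cfg2), "overlapping")
})

test_that("null cohort has empty truth and centred LRR", {
  sim <- fx_null()
  expect_equal(nrow(sim$truth$germline_cnvs), 0)
  expect_equal(nrow(sim$truth$mosaic_arms), 0)
  n <- ncol(sim$panel$lrr)
  tol <- 3 * sim$cfg$lrr_sd / sqrt(n)
  expect_true(all(abs(rowMeans(sim$panel$lrr)) < tol))
  expect_true(all(sim$panel$baf >= 0 & sim$panel$baf <= 1))
})

test_that("implanted CNV emissions sit at the configured state means", {
  sim <- fx_cnv()
  map <- sim$map
  mu <- sim$cfg$lrr_means
  for (j in seq_len(nrow(sim$implants))) {
    im <- sim$implants[j, ]
    i <- match(im$sample_id, sim$samples$sample_id)
    idx <- markers_in(map, im$chrom, im$start, im$end)
    expect_gt(length(idx), 10)
    expect_lt(abs(mean(sim$panel$lrr[i, idx]) - mu[im$cn + 1]), 0.1)
  }
  # CN1 deletion: no heterozygote band left beyond the cluster-tail rate
  del <- sim$implants[1, ]
  i <- match(del$sample_id, sim$samples$sample_id)
  idx <- markers_in(map, del$chrom, del$start, del$end)
  idx <- idx[map$probe_class[idx] == "snp"]
  mid <- mean(sim$panel$baf[i, idx] > 0.2 & sim$panel$baf[i, idx] < 0.8)
  expect_lt(mid, 0.02)
})

test_that("mosaic heterozygote bands follow the mixture geometry", {
  imp <- tibble::tibble(sample_id = "S0001", chrom = "1", arm = "q",
                        direction = "loss", fraction = 0.5)
  cfg <- sim_config(chrom_lengths = c(`1` = 12e6), n_markers = 800,
                    n_cases = 3, n_controls = 3, implant_mosaics = imp,
                    seed = 104)
  map <- build_marker_map(cfg)
  sim <- simulate_cohort(map, cfg)
  idx <- which(map$arm == "q" & map$probe_class == "snp")
  baf <- sim$panel$baf[1, idx]
  mid <- baf[baf > 0.15 & baf < 0.85]
  # bands at (1-f)/(2-f) = 1/3 and 1/(2-f) = 2/3 for f = 0.5
  expect_lt(abs(mean(mid[mid < 0.5]) - 1 / 3), 3 * cfg$baf_sd)
  expect_lt(abs(mean(mid[mid >= 0.5]) - 2 / 3), 3 * cfg$baf_sd)
})

test_that("diploid heterozygote rate is binomially calibrated at pfb 0.5", {
  cfg <- sim_config(chrom_lengths = c(`1` = 40e6), n_markers = 2000,
                    n_cases = 5, n_controls = 5, cnv_probe_frac = 0,
                    seed = 105)
  map <- build_marker_map(cfg)
  map$pfb <- 0.5
  sim <- simulate_cohort(map, cfg)
  g <- sim$panel$genotypes
  n_draw <- length(g)
  expect_gte(n_draw, 1e4)
  het <- mean(g == 1L)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / n_draw))
})

test_that("LOH block with haplotype frequency zero is fully homozygous", {
  cfg <- sim_config(chrom_lengths = c(`1` = 12e6), n_markers = 600,
                    n_cases = 10, n_controls = 10,
                    loh = list(enabled = TRUE, hap_freq = 0,
                               source_lrr_shift = 0), seed = 106)
  map <- build_marker_map(cfg)
  sim <- simulate_cohort(map, cfg)
  idx <- match(sim$truth$loh$marker_ids, map$marker_id)
  baf <- sim$panel$baf[, idx]
  expect_true(all(baf < 0.2 | baf > 0.8))
  expect_true(all(sim$panel$genotypes[, idx] == 0L))
})

test_that("null VNTR injection is indistinguishable from ordinary probes", {
  cfg <- sim_config(chrom_lengths = c(`1` = 12e6), n_markers = 600,
                    n_cases = 15, n_controls = 15,
                    vntr = list(enabled = TRUE, slope = 0, source_shift = 0,
                                probe_noise_sd = 0.15),
                    seed = 107)
  map <- build_marker_map(cfg)
  sim <- simulate_cohort(map, cfg)
  vidx <- match(sim$truth$vntr$probe_ids, sim$panel$markers$marker_id)
  oidx <- setdiff(which(sim$panel$markers$probe_class == "cnv_probe"), vidx)
  p <- t.test(as.vector(sim$panel$lrr[, vidx]),
              as.vector(sim$panel$lrr[, oidx]))$p.value
  expect_gt(p, 0.01)
})

test_that("gender-linked pattern B separates the sexes in signal space", {
  cfg <- sim_config(chrom_lengths = c(`1` = 12e6), n_markers = 600,
                    n_cases = 15, n_controls = 15, with_xy = TRUE,
                    gender_linked = list(n_b = 2), seed = 108)
  map <- build_marker_map(cfg)
  sim <- simulate_cohort(map, cfg)
  inj <- sim$truth$gender_linked_markers
  expect_equal(nrow(inj), 2)
  male <- sim$panel$samples$sex == "male"
  for (id in inj$marker_id) {
    m <- match(id, map$marker_id)
    baf <- sim$panel$baf[, m]
    # females heterozygous-like, males homozygous-like
    expect_true(all(baf[!male] > 0.3 & baf[!male] < 0.7))
    expect_true(all(baf[male] < 0.3 | baf[male] > 0.7))
    # hemizygous intensity drop shifts male total intensity R = X + Y down
    r <- sim$panel$x[, m] + sim$panel$y[, m]
    expect_lt(mean(r[male]) + 0.1, mean(r[!male]))
  }
})
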