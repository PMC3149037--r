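make_map <- function(n = 100, spacing = 10000L) {
  tibble::tibble(marker_id = sprintf("m%03d", seq_len(n)), chrom = "1",
                 arm = "p", pos = seq_len(n) * spacing,
                 probe_class = "snp", pfb = 0.5,
                 unstable_region = FALSE, gender_linked = FALSE)
}

call_row <- function(sample_id, start, end, cn, map) {
  n_mk <- sum(map$pos >= start & map$pos <= end)
  tibble::tibble(sample_id = sample_id, chrom = "1", start = start,
                 end = end, cn = cn, n_markers = n_mk,
                 length_bp = end - start + 1, confidence = 20)
}

test_that("probe recurrence counts direction-specific events per call", {
  map <- make_map()
  calls <- call_row("S1", 10000, 50000, 1L, map)
  rec <- probe_recurrence(calls, map)
  expect_equal(nrow(rec), 5)
  expect_true(all(rec$n_deleted == 1 & rec$n_duplicated == 0))
  # three samples deleted over a shared probe reach the Common threshold
  calls3 <- dplyr::bind_rows(
    call_row("S1", 10000, 50000, 1L, map),
    call_row("S2", 30000, 70000, 1L, map),
    call_row("S3", 40000, 90000, 3L, map))
  rec3 <- probe_recurrence(calls3, map)
  shared <- rec3[rec3$marker_id == "m004", ]
  expect_equal(shared$n_deleted + shared$n_duplicated, 3)
  expect_equal(nrow(probe_recurrence(calls[0, ], map)), 0)
  corrupt <- call_row("S1", 10001, 10002, 1L, map)
  expect_error(probe_recurrence(corrupt, map), "zero markers")
})

test_that("filter membership honours every boundary contract", {
  map <- make_map(300, 10000L)
  genes <- tibble::tibble(chrom = "1", start = 1500000, end = 1600000,
                          name = "GENE1")
  calls <- dplyr::bind_rows(
    call_row("S1", 10000, 160000, 1L, map),    # 150 kb, 16 markers: neither
    call_row("S2", 1000000, 1210000, 1L, map), # 210 kb, 22 markers: conservative
    call_row("S3", 1500000, 1540000, 1L, map), # 5 markers, recurrence 3
    call_row("S4", 1500000, 1540000, 1L, map),
    call_row("S5", 1500000, 1540000, 3L, map))
  cls <- classify_calls(calls, map, genes)
  expect_equal(cls$conservative, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(cls$common, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(cls$in_union, cls$conservative | cls$common)
  # gene-centric implies union and needs only 1 bp of gene overlap
  expect_true(all(cls$gene_centric[3:5]))
  expect_true(all(!cls$gene_centric | cls$in_union))
  # a 4-marker call is never Common regardless of recurrence
  short <- classify_calls(call_row("S9", 1500000, 1530000, 1L, map),
                          map, genes,
                          recurrence = probe_recurrence(calls, map))
  expect_false(short$common)
})

test_that("exact 1 bp gene overlap is enough for the gene-centric set", {
  map <- make_map(50, 10000L)
  genes <- tibble::tibble(chrom = "1", start = 100000, end = 120000)
  touching <- classify_calls(
    dplyr::bind_rows(replicate(3, call_row("S1", 50000, 100000, 1L, map),
                               simplify = FALSE)) %>%
      dplyr::mutate(sample_id = c("S1", "S2", "S3")),
    map, genes)
  expect_true(all(touching$gene_centric))
  disjoint <- classify_calls(
    dplyr::bind_rows(replicate(3, call_row("S1", 50000, 90000, 1L, map),
                               simplify = FALSE)) %>%
      dplyr::mutate(sample_id = c("S1", "S2", "S3")),
    map, genes)
  expect_false(any(disjoint$gene_centric))
})

test_that("filter accounting obeys inclusion-exclusion on any input", {
  map <- make_map(500, 10000L)
  set.seed(7)
  calls <- dplyr::bind_rows(lapply(1:40, function(j) {
    s <- sample(400, 1) * 10000
    w <- sample(4:30, 1) * 10000
    call_row(sprintf("S%02d", sample(8, 1)), s, min(s + w, 5e6),
             sample(c(1L, 3L), 1), map)
  }))
  cls <- classify_calls(calls, map, genes = NULL)
  acc <- filter_accounting(cls)
  expect_equal(acc$counts$union,
               acc$counts$conservative + acc$counts$common -
                 acc$counts$intersection)
  expect_equal(acc$counts$total, acc$counts$union + acc$counts$unanalyzed)
  expect_equal(sum(acc$rejected_bins$n), acc$counts$unanalyzed)
  # relaxing the recurrence threshold never shrinks the Common set
  cls2 <- classify_calls(calls, map, genes = NULL, recurrence_min = 2)
  expect_gte(sum(cls2$common), sum(cls$common))
  expect_true(all(cls$common <= cls2$common))
})

test_that("direction-specific recurrence is stricter than pooled", {
  map <- make_map(100, 10000L)
  calls <- dplyr::bind_rows(
    call_row("S1", 100000, 150000, 1L, map),
    call_row("S2", 100000, 150000, 3L, map),
    call_row("S3", 100000, 150000, 3L, map))
  pooled <- classify_calls(calls, map, genes = NULL, pool_directions = TRUE)
  split <- classify_calls(calls, map, genes = NULL, pool_directions = FALSE)
  expect_true(all(pooled$common))
  expect_false(any(split$common))  # 1 deletion + 2 duplications < 3 each way
})
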