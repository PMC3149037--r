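test_that("qPCR proportions classify by the exclusive 0.80/1.20 limits", {
  expect_equal(qpcr_classify(0.74, 1)$verdict, "deletion")
  expect_equal(qpcr_classify(1.57, 1)$verdict, "duplication")
  expect_equal(qpcr_classify(1.00, 1)$verdict, "normal")
  # bounds are exclusive: exactly 0.80 and 1.20 are normal
  expect_equal(qpcr_classify(0.80, 1)$verdict, "normal")
  expect_equal(qpcr_classify(1.20, 1)$verdict, "normal")
  # replicates are averaged against their own control means first
  res <- qpcr_classify(c(15, 16), list(c(20, 20), c(20, 20)))
  expect_equal(res$proportion, mean(c(15 / 20, 16 / 20)))
  expect_equal(res$verdict, "deletion")
  expect_error(qpcr_classify(-1, 1), "non-positive")
  expect_error(qpcr_classify(1, 0), "positive")
})

test_that("MLPA ratios classify with inclusive normal bounds", {
  expect_equal(mlpa_classify(1.0)$verdict, "normal")
  expect_equal(mlpa_classify(0.5)$verdict, "deletion")  # one of two copies
  expect_equal(mlpa_classify(0.8)$verdict, "normal")
  expect_equal(mlpa_classify(1.2)$verdict, "normal")
  expect_equal(mlpa_classify(1.201)$verdict, "duplication")
  # pure threshold function over the whole ratio range
  r <- seq(0.05, 2.5, by = 0.05)
  v <- mlpa_classify(r)$verdict
  expect_equal(v, ifelse(r < 0.8, "deletion",
                         ifelse(r > 1.2, "duplication", "normal")))
  expect_true(all(v[order(r)] == c(sort(v[r < 0.8]),
                                   rep("normal", sum(r >= 0.8 & r <= 1.2)),
                                   rep("duplication", sum(r > 1.2)))))
})

test_that("gel sizing interpolates between the two nearest ladder bands", {
  ladder <- data.frame(pixel = c(100, 200, 300), bp = c(1000, 900, 800))
  at_band <- gel_size_and_repeats(200, ladder, flank_bp = 4)
  expect_equal(at_band$size_bp, 900)
  expect_equal(at_band$n_repeats, (900 - 4) / 32)
  expect_equal(at_band$n_repeats_rounded, 28)
  halfway <- gel_size_and_repeats(150, ladder, flank_bp = 4)
  expect_equal(halfway$size_bp, 950)
  zero <- gel_size_and_repeats(300, ladder, flank_bp = 800)
  expect_equal(zero$n_repeats, 0)
  expect_error(gel_size_and_repeats(50, ladder, 4), "outside")
})

test_that("repeat decomposition recovers a constructed 13+2+13 structure", {
  simple <- repeat_decompose(strrep("ACGT", 5), unit_len = 4)
  expect_equal(nrow(simple$units), 1)
  expect_equal(simple$units$count, 5)
  expect_equal(simple$partial, "")

  # three 32-mer forms differing at exactly two positions
  base <- strrep("ACGTACGTACGTACGTACGTACGTACGTACGT", 1)
  formA <- base
  formB <- sub("^ACGTA", "ACTTA", base)          # position 3 changed
  formC <- sub("CGT$", "CAT", sub("^ACGTA", "ACTTA", base))  # 3 and 30
  seqs <- paste0(strrep(formA, 13), strrep(formB, 2), strrep(formC, 13))
  dec <- repeat_decompose(seqs, unit_len = 32)
  expect_equal(dec$n_units, 28)
  expect_equal(nrow(dec$units), 3)
  expect_equal(dec$units$count, c(13, 2, 13))
  expect_length(dec$variable_positions, 2)

  # trailing partial unit reported, not counted
  with_tail <- repeat_decompose(paste0(strrep(formA, 3), "ACG"), unit_len = 32)
  expect_equal(with_tail$n_units, 3)
  expect_equal(with_tail$partial, "ACG")
  expect_error(repeat_decompose("ACGT", unit_len = 32), "shorter")
})

test_that("decomposition inverts construction for random repeat fixtures", {
  set.seed(9)
  for (r in 1:10) {
    n_var <- sample(2:4, 1)
    variants <- vapply(seq_len(n_var), function(i) {
      paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
    }, character(1))
    variants <- unique(variants)
    counts <- sample(1:6, length(variants), replace = TRUE)
    seqs <- paste(rep(variants, counts), collapse = "")
    dec <- repeat_decompose(seqs, unit_len = 8)
    got <- setNames(dec$units$count, dec$units$variant)
    want <- tapply(rep(counts, 1), variants, sum)
    expect_equal(sum(dec$units$count), sum(counts))
    expect_setequal(dec$units$variant, unique(variants))
  }
})

test_that("summed-allele t-test matches the closed form and its edge cases", {
  expect_equal(summed_allele_test(c(5, 6, 7), c(5, 6, 7))$p_value, 1,
               tolerance = 1e-12)
  burst <- summed_allele_test(c(10, 10, 10), c(20, 20, 20))
  expect_lt(burst$p_value, 0.01)
  same <- summed_allele_test(c(10, 10, 10), c(10, 10, 10))
  expect_equal(same$p_value, 1)
  set.seed(13)
  a <- rnorm(8, 50, 4); b <- rnorm(11, 56, 4)
  got <- summed_allele_test(a, b)
  sp <- sqrt(((8 - 1) * var(a) + (11 - 1) * var(b)) / (8 + 11 - 2))
  t_manual <- (mean(a) - mean(b)) / (sp * sqrt(1 / 8 + 1 / 11))
  expect_equal(got$t, t_manual, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * pt(-abs(t_manual), 17), tolerance = 1e-12)
  expect_error(summed_allele_test(1, c(2, 3)), "n >= 2")
})
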