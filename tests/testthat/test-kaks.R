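test_that("codon alignment of an identical pair keeps every codon", {
  set.seed(21)
  a <- random_sense_cds(100)
  aln <- codon_align(a, a)
  expect_identical(aln$L, 100L)
  expect_identical(aln$a, aln$b)
})

test_that("codon alignment drops a deleted codon cleanly", {
  set.seed(22)
  a <- random_sense_cds(100)
  b <- paste0(substr(a, 1, 150), substr(a, 154, nchar(a)))  # codon 51 gone
  aln <- codon_align(a, b)
  expect_identical(aln$L, 99L)
  codons_a <- substring(a, seq(1, 298, 3), seq(3, 300, 3))
  expect_identical(aln$a, codons_a[-51])
})

test_that("back-threaded codon identity matches the substitution pattern", {
  set.seed(23)
  for (k in 1:5) {
    a <- random_sense_cds(50)
    repeat {  # keep b stop-free so no alignment column is filtered
      b <- retrotracer:::apply_substitutions(a, 8)
      if (!grepl("\\*", translate_cds(b))) break
    }
    aln <- codon_align(a, b)
    # stops/N are absent here, so only whole-codon columns survive and the
    # mismatch columns are exactly the mutated codons
    expect_identical(sum(aln$a != aln$b),
                     sum(substring(a, seq(1, 148, 3), seq(3, 150, 3)) !=
                           substring(b, seq(1, 148, 3), seq(3, 150, 3))))
  }
})

test_that("NG86 returns zero divergence for identical sequences", {
  set.seed(24)
  a <- random_sense_cds(60)
  r <- ng86(codon_align(a, a))
  expect_identical(r$ka, 0)
  expect_identical(r$ks, 0)
  expect_true(is.na(r$omega))
  expect_equal(r$N + r$S, 3 * r$L)
})

test_that("pure synonymous third-position changes give Ka = 0", {
  # 5 changed TTT->TTC codons among 25 unchanged: all differences synonymous
  a <- paste(rep("TTT", 30), collapse = "")
  b <- paste(c(rep("TTC", 5), rep("TTT", 25)), collapse = "")
  r <- ng86(codon_align(a, b))
  expect_identical(r$Nd, 0)
  expect_identical(r$ka, 0)
  expect_gt(r$ks, 0)
  # with every codon changed the synonymous proportion saturates
  b_all <- paste(rep("TTC", 30), collapse = "")
  r_all <- ng86(codon_align(a, b_all))
  expect_identical(r_all$Nd, 0)
  expect_true(r_all$saturated_ks)
})

test_that("NG86 site and difference counts match the brute-force oracle", {
  set.seed(25)
  for (k in 1:20) {
    a <- random_sense_cds(100)
    b <- retrotracer:::apply_substitutions(a, sample(5:40, 1))
    aln <- codon_align(a, b)
    r <- ng86(aln)
    o <- oracle_ng86_counts(aln$a, aln$b)
    expect_equal(r$N, o$N, tolerance = 1e-12)
    expect_equal(r$S, o$S, tolerance = 1e-12)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-12)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-12)
  }
})

test_that("NG86 is symmetric in its two sequences", {
  set.seed(26)
  for (k in 1:5) {
    a <- random_sense_cds(80)
    b <- retrotracer:::apply_substitutions(a, 20)
    r1 <- ng86(codon_align(a, b))
    r2 <- ng86(codon_align(b, a))
    expect_identical(r1$ka, r2$ka)
    expect_identical(r1$ks, r2$ks)
    expect_identical(r1$N, r2$N)
  }
})

test_that("dating follows T = Ks / 2 lambda", {
  dp <- dating_params()
  expect_equal(dp$lambda_per_year, 0.4e-8 / 3)
  expect_identical(estimate_age(0, dp), 0)
  expect_equal(round(estimate_age(0.02, dp), 1), 7.5)
  expect_equal(round(estimate_age(0.0266, dating_params(
    rate_per_generation = 1.33e-9 * 3)), 1), 10.0)
  # linear in Ks
  k <- 0.037
  expect_equal(estimate_age(2 * k, dp), 2 * estimate_age(k, dp))
})

test_that("selection classes partition the omega scale", {
  expect_identical(classify_selection(0.3, 0.1), "constrained")
  expect_identical(classify_selection(0.5, 0.1), "intermediate")
  expect_identical(classify_selection(1.2, 0.1), "intermediate")
  expect_identical(classify_selection(1.21, 0.1), "elevated")
  expect_identical(classify_selection(NA_real_, 0), "undefined")
  expect_identical(classify_selection(NA_real_, NA_real_), "undefined")
  expect_identical(classify_selection(c(0.3, 0.7, 2), c(0.1, 0.1, 0.1)),
                   c("constrained", "intermediate", "elevated"))
})

test_that("Ks histogram pools the [1,2) and [2,Inf) tails", {
  h <- ks_histogram(rep(0.03, 10))
  expect_identical(h$bins$count[h$bins$lower == 0.02], 10)
  expect_identical(h$bins$fraction[h$bins$lower == 0.02], 1)
  expect_identical(h$bins$lower[h$modal_bin], 0.02)

  h2 <- ks_histogram(c(0.5, 1.5, 2.5))
  expect_identical(h2$bins$count[h2$bins$lower == 0.5], 1)
  expect_identical(h2$bins$count[h2$bins$lower == 1 & h2$bins$upper == 2], 1)
  expect_identical(h2$bins$count[is.infinite(h2$bins$upper)], 1)
})

test_that("short alignments are flagged rather than estimated", {
  a <- random_sense_cds(5)
  r <- ng86(codon_align(a, a))
  expect_true(r$too_short)
  expect_true(is.na(r$ka))
})
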