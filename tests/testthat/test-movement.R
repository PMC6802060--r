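test_meta <- data.frame(
  chrom = c("chr2", "chr5", "chrX", "scaffold_17"),
  is_x = c(FALSE, FALSE, TRUE, FALSE),
  is_scaffold_mt = c(FALSE, FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE)

test_that("movement categories follow chromosome identity and type", {
  expect_identical(classify_movement("chr2", "chr5", test_meta),
                   "interchromosomal")
  expect_identical(classify_movement("chr2", "chr2", test_meta),
                   "intrachromosomal")
  expect_identical(classify_movement("chr2", "scaffold_17", test_meta),
                   "scaffold_mt")
  expect_identical(classify_movement("chrX", "chr2", test_meta),
                   "interchromosomal")
})

test_that("movement fractions reproduce published-style percentages", {
  mv <- data.frame(category = rep(c("interchromosomal", "intrachromosomal",
                                    "scaffold_mt"), c(2902, 77, 46)))
  fr <- movement_fractions(mv)
  expect_identical(round(fr$percent, 2), c(95.93, 2.55, 1.52))
  expect_equal(sum(fr$n), 3025)
  expect_equal(sum(fr$percent), 100)

  same <- data.frame(category = rep("intrachromosomal", 10))
  fr2 <- movement_fractions(same)
  expect_identical(fr2$percent, c(0, 100, 0))

  expect_error(movement_fractions(mv[0, , drop = FALSE]), "no movement")
})

test_that("functional and neutral sets follow the omega boundaries", {
  catalogue <- data.frame(
    retro_id = c("r1", "r2", "r3", "r4", "r5"),
    class = c("intact", "pseudogene", "intact", "pseudogene", "pseudogene"),
    stringsAsFactors = FALSE)
  kaks <- data.frame(retro_id = catalogue$retro_id,
                     omega = c(0.2, 0.7, 0.7, 0.5, 1.0))
  movements <- data.frame(retro_id = catalogue$retro_id,
                          category = "interchromosomal")
  sets <- select_sets(catalogue, kaks, movements)
  expect_identical(sets$functional$retro_id, "r1")
  expect_identical(sets$neutral$retro_id, "r2")  # 0.5 and 1.0 are excluded
})

test_that("regression on proportional counts gives r = 1 and zero residuals", {
  st <- data.frame(chrom = paste0("chr", 1:8),
                   is_x = c(rep(FALSE, 7), TRUE),
                   n_genes = c(100, 200, 300, 400, 500, 600, 700, 550),
                   length = 1:8 * 1e6,
                   n_parents = 0, n_insertions = 0)
  st$n_parents <- st$n_genes * 0.1
  reg <- regress_counts(st, "n_parents", "n_genes")
  expect_equal(reg$r, 1)
  expect_equal(max(abs(reg$residuals$residual)), 0, tolerance = 1e-10)
  expect_equal(reg$slope, 0.1)
})

test_that("OLS matches the closed form on a hand-computed dataset", {
  st <- data.frame(chrom = paste0("chr", 1:4), is_x = FALSE,
                   n_genes = c(1, 2, 3, 4),
                   n_parents = c(2, 1, 4, 3))
  reg <- regress_counts(st, "n_parents", "n_genes")
  expect_equal(reg$slope, 0.6)       # Sxy/Sxx = 3/5
  expect_equal(reg$intercept, 1.0)   # 2.5 - 0.6 * 2.5
  expect_equal(reg$r, 0.6)           # 3 / sqrt(5 * 5)
})

test_that("an X chromosome on the autosome trend is not an outlier", {
  st <- calibration_chromosomes(n_autosomes = 10)
  st$n_parents <- 0.5 * st$n_genes          # exactly on the line
  xt <- x_outlier_test(st, "n_parents", "n_genes")
  expect_equal(xt$t, 0)
  expect_equal(xt$p, 1)
})

test_that("the autosome fit is unaffected by the presence of the X row", {
  set.seed(61)
  st <- calibration_chromosomes(n_autosomes = 12)
  st$n_parents <- rpois(nrow(st), st$n_genes * 0.05)
  reg_aut <- regress_counts(st, "n_parents", "n_genes", include_x = FALSE)
  xt <- x_outlier_test(st, "n_parents", "n_genes")
  expect_equal(xt$expected,
               reg_aut$intercept + reg_aut$slope * st$n_genes[st$is_x])
})

test_that("too few autosomes abort the outlier test", {
  st <- calibration_chromosomes(n_autosomes = 4)
  st$n_parents <- st$n_genes * 0.1
  expect_error(x_outlier_test(st, "n_parents", "n_genes"), "fewer than 5")
})

test_that("a strong X-origin excess is detected, matched null is not", {
  set.seed(62)
  ct <- calibration_chromosomes()
  p_enriched <- replicate(20, {
    ct$n_parents <- simulate_movement_counts(200, ct, x_multiplier = 3)
    x_outlier_test(ct, "n_parents", "n_genes")$p
  })
  p_null <- replicate(20, {
    ct$n_parents <- simulate_movement_counts(200, ct, x_multiplier = 1)
    x_outlier_test(ct, "n_parents", "n_genes")$p
  })
  expect_lt(median(p_enriched), 0.01)
  expect_gt(median(p_null), 0.1)
})

test_that("movement table and regressions run on the fixture pipeline", {
  fx <- rt_fixture()
  kaks <- kaks_catalogue(fx$disc, fx$sim$genome, fx$sim$models)
  mv <- movement_table(fx$disc$catalogue, fx$sim$models, fx$sim$genome)
  expect_identical(nrow(mv), nrow(fx$disc$catalogue))
  fr <- movement_fractions(mv)
  expect_equal(sum(fr$n), nrow(mv))
  expect_equal(sum(fr$percent), 100)
  sets <- select_sets(fx$disc$catalogue, kaks, mv)
  regs <- movement_regressions(sets, fx$sim$models, fx$sim$genome)
  expect_identical(nrow(regs), 8L)
  expect_true(all(regs$set %in% c("functional", "neutral")))
  ok <- !is.na(regs$r_with_x)
  expect_true(all(abs(regs$r_with_x[ok]) <= 1 + 1e-12))
})
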