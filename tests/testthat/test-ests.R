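test_that("cleaning trims poly-A tails and drops short or low-complexity reads", {
  set.seed(51)
  good <- retrotracer:::random_dna(300, 0.41)
  ests <- c(tailed = paste0(good, strrep("A", 25)),
            short = retrotracer:::random_dna(60, 0.41),
            dimer = strrep("AT", 150),
            mono = paste0(strrep("G", 260), retrotracer:::random_dna(40, 0.5)),
            clean = retrotracer:::random_dna(250, 0.41))
  cl <- clean_ests(ests)
  expect_identical(unname(cl$ests[["tailed"]]), good)
  expect_false("short" %in% names(cl$ests))
  expect_false("dimer" %in% names(cl$ests))
  expect_false("mono" %in% names(cl$ests))
  expect_true("clean" %in% names(cl$ests))
  expect_true("dropped_short" %in% cl$log$action)
  expect_true(any(grepl("dropped", cl$log$action[cl$log$est_id == "dimer"])))
})

test_that("error-free reads map to their source locus; 8% error fails the gate", {
  set.seed(52)
  locus <- random_sense_cds(150)  # 450 bp
  chr <- paste0(retrotracer:::random_dna(20e3, 0.41), locus,
                retrotracer:::random_dna(20e3, 0.41))
  genome <- genome_assembly(c(chr1 = chr))
  read <- substr(locus, 50, 349)
  m_clean <- map_ests(c(e1 = read), genome)
  expect_gte(nrow(m_clean$alignments), 1)
  a <- m_clean$alignments[1, ]
  expect_identical(a$identity, 1)
  expect_equal(a$g_start, 20e3 + 49)
  # reverse-strand read maps to the same place
  m_rc <- map_ests(c(e1 = revcomp(read)), genome)
  expect_identical(m_rc$alignments$g_start[1], a$g_start)
  expect_identical(m_rc$alignments$strand[1], "-")
  # 8% uniform error: identity gate fails
  noisy <- retrotracer:::apply_substitutions(read, round(0.08 * nchar(read)))
  m_noisy <- map_ests(c(e1 = noisy), genome)
  expect_identical(nrow(m_noisy$alignments), 0L)
})

test_that("1% error reads recover the source locus nearly always", {
  set.seed(53)
  locus <- random_sense_cds(150)
  chr <- paste0(retrotracer:::random_dna(15e3, 0.41), locus,
                retrotracer:::random_dna(15e3, 0.41))
  genome <- genome_assembly(c(chr1 = chr))
  ok <- 0L
  for (k in 1:15) {
    read <- substr(locus, 1, 300)
    noisy <- retrotracer:::apply_substitutions(read, rbinom(1, 300, 0.01))
    m <- map_ests(c(e = noisy), genome)
    if (nrow(m$alignments) >= 1 &&
        abs(m$alignments$g_start[1] - 15e3) < 50) ok <- ok + 1L
  }
  expect_gte(ok, 14L)
})

test_that("ambiguous placements are discarded unless one clearly wins", {
  set.seed(54)
  locus <- random_sense_cds(120)
  chr <- paste0(retrotracer:::random_dna(8e3, 0.41), locus,
                retrotracer:::random_dna(8e3, 0.41), locus,
                retrotracer:::random_dna(8e3, 0.41))
  genome <- genome_assembly(c(chr1 = chr))
  read <- substr(locus, 1, 280)
  mapped <- map_ests(c(e1 = read), genome)
  expect_identical(nrow(mapped$alignments), 2L)
  uni <- filter_unique(mapped)
  expect_identical(nrow(uni$alignments), 0L)  # two equal copies: ambiguous
  # synthetic margins: 200 vs 180 passes the 5% margin, 200 vs 195 does not
  fake <- function(s1, s2) list(
    alignments = data.frame(est_id = "e", chrom = "chr1", strand = "+",
                            g_start = c(0, 5000), g_end = c(300, 5300),
                            score = c(s1, s2), identity = 0.99,
                            coverage = 0.95, n_blocks = 1L,
                            stringsAsFactors = FALSE),
    details = list(list(g_pos = 1:300, match = rep(1L, 300)),
                   list(g_pos = 5001:5300, match = rep(1L, 300))))
  expect_identical(nrow(filter_unique(fake(200, 180))$alignments), 1L)
  expect_identical(nrow(filter_unique(fake(200, 195))$alignments), 0L)
})

test_that("support requires >100 bp overlap at >97% identity", {
  catalogue <- data.frame(retro_id = "rc0001", chrom = "chr1", strand = "+",
                          start = 1000, end = 1600, class = "intact",
                          stringsAsFactors = FALSE)
  mk_mapped <- function(g_start, g_end, match_rate = 1) {
    n <- g_end - g_start
    list(alignments = data.frame(
      est_id = "e1", chrom = "chr1", strand = "+", g_start = g_start,
      g_end = g_end, score = n, identity = 0.99, coverage = 0.95,
      n_blocks = 1L, stringsAsFactors = FALSE),
      details = list(list(g_pos = (g_start + 1):g_end,
                          match = rbinom(n, 1, match_rate))))
  }
  expect_identical(count_support(mk_mapped(920, 1000 + 80), catalogue)$n_supporting_ests, 0L)
  expect_identical(count_support(mk_mapped(900, 1400), catalogue)$n_supporting_ests, 1L)
  set.seed(55)
  low <- mk_mapped(900, 1400, match_rate = 0.9)  # ~90% identity in overlap
  expect_identical(count_support(low, catalogue)$n_supporting_ests, 0L)
  # empty EST set
  empty <- list(alignments = mk_mapped(900, 1400)$alignments[0, ],
                details = list())
  expect_identical(count_support(empty, catalogue)$n_supporting_ests, 0L)
})

test_that("loosening thresholds never decreases support counts", {
  fx <- rt_fixture()
  strict <- est_params()
  loose <- est_params(support_min_overlap = 50L, support_min_identity = 0.90,
                      min_identity = 0.93, min_coverage = 0.85)
  s1 <- est_support(fx$sim$ests, fx$sim$genome, fx$disc$catalogue, strict)
  s2 <- est_support(fx$sim$ests, fx$sim$genome, fx$disc$catalogue, loose)
  m <- merge(s1$support, s2$support, by = "retro_id")
  expect_true(all(m$n_supporting_ests.y >= m$n_supporting_ests.x))
})

test_that("supported retrocopies recover the expressed truth set", {
  fx <- rt_fixture()
  sup <- est_support(fx$sim$ests, fx$sim$genome, fx$disc$catalogue)
  tr <- fx$sim$truth[fx$sim$truth$type == "retro", ]
  hits <- match_truth(fx$sim$truth, fx$disc$catalogue)
  truth_expressed <- character(0)
  for (r in seq_len(nrow(tr))) {
    if (length(hits[[r]]) && tr$expressed[r])
      truth_expressed <- c(truth_expressed,
                           fx$disc$catalogue$retro_id[hits[[r]][1]])
  }
  called <- sup$support$retro_id[sup$support$n_supporting_ests > 0]
  precision <- if (length(called)) mean(called %in% truth_expressed) else 1
  recall <- if (length(truth_expressed))
    mean(truth_expressed %in% called) else 1
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.8)
})

test_that("support output is deterministic", {
  fx <- rt_fixture()
  s1 <- est_support(fx$sim$ests, fx$sim$genome, fx$disc$catalogue)
  s2 <- est_support(fx$sim$ests, fx$sim$genome, fx$disc$catalogue)
  expect_identical(s1$support, s2$support)
})
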