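make_test_genome <- function(..., gc = 0.41) {
  genome_assembly(c(...))
}

test_that("a protein finds its exact back-translated copy at full identity", {
  set.seed(31)
  cds <- random_sense_cds(100)
  prot <- translate_cds(cds)
  chr <- paste0(retrotracer:::random_dna(3000, 0.41), cds,
                retrotracer:::random_dna(3000, 0.41))
  genome <- make_test_genome(chr1 = chr)
  hsps <- search_protein_vs_genome(prot, "p1", genome)
  expect_gte(nrow(hsps), 1)
  best <- hsps[which.max(hsps$score), ]
  expect_identical(best$strand, "+")
  expect_identical(best$identity, 1)
  expect_identical(c(best$p_start, best$p_end), c(1L, 100L))
  expect_identical(c(best$g_start, best$g_end), c(3000, 3300))
})

test_that("reverse-complement insertions are found on '-' with equal score", {
  set.seed(32)
  cds <- random_sense_cds(90)
  prot <- translate_cds(cds)
  pad1 <- retrotracer:::random_dna(2500, 0.41)
  pad2 <- retrotracer:::random_dna(2500, 0.41)
  g_fwd <- make_test_genome(chr1 = paste0(pad1, cds, pad2))
  g_rev <- make_test_genome(chr1 = paste0(pad1, revcomp(cds), pad2))
  h_fwd <- search_protein_vs_genome(prot, "p1", g_fwd)
  h_rev <- search_protein_vs_genome(prot, "p1", g_rev)
  b_fwd <- h_fwd[which.max(h_fwd$score), ]
  b_rev <- h_rev[which.max(h_rev$score), ]
  expect_identical(b_rev$strand, "-")
  expect_identical(b_rev$score, b_fwd$score)
  expect_identical(b_rev$identity, 1)
  expect_identical(c(b_rev$g_start, b_rev$g_end), c(2500, 2770))
})

test_that("partial copies below 50 aligned amino acids are rejected", {
  set.seed(33)
  cds <- random_sense_cds(60)
  prot <- translate_cds(cds)
  partial <- substr(cds, 1, 45 * 3)  # 45-aa fragment
  genome <- make_test_genome(chr1 = paste0(retrotracer:::random_dna(2000, 0.41),
                                           partial,
                                           retrotracer:::random_dna(2000, 0.41)))
  hsps <- search_protein_vs_genome(prot, "p1", genome)
  expect_identical(nrow(hsps), 0L)
})

test_that("collinear HSPs chain within the intron bound, crossed ones do not", {
  base <- data.frame(protein_id = "p", chrom = "chr1", strand = "+",
                     frame = 0L, score = 100, identity = 0.9, aligned = 60L,
                     stringsAsFactors = FALSE)
  two <- rbind(base, base)
  two$p_start <- c(1L, 61L); two$p_end <- c(60L, 120L)
  two$g_start <- c(1000, 5180); two$g_end <- c(1180, 5360)  # 2 kb apart
  loci <- chain_hsps(two)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$n_hsps, 2L)
  expect_identical(c(loci$start, loci$end), c(1000, 5360))

  far <- two; far$g_start[2] <- 550e3; far$g_end[2] <- 550e3 + 180
  expect_identical(nrow(chain_hsps(far)), 2L)

  crossed <- two
  crossed$p_start <- c(61L, 1L); crossed$p_end <- c(120L, 60L)
  expect_identical(nrow(chain_hsps(crossed)), 2L)
})

test_that("chaining matches brute-force enumeration on random HSP sets", {
  set.seed(34)
  for (k in 1:5) {
    n <- sample(3:6, 1)
    h <- data.frame(
      protein_id = "p", chrom = "chr1", strand = sample(c("+", "-"), 1),
      frame = 0L,
      p_start = sample(1:200, n), score = sample(50:150, n, TRUE),
      identity = 0.9, aligned = 60L, stringsAsFactors = FALSE)
    h$p_end <- h$p_start + sample(30:80, n, TRUE)
    h$g_start <- sample(1:60000, n)
    h$g_end <- h$g_start + (h$p_end - h$p_start) * 3
    loci <- chain_hsps(h)
    expect_equal(max(loci$score), oracle_best_chain_score(h))
  }
})

test_that("the spliced aligner recovers parent gene structures exactly", {
  fx <- rt_fixture()
  for (gid in names(fx$sim$models)[1:3]) {
    m <- fx$sim$models[[gid]]
    sp <- model_span(m)
    st <- align_locus(fx$sim$proteins[[m$protein_id]], fx$sim$genome,
                      m$chrom, m$strand, sp[1], sp[2])
    expect_false(isTRUE(st$rejected))
    expect_identical(st$n_intron, nrow(m$exons) - 1L)
    expect_length(st$frameshift_pos, 0)
    expect_length(st$stop_pos, 0)
    expect_identical(st$identity, 1)
    expect_identical(st$coverage, 1)
  }
})

test_that("an intronless mutation-free copy parses with no introns", {
  set.seed(35)
  cds <- random_sense_cds(120)
  st <- spliced_align(translate_cds(cds), cds)
  expect_identical(st$n_intron, 0L)
  expect_identical(st$coverage, 1)
  expect_identical(st$identity, 1)
})

test_that("single-base deletions are reported near the disrupted codon", {
  set.seed(36)
  hits <- 0L
  for (k in 1:20) {
    cds <- random_sense_cds(120)
    pos_codon <- sample(20:100, 1)
    del <- (pos_codon - 1) * 3 + 2
    mut <- paste0(substr(cds, 1, del - 1), substr(cds, del + 1, nchar(cds)))
    st <- spliced_align(translate_cds(cds), mut)
    if (length(st$frameshift_pos) == 1 &&
        abs(st$frameshift_pos - pos_codon) <= 2) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("six-frame search scores are preserved under genome reversal", {
  set.seed(37)
  cds <- random_sense_cds(80)
  prot <- translate_cds(cds)
  chr <- paste0(retrotracer:::random_dna(2000, 0.41), cds,
                retrotracer:::random_dna(2000, 0.41))
  g1 <- make_test_genome(chr1 = chr)
  g2 <- make_test_genome(chr1 = revcomp(chr))
  h1 <- search_protein_vs_genome(prot, "p1", g1)
  h2 <- search_protein_vs_genome(prot, "p1", g2)
  expect_identical(sort(h1$score), sort(h2$score))
  expect_identical(sort(h1$identity), sort(h2$identity))
  # strands swap, coordinates mirror
  b1 <- h1[which.max(h1$score), ]; b2 <- h2[which.max(h2$score), ]
  expect_identical(b2$strand, "-")
  expect_identical(b2$g_start, nchar(chr) - b1$g_end)
})

test_that("the spliced DP attains the exhaustively enumerated optimum", {
  set.seed(38)
  p <- spliced_align_params(min_intron = 10L)
  S <- retrotracer:::score_matrix()
  cases <- list()
  # exact 4-codon match
  cds <- random_sense_cds(4)
  cases[["exact"]] <- list(prot = translate_cds(cds), dna = cds)
  # 1-bp deletion inside
  mut <- paste0(substr(cds, 1, 5), substr(cds, 7, 12))
  cases[["fs"]] <- list(prot = translate_cds(cds), dna = mut)
  # phase-0 intron of 12 bp between codons 2 and 3
  intr <- paste0("GT", "ACACACAC", "AG")
  cases[["intron"]] <- list(prot = translate_cds(cds),
                            dna = paste0(substr(cds, 1, 6), intr,
                                         substr(cds, 7, 12)))
  for (k in 1:3) {
    cds_k <- random_sense_cds(4)
    dna_k <- retrotracer:::apply_substitutions(cds_k, 2)
    cases[[paste0("rand", k)]] <- list(prot = translate_cds(cds_k), dna = dna_k)
  }
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    st <- spliced_align(cs$prot, cs$dna, p)
    got <- if (isTRUE(st$rejected)) st$score else st$score
    want <- oracle_spliced_score(cs$prot, cs$dna, S, p$fs_pen, p$intron_pen,
                                 p$gap_pen, p$min_intron)
    expect_equal(got, want, info = nm)
  }
})
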