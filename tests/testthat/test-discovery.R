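fake_structure <- function(chrom, start, end, n_intron = 0L,
                           rejected = FALSE) {
  structure(list(rejected = rejected, n_intron = n_intron, chrom = chrom,
                 g_start = start, g_end = end, score = 100),
            class = "spliced_structure")
}

test_that("candidate calling keeps intronless non-self structures only", {
  self <- gene_model("gQ", "tQ", "chr1", "+",
                     cbind(start = c(1000, 2000), end = c(1500, 2600)))
  sts <- list(
    fake_structure("chr1", 950, 2650, n_intron = 1L),    # self parse, introns
    fake_structure("chr1", 1100, 1400),                  # overlaps own gene
    fake_structure("chr1", 50000, 50900),                # true candidate
    fake_structure("chr2", 100, 1000, n_intron = 2L),    # introns elsewhere
    fake_structure("chr2", 5000, 5900))                  # candidate
  out <- call_candidates(sts, self)
  expect_length(out, 2)
  expect_identical(vapply(out, `[[`, numeric(1), "g_start"), c(50000, 5000))
})

test_that("parent assignment recovers the source gene at full identity", {
  set.seed(41)
  cds <- random_sense_cds(100)
  prot <- translate_cds(cds)
  st <- spliced_align(prot, cds)   # mutation-free copy
  models <- list(
    gA = gene_model("gA", "tA", "chr9", "+",
                    cbind(start = c(0, 200), end = c(150, 350)),
                    protein_id = "pA"))
  proteins <- c(pA = prot)
  pa <- assign_parent(st, proteins, models)
  expect_identical(pa$parent_gene, "gA")
  expect_identical(pa$identity, 1)
})

test_that("a best hit on a single-exon gene discards the candidate", {
  set.seed(42)
  cds <- random_sense_cds(90)
  prot <- translate_cds(cds)
  st <- spliced_align(prot, cds)
  single <- list(gS = gene_model("gS", "tS", "chr9", "+",
                                 cbind(start = 0, end = 270),
                                 protein_id = "pS"))
  expect_null(assign_parent(st, c(pS = prot), single))
})

test_that("tied parents break deterministically by gene id", {
  set.seed(43)
  cds <- random_sense_cds(80)
  prot <- translate_cds(cds)
  st <- spliced_align(prot, cds)
  mk <- function(g, p) gene_model(g, paste0("t", g), "chr9", "+",
                                  cbind(start = c(0, 200), end = c(120, 320)),
                                  protein_id = p)
  models <- list(gB = mk("gB", "pB"), gA = mk("gA", "pA"))
  proteins <- c(pB = prot, pA = prot)  # identical sequences, tied scores
  pa <- assign_parent(st, proteins, models)
  expect_identical(pa$parent_gene, "gA")
})

test_that("intron retention is detected for DNA-level duplicates", {
  # a gene with two large exons; its 'candidate' is a window over one exon
  # of an exact genomic (intron-retaining) copy
  set.seed(44)
  k <- 160
  cds <- random_sense_cds(k)
  ex1 <- substr(cds, 1, 240); ex2 <- substr(cds, 241, k * 3)
  intron <- paste0("GT", retrotracer:::random_dna(116, 0.41), "AG")
  gene_seg <- paste0(ex1, intron, ex2)
  pad <- function(n) retrotracer:::random_dna(n, 0.41)
  chr <- paste0(pad(2500), gene_seg, pad(3000), gene_seg, pad(2500))
  genome <- genome_assembly(c(chr1 = chr))
  g_off <- 2500
  dup_off <- 2500 + nchar(gene_seg) + 3000
  model <- gene_model("gD", "tD", "chr1", "+",
                      cbind(start = c(g_off, g_off + 240 + 120),
                            end = c(g_off + 240, g_off + nchar(gene_seg))),
                      protein_id = "pD")
  prot <- translate_cds(cds)
  # candidate restricted to the duplicate's first exon looks intronless
  st <- align_locus(prot, genome, "chr1", "+", dup_off, dup_off + 240,
                    flank = 0L)
  expect_identical(st$n_intron, 0L)
  expect_false(check_intron_loss(st, model, prot, genome))
  # a genuine intronless retrocopy passes the same check
  chr2 <- paste0(pad(2500), cds, pad(2500))
  genome2 <- genome_assembly(c(chr1 = chr2))
  st2 <- align_locus(prot, genome2, "chr1", "+", 2500, 2500 + nchar(cds),
                     flank = 0L)
  expect_true(check_intron_loss(st2, model, prot, genome2))
})

test_that("classification counts frameshifts and premature stops", {
  set.seed(45)
  cds <- random_sense_cds(200)
  prot <- translate_cds(cds)
  clean <- spliced_align(prot, cds)
  expect_identical(classify_structure(clean, nchar(prot)), "intact")
  stopd <- cds
  substr(stopd, 118, 120) <- "TGA"   # codon 40 of 200
  st <- spliced_align(prot, stopd)
  expect_identical(classify_structure(st, nchar(prot)), "pseudogene")
})

test_that("chimeric flags require an intact copy inside a foreign host", {
  host <- gene_model("gH", "tH", "chr1", "+",
                     cbind(start = c(1000, 9000), end = c(1300, 9300)))
  models <- list(gH = host,
                 gP = gene_model("gP", "tP", "chr2", "+",
                                 cbind(start = c(0, 500), end = c(300, 800))))
  # intact copy inside gH's intron, same strand
  expect_true(flag_chimeric("chr1", "+", 3000, 3600, "intact", "gP", models))
  # intergenic
  expect_false(flag_chimeric("chr1", "+", 20000, 20600, "intact", "gP", models))
  # pseudogene inside the host intron
  expect_false(flag_chimeric("chr1", "+", 3000, 3600, "pseudogene", "gP", models))
  # opposite strand
  expect_false(flag_chimeric("chr1", "-", 3000, 3600, "intact", "gP", models))
  # host is the parent itself
  expect_false(flag_chimeric("chr1", "+", 3000, 3600, "intact", "gH", models))
})

test_that("end-to-end discovery recovers the fixture truth", {
  fx <- rt_fixture()
  tr <- fx$sim$truth[fx$sim$truth$type == "retro", ]
  hits <- match_truth(fx$sim$truth, fx$disc$catalogue)
  recall <- mean(lengths(hits) > 0)
  expect_gte(recall, 0.9)
  ok_parent <- mapply(function(h, r) length(h) > 0 &&
                        fx$disc$catalogue$parent_gene[h[1]] == tr$parent_gene[r],
                      hits, seq_len(nrow(tr)))
  expect_gte(mean(ok_parent), 0.9)
  ok_class <- mapply(function(h, r) length(h) > 0 &&
                       fx$disc$catalogue$class[h[1]] == tr$class[r],
                     hits, seq_len(nrow(tr)))
  expect_gte(mean(ok_class), 0.9)
})

test_that("catalogue invariants hold", {
  fx <- rt_fixture()
  df <- fx$disc$catalogue
  # intact <=> no disruptions
  expect_identical(df$class == "intact",
                   df$n_frameshift == 0L & df$n_stop == 0L)
  expect_true(all(df$identity > 0.5))
  expect_true(all(df$coverage > 0.5))
  # no parent is single-exon; no record overlaps its parent's locus
  for (i in seq_len(nrow(df))) {
    pm <- fx$sim$models[[df$parent_gene[i]]]
    expect_gte(nrow(pm$exons), 2)
    if (pm$chrom == df$chrom[i]) {
      sp <- model_span(pm)
      expect_identical(retrotracer:::interval_overlap(
        df$start[i], df$end[i], sp[1], sp[2]), 0)
    }
  }
  # chimeric records are intact
  expect_true(all(df$class[df$chimeric] == "intact"))
})

test_that("DNA-level duplicates never reach the catalogue", {
  cfg <- simulation_config(
    seed = 19, chrom_lengths = c(chr1 = 150e3, chr2 = 150e3, chrX = 100e3),
    n_genes = 8, n_retro_events = 6, n_dna_duplicates = 3, n_ests = 0,
    gene_codons = c(150L, 300L), exons_per_gene = c(2L, 3L))
  sim <- simulate_dataset(cfg)
  disc <- discover_retrocopies(sim$genome, sim$models, sim$proteins)
  dups <- sim$truth[sim$truth$type == "dna_duplicate", ]
  for (r in seq_len(nrow(dups))) {
    ov <- disc$catalogue$chrom == dups$chrom[r] &
      pmin(disc$catalogue$end, dups$end[r]) -
        pmax(disc$catalogue$start, dups$start[r]) > 0
    expect_false(any(ov), info = dups$event_id[r])
  }
  # true retrocopies are still recovered
  hits <- match_truth(sim$truth, disc$catalogue)
  expect_gte(mean(lengths(hits) > 0), 0.8)
})

test_that("summaries report totals, fractions and the per-parent distribution", {
  df <- data.frame(
    retro_id = sprintf("rc%02d", 1:6), chrom = "chr1", strand = "+",
    start = 1:6 * 1000, end = 1:6 * 1000 + 500,
    parent_gene = c("g1", "g1", "g1", "g2", "g3", "g4"),
    parent_protein = "p", class = c("intact", "pseudogene", "pseudogene",
                                    "intact", "pseudogene", "pseudogene"),
    chimeric = c(TRUE, rep(FALSE, 5)),
    overlaps_annotation = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    identity = 0.9, coverage = 0.9, n_frameshift = 0L, n_stop = 0L,
    score = 100, stringsAsFactors = FALSE)
  s <- summarize_catalogue(df)
  expect_identical(s$total, 6L)
  expect_identical(s$n_intact + s$n_pseudogene, s$total)
  expect_identical(s$n_parents, 4L)
  expect_identical(s$parents_single, 3L)
  expect_equal(s$mean_per_parent, 1.5)
  expect_identical(unname(s$per_parent["g1"]), 3L)
  expect_identical(s$n_novel, 4L)

  empty <- summarize_catalogue(df[0, ])
  expect_identical(empty$total, 0L)
  expect_identical(empty$intact_fraction, 0)
})

test_that("discovery output is deterministic", {
  fx <- rt_fixture()
  again <- discover_retrocopies(fx$sim$genome, fx$sim$models,
                                fx$sim$proteins)
  expect_identical(again$catalogue, fx$disc$catalogue)
})
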