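# Shared small simulation + discovery, built once per test run and reused
# across test files.

rt_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(
        seed = 7,
        chrom_lengths = c(chr1 = 120e3, chr2 = 120e3, chrX = 80e3),
        n_genes = 10, n_retro_events = 10, n_ests = 60)
      sim <- simulate_dataset(cfg)
      disc <- discover_retrocopies(sim$genome, sim$models, sim$proteins)
      cache <<- list(cfg = cfg, sim = sim, disc = disc)
    }
    cache
  }
})

# map truth retro events to catalogue rows by >50% overlap of the truth span
match_truth <- function(truth, catalogue) {
  tr <- truth[truth$type == "retro", , drop = FALSE]
  lapply(seq_len(nrow(tr)), function(r) {
    hit <- catalogue$chrom == tr$chrom[r] &
      pmin(catalogue$end, tr$end[r]) - pmax(catalogue$start, tr$start[r]) >
        0.5 * (tr$end[r] - tr$start[r])
    which(hit)
  })
}

random_sense_cds <- function(n_codons) {
  paste(c("ATG", sample(retrotracer:::SENSE_CODONS, n_codons - 1L, TRUE)),
        collapse = "")
}
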