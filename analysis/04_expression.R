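#!/usr/bin/env Rscript
# EST transcription support: clean the reads, map them to the genome,
# keep unique placements, and count supporting ESTs per retrocopy with the
# >100 bp / >97% identity overlap rule.

library(retrotracer)

genome <- read_genome("results/sim/genome.fa")
catalogue <- read_tsv("results/catalogue.tsv")
ests <- read_fasta("results/sim/ests.fa")

sup <- est_support(ests, genome, catalogue)
write_tsv(sup$support, "results/est_support.tsv")
write_tsv(sup$summary, "results/est_summary.tsv")

cat(sprintf("ESTs: %d raw, %d after cleaning, %d uniquely mapped\n",
            length(ests), length(sup$cleaned$ests),
            nrow(sup$unique$alignments)))
for (i in seq_len(nrow(sup$summary))) {
  s <- sup$summary[i, ]
  cat(sprintf("  %s retrocopies with >=1 supporting EST: %d/%d (%.1f%%)\n",
              s$class, s$n_supported, s$n, 100 * s$fraction))
}
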