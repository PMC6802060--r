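#!/usr/bin/env Rscript
# Generate the synthetic study dataset: a 2-Mb genome (five autosomes + X)
# carrying 40 multi-exon genes, 50 retrotransposition events and 300 EST
# reads, with the ground-truth event table. All downstream steps read the
# files written here.

library(retrotracer)

out <- "results/sim"
cfg <- simulation_config(seed = 1)
sim <- simulate_dataset(cfg, out_dir = out)

cat("Simulated dataset written to", out, "\n")
cat("  genes:       ", length(sim$models), "\n")
cat("  retro events:", sum(sim$truth$type == "retro"),
    sprintf("(%d intact, %d pseudogene, %d chimeric)\n",
            sum(sim$truth$class == "intact", na.rm = TRUE),
            sum(sim$truth$class == "pseudogene", na.rm = TRUE),
            sum(sim$truth$chimeric)))
cat("  ESTs:        ", length(sim$ests), "\n")
cat("  genome:      ", format(sum(sim$genome$lengths), big.mark = ","),
    "bp on", length(sim$genome$sequences), "chromosomes\n")
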