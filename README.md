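# retrotracer

Retrocopy discovery, molecular dating and chromosomal gene-traffic analysis
for annotated genomes, with a ground-truthed synthetic-genome simulator.

## The problem

Retrotransposition reverse-transcribes a spliced mRNA and inserts the cDNA
at a new genomic locus. The resulting **retrocopy** is intronless, often
poly-A tailed, and recognisable as the single-exon member of a gene pair
whose other member — the **parental gene** — has multiple coding exons.
Most retrocopies decay into **retropseudogenes** (frameshifts, premature
stop codons); some remain intact **retrogenes**, and a few insert into a
host gene's intron and evolve into **chimeric** fusion genes. Synonymous
divergence between copy and parent dates each insertion, and the
chromosomal distribution of functional pairs tests the classic pattern of
biased gene traffic off the X chromosome.

retrotracer is for researchers who want this analysis chain as tested,
reusable functions rather than a pipeline of external binaries:

* **discovery** — six-frame seeded protein-to-genome search (BLOSUM62,
  word size 4), collinear HSP chaining, and a splice- and frameshift-aware
  alignment DP (GT..AG introns, 1–2 bp slips, recorded in-frame stops);
  single-exon calling, best-parent assignment (identity > 50%, overlap
  > 50%, ≥ 50 aa), intron-retention discard, intact/pseudogene
  classification, chimeric flagging;
* **selection & dating** — Nei–Gojobori (NG86) counting with pathway
  averaging and Jukes–Cantor correction: Ka, Ks, ω = Ka/Ks, and the age
  **T = Ks / 2λ** (λ = 1.33 × 10⁻⁹ yr⁻¹ from 0.4 × 10⁻⁸ per generation and
  3-year generations); ω classes `<0.5` / `0.5–1.2` / `>1.2`; Ks histogram
  with pooled tails;
* **expression** — EST cleaning, unique genome mapping (identity > 95%,
  coverage > 90%), and per-retrocopy support (> 100 bp overlap at > 97%
  identity);
* **gene traffic** — movement classification, per-chromosome OLS
  regressions of parent/insertion counts on gene count and length, and an
  X-outlier test (externally studentized residual against an autosome-only
  fit);
* **simulation** — a multi-chromosome genome generator with configurable
  substitution, frameshift, premature-stop, chimeric and expression rates,
  emitting FASTA/GTF/TSV files and a truth table for recovery testing.

## Worked example

The `analysis/` scripts run the whole study end-to-end on the simulated
dataset (`01_simulate.R` … `06_report.R`, writing tables under `results/`).
In short:

```r
library(retrotracer)

sim  <- simulate_dataset(simulation_config(seed = 1))   # 2 Mb, 40 genes, 50 events
disc <- discover_retrocopies(sim$genome, sim$models, sim$proteins)
kaks <- kaks_catalogue(disc, sim$genome, sim$models)
est  <- est_support(sim$ests, sim$genome, disc$catalogue)
mv   <- movement_table(disc$catalogue, sim$models, sim$genome)
make_report(disc$catalogue, kaks, est, mv,
            movement_regressions(select_sets(disc$catalogue, kaks, mv),
                                 sim$models, sim$genome))
```

prints

```
Retrocopy catalogue report
  50 retrocopies from 29 parents (1.72 per parent)
  intact: 28 (56.0%), pseudogene: 22, chimeric: 1
  parents with one retrocopy: 52%
  chimeric rate: 0.04 per Myr over the last 22.5 Myr
  EST-supported intact: 11/28 (39.3%)
  EST-supported pseudogene: 12/22 (54.5%)
  movements: interchromosomal 92.00%, intrachromosomal 8.00%, scaffold_mt 0.00%
```

All 50 simulated events are recovered (recall 1.00), every parent is
assigned correctly, and 49/50 intact/pseudogene labels match the truth
table (`analysis/02_discover.R` prints these comparisons). The 22.5 Myr
window is `estimate_age(0.06)`: the age of a copy at the upper edge of the
recent Ks range, since `T = Ks / 2λ` maps Ks = 0.02–0.06 to 7.5–22.5 Mya.

The same report arithmetic applies to externally supplied counts
(`report_from_counts()`), e.g. a catalogue of 3,025 retrocopies from 1,227
parents with 507 intact copies yields an intact fraction of 16.8%, 2.47
copies per parent, and — with 165/507 and 126/2,518 EST-supported — support
rates of 32.5% and 5.0%.

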