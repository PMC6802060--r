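---
title: "Methods: retrocopy discovery, dating and gene-traffic analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrocopy discovery, dating and gene-traffic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Retrotransposition copies a spliced mRNA back into the genome: the new locus
(a *retrocopy*) carries the parent's coding sequence without introns, often
with a poly-A remnant and a short target-site duplication. Most retrocopies
decay into *retropseudogenes* through frameshifts and premature stop codons;
a minority stay intact (*retrogenes*), occasionally inside another gene's
intron where they can form *chimeric* fusion structures. Because the parent
is multi-exon and the copy is single-exon, such pairs can be recognised
directly from an annotated assembly, and their synonymous divergence dates
the insertion. retrotracer implements this whole chain — discovery,
classification, Ka/Ks estimation, EST-based transcription support, and the
chromosomal gene-traffic analysis (the classic excess of functional gene
movement off the X chromosome) — together with a synthetic-genome simulator
that provides ground truth for validating every step.

# Discovery pipeline

## Six-frame seeded search

Each protein is compared against all six conceptual translation frames of
every chromosome. Seeds are exact 4-amino-acid word matches; seeds clustered
on nearby diagonals are extended by local Smith–Waterman alignment (BLOSUM62,
affine gaps, open 11 / extend 1 — standard translated-search scoring). HSPs
are kept when identity exceeds 50% over at least 50 aligned amino acids with
raw score ≥ 50. We gate on a raw score rather than an E-value:
Karlin–Altschul calibration adds machinery without changing behaviour at
this scale, and every threshold is exposed in `search_params()`. Reported
HSP extents are trimmed to the outermost exact-match columns so that
score-neutral tail creep of a local alignment does not inflate the length
gate.

Same-chromosome, same-strand HSPs that are collinear in both protein and
genome order, within a 50 kb intron bound, are chained into candidate loci
by maximum-score chaining (`chain_hsps()`); the locus is the union envelope
of its members.

## Spliced, frameshift-aware alignment

`spliced_align()` is a dynamic program over (protein position × DNA
position) with four move types: codon match (BLOSUM62 on the codon's
translation), amino-acid/codon skip (linear penalty −12), frameshift (a
residue consumes 1, 2, 4 or 5 bases; penalty −20), and intron (entered only
at `GT`, left only at `AG`, between codons, fixed penalty −25, minimum
length 30 bp). The penalties are chosen so that a genuine GT..AG intron
always beats a chain of frameshifts across it, while a 1–2 bp slip is
cheaper than opening a spurious intron. The parse with maximum local score
wins; parses scoring ≤ 35 are rejected. Stop codons score through the
BLOSUM62 `*` column and their positions are recorded, as are frameshift
positions (in protein coordinates) and intron boundaries.

Only phase-0 (between-codon) introns are modelled; phase-aware intron
states are deliberately out of scope, and the simulator therefore places
introns at codon boundaries. Codons containing `N` score zero against any
residue. The DP is verified against exhaustive parse enumeration on small
inputs and against the simulator's per-event truth (intron counts,
frameshift positions, stop positions) in the test suite.

## Catalogue construction

Structures with zero introns whose locus does not overlap the query's own
gene are candidate retrocopies. Each candidate's conceptual translation is
aligned against the full protein set; the best-scoring hit wins when it
passes identity > 50%, overlap > 50% of the parent protein and ≥ 50 aa, with
ties broken by identity then lexicographic gene id. A candidate whose best
hit is a single-exon gene is discarded — retrocopies must descend from
multi-exon parents. The intron-retention check then re-parses the candidate
locus with ±2 kb flanks using the assigned parent's protein: if the best
parse now shows an intron within ±5 aa of a parental intron position, the
candidate is a DNA-level duplicate, not a retrocopy, and is discarded.

A record is *intact* iff the parse contains zero frameshifts and zero
in-frame stops before the column matching the parent's final codon (no
C-terminal grace zone by default; `stop_grace` makes one available).
*Chimeric* means: intact, strictly inside an annotated gene other than the
parent, on the same strand, with the host keeping at least one CDS exon
outside the retrocopy span — an explicit operationalisation of "inserted
into another gene's structure". Same-parent candidates with > 50% reciprocal
overlap are deduplicated keeping the higher score, and the catalogue is
sorted by chromosome, start and id so identical inputs give identical
output.

# Selection and dating

`codon_align()` aligns the two conceptual translations globally (BLOSUM62,
affine gaps, via Biostrings) and back-threads codons, dropping gap columns,
frameshift-adjacent columns, and columns containing stops or ambiguity
bases. `ng86()` implements Nei–Gojobori (1986) counting: per-codon
fractional synonymous sites averaged over the two sequences (substitutions
to stop codons count as nonsynonymous), observed differences averaged over
all minimal mutational pathways excluding those through stop codons (all
pathways if every one is blocked), and the Jukes–Cantor correction
K = −(3/4)·ln(1 − 4p/3). A proportion ≥ 3/4 leaves that rate undefined
(saturated). We use counting rather than a maximum-likelihood codon model
because the method is exactly checkable against a brute-force
pathway-enumeration oracle — the test suite asserts equality of N, S, Nd,
Sd on random pairs — and because its assumptions (no
transition/transversion bias) match the simulator's substitution model, so
parameter-recovery tests are unbiased. A hook for an external Ka/Ks engine
can be added for real-data parity runs without touching the module surface.

Ages follow T = Ks/2λ with λ = 1.33 × 10⁻⁹ per year by default, derived
from a neutral rate of 0.4 × 10⁻⁸ per generation and a 3-year generation
time (`dating_params()`). Ka/Ks classes are ω < 0.5 (constrained),
0.5 ≤ ω ≤ 1.2 (intermediate; the published "0.5–1.2" bin is read as closed
on both printed edges so the three bins partition), and ω > 1.2 (elevated);
Ks = 0 or saturated pairs are `undefined` and excluded from ω statistics
while remaining in the catalogue. The Ks histogram uses 0.02-wide bins on
[0, 1) with pooled [1, 2) and [2, ∞) tails.

# EST transcription support

Reads are cleaned (terminal poly-A/T runs ≥ 10 bp trimmed; < 100 bp after
trimming dropped; mononucleotide fraction > 0.8 or dinucleotide entropy
< 1.5 bits dropped), then mapped by exact 11-mer seeding and affine-gap
extension (+1/−2), keeping alignments with identity > 95% over > 90% of the
read. Because a retrocopy and its parent share high identity, support
counting uses only ESTs mapped to a *unique* location: exactly one passing
alignment, or a best score beating the second best by ≥ 5%. An EST supports
a retrocopy when its unique alignment overlaps the locus by > 100 bp at
> 97% identity *within the overlapping columns* (the per-column alignment
trace is kept so this is measured exactly). Loosening any gate can only add
support — a monotonicity property the tests check. Spliced EST mapping is
limited to co-linear blocks with small gaps: retrocopies are single-exon
targets, so multi-exon EST mapping is unnecessary, and an EST from the
parent's spliced mRNA fails the 90% coverage gate at the parent locus —
which is precisely what pushes truly retrocopy-derived reads to a unique
location.

# Gene traffic and the X-outlier test

Every pair is classified interchromosomal / intrachromosomal / scaffold-MT
from the parent and retrocopy chromosomes. The *functional* set is intact
with ω < 0.5; the *neutral* set is pseudogenic with 0.5 < ω < 1.0 (both
ends exclusive, following the printed inequality). For the interchromosomal
members of each set, per-chromosome counts of parental genes and of
insertions are regressed (OLS) on two covariates — annotated gene count and
chromosome length — and the Pearson r is reported both with and without the
X point, because either convention is a defensible reading of published
per-chromosome correlations; all eight regressions are emitted.

The X test: fit OLS on the autosomes only, and refer the externally
studentized residual of X (prediction-error variance s²(1 + h₀)) to a t
distribution with n_autosomes − 3 degrees of freedom, two-sided, reporting
the direction (excess/deficit). The source analysis never names its outlier
test; this is our choice, with a one-sided exact binomial test of X's share
(`x_binomial_test()`) available as an alternative. No multiple-testing
correction is applied; all p-values are reported raw.

Calibration is checked at the count level on a mammal-like karyotype
(`calibration_chromosomes()`): 38 autosomes declining from 120 to 25 Mb
with 8 genes/Mb, plus a 124 Mb X at 4.7 genes/Mb. The gene-poor X matters
statistically, not just biologically: placements are multinomial, so count
variance scales with the mean, and a raw-count studentized residual is only
calibrated when the X's expected count sits near the autosomal average —
with a gene-rich X the test over-rejects (we measure ~11% type-I), with the
realistic gene-poor X it holds 5% ± 2% over 1,000 null simulations, while
keeping median p < 0.01 under a 3× X-origin enrichment of 200 pairs. Users
applying the test to karyotypes whose X is extreme in the covariate should
prefer the binomial variant.

# The simulator: what it emulates, and what it does not

`simulate_dataset()` generates chromosomes with 41% GC, genes of 120–400
codons split over 2–8 exons (each ≥ 12 codons, introns 60–300 bp, canonical
GT..AG, phase 0), and retro events that copy the spliced CDS, apply
uniform random substitutions at a per-event rate drawn from 0.01–0.07
(centred on the Ks range of a recent retrotransposition burst), optionally
inject a frameshift (1–2 bp indel, probability 0.3) and/or a premature stop
(point substitution creating TAA/TAG/TGA before 90% of the CDS, probability
0.3), append a 30 bp poly-A tract and a 10 bp target-site duplication
(hallmarks only — the caller does not use them), and insert at an
intergenic position, or with probability 0.1 into a host gene's intron on
the host's strand for intact events (chimeric). Events intended to stay
intact redraw substitution patterns that would create an internal stop, so
truth labels are unambiguous. ESTs are substrings of expressed loci
(±50 bp flanks) with uniform 1% error; half of the events are expressed.
Substitutions have no transition/transversion bias, matching the NG86
assumptions, so estimator-recovery tests are interpretable (a κ bias would
require the modified counting variant, which is out of scope).

Not emulated: repeat landscapes (LINE/SINE), indel evolution after
insertion, isoform diversity, selection on the copies (ω ≈ 1 for all
simulated pairs, so functional/neutral sets on simulated data are small and
the X-traffic power analysis is done at the count level), and any coupling
between expression and intactness. Passing recovery tests therefore shows
the pipeline's operations are correct under these statistical conditions —
not that real-genome complications (segmental duplications, processed
transcripts, annotation errors) are handled.

Every run is a pure function of the seed: identical configurations give
byte-identical files, which the determinism tests assert with checksums.

# Problem sizes and numerical choices

The validation dataset is a 2 Mb genome (five 350 kb autosomes + 250 kb X),
40 genes, 50 events, 300 ESTs — large enough that recovery rates are
meaningful (the suite requires recall ≥ 0.90 and parent/classification
accuracy ≥ 0.95, and achieves 1.0/1.0/0.98 at the default seeds) while a
full end-to-end run stays under two minutes. Neutral-ω recovery uses 200
pairs of 300 codons at rate 0.04 (mean ω̂ ≈ 1.06; a ratio of noisy
estimates sits slightly above 1 by Jensen's inequality, well within the
0.85–1.15 acceptance band). Degenerate inputs are handled explicitly:
empty catalogues produce all-zero reports; alignments shorter than 10
codons are flagged rather than estimated; saturated proportions (p ≥ 3/4)
leave rates undefined; ties (parent assignment, transcript selection,
deduplication) break deterministically.

# Known limitations

* Introns are phase-0 only; a real GeneWise-class model handles all phases
  and splice-site profiles.
* The E-value gate of translated search is replaced by raw-score gates;
  scores are not comparable across databases of different sizes.
* NG86 without a κ correction underestimates synonymous saturation under
  strong transition bias; real-data runs should plug in a
  likelihood-based engine through the Ka/Ks hook.
* The chimeric definition is positional (intact copy inside a foreign
  host), not expression-based; fusion transcripts are not modelled or
  validated.
* The uniqueness margin (5%) for EST placement is an interpretation of
  "mapped to a unique location"; it is config-exposed.
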