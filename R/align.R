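# Alignment scoring setup shared by the search and spliced-alignment layers.
# Alphabet = the 25 BLOSUM62 letters (including '*') plus one extra index for
# codons containing N, which score 0 against everything.

.rt_cache <- new.env(parent = emptyenv())

aa_alphabet <- function() {
  if (is.null(.rt_cache$alpha)) {
    S <- score_matrix()
    .rt_cache$alpha <- attr(S, "alphabet")
  }
  .rt_cache$alpha
}

#' Substitution matrix used for protein-level scoring
#'
#' BLOSUM62 extended with an `N-codon` row/column of zeros so that genomic
#' codons containing ambiguity bases are neutral in alignment scores.
#'
#' @return Integer matrix with an `alphabet` attribute.
#' @keywords internal
score_matrix <- function() {
  if (is.null(.rt_cache$S)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    B <- e$BLOSUM62
    k <- nrow(B)
    S <- matrix(0L, k + 1, k + 1)
    S[1:k, 1:k] <- as.integer(B)
    alpha <- c(rownames(B), "?")  # '?' = N-containing codon
    dimnames(S) <- list(alpha, alpha)
    attr(S, "alphabet") <- alpha
    .rt_cache$S <- S
  }
  .rt_cache$S
}

# 0-based indices into the alphabet
aa_encode <- function(aa) {
  alpha <- aa_alphabet()
  idx <- match(strsplit(aa, "")[[1]], alpha)
  idx[is.na(idx)] <- match("X", alpha)
  as.integer(idx - 1L)
}

ncodon_index <- function() match("?", aa_alphabet()) - 1L
stop_index <- function() match("*", aa_alphabet()) - 1L

# length-64 codon -> alphabet index map; codon index = 16*b1 + 4*b2 + b3 with
# A=0, C=1, G=2, T=3
codon_aa_table <- function() {
  if (is.null(.rt_cache$codon_aa)) {
    bases <- c("A", "C", "G", "T")
    alpha <- aa_alphabet()
    tab <- integer(64)
    gc <- Biostrings::GENETIC_CODE
    for (b1 in 0:3) for (b2 in 0:3) for (b3 in 0:3) {
      codon <- paste0(bases[b1 + 1], bases[b2 + 1], bases[b3 + 1])
      tab[16 * b1 + 4 * b2 + b3 + 1] <- match(gc[[codon]], alpha) - 1L
    }
    .rt_cache$codon_aa <- tab
  }
  .rt_cache$codon_aa
}

#' Local protein-protein alignment (Smith-Waterman, BLOSUM62, affine gaps)
#'
#' @param a,b Protein strings.
#' @param gap_open,gap_ext Gap penalties in the BLAST convention (a gap of
#'   length k costs `gap_open + k * gap_ext`).
#' @return List with `score`, 1-based spans `a_start`,`a_end`,`b_start`,
#'   `b_end`, `matches`, `aligned` (residue-pair columns), and `identity`.
#' @export
sw_protein <- function(a, b, gap_open = 11L, gap_ext = 1L) {
  r <- cpp_sw_aa(aa_encode(a), aa_encode(b), score_matrix(),
                 as.integer(gap_open), as.integer(gap_ext))
  r$identity <- if (r$aligned > 0) r$matches / r$aligned else 0
  r
}

#' Default parameters of the spliced protein-to-genome aligner
#'
#' Penalties are in BLOSUM62 half-bit units. `fs_pen` (frameshift) and
#' `intron_pen` are chosen so that a genuine GT..AG intron beats a frameshift
#' parse while a 1-2 bp slip beats opening an intron; `min_structure_score`
#' is the acceptance gate for a parsed structure.
#'
#' @export
spliced_align_params <- function(fs_pen = -20L, intron_pen = -25L,
                                 gap_pen = -12L, min_intron = 30L,
                                 min_structure_score = 35L) {
  list(fs_pen = as.integer(fs_pen), intron_pen = as.integer(intron_pen),
       gap_pen = as.integer(gap_pen), min_intron = as.integer(min_intron),
       min_structure_score = as.integer(min_structure_score))
}

#' Spliced, frameshift-aware alignment of a protein to a DNA segment
#'
#' Dynamic program over (protein position, DNA position) with codon-match,
#' amino-acid gap, frameshift (1-2 bp slip) and intron states. Introns are
#' entered only at GT and left only at AG, between codons, with a fixed
#' penalty and a minimum length. The maximum-scoring local parse is returned;
#' parses scoring at or below `params$min_structure_score` are rejected.
#'
#' @param protein Protein string (query).
#' @param dna DNA string (the candidate locus, plus strand of the alignment).
#' @param params See [spliced_align_params()].
#' @return Object of class `spliced_structure` (or one with `rejected = TRUE`
#'   when no acceptable parse exists): score, identity, protein coverage,
#'   1-based DNA span within `dna`, exon segments, intron/frameshift/stop
#'   records, and the aligned codons with their protein positions.
#' @export
spliced_align <- function(protein, dna, params = spliced_align_params()) {
  m <- nchar(protein)
  r <- cpp_spliced_align(aa_encode(protein), dna, score_matrix(),
                         codon_aa_table(), ncodon_index(), stop_index(),
                         params$fs_pen, params$intron_pen, params$gap_pen,
                         params$min_intron)
  if (r$aligned == 0 || r$score <= params$min_structure_score) {
    return(structure(list(rejected = TRUE, score = if (r$aligned) r$score else 0),
                     class = "spliced_structure"))
  }
  introns <- if (r$n_intron > 0) {
    cbind(start = r$intron_start, end = r$intron_end)
  } else {
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  }
  # exon segments: split the aligned DNA range at introns
  ex_start <- c(r$dna_start, if (r$n_intron > 0) introns[, "end"] + 1L)
  ex_end <- c(if (r$n_intron > 0) introns[, "start"] - 1L, r$dna_end)
  structure(list(
    rejected = FALSE,
    score = r$score,
    aligned = r$aligned,
    matches = r$matches,
    identity = r$matches / r$aligned,
    coverage = r$aligned / m,
    prot_start = r$prot_start, prot_end = r$prot_end,
    dna_start = r$dna_start, dna_end = r$dna_end,
    n_intron = r$n_intron,
    introns = introns,
    intron_prot = if (r$n_intron > 0) r$intron_prot else integer(0),
    exons = cbind(start = ex_start, end = ex_end),
    frameshift_pos = r$res_prot[r$res_fs == 1],
    stop_pos = r$res_prot[r$res_stop == 1],
    codons = r$codons,
    codon_prot_pos = r$res_prot,
    codon_is_fs = r$res_fs == 1
  ), class = "spliced_structure")
}

#' @export
print.spliced_structure <- function(x, ...) {
  if (isTRUE(x$rejected)) {
    cat("<spliced_structure> rejected (score ", x$score, ")\n", sep = "")
  } else {
    cat(sprintf(
      "<spliced_structure> score %d, %d intron(s), %d frameshift(s), %d stop(s), identity %.3f, coverage %.3f\n",
      x$score, x$n_intron, length(x$frameshift_pos), length(x$stop_pos),
      x$identity, x$coverage))
  }
  invisible(x)
}
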