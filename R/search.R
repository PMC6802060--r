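# Six-frame seeded protein-to-genome search: exact amino-acid word seeds,
# diagonal clustering, local affine-gap extension, and collinear chaining of
# the resulting HSPs into candidate loci.

#' Default parameters of the protein-to-genome search
#'
#' Word size 4 and BLOSUM62 with gap open 11 / extend 1 follow standard
#' translated-search defaults. HSPs must exceed 50% identity over at least
#' 50 aligned amino acids; `min_score` replaces an E-value gate with a raw
#' score threshold.
#'
#' @export
search_params <- function(word_size = 4L, min_aa = 50L, min_identity = 0.5,
                          min_len = 50L, min_score = 50L, gap_open = 11L,
                          gap_ext = 1L, min_seeds = 2L, cluster_diag = 25L,
                          cluster_gap = 250L, max_intron = 50000L) {
  as.list(environment())
}

# translate one strand/frame of a chromosome; returns aa string
frame_translation <- function(seq, strand, frame) {
  if (strand == "-") seq <- revcomp(seq)
  n <- nchar(seq)
  if (n - frame < 3) return("")
  len <- ((n - frame) %/% 3) * 3
  sub <- substr(seq, frame + 1L, frame + len)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X"))
}

#' Build a six-frame translation index of a genome
#'
#' Precomputes, for every chromosome and frame, the conceptual translation,
#' its integer encoding, and the amino-acid word list used for seeding.
#' Building the index once and passing it to [search_protein_vs_genome()]
#' amortises the translation cost across query proteins.
#'
#' @param genome A `genome_assembly`.
#' @param word_size Seed word size in amino acids.
#' @return Opaque index object.
#' @export
build_search_index <- function(genome, word_size = 4L) {
  frames <- list()
  for (chrom in names(genome$sequences)) {
    seq <- genome$sequences[[chrom]]
    for (strand in c("+", "-")) for (f in 0:2) {
      aa <- frame_translation(seq, strand, f)
      la <- nchar(aa)
      if (la < word_size) next
      words <- substring(aa, 1:(la - word_size + 1L), word_size:la)
      frames[[paste(chrom, strand, f, sep = "/")]] <- list(
        chrom = chrom, strand = strand, frame = f, len = la,
        enc = aa_encode(aa), words = words)
    }
  }
  structure(list(frames = frames, word_size = word_size,
                 chrom_len = genome$lengths),
            class = "search_index")
}

# genomic half-open interval of aa span [q1, q2] (1-based incl) in a frame
frame_to_genomic <- function(q1, q2, strand, frame, chrom_len) {
  if (strand == "+") {
    c(frame + 3 * (q1 - 1), frame + 3 * q2)
  } else {
    c(chrom_len - frame - 3 * q2, chrom_len - frame - 3 * (q1 - 1))
  }
}

#' Search a protein against all six frames of a genome
#'
#' Seeds are exact `word_size`-mer amino-acid matches against the six
#' conceptual translations; seed clusters on nearby diagonals are extended by
#' local Smith-Waterman (BLOSUM62, affine gaps). HSPs are kept when identity
#' exceeds `min_identity` over at least `min_len` aligned residues with score
#' at least `min_score`; overlapping same-frame HSPs are merged.
#'
#' @param protein Protein string.
#' @param protein_id Identifier carried into the output.
#' @param index A `search_index` from [build_search_index()] (or a
#'   `genome_assembly`, in which case a throwaway index is built).
#' @param params See [search_params()].
#' @return Data frame of HSPs: `protein_id`, `chrom`, `strand`, `frame`,
#'   `p_start`, `p_end` (1-based inclusive aa), `g_start`, `g_end` (0-based
#'   half-open genomic), `score`, `identity`, `aligned`.
#' @export
search_protein_vs_genome <- function(protein, protein_id, index,
                                     params = search_params()) {
  if (inherits(index, "genome_assembly"))
    index <- build_search_index(index, params$word_size)
  m <- nchar(protein)
  if (m < params$min_aa)
    stop("protein ", protein_id, " shorter than min_aa (", params$min_aa, ")")
  w <- params$word_size
  pwords <- substring(protein, 1:(m - w + 1L), w:m)
  # word -> protein positions
  ppos <- split(seq_along(pwords), pwords)
  penc <- aa_encode(protein)
  S <- score_matrix()
  out <- list()
  for (fr in index$frames) {
    hits <- which(fr$words %in% names(ppos))
    if (length(hits) < params$min_seeds) next
    pp <- ppos[fr$words[hits]]
    q <- rep.int(hits, lengths(pp))
    p <- unlist(pp, use.names = FALSE)
    diag <- q - p
    o <- order(diag, q)
    q <- q[o]; p <- p[o]; diag <- diag[o]
    grp <- cumsum(c(TRUE, diff(diag) > params$cluster_diag |
                      diff(q) > params$cluster_gap))
    for (g in split(seq_along(q), grp)) {
      if (length(unique(p[g])) < params$min_seeds) next
      qlo <- max(1L, min(q[g]) - min(p[g]) - 10L)
      qhi <- min(fr$len, max(q[g]) + (m - max(p[g])) + 10L)
      r <- cpp_sw_aa(penc, fr$enc[qlo:qhi], S,
                     params$gap_open, params$gap_ext)
      if (r$aligned < params$min_len || r$score < params$min_score) next
      if (r$matches / r$aligned <= params$min_identity) next
      gs <- frame_to_genomic(qlo - 1L + r$b_start, qlo - 1L + r$b_end,
                             fr$strand, fr$frame, index$chrom_len[[fr$chrom]])
      out[[length(out) + 1L]] <- data.frame(
        protein_id = protein_id, chrom = fr$chrom, strand = fr$strand,
        frame = fr$frame, p_start = r$a_start, p_end = r$a_end,
        g_start = gs[1], g_end = gs[2], score = r$score,
        identity = r$matches / r$aligned, aligned = r$aligned,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(protein_id = character(0), chrom = character(0),
                      strand = character(0), frame = integer(0),
                      p_start = integer(0), p_end = integer(0),
                      g_start = numeric(0), g_end = numeric(0),
                      score = numeric(0), identity = numeric(0),
                      aligned = integer(0), stringsAsFactors = FALSE))
  }
  hsps <- do.call(rbind, out)
  merge_hsps(hsps)
}

# merge overlapping HSPs from the same chrom/strand/frame: keep the envelope,
# score/identity of the strongest member
merge_hsps <- function(hsps) {
  key <- paste(hsps$chrom, hsps$strand, hsps$frame)
  res <- list()
  for (k in unique(key)) {
    h <- hsps[key == k, , drop = FALSE]
    h <- h[order(h$g_start, -h$score), , drop = FALSE]
    cur <- h[1, , drop = FALSE]
    for (i in seq_len(nrow(h))[-1]) {
      if (h$g_start[i] < cur$g_end) {
        cur$g_end <- max(cur$g_end, h$g_end[i])
        cur$g_start <- min(cur$g_start, h$g_start[i])
        if (h$score[i] > cur$score) {
          cur$score <- h$score[i]; cur$identity <- h$identity[i]
          cur$aligned <- h$aligned[i]
          cur$p_start <- h$p_start[i]; cur$p_end <- h$p_end[i]
        } else {
          cur$p_start <- min(cur$p_start, h$p_start[i])
          cur$p_end <- max(cur$p_end, h$p_end[i])
        }
      } else {
        res[[length(res) + 1L]] <- cur
        cur <- h[i, , drop = FALSE]
      }
    }
    res[[length(res) + 1L]] <- cur
  }
  out <- do.call(rbind, res)
  out[order(out$chrom, out$strand, out$g_start), , drop = FALSE]
}

#' Chain collinear HSPs of one protein into candidate loci
#'
#' Same-chromosome, same-strand HSPs that are collinear in both protein and
#' genome order (transcription direction on the minus strand), with genomic
#' gaps no larger than `max_intron`, are grouped into loci by maximum-score
#' chaining. The locus span is the union envelope of its members.
#'
#' @param hsps HSP data frame from [search_protein_vs_genome()] (one protein).
#' @param max_intron Maximum genomic gap (bp) bridged within one locus.
#' @param overlap_tol_p,overlap_tol_g Tolerated overlap between chained HSPs
#'   in protein (aa) and genomic (bp) coordinates.
#' @return Data frame of loci: `protein_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open), `score` (sum of member scores), `n_hsps`.
#' @export
chain_hsps <- function(hsps, max_intron = 50000L, overlap_tol_p = 10L,
                       overlap_tol_g = 30L) {
  if (nrow(hsps) == 0) {
    return(data.frame(protein_id = character(0), chrom = character(0),
                      strand = character(0), start = numeric(0),
                      end = numeric(0), score = numeric(0),
                      n_hsps = integer(0), stringsAsFactors = FALSE))
  }
  stopifnot(length(unique(hsps$protein_id)) == 1)
  loci <- list()
  key <- paste(hsps$chrom, hsps$strand)
  for (k in unique(key)) {
    h <- hsps[key == k, , drop = FALSE]
    minus <- h$strand[1] == "-"
    # transcription-direction coordinate: increasing along the protein
    ts <- if (minus) -h$g_end else h$g_start
    te <- if (minus) -h$g_start else h$g_end
    o <- order(ts, h$p_start)
    h <- h[o, , drop = FALSE]; ts <- ts[o]; te <- te[o]
    nh <- nrow(h)
    dp <- h$score
    par <- rep(NA_integer_, nh)
    for (i in seq_len(nh)) {
      for (j in seq_len(i - 1L)) {
        compat <- ts[i] >= te[j] - overlap_tol_g &&
          ts[i] - te[j] <= max_intron &&
          h$p_start[i] >= h$p_end[j] - overlap_tol_p &&
          h$p_end[i] > h$p_end[j]
        if (compat && dp[j] + h$score[i] > dp[i]) {
          dp[i] <- dp[j] + h$score[i]
          par[i] <- j
        }
      }
    }
    used <- rep(FALSE, nh)
    for (i in order(-dp)) {
      if (used[i]) next
      chain <- i
      j <- par[i]
      while (!is.na(j) && !used[j]) { chain <- c(j, chain); j <- par[j] }
      used[chain] <- TRUE
      loci[[length(loci) + 1L]] <- data.frame(
        protein_id = h$protein_id[1], chrom = h$chrom[1],
        strand = h$strand[1], start = min(h$g_start[chain]),
        end = max(h$g_end[chain]), score = sum(h$score[chain]),
        n_hsps = length(chain), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, loci)
  out[order(out$chrom, out$strand, out$start), , drop = FALSE]
}

#' Spliced alignment of a protein to a genomic locus
#'
#' Extracts the locus with flanks, reverse-complements for minus-strand loci,
#' runs [spliced_align()], and maps the parse back to genomic coordinates.
#'
#' @param protein Protein string.
#' @param genome A `genome_assembly`.
#' @param chrom,strand,start,end Locus (0-based half-open genomic).
#' @param flank Flank added on both sides (bp).
#' @param params See [spliced_align_params()].
#' @return A `spliced_structure` with genomic fields `chrom`, `strand`,
#'   `g_start`, `g_end` (0-based half-open) added, or a rejected structure.
#' @export
align_locus <- function(protein, genome, chrom, strand, start, end,
                        flank = 1000L, params = spliced_align_params()) {
  L <- genome$lengths[[chrom]]
  s0 <- max(0, start - flank)
  e0 <- min(L, end + flank)
  dna <- substr(genome$sequences[[chrom]], s0 + 1, e0)
  if (strand == "-") dna <- revcomp(dna)
  st <- spliced_align(protein, dna, params)
  if (isTRUE(st$rejected)) return(st)
  W <- nchar(dna)
  if (strand == "+") {
    st$g_start <- s0 + st$dna_start - 1
    st$g_end <- s0 + st$dna_end
  } else {
    st$g_start <- s0 + W - st$dna_end
    st$g_end <- s0 + W - st$dna_start + 1
  }
  st$chrom <- chrom
  st$strand <- strand
  st
}
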