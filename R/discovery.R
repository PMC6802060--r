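# Retrocopy catalogue construction: single-exon candidate calling,
# best-parent assignment, intron-retention discard, intact/pseudogene
# classification, chimeric flagging and catalogue summaries.

#' Default parameters of retrocopy discovery
#'
#' Thresholds follow the standard retrogene-identification recipe: parent
#' assignment requires identity > 50% over > 50% of the parent protein and
#' at least 50 aligned amino acids; structures must clear the spliced-aligner
#' score gate; a candidate is discarded when re-parsing with wide flanks
#' reveals an intron within `intron_match_tol` amino acids of a parental
#' intron position.
#'
#' @export
discovery_params <- function(search = search_params(),
                             splice = spliced_align_params(),
                             min_parent_identity = 0.5,
                             min_parent_overlap = 0.5,
                             min_parent_aligned = 50L,
                             flank_call = 1000L,
                             flank_intron_check = 2000L,
                             intron_match_tol = 5L,
                             dedup_overlap = 0.5,
                             stop_grace = 0) {
  as.list(environment())
}

interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

#' Call single-exon candidate structures
#'
#' Keeps spliced structures with zero introns, dropping any whose locus
#' overlaps the query protein's own gene locus (self-hits).
#'
#' @param structures List of `spliced_structure` objects with genomic fields
#'   (from [align_locus()]), all from one query protein.
#' @param self_model The query protein's own `gene_model` (or NULL).
#' @return The subset of `structures` that are candidates.
#' @export
call_candidates <- function(structures, self_model = NULL) {
  keep <- vapply(structures, function(st) {
    if (isTRUE(st$rejected)) return(FALSE)
    if (st$n_intron > 0) return(FALSE)
    if (!is.null(self_model) && st$chrom == self_model$chrom) {
      sp <- model_span(self_model)
      if (interval_overlap(st$g_start, st$g_end, sp[1], sp[2]) > 0)
        return(FALSE)
    }
    TRUE
  }, logical(1))
  structures[keep]
}

# conceptual translation of a candidate structure's matched codons
structure_translation <- function(st) {
  tab <- .codon_table()
  aa <- unname(tab[st$codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Assign the best parental protein to a candidate
#'
#' The candidate's conceptual translation is aligned (local, BLOSUM62)
#' against every protein in the database. The best-scoring hit wins when it
#' passes the identity/overlap/length gates; when that hit's gene is
#' single-exon the candidate is discarded (retrocopies must descend from
#' multi-exon genes). Ties are broken by higher identity, then lexicographic
#' gene id.
#'
#' @param st Candidate `spliced_structure`.
#' @param proteins Named character vector of proteins (by protein id).
#' @param models Gene models named by gene id.
#' @param params See [discovery_params()].
#' @return List with `parent_gene`, `parent_protein`, `identity`, `overlap`,
#'   `aligned`, `score`, or NULL when no acceptable parent exists.
#' @export
assign_parent <- function(st, proteins, models, params = discovery_params()) {
  qt <- structure_translation(st)
  gene_of <- setNames(vapply(models, `[[`, "", "gene_id"),
                      vapply(models, `[[`, "", "protein_id"))
  hits <- list()
  for (pid in names(proteins)) {
    r <- sw_protein(qt, proteins[[pid]],
                    params$search$gap_open, params$search$gap_ext)
    if (r$aligned == 0) next
    hits[[pid]] <- data.frame(
      protein_id = pid, score = r$score, identity = r$identity,
      aligned = r$aligned,
      overlap = r$aligned / nchar(proteins[[pid]]),
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0) return(NULL)
  h <- do.call(rbind, hits)
  h$gene_id <- unname(gene_of[h$protein_id])
  h <- h[h$identity > params$min_parent_identity &
           h$overlap > params$min_parent_overlap &
           h$aligned >= params$min_parent_aligned, , drop = FALSE]
  if (nrow(h) == 0) return(NULL)
  h <- h[order(-h$score, -h$identity, h$gene_id), , drop = FALSE]
  best <- h[1, ]
  if (nrow(models[[best$gene_id]]$exons) < 2) return(NULL)  # single-exon best hit
  list(parent_gene = best$gene_id, parent_protein = best$protein_id,
       identity = best$identity, overlap = best$overlap,
       aligned = best$aligned, score = best$score)
}

#' Intron-retention check for an assigned candidate
#'
#' Re-runs the spliced aligner for the parent protein on the candidate locus
#' with wide flanks; the candidate is discarded when the best parse contains
#' an intron whose protein-coordinate position falls within
#' `params$intron_match_tol` amino acids of a parental intron position
#' (the hallmark of a DNA-level duplicate rather than a retrocopy).
#'
#' @param st Candidate structure (with genomic fields).
#' @param parent_model The assigned parent's `gene_model`.
#' @param parent_protein Parent protein sequence.
#' @param genome A `genome_assembly`.
#' @param params See [discovery_params()].
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
check_intron_loss <- function(st, parent_model, parent_protein, genome,
                              params = discovery_params()) {
  re <- align_locus(parent_protein, genome, st$chrom, st$strand,
                    st$g_start, st$g_end,
                    flank = params$flank_intron_check, params = params$splice)
  if (isTRUE(re$rejected) || re$n_intron == 0) return(TRUE)
  par_introns <- model_intron_positions_aa(parent_model)
  if (length(par_introns) == 0) return(TRUE)
  for (ip in re$intron_prot) {
    if (any(abs(ip - par_introns) <= params$intron_match_tol)) return(FALSE)
  }
  TRUE
}

#' Classify a candidate structure as intact or pseudogene
#'
#' Intact means zero frameshifts and zero in-frame stop codons before the
#' alignment column matching the parent's last codon. `stop_grace` optionally
#' ignores stops within the final fraction of the parent protein.
#'
#' @param st Candidate structure.
#' @param parent_len_aa Parent protein length (aa).
#' @param stop_grace Fraction of the parent's C-terminus in which stops are
#'   tolerated (0 = every aligned stop is premature).
#' @return `"intact"` or `"pseudogene"`.
#' @export
classify_structure <- function(st, parent_len_aa, stop_grace = 0) {
  stops <- st$stop_pos
  if (stop_grace > 0) {
    stops <- stops[stops < parent_len_aa * (1 - stop_grace)]
  }
  if (length(st$frameshift_pos) == 0 && length(stops) == 0) "intact"
  else "pseudogene"
}

#' Flag a chimeric retrogene
#'
#' TRUE iff the record is intact and its locus lies strictly inside an
#' annotated gene other than its parent, on the same strand, with that host
#' retaining at least one CDS exon outside the retrocopy span.
#'
#' @param chrom,strand,start,end Retrocopy locus.
#' @param class_label `"intact"` or `"pseudogene"`.
#' @param parent_gene Parent gene id.
#' @param models Gene models named by gene id.
#' @export
flag_chimeric <- function(chrom, strand, start, end, class_label,
                          parent_gene, models) {
  if (class_label != "intact") return(FALSE)
  for (m in models) {
    if (m$gene_id == parent_gene || m$chrom != chrom || m$strand != strand)
      next
    sp <- model_span(m)
    if (start > sp[1] && end < sp[2]) {
      ex <- m$exons
      outside <- ex[, "end"] <= start | ex[, "start"] >= end
      if (any(outside)) return(TRUE)
    }
  }
  FALSE
}

overlaps_any_annotation <- function(chrom, start, end, models) {
  for (m in models) {
    if (m$chrom != chrom) next
    sp <- model_span(m)
    if (interval_overlap(start, end, sp[1], sp[2]) > 0) return(TRUE)
  }
  FALSE
}

#' Discover retrocopies in an annotated genome
#'
#' Full catalogue construction: six-frame search of every protein, HSP
#' chaining, spliced alignment of each candidate locus, single-exon calling,
#' best-parent assignment, intron-retention discard, intact/pseudogene
#' classification, same-parent deduplication and chimeric flagging. The
#' catalogue is sorted by chromosome, start and retro id, so identical
#' inputs give identical output.
#'
#' @param genome A `genome_assembly`.
#' @param models Gene models named by gene id.
#' @param proteins Named character vector of proteins (by protein id).
#' @param params See [discovery_params()].
#' @param verbose Print progress.
#' @return Object of class `retro_catalogue`: `catalogue` (data frame),
#'   `structures` (named list of `spliced_structure`), `discarded`
#'   (data frame of discarded candidates with reasons).
#' @export
discover_retrocopies <- function(genome, models, proteins,
                                 params = discovery_params(),
                                 verbose = FALSE) {
  index <- build_search_index(genome, params$search$word_size)
  model_of_protein <- setNames(models, vapply(models, `[[`, "", "protein_id"))
  cand <- list()
  discarded <- list()
  note_discard <- function(pid, st, reason) {
    discarded[[length(discarded) + 1L]] <<- data.frame(
      query_protein = pid, chrom = st$chrom %||% NA_character_,
      start = st$g_start %||% NA_real_, end = st$g_end %||% NA_real_,
      reason = reason, stringsAsFactors = FALSE)
  }
  for (pid in sort(names(proteins))) {
    prot <- proteins[[pid]]
    if (nchar(prot) < params$search$min_aa) next
    hsps <- search_protein_vs_genome(prot, pid, index, params$search)
    loci <- chain_hsps(hsps, params$search$max_intron)
    if (nrow(loci) == 0) next
    structures <- lapply(seq_len(nrow(loci)), function(i)
      align_locus(prot, genome, loci$chrom[i], loci$strand[i],
                  loci$start[i], loci$end[i],
                  flank = params$flank_call, params = params$splice))
    structures <- Filter(function(st) !isTRUE(st$rejected), structures)
    cands <- call_candidates(structures, model_of_protein[[pid]])
    for (st in cands) {
      pa <- assign_parent(st, proteins, models, params)
      if (is.null(pa)) { note_discard(pid, st, "no_parent"); next }
      pm <- models[[pa$parent_gene]]
      pprot <- proteins[[pa$parent_protein]]
      if (!check_intron_loss(st, pm, pprot, genome, params)) {
        note_discard(pid, st, "intron_retained"); next
      }
      st$parent <- pa
      cand[[length(cand) + 1L]] <- st
    }
    if (verbose) message("searched ", pid, ": ", length(cand), " candidates so far")
  }
  # assemble rows
  rows <- lapply(cand, function(st) {
    cls <- classify_structure(st, nchar(proteins[[st$parent$parent_protein]]),
                              params$stop_grace)
    data.frame(chrom = st$chrom, strand = st$strand, start = st$g_start,
               end = st$g_end, parent_gene = st$parent$parent_gene,
               parent_protein = st$parent$parent_protein, class = cls,
               identity = st$parent$identity, coverage = st$coverage,
               n_frameshift = length(st$frameshift_pos),
               n_stop = length(st$stop_pos), score = st$score,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    cat_df <- data.frame(retro_id = character(0), chrom = character(0),
                         strand = character(0), start = numeric(0),
                         end = numeric(0), parent_gene = character(0),
                         parent_protein = character(0), class = character(0),
                         chimeric = logical(0), overlaps_annotation = logical(0),
                         identity = numeric(0), coverage = numeric(0),
                         n_frameshift = integer(0), n_stop = integer(0),
                         score = numeric(0), stringsAsFactors = FALSE)
    return(structure(list(catalogue = cat_df, structures = list(),
                          discarded = bind_discards(discarded)),
                     class = "retro_catalogue"))
  }
  df <- do.call(rbind, rows)
  ord <- order(df$chrom, df$start, df$end, df$parent_gene)
  df <- df[ord, , drop = FALSE]
  cand <- cand[ord]
  # same-parent deduplication: >50% reciprocal overlap keeps the higher score
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(df))) {
      if (i == j || !keep[j]) next
      if (df$parent_gene[i] != df$parent_gene[j] ||
          df$chrom[i] != df$chrom[j]) next
      ov <- interval_overlap(df$start[i], df$end[i], df$start[j], df$end[j])
      if (ov > params$dedup_overlap * (df$end[i] - df$start[i]) &&
          ov > params$dedup_overlap * (df$end[j] - df$start[j])) {
        drop <- if (df$score[i] >= df$score[j]) j else i
        keep[drop] <- FALSE
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  cand <- cand[keep]
  df$retro_id <- sprintf("rc%04d", seq_len(nrow(df)))
  df$chimeric <- vapply(seq_len(nrow(df)), function(i)
    flag_chimeric(df$chrom[i], df$strand[i], df$start[i], df$end[i],
                  df$class[i], df$parent_gene[i], models), logical(1))
  df$overlaps_annotation <- vapply(seq_len(nrow(df)), function(i)
    overlaps_any_annotation(df$chrom[i], df$start[i], df$end[i], models),
    logical(1))
  df <- df[, c("retro_id", "chrom", "strand", "start", "end", "parent_gene",
               "parent_protein", "class", "chimeric", "overlaps_annotation",
               "identity", "coverage", "n_frameshift", "n_stop", "score")]
  rownames(df) <- NULL
  structures <- setNames(cand, df$retro_id)
  structure(list(catalogue = df, structures = structures,
                 discarded = bind_discards(discarded)),
            class = "retro_catalogue")
}

bind_discards <- function(discarded) {
  if (length(discarded) == 0) {
    return(data.frame(query_protein = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, discarded)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.retro_catalogue <- function(x, ...) {
  s <- summarize_catalogue(x$catalogue)
  cat(sprintf("<retro_catalogue> %d retrocopies (%d intact, %d pseudogene, %d chimeric) from %d parent(s)\n",
              s$total, s$n_intact, s$n_pseudogene, s$n_chimeric, s$n_parents))
  invisible(x)
}

#' Summarise a retrocopy catalogue
#'
#' @param catalogue Catalogue data frame (from [discover_retrocopies()]).
#' @param top_n Number of top parents to tabulate.
#' @return List: `total`, `n_intact`, `n_pseudogene`, `intact_fraction`,
#'   `n_chimeric`, `n_parents`, `mean_per_parent`,
#'   `per_parent` (named counts), `parents_single` (count with exactly one
#'   retrocopy), `top_parents` (data frame), `n_novel`, `n_novel_intact`.
#' @export
summarize_catalogue <- function(catalogue, top_n = 20L) {
  if (nrow(catalogue) == 0) {
    return(list(total = 0L, n_intact = 0L, n_pseudogene = 0L,
                intact_fraction = 0, n_chimeric = 0L, n_parents = 0L,
                mean_per_parent = 0, per_parent = integer(0),
                parents_single = 0L,
                top_parents = data.frame(parent_gene = character(0),
                                         n = integer(0)),
                n_novel = 0L, n_novel_intact = 0L))
  }
  per_parent <- sort(table(catalogue$parent_gene), decreasing = TRUE)
  top <- data.frame(parent_gene = names(per_parent),
                    n = as.integer(per_parent),
                    stringsAsFactors = FALSE)[seq_len(min(top_n, length(per_parent))), ]
  n_int <- sum(catalogue$class == "intact")
  list(total = nrow(catalogue),
       n_intact = n_int,
       n_pseudogene = sum(catalogue$class == "pseudogene"),
       intact_fraction = n_int / nrow(catalogue),
       n_chimeric = sum(catalogue$chimeric),
       n_parents = length(per_parent),
       mean_per_parent = nrow(catalogue) / length(per_parent),
       per_parent = setNames(as.integer(per_parent), names(per_parent)),
       parents_single = sum(per_parent == 1L),
       top_parents = top,
       n_novel = sum(!catalogue$overlaps_annotation),
       n_novel_intact = sum(!catalogue$overlaps_annotation &
                              catalogue$class == "intact"))
}
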