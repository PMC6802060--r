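# Synthetic-genome simulator: multi-chromosome genome with multi-exon coding
# genes, retrotransposition events (intronless CDS copies with configurable
# substitution / frameshift / premature-stop / chimeric-insertion rates,
# poly-A tail and target-site duplication), EST reads from expressed loci,
# and a ground-truth event table.

SENSE_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  all[!all %in% c("TAA", "TAG", "TGA")]
})

#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the package's
#' validation: a 2-Mb genome of five autosomes plus an X chromosome, 40
#' multi-exon genes, 50 retrotransposition events with per-event substitution
#' rates spanning the recent-burst range of synonymous divergence, 30%
#' frameshift and 30% premature-stop injection, 10% chimeric insertion among
#' intact events, and 300 ESTs at 1% error from half of the events.
#'
#' @param seed Integer RNG seed; identical seeds give byte-identical outputs.
#' @param chrom_lengths Named vector of chromosome lengths (bp); one name
#'   should be an X chromosome (`X`/`chrX`).
#' @param n_genes Number of parental genes.
#' @param exons_per_gene Integer range (min, max), minimum 2.
#' @param gene_codons Range of CDS lengths in codons.
#' @param intron_length Range of intron lengths (bp, >= 60 so that true
#'   introns always exceed the aligner's minimum).
#' @param gc Intergenic/intronic GC content.
#' @param n_retro_events Number of retrotransposition events.
#' @param retro_sub_rate Range of per-site substitution rates applied to each
#'   copied CDS (drawn uniformly per event; controls the target Ks).
#' @param p_frameshift,p_stop Probability that an event receives a frameshift
#'   (1-2 bp indel at a uniform CDS position) / a premature stop (point
#'   substitution creating TAA/TAG/TGA before 90% of the CDS).
#' @param p_chimeric Probability that an intact event inserts into a host
#'   gene's intron (same strand) instead of intergenic DNA.
#' @param polya_len Poly-A tract length appended to every insert.
#' @param tsd_len Target-site duplication length (hallmark only; unused by the
#'   caller).
#' @param n_dna_duplicates DNA-level gene duplicates (introns retained),
#'   used to exercise the intron-retention discard.
#' @param n_ests,est_length,est_error EST count, read length, uniform
#'   per-base error rate.
#' @param expressed_fraction Fraction of retro events that seed ESTs.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = c(chr1 = 350e3, chr2 = 350e3,
                                                chr3 = 350e3, chr4 = 350e3,
                                                chr5 = 350e3, chrX = 250e3),
                              n_genes = 40L,
                              exons_per_gene = c(2L, 8L),
                              gene_codons = c(120L, 400L),
                              intron_length = c(60L, 300L),
                              gc = 0.41,
                              n_retro_events = 50L,
                              retro_sub_rate = c(0.01, 0.07),
                              p_frameshift = 0.3,
                              p_stop = 0.3,
                              p_chimeric = 0.1,
                              polya_len = 30L,
                              tsd_len = 10L,
                              n_dna_duplicates = 0L,
                              n_ests = 300L,
                              est_length = 300L,
                              est_error = 0.01,
                              expressed_fraction = 0.5) {
  cfg <- as.list(environment())
  probs <- c(p_frameshift, p_stop, p_chimeric, est_error, expressed_fraction, gc)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(chrom_lengths <= 0) || n_genes < 1) stop("lengths must be positive")
  if (exons_per_gene[1] < 2) stop("genes must have at least 2 exons")
  if (intron_length[1] < 40) stop("introns must be at least 40 bp")
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_cds <- function(n_codons) {
  codons <- c("ATG", sample(SENSE_CODONS, n_codons - 1L, replace = TRUE))
  paste(codons, collapse = "")
}

# split k codons into n parts, each >= min_chunk
split_codons <- function(k, n, min_chunk = 12L) {
  n <- min(n, k %/% min_chunk)
  if (n < 2) n <- 2L
  extra <- k - n * min_chunk
  cuts <- sort(sample.int(extra + 1L, n - 1L, replace = TRUE) - 1L)
  min_chunk + diff(c(0L, cuts, extra))
}

apply_substitutions <- function(seq, n_subs) {
  if (n_subs == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(chars), min(n_subs, length(chars)))
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

has_internal_stop <- function(cds) {
  n <- (nchar(cds) %/% 3) * 3
  aa <- translate_cds(substr(cds, 1, n))
  grepl("\\*", aa)
}

# point substitution creating a stop codon before frac of the CDS
inject_premature_stop <- function(cds, max_frac = 0.9) {
  k <- nchar(cds) %/% 3
  lim <- max(2L, floor(k * max_frac))
  idx <- 2:lim
  codons <- substring(cds, (idx - 1) * 3 + 1, idx * 3)
  stops <- c("TAA", "TAG", "TGA")
  one_off <- vapply(codons, function(cd) {
    any(vapply(stops, function(st) {
      sum(strsplit(cd, "")[[1]] != strsplit(st, "")[[1]]) == 1
    }, logical(1)))
  }, logical(1))
  if (any(one_off)) {
    ci <- sample(rep(idx[one_off], 2), 1)  # rep() guards length-1 sample()
    cd <- substring(cds, (ci - 1) * 3 + 1, ci * 3)
    cand <- stops[vapply(stops, function(st)
      sum(strsplit(cd, "")[[1]] != strsplit(st, "")[[1]]) == 1, logical(1))]
    new <- sample(rep(cand, 2), 1)
  } else {
    ci <- sample(rep(idx, 2), 1)
    new <- "TAA"
  }
  substr(cds, (ci - 1) * 3 + 1, ci * 3) <- new
  list(cds = cds, pos_aa = ci)
}

inject_frameshift <- function(cds) {
  n <- nchar(cds)
  width <- sample(1:2, 1)
  ins <- runif(1) < 0.5
  pos <- sample.int(n - 6L, 1) + 3L  # keep away from the very ends
  if (ins) {
    cds <- paste0(substr(cds, 1, pos), random_dna(width, 0.5),
                  substr(cds, pos + 1, n))
  } else {
    cds <- paste0(substr(cds, 1, pos), substr(cds, pos + width + 1, n))
  }
  list(cds = cds, pos_aa = ceiling(pos / 3))
}

#' Simulate a genome, annotation, proteins, retro events and ESTs
#'
#' Generates parental genes with canonical GT..AG introns placed at codon
#' boundaries, applies the configured retrotransposition process (the spliced
#' CDS is copied, mutated, given a poly-A tract and target-site duplication,
#' and inserted at an intergenic or, for chimeric events, intronic locus),
#' samples error-bearing EST reads from expressed events, and records every
#' event in a ground-truth table. For events intended to stay intact,
#' substitution draws that would create an internal stop codon are rejected
#' and redrawn, so the truth labels are unambiguous.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `annotation.gtf`, `proteins.fa`, `ests.fa` and `truth.tsv`.
#' @return Object of class `retro_simulation`: `genome` (a
#'   `genome_assembly`), `models`, `proteins`, `ests`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = simulation_config(), out_dir = NULL) {
  set.seed(config$seed)
  chroms <- names(config$chrom_lengths)

  # --- genes ------------------------------------------------------------
  gene_chrom <- sample(chroms, config$n_genes, replace = TRUE,
                       prob = config$chrom_lengths / sum(config$chrom_lengths))
  genes <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    k <- sample(config$gene_codons[1]:config$gene_codons[2], 1)
    n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1)
    chunks <- split_codons(k, n_ex)
    cds <- random_cds(k)
    introns <- replicate(length(chunks) - 1L, {
      len <- sample(config$intron_length[1]:config$intron_length[2], 1)
      paste0("GT", random_dna(len - 4L, config$gc), "AG")
    })
    # transcript-orientation segment and exon boundaries within it
    seg_parts <- character(0)
    bounds <- matrix(0L, length(chunks), 2)
    off <- 0L
    cpos <- 0L
    for (e in seq_along(chunks)) {
      ex_seq <- substr(cds, cpos * 3 + 1, (cpos + chunks[e]) * 3)
      seg_parts <- c(seg_parts, ex_seq)
      bounds[e, ] <- c(off, off + nchar(ex_seq))
      off <- off + nchar(ex_seq)
      cpos <- cpos + chunks[e]
      if (e < length(chunks)) {
        seg_parts <- c(seg_parts, introns[e])
        off <- off + nchar(introns[e])
      }
    }
    segment <- paste(seg_parts, collapse = "")
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") {
      Lg <- nchar(segment)
      segment <- revcomp(segment)
      bounds <- cbind(Lg - bounds[, 2], Lg - bounds[, 1])
      bounds <- bounds[order(bounds[, 1]), , drop = FALSE]
    }
    gid <- sprintf("gene_%03d", i)
    genes[[i]] <- list(gene_id = gid, transcript_id = sprintf("tx_%03d", i),
                       protein_id = sprintf("prot_%03d", i),
                       chrom = gene_chrom[i], strand = strand,
                       segment = segment, bounds = bounds, cds = cds)
  }

  # --- placement on chromosomes ----------------------------------------
  min_gap <- 1000L
  placements <- list()  # per gene: chrom offset
  chrom_layout <- list()
  for (chrom in chroms) {
    idx <- which(gene_chrom == chrom)
    lens <- vapply(genes[idx], function(g) nchar(g$segment), numeric(1))
    total <- sum(lens)
    L <- config$chrom_lengths[[chrom]]
    free <- L - total
    if (free < (length(idx) + 1L) * min_gap)
      stop("insufficient intergenic space on ", chrom,
           ": increase chromosome lengths or reduce genes")
    extra <- free - (length(idx) + 1L) * min_gap
    cuts <- sort(sample.int(extra + 1L, length(idx), replace = TRUE) - 1L)
    gaps <- min_gap + diff(c(0L, cuts, extra))
    offs <- numeric(length(idx))
    pos <- 0
    for (j in seq_along(idx)) {
      pos <- pos + gaps[j]
      offs[j] <- pos
      pos <- pos + lens[j]
    }
    chrom_layout[[chrom]] <- list(idx = idx, offs = offs, gaps = gaps,
                                  lens = lens)
    for (j in seq_along(idx)) placements[[idx[j]]] <- offs[j]
  }
  # base (pre-insertion) chromosome sequences
  base_seq <- list()
  for (chrom in chroms) {
    lay <- chrom_layout[[chrom]]
    parts <- character(0)
    for (j in seq_along(lay$idx)) {
      parts <- c(parts, random_dna(lay$gaps[j], config$gc),
                 genes[[lay$idx[j]]]$segment)
    }
    parts <- c(parts, random_dna(lay$gaps[length(lay$gaps)], config$gc))
    base_seq[[chrom]] <- paste(parts, collapse = "")
  }

  gene_span <- function(i) {
    off <- placements[[i]]
    c(off, off + nchar(genes[[i]]$segment))
  }
  # intron intervals of gene i in base coordinates
  gene_introns <- function(i) {
    b <- genes[[i]]$bounds
    off <- placements[[i]]
    if (nrow(b) < 2) return(matrix(numeric(0), 0, 2))
    cbind(off + b[-nrow(b), 2], off + b[-1, 1])
  }

  # --- retro + duplicate events on base coordinates --------------------
  n_ev <- config$n_retro_events
  events <- list()
  # occupied intervals (genes, with margin) per chromosome, to keep
  # intergenic inserts clear of annotation
  margin <- 100L
  occupied <- lapply(chroms, function(chrom) {
    idx <- chrom_layout[[chrom]]$idx
    if (length(idx) == 0) return(matrix(numeric(0), 0, 2))
    do.call(rbind, lapply(idx, function(i) gene_span(i) + c(-margin, margin)))
  })
  names(occupied) <- chroms
  taken <- lapply(chroms, function(chrom) numeric(0))  # insertion points used
  names(taken) <- chroms

  pick_intergenic <- function() {
    for (try in 1:200) {
      chrom <- sample(chroms, 1, prob = config$chrom_lengths / sum(config$chrom_lengths))
      p <- sample.int(config$chrom_lengths[[chrom]] - 2 * margin, 1) + margin
      occ <- occupied[[chrom]]
      if (nrow(occ) > 0 && any(p > occ[, 1] & p < occ[, 2])) next
      if (any(abs(taken[[chrom]] - p) < 50)) next
      taken[[chrom]] <<- c(taken[[chrom]], p)
      return(list(chrom = chrom, pos = p))
    }
    stop("insufficient intergenic space for insertions; increase chromosome lengths")
  }

  ev_rows <- list()
  inserts <- list()  # chrom, pos (base coords), block, meta index
  for (e in seq_len(n_ev + config$n_dna_duplicates)) {
    is_dup <- e > n_ev
    pi <- sample.int(config$n_genes, 1)
    parent <- genes[[pi]]
    if (is_dup) {
      core <- parent$segment
      site <- pick_intergenic()
      strand <- sample(c("+", "-"), 1)
      block <- if (strand == "-") revcomp(core) else core
      ev_rows[[e]] <- data.frame(
        event_id = sprintf("dup_%03d", e - n_ev), type = "dna_duplicate",
        parent_gene = parent$gene_id, parent_protein = parent$protein_id,
        chrom = site$chrom, base_pos = site$pos, core_len = nchar(block),
        strand = strand, class = NA_character_, chimeric = FALSE,
        host_gene = NA_character_, n_subs = 0L, frameshift_pos = "",
        stop_pos = "", expressed = FALSE, stringsAsFactors = FALSE)
      inserts[[e]] <- list(chrom = site$chrom, pos = site$pos, block = block)
      next
    }
    cds <- parent$cds
    rate <- runif(1, config$retro_sub_rate[1], config$retro_sub_rate[2])
    n_subs <- rbinom(1, nchar(cds), rate)
    want_fs <- runif(1) < config$p_frameshift
    want_stop <- runif(1) < config$p_stop
    intact <- !want_fs && !want_stop
    mut <- apply_substitutions(cds, n_subs)
    if (intact) {
      tries <- 0
      while (has_internal_stop(mut) && tries < 100) {
        mut <- apply_substitutions(cds, n_subs)
        tries <- tries + 1
      }
      if (has_internal_stop(mut))
        stop("could not draw a stop-free substitution pattern")
    }
    fs_pos <- integer(0)
    stop_pos <- integer(0)
    if (want_stop) {
      r <- inject_premature_stop(mut)
      mut <- r$cds
      stop_pos <- r$pos_aa
    }
    if (want_fs) {
      r <- inject_frameshift(mut)
      mut <- r$cds
      fs_pos <- r$pos_aa
    }
    chim <- intact && runif(1) < config$p_chimeric
    host <- NA_character_
    if (chim) {
      cand <- setdiff(seq_len(config$n_genes), pi)
      hi <- sample(rep(cand, 2), 1)
      host <- genes[[hi]]$gene_id
      intr <- gene_introns(hi)
      row <- sample(rep(seq_len(nrow(intr)), 2), 1)
      lo <- intr[row, 1] + 5
      hi_ <- intr[row, 2] - 5
      pos <- if (hi_ > lo) lo + sample.int(floor(hi_ - lo), 1) else floor((lo + hi_) / 2)
      site <- list(chrom = genes[[hi]]$chrom, pos = pos)
      strand <- genes[[hi]]$strand
    } else {
      site <- pick_intergenic()
      strand <- sample(c("+", "-"), 1)
    }
    core <- paste0(mut, strrep("A", config$polya_len))
    # target-site duplication: repeat the tsd_len bases upstream of the site
    tsd <- substr(base_seq[[site$chrom]], site$pos - config$tsd_len + 1, site$pos)
    block_fwd <- paste0(core, tsd)
    block <- if (strand == "-") paste0(revcomp(core), tsd) else block_fwd
    ev_rows[[e]] <- data.frame(
      event_id = sprintf("retro_%03d", e), type = "retro",
      parent_gene = parent$gene_id, parent_protein = parent$protein_id,
      chrom = site$chrom, base_pos = site$pos, core_len = nchar(mut),
      strand = strand, class = if (intact) "intact" else "pseudogene",
      chimeric = chim, host_gene = host, n_subs = n_subs,
      frameshift_pos = paste(fs_pos, collapse = ","),
      stop_pos = paste(stop_pos, collapse = ","),
      expressed = runif(1) < config$expressed_fraction,
      stringsAsFactors = FALSE)
    inserts[[e]] <- list(chrom = site$chrom, pos = site$pos, block = block,
                         core_len = nchar(mut), strand = strand)
  }
  truth <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(event_id = character(0), type = character(0),
               parent_gene = character(0), parent_protein = character(0),
               chrom = character(0), base_pos = numeric(0),
               core_len = integer(0), strand = character(0),
               class = character(0), chimeric = logical(0),
               host_gene = character(0), n_subs = integer(0),
               frameshift_pos = character(0), stop_pos = character(0),
               expressed = logical(0), stringsAsFactors = FALSE)

  # --- apply insertions, shifting coordinates --------------------------
  final_seq <- base_seq
  shift_of <- function(chrom, pos) {
    # total inserted length strictly before a base-coordinate position
    if (length(inserts) == 0) return(0)
    s <- 0
    for (ins in inserts) {
      if (ins$chrom == chrom && ins$pos < pos) s <- s + nchar(ins$block)
    }
    s
  }
  for (chrom in chroms) {
    ins_here <- Filter(function(x) x$chrom == chrom, inserts)
    if (length(ins_here) == 0) next
    ord <- order(vapply(ins_here, `[[`, numeric(1), "pos"))
    ins_here <- ins_here[ord]
    seq <- final_seq[[chrom]]
    parts <- character(0)
    prev <- 0
    for (ins in ins_here) {
      parts <- c(parts, substr(seq, prev + 1, ins$pos), ins$block)
      prev <- ins$pos
    }
    parts <- c(parts, substr(seq, prev + 1, nchar(seq)))
    final_seq[[chrom]] <- paste(parts, collapse = "")
  }
  # final truth coordinates: span of the copied CDS within the insert
  if (nrow(truth) > 0) {
    start <- numeric(nrow(truth))
    end <- numeric(nrow(truth))
    for (r in seq_len(nrow(truth))) {
      ins <- inserts[[r]]
      base_start <- truth$base_pos[r] + shift_of(truth$chrom[r], truth$base_pos[r])
      if (truth$type[r] == "retro" && !is.null(ins$strand) && ins$strand == "-") {
        # block = revcomp(mut + polyA) + tsd: the copied CDS sits after the
        # poly-T run at the block start
        start[r] <- base_start + config$polya_len
        end[r] <- start[r] + truth$core_len[r]
      } else {
        start[r] <- base_start
        end[r] <- base_start + truth$core_len[r]
      }
    }
    truth$start <- start
    truth$end <- end
    truth$base_pos <- NULL
  } else {
    truth$start <- numeric(0)
    truth$end <- numeric(0)
    truth$base_pos <- NULL
  }

  genome <- genome_assembly(setNames(unlist(final_seq), chroms))

  # shifted gene models
  models <- list()
  proteins <- character(0)
  for (i in seq_len(config$n_genes)) {
    g <- genes[[i]]
    off <- placements[[i]]
    ex <- g$bounds + off
    ex[, 1] <- ex[, 1] + vapply(ex[, 1], function(p) shift_of(g$chrom, p), numeric(1))
    ex[, 2] <- ex[, 2] + vapply(ex[, 2], function(p) shift_of(g$chrom, p), numeric(1))
    m <- gene_model(g$gene_id, g$transcript_id, g$chrom, g$strand,
                    cbind(start = ex[, 1], end = ex[, 2]),
                    protein_id = g$protein_id)
    models[[g$gene_id]] <- m
    proteins[[g$protein_id]] <- translate_cds(g$cds)
  }

  # --- ESTs -------------------------------------------------------------
  ests <- character(0)
  expressed_rows <- which(truth$type == "retro" & truth$expressed)
  if (config$n_ests > 0 && length(expressed_rows) > 0) {
    for (k in seq_len(config$n_ests)) {
      r <- sample(rep(expressed_rows, 2), 1)
      L <- genome$lengths[[truth$chrom[r]]]
      lo <- max(0, truth$start[r] - 50)
      hi <- min(L, truth$end[r] + 50)
      len <- min(config$est_length, hi - lo)
      s0 <- lo + sample.int(max(1, hi - lo - len + 1), 1) - 1
      read <- substr(genome$sequences[[truth$chrom[r]]], s0 + 1, s0 + len)
      if (runif(1) < 0.5) read <- revcomp(read)
      read <- apply_substitutions(read, rbinom(1, nchar(read), config$est_error))
      ests[[sprintf("est_%04d", k)]] <- read
    }
  }

  sim <- structure(list(genome = genome, models = models, proteins = proteins,
                        ests = ests, truth = truth, config = config),
                   class = "retro_simulation")
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

#' Write the five simulator outputs to a directory
#'
#' @param sim A `retro_simulation`.
#' @param out_dir Output directory (created if absent).
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome$sequences, file.path(out_dir, "genome.fa"))
  write_gtf(sim$models, file.path(out_dir, "annotation.gtf"))
  write_fasta(sim$proteins, file.path(out_dir, "proteins.fa"))
  write_fasta(sim$ests, file.path(out_dir, "ests.fa"))
  write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
  invisible(out_dir)
}

#' @export
print.retro_simulation <- function(x, ...) {
  cat("<retro_simulation> ", length(x$models), " genes, ",
      sum(x$truth$type == "retro"), " retro events, ",
      length(x$ests), " ESTs on ", length(x$genome$sequences),
      " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Expected synonymous divergence implied by a substitution rate
#'
#' Monte-Carlo estimate of the mean NG86 Ks produced by applying uniform
#' random substitutions at per-site rate `rate` to random coding sequences.
#' Links the simulator's divergence dial to the observable Ks scale.
#'
#' @param rate Per-site substitution rate in `[0, 0.7]`.
#' @param n_pairs Number of simulated pairs.
#' @param n_codons Codons per pair.
#' @param seed RNG seed.
#' @return Mean Ks across pairs (0 when `rate` is 0).
#' @export
expected_ks <- function(rate, n_pairs = 200L, n_codons = 300L, seed = 1L) {
  stopifnot(rate >= 0, rate < 0.75)
  if (rate == 0) return(0)
  set.seed(seed)
  ks <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    a <- random_cds(n_codons)
    b <- apply_substitutions(a, rbinom(1, nchar(a), rate))
    r <- ng86(codon_align(a, b))
    ks[i] <- if (is.na(r$ks)) NA_real_ else r$ks
  }
  mean(ks, na.rm = TRUE)
}
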