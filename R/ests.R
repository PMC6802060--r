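# EST-based transcription evidence: cleaning, seeded genome mapping,
# unique-location filtering, and per-retrocopy support counting.

#' Default parameters of the EST analysis
#'
#' Mapped alignments are retained at identity > 95% with > 90% of the EST
#' aligned; a retrocopy is supported by an EST whose unique alignment
#' overlaps it by more than 100 bp at more than 97% identity within the
#' overlap. `unique_margin` operationalises "mapped to a unique location":
#' an EST with several passing alignments is kept only when the best score
#' beats the second best by at least this fraction.
#'
#' @export
est_params <- function(word_size = 11L, seed_stride = 25L,
                       match = 1L, mismatch = -2L,
                       gap_open = 2L, gap_ext = 1L,
                       min_identity = 0.95, min_coverage = 0.90,
                       unique_margin = 0.05,
                       support_min_overlap = 100L,
                       support_min_identity = 0.97,
                       polya_min = 10L, min_length = 100L,
                       max_mono_fraction = 0.8,
                       min_dinuc_entropy = 1.5) {
  as.list(environment())
}

dinuc_entropy <- function(s) {
  n <- nchar(s)
  if (n < 2) return(0)
  d <- substring(s, 1:(n - 1), 2:n)
  p <- table(d) / (n - 1)
  -sum(p * log2(p))
}

#' Clean EST reads
#'
#' Trims terminal poly-A/poly-T runs of at least `polya_min` bp, drops reads
#' shorter than `min_length` after trimming, and drops low-complexity reads
#' (mononucleotide fraction above `max_mono_fraction` or dinucleotide
#' entropy below `min_dinuc_entropy` bits).
#'
#' @param ests Named character vector of reads.
#' @param params See [est_params()].
#' @return List: `ests` (cleaned, named) and `log` (data frame `est_id`,
#'   `action`, one row per modified or rejected read).
#' @export
clean_ests <- function(ests, params = est_params()) {
  out <- character(0)
  log <- list()
  note <- function(id, action)
    log[[length(log) + 1L]] <<- data.frame(est_id = id, action = action,
                                           stringsAsFactors = FALSE)
  k <- params$polya_min
  for (id in names(ests)) {
    s <- ests[[id]]
    s2 <- sub(sprintf("A{%d,}$", k), "", s)
    s2 <- sub(sprintf("T{%d,}$", k), "", s2)
    s2 <- sub(sprintf("^A{%d,}", k), "", s2)
    s2 <- sub(sprintf("^T{%d,}", k), "", s2)
    if (nchar(s2) < nchar(s)) note(id, "trimmed")
    if (nchar(s2) < params$min_length) { note(id, "dropped_short"); next }
    counts <- table(strsplit(s2, "")[[1]])
    if (max(counts) / nchar(s2) > params$max_mono_fraction) {
      note(id, "dropped_mononucleotide"); next
    }
    if (dinuc_entropy(s2) < params$min_dinuc_entropy) {
      note(id, "dropped_low_complexity"); next
    }
    out[[id]] <- s2
  }
  list(ests = out,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(est_id = character(0), action = character(0),
                    stringsAsFactors = FALSE))
}

# seed positions (1-based starts) of an EST
est_seed_starts <- function(len, word, stride) {
  if (len < word) return(integer(0))
  unique(pmin(seq(1L, len, by = stride), len - word + 1L))
}

#' Map cleaned ESTs to a genome
#'
#' Exact `word_size`-mer seeds (forward and reverse-complement, found with a
#' preprocessed dictionary), diagonal clustering, and affine-gap local
#' extension (+1 match / -2 mismatch). Alignments are kept at identity above
#' `min_identity` and EST coverage above `min_coverage`.
#'
#' @param ests Named character vector of cleaned reads.
#' @param genome A `genome_assembly`.
#' @param params See [est_params()].
#' @return List: `alignments` (data frame: `est_id`, `chrom`, `strand`,
#'   `g_start`, `g_end` 0-based half-open, `score`, `identity`, `coverage`,
#'   `n_blocks`) and `details` (per-row list of aligned-column vectors
#'   `g_pos` 1-based, `match`).
#' @export
map_ests <- function(ests, genome, params = est_params()) {
  empty <- list(alignments = data.frame(
    est_id = character(0), chrom = character(0), strand = character(0),
    g_start = numeric(0), g_end = numeric(0), score = numeric(0),
    identity = numeric(0), coverage = numeric(0), n_blocks = integer(0),
    stringsAsFactors = FALSE), details = list())
  if (length(ests) == 0) return(empty)
  w <- params$word_size
  seeds <- list()
  meta <- list()
  for (id in names(ests)) {
    s <- ests[[id]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") s else revcomp(s)
      st <- est_seed_starts(nchar(q), w, params$seed_stride)
      for (p in st) {
        seeds[[length(seeds) + 1L]] <- substr(q, p, p + w - 1L)
        meta[[length(meta) + 1L]] <- c(id = id, strand = strand, off = p)
      }
    }
  }
  kmers <- unlist(seeds)
  valid <- !grepl("[^ACGT]", kmers)
  if (!any(valid)) return(empty)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[valid]))
  vmeta <- meta[valid]
  hits <- list()  # est_id, strand, chrom, diag (genomic start of read)
  for (chrom in names(genome$sequences)) {
    mm <- Biostrings::matchPDict(pd, Biostrings::DNAString(genome$sequences[[chrom]]))
    st <- Biostrings::startIndex(mm)
    for (k in seq_along(st)) {
      if (is.null(st[[k]]) || length(st[[k]]) == 0) next
      m <- vmeta[[k]]
      for (gp in st[[k]]) {
        hits[[length(hits) + 1L]] <- data.frame(
          est_id = m[["id"]], strand = m[["strand"]], chrom = chrom,
          diag = gp - as.integer(m[["off"]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) return(empty)
  hits <- unique(do.call(rbind, hits))
  aln_rows <- list()
  details <- list()
  key <- paste(hits$est_id, hits$strand, hits$chrom)
  for (kk in unique(key)) {
    h <- hits[key == kk, , drop = FALSE]
    h <- h[order(h$diag), , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(h$diag) > 40))
    id <- h$est_id[1]
    q <- if (h$strand[1] == "+") ests[[id]] else revcomp(ests[[id]])
    len <- nchar(q)
    for (g in split(seq_len(nrow(h)), grp)) {
      d0 <- min(h$diag[g]); d1 <- max(h$diag[g])
      lo <- max(1L, d0 - 30L)
      hi <- min(genome$lengths[[h$chrom[1]]], d1 + len + 30L)
      win <- substr(genome$sequences[[h$chrom[1]]], lo, hi)
      r <- cpp_sw_nt(q, win, params$match, params$mismatch,
                     params$gap_open, params$gap_ext)
      ncol_ <- length(r$a_pos)
      if (ncol_ == 0) next
      identity <- sum(r$match) / ncol_
      coverage <- ncol_ / len
      if (identity <= params$min_identity || coverage <= params$min_coverage)
        next
      gpos <- r$b_pos + lo - 1L  # 1-based genomic
      blocks <- 1L + sum(diff(gpos) > 1L)
      aln_rows[[length(aln_rows) + 1L]] <- data.frame(
        est_id = id, chrom = h$chrom[1], strand = h$strand[1],
        g_start = min(gpos) - 1L, g_end = max(gpos), score = r$score,
        identity = identity, coverage = coverage, n_blocks = blocks,
        stringsAsFactors = FALSE)
      details[[length(aln_rows)]] <- list(g_pos = gpos, match = r$match)
    }
  }
  if (length(aln_rows) == 0) return(empty)
  df <- do.call(rbind, aln_rows)
  # deduplicate alignments of one EST covering the same locus (from several
  # seed clusters): keep the best score
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(df))) {
      if (i == j || !keep[j]) next
      if (df$est_id[i] != df$est_id[j] || df$chrom[i] != df$chrom[j]) next
      if (interval_overlap(df$g_start[i], df$g_end[i],
                           df$g_start[j], df$g_end[j]) > 0) {
        drop <- if (df$score[i] >= df$score[j]) j else i
        keep[drop] <- FALSE
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  details <- details[keep]
  ord <- order(df$est_id, df$chrom, df$g_start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  list(alignments = df, details = details[ord])
}

#' Keep each EST's unique alignment, if any
#'
#' An EST maps uniquely when exactly one alignment passed the gates, or when
#' the best score exceeds the second best by at least `unique_margin`
#' (fraction of the best). Otherwise the EST is discarded from support
#' counting.
#'
#' @param mapped Result of [map_ests()].
#' @param params See [est_params()].
#' @return Same shape as `mapped`, restricted to unique alignments.
#' @export
filter_unique <- function(mapped, params = est_params()) {
  df <- mapped$alignments
  if (nrow(df) == 0) return(mapped)
  keep <- logical(nrow(df))
  for (id in unique(df$est_id)) {
    idx <- which(df$est_id == id)
    if (length(idx) == 1) { keep[idx] <- TRUE; next }
    sc <- df$score[idx]
    o <- order(-sc)
    best <- sc[o[1]]; second <- sc[o[2]]
    if ((best - second) / best >= params$unique_margin) keep[idx[o[1]]] <- TRUE
  }
  list(alignments = df[keep, , drop = FALSE],
       details = mapped$details[keep])
}

#' Count EST support per retrocopy
#'
#' An EST supports a retrocopy when its unique alignment overlaps the
#' retrocopy locus by more than `support_min_overlap` bp with identity above
#' `support_min_identity` within the overlapping columns.
#'
#' @param unique_mapped Result of [filter_unique()].
#' @param catalogue Catalogue data frame.
#' @param params See [est_params()].
#' @return Data frame: `retro_id`, `n_supporting_ests`, `supporting_ests`
#'   (comma-separated ids).
#' @export
count_support <- function(unique_mapped, catalogue, params = est_params()) {
  df <- unique_mapped$alignments
  out <- data.frame(retro_id = catalogue$retro_id,
                    n_supporting_ests = 0L,
                    supporting_ests = "",
                    stringsAsFactors = FALSE)
  if (nrow(df) == 0 || nrow(catalogue) == 0) return(out)
  for (i in seq_len(nrow(catalogue))) {
    hits <- character(0)
    for (j in seq_len(nrow(df))) {
      if (df$chrom[j] != catalogue$chrom[i]) next
      ov <- interval_overlap(df$g_start[j], df$g_end[j],
                             catalogue$start[i], catalogue$end[i])
      if (ov <= params$support_min_overlap) next
      det <- unique_mapped$details[[j]]
      inside <- det$g_pos > catalogue$start[i] & det$g_pos <= catalogue$end[i]
      if (sum(inside) == 0) next
      if (sum(det$match[inside]) / sum(inside) <= params$support_min_identity)
        next
      hits <- c(hits, df$est_id[j])
    }
    hits <- unique(hits)
    out$n_supporting_ests[i] <- length(hits)
    out$supporting_ests[i] <- paste(hits, collapse = ",")
  }
  out
}

#' EST transcription support for a retrocopy catalogue
#'
#' Runs cleaning, mapping, unique filtering and support counting, and
#' summarises support rates for intact retrogenes vs retropseudogenes.
#'
#' @param ests Named character vector of raw reads.
#' @param genome A `genome_assembly`.
#' @param catalogue Catalogue data frame.
#' @param params See [est_params()].
#' @return List: `support` (per-retrocopy counts), `summary` (data frame by
#'   class: n, n_supported, fraction), `cleaned`, `unique`.
#' @export
est_support <- function(ests, genome, catalogue, params = est_params()) {
  cl <- clean_ests(ests, params)
  mapped <- map_ests(cl$ests, genome, params)
  uni <- filter_unique(mapped, params)
  sup <- count_support(uni, catalogue, params)
  merged <- merge(catalogue[, c("retro_id", "class")], sup, by = "retro_id")
  summ <- do.call(rbind, lapply(c("intact", "pseudogene"), function(cls) {
    sub <- merged[merged$class == cls, , drop = FALSE]
    data.frame(class = cls, n = nrow(sub),
               n_supported = sum(sub$n_supporting_ests > 0),
               fraction = if (nrow(sub)) mean(sub$n_supporting_ests > 0) else 0,
               stringsAsFactors = FALSE)
  }))
  list(support = sup, summary = summ, cleaned = cl, unique = uni)
}
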