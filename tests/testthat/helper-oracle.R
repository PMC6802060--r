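# Independent brute-force oracles. These re-derive quantities from first
# principles (explicit enumeration, no cached matrices) so they can check the
# package implementations.

# --- NG86 oracle -----------------------------------------------------------

oracle_translate1 <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[codon]])
}

# synonymous-site fraction of one codon by enumerating its 9 neighbours
oracle_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- oracle_translate1(codon)
  syn <- 0
  for (p in 1:3) {
    for (b in bases) {
      if (b == substr(codon, p, p)) next
      alt <- codon
      substr(alt, p, p) <- b
      if (oracle_translate1(alt) == aa) syn <- syn + 1
    }
  }
  syn / 3
}

# all permutations of a vector, generated recursively
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# observed syn/nonsyn differences between two codons, averaging over all
# substitution orders that avoid stop-codon intermediates (all orders if
# every one is blocked)
oracle_diff_counts <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  paths <- oracle_perms(pos)
  res <- matrix(NA_real_, length(paths), 3)
  for (k in seq_along(paths)) {
    cur <- a
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in paths[[k]]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (oracle_translate1(nxt) == "*" || oracle_translate1(cur) == "*")
        blocked <- TRUE
      if (oracle_translate1(nxt) == oracle_translate1(cur)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    res[k, ] <- c(sd, nd, blocked)
  }
  ok <- res[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(res))
  c(sd = mean(res[ok, 1]), nd = mean(res[ok, 2]))
}

# full NG86 site and difference counts for two codon vectors
oracle_ng86_counts <- function(codons_a, codons_b) {
  S <- 0; Nd <- 0; Sd <- 0
  for (i in seq_along(codons_a)) {
    S <- S + (oracle_syn_sites(codons_a[i]) + oracle_syn_sites(codons_b[i])) / 2
    d <- oracle_diff_counts(codons_a[i], codons_b[i])
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  list(N = 3 * length(codons_a) - S, S = S, Nd = Nd, Sd = Sd)
}

# --- HSP chaining oracle ---------------------------------------------------

# maximum chain score by enumerating every ordered subset of HSPs that
# satisfies the collinearity constraints
oracle_best_chain_score <- function(h, max_intron = 50000, tol_p = 10,
                                    tol_g = 30) {
  minus <- h$strand[1] == "-"
  ts <- if (minus) -h$g_end else h$g_start
  te <- if (minus) -h$g_start else h$g_end
  n <- nrow(h)
  best <- 0
  extend <- function(chain, score) {
    best <<- max(best, score)
    last <- chain[length(chain)]
    for (k in seq_len(n)) {
      if (k %in% chain) next
      ok <- ts[k] >= te[last] - tol_g &&
        ts[k] - te[last] <= max_intron &&
        h$p_start[k] >= h$p_end[last] - tol_p &&
        h$p_end[k] > h$p_end[last]
      if (ok) extend(c(chain, k), score + h$score[k])
    }
  }
  for (i in seq_len(n)) extend(i, h$score[i])
  best
}

# --- spliced-alignment oracle ----------------------------------------------

# exhaustive enumeration of local parses with codon / frameshift / gap /
# intron moves, mirroring the DP's move semantics (introns enter at GT,
# leave at AG, between codons, followed immediately by a plain codon).
# Budgets keep the enumeration tractable; test cases are constructed so the
# optimum stays within them.
oracle_spliced_score <- function(prot_aa, dna, S, fs_pen, intron_pen,
                                 gap_pen, min_intron,
                                 gap_budget = 2, fs_budget = 2,
                                 intron_budget = 1) {
  alpha <- attr(S, "alphabet")
  pidx <- match(strsplit(prot_aa, "")[[1]], alpha)
  m <- length(pidx)
  n <- nchar(dna)
  tab <- Biostrings::GENETIC_CODE
  codon_score <- function(i, j) {  # codon ending at j for residue i
    if (j < 3 || j > n) return(NA_real_)
    cod <- substr(dna, j - 2, j)
    if (grepl("[^ACGT]", cod)) return(0)  # N-codon scores 0
    S[pidx[i], match(tab[[cod]], alpha)]
  }
  best <- 0
  step <- function(i, j, score, gb, fb, ib) {
    best <<- max(best, score)
    if (i > m) return()
    if (gb > 0) {
      step(i + 1, j, score + gap_pen, gb - 1, fb, ib)          # skip residue
      if (j + 3 <= n) step(i, j + 3, score + gap_pen, gb - 1, fb, ib)  # skip codon
    }
    for (cl in c(1L, 2L, 3L, 4L, 5L)) {
      j2 <- j + cl
      sc <- codon_score(i, j2)
      if (is.na(sc)) next
      if (cl == 3L) {
        step(i + 1, j2, score + sc, gb, fb, ib)
      } else if (fb > 0) {
        step(i + 1, j2, score + fs_pen + sc, gb, fb - 1, ib)
      }
    }
    if (ib > 0 && j >= 3 && j + 2 <= n && j + min_intron <= n - 3 &&
        substr(dna, j + 1, j + 2) == "GT") {
      for (j2 in seq(j + min_intron, n - 3)) {
        if (substr(dna, j2 - 1, j2) != "AG") next
        sc <- codon_score(i, j2 + 3)
        if (is.na(sc)) next
        step(i + 1, j2 + 3, score + intron_pen + sc, gb, fb, ib - 1)
      }
    }
  }
  for (i0 in seq_len(m)) {
    for (j0 in 3:n) {
      sc <- codon_score(i0, j0)
      if (!is.na(sc) && sc > 0)
        step(i0 + 1, j0, sc, gap_budget, fs_budget, intron_budget)
    }
  }
  best
}
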