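# Codon-level evolution statistics: protein-guided codon alignment, the
# Nei-Gojobori (1986) counting method with Jukes-Cantor correction, Ks-based
# dating (T = Ks / 2 lambda), omega classification and the pooled-tail Ks
# histogram.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# fractional synonymous sites per sense codon (stop-creating substitutions
# count as nonsynonymous, classic NG86)
.syn_sites_table <- function() {
  if (!is.null(.rt_cache$syn_sites)) return(.rt_cache$syn_sites)
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  out <- numeric(0)
  for (codon in names(gc)) {
    if (gc[[codon]] == "*") next
    n_syn <- 0
    for (p in 1:3) for (b in setdiff(bases, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      if (gc[[alt]] == gc[[codon]]) n_syn <- n_syn + 1
    }
    out[[codon]] <- n_syn / 3
  }
  .rt_cache$syn_sites <- out
  out
}

# per codon pair: observed synonymous/nonsynonymous differences, averaged
# over all minimal mutational pathways that avoid stop codons (falling back
# to all pathways when every one passes through a stop)
.path_counts <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(pos) else if (k == 2) {
    list(pos, rev(pos))
  } else {
    list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
         pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  }
  eval_path <- function(ord) {
    cur <- a
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (gc[[nxt]] == "*" || gc[[cur]] == "*") blocked <- TRUE
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd, blocked = as.numeric(blocked))
  }
  res <- vapply(perms, eval_path, numeric(3))
  ok <- res["blocked", ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(res))
  c(sd = mean(res["sd", ok]), nd = mean(res["nd", ok]))
}

# cached 61x61 (sense codons) difference-count tables
.ndsd_tables <- function() {
  if (!is.null(.rt_cache$ndsd)) return(.rt_cache$ndsd)
  codons <- names(.syn_sites_table())
  n <- length(codons)
  SD <- matrix(0, n, n, dimnames = list(codons, codons))
  ND <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j < i) {
      SD[i, j] <- SD[j, i]; ND[i, j] <- ND[j, i]
    } else if (i != j) {
      pc <- .path_counts(codons[i], codons[j])
      SD[i, j] <- pc[["sd"]]; ND[i, j] <- pc[["nd"]]
    }
  }
  .rt_cache$ndsd <- list(SD = SD, ND = ND)
  .rt_cache$ndsd
}

#' Protein-guided codon alignment of a parent CDS and a retrocopy region
#'
#' The two conceptual translations are aligned globally (BLOSUM62, affine
#' gaps, via Biostrings) and the alignment is back-threaded onto codons.
#' Gap columns, columns whose codons contain ambiguity bases or stops, and
#' columns at retrocopy positions listed in `exclude` (plus their immediate
#' neighbours; used for frameshift-adjacent codons) are dropped.
#'
#' @param parent_cds,retro_region DNA strings with length divisible by 3
#'   (trailing partial codons of `retro_region` are ignored).
#' @param exclude Retrocopy codon indices to drop (with +-1 neighbours).
#' @return Object of class `codon_alignment`: parallel codon vectors `a`,
#'   `b` and the codon count `L`.
#' @export
codon_align <- function(parent_cds, retro_region, exclude = integer(0)) {
  la <- (nchar(parent_cds) %/% 3) * 3
  lb <- (nchar(retro_region) %/% 3) * 3
  a_cod <- substring(parent_cds, seq(1, la, 3), seq(3, la, 3))
  b_cod <- substring(retro_region, seq(1, lb, 3), seq(3, lb, 3))
  tab <- .codon_table()
  a_aa <- unname(tab[a_cod]); a_aa[is.na(a_aa)] <- "X"
  b_aa <- unname(tab[b_cod]); b_aa[is.na(b_aa)] <- "X"
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(a_aa, collapse = "")),
    Biostrings::AAString(paste(b_aa, collapse = "")),
    substitutionMatrix = e$BLOSUM62, gapOpening = 10, gapExtension = 1,
    type = "global")
  ap <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  as <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  ia <- 0L; ib <- 0L
  keep_a <- integer(0); keep_b <- integer(0)
  excl <- unique(c(exclude, exclude - 1L, exclude + 1L))
  for (k in seq_along(ap)) {
    ga <- ap[k] == "-"; gb <- as[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (ga || gb) next
    if (ib %in% excl) next
    keep_a <- c(keep_a, ia); keep_b <- c(keep_b, ib)
  }
  a_k <- a_cod[keep_a]; b_k <- b_cod[keep_b]
  ok <- !grepl("[^ACGT]", a_k) & !grepl("[^ACGT]", b_k) &
    !a_k %in% STOP_CODONS & !b_k %in% STOP_CODONS
  structure(list(a = a_k[ok], b = b_k[ok], L = sum(ok)),
            class = "codon_alignment")
}

#' NG86 Ka/Ks estimation on a codon alignment
#'
#' Fractional synonymous site counting per codon (averaged over the two
#' sequences), observed differences averaged over all minimal mutational
#' pathways excluding those through stop codons, and Jukes-Cantor correction
#' `K = -3/4 ln(1 - 4p/3)`. A proportion of 3/4 or more leaves the
#' corresponding rate undefined (saturated).
#'
#' @param aln A `codon_alignment`.
#' @param min_codons Minimum codon count required.
#' @return Object of class `kaks_result`: `L`, `N`, `S`, `Nd`, `Sd`, `pn`,
#'   `ps`, `ka`, `ks`, `omega` (NA when Ks is 0 or undefined), and saturation
#'   flags.
#' @export
ng86 <- function(aln, min_codons = 10L) {
  if (aln$L < min_codons) {
    return(structure(list(L = aln$L, N = NA_real_, S = NA_real_,
                          Nd = NA_real_, Sd = NA_real_, pn = NA_real_,
                          ps = NA_real_, ka = NA_real_, ks = NA_real_,
                          omega = NA_real_, saturated_ka = FALSE,
                          saturated_ks = FALSE, too_short = TRUE),
                     class = "kaks_result"))
  }
  syn <- .syn_sites_table()
  tabs <- .ndsd_tables()
  s_a <- syn[aln$a]; s_b <- syn[aln$b]
  S <- sum((s_a + s_b) / 2)
  N <- 3 * aln$L - S
  idx <- cbind(match(aln$a, rownames(tabs$SD)), match(aln$b, colnames(tabs$SD)))
  Sd <- sum(tabs$SD[idx])
  Nd <- sum(tabs$ND[idx])
  pn <- Nd / N
  ps <- Sd / S
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ka <- jc(pn)
  ks <- jc(ps)
  omega <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  structure(list(L = aln$L, N = N, S = S, Nd = Nd, Sd = Sd, pn = pn, ps = ps,
                 ka = ka, ks = ks, omega = omega,
                 saturated_ka = is.na(ka), saturated_ks = is.na(ks),
                 too_short = FALSE),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result> L=%d N=%.1f S=%.1f Nd=%.1f Sd=%.1f Ka=%s Ks=%s omega=%s\n",
              x$L, x$N, x$S, x$Nd, x$Sd,
              format(x$ka, digits = 4), format(x$ks, digits = 4),
              format(x$omega, digits = 4)))
  invisible(x)
}

#' Molecular dating parameters
#'
#' The per-year neutral substitution rate lambda is derived from a
#' per-generation rate and a generation time; the defaults (0.4e-8 per
#' generation, 3-year generations) give lambda = 1.33e-9 per year.
#'
#' @param rate_per_generation Neutral substitution rate per site per
#'   generation.
#' @param generation_time Generation time in years.
#' @return List with `rate_per_generation`, `generation_time`,
#'   `lambda_per_year`.
#' @export
dating_params <- function(rate_per_generation = 0.4e-8, generation_time = 3) {
  list(rate_per_generation = rate_per_generation,
       generation_time = generation_time,
       lambda_per_year = rate_per_generation / generation_time)
}

#' Insertion age from synonymous divergence
#'
#' `T = Ks / (2 lambda)`, reported in millions of years.
#'
#' @param ks Synonymous divergence (substitutions per synonymous site).
#' @param params See [dating_params()].
#' @return Age in Mya (NA for NA/saturated Ks).
#' @export
estimate_age <- function(ks, params = dating_params()) {
  ks / (2 * params$lambda_per_year) / 1e6
}

#' Selection class from the Ka/Ks ratio
#'
#' Bins follow the three-way partition used for retrocopy selection tables:
#' constrained (omega < 0.5), intermediate (0.5 <= omega <= 1.2) and
#' elevated (omega > 1.2); pairs with Ks = 0 or saturated Ks are `undefined`
#' and excluded from omega statistics.
#'
#' @param omega Ka/Ks ratio (NA allowed).
#' @param ks Ks value backing the ratio.
#' @return Character vector of classes.
#' @export
classify_selection <- function(omega, ks) {
  out <- rep("undefined", length(omega))
  ok <- !is.na(omega) & !is.na(ks) & ks > 0
  out[ok & omega < 0.5] <- "constrained"
  out[ok & omega >= 0.5 & omega <= 1.2] <- "intermediate"
  out[ok & omega > 1.2] <- "elevated"
  out
}

#' Ks histogram with pooled tails
#'
#' Regular bins of width `binwidth` on [0, 1), one pooled bin [1, 2) and one
#' pooled bin [2, Inf).
#'
#' @param ks Numeric vector of Ks values (NA dropped).
#' @param binwidth Regular bin width.
#' @return List with `bins` (data frame: `lower`, `upper`, `count`,
#'   `fraction`) and `modal_bin` (row index of the highest count).
#' @export
ks_histogram <- function(ks, binwidth = 0.02) {
  ks <- ks[!is.na(ks)]
  lower <- c(seq(0, 1 - binwidth, by = binwidth), 1, 2)
  upper <- c(seq(binwidth, 1, by = binwidth), 2, Inf)
  count <- vapply(seq_along(lower), function(i)
    sum(ks >= lower[i] & ks < upper[i]), numeric(1))
  bins <- data.frame(lower = lower, upper = upper, count = count,
                     fraction = if (length(ks)) count / length(ks) else 0)
  list(bins = bins, modal_bin = if (length(ks)) which.max(count) else NA_integer_)
}

#' Ka/Ks, age and selection class for every record of a catalogue
#'
#' Aligns each retrocopy's matched codons back to its parent CDS, applies
#' NG86, dates the insertion and assigns the selection class.
#'
#' @param disc Discovery result from [discover_retrocopies()].
#' @param genome A `genome_assembly`.
#' @param models Gene models (named by gene id).
#' @param dating See [dating_params()].
#' @param min_codons Minimum codons for NG86.
#' @return Data frame: `retro_id`, `parent_gene`, `L`, `N`, `S`, `Nd`, `Sd`,
#'   `ka`, `ks`, `omega`, `age_mya`, `class`.
#' @export
kaks_catalogue <- function(disc, genome, models, dating = dating_params(),
                           min_codons = 10L) {
  cat_df <- disc$catalogue
  rows <- vector("list", nrow(cat_df))
  for (i in seq_len(nrow(cat_df))) {
    rid <- cat_df$retro_id[i]
    st <- disc$structures[[rid]]
    parent <- models[[cat_df$parent_gene[i]]]
    parent_cds <- extract_cds(parent, genome)
    retro_region <- paste(st$codons, collapse = "")
    fs_idx <- which(st$codon_is_fs)
    aln <- codon_align(parent_cds, retro_region, exclude = fs_idx)
    r <- ng86(aln, min_codons = min_codons)
    age <- if (!is.na(r$ks)) estimate_age(r$ks, dating) else NA_real_
    rows[[i]] <- data.frame(
      retro_id = rid, parent_gene = cat_df$parent_gene[i], L = r$L,
      N = r$N, S = r$S, Nd = r$Nd, Sd = r$Sd, ka = r$ka, ks = r$ks,
      omega = r$omega, age_mya = age,
      class = classify_selection(r$omega, r$ks),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(retro_id = character(0), parent_gene = character(0),
                      L = integer(0), N = numeric(0), S = numeric(0),
                      Nd = numeric(0), Sd = numeric(0), ka = numeric(0),
                      ks = numeric(0), omega = numeric(0),
                      age_mya = numeric(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
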