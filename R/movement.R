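# Chromosomal gene-traffic analysis: movement classification, functional and
# neutral pair selection, per-chromosome count regressions, and the
# X-chromosome outlier test (externally studentized residual against an
# autosome-only fit).

#' Classify the movement of one retrocopy
#'
#' @param parent_chrom,retro_chrom Chromosome names.
#' @param meta Chromosome metadata data frame (`chrom`, `is_scaffold_mt`),
#'   e.g. `genome$meta`.
#' @return `"interchromosomal"`, `"intrachromosomal"` or `"scaffold_mt"`.
#' @export
classify_movement <- function(parent_chrom, retro_chrom, meta) {
  sc <- setNames(meta$is_scaffold_mt, meta$chrom)
  mapply(function(p, r) {
    if (isTRUE(sc[[p]]) || isTRUE(sc[[r]])) return("scaffold_mt")
    if (p == r) "intrachromosomal" else "interchromosomal"
  }, parent_chrom, retro_chrom, USE.NAMES = FALSE)
}

#' Movement table for a catalogue
#'
#' @param catalogue Catalogue data frame.
#' @param models Gene models named by gene id.
#' @param genome A `genome_assembly`.
#' @return Data frame: `retro_id`, `parent_chrom`, `retro_chrom`, `category`.
#' @export
movement_table <- function(catalogue, models, genome) {
  parent_chrom <- vapply(catalogue$parent_gene,
                         function(g) models[[g]]$chrom, "")
  data.frame(retro_id = catalogue$retro_id,
             parent_chrom = unname(parent_chrom),
             retro_chrom = catalogue$chrom,
             category = classify_movement(parent_chrom, catalogue$chrom,
                                          genome$meta),
             stringsAsFactors = FALSE)
}

#' Per-category movement counts and percentages
#'
#' @param movements Data frame with a `category` column.
#' @return Data frame: `category`, `n`, `percent`.
#' @export
movement_fractions <- function(movements) {
  if (nrow(movements) == 0) stop("no movement records")
  cats <- c("interchromosomal", "intrachromosomal", "scaffold_mt")
  n <- vapply(cats, function(cc) sum(movements$category == cc), numeric(1))
  data.frame(category = cats, n = n, percent = 100 * n / sum(n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select functional and neutral retrocopy-parent pair sets
#'
#' Functional pairs are intact retrogenes under strong purifying selection
#' (omega < 0.5); neutral pairs are retropseudogenes evolving near
#' neutrality (0.5 < omega < 1.0, exclusive at both ends). Regression
#' analyses use the interchromosomal members of each set.
#'
#' @param catalogue Catalogue data frame.
#' @param kaks Ka/Ks table from [kaks_catalogue()].
#' @param movements Movement table from [movement_table()].
#' @return List of data frames `functional` and `neutral`, each with
#'   catalogue columns plus `omega` and `category`.
#' @export
select_sets <- function(catalogue, kaks, movements) {
  m <- merge(catalogue, kaks[, c("retro_id", "omega")], by = "retro_id")
  m <- merge(m, movements[, c("retro_id", "category")], by = "retro_id")
  functional <- m[m$class == "intact" & !is.na(m$omega) & m$omega < 0.5, ]
  neutral <- m[m$class == "pseudogene" & !is.na(m$omega) &
                 m$omega > 0.5 & m$omega < 1.0, ]
  list(functional = functional, neutral = neutral)
}

#' Per-chromosome statistics for movement regressions
#'
#' Counts, for the primary chromosomes (scaffolds/MT excluded), annotated
#' genes, parental genes of the given pairs, and retrocopy insertions.
#'
#' @param pairs Data frame of pairs (catalogue columns + `category`),
#'   typically one of the [select_sets()] sets restricted to
#'   interchromosomal movements by the caller.
#' @param models Gene models named by gene id.
#' @param genome A `genome_assembly`.
#' @return Data frame: `chrom`, `is_x`, `length`, `n_genes`, `n_parents`,
#'   `n_insertions`.
#' @export
chromosome_stats <- function(pairs, models, genome) {
  meta <- genome$meta[!genome$meta$is_scaffold_mt, , drop = FALSE]
  gene_chrom <- vapply(models, `[[`, "", "chrom")
  parent_chrom <- vapply(pairs$parent_gene, function(g) models[[g]]$chrom, "")
  data.frame(
    chrom = meta$chrom,
    is_x = meta$is_x,
    length = unname(genome$lengths[meta$chrom]),
    n_genes = vapply(meta$chrom, function(cc) sum(gene_chrom == cc), numeric(1)),
    n_parents = vapply(meta$chrom, function(cc) sum(parent_chrom == cc), numeric(1)),
    n_insertions = vapply(meta$chrom, function(cc) sum(pairs$chrom == cc), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Regress per-chromosome counts on a chromosomal covariate
#'
#' Ordinary least squares of `count_col` on `covariate_col`, with the Pearson
#' correlation over the same points. `include_x` controls whether the X
#' chromosome contributes to the fit (both variants are reported by the
#' pipeline because either reading of published per-chromosome correlations
#' is defensible).
#'
#' @param stats Data frame from [chromosome_stats()].
#' @param count_col,covariate_col Column names.
#' @param include_x Include the X point in fit and correlation.
#' @return Object of class `movement_regression`: `slope`, `intercept`, `r`,
#'   `n`, `residuals` (data frame `chrom`, `observed`, `fitted`, `residual`).
#' @export
regress_counts <- function(stats, count_col, covariate_col,
                           include_x = TRUE) {
  use <- if (include_x) rep(TRUE, nrow(stats)) else !stats$is_x
  d <- data.frame(y = stats[[count_col]][use], x = stats[[covariate_col]][use])
  fit <- stats::lm(y ~ x, data = d)
  r <- if (stats::sd(d$x) == 0 || stats::sd(d$y) == 0) NA_real_
       else stats::cor(d$x, d$y)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = r,
    n = nrow(d),
    residuals = data.frame(chrom = stats$chrom[use],
                           observed = d$y,
                           fitted = unname(stats::fitted(fit)),
                           residual = unname(stats::resid(fit)),
                           stringsAsFactors = FALSE)),
    class = "movement_regression")
}

#' @export
print.movement_regression <- function(x, ...) {
  cat(sprintf("<movement_regression> slope %.4g, intercept %.4g, r %.3f (n = %d)\n",
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' X-chromosome outlier test against an autosome-only fit
#'
#' Fits OLS of counts on the covariate over the autosomes only, then
#' computes the externally studentized residual of the X chromosome against
#' that fit (prediction-error variance `s^2 (1 + h0)`) and a two-sided
#' p-value from the t distribution with `n_autosomes - 3` degrees of
#' freedom. The direction reports whether X is in excess or deficit
#' relative to its autosomal expectation.
#'
#' @param stats Data frame from [chromosome_stats()] containing exactly one
#'   X chromosome row.
#' @param count_col,covariate_col Column names.
#' @return List: `t`, `p`, `direction` (`"excess"`/`"deficit"`), `observed`,
#'   `expected`, `df`.
#' @export
x_outlier_test <- function(stats, count_col, covariate_col) {
  aut <- stats[!stats$is_x, , drop = FALSE]
  xr <- stats[stats$is_x, , drop = FALSE]
  if (nrow(xr) != 1) stop("stats must contain exactly one X chromosome row")
  if (nrow(aut) < 5) stop("fewer than 5 autosomes: X-outlier test undefined")
  d <- data.frame(y = aut[[count_col]], x = aut[[covariate_col]])
  fit <- stats::lm(y ~ x, data = d)
  # degenerate (noise-free) fits are handled explicitly below
  s <- suppressWarnings(summary(fit)$sigma)
  new <- data.frame(x = xr[[covariate_col]])
  pr <- stats::predict(fit, newdata = new, se.fit = TRUE)
  resid <- xr[[count_col]] - pr$fit
  df <- nrow(aut) - 3
  if (!is.finite(s) || s == 0) {
    tval <- if (resid == 0) 0 else Inf * sign(resid)
    p <- if (resid == 0) 1 else 0
  } else {
    h0 <- (pr$se.fit / s)^2
    tval <- resid / (s * sqrt(1 + h0))
    p <- 2 * stats::pt(-abs(tval), df = df)
  }
  list(t = unname(tval), p = unname(p),
       direction = if (resid >= 0) "excess" else "deficit",
       observed = unname(xr[[count_col]]), expected = unname(pr$fit),
       df = df)
}

#' Binomial alternative to the X-outlier test
#'
#' One-sided exact binomial test of the X chromosome's share of parental
#' genes against its share of the covariate (its null placement
#' probability).
#'
#' @param stats Data frame from [chromosome_stats()].
#' @param count_col,covariate_col Column names.
#' @param alternative Passed to [stats::binom.test()].
#' @return The `htest` object.
#' @export
x_binomial_test <- function(stats, count_col, covariate_col,
                            alternative = "greater") {
  xr <- stats[stats$is_x, , drop = FALSE]
  stats::binom.test(xr[[count_col]], sum(stats[[count_col]]),
                    p = xr[[covariate_col]] / sum(stats[[covariate_col]]),
                    alternative = alternative)
}

#' Synthetic chromosome table for count-level calibration studies
#'
#' A mammal-like karyotype: `n_autosomes` autosomes with lengths declining
#' from 120 to 25 Mb and gene counts proportional to length, plus a long but
#' gene-poor X chromosome (mammalian X chromosomes carry markedly fewer
#' protein-coding genes per Mb than autosomes). Used for null-calibration
#' and power studies of the X-outlier test.
#'
#' @param n_autosomes Number of autosomes.
#' @param genes_per_mb Autosomal gene density.
#' @param x_genes_per_mb X-chromosome gene density.
#' @return Data frame with `chrom`, `is_x`, `length`, `n_genes`.
#' @export
calibration_chromosomes <- function(n_autosomes = 38L, genes_per_mb = 8,
                                    x_genes_per_mb = 4.7) {
  lengths <- round(seq(120, 25, length.out = n_autosomes)) * 1e6
  data.frame(
    chrom = c(paste0("chr", seq_len(n_autosomes)), "chrX"),
    is_x = c(rep(FALSE, n_autosomes), TRUE),
    length = c(lengths, 124e6),
    n_genes = round(c(lengths * genes_per_mb, 124e6 * x_genes_per_mb) / 1e6),
    stringsAsFactors = FALSE)
}

#' Simulate per-chromosome parent counts under proportional placement
#'
#' Places `n_pairs` parental genes on chromosomes with probability
#' proportional to the covariate, multiplying the X chromosome's weight by
#' `x_multiplier` (1 = null).
#'
#' @param n_pairs Number of pairs.
#' @param chrom_table Data frame with `is_x` and the covariate column.
#' @param covariate_col Covariate column name.
#' @param x_multiplier Enrichment factor for the X.
#' @return Integer vector of counts aligned with `chrom_table` rows.
#' @export
simulate_movement_counts <- function(n_pairs, chrom_table,
                                     covariate_col = "n_genes",
                                     x_multiplier = 1) {
  w <- chrom_table[[covariate_col]] * ifelse(chrom_table$is_x, x_multiplier, 1)
  as.integer(stats::rmultinom(1, n_pairs, w / sum(w)))
}
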