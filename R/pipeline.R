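# Orchestration: configuration, the end-to-end run, and the report module
# that recomputes catalogue/selection/expression/movement summary arithmetic
# from the pipeline's own tables (or from externally supplied counts).

#' Pipeline configuration
#'
#' Bundles every module's parameter block. Defaults reproduce the standard
#' thresholds of the retrogene-identification recipe (parent identity/overlap
#' 0.50 over >= 50 aa, structure score 35, EST mapping 0.95/0.90, support
#' 100 bp / 0.97, omega cut 0.5, lambda 1.33e-9 per year).
#'
#' @param sim A `sim_config` to simulate inputs, or NULL to read from paths.
#' @param genome_path,annotation_path,proteins_path,ests_path Input files
#'   (used when `sim` is NULL).
#' @param out_dir Output directory (NULL = no files written).
#' @param discovery,est,dating Module parameter blocks.
#' @param recent_ks_cutoff Ks below which an insertion counts as recent in
#'   the chimeric-rate calculation.
#' @param seed Seed forwarded to the simulator.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            genome_path = NULL, annotation_path = NULL,
                            proteins_path = NULL, ests_path = NULL,
                            out_dir = NULL,
                            discovery = discovery_params(),
                            est = est_params(),
                            dating = dating_params(),
                            recent_ks_cutoff = 0.06,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (!is.null(cfg$sim)) cfg$sim$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' simulate (optional) -> discover -> Ka/Ks -> EST support -> movement ->
#' report. When `config$out_dir` is set, every stage writes its table there
#' and a run manifest records the configuration; identical configurations
#' (including seed) give byte-identical outputs.
#'
#' @param config A `pipeline_config`.
#' @param verbose Print progress.
#' @return List: `sim` (or NULL), `genome`, `models`, `proteins`,
#'   `discovery`, `kaks`, `est`, `movements`, `sets`, `regressions`,
#'   `report`.
#' @export
run_all <- function(config = pipeline_config(), verbose = FALSE) {
  if (is.null(config$sim)) {
    paths <- c(genome = config$genome_path, annotation = config$annotation_path,
               proteins = config$proteins_path, ests = config$ests_path)
    missing <- paths[!vapply(paths, function(p) !is.null(p) && file.exists(p),
                             logical(1))]
    if (length(missing))
      stop("missing input file(s): ",
           paste(names(missing), unlist(missing), sep = "=", collapse = ", "))
    genome <- read_genome(config$genome_path)
    models <- read_annotation(config$annotation_path, genome)
    proteins <- read_fasta(config$proteins_path)
    ests <- read_fasta(config$ests_path)
    sim <- NULL
  } else {
    sim <- simulate_dataset(config$sim)
    genome <- sim$genome
    models <- sim$models
    proteins <- sim$proteins
    ests <- sim$ests
  }
  if (verbose) message("discovering retrocopies ...")
  disc <- discover_retrocopies(genome, models, proteins, config$discovery,
                               verbose = verbose)
  if (verbose) message("estimating Ka/Ks ...")
  kaks <- kaks_catalogue(disc, genome, models, config$dating)
  if (verbose) message("EST support ...")
  est <- est_support(ests, genome, disc$catalogue, config$est)
  movements <- movement_table(disc$catalogue, models, genome)
  sets <- select_sets(disc$catalogue, kaks, movements)
  regressions <- movement_regressions(sets, models, genome)
  report <- make_report(disc$catalogue, kaks, est, movements, regressions,
                        dating = config$dating,
                        recent_ks_cutoff = config$recent_ks_cutoff)
  out <- list(sim = sim, genome = genome, models = models,
              proteins = proteins, discovery = disc, kaks = kaks, est = est,
              movements = movements, sets = sets, regressions = regressions,
              report = report)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  out
}

#' All movement regressions (sets x sides x covariates)
#'
#' For the functional and neutral interchromosomal pair sets, regresses both
#' parental-gene and insertion counts on both chromosomal covariates (gene
#' count and length), each with and without the X point, and runs the
#' X-outlier test against the autosome-only fit.
#'
#' @param sets Result of [select_sets()].
#' @param models Gene models.
#' @param genome A `genome_assembly`.
#' @return Data frame with one row per regression: `set`, `side`,
#'   `covariate`, `r_with_x`, `r_without_x`, `slope`, `x_t`, `x_p`,
#'   `x_direction`, `n_pairs`.
#' @export
movement_regressions <- function(sets, models, genome) {
  rows <- list()
  n_autosomes <- sum(!genome$meta$is_x & !genome$meta$is_scaffold_mt)
  for (set_name in c("functional", "neutral")) {
    pairs <- sets[[set_name]]
    pairs <- pairs[pairs$category == "interchromosomal", , drop = FALSE]
    st <- chromosome_stats(pairs, models, genome)
    for (side in c("n_parents", "n_insertions")) {
      for (cov in c("n_genes", "length")) {
        rw <- regress_counts(st, side, cov, include_x = TRUE)
        ro <- regress_counts(st, side, cov, include_x = FALSE)
        xt <- if (n_autosomes >= 5) x_outlier_test(st, side, cov) else
          list(t = NA_real_, p = NA_real_, direction = NA_character_)
        rows[[length(rows) + 1L]] <- data.frame(
          set = set_name, side = side, covariate = cov,
          r_with_x = rw$r, r_without_x = ro$r, slope = rw$slope,
          x_t = xt$t, x_p = xt$p, x_direction = xt$direction,
          n_pairs = nrow(pairs), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Build the summary report from the pipeline's tables
#'
#' Every number here is recomputed from the tables passed in; the same
#' arithmetic is exposed for externally supplied counts via
#' [report_from_counts()].
#'
#' @param catalogue Catalogue data frame.
#' @param kaks Ka/Ks table.
#' @param est Result of [est_support()] (or NULL).
#' @param movements Movement table.
#' @param regressions Result of [movement_regressions()] (or NULL).
#' @param dating See [dating_params()].
#' @param recent_ks_cutoff Ks bound for the chimeric-rate window.
#' @return List of summary blocks (class `retro_report`).
#' @export
make_report <- function(catalogue, kaks, est = NULL, movements = NULL,
                        regressions = NULL, dating = dating_params(),
                        recent_ks_cutoff = 0.06) {
  summ <- summarize_catalogue(catalogue)
  # omega class table by catalogue class, excluding undefined
  km <- merge(catalogue[, c("retro_id", "class", "chimeric")],
              kaks[, c("retro_id", "ks", "omega", "age_mya", "class")],
              by = "retro_id", suffixes = c("", "_omega"))
  omega_tab <- do.call(rbind, lapply(c("intact", "pseudogene"), function(cls) {
    sub <- km[km$class == cls & km$class_omega != "undefined", , drop = FALSE]
    n <- nrow(sub)
    data.frame(class = cls, n = n,
               constrained = sum(sub$class_omega == "constrained"),
               intermediate = sum(sub$class_omega == "intermediate"),
               elevated = sum(sub$class_omega == "elevated"),
               pct_constrained = if (n) 100 * mean(sub$class_omega == "constrained") else NA,
               pct_intermediate = if (n) 100 * mean(sub$class_omega == "intermediate") else NA,
               pct_elevated = if (n) 100 * mean(sub$class_omega == "elevated") else NA,
               stringsAsFactors = FALSE)
  }))
  hist <- ks_histogram(kaks$ks)
  age_window <- estimate_age(recent_ks_cutoff, dating)
  n_chim_recent <- sum(km$chimeric & !is.na(km$ks) & km$ks < recent_ks_cutoff)
  chimeric_rate <- if (age_window > 0) n_chim_recent / age_window else NA_real_
  mv <- if (!is.null(movements) && nrow(movements) > 0)
    movement_fractions(movements) else NULL
  structure(list(
    catalogue = summ,
    intact_pct = 100 * summ$intact_fraction,
    mean_per_parent = summ$mean_per_parent,
    parents_single_pct = if (summ$n_parents)
      100 * summ$parents_single / summ$n_parents else NA_real_,
    omega_classes = omega_tab,
    n_ks_zero = sum(!is.na(km$ks) & km$ks == 0),
    ks_histogram = hist,
    recent_ks_cutoff = recent_ks_cutoff,
    age_window_myr = age_window,
    n_chimeric_recent = n_chim_recent,
    chimeric_rate_per_myr = chimeric_rate,
    est_summary = if (!is.null(est)) est$summary else NULL,
    movement_fractions = mv,
    regressions = regressions),
    class = "retro_report")
}

#' @export
print.retro_report <- function(x, ...) {
  s <- x$catalogue
  cat("Retrocopy catalogue report\n")
  cat(sprintf("  %d retrocopies from %d parents (%.2f per parent)\n",
              s$total, s$n_parents, x$mean_per_parent))
  cat(sprintf("  intact: %d (%.1f%%), pseudogene: %d, chimeric: %d\n",
              s$n_intact, x$intact_pct, s$n_pseudogene, s$n_chimeric))
  cat(sprintf("  parents with one retrocopy: %.0f%%\n", x$parents_single_pct))
  cat(sprintf("  chimeric rate: %.2f per Myr over the last %.1f Myr\n",
              x$chimeric_rate_per_myr, x$age_window_myr))
  if (!is.null(x$est_summary)) {
    for (i in seq_len(nrow(x$est_summary)))
      cat(sprintf("  EST-supported %s: %d/%d (%.1f%%)\n",
                  x$est_summary$class[i], x$est_summary$n_supported[i],
                  x$est_summary$n[i], 100 * x$est_summary$fraction[i]))
  }
  if (!is.null(x$movement_fractions)) {
    mf <- x$movement_fractions
    cat(sprintf("  movements: %s\n",
                paste(sprintf("%s %.2f%%", mf$category, mf$percent),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Recompute summary ratios from externally supplied counts
#'
#' The report module's arithmetic applied to a plain list of counts, so that
#' published worked examples can be recomputed without rerunning discovery.
#'
#' @param counts Named list/vector. Recognised fields: `total`, `intact`,
#'   `n_parents`, `parents_single`, `inter`, `intra`, `scaffold_mt`,
#'   `est_supported_intact`, `est_intact_total`, `est_supported_pseudo`,
#'   `est_pseudo_total`, `chimeric_recent`, `age_window_myr`, and omega-bin
#'   counts `omega_lt05`, `omega_mid`, `omega_gt12` with `omega_total` (per
#'   class via `intact_` / `pseudo_` prefixes).
#' @return List of derived percentages/ratios (only those whose inputs are
#'   present).
#' @export
report_from_counts <- function(counts) {
  counts <- as.list(counts)
  out <- list()
  has <- function(...) all(vapply(list(...), function(k)
    !is.null(counts[[k]]), logical(1)))
  if (has("total", "intact"))
    out$intact_pct <- 100 * counts$intact / counts$total
  if (has("total", "n_parents"))
    out$mean_per_parent <- counts$total / counts$n_parents
  if (has("n_parents", "parents_single"))
    out$parents_single_pct <- 100 * counts$parents_single / counts$n_parents
  if (has("inter", "intra", "scaffold_mt")) {
    tot <- counts$inter + counts$intra + counts$scaffold_mt
    out$inter_pct <- 100 * counts$inter / tot
    out$intra_pct <- 100 * counts$intra / tot
    out$scaffold_mt_pct <- 100 * counts$scaffold_mt / tot
  }
  if (has("est_supported_intact", "est_intact_total"))
    out$est_intact_pct <- 100 * counts$est_supported_intact / counts$est_intact_total
  if (has("est_supported_pseudo", "est_pseudo_total"))
    out$est_pseudo_pct <- 100 * counts$est_supported_pseudo / counts$est_pseudo_total
  if (has("chimeric_recent", "age_window_myr"))
    out$chimeric_rate_per_myr <- counts$chimeric_recent / counts$age_window_myr
  for (cls in c("intact", "pseudo")) {
    tot_k <- paste0(cls, "_omega_total")
    if (!has(tot_k)) next
    for (bin in c("omega_lt05", "omega_mid", "omega_gt12")) {
      k <- paste0(cls, "_", bin)
      if (has(k))
        out[[paste0(cls, "_", bin, "_pct")]] <-
          100 * counts[[k]] / counts[[tot_k]]
    }
  }
  out
}

write_pipeline_outputs <- function(res, config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cat_df <- res$discovery$catalogue
  write_tsv(cat_df, file.path(out, "catalogue.tsv"))
  if (nrow(cat_df) > 0) {
    bed <- data.frame(chrom = cat_df$chrom, start = cat_df$start,
                      end = cat_df$end, name = cat_df$retro_id,
                      score = round(cat_df$score), strand = cat_df$strand)
    write_bed(bed, file.path(out, "catalogue.bed"))
  }
  write_tsv(res$kaks, file.path(out, "kaks.tsv"))
  write_tsv(res$est$support, file.path(out, "est_support.tsv"))
  write_tsv(res$movements, file.path(out, "movements.tsv"))
  write_tsv(res$regressions, file.path(out, "regressions.tsv"))
  write_tsv(res$report$ks_histogram$bins, file.path(out, "ks_histogram.tsv"))
  # manifest: the configuration that produced this run (no timestamps and no
  # output location, so identical runs stay byte-identical)
  shown <- config[setdiff(names(config), "out_dir")]
  manifest <- utils::capture.output(utils::str(shown, give.attr = FALSE))
  writeLines(manifest, file.path(out, "manifest.txt"))
  report_lines <- utils::capture.output(print(res$report))
  writeLines(report_lines, file.path(out, "report.md"))
  invisible(out)
}
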