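#' @useDynLib retrotracer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
NULL

# Internal coordinate convention: 0-based half-open everywhere. Conversion to
# and from 1-based inclusive happens only at the GTF boundary; BED is already
# 0-based half-open.

#' Read a FASTA file
#'
#' Reads a plain (uncompressed) FASTA file into a named character vector.
#' Sequences are uppercased and the record id is the first whitespace-delimited
#' token of the header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty FASTA record(s): ", paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in characters.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1L, n))), con)
  }
  invisible(path)
}

#' Construct a genome assembly object
#'
#' Wraps a set of chromosome sequences with per-chromosome metadata. The X
#' chromosome and scaffold/mitochondrial sequences are identified by name so
#' that downstream movement analysis can separate primary chromosomes from
#' scaffold/MT placements.
#'
#' @param sequences Named character vector of uppercase DNA (A/C/G/T/N).
#' @param x_chrom Name(s) treated as the X chromosome.
#' @param scaffold_pattern Regex matched against names to flag scaffolds and MT.
#' @return An object of class `genome_assembly` with elements `sequences`,
#'   `lengths`, and `meta` (data.frame with `chrom`, `is_x`, `is_scaffold_mt`).
#' @export
genome_assembly <- function(sequences, x_chrom = c("X", "chrX"),
                            scaffold_pattern = "^(scaffold|Scaffold|MT|chrM)") {
  stopifnot(!is.null(names(sequences)), !anyDuplicated(names(sequences)))
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) stop("non-ACGTN characters in: ",
                     paste(names(sequences)[bad], collapse = ", "))
  meta <- data.frame(
    chrom = names(sequences),
    is_x = names(sequences) %in% x_chrom,
    is_scaffold_mt = grepl(scaffold_pattern, names(sequences)),
    stringsAsFactors = FALSE
  )
  structure(list(sequences = sequences,
                 lengths = setNames(nchar(sequences), names(sequences)),
                 meta = meta),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("<genome_assembly> ", length(x$sequences), " sequence(s), ",
      format(sum(x$lengths), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Read a genome FASTA as a `genome_assembly`
#'
#' @inheritParams read_fasta
#' @inheritParams genome_assembly
#' @export
read_genome <- function(path, x_chrom = c("X", "chrX"),
                        scaffold_pattern = "^(scaffold|Scaffold|MT|chrM)") {
  genome_assembly(read_fasta(path), x_chrom = x_chrom,
                  scaffold_pattern = scaffold_pattern)
}

#' Construct a gene model
#'
#' A gene model is the parental side of every retrocopy pair: one transcript
#' per gene, described by its ordered CDS exons in genomic coordinates
#' (0-based half-open).
#'
#' @param gene_id,transcript_id,protein_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of CDS exon `start`,`end` (0-based half-open),
#'   sorted by genomic start, non-overlapping.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, exons,
                       protein_id = paste0(transcript_id, "_P")) {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons), ncol(exons) == 2)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1])) stop("empty exon in ", gene_id)
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in ", gene_id)
  colnames(exons) <- c("start", "end")
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 protein_id = protein_id, chrom = chrom, strand = strand,
                 exons = exons),
            class = "gene_model")
}

#' Genomic span of a gene model
#' @param model A `gene_model`.
#' @return Numeric `c(start, end)`, 0-based half-open.
#' @export
model_span <- function(model) {
  c(min(model$exons[, "start"]), max(model$exons[, "end"]))
}

#' CDS length (bp) of a gene model
#' @param model A `gene_model`.
#' @export
model_cds_length <- function(model) sum(model$exons[, "end"] - model$exons[, "start"])

#' Intron positions of a gene model in protein coordinates
#'
#' Positions (in amino acids, measured 5' to 3' along the transcript) at which
#' the coding sequence is interrupted by an intron. Used by the
#' intron-retention check.
#'
#' @param model A `gene_model`.
#' @return Numeric vector (possibly empty) of cumulative codon positions.
#' @export
model_intron_positions_aa <- function(model) {
  lens <- model$exons[, "end"] - model$exons[, "start"]
  if (model$strand == "-") lens <- rev(lens)
  if (length(lens) < 2) return(numeric(0))
  cumsum(lens)[-length(lens)] / 3
}

parse_gtf_attr <- function(attr, key) {
  m <- regmatches(attr, regexpr(paste0(key, ' "[^"]*"'), attr))
  out <- rep(NA_character_, length(attr))
  hit <- lengths(regmatches(attr, gregexpr(paste0(key, ' "'), attr))) > 0
  out[hit] <- sub('"$', "", sub(paste0('^', key, ' "'), "", m))
  out
}

#' Read CDS annotation from a GTF file
#'
#' Consumes CDS rows only (UTR/exon rows are ignored); coordinates are
#' converted from GTF's 1-based inclusive convention to the package's 0-based
#' half-open convention. When a gene has several transcripts the one with the
#' longest CDS is kept (ties broken by lexicographic transcript id). Models
#' whose CDS length is not divisible by 3, or whose translation contains an
#' internal stop codon when `genome` is supplied, are excluded with a warning.
#'
#' @param path Path to a GTF file with CDS features.
#' @param genome Optional `genome_assembly` used to validate coordinates and
#'   translations.
#' @return Named list of `gene_model` objects (by gene id).
#' @export
read_annotation <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(list())
  f <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(f) >= 9
  f <- f[ok]
  feat <- vapply(f, `[[`, "", 3L)
  f <- f[feat == "CDS"]
  if (length(f) == 0) return(list())
  df <- data.frame(
    chrom = vapply(f, `[[`, "", 1L),
    start = as.integer(vapply(f, `[[`, "", 4L)) - 1L,  # to 0-based
    end = as.integer(vapply(f, `[[`, "", 5L)),          # half-open
    strand = vapply(f, `[[`, "", 7L),
    attr = vapply(f, `[[`, "", 9L),
    stringsAsFactors = FALSE
  )
  df$gene_id <- parse_gtf_attr(df$attr, "gene_id")
  df$transcript_id <- parse_gtf_attr(df$attr, "transcript_id")
  df$protein_id <- parse_gtf_attr(df$attr, "protein_id")
  if (anyNA(df$gene_id) || anyNA(df$transcript_id))
    stop("CDS rows without gene_id/transcript_id attributes")

  models <- list()
  dropped <- character(0)
  for (tid in unique(df$transcript_id)) {
    rows <- df[df$transcript_id == tid, , drop = FALSE]
    exons <- cbind(start = rows$start, end = rows$end)
    pid <- rows$protein_id[1]
    if (is.na(pid)) pid <- paste0(tid, "_P")
    m <- tryCatch(
      gene_model(rows$gene_id[1], tid, rows$chrom[1], rows$strand[1], exons,
                 protein_id = pid),
      error = function(e) NULL)
    if (is.null(m)) { dropped <- c(dropped, tid); next }
    if (model_cds_length(m) %% 3 != 0) { dropped <- c(dropped, tid); next }
    if (!is.null(genome)) {
      if (!m$chrom %in% names(genome$sequences) ||
          model_span(m)[2] > genome$lengths[[m$chrom]]) {
        dropped <- c(dropped, tid); next
      }
      aa <- translate_cds(extract_cds(m, genome))
      if (grepl("\\*", aa)) { dropped <- c(dropped, tid); next }
    }
    models[[tid]] <- m
  }
  if (length(dropped))
    warning("excluded ", length(dropped), " invalid transcript model(s): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  # one transcript per gene: longest CDS, then lexicographic transcript id
  gids <- vapply(models, `[[`, "", "gene_id")
  keep <- character(0)
  for (g in unique(gids)) {
    tids <- names(models)[gids == g]
    lens <- vapply(models[tids], model_cds_length, numeric(1))
    tids <- tids[order(-lens, tids)]
    keep <- c(keep, tids[1])
  }
  out <- models[keep]
  names(out) <- vapply(out, `[[`, "", "gene_id")
  out[order(names(out))]
}

#' Write gene models as GTF CDS rows
#'
#' @param models List of `gene_model` objects.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @export
write_gtf <- function(models, path, source = "retrotracer") {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    ex <- m$exons
    for (i in seq_len(nrow(ex))) {
      writeLines(paste(m$chrom, source, "CDS",
                       ex[i, "start"] + 1L, ex[i, "end"], ".", m$strand, "0",
                       sprintf('gene_id "%s"; transcript_id "%s"; protein_id "%s";',
                               m$gene_id, m$transcript_id, m$protein_id),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Extract the spliced CDS of a gene model
#'
#' Exons are concatenated 5' to 3' of the transcript: on the minus strand each
#' exon is reverse-complemented and exon order is reversed.
#'
#' @param model A `gene_model`.
#' @param genome A `genome_assembly`.
#' @return DNA string of the spliced CDS.
#' @export
extract_cds <- function(model, genome) {
  seq <- genome$sequences[[model$chrom]]
  if (is.null(seq)) stop("chromosome not in genome: ", model$chrom)
  parts <- substring(seq, model$exons[, "start"] + 1L, model$exons[, "end"])
  if (model$strand == "-") parts <- rev(vapply(parts, revcomp, ""))
  paste(parts, collapse = "")
}

#' Reverse-complement a DNA string
#' @param s DNA string (A/C/G/T/N).
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# cached codon -> amino-acid lookup (standard genetic code); codons containing
# N or other ambiguity translate to X
.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- setNames(unname(gc), names(gc))
    }
    tab
  }
})

#' Translate a CDS with the standard genetic code
#'
#' A trailing stop codon is stripped. Codons containing `N` translate to `X`.
#'
#' @param cds DNA string with length divisible by 3.
#' @param strict If `TRUE`, an internal stop codon raises an error.
#' @return Protein string (stops, if any and not trailing, appear as `*`
#'   unless `strict`).
#' @export
translate_cds <- function(cds, strict = FALSE) {
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length not divisible by 3")
  if (n == 0) return("")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- .codon_table()[codons]
  aa[is.na(aa)] <- "X"
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (strict && any(aa == "*"))
    stop("internal stop codon at codon ", which(aa == "*")[1])
  paste(aa, collapse = "")
}

#' Write a catalogue-style table as BED6
#'
#' @param df Data frame with `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   columns (0-based half-open coordinates).
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df[, c("chrom", "start", "end", "name", "score", "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a TSV table with headers
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_tsv()]
#' @param path Input path.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}
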