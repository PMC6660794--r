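#' Readers and writers for the package's plain-text formats
#'
#' FASTA goes through Biostrings; methylomes, gene panels and count
#' profiles are tab-separated tables that round-trip losslessly.
#'
#' @name io
NULL

#' Write/read a genome sequence as FASTA
#'
#' @param sequence Character scalar DNA sequence.
#' @param path Output file.
#' @param name Sequence name (default "synthetic").
#' @export
write_genome_fasta <- function(sequence, path, name = "synthetic") {
  x <- Biostrings::DNAStringSet(sequence)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @return `read_genome_fasta` returns the sequence as a character scalar.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  as.character(x[[1L]])
}

#' Write a methylome as a BED-like TSV
#'
#' Columns: chrom, start (0-based position of the C), end (start + 2),
#' meth_state, coverage, meth_reads. A header line keeps the sequence
#' length so the table round-trips.
#'
#' @param m A [methylome].
#' @param path Output file.
#' @param chrom Chromosome label.
#' @export
write_methylome <- function(m, path, chrom = "chrS") {
  stopifnot(inherits(m, "methylome"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#sequence_length=", m$sequence_length), con)
  df <- data.frame(chrom = chrom, start = m$cg_positions,
                   end = m$cg_positions + 2L,
                   meth_state = as.integer(m$meth_state),
                   coverage = m$coverage, meth_reads = m$meth_reads)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_methylome
#' @return `read_methylome` returns a [methylome].
#' @export
read_methylome <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#sequence_length="))
    stop("not a methylome table: missing #sequence_length header")
  len <- as.integer(sub("#sequence_length=", "", first, fixed = TRUE))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  methylome(len, df$start, as.logical(df$meth_state),
            df$coverage, df$meth_reads)
}

#' Write/read a gene panel as TSV
#'
#' The `mcg_pos` list column is serialised as a comma-separated field.
#'
#' @param panel A `gene_panel`.
#' @param path Output file.
#' @export
write_gene_panel <- function(panel, path) {
  stopifnot(inherits(panel, "gene_panel"))
  df <- as.data.frame(panel)[setdiff(names(panel), "mcg_pos")]
  df$mcg_pos <- vapply(panel$mcg_pos, paste, character(1), collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_gene_panel
#' @return `read_gene_panel` returns a `gene_panel`.
#' @export
read_gene_panel <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  mcg <- lapply(strsplit(ifelse(is.na(df$mcg_pos), "", df$mcg_pos), ","),
                function(v) as.integer(v[nzchar(v)]))
  df$mcg_pos <- NULL
  df$mcg_pos <- mcg
  class(df) <- c("gene_panel", "data.frame")
  df
}

#' Write/read a counts profile as TSV (bedGraph-like offset table)
#'
#' Columns: offset, count, and (if the profile has been flank-normalized)
#' the normalized value.
#'
#' @param profile A `counts_profile`.
#' @param path Output file.
#' @param normalized Optional numeric vector of flank-normalized values.
#' @export
write_profile <- function(profile, path, normalized = NULL) {
  stopifnot(inherits(profile, "counts_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#mode=%s n_anchors=%d radius=%d",
                     profile$mode, profile$n_anchors, profile$radius), con)
  df <- data.frame(offset = seq(-profile$radius, profile$radius),
                   count = profile$counts)
  if (!is.null(normalized)) df$normalized <- normalized
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_profile
#' @return `read_profile` returns a `counts_profile`.
#' @export
read_profile <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("#mode=(\\w+) n_anchors=(\\d+) radius=(\\d+)", first))[[1L]]
  if (length(m) != 4L) stop("not a profile table: malformed header")
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  counts_profile(df$count, radius = as.integer(m[4L]), mode = m[2L],
                 n_anchors = as.integer(m[3L]))
}
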