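# File-format boundaries: FASTA/FASTQ via Biostrings, RepeatMasker .out and
# 12-column tabular alignment (blast outfmt 6) parsers with explicit
# coordinate-convention conversion. All internal coordinates are 0-based
# half-open; the on-disk formats are 1-based inclusive.

#' Write sequences to FASTA
#'
#' @param sequences Named character vector, or data.frame with `name` and
#'   `sequence` (or `consensus`) columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.data.frame(sequences)) {
    seqcol <- if ("sequence" %in% names(sequences)) "sequence" else "consensus"
    sequences <- setNames(sequences[[seqcol]], sequences$name)
  }
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write simulated reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality` (as
#'   produced by [simulate_reads()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Parse a RepeatMasker .out-style table into repeat hits
#'
#' Accepts the whitespace-delimited `.out` layout (two header lines plus a
#' blank line, then one hit per row). Only the columns used downstream are
#' retained. 1-based inclusive query coordinates are converted to 0-based
#' half-open; strand `C` becomes `-`.
#'
#' @param path File path.
#' @return data.frame of repeat hits: `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `family_name`, `divergence` (percent).
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*(SW|score)", lines)]
  if (!length(lines)) return(empty_repeat_hits())
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) < 11L)
  if (length(bad)) {
    warning(sprintf("skipping %d malformed line(s): %s", length(bad),
                    paste(bad, collapse = ", ")), call. = FALSE)
    fields <- fields[-bad]
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  data.frame(
    contig = get(5L),
    start = as.integer(get(6L)) - 1L,
    end = as.integer(get(7L)),
    strand = ifelse(get(9L) %in% c("C", "-"), "-", "+"),
    family_name = get(10L),
    divergence = as.numeric(get(2L)),
    stringsAsFactors = FALSE)
}

empty_repeat_hits <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), family_name = character(0),
             divergence = numeric(0), stringsAsFactors = FALSE)
}

#' Write repeat hits in RepeatMasker .out layout
#'
#' Inverse of [read_repeatmasker_out()] for the retained columns; unused
#' columns are written as placeholders.
#'
#' @param hits data.frame of repeat hits.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(hits, path) {
  hdr <- c("   SW   perc perc perc  query     position in query    matching repeat",
           "score   div. del. ins.  sequence  begin  end   (left)  repeat  class/family  begin  end (left)  ID",
           "")
  rows <- sprintf("%5d %6.1f %4.1f %4.1f  %s %7d %7d  (0) %s  %s  Unknown %6d %6d  (0) %4d",
                  1000L, hits$divergence, 0, 0, hits$contig,
                  hits$start + 1L, hits$end,
                  ifelse(hits$strand == "-", "C", "+"),
                  hits$family_name, 1L, hits$end - hits$start,
                  seq_len(nrow(hits)))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Parse 12-column tabular pairwise alignments
#'
#' Reads the standard 12-column tabular alignment format (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore).
#' Query and subject coordinates are converted from 1-based inclusive to
#' 0-based half-open; subject hits with reversed coordinates are normalised
#' to `sstart < send` with strand `-`. Malformed lines are skipped with a
#' warning naming their line numbers.
#'
#' @param path File path.
#' @param dialect Only `"blast6"` is recognised.
#' @param subject_kind Optional named character vector mapping subject names
#'   to `"te"` or `"virus"`; when given, a `subject_kind` column is filled.
#' @return data.frame of read alignments: `read_id`, `subject_kind`,
#'   `subject_name`, `qstart`, `qend`, `sstart`, `send` (all 0-based
#'   half-open), `strand`, `pident`, `aligned_length`, `evalue`, `bitscore`.
#' @export
parse_alignments <- function(path, dialect = "blast6", subject_kind = NULL) {
  if (!identical(dialect, "blast6")) {
    stop(sprintf("unknown alignment dialect '%s'", dialect), call. = FALSE)
  }
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  n_ok <- vapply(fields, length, integer(1)) == 12L
  num_ok <- vapply(fields, function(f) {
    length(f) == 12L && !anyNA(suppressWarnings(as.numeric(f[3:12])))
  }, logical(1))
  bad <- lineno[!(n_ok & num_ok)]
  if (length(bad)) {
    warning(sprintf("skipping %d malformed line(s): %s", length(bad),
                    paste(bad, collapse = ", ")), call. = FALSE)
  }
  fields <- fields[n_ok & num_ok]
  if (!length(fields)) return(empty_alignments())
  m <- do.call(rbind, fields)
  qstart <- as.integer(m[, 7L]); qend <- as.integer(m[, 8L])
  s1 <- as.integer(m[, 9L]); s2 <- as.integer(m[, 10L])
  rev <- s1 > s2
  out <- data.frame(
    read_id = m[, 1L],
    subject_kind = NA_character_,
    subject_name = m[, 2L],
    qstart = qstart - 1L,
    qend = qend,
    sstart = ifelse(rev, s2 - 1L, s1 - 1L),
    send = ifelse(rev, s1, s2),
    strand = ifelse(rev, "-", "+"),
    pident = as.numeric(m[, 3L]),
    aligned_length = as.integer(m[, 4L]),
    evalue = as.numeric(m[, 11L]),
    bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE)
  if (!is.null(subject_kind)) {
    out$subject_kind <- unname(subject_kind[out$subject_name])
  }
  out
}

empty_alignments <- function() {
  data.frame(read_id = character(0), subject_kind = character(0),
             subject_name = character(0), qstart = integer(0),
             qend = integer(0), sstart = integer(0), send = integer(0),
             strand = character(0), pident = numeric(0),
             aligned_length = integer(0), evalue = numeric(0),
             bitscore = numeric(0), stringsAsFactors = FALSE)
}

#' Write alignments back to 12-column tabular format
#'
#' Inverse of [parse_alignments()]: 0-based half-open coordinates become
#' 1-based inclusive, and `-`-strand subject intervals are written with
#' reversed coordinates. Re-parsing and re-writing a file produced by this
#' writer is byte-identical.
#'
#' @param aln Alignment data.frame ([parse_alignments()] layout).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path) {
  minus <- aln$strand == "-"
  s1 <- ifelse(minus, aln$send, aln$sstart + 1L)
  s2 <- ifelse(minus, aln$sstart + 1L, aln$send)
  rows <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2e\t%.1f",
                  aln$read_id, aln$subject_name, aln$pident,
                  aln$aligned_length, 0L, 0L,
                  aln$qstart + 1L, aln$qend, s1, s2,
                  aln$evalue, aln$bitscore)
  writeLines(rows, path)
  invisible(path)
}

#' Read gene intervals from a GFF3 file
#'
#' Thin wrapper over `rtracklayer::import` keeping rows of the requested
#' feature type and returning 0-based half-open intervals.
#'
#' @param path GFF3 file.
#' @param feature Feature type to keep (default `"gene"`).
#' @return data.frame with `contig`, `start`, `end` (0-based half-open).
#' @export
read_gene_gff <- function(path, feature = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  gr <- gr[as.character(gr$type) == feature]
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
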