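# Built-in exact-seed ungapped aligner. External local alignments (parsed
# with parse_alignments()) are the primary path for real data; this aligner
# exists so that the synthetic pipeline runs end-to-end with no external
# binary. It seeds with the terminal k-mers of each read (both orientations)
# and extends each seed hit exactly, so on error-free reads it recovers the
# maximal end-anchored local alignments that chimera detection needs.

#' Exact-seed ungapped read alignment
#'
#' For each read, the first and last `k`-mers of the read and of its
#' reverse complement are matched exactly against every subject; each seed
#' hit is extended, without gaps or mismatches, as far as the read and
#' subject agree. The result is the set of maximal exact alignments anchored
#' at either read end -- exactly the segments a chimeric (TE + virus) read is
#' made of. A default `k` of 20 mirrors the shortest exact substring match
#' accepted by sensitive short-read mappers.
#'
#' @param reads data.frame with `read_id`, `sequence`, or a named character
#'   vector.
#' @param subjects Named character vector of subject sequences.
#' @param subject_kind Named character vector over the same names, each
#'   `"te"` or `"virus"`.
#' @param k Seed length in bp (default 20).
#' @return Alignment data.frame in the [parse_alignments()] layout
#'   (`pident` is always 100).
#' @export
align_reads_exact <- function(reads, subjects, subject_kind, k = 20L) {
  if (!is.data.frame(reads)) {
    reads <- data.frame(read_id = names(reads), sequence = unname(reads),
                        stringsAsFactors = FALSE)
  }
  check_that(!is.null(names(subjects)) && all(nzchar(names(subjects))),
             "'subjects' must be named")
  check_that(all(names(subjects) %in% names(subject_kind)),
             "every subject needs a kind ('te' or 'virus')")
  nr <- nchar(reads$sequence)
  keep <- nr >= k
  reads <- reads[keep, , drop = FALSE]
  nr <- nr[keep]
  if (!nrow(reads)) return(empty_alignments())
  rc <- revcomp(reads$sequence)
  # seed slots: 1 = fwd prefix, 2 = fwd suffix, 3 = rc prefix, 4 = rc suffix
  seed_df <- data.frame(
    read = rep(seq_len(nrow(reads)), 4L),
    slot = rep(1:4, each = nrow(reads)),
    seed = c(substr(reads$sequence, 1L, k),
             substr(reads$sequence, nr - k + 1L, nr),
             substr(rc, 1L, k),
             substr(rc, nr - k + 1L, nr)),
    stringsAsFactors = FALSE)
  useeds <- unique(seed_df$seed)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(useeds))
  read_raw <- lapply(reads$sequence, charToRaw)
  rc_raw <- lapply(rc, charToRaw)
  out <- list()
  for (sn in names(subjects)) {
    subj_raw <- charToRaw(subjects[[sn]])
    hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(subjects[[sn]]))
    starts <- Biostrings::startIndex(hits)
    n_hits <- lengths(starts)
    if (!sum(n_hits)) next
    hit_df <- data.frame(
      seed = rep(useeds, n_hits),
      pos = unlist(starts[n_hits > 0]),  # 1-based seed start on subject
      stringsAsFactors = FALSE)
    j <- merge(seed_df, hit_df, by = "seed")
    if (!nrow(j)) next
    rows <- vector("list", nrow(j))
    for (i in seq_len(nrow(j))) {
      ri <- j$read[i]; slot <- j$slot[i]; p0 <- j$pos[i] - 1L
      L <- nr[ri]
      qr <- if (slot <= 2L) read_raw[[ri]] else rc_raw[[ri]]
      if (slot %in% c(1L, 3L)) {
        len <- lcp_raw(qr, subj_raw[(p0 + 1L):min(length(subj_raw), p0 + L)])
        q0 <- 0L; q1 <- len
        s0 <- p0; s1 <- p0 + len
      } else {
        send <- p0 + k
        len <- lcs_raw(qr, subj_raw[seq_len(send)])
        q0 <- L - len; q1 <- L
        s0 <- send - len; s1 <- send
      }
      if (slot >= 3L) {  # map rc coordinates back to the read
        tmp <- q0
        q0 <- L - q1
        q1 <- L - tmp
      }
      rows[[i]] <- c(ri, q0, q1, s0, s1, if (slot <= 2L) 1L else 0L)
    }
    m <- do.call(rbind, rows)
    df <- data.frame(
      read_id = reads$read_id[m[, 1L]],
      subject_kind = unname(subject_kind[sn]),
      subject_name = sn,
      qstart = m[, 2L], qend = m[, 3L],
      sstart = m[, 4L], send = m[, 5L],
      strand = ifelse(m[, 6L] == 1L, "+", "-"),
      stringsAsFactors = FALSE)
    out[[sn]] <- df
  }
  if (!length(out)) return(empty_alignments())
  aln <- do.call(rbind, out)
  aln <- aln[!duplicated(aln[, c("read_id", "subject_name", "qstart",
                                 "qend", "sstart", "send", "strand")]), ]
  aln$pident <- 100
  aln$aligned_length <- aln$qend - aln$qstart
  aln$evalue <- 0
  aln$bitscore <- 2 * aln$aligned_length
  rownames(aln) <- NULL
  aln
}
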