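# Chimeric-read detection: reads split between a TE consensus and the viral
# genome, junction-side classification, tabulation, hotspot binning, and
# junction-level RPKM.

#' Detect TE-virus chimeric reads
#'
#' A read is chimeric when it carries a TE alignment and a virus alignment,
#' each at least `min_segment` bp long, whose read intervals overlap by at
#' most `overlap_tol` bp and leave a gap of at most `max_gap` bp, so that
#' the two segments jointly cover distinct read portions. When several
#' TE/virus pairs qualify, the pair with the largest combined aligned length
#' is kept (ties broken by the lowest virus coordinate), yielding one call
#' per read.
#'
#' The virus junction coordinate is the 0-based viral position immediately
#' adjacent to the TE-facing end of the virus segment. When the two read
#' segments overlap (micro-homology shared by the TE extremity and the
#' integration site), the shared bases are attributed to the TE side -- whose
#' boundary is pinned by the consensus extremity -- and the virus coordinate
#' is shifted by the overlap accordingly. This makes the reported
#' coordinate identical for all reads spanning one junction.
#'
#' @param alignments Alignment data.frame ([parse_alignments()] or
#'   [align_reads_exact()] layout) with `subject_kind` filled.
#' @param min_segment Minimum aligned length per segment in bp (default 28,
#'   the shortest alignment a default megablast search reports on 51-bp
#'   reads).
#' @param overlap_tol Maximum overlap in bp between the TE and virus read
#'   intervals (default 10).
#' @param max_gap Maximum uncovered gap in bp between them (default 10).
#' @return data.frame of chimeric reads: `read_id`, `family_name`,
#'   `te_qstart`, `te_qend`, `virus_qstart`, `virus_qend`, `te_sstart`,
#'   `te_send`, `te_strand`, `virus_strand`, `virus_name`,
#'   `virus_junction_coord`, `orientation` (TE strand relative to the
#'   virus), `overlap`, `te_right` (TRUE when the TE segment is the
#'   read's right portion).
#' @export
detect_chimeras <- function(alignments, min_segment = 28L, overlap_tol = 10L,
                            max_gap = 10L) {
  check_that("subject_kind" %in% names(alignments) &&
               !anyNA(alignments$subject_kind),
             "'alignments' must carry subject_kind ('te'/'virus')")
  aln <- alignments[alignments$aligned_length >= min_segment, , drop = FALSE]
  te <- aln[aln$subject_kind == "te", , drop = FALSE]
  vi <- aln[aln$subject_kind == "virus", , drop = FALSE]
  both <- intersect(unique(te$read_id), unique(vi$read_id))
  if (!length(both)) return(empty_chimeras())
  te <- te[te$read_id %in% both, , drop = FALSE]
  vi <- vi[vi$read_id %in% both, , drop = FALSE]
  te_by <- split(seq_len(nrow(te)), te$read_id)
  vi_by <- split(seq_len(nrow(vi)), vi$read_id)
  out <- vector("list", length(both))
  for (ii in seq_along(both)) {
    rid <- both[ii]
    tt <- te[te_by[[rid]], , drop = FALSE]
    vv <- vi[vi_by[[rid]], , drop = FALSE]
    grid <- expand.grid(a = seq_len(nrow(tt)), b = seq_len(nrow(vv)))
    ta <- tt[grid$a, ]; vb <- vv[grid$b, ]
    ov <- pmax(0L, pmin(ta$qend, vb$qend) - pmax(ta$qstart, vb$qstart))
    gap <- pmax(0L, pmax(ta$qstart, vb$qstart) - pmin(ta$qend, vb$qend))
    contained <- (ta$qstart >= vb$qstart & ta$qend <= vb$qend) |
      (vb$qstart >= ta$qstart & vb$qend <= ta$qend)
    ok <- ov <= overlap_tol & gap <= max_gap & !contained
    if (!any(ok)) next
    score <- ta$aligned_length + vb$aligned_length
    cand <- which(ok)
    cand <- cand[order(-score[cand], vb$sstart[cand])]
    a <- ta[cand[1L], ]; b <- vb[cand[1L], ]
    h <- ov[cand[1L]]
    v_left <- b$qstart < a$qstart ||
      (b$qstart == a$qstart && b$qend < a$qend)
    coord <- if (v_left) {
      if (b$strand == "+") b$send - h else b$sstart + h
    } else {
      if (b$strand == "+") b$sstart + h else b$send - h
    }
    out[[ii]] <- data.frame(
      read_id = rid, family_name = a$subject_name,
      te_qstart = a$qstart, te_qend = a$qend,
      virus_qstart = b$qstart, virus_qend = b$qend,
      te_sstart = a$sstart, te_send = a$send,
      te_strand = a$strand, virus_strand = b$strand,
      virus_name = b$subject_name,
      virus_junction_coord = coord,
      orientation = if (a$strand == b$strand) "+" else "-",
      overlap = h, te_right = v_left,
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_chimeras())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_chimeras <- function() {
  data.frame(read_id = character(0), family_name = character(0),
             te_qstart = integer(0), te_qend = integer(0),
             virus_qstart = integer(0), virus_qend = integer(0),
             te_sstart = integer(0), te_send = integer(0),
             te_strand = character(0), virus_strand = character(0),
             virus_name = character(0), virus_junction_coord = integer(0),
             orientation = character(0), overlap = integer(0),
             te_right = logical(0), stringsAsFactors = FALSE)
}

#' Classify the TE side of each chimeric junction
#'
#' Maps the junction-adjacent end of the TE segment onto the consensus and
#' measures its distance to the nearest consensus extremity. A junction
#' within `tip_tol` bp of consensus position 0 is `five_prime`, within
#' `tip_tol` of the consensus end `three_prime`, anything else `internal`.
#' Chimeras at TE tips are the expected product of bona fide transposition;
#' internal junctions indicate fragmented or rearranged copies.
#'
#' @param chimeras data.frame from [detect_chimeras()].
#' @param te_lengths Named numeric vector of consensus lengths per family.
#' @param tip_tol Tolerance in bp for "at the extremity" (default 5,
#'   absorbing alignment-end fraying).
#' @return `chimeras` with `te_side` (`five_prime` / `three_prime` /
#'   `internal`) and `te_offset` (exact distance in bp to the nearest
#'   consensus extremity) columns added.
#' @export
classify_junction_side <- function(chimeras, te_lengths, tip_tol = 5L) {
  if (!nrow(chimeras)) {
    chimeras$te_side <- character(0)
    chimeras$te_offset <- integer(0)
    return(chimeras)
  }
  L <- unname(te_lengths[chimeras$family_name])
  check_that(!anyNA(L) && all(L > 0),
             "every chimera's family needs a positive consensus length")
  plus <- chimeras$te_strand == "+"
  # consensus position of the junction-adjacent end of the TE segment
  b <- ifelse(chimeras$te_right,
              ifelse(plus, chimeras$te_sstart, chimeras$te_send),
              ifelse(plus, chimeras$te_send, chimeras$te_sstart))
  d5 <- b
  d3 <- L - b
  side <- ifelse(pmin(d5, d3) > tip_tol, "internal",
                 ifelse(d5 <= d3, "five_prime", "three_prime"))
  chimeras$te_side <- side
  chimeras$te_offset <- as.integer(pmin(d5, d3))
  chimeras
}

#' Tabulate chimeric reads by family, time point, replicate and side
#'
#' Counts tip-mapping chimeras (5' or 3' side) per family, time point,
#' replicate and side. Families with fewer than `min_total` chimeric reads
#' over all data sets jointly are lumped into an `"Others"` row. The grand
#' total equals the number of side-classified tip chimeras.
#'
#' @param chimeras data.frame from [classify_junction_side()], carrying
#'   `time_point` and `replicate` columns (or join them via `samples`).
#' @param samples Optional data.frame `read_id`, `time_point`, `replicate`
#'   to merge sample metadata by read.
#' @param min_total Lumping threshold (default 10 reads).
#' @param tips_only Keep only 5'/3' chimeras (default TRUE, as in a
#'   transposition-evidence table).
#' @return data.frame `family_name`, `time_point`, `replicate`, `te_side`,
#'   `n`; the grand total is in attribute `"grand_total"`.
#' @export
tabulate_chimeras <- function(chimeras, samples = NULL, min_total = 10L,
                              tips_only = TRUE) {
  if (!is.null(samples)) {
    chimeras <- merge(chimeras, samples, by = "read_id", sort = FALSE)
  }
  check_that(all(c("time_point", "replicate") %in% names(chimeras)),
             "chimeras need time_point and replicate metadata")
  x <- chimeras
  if (tips_only) {
    x <- x[x$te_side %in% c("five_prime", "three_prime"), , drop = FALSE]
  }
  if (!nrow(x)) {
    out <- data.frame(family_name = character(0), time_point = numeric(0),
                      replicate = character(0), te_side = character(0),
                      n = integer(0), stringsAsFactors = FALSE)
    attr(out, "grand_total") <- 0L
    return(out)
  }
  totals <- table(x$family_name)
  lump <- names(totals)[totals < min_total]
  x$family_name[x$family_name %in% lump] <- "Others"
  out <- aggregate(list(n = rep(1L, nrow(x))),
                   by = list(family_name = x$family_name,
                             time_point = x$time_point,
                             replicate = x$replicate,
                             te_side = x$te_side),
                   FUN = sum)
  out <- out[order(out$family_name, out$time_point, out$replicate,
                   out$te_side), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grand_total") <- nrow(x)
  out
}

#' Bin insertion junctions into fixed windows along the viral genome
#'
#' Each chimera with junction coordinate c increments the half-open window
#' `[k*window, (k+1)*window)` containing c; counts are reported per time
#' point when a `time_point` column is present.
#'
#' @param chimeras data.frame with `virus_junction_coord` (and optionally
#'   `time_point`).
#' @param window Window size in bp (default 50).
#' @param genome_length Viral genome length in bp; coordinates at or past it
#'   are an error.
#' @return data.frame `window` (0-based index), `window_start`,
#'   `time_point` (NA when absent), `n`. Window counts sum to the number of
#'   binned chimeras.
#' @export
bin_hotspots <- function(chimeras, window = 50L, genome_length) {
  check_that(genome_length > 0, "'genome_length' must be positive")
  cc <- chimeras$virus_junction_coord
  check_that(all(cc >= 0 & cc < genome_length),
             "junction coordinates must lie within [0, genome_length)")
  tp <- if ("time_point" %in% names(chimeras)) chimeras$time_point else
    rep(NA_real_, length(cc))
  win <- floor(cc / window)
  out <- aggregate(list(n = rep(1L, length(cc))),
                   by = list(window = win,
                             time_point = factor(tp, exclude = NULL)),
                   FUN = sum)
  out$time_point <- suppressWarnings(as.numeric(as.character(out$time_point)))
  out$window_start <- out$window * window
  out <- out[order(out$time_point, out$window),
             c("window", "window_start", "time_point", "n")]
  rownames(out) <- NULL
  out
}

#' Reads per kilobase per million mapped reads at a junction feature
#'
#' `RPKM = count / (length/1000) / (total/10^6)`; the measure used to
#' compare the expression of a virus-borne TE copy (counting only reads on
#' its virus-TE junctions) with the expression of the viral gene that hosts
#' it.
#'
#' @param count Junction read count(s).
#' @param length_bp Junction feature length(s) in bp (> 0).
#' @param total_mapped Total mapped reads in the library (> 0).
#' @return Numeric RPKM, vectorised over its arguments.
#' @examples
#' junction_rpkm(1, 1000, 1e6)  # 1
#' @export
junction_rpkm <- function(count, length_bp, total_mapped) {
  check_that(all(length_bp > 0), "'length_bp' must be positive")
  check_that(all(total_mapped > 0), "'total_mapped' must be positive")
  count / (length_bp / 1000) / (total_mapped / 1e6)
}
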