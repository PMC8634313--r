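# Target-site-duplication validation: pair 5' and 3' chimeric junctions
# into insertion calls, extract the duplicated motif from the viral
# reference, and count distinct insertions.

#' Pair 5' and 3' chimeric junctions into insertion calls
#'
#' Within each (family, orientation[, time point]) group, junctions
#' supported by 5'-side chimeras are matched to junctions supported by
#' 3'-side chimeras whose viral coordinates differ by at most `max_delta`
#' bp (inclusive): the hallmark of a target-site duplication, whose length
#' is the coordinate difference. The same TE family and a concordant
#' orientation are required by construction of the grouping; internal-side
#' chimeras never pair. Pairing is greedy one-to-one by descending read
#' support (ties by coordinate), so each junction -- and therefore each read
#' -- supports at most one call, which prevents combinatorial inflation of
#' insertion counts.
#'
#' @param chimeras data.frame from [classify_junction_side()]; columns
#'   `family_name`, `orientation`, `te_side`, `virus_junction_coord`, and
#'   optionally `time_point`.
#' @param max_delta Maximum 5'-3' coordinate difference in bp (default 5).
#' @return data.frame of insertion calls: `family_name`, `orientation`,
#'   `time_point` (NA when absent), `viral_coord_5p`, `viral_coord_3p`,
#'   `tsd_length`, `n_reads_5p`, `n_reads_3p`.
#' @export
pair_junctions <- function(chimeras, max_delta = 5L) {
  x <- chimeras[chimeras$te_side %in% c("five_prime", "three_prime"), ,
                drop = FALSE]
  if (!nrow(x)) return(empty_insertion_calls())
  if (!"time_point" %in% names(x)) x$time_point <- NA_real_
  key <- paste(x$family_name, x$orientation, x$time_point, sep = "\r")
  out <- lapply(split(x, key), function(g) {
    tal <- function(side) {
      s <- g[g$te_side == side, , drop = FALSE]
      if (!nrow(s)) return(NULL)
      t <- table(s$virus_junction_coord)
      data.frame(coord = as.integer(names(t)), n = as.integer(t))
    }
    j5 <- tal("five_prime"); j3 <- tal("three_prime")
    if (is.null(j5) || is.null(j3)) return(NULL)
    grid <- expand.grid(a = seq_len(nrow(j5)), b = seq_len(nrow(j3)))
    grid <- grid[abs(j5$coord[grid$a] - j3$coord[grid$b]) <= max_delta, ,
                 drop = FALSE]
    if (!nrow(grid)) return(NULL)
    support <- j5$n[grid$a] + j3$n[grid$b]
    grid <- grid[order(-support, pmin(j5$coord[grid$a], j3$coord[grid$b]),
                       j5$coord[grid$a]), , drop = FALSE]
    used5 <- logical(nrow(j5)); used3 <- logical(nrow(j3))
    calls <- list()
    for (i in seq_len(nrow(grid))) {
      a <- grid$a[i]; b <- grid$b[i]
      if (used5[a] || used3[b]) next
      used5[a] <- TRUE; used3[b] <- TRUE
      calls[[length(calls) + 1L]] <- data.frame(
        family_name = g$family_name[1L],
        orientation = g$orientation[1L],
        time_point = g$time_point[1L],
        viral_coord_5p = j5$coord[a],
        viral_coord_3p = j3$coord[b],
        tsd_length = abs(j5$coord[a] - j3$coord[b]),
        n_reads_5p = j5$n[a],
        n_reads_3p = j3$n[b],
        stringsAsFactors = FALSE)
    }
    if (length(calls)) do.call(rbind, calls) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_insertion_calls())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_insertion_calls <- function() {
  data.frame(family_name = character(0), orientation = character(0),
             time_point = numeric(0), viral_coord_5p = integer(0),
             viral_coord_3p = integer(0), tsd_length = integer(0),
             n_reads_5p = integer(0), n_reads_3p = integer(0),
             stringsAsFactors = FALSE)
}

#' Extract the duplicated target-site motif of each insertion call
#'
#' The motif is the TE-free viral reference substring between the smaller
#' and larger of the two junction coordinates -- the sequence duplicated on
#' both TE flanks by canonical transposition (e.g. TTAA/ATAA for piggyBac,
#' a 3-bp motif such as TTA for Harbinger). Equal coordinates (a blunt
#' insertion) give an empty motif.
#'
#' @param calls data.frame from [pair_junctions()].
#' @param viral_reference TE-free viral genome (character scalar).
#' @return `calls` with a `tsd_motif` column added.
#' @export
extract_tsd_motif <- function(calls, viral_reference) {
  L <- nchar(viral_reference)
  lo <- pmin(calls$viral_coord_5p, calls$viral_coord_3p)
  hi <- pmax(calls$viral_coord_5p, calls$viral_coord_3p)
  check_that(all(lo >= 0) && all(hi <= L),
             "call coordinates fall outside the viral reference")
  calls$tsd_motif <- substring(viral_reference, lo + 1L, hi)
  calls$tsd_motif[lo == hi] <- ""
  calls
}

#' Count distinct TSD-validated insertions
#'
#' A distinct insertion is a unique (family, orientation, 5' coordinate,
#' 3' coordinate) combination; with `merge_tol > 0`, calls whose 5' and 3'
#' coordinates each lie within `merge_tol` bp of an already-seen insertion
#' are collapsed onto it. Counts are reported overall and per time point,
#' together with supporting-read totals and a motif frequency table.
#'
#' @param calls data.frame from [pair_junctions()] (with `tsd_motif` for
#'   the motif table, see [extract_tsd_motif()]).
#' @param merge_tol Collapsing tolerance in bp (default 0: exact coordinate
#'   pairs).
#' @return A list: `n_distinct` (overall), `per_time_point` (data.frame
#'   `time_point`, `n_distinct`, `n_reads`), `per_family` (data.frame
#'   `family_name`, `n_distinct`), `motif_table` (data.frame `tsd_motif`,
#'   `n_calls`; sums to the number of calls), `n_calls`, `n_reads`.
#' @export
count_distinct_insertions <- function(calls, merge_tol = 0L) {
  if (!nrow(calls)) {
    return(list(n_distinct = 0L,
                per_time_point = data.frame(time_point = numeric(0),
                                            n_distinct = integer(0),
                                            n_reads = integer(0)),
                per_family = data.frame(family_name = character(0),
                                        n_distinct = integer(0)),
                motif_table = data.frame(tsd_motif = character(0),
                                         n_calls = integer(0)),
                n_calls = 0L, n_reads = 0L))
  }
  calls$.ins <- insertion_ids(calls, merge_tol)
  tpf <- factor(calls$time_point, exclude = NULL)  # keep NA time points
  per_tp <- aggregate(list(n_distinct = calls$.ins),
                      by = list(time_point = tpf),
                      FUN = function(v) length(unique(v)))
  reads_tp <- aggregate(list(n_reads = calls$n_reads_5p + calls$n_reads_3p),
                        by = list(time_point = tpf), FUN = sum)
  per_tp$n_reads <- reads_tp$n_reads
  per_tp$time_point <- suppressWarnings(
    as.numeric(as.character(per_tp$time_point)))
  per_fam <- aggregate(list(n_distinct = calls$.ins),
                       by = list(family_name = calls$family_name),
                       FUN = function(v) length(unique(v)))
  motif <- if ("tsd_motif" %in% names(calls)) {
    t <- table(calls$tsd_motif)
    data.frame(tsd_motif = names(t), n_calls = as.integer(t),
               stringsAsFactors = FALSE)
  } else {
    data.frame(tsd_motif = character(0), n_calls = integer(0))
  }
  list(n_distinct = length(unique(calls$.ins)),
       per_time_point = per_tp,
       per_family = per_fam,
       motif_table = motif,
       n_calls = nrow(calls),
       n_reads = sum(calls$n_reads_5p + calls$n_reads_3p))
}

# Assign an insertion id to each call: identical (family, orientation,
# coordinate pair) share an id; with merge_tol > 0, coordinate pairs within
# the tolerance of an earlier call collapse onto it.
insertion_ids <- function(calls, merge_tol) {
  if (merge_tol == 0L) {
    return(paste(calls$family_name, calls$orientation,
                 calls$viral_coord_5p, calls$viral_coord_3p, sep = "\r"))
  }
  ids <- character(nrow(calls))
  seen <- list()
  o <- order(calls$family_name, calls$orientation, calls$viral_coord_5p,
             calls$viral_coord_3p)
  for (i in o) {
    key <- paste(calls$family_name[i], calls$orientation[i], sep = "\r")
    reps <- seen[[key]]
    hit <- NULL
    if (!is.null(reps)) {
      m <- abs(reps$c5 - calls$viral_coord_5p[i]) <= merge_tol &
        abs(reps$c3 - calls$viral_coord_3p[i]) <= merge_tol
      if (any(m)) hit <- which(m)[1L]
    }
    if (is.null(hit)) {
      reps <- rbind(reps, data.frame(c5 = calls$viral_coord_5p[i],
                                     c3 = calls$viral_coord_3p[i]))
      seen[[key]] <- reps
      hit <- nrow(reps)
    }
    ids[i] <- paste(key, hit, sep = "\r")
  }
  ids
}
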