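# TE annotation: aggregate repeat-annotation fragments into copies, apply
# the copy and library filters, and summarise the TE landscape.

#' Aggregate repeat hits into TE copies
#'
#' Repeat annotators report fragmented hits; fragments of the same family on
#' the same contig and strand whose gap is at most `max_gap` bp are merged
#' into one TE copy (nested and overlapping fragments are merged by interval
#' union, so masked bp are never double counted). The copy divergence is the
#' length-weighted mean of its fragments' divergences.
#'
#' Aggregation is idempotent: feeding the output back in (as hits) changes
#' nothing, because remaining gaps all exceed `max_gap`.
#'
#' @param hits data.frame of repeat hits: `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `family_name`, `divergence`.
#' @param max_gap Maximum gap in bp between fragments of one copy.
#' @return data.frame of TE copies: `family_name`, `contig`, `start`, `end`,
#'   `strand`, `mean_divergence`, `n_fragments`, ordered by contig and
#'   start.
#' @examples
#' hits <- data.frame(contig = "c1", start = c(0, 200), end = c(100, 300),
#'                    strand = "+", family_name = "TE1",
#'                    divergence = c(10, 20))
#' aggregate_hits(hits, max_gap = 150)   # one copy, two fragments
#' @export
aggregate_hits <- function(hits, max_gap = 150L) {
  if (nrow(hits) == 0L) return(empty_te_copies())
  check_that(all(hits$start < hits$end), "hits must satisfy start < end")
  check_that(all(hits$divergence >= 0 & hits$divergence <= 100),
             "divergence must be a percentage in [0, 100]")
  o <- order(hits$contig, hits$family_name, hits$strand, hits$start, hits$end)
  h <- hits[o, , drop = FALSE]
  key <- paste(h$contig, h$family_name, h$strand, sep = "\r")
  new_key <- key != c("", head(key, -1L))
  run_end <- stats::ave(h$end, cumsum(new_key), FUN = cummax)
  prev_end <- c(-Inf, head(run_end, -1L))
  new_copy <- new_key | (h$start - prev_end > max_gap)
  id <- cumsum(new_copy)
  w <- h$end - h$start
  agg <- data.frame(
    family_name = h$family_name[new_copy],
    contig = h$contig[new_copy],
    start = as.integer(tapply(h$start, id, min)),
    end = as.integer(tapply(h$end, id, max)),
    strand = h$strand[new_copy],
    mean_divergence = as.numeric(tapply(h$divergence * w, id, sum) /
                                   tapply(w, id, sum)),
    n_fragments = as.integer(tabulate(id)),
    stringsAsFactors = FALSE)
  agg[order(agg$contig, agg$start, agg$family_name), , drop = FALSE]
}

empty_te_copies <- function() {
  data.frame(family_name = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             mean_divergence = numeric(0), n_fragments = integer(0),
             stringsAsFactors = FALSE)
}

#' Filter TE copies on length and identity
#'
#' Keeps copies strictly longer than `min_length` bp and with strictly more
#' than `min_identity` percent identity to their consensus (identity is
#' `100 - mean_divergence`). Both inequalities are strict, so a copy of
#' exactly 80 bp, or with exactly 80% identity, is removed. Input order is
#' preserved.
#'
#' @param copies data.frame of TE copies ([aggregate_hits()] layout).
#' @param min_length,min_identity Strict thresholds (defaults 80 bp, 80%).
#' @return The retained subset of `copies`.
#' @export
filter_copies <- function(copies, min_length = 80L, min_identity = 80) {
  keep <- (copies$end - copies$start) > min_length &
    (100 - copies$mean_divergence) > min_identity
  copies[keep, , drop = FALSE]
}

#' Filter a candidate TE consensus library
#'
#' Retains candidates strictly longer than 300 bp whose best alignment
#' covers at least half of a TE protein, and discards categories that do not
#' represent robustly annotated TEs (`SINE`, `tRNA`, `rRNA`, `Unknown`).
#'
#' @param candidates data.frame with `name`, `length`,
#'   `best_protein_coverage` (fraction in `[0, 1]`), `category`.
#' @param min_length Strict length threshold (default 300 bp).
#' @param min_coverage Minimum protein coverage (inclusive, default 0.5).
#' @param drop_categories Categories to discard.
#' @return The retained subset of `candidates`.
#' @export
filter_library <- function(candidates, min_length = 300L, min_coverage = 0.5,
                           drop_categories = c("SINE", "tRNA", "rRNA",
                                               "Unknown")) {
  check_that(all(candidates$best_protein_coverage >= 0 &
                   candidates$best_protein_coverage <= 1),
             "'best_protein_coverage' must be a fraction in [0, 1]")
  keep <- candidates$length > min_length &
    candidates$best_protein_coverage >= min_coverage &
    !(candidates$category %in% drop_categories)
  candidates[keep, , drop = FALSE]
}

#' Summarise a TE landscape
#'
#' Computes per-superfamily copy counts, class fractions, the divergence
#' histogram in 1% bins, total masked bp (overlapping copies merged before
#' summing) and the masked fraction of the genome.
#'
#' @param copies data.frame of TE copies.
#' @param families TE library data.frame with `name`, `superfamily`,
#'   `te_class` (copies are joined on `family_name`).
#' @param genome_size Genome size in bp (> 0).
#' @return A list with `superfamily_counts` (data.frame `superfamily`,
#'   `te_class`, `n_copies`), `class_fractions` (named numeric),
#'   `divergence_histogram` (data.frame `bin` = lower percent bound,
#'   `n_copies` for bins `[i, i+1)`), `total_copies`, `masked_bp`,
#'   `genome_fraction`.
#' @export
landscape_summary <- function(copies, families, genome_size) {
  check_that(genome_size > 0, "'genome_size' must be positive")
  fam <- families[, c("name", "superfamily", "te_class")]
  merged <- merge(copies, fam, by.x = "family_name", by.y = "name",
                  all.x = TRUE)
  sf_levels <- unique(fam[, c("superfamily", "te_class")])
  n_by_sf <- table(factor(merged$superfamily, levels = sf_levels$superfamily))
  superfamily_counts <- data.frame(
    superfamily = sf_levels$superfamily,
    te_class = sf_levels$te_class,
    n_copies = as.integer(n_by_sf[sf_levels$superfamily]),
    stringsAsFactors = FALSE)
  cls <- table(factor(merged$te_class, levels = c("I", "II")))
  class_fractions <- if (nrow(merged)) as.numeric(cls) / nrow(merged) else
    c(0, 0)
  names(class_fractions) <- c("I", "II")
  bins <- floor(pmin(copies$mean_divergence, 100 - 1e-9))
  hist_counts <- tabulate(bins + 1L, nbins = 100L)
  divergence_histogram <- data.frame(bin = 0:99, n_copies = hist_counts)
  masked_bp <- 0L
  if (nrow(copies)) {
    per_contig <- split(copies, copies$contig)
    masked_bp <- sum(vapply(per_contig, function(cc) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(cc$start + 1L, cc$end))))
    }, numeric(1)))
  }
  list(superfamily_counts = superfamily_counts,
       class_fractions = class_fractions,
       divergence_histogram = divergence_histogram,
       total_copies = nrow(copies),
       masked_bp = masked_bp,
       genome_fraction = masked_bp / genome_size)
}

#' Distance from each TE copy to the nearest gene
#'
#' A copy overlapping any gene interval gets distance 0; otherwise the gap
#' in bp to the nearest gene boundary. Strand is ignored. Copies on contigs
#' without any gene get `NA` with a warning.
#'
#' @param copies data.frame of TE copies.
#' @param genes data.frame of gene intervals: `contig`, `start`, `end`
#'   (0-based half-open).
#' @return A list with `per_copy` (`copies` plus a `gene_distance` column)
#'   and `per_family` (data.frame `family_name`, `mean_gene_distance`).
#' @export
distance_to_nearest_gene <- function(copies, genes) {
  if (is.null(genes) || nrow(genes) == 0L) {
    warning("empty gene set: distances are undefined", call. = FALSE)
    per_copy <- copies
    per_copy$gene_distance <- NA_real_
    return(list(per_copy = per_copy,
                per_family = data.frame(family_name = unique(copies$family_name),
                                        mean_gene_distance = NA_real_)))
  }
  gr_c <- GenomicRanges::GRanges(copies$contig,
                                 IRanges::IRanges(copies$start + 1L,
                                                  copies$end))
  gr_g <- GenomicRanges::GRanges(genes$contig,
                                 IRanges::IRanges(genes$start + 1L,
                                                  genes$end))
  hits <- GenomicRanges::distanceToNearest(gr_c, gr_g, ignore.strand = TRUE)
  d <- rep(NA_real_, nrow(copies))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  if (anyNA(d)) {
    warning("some copies lie on contigs with no annotated gene (NA distance)",
            call. = FALSE)
  }
  per_copy <- copies
  per_copy$gene_distance <- d
  means <- tapply(d, copies$family_name, mean, na.rm = TRUE)
  per_family <- data.frame(family_name = names(means),
                           mean_gene_distance = as.numeric(means),
                           stringsAsFactors = FALSE)
  list(per_copy = per_copy, per_family = per_family)
}

#' Simulate a random table of repeat hits
#'
#' Random fragments over a handful of contigs and families, used to exercise
#' aggregation and filtering against brute-force oracles.
#'
#' @param n Number of hits.
#' @param n_contigs Number of contigs.
#' @param families Character vector of family names.
#' @param contig_length Contig length in bp.
#' @param seed RNG seed.
#' @return data.frame of repeat hits ([read_repeatmasker_out()] layout).
#' @export
simulate_repeat_hits <- function(n = 500L, n_contigs = 4L,
                                 families = paste0("TE_", 1:8),
                                 contig_length = 100000L, seed = 1L) {
  with_seed(seed, {
    start <- sample.int(contig_length - 600L, n, replace = TRUE) - 1L
    len <- pmax(20L, as.integer(stats::rgeom(n, 1 / 200) + 20L))
    data.frame(
      contig = sprintf("contig_%d", sample.int(n_contigs, n, replace = TRUE)),
      start = start,
      end = start + len,
      strand = sample(c("+", "-"), n, replace = TRUE),
      family_name = sample(families, n, replace = TRUE),
      divergence = round(stats::runif(n, 0, 40), 1),
      stringsAsFactors = FALSE)
  })
}
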