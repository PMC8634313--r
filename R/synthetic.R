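#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generators. The defaults emulate
#' the study conditions this package targets: a circular ~100-kb dsDNA viral
#' genome treated as linear, single-end Illumina reads of 101 bp (the cell
#' line libraries; the midgut libraries used 51 bp), deep coverage across
#' junctions, and error-free bases unless asked otherwise.
#'
#' @param seed Integer seed; every generator that receives this config is
#'   bit-reproducible under it.
#' @param viral_length Viral genome length in bp (>= 1000).
#' @param gc GC fraction of the simulated genome, in `[0, 1]`. Default 0.41,
#'   typical of an alphabaculovirus genome.
#' @param read_length Single-end read length in bp; 51 and 101 are the usual
#'   values but any length >= 30 is accepted.
#' @param depth Mean per-base coverage aimed at each template.
#' @param error_rate Per-base substitution probability, in `[0, 0.1)`.
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(seed = 1, viral_length = 5000)
#' @export
sim_config <- function(seed = 1L, viral_length = 100000L, gc = 0.41,
                       read_length = 101L, depth = 30, error_rate = 0) {
  check_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
             "'seed' must be a single finite number")
  check_that(is.numeric(viral_length) && viral_length >= 1000,
             "'viral_length' must be >= 1000 bp")
  check_that(is.numeric(gc) && gc >= 0 && gc <= 1,
             "'gc' must be a fraction in [0, 1]")
  check_that(is.numeric(read_length) && read_length >= 30,
             "'read_length' must be >= 30 bp")
  check_that(is.numeric(depth) && depth > 0, "'depth' must be positive")
  check_that(is.numeric(error_rate) && error_rate >= 0 && error_rate < 0.1,
             "'error_rate' must be in [0, 0.1)")
  structure(list(seed = as.integer(seed),
                 viral_length = as.integer(viral_length),
                 gc = gc,
                 read_length = as.integer(read_length),
                 depth = depth,
                 error_rate = error_rate),
            class = "sim_config")
}

#' Generate a random viral genome sequence
#'
#' Draws an i.i.d. nucleotide sequence of the configured length and GC
#' content. The genome is treated as linear: simulated reads never span the
#' origin, matching how insertion coordinates are plotted along the genome.
#'
#' @param config A [sim_config()].
#' @return A single character string over A/C/G/T of length
#'   `config$viral_length`. Identical seeds give identical sequences.
#' @examples
#' g <- generate_viral_genome(sim_config(seed = 7, viral_length = 2000))
#' nchar(g)
#' @export
generate_viral_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  with_seed(config$seed, {
    paste(sample(names(p), config$viral_length, replace = TRUE, prob = p),
          collapse = "")
  })
}

#' Construct a TE family record
#'
#' A TE family is one consensus sequence with class and superfamily labels;
#' each family is the unit of expression analysis.
#'
#' @param name Family name.
#' @param consensus Consensus nucleotide sequence (non-empty).
#' @param te_class `"I"` (retrotransposon) or `"II"` (DNA transposon).
#' @param superfamily Superfamily label, e.g. `"PiggyBac"`.
#' @return A one-row data.frame with columns `name`, `te_class`,
#'   `superfamily`, `length`, `consensus`.
#' @export
te_family <- function(name, consensus, te_class = c("II", "I"),
                      superfamily = "Unknown_superfamily") {
  te_class <- match.arg(te_class)
  check_that(nchar(consensus) > 0, "TE consensus must be non-empty")
  data.frame(name = name, te_class = te_class, superfamily = superfamily,
             length = nchar(consensus), consensus = consensus,
             stringsAsFactors = FALSE)
}

#' Generate a random TE consensus library
#'
#' Produces `n` random consensus sequences with labels cycling through common
#' lepidopteran superfamilies. Lengths default to a spread between 0.4 and
#' 2 kb so that every consensus is longer than a read.
#'
#' @param n Number of families.
#' @param lengths Integer vector of consensus lengths, recycled to `n`.
#' @param seed RNG seed.
#' @param gc GC fraction of the consensus sequences.
#' @return A data.frame in the layout of [te_family()], one row per family.
#' @export
generate_te_library <- function(n = 6L,
                                lengths = c(831L, 1200L, 450L, 2000L, 640L, 980L),
                                seed = 1L, gc = 0.38) {
  supers <- c("PiggyBac", "PIF-Harbinger", "TcMar", "Gypsy", "L2", "Helitron")
  classes <- c("II", "II", "II", "I", "I", "II")
  lengths <- rep_len(as.integer(lengths), n)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(n), function(i) {
      s <- paste(sample(names(p), lengths[i], replace = TRUE, prob = p),
                 collapse = "")
      k <- (i - 1L) %% length(supers) + 1L
      te_family(sprintf("TE_%s_%d", supers[k], i), s,
                te_class = classes[k], superfamily = supers[k])
    }))
  })
}

#' Describe a planted TE insertion
#'
#' @param family_name Name of the inserted TE family.
#' @param viral_coord 0-based position on the TE-free viral reference where
#'   the duplicated target-site motif starts.
#' @param tsd_motif Target-site-duplication motif (possibly empty for a
#'   blunt insertion); must match the reference at `viral_coord`.
#' @param orientation `"+"` or `"-"`: strand of the TE relative to the virus.
#' @return A one-row data.frame.
#' @export
planted_insertion <- function(family_name, viral_coord, tsd_motif = "",
                              orientation = c("+", "-")) {
  orientation <- match.arg(orientation)
  check_that(viral_coord >= 0, "'viral_coord' must be >= 0")
  data.frame(family_name = family_name, viral_coord = as.integer(viral_coord),
             tsd_motif = tsd_motif, orientation = orientation,
             stringsAsFactors = FALSE)
}

#' Insert a TE into a viral reference with target-site duplication
#'
#' Models canonical transposition: the `tsd_motif` found at `viral_coord` on
#' the TE-free reference is duplicated so that it flanks the inserted TE on
#' both sides. With a k-bp motif, the two junctions map back to the TE-free
#' reference at `viral_coord + k` (left junction) and `viral_coord` (right
#' junction), i.e. exactly k bp apart -- the signature used downstream to
#' validate insertions (e.g. a 3-bp separation with a TTA motif for a
#' Harbinger element, 4 bp with TTAA/ATAA for piggyBac).
#'
#' @param reference TE-free viral sequence (character scalar).
#' @param te A [te_family()] row (data.frame or list with `consensus`).
#' @param ins A [planted_insertion()] row.
#' @return A list with elements `sequence` (modified genome),
#'   `left_junction` and `right_junction` (0-based coordinates on the TE-free
#'   reference), and `te_start`/`te_end` (0-based half-open TE interval on
#'   the modified genome).
#' @examples
#' ref <- strrep("ACGT", 300)
#' te <- te_family("toy", strrep("GATTACA", 60))
#' # "ACGT" occurs at 0-based position 40
#' mod <- plant_insertion(ref, te, planted_insertion("toy", 40, "ACGT"))
#' mod$left_junction - mod$right_junction  # TSD length
#' @export
plant_insertion <- function(reference, te, ins) {
  k <- nchar(ins$tsd_motif)
  L <- nchar(reference)
  check_that(ins$viral_coord + k <= L,
             "insertion coordinate + motif length exceeds the reference")
  if (k > 0L) {
    at_ref <- substr(reference, ins$viral_coord + 1L, ins$viral_coord + k)
    if (!identical(at_ref, ins$tsd_motif)) {
      stop(sprintf(
        "tsd_motif '%s' does not match the reference at %d (found '%s')",
        ins$tsd_motif, ins$viral_coord, at_ref), call. = FALSE)
    }
  }
  te_seq <- te$consensus
  if (identical(ins$orientation, "-")) te_seq <- revcomp(te_seq)
  left <- ins$viral_coord + k
  seq <- paste0(substr(reference, 1L, left), te_seq,
                substr(reference, ins$viral_coord + 1L, L))
  list(sequence = seq,
       left_junction = left,
       right_junction = ins$viral_coord,
       te_start = left,
       te_end = left + nchar(te_seq))
}

#' Choose insertion sites at genuine motif occurrences
#'
#' Scans the TE-free reference for occurrences of each requested TSD motif
#' and samples well-separated sites, cycling families, motifs and
#' orientations. Empty motifs (blunt insertions) get uniformly random
#' coordinates.
#'
#' @param reference TE-free viral sequence.
#' @param families TE library data.frame ([generate_te_library()]).
#' @param n Number of insertions.
#' @param motifs Character vector of TSD motifs to cycle through; may
#'   include `""`.
#' @param min_spacing Minimum distance in bp between chosen sites (and from
#'   the genome ends).
#' @param seed RNG seed.
#' @return A data.frame of [planted_insertion()] rows.
#' @export
plan_insertions <- function(reference, families, n = 20L,
                            motifs = c("TTAA", "ATAA", "TTA", ""),
                            min_spacing = 2000L, seed = 1L) {
  L <- nchar(reference)
  check_that(L > 2L * min_spacing + n, "reference too short for the spacing")
  with_seed(seed, {
    chosen <- integer(0)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      motif <- motifs[(i - 1L) %% length(motifs) + 1L]
      if (nzchar(motif)) {
        cand <- gregexpr(motif, reference, fixed = TRUE)[[1L]]
        cand <- as.integer(cand[cand > 0L]) - 1L
      } else {
        cand <- sample.int(L, min(200L, L)) - 1L
      }
      cand <- cand[cand > min_spacing & cand < L - min_spacing]
      if (length(chosen)) {
        ok <- vapply(cand, function(p) all(abs(p - chosen) >= min_spacing),
                     logical(1))
        cand <- cand[ok]
      }
      check_that(length(cand) > 0L,
                 sprintf("no eligible site left for motif '%s'", motif))
      pos <- if (length(cand) == 1L) cand else sample(cand, 1L)
      chosen <- c(chosen, pos)
      fam <- families$name[(i - 1L) %% nrow(families) + 1L]
      out[[i]] <- planted_insertion(fam, pos, motif,
                                    sample(c("+", "-"), 1L))
    }
    do.call(rbind, out)
  })
}

#' Simulate single-end reads from templates
#'
#' Uniform-start model: for a template of length L and read length r, the
#' number of reads is Poisson with mean `depth * (L - r + 1) / r` (so the
#' average per-base coverage is about `depth`), starts are uniform, and each
#' base is substituted independently with probability `error_rate`.
#' Templates shorter than the read length are skipped with a warning.
#'
#' @param templates data.frame with columns `name`, `sequence` and
#'   optionally `origin` (default `"unknown"`); extra columns are carried
#'   into the provenance table.
#' @param config A [sim_config()]; `seed`, `read_length`, `depth` and
#'   `error_rate` are used.
#' @return A list with `reads` (data.frame `read_id`, `sequence`,
#'   `quality`) and `provenance` (data.frame `read_id`, `template`,
#'   `origin`, `start` 0-based on the template, plus any extra template
#'   columns). Deterministic under `config$seed`.
#' @export
simulate_reads <- function(templates, config) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot(is.data.frame(templates),
            all(c("name", "sequence") %in% names(templates)))
  if (!"origin" %in% names(templates)) templates$origin <- "unknown"
  rl <- config$read_length
  extra <- setdiff(names(templates), c("name", "sequence", "origin"))
  with_seed(config$seed, {
    res <- vector("list", nrow(templates))
    for (i in seq_len(nrow(templates))) {
      L <- nchar(templates$sequence[i])
      S <- L - rl + 1L
      if (S < 1L) {
        warning(sprintf("template '%s' (%d bp) is shorter than the read length; skipped",
                        templates$name[i], L), call. = FALSE)
        next
      }
      n <- rpois(1L, config$depth * S / rl)
      if (n == 0L) next
      starts <- sample.int(S, n, replace = TRUE)
      seqs <- substring(templates$sequence[i], starts, starts + rl - 1L)
      if (config$error_rate > 0) seqs <- mutate_bases(seqs, config$error_rate)
      df <- data.frame(
        read_id = sprintf("%s:%d", templates$name[i], seq_len(n)),
        sequence = seqs,
        template = templates$name[i],
        origin = templates$origin[i],
        start = starts - 1L,
        stringsAsFactors = FALSE)
      for (cl in extra) df[[cl]] <- templates[[cl]][i]
      res[[i]] <- df
    }
    res <- res[!vapply(res, is.null, logical(1))]
    all <- if (length(res)) do.call(rbind, res) else
      data.frame(read_id = character(0), sequence = character(0),
                 template = character(0), origin = character(0),
                 start = integer(0))
    list(reads = data.frame(read_id = all$read_id, sequence = all$sequence,
                            quality = strrep("I", rl),
                            stringsAsFactors = FALSE),
         provenance = all[, setdiff(names(all), c("sequence")), drop = FALSE])
  })
}

# Apply i.i.d. substitutions at rate `er` to each sequence.
mutate_bases <- function(seqs, er) {
  bases <- c("A", "C", "G", "T")
  n_err <- rbinom(length(seqs), nchar(seqs), er)
  idx <- which(n_err > 0L)
  for (i in idx) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(length(ch), n_err[i])
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate reads across planted insertion junctions
#'
#' For each planted insertion, builds the singly-modified genome, extracts a
#' template spanning the whole TE plus `flank` bp of virus on each side, and
#' simulates reads from both strands (each at half the configured depth, so
#' total junction coverage matches `config$depth`). Every read is labelled
#' with its provenance: `junction_5p` / `junction_3p` when it covers the
#' junction at the TE's 5' / 3' consensus extremity, `te` when fully inside
#' the TE, `virus` when fully in flanking virus sequence.
#'
#' @param reference TE-free viral genome.
#' @param te_library TE library data.frame.
#' @param insertions data.frame of [planted_insertion()] rows.
#' @param config A [sim_config()].
#' @param flank Virus flank length (bp) on each side of the TE.
#' @return A list with `reads`, `provenance` (columns `read_id`, `origin`,
#'   `insertion` index, `family_name`) and `truth`: `insertions` augmented
#'   with the expected 0-based junction coordinates on the TE-free reference
#'   (`coord_5p`, `coord_3p`) and `tsd_length`.
#' @export
simulate_insertion_reads <- function(reference, te_library, insertions,
                                     config, flank = 200L) {
  stopifnot(inherits(config, "sim_config"))
  half <- config
  half$depth <- config$depth / 2
  tmpl <- vector("list", 2L * nrow(insertions))
  meta <- vector("list", 2L * nrow(insertions))
  for (i in seq_len(nrow(insertions))) {
    ins <- insertions[i, ]
    te <- te_library[te_library$name == ins$family_name, ]
    check_that(nrow(te) == 1L,
               sprintf("family '%s' not found in library", ins$family_name))
    mod <- plant_insertion(reference, te, ins)
    t0 <- max(0L, mod$te_start - flank)
    t1 <- min(nchar(mod$sequence), mod$te_end + flank)
    fwd <- substr(mod$sequence, t0 + 1L, t1)
    Lt <- nchar(fwd)
    jl <- mod$te_start - t0          # left genome junction, template coords
    jr <- mod$te_end - t0            # right genome junction, template coords
    # genome-left junction abuts the TE 5' end for "+" insertions, 3' for "-"
    lab_l <- if (ins$orientation == "+") "junction_5p" else "junction_3p"
    lab_r <- if (ins$orientation == "+") "junction_3p" else "junction_5p"
    nm_f <- sprintf("ins%02d_fwd", i)
    nm_r <- sprintf("ins%02d_rev", i)
    tmpl[[2L * i - 1L]] <- data.frame(name = nm_f, sequence = fwd,
                                      stringsAsFactors = FALSE)
    tmpl[[2L * i]] <- data.frame(name = nm_r, sequence = revcomp(fwd),
                                 stringsAsFactors = FALSE)
    meta[[2L * i - 1L]] <- data.frame(
      template = nm_f, insertion = i, family_name = ins$family_name,
      jl = jl, jr = jr, lab_l = lab_l, lab_r = lab_r,
      stringsAsFactors = FALSE)
    meta[[2L * i]] <- data.frame(
      template = nm_r, insertion = i, family_name = ins$family_name,
      jl = Lt - jr, jr = Lt - jl, lab_l = lab_r, lab_r = lab_l,
      stringsAsFactors = FALSE)
  }
  tmpl <- do.call(rbind, tmpl)
  meta <- do.call(rbind, meta)
  sim <- simulate_reads(tmpl, half)
  prov <- merge(sim$provenance, meta, by = "template", sort = FALSE)
  rl <- config$read_length
  covers <- function(start, j) start < j & start + rl > j
  origin <- ifelse(covers(prov$start, prov$jl), prov$lab_l,
            ifelse(covers(prov$start, prov$jr), prov$lab_r,
            ifelse(prov$start >= prov$jl & prov$start + rl <= prov$jr,
                   "te", "virus")))
  provenance <- data.frame(read_id = prov$read_id, origin = origin,
                           insertion = prov$insertion,
                           family_name = prov$family_name,
                           stringsAsFactors = FALSE)
  truth <- insertions
  k <- nchar(insertions$tsd_motif)
  truth$tsd_length <- k
  truth$coord_5p <- ifelse(insertions$orientation == "+",
                           insertions$viral_coord + k, insertions$viral_coord)
  truth$coord_3p <- ifelse(insertions$orientation == "+",
                           insertions$viral_coord, insertions$viral_coord + k)
  list(reads = sim$reads, provenance = provenance, truth = truth)
}

#' Simulate a matched read set with no insertions
#'
#' Control read set drawn from the unmodified viral genome and from the TE
#' consensus sequences themselves (TE transcripts with no viral context).
#' Useful to measure the false-positive rate of chimera detection.
#'
#' @inheritParams simulate_insertion_reads
#' @param n_virus_windows Number of viral windows to sample reads from.
#' @param window Viral window size in bp.
#' @return As [simulate_reads()].
#' @export
simulate_negative_reads <- function(reference, te_library, config,
                                    n_virus_windows = 10L, window = 2000L) {
  L <- nchar(reference)
  starts <- with_seed(config$seed + 1L,
                      sort(sample.int(L - window, n_virus_windows)))
  tmpl <- rbind(
    data.frame(name = sprintf("virus_w%02d", seq_along(starts)),
               sequence = substring(reference, starts, starts + window - 1L),
               origin = "virus", stringsAsFactors = FALSE),
    data.frame(name = paste0("tx_", te_library$name),
               sequence = te_library$consensus,
               origin = "te", stringsAsFactors = FALSE))
  simulate_reads(tmpl, config)
}

#' Simulate a negative-binomial count table with planted effects
#'
#' Counts for entity e in replicate j are drawn from a negative binomial
#' with mean `true_mean * size_factor_j * 2^(true_log2fc * infected_j)` and
#' variance `mu + dispersion * mu^2`. `dispersion = 0` reduces to Poisson.
#'
#' @param truth data.frame with columns `entity`, `true_log2fc`,
#'   `true_mean` (> 0), `dispersion` (>= 0); optional `kind` (default
#'   `"te_family"`) and `length` (default 1000 bp).
#' @param n_replicates Replicates per condition (>= 2).
#' @param library_sizes Positive size factors, one per replicate column
#'   (mock replicates first); default all 1.
#' @param seed RNG seed.
#' @return A [count_table()] whose `entities` carry the truth columns.
#' @export
simulate_count_table <- function(truth, n_replicates = 3L,
                                 library_sizes = NULL, seed = 1L) {
  check_that(n_replicates >= 2L, "need at least 2 replicates per condition")
  check_that(all(truth$true_mean > 0), "'true_mean' must be positive")
  check_that(all(truth$dispersion >= 0),
             "'dispersion' must be non-negative")
  m <- nrow(truth)
  ncol_tot <- 2L * n_replicates
  if (is.null(library_sizes)) library_sizes <- rep(1, ncol_tot)
  check_that(length(library_sizes) == ncol_tot && all(library_sizes > 0),
             "'library_sizes' must be positive, one per replicate column")
  infected <- rep(c(0, 1), each = n_replicates)
  mu <- outer(truth$true_mean, library_sizes) *
    2^outer(truth$true_log2fc, infected)
  counts <- with_seed(seed, {
    x <- matrix(0L, m, ncol_tot)
    for (j in seq_len(ncol_tot)) {
      pois <- truth$dispersion == 0
      if (any(pois)) x[pois, j] <- rpois(sum(pois), mu[pois, j])
      if (any(!pois)) {
        x[!pois, j] <- rnbinom(sum(!pois), mu = mu[!pois, j],
                               size = 1 / truth$dispersion[!pois])
      }
    }
    x
  })
  rownames(counts) <- truth$entity
  colnames(counts) <- paste0(rep(c("mock", "infected"), each = n_replicates),
                             "_", rep(seq_len(n_replicates), 2L))
  entities <- data.frame(
    name = truth$entity,
    kind = if ("kind" %in% names(truth)) truth$kind else "te_family",
    length = if ("length" %in% names(truth)) truth$length else 1000L,
    stringsAsFactors = FALSE)
  entities <- cbind(entities,
                    truth[, c("true_log2fc", "true_mean", "dispersion")])
  count_table(counts, entities,
              condition = rep(c("mock", "infected"), each = n_replicates),
              timepoint = rep(0, ncol_tot))
}
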