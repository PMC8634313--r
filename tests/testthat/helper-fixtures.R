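# Shared fixtures (built in code) and independent brute-force oracles.

# Small end-to-end chimera fixture: 20-kb genome, 3 families, 6 planted
# insertions, built once per test run.
small_pipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(seed = 101, viral_length = 20000, read_length = 101,
                      depth = 20)
    ref <- generate_viral_genome(cfg)
    lib <- generate_te_library(n = 3, lengths = c(831L, 1200L, 450L),
                               seed = 102)
    ins <- plan_insertions(ref, lib, n = 6, min_spacing = 1500, seed = 103)
    sim <- simulate_insertion_reads(ref, lib, ins, cfg)
    subjects <- c(setNames(lib$consensus, lib$name), virus = ref)
    kinds <- c(setNames(rep("te", nrow(lib)), lib$name), virus = "virus")
    aln <- align_reads_exact(sim$reads, subjects, kinds)
    ch <- classify_junction_side(detect_chimeras(aln),
                                 setNames(lib$length, lib$name))
    cache <<- list(cfg = cfg, ref = ref, lib = lib, ins = ins, sim = sim,
                   subjects = subjects, kinds = kinds, aln = aln,
                   chimeras = ch)
    cache
  }
})

# Brute-force fragment merging: repeatedly merge any two hits of the same
# (contig, family, strand) whose gap is <= max_gap until a fixed point.
brute_merge <- function(hits, max_gap) {
  # track the fragment lengths and divergences of each growing copy so the
  # final divergence is the length-weighted mean of ORIGINAL fragments
  frags <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, , drop = FALSE]
    list(row = h, w = h$end - h$start, d = h$divergence, n = 1L)
  })
  alive <- rep(TRUE, length(frags))
  repeat {
    merged <- FALSE
    for (i in seq_along(frags)) {
      if (!alive[i]) next
      for (j in seq_along(frags)) {
        if (i >= j || !alive[i] || !alive[j]) next
        a <- frags[[i]]; b <- frags[[j]]
        if (a$row$contig != b$row$contig ||
            a$row$family_name != b$row$family_name ||
            a$row$strand != b$row$strand) next
        gap <- max(a$row$start, b$row$start) - min(a$row$end, b$row$end)
        if (gap > max_gap) next
        a$row$start <- min(a$row$start, b$row$start)
        a$row$end <- max(a$row$end, b$row$end)
        a$w <- c(a$w, b$w); a$d <- c(a$d, b$d); a$n <- a$n + b$n
        frags[[i]] <- a
        alive[j] <- FALSE
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  out <- do.call(rbind, lapply(frags[alive], function(f) {
    r <- f$row
    r$divergence <- sum(f$d * f$w) / sum(f$w)
    r$n_fragments <- f$n
    r
  }))
  out[order(out$contig, out$start, out$family_name), , drop = FALSE]
}

# Brute-force copy filter with the strict >80 bp / >80% identity rule.
brute_filter_copies <- function(copies) {
  keep <- logical(nrow(copies))
  for (i in seq_len(nrow(copies))) {
    len <- copies$end[i] - copies$start[i]
    ident <- 100 - copies$mean_divergence[i]
    keep[i] <- len > 80 && ident > 80
  }
  copies[keep, , drop = FALSE]
}

# Textbook Benjamini-Hochberg step-up: returns the rejection set at level
# alpha, computed from first principles.
bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= alpha * seq_len(m) / m)
  if (!length(k)) return(logical(m))
  thresh <- p[o][max(k)]
  p <= thresh
}

# Exhaustive O(n*m) copy-to-gene distance.
brute_gene_distance <- function(copies, genes) {
  vapply(seq_len(nrow(copies)), function(i) {
    g <- genes[genes$contig == copies$contig[i], , drop = FALSE]
    if (!nrow(g)) return(NA_real_)
    d <- vapply(seq_len(nrow(g)), function(j) {
      if (copies$start[i] < g$end[j] && g$start[j] < copies$end[i]) return(0)
      max(g$start[j] - copies$end[i], copies$start[i] - g$end[j])
    }, numeric(1))
    min(d)
  }, numeric(1))
}
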