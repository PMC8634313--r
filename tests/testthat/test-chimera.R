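# Chimeric-read detection, junction-side classification, tabulation,
# hotspot binning and junction RPKM.

mk_aln <- function(read_id, kind, name, qstart, qend, sstart, send,
                   strand = "+") {
  data.frame(read_id = read_id, subject_kind = kind, subject_name = name,
             qstart = qstart, qend = qend, sstart = sstart, send = send,
             strand = strand, pident = 100,
             aligned_length = qend - qstart, evalue = 0,
             bitscore = 2 * (qend - qstart), stringsAsFactors = FALSE)
}

test_that("a virus+TE split read yields exactly one chimera call", {
  aln <- rbind(mk_aln("r1", "virus", "virus", 0, 40, 5000, 5040),
               mk_aln("r1", "te", "TFP3", 40, 101, 0, 61))
  ch <- detect_chimeras(aln)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$family_name, "TFP3")
  expect_equal(ch$virus_junction_coord, 5040L)
  expect_equal(ch$orientation, "+")
  expect_false(ch$te_right == FALSE)

  # virus-only alignments: no call
  expect_equal(nrow(detect_chimeras(
    mk_aln("r2", "virus", "virus", 0, 101, 0, 101))), 0L)

  # TE portion below the minimum segment length: no call
  short <- rbind(mk_aln("r3", "virus", "virus", 0, 81, 5000, 5081),
                 mk_aln("r3", "te", "TFP3", 81, 101, 0, 20))
  expect_equal(nrow(detect_chimeras(short)), 0L)

  # containment is not a split read
  nested <- rbind(mk_aln("r4", "virus", "virus", 0, 101, 5000, 5101),
                  mk_aln("r4", "te", "TFP3", 30, 70, 0, 40))
  expect_equal(nrow(detect_chimeras(nested)), 0L)
})

test_that("micro-homology overlap is attributed to the TE side of the junction", {
  # virus segment over-extends 3 bp into the TE: coordinate shifts back
  aln <- rbind(mk_aln("r1", "virus", "virus", 0, 43, 5000, 5043),
               mk_aln("r1", "te", "TFP3", 40, 101, 0, 61))
  expect_equal(detect_chimeras(aln)$virus_junction_coord, 5040L)
  # same junction read on the other strand
  aln2 <- rbind(mk_aln("r2", "virus", "virus", 58, 101, 5000, 5043, "-"),
                mk_aln("r2", "te", "TFP3", 0, 61, 0, 61, "-"))
  ch2 <- detect_chimeras(aln2)
  expect_equal(ch2$virus_junction_coord, 5040L)
  expect_equal(ch2$orientation, "+")
})

test_that("junction sides classify by exact distance to the consensus tips", {
  L <- c(TFP3 = 831)
  base <- rbind(mk_aln("a", "virus", "virus", 0, 40, 5000, 5040),
                mk_aln("a", "te", "TFP3", 40, 101, 0, 61))
  ch <- classify_junction_side(detect_chimeras(base), L)
  expect_equal(ch$te_side, "five_prime")
  expect_equal(ch$te_offset, 0L)

  tail <- rbind(mk_aln("b", "te", "TFP3", 0, 61, 770, 831),
                mk_aln("b", "virus", "virus", 61, 101, 5040, 5080))
  ch <- classify_junction_side(detect_chimeras(tail), L)
  expect_equal(ch$te_side, "three_prime")
  expect_equal(ch$te_offset, 0L)

  mid <- rbind(mk_aln("c", "virus", "virus", 0, 41, 5000, 5041),
               mk_aln("c", "te", "TFP3", 41, 101, 200, 260))
  ch <- classify_junction_side(detect_chimeras(mid), L)
  expect_equal(ch$te_side, "internal")
  expect_equal(ch$te_offset, 200L)
})

test_that("no false chimeras arise from insertion-free synthetic reads", {
  sp <- small_pipeline()
  neg <- simulate_negative_reads(sp$ref, sp$lib, sp$cfg)
  aln <- align_reads_exact(neg$reads, sp$subjects, sp$kinds)
  expect_equal(nrow(detect_chimeras(aln)), 0L)
})

test_that("every planted junction is recovered at its exact coordinate", {
  sp <- small_pipeline()
  tr <- sp$sim$truth
  ch <- sp$chimeras
  for (i in seq_len(nrow(tr))) {
    got <- ch$virus_junction_coord[ch$family_name == tr$family_name[i]]
    expect_true(tr$coord_5p[i] %in% got)
    expect_true(tr$coord_3p[i] %in% got)
  }
  # and no coordinate beyond the planted ones
  expect_true(all(ch$virus_junction_coord %in% c(tr$coord_5p, tr$coord_3p)))
  # all junction-spanning reads classify at a tip with zero offset
  expect_true(all(ch$te_side %in% c("five_prime", "three_prime")))
  expect_true(all(ch$te_offset == 0L))
})

test_that("reads entering a fragmented TE mid-consensus classify internal", {
  sp <- small_pipeline()
  full <- sp$lib[1, ]
  frag <- full
  frag$consensus <- substr(full$consensus, 301, 600)  # internal fragment
  frag$length <- 300L
  ins <- planted_insertion(full$name, 10000L, "")
  sim <- simulate_insertion_reads(sp$ref, frag, ins,
                                  sim_config(seed = 77, viral_length = 20000,
                                             depth = 20))
  aln <- align_reads_exact(sim$reads, sp$subjects, sp$kinds)
  ch <- classify_junction_side(detect_chimeras(aln),
                               setNames(sp$lib$length, sp$lib$name))
  expect_gt(nrow(ch), 0L)
  expect_true(all(ch$te_side == "internal"))
})

test_that("tabulation lumps rare families and conserves the grand total", {
  set.seed(10)
  n_big <- 25L; n_rare <- 9L
  ch <- data.frame(
    read_id = sprintf("r%03d", seq_len(n_big + n_rare)),
    family_name = c(rep("TFP3", n_big), rep("Harbinger_H", n_rare)),
    te_side = sample(c("five_prime", "three_prime"), n_big + n_rare, TRUE),
    time_point = sample(c(0, 6, 12), n_big + n_rare, TRUE),
    replicate = sample(c("rep1", "rep2"), n_big + n_rare, TRUE))
  tab <- tabulate_chimeras(ch, min_total = 10)
  expect_equal(attr(tab, "grand_total"), n_big + n_rare)
  expect_equal(sum(tab$n), n_big + n_rare)
  expect_false("Harbinger_H" %in% tab$family_name)
  expect_true("Others" %in% tab$family_name)
  expect_equal(sum(tab$n[tab$family_name == "Others"]), n_rare)

  # internal-side chimeras are excluded from the tip table
  ch$te_side[1] <- "internal"
  expect_equal(attr(tabulate_chimeras(ch, min_total = 10), "grand_total"),
               n_big + n_rare - 1L)

  empty <- tabulate_chimeras(ch[0, ], min_total = 10)
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "grand_total"), 0L)
})

test_that("hotspot binning uses half-open 50-bp windows and matches a direct tally", {
  ch <- data.frame(virus_junction_coord = c(0L, 49L, 50L, 125L))
  h <- bin_hotspots(ch, window = 50, genome_length = 1000)
  expect_equal(h$window[h$n == 2], 0L)          # 0 and 49 share window 0
  expect_true(1L %in% h$window)                 # 50 goes to window 1
  expect_equal(sum(h$n), 4L)

  set.seed(8)
  cc <- data.frame(virus_junction_coord = sample.int(100000, 1000) - 1L)
  h <- bin_hotspots(cc, window = 50, genome_length = 100000)
  want <- table(floor(cc$virus_junction_coord / 50))
  expect_equal(sum(h$n), 1000L)
  got <- setNames(h$n, h$window)
  expect_equal(got[names(want)], setNames(as.integer(want), names(want)))

  expect_error(bin_hotspots(data.frame(virus_junction_coord = 1000L),
                            genome_length = 1000), "within")
})

test_that("junction RPKM follows its defining formula and is linear in counts", {
  expect_equal(junction_rpkm(1, 1000, 1e6), 1)
  expect_equal(junction_rpkm(20, 1000, 1e6), 2 * junction_rpkm(10, 1000, 1e6))
  expect_equal(junction_rpkm(10, 500, 2e6), 10 / 0.5 / 2)
  expect_error(junction_rpkm(1, 0, 1e6), "length_bp")
  expect_error(junction_rpkm(1, 100, 0), "total_mapped")

  # a co-expression series built proportional to a driver gene correlates ~1
  driver <- c(5, 40, 900, 700, 800, 850, 950)
  junction_counts <- round(driver * 0.12)
  r <- cor(junction_rpkm(junction_counts, 202, 2e6),
           junction_rpkm(driver, 1500, 2e6))
  expect_gte(r, 0.99)
})
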