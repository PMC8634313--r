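# Family counting, TPM, expression categories, differential expression
# (built-in NB Wald engine and external-results path), correlations.

test_that("family counting keeps a single alignment per read with a deterministic tie-break", {
  map <- c(copyA1 = "famA", copyA2 = "famA", copyB1 = "famB")
  aln <- data.frame(read_id = sprintf("r%02d", 1:10), copy_name = "copyA1")
  got <- count_reads_per_family(aln, map)
  expect_equal(got$count[got$family_name == "famA"], 10L)
  expect_equal(got$count[got$family_name == "famB"], 0L)

  # a read hitting two families counts once, to the first sorted family
  tie <- data.frame(read_id = c("r1", "r1"), copy_name = c("copyB1", "copyA2"))
  got <- count_reads_per_family(tie, map)
  expect_equal(got$count, c(famA = 1L, famB = 0L), ignore_attr = TRUE)

  expect_warning(count_reads_per_family(
    data.frame(read_id = "r1", copy_name = "mystery"), map), "unknown")
})

test_that("family counts equal generator provenance tallies on error-free reads", {
  sp <- small_pipeline()
  prov <- sp$sim$provenance
  te_reads <- prov[prov$origin == "te", ]
  # the retained alignment of a pure TE read is its source family's copy
  aln <- data.frame(read_id = te_reads$read_id,
                    copy_name = paste0(te_reads$family_name, "_copy1"))
  map <- setNames(sp$lib$name, paste0(sp$lib$name, "_copy1"))
  got <- count_reads_per_family(aln, map)
  want <- table(factor(te_reads$family_name, levels = got$family_name))
  expect_equal(got$count, as.integer(want))
})

test_that("TPM columns sum to one million and degenerate cases behave", {
  # one entity: all mass
  expect_equal(as.numeric(compute_tpm(matrix(7, 1, 1), lengths = 500)), 1e6)
  # two entities, equal counts and lengths: half each
  expect_equal(as.numeric(compute_tpm(matrix(c(3, 3), 2, 1), lengths = c(100, 100))),
               c(5e5, 5e5))
  # conservation on random tables
  set.seed(42)
  for (i in 1:50) {
    counts <- matrix(rpois(60, 50), 20, 3)
    lens <- sample(100:5000, 20)
    tpm <- compute_tpm(counts, lengths = lens)
    expect_equal(colSums(tpm), rep(1e6, 3), tolerance = 1e-9)
  }
  expect_warning(z <- compute_tpm(matrix(0, 2, 1), lengths = c(1, 1)),
                 "zero total")
  expect_true(all(is.nan(z)))
})

test_that("expression categories reproduce the 4 / 50 TPM boundaries", {
  expect_equal(classify_expression(c(0.37, 3.999, 4, 49.9, 50, 65.6)),
               c("not_expressed", "not_expressed", "expressed", "expressed",
                 "highly_expressed", "highly_expressed"))
  expect_error(classify_expression(-1), "non-negative")
})

test_that("median-of-ratios size factors recover known library scalings", {
  set.seed(9)
  base <- rpois(500, 200) + 1
  counts <- cbind(r1 = base, r2 = round(base * 2), r3 = round(base * 0.5))
  sf <- estimate_size_factors(counts)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 0.02)
  expect_equal(unname(sf[3] / sf[1]), 0.5, tolerance = 0.02)
})

test_that("the DE threshold rule is exact: padj < 0.05 and |log2FC| >= 2", {
  ext <- data.frame(entity = c("a", "b", "c", "d", "e"),
                    log2fc = c(1.9, 2.0, -2.0, 5, -5),
                    padj = c(0.01, 0.049, 0.049, 0.5, NA))
  got <- call_de(NULL, engine = "external", external_results = ext)
  expect_equal(got$de_flag, c("ns", "up", "down", "ns", "ns"))
})

test_that("adjusted p-values agree with a first-principles Benjamini-Hochberg oracle", {
  truth <- data.frame(entity = sprintf("e%04d", 1:1000),
                      true_log2fc = c(rep(4, 30), rep(0, 970)),
                      true_mean = exp(runif(1000, log(10), log(400))),
                      dispersion = 0.05)
  ct <- simulate_count_table(truth, n_replicates = 3, seed = 33)
  de <- call_de(ct, design = "matched")
  for (alpha in c(0.01, 0.05, 0.2)) {
    expect_equal(de$padj < alpha, bh_reject(de$pvalue, alpha))
  }
})

test_that("under a global null the false-call proportion stays within the FDR band", {
  set.seed(11)
  truth <- data.frame(entity = sprintf("e%04d", 1:2000), true_log2fc = 0,
                      true_mean = exp(runif(2000, log(5), log(500))),
                      dispersion = 0.05)
  ct <- simulate_count_table(truth, n_replicates = 3, seed = 44)
  de <- call_de(ct, design = "matched")
  band <- 0.05 + 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lte(mean(de$padj < 0.05), band)
  expect_lte(mean(de$de_flag != "ns"), band)
})

test_that("strong planted effects are detected and estimates track the truth", {
  hits <- 0L
  for (s in 1:40) {
    set.seed(s)
    truth <- data.frame(entity = sprintf("g%03d", 1:100),
                        true_log2fc = c(4, rep(0, 99)),
                        true_mean = c(200, exp(runif(99, log(5), log(500)))),
                        dispersion = 0.05)
    ct <- simulate_count_table(truth, n_replicates = 3, seed = 500 + s)
    de <- call_de(ct, design = "matched")
    hits <- hits + (de$de_flag[de$entity == "g001"] == "up")
  }
  expect_gte(hits / 40, 0.9)

  # rank agreement between planted and estimated fold changes
  truth <- data.frame(entity = sprintf("m%03d", 1:200),
                      true_log2fc = seq(-4, 4, length.out = 200),
                      true_mean = 150, dispersion = 0.08)
  ct <- simulate_count_table(truth, n_replicates = 3, seed = 7)
  de <- call_de(ct, design = "matched")
  expect_gte(cor(de$log2fc, truth$true_log2fc, method = "spearman"), 0.9)
  # monotonicity of calls: strongly positive truths are never called down
  expect_false(any(de$de_flag[truth$true_log2fc >= 2] == "down"))
  expect_false(any(de$de_flag[truth$true_log2fc <= -2] == "up"))
})

test_that("fold-change estimates agree with an independent DESeq2 run", {
  skip_if_not_installed("DESeq2")
  truth <- data.frame(entity = sprintf("x%03d", 1:300),
                      true_log2fc = rep(c(-3, 0, 0, 0, 3), 60),
                      true_mean = exp(runif(300, log(20), log(500))),
                      dispersion = 0.05)
  ct <- simulate_count_table(truth, n_replicates = 3, seed = 99)
  de <- call_de(ct, design = "matched")
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      ct$counts, data.frame(condition = factor(ct$condition,
                                               c("mock", "infected"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, contrast = c("condition", "infected", "mock"))
  })
  expect_gte(cor(de$log2fc, res$log2FoldChange, use = "complete.obs"), 0.95)
  both_up <- de$de_flag == "up" & !is.na(res$padj)
  # families we call up are overwhelmingly significant+up for DESeq2 too
  agree <- mean(res$padj[both_up] < 0.05 & res$log2FoldChange[both_up] > 0)
  expect_gte(agree, 0.9)
})

test_that("matched and baseline designs pick the intended mock replicates", {
  set.seed(21)
  counts <- matrix(rpois(10 * 12, 100), 10, 12)
  entities <- data.frame(name = sprintf("t%02d", 1:10), kind = "te_family",
                         length = 1000L)
  cond <- rep(c("mock", "infected"), each = 6)
  tp <- rep(c(0, 0, 6, 6, 12, 12), 2)
  ct <- count_table(counts, entities, cond, tp)
  de_m <- call_de(ct, design = "matched")
  expect_setequal(unique(de_m$timepoint), c(0, 6, 12))
  de_b <- call_de(ct, design = "baseline")
  expect_setequal(unique(de_b$timepoint), c(0, 6, 12))

  # a missing mock time point is skipped with a warning under matched design
  tp2 <- tp; tp2[5:6] <- 6  # no mock at 12 hpi
  ct2 <- count_table(counts, entities, cond, tp2)
  expect_warning(de2 <- call_de(ct2, design = "matched"), "skipped")
  expect_false(12 %in% de2$timepoint)
})

test_that("genes are used for normalisation but dropped from DE reporting", {
  set.seed(3)
  counts <- matrix(rpois(40 * 6, 80), 40, 6)
  entities <- data.frame(name = sprintf("e%02d", 1:40),
                         kind = rep(c("gene", "te_family"), each = 20),
                         length = 1000L)
  ct <- count_table(counts, entities, rep(c("mock", "infected"), each = 3))
  de <- call_de(ct, design = "matched")
  expect_equal(sort(de$entity), sort(entities$name[entities$kind == "te_family"]))
})

test_that("induced and repressed flags follow the 4-TPM crossing rule", {
  de <- data.frame(entity = c("A", "B", "C"), timepoint = 48,
                   de_flag = c("up", "down", "up"))
  mock <- matrix(c(1, 11, 10), 3, 1, dimnames = list(c("A", "B", "C"), "t48"))
  inf <- matrix(c(63, 2, 80), 3, 1, dimnames = list(c("A", "B", "C"), "t48"))
  got <- classify_induced_repressed(de, mock, inf)
  expect_equal(got$induced, c(TRUE, FALSE, FALSE))   # C was already expressed
  expect_equal(got$repressed, c(FALSE, TRUE, FALSE))
})

test_that("factor correlations are exact in degenerate cases and null-calibrated", {
  fam <- sprintf("f%03d", 1:50)
  x <- seq_len(50)
  expr <- data.frame(family_name = fam, tpm = 2 * x)
  fac <- data.frame(family_name = fam, copy_number = x,
                    mean_divergence = -3 * x + 200)
  got <- correlate_factors(expr, fac)
  expect_equal(got$r[got$factor == "copy_number"], 1)
  expect_equal(got$r[got$factor == "mean_divergence"], -1)

  set.seed(15)
  fam <- sprintf("g%04d", 1:1000)
  got <- correlate_factors(
    data.frame(family_name = fam, tpm = rnorm(1000)),
    data.frame(family_name = fam, copy_number = rnorm(1000)))
  expect_lt(abs(got$r), 0.1)

  expect_warning(correlate_factors(
    data.frame(family_name = fam[1:5], tpm = rnorm(5)),
    data.frame(family_name = fam[1:5], copy_number = rep(3, 5))),
    "undefined")
})
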