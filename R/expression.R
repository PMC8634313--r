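# Family-level expression: counting, TPM over genes + TE families jointly,
# expression categories, differential expression, factor correlations.

#' Build a joint gene/TE count table
#'
#' Container for the concatenated gene and TE-family counts that the TPM and
#' differential-expression steps operate on. Genes are carried along purely
#' so that normalisation sees the whole library; they are dropped again
#' before differential-expression reporting.
#'
#' @param counts Non-negative integer matrix, entities x replicates.
#' @param entities data.frame with `name`, `kind` (`"gene"` or
#'   `"te_family"`), `length` (bp, > 0); one row per matrix row.
#' @param condition Character/factor per replicate, `"mock"` or
#'   `"infected"`.
#' @param timepoint Numeric hours-post-infection label per replicate.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, entities, condition,
                        timepoint = rep(0, ncol(counts))) {
  counts <- as.matrix(counts)
  check_that(nrow(counts) == nrow(entities),
             "one entity row per count row is required")
  check_that(all(counts >= 0), "counts must be non-negative")
  check_that(all(entities$length > 0), "entity lengths must be positive")
  check_that(length(condition) == ncol(counts) &&
               all(condition %in% c("mock", "infected")),
             "'condition' must be mock/infected, one per replicate")
  check_that(length(timepoint) == ncol(counts),
             "'timepoint' must have one value per replicate")
  check_that(all(entities$kind %in% c("gene", "te_family")),
             "entity kind must be 'gene' or 'te_family'")
  structure(list(counts = counts, entities = entities,
                 condition = as.character(condition),
                 timepoint = as.numeric(timepoint)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d entities (%d genes, %d TE families) x %d replicates\n",
              nrow(x$counts), sum(x$entities$kind == "gene"),
              sum(x$entities$kind == "te_family"), ncol(x$counts)))
  cat(sprintf("conditions: %s; time points: %s hpi\n",
              paste(unique(x$condition), collapse = "/"),
              paste(sort(unique(x$timepoint)), collapse = ", ")))
  invisible(x)
}

#' Count reads per TE family
#'
#' Each read contributes exactly one alignment (reads mapping to multiple
#' positions keep a single one); copies are mapped to their family and reads
#' tallied per family. If a read nevertheless arrives with alignments to
#' copies of several families, it is counted once, for the alphabetically
#' first family (a deterministic tie-break).
#'
#' @param alignments data.frame with `read_id` and `copy_name`.
#' @param copy_to_family Named character vector mapping copy names to family
#'   names.
#' @param families Optional character vector of families to report (zeros
#'   included); defaults to all families in the map.
#' @return data.frame `family_name`, `count`.
#' @export
count_reads_per_family <- function(alignments, copy_to_family,
                                   families = NULL) {
  if (is.null(families)) families <- sort(unique(unname(copy_to_family)))
  fam <- unname(copy_to_family[alignments$copy_name])
  unknown <- is.na(fam)
  if (any(unknown)) {
    warning(sprintf("%d alignment(s) to unknown copies skipped",
                    sum(unknown)), call. = FALSE)
  }
  df <- data.frame(read_id = alignments$read_id[!unknown],
                   family = fam[!unknown], stringsAsFactors = FALSE)
  df <- df[order(df$read_id, df$family), , drop = FALSE]
  df <- df[!duplicated(df$read_id), , drop = FALSE]
  tab <- table(factor(df$family, levels = families))
  data.frame(family_name = families, count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Transcripts-per-million normalisation
#'
#' Per replicate, counts are first divided by entity length in kilobases
#' (reads per kilobase, RPK); the RPK of all genes and TE families are then
#' summed and divided by one million, and every RPK is divided by this
#' per-replicate factor. Each replicate column therefore sums to exactly
#' 10^6 (up to floating-point error). An all-zero replicate has no defined
#' TPM and is returned as `NaN` with a warning.
#'
#' @param x A [count_table()], or a counts matrix.
#' @param lengths Entity lengths in bp (required when `x` is a matrix).
#' @return Numeric matrix of TPM, same dimensions as the counts.
#' @export
compute_tpm <- function(x, lengths = NULL) {
  if (inherits(x, "count_table")) {
    counts <- x$counts
    lengths <- x$entities$length
  } else {
    counts <- as.matrix(x)
    check_that(!is.null(lengths), "'lengths' is required for a plain matrix")
  }
  check_that(all(lengths > 0), "entity lengths must be positive")
  rpk <- counts / (lengths / 1000)
  per_million <- colSums(rpk) / 1e6
  if (any(per_million == 0)) {
    warning("replicate(s) with zero total counts: TPM undefined (NaN)",
            call. = FALSE)
  }
  sweep(rpk, 2L, per_million, "/")
}

#' Categorise expression level
#'
#' `< 4` TPM is treated as not expressed (a standard cutoff for
#' non-expressed genes), `>= 50` TPM as highly expressed (about 100 RPKM in
#' short-read libraries), anything between as expressed.
#'
#' @param mean_tpm Non-negative numeric vector of (condition-mean) TPM.
#' @param low,high Category boundaries (default 4 and 50 TPM).
#' @return Character vector over `not_expressed` / `expressed` /
#'   `highly_expressed`.
#' @examples
#' classify_expression(c(0.37, 4, 65.6))
#' @export
classify_expression <- function(mean_tpm, low = 4, high = 50) {
  check_that(!anyNA(mean_tpm) && all(mean_tpm >= 0),
             "'mean_tpm' must be non-negative and non-missing")
  ifelse(mean_tpm < low, "not_expressed",
         ifelse(mean_tpm >= high, "highly_expressed", "expressed"))
}

#' Median-of-ratios size factors
#'
#' The classical median-of-ratios estimator: per replicate, the median of
#' count / (row geometric mean) over entities whose geometric mean is
#' finite and whose count is positive.
#'
#' @param counts Counts matrix (entities x replicates).
#' @return Numeric vector of size factors, one per replicate.
#' @export
estimate_size_factors <- function(counts) {
  logg <- rowMeans(log(counts))
  apply(counts, 2L, function(cnt) {
    r <- (log(cnt) - logg)[is.finite(logg) & cnt > 0]
    check_that(length(r) > 0,
               "cannot estimate size factors: no entity with all-positive counts")
    exp(median(r))
  })
}

# NB Wald test for one two-group contrast on normalised counts.
# Dispersion per entity by method of moments, pooled across the two groups;
# the log fold change uses a 0.5 pseudocount on normalised means so that
# zero counts give finite estimates.
nb_wald <- function(norm_mock, norm_inf, pseudo = 0.5) {
  n1 <- ncol(norm_mock); n2 <- ncol(norm_inf)
  m1 <- rowMeans(norm_mock); m2 <- rowMeans(norm_inf)
  v1 <- apply(norm_mock, 1L, var); v2 <- apply(norm_inf, 1L, var)
  a1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, NA_real_)
  a2 <- ifelse(m2 > 0, (v2 - m2) / m2^2, NA_real_)
  disp <- pmax(rowMeans(cbind(a1, a2), na.rm = TRUE), 0)
  disp[is.nan(disp)] <- 0
  lnfc <- log((m2 + pseudo) / (m1 + pseudo))
  se2 <- (1 / (m1 + pseudo) + disp) / n1 + (1 / (m2 + pseudo) + disp) / n2
  z <- lnfc / sqrt(se2)
  p <- 2 * pnorm(-abs(z))
  p[m1 == 0 & m2 == 0] <- 1
  data.frame(base_mean_mock = m1, base_mean_infected = m2,
             dispersion = disp,
             log2fc = lnfc / log(2), pvalue = p)
}

#' Call differential expression of TE families
#'
#' Size factors are estimated by median-of-ratios over genes and TE families
#' jointly; each contrast is tested with a negative-binomial Wald test
#' (method-of-moments dispersion, 0.5 pseudocount on normalised means), or
#' taken from an externally computed results table. Genes are then dropped,
#' p-values adjusted by Benjamini-Hochberg, and a family is flagged `up`
#' when `padj < alpha` and `log2fc >= lfc_min`, `down` when `padj < alpha`
#' and `log2fc <= -lfc_min`, `ns` otherwise.
#'
#' Two contrast designs are supported. `"matched"` compares infected to mock
#' replicates at the same time point (as in a midgut time course with
#' matched mocks); a time point with no mock replicates is skipped with a
#' warning. `"baseline"` compares every infected time point to the mock at
#' the earliest time point (as in a cell-line time course where later mocks
#' drift for reasons unrelated to infection).
#'
#' @param table A [count_table()].
#' @param design `"matched"` or `"baseline"`.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param lfc_min Minimum absolute log2 fold change (default 2).
#' @param engine `"nb_wald"` (built-in) or `"external"`.
#' @param external_results For `engine = "external"`: data.frame with
#'   `entity`, `timepoint`, `log2fc`, `padj` as computed by an external DE
#'   tool; only the thresholding/classification layer is applied.
#' @param drop_genes Drop `kind == "gene"` entities before adjusting
#'   p-values and reporting (default TRUE; genes are only used for
#'   normalisation).
#' @return data.frame with one row per TE family and contrast: `entity`,
#'   `timepoint`, `base_mean_mock`, `base_mean_infected`, `log2fc`,
#'   `pvalue`, `padj`, `de_flag`.
#' @export
call_de <- function(table, design = c("matched", "baseline"), alpha = 0.05,
                    lfc_min = 2, engine = c("nb_wald", "external"),
                    external_results = NULL, drop_genes = TRUE) {
  design <- match.arg(design)
  engine <- match.arg(engine)
  if (engine == "external") {
    check_that(is.data.frame(external_results) &&
                 all(c("entity", "log2fc", "padj") %in%
                       names(external_results)),
               "'external_results' needs entity, log2fc, padj columns")
    res <- external_results
    if (!"timepoint" %in% names(res)) res$timepoint <- 0
    res$de_flag <- de_flag(res$log2fc, res$padj, alpha, lfc_min)
    return(res)
  }
  stopifnot(inherits(table, "count_table"))
  sf <- estimate_size_factors(table$counts)
  norm <- sweep(table$counts, 2L, sf, "/")
  cond <- table$condition
  tp <- table$timepoint
  inf_tps <- sort(unique(tp[cond == "infected"]))
  mock_tps <- sort(unique(tp[cond == "mock"]))
  contrasts <- lapply(inf_tps, function(t1) {
    mock_cols <- if (design == "matched") {
      which(cond == "mock" & tp == t1)
    } else {
      which(cond == "mock" & tp == min(mock_tps))
    }
    inf_cols <- which(cond == "infected" & tp == t1)
    if (length(mock_cols) == 0L) {
      warning(sprintf("no mock replicates for %g hpi; contrast skipped", t1),
              call. = FALSE)
      return(NULL)
    }
    check_that(length(mock_cols) >= 2L && length(inf_cols) >= 2L,
               sprintf("contrast at %g hpi has fewer than 2 replicates per condition", t1))
    res <- nb_wald(norm[, mock_cols, drop = FALSE],
                   norm[, inf_cols, drop = FALSE])
    res <- cbind(entity = table$entities$name, timepoint = t1, res,
                 kind = table$entities$kind, stringsAsFactors = FALSE)
    if (drop_genes) res <- res[res$kind != "gene", , drop = FALSE]
    res$padj <- p.adjust(res$pvalue, method = "BH")
    res$de_flag <- de_flag(res$log2fc, res$padj, alpha, lfc_min)
    res$kind <- NULL
    res
  })
  contrasts <- contrasts[!vapply(contrasts, is.null, logical(1))]
  check_that(length(contrasts) > 0, "no testable contrast in the design")
  out <- do.call(rbind, contrasts)
  rownames(out) <- NULL
  out
}

de_flag <- function(log2fc, padj, alpha, lfc_min) {
  ifelse(!is.na(padj) & padj < alpha & log2fc >= lfc_min, "up",
         ifelse(!is.na(padj) & padj < alpha & log2fc <= -lfc_min, "down",
                "ns"))
}

#' Flag induced and repressed TE families
#'
#' A family is induced when it is essentially silent in the mock (TPM below
#' the expression cutoff -- in all mock time points for a matched design, in
#' the baseline mock otherwise), expressed (TPM at or above the cutoff) in
#' at least one infected time point, and called `up`. It is repressed when
#' mock TPM is at or above the cutoff, infected TPM falls below it in at
#' least one time point, and it is called `down`.
#'
#' @param de data.frame from [call_de()].
#' @param mock_tpm Numeric matrix of condition-mean mock TPM, families x
#'   time points (a single column for a baseline design).
#' @param infected_tpm Numeric matrix of condition-mean infected TPM,
#'   families x time points.
#' @param cutoff Expression cutoff in TPM (default 4).
#' @return data.frame `entity`, `induced`, `repressed`.
#' @export
classify_induced_repressed <- function(de, mock_tpm, infected_tpm,
                                       cutoff = 4) {
  mock_tpm <- as.matrix(mock_tpm)
  infected_tpm <- as.matrix(infected_tpm)
  fams <- rownames(mock_tpm)
  check_that(!is.null(fams) && identical(fams, rownames(infected_tpm)),
             "TPM matrices must share family row names")
  up_any <- tapply(de$de_flag == "up", de$entity, any)
  down_any <- tapply(de$de_flag == "down", de$entity, any)
  up <- setNames(rep(FALSE, length(fams)), fams)
  down <- up
  up[names(up_any)] <- up_any
  down[names(down_any)] <- down_any
  mock_low <- apply(mock_tpm < cutoff, 1L, all)
  mock_high <- apply(mock_tpm >= cutoff, 1L, all)
  inf_high <- apply(infected_tpm >= cutoff, 1L, any)
  inf_low <- apply(infected_tpm < cutoff, 1L, any)
  data.frame(entity = fams,
             induced = unname(mock_low & inf_high & up[fams]),
             repressed = unname(mock_high & inf_low & down[fams]),
             stringsAsFactors = FALSE)
}

#' Correlate family expression with genomic factors
#'
#' Pearson correlation (with two-sided p-value) between per-family
#' expression and each genomic factor: copy number, mean divergence (an age
#' proxy) and mean distance to the nearest gene. Pairs with missing values
#' are dropped per factor; a factor with zero variance is flagged and
#' returned as `NA`.
#'
#' @param expression data.frame with `family_name` and `tpm`.
#' @param factors data.frame with `family_name`, `copy_number`,
#'   `mean_divergence`, `mean_gene_distance` (missing columns are skipped).
#' @return data.frame `factor`, `r`, `p`, `n`.
#' @export
correlate_factors <- function(expression, factors) {
  merged <- merge(expression, factors, by = "family_name")
  check_that(nrow(merged) >= 3L,
             "need at least 3 families with complete factors")
  cols <- intersect(c("copy_number", "mean_divergence", "mean_gene_distance"),
                    names(factors))
  out <- lapply(cols, function(cl) {
    ok <- stats::complete.cases(merged$tpm, merged[[cl]])
    x <- merged$tpm[ok]; y <- merged[[cl]][ok]
    if (length(x) < 3L || sd(x) == 0 || sd(y) == 0) {
      warning(sprintf("factor '%s': undefined correlation (constant or too few values)",
                      cl), call. = FALSE)
      return(data.frame(factor = cl, r = NA_real_, p = NA_real_,
                        n = length(x)))
    }
    ct <- cor.test(x, y, method = "pearson")
    data.frame(factor = cl, r = unname(ct$estimate), p = ct$p.value,
               n = length(x))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
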