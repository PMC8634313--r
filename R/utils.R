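# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of sequences over A/C/G/T.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Stop with a consistent "configuration error" style message.
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Length of the common prefix of two raw vectors.
lcp_raw <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  d <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(d)) d[1L] - 1L else n
}

# Length of the common suffix of two raw vectors.
lcs_raw <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  la <- length(a); lb <- length(b)
  d <- which(a[seq.int(la, la - n + 1L)] != b[seq.int(lb, lb - n + 1L)])
  if (length(d)) d[1L] - 1L else n
}
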