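# Independent brute-force oracles used against the implementation.

randomProtein <- function(n) paste(sample(AA_STANDARD, n, replace = TRUE),
                                   collapse = "")

# Maximum score over ALL global alignments by exhaustive path enumeration
# (no dynamic programming): moves are diagonal / query-gap / ref-gap, a gap
# run of length L costing open + L * ext. Exponential on purpose.
bruteAlignScore <- function(a, b, scoring = needleScoring()) {
  mat <- scoring$matrix
  open <- scoring$gapOpening
  ext <- scoring$gapExtension
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(A); m <- length(B)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, mat[A[i], B[j]] + rec(i + 1L, j + 1L, "d"))
    if (i <= n)
      best <- max(best, -(if (prev == "u") ext else open + ext) +
                    rec(i + 1L, j, "u"))
    if (j <= m)
      best <- max(best, -(if (prev == "l") ext else open + ext) +
                    rec(i, j + 1L, "l"))
    best
  }
  rec(1L, 1L, "s")
}

# every window tested one by one with matchAt
bruteScan <- function(pattern, seq) {
  plen <- length(pattern)
  n <- nchar(seq)
  if (n < plen) return(integer(0))
  which(vapply(seq_len(n - plen + 1L),
               function(s) matchAt(pattern, seq, s), logical(1L)))
}

# minimal per-sample relative-quantity table for CNRQ tests
rqTable <- function(sample_id, group, gene, rq, rq_rel_se = 0) {
  data.frame(sample_id = sample_id, group = group, gene = gene,
             rq = rq, rq_rel_se = rq_rel_se, stringsAsFactors = FALSE)
}

geomMeanOracle <- function(x) exp(mean(log(x)))
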