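# Independent brute-force affine-gap Smith-Waterman oracle (score only).
# Triple-matrix DP in plain R; a gap of length L costs open + L * extend.
# Deliberately separate from the package's C++ implementation.
sw_oracle_one <- function(query, subject, match = 2, mismatch = -4,
                          gap_open = -4, gap_extend = -2) {
  n <- nchar(query); m <- nchar(subject)
  q <- strsplit(query, "")[[1]]; s <- strsplit(subject, "")[[1]]
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  FF <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     E[i, j - 1] + gap_extend)
      FF[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                      FF[i - 1, j] + gap_extend)
      sc <- if (q[i - 1] == s[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sc, E[i, j], FF[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

sw_oracle <- function(query, subject, ...) {
  max(sw_oracle_one(query, subject, ...),
      sw_oracle_one(revcomp(query), subject, ...))
}
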