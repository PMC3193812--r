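# Independent oracles, deliberately written without reusing any package
# alignment code: plain-R affine-gap Smith-Waterman (local) and
# Needleman-Wunsch (global), used to check the seeded aligner.

ORACLE_MATCH <- 1
ORACLE_MISMATCH <- -2
ORACLE_GAP_OPEN <- 5   # a gap of length n costs open + n * ext
ORACLE_GAP_EXT <- 2

sw_oracle_score <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) ORACLE_MATCH else ORACLE_MISMATCH
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1]) + s)
      Ix[i, j] <- max(M[i - 1, j] - ORACLE_GAP_OPEN - ORACLE_GAP_EXT,
                      Ix[i - 1, j] - ORACLE_GAP_EXT)
      Iy[i, j] <- max(M[i, j - 1] - ORACLE_GAP_OPEN - ORACLE_GAP_EXT,
                      Iy[i, j - 1] - ORACLE_GAP_EXT)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

nw_oracle <- function(a, b) {
  # global affine alignment; returns list(score, columns, matches)
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1))
    Ix[i, 1] <- -ORACLE_GAP_OPEN - (i - 1) * ORACLE_GAP_EXT
  for (j in 2:(m + 1))
    Iy[1, j] <- -ORACLE_GAP_OPEN - (j - 1) * ORACLE_GAP_EXT
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) ORACLE_MATCH else ORACLE_MISMATCH
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                     Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - ORACLE_GAP_OPEN - ORACLE_GAP_EXT,
                      Ix[i - 1, j] - ORACLE_GAP_EXT)
      Iy[i, j] <- max(M[i, j - 1] - ORACLE_GAP_OPEN - ORACLE_GAP_EXT,
                      Iy[i, j - 1] - ORACLE_GAP_EXT)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# mutate a sequence with k substitutions (no indels)
mutate_subs <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  at <- sample(length(ch), k)
  for (i in at) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}
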