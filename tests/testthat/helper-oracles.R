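# Independent oracles used across tests. These deliberately share no code
# with the package implementation.

# Brute-force affine-gap local alignment score (Gotoh), O(mn).
sw_affine_score <- function(q, t, match = 1, mismatch = -1, gap_open = 7,
                            gap_extend = 1) {
  q <- strsplit(toupper(q), "")[[1]]
  t <- strsplit(toupper(t), "")[[1]]
  n <- length(q); m <- length(t)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (q[i - 1] == t[j - 1] && q[i - 1] != "N") match else mismatch
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1]) + s)
      Ix[i, j] <- max(M[i - 1, j] - (gap_open + gap_extend),
                      Ix[i - 1, j] - gap_extend)
      Iy[i, j] <- max(M[i, j - 1] - (gap_open + gap_extend),
                      Iy[i, j - 1] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum of P(X = k) over all k with P(X = k) <= P(X = a) (within tolerance).
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# UPGMA by direct agglomeration on a distance matrix; returns merge heights
# (sorted) for comparison against hclust.
upgma_heights_oracle <- function(d) {
  d <- as.matrix(d)
  sizes <- rep(1L, nrow(d))
  heights <- numeric(0)
  active <- seq_len(nrow(d))
  while (length(active) > 1L) {
    sub <- d[active, active, drop = FALSE]
    diag(sub) <- Inf
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[ij[1]]; j <- active[ij[2]]
    heights <- c(heights, min(sub))
    # average linkage update
    ni <- sizes[i]; nj <- sizes[j]
    new_d <- (d[i, ] * ni + d[j, ] * nj) / (ni + nj)
    d[i, ] <- new_d; d[, i] <- new_d
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  sort(heights)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

k80_distance_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  ts_pairs <- c(A = "G", G = "A", C = "T", T = "C")
  diff <- x != y
  ts <- diff & ts_pairs[x] == y
  P <- mean(ts); Q <- mean(diff & !ts)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# Row-vectorised version of the same DP (for the larger oracle sweeps);
# cross-checked against sw_affine_score in the tests that use it.
sw_affine_score_fast <- function(q, t, match = 1, mismatch = -1,
                                 gap_open = 7, gap_extend = 1) {
  qv <- strsplit(toupper(q), "")[[1]]
  tv <- strsplit(toupper(t), "")[[1]]
  n <- length(qv); m <- length(tv)
  go <- gap_open + gap_extend
  prevM <- numeric(m + 1)
  prevIx <- rep(-Inf, m + 1)
  prevIy <- rep(-Inf, m + 1)
  best <- 0
  j <- seq_len(m)
  for (i in seq_len(n)) {
    s <- ifelse(tv == qv[i] & qv[i] != "N", match, mismatch)
    diag_best <- pmax(prevM[j], prevIx[j], prevIy[j])
    Mrow <- c(0, pmax(0, diag_best + s))
    Ixrow <- c(-Inf, pmax(prevM[j + 1] - go, prevIx[j + 1] - gap_extend))
    # Iy[col j] = max_{k<=j-1} (M[col k] - go - (j-k-1)*ext)
    #           = cummax_{k} (M[col k] + k*ext) - go - (j-1)*ext
    acc <- cummax(Mrow[j] + (j - 1) * gap_extend)
    Iyrow <- c(-Inf, acc - go - (j - 1) * gap_extend)
    best <- max(best, Mrow)
    prevM <- Mrow; prevIx <- Ixrow; prevIy <- Iyrow
  }
  best
}
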