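# Independent brute-force oracles used across the suite. These stay
# deliberately naive (explicit loops, O(n^2) pair counting, observation
# expansion) so they share no code path with the implementation.

# Pearson chi-square by explicit (O - E)^2 / E summation.
oracle_chisq <- function(counts) {
  n <- sum(counts)
  stat <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      e <- sum(counts[i, ]) * sum(counts[, j]) / n
      stat <- stat + (counts[i, j] - e)^2 / e
    }
  }
  stat
}

# Linear-by-linear M^2 by expanding the table into N (x, y) observations.
oracle_lbl <- function(counts, rs = seq_len(nrow(counts)) - 1,
                       cs = seq_len(ncol(counts)) - 1) {
  x <- numeric(0)
  y <- numeric(0)
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      x <- c(x, rep(rs[i], counts[i, j]))
      y <- c(y, rep(cs[j], counts[i, j]))
    }
  }
  (length(x) - 1) * cor(x, y)^2
}

# AUC by counting concordant (pos, neg) pairs, ties worth 1/2.
oracle_auc <- function(predictor, positive) {
  pos <- predictor[positive]
  neg <- predictor[!positive]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Raw data whose sample mean and SD match a summary triple exactly.
raw_from_summary <- function(n, m, s) {
  if (n == 1) {
    return(m)
  }
  z <- seq_len(n)
  z <- (z - mean(z)) / sd(z)
  m + s * z
}

# A small synthetic field triple with known pixel counts: rectangular
# regions, so every area is exact by construction.
rect_field <- function(w = 100, h = 100,
                       stroma = c(1, 80, 1, 80),
                       til = c(10, 40, 10, 40),
                       excl = NULL) {
  mk <- function(b) {
    m <- matrix(FALSE, w, h)
    if (!is.null(b)) m[b[1]:b[2], b[3]:b[4]] <- TRUE
    m
  }
  field_annotation(mk(stroma), mk(til), if (!is.null(excl)) mk(excl))
}
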