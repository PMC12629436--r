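# Independent brute-force oracles, coded as plain summations so they share
# no code path with the package implementations they check.

# Stationary and transition entropy by direct counting and summation.
brute_entropy <- function(bins, n_bins) {
  N <- length(bins)
  Hs <- 0
  for (i in seq_len(n_bins)) {
    p <- sum(bins == i) / N
    if (p > 0) Hs <- Hs - p * log2(p)
  }
  Ht <- 0
  for (i in seq_len(n_bins)) {
    p_i <- sum(bins == i) / N
    exits <- sum(bins[-N] == i)
    if (exits == 0 || p_i == 0) next
    h_row <- 0
    for (j in seq_len(n_bins)) {
      nij <- sum(bins[-N] == i & bins[-1] == j)
      if (nij > 0) {
        tij <- nij / exits
        h_row <- h_row - tij * log2(tij)
      }
    }
    Ht <- Ht + p_i * h_row
  }
  list(Hs = Hs, Ht = Ht)
}

# AUC by enumerating every event/non-event pair, ties counted 1/2.
brute_auc <- function(probs, y) {
  pos <- probs[y == 1]
  neg <- probs[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Leave-one-out CV Brier score by an explicit loop over held-out rows.
brute_loo_brier <- function(X, y) {
  n <- length(y)
  errs <- numeric(n)
  for (i in seq_len(n)) {
    f <- suppressWarnings(
      stats::glm.fit(X[-i, , drop = FALSE], y[-i], family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
    p <- stats::plogis(drop(X[i, , drop = FALSE] %*% f$coefficients))
    errs[i] <- (p - y[i])^2
  }
  mean(errs)
}

# Random fixation sequence landing in given bin rectangles of a grid.
random_bin_sequence <- function(n, n_bins) {
  sample.int(n_bins, n, replace = TRUE)
}

# Build a fixation_sequence whose fixations land in prescribed bins of an
# r x c unit-square grid (bin centres).
seq_from_bins <- function(bins, n_rows, n_cols) {
  col <- (bins - 1L) %% n_cols + 1L
  row <- (bins - 1L) %/% n_cols + 1L
  x <- (col - 0.5) / n_cols
  y <- (row - 0.5) / n_rows
  n <- length(bins)
  fixation_sequence(onset = seq_len(n), duration = rep(0.3, n), x = x, y = y)
}
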