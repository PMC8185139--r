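# Independent brute-force oracles used to validate the estimators.
# Everything here follows the textbook definitions directly (double loops,
# explicit matrices) and shares no code with the package implementations.

# Phi^m(r): mean log fraction of templates within Chebyshev distance r,
# self-match included.
oracle_phi <- function(x, m, r) {
  n <- length(x)
  nm <- n - m + 1
  counts <- vapply(seq_len(nm), function(i) {
    ti <- x[i:(i + m - 1)]
    sum(vapply(seq_len(nm), function(j)
      max(abs(ti - x[j:(j + m - 1)])) <= r, logical(1)))
  }, numeric(1))
  mean(log(counts / nm))
}

oracle_apen <- function(x, m, r)
  oracle_phi(x, m, r) - oracle_phi(x, m + 1, r)

oracle_sampen <- function(x, m, r) {
  n <- length(x)
  nm <- n - m  # number of (m+1)-templates; SampEn uses the first nm m-templates
  A <- 0; B <- 0
  for (i in seq_len(nm - 1)) {
    for (j in (i + 1):nm) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) B <- B + 1
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1
    }
  }
  -log(A / B)
}

# Explicit matrix form of one periodized analysis step:
# row n (0-based) holds filter tap k at column (2n + k - 2) mod N.
oracle_dwt_matrix <- function(f, N) {
  M <- matrix(0, N / 2, N)
  for (n in seq_len(N / 2) - 1) {
    for (k in seq_along(f) - 1) {
      col <- (2 * n + k) %% N + 1
      M[n + 1, col] <- M[n + 1, col] + f[k + 1]
    }
  }
  M
}

# Detail-band energies by composing explicit matrices level by level.
oracle_wavelet_energies <- function(x, h, g, levels) {
  s <- x
  energies <- numeric(levels)
  for (lev in seq_len(levels)) {
    N <- length(s)
    d <- oracle_dwt_matrix(g, N) %*% s
    s <- as.numeric(oracle_dwt_matrix(h, N) %*% s)
    energies[lev] <- sum(d^2)
  }
  energies
}

# Direct windowed-DFT spectrogram entropy (definition, no FFT).
oracle_stft_entropy <- function(x, rate, win_s, hop_s) {
  win <- round(win_s * rate); hop <- round(hop_s * rate)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  starts <- seq(1, length(x) - win + 1, by = hop)
  nb <- win %/% 2 + 1
  P <- matrix(0, nb, length(starts))
  for (s in seq_along(starts)) {
    seg <- x[starts[s]:(starts[s] + win - 1)] * w
    for (k in seq_len(nb)) {
      ph <- -2i * pi * (k - 1) * (seq_len(win) - 1) / win
      P[k, s] <- Mod(sum(seg * exp(ph)))^2
    }
  }
  p <- P / sum(P)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Welch t statistic from the closed-form formula.
oracle_welch_t <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(statistic = t, p_value = p)
}

# Small helper: an eeg_segment around a bare matrix.
make_segment <- function(data, rate_hz = 256, index = 0L) {
  structure(list(data = data, index = index, rate_hz = rate_hz),
            class = "eeg_segment")
}
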