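#' Split a recording into fixed-length segments
#'
#' Contiguous windows starting at time zero; a trailing partial window is
#' discarded.  The study convention is 4 s windows with no overlap.
#'
#' @param rec an [eeg_recording()].
#' @param window_s window length in seconds.
#' @param overlap_s overlap between consecutive windows, `0 <= overlap_s <
#'   window_s`.
#' @return list of `eeg_segment` objects (fields `data`, `index`,
#'   `rate_hz`); empty list with a warning if the recording is shorter than
#'   one window.
#' @export
segment_recording <- function(rec, window_s = 4, overlap_s = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (overlap_s < 0 || overlap_s >= window_s)
    stop("need 0 <= overlap_s < window_s")
  win <- round(window_s * rec$rate_hz)
  hop <- round((window_s - overlap_s) * rec$rate_hz)
  n <- ncol(rec$data)
  if (n < win) {
    warning("recording shorter than one window; no segments produced")
    return(list())
  }
  starts <- seq(1L, n - win + 1L, by = hop)
  lapply(seq_along(starts), function(i) {
    structure(list(data = rec$data[, starts[i]:(starts[i] + win - 1L),
                                   drop = FALSE],
                   index = i - 1L, rate_hz = rec$rate_hz),
              class = "eeg_segment")
  })
}

#' Approximate entropy
#'
#' Regularity statistic \eqn{\Phi^m(r) - \Phi^{m+1}(r)} where
#' \eqn{\Phi^m(r)} is the mean log fraction of length-`m` templates lying
#' within Chebyshev distance `r` of each template (self-matches included).
#' Lower values indicate a more regular series.
#'
#' @param x numeric series, length `> m + 1`.
#' @param m embedding dimension (default 2).
#' @param r tolerance; default `0.2 * sd(x)`.  A constant series (sd 0)
#'   returns 0: every template matches.
#' @return non-negative scalar (up to floating error).
#' @export
approximate_entropy <- function(x, m = 2L, r = 0.2 * sd(x)) {
  x <- as.numeric(x)
  if (length(x) <= m + 1) stop("series too short: need length > m + 1")
  cnt <- entropy_match_counts(x, as.integer(m), r)
  phi_m <- mean(log(cnt$cm / cnt$n_m))
  phi_m1 <- mean(log(cnt$cm1 / cnt$n_m1))
  phi_m - phi_m1
}

#' Sample entropy
#'
#' \eqn{-\ln(A/B)} where `B` counts pairs of length-`m` templates within
#' Chebyshev distance `r` and `A` the corresponding length-`m+1` pairs,
#' self-matches excluded.  When either count is zero the estimator is
#' undefined; a finite sentinel is returned instead of `NaN`/`Inf`: the
#' log of the number of possible template pairs (the largest value the
#' statistic could attain with at least one match), configurable via `cap`.
#'
#' @inheritParams approximate_entropy
#' @param cap value returned when `A == 0` or `B == 0`; default
#'   `log((n-m)*(n-m-1)/2)`.
#' @return scalar; 0 for a constant or strictly periodic series.
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * sd(x),
                           cap = NULL) {
  x <- as.numeric(x)
  if (length(x) <= m + 1) stop("series too short: need length > m + 1")
  cnt <- entropy_match_counts(x, as.integer(m), r)
  if (is.null(cap)) {
    np <- cnt$n_m1 * (cnt$n_m1 - 1) / 2
    cap <- log(max(np, 2))
  }
  if (cnt$A == 0 || cnt$B == 0) return(cap)
  -log(cnt$A / cnt$B)
}

# ApEn and SampEn from one template-counting pass (they share m and r in
# the feature extractor, and the O(n^2) count dominates the cost).
complexity_entropies <- function(x, m, r) {
  cnt <- entropy_match_counts(x, as.integer(m), r)
  apen <- mean(log(cnt$cm / cnt$n_m)) - mean(log(cnt$cm1 / cnt$n_m1))
  sampen <- if (cnt$A == 0 || cnt$B == 0)
    log(max(cnt$n_m1 * (cnt$n_m1 - 1) / 2, 2))
  else -log(cnt$A / cnt$B)
  c(apen = apen, sampen = sampen)
}

#' Normalized permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution of the series,
#' divided by `log(order!)` so the value lies in `[0, 1]`.  Ties are broken
#' by order of appearance (the earlier sample ranks lower), so the ordinal
#' pattern is always well defined.
#'
#' @param x numeric series of length at least `(order - 1) * delay + 2`.
#' @param order pattern length (default 3).
#' @param delay lag between pattern elements (default 1).
#' @return scalar in `[0, 1]`; 0 iff a single pattern occurs.
#' @export
permutation_entropy <- function(x, order = 3L, delay = 1L) {
  x <- as.numeric(x)
  n_pat <- length(x) - (order - 1L) * delay
  if (n_pat < 2L) stop("series too short for this order/delay")
  emb <- vapply(seq_len(order),
                function(k) x[seq_len(n_pat) + (k - 1L) * delay],
                numeric(n_pat))
  emb <- matrix(emb, nrow = n_pat)
  # rank of column i among the pattern, ties to the earlier column
  code <- numeric(n_pat)
  for (i in seq_len(order)) {
    r_i <- rep(1, n_pat)
    for (j in seq_len(order)) {
      if (j == i) next
      r_i <- r_i + (emb[, j] < emb[, i]) +
        (emb[, j] == emb[, i] & j < i)
    }
    code <- code + r_i * (order + 1)^(i - 1)
  }
  p <- tabulate(as.integer(factor(code)))
  p <- p / n_pat
  -sum(p * log(p)) / log(factorial(order))
}

# ---------------------------------------------------------------------------
# Discrete wavelet transform (periodized pyramid) used by wavelet_entropy().
# Orthonormal filter banks; "db4" is the 8-tap Daubechies filter with four
# vanishing moments, "haar" the 2-tap Haar filter.

wavelet_filters <- function(wavelet) {
  h <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    db4 = c(0.230377813308855, 0.714846570552542, 0.630880767929590,
            -0.027983769416984, -0.187034811718881, 0.030841381835987,
            0.032883011666983, -0.010597401784997),
    stop("unknown wavelet: ", wavelet))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g)
}

# One periodized analysis step: y[n] = sum_k f[k] s[(2n + k - 2) mod N + 1]
dwt_step <- function(s, f) {
  N <- length(s)
  half <- N %/% 2
  idx <- outer((seq_len(half) - 1) * 2, seq_along(f) - 1, `+`) %% N + 1
  as.numeric(matrix(s[idx], nrow = half) %*% f)
}

dwt_periodized <- function(x, wavelet, levels) {
  flt <- wavelet_filters(wavelet)
  details <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    if (length(a) %% 2 != 0)
      stop("series length not divisible by 2^levels after truncation")
    details[[lev]] <- dwt_step(a, flt$g)
    a <- dwt_step(a, flt$h)
  }
  list(details = details, approx = a)
}

#' Wavelet entropy
#'
#' Shannon entropy (nats) of the relative energy distribution across the
#' detail bands of an orthonormal discrete wavelet decomposition.  Low
#' values mean the signal's energy concentrates in few scales; a flat
#' distribution over `levels` bands gives `log(levels)`.
#'
#' The series is truncated to the largest prefix whose length is a multiple
#' of `2^levels` (the periodized pyramid needs even length at every step).
#'
#' @param x numeric series, `length(x) >= 2^levels`.
#' @param wavelet `"db4"` (default) or `"haar"`.
#' @param levels decomposition depth (default 5).
#' @return non-negative scalar; 0 for a zero series or single-band signal.
#' @export
wavelet_entropy <- function(x, wavelet = "db4", levels = 5L) {
  x <- as.numeric(x)
  if (length(x) < 2^levels)
    stop("series too short for ", levels, " decomposition levels")
  keep <- (length(x) %/% 2^levels) * 2^levels
  dec <- dwt_periodized(x[seq_len(keep)], wavelet, levels)
  energies <- vapply(dec$details, function(d) sum(d^2), 0)
  total <- sum(energies)
  if (total <= 0) return(0)
  p <- energies / total
  p <- p[p > 0]
  -sum(p * log(p))
}

#' STFT spectral entropy of a segment
#'
#' Short-time Fourier transform with a Hann window; the magnitude-squared
#' spectrogram over all (time, frequency) bins is normalized to a
#' probability distribution and its Shannon entropy (nats) taken, then
#' averaged over channels.  High values indicate energy spread over the
#' whole time-frequency plane (noise-like), low values a concentrated
#' rhythm.
#'
#' @param seg an `eeg_segment` from [segment_recording()].
#' @param win_s analysis window in seconds (default 1).
#' @param hop_s hop between windows (default 0.5); `0 < hop_s <= win_s`.
#' @return non-negative scalar; 0 for an all-zero segment.
#' @export
stft_spectral_entropy <- function(seg, win_s = 1, hop_s = 0.5) {
  stopifnot(inherits(seg, "eeg_segment"))
  win <- round(win_s * seg$rate_hz)
  hop <- round(hop_s * seg$rate_hz)
  n <- ncol(seg$data)
  if (hop <= 0 || win > n || hop > win)
    stop("need 0 < hop_s <= win_s <= segment length")
  w <- hann_window(win)
  starts <- seq(1L, n - win + 1L, by = hop)
  ent <- apply(seg$data, 1, function(x) {
    P <- vapply(starts, function(s0) {
      X <- fft(x[s0:(s0 + win - 1L)] * w)
      Mod(X[seq_len(win %/% 2 + 1L)])^2
    }, numeric(win %/% 2 + 1L))
    total <- sum(P)
    if (total <= 0) return(0)
    p <- P / total
    p <- p[p > 0]
    -sum(p * log(p))
  })
  mean(ent)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' Pearson-correlation channel synchronization
#'
#' Pairwise Pearson correlation between all channels of a segment, the
#' standard functional-connectivity measure.  The scalar summary used as a
#' graph-node attribute is the mean of the strict upper triangle.
#'
#' @param seg an `eeg_segment` with at least 2 channels.
#' @return list with `matrix` (symmetric, unit diagonal, entries in
#'   `[-1, 1]`) and `scalar` (mean off-diagonal correlation).
#' @export
pcc_synchronization <- function(seg) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (nrow(seg$data) < 2) stop("need at least 2 channels")
  sds <- apply(seg$data, 1, sd)
  if (any(sds == 0))
    stop("zero-variance channel(s): ",
         paste(which(sds == 0), collapse = ", "))
  C <- cor(t(seg$data))
  list(matrix = C, scalar = mean(C[upper.tri(C)]))
}

#' EEG feature-extraction configuration
#'
#' Defaults for the seven EEG node features.  Per-channel statistics (mean,
#' entropies) are reduced to one scalar per segment by `reduce` across
#' channels.
#'
#' @param m,r_factor embedding dimension and relative tolerance
#'   (`r = r_factor * sd`) for approximate/sample entropy.
#' @param perm_order,perm_delay ordinal-pattern parameters.
#' @param wavelet,levels wavelet basis and decomposition depth.
#' @param stft_win_s,stft_hop_s STFT window and hop (seconds).
#' @param reduce `"mean"` (default) or `"median"` channel reduction.
#' @return list of class `eeg_feature_config`.
#' @export
eeg_feature_config <- function(m = 2L, r_factor = 0.2,
                               perm_order = 3L, perm_delay = 1L,
                               wavelet = "db4", levels = 5L,
                               stft_win_s = 1, stft_hop_s = 0.5,
                               reduce = c("mean", "median")) {
  reduce <- match.arg(reduce)
  structure(list(m = m, r_factor = r_factor, perm_order = perm_order,
                 perm_delay = perm_delay, wavelet = wavelet,
                 levels = levels, stft_win_s = stft_win_s,
                 stft_hop_s = stft_hop_s, reduce = reduce),
            class = "eeg_feature_config")
}

#' Extract the seven EEG node features from a segment
#'
#' Returns, in fixed order: `mean_value`, `stft_entropy`, `pcc_sync`,
#' `appr_en`, `samp_en`, `perm_en`, `wavelet_en`.  Per-channel quantities
#' are reduced across channels per the configuration.
#'
#' @param seg an `eeg_segment`.
#' @param config an [eeg_feature_config()].
#' @return named numeric vector of length 7.
#' @export
extract_eeg_features <- function(seg, config = eeg_feature_config()) {
  stopifnot(inherits(seg, "eeg_segment"))
  red <- if (config$reduce == "mean") mean else stats::median
  per_channel <- function(f) red(apply(seg$data, 1, f))
  complexity <- apply(seg$data, 1, function(x)
    complexity_entropies(x, config$m, config$r_factor * sd(x)))
  feats <- c(
    mean_value = per_channel(mean),
    stft_entropy = stft_spectral_entropy(seg, config$stft_win_s,
                                         config$stft_hop_s),
    pcc_sync = pcc_synchronization(seg)$scalar,
    appr_en = red(complexity["apen", ]),
    samp_en = red(complexity["sampen", ]),
    perm_en = per_channel(function(x)
      permutation_entropy(x, config$perm_order, config$perm_delay)),
    wavelet_en = per_channel(function(x)
      wavelet_entropy(x, config$wavelet, config$levels)))
  feats[EEG_FEATURE_NAMES]
}

#' Zero-phase band-pass filter
#'
#' Optional plumbing for real recordings: 4th-order Butterworth band-pass
#' applied forward and backward ([signal::filtfilt()]) channel by channel.
#' Synthetic recordings are generated in-band and do not need it.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz (defaults 0.5 and 45).
#' @return filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 45) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate_hz / 2
  if (high >= nyq) stop("high edge must be below the Nyquist frequency")
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  filtered <- t(apply(rec$data, 1, function(x)
    signal::filtfilt(bf, x)))
  eeg_recording(filtered, rec$rate_hz, rec$channel_names)
}

#' Per-segment EEG feature table for a cohort
#'
#' Segments every subject's recording and extracts the seven EEG features,
#' returning one row per (subject, segment).
#'
#' @param cohort a [simulate_dataset()] result or [read_cohort()] output.
#' @param window_s,overlap_s segmentation parameters.
#' @param config an [eeg_feature_config()].
#' @return data frame: `subject_id`, `group`, `segment_index`, then the 7
#'   feature columns.
#' @export
eeg_feature_table <- function(cohort, window_s = 4, overlap_s = 0,
                              config = eeg_feature_config()) {
  rows <- lapply(cohort, function(s) {
    segs <- segment_recording(s$eeg, window_s, overlap_s)
    feats <- t(vapply(segs, extract_eeg_features, numeric(7),
                      config = config))
    data.frame(subject_id = s$subject_id, group = s$group,
               segment_index = vapply(segs, `[[`, 0L, "index"),
               feats, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
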