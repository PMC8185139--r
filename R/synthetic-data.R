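#' Group specification for the synthetic cohort generator
#'
#' A `group_spec` bundles every generative knob for one subject group.  EEG
#' channels are simulated as an AR(1) process plus an in-band 10 Hz
#' oscillation plus white noise, with a shared latent driver mixed into all
#' channels so that channel-pair Pearson correlations are non-degenerate:
#' \deqn{x_t = \phi x_{t-1} + A \sin(2\pi \cdot 10 \cdot t / f_s) +
#'       \epsilon_t + w z_t}
#' Each knob maps onto one extracted feature family: `eeg_ar_coefficient`
#' (regularity) drives the entropy features, `eeg_sine_amplitude` the
#' spectral/wavelet features, `eeg_coupling` the synchronization feature,
#' and the fixation parameters the per-test eye features.
#'
#' @param label group name, e.g. `"ASD"` or `"TD"`.
#' @param eeg_ar_coefficient lag-1 autoregression weight in `[0, 1)`; larger
#'   values give smoother, more regular signals (lower entropies).
#' @param eeg_sine_amplitude amplitude (uV) of the 10 Hz oscillation.
#' @param eeg_noise_sd standard deviation (uV) of the innovation noise;
#'   must be positive.
#' @param eeg_coupling mixing weight of the latent driver shared by all
#'   channels; controls inter-channel correlation.
#' @param fixation_mean_ms per-test mean total fixation duration (ms);
#'   either a single number recycled over the 7 tests or a named vector
#'   over [eye_test_names()].
#' @param fixation_sd_ms per-test standard deviation (ms), recycled likewise.
#' @param subthreshold_rate expected number of sub-60 ms (invalid) fixation
#'   events per test; these should be filtered out downstream.
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(label,
                       eeg_ar_coefficient = 0.5,
                       eeg_sine_amplitude = 1.0,
                       eeg_noise_sd = 1.0,
                       eeg_coupling = 0.8,
                       fixation_mean_ms = 12000,
                       fixation_sd_ms = 1500,
                       subthreshold_rate = 3) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.numeric(eeg_noise_sd) || eeg_noise_sd <= 0)
    stop("eeg_noise_sd must be > 0")
  if (eeg_ar_coefficient < 0 || eeg_ar_coefficient >= 1)
    stop("eeg_ar_coefficient must lie in [0, 1)")
  fixation_mean_ms <- expand_per_test(fixation_mean_ms, "fixation_mean_ms")
  fixation_sd_ms <- expand_per_test(fixation_sd_ms, "fixation_sd_ms")
  if (any(fixation_mean_ms < 0)) stop("fixation_mean_ms must be >= 0")
  if (any(fixation_sd_ms < 0)) stop("fixation_sd_ms must be >= 0")
  if (subthreshold_rate < 0) stop("subthreshold_rate must be >= 0")
  structure(list(label = label,
                 eeg_ar_coefficient = eeg_ar_coefficient,
                 eeg_sine_amplitude = eeg_sine_amplitude,
                 eeg_noise_sd = eeg_noise_sd,
                 eeg_coupling = eeg_coupling,
                 fixation_mean_ms = fixation_mean_ms,
                 fixation_sd_ms = fixation_sd_ms,
                 subthreshold_rate = subthreshold_rate),
            class = "group_spec")
}

expand_per_test <- function(x, what) {
  if (length(x) == 1L) x <- rep(x, length(EYE_TEST_NAMES))
  if (length(x) != length(EYE_TEST_NAMES))
    stop(what, " must have length 1 or ", length(EYE_TEST_NAMES))
  if (is.null(names(x))) names(x) <- EYE_TEST_NAMES
  x <- x[EYE_TEST_NAMES]
  if (anyNA(x)) stop(what, " must name every test")
  x
}

#' Default strong-effect group specifications
#'
#' Two ready-made `group_spec`s emulating a well-separated two-group study.
#' The case group ("ASD") has smoother, more regular EEG (stronger lag-1
#' autoregression, so lower approximate/sample/permutation entropy) and a
#' much weaker 10 Hz rhythm (so higher STFT spectral entropy and higher
#' wavelet entropy: without the concentrated oscillation, energy spreads
#' over scales), plus markedly shorter fixation durations on every test.
#' Channel synchronization is left essentially unchanged between groups.
#' Each contrast is several pooled standard deviations at the subject
#' level, i.e. a deliberately well-separated cohort for end-to-end
#' validation rather than a realistic clinical effect size.
#'
#' @return named list with elements `case` and `control`.
#' @export
default_group_specs <- function() {
  list(
    case = group_spec("ASD",
                      eeg_ar_coefficient = 0.75,
                      eeg_sine_amplitude = 0.4,
                      eeg_noise_sd = 1.0,
                      eeg_coupling = 0.8,
                      fixation_mean_ms = 8000,
                      fixation_sd_ms = 1500,
                      subthreshold_rate = 3),
    control = group_spec("TD",
                         eeg_ar_coefficient = 0.35,
                         eeg_sine_amplitude = 1.4,
                         eeg_noise_sd = 1.0,
                         eeg_coupling = 0.8,
                         fixation_mean_ms = 14000,
                         fixation_sd_ms = 1500,
                         subthreshold_rate = 3)
  )
}

#' Simulate a multichannel EEG recording
#'
#' Channels are AR(1)-plus-sinusoid-plus-noise processes with a shared
#' latent AR(1) driver mixed into every channel (see [group_spec()]), so
#' pairwise Pearson correlations are non-degenerate.  Identical
#' `(spec, seed)` give bit-identical output.
#'
#' @param spec a [group_spec()].
#' @param n_channels number of channels (>= 2); 8 channels get the standard
#'   F3/F4/T3/C3/C4/T4/O1/O2 labels.
#' @param duration_s recording length in seconds (> 0).
#' @param rate_hz sampling frequency in Hz (> 0).
#' @param seed integer seed.
#' @return an [eeg_recording()].
#' @export
simulate_eeg <- function(spec, n_channels = 8, duration_s = 60,
                         rate_hz = 256, seed = 1) {
  stopifnot(inherits(spec, "group_spec"))
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (rate_hz <= 0) stop("rate_hz must be > 0")
  if (n_channels < 2) stop("need at least 2 channels")
  n <- round(duration_s * rate_hz)
  phi <- spec$eeg_ar_coefficient
  tt <- seq_len(n) / rate_hz
  withr::with_seed(seed, {
    # shared latent driver: mild AR(1) so coupling survives band structure
    z <- as.numeric(stats::filter(rnorm(n, sd = spec$eeg_noise_sd),
                                  0.5, method = "recursive"))
    data <- matrix(0, nrow = n_channels, ncol = n)
    phases <- runif(n_channels, 0, 2 * pi)
    for (ch in seq_len(n_channels)) {
      eps <- rnorm(n, sd = spec$eeg_noise_sd)
      ar <- as.numeric(stats::filter(eps, phi, method = "recursive"))
      data[ch, ] <- ar +
        spec$eeg_sine_amplitude * sin(2 * pi * 10 * tt + phases[ch]) +
        spec$eeg_coupling * z
    }
  })
  names <- if (n_channels == length(DEFAULT_CHANNELS)) DEFAULT_CHANNELS
           else sprintf("Ch%02d", seq_len(n_channels))
  eeg_recording(data, rate_hz, names)
}

#' Simulate one subject's eye-tracking fixation log
#'
#' For each of the seven tests the subject's total valid fixation time is
#' drawn as Normal(`fixation_mean_ms`, `fixation_sd_ms`) truncated at zero,
#' then partitioned into individual fixation events of at least 60 ms.
#' Invalid sub-60 ms events ("unconscious gazing") are added at the
#' configured Poisson rate per test, with durations uniform on [10, 59] ms,
#' so that downstream threshold filtering is exercised.
#'
#' @param spec a [group_spec()].
#' @param seed integer seed.
#' @return data frame with columns `test`, `aoi`, `onset_ms`, `duration_ms`;
#'   one row per fixation event.
#' @export
simulate_fixations <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "group_spec"))
  aois <- c("face", "eyes", "body", "background")
  withr::with_seed(seed, {
    recs <- lapply(EYE_TEST_NAMES, function(test) {
      total <- max(0, rnorm(1, spec$fixation_mean_ms[[test]],
                            spec$fixation_sd_ms[[test]]))
      durations <- partition_fixation_total(total, min_ms = 60)
      n_bad <- rpois(1, spec$subthreshold_rate)
      if (n_bad > 0) durations <- c(durations, runif(n_bad, 10, 59))
      if (length(durations) == 0L)
        return(data.frame(test = character(), aoi = character(),
                          onset_ms = numeric(), duration_ms = numeric()))
      durations <- sample(durations)  # interleave valid and invalid events
      gaps <- runif(length(durations), 0, 400)
      onsets <- cumsum(gaps) + c(0, cumsum(durations))[seq_along(durations)]
      data.frame(test = test,
                 aoi = sample(aois, length(durations), replace = TRUE),
                 onset_ms = onsets,
                 duration_ms = durations)
    })
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# Split a total duration into events all >= min_ms; number of events grows
# with the total so long dwells become several fixations, not one.
partition_fixation_total <- function(total, min_ms) {
  if (total < min_ms) return(numeric(0))
  n_fix <- max(1L, min(rpois(1, total / 1200), floor(total / min_ms)))
  w <- rexp(n_fix)
  min_ms + (total - min_ms * n_fix) * w / sum(w)
}

#' Simulate a two-group cohort
#'
#' Generates `n_a + n_b` subjects with unique ids, each holding one EEG
#' recording and one fixation log.  Per-subject seeds are derived
#' deterministically from the master seed and the subject index, so growing
#' the cohort never reshuffles existing subjects.
#'
#' @param spec_a,spec_b [group_spec()]s for the two groups (defaults:
#'   [default_group_specs()]).
#' @param n_a,n_b subjects per group (default 21 + 21).
#' @param seed master integer seed.
#' @param n_channels,duration_s,rate_hz passed to [simulate_eeg()].
#' @return object of class `cohort`: a list of subjects, each a list with
#'   `subject_id`, `group`, `eeg`, `fixations`; group labels in attribute
#'   `"groups"` (first = `spec_a`'s label).
#' @export
simulate_dataset <- function(spec_a = default_group_specs()$case,
                             spec_b = default_group_specs()$control,
                             n_a = 21, n_b = 21, seed = 1,
                             n_channels = 8, duration_s = 60,
                             rate_hz = 256) {
  stopifnot(n_a >= 1, n_b >= 1)
  specs <- c(rep(list(spec_a), n_a), rep(list(spec_b), n_b))
  n <- n_a + n_b
  subjects <- lapply(seq_len(n), function(i) {
    spec <- specs[[i]]
    list(subject_id = sprintf("S%03d", i),
         group = spec$label,
         eeg = simulate_eeg(spec, n_channels, duration_s, rate_hz,
                            seed = mix_seed(seed, 2L * i)),
         fixations = simulate_fixations(spec, seed = mix_seed(seed, 2L * i + 1L)))
  })
  structure(subjects,
            class = "cohort",
            groups = c(spec_a$label, spec_b$label),
            seed = seed)
}

#' @export
print.cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, "", "group")
  cat("Synthetic cohort:", length(x), "subjects (",
      paste(sprintf("%s=%d", names(table(groups)), table(groups)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Write a cohort to disk
#'
#' One EEG file per subject (plain tab-separated channels-by-samples matrix
#' or 16-bit EDF), a combined fixation log
#' (`subject_id,test,aoi,onset_ms,duration_ms`) and a JSON manifest with
#' ids, groups and the master seed.
#'
#' @param cohort a [simulate_dataset()] result.
#' @param dir output directory (created if missing).
#' @param eeg_format `"matrix"` (TSV) or `"edf"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, eeg_format = c("matrix", "edf")) {
  eeg_format <- match.arg(eeg_format)
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fix_all <- do.call(rbind, lapply(cohort, function(s)
    cbind(subject_id = s$subject_id, s$fixations)))
  write.csv(fix_all, file.path(dir, "fixations.csv"), row.names = FALSE)
  for (s in cohort) {
    path <- file.path(dir, paste0(s$subject_id,
                                  if (eeg_format == "edf") ".edf" else ".tsv"))
    if (eeg_format == "edf") write_edf(s$eeg, path)
    else utils::write.table(s$eeg$data, path, sep = "\t",
                            row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(
    subjects = data.frame(
      subject_id = vapply(cohort, `[[`, "", "subject_id"),
      group = vapply(cohort, `[[`, "", "group"),
      eeg_file = paste0(vapply(cohort, `[[`, "", "subject_id"),
                        if (eeg_format == "edf") ".edf" else ".tsv"),
      rate_hz = vapply(cohort, function(s) s$eeg$rate_hz, 0)),
    groups = attr(cohort, "groups"),
    seed = attr(cohort, "seed"),
    eeg_format = eeg_format)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `manifest.json`, `fixations.csv` and the
#'   per-subject EEG files.
#' @return a `cohort` object.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  fix_all <- read.csv(file.path(dir, "fixations.csv"),
                      stringsAsFactors = FALSE)
  subjects <- lapply(seq_len(nrow(manifest$subjects)), function(i) {
    row <- manifest$subjects[i, ]
    path <- file.path(dir, row$eeg_file)
    eeg <- if (grepl("\\.edf$", row$eeg_file)) read_edf(path)
    else {
      m <- as.matrix(utils::read.table(path, sep = "\t"))
      dimnames(m) <- NULL
      names <- if (nrow(m) == length(DEFAULT_CHANNELS)) DEFAULT_CHANNELS
               else sprintf("Ch%02d", seq_len(nrow(m)))
      eeg_recording(m, row$rate_hz, names)
    }
    fx <- fix_all[fix_all$subject_id == row$subject_id,
                  c("test", "aoi", "onset_ms", "duration_ms")]
    rownames(fx) <- NULL
    list(subject_id = row$subject_id, group = row$group,
         eeg = eeg, fixations = fx)
  })
  structure(subjects, class = "cohort",
            groups = manifest$groups, seed = manifest$seed)
}
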