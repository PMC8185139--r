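#' Stratified train/test split
#'
#' Splits samples into disjoint, covering train and test sets, stratified
#' by group.  In `"subject"` mode whole subjects are assigned to one side,
#' so no subject's segments straddle the split — the safer protocol when
#' eye-tracking features repeat across a subject's segments.  The default
#' `"segment"` mode splits at the sample level, mirroring the common 8:2
#' segment-level protocol.
#'
#' @param samples data frame with `subject_id` and `group` columns (e.g.
#'   [assemble_feature_vectors()] output).
#' @param ratio training fraction in (0, 1), default 0.8.
#' @param seed integer seed.
#' @param unit `"segment"` (default) or `"subject"`.
#' @return list with integer row indices `train` and `test`.
#' @export
train_test_split <- function(samples, ratio = 0.8, seed = 1,
                             unit = c("segment", "subject")) {
  unit <- match.arg(unit)
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  groups <- unique(samples$group)
  withr::with_seed(seed, {
    test_idx <- integer(0)
    if (unit == "segment") {
      for (g in groups) {
        idx <- which(samples$group == g)
        n_test <- max(1L, round(length(idx) * (1 - ratio)))
        test_idx <- c(test_idx, sample(idx, n_test))
      }
    } else {
      for (g in groups) {
        subj <- unique(samples$subject_id[samples$group == g])
        n_test <- max(1L, round(length(subj) * (1 - ratio)))
        held <- sample(subj, n_test)
        test_idx <- c(test_idx, which(samples$subject_id %in% held))
      }
    }
  })
  train_idx <- setdiff(seq_len(nrow(samples)), test_idx)
  for (side in list(train_idx, test_idx))
    if (!setequal(unique(samples$group[side]), groups))
      stop("a group is absent from one side of the split; ",
           "use more samples or a different ratio")
  list(train = sort(train_idx), test = sort(test_idx))
}

#' Confusion matrix for two-class predictions
#'
#' @param predicted,truth label vectors.
#' @param positive label of the positive class (e.g. `"ASD"`).
#' @return list of class `confusion_matrix` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_matrix <- function(predicted, truth, positive) {
  stopifnot(length(predicted) == length(truth))
  structure(list(
    tp = sum(predicted == positive & truth == positive),
    fp = sum(predicted == positive & truth != positive),
    fn = sum(predicted != positive & truth == positive),
    tn = sum(predicted != positive & truth != positive)),
    class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall and F1 with the positive class in the
#' numerator.  A zero denominator yields 0 for that metric, with a warning.
#'
#' @param cm a [confusion_matrix()] (or list with `tp`, `fp`, `fn`, `tn`).
#' @return list of class `metrics_report`: `accuracy`, `precision`,
#'   `recall`, `f1`, all in `[0, 1]`.
#' @export
classification_metrics <- function(cm) {
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0) stop("empty confusion matrix")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting 0")
      return(0)
    }
    num / den
  }
  precision <- safe_div(cm$tp, cm$tp + cm$fp, "precision")
  recall <- safe_div(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("f1 undefined (zero denominator); reporting 0")
    0
  } else f1_score(precision, recall)
  structure(list(accuracy = (cm$tp + cm$tn) / total,
                 precision = precision, recall = recall, f1 = f1),
            class = "metrics_report")
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`.
#'
#' @param precision,recall values in `[0, 1]`, not both zero.
#' @return scalar in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  2 * precision * recall / (precision + recall)
}

#' Two-sample t-test
#'
#' Two-sided independent-samples t-test, Welch (unequal variances) by
#' default; the pooled-variance Student variant via `var_equal = TRUE`.
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @param var_equal assume equal variances (default `FALSE`).
#' @param feature optional feature name carried through to the result.
#' @return list of class `ttest_result`: `statistic`, `p_value`, `df`,
#'   `feature`.
#' @export
two_sample_ttest <- function(a, b, var_equal = FALSE, feature = NA_character_) {
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 values per sample")
  if (var(a) + var(b) == 0)
    stop("degenerate (zero) variance in both samples")
  tt <- t.test(a, b, var.equal = var_equal)
  structure(list(statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 df = unname(tt$parameter),
                 feature = feature),
            class = "ttest_result")
}

#' Per-feature group t-test table
#'
#' Subject-level two-sample t-tests for every feature column, the standard
#' single-modality difference report.  EEG features should be aggregated to
#' one value per subject (mean over segments) before calling.
#'
#' @param features data frame with `group` plus numeric feature columns.
#' @param positive group treated as sample `a` (its deficit gives negative
#'   statistics).
#' @param var_equal passed to [two_sample_ttest()].
#' @return data frame with `feature`, `statistic`, `p_value`.
#' @export
feature_ttest_table <- function(features, positive = NULL,
                                var_equal = FALSE) {
  groups <- unique(features$group)
  stopifnot(length(groups) == 2)
  positive <- positive %||% groups[1]
  other <- setdiff(groups, positive)
  cols <- setdiff(names(features),
                  c("group", "subject_id", "sample_id", "segment_index"))
  rows <- lapply(cols, function(f) {
    tt <- two_sample_ttest(features[features$group == positive, f],
                           features[features$group == other, f],
                           var_equal = var_equal, feature = f)
    data.frame(feature = f, statistic = tt$statistic,
               p_value = tt$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Every tunable of [run_pipeline()] in one place.
#'
#' @param modality `"both"` (14-node graphs), `"eeg"` or `"eye"` (7-node
#'   single-modality ablations).
#' @param tau correlation threshold for the shared adjacency.
#' @param adjacency_mode `"absolute"` or `"signed"`.
#' @param split_ratio training fraction (default 0.8).
#' @param split_unit `"segment"` (default) or `"subject"`.
#' @param window_s,overlap_s EEG segmentation.
#' @param min_fix_ms fixation validity threshold (ms).
#' @param keep_k eye features retained by the random-forest ranking
#'   (default 7 = all; the ranking is still computed and reported).
#' @param seed master seed; split/forest/weight seeds derive from it.
#' @param train a [train_config()] (its seed is overridden by the derived
#'   seed).
#' @param eeg an [eeg_feature_config()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(modality = c("both", "eeg", "eye"),
                            tau = 0.3,
                            adjacency_mode = c("absolute", "signed"),
                            split_ratio = 0.8,
                            split_unit = c("segment", "subject"),
                            window_s = 4, overlap_s = 0,
                            min_fix_ms = 60, keep_k = 7L, seed = 1,
                            train = train_config(),
                            eeg = eeg_feature_config()) {
  structure(list(modality = match.arg(modality), tau = tau,
                 adjacency_mode = match.arg(adjacency_mode),
                 split_ratio = split_ratio,
                 split_unit = match.arg(split_unit),
                 window_s = window_s, overlap_s = overlap_s,
                 min_fix_ms = min_fix_ms, keep_k = keep_k, seed = seed,
                 train = train, eeg = eeg),
            class = "pipeline_config")
}

#' Run the full multimodal classification pipeline
#'
#' Feature extraction (both modalities) -> random-forest eye-feature
#' ranking -> per-sample feature graphs with one covariance-thresholded
#' adjacency fitted on the training fold -> GCN training -> held-out
#' metrics.  Standardization statistics, adjacency and the forest ranking
#' are all fitted on the training fold only.  Fully reproducible from
#' (cohort, config).
#'
#' @param cohort a [simulate_dataset()] / [read_cohort()] cohort.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, feature tables, the
#'   adjacency/covariance, the t-test table, the loss trace and the metrics
#'   are written there as CSV/JSON.
#' @return list with `metrics`, `confusion`, `ttests`, `adjacency`,
#'   `covariance`, `loss_trace`, `predictions` (test-sample data frame),
#'   `rf_ranking`, `n_train`, `n_test`, `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort") || is.list(cohort))
  groups <- attr(cohort, "groups") %||%
    unique(vapply(cohort, `[[`, "", "group"))
  positive <- groups[1]

  eeg_tab <- eeg_feature_table(cohort, config$window_s, config$overlap_s,
                               config$eeg)
  eye_tab <- eye_feature_table(cohort, config$min_fix_ms)
  vectors <- assemble_feature_vectors(eeg_tab, eye_tab)

  split <- train_test_split(vectors, config$split_ratio,
                            seed = mix_seed(config$seed, 11L),
                            unit = config$split_unit)

  # subject-level t-test table (EEG features averaged over segments)
  subj_eeg <- stats::aggregate(eeg_tab[, EEG_FEATURE_NAMES],
                               by = list(subject_id = eeg_tab$subject_id,
                                         group = eeg_tab$group),
                               FUN = mean)
  subj_feats <- merge(subj_eeg, eye_tab, by = c("subject_id", "group"))
  ttests <- feature_ttest_table(subj_feats, positive = positive)

  # random-forest ranking of the eye features, training subjects only
  train_subj <- unique(vectors$subject_id[split$train])
  eye_train <- eye_tab[eye_tab$subject_id %in% train_subj, ]
  rf <- rank_features_random_forest(eye_train[, EYE_TEST_NAMES],
                                    eye_train$group,
                                    keep_k = config$keep_k,
                                    seed = mix_seed(config$seed, 13L))
  eye_nodes <- EYE_TEST_NAMES[EYE_TEST_NAMES %in% rf$selected]

  nodes <- switch(config$modality,
                  both = c(EEG_FEATURE_NAMES, eye_nodes),
                  eeg = EEG_FEATURE_NAMES,
                  eye = eye_nodes)

  m_all <- feature_matrix(vectors, nodes)
  std <- fit_standardizer(m_all[split$train, , drop = FALSE])
  m_std <- apply_standardizer(m_all, std)
  ca <- covariance_adjacency(m_std[split$train, , drop = FALSE],
                             tau = config$tau,
                             mode = config$adjacency_mode,
                             standardize = FALSE)

  std_vectors <- cbind(vectors[, c("sample_id", "subject_id", "group")],
                       as.data.frame(m_std))
  make_batch <- function(idx)
    batch_graphs(graphs_from_vectors(std_vectors[idx, , drop = FALSE],
                                     ca$adjacency, nodes))
  train_batch <- make_batch(split$train)
  test_batch <- make_batch(split$test)

  cfg_train <- config$train
  cfg_train$seed <- mix_seed(config$seed, 17L)
  fit <- train_gcn(train_batch, cfg = cfg_train, classes = groups)

  test_adj <- normalize_adjacency(test_batch$adjacency)
  Z <- gcn_forward(test_batch$x, test_adj, fit$params)
  pred <- predict_graphs(Z, test_batch$membership)
  pred_labels <- fit$classes[pred$class_index]
  truth <- vectors$group[split$test]
  cm <- confusion_matrix(pred_labels, truth, positive)
  metrics <- classification_metrics(cm)

  predictions <- data.frame(sample_id = vectors$sample_id[split$test],
                            subject_id = vectors$subject_id[split$test],
                            truth = truth, predicted = pred_labels)

  result <- list(metrics = metrics, confusion = cm, ttests = ttests,
                 adjacency = ca$adjacency, covariance = ca$covariance,
                 loss_trace = fit$trace, predictions = predictions,
                 rf_ranking = rf, n_train = length(split$train),
                 n_test = length(split$test), config = config)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, eeg_tab,
                                                  eye_tab, out_dir)
  result
}

write_pipeline_artifacts <- function(result, eeg_tab, eye_tab, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(eeg_tab, file.path(out_dir, "eeg_features.csv"),
            row.names = FALSE)
  write.csv(eye_tab, file.path(out_dir, "eye_features.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(result$adjacency),
            file.path(out_dir, "adjacency.csv"))
  write.csv(as.data.frame(result$covariance),
            file.path(out_dir, "covariance.csv"))
  write.csv(result$ttests, file.path(out_dir, "ttests.csv"),
            row.names = FALSE)
  write.csv(data.frame(epoch = seq_along(result$loss_trace),
                       loss = result$loss_trace),
            file.path(out_dir, "loss_trace.csv"), row.names = FALSE)
  write.csv(result$predictions, file.path(out_dir, "predictions.csv"),
            row.names = FALSE)
  jsonlite::write_json(unclass(result$metrics),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}
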