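#' Total valid fixation duration for one test
#'
#' Sums fixation durations for one eye-tracking test, discarding events
#' shorter than `min_ms` — the standard 60 ms validity threshold that rules
#' out unconscious gazing.
#'
#' @param records data frame of fixation events (`test`, `aoi`, `onset_ms`,
#'   `duration_ms`).
#' @param test one of [eye_test_names()].
#' @param min_ms validity threshold in ms (default 60).
#' @return scalar total duration in ms (0 if no valid events).
#' @export
total_fixation_duration <- function(records, test, min_ms = 60) {
  if (!test %in% EYE_TEST_NAMES)
    stop("unknown test name: ", test)
  if (min_ms < 0) stop("min_ms must be >= 0")
  if (nrow(records) == 0L) return(0)
  keep <- records$test == test & records$duration_ms >= min_ms
  sum(records$duration_ms[keep])
}

#' Extract the seven per-test eye-tracking features of one subject
#'
#' One total valid fixation duration per test, in the fixed canonical test
#' order.  Tests absent from the log contribute 0 with a warning.
#'
#' @inheritParams total_fixation_duration
#' @return named numeric vector of length 7, all entries `>= 0`.
#' @export
extract_eye_features <- function(records, min_ms = 60) {
  missing <- setdiff(EYE_TEST_NAMES, unique(records$test))
  if (length(missing) > 0)
    warning("no fixation records for test(s): ",
            paste(missing, collapse = ", "), "; reporting 0")
  vapply(EYE_TEST_NAMES, function(tst)
    total_fixation_duration(records, tst, min_ms), numeric(1))
}

#' Rank eye-tracking features with a random forest
#'
#' Fits a classification random forest of the group labels on the feature
#' table and orders features by mean decrease in node impurity (Gini),
#' keeping the top `keep_k`.  With `keep_k` equal to the number of features
#' (the default downstream) the step reports the ranking without dropping
#' anything.
#'
#' @param feature_table numeric matrix or data frame, subjects in rows,
#'   features in columns.
#' @param labels group label per subject (2 classes required).
#' @param keep_k how many features to retain.
#' @param seed integer seed (forest bootstrap is stochastic).
#' @param num_trees forest size (default 500).
#' @return list with `selected` (top `keep_k` names), `ranking` (all names,
#'   most important first) and `importance` (named numeric).
#' @export
rank_features_random_forest <- function(feature_table, labels,
                                        keep_k = ncol(feature_table),
                                        seed = 1, num_trees = 500) {
  x <- as.data.frame(feature_table)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("labels must contain at least 2 classes")
  if (any(table(y) < 2)) stop("need at least 2 subjects per group")
  if (keep_k < 1 || keep_k > ncol(x))
    stop("keep_k must lie in [1, #features]")
  fit <- withr::with_seed(seed,
    randomForest::randomForest(x, y, ntree = num_trees))
  imp <- fit$importance[, "MeanDecreaseGini"]
  ranking <- names(sort(imp, decreasing = TRUE))
  list(selected = ranking[seq_len(keep_k)],
       ranking = ranking,
       importance = imp)
}

#' Per-subject eye-tracking feature table for a cohort
#'
#' @param cohort a [simulate_dataset()] result or [read_cohort()] output.
#' @param min_ms fixation validity threshold in ms.
#' @return data frame: `subject_id`, `group`, then one column per test.
#' @export
eye_feature_table <- function(cohort, min_ms = 60) {
  rows <- lapply(cohort, function(s) {
    feats <- extract_eye_features(s$fixations, min_ms)
    data.frame(subject_id = s$subject_id, group = s$group,
               t(feats), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
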