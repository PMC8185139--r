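#' Assemble per-sample multimodal feature vectors
#'
#' The sample unit is one EEG segment paired with its subject's
#' (segment-invariant) eye-tracking features: EEG features occupy node
#' positions 1-7, eye features positions 8-14, so every sample carries the
#' full 14-node attribute vector.  Values pass through unchanged;
#' standardization happens later, on the training fold.
#'
#' @param eeg_table per-segment table from [eeg_feature_table()].
#' @param eye_table per-subject table from [eye_feature_table()].
#' @return data frame with `sample_id`, `subject_id`, `group` and the 14
#'   feature columns in canonical node order.
#' @export
assemble_feature_vectors <- function(eeg_table, eye_table) {
  missing <- setdiff(unique(eeg_table$subject_id), eye_table$subject_id)
  if (length(missing) > 0)
    stop("subjects without eye-tracking features: ",
         paste(missing, collapse = ", "))
  idx <- match(eeg_table$subject_id, eye_table$subject_id)
  out <- data.frame(
    sample_id = sprintf("%s_seg%03d", eeg_table$subject_id,
                        eeg_table$segment_index),
    subject_id = eeg_table$subject_id,
    group = eeg_table$group,
    eeg_table[, EEG_FEATURE_NAMES],
    eye_table[idx, EYE_TEST_NAMES],
    check.names = FALSE)
  rownames(out) <- NULL
  out
}

feature_matrix <- function(vectors, nodes = feature_node_names()) {
  m <- as.matrix(vectors[, nodes, drop = FALSE])
  rownames(m) <- vectors$sample_id
  m
}

#' Fit / apply a feature standardizer
#'
#' Column means and standard deviations estimated on the training fold
#' only, so test-fold statistics never leak into the graph or the model.
#'
#' @param x numeric matrix, samples in rows.
#' @return `fit_standardizer`: list with `center`, `scale`.
#' @export
fit_standardizer <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  if (any(scale == 0))
    stop("zero-variance feature(s): ",
         paste(colnames(x)[scale == 0], collapse = ", "))
  list(center = center, scale = scale)
}

#' @rdname fit_standardizer
#' @param std a fitted standardizer.
#' @export
apply_standardizer <- function(x, std) {
  sweep(sweep(x, 2, std$center), 2, std$scale, `/`)
}

#' Covariance-thresholded shared adjacency
#'
#' Computes the sample covariance of the node features across the training
#' vectors (with standardization on by default, making it a correlation
#' matrix) and binarizes it: an edge joins features i and j when their
#' covariance magnitude exceeds `tau` (`absolute` mode, default) or when
#' the signed covariance does (`signed` mode).  One adjacency is computed
#' from the training fold and shared by every sample graph.
#'
#' @param x numeric matrix of training feature vectors (samples x nodes).
#' @param tau edge threshold; on standardized features this is a
#'   correlation threshold (default 0.3).
#' @param mode `"absolute"` (default) or `"signed"`.
#' @param standardize standardize columns before the covariance (default
#'   `TRUE`).
#' @return list with `covariance` (n x n) and `adjacency` (binary,
#'   symmetric, zero diagonal).
#' @export
covariance_adjacency <- function(x, tau = 0.3,
                                 mode = c("absolute", "signed"),
                                 standardize = TRUE) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 training vectors")
  if (!is.finite(tau)) stop("tau must be finite")
  if (standardize) {
    std <- fit_standardizer(x)
    x <- apply_standardizer(x, std)
  }
  S <- cov(x)  # symmetric, so A below is too
  A <- if (mode == "absolute") (abs(S) > tau) * 1 else (S > tau) * 1
  diag(A) <- 0
  list(covariance = S, adjacency = A)
}

#' Edge density across thresholds
#'
#' Diagnostic for choosing `tau`: fraction of possible off-diagonal edges
#' present at each threshold.
#'
#' @inheritParams covariance_adjacency
#' @param taus thresholds to scan.
#' @return data frame with `tau` and `density`.
#' @export
edge_density_profile <- function(x, taus = seq(0, 0.9, by = 0.1),
                                 mode = "absolute", standardize = TRUE) {
  n <- ncol(as.matrix(x))
  dens <- vapply(taus, function(tau) {
    A <- covariance_adjacency(x, tau, mode, standardize)$adjacency
    sum(A) / (n * (n - 1))
  }, numeric(1))
  data.frame(tau = taus, density = dens)
}

#' Feature graph constructor
#'
#' @param x node attribute vector (length n, named).
#' @param adjacency binary symmetric n x n matrix, zero diagonal.
#' @param label optional group label.
#' @return object of class `feature_graph`.
#' @export
feature_graph <- function(x, adjacency, label = NULL) {
  x <- unlist(x)
  adjacency <- as.matrix(adjacency)
  n <- length(x)
  stopifnot(nrow(adjacency) == n, ncol(adjacency) == n)
  if (!all(adjacency %in% c(0, 1))) stop("adjacency must be binary")
  if (!isTRUE(all.equal(adjacency, t(adjacency), check.attributes = FALSE)))
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (!all(is.finite(x))) stop("node attributes must be finite")
  structure(list(x = x, adjacency = adjacency, label = label,
                 nodes = names(x) %||% sprintf("v%d", seq_len(n))),
            class = "feature_graph")
}

#' Batch graphs into one block-diagonal structure
#'
#' Stacks N n-node graphs into a sparse block-diagonal adjacency of size
#' (N n) x (N n), a stacked attribute column and a graph-membership index,
#' so a single forward pass processes all graphs with no cross-graph edges.
#'
#' @param graphs list of [feature_graph()]s sharing node count and order.
#' @return object of class `graph_batch` with fields `adjacency`
#'   (`Matrix::sparseMatrix`), `x` (N n x 1 matrix), `membership`, `labels`,
#'   `n_nodes`, `nodes`.
#' @export
batch_graphs <- function(graphs) {
  stopifnot(length(graphs) > 0)
  ns <- vapply(graphs, function(g) length(g$x), 0L)
  if (length(unique(ns)) != 1L)
    stop("graphs have heterogeneous node counts: ",
         paste(unique(ns), collapse = ", "))
  n <- ns[1]
  adj <- Matrix::bdiag(lapply(graphs, function(g)
    Matrix::Matrix(g$adjacency, sparse = TRUE)))
  x <- matrix(unlist(lapply(graphs, `[[`, "x")), ncol = 1)
  labels <- vapply(graphs, function(g)
    if (is.null(g$label)) NA_character_ else as.character(g$label), "")
  structure(list(adjacency = adj, x = x,
                 membership = rep(seq_along(graphs), each = n),
                 labels = labels, n_nodes = n,
                 nodes = graphs[[1]]$nodes),
            class = "graph_batch")
}

#' Recover individual graphs from a batch
#'
#' Inverse of [batch_graphs()].
#'
#' @param batch a `graph_batch`.
#' @return list of [feature_graph()]s.
#' @export
unbatch_graphs <- function(batch) {
  stopifnot(inherits(batch, "graph_batch"))
  n <- batch$n_nodes
  N <- length(batch$labels)
  lapply(seq_len(N), function(i) {
    idx <- ((i - 1) * n + 1):(i * n)
    x <- batch$x[idx, 1]
    names(x) <- batch$nodes
    feature_graph(x, as.matrix(batch$adjacency[idx, idx]),
                  label = if (is.na(batch$labels[i])) NULL
                          else batch$labels[i])
  })
}

#' Build one shared-adjacency graph per sample
#'
#' @param vectors assembled feature vectors ([assemble_feature_vectors()]
#'   output or any data frame with the node columns).
#' @param adjacency shared binary adjacency from [covariance_adjacency()].
#' @param nodes node columns to use (canonical order).
#' @return list of [feature_graph()]s.
#' @export
graphs_from_vectors <- function(vectors, adjacency,
                                nodes = feature_node_names()) {
  m <- feature_matrix(vectors, nodes)
  lapply(seq_len(nrow(m)), function(i)
    feature_graph(m[i, ], adjacency, label = vectors$group[i]))
}
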