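#' Renormalized graph adjacency
#'
#' Symmetric degree normalization \eqn{\tilde A = \tilde D^{-1/2} (\hat A +
#' I) \tilde D^{-1/2}} with self-loops added by default (the
#' renormalization trick); without self-loops an isolated node has zero
#' degree and no valid normalization.  All eigenvalues of the result lie in
#' `[-1, 1]` and block-diagonal structure is preserved.
#'
#' @param adjacency square symmetric binary matrix (dense or
#'   `Matrix` sparse), e.g. a batch adjacency.
#' @param add_self_loops add the identity before normalizing (default
#'   `TRUE`).
#' @return object of class `normalized_adjacency`: list with `matrix`
#'   (sparse symmetric) and `degrees`.
#' @export
normalize_adjacency <- function(adjacency, add_self_loops = TRUE) {
  A <- Matrix::Matrix(adjacency, sparse = TRUE)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (add_self_loops) A <- A + Matrix::Diagonal(nrow(A))
  d <- Matrix::rowSums(A)
  if (any(d == 0))
    stop("zero-degree node(s) with self-loops disabled: ",
         paste(head(which(d == 0), 10), collapse = ", "))
  Dinv <- Matrix::Diagonal(x = 1 / sqrt(d))
  structure(list(matrix = Dinv %*% A %*% Dinv, degrees = d),
            class = "normalized_adjacency")
}

#' GCN parameter initialization
#'
#' Two weight matrices: `W0` maps node attributes to the hidden layer, `W1`
#' the hidden layer to class scores.  Seeded uniform Glorot-style
#' initialization.
#'
#' @param input_dim attribute dimension per node (1 for scalar node
#'   attributes).
#' @param hidden hidden width (default 16).
#' @param classes number of classes (default 2).
#' @param seed integer seed.
#' @return list of class `gcn_params` with `W0`, `W1`.
#' @export
gcn_params_init <- function(input_dim = 1L, hidden = 16L, classes = 2L,
                            seed = 1) {
  glorot <- function(nin, nout) {
    a <- sqrt(6 / (nin + nout))
    matrix(runif(nin * nout, -a, a), nin, nout)
  }
  withr::with_seed(seed, {
    params <- list(W0 = glorot(input_dim, hidden),
                   W1 = glorot(hidden, classes))
  })
  structure(params, class = "gcn_params")
}

#' Two-layer GCN forward pass
#'
#' \deqn{Z = \mathrm{softmax}(\tilde A\, \mathrm{ReLU}(\tilde A X W^0) W^1)}
#' Softmax is applied row-wise (per node), so each row of `Z` is a
#' probability distribution over classes.
#'
#' @param X node attribute matrix (nodes x input_dim).
#' @param adj a [normalize_adjacency()] result (or plain matrix already
#'   normalized).
#' @param params a [gcn_params_init()]-shaped parameter list.
#' @param details also return hidden pre-activations (used by training).
#' @return nodes x classes matrix of probabilities, or (with
#'   `details = TRUE`) a list with `Z`, `H1`, `SX`, `logits`.
#' @export
gcn_forward <- function(X, adj, params, details = FALSE) {
  S <- if (inherits(adj, "normalized_adjacency")) adj$matrix else adj
  X <- as.matrix(X)
  if (nrow(X) != nrow(S))
    stop(sprintf("shape mismatch: X has %d rows, adjacency %d",
                 nrow(X), nrow(S)))
  if (ncol(X) != nrow(params$W0))
    stop(sprintf("shape mismatch: X has %d columns, W0 expects %d",
                 ncol(X), nrow(params$W0)))
  SX <- as.matrix(S %*% X)
  H1 <- pmax(SX %*% params$W0, 0)
  logits <- as.matrix(S %*% (H1 %*% params$W1))
  Z <- row_softmax(logits)
  if (details) list(Z = Z, H1 = H1, SX = SX, logits = logits) else Z
}

row_softmax <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Cross-entropy loss over labeled nodes
#'
#' \eqn{L = -\sum_{l \in y_L} \sum_f Y_{lf} \ln Z_{lf}}.  Zero predicted
#' probabilities at a labeled class are clamped at the machine epsilon so
#' the loss stays finite.
#'
#' @param Z node probability matrix.
#' @param Y one-hot label matrix with the same shape.
#' @param labeled indices of labeled rows (default: all rows).
#' @return non-negative scalar; 0 iff labeled predictions are exactly
#'   one-hot correct.
#' @export
cross_entropy_loss <- function(Z, Y, labeled = seq_len(nrow(Z))) {
  stopifnot(all(dim(Z) == dim(Y)), all(labeled >= 1),
            all(labeled <= nrow(Z)))
  Zl <- pmax(Z[labeled, , drop = FALSE], .Machine$double.eps)
  -sum(Y[labeled, , drop = FALSE] * log(Zl))
}

#' Training configuration
#'
#' @param learning_rate gradient step size (> 0, default 0.01).
#' @param epochs full-batch gradient steps (default 200).
#' @param seed integer seed governing weight initialization.
#' @param hidden hidden width (default 16).
#' @param pooling `"all_nodes"` (every node carries its graph's label in
#'   the loss; default) or `"mean_pool"` (loss on per-graph mean
#'   probabilities).
#' @param momentum heavy-ball momentum coefficient (default 0.9).
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 200, seed = 1,
                         hidden = 16L,
                         pooling = c("all_nodes", "mean_pool"),
                         momentum = 0.9) {
  pooling <- match.arg(pooling)
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 seed = seed, hidden = hidden, pooling = pooling,
                 momentum = momentum),
            class = "train_config")
}

#' Train the two-weight-matrix GCN
#'
#' Full-batch gradient descent with momentum on the cross-entropy loss,
#' using the analytic gradients of the two-layer model.  In the default
#' `all_nodes` mode every node of a labeled graph carries the graph's
#' one-hot label.  Deterministic given the config seed.
#'
#' @param batch a [batch_graphs()] result whose graphs carry labels.
#' @param adj [normalize_adjacency()] of `batch$adjacency`; computed here
#'   when `NULL`.
#' @param cfg a [train_config()].
#' @param classes class labels in order (default: sorted unique batch
#'   labels); the first class is "class 0", the tie-break winner.
#' @return list with `params`, `trace` (loss per epoch), `classes`, `cfg`.
#' @export
train_gcn <- function(batch, adj = NULL, cfg = train_config(),
                      classes = NULL) {
  stopifnot(inherits(batch, "graph_batch"))
  if (anyNA(batch$labels)) stop("training requires labels on every graph")
  if (is.null(adj)) adj <- normalize_adjacency(batch$adjacency)
  S <- adj$matrix
  classes <- classes %||% sort(unique(batch$labels))
  y <- match(batch$labels, classes)
  if (anyNA(y)) stop("labels outside the provided class set")
  F_ <- length(classes)
  n <- batch$n_nodes
  # one-hot targets: per node in all_nodes mode, per graph in mean_pool
  Y_node <- matrix(0, nrow(batch$x), F_)
  Y_node[cbind(seq_len(nrow(batch$x)), rep(y, each = n))] <- 1
  Y_graph <- matrix(0, length(y), F_)
  Y_graph[cbind(seq_along(y), y)] <- 1

  params <- gcn_params_init(ncol(batch$x), cfg$hidden, F_, seed = cfg$seed)
  v0 <- params$W0 * 0; v1 <- params$W1 * 0
  trace <- numeric(cfg$epochs)
  X <- batch$x
  SX <- as.matrix(S %*% X)  # constant across epochs
  memb <- batch$membership
  for (ep in seq_len(cfg$epochs)) {
    H1 <- pmax(SX %*% params$W0, 0)
    logits <- as.matrix(S %*% (H1 %*% params$W1))
    Z <- row_softmax(logits)
    # gradients are taken on the per-labeled-unit mean of the summed
    # cross-entropy, so the learning rate is insensitive to batch size
    if (cfg$pooling == "all_nodes") {
      loss <- cross_entropy_loss(Z, Y_node)
      dlogits <- (Z - Y_node) / nrow(Y_node)
    } else {
      P <- rowsum(Z, memb) / n
      loss <- cross_entropy_loss(P, Y_graph)
      dP <- -(Y_graph / pmax(P, .Machine$double.eps)) / nrow(Y_graph)
      # back through the mean-pool and the row softmax
      dZ <- dP[memb, , drop = FALSE] / n
      dlogits <- Z * (dZ - rowSums(dZ * Z))
    }
    if (!is.finite(loss)) stop("non-finite loss at epoch ", ep)
    trace[ep] <- loss
    G <- as.matrix(S %*% dlogits)          # S is symmetric
    dW1 <- t(H1) %*% G
    dH1 <- (G %*% t(params$W1)) * (H1 > 0)
    dW0 <- t(SX) %*% dH1
    v0 <- cfg$momentum * v0 - cfg$learning_rate * dW0
    v1 <- cfg$momentum * v1 - cfg$learning_rate * dW1
    params$W0 <- params$W0 + v0
    params$W1 <- params$W1 + v1
  }
  list(params = params, trace = trace, classes = classes, cfg = cfg)
}

#' Graph-level prediction by mean-pooling node probabilities
#'
#' Averages node class probabilities within each graph and takes the
#' argmax; ties go to the lower class index.
#'
#' @param Z node probability matrix.
#' @param membership graph index per row of `Z`.
#' @return list with `class_index` (1-based), `probabilities` (graphs x
#'   classes).
#' @export
predict_graphs <- function(Z, membership) {
  stopifnot(nrow(Z) == length(membership))
  counts <- table(membership)
  if (any(counts == 0)) stop("empty graph in membership index")
  P <- rowsum(as.matrix(Z), membership) / as.integer(counts)
  list(class_index = max.col(P, ties.method = "first"),
       probabilities = P)
}

#' Analytic GCN gradients (for verification)
#'
#' Gradients of the all-nodes-labeled cross-entropy loss with respect to
#' both weight matrices, as used inside [train_gcn()]; exposed so they can
#' be checked against finite differences.
#'
#' @inheritParams gcn_forward
#' @param Y one-hot node label matrix.
#' @return list with `dW0`, `dW1`, `loss`.
#' @export
gcn_gradients <- function(X, adj, params, Y) {
  S <- if (inherits(adj, "normalized_adjacency")) adj$matrix else adj
  fw <- gcn_forward(X, adj, params, details = TRUE)
  dlogits <- fw$Z - Y
  G <- as.matrix(S %*% dlogits)
  list(dW0 = t(fw$SX) %*% ((G %*% t(params$W1)) * (fw$H1 > 0)),
       dW1 = t(fw$H1) %*% G,
       loss = cross_entropy_loss(fw$Z, Y))
}

#' Serialize / restore GCN parameters
#'
#' Portable JSON archive: shapes, flat weight arrays and a config echo.
#'
#' @param fit a [train_gcn()] result.
#' @param path output file.
#' @export
save_gcn_params <- function(fit, path) {
  obj <- list(W0 = list(dim = dim(fit$params$W0),
                        values = as.numeric(fit$params$W0)),
              W1 = list(dim = dim(fit$params$W1),
                        values = as.numeric(fit$params$W1)),
              classes = fit$classes,
              config = unclass(fit$cfg))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_gcn_params
#' @export
load_gcn_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(params = structure(list(
         W0 = matrix(obj$W0$values, obj$W0$dim[1], obj$W0$dim[2]),
         W1 = matrix(obj$W1$values, obj$W1$dim[1], obj$W1$dim[2])),
         class = "gcn_params"),
       classes = obj$classes,
       cfg = obj$config)
}
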