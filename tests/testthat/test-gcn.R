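random_batch <- function(n_graphs = 4, n = 6, seed = 1, p_edge = 0.4,
                         labels = NULL) {
  withr::with_seed(seed, {
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- runif(n * (n - 1) / 2) < p_edge
    A <- A + t(A)
    graphs <- lapply(seq_len(n_graphs), function(i)
      feature_graph(rnorm(n), A,
                    label = if (is.null(labels)) c("A", "B")[i %% 2 + 1]
                            else labels[i]))
  })
  batch_graphs(graphs)
}

test_that("adjacency renormalization matches hand computations", {
  # empty graph with self-loops: every node self-normalizes to identity
  na <- normalize_adjacency(matrix(0, 3, 3))
  expect_equal(as.matrix(na$matrix), diag(3), ignore_attr = TRUE)
  # single edge: A + I = [[1,1],[1,1]], degrees 2 -> all entries 1/2
  edge <- matrix(c(0, 1, 1, 0), 2)
  na2 <- normalize_adjacency(edge)
  expect_equal(as.matrix(na2$matrix), matrix(0.5, 2, 2), ignore_attr = TRUE)
  expect_equal(unname(na2$degrees), c(2, 2))
  # isolated node without self-loops is an error naming the node
  expect_error(normalize_adjacency(matrix(0, 3, 3), add_self_loops = FALSE),
               "zero-degree")
})

test_that("renormalized adjacency is symmetric with spectral radius <= 1", {
  for (s in 1:5) {
    b <- random_batch(n_graphs = 3, n = 8, seed = s)
    S <- as.matrix(normalize_adjacency(b$adjacency)$matrix)
    expect_equal(S, t(S), tolerance = 1e-12)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-10)
  }
})

test_that("forward pass produces row-stochastic output", {
  b <- random_batch(seed = 2)
  adj <- normalize_adjacency(b$adjacency)
  params <- gcn_params_init(1, 8, 2, seed = 3)
  Z <- gcn_forward(b$x, adj, params)
  expect_true(all(Z >= 0))
  expect_equal(unname(rowSums(Z)), rep(1, nrow(Z)), tolerance = 1e-12)
  # zero weights -> uniform class probabilities
  zero <- list(W0 = matrix(0, 1, 8), W1 = matrix(0, 8, 2))
  Z0 <- gcn_forward(b$x, adj, zero)
  expect_equal(unname(Z0), matrix(0.5, nrow(Z0), 2))
  expect_error(gcn_forward(b$x[1:3, , drop = FALSE], adj, params),
               "shape mismatch")
})

test_that("forward pass is permutation-equivariant", {
  for (s in 1:5) {
    b <- random_batch(n_graphs = 2, n = 7, seed = s)
    S <- as.matrix(normalize_adjacency(b$adjacency)$matrix)
    params <- gcn_params_init(1, 5, 2, seed = s + 10)
    withr::with_seed(s + 20, perm <- sample(nrow(S)))
    P <- diag(nrow(S))[perm, ]
    Z <- gcn_forward(b$x, S, params)
    Zp <- gcn_forward(P %*% b$x, P %*% S %*% t(P), params)
    expect_equal(Zp, P %*% Z, tolerance = 1e-10)
  }
})

test_that("cross-entropy loss has its closed forms and matches a double-sum", {
  # perfect one-hot predictions -> 0
  Y <- diag(2)[c(1, 2, 1), ]
  expect_equal(cross_entropy_loss(Y, Y), 0, tolerance = 1e-12)
  # uniform 2-class predictions over 10 labeled nodes -> 10 log 2
  Zu <- matrix(0.5, 10, 2)
  Yu <- diag(2)[rep(1:2, 5), ]
  expect_equal(cross_entropy_loss(Zu, Yu), 10 * log(2), tolerance = 1e-12)
  # random case vs direct double sum
  withr::with_seed(31, {
    logits <- matrix(rnorm(24), 12, 2)
    Z <- exp(logits) / rowSums(exp(logits))
    y <- sample(1:2, 12, replace = TRUE)
  })
  Yr <- diag(2)[y, ]
  labeled <- c(2, 5, 7, 11)
  direct <- -sum(vapply(labeled, function(l)
    sum(Yr[l, ] * log(Z[l, ])), numeric(1)))
  expect_equal(cross_entropy_loss(Z, Yr, labeled), direct, tolerance = 1e-12)
  # zero probability at a labeled class is clamped, not -Inf
  Zbad <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_true(is.finite(cross_entropy_loss(Zbad, matrix(c(0, 1, 1, 0), 2,
                                                        byrow = TRUE))))
})

test_that("analytic gradients match central finite differences", {
  b <- random_batch(n_graphs = 3, n = 5, seed = 7)
  adj <- normalize_adjacency(b$adjacency)
  params <- gcn_params_init(1, 4, 2, seed = 8)
  y <- rep(1:2, length.out = nrow(b$x))
  Y <- diag(2)[y, ]
  gr <- gcn_gradients(b$x, adj, params, Y)
  eps <- 1e-6
  for (w in c("W0", "W1")) {
    G <- gr[[paste0("d", w)]]
    num <- G * 0
    for (i in seq_len(nrow(G))) for (j in seq_len(ncol(G))) {
      pp <- params; pp[[w]][i, j] <- pp[[w]][i, j] + eps
      pm <- params; pm[[w]][i, j] <- pm[[w]][i, j] - eps
      lp <- cross_entropy_loss(gcn_forward(b$x, adj, pp), Y)
      lm <- cross_entropy_loss(gcn_forward(b$x, adj, pm), Y)
      num[i, j] <- (lp - lm) / (2 * eps)
    }
    denom <- pmax(abs(num), abs(G), 1e-8)
    expect_lt(max(abs(num - G) / denom), 1e-5)
  }
})

test_that("block-diagonal batching keeps graphs independent", {
  b1 <- random_batch(n_graphs = 3, n = 6, seed = 9)
  graphs <- unbatch_graphs(b1)
  params <- gcn_params_init(1, 4, 2, seed = 10)
  Z_all <- gcn_forward(b1$x, normalize_adjacency(b1$adjacency), params)
  # replace the other graphs entirely; graph 2's rows must not move
  withr::with_seed(99, other <- feature_graph(rnorm(6) * 10,
                                              graphs[[1]]$adjacency))
  b2 <- batch_graphs(list(other, graphs[[2]], other))
  Z_mix <- gcn_forward(b2$x, normalize_adjacency(b2$adjacency), params)
  expect_equal(Z_mix[7:12, ], Z_all[7:12, ], tolerance = 1e-12)
})

test_that("training is deterministic, descends, and fits separable graphs", {
  A <- matrix(1, 5, 5) - diag(5)
  withr::with_seed(12, graphs <- lapply(1:20, function(i) {
    label <- c("neg", "pos")[i %% 2 + 1]
    margin <- if (label == "pos") 1 else -1
    feature_graph(margin + rnorm(5, sd = 0.1), A, label)
  }))
  batch <- batch_graphs(graphs)
  cfg <- train_config(epochs = 200, seed = 4)
  fit1 <- train_gcn(batch, cfg = cfg)
  fit2 <- train_gcn(batch, cfg = cfg)
  expect_identical(fit1$params, fit2$params)
  expect_length(fit1$trace, 200)
  expect_lte(fit1$trace[200], fit1$trace[1])
  pred <- predict_graphs(gcn_forward(batch$x,
                                     normalize_adjacency(batch$adjacency),
                                     fit1$params),
                         batch$membership)
  expect_equal(fit1$classes[pred$class_index],
               vapply(graphs, `[[`, "", "label"))
  expect_error(train_gcn(batch_graphs(list(feature_graph(rnorm(5), A)))),
               "labels")
})

test_that("loss decreases on every seed of a 10-seed sweep", {
  for (s in 1:10) {
    b <- random_batch(n_graphs = 10, n = 6, seed = s)
    fit <- train_gcn(b, cfg = train_config(epochs = 50, seed = s))
    expect_lte(tail(fit$trace, 1), fit$trace[1])
  }
})

test_that("mean-pool readout matches manual per-graph averaging", {
  withr::with_seed(41, Z <- matrix(runif(24), 12, 2))
  Z <- Z / rowSums(Z)
  memb <- rep(1:3, each = 4)
  pred <- predict_graphs(Z, memb)
  manual <- t(vapply(1:3, function(g) colMeans(Z[memb == g, ]), numeric(2)))
  expect_equal(unname(as.matrix(pred$probabilities)), manual)
  expect_equal(pred$class_index, unname(apply(manual, 1, which.max)))
  # unanimous nodes and ties
  sure <- matrix(rep(c(0.9, 0.1), each = 3), 3)
  expect_equal(predict_graphs(sure, rep(1, 3))$class_index, 1L)
  tie <- matrix(0.5, 2, 2)
  expect_equal(predict_graphs(tie, c(1, 1))$class_index, 1L)  # lower class
})

test_that("mean-pool training mode also learns separable graphs", {
  A <- matrix(1, 4, 4) - diag(4)
  withr::with_seed(13, graphs <- lapply(1:16, function(i) {
    label <- c("neg", "pos")[i %% 2 + 1]
    feature_graph((if (label == "pos") 1 else -1) + rnorm(4, sd = 0.1),
                  A, label)
  }))
  batch <- batch_graphs(graphs)
  fit <- train_gcn(batch, cfg = train_config(epochs = 300, seed = 2,
                                             pooling = "mean_pool"))
  pred <- predict_graphs(gcn_forward(batch$x,
                                     normalize_adjacency(batch$adjacency),
                                     fit$params),
                         batch$membership)
  expect_equal(mean(fit$classes[pred$class_index] ==
                      vapply(graphs, `[[`, "", "label")), 1)
})

test_that("parameters survive a JSON round-trip", {
  b <- random_batch(seed = 3)
  fit <- train_gcn(b, cfg = train_config(epochs = 5, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  save_gcn_params(fit, path)
  back <- load_gcn_params(path)
  expect_equal(back$params$W0, fit$params$W0)
  expect_equal(back$params$W1, fit$params$W1)
  expect_equal(back$classes, fit$classes)
})
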