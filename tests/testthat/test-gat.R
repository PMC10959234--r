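test_that("linear transform is plain matrix multiplication", {
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(linear_transform(X, diag(3)), X)
  E <- diag(3)[c(1, 3), ]  # one-hot rows pick rows of W
  W <- matrix(rnorm(6), 3, 2)
  expect_equal(linear_transform(E, W), W[c(1, 3), ])
  oracle <- matrix(0, 4, 2)
  for (i in 1:4) for (j in 1:2)
    oracle[i, j] <- sum(X[i, ] * W[, j])
  expect_equal(linear_transform(X, W), oracle, tolerance = 1e-12)
  expect_error(linear_transform(X, matrix(0, 2, 2)), "dimensions")
})

test_that("affinity scores follow the LeakyReLU of concatenated features", {
  H <- rbind(c(1, 0), c(0, 1), c(1, 1))
  edges <- cbind(i = c(1, 2, 2, 3), j = c(2, 1, 3, 3))
  expect_equal(affinity_scores(H, rep(0, 4), edges), rep(0, 4))
  a <- c(0.5, -1, 2, 0.3)
  e <- affinity_scores(H, a, edges, leaky_slope = 0.2)
  for (r in 1:4) {
    pre <- sum(a * c(H[edges[r, 1], ], H[edges[r, 2], ]))
    expect_equal(e[r], if (pre > 0) pre else 0.2 * pre, tolerance = 1e-12)
  }
  expect_error(affinity_scores(H, rep(0, 3), edges), "length")
})

test_that("attention weights are a per-neighborhood softmax", {
  edges <- cbind(i = rep(1, 4), j = 1:4)
  expect_equal(attention_weights(rep(0.7, 4), edges), rep(0.25, 4))
  e2 <- c(0, log(2))
  a2 <- attention_weights(e2, cbind(i = c(1, 1), j = c(1, 2)))
  expect_equal(a2, c(1 / 3, 2 / 3), tolerance = 1e-12)
  set.seed(3)
  edges3 <- cbind(i = rep(1:3, each = 3), j = rep(1:3, 3))
  a3 <- attention_weights(rnorm(9), edges3)
  expect_equal(as.vector(rowsum(a3, edges3[, 1])), rep(1, 3),
               tolerance = 1e-9)
})

test_that("feature updates are attention-weighted neighbor sums", {
  H <- rbind(c(1, 2), c(3, 4), c(5, 6))
  # single neighbor: copy
  out <- update_features(H, 1, cbind(i = 1, j = 2))
  expect_equal(out[1, ], H[2, ])
  # uniform weights over identical features: that common vector
  Hc <- rbind(c(2, 2), c(2, 2), c(2, 2))
  out2 <- update_features(Hc, rep(1 / 3, 3), cbind(i = rep(1, 3), j = 1:3))
  expect_equal(out2[1, ], c(2, 2))
  # 3-node toy with hand-set alpha
  edges <- cbind(i = c(1, 1, 2, 3), j = c(2, 3, 2, 1))
  alpha <- c(0.3, 0.7, 1, 1)
  out3 <- update_features(H, alpha, edges)
  expect_equal(out3[1, ], 0.3 * H[2, ] + 0.7 * H[3, ], tolerance = 1e-12)
  expect_equal(out3[2, ], H[2, ])
  expect_equal(out3[3, ], H[1, ])
})

test_that("multi-head combination averages or concatenates", {
  set.seed(5)
  hs <- lapply(1:3, function(i) matrix(rnorm(6), 3, 2))
  avg <- multi_head_combine(hs, "average")
  oracle <- (hs[[1]] + hs[[2]] + hs[[3]]) / 3
  expect_equal(avg, oracle, tolerance = 1e-12)
  expect_equal(multi_head_combine(hs[1], "average"), hs[[1]])
  same <- multi_head_combine(list(hs[[1]], hs[[1]]), "average")
  expect_equal(same, hs[[1]])
  cc <- multi_head_combine(hs, "concatenate")
  expect_equal(dim(cc), c(3, 6))
  expect_error(multi_head_combine(list(hs[[1]], matrix(0, 2, 2)),
                                  "average"), "shapes")
})

test_that("zero attention vector reduces to unweighted neighborhood means", {
  set.seed(8)
  L <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(paste0("c", 1:6), NULL))
  g <- build_knn_graph(L, K = 2)
  edges <- scMultiView:::gat_edges(g)
  H <- matrix(rnorm(12), 6, 2)
  e <- affinity_scores(H, rep(0, 4), edges)
  alpha <- attention_weights(e, edges)
  out <- update_features(H, alpha, edges)
  for (i in 1:6) {
    nb <- edges[edges[, 1] == i, 2]
    expect_equal(out[i, ], colMeans(H[nb, , drop = FALSE]),
                 tolerance = 1e-10)
  }
})

test_that("GAT forward is equivariant to node permutation", {
  set.seed(10)
  L <- matrix(rnorm(8 * 4), 8, 4, dimnames = list(paste0("c", 1:8), NULL))
  g <- build_knn_graph(L, K = 3)
  cfg <- gat_config(layers = 2, heads = 2, hidden_dim = 4, seed = 1)
  params <- scMultiView:::with_seed(1, scMultiView:::gat_init(cfg, 4, 3))
  edges <- scMultiView:::gat_edges(g)
  base <- scMultiView:::gat_forward(L, edges, params, cfg)$out
  perm <- sample(8)
  inv <- order(perm)
  g2 <- g
  g2$edges$u <- inv[g$edges$u]; g2$edges$v <- inv[g$edges$v]
  edges2 <- scMultiView:::gat_edges(g2)
  out2 <- scMultiView:::gat_forward(L[perm, , drop = FALSE], edges2,
                                    params, cfg)$out
  expect_equal(out2, base[perm, , drop = FALSE], tolerance = 1e-10)
})

test_that("GAT separates well-separated latent blobs wired by KNN", {
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    n <- 60
    labels <- rep(c("p", "q"), each = n / 2)
    # blob means differ in direction, not by a constant offset, so both
    # Exp-Mah components (correlation and Manhattan) separate them
    shift <- rep(c(2.5, -2.5), 2)
    L <- rbind(matrix(rnorm(n / 2 * 4, mean = 0), n / 2, 4),
               sweep(matrix(rnorm(n / 2 * 4), n / 2, 4), 2, shift, `+`))
    rownames(L) <- paste0("c", 1:n)
    g <- build_knn_graph(L, K = 5)
    split <- holdout_split(labels, 0.3, seed = s)
    fit <- train_gat(g, L, labels, split,
                     gat_config(layers = 2, heads = 2, hidden_dim = 8,
                                epochs = 80, seed = s))
    expect_equal(unname(rowSums(fit$probs$probs)), rep(1, n), tolerance = 1e-6)
    if (fit$perf >= 0.95) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("GAT training is seed-deterministic and rejects one class", {
  set.seed(2)
  L <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(paste0("c", 1:30),
                                                    NULL))
  labels <- rep(c("a", "b", "c"), 10)
  g <- build_knn_graph(L, K = 4)
  split <- holdout_split(labels, 0.3, seed = 2)
  cfg <- gat_config(layers = 2, heads = 2, hidden_dim = 4, epochs = 30,
                    seed = 6)
  f1 <- train_gat(g, L, labels, split, cfg)
  f2 <- train_gat(g, L, labels, split, cfg)
  expect_identical(f1$perf, f2$perf)
  expect_error(train_gat(g, L, rep("a", 30), split, cfg), "classes")
})
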