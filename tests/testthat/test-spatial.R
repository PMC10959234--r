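test_that("cosine similarity matches its definition", {
  x <- c(1, 2, 3)
  expect_equal(cosine_similarity(x, x), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20)
  num <- 0; na <- 0; nb <- 0
  for (i in 1:20) {
    num <- num + a[i] * b[i]; na <- na + a[i]^2; nb <- nb + b[i]^2
  }
  expect_equal(cosine_similarity(a, b), num / sqrt(na * nb),
               tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("co-expression network links duplicates and drops orthogonals", {
  v <- c(1, 0, 2, 0, 3)
  X <- cbind(g1 = v, g2 = v, g3 = c(0, 1, 0, 0, 0))
  norm <- structure(list(values = X, gene_ids = colnames(X),
                         cell_ids = paste0("c", 1:5), labels = NULL),
                    class = "NormalizedMatrix")
  net <- build_coexpression_network(norm, 2)
  e <- net$edges
  expect_equal(e$weight[e$u == "g1" & e$v == "g2"], 1)
  # three mutually orthogonal genes yield no positive-cosine edges
  O <- structure(list(values = diag(3), gene_ids = paste0("g", 1:3),
                      cell_ids = paste0("c", 1:3), labels = NULL),
                 class = "NormalizedMatrix")
  expect_equal(nrow(build_coexpression_network(O, 2)$edges), 0)
})

test_that("network edges are symmetric and block structure is ranked", {
  set.seed(6)
  f1 <- rnorm(40); f2 <- rnorm(40)
  X <- cbind(sapply(1:4, function(i) f1 + rnorm(40, sd = 0.3)),
             sapply(1:4, function(i) f2 + rnorm(40, sd = 0.3)))
  X <- abs(X)
  colnames(X) <- paste0("g", 1:8)
  norm <- structure(list(values = X, gene_ids = colnames(X),
                         cell_ids = paste0("c", 1:40), labels = NULL),
                    class = "NormalizedMatrix")
  net <- build_coexpression_network(norm, 4)
  for (r in seq_len(nrow(net$edges))) {
    u <- net$edges$u[r]; v <- net$edges$v[r]
    expect_true(v %in% net$adjacency[[u]]$ids)
    expect_true(u %in% net$adjacency[[v]]$ids)
    expect_equal(net$adjacency[[u]]$w[net$adjacency[[u]]$ids == v],
                 net$adjacency[[v]]$w[net$adjacency[[v]]$ids == u])
  }
  blk <- function(g) if (g %in% paste0("g", 1:4)) 1 else 2
  w_within <- net$edges$weight[mapply(function(u, v) blk(u) == blk(v),
                                      net$edges$u, net$edges$v)]
  w_between <- net$edges$weight[mapply(function(u, v) blk(u) != blk(v),
                                       net$edges$u, net$edges$v)]
  if (length(w_between) > 0)
    expect_gt(min(w_within), max(w_between))
  expect_warning(
    build_coexpression_network(structure(
      list(values = cbind(g1 = rep(2, 4), g2 = c(1, 2, 1, 3)),
           gene_ids = c("g1", "g2"), cell_ids = paste0("c", 1:4),
           labels = NULL), class = "NormalizedMatrix"), 1),
    "constant")
})

test_that("walk bias factors follow the distance cases", {
  expect_equal(transition_alpha(0, p = 4, q = 0.25), 0.25)
  expect_equal(transition_alpha(1, p = 4, q = 0.25), 1)
  expect_equal(transition_alpha(2, p = 4, q = 0.25), 4)
})

test_that("transition distributions normalize and reduce to simple walks", {
  # triangle a-b-c plus pendant d attached to b
  net <- toy_network(data.frame(u = c("a", "a", "b", "b"),
                                v = c("b", "c", "c", "d"),
                                weight = 1))
  cfg1 <- random_walk_config(p = 1, q = 1, seed = 1)
  pr <- transition_probs(net, NULL, "b", cfg1)
  expect_equal(unname(pr), rep(1 / 3, 3))
  cfg2 <- random_walk_config(p = 4, q = 0.25, seed = 1)
  pr2 <- transition_probs(net, "a", "b", cfg2)
  # enumeration oracle: neighbors of b are a (prev, d=0), c (adj to a,
  # d=1), d (d=2); unnormalized 1/4, 1, 4
  oracle <- c(a = 0.25, c = 1, d = 4)
  oracle <- oracle / sum(oracle)
  expect_equal(pr2[names(oracle)], oracle, tolerance = 1e-12)
  expect_equal(sum(pr2), 1, tolerance = 1e-9)
  expect_error(transition_probs(toy_network(
    data.frame(u = "a", v = "b", weight = 1), nodes = c("a", "b", "z")),
    NULL, "z", cfg1), "no neighbors")
})

test_that("raising p drains return probability mass", {
  net <- toy_network(data.frame(u = c("a", "b", "b"),
                                v = c("b", "c", "d"), weight = 1))
  back_mass <- vapply(c(0.5, 1, 2, 8), function(p)
    transition_probs(net, "a", "b",
                     random_walk_config(p = p, q = 1, seed = 1))[["a"]],
    numeric(1))
  expect_true(all(diff(back_mass) < 0))
})

test_that("walks respect edges and are seed-deterministic", {
  path <- toy_network(data.frame(u = "a", v = "b", weight = 1))
  cfg <- random_walk_config(walk_length = 3, walks_per_node = 2, seed = 2)
  walks <- generate_walks(path, cfg)
  expect_length(walks, 4)
  for (w in walks) expect_true(all(w %in% c("a", "b")) &&
                                 all(w[-1] != w[-3]))
  walks2 <- generate_walks(path, cfg)
  expect_identical(walks, walks2)
  lone <- toy_network(data.frame(u = "a", v = "b", weight = 1),
                      nodes = c("a", "b", "iso"))
  expect_warning(generate_walks(lone, cfg), "isolated")
})

test_that("empirical step frequencies match the transition law", {
  net <- toy_network(data.frame(u = c("a", "a", "b", "b"),
                                v = c("b", "c", "c", "d"),
                                weight = c(1, 0.5, 1, 2)))
  cfg <- random_walk_config(p = 4, q = 0.25, walk_length = 3,
                            walks_per_node = 2500, seed = 11)
  walks <- generate_walks(net, cfg)
  # condition on the walk history (a, b) and look at the third vertex
  third <- vapply(walks[vapply(walks, function(w)
    w[1] == "a" && w[2] == "b", logical(1))], `[[`, character(1), 3L)
  pr <- transition_probs(net, "a", "b", cfg)
  n <- length(third)
  for (x in names(pr)) {
    phat <- mean(third == x)
    sigma <- sqrt(pr[[x]] * (1 - pr[[x]]) / n)
    expect_lt(abs(phat - pr[[x]]), 3 * sigma + 1e-9)
  }
})

test_that("node embeddings separate disconnected cliques", {
  cl1 <- paste0("a", 1:4); cl2 <- paste0("b", 1:4)
  mk_clique <- function(ids) {
    g <- expand.grid(u = ids, v = ids, stringsAsFactors = FALSE)
    g <- g[g$u < g$v, ]; g$weight <- 1; g
  }
  net <- toy_network(rbind(mk_clique(cl1), mk_clique(cl2)))
  hits <- 0
  for (s in 1:10) {
    walks <- generate_walks(net, random_walk_config(walk_length = 8,
                                                    walks_per_node = 4,
                                                    seed = s))
    tab <- train_node_embeddings(walks, dim = 8, window = 2, epochs = 40,
                                 learning_rate = 0.2, seed = s)
    V <- tab$vectors / sqrt(rowSums(tab$vectors^2))
    C <- tcrossprod(V)
    i1 <- match(cl1, rownames(V)); i2 <- match(cl2, rownames(V))
    within <- mean(c(C[i1, i1][upper.tri(C[i1, i1])],
                     C[i2, i2][upper.tri(C[i2, i2])]))
    if (within > mean(C[i1, i2])) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("unwalked genes get zero vectors and bad inputs error", {
  walks <- list(c("a", "b", "a"))
  tab <- train_node_embeddings(walks, dim = 4, window = 1, epochs = 2,
                               seed = 1, vocabulary = c("a", "b", "iso"))
  expect_equal(unname(tab$vectors["iso", ]), rep(0, 4))
  expect_true(any(tab$vectors["a", ] != 0))
  expect_error(train_node_embeddings(list(), dim = 4, window = 1), "empty")
  expect_error(train_node_embeddings(walks, dim = 4, window = 0), "window")
})

test_that("networks round-trip through the edge-list file", {
  d <- tiny_dataset(seed = 3, n_cells = 30, n_genes = 12)
  net <- build_coexpression_network(log_normalize(d$raw), 4)
  path <- withr::local_tempfile()
  write_coexpression_network(net, path)
  back <- read_coexpression_network(path, nodes = net$nodes)
  expect_equal(back$edges$weight, net$edges$weight, tolerance = 1e-12)
  expect_identical(back$nodes, net$nodes)
})
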