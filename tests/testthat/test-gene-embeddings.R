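test_that("corpus pairs mirror co-expression neighborhoods", {
  net <- toy_network(data.frame(u = "g1", v = "g2", weight = 0.9))
  binned <- list(gene_ids = c("g1", "g2"))
  corpus <- build_corpus(binned, net, max_pairs_per_gene = 5, seed = 1)
  expect_s3_class(corpus, "GeneCorpus")
  expect_equal(nrow(corpus$pairs), 2)
  expect_setequal(paste(corpus$pairs[, 1], corpus$pairs[, 2]),
                  c("1 2", "2 1"))
})

test_that("context subsampling caps pairs per gene deterministically", {
  star <- data.frame(u = "hub", v = paste0("leaf", 1:5), weight = 0.5)
  net <- toy_network(star)
  binned <- list(gene_ids = net$nodes)
  c1 <- build_corpus(binned, net, max_pairs_per_gene = 3, seed = 7)
  c2 <- build_corpus(binned, net, max_pairs_per_gene = 3, seed = 7)
  hub_tok <- c1$vocabulary[["hub"]]
  expect_equal(sum(c1$pairs[, 1] == hub_tok), 3)
  expect_identical(c1$pairs, c2$pairs)
})

test_that("skip-gram softmax matches the hand formula and normalizes", {
  tab <- scMultiView:::new_embedding_table(matrix(1, 4, 3),
                                           paste0("g", 1:4))
  expect_equal(skipgram_prob("g1", "g2", tab), 0.25)
  set.seed(3)
  tab2 <- random_table(paste0("g", 1:6), 4, seed = 3)
  total <- sum(vapply(paste0("g", 1:6), function(c)
    skipgram_prob("g2", c, tab2), numeric(1)))
  expect_equal(total, 1, tolerance = 1e-9)
  # 3-gene hand-computed softmax
  V <- rbind(c(1, 0), c(0, 1), c(1, 1))
  tab3 <- scMultiView:::new_embedding_table(V, c("a", "b", "c"))
  s <- exp(c(V[1, ] %*% V[1, ], V[2, ] %*% V[1, ], V[3, ] %*% V[1, ]))
  expect_equal(skipgram_prob("a", "c", tab3), s[3] / sum(s),
               tolerance = 1e-12)
  expect_error(skipgram_prob("a", "zz", tab3), "unknown")
})

test_that("skip-gram training recovers planted co-expression blocks", {
  blocks <- list(paste0("a", 1:4), paste0("b", 1:4))
  edges <- do.call(rbind, lapply(blocks, function(bl)
    expand.grid(u = bl, v = bl, stringsAsFactors = FALSE)))
  edges <- edges[edges$u < edges$v, ]
  edges$weight <- 0.8
  net <- toy_network(edges)
  binned <- list(gene_ids = net$nodes)
  hits <- 0
  for (s in 1:10) {
    corpus <- build_corpus(binned, net, max_pairs_per_gene = 6, seed = s)
    tab <- train_skipgram(corpus, dim = 8, epochs = 40, negatives = 4,
                          learning_rate = 0.2, seed = s)
    V <- tab$vectors / sqrt(rowSums(tab$vectors^2))
    C <- tcrossprod(V)
    ix1 <- match(blocks[[1]], rownames(V))
    ix2 <- match(blocks[[2]], rownames(V))
    within <- mean(c(C[ix1, ix1][upper.tri(C[ix1, ix1])],
                     C[ix2, ix2][upper.tri(C[ix2, ix2])]))
    between <- mean(C[ix1, ix2])
    if (within > between) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("skip-gram training is seed-deterministic and order-invariant", {
  net <- toy_network(data.frame(u = c("g1", "g2", "g1"),
                                v = c("g2", "g3", "g3"),
                                weight = c(0.9, 0.8, 0.7)))
  binned <- list(gene_ids = c("g1", "g2", "g3"))
  corpus <- build_corpus(binned, net, max_pairs_per_gene = 5, seed = 2)
  t1 <- train_skipgram(corpus, dim = 4, epochs = 3, seed = 5)
  t2 <- train_skipgram(corpus, dim = 4, epochs = 3, seed = 5)
  expect_identical(t1$vectors, t2$vectors)
  shuffled <- corpus
  shuffled$pairs <- corpus$pairs[rev(seq_len(nrow(corpus$pairs))), ]
  t3 <- train_skipgram(shuffled, dim = 4, epochs = 3, seed = 5)
  expect_identical(t1$vectors, t3$vectors)
  expect_error(train_skipgram(corpus, dim = 4, epochs = 0), "epochs")
})

test_that("skip-gram loss trace is non-increasing within tolerance", {
  d <- tiny_dataset(seed = 2, n_cells = 50, n_genes = 30)
  norm <- log_normalize(d$raw)
  binned <- bin_expression(norm, 5)
  net <- build_coexpression_network(norm, 5)
  corpus <- build_corpus(binned, net, 10, seed = 1)
  tab <- train_skipgram(corpus, dim = 8, epochs = 6, seed = 1)
  tr <- attr(tab, "loss_trace")
  expect_true(all(diff(tr) <= 0.05 * tr[-length(tr)]))
})

test_that("embedding tables round-trip through the text dialect", {
  tab <- random_table(c("g1", "g2", "g9"), 5, seed = 4)
  path <- withr::local_tempfile()
  write_embedding_table(tab, path)
  back <- read_embedding_table(path)
  expect_equal(back$vectors, tab$vectors, tolerance = 1e-12)
})

test_that("token sequences sum the three embedding streams elementwise", {
  genes <- c("g1", "g2", "g3")
  tok <- matrix(c(0L, 2L, 1L, 1L, 0L, 3L), 2, 3, byrow = TRUE,
                dimnames = list(NULL, genes))
  binned <- list(tokens = tok, gene_ids = genes, n_bins = 4L,
                 cell_ids = c("c1", "c2"), labels = NULL)
  g_tab <- random_table(genes, 4, seed = 1)
  e_tab <- random_table(as.character(0:3), 4, seed = 2)
  s_tab <- random_table(genes, 4, seed = 3)
  seqs <- assemble_token_sequences(binned, g_tab, e_tab, s_tab)
  for (cell in 1:2) for (gi in 1:3) {
    oracle <- g_tab$vectors[gi, ] + s_tab$vectors[gi, ] +
      e_tab$vectors[tok[cell, gi] + 1L, ]
    expect_equal(as.vector(seqs$embeddings[cell, gi, ]), unname(oracle))
  }
  # zero spatial table = gene + expression only; NULL behaves the same
  z_tab <- scMultiView:::new_embedding_table(matrix(0, 3, 4), genes)
  s0 <- assemble_token_sequences(binned, g_tab, e_tab, z_tab)
  s_null <- assemble_token_sequences(binned, g_tab, e_tab, NULL)
  expect_equal(s0$embeddings, s_null$embeddings)
})

test_that("sequence assembly is linear in each table", {
  genes <- c("g1", "g2")
  tok <- matrix(c(1L, 2L), 1, 2, dimnames = list(NULL, genes))
  binned <- list(tokens = tok, gene_ids = genes, n_bins = 3L,
                 cell_ids = "c1", labels = NULL)
  g_tab <- random_table(genes, 3, seed = 5)
  e_tab <- random_table(as.character(0:2), 3, seed = 6)
  s_tab <- random_table(genes, 3, seed = 7)
  base <- assemble_token_sequences(binned, g_tab, e_tab, s_tab)$embeddings
  s2 <- s_tab; s2$vectors <- 2 * s2$vectors
  doubled <- assemble_token_sequences(binned, g_tab, e_tab, s2)$embeddings
  spatial_part <- doubled - base
  only_spatial <- assemble_token_sequences(
    binned, scMultiView:::new_embedding_table(matrix(0, 2, 3), genes),
    scMultiView:::new_embedding_table(matrix(0, 3, 3), as.character(0:2)),
    s_tab)$embeddings
  expect_equal(spatial_part, only_spatial)
  bad <- random_table(genes, 5, seed = 8)
  expect_error(assemble_token_sequences(binned, g_tab, e_tab, bad),
               "dimension mismatch")
})
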