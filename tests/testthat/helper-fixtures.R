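# Shared fixtures, generated in code at test time.

# Small labeled dataset for unit tests (weaker settings than the
# desk-scale defaults; used where only plumbing is under test).
tiny_dataset <- function(seed = 1, n_cells = 80, n_genes = 40) {
  simulate_counts(synthetic_config(n_cells = n_cells, n_genes = n_genes,
                                   module_count = 2, module_size = 5,
                                   seed = seed))
}

# Random embedding table over the given ids.
random_table <- function(ids, dim, seed = 1, sd = 1) {
  set.seed(seed)
  scMultiView:::new_embedding_table(
    matrix(rnorm(length(ids) * dim, sd = sd), length(ids), dim), ids)
}

# Hand-built co-expression network from an explicit edge list.
toy_network <- function(edges_df, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edges_df$u, edges_df$v)))
  adjacency <- stats::setNames(
    lapply(nodes, function(g) list(ids = character(0), w = numeric(0))),
    nodes)
  for (r in seq_len(nrow(edges_df))) {
    u <- edges_df$u[r]; v <- edges_df$v[r]; w <- edges_df$weight[r]
    adjacency[[u]]$ids <- c(adjacency[[u]]$ids, v)
    adjacency[[u]]$w <- c(adjacency[[u]]$w, w)
    adjacency[[v]]$ids <- c(adjacency[[v]]$ids, u)
    adjacency[[v]]$w <- c(adjacency[[v]]$w, w)
  }
  structure(list(nodes = nodes, edges = edges_df, adjacency = adjacency),
            class = "CoexpressionNetwork")
}

`%||%` <- scMultiView:::`%||%`

# Pipeline config shrunk for fast smoke/replicate tests.
tiny_pipeline_config <- function(seed = 1, ...) {
  pipeline_config(
    seed = seed,
    simulate = synthetic_config(n_cells = 90, n_genes = 60,
                                module_count = 2, module_size = 5,
                                seed = seed),
    embedding_dim = 8, coexpr_neighbors = 5,
    walk = list(p = 2, q = 0.5, walk_length = 10, walks_per_node = 2),
    skipgram = list(epochs = 2, negatives = 3, learning_rate = 0.05,
                    max_pairs_per_gene = 10, window = 2, node_epochs = 2),
    vae = list(hidden_dim = 32, latent_dim = 8, alpha_vae = 0.99,
               epochs = 150, learning_rate = 3e-3),
    graph = list(K = 8, alpha = 0.25, prune_quantile = 0),
    performer = list(layers = 1, heads = 2, feature_count = 16,
                     hidden_dim = 16, epochs = 15, learning_rate = 5e-3,
                     batch_size = 72),
    gat = list(layers = 2, heads = 2, hidden_dim = 8, epochs = 60,
               learning_rate = 5e-3),
    ...)
}
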