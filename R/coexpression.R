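# Gene co-expression network and "spatial" gene embeddings learned from it
# by biased (node2vec-style) random walks plus skip-gram.

#' Cosine similarity between two expression vectors
#'
#' @param x,y numeric vectors of equal length >= 2 (a gene's expression
#'   across cells); neither may be all-zero.
#' @return `x . y / (||x|| ||y||)` in `[-1, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 2) stop("vectors must have length >= 2")
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("undefined similarity for a zero vector")
  sum(x * y) / (nx * ny)
}

#' Build the gene co-expression network
#'
#' Connects each gene to its `neighbors_per_gene` highest-cosine partners
#' (union over genes, symmetrized); edge weight is the cosine similarity and
#' non-positive-cosine edges are discarded. Constant genes are excluded
#' with a warning.
#'
#' @param norm a `NormalizedMatrix`.
#' @param neighbors_per_gene per-gene neighbor budget (default 10).
#' @return A list of class `CoexpressionNetwork` with `nodes`, an `edges`
#'   data frame (`u`, `v`, `weight`, `u < v`) and an `adjacency` list.
#' @export
build_coexpression_network <- function(norm, neighbors_per_gene = 10) {
  X <- norm$values
  if (ncol(X) < 2) stop("need at least 2 genes")
  sds <- apply(X, 2L, function(v) max(v) - min(v))
  keep <- sds > 0 & colSums(abs(X)) > 0
  if (any(!keep))
    warning(sum(!keep), " constant gene(s) excluded from the network")
  X <- X[, keep, drop = FALSE]
  genes <- norm$gene_ids[keep]
  Xn <- sweep(X, 2L, sqrt(colSums(X^2)), `/`)
  C <- crossprod(Xn)
  diag(C) <- -Inf
  g <- length(genes)
  m <- min(neighbors_per_gene, g - 1L)
  pair_u <- integer(0); pair_v <- integer(0)
  for (i in seq_len(g)) {
    top <- order(C[, i], decreasing = TRUE)[seq_len(m)]
    top <- top[C[top, i] > 0]
    pair_u <- c(pair_u, rep(i, length(top)))
    pair_v <- c(pair_v, top)
  }
  if (length(pair_u)) {
    a <- pmin(pair_u, pair_v)
    b <- pmax(pair_u, pair_v)
    key <- paste(a, b)
    dup <- duplicated(key)
    a <- a[!dup]; b <- b[!dup]
    edges <- data.frame(u = genes[a], v = genes[b],
                        weight = C[cbind(a, b)],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(u = character(0), v = character(0),
                        weight = numeric(0))
  }
  adjacency <- stats::setNames(
    lapply(genes, function(gn) list(ids = character(0), w = numeric(0))),
    genes)
  for (r in seq_len(nrow(edges))) {
    u <- edges$u[r]; v <- edges$v[r]; w <- edges$weight[r]
    adjacency[[u]]$ids <- c(adjacency[[u]]$ids, v)
    adjacency[[u]]$w <- c(adjacency[[u]]$w, w)
    adjacency[[v]]$ids <- c(adjacency[[v]]$ids, u)
    adjacency[[v]]$w <- c(adjacency[[v]]$w, w)
  }
  structure(list(nodes = genes, edges = edges, adjacency = adjacency),
            class = "CoexpressionNetwork")
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat("CoexpressionNetwork:", length(x$nodes), "genes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Persist / load a co-expression network as a 3-column edge list
#' @param net a `CoexpressionNetwork`.
#' @param path tab-separated file `gene_u  gene_v  weight`.
#' @export
write_coexpression_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_coexpression_network
#' @param nodes optional full gene set (restores isolated genes).
#' @export
read_coexpression_network <- function(path, nodes = NULL) {
  edges <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  nodes <- nodes %||% sort(unique(c(edges$u, edges$v)))
  adjacency <- stats::setNames(
    lapply(nodes, function(gn) list(ids = character(0), w = numeric(0))),
    nodes)
  for (r in seq_len(nrow(edges))) {
    u <- edges$u[r]; v <- edges$v[r]; w <- edges$weight[r]
    adjacency[[u]]$ids <- c(adjacency[[u]]$ids, v)
    adjacency[[u]]$w <- c(adjacency[[u]]$w, w)
    adjacency[[v]]$ids <- c(adjacency[[v]]$ids, u)
    adjacency[[v]]$w <- c(adjacency[[v]]$w, w)
  }
  structure(list(nodes = nodes, edges = edges, adjacency = adjacency),
            class = "CoexpressionNetwork")
}

#' Biased random-walk configuration
#'
#' `p` penalizes immediate returns, `q` steers the walk inward (`q > 1`) or
#' outward (`q < 1`). Defaults `p = 2`, `q = 0.5` favour exploration of
#' co-expression neighborhoods.
#'
#' @param p,q positive return / in-out parameters.
#' @param walk_length nodes per walk (>= 2).
#' @param walks_per_node walks started from every non-isolated gene.
#' @param seed integer seed.
#' @export
random_walk_config <- function(p = 2, q = 0.5, walk_length = 20,
                               walks_per_node = 5, seed = 1) {
  if (p <= 0 || q <= 0) stop("p and q must be positive")
  if (walk_length < 2) stop("walk_length must be >= 2")
  structure(list(p = p, q = q, walk_length = as.integer(walk_length),
                 walks_per_node = as.integer(walks_per_node),
                 seed = as.integer(seed)),
            class = "RandomWalkConfig")
}

#' Second-order bias factor of the biased walk
#'
#' Returns `1/p` when the candidate is the previous vertex (distance 0),
#' `1` when it neighbours the previous vertex (distance 1) and `1/q`
#' otherwise (distance 2).
#'
#' @param d_tx shortest-path distance (0, 1 or 2) between the previous
#'   vertex and the candidate.
#' @param p,q walk bias parameters.
#' @export
transition_alpha <- function(d_tx, p, q) {
  ifelse(d_tx == 0, 1 / p, ifelse(d_tx == 1, 1, 1 / q))
}

#' Transition distribution of the biased walk
#'
#' Unnormalized probabilities are the bias factor times the edge weight,
#' normalized over the neighbors of `current`. On the first step
#' (`prev = NULL`) the bias factor is 1 for every neighbor.
#'
#' @param net a `CoexpressionNetwork`.
#' @param prev previous vertex id or `NULL`.
#' @param current current vertex id (must have at least one neighbor).
#' @param config a [random_walk_config()].
#' @return Named probability vector over the neighbors of `current`.
#' @export
transition_probs <- function(net, prev, current, config) {
  nb <- net$adjacency[[current]]
  if (is.null(nb) || length(nb$ids) == 0)
    stop("vertex ", current, " has no neighbors")
  if (is.null(prev)) {
    pi_vx <- nb$w
  } else {
    prev_nb <- net$adjacency[[prev]]$ids
    d_tx <- ifelse(nb$ids == prev, 0L, ifelse(nb$ids %in% prev_nb, 1L, 2L))
    pi_vx <- transition_alpha(d_tx, config$p, config$q) * nb$w
  }
  stats::setNames(pi_vx / sum(pi_vx), nb$ids)
}

#' Generate biased random walks over the network
#'
#' Starts `walks_per_node` walks of `walk_length` vertices from every
#' non-isolated gene; isolated genes are skipped with a warning.
#' Deterministic given the config seed.
#'
#' @param net a `CoexpressionNetwork`.
#' @param config a [random_walk_config()].
#' @return List of character vectors (gene-id walks).
#' @export
generate_walks <- function(net, config) {
  deg <- vapply(net$adjacency, function(a) length(a$ids), integer(1))
  starts <- net$nodes[deg[net$nodes] > 0]
  if (length(starts) == 0) stop("network has no edges")
  if (length(starts) < length(net$nodes))
    warning(length(net$nodes) - length(starts), " isolated gene(s) skipped")
  with_seed(config$seed, {
    walks <- vector("list", length(starts) * config$walks_per_node)
    k <- 0L
    for (rep in seq_len(config$walks_per_node)) {
      for (s in starts) {
        walk <- character(config$walk_length)
        walk[1] <- s
        prev <- NULL
        for (step in 2:config$walk_length) {
          pr <- transition_probs(net, prev, walk[step - 1L], config)
          nxt <- if (length(pr) == 1) names(pr)
                 else sample(names(pr), 1L, prob = pr)
          prev <- walk[step - 1L]
          walk[step] <- nxt
        }
        k <- k + 1L
        walks[[k]] <- walk
      }
    }
    walks
  })
}

#' Learn gene embeddings from walk corpora
#'
#' Slides a symmetric window over every walk to produce skip-gram pairs and
#' trains them with the shared negative-sampling engine. Genes never
#' visited by a walk receive the zero vector.
#'
#' @param walks list of gene-id walks from [generate_walks()].
#' @param dim embedding dimension.
#' @param window context window half-width (>= 1).
#' @param epochs,negatives,learning_rate,seed training controls, as in
#'   [train_skipgram()].
#' @param vocabulary optional full gene-id set (default: walked genes only).
#' @return An `EmbeddingTable` over `vocabulary` (class also used for the
#'   spatial stream), with attribute `loss_trace`.
#' @export
train_node_embeddings <- function(walks, dim = 200, window = 3, epochs = 3,
                                  negatives = 5, learning_rate = 0.05,
                                  seed = 1, vocabulary = NULL) {
  if (length(walks) == 0) stop("walk corpus is empty")
  if (window < 1) stop("window must be >= 1")
  walked <- unique(unlist(walks))
  vocabulary <- vocabulary %||% sort(walked)
  vmap <- stats::setNames(seq_along(vocabulary), vocabulary)
  pair_list <- lapply(walks, function(w) {
    L <- length(w)
    ctr <- integer(0); ctx <- integer(0)
    for (off in seq_len(window)) {
      if (off >= L) break
      i <- seq_len(L - off)
      ctr <- c(ctr, i, i + off)
      ctx <- c(ctx, i + off, i)
    }
    cbind(center = vmap[w[ctr]], context = vmap[w[ctx]])
  })
  pairs <- do.call(rbind, pair_list)
  fit <- skipgram_engine(pairs, length(vocabulary), dim, epochs, negatives,
                         learning_rate, seed)
  V <- fit$W_in
  V[!(vocabulary %in% walked), ] <- 0
  tab <- new_embedding_table(V, vocabulary)
  attr(tab, "loss_trace") <- fit$loss_trace
  tab
}
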