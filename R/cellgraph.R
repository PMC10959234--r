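# Exponential-Manhattan cell similarity, KNN cell graphs and the
# degree-normalized neighbor aggregation used to smooth them.

#' Manhattan distance between latent cell vectors
#' @param x,y numeric vectors of equal length.
#' @return `sum(|x_i - y_i|)`.
#' @export
manhattan_distance <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  sum(abs(x - y))
}

#' Pearson correlation between latent cell vectors
#' @param x,y numeric non-constant vectors of length >= 2.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 2) stop("vectors must have length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation for a constant vector")
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

#' Exp-Mah similarity configuration
#'
#' `alpha` balances the correlation and Manhattan components; 0.25 gives a
#' balanced trade-off on droplet data. The default `"decay"` convention
#' multiplies the correlation by `exp(-alpha * d_M)` so similarity falls
#' with distance and nearest neighbors are the K shortest; the
#' `"paper_literal"` convention uses `exp(+alpha * d_M)` for comparison.
#'
#' @param alpha positive metric weight (default 0.25).
#' @param sign_convention `"decay"` or `"paper_literal"`.
#' @export
exp_mah_config <- function(alpha = 0.25,
                           sign_convention = c("decay", "paper_literal")) {
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(alpha = alpha,
                 sign_convention = match.arg(sign_convention)),
            class = "ExpMahConfig")
}

#' Exponential-Manhattan cell similarity
#'
#' Combines the Pearson correlation of two latent vectors with an
#' exponential of their Manhattan distance:
#' `sim = R_cor * exp(-alpha * d_M)` under the decay convention.
#' Symmetric in its arguments; identical cells score 1.
#'
#' @param x,y latent cell vectors.
#' @param config an [exp_mah_config()].
#' @export
exp_mah_similarity <- function(x, y, config = exp_mah_config()) {
  r <- pearson_correlation(x, y)
  d <- manhattan_distance(x, y)
  s <- if (config$sign_convention == "decay") -config$alpha else config$alpha
  r * exp(s * d)
}

# Dense pairwise Exp-Mah similarity over latent rows.
exp_mah_similarity_matrix <- function(latents, config = exp_mah_config()) {
  sds <- apply(latents, 1L, stats::sd)
  if (any(sds == 0))
    stop("undefined correlation for a constant latent vector")
  R <- stats::cor(t(latents))
  D <- as.matrix(stats::dist(latents, method = "manhattan"))
  s <- if (config$sign_convention == "decay") -config$alpha else config$alpha
  R * exp(s * D)
}

#' Build the KNN cell graph under a similarity metric
#'
#' Links every cell to its `K` most similar cells (ties broken by cell-id
#' order) and symmetrizes the edge set by union; stored edges carry the
#' similarity weight and no self-loops.
#'
#' @param latents cells x d latent matrix (rownames used as cell ids).
#' @param K neighbors per cell, `1 <= K < n`.
#' @param config an [exp_mah_config()].
#' @param metric `"exp_mah"` (default) or the `"euclidean"` baseline
#'   (similarity = negative Euclidean distance).
#' @return A list of class `CellGraph` with `nodes`, integer-indexed `edges`
#'   (`u < v`, `weight`), `K` and per-node `degree`.
#' @export
build_knn_graph <- function(latents, K = 15, config = exp_mah_config(),
                            metric = c("exp_mah", "euclidean")) {
  metric <- match.arg(metric)
  latents <- as.matrix(latents)
  n <- nrow(latents)
  if (K < 1 || K >= n) stop("K must satisfy 1 <= K < number of cells")
  S <- if (metric == "exp_mah") exp_mah_similarity_matrix(latents, config)
       else -as.matrix(stats::dist(latents))
  diag(S) <- -Inf
  pair_u <- integer(0); pair_v <- integer(0)
  for (i in seq_len(n)) {
    top <- order(-S[i, ], seq_len(n))[seq_len(K)]  # ties: cell order
    pair_u <- c(pair_u, rep(i, K))
    pair_v <- c(pair_v, top)
  }
  a <- pmin(pair_u, pair_v); b <- pmax(pair_u, pair_v)
  key <- paste(a, b)
  dup <- duplicated(key)
  a <- a[!dup]; b <- b[!dup]
  edges <- data.frame(u = a, v = b, weight = S[cbind(a, b)])
  degree <- tabulate(c(a, b), nbins = n)
  ids <- rownames(latents) %||% as.character(seq_len(n))
  structure(list(nodes = ids, edges = edges, K = as.integer(K),
                 degree = degree, metric = metric),
            class = "CellGraph")
}

#' @export
print.CellGraph <- function(x, ...) {
  cat("CellGraph:", length(x$nodes), "cells,", nrow(x$edges),
      "edges (K =", x$K, ",", x$metric, "metric)\n")
  invisible(x)
}

#' Degree normalization factor for neighbor aggregation
#'
#' `c_ij = sqrt(d_i) * sqrt(d_j)`; degrees 4 and 9 give 6.
#' @param d_i,d_j node degrees (counted with the aggregation self-loop).
#' @export
degree_normalizer <- function(d_i, d_j) sqrt(d_i) * sqrt(d_j)

#' Degree-normalized neighbor aggregation over the cell graph
#'
#' `h_agg(i) = ReLU(sum_{j in N(i) + {i}} W h_in(j) / c_ij)` with
#' `c_ij = sqrt(d_i d_j)` and degrees counted with the self-loop. Used as a
#' smoothing operator on node features; the stored graph keeps no
#' self-loops (they are added only here).
#'
#' @param graph a `CellGraph`.
#' @param features nodes x F feature matrix.
#' @param W F x F' weight matrix (applied as `features %*% W`).
#' @return nodes x F' non-negative aggregated features.
#' @export
aggregate_neighbors <- function(graph, features, W = NULL) {
  features <- as.matrix(features)
  n <- length(graph$nodes)
  if (nrow(features) != n) stop("feature rows must match nodes")
  if (is.null(W)) W <- diag(ncol(features))
  H <- features %*% W
  ei <- c(graph$edges$u, graph$edges$v, seq_len(n))
  ej <- c(graph$edges$v, graph$edges$u, seq_len(n))
  d <- graph$degree + 1  # self-loop
  coef <- 1 / degree_normalizer(d[ei], d[ej])
  agg <- rowsum(H[ej, , drop = FALSE] * coef, group = ei)
  out <- relu(agg[order(as.integer(rownames(agg))), , drop = FALSE])
  dimnames(out) <- NULL
  out
}

#' Drop weak edges of a cell graph
#'
#' Removes edges whose similarity falls below the given quantile of the
#' edge-weight distribution.
#'
#' @param graph a `CellGraph`.
#' @param quantile value in `[0, 1)`; 0 keeps every edge.
#' @export
prune_graph <- function(graph, quantile = 0) {
  if (quantile <= 0) return(graph)
  thr <- stats::quantile(graph$edges$weight, quantile)
  keep <- graph$edges$weight >= thr
  graph$edges <- graph$edges[keep, , drop = FALSE]
  graph$degree <- tabulate(c(graph$edges$u, graph$edges$v),
                           nbins = length(graph$nodes))
  graph
}

#' Persist / load a cell graph as an edge list
#' @param graph a `CellGraph`.
#' @param path tab-separated `cell_u  cell_v  similarity` file.
#' @export
write_cell_graph <- function(graph, path) {
  df <- data.frame(cell_u = graph$nodes[graph$edges$u],
                   cell_v = graph$nodes[graph$edges$v],
                   similarity = graph$edges$weight)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_graph
#' @param nodes full cell-id vector (fixes node order).
#' @param K neighbor parameter to record.
#' @export
read_cell_graph <- function(path, nodes, K = NA_integer_) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  u <- match(df$cell_u, nodes)
  v <- match(df$cell_v, nodes)
  if (anyNA(u) || anyNA(v)) stop("edge references unknown cell id")
  edges <- data.frame(u = pmin(u, v), v = pmax(u, v),
                      weight = df$similarity)
  structure(list(nodes = nodes, edges = edges, K = as.integer(K),
                 degree = tabulate(c(edges$u, edges$v),
                                   nbins = length(nodes)),
                 metric = "loaded"),
            class = "CellGraph")
}
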