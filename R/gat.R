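# Multi-head graph attention network over the cell graph, with VAE
# posterior means as node features. Layer operations follow the standard
# GAT recipe: linear transform, LeakyReLU affinity on concatenated
# features, per-node softmax attention, weighted neighbor sum; hidden
# layers concatenate heads, the output layer averages them.

#' GAT branch configuration
#'
#' @param layers number of attention layers (default 2: one hidden, one
#'   output).
#' @param heads attention heads per layer.
#' @param hidden_dim features per head in hidden layers.
#' @param leaky_slope LeakyReLU slope for affinity scores (default 0.2).
#' @param epochs,learning_rate full-batch Adam controls.
#' @param seed integer seed.
#' @export
gat_config <- function(layers = 2, heads = 4, hidden_dim = 8,
                       leaky_slope = 0.2, epochs = 150,
                       learning_rate = 5e-3, seed = 1) {
  if (heads < 1) stop("heads must be >= 1")
  if (layers < 1) stop("layers must be >= 1")
  structure(list(layers = layers, heads = heads, hidden_dim = hidden_dim,
                 leaky_slope = leaky_slope, epochs = epochs,
                 learning_rate = learning_rate, seed = seed),
            class = "GATConfig")
}

#' Linear feature transform `H = X W`
#' @param X node feature matrix (N x F).
#' @param W weight matrix (F x F').
#' @export
linear_transform <- function(X, W) {
  if (ncol(X) != nrow(W)) stop("inner dimensions do not agree")
  X %*% W
}

# Directed edge list (target i, source j) with self-loops, from a CellGraph.
gat_edges <- function(graph) {
  n <- length(graph$nodes)
  cbind(i = c(graph$edges$u, graph$edges$v, seq_len(n)),
        j = c(graph$edges$v, graph$edges$u, seq_len(n)))
}

#' Affinity scores along directed edges
#'
#' `e_ij = LeakyReLU(a^T [H_i || H_j])` for every listed edge.
#'
#' @param H transformed node features (N x F').
#' @param a attention vector of length `2 F'`.
#' @param edges 2-column integer matrix (target `i`, source `j`),
#'   self-loops included.
#' @param leaky_slope negative-part slope.
#' @return Numeric vector of scores, one per edge row.
#' @export
affinity_scores <- function(H, a, edges, leaky_slope = 0.2) {
  Fp <- ncol(H)
  if (length(a) != 2 * Fp) stop("a must have length 2 * ncol(H)")
  s1 <- drop(H %*% a[seq_len(Fp)])
  s2 <- drop(H %*% a[Fp + seq_len(Fp)])
  leaky_relu(s1[edges[, 1]] + s2[edges[, 2]], leaky_slope)
}

#' Softmax attention weights per node neighborhood
#'
#' Normalizes affinity scores over each target node's neighborhood
#' (self-loop included) so per-node weights sum to 1.
#'
#' @param e affinity scores per edge.
#' @param edges matching 2-column edge matrix.
#' @return Numeric vector of attention weights aligned with `e`.
#' @export
attention_weights <- function(e, edges) {
  grp <- edges[, 1]
  mx <- stats::ave(e, grp, FUN = max)
  ex <- exp(e - mx)
  denom <- rowsum(ex, grp)
  unname(ex / denom[as.character(grp), 1])
}

#' Attention-weighted neighbor aggregation
#'
#' `H'_i = sum_{j in N(i)} alpha_ij H_j` over the listed edges.
#'
#' @param H node features (N x F').
#' @param alpha attention weights per edge.
#' @param edges 2-column edge matrix.
#' @export
update_features <- function(H, alpha, edges) {
  out <- matrix(0, nrow(H), ncol(H))
  rs <- rowsum(H[edges[, 2], , drop = FALSE] * alpha, group = edges[, 1])
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Combine multi-head outputs
#'
#' @param head_outputs list of per-head feature matrices.
#' @param mode `"average"` (output layers) or `"concatenate"` (hidden
#'   layers only).
#' @export
multi_head_combine <- function(head_outputs, mode = c("average",
                                                      "concatenate")) {
  mode <- match.arg(mode)
  if (mode == "average") {
    shapes <- vapply(head_outputs, dim, integer(2))
    if (any(shapes != shapes[, 1])) stop("head shapes must agree")
    Reduce(`+`, head_outputs) / length(head_outputs)
  } else {
    do.call(cbind, head_outputs)
  }
}

# rowsum to a fixed number of groups, absent groups filled with zero.
rowsum_full <- function(x, grp, n) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  out <- matrix(0, n, ncol(x))
  rs <- rowsum(x, grp)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

gat_init <- function(config, input_dim, n_classes) {
  params <- list()
  f_in <- input_dim
  for (l in seq_len(config$layers)) {
    f_out <- if (l == config$layers) n_classes else config$hidden_dim
    for (k in seq_len(config$heads)) {
      p <- paste0("L", l, "_h", k, "_")
      params[[paste0(p, "W")]] <- init_weight(f_in, f_out)
      params[[paste0(p, "a")]] <- stats::runif(2 * f_out, -0.1, 0.1)
    }
    f_in <- if (l == config$layers) f_out else f_out * config$heads
  }
  params
}

gat_forward <- function(X, edges, params, config, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    final <- l == config$layers
    heads <- vector("list", config$heads)
    hc <- if (keep_cache) vector("list", config$heads)
    for (k in seq_len(config$heads)) {
      p <- paste0("L", l, "_h", k, "_")
      W <- params[[paste0(p, "W")]]
      a <- params[[paste0(p, "a")]]
      H <- linear_transform(X, W)
      Fp <- ncol(H)
      s1 <- drop(H %*% a[seq_len(Fp)])
      s2 <- drop(H %*% a[Fp + seq_len(Fp)])
      pre <- s1[edges[, 1]] + s2[edges[, 2]]
      e <- leaky_relu(pre, config$leaky_slope)
      alpha <- attention_weights(e, edges)
      heads[[k]] <- update_features(H, alpha, edges)
      if (keep_cache) hc[[k]] <- list(H = H, pre = pre, alpha = alpha)
    }
    Z <- multi_head_combine(heads,
                            if (final) "average" else "concatenate")
    if (keep_cache)
      caches[[l]] <- list(X = X, heads = hc, Z_pre = Z, final = final)
    X <- if (final) Z else elu(Z)
  }
  list(out = X, caches = caches)
}

gat_backward <- function(dOut, edges, params, config, caches) {
  grads <- list()
  n <- nrow(dOut)
  dX_next <- dOut
  for (l in rev(seq_len(config$layers))) {
    cc <- caches[[l]]
    dZ <- if (cc$final) dX_next else dX_next * d_elu(cc$Z_pre)
    X <- cc$X
    dX <- matrix(0, nrow(X), ncol(X))
    for (k in seq_len(config$heads)) {
      p <- paste0("L", l, "_h", k, "_")
      W <- params[[paste0(p, "W")]]
      a <- params[[paste0(p, "a")]]
      hc <- cc$heads[[k]]
      H <- hc$H; alpha <- hc$alpha; pre <- hc$pre
      Fp <- ncol(H)
      dOut_k <- if (cc$final) dZ / config$heads
                else dZ[, ((k - 1) * Fp + 1):(k * Fp), drop = FALSE]
      dalpha <- rowSums(dOut_k[edges[, 1], , drop = FALSE] *
                          H[edges[, 2], , drop = FALSE])
      dH <- rowsum_full(dOut_k[edges[, 1], , drop = FALSE] * alpha,
                        edges[, 2], n)
      S <- rowsum_full(alpha * dalpha, edges[, 1], n)
      de <- alpha * (dalpha - S[edges[, 1], 1])
      de <- de * ifelse(pre > 0, 1, config$leaky_slope)
      ds1 <- rowsum_full(de, edges[, 1], n)[, 1]
      ds2 <- rowsum_full(de, edges[, 2], n)[, 1]
      a1 <- a[seq_len(Fp)]; a2 <- a[Fp + seq_len(Fp)]
      grads[[paste0(p, "a")]] <- c(drop(crossprod(H, ds1)),
                                   drop(crossprod(H, ds2)))
      dH <- dH + outer(ds1, a1) + outer(ds2, a2)
      grads[[paste0(p, "W")]] <- crossprod(X, dH)
      dX <- dX + tcrossprod(dH, W)
    }
    dX_next <- dX
  }
  grads
}

#' Train the graph-attention branch on a cell graph
#'
#' Stacked attention layers (hidden layers concatenate heads with ELU
#' between, output layer averages heads into class logits), trained
#' full-batch with cross-entropy on the training nodes. The reported
#' performance is validation accuracy; probabilities cover every cell.
#'
#' @param graph a `CellGraph`.
#' @param latents node feature matrix (VAE posterior means).
#' @param labels per-node class labels (>= 2 classes).
#' @param split list with `train` and `validation` index vectors.
#' @param config a [gat_config()].
#' @return List of class `GATFit`: `params`, validation accuracy `perf`,
#'   `probs` (a `ClassProbabilities`), `loss_trace`.
#' @export
train_gat <- function(graph, latents, labels, split, config = gat_config()) {
  latents <- as.matrix(latents)
  n <- length(graph$nodes)
  if (nrow(latents) != n) stop("latent rows must match graph nodes")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes to train")
  if (any(graph$degree == 0))
    warning("graph has isolated node(s); they see only themselves")
  y_idx <- match(labels, classes)
  edges <- gat_edges(graph)
  with_seed(config$seed, {
    params <- gat_init(config, ncol(latents), length(classes))
    opt <- adam_state(params)
    tr <- split$train
    loss_trace <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      fw <- gat_forward(latents, edges, params, config, keep_cache = TRUE)
      probs <- softmax_rows(fw$out)
      loss_trace[ep] <- cross_entropy(probs[tr, , drop = FALSE], y_idx[tr])
      dlogits <- matrix(0, n, length(classes))
      g <- probs[tr, , drop = FALSE]
      g[cbind(seq_along(tr), y_idx[tr])] <-
        g[cbind(seq_along(tr), y_idx[tr])] - 1
      dlogits[tr, ] <- g / length(tr)
      grads <- gat_backward(dlogits, edges, params, config, fw$caches)
      st <- adam_step(params, grads, opt, config$learning_rate)
      params <- st$params; opt <- st$state
    }
    fw <- gat_forward(latents, edges, params, config)
    probs <- class_probabilities(softmax_rows(fw$out), classes, graph$nodes)
    pred <- predicted_labels(probs)
    perf <- mean(pred[split$validation] == labels[split$validation])
    structure(list(params = params, config = config, classes = classes,
                   perf = perf, probs = probs, loss_trace = loss_trace),
              class = "GATFit")
  })
}
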