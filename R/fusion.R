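# Performance-weighted adaptive fusion of the two branches' class
# probabilities, plus the MLP fusion variant.

#' Adaptive fusion weights from branch performances
#'
#' `W1 = perf_a / (perf_a + perf_b)`, `W2 = perf_b / (perf_a + perf_b)`.
#'
#' @param perf_a,perf_b non-negative branch performances (validation
#'   accuracy by default), not both zero.
#' @return List of class `FusionWeights` with `W1`, `W2` (summing to 1).
#' @export
fusion_weights <- function(perf_a, perf_b) {
  if (perf_a < 0 || perf_b < 0) stop("performances must be non-negative")
  if (perf_a + perf_b == 0) stop("at least one performance must be positive")
  structure(list(W1 = perf_a / (perf_a + perf_b),
                 W2 = perf_b / (perf_a + perf_b)),
            class = "FusionWeights")
}

#' Fuse two class-probability matrices
#'
#' Convex combination `P = W1 A + W2 B`; rows stay stochastic.
#'
#' @param A,B `ClassProbabilities` with identical class vocabularies.
#' @param w a [fusion_weights()].
#' @return A `ClassProbabilities`.
#' @export
fuse <- function(A, B, w) {
  if (!identical(A$class_ids, B$class_ids))
    stop("class vocabularies do not match")
  if (!all(dim(A$probs) == dim(B$probs)))
    stop("probability matrices must have the same shape")
  class_probabilities(w$W1 * A$probs + w$W2 * B$probs, A$class_ids,
                      A$cell_ids)
}

#' MLP fusion of two branches' probabilities
#'
#' One-hidden-layer perceptron on the concatenated rows `[A || B]`, trained
#' with cross-entropy on the training split; row-stochastic output over all
#' cells. Deterministic given `seed`.
#'
#' @param A,B `ClassProbabilities` with identical class vocabularies.
#' @param labels per-cell class labels.
#' @param split list with `train` (and optionally `validation`) indices.
#' @param seed integer seed.
#' @param hidden_dim hidden width (default 16).
#' @param epochs,learning_rate full-batch Adam controls.
#' @return A `ClassProbabilities`.
#' @export
mlp_fuse <- function(A, B, labels, split, seed = 1, hidden_dim = 16,
                     epochs = 200, learning_rate = 1e-2) {
  if (!identical(A$class_ids, B$class_ids))
    stop("class vocabularies do not match")
  classes <- A$class_ids
  if (length(unique(labels[split$train])) < 2)
    stop("need at least 2 classes in the training split")
  X <- cbind(A$probs, B$probs)
  y_idx <- match(labels, classes)
  with_seed(seed, {
    params <- list(W1 = init_weight(ncol(X), hidden_dim),
                   b1 = numeric(hidden_dim),
                   W2 = init_weight(hidden_dim, length(classes)),
                   b2 = numeric(length(classes)))
    opt <- adam_state(params)
    tr <- split$train
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y_idx[tr]
    for (ep in seq_len(epochs)) {
      pre <- sweep(Xtr %*% params$W1, 2L, params$b1, `+`)
      H <- relu(pre)
      probs <- softmax_rows(sweep(H %*% params$W2, 2L, params$b2, `+`))
      dlogits <- softmax_ce_grad(probs, ytr)
      dH <- tcrossprod(dlogits, params$W2) * (pre > 0)
      grads <- list(W1 = crossprod(Xtr, dH), b1 = colSums(dH),
                    W2 = crossprod(H, dlogits), b2 = colSums(dlogits))
      st <- adam_step(params, grads, opt, learning_rate)
      params <- st$params; opt <- st$state
    }
    H <- relu(sweep(X %*% params$W1, 2L, params$b1, `+`))
    probs <- softmax_rows(sweep(H %*% params$W2, 2L, params$b2, `+`))
    class_probabilities(probs, classes, A$cell_ids)
  })
}
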