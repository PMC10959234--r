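# Linear-attention transformer branch over per-cell gene-token sequences.
# Attention is computed through a positive random-feature map of the softmax
# kernel, in the associativity order Q'(K'^T V) so cost grows linearly with
# sequence length; an exact-softmax kernel mode is kept for cross-checks.
# All gradients are hand-derived; parameters are updated with Adam.

#' Performer branch configuration
#'
#' @param model_dim token embedding dimension (must be divisible by heads).
#' @param layers number of transformer blocks (default 1).
#' @param heads attention heads.
#' @param feature_count random features per head for the kernel map.
#' @param kernel `"positive_random_features"` (default) or
#'   `"exact_softmax"` (quadratic; used for oracle checks).
#' @param dropout dropout rate on the feed-forward hidden layer during
#'   training (default 0 for full determinism).
#' @param train_embeddings learn additive per-position (gene) and per-bin
#'   corrections to the input token embeddings jointly with the
#'   transformer (end-to-end training; default `TRUE`).
#' @param hidden_dim classifier hidden width on top of the mean-pooled
#'   representation.
#' @param epochs,learning_rate,batch_size minibatch Adam controls.
#' @param seed integer seed (initialization, kernel draws, shuffling).
#' @export
performer_config <- function(model_dim, layers = 1, heads = 2,
                             feature_count = 32,
                             kernel = c("positive_random_features",
                                        "exact_softmax"),
                             dropout = 0, train_embeddings = TRUE,
                             hidden_dim = 32, epochs = 60,
                             learning_rate = 1e-3, batch_size = 64,
                             seed = 1) {
  kernel <- match.arg(kernel)
  if (model_dim %% heads != 0) stop("model_dim must be divisible by heads")
  if (feature_count < 1) stop("feature_count must be >= 1")
  structure(list(model_dim = model_dim, layers = layers, heads = heads,
                 feature_count = feature_count, kernel = kernel,
                 dropout = dropout, train_embeddings = train_embeddings,
                 hidden_dim = hidden_dim,
                 epochs = epochs, learning_rate = learning_rate,
                 batch_size = batch_size, seed = seed),
            class = "PerformerConfig")
}

#' Positive random-feature map of the softmax kernel
#'
#' `phi(x) = exp(omega^T x - ||x||^2 / 2) / sqrt(m)` with `m` Gaussian
#' draws; all entries are strictly positive and
#' `E[phi(x) . phi(y)] = exp(x . y)`.
#'
#' @param M rows to map (queries or keys).
#' @param feature_count number of random features `m`.
#' @param seed seed for the Gaussian draws (ignored when `omega` given).
#' @param omega optional fixed `m x d` draw matrix.
#' @return Non-negative `nrow(M) x m` feature matrix.
#' @export
kernel_feature_map <- function(M, feature_count, seed = 1, omega = NULL) {
  M <- as.matrix(M)
  if (is.null(omega))
    omega <- with_seed(seed, matrix(stats::rnorm(feature_count * ncol(M)),
                                    feature_count, ncol(M)))
  E <- tcrossprod(M, omega) - 0.5 * rowSums(M^2)
  exp(E) / sqrt(nrow(omega))
}

#' Linear attention over feature-mapped queries and keys
#'
#' `D^{-1} (Q' K'^T) V` with `D = diag(Q' K'^T 1)`, evaluated as
#' `Q'(K'^T V)` so the cost is linear in sequence length. The implied
#' attention rows sum to 1.
#'
#' @param Qp,Kp non-negative feature-mapped queries / keys (L x m).
#' @param V value matrix (L x d_v).
#' @export
linear_attention <- function(Qp, Kp, V) {
  S <- crossprod(Kp, V)
  den <- drop(Qp %*% colSums(Kp))
  if (any(den == 0)) stop("zero attention normalizer")
  (Qp %*% S) / den
}

#' Quadratic softmax attention (oracle)
#'
#' Standard `softmax(Q K^T) V` with row-wise stabilized softmax; the
#' reference the linear path is checked against.
#' @param Q,K,V query/key/value matrices.
#' @export
softmax_attention <- function(Q, K, V) {
  softmax_rows(tcrossprod(Q, K)) %*% V
}

#' Multiplication count of the factorized linear-attention evaluation
#'
#' Multiplications needed for `Q'(K'^T V)` plus the normalizer at sequence
#' length `L`, `m` features and value width `d`: linear in `L` (the
#' quadratic order would cost `L^2 (m + d)`).
#' @param L,m,d sequence length, feature count, value width.
#' @export
linear_attention_flops <- function(L, m, d) L * m * d * 2 + 2 * L * m

# One attention head. Q, K, V are L x dh slices; scaling by dh^(-1/4) on Q
# and K matches softmax(QK^T / sqrt(dh)) in exact mode.
performer_attention <- function(Q, K, V, kernel, omega) {
  s <- ncol(Q)^(-0.25)
  if (kernel == "positive_random_features") {
    Qp <- kernel_feature_map(Q * s, omega = omega)
    Kp <- kernel_feature_map(K * s, omega = omega)
    linear_attention(Qp, Kp, V)
  } else {
    softmax_attention(Q * s, K * s, V)
  }
}

performer_attention_bwd <- function(Q, K, V, kernel, omega, dO) {
  s <- ncol(Q)^(-0.25)
  Qs <- Q * s; Ks <- K * s
  if (kernel == "positive_random_features") {
    Qp <- kernel_feature_map(Qs, omega = omega)
    Kp <- kernel_feature_map(Ks, omega = omega)
    S <- crossprod(Kp, V)
    u <- colSums(Kp)
    den <- drop(Qp %*% u)
    O <- (Qp %*% S) / den
    dOn <- dO / den
    dden <- -rowSums(O * dO) / den
    dQp <- tcrossprod(dOn, S) + outer(dden, u)
    dS <- crossprod(Qp, dOn)
    du <- drop(crossprod(Qp, dden))
    dKp <- sweep(V %*% t(dS), 2L, du, `+`)
    dV <- Kp %*% dS
    Gq <- dQp * Qp
    dQs <- Gq %*% omega - Qs * rowSums(Gq)
    Gk <- dKp * Kp
    dKs <- Gk %*% omega - Ks * rowSums(Gk)
    list(dQ = dQs * s, dK = dKs * s, dV = dV)
  } else {
    A <- softmax_rows(tcrossprod(Qs, Ks))
    dV <- crossprod(A, dO)
    dA <- tcrossprod(dO, V)
    dM <- A * (dA - rowSums(A * dA))
    list(dQ = (dM %*% Ks) * s, dK = crossprod(dM, Qs) * s, dV = dV)
  }
}

performer_init <- function(config, n_classes) {
  d <- config$model_dim
  dh <- d %/% config$heads
  f <- 2L * d
  params <- list()
  omega <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    p <- paste0("L", l, "_")
    params[[paste0(p, "Wq")]] <- init_weight(d, d)
    params[[paste0(p, "Wk")]] <- init_weight(d, d)
    params[[paste0(p, "Wv")]] <- init_weight(d, d)
    params[[paste0(p, "Wo")]] <- init_weight(d, d)
    params[[paste0(p, "g1")]] <- rep(1, d)
    params[[paste0(p, "b1")]] <- numeric(d)
    params[[paste0(p, "Wf1")]] <- init_weight(d, f)
    params[[paste0(p, "bf1")]] <- numeric(f)
    params[[paste0(p, "Wf2")]] <- init_weight(f, d)
    params[[paste0(p, "bf2")]] <- numeric(d)
    params[[paste0(p, "g2")]] <- rep(1, d)
    params[[paste0(p, "b2")]] <- numeric(d)
    omega[[l]] <- lapply(seq_len(config$heads), function(h)
      matrix(stats::rnorm(config$feature_count * dh),
             config$feature_count, dh))
  }
  params$Wh <- init_weight(d, config$hidden_dim)
  params$bh <- numeric(config$hidden_dim)
  params$Wc <- init_weight(config$hidden_dim, n_classes)
  params$bc <- numeric(n_classes)
  list(params = params, omega = omega)
}

# Stack a cells x tokens x dim array into a (cells*tokens) x dim matrix with
# cell-contiguous row blocks.
stack_sequences <- function(arr) {
  d <- dim(arr)
  matrix(aperm(arr, c(2L, 1L, 3L)), d[1] * d[2], d[3])
}

# Encoder forward over stacked sequences; returns pooled reps and caches.
performer_encode <- function(X_all, n, L, params, omega, config,
                             keep_cache = FALSE) {
  d <- config$model_dim
  H <- config$heads
  dh <- d %/% H
  caches <- if (keep_cache) vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    p <- paste0("L", l, "_")
    Q <- X_all %*% params[[paste0(p, "Wq")]]
    K <- X_all %*% params[[paste0(p, "Wk")]]
    V <- X_all %*% params[[paste0(p, "Wv")]]
    O <- matrix(0, nrow(X_all), d)
    for (cidx in seq_len(n)) {
      rs <- ((cidx - 1L) * L + 1L):(cidx * L)
      for (h in seq_len(H)) {
        cs <- ((h - 1L) * dh + 1L):(h * dh)
        O[rs, cs] <- performer_attention(Q[rs, cs, drop = FALSE],
                                         K[rs, cs, drop = FALSE],
                                         V[rs, cs, drop = FALSE],
                                         config$kernel, omega[[l]][[h]])
      }
    }
    attn <- O %*% params[[paste0(p, "Wo")]]
    ln1 <- layernorm_forward(X_all + attn, params[[paste0(p, "g1")]],
                             params[[paste0(p, "b1")]])
    X1 <- ln1$y
    F1 <- relu(sweep(X1 %*% params[[paste0(p, "Wf1")]], 2L,
                     params[[paste0(p, "bf1")]], `+`))
    F2 <- sweep(F1 %*% params[[paste0(p, "Wf2")]], 2L,
                params[[paste0(p, "bf2")]], `+`)
    ln2 <- layernorm_forward(X1 + F2, params[[paste0(p, "g2")]],
                             params[[paste0(p, "b2")]])
    if (keep_cache)
      caches[[l]] <- list(Xin = X_all, Q = Q, K = K, V = V, O = O,
                          ln1 = ln1, X1 = X1, F1 = F1, ln2 = ln2)
    X_all <- ln2$y
  }
  pooled <- rowsum(X_all, group = rep(seq_len(n), each = L)) / L
  dimnames(pooled) <- NULL
  list(pooled = pooled, caches = caches)
}

performer_encode_bwd <- function(dPooled, n, L, params, omega, config,
                                 caches) {
  d <- config$model_dim
  H <- config$heads
  dh <- d %/% H
  grads <- list()
  dX <- dPooled[rep(seq_len(n), each = L), , drop = FALSE] / L
  for (l in rev(seq_len(config$layers))) {
    p <- paste0("L", l, "_")
    cc <- caches[[l]]
    lb2 <- layernorm_backward(cc$ln2, params[[paste0(p, "g2")]], dX)
    grads[[paste0(p, "g2")]] <- lb2$dgamma
    grads[[paste0(p, "b2")]] <- lb2$dbeta
    dF2 <- lb2$dx
    dX1 <- lb2$dx
    grads[[paste0(p, "Wf2")]] <- crossprod(cc$F1, dF2)
    grads[[paste0(p, "bf2")]] <- colSums(dF2)
    dF1 <- tcrossprod(dF2, params[[paste0(p, "Wf2")]]) * (cc$F1 > 0)
    grads[[paste0(p, "Wf1")]] <- crossprod(cc$X1, dF1)
    grads[[paste0(p, "bf1")]] <- colSums(dF1)
    dX1 <- dX1 + tcrossprod(dF1, params[[paste0(p, "Wf1")]])
    lb1 <- layernorm_backward(cc$ln1, params[[paste0(p, "g1")]], dX1)
    grads[[paste0(p, "g1")]] <- lb1$dgamma
    grads[[paste0(p, "b1")]] <- lb1$dbeta
    dXin <- lb1$dx
    dAttn <- lb1$dx
    grads[[paste0(p, "Wo")]] <- crossprod(cc$O, dAttn)
    dO <- tcrossprod(dAttn, params[[paste0(p, "Wo")]])
    dQ <- matrix(0, nrow(dO), d)
    dK <- matrix(0, nrow(dO), d)
    dV <- matrix(0, nrow(dO), d)
    for (cidx in seq_len(n)) {
      rs <- ((cidx - 1L) * L + 1L):(cidx * L)
      for (h in seq_len(H)) {
        cs <- ((h - 1L) * dh + 1L):(h * dh)
        bk <- performer_attention_bwd(cc$Q[rs, cs, drop = FALSE],
                                      cc$K[rs, cs, drop = FALSE],
                                      cc$V[rs, cs, drop = FALSE],
                                      config$kernel, omega[[l]][[h]],
                                      dO[rs, cs, drop = FALSE])
        dQ[rs, cs] <- bk$dQ
        dK[rs, cs] <- bk$dK
        dV[rs, cs] <- bk$dV
      }
    }
    grads[[paste0(p, "Wq")]] <- crossprod(cc$Xin, dQ)
    grads[[paste0(p, "Wk")]] <- crossprod(cc$Xin, dK)
    grads[[paste0(p, "Wv")]] <- crossprod(cc$Xin, dV)
    dX <- dXin + tcrossprod(dQ, params[[paste0(p, "Wq")]]) +
      tcrossprod(dK, params[[paste0(p, "Wk")]]) +
      tcrossprod(dV, params[[paste0(p, "Wv")]])
  }
  list(grads = grads, dX = dX)
}

#' Forward pass of the transformer branch
#'
#' Runs the configured number of blocks (multi-head linear attention,
#' feed-forward, residual connections, layer normalization) over each
#' cell's token sequence and mean-pools over tokens. With zero layers this
#' reduces to plain mean pooling of the input token vectors.
#'
#' @param model a trained `PerformerModel` (or list with `params`, `omega`,
#'   `config`).
#' @param seqs a `TokenEmbeddingSequence`.
#' @return cells x model_dim representation matrix.
#' @export
performer_forward <- function(model, seqs) {
  arr <- seqs$embeddings
  n <- dim(arr)[1]; L <- dim(arr)[2]
  if (dim(arr)[3] != model$config$model_dim)
    stop("token dimension ", dim(arr)[3], " != model_dim ",
         model$config$model_dim)
  X_all <- stack_sequences(arr)
  if (!is.null(model$params$Emb_pos)) {
    if (nrow(model$params$Emb_pos) != L)
      stop("sequence length differs from the trained token order")
    X_all <- X_all + model$params$Emb_pos[rep(seq_len(L), n), , drop = FALSE] +
      model$params$Emb_bin[as.vector(t(seqs$tokens)) + 1L, , drop = FALSE]
  }
  performer_encode(X_all, n, L, model$params, model$omega, model$config)$pooled
}

#' Class probabilities from the transformer branch
#' @param model a `PerformerModel`.
#' @param seqs a `TokenEmbeddingSequence`.
#' @return A `ClassProbabilities` object (row-stochastic).
#' @export
predict_performer <- function(model, seqs) {
  pooled <- performer_forward(model, seqs)
  Hh <- relu(sweep(pooled %*% model$params$Wh, 2L, model$params$bh, `+`))
  probs <- softmax_rows(sweep(Hh %*% model$params$Wc, 2L,
                              model$params$bc, `+`))
  class_probabilities(probs, model$classes, seqs$cell_ids)
}

#' Train the transformer branch
#'
#' Cross-entropy minibatch training on the training split; the reported
#' performance is accuracy on the validation split and probabilities are
#' produced for every cell. Deterministic given the config seed.
#'
#' @param seqs a `TokenEmbeddingSequence`.
#' @param labels per-cell class labels (>= 2 classes).
#' @param split list with `train` and `validation` index vectors.
#' @param config a [performer_config()].
#' @return List of class `PerformerFit`: `model`, validation accuracy
#'   `perf`, `probs` (a `ClassProbabilities`), and `loss_trace`.
#' @export
train_performer <- function(seqs, labels, split, config) {
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes to train")
  if (length(intersect(split$train, split$validation)) > 0)
    stop("train and validation must be disjoint")
  y_idx <- match(labels, classes)
  arr <- seqs$embeddings
  L <- dim(arr)[2]
  with_seed(config$seed, {
    ini <- performer_init(config, length(classes))
    params <- ini$params
    omega <- ini$omega
    n_bins <- max(seqs$tokens) + 1L
    if (config$train_embeddings) {
      # small random bin init breaks the uniform-prediction plateau
      params$Emb_pos <- matrix(0, L, config$model_dim)
      params$Emb_bin <- matrix(stats::rnorm(n_bins * config$model_dim,
                                            sd = 0.05),
                               n_bins, config$model_dim)
    }
    opt <- adam_state(params)
    tr <- split$train
    loss_trace <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      perm <- sample(tr)
      ep_loss <- 0; n_batches <- 0L
      for (start in seq(1L, length(perm), by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, length(perm))]
        nb <- length(idx)
        X_all <- stack_sequences(arr[idx, , , drop = FALSE])
        if (config$train_embeddings) {
          pos_idx <- rep(seq_len(L), nb)
          bin_idx <- as.vector(t(seqs$tokens[idx, , drop = FALSE])) + 1L
          X_all <- X_all + params$Emb_pos[pos_idx, , drop = FALSE] +
            params$Emb_bin[bin_idx, , drop = FALSE]
        }
        enc <- performer_encode(X_all, nb, L, params, omega, config,
                                keep_cache = TRUE)
        pre_h <- sweep(enc$pooled %*% params$Wh, 2L, params$bh, `+`)
        Hh <- relu(pre_h)
        if (config$dropout > 0) {
          mask <- matrix(stats::runif(length(Hh)) >= config$dropout,
                         nrow(Hh), ncol(Hh))
          Hh <- Hh * mask / (1 - config$dropout)
        }
        logits <- sweep(Hh %*% params$Wc, 2L, params$bc, `+`)
        probs <- softmax_rows(logits)
        yb <- y_idx[idx]
        ep_loss <- ep_loss + cross_entropy(probs, yb)
        n_batches <- n_batches + 1L
        dlogits <- softmax_ce_grad(probs, yb)
        grads <- list(Wc = crossprod(Hh, dlogits), bc = colSums(dlogits))
        dHh <- tcrossprod(dlogits, params$Wc)
        if (config$dropout > 0) dHh <- dHh * mask / (1 - config$dropout)
        dpre <- dHh * (pre_h > 0)
        grads$Wh <- crossprod(enc$pooled, dpre)
        grads$bh <- colSums(dpre)
        dPooled <- tcrossprod(dpre, params$Wh)
        bk <- performer_encode_bwd(dPooled, nb, L, params, omega, config,
                                   enc$caches)
        grads <- c(grads, bk$grads)
        if (config$train_embeddings) {
          grads$Emb_pos <- rowsum_full(bk$dX, pos_idx, L)
          grads$Emb_bin <- rowsum_full(bk$dX, bin_idx, n_bins)
        }
        grads <- clip_grads(grads, 1)
        st <- adam_step(params, grads, opt, config$learning_rate)
        params <- st$params; opt <- st$state
      }
      loss_trace[ep] <- ep_loss / max(n_batches, 1L)
    }
    model <- structure(list(params = params, omega = omega, config = config,
                            classes = classes),
                       class = "PerformerModel")
    probs <- predict_performer(model, seqs)
    pred <- classes[max.col(probs$probs, ties.method = "first")]
    perf <- mean(pred[split$validation] == labels[split$validation])
    structure(list(model = model, perf = perf, probs = probs,
                   loss_trace = loss_trace),
              class = "PerformerFit")
  })
}
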