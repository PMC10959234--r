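# Small numerical helpers shared by the hand-written training engines.

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

elu <- function(x) ifelse(x > 0, x, expm1(x))

d_elu <- function(x) ifelse(x > 0, 1, exp(x))

#' Row-wise numerically stable softmax
#'
#' @param x numeric matrix.
#' @return Matrix of the same shape whose rows sum to 1.
#' @keywords internal
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

one_hot <- function(idx, n_classes) {
  out <- matrix(0, length(idx), n_classes)
  out[cbind(seq_along(idx), idx)] <- 1
  out
}

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals do not disturb the
#' caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Glorot-style init used by all dense layers.
init_weight <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

# ---- Adam optimizer over a flat named list of arrays -----------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- Layer normalization (row-wise) with cached backward -------------------

layernorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  y <- sweep(xhat, 2L, gamma, `*`)
  y <- sweep(y, 2L, beta, `+`)
  list(y = y, xhat = xhat, inv_sd = inv_sd)
}

layernorm_backward <- function(cache, gamma, dy) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv_sd
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Mean cross-entropy of row-stochastic probs against integer class labels,
# plus the gradient w.r.t. the logits that produced probs via softmax.
cross_entropy <- function(probs, y_idx) {
  p <- probs[cbind(seq_along(y_idx), y_idx)]
  -mean(log(pmax(p, 1e-12)))
}

softmax_ce_grad <- function(probs, y_idx) {
  g <- probs
  g[cbind(seq_along(y_idx), y_idx)] <- g[cbind(seq_along(y_idx), y_idx)] - 1
  g / length(y_idx)
}

# Rescale a gradient list so its global L2 norm is at most max_norm.
clip_grads <- function(grads, max_norm) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(gn) && gn > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / gn))
  grads
}

# Deterministic derived seeds for pipeline stages; kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset)
}

#' Stage seed derived from the pipeline's global seed
#'
#' The pipeline gives each stage its own deterministic seed; offset 1 is
#' the simulated dataset, so
#' `derive_pipeline_seed(seed, 1)` reproduces the dataset a
#' [run_pipeline()] call with that global seed consumed.
#'
#' @param seed global pipeline seed.
#' @param offset stage offset (1 = simulation).
#' @return Integer seed below 2^31.
#' @export
derive_pipeline_seed <- function(seed, offset = 1L) derive_seed(seed, offset)
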