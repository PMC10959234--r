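# Variational autoencoder for latent cell representations. One hidden layer
# on each side: encoder fc1 -> relu -> (fc21: mu, fc22: log-variance),
# decoder fc3 -> relu -> fc4 -> sigmoid. Written directly on matrices with
# hand-derived gradients and Adam updates.

#' VAE configuration
#'
#' @param input_dim number of genes.
#' @param hidden_dim encoder/decoder hidden width (default 256).
#' @param latent_dim latent dimension `d` (< input_dim, default 32).
#' @param alpha_vae mixing weight of the reconstruction term in
#'   `alpha * L_MSE + (1 - alpha) * L_KL` (default 0.9).
#' @param epochs,learning_rate full-batch Adam controls.
#' @param reconstruction `"mse"` (default) or `"mae"`.
#' @param seed integer seed (initialization and reparameterization noise).
#' @export
vae_config <- function(input_dim, hidden_dim = 256, latent_dim = 32,
                       alpha_vae = 0.9, epochs = 150, learning_rate = 1e-3,
                       reconstruction = c("mse", "mae"), seed = 1) {
  reconstruction <- match.arg(reconstruction)
  if (latent_dim >= input_dim) stop("latent_dim must be < input_dim")
  if (alpha_vae < 0 || alpha_vae > 1) stop("alpha_vae must be in [0, 1]")
  structure(list(input_dim = input_dim, hidden_dim = hidden_dim,
                 latent_dim = latent_dim, alpha_vae = alpha_vae,
                 epochs = epochs, learning_rate = learning_rate,
                 reconstruction = reconstruction, seed = seed),
            class = "VAEConfig")
}

vae_init <- function(config) {
  g <- config$input_dim; h <- config$hidden_dim; d <- config$latent_dim
  list(W1 = init_weight(g, h), b1 = numeric(h),
       W21 = init_weight(h, d), b21 = numeric(d),
       W22 = init_weight(h, d), b22 = numeric(d),
       W3 = init_weight(d, h), b3 = numeric(h),
       W4 = init_weight(h, g), b4 = numeric(g))
}

#' Encode cells to posterior mean and log-variance
#'
#' @param x cells x genes matrix (scaled to the decoder's output range).
#' @param params parameter list as produced by [train_vae()].
#' @return List with `mu` and `log_var` matrices (cells x latent).
#' @export
vae_encode <- function(x, params) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(params$W1)) stop("input dimension mismatch")
  h1 <- relu(sweep(x %*% params$W1, 2L, params$b1, `+`))
  list(mu = sweep(h1 %*% params$W21, 2L, params$b21, `+`),
       log_var = sweep(h1 %*% params$W22, 2L, params$b22, `+`),
       h1 = h1)
}

#' Reparameterization trick
#'
#' `z = mu + exp(log_var / 2) * eps`, `eps ~ N(0, I)` drawn with `seed`.
#'
#' @param mu,log_var matrices of equal shape.
#' @param seed integer seed.
#' @export
reparameterize <- function(mu, log_var, seed = 1) {
  stopifnot(all(dim(mu) == dim(log_var)))
  with_seed(seed, {
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
    mu + exp(log_var / 2) * eps
  })
}

#' Decode latents to reconstructions in (0, 1)
#'
#' @param z cells x latent matrix.
#' @param params parameter list.
#' @export
vae_decode <- function(z, params) {
  z <- as.matrix(z)
  if (ncol(z) != nrow(params$W3)) stop("latent dimension mismatch")
  h3 <- relu(sweep(z %*% params$W3, 2L, params$b3, `+`))
  sigmoid(sweep(h3 %*% params$W4, 2L, params$b4, `+`))
}

#' Mean squared reconstruction loss
#'
#' `(1/N) sum_i ||x_i - x'_i||^2` over cells.
#' @param x,x_hat matrices of equal shape.
#' @export
mse_loss <- function(x, x_hat) {
  stopifnot(all(dim(x) == dim(x_hat)))
  sum((x - x_hat)^2) / nrow(x)
}

#' KL divergence to the standard normal prior
#'
#' Per-cell `0.5 * sum_d (mu^2 + sigma^2 - 1 - log sigma^2)`, averaged over
#' cells. This is the standard non-negative KL(N(mu, sigma^2) || N(0, 1));
#' it vanishes iff mu = 0 and sigma^2 = 1.
#'
#' @param mu,log_var matrices of equal shape.
#' @export
kl_loss <- function(mu, log_var) {
  stopifnot(all(dim(mu) == dim(log_var)))
  sum(mu^2 + exp(log_var) - 1 - log_var) / (2 * nrow(mu))
}

#' Train the VAE on a normalized expression matrix
#'
#' Inputs are min-max scaled to `[0, 1]` to match the sigmoid decoder.
#' Full-batch Adam on `alpha * L_MSE + (1 - alpha) * L_KL`; fresh
#' reparameterization noise every epoch, all driven by the config seed. At
#' inference the latent representation is the posterior mean.
#'
#' @param norm a `NormalizedMatrix` (or plain cells x genes matrix).
#' @param config a [vae_config()].
#' @return List of class `VAEFit`: `params`, `latent` (`mu`, `log_var`,
#'   `z = mu`), `loss_trace`, and the scaling range used.
#' @export
train_vae <- function(norm, config) {
  X <- if (inherits(norm, "NormalizedMatrix")) norm$values else as.matrix(norm)
  if (ncol(X) != config$input_dim)
    stop("config input_dim (", config$input_dim, ") != genes (", ncol(X), ")")
  rng <- range(X)
  Xs <- if (diff(rng) > 0) (X - rng[1]) / diff(rng) else X * 0
  n <- nrow(Xs)
  a <- config$alpha_vae
  with_seed(config$seed, {
    params <- vae_init(config)
    opt <- adam_state(params)
    loss_trace <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      enc <- vae_encode(Xs, params)
      mu <- enc$mu; lv <- enc$log_var; h1 <- enc$h1
      eps <- matrix(stats::rnorm(length(mu)), n, ncol(mu))
      sd_ <- exp(lv / 2)
      z <- mu + sd_ * eps
      h3 <- relu(sweep(z %*% params$W3, 2L, params$b3, `+`))
      Xr <- sigmoid(sweep(h3 %*% params$W4, 2L, params$b4, `+`))
      rec <- if (config$reconstruction == "mse") mse_loss(Xs, Xr)
             else sum(abs(Xs - Xr)) / n
      kl <- kl_loss(mu, lv)
      loss <- a * rec + (1 - a) * kl
      if (!is.finite(loss))
        stop("non-finite loss at epoch ", ep)
      loss_trace[ep] <- loss
      # backward
      dXr <- if (config$reconstruction == "mse") a * 2 * (Xr - Xs) / n
             else a * sign(Xr - Xs) / n
      dA4 <- dXr * Xr * (1 - Xr)
      gW4 <- crossprod(h3, dA4); gb4 <- colSums(dA4)
      dh3 <- tcrossprod(dA4, params$W4)
      dA3 <- dh3 * (h3 > 0)
      gW3 <- crossprod(z, dA3); gb3 <- colSums(dA3)
      dz <- tcrossprod(dA3, params$W3)
      dmu <- dz + (1 - a) * mu / n
      dlv <- dz * eps * sd_ / 2 + (1 - a) * (exp(lv) - 1) / (2 * n)
      gW21 <- crossprod(h1, dmu); gb21 <- colSums(dmu)
      gW22 <- crossprod(h1, dlv); gb22 <- colSums(dlv)
      dh1 <- tcrossprod(dmu, params$W21) + tcrossprod(dlv, params$W22)
      dA1 <- dh1 * (h1 > 0)
      gW1 <- crossprod(Xs, dA1); gb1 <- colSums(dA1)
      grads <- list(W1 = gW1, b1 = gb1, W21 = gW21, b21 = gb21,
                    W22 = gW22, b22 = gb22, W3 = gW3, b3 = gb3,
                    W4 = gW4, b4 = gb4)
      st <- adam_step(params, grads, opt, config$learning_rate)
      params <- st$params; opt <- st$state
    }
    enc <- vae_encode(Xs, params)
    latent <- list(mu = enc$mu, log_var = enc$log_var, z = enc$mu)
    rownames(latent$mu) <- rownames(X)
    structure(list(params = params, latent = latent,
                   loss_trace = loss_trace, input_range = rng,
                   config = config),
              class = "VAEFit")
  })
}

#' Write latent representations as CSV (cell id plus coordinates)
#' @param fit a `VAEFit`.
#' @param cell_ids cell identifiers.
#' @param path output path.
#' @export
write_latents <- function(fit, cell_ids, path) {
  df <- data.frame(cell_id = cell_ids, fit$latent$mu, check.names = FALSE)
  colnames(df) <- c("cell_id", paste0("z", seq_len(ncol(fit$latent$mu))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
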