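# Relational variational auto-encoder over normalized postures.
#
# Architecture (5 layers): 66 inputs -> 200 rectified hidden units ->
# 2-dimensional latent -> 200 rectified hidden units -> 66 linear outputs.
# The encoder outputs a Gaussian q(z0|x) = N(mu0, diag(sigma0^2)) in a
# pre-squash space; the latent actually consumed by the decoder (and by the
# maps) is z = tanh(z0), so latent codes live in [-1, 1]^2. The decoder
# likelihood is Gaussian with fixed observation noise sigma_x. A small
# one-hidden-layer relation head predicts the (unit-scaled) score from z;
# its negative log-likelihood enters the loss with weight alpha, the
# evidence lower bound with weight (1 - alpha), so alpha = 0 recovers the
# plain VAE objective. Training is plain backpropagation with Adam; all
# randomness flows from the configured seed.

relu <- function(x) x * (x > 0)

#' VAE training configuration
#'
#' @param alpha mixing weight in [0, 1] between the ELBO term (weight
#'   1 - alpha) and the relation-reconstruction term (weight alpha).
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param seed integer seed; fixes initialization, shuffling and
#'   reparameterization noise (bit-reproducible runs).
#' @param hidden hidden layer width.
#' @param latent latent dimensionality.
#' @param sigma_x decoder observation noise (normalized units); the
#'   reconstruction NLL is sum(err^2) / (2 sigma_x^2).
#' @param sigma_rel relation-head observation noise (unit-scaled score).
#' @param kl_warmup epochs over which the KL weight ramps linearly 0 -> 1.
#' @return list of class `vae_config`.
#' @export
vae_config <- function(alpha = 0.2, epochs = 200, batch_size = 128,
                       lr = 1e-3, seed = 1, hidden = 200, latent = 2,
                       sigma_x = 0.1, sigma_rel = 0.1, kl_warmup = 20) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  structure(list(alpha = alpha, epochs = epochs, batch_size = batch_size,
                 lr = lr, seed = as.integer(seed), hidden = hidden,
                 latent = latent, sigma_x = sigma_x, sigma_rel = sigma_rel,
                 kl_warmup = kl_warmup), class = "vae_config")
}

#' Initialize VAE parameters
#'
#' He-scaled Gaussian initialization of all weight matrices, zero biases.
#'
#' @param n_in input (= output) dimensionality.
#' @param config a [vae_config()].
#' @return list of class `vae_params` with encoder weights (`W1`, `b1`,
#'   `Wm`, `bm`, `Wv`, `bv`), decoder weights (`W3`, `b3`, `W4`, `b4`),
#'   the small relation head (`Wr1`, `br1`, `Wr2`, `br2`; one 8-unit tanh
#'   hidden layer), and the architecture/config.
#' @export
vae_init <- function(n_in = 66, config = vae_config()) {
  set.seed(config$seed)
  h <- config$hidden; k <- config$latent
  gauss <- function(n, m, sd) matrix(rnorm(n * m, 0, sd), n, m)
  p <- list(
    W1 = gauss(n_in, h, sqrt(2 / n_in)), b1 = numeric(h),
    Wm = gauss(h, k, sqrt(1 / h)), bm = numeric(k),
    Wv = gauss(h, k, sqrt(1 / h)), bv = rep(-2, k),
    W3 = gauss(k, h, sqrt(1 / k)), b3 = numeric(h),
    W4 = gauss(h, n_in, sqrt(2 / h)), b4 = numeric(n_in),
    Wr1 = gauss(k, 8, sqrt(1 / k)), br1 = numeric(8),
    Wr2 = gauss(8, 1, sqrt(1 / 8)), br2 = 0,
    n_in = n_in, config = config)
  class(p) <- "vae_params"
  p
}

#' @export
print.vae_params <- function(x, ...) {
  cat("Relational VAE: ", x$n_in, "-", x$config$hidden, "-",
      x$config$latent, "-", x$config$hidden, "-", x$n_in,
      " (rectifier / tanh latent / identity output)\n", sep = "")
  cat("  alpha =", x$config$alpha, " seed =", x$config$seed, "\n")
  invisible(x)
}

# Forward pass; X is n x n_in, eps the reparameterization noise (n x k).
vae_forward <- function(p, X, eps = NULL) {
  H1 <- relu(sweep(X %*% p$W1, 2, p$b1, "+"))
  mu0 <- sweep(H1 %*% p$Wm, 2, p$bm, "+")
  logv <- sweep(H1 %*% p$Wv, 2, p$bv, "+")
  logv <- pmin(pmax(logv, -10), 10)
  sd0 <- exp(0.5 * logv)
  z0 <- if (is.null(eps)) mu0 else mu0 + sd0 * eps
  Z <- tanh(z0)
  H2 <- relu(sweep(Z %*% p$W3, 2, p$b3, "+"))
  Xh <- sweep(H2 %*% p$W4, 2, p$b4, "+")
  Hr <- tanh(sweep(Z %*% p$Wr1, 2, p$br1, "+"))
  Eh <- as.numeric(Hr %*% p$Wr2 + p$br2)
  list(H1 = H1, mu0 = mu0, logv = logv, sd0 = sd0, z0 = z0, Z = Z,
       H2 = H2, Xh = Xh, Hr = Hr, Eh = Eh)
}

#' Relational VAE loss
#'
#' Per-sample mean of
#' `(1 - alpha) * (recon NLL + beta_kl * KL(q(z0|x) || N(0, I))) +
#'  alpha * relation NLL`, with Gaussian NLLs at the configured fixed
#' observation noises. `alpha = 0` is the plain VAE evidence lower bound;
#' at `alpha = 1` the posture-reconstruction branch carries no gradient.
#'
#' @param p a `vae_params`.
#' @param X n x n_in matrix of normalized postures in [0, 1].
#' @param eps_rel numeric vector of unit-scaled ergonomics scores.
#' @param alpha mixing weight; defaults to the trained configuration.
#' @param eps optional reparameterization noise (deterministic if omitted).
#' @param beta_kl KL weight (training ramps it during warm-up).
#' @return scalar loss; components as attributes `recon`, `kl`, `rel`.
#' @export
vae_loss <- function(p, X, eps_rel, alpha = p$config$alpha, eps = NULL,
                     beta_kl = 1) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  f <- vae_forward(p, X, eps)
  n <- nrow(X)
  recon <- sum((f$Xh - X)^2) / (2 * p$config$sigma_x^2) / n
  kl <- sum(0.5 * (f$mu0^2 + exp(f$logv) - f$logv - 1)) / n
  rel <- sum((f$Eh - eps_rel)^2) / (2 * p$config$sigma_rel^2) / n
  out <- (1 - alpha) * (recon + beta_kl * kl) + alpha * rel
  attr(out, "recon") <- recon; attr(out, "kl") <- kl; attr(out, "rel") <- rel
  out
}

# Gradient of vae_loss w.r.t. every parameter (same list layout).
vae_grad <- function(p, X, eps_rel, alpha, eps, beta_kl = 1) {
  f <- vae_forward(p, X, eps)
  n <- nrow(X)
  w_rec <- (1 - alpha) / (p$config$sigma_x^2 * n)
  w_rel <- alpha / (p$config$sigma_rel^2 * n)
  w_kl <- (1 - alpha) * beta_kl / n
  dXh <- w_rec * (f$Xh - X)
  gW4 <- crossprod(f$H2, dXh); gb4 <- colSums(dXh)
  dH2 <- tcrossprod(dXh, p$W4) * (f$H2 > 0)
  gW3 <- crossprod(f$Z, dH2); gb3 <- colSums(dH2)
  dZ <- tcrossprod(dH2, p$W3)
  dEh <- w_rel * (f$Eh - eps_rel)
  gWr2 <- crossprod(f$Hr, dEh); gbr2 <- sum(dEh)
  dHr <- tcrossprod(matrix(dEh, ncol = 1), p$Wr2) * (1 - f$Hr^2)
  gWr1 <- crossprod(f$Z, dHr); gbr1 <- colSums(dHr)
  dZ <- dZ + tcrossprod(dHr, p$Wr1)
  dz0 <- dZ * (1 - f$Z^2)
  dmu0 <- dz0 + w_kl * f$mu0
  if (is.null(eps)) {
    dlogv <- w_kl * 0.5 * (exp(f$logv) - 1)
  } else {
    dlogv <- dz0 * eps * 0.5 * f$sd0 + w_kl * 0.5 * (exp(f$logv) - 1)
  }
  gWm <- crossprod(f$H1, dmu0); gbm <- colSums(dmu0)
  gWv <- crossprod(f$H1, dlogv); gbv <- colSums(dlogv)
  dH1 <- (tcrossprod(dmu0, p$Wm) + tcrossprod(dlogv, p$Wv)) *
    (f$H1 > 0)
  gW1 <- crossprod(X, dH1); gb1 <- colSums(dH1)
  list(W1 = gW1, b1 = gb1, Wm = gWm, bm = gbm, Wv = gWv, bv = gbv,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4,
       Wr1 = gWr1, br1 = gbr1, Wr2 = gWr2, br2 = gbr2)
}

vae_param_names <- c("W1", "b1", "Wm", "bm", "Wv", "bv",
                     "W3", "b3", "W4", "b4", "Wr1", "br1", "Wr2", "br2")

#' Train the relational VAE
#'
#' Minibatch Adam on [vae_loss()]. The KL weight ramps linearly from 0 to 1
#' over `kl_warmup` epochs (standard warm-up against early posterior
#' collapse of the two-dimensional latent). Runs with the same seed and
#' data are bit-identical. Aborts with a diagnostic if the loss diverges.
#'
#' @param X n x n_in matrix of normalized postures in [0, 1].
#' @param eps_rel numeric vector of unit-scaled ergonomics scores
#'   (relation targets), length n.
#' @param config a [vae_config()].
#' @param init optional `vae_params` to continue training from
#'   (fine-tuning); the configuration's seed still governs shuffling.
#' @param verbose print the loss every 20 epochs.
#' @return trained `vae_params`, with the per-epoch mean loss in
#'   `$history`.
#' @export
vae_train <- function(X, eps_rel, config = vae_config(), init = NULL,
                      verbose = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("training needs at least two postures")
  if (length(eps_rel) != nrow(X)) stop("one relation value per posture")
  p <- if (is.null(init)) vae_init(ncol(X), config) else init
  if (!is.null(init) && ncol(X) != p$n_in) stop("dimension mismatch")
  cfg <- config
  set.seed(cfg$seed + 1L)
  mstate <- lapply(p[vae_param_names], function(w) w * 0)
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; ade <- 1e-8
  tstep <- 0
  n <- nrow(X)
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    beta_kl <- if (cfg$kl_warmup > 0) min(1, ep / cfg$kl_warmup) else 1
    idx <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      rows <- idx[start:min(start + cfg$batch_size - 1, n)]
      Xb <- X[rows, , drop = FALSE]
      eb <- eps_rel[rows]
      eps <- matrix(rnorm(length(rows) * cfg$latent), length(rows),
                    cfg$latent)
      loss <- vae_loss(p, Xb, eb, cfg$alpha, eps, beta_kl)
      if (!is.finite(loss))
        stop("training diverged at epoch ", ep, " (non-finite loss); ",
             "reduce the learning rate")
      g <- vae_grad(p, Xb, eb, cfg$alpha, eps, beta_kl)
      tstep <- tstep + 1
      corr <- sqrt(1 - b2^tstep) / (1 - b1^tstep)
      for (nm in vae_param_names) {
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g[[nm]]
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g[[nm]]^2
        p[[nm]] <- p[[nm]] - cfg$lr * corr * mstate[[nm]] /
          (sqrt(vstate[[nm]]) + ade)
      }
      ep_loss <- ep_loss + as.numeric(loss); nb <- nb + 1
    }
    history[ep] <- ep_loss / nb
    if (verbose && ep %% 20 == 0)
      message(sprintf("epoch %d  loss %.4f", ep, history[ep]))
  }
  p$config <- cfg
  p$history <- history
  p
}

#' Fine-tune a trained VAE on a task-specific dataset
#'
#' Continues training from existing parameters (typically pre-trained on a
#' broad posture set) on a smaller task-specific set, at a reduced learning
#' rate.
#'
#' @param p trained `vae_params`.
#' @param X,eps_rel task dataset (normalized postures, unit-scaled scores).
#' @param epochs fine-tuning epochs.
#' @param lr learning rate (default: a tenth of the pre-training rate).
#' @param seed seed for the fine-tuning phase.
#' @return updated `vae_params`.
#' @export
vae_fine_tune <- function(p, X, eps_rel, epochs = 30, lr = p$config$lr / 10,
                          seed = p$config$seed + 100L) {
  cfg <- p$config
  cfg$epochs <- epochs; cfg$lr <- lr; cfg$seed <- as.integer(seed)
  cfg$kl_warmup <- 0
  vae_train(X, eps_rel, cfg, init = p)
}

#' Encode postures to the latent space / decode latent points
#'
#' `vae_encode` maps normalized postures to the 2-D latent: the posterior
#' mean `mu` (= tanh of the pre-squash mean, in [-1,1]^2), the pre-squash
#' standard deviation `sigma`, and a sample `z` (equal to `mu` in
#' deterministic mode). `vae_decode` maps latent points to normalized
#' postures, clamped to [0, 1].
#'
#' @param p trained `vae_params`.
#' @param X matrix (or single vector) of normalized postures.
#' @param deterministic if `TRUE` the returned `z` is the posterior mean.
#' @return `vae_encode`: list with `mu`, `sigma`, `z` (n x 2 matrices);
#'   `vae_decode`: n x n_in matrix in [0, 1].
#' @export
vae_encode <- function(p, X, deterministic = TRUE) {
  single <- is.null(dim(X))
  if (single) X <- matrix(X, 1)
  if (ncol(X) != p$n_in) stop("input dimension must be ", p$n_in)
  f <- vae_forward(p, X)
  mu <- tanh(f$mu0)
  if (deterministic) {
    z <- mu
  } else {
    eps <- matrix(rnorm(length(f$mu0)), nrow(f$mu0))
    z <- tanh(f$mu0 + f$sd0 * eps)
  }
  list(mu = mu, sigma = f$sd0, z = z)
}

#' @rdname vae_encode
#' @param Z matrix (or single 2-vector) of latent points in [-1, 1]^2.
#' @export
vae_decode <- function(p, Z) {
  single <- is.null(dim(Z))
  if (single) Z <- matrix(Z, 1)
  if (ncol(Z) != p$config$latent)
    stop("latent dimension must be ", p$config$latent)
  H2 <- relu(sweep(Z %*% p$W3, 2, p$b3, "+"))
  Xh <- sweep(H2 %*% p$W4, 2, p$b4, "+")
  out <- pmin(pmax(Xh, 0), 1)
  if (single) out[1, ] else out
}

#' Predict the relation (ergonomics score) from latent points
#' @param p trained `vae_params`.
#' @param Z n x 2 matrix of latent points.
#' @return numeric vector of unit-scaled score predictions.
#' @export
vae_relation <- function(p, Z) {
  if (is.null(dim(Z))) Z <- matrix(Z, 1)
  Hr <- tanh(sweep(Z %*% p$Wr1, 2, p$br1, "+"))
  as.numeric(Hr %*% p$Wr2 + p$br2)
}

#' Save / load VAE checkpoints
#'
#' Checkpoints are written as an RDS container holding the parameter list,
#' alongside a plain-text `.meta.yaml` with the architecture, configuration
#' and seed for human inspection.
#'
#' @param p trained `vae_params`.
#' @param path checkpoint path (`.rds`).
#' @return `vae_load` returns the `vae_params`.
#' @export
vae_save <- function(p, path) {
  saveRDS(p, path)
  meta <- list(n_in = p$n_in, hidden = p$config$hidden,
               latent = p$config$latent, alpha = p$config$alpha,
               epochs = p$config$epochs, batch_size = p$config$batch_size,
               lr = p$config$lr, seed = p$config$seed,
               final_loss = if (!is.null(p$history))
                 p$history[length(p$history)] else NA)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname vae_save
#' @export
vae_load <- function(path) {
  p <- readRDS(path)
  if (!inherits(p, "vae_params")) stop("not a VAE checkpoint")
  p
}
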