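#' Training configuration
#'
#' The model is trained with plain stochastic gradient descent; each of the
#' five per-minibatch steps has its own learning rate (the steps are
#' sequential separate updates, not a weighted sum). The shared defaults
#' assume standardized conditioning variables (see `standardize`); on raw
#' percent-scale GI the squared-error gradients are orders of magnitude
#' larger than the cross-entropy and adversarial ones and the `gi` rate
#' must be reduced accordingly.
#'
#' @param batch_size minibatch size.
#' @param epochs passes over the training set.
#' @param lr named learning rates for the five steps: `disc` (a:
#'   discriminator), `confuse` (b: encoder vs discriminator), `recon` (c:
#'   joint autoencoder), `gi` (d: GI regression), `manifold` (e: manifold
#'   cost). Partial named vectors override the defaults.
#' @param manifold_batch concentration draws per fingerprint in step e
#'   (>= 2).
#' @param grad_clip per-step global L2 gradient-norm ceiling (the step's
#'   gradients are rescaled to this norm when they exceed it); a standard
#'   SGD stabilizer against occasional large minibatch gradients.
#'   `Inf` disables clipping.
#' @param eps probability clamp for all log terms.
#' @param holdout_frac fraction of records held out to track discriminator
#'   accuracy (prior vs encoded) per epoch.
#' @param standardize if `TRUE` (default), z-score LCONC and GI by the
#'   training-set moments before training, so all five objectives live on
#'   comparable O(1) scales and one SGD step size serves them all; decoded
#'   LCONC is mapped back to the raw log10 molar scale at generation, and
#'   [predict_gi()] maps the latent GI neuron back to raw percent. With
#'   `FALSE` the network sees raw LCONC/GI and the per-step rates must be
#'   retuned to the data's scale.
#' @param seed seed for shuffling, prior draws and manifold draws.
#' @return a `molaae_train_config` list.
#' @export
train_config <- function(batch_size = 64L, epochs = 200L,
                         lr = NULL, manifold_batch = 8L, grad_clip = 5,
                         eps = 1e-7, holdout_frac = 0.1, standardize = TRUE,
                         seed = 1L) {
  defaults <- c(disc = 0.05, confuse = 0.05, recon = 0.05, gi = 0.1,
                manifold = 0.5)
  if (!is.null(lr)) {
    bad <- setdiff(names(lr), names(defaults))
    if (length(bad) > 0L) stop("unknown lr name(s): ", paste(bad, collapse = ", "),
                               call. = FALSE)
    defaults[names(lr)] <- lr
  }
  stopifnot(batch_size >= 1L, epochs >= 0L, all(defaults >= 0),
            manifold_batch >= 2L, grad_clip > 0, eps > 0, eps <= 1e-3,
            holdout_frac >= 0, holdout_frac < 1)
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 lr = defaults, manifold_batch = as.integer(manifold_batch),
                 grad_clip = grad_clip, eps = eps, holdout_frac = holdout_frac,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "molaae_train_config")
}

#' Autoencoder reconstruction loss
#'
#' Sum of the per-bit binary cross-entropy (logloss) of the fingerprint
#' part and the squared error of the concentration part, averaged over the
#' minibatch: `sum_i -[b_i ln p_i + (1-b_i) ln(1-p_i)] + (lconc_pred -
#' lconc_true)^2`. Probabilities are clamped to `[eps, 1-eps]` before logs.
#'
#' @param probs decoded probabilities, vector (length 166) or n x 166 matrix.
#' @param bits target fingerprint bits, same shape.
#' @param lconc_pred,lconc_true decoded and target concentrations.
#' @param eps probability clamp.
#' @return scalar loss.
#' @export
reconstruction_loss <- function(probs, bits, lconc_pred, lconc_true, eps = 1e-7) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1L)
  stopifnot(all(dim(probs) == dim(bits)),
            length(lconc_pred) == nrow(probs),
            length(lconc_true) == nrow(probs))
  p <- clamp_prob(probs, eps)
  bce <- -rowSums(bits * log(p) + (1 - bits) * log(1 - p))
  loss <- mean(bce + (lconc_pred - lconc_true)^2)
  if (!is.finite(loss)) stop("non-finite reconstruction loss", call. = FALSE)
  loss
}

#' GI regression loss
#'
#' Mean squared error between the latent GI neuron and the target growth
#' inhibition, averaged over the minibatch.
#'
#' @param gi_pred encoded GI values (the latent GI neuron).
#' @param gi_true target GI values.
#' @return scalar loss.
#' @export
gi_regression_loss <- function(gi_pred, gi_true) {
  stopifnot(length(gi_pred) == length(gi_true))
  mean((gi_pred - gi_true)^2)
}

# Manifold loss and gradient for one group of representations (m x 4).
# loss = 1 - mean pairwise cosine similarity; pairs involving a zero-norm
# representation contribute similarity 0 and no gradient.
manifold_group <- function(R) {
  m <- nrow(R)
  npairs <- m * (m - 1) / 2
  nrm <- sqrt(rowSums(R^2))
  zero <- nrm < 1e-12
  U <- R / pmax(nrm, 1e-12)
  if (any(zero)) U[zero, ] <- 0
  C <- tcrossprod(U)
  sum_cos <- (sum(C) - sum(diag(C))) / 2
  loss <- 1 - sum_cos / npairs
  row_cos <- rowSums(C) - diag(C)
  S <- sweep(-U, 2L, colSums(U), "+")   # row i: sum over j != i of u_j
  dR <- -(S - row_cos * U) / pmax(nrm, 1e-12) / npairs
  if (any(zero)) dR[zero, ] <- 0
  list(loss = loss, dR = dR, any_zero = any(zero))
}

#' Manifold (concentration-invariance) loss
#'
#' Encodes the same fingerprint at each concentration in `lconc_draws` and
#' returns one minus the mean pairwise cosine similarity of the resulting
#' 4-d representations. Minimizing it maximizes cosine similarity between
#' representations of the same fingerprint at different concentrations
#' (0 when all representations are parallel, 1 for orthogonal pairs, 2 for
#' antiparallel pairs). Draws are meant to come from a normal with the
#' dataset's concentration mean and variance.
#'
#' @param model a `molaae_model`.
#' @param fingerprint one binary fingerprint (length 166).
#' @param lconc_draws at least two concentration values.
#' @return scalar loss in `[0, 2]`.
#' @export
manifold_loss <- function(model, fingerprint, lconc_draws) {
  stopifnot(length(lconc_draws) >= 2L)
  X <- matrix(rep(as.numeric(fingerprint), length(lconc_draws)),
              ncol = length(fingerprint), byrow = TRUE)
  code <- encode(model, X, lconc_draws)
  g <- manifold_group(code$representation)
  if (g$any_zero)
    warning("zero-norm representation in manifold loss; affected pairs scored 0")
  g$loss
}

#' Adversarial losses for discriminator and encoder
#'
#' Binary cross-entropy with the fixed label convention prior = 1,
#' encoded = 0. `d_loss` is the discriminator's mean cross-entropy over the
#' combined prior + encoded batch (so a constant-0.5 discriminator scores
#' ln 2); `g_loss` is the encoder's confusion loss, the cross-entropy of
#' the encoded representations against label 1.
#'
#' @param model a `molaae_model`.
#' @param representations encoded 4-d representations (n x 4).
#' @param prior_samples draws from the 4-d standard-normal prior (m x 4).
#' @param eps probability clamp.
#' @return list with `d_loss` and `g_loss`.
#' @export
adversarial_losses <- function(model, representations, prior_samples, eps = 1e-7) {
  s_enc <- clamp_prob(discriminate(model, representations), eps)
  s_pri <- clamp_prob(discriminate(model, prior_samples), eps)
  d_loss <- mean(c(-log(s_pri), -log(1 - s_enc)))
  g_loss <- mean(-log(s_enc))
  if (!is.finite(d_loss) || !is.finite(g_loss))
    stop("non-finite adversarial loss", call. = FALSE)
  list(d_loss = d_loss, g_loss = g_loss)
}

manifold_moments <- function(model, batch) {
  ns <- model$norm_stats
  if (isTRUE(model$standardized)) return(c(mean = 0, sd = 1))
  if (!is.null(ns)) return(c(mean = ns$lconc_mean, sd = sqrt(ns$lconc_var)))
  c(mean = mean(batch$lconc), sd = stats::sd(batch$lconc))
}

step_abort <- function(step, loss) {
  if (!is.finite(loss))
    stop("non-finite loss at training step (", step, ")", call. = FALSE)
  loss
}

#' One 5-step training iteration on a minibatch
#'
#' Applies, in order, the five per-minibatch updates, each with its own SGD
#' step: (a) the discriminator learns to distinguish prior draws (label 1)
#' from encoded representations (label 0, detached from the encoder);
#' (b) the encoder learns to confuse the discriminator (discriminator
#' frozen); (c) encoder and decoder jointly minimize the reconstruction
#' loss; (d) the encoder fits the latent GI neuron to the target GI;
#' (e) the encoder minimizes the manifold cost, encoding each fingerprint
#' at `manifold_batch` concentrations drawn from a normal with the
#' dataset's concentration moments. Each step updates exactly its
#' contracted parameter group and nothing else.
#'
#' @param model a `molaae_model`.
#' @param batch list with `X` (n x 166), `lconc`, `gi`.
#' @param config a [train_config()].
#' @return list with the updated `model` and `losses` (named: `d_loss`,
#'   `g_loss`, `recon`, `gi`, `manifold`), each evaluated before its
#'   update.
#' @export
train_iteration <- function(model, batch, config = train_config()) {
  stopifnot(inherits(model, "molaae_model"), inherits(config, "molaae_train_config"))
  B <- nrow(batch$X)
  leak <- model$config$leak
  rw <- rep_width(model$config)
  eps <- config$eps
  lr <- config$lr
  clip <- config$grad_clip

  # (a) discriminator update: prior vs detached encoded representations
  rep_enc <- encode(model, batch$X, batch$lconc)$representation
  prior <- matrix(stats::rnorm(B * rw), ncol = rw)
  d_in <- rbind(prior, rep_enc)
  y <- c(rep(1, B), rep(0, B))
  fwd <- discriminator_forward(model, d_in)
  s <- clamp_prob(fwd$score, eps)
  d_loss <- step_abort("a: discriminator", mean(-(y * log(s) + (1 - y) * log(1 - s))))
  gd <- mlp_backward(model$discriminator, fwd,
                     matrix((fwd$score - y) / (2 * B), ncol = 1L), leak)
  model$discriminator <- sgd_step(model$discriminator, gd,
                                  lr[["disc"]] * grad_scale(list(gd), clip))

  # (b) encoder confusion update: discriminator frozen
  enc <- encode_forward(model, batch$X, batch$lconc)
  repr <- enc$out[, -1L, drop = FALSE]
  fwd <- discriminator_forward(model, repr)
  s <- clamp_prob(fwd$score, eps)
  g_loss <- step_abort("b: confusion", mean(-log(s)))
  back_d <- mlp_backward(model$discriminator, fwd,
                         matrix((fwd$score - 1) / B, ncol = 1L), leak)
  dZ <- cbind(0, back_d$d_in)
  ge <- mlp_backward(model$encoder, enc, dZ, leak)
  model$encoder <- sgd_step(model$encoder, ge,
                            lr[["confuse"]] * grad_scale(list(ge), clip))

  # (c) joint reconstruction update
  enc <- encode_forward(model, batch$X, batch$lconc)
  dec <- mlp_forward(model$decoder, enc$out, leak)
  nb <- model$config$n_bits
  probs <- stats::plogis(dec$out[, seq_len(nb), drop = FALSE])
  lconc_pred <- dec$out[, nb + 1L]
  recon <- step_abort("c: reconstruction",
                      reconstruction_loss(probs, batch$X, lconc_pred, batch$lconc, eps))
  d_out <- cbind((probs - batch$X) / B,
                 2 * (lconc_pred - batch$lconc) / B)
  back_dec <- mlp_backward(model$decoder, dec, d_out, leak)
  back_enc <- mlp_backward(model$encoder, enc, back_dec$d_in, leak)
  sc <- grad_scale(list(back_dec, back_enc), clip)
  model$decoder <- sgd_step(model$decoder, back_dec, lr[["recon"]] * sc)
  model$encoder <- sgd_step(model$encoder, back_enc, lr[["recon"]] * sc)

  # (d) GI regression update
  enc <- encode_forward(model, batch$X, batch$lconc)
  gi_pred <- enc$out[, 1L]
  gi_loss <- step_abort("d: GI regression", gi_regression_loss(gi_pred, batch$gi))
  dZ <- matrix(0, nrow = B, ncol = model$config$latent_width)
  dZ[, 1L] <- 2 * (gi_pred - batch$gi) / B
  ge <- mlp_backward(model$encoder, enc, dZ, leak)
  model$encoder <- sgd_step(model$encoder, ge,
                            lr[["gi"]] * grad_scale(list(ge), clip))

  # (e) manifold update: same fingerprint, manifold_batch concentrations
  m <- config$manifold_batch
  mm <- manifold_moments(model, batch)
  idx <- rep(seq_len(B), each = m)
  draws <- stats::rnorm(B * m, mm[["mean"]], mm[["sd"]])
  enc <- encode_forward(model, batch$X[idx, , drop = FALSE], draws)
  R_all <- enc$out[, -1L, drop = FALSE]
  dR_all <- matrix(0, nrow = B * m, ncol = rw)
  man_loss <- 0
  for (g in seq_len(B)) {
    rows <- ((g - 1L) * m + 1L):(g * m)
    res <- manifold_group(R_all[rows, , drop = FALSE])
    man_loss <- man_loss + res$loss
    dR_all[rows, ] <- res$dR / B
  }
  man_loss <- step_abort("e: manifold", man_loss / B)
  ge <- mlp_backward(model$encoder, enc, cbind(0, dR_all), leak)
  model$encoder <- sgd_step(model$encoder, ge,
                            lr[["manifold"]] * grad_scale(list(ge), clip))

  list(model = model,
       losses = c(d_loss = d_loss, g_loss = g_loss, recon = recon,
                  gi = gi_loss, manifold = man_loss))
}

disc_holdout_accuracy <- function(model, X, lconc) {
  n <- nrow(X)
  repr <- encode(model, X, lconc)$representation
  prior <- matrix(stats::rnorm(n * rep_width(model$config)), ncol = rep_width(model$config))
  mean(c(discriminate(model, prior) > 0.5, discriminate(model, repr) <= 0.5))
}

#' Fit the adversarial autoencoder
#'
#' Runs the 5-step iteration over seeded, shuffled minibatches for the
#' configured number of epochs. A held-out fraction of records (never used
#' for updates) tracks the discriminator's prior-vs-encoded accuracy per
#' epoch; at equilibrium the encoder's representations are
#' indistinguishable from the prior and this accuracy sits near 0.5.
#'
#' @param training_set a `molaae_training_set`.
#' @param model_config a [aae_config()].
#' @param config a [train_config()].
#' @return list with the trained `model`, `log` (a data.frame with one row
#'   per epoch: the five mean step losses plus `disc_acc`), and `holdout`
#'   (the indices of the held-out records, never used for updates).
#' @export
fit_aae <- function(training_set, model_config = aae_config(),
                    config = train_config()) {
  stopifnot(inherits(training_set, "molaae_training_set"))
  model <- init_aae(model_config, norm_stats = training_set$norm_stats)
  lconc <- training_set$lconc
  gi <- training_set$gi
  if (config$standardize) {
    ns <- training_set$norm_stats
    lconc <- (lconc - ns$lconc_mean) / sqrt(ns$lconc_var)
    gi <- (gi - ns$gi_mean) / sqrt(ns$gi_var)
    model$standardized <- TRUE
  }
  N <- nrow(training_set$X)
  set.seed(config$seed)
  n_hold <- floor(config$holdout_frac * N)
  hold <- if (n_hold >= 2L) sample.int(N, n_hold) else integer(0)
  train_idx <- setdiff(seq_len(N), hold)
  acc_idx <- if (length(hold) > 0L) hold else
    sample(train_idx, min(length(train_idx), 256L))
  log_rows <- vector("list", config$epochs)
  if (config$epochs > 0L) {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample(train_idx)
      starts <- seq(1L, length(perm), by = config$batch_size)
      acc <- numeric(5L)
      for (s0 in starts) {
        rows <- perm[s0:min(s0 + config$batch_size - 1L, length(perm))]
        if (length(rows) < 2L) next
        batch <- list(X = training_set$X[rows, , drop = FALSE],
                      lconc = lconc[rows], gi = gi[rows])
        it <- train_iteration(model, batch, config)
        model <- it$model
        acc <- acc + it$losses
      }
      losses <- acc / length(starts)
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, d_loss = losses[1L], g_loss = losses[2L],
        recon = losses[3L], gi = losses[4L], manifold = losses[5L],
        disc_acc = disc_holdout_accuracy(
          model, training_set$X[acc_idx, , drop = FALSE], lconc[acc_idx]))
    }
  }
  log <- if (config$epochs > 0L) do.call(rbind, log_rows) else
    data.frame(epoch = integer(0), d_loss = numeric(0), g_loss = numeric(0),
               recon = numeric(0), gi = numeric(0), manifold = numeric(0),
               disc_acc = numeric(0))
  rownames(log) <- NULL
  list(model = model, log = log, holdout = hold)
}
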