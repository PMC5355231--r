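# Internal multilayer-perceptron machinery: fan-in-scaled initialization,
# cached forward passes, exact backpropagation, and plain SGD updates.
# All nets in the package (encoder, decoder, discriminator) are stacks of
# affine layers with a leaky rectified linear activation on hidden layers
# and a linear final layer; output nonlinearities (logistic on fingerprint
# probabilities, logistic on the discriminator score) are applied by the
# caller so that loss gradients can be taken directly at the logits.

mlp_init <- function(widths) {
  # widths: full layer widths, input first, e.g. c(167, 128, 64, 5)
  n_layers <- length(widths) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- widths[l]
    W[[l]] <- matrix(stats::rnorm(fan_in * widths[l + 1L], sd = 1 / sqrt(fan_in)),
                     nrow = fan_in, ncol = widths[l + 1L])
    b[[l]] <- numeric(widths[l + 1L])
  }
  list(W = W, b = b, widths = widths)
}

lrelu <- function(z, leak) ifelse(z > 0, z, leak * z)
lrelu_grad <- function(z, leak) ifelse(z > 0, 1, leak)

# Forward pass caching pre-activations (Z) and post-activations (A).
# A[[1]] is the input; A[[l+1]] the output of layer l. The final layer is
# linear: A[[L+1]] == Z[[L]].
mlp_forward <- function(net, X, leak) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) lrelu(Z[[l]], leak) else Z[[l]]
  }
  list(out = A[[L + 1L]], A = A, Z = Z)
}

# Backpropagate d(loss)/d(output) through the cached forward pass.
# Returns per-parameter gradients and the gradient w.r.t. the input.
mlp_backward <- function(net, cache, d_out, leak) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  dZ <- d_out
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(cache$A[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    dA <- dZ %*% t(net$W[[l]])
    if (l > 1L) dZ <- dA * lrelu_grad(cache$Z[[l - 1L]], leak)
  }
  list(W = gW, b = gb, d_in = dA)
}

# Scale a set of gradient lists so their joint global L2 norm is at most
# `clip`; returns the common scale factor applied.
grad_scale <- function(grad_sets, clip) {
  if (!is.finite(clip) || clip <= 0) return(1)
  sq <- 0
  for (g in grad_sets) {
    sq <- sq + sum(vapply(g$W, function(w) sum(w^2), numeric(1)))
    sq <- sq + sum(vapply(g$b, function(b) sum(b^2), numeric(1)))
  }
  nrm <- sqrt(sq)
  if (nrm > clip) clip / nrm else 1
}

sgd_step <- function(net, grads, lr) {
  if (lr == 0) return(net)
  for (l in seq_along(net$W)) {
    net$W[[l]] <- net$W[[l]] - lr * grads$W[[l]]
    net$b[[l]] <- net$b[[l]] - lr * grads$b[[l]]
  }
  net
}

clamp_prob <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

as_row_matrix <- function(x, width, what) {
  if (is.null(dim(x))) {
    if (length(x) != width)
      stop(sprintf("%s must have width %d, got %d", what, width, length(x)),
           call. = FALSE)
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != width)
    stop(sprintf("%s must have width %d, got %d", what, width, ncol(x)),
         call. = FALSE)
  storage.mode(x) <- "double"
  x
}
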