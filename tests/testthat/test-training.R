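test_that("reconstruction loss matches its closed forms", {
  bits <- rbinom(166, 1, 0.5)
  # uniform probabilities: 166 ln 2 plus the concentration MSE
  expect_equal(reconstruction_loss(rep(0.5, 166), bits, 0, 0),
               166 * log(2), tolerance = 1e-6)
  expect_equal(reconstruction_loss(rep(0.5, 166), bits, -4, -6),
               166 * log(2) + 4, tolerance = 1e-6)

  # probabilities matching bits at 0.9/0.1: per-bit term -ln 0.9
  b <- c(1, 0, rep(0, 164))
  p <- c(0.9, 0.1, rep(1e-7, 164))
  expect_equal(reconstruction_loss(p, b, 0, 0),
               2 * -log(0.9) + 164 * -log(1 - 1e-7), tolerance = 1e-6)

  # perfect probabilities hit the clamp boundary
  eps <- 1e-7
  expect_equal(reconstruction_loss(as.numeric(bits), bits, 2, 0, eps = eps),
               166 * -log(1 - eps) + 4, tolerance = 1e-6)

  # batch averaging
  P <- rbind(rep(0.5, 166), rep(0.5, 166))
  B <- rbind(bits, bits)
  expect_equal(reconstruction_loss(P, B, c(0, 2), c(0, 0)),
               166 * log(2) + 2, tolerance = 1e-6)
})

test_that("GI regression loss is the batch-mean squared error", {
  expect_equal(gi_regression_loss(5, 5), 0)
  expect_equal(gi_regression_loss(2, -1), 9)
  expect_equal(gi_regression_loss(c(1, 3), c(0, 0)), 5)
})

test_that("manifold loss hits its geometric anchors", {
  mg <- molaae:::manifold_group
  expect_equal(mg(rbind(c(1, 0, 0, 0), c(2, 0, 0, 0)))$loss, 0, tolerance = 1e-6)
  expect_equal(mg(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))$loss, 1, tolerance = 1e-6)
  expect_equal(mg(rbind(c(1, 0, 0, 0), c(-1, 0, 0, 0)))$loss, 2, tolerance = 1e-6)

  # a model whose encoder ignores the concentration input maps the same
  # fingerprint to one representation: loss exactly 0
  m <- init_aae(tiny_config(seed = 4))
  m$encoder$W[[1]][167, ] <- 0
  expect_equal(manifold_loss(m, random_bits(1, seed = 5)[1, ], rnorm(8)),
               0, tolerance = 1e-12)

  # zero-norm representations are scored 0 with a warning
  mz <- zero_last_layer(m, "encoder")
  expect_warning(l <- manifold_loss(mz, random_bits(1)[1, ], c(-6, -5)),
                 "zero-norm")
  expect_equal(l, 1)
})

test_that("adversarial losses match the constant-discriminator closed form", {
  m <- zero_last_layer(init_aae(tiny_config(seed = 6)), "discriminator")
  losses <- adversarial_losses(m, matrix(rnorm(40), ncol = 4),
                               matrix(rnorm(40), ncol = 4))
  expect_equal(losses$d_loss, log(2), tolerance = 1e-6)
  expect_equal(losses$g_loss, log(2), tolerance = 1e-6)
})

test_that("backpropagation agrees with central finite differences", {
  ns <- asNamespace("molaae")
  set.seed(21)
  m <- init_aae(tiny_config(seed = 21))
  B <- 4L
  X <- random_bits(B, seed = 22)
  lc <- rnorm(B); gi <- rnorm(B)
  eps <- 1e-7

  num_grad <- function(f, net, l, i, j, h = 1e-5) {
    m1 <- m; m1[[net]]$W[[l]][i, j] <- m1[[net]]$W[[l]][i, j] + h
    m2 <- m; m2[[net]]$W[[l]][i, j] <- m2[[net]]$W[[l]][i, j] - h
    (f(m1) - f(m2)) / (2 * h)
  }
  pick <- function(net, l) c(sample(nrow(m[[net]]$W[[l]]), 1),
                             sample(ncol(m[[net]]$W[[l]]), 1))

  # reconstruction path: encoder and decoder gradients
  f_recon <- function(mm) {
    p <- decode(mm, encode(mm, X, lc))
    reconstruction_loss(p$probs, X, p$lconc, lc, eps)
  }
  enc <- ns$encode_forward(m, X, lc)
  dec <- ns$mlp_forward(m$decoder, enc$out, m$config$leak)
  probs <- plogis(dec$out[, 1:166]); lp <- dec$out[, 167]
  d_out <- cbind((probs - X) / B, 2 * (lp - lc) / B)
  bd <- ns$mlp_backward(m$decoder, dec, d_out, m$config$leak)
  be <- ns$mlp_backward(m$encoder, enc, bd$d_in, m$config$leak)
  for (l in 1:3) {
    ij <- pick("encoder", l)
    expect_equal(be$W[[l]][ij[1], ij[2]],
                 num_grad(f_recon, "encoder", l, ij[1], ij[2]), tolerance = 1e-5)
    ij <- pick("decoder", l)
    expect_equal(bd$W[[l]][ij[1], ij[2]],
                 num_grad(f_recon, "decoder", l, ij[1], ij[2]), tolerance = 1e-5)
  }

  # GI regression path
  f_gi <- function(mm) gi_regression_loss(encode(mm, X, lc)$gi, gi)
  dZ <- matrix(0, B, 5); dZ[, 1] <- 2 * (enc$out[, 1] - gi) / B
  bg <- ns$mlp_backward(m$encoder, enc, dZ, m$config$leak)
  for (l in 1:3) {
    ij <- pick("encoder", l)
    expect_equal(bg$W[[l]][ij[1], ij[2]],
                 num_grad(f_gi, "encoder", l, ij[1], ij[2]), tolerance = 1e-5)
  }

  # manifold path
  draws <- rnorm(6)
  f_man <- function(mm) manifold_loss(mm, X[1, ], draws)
  encm <- ns$encode_forward(m, X[rep(1L, 6), ], draws)
  mg <- ns$manifold_group(encm$out[, -1, drop = FALSE])
  bm <- ns$mlp_backward(m$encoder, encm, cbind(0, mg$dR), m$config$leak)
  for (l in 1:3) {
    ij <- pick("encoder", l)
    expect_equal(bm$W[[l]][ij[1], ij[2]],
                 num_grad(f_man, "encoder", l, ij[1], ij[2]), tolerance = 1e-4)
  }

  # confusion path through the frozen discriminator
  f_conf <- function(mm) {
    r <- encode(mm, X, lc)$representation
    mean(-log(pmin(pmax(discriminate(m, r), eps), 1 - eps)))
  }
  fwdD <- ns$discriminator_forward(m, enc$out[, -1, drop = FALSE])
  bD <- ns$mlp_backward(m$discriminator, fwdD,
                        matrix((fwdD$score - 1) / B, ncol = 1), m$config$leak)
  bC <- ns$mlp_backward(m$encoder, enc, cbind(0, bD$d_in), m$config$leak)
  for (l in 1:3) {
    ij <- pick("encoder", l)
    expect_equal(bC$W[[l]][ij[1], ij[2]],
                 num_grad(f_conf, "encoder", l, ij[1], ij[2]), tolerance = 1e-5)
  }
})

test_that("each training step touches only its contracted parameters", {
  m <- init_aae(tiny_config(seed = 31))
  batch <- random_batch(8, seed = 32)
  one_step <- function(step) {
    lr <- c(disc = 0, confuse = 0, recon = 0, gi = 0, manifold = 0)
    lr[step] <- 0.05
    set.seed(77)
    train_iteration(m, batch, train_config(lr = lr, seed = 1))$model
  }
  changed <- function(m2, net) !identical(m[[net]], m2[[net]])

  ma <- one_step("disc")
  expect_true(changed(ma, "discriminator"))
  expect_false(changed(ma, "encoder") || changed(ma, "decoder"))

  for (step in c("confuse", "gi", "manifold")) {
    ms <- one_step(step)
    expect_true(changed(ms, "encoder"), label = step)
    expect_false(changed(ms, "decoder") || changed(ms, "discriminator"),
                 label = step)
  }

  mc <- one_step("recon")
  expect_true(changed(mc, "encoder") && changed(mc, "decoder"))
  expect_false(changed(mc, "discriminator"))
})

test_that("zero learning rates leave parameters untouched but report losses", {
  m <- init_aae(tiny_config(seed = 41))
  batch <- random_batch(8, seed = 42)
  lr0 <- c(disc = 0, confuse = 0, recon = 0, gi = 0, manifold = 0)
  set.seed(1)
  it <- train_iteration(m, batch, train_config(lr = lr0))
  expect_identical(it$model$encoder, m$encoder)
  expect_identical(it$model$decoder, m$decoder)
  expect_identical(it$model$discriminator, m$discriminator)
  expect_length(it$losses, 5L)
  expect_true(all(is.finite(it$losses)))
})

test_that("training iterations are seed-deterministic", {
  m <- init_aae(tiny_config(seed = 51))
  batch <- random_batch(8, seed = 52)
  set.seed(7); it1 <- train_iteration(m, batch, train_config())
  set.seed(7); it2 <- train_iteration(m, batch, train_config())
  expect_identical(it1, it2)
})

test_that("fit returns init parameters at zero epochs and a reproducible log", {
  sim <- generate_synthetic(synthetic_spec(n_compounds = 60L, seed = 61L))
  r0 <- fit_aae(sim$training_set, tiny_config(seed = 62), train_config(epochs = 0L))
  m0 <- init_aae(tiny_config(seed = 62), sim$training_set$norm_stats)
  expect_identical(r0$model$encoder, m0$encoder)
  expect_equal(nrow(r0$log), 0L)

  cfg <- train_config(epochs = 3L, batch_size = 16L, seed = 63L)
  r1 <- fit_aae(sim$training_set, tiny_config(seed = 62), cfg)
  r2 <- fit_aae(sim$training_set, tiny_config(seed = 62), cfg)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$model$encoder, r2$model$encoder)
  expect_equal(nrow(r1$log), 3L)
  expect_true(all(is.finite(as.matrix(r1$log))))
})

test_that("short training already reduces the reconstruction loss", {
  sim <- generate_synthetic(synthetic_spec(n_compounds = 120L, seed = 71L))
  r <- fit_aae(sim$training_set, tiny_config(seed = 72),
               train_config(epochs = 30L, seed = 73L))
  expect_lt(tail(r$log$recon, 1), r$log$recon[1])
})
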