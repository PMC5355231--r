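# Shared test fixtures, built in code.

# A deliberately small architecture so forward/backward tests run in
# milliseconds; the default (128/64) architecture is exercised in the
# acceptance suite.
tiny_config <- function(seed = 1L) {
  aae_config(encoder_widths = c(12L, 8L), decoder_widths = c(8L, 12L),
             discriminator_widths = c(6L, 6L), seed = seed)
}

random_bits <- function(n, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rbinom(n * 166L, 1L, p), nrow = n)
  storage.mode(X) <- "integer"
  rownames(X) <- sprintf("FP%05d", seq_len(n))
  X
}

random_batch <- function(n = 8L, seed = 1L) {
  set.seed(seed)
  list(X = random_bits(n), lconc = rnorm(n), gi = rnorm(n))
}

# Zero out one network's final affine layer in place.
zero_last_layer <- function(model, net) {
  L <- length(model[[net]]$W)
  model[[net]]$W[[L]][] <- 0
  model[[net]]$b[[L]][] <- 0
  model
}

write_toy_smiles <- function(path, lines = c("c1ccccc1 mol1", "CCO mol2")) {
  writeLines(lines, path)
  path
}

flat_params <- function(net) unlist(c(net$W, net$b))
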