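#' Model configuration for the adversarial autoencoder
#'
#' The default architecture is: encoder 167 -> 128 -> 64 -> 5 (166
#' fingerprint bits plus one concentration input neuron down to a 5-neuron
#' latent layer), decoder 5 -> 64 -> 128 -> 167 (166 per-bit probabilities
#' via a logistic output plus one linear concentration output), and a
#' discriminator over the 4-dimensional latent "representation" (the latent
#' splits into 1 GI neuron + 4 representation neurons; only the
#' representation is ever discriminated against the prior). Hidden layers
#' use a leaky rectified linear activation; latent and concentration
#' outputs are linear.
#'
#' @param encoder_widths,decoder_widths hidden-layer widths.
#' @param latent_width total latent width (GI neuron + representation).
#'   Values other than 5 are accepted but flagged, since the reference
#'   architecture fixes 5.
#' @param discriminator_widths hidden widths of the discriminator.
#' @param leak negative-side slope of the leaky rectifier.
#' @param seed seed for parameter initialization.
#' @return a `molaae_config` list.
#' @export
aae_config <- function(encoder_widths = c(128L, 64L),
                       decoder_widths = c(64L, 128L),
                       latent_width = 5L,
                       discriminator_widths = c(64L, 64L),
                       leak = 0.01, seed = 1L) {
  stopifnot(length(encoder_widths) >= 1L, length(decoder_widths) >= 1L,
            all(encoder_widths > 0), all(decoder_widths > 0),
            all(discriminator_widths > 0), latent_width >= 2L, leak >= 0)
  if (latent_width != 5L)
    message("non-reference configuration: latent_width = ", latent_width,
            " (reference architecture uses 5)")
  structure(list(encoder_widths = as.integer(encoder_widths),
                 decoder_widths = as.integer(decoder_widths),
                 latent_width = as.integer(latent_width),
                 discriminator_widths = as.integer(discriminator_widths),
                 n_bits = MACCS_NBITS, leak = leak, seed = as.integer(seed)),
            class = "molaae_config")
}

rep_width <- function(config) config$latent_width - 1L

#' Initialize model parameters
#'
#' Weights are drawn from a fan-in-scaled normal (sd = 1/sqrt(fan_in)),
#' biases start at zero; the same seed always yields identical parameters.
#'
#' @param config a [aae_config()].
#' @param norm_stats optional dataset moments (from a
#'   `molaae_training_set`), stored with the model so generation and
#'   manifold sampling can reuse them.
#' @return a `molaae_model`: encoder/decoder/discriminator parameter lists
#'   plus the immutable config and `norm_stats`.
#' @export
init_aae <- function(config = aae_config(), norm_stats = NULL) {
  stopifnot(inherits(config, "molaae_config"))
  set.seed(config$seed)
  io <- config$n_bits + 1L
  model <- structure(list(
    encoder = mlp_init(c(io, config$encoder_widths, config$latent_width)),
    decoder = mlp_init(c(config$latent_width, config$decoder_widths, io)),
    discriminator = mlp_init(c(rep_width(config), config$discriminator_widths, 1L)),
    config = config, norm_stats = norm_stats,
    standardized = FALSE),
    class = "molaae_model")
  model
}

#' @export
print.molaae_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("molaae adversarial autoencoder: %d -> %s -> %d -> %s -> %d\n",
              cfg$n_bits + 1L, paste(cfg$encoder_widths, collapse = " -> "),
              cfg$latent_width, paste(cfg$decoder_widths, collapse = " -> "),
              cfg$n_bits + 1L))
  cat(sprintf("  discriminator on %d-d representation: %s -> 1\n",
              rep_width(cfg), paste(cfg$discriminator_widths, collapse = " -> ")))
  invisible(x)
}

encoder_input <- function(model, fingerprint, lconc) {
  X <- as_row_matrix(fingerprint, model$config$n_bits, "fingerprint")
  if (!all(X %in% c(0, 1)))
    stop("fingerprint input must be binary (0/1)", call. = FALSE)
  if (length(lconc) != nrow(X))
    stop("lconc must have one value per fingerprint row", call. = FALSE)
  cbind(X, as.numeric(lconc))
}

encode_forward <- function(model, fingerprint, lconc) {
  mlp_forward(model$encoder, encoder_input(model, fingerprint, lconc),
              model$config$leak)
}

#' Encode fingerprints and concentrations into latent codes
#'
#' Runs the encoder on one fingerprint (length-166 binary vector) or a
#' batch (n x 166 matrix) with matching concentration value(s). The
#' 5-neuron latent output splits into the GI neuron (first position) and
#' the 4-d representation.
#'
#' @param model a `molaae_model`.
#' @param fingerprint binary vector or matrix.
#' @param lconc numeric vector, one log10 molar concentration per row.
#' @return list with `gi` (numeric, length n) and `representation`
#'   (n x 4 matrix).
#' @export
encode <- function(model, fingerprint, lconc) {
  z <- encode_forward(model, fingerprint, lconc)$out
  list(gi = z[, 1L], representation = z[, -1L, drop = FALSE])
}

#' Predict growth inhibition from fingerprints and concentrations
#'
#' Reads the latent GI neuron for each input and reports it on the raw GI
#' percent scale (undoing the training-time standardization when the model
#' was trained on z-scored targets).
#'
#' @param model a `molaae_model`.
#' @param fingerprint binary vector or matrix.
#' @param lconc numeric vector of log10 molar concentrations.
#' @return numeric vector of predicted GI percentages.
#' @export
predict_gi <- function(model, fingerprint, lconc) {
  gi <- encode(model, fingerprint, lconc)$gi
  if (isTRUE(model$standardized) && !is.null(model$norm_stats))
    gi <- gi * sqrt(model$norm_stats$gi_var) + model$norm_stats$gi_mean
  gi
}

latent_matrix <- function(model, code) {
  if (is.list(code) && !is.null(code$representation))
    code <- cbind(code$gi, code$representation)
  as_row_matrix(code, model$config$latent_width, "latent code")
}

#' Decode latent codes into fingerprint-probability profiles
#'
#' Runs the decoder on one latent code (length-5 vector, GI first) or a
#' batch; the 166 fingerprint outputs pass through a logistic so every
#' probability is strictly inside (0, 1), the concentration output is
#' linear. If the model was trained on standardized concentrations the
#' decoded LCONC is mapped back to the raw log10 molar scale.
#'
#' @param model a `molaae_model`.
#' @param code latent code(s): vector, n x 5 matrix, or an
#'   [encode()] result.
#' @return a `molaae_profiles` object: list with `probs` (n x 166 in
#'   (0,1)), `lconc` (length n), and `index` (original sample indices).
#' @export
decode <- function(model, code) {
  Z <- latent_matrix(model, code)
  out <- mlp_forward(model$decoder, Z, model$config$leak)$out
  nb <- model$config$n_bits
  lconc <- out[, nb + 1L]
  if (isTRUE(model$standardized) && !is.null(model$norm_stats))
    lconc <- lconc * sqrt(model$norm_stats$lconc_var) + model$norm_stats$lconc_mean
  structure(list(probs = stats::plogis(out[, seq_len(nb), drop = FALSE]),
                 lconc = as.numeric(lconc),
                 index = seq_len(nrow(Z))),
            class = "molaae_profiles")
}

discriminator_forward <- function(model, representation) {
  R <- as_row_matrix(representation, rep_width(model$config), "representation")
  fwd <- mlp_forward(model$discriminator, R, model$config$leak)
  fwd$score <- stats::plogis(fwd$out[, 1L])
  fwd
}

#' Score representations against the latent prior
#'
#' The discriminator sees only the 4-d representation part of the latent
#' code (never the GI neuron; enforced by width) and returns the
#' probability-like score that its input was drawn from the prior.
#'
#' @param model a `molaae_model`.
#' @param representation vector of width 4 or n x 4 matrix.
#' @return numeric vector of scores strictly in (0, 1).
#' @export
discriminate <- function(model, representation) {
  discriminator_forward(model, representation)$score
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-contained container (config, dataset
#' `norm_stats`, and all parameter arrays) restorable without any training
#' state; forward passes of the restored model reproduce the original
#' bit-for-bit.
#'
#' @param model a `molaae_model`.
#' @param path checkpoint file path (`.rds`).
#' @export
save_aae <- function(model, path) {
  stopifnot(inherits(model, "molaae_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_aae
#' @export
load_aae <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "molaae_model")) stop("not a molaae checkpoint: ", path, call. = FALSE)
  model
}
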