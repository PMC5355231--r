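#' Prior specification for latent sampling
#'
#' Latent codes are drawn with the GI neuron from Normal(gi_mean, gi_sd^2)
#' — the default N(5, 1) targets compounds with a desired growth-inhibition
#' level — and the 4-d representation from the standard normal prior the
#' discriminator imposed during training.
#'
#' @param n_samples number of latent codes (default 640).
#' @param gi_mean,gi_sd moments of the GI neuron draw.
#' @param seed optional seed; when given, sampling is reproducible.
#' @return a `molaae_prior_spec` list.
#' @export
prior_spec <- function(n_samples = 640L, gi_mean = 5, gi_sd = 1, seed = NULL) {
  stopifnot(n_samples >= 1L, gi_sd > 0)
  structure(list(n_samples = as.integer(n_samples), gi_mean = gi_mean,
                 gi_sd = gi_sd, seed = seed),
            class = "molaae_prior_spec")
}

#' Sample latent codes from the prior
#'
#' @param spec a [prior_spec()].
#' @return an `n_samples` x 5 matrix with columns `gi`, `r1`..`r4`.
#' @export
sample_prior <- function(spec = prior_spec()) {
  stopifnot(inherits(spec, "molaae_prior_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_samples
  codes <- cbind(stats::rnorm(n, spec$gi_mean, spec$gi_sd),
                 matrix(stats::rnorm(n * 4L), ncol = 4L))
  colnames(codes) <- c("gi", paste0("r", 1:4))
  codes
}

#' Decode sampled latent codes into generated profiles
#'
#' Pure function of (model, codes): each latent code decodes to one
#' 166-probability fingerprint profile with its decoded LCONC, order
#' preserved. The GI column of `codes` is interpreted on the raw GI
#' percent scale; if the model was trained on standardized targets it is
#' converted to the latent (z-scored) units the GI neuron was regressed
#' on, so a prior like N(5, 1) keeps its meaning — compounds whose
#' predicted growth is about 5% of control — regardless of the training
#' parameterization.
#'
#' @param model a trained `molaae_model`.
#' @param codes matrix of latent codes from [sample_prior()].
#' @return a `molaae_profiles` object (`probs`, `lconc`, `index`).
#' @export
generate_profiles <- function(model, codes) {
  codes <- latent_matrix(model, codes)
  if (isTRUE(model$standardized) && !is.null(model$norm_stats))
    codes[, 1L] <- (codes[, 1L] - model$norm_stats$gi_mean) /
      sqrt(model$norm_stats$gi_var)
  decode(model, codes)
}

#' Filter generated profiles by decoded concentration
#'
#' Keeps exactly the profiles whose decoded LCONC is strictly below the
#' threshold (default -5.0 log10 molar, i.e. concentrations below 10 uM),
#' preserving order and the original sample indices. An empty result is
#' valid and warned about.
#'
#' @param profiles a `molaae_profiles` object.
#' @param threshold strict upper bound on decoded LCONC.
#' @return the filtered `molaae_profiles`, `index` holding original
#'   indices, with attribute `n_dropped`.
#' @export
filter_by_lconc <- function(profiles, threshold = -5.0) {
  stopifnot(inherits(profiles, "molaae_profiles"))
  keep <- profiles$lconc < threshold
  out <- structure(list(probs = profiles$probs[keep, , drop = FALSE],
                        lconc = profiles$lconc[keep],
                        index = profiles$index[keep]),
                   class = "molaae_profiles")
  attr(out, "n_dropped") <- sum(!keep)
  if (!any(keep))
    warning("no generated profile passed the LCONC < ", threshold, " filter")
  out
}

#' @export
print.molaae_profiles <- function(x, ...) {
  cat(sprintf("molaae profiles: %d profile(s), decoded LCONC in [%.3f, %.3f]\n",
              length(x$lconc),
              if (length(x$lconc)) min(x$lconc) else NA,
              if (length(x$lconc)) max(x$lconc) else NA))
  invisible(x)
}

#' Write / read generated profiles as delimited text
#'
#' Tab-separated with header: `index`, `lconc`, `p001`..`p166`.
#' Probabilities and LCONC are written with fixed 6-decimal formatting so
#' downstream screening is bit-reproducible across platforms.
#'
#' @param profiles a `molaae_profiles` object.
#' @param path file path.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "molaae_profiles"))
  P <- matrix(sprintf("%.6f", profiles$probs), nrow = nrow(profiles$probs))
  dt <- data.table::data.table(index = profiles$index,
                               lconc = sprintf("%.6f", profiles$lconc))
  dt <- cbind(dt, data.table::as.data.table(P))
  data.table::setnames(dt, c("index", "lconc", sprintf("p%03d", seq_len(ncol(P)))))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  structure(list(probs = as.matrix(dt[, -(1:2)]),
                 lconc = as.numeric(dt$lconc),
                 index = as.integer(dt$index)),
            class = "molaae_profiles")
}
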