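Package: molaae
Title: Adversarial Autoencoder for Conditional Molecular Fingerprint Generation and Likelihood Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains an adversarial autoencoder on 166-bit MACCS molecular
    fingerprints jointly with assay concentration (log10 molar, LCONC) and
    tumor growth-inhibition percentage (GI), using a five-step per-minibatch
    SGD iteration (adversarial discriminator/confusion updates, joint
    reconstruction, GI regression, and a cosine-similarity manifold cost that
    makes the latent representation concentration-invariant). Trained decoders
    map latent codes sampled from the prior, with a chosen GI distribution, to
    per-bit fingerprint probability profiles plus a decoded concentration;
    profiles passing an LCONC cutoff are screened against arbitrarily large
    fingerprint libraries by streamed independent-Bernoulli log-likelihood to
    nominate candidate compounds. Includes SMILES featurization through Open
    Babel MACCS keys, loaders for dose-response tables, and a fully seeded
    synthetic-data generator for desk-scale end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
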