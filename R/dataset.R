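#' Load a dose-response table
#'
#' Reads a delimited text table of assay records (one row per compound x
#' concentration measurement) with a log10 molar concentration column
#' (LCONC) and a growth-inhibition percentage column (GI; negative values
#' mean a net reduction of tumor cells). Rows with non-finite LCONC or GI
#' are dropped with a count. An optional cell-line filter restricts the
#' table to one line (e.g. MCF7) before any downstream join.
#'
#' @param path delimited text file (separator sniffed by `data.table::fread`).
#' @param columns named character vector mapping the required record fields
#'   to column names in the file: `c(id = ..., lconc = ..., gi = ...)`.
#' @param cell_line optional value to filter on; requires `cell_line_col`.
#' @param cell_line_col column holding the cell-line label.
#' @return a `data.frame` with columns `compound_id`, `lconc`, `gi` and
#'   attribute `n_dropped` (rows removed for non-finite values; the
#'   cell-line filter is not counted as a drop).
#' @export
load_dose_response <- function(path,
                               columns = c(id = "compound_id", lconc = "lconc", gi = "gi"),
                               cell_line = NULL, cell_line_col = NULL) {
  if (!file.exists(path)) stop("dose-response table not found: ", path, call. = FALSE)
  stopifnot(all(c("id", "lconc", "gi") %in% names(columns)))
  dt <- data.table::fread(path, header = TRUE)
  missing_cols <- setdiff(unname(columns), names(dt))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!is.null(cell_line)) {
    if (is.null(cell_line_col) || !cell_line_col %in% names(dt))
      stop("cell_line filter requested but cell_line_col not present", call. = FALSE)
    dt <- dt[dt[[cell_line_col]] == cell_line, ]
  }
  rec <- data.frame(compound_id = as.character(dt[[columns[["id"]]]]),
                    lconc = suppressWarnings(as.numeric(dt[[columns[["lconc"]]]])),
                    gi = suppressWarnings(as.numeric(dt[[columns[["gi"]]]])),
                    stringsAsFactors = FALSE)
  ok <- is.finite(rec$lconc) & is.finite(rec$gi) & nzchar(rec$compound_id)
  n_dropped <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]
  rownames(rec) <- NULL
  if (nrow(rec) == 0L) stop("no usable assay records in ", path, call. = FALSE)
  if (n_dropped > 0L)
    message(n_dropped, " assay record(s) dropped for non-finite LCONC/GI or blank id")
  attr(rec, "n_dropped") <- n_dropped
  rec
}

norm_stats_of <- function(lconc, gi) {
  list(lconc_mean = mean(lconc), lconc_var = stats::var(lconc),
       gi_mean = mean(gi), gi_var = stats::var(gi))
}

#' Assemble a training set from assay records and fingerprints
#'
#' Joins assay records to fingerprints by compound id. One training row is
#' produced per assay record (compound x concentration), so the same
#' fingerprint appears once per tested concentration; duplicate
#' (id, concentration) rows are kept as replicates. Records whose id has no
#' fingerprint are dropped with a count. Column means/variances of LCONC
#' and GI are stored as `norm_stats` (the concentration moments drive the
#' manifold training step; both pairs drive optional standardization).
#'
#' @param records a `data.frame` from [load_dose_response()].
#' @param fingerprints binary matrix with rownames = compound ids
#'   ([maccs_fingerprints()] / [read_fingerprint_matrix()]).
#' @return a `molaae_training_set`: list with `X` (N x 166), `lconc`, `gi`,
#'   `ids` (all length N), `norm_stats`, and `counts` (records in/kept/
#'   dropped, distinct compounds).
#' @export
build_training_set <- function(records, fingerprints) {
  check_fingerprint_matrix(fingerprints)
  ok <- records$compound_id %in% rownames(fingerprints)
  n_dropped <- sum(!ok)
  kept <- records[ok, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no assay record joins to a fingerprint", call. = FALSE)
  if (n_dropped > 0L)
    message(n_dropped, " assay record(s) dropped: no fingerprint for id")
  X <- fingerprints[kept$compound_id, , drop = FALSE]
  rownames(X) <- NULL
  ts <- structure(list(
    X = X, lconc = kept$lconc, gi = kept$gi, ids = kept$compound_id,
    norm_stats = norm_stats_of(kept$lconc, kept$gi),
    counts = list(n_records_in = nrow(records), n_records = nrow(kept),
                  n_dropped = n_dropped,
                  n_compounds = length(unique(kept$compound_id)))),
    class = "molaae_training_set")
  ts
}

#' @export
print.molaae_training_set <- function(x, ...) {
  cat(sprintf("molaae training set: %d records, %d distinct compounds\n",
              x$counts$n_records, x$counts$n_compounds))
  cat(sprintf("  LCONC mean %.3f var %.3f | GI mean %.2f var %.2f\n",
              x$norm_stats$lconc_mean, x$norm_stats$lconc_var,
              x$norm_stats$gi_mean, x$norm_stats$gi_var))
  invisible(x)
}

#' Specification for the synthetic benchmark generator
#'
#' Describes a fully seeded synthetic stand-in for a dose-response screen
#' joined to fingerprints: structured 166-bit fingerprints drawn from noisy
#' prototypes, assay concentrations from a normal on the log10 molar scale,
#' and GI as a known linear function of fingerprint bits and concentration
#' plus Gaussian noise, so every downstream stage has recoverable ground
#' truth.
#'
#' Defaults emulate a single-cell-line slice of a tumor drug screen at desk
#' scale: 500 compounds from 4 structural prototypes with 5% bit noise,
#' concentrations centered at 1 uM (`lconc_mean = -6`, sd 1.5 log units),
#' and GI on the percent scale (negative = net cell kill) with a negative
#' dose slope so higher concentrations inhibit more.
#'
#' @param n_compounds number of compounds (one assay record each).
#' @param n_prototypes number of fingerprint prototypes.
#' @param bit_flip_rate per-bit flip probability in (0, 0.5).
#' @param prototype_density expected fraction of on-bits in a prototype.
#' @param lconc_mean,lconc_sd moments of the log10 molar concentration.
#' @param gi_coefficients length-166 vector of GI weights on bits (sparse:
#'   default puts weight on 8 designated bits).
#' @param gi_dose_slope GI change per log10 concentration unit.
#' @param gi_noise_sd SD of the additive GI noise, percent points.
#' @param seed integer seed making generation fully reproducible.
#' @return a `molaae_synthetic_spec` list.
#' @export
synthetic_spec <- function(n_compounds = 500L, n_prototypes = 4L,
                           bit_flip_rate = 0.05, prototype_density = 0.3,
                           lconc_mean = -6, lconc_sd = 1.5,
                           gi_coefficients = NULL, gi_dose_slope = -10,
                           gi_noise_sd = 5, seed = 1L) {
  if (n_compounds < 1L) stop("n_compounds must be >= 1", call. = FALSE)
  if (n_prototypes < 1L) stop("n_prototypes must be >= 1", call. = FALSE)
  if (bit_flip_rate < 0 || bit_flip_rate >= 0.5)
    stop("bit_flip_rate must lie in [0, 0.5)", call. = FALSE)
  if (lconc_sd <= 0 || gi_noise_sd < 0)
    stop("lconc_sd must be > 0 and gi_noise_sd >= 0", call. = FALSE)
  if (is.null(gi_coefficients)) {
    gi_coefficients <- numeric(MACCS_NBITS)
    gi_coefficients[c(5L, 23L, 47L, 71L, 96L, 120L, 141L, 160L)] <-
      c(-40, -30, -20, -10, 10, 20, 30, 40)
  }
  if (length(gi_coefficients) != MACCS_NBITS)
    stop("gi_coefficients must have length ", MACCS_NBITS, call. = FALSE)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_prototypes = as.integer(n_prototypes),
                 bit_flip_rate = bit_flip_rate,
                 prototype_density = prototype_density,
                 lconc_mean = lconc_mean, lconc_sd = lconc_sd,
                 gi_coefficients = gi_coefficients,
                 gi_dose_slope = gi_dose_slope, gi_noise_sd = gi_noise_sd,
                 seed = as.integer(seed)),
            class = "molaae_synthetic_spec")
}

draw_fingerprints <- function(n, prototypes, flip_rate, prefix) {
  assignment <- sample.int(nrow(prototypes), n, replace = TRUE)
  X <- prototypes[assignment, , drop = FALSE]
  flips <- matrix(stats::runif(n * MACCS_NBITS) < flip_rate, nrow = n)
  X <- abs(X - flips * 1L)
  storage.mode(X) <- "integer"
  rownames(X) <- sprintf("%s%05d", prefix, seq_len(n))
  list(X = X, assignment = assignment)
}

#' Generate a synthetic training set with known ground truth
#'
#' Fingerprints are drawn by picking a prototype uniformly and flipping each
#' bit independently with `bit_flip_rate`; LCONC ~ Normal(lconc_mean,
#' lconc_sd^2); GI = sum(gi_coefficients * bits) + gi_dose_slope * lconc +
#' Normal(0, gi_noise_sd^2). The generating prototypes, prototype
#' assignment, and GI function are returned for recovery tests.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `training_set` (a `molaae_training_set`) and `truth`
#'   (prototypes, assignment, gi_coefficients, gi_dose_slope, gi_noise_sd).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "molaae_synthetic_spec"))
  set.seed(spec$seed)
  prototypes <- matrix(
    as.integer(stats::runif(spec$n_prototypes * MACCS_NBITS) < spec$prototype_density),
    nrow = spec$n_prototypes)
  drawn <- draw_fingerprints(spec$n_compounds, prototypes, spec$bit_flip_rate, "SYN")
  lconc <- stats::rnorm(spec$n_compounds, spec$lconc_mean, spec$lconc_sd)
  gi <- as.numeric(drawn$X %*% spec$gi_coefficients) +
    spec$gi_dose_slope * lconc +
    stats::rnorm(spec$n_compounds, 0, spec$gi_noise_sd)
  records <- data.frame(compound_id = rownames(drawn$X), lconc = lconc, gi = gi,
                        stringsAsFactors = FALSE)
  ts <- build_training_set(records, drawn$X)
  list(training_set = ts,
       truth = list(prototypes = prototypes, assignment = drawn$assignment,
                    gi_coefficients = spec$gi_coefficients,
                    gi_dose_slope = spec$gi_dose_slope,
                    gi_noise_sd = spec$gi_noise_sd, spec = spec))
}

#' Generate a synthetic screening library
#'
#' Draws `n` fingerprints from the same prototype + bit-flip process as the
#' training set (sharing `spec`'s prototypes when `truth` is supplied), so
#' that likelihood screening against profiles decoded from a model trained
#' on the matching synthetic set has structure to find.
#'
#' @param n library size.
#' @param spec a [synthetic_spec()] (defines flip rate / density).
#' @param truth optional `truth` element from [generate_synthetic()]; when
#'   given, its prototypes are reused, otherwise fresh ones are drawn.
#' @param seed integer seed.
#' @return binary matrix n x 166 with rownames `LIB#####`.
#' @export
synthetic_library <- function(n, spec = synthetic_spec(), truth = NULL,
                              seed = spec$seed + 1L) {
  set.seed(seed)
  prototypes <- if (!is.null(truth)) truth$prototypes else
    matrix(as.integer(stats::runif(spec$n_prototypes * MACCS_NBITS) < spec$prototype_density),
           nrow = spec$n_prototypes)
  draw_fingerprints(n, prototypes, spec$bit_flip_rate, "LIB")$X
}

#' Save / load a training set as a plain-text archive
#'
#' Writes a directory holding `data.tsv` (id, lconc, gi, b001..b166) and
#' `meta.json` (norm_stats and counts). The round trip restores the
#' training set exactly (bits and ids) and numerically (doubles serialized
#' at full precision).
#'
#' @param ts a `molaae_training_set`.
#' @param dir archive directory (created if needed).
#' @return `save_training_set` returns `dir` invisibly; `load_training_set`
#'   the restored training set.
#' @export
save_training_set <- function(ts, dir) {
  stopifnot(inherits(ts, "molaae_training_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dt <- data.table::as.data.table(ts$X)
  data.table::setnames(dt, sprintf("b%03d", seq_len(MACCS_NBITS)))
  dt <- cbind(data.table::data.table(id = ts$ids, lconc = ts$lconc, gi = ts$gi), dt)
  data.table::fwrite(dt, file.path(dir, "data.tsv"), sep = "\t")
  jsonlite::write_json(list(norm_stats = ts$norm_stats, counts = ts$counts),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_training_set
#' @export
load_training_set <- function(dir) {
  dt <- data.table::fread(file.path(dir, "data.tsv"), sep = "\t",
                          colClasses = list(character = "id"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  X <- as.matrix(dt[, -(1:3)])
  storage.mode(X) <- "integer"
  structure(list(X = X, lconc = dt$lconc, gi = dt$gi, ids = dt$id,
                 norm_stats = as.list(meta$norm_stats),
                 counts = as.list(meta$counts)),
            class = "molaae_training_set")
}
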