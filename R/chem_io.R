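#' @importFrom data.table fread fwrite as.data.table
NULL

MACCS_NBITS <- 166L

#' Parse a SMILES file into molecule records
#'
#' Reads a delimited SMILES file (one molecule per line) and returns the
#' parseable records. Lines are split on the given separator; the SMILES
#' string and identifier are taken from configurable columns (`.smi`
#' convention: SMILES first, id second). Lines without a SMILES token are
#' rejected and counted, never silently dropped. Chemical parseability is
#' checked later, at featurization.
#'
#' @param path path to the SMILES file.
#' @param smiles_col,id_col 1-based column holding the SMILES string and the
#'   identifier. If a line has no id column, an id is synthesized from the
#'   line number (`mol<line>`).
#' @param sep field separator; `""` (default) splits on any whitespace.
#' @param comment_char lines starting with this character are ignored
#'   (not counted as rejections).
#' @return a `data.frame` with columns `id` and `smiles`, one row per
#'   parseable line, with attribute `n_rejected` (count of malformed lines)
#'   and `rejected_lines` (their line numbers).
#' @export
parse_smiles_file <- function(path, smiles_col = 1L, id_col = 2L, sep = "",
                              comment_char = "#") {
  if (!file.exists(path)) stop("SMILES file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), comment_char) | trimws(lines) == ""
  ids <- character(0); smiles <- character(0); rejected <- integer(0)
  split_re <- if (identical(sep, "")) "[[:space:]]+" else sep
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    tokens <- strsplit(trimws(lines[i]), split_re)[[1L]]
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) < smiles_col || !nzchar(tokens[smiles_col])) {
      rejected <- c(rejected, i)
      next
    }
    ids <- c(ids, if (length(tokens) >= id_col && nzchar(tokens[id_col]))
      tokens[id_col] else paste0("mol", i))
    smiles <- c(smiles, tokens[smiles_col])
  }
  if (length(smiles) == 0L)
    stop("no parseable molecules in ", path, call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate molecule ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (length(rejected) > 0L)
    message(length(rejected), " malformed line(s) rejected from ", path,
            " (lines ", paste(rejected, collapse = ", "), ")")
  out <- data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
  attr(out, "n_rejected") <- length(rejected)
  attr(out, "rejected_lines") <- rejected
  out
}

parse_one_smiles <- function(smiles) {
  tryCatch(
    ChemmineOB::forEachMol("SMI", paste0(smiles, "\n"), identity)[[1L]],
    error = function(e) NULL)
}

#' Compute the 166-bit MACCS fingerprint of one molecule
#'
#' Featurizes a SMILES string into the 166 MACCS structural keys using the
#' Open Babel key definitions (via ChemmineOB). Key i (1..166) maps to
#' vector position i. Featurization is deterministic: identical SMILES give
#' identical bits.
#'
#' @param smiles a SMILES string.
#' @param id identifier reported in the error if the SMILES cannot be parsed.
#' @return integer vector of length 166 with elements in \{0, 1\}.
#' @export
maccs_fingerprint <- function(smiles, id = smiles) {
  mol <- parse_one_smiles(smiles)
  if (is.null(mol)) {
    cond <- structure(
      class = c("molaae_featurization_error", "error", "condition"),
      list(message = paste0("unparseable SMILES for id '", id, "': ", smiles),
           call = sys.call(-1), id = id, smiles = smiles))
    stop(cond)
  }
  bits <- ChemmineOB::fingerprint_OB(list(mol), "MACCS")
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1L)
  as.integer(bits[1L, seq_len(MACCS_NBITS)])
}

#' Featurize a set of molecules into a fingerprint matrix
#'
#' Applies [maccs_fingerprint()] to every molecule; records whose SMILES do
#' not parse are excluded and reported by id, never silently dropped.
#'
#' @param molecules a `data.frame` with columns `id` and `smiles`, as
#'   returned by [parse_smiles_file()].
#' @return an integer matrix (one row per featurized molecule, 166 columns,
#'   rownames = ids) with attributes `n_rejected` and `rejected_ids`.
#' @export
maccs_fingerprints <- function(molecules) {
  stopifnot(is.data.frame(molecules), all(c("id", "smiles") %in% names(molecules)))
  rows <- vector("list", nrow(molecules))
  ok <- logical(nrow(molecules))
  for (i in seq_len(nrow(molecules))) {
    fp <- tryCatch(maccs_fingerprint(molecules$smiles[i], molecules$id[i]),
                   molaae_featurization_error = function(e) NULL)
    if (!is.null(fp)) { rows[[i]] <- fp; ok[i] <- TRUE }
  }
  if (!any(ok)) stop("no molecule could be featurized", call. = FALSE)
  X <- do.call(rbind, rows[ok])
  rownames(X) <- molecules$id[ok]
  if (any(!ok))
    message(sum(!ok), " molecule(s) rejected at featurization: ",
            paste(molecules$id[!ok], collapse = ", "))
  attr(X, "n_rejected") <- sum(!ok)
  attr(X, "rejected_ids") <- molecules$id[!ok]
  X
}

check_fingerprint_matrix <- function(X) {
  if (is.null(dim(X)) || ncol(X) != MACCS_NBITS)
    stop("fingerprint matrix must have exactly ", MACCS_NBITS, " columns",
         call. = FALSE)
  if (nrow(X) == 0L) stop("refusing an empty fingerprint matrix", call. = FALSE)
  if (!all(X %in% c(0L, 1L)))
    stop("fingerprint matrix must be binary (0/1)", call. = FALSE)
  if (is.null(rownames(X)))
    stop("fingerprint matrix must carry row identifiers", call. = FALSE)
  invisible(X)
}

#' Write / read a fingerprint matrix as delimited text
#'
#' The on-disk format is a tab-separated table with a header row: column
#' `id` followed by `b001`..`b166` holding 0/1 values. The round trip
#' `read_fingerprint_matrix(write_fingerprint_matrix(X, p))` preserves ids,
#' row order and every bit. The format is line-oriented and therefore
#' streamable (see [screen_library()]).
#'
#' @param X integer matrix, n x 166, rownames = compound ids.
#' @param path output (input) file path.
#' @return `write_fingerprint_matrix` returns `path` invisibly;
#'   `read_fingerprint_matrix` returns the matrix.
#' @export
write_fingerprint_matrix <- function(X, path) {
  check_fingerprint_matrix(X)
  dt <- data.table::as.data.table(X)
  data.table::setnames(dt, sprintf("b%03d", seq_len(MACCS_NBITS)))
  dt <- cbind(data.table::data.table(id = rownames(X)), dt)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_fingerprint_matrix
#' @export
read_fingerprint_matrix <- function(path) {
  if (!file.exists(path)) stop("fingerprint matrix not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = list(character = "id"))
  if (!identical(names(dt)[1L], "id") || ncol(dt) != MACCS_NBITS + 1L)
    stop("malformed fingerprint matrix: expected 'id' + ", MACCS_NBITS,
         " bit columns in ", path, call. = FALSE)
  X <- as.matrix(dt[, -1L])
  storage.mode(X) <- "integer"
  dimnames(X) <- list(dt$id, NULL)   # bit columns are positional (keys 1..166)
  check_fingerprint_matrix(X)
  X
}
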