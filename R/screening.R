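#' Bernoulli log-likelihood of a fingerprint under a probability profile
#'
#' The matching score between a binary fingerprint and a decoded per-bit
#' probability profile: `sum_i [b_i ln p_i + (1-b_i) ln(1-p_i)]`, treating
#' the 166 bits as independent Bernoulli variables. Higher is a better
#' match. Probabilities are clamped to `[eps, 1-eps]` before logs.
#'
#' @param probs numeric vector of 166 probabilities in (0, 1).
#' @param bits binary vector of 166 fingerprint bits.
#' @param eps probability clamp.
#' @return scalar log-likelihood (<= 0).
#' @export
bernoulli_loglik <- function(probs, bits, eps = 1e-7) {
  if (length(probs) != length(bits))
    stop("probs and bits must have equal length", call. = FALSE)
  p <- clamp_prob(probs, eps)
  sum(bits * log(p) + (1 - bits) * log(1 - p))
}

# All-profile chunk scorer: L[i, j] = loglik of library row i under profile j.
chunk_logliks <- function(B, logP, log1mP) {
  B %*% logP + (1 - B) %*% log1mP
}

merge_topk <- function(current, ll, row_idx, ids, k) {
  cand <- data.frame(id = c(current$id, ids),
                     ll = c(current$ll, ll),
                     idx = c(current$idx, row_idx),
                     stringsAsFactors = FALSE)
  ord <- order(-cand$ll, cand$idx)
  cand[ord[seq_len(min(k, nrow(cand)))], , drop = FALSE]
}

#' Screen a fingerprint library against generated profiles
#'
#' Scores every library fingerprint against every profile by
#' [bernoulli_loglik()] and keeps the top `k` hits per profile. The library
#' is streamed in chunks — either from a fingerprint-matrix file (the
#' [write_fingerprint_matrix()] format) or an in-memory matrix — so
#' arbitrarily large libraries never need to fit in memory; all profiles
#' are scored in a single pass. Ties are broken by library order
#' (first-seen wins).
#'
#' @param profiles a `molaae_profiles` object.
#' @param library path to a fingerprint matrix file, or a binary matrix
#'   with rownames.
#' @param k hits to keep per profile (default 10).
#' @param chunk_size library rows scored per chunk.
#' @param eps probability clamp shared with training.
#' @return a `data.frame` of hits: `profile_index`, `rank` (1..k,
#'   log-likelihood non-increasing), `compound_id`, `log_likelihood`. If
#'   the library holds fewer than `k` compounds all are returned with a
#'   warning.
#' @export
screen_library <- function(profiles, library, k = 10L, chunk_size = 1000L,
                           eps = 1e-7) {
  stopifnot(inherits(profiles, "molaae_profiles"), k >= 1L, chunk_size >= 1L)
  np <- nrow(profiles$probs)
  if (np == 0L) stop("no profiles to screen", call. = FALSE)
  P <- clamp_prob(profiles$probs, eps)
  logP <- t(log(P))        # 166 x np
  log1mP <- t(log(1 - P))
  tops <- replicate(np, list(id = character(0), ll = numeric(0), idx = integer(0)),
                    simplify = FALSE)
  n_seen <- 0L

  score_chunk <- function(B, ids) {
    L <- chunk_logliks(B, logP, log1mP)
    row_idx <- n_seen + seq_len(nrow(B))
    for (j in seq_len(np))
      tops[[j]] <<- merge_topk(tops[[j]], L[, j], row_idx, ids, k)
    n_seen <<- n_seen + nrow(B)
  }

  if (is.character(library)) {
    if (!file.exists(library)) stop("library not found: ", library, call. = FALSE)
    con <- file(library, "r")
    on.exit(close(con))
    header <- strsplit(readLines(con, n = 1L), "\t", fixed = TRUE)[[1L]]
    if (!identical(header[1L], "id") || length(header) != MACCS_NBITS + 1L)
      stop("malformed library header in ", library, call. = FALSE)
    repeat {
      lines <- readLines(con, n = chunk_size)
      if (length(lines) == 0L) break
      dt <- data.table::fread(text = lines, sep = "\t", header = FALSE,
                              colClasses = c("character", rep("integer", MACCS_NBITS)))
      B <- as.matrix(dt[, -1L])
      storage.mode(B) <- "double"
      score_chunk(B, dt[[1L]])
    }
  } else {
    check_fingerprint_matrix(library)
    B_all <- library
    storage.mode(B_all) <- "double"
    for (s0 in seq(1L, nrow(B_all), by = chunk_size)) {
      rows <- s0:min(s0 + chunk_size - 1L, nrow(B_all))
      score_chunk(B_all[rows, , drop = FALSE], rownames(B_all)[rows])
    }
  }
  if (n_seen < k)
    warning("library holds ", n_seen, " compounds, fewer than k = ", k)
  hits <- do.call(rbind, lapply(seq_len(np), function(j) {
    tj <- tops[[j]]
    if (nrow(tj) == 0L) return(NULL)
    data.frame(profile_index = profiles$index[j], rank = seq_len(nrow(tj)),
               compound_id = tj$id, log_likelihood = tj$ll,
               stringsAsFactors = FALSE)
  }))
  rownames(hits) <- NULL
  hits
}

#' Collect unique hits across profiles
#'
#' Deduplicates per-profile hit lists by compound id, recording for each
#' unique compound its best (highest) log-likelihood, best rank, and the
#' number of profiles that selected it. Ordered by best log-likelihood,
#' descending.
#'
#' @param hits a hit `data.frame` from [screen_library()].
#' @return `data.frame` with `compound_id`, `best_log_likelihood`,
#'   `best_rank`, `n_profiles`.
#' @export
collect_unique_hits <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L)
    return(data.frame(compound_id = character(0), best_log_likelihood = numeric(0),
                      best_rank = integer(0), n_profiles = integer(0),
                      stringsAsFactors = FALSE))
  dt <- data.table::as.data.table(hits)
  out <- dt[, list(best_log_likelihood = max(log_likelihood),
                   best_rank = min(rank),
                   n_profiles = length(unique(profile_index))),
            by = "compound_id"]
  out <- out[order(-out$best_log_likelihood), ]
  as.data.frame(out)
}
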