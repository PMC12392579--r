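#' Compatibility-scoring configuration
#'
#' Controls how deduplicated alignments are converted into the compatibility
#' score matrix: the exponential score-decay rate, the optional 5'/3'
#' end-distance filters, and the optional position-specific coverage
#' weights.
#'
#' Both end filters are disabled (`-Inf`) by default: their useful
#' thresholds depend on the library protocol, so they are opt-in. Protocol
#' presets reflecting recommended thresholds are available via
#' [compat_preset()].
#'
#' @param lambda_decay Positive decay rate of the alignment-score prior
#'   (score units per e-fold; default 5).
#' @param beta_s,beta_e 5' / 3' end-distance tolerances. An alignment passes
#'   a filter when its end distance exceeds the read's primary alignment's
#'   end distance by at most `abs(beta)`; `-Inf` disables the filter.
#' @param psw Use position-specific coverage weights (default `FALSE`).
#' @return A list of class `compat_config`.
#' @export
compat_config <- function(lambda_decay = 5, beta_s = -Inf, beta_e = -Inf,
                          psw = FALSE) {
  stopifnot(is.numeric(lambda_decay), lambda_decay > 0,
            is.numeric(beta_s), is.numeric(beta_e), is.logical(psw))
  structure(list(lambda_decay = lambda_decay, beta_s = beta_s,
                 beta_e = beta_e, psw = psw), class = "compat_config")
}

#' Protocol presets for the end-distance filters
#'
#' Recommended end-filter tolerances by protocol: direct RNA reads are
#' heavily 3'-biased, so only the 5' filter is useful there; cDNA and
#' PacBio reads get both.
#'
#' @param protocol `"ont-drna"`, `"ont-cdna"` or `"pacbio"`.
#' @param psw Enable position-specific weights on top of the preset.
#' @return A `compat_config`.
#' @export
compat_preset <- function(protocol = c("ont-drna", "ont-cdna", "pacbio"),
                          psw = FALSE) {
  protocol <- match.arg(protocol)
  if (protocol == "ont-drna")
    compat_config(beta_s = -800, beta_e = -Inf, psw = psw)
  else
    compat_config(beta_s = -600, beta_e = -500, psw = psw)
}

#' End distances of an alignment on its transcript
#'
#' The 5' end distance is the alignment start (distance from the transcript
#' 5' end); the 3' end distance is the transcript length minus the alignment
#' end. Vectorized over records.
#'
#' @param start,end 0-based half-open alignment interval(s).
#' @param transcript_length Transcript length(s), nt.
#' @return A list with numeric vectors `delta_s` and `delta_e`.
#' @export
end_distances <- function(start, end, transcript_length) {
  stopifnot(all(start >= 0), all(end > start), all(end <= transcript_length))
  list(delta_s = as.numeric(start),
       delta_e = as.numeric(transcript_length - end))
}

#' End-filter pass indicators relative to the primary alignment
#'
#' An alignment passes when its end distance exceeds the primary
#' alignment's corresponding end distance by at most the tolerance
#' `abs(beta)`; the threshold is relative so the primary alignment always
#' passes. `beta = -Inf` deactivates the filter (indicator always 1).
#'
#' @param delta End distance(s) of the candidate alignment(s).
#' @param delta_primary End distance of the read's primary alignment.
#' @param beta Filter tolerance (`-Inf` disables).
#' @return Integer vector of 0/1 indicators.
#' @export
end_filter_indicator <- function(delta, delta_primary, beta) {
  as.integer(delta - delta_primary <= abs(beta))
}

#' Exponential score decay within a read's alignments
#'
#' Converts a read's alignment scores into relative priors
#' `sigma = exp(-(max(scores) - score) / lambda)`: the best-scoring
#' transcript gets 1, others decay exponentially with the score gap.
#'
#' @param scores Named numeric vector of one read's per-transcript
#'   alignment scores.
#' @param lambda_decay Positive decay rate.
#' @return Numeric vector of sigma values in (0, 1], same names.
#' @export
score_decay <- function(scores, lambda_decay = 5) {
  stopifnot(length(scores) >= 1, lambda_decay > 0)
  exp(-(max(scores) - scores) / lambda_decay)
}

#' Per-base and per-transcript coverage from alignments
#'
#' `per_base[[t]][k]` counts the reads whose alignment covers base `k`
#' (1-based) of transcript `t`; `per_transcript[t]` is the total number of
#' aligned bases on `t` divided by the transcript length.
#'
#' @param records Deduplicated alignment records.
#' @param index A [transcriptome_index()].
#' @return A list of class `coverage_profile` with elements `per_base`
#'   (list of integer vectors, one per transcript in the index) and
#'   `per_transcript` (named numeric).
#' @export
coverage_profile <- function(records, index) {
  lens <- index$lengths
  per_base <- lapply(lens, function(l) integer(l))
  per_tx <- stats::setNames(numeric(length(lens)), names(lens))
  if (nrow(records)) {
    by_tx <- split(seq_len(nrow(records)), records$transcript_id)
    for (tx in names(by_tx)) {
      l <- lens[[tx]]
      i <- by_tx[[tx]]
      # difference-array trick: +1 at start, -1 past end, cumulative sum
      d <- integer(l + 1L)
      s <- records$start[i] + 1L
      e <- records$end[i] + 1L
      d[seq_len(l + 1L)] <- tabulate(s, l + 1L) - tabulate(e, l + 1L)
      per_base[[tx]] <- cumsum(d)[seq_len(l)]
      per_tx[[tx]] <- sum(records$end[i] - records$start[i]) / l
    }
  }
  structure(list(per_base = per_base, per_transcript = per_tx),
            class = "coverage_profile")
}

#' Position-specific weights for one transcript
#'
#' Turns a transcript's coverage profile into per-base weights favoring
#' sparsely covered positions: differences `eta_k = c^t - c_k` are shifted
#' by `abs(min(eta))` to be nonnegative and normalized to sum to 1. When
#' coverage is uniform every shifted difference is zero and the weights are
#' degenerate; consumers fall back to a flat factor of 1 in that case.
#'
#' @param profile A [coverage_profile()].
#' @param transcript_id Transcript to compute weights for.
#' @return A list with `weights` (numeric vector of length `l(t)`, or
#'   `NULL`) and `degenerate` (logical).
#' @export
position_weights <- function(profile, transcript_id) {
  stopifnot(inherits(profile, "coverage_profile"))
  cb <- profile$per_base[[transcript_id]]
  if (is.null(cb)) stop("transcript '", transcript_id, "' not in profile")
  eta <- profile$per_transcript[[transcript_id]] - cb
  eta_shift <- eta + abs(min(eta))
  s <- sum(eta_shift)
  if (s <= 0)
    return(list(weights = NULL, degenerate = TRUE))
  list(weights = eta_shift / s, degenerate = FALSE)
}

#' Position-weight factor of one alignment
#'
#' Sums the transcript's position-specific weights over the aligned
#' interval `[start, end)`; a full-span alignment therefore gets 1.
#'
#' @param start,end 0-based half-open alignment interval.
#' @param weights Non-degenerate weight vector from [position_weights()].
#' @return Numeric factor in `[0, 1]`.
#' @export
psw_factor <- function(start, end, weights) {
  stopifnot(!is.null(weights), start >= 0, end <= length(weights))
  sum(weights[(start + 1L):end])
}

#' Build the read-by-transcript compatibility matrix
#'
#' The prefilter stage: combines, for every retained alignment, the
#' score-decay prior `sigma`, the 5'/3' end-filter indicators and (when
#' `psw` is on) the position-weight factor `f_eta` into a sparse
#' nonnegative matrix `X` with one row per read and one column per
#' transcript with at least one alignment. `X` is fixed before the EM; only
#' the transcript abundances change across iterations.
#'
#' When `psw` leaves a read with zero total mass (all its aligned positions
#' carry negligible weight — typical of reads on lowly covered transcripts),
#' the position-weight factor is reset to 1 for that read, so the read falls
#' back to the pure score-decay model and never goes unassigned.
#'
#' @param records Deduplicated alignment records (one primary per read).
#' @param index A [transcriptome_index()].
#' @param config A [compat_config()].
#' @return A list of class `compat_matrix` with elements `X` (a
#'   `dgCMatrix`, rows = reads, cols = transcripts with alignments),
#'   `read_lengths` (named integer), `n_psw_fallback` (reads rescued by the
#'   flat-factor fallback) and `config`.
#' @export
build_compatibility <- function(records, index, config = compat_config()) {
  stopifnot(inherits(config, "compat_config"))
  if (nrow(records) == 0L) stop("no alignment records; nothing to score")
  prim_per_read <- tapply(records$is_primary, records$read_id, sum)
  if (any(prim_per_read != 1L))
    stop("each read must have exactly one primary alignment; run ",
         "dedupe_best_per_pair() first")

  rec <- records[order(records$read_id,
                       match(records$transcript_id, index$ids)), ,
                 drop = FALSE]
  read_ids <- sort(unique(rec$read_id))
  tx_ids <- index$ids[index$ids %in% unique(rec$transcript_id)]
  ri <- match(rec$read_id, read_ids)
  ti <- match(rec$transcript_id, tx_ids)
  tlen <- index$lengths[rec$transcript_id]

  # sigma: decay from each read's maximum score
  max_score <- stats::ave(rec$score, ri, FUN = max)
  sigma <- exp(-(max_score - rec$score) / config$lambda_decay)

  # upsilon/omega: end distances relative to the read's primary alignment
  d <- end_distances(rec$start, rec$end, tlen)
  prim_row <- which(rec$is_primary)
  prim_of_read <- prim_row[match(ri, ri[prim_row])]
  ups <- end_filter_indicator(d$delta_s, d$delta_s[prim_of_read],
                              config$beta_s)
  omg <- end_filter_indicator(d$delta_e, d$delta_e[prim_of_read],
                              config$beta_e)

  # f_eta: position-specific weights, flat when off or degenerate
  f_eta <- rep(1, nrow(rec))
  if (config$psw) {
    prof <- coverage_profile(rec, index)
    for (tx in tx_ids) {
      pw <- position_weights(prof, tx)
      if (pw$degenerate) next
      i <- which(rec$transcript_id == tx)
      cw <- c(0, cumsum(pw$weights))
      f_eta[i] <- cw[rec$end[i] + 1L] - cw[rec$start[i] + 1L]
    }
  }

  # fallback: a read whose psw-weighted mass vanishes reverts to f_eta = 1
  mass <- rowsum(f_eta * sigma * ups * omg, ri)
  zero_reads <- as.integer(rownames(mass))[mass[, 1] <= 0]
  n_fallback <- 0L
  if (length(zero_reads)) {
    hit <- ri %in% zero_reads
    f_eta[hit] <- 1
    n_fallback <- length(zero_reads)
  }

  x <- ups * omg * f_eta * sigma
  pos <- x > 0
  X <- Matrix::sparseMatrix(i = ri[pos], j = ti[pos], x = x[pos],
                            dims = c(length(read_ids), length(tx_ids)),
                            dimnames = list(read_ids, tx_ids))
  if (any(Matrix::rowSums(X) <= 0))
    stop("internal error: a read lost all compatibility entries")

  rl <- rec$read_length[prim_row]
  names(rl) <- rec$read_id[prim_row]
  structure(list(X = X, read_lengths = rl[read_ids],
                 n_psw_fallback = n_fallback, config = config),
            class = "compat_matrix")
}

#' @export
print.compat_matrix <- function(x, ...) {
  cat("compat_matrix:", nrow(x$X), "reads x", ncol(x$X), "transcripts,",
      length(x$X@x), "nonzero entries\n")
  invisible(x)
}

#' Dump a compatibility matrix as TSV
#'
#' One row per positive entry: `read_id`, `transcript_id`, `score`.
#'
#' @param compat A `compat_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_compatibility_tsv <- function(compat, path) {
  tr <- Matrix::summary(compat$X)
  df <- data.frame(read_id = rownames(compat$X)[tr$i],
                   transcript_id = colnames(compat$X)[tr$j],
                   score = tr$x)
  df <- df[order(df$read_id, df$transcript_id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
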