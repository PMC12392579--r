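#' EM configuration
#'
#' @param convergence_threshold Stop when the total absolute change in
#'   per-transcript read counts between successive iterations (an L1
#'   distance on the read-count vector) falls below this value. The default
#'   of 10 reads is tuned for experiments with millions of reads; tighten
#'   it (e.g. `1e-6`) for small instances or oracle comparisons.
#' @param max_iterations Iteration cap; hitting it warns but still returns.
#' @param drop_enabled Apply the one-shot drop pruning after the first
#'   E-step (default `TRUE`).
#' @param drop_fraction `f` in the drop threshold
#'   `tau'_r = (1 + f) / |T_r|`, in `[0, 1]` (default 0.1).
#' @return A list of class `em_config`.
#' @export
em_config <- function(convergence_threshold = 10, max_iterations = 5000L,
                      drop_enabled = TRUE, drop_fraction = 0.1) {
  stopifnot(convergence_threshold > 0, max_iterations >= 1,
            drop_fraction >= 0, drop_fraction <= 1)
  structure(list(convergence_threshold = convergence_threshold,
                 max_iterations = as.integer(max_iterations),
                 drop_enabled = isTRUE(drop_enabled),
                 drop_fraction = drop_fraction),
            class = "em_config")
}

.as_X <- function(X) {
  if (inherits(X, "compat_matrix")) X$X else X
}

#' Uniform initial abundances over aligned transcripts
#'
#' Relative abundances start uniform over `T_A`, the transcripts with at
#' least one alignment (the columns of the compatibility matrix);
#' transcripts without alignments keep zero abundance throughout.
#'
#' @param X A `compat_matrix` or sparse reads-by-transcripts matrix.
#' @return Named numeric vector `rho` summing to 1.
#' @export
initialize_rho <- function(X) {
  X <- .as_X(X)
  if (nrow(X) == 0L || ncol(X) == 0L)
    stop("no aligned reads: compatibility matrix is empty")
  stats::setNames(rep(1 / ncol(X), ncol(X)), colnames(X))
}

#' E-step: expected read-to-transcript fractions
#'
#' `alpha_rt = rho_t X_rt / sum_t' rho_t' X_rt'`; each read's row sums
#' to 1.
#'
#' @param rho Named abundance vector over the matrix columns.
#' @param X A `compat_matrix` or sparse matrix.
#' @return Sparse matrix `alpha` with the sparsity pattern of `X`.
#' @export
e_step <- function(rho, X) {
  X <- .as_X(X)
  num <- X %*% Matrix::Diagonal(x = as.numeric(rho[colnames(X)]))
  denom <- Matrix::rowSums(num)
  if (any(denom <= 0))
    stop("E-step denominator is zero for ",
         sum(denom <= 0), " read(s): every read needs a compatible ",
         "transcript with positive abundance")
  alpha <- Matrix::Diagonal(x = 1 / denom) %*% num
  dimnames(alpha) <- dimnames(X)
  methods::as(alpha, "CsparseMatrix")
}

#' M-step: abundance update from assigned fractions
#'
#' Per-transcript read counts are the column sums of `alpha`; relative
#' abundances divide by the total read count `N`, which is constant across
#' iterations.
#'
#' @param alpha Assignment matrix from [e_step()].
#' @param n_reads Total number of assigned reads `N` (defaults to
#'   `nrow(alpha)`).
#' @return A list of class `abundance_estimate` with `rho`, `read_count`
#'   and `n_reads`.
#' @export
m_step <- function(alpha, n_reads = nrow(alpha)) {
  rc <- Matrix::colSums(alpha)
  structure(list(rho = rc / n_reads, read_count = rc, n_reads = n_reads),
            class = "abundance_estimate")
}

#' One-shot drop pruning of weak compatibilities
#'
#' Applied once, right after the first E-step: entries whose assigned
#' fraction falls below the read-specific threshold
#' `tau'_r = (1 + f) / |T_r|` are zeroed in `X`, permanently removing the
#' read-transcript compatibility. Each read's highest-fraction entry is
#' always retained (ties broken toward the lowest transcript index) so
#' that no read is left without a compatible transcript — with `f > 0` an
#' evenly split read would otherwise lose every entry.
#'
#' @param alpha Assignment matrix from the first E-step.
#' @param X Sparse compatibility matrix (same pattern as `alpha`).
#' @param drop_fraction `f` in `[0, 1]`.
#' @return The pruned `X` (zeros dropped from the sparse pattern).
#' @export
drop_compatibilities <- function(alpha, X, drop_fraction = 0.1) {
  X <- .as_X(X)
  tr <- Matrix::summary(methods::as(alpha, "TsparseMatrix"))
  n_per_read <- tabulate(tr$i, nrow(alpha))
  tau <- (1 + drop_fraction) / n_per_read[tr$i]
  keep <- tr$x >= tau
  # guard: retain each read's argmax (lowest column index on ties)
  o <- order(tr$i, -tr$x, tr$j)
  argmax <- o[!duplicated(tr$i[o])]
  keep[argmax] <- TRUE
  Matrix::sparseMatrix(i = tr$i[keep], j = tr$j[keep],
                       x = X[cbind(tr$i[keep], tr$j[keep])],
                       dims = dim(X), dimnames = dimnames(X))
}

#' Complete-data log-likelihood
#'
#' `sum_r log sum_t rho_t X_rt`, evaluated with the current (possibly
#' drop-pruned) compatibility matrix.
#'
#' @param rho Named abundance vector.
#' @param X A `compat_matrix` or sparse matrix.
#' @return Scalar log-likelihood.
#' @export
em_log_likelihood <- function(rho, X) {
  X <- .as_X(X)
  sum(log(as.numeric(X %*% rho[colnames(X)])))
}

#' Run the alignment-guided EM
#'
#' Sequence: uniform initialization over aligned transcripts, first E-step,
#' optional one-shot drop followed by a fresh E-step, then alternating M/E
#' steps until the L1 change in read counts drops below the threshold or
#' the iteration cap is hit.
#'
#' @param X A `compat_matrix` (or bare sparse matrix) from
#'   [build_compatibility()].
#' @param config An [em_config()].
#' @param record_history Keep per-iteration read counts, abundances and
#'   log-likelihoods (for diagnostics and convergence plots).
#' @param verbose Print one line per iteration (iteration, L1 change).
#' @return A list of class `em_fit`: `alpha` (sparse assignment matrix),
#'   `abundance` (an `abundance_estimate`), `iterations`, `converged`,
#'   `X` (the post-drop compatibility matrix) and optionally `history`.
#' @export
run_em <- function(X, config = em_config(), record_history = FALSE,
                   verbose = FALSE) {
  stopifnot(inherits(config, "em_config"))
  Xm <- .as_X(X)
  n_reads <- nrow(Xm)
  rho <- initialize_rho(Xm)

  alpha <- e_step(rho, Xm)
  if (config$drop_enabled) {
    Xm <- drop_compatibilities(alpha, Xm, config$drop_fraction)
    alpha <- e_step(rho, Xm)
  }

  history <- list()
  prev_rc <- numeric(ncol(Xm))
  iter <- 0L
  converged <- FALSE
  repeat {
    est <- m_step(alpha, n_reads)
    iter <- iter + 1L
    delta <- sum(abs(est$read_count - prev_rc))
    if (verbose)
      message(sprintf("iteration %d: L1 read-count change %.6g", iter, delta))
    if (record_history)
      history[[iter]] <- list(read_count = est$read_count, rho = est$rho,
                              log_likelihood = em_log_likelihood(est$rho, Xm))
    if (delta < config$convergence_threshold) {
      converged <- TRUE
      break
    }
    if (iter >= config$max_iterations) break
    prev_rc <- est$read_count
    alpha <- e_step(est$rho, Xm)
  }
  if (!converged)
    warning("EM stopped at the iteration cap (", config$max_iterations,
            ") without meeting the convergence threshold")
  structure(list(alpha = alpha, abundance = est, iterations = iter,
                 converged = converged, X = Xm,
                 history = if (record_history) history else NULL),
            class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  cat("em_fit:", nrow(x$alpha), "reads,", ncol(x$alpha), "transcripts,",
      x$iterations, "iterations",
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  invisible(x)
}
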