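# Small record/matrix builders and independent oracles used across tests.

make_index <- function(lengths) transcriptome_index(lengths)

make_records <- function(read_id, transcript_id, score, start, end,
                         is_primary, read_length = end - start,
                         strand = "forward") {
  data.frame(read_id = read_id, transcript_id = transcript_id,
             score = score, start = as.integer(start), end = as.integer(end),
             is_primary = is_primary, read_length = as.integer(read_length),
             strand = strand, stringsAsFactors = FALSE)
}

# random read x transcript compatibility instance (dense + sparse views)
random_instance <- function(n_reads, n_tx, seed) {
  set.seed(seed)
  X <- matrix(0, n_reads, n_tx,
              dimnames = list(sprintf("r%02d", seq_len(n_reads)),
                              sprintf("t%d", seq_len(n_tx))))
  for (r in seq_len(n_reads)) {
    k <- sample.int(n_tx, 1)
    cols <- sample.int(n_tx, k)
    X[r, cols] <- runif(k, 0.05, 1)
  }
  list(dense = X, sparse = methods::as(Matrix::Matrix(X, sparse = TRUE),
                                       "CsparseMatrix"))
}

# independent, deliberately naive EM: dense matrices, explicit loops,
# uniform initialization, first E-step before the first M-step
naive_em_history <- function(X, n_iter) {
  n <- nrow(X); m <- ncol(X)
  rho <- rep(1 / m, m)
  alpha <- matrix(0, n, m)
  history <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    for (r in seq_len(n)) {
      w <- rho * X[r, ]
      alpha[r, ] <- w / sum(w)
    }
    rc <- colSums(alpha)
    rho <- rc / n
    history[[it]] <- list(read_count = rc, rho = rho)
  }
  history
}

# reference correlation / error metrics written from the textbook formulas
ref_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
ref_spearman <- function(x, y) ref_pearson(rank(x), rank(y))
ref_rmse <- function(x, y) sqrt(sum((x - y)^2) / length(x))

# run the EM with per-iteration history at a tight threshold
em_history <- function(X, n_iter, drop_enabled = FALSE) {
  suppressWarnings(run_em(
    X, em_config(convergence_threshold = 1e-12, max_iterations = n_iter,
                 drop_enabled = drop_enabled),
    record_history = TRUE))
}
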