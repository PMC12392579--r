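#' Read a read-origin truth table
#'
#' @param path TSV with columns `read_id`, `transcript_id` (header
#'   optional).
#' @return Named character vector mapping read_id to origin transcript.
#' @export
read_truth_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          header = FALSE, col.names = c("read_id",
                                                        "transcript_id"))
  if (nrow(df) && df$read_id[1] == "read_id") df <- df[-1, , drop = FALSE]
  if (anyDuplicated(df$read_id))
    stop("truth table assigns multiple origins to some reads")
  stats::setNames(df$transcript_id, df$read_id)
}

#' Confusion tally of read assignments against known origins
#'
#' Fractional convention: the fraction of a read assigned to its origin
#' transcript counts toward TP, any other assigned mass toward FP, and the
#' unassigned remainder (including reads absent from the assignments
#' entirely) toward FN. When a read is assigned to several transcripts with
#' no fractions given (`fraction` column `NA` or missing), its mass is
#' split evenly among them. Every truth read contributes total mass 1 to
#' TP + FN.
#'
#' @param assignments Either a sparse assignment matrix (rows = reads), a
#'   `hard_assignment`, or a data frame with `read_id`, `transcript_id` and
#'   optionally `fraction`.
#' @param truth Named character vector (read -> origin transcript), e.g.
#'   from [read_truth_tsv()].
#' @return A list of class `confusion_tally` with numeric `tp`, `fp`, `fn`
#'   and `n_reads` (number of truth reads).
#' @export
assignment_confusion <- function(assignments, truth) {
  df <- .as_assignment_df(assignments)
  unknown <- setdiff(df$read_id, names(truth))
  if (length(unknown))
    stop("assigned read(s) absent from the truth table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  if (is.null(df$fraction)) df$fraction <- NA_real_
  # even split for reads whose fractions are not specified
  na_rows <- is.na(df$fraction)
  if (any(na_rows)) {
    n_per_read <- table(df$read_id[na_rows])
    df$fraction[na_rows] <- 1 / as.numeric(n_per_read[df$read_id[na_rows]])
  }
  mass <- tapply(df$fraction, df$read_id, sum)
  if (any(mass > 1 + 1e-9))
    stop("assigned fractions exceed 1 for read(s): ",
         paste(utils::head(names(mass)[mass > 1 + 1e-9], 5), collapse = ", "))
  on_origin <- df$transcript_id == truth[df$read_id]
  tp <- sum(df$fraction[on_origin])
  fp <- sum(df$fraction[!on_origin])
  fn <- length(truth) - tp
  structure(list(tp = tp, fp = fp, fn = fn, n_reads = length(truth)),
            class = "confusion_tally")
}

.as_assignment_df <- function(assignments) {
  if (inherits(assignments, "hard_assignment"))
    return(data.frame(read_id = names(assignments$assignment),
                      transcript_id = unname(assignments$assignment),
                      fraction = 1, stringsAsFactors = FALSE))
  if (methods::is(assignments, "Matrix")) {
    tr <- Matrix::summary(methods::as(assignments, "TsparseMatrix"))
    return(data.frame(read_id = rownames(assignments)[tr$i],
                      transcript_id = colnames(assignments)[tr$j],
                      fraction = tr$x, stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(assignments),
            all(c("read_id", "transcript_id") %in% names(assignments)))
  assignments
}

#' Recall, precision and F1 of read assignments
#'
#' Recall divides TP by the total number of reads sequenced (not the
#' number assigned), so unassigned reads depress recall; precision divides
#' TP by all assigned mass; F1 is their harmonic mean. An empty assignment
#' set has undefined precision, reported as 0 with the `undefined_precision`
#' flag set.
#'
#' @param tally A `confusion_tally`.
#' @param total_reads Total reads sequenced (defaults to the tally's truth
#'   size).
#' @return List with `recall`, `precision`, `f1`, `undefined_precision`.
#' @export
precision_recall_f1 <- function(tally, total_reads = tally$n_reads) {
  stopifnot(total_reads > 0)
  recall <- tally$tp / total_reads
  undef <- (tally$tp + tally$fp) == 0
  precision <- if (undef) 0 else tally$tp / (tally$tp + tally$fp)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(recall = recall, precision = precision, f1 = f1,
       undefined_precision = undef)
}

#' Abundance-estimate accuracy metrics
#'
#' Spearman correlation on raw counts, Pearson correlation on
#' log2(count + 1), and RMSE on raw counts, computed over the union of
#' transcripts in the two maps with missing entries as 0. With
#' `min_count`, transcripts where both the estimate and the truth fall
#' below the cutoff are excluded before computing the metrics.
#'
#' @param estimated Named numeric vector of estimated read counts.
#' @param truth Named numeric vector of true read counts.
#' @param min_count Optional filtering cutoff (e.g. 1).
#' @return List with `scc`, `pcc_log`, `rmse`, `n` (transcripts compared)
#'   and `undefined` (character vector of correlations that were undefined
#'   because a vector was constant).
#' @export
abundance_metrics <- function(estimated, truth, min_count = NULL) {
  keys <- union(names(estimated), names(truth))
  if (length(keys) < 3)
    stop("need at least 3 transcripts to compute abundance metrics")
  e <- stats::setNames(numeric(length(keys)), keys)
  t_ <- e
  e[names(estimated)] <- estimated
  t_[names(truth)] <- truth
  if (!is.null(min_count)) {
    keep <- e >= min_count | t_ >= min_count
    e <- e[keep]
    t_ <- t_[keep]
  }
  undefined <- character()
  scc <- if (stats::sd(e) == 0 || stats::sd(t_) == 0) {
    undefined <- c(undefined, "scc"); NA_real_
  } else stats::cor(e, t_, method = "spearman")
  le <- log2(e + 1); lt <- log2(t_ + 1)
  pcc <- if (stats::sd(le) == 0 || stats::sd(lt) == 0) {
    undefined <- c(undefined, "pcc_log"); NA_real_
  } else stats::cor(le, lt, method = "pearson")
  list(scc = scc, pcc_log = pcc, rmse = sqrt(mean((e - t_)^2)),
       n = length(e), undefined = undefined)
}

#' Ground-truth CPM for spike-in (sequin) transcripts
#'
#' Converts raw spike-in abundances and the sample's spike-in concentration
#' into expected counts per million:
#' `CPM_x = a_x / sum(a) * c_s * 1e6`.
#'
#' @param raw_abundances Named numeric vector of raw sequin abundances.
#' @param spike_concentration Spike-in concentration `c_s` of the sample.
#' @return Named numeric CPM vector.
#' @export
sequin_cpm <- function(raw_abundances, spike_concentration) {
  total <- sum(raw_abundances)
  if (total <= 0) stop("total sequin abundance must be positive")
  if (spike_concentration <= 0) stop("spike concentration must be positive")
  raw_abundances / total * spike_concentration * 1e6
}
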