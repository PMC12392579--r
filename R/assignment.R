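# run code under a temporary RNG state so callers' streams are untouched
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Convert fractional assignments into hard 1-to-1 assignments
#'
#' Each read is assigned to exactly one transcript. The default strategy
#' samples the transcript from the read's fractional assignment
#' distribution (`alpha` row), which perturbs abundance estimates far less
#' than taking the argmax; the argmax strategy is kept for comparison
#' experiments. Abundances are recomputed from the hard assignments.
#'
#' @param alpha Sparse assignment matrix (rows sum to 1).
#' @param seed Integer seed driving the sampling (default 0); the caller's
#'   RNG state is preserved.
#' @param method `"sample"` (default) or `"argmax"`.
#' @return A list of class `hard_assignment`: `assignment` (named character
#'   vector, read -> transcript) and `abundance` (an `abundance_estimate`
#'   recomputed from the hard counts).
#' @export
push_assignments <- function(alpha, seed = 0L,
                             method = c("sample", "argmax")) {
  method <- match.arg(method)
  tr <- Matrix::summary(methods::as(alpha, "TsparseMatrix"))
  o <- order(tr$i, tr$j)
  i <- tr$i[o]; j <- tr$j[o]; x <- tr$x[o]
  n_reads <- nrow(alpha)
  if (method == "sample") {
    csum <- stats::ave(x, i, FUN = cumsum)
    # guard the final cumulative value against rounding below 1
    last <- !duplicated(i, fromLast = TRUE)
    csum[last] <- 1
    u <- with_local_seed(seed, stats::runif(n_reads))
    sel <- which(csum >= u[i])
    first <- sel[!duplicated(i[sel])]
  } else {
    oo <- order(i, -x, j)
    first <- oo[!duplicated(i[oo])]
  }
  chosen_tx <- colnames(alpha)[j[first]]
  assignment <- stats::setNames(chosen_tx, rownames(alpha)[i[first]])
  assignment <- assignment[rownames(alpha)]
  counts <- table(factor(assignment, levels = colnames(alpha)))
  rc <- stats::setNames(as.numeric(counts), colnames(alpha))
  structure(list(assignment = assignment,
                 abundance = structure(list(rho = rc / n_reads,
                                            read_count = rc,
                                            n_reads = n_reads),
                                       class = "abundance_estimate")),
            class = "hard_assignment")
}

#' Per-transcript read counts from fractional assignments
#'
#' @param alpha Sparse assignment matrix.
#' @return Named numeric vector of column sums; sums to the number of
#'   reads.
#' @export
read_counts <- function(alpha) {
  Matrix::colSums(alpha)
}

#' Counts per million
#'
#' `CPM_t = rc_t / l * 1e6` where `l` is the total number of aligned
#' reads.
#'
#' @param read_count Named numeric vector of per-transcript read counts.
#' @param total_aligned Total number of aligned reads `l`.
#' @return Named numeric CPM vector.
#' @export
cpm <- function(read_count, total_aligned) {
  if (total_aligned <= 0) stop("total_aligned must be positive")
  read_count / total_aligned * 1e6
}

#' Per-transcript coverage from fractional assignments
#'
#' `lambda_t = sum_r alpha_rt * l(r) / l(t)`: the expected read bases
#' attributed to the transcript divided by its length.
#'
#' @param alpha Sparse assignment matrix.
#' @param read_lengths Named integer vector of read lengths; every read in
#'   `alpha` must be present.
#' @param index A [transcriptome_index()].
#' @return Named numeric vector over all transcripts in the index (0 for
#'   transcripts with no assigned reads).
#' @export
transcript_coverage <- function(alpha, read_lengths, index) {
  missing <- setdiff(rownames(alpha), names(read_lengths))
  if (length(missing))
    stop("no recorded read length for read(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  lr <- as.numeric(read_lengths[rownames(alpha)])
  weighted <- as.numeric(Matrix::crossprod(alpha, lr))
  names(weighted) <- colnames(alpha)
  out <- stats::setNames(numeric(length(index$ids)), index$ids)
  out[names(weighted)] <- weighted / index$lengths[names(weighted)]
  out
}

#' Full abundance report over the annotated transcriptome
#'
#' Combines read counts, CPM and coverage into one table covering every
#' transcript in the index; transcripts with no alignments get zero rows
#' rather than being omitted.
#'
#' @param alpha Sparse assignment matrix.
#' @param read_lengths Named read lengths (from a `compat_matrix`).
#' @param index A [transcriptome_index()].
#' @return A data frame with columns `transcript_id`, `read_count`, `cpm`,
#'   `coverage`; attribute `total_aligned` carries `l`.
#' @export
abundance_report <- function(alpha, read_lengths, index) {
  l <- nrow(alpha)
  rc_full <- stats::setNames(numeric(length(index$ids)), index$ids)
  rc <- read_counts(alpha)
  rc_full[names(rc)] <- rc
  out <- data.frame(transcript_id = index$ids,
                    read_count = as.numeric(rc_full),
                    cpm = as.numeric(cpm(rc_full, l)),
                    coverage = as.numeric(
                      transcript_coverage(alpha, read_lengths, index)),
                    stringsAsFactors = FALSE)
  attr(out, "total_aligned") <- l
  out
}

#' Write assignment and abundance TSV outputs
#'
#' Writes `assignments.tsv` (one row per positive fractional assignment),
#' `abundances.tsv` (one row per annotated transcript) and, when hard
#' assignments are supplied, `hard_assignments.tsv`. Fractions are printed
#' with enough significant digits to round-trip losslessly at the tested
#' precision.
#'
#' @param alpha Sparse assignment matrix.
#' @param report Abundance report from [abundance_report()].
#' @param out_dir Output directory (created if needed).
#' @param hard Optional `hard_assignment` from [push_assignments()].
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(alpha, report, out_dir, hard = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tr <- Matrix::summary(methods::as(alpha, "TsparseMatrix"))
  assign_df <- data.frame(read_id = rownames(alpha)[tr$i],
                          transcript_id = colnames(alpha)[tr$j],
                          fraction = sprintf("%.10g", tr$x),
                          stringsAsFactors = FALSE)
  assign_df <- assign_df[order(assign_df$read_id, assign_df$transcript_id), ]
  files <- c(assignments = file.path(out_dir, "assignments.tsv"),
             abundances = file.path(out_dir, "abundances.tsv"))
  utils::write.table(assign_df, files[["assignments"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  out_report <- report
  for (col in c("read_count", "cpm", "coverage"))
    out_report[[col]] <- sprintf("%.10g", report[[col]])
  utils::write.table(out_report, files[["abundances"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(hard)) {
    files <- c(files, hard = file.path(out_dir, "hard_assignments.tsv"))
    hard_df <- data.frame(read_id = names(hard$assignment),
                          transcript_id = unname(hard$assignment),
                          stringsAsFactors = FALSE)
    utils::write.table(hard_df, files[["hard"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(files)
}

#' Read a fractional-assignment TSV back into a data frame
#'
#' @param path Path to an `assignments.tsv` written by [write_outputs()].
#' @return Data frame with `read_id`, `transcript_id`, `fraction`
#'   (numeric).
#' @export
read_assignments_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  names(df) <- c("read_id", "transcript_id", "fraction")
  df
}
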