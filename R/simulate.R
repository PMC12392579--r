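#' Configuration for the synthetic long-read fixtures
#'
#' The generator emulates the quantities the pipeline consumes: a
#' multi-isoform transcriptome in which isoforms of a locus share their 3'
#' suffix (so 3'-truncated reads multi-map within the locus), reads drawn
#' from known origin transcripts with 5'/3' truncation, and aligner-like
#' primary/secondary alignment records whose scores follow the overlap
#' geometry. Defaults describe a 10-locus, 50-transcript, 10,000-read
#' direct-RNA-like experiment.
#'
#' @param n_loci Number of gene loci.
#' @param isoforms_per_locus Isoforms per locus; isoform `k` carries a
#'   distinct random 5' extension of `k * unique_step` nt ahead of the
#'   locus-shared 3' suffix.
#' @param shared_suffix Length (nt) of the 3' suffix shared by all isoforms
#'   of a locus.
#' @param unique_step Increment (nt) of the isoform-specific 5' extension.
#' @param n_reads Number of reads to simulate.
#' @param rho_true Optional true relative abundances (length
#'   `n_loci * isoforms_per_locus`, summing to 1); when `NULL`, drawn from a
#'   symmetric Dirichlet with parameter `concentration`.
#' @param concentration Dirichlet concentration for `rho_true`.
#' @param three_prime_frac Fraction of reads anchored at the transcript 3'
#'   end (1 = direct-RNA-like; lower values emulate cDNA, with the
#'   remainder placed uniformly).
#' @param read_frac_range Read length as a uniform fraction of the origin
#'   transcript length, `c(min, max)`.
#' @param match_reward Score units per aligned base.
#' @param error_rate Per-base error probability; each error subtracts
#'   `error_penalty` score units.
#' @param error_penalty Score penalty per error.
#' @param min_overlap Minimum overlap (nt) for a secondary alignment record
#'   to be emitted.
#' @param seed Integer seed; every generator draw derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 10L, isoforms_per_locus = 5L,
                       shared_suffix = 400L, unique_step = 150L,
                       n_reads = 10000L, rho_true = NULL,
                       concentration = 1.5, three_prime_frac = 1,
                       read_frac_range = c(0.3, 1),
                       match_reward = 2, error_rate = 0.02,
                       error_penalty = 4, min_overlap = 25L, seed = 1L) {
  n_tx <- n_loci * isoforms_per_locus
  if (!is.null(rho_true)) {
    stopifnot(length(rho_true) == n_tx, all(rho_true >= 0))
    rho_true <- rho_true / sum(rho_true)
  }
  stopifnot(shared_suffix >= 1, unique_step >= 1, n_reads >= 1,
            three_prime_frac >= 0, three_prime_frac <= 1,
            length(read_frac_range) == 2,
            read_frac_range[1] > 0, read_frac_range[2] <= 1,
            read_frac_range[1] <= read_frac_range[2],
            error_rate >= 0, error_rate < 1, match_reward > 0)
  structure(list(n_loci = as.integer(n_loci),
                 isoforms_per_locus = as.integer(isoforms_per_locus),
                 shared_suffix = as.integer(shared_suffix),
                 unique_step = as.integer(unique_step),
                 n_reads = as.integer(n_reads), rho_true = rho_true,
                 concentration = concentration,
                 three_prime_frac = three_prime_frac,
                 read_frac_range = read_frac_range,
                 match_reward = match_reward, error_rate = error_rate,
                 error_penalty = error_penalty,
                 min_overlap = as.integer(min_overlap),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a toy multi-isoform transcriptome
#'
#' Isoform `k` of locus `g` (id `Lg.k`) is a distinct random 5' extension
#' of length `k * unique_step` followed by the locus's shared 3' suffix, so
#' reads confined to the suffix are sequence-identical across the locus's
#' isoforms while reads reaching the extension are unique to their origin.
#' Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A `transcriptome_index` with sequences attached; attribute
#'   `locus` maps transcript_id to locus id.
#' @export
make_toy_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    ids <- character(0)
    seqs <- character(0)
    locus <- character(0)
    for (g in seq_len(config$n_loci)) {
      suffix <- .random_bases(config$shared_suffix)
      for (k in seq_len(config$isoforms_per_locus)) {
        ids <- c(ids, sprintf("L%d.%d", g, k))
        seqs <- c(seqs, paste0(.random_bases(k * config$unique_step), suffix))
        locus <- c(locus, sprintf("L%d", g))
      }
    }
    dss <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
    idx <- transcriptome_index(
      stats::setNames(Biostrings::width(dss), ids), sequences = dss)
    attr(idx, "locus") <- stats::setNames(locus, ids)
    idx
  })
}

#' Simulate long reads with known origins
#'
#' Each read's origin transcript is drawn from the true abundance vector;
#' its length is a uniform fraction of the origin length; its 3' end is
#' anchored at the transcript 3' end with probability `three_prime_frac`
#' and placed uniformly otherwise. The empirical origin counts are
#' multinomial in the true abundances.
#'
#' @param index Toy transcriptome from [make_toy_transcriptome()].
#' @param config The same [sim_config()].
#' @return A list of class `sim_reads`: `reads` (data frame with `read_id`,
#'   `origin`, `start`, `end`, `length`), `truth` (named read -> origin
#'   vector), `rho_true` (the abundance vector used) and `sequences`
#'   (named character, read sequences).
#' @export
simulate_reads <- function(index, config) {
  stopifnot(inherits(index, "transcriptome_index"),
            inherits(config, "sim_config"))
  with_local_seed(config$seed + 1L, {
    rho <- config$rho_true
    if (is.null(rho)) {
      g <- stats::rgamma(length(index$ids), shape = config$concentration)
      rho <- g / sum(g)
    }
    origin <- sample(index$ids, config$n_reads, replace = TRUE, prob = rho)
    tlen <- index$lengths[origin]
    frac <- stats::runif(config$n_reads, config$read_frac_range[1],
                         config$read_frac_range[2])
    len <- pmax(20L, as.integer(round(frac * tlen)))
    anchored <- stats::runif(config$n_reads) < config$three_prime_frac
    end <- ifelse(anchored, tlen,
                  len + as.integer(floor(stats::runif(config$n_reads) *
                                           (tlen - len + 1L))))
    start <- end - len
    read_id <- sprintf("read_%06d", seq_len(config$n_reads))
    seqs <- substring(as.character(index$sequences[origin]),
                      start + 1L, end)
    names(seqs) <- read_id
    reads <- data.frame(read_id = read_id, origin = origin,
                        start = as.integer(start), end = as.integer(end),
                        length = as.integer(len), stringsAsFactors = FALSE)
    structure(list(reads = reads,
                   truth = stats::setNames(origin, read_id),
                   rho_true = stats::setNames(rho, index$ids),
                   sequences = seqs),
              class = "sim_reads")
  })
}

#' Simulate aligner-like alignment records for simulated reads
#'
#' A score-faithful stand-in for a real transcriptomic aligner: instead of
#' re-running dynamic programming it derives each candidate alignment from
#' the known overlap geometry. A read aligns to its origin over its full
#' span, and to the other isoforms of the origin's locus over the part of
#' the read lying in the locus-shared 3' suffix (emitted when at least
#' `min_overlap` nt). Scores are `match_reward * overlap` minus a sampled
#' per-base error penalty, so the origin's record has the maximal expected
#' score whenever the read extends into its unique 5' region. The top-score
#' record of each read is flagged primary.
#'
#' @param sim A `sim_reads` object.
#' @param index The toy transcriptome the reads were simulated from.
#' @param config The same [sim_config()].
#' @return Alignment-record data frame (same shape as
#'   [parse_alignments()] output).
#' @export
simulate_alignments <- function(sim, index, config) {
  stopifnot(inherits(sim, "sim_reads"), inherits(config, "sim_config"))
  locus <- attr(index, "locus")
  if (is.null(locus)) stop("index lacks locus structure; use ",
                           "make_toy_transcriptome()")
  with_local_seed(config$seed + 2L, {
    by_locus <- split(index$ids, locus)
    reads <- sim$reads
    out <- vector("list", nrow(reads))
    for (i in seq_len(nrow(reads))) {
      org <- reads$origin[i]
      lt <- index$lengths[[org]]
      d_e <- lt - reads$end[i]          # 3'-end distance of the read
      d_s <- lt - reads$start[i]        # span measured from the 3' end
      sibs <- by_locus[[locus[[org]]]]
      tx <- character(0); st <- integer(0); en <- integer(0); ov <- integer(0)
      for (t2 in sibs) {
        l2 <- index$lengths[[t2]]
        if (t2 == org) {
          o <- reads$length[i]
          s2 <- reads$start[i]; e2 <- reads$end[i]
        } else {
          # overlap of the read with the shared suffix, mapped via the
          # common 3' anchor
          hi <- min(d_s, config$shared_suffix)
          o <- hi - d_e
          if (o < config$min_overlap) next
          s2 <- l2 - hi; e2 <- l2 - d_e
        }
        tx <- c(tx, t2); st <- c(st, s2); en <- c(en, e2); ov <- c(ov, o)
      }
      n_err <- stats::rbinom(length(ov), ov, config$error_rate)
      score <- config$match_reward * ov - config$error_penalty * n_err
      best <- order(-score, match(tx, index$ids))[1]
      out[[i]] <- data.frame(read_id = reads$read_id[i], transcript_id = tx,
                             score = as.numeric(score), start = st, end = en,
                             is_primary = seq_along(tx) == best,
                             read_length = reads$length[i],
                             strand = "forward", stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, out)
    rownames(rec) <- NULL
    rec
  })
}

#' Generate a complete synthetic fixture
#'
#' Convenience wrapper chaining [make_toy_transcriptome()],
#' [simulate_reads()] and [simulate_alignments()].
#'
#' @param config A [sim_config()].
#' @return List with `index`, `sim` (a `sim_reads`), `records` and
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  index <- make_toy_transcriptome(config)
  sim <- simulate_reads(index, config)
  records <- simulate_alignments(sim, index, config)
  list(index = index, sim = sim, records = records, config = config)
}

#' True per-transcript read counts of a simulated read set
#'
#' @param sim A `sim_reads`.
#' @param index The transcriptome the reads came from.
#' @return Named numeric vector over all transcripts in the index.
#' @export
true_read_counts <- function(sim, index) {
  counts <- table(factor(sim$sim$truth %||% sim$truth,
                         levels = index$ids))
  stats::setNames(as.numeric(counts), index$ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write fixture files to disk
#'
#' Writes the transcriptome FASTA, the reads as FASTQ, the alignments as
#' SAM and the read-origin truth TSV so the full file-based pipeline can be
#' exercised (and, optionally, a real aligner run on the FASTA/FASTQ pair).
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_files <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "transcripts.fa"),
             fastq = file.path(dir, "reads.fastq"),
             sam = file.path(dir, "alignments.sam"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(dataset$index$sequences, paths[["fasta"]])
  seqs <- dataset$sim$sequences
  writeLines(paste0("@", names(seqs), "\n", seqs, "\n+\n",
                    vapply(nchar(seqs), function(n)
                      strrep("I", n), character(1))),
             paths[["fastq"]])
  write_sam(dataset$records, dataset$index, paths[["sam"]],
            read_seqs = seqs)
  utils::write.table(data.frame(read_id = names(dataset$sim$truth),
                                transcript_id = unname(dataset$sim$truth)),
                     paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
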