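#' Parse transcriptomic long-read alignments
#'
#' Reads SAM/BAM (via Rsamtools) or PAF alignments of long reads against a
#' transcriptome and returns one record per aligned segment, in the internal
#' 0-based half-open coordinate convention on the transcript. Unmapped
#' records are skipped and counted; supplementary alignments are treated as
#' secondary; reverse-strand hits are dropped by default since reads are
#' expected to originate from the sense strand of transcripts.
#'
#' Per-alignment scores are taken from the `ms` tag when any record carries
#' it, falling back to `AS` otherwise. Records missing the chosen tag are
#' skipped with a count; if no record carries either tag, parsing fails.
#'
#' @param path Path to the alignment file.
#' @param index A [transcriptome_index()]; every reference name in the file
#'   must be present in it.
#' @param dialect One of `"auto"` (by file extension), `"sam"`, `"bam"`,
#'   `"paf"`.
#' @param keep_reverse Keep reverse-strand alignments (default `FALSE`).
#' @return A data frame of alignment records with columns `read_id`,
#'   `transcript_id`, `score`, `start`, `end`, `is_primary`, `read_length`,
#'   `strand`, plus attributes `n_unmapped`, `n_missing_score`,
#'   `n_reverse_dropped` and `score_tag`.
#' @export
parse_alignments <- function(path, index,
                             dialect = c("auto", "sam", "bam", "paf"),
                             keep_reverse = FALSE) {
  stopifnot(inherits(index, "transcriptome_index"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    dialect <- switch(ext, sam = "sam", bam = "bam", paf = "paf",
                      stop("cannot infer alignment dialect from '", path,
                           "'; pass dialect explicitly"))
  }
  if (!file.exists(path)) stop("alignment file not found: ", path)
  raw <- if (dialect == "paf") .parse_paf(path) else .parse_sam_bam(path, dialect)
  .finalize_records(raw, index, keep_reverse)
}

.parse_sam_bam <- function(path, dialect) {
  bam <- if (dialect == "sam") {
    Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = c("ms", "AS"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- res$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  n_unmapped <- sum(unmapped)
  keep <- !unmapped
  cigar <- res$cigar[keep]
  start <- res$pos[keep] - 1L
  list(
    read_id = res$qname[keep],
    transcript_id = as.character(res$rname[keep]),
    start = start,
    end = start + GenomicAlignments::cigarWidthAlongReferenceSpace(cigar),
    read_length = GenomicAlignments::cigarWidthAlongQuerySpace(
      cigar, after.soft.clipping = FALSE),
    is_primary = bitwAnd(flag[keep], bitwOr(256L, 2048L)) == 0L,
    strand = ifelse(bitwAnd(flag[keep], 16L) != 0L, "reverse", "forward"),
    ms = unlist_tag(res$tag$ms, sum(keep)),
    AS = unlist_tag(res$tag$AS, sum(keep)),
    n_unmapped = n_unmapped)
}

# scanBam tag vectors may be NULL (tag absent everywhere) or contain NAs
unlist_tag <- function(x, n) {
  if (is.null(x)) rep(NA_real_, n) else as.numeric(x)
}

.parse_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(list(read_id = character(), transcript_id = character(),
                start = integer(), end = integer(), read_length = integer(),
                is_primary = logical(), strand = character(),
                ms = numeric(), AS = numeric(), n_unmapped = 0L))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 12L
  if (any(bad))
    stop("malformed PAF line (fewer than 12 columns): line ", which(bad)[1])
  get_tag <- function(f, tag) {
    hit <- grep(paste0("^", tag, ":[iAf]:"), f[-(1:12)], value = TRUE)
    if (length(hit)) sub("^[^:]+:[iAf]:", "", hit[1]) else NA_character_
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  tp <- vapply(fields, get_tag, character(1), tag = "tp")
  # a missing tp tag is treated as primary (single-hit PAF from some tools)
  list(
    read_id = col(1),
    transcript_id = col(6),
    start = as.integer(col(8)),
    end = as.integer(col(9)),
    read_length = as.integer(col(2)),
    is_primary = is.na(tp) | tp == "P",
    strand = ifelse(col(5) == "-", "reverse", "forward"),
    ms = as.numeric(vapply(fields, get_tag, character(1), tag = "ms")),
    AS = as.numeric(vapply(fields, get_tag, character(1), tag = "AS")),
    n_unmapped = 0L)
}

.finalize_records <- function(raw, index, keep_reverse) {
  n <- length(raw$read_id)
  tag <- if (any(!is.na(raw$ms))) "ms" else if (any(!is.na(raw$AS))) "AS" else
    if (n == 0L) "ms" else
      stop("no alignment record carries an 'ms' or 'AS' score tag")
  score <- if (tag == "ms") raw$ms else raw$AS
  missing_score <- is.na(score)
  n_missing <- sum(missing_score)
  if (n_missing > 0L)
    warning(n_missing, " alignment record(s) missing the '", tag,
            "' score tag were skipped")
  rec <- data.frame(
    read_id = raw$read_id, transcript_id = raw$transcript_id,
    score = score, start = raw$start, end = raw$end,
    is_primary = raw$is_primary, read_length = raw$read_length,
    strand = raw$strand, stringsAsFactors = FALSE)[!missing_score, ,
                                                   drop = FALSE]
  unknown <- !(rec$transcript_id %in% index$ids)
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop("alignment of read '", rec$read_id[i], "' references transcript '",
         rec$transcript_id[i], "' absent from the transcriptome index")
  }
  n_reverse <- 0L
  if (!keep_reverse) {
    rev <- rec$strand == "reverse"
    n_reverse <- sum(rev)
    rec <- rec[!rev, , drop = FALSE]
  }
  tlen <- index$lengths[rec$transcript_id]
  bad <- rec$start < 0L | rec$end <= rec$start | rec$end > tlen
  if (any(bad)) {
    i <- which(bad)[1]
    stop("alignment interval [", rec$start[i], ",", rec$end[i],
         ") of read '", rec$read_id[i], "' is invalid on transcript '",
         rec$transcript_id[i], "' (length ", tlen[i], ")")
  }
  rownames(rec) <- NULL
  attr(rec, "n_unmapped") <- raw$n_unmapped
  attr(rec, "n_missing_score") <- n_missing
  attr(rec, "n_reverse_dropped") <- n_reverse
  attr(rec, "score_tag") <- tag
  rec
}

#' Keep the best-scoring alignment per (read, transcript) pair
#'
#' When a read aligns several times to the same transcript only the
#' maximum-score alignment is retained. Ties are broken deterministically by
#' smaller start, then smaller end. If a read's primary record is removed by
#' the dedup (its pair kept a higher-scoring secondary), the read's
#' top-score retained record is promoted to primary so that each read keeps
#' exactly one primary alignment.
#'
#' @param records Alignment record data frame from [parse_alignments()].
#' @return The deduplicated records, one row per (read, transcript) pair.
#' @export
dedupe_best_per_pair <- function(records) {
  if (nrow(records) == 0L) return(records)
  o <- order(records$read_id, records$transcript_id, -records$score,
             records$start, records$end)
  rec <- records[o, , drop = FALSE]
  keep <- !duplicated(rec[c("read_id", "transcript_id")])
  rec <- rec[keep, , drop = FALSE]
  # repair the one-primary-per-read invariant
  prim <- tapply(rec$is_primary, rec$read_id, sum)
  fix <- names(prim)[prim != 1L]
  for (r in fix) {
    i <- which(rec$read_id == r)
    rec$is_primary[i] <- FALSE
    best <- i[order(-rec$score[i], rec$start[i], rec$end[i])][1]
    rec$is_primary[best] <- TRUE
  }
  rownames(rec) <- NULL
  rec
}

#' Write alignment records as SAM
#'
#' Emits a minimal, valid SAM file (used by the synthetic-fixture pipeline
#' and round-trip tests): `@SQ` header lines from the transcriptome index
#' and one alignment line per record. The aligned span is encoded as a
#' match run with a trailing soft clip so that the CIGAR query width equals
#' the recorded read length; scores go in the `ms:i` tag.
#'
#' @param records Alignment record data frame.
#' @param index A [transcriptome_index()].
#' @param path Output SAM path.
#' @param read_seqs Optional named character vector of read sequences; reads
#'   without a sequence get `*`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, index, path, read_seqs = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", index$ids, index$lengths))
  span <- records$end - records$start
  clip <- records$read_length - span
  if (any(clip < 0))
    stop("read_length smaller than aligned span; cannot encode CIGAR")
  cigar <- paste0(span, "M", ifelse(clip > 0, paste0(clip, "S"), ""))
  flag <- ifelse(records$is_primary, 0L, 256L) +
    ifelse(records$strand == "reverse", 16L, 0L)
  seq <- rep("*", nrow(records))
  if (!is.null(read_seqs)) {
    hit <- records$read_id %in% names(read_seqs) & records$is_primary
    seq[hit] <- read_seqs[records$read_id[hit]]
  }
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tms:i:%d",
                   records$read_id, flag, records$transcript_id,
                   records$start + 1L, ifelse(records$is_primary, 60L, 0L),
                   cigar, seq, as.integer(round(records$score)))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Align long reads to a transcriptome with minimap2
#'
#' Thin wrapper around a non-spliced minimap2 invocation. The number of
#' retained secondary alignments defaults to 181, large enough to keep every
#' plausible read-transcript pairing in a multi-isoform locus for the EM to
#' arbitrate; `map-ont` is the default preset, switchable for PacBio data.
#'
#' @param reads FASTQ/FASTA path of long reads.
#' @param transcriptome FASTA path of transcript sequences.
#' @param out Output SAM path.
#' @param n_secondary Maximum secondary alignments per read (`-N`).
#' @param preset minimap2 preset (`-x`), e.g. `"map-ont"` or `"map-pb"`.
#' @param threads Number of alignment threads.
#' @return `out` invisibly; stops with guidance if minimap2 is unavailable.
#' @export
run_aligner <- function(reads, transcriptome, out = tempfile(fileext = ".sam"),
                        n_secondary = 181L, preset = "map-ont", threads = 1L) {
  stopifnot(n_secondary >= 0L)
  if (Sys.which("minimap2") == "")
    stop("minimap2 not found on PATH; align the reads yourself and supply ",
         "the SAM/BAM/PAF file to parse_alignments() instead")
  args <- aligner_args(reads, transcriptome, out, n_secondary, preset, threads)
  status <- system2("minimap2", args, stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("minimap2 exited with status ", status)
  invisible(out)
}

# exposed separately so the invocation can be inspected without an aligner
aligner_args <- function(reads, transcriptome, out, n_secondary = 181L,
                         preset = "map-ont", threads = 1L) {
  c("-a", "-x", preset, "-N", as.character(as.integer(n_secondary)),
    "-t", as.character(as.integer(threads)),
    "-o", out, transcriptome, reads)
}
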