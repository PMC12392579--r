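#' Build a transcriptome index
#'
#' The index is the target of all read assignments: a stable, ordered map
#' from transcript identifier to transcript length (and optionally the
#' transcript sequence). All downstream matrices use the integer ordering
#' fixed here.
#'
#' @param lengths Named integer vector of transcript lengths in nucleotides.
#'   Names are transcript identifiers and must be unique; every length must
#'   be at least 1.
#' @param sequences Optional [Biostrings::DNAStringSet] of transcript
#'   sequences. When given, its names and widths must agree with `lengths`.
#' @return An object of class `transcriptome_index`: a list with elements
#'   `ids` (character), `lengths` (named integer) and `sequences`
#'   (`DNAStringSet` or `NULL`).
#' @examples
#' idx <- transcriptome_index(c(t1 = 1000L, t2 = 800L))
#' transcript_lengths(idx)
#' @export
transcriptome_index <- function(lengths, sequences = NULL) {
  ids <- names(lengths)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("'lengths' must be a named vector of transcript lengths")
  if (anyDuplicated(ids))
    stop("duplicated transcript identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lengths <- as.integer(lengths)
  if (anyNA(lengths) || any(lengths < 1L))
    stop("every transcript length must be an integer >= 1")
  names(lengths) <- ids
  if (!is.null(sequences)) {
    if (!all(ids %in% names(sequences)))
      stop("sequences missing for some transcripts")
    sequences <- sequences[ids]
    if (!all(Biostrings::width(sequences) == lengths))
      stop("sequence widths disagree with declared lengths")
  }
  structure(list(ids = ids, lengths = lengths, sequences = sequences),
            class = "transcriptome_index")
}

#' Read a transcriptome index from a transcript FASTA file
#'
#' Transcript lengths are taken from the sequence widths; identifiers are
#' the first whitespace-delimited token of each FASTA header.
#'
#' @param fasta Path to a (optionally gzipped) FASTA file of transcript
#'   sequences.
#' @return A `transcriptome_index` carrying the sequences.
#' @export
read_transcriptome <- function(fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  transcriptome_index(lens, sequences = seqs)
}

#' Read a transcriptome index from a GTF annotation plus transcript FASTA
#'
#' The GTF fixes the transcript set (and the order in which transcripts are
#' reported); sequences and lengths come from the FASTA. Transcripts present
#' in the GTF but absent from the FASTA are an error, since reads cannot be
#' aligned to them.
#'
#' @param gtf Path to a GTF annotation with `transcript_id` attributes.
#' @param fasta Path to the matching transcript FASTA.
#' @return A `transcriptome_index` restricted to the GTF's transcripts.
#' @export
read_transcriptome_gtf <- function(gtf, fasta) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF annotations requires the 'rtracklayer' package")
  anno <- rtracklayer::import(gtf, format = "gtf")
  tx <- unique(stats::na.omit(anno$transcript_id))
  idx <- read_transcriptome(fasta)
  missing <- setdiff(tx, idx$ids)
  if (length(missing))
    stop("transcripts in GTF but not in FASTA: ",
         paste(utils::head(missing, 5), collapse = ", "))
  transcriptome_index(idx$lengths[tx], sequences = idx$sequences[tx])
}

#' @export
print.transcriptome_index <- function(x, ...) {
  cat("transcriptome_index with", length(x$ids), "transcripts",
      if (!is.null(x$sequences)) "(sequences attached)" else "", "\n")
  invisible(x)
}

#' Transcript lengths of an index
#' @param index A `transcriptome_index`.
#' @return Named integer vector of lengths (nt).
#' @export
transcript_lengths <- function(index) {
  stopifnot(inherits(index, "transcriptome_index"))
  index$lengths
}
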