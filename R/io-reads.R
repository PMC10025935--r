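simulated_read_id <- function(read) {
  seg <- read$segments
  n <- nrow(seg)
  paste(sprintf("%s;%s:%d-%d;%s;seg%dof%d;%d",
                seg$species, seg$seq_id, as.integer(seg$ref_start),
                as.integer(seg$ref_end), seg$strand, seq_len(n), n,
                as.integer(read$read_index)),
        collapse = "|")
}

truth_table <- function(reads) {
  segs <- lapply(reads, `[[`, "segments")
  n <- vapply(segs, nrow, integer(1))
  ids <- vapply(reads, simulated_read_id, "")
  grab <- function(col) unlist(lapply(segs, `[[`, col), use.names = FALSE)
  data.frame(read_id = rep(ids, n),
             segment_index = sequence(n),
             species = grab("species"), seq_id = grab("seq_id"),
             ref_start = as.integer(grab("ref_start")),
             ref_end = as.integer(grab("ref_end")),
             strand = grab("strand"),
             head_trim = rep(as.integer(
               vapply(reads, function(r) r$head_junk %||% 0, numeric(1))), n),
             tail_trim = rep(as.integer(
               vapply(reads, function(r) r$tail_junk %||% 0, numeric(1))), n),
             stringsAsFactors = FALSE)
}

#' Write simulated reads to FASTA/FASTQ with a ground-truth table
#'
#' Read ids encode the per-segment ground truth as
#' `<species>;<seq_id>:<start>-<end>;<strand>;seg<i>of<n>;<readindex>`
#' joined with `|` across segments. A companion TSV with one row per
#' segment (`read_id, segment_index, species, seq_id, ref_start, ref_end,
#' strand, head_trim, tail_trim`) is written alongside.
#'
#' @param reads List of simulated reads (see [simulateRead()]).
#' @param path Output FASTA/FASTQ path.
#' @param format "fasta" or "fastq". FASTQ requires simulated qualities.
#' @param truth_path Path for the ground-truth TSV (default: `path` with a
#'   `_truth.tsv` suffix).
#' @return Invisibly, a list with the reads path and the truth path.
#' @export
writeReads <- function(reads, path, format = c("fasta", "fastq"),
                       truth_path = NULL) {
  format <- match.arg(format)
  if (!length(reads)) stop("no reads to write")
  if (any(vapply(reads, function(r) is.null(r$sequence), logical(1))))
    stop("reads lack sequences (simulated with emit_sequence = FALSE?)")
  ids <- vapply(reads, simulated_read_id, "")
  seqs <- Biostrings::DNAStringSet(vapply(reads, `[[`, "", "sequence"))
  names(seqs) <- ids
  if (format == "fastq") {
    quals <- lapply(reads, `[[`, "qualities")
    if (any(vapply(quals, is.null, logical(1))))
      stop("FASTQ output requires simulated quality scores; ",
           "use format = 'fasta' or simulate with a quality-trained model")
    q <- Biostrings::PhredQuality(unlist(quals))
    qs <- Biostrings::QualityScaledDNAStringSet(seqs, q)
    Biostrings::writeQualityScaledXStringSet(qs, path)
  } else {
    Biostrings::writeXStringSet(seqs, path)
  }
  if (is.null(truth_path))
    truth_path <- paste0(tools::file_path_sans_ext(path), "_truth.tsv")
  write.table(truth_table(reads), truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(reads = path, truth = truth_path))
}
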