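#' Load a reference metagenome from genome and topology lists
#'
#' Takes the two TSV configuration files the simulator consumes: a genome
#' list (`species <TAB> path-to-FASTA`) and an optional topology list
#' (`species <TAB> linear|circular`). Every FASTA may hold multiple contigs
#' (chromosomes, plasmids); contig ids are the first whitespace-delimited
#' token of each FASTA header. Species without a topology entry default to
#' linear.
#'
#' A loader hook is provided for non-local addresses: paths that are not
#' existing files are passed to `fetch`, which must return a local FASTA
#' path. The default build resolves local files only.
#'
#' @param genome_list Path to the genome list TSV, or a named character
#'   vector `species -> FASTA path`.
#' @param topology_list Optional path to the topology TSV, or a named
#'   character vector `species -> topology`.
#' @param fetch Optional function(address) -> local FASTA path, for remote
#'   genome addresses.
#' @return A [GenomeSet-class].
#' @export
loadGenomes <- function(genome_list, topology_list = NULL, fetch = NULL) {
  if (is.character(genome_list) && is.null(names(genome_list)) &&
      length(genome_list) == 1) {
    tab <- read.table(genome_list, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    genome_list <- stats::setNames(tab[[2]], tab[[1]])
  }
  topo <- character()
  if (!is.null(topology_list)) {
    if (is.character(topology_list) && is.null(names(topology_list)) &&
        length(topology_list) == 1) {
      tab <- read.table(topology_list, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE)
      topology_list <- stats::setNames(tab[[2]], tab[[1]])
    }
    bad <- setdiff(names(topology_list), names(genome_list))
    if (length(bad))
      stop("species in topology list but not in genome list: ",
           paste(bad, collapse = ", "))
    bad_val <- setdiff(unique(topology_list), c("linear", "circular"))
    if (length(bad_val))
      stop("topology must be 'linear' or 'circular', got: ",
           paste(bad_val, collapse = ", "))
    topo <- topology_list
  }
  all_seqs <- NULL
  seq_species <- character()
  for (sp in names(genome_list)) {
    p <- genome_list[[sp]]
    if (!file.exists(p)) {
      if (is.null(fetch))
        stop("genome file not found for species '", sp, "': ", p)
      p <- fetch(p)
    }
    seqs <- Biostrings::readDNAStringSet(p)
    names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
    seq_species <- c(seq_species,
                     stats::setNames(rep(sp, length(seqs)), names(seqs)))
    all_seqs <- if (is.null(all_seqs)) seqs else c(all_seqs, seqs)
  }
  genomeSet(all_seqs, seq_species, topo)
}
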