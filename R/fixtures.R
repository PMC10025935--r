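#' Generate a deterministic synthetic community
#'
#' Builds random genomes for a set of species, optionally planting shared
#' homologous blocks (byte-identical subsequences copied between species
#' pairs) to induce controlled multialignments, and writes per-species
#' FASTA files plus the genome-list, topology-list and species-map TSVs the
#' tool consumes. Output is byte-for-byte reproducible for a fixed seed.
#'
#' @param n_species Number of species (ignored when `genome_sizes` is
#'   named).
#' @param genome_sizes Numeric vector of genome sizes in bp (recycled);
#'   names become species names, default `sp1..spN`.
#' @param topology Character vector of topologies (recycled), default
#'   linear.
#' @param shared_blocks List of `list(a, b, length)` entries: copy a random
#'   block of `length` bp from species `a` into species `b`.
#' @param abundance Optional named abundance weights; default uniform.
#' @param seed Integer seed.
#' @param dir Output directory (created); default a tempdir subdirectory.
#' @return List with `genomes` ([GenomeSet-class]), `profile`
#'   ([AbundanceProfile-class]), `paths` (genome_list, topology_list,
#'   species_map, fastas), and `shared` (data.frame of planted block
#'   coordinates).
#' @export
makeCommunity <- function(n_species = 5, genome_sizes = 50000,
                          topology = "linear", shared_blocks = list(),
                          abundance = NULL, seed = 1L, dir = NULL) {
  set.seed(seed)
  sizes <- rep_len(genome_sizes, n_species)
  species <- names(genome_sizes) %||% paste0("sp", seq_len(n_species))
  if (length(species) != n_species) species <- paste0("sp", seq_len(n_species))
  names(sizes) <- species
  topo <- stats::setNames(rep_len(topology, n_species), species)
  seqs <- lapply(sizes, function(L)
    paste(sample(BASES, L, replace = TRUE), collapse = ""))
  shared <- NULL
  for (blk in shared_blocks) {
    a <- blk$a; b <- blk$b; len <- blk$length
    if (len > nchar(seqs[[a]]) || len > nchar(seqs[[b]]))
      stop("shared block longer than a genome")
    sa <- sample.int(nchar(seqs[[a]]) - len + 1, 1)
    sb <- sample.int(nchar(seqs[[b]]) - len + 1, 1)
    block <- substr(seqs[[a]], sa, sa + len - 1)
    substr(seqs[[b]], sb, sb + len - 1) <- block
    shared <- rbind(shared, data.frame(
      a = a, b = b, length = len, a_start = sa - 1, b_start = sb - 1,
      stringsAsFactors = FALSE))
  }
  if (is.null(dir)) dir <- tempfile("community")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fastas <- character()
  contig_ids <- paste0(species, "|chr1")
  for (i in seq_along(species)) {
    f <- file.path(dir, paste0(species[i], ".fasta"))
    writeLines(c(paste0(">", contig_ids[i]), seqs[[i]]), f)
    fastas[species[i]] <- f
  }
  glist <- file.path(dir, "genome_list.tsv")
  write.table(data.frame(species, unname(fastas)), glist, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  tlist <- file.path(dir, "topology_list.tsv")
  write.table(data.frame(species, unname(topo)), tlist, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  smap <- file.path(dir, "species_map.tsv")
  write.table(data.frame(contig_ids, species), smap, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  gs <- genomeSet(stats::setNames(Biostrings::DNAStringSet(unlist(seqs)),
                                  contig_ids),
                  stats::setNames(species, contig_ids), topo)
  prof <- abundanceProfile(abundance %||%
                             stats::setNames(rep(1, n_species), species))
  list(genomes = gs, profile = prof,
       paths = list(genome_list = glist, topology_list = tlist,
                    species_map = smap, fastas = fastas, dir = dir),
       shared = shared)
}

# draw a reference interval avoiding previously used intervals on the same
# contig (keeps planted same-species chimeric segments compatible)
random_ref_interval <- function(contig_len, len, used = NULL) {
  for (try in 1:50) {
    start <- sample.int(max(1, contig_len - len), 1) - 1
    iv <- c(start, start + len)
    if (is.null(used) ||
        all(interval_overlap(iv[1], iv[2], used[, 1], used[, 2]) == 0))
      return(iv)
  }
  iv
}

#' Generate an aligner-free PAF fixture with planted structure
#'
#' Emits PAF records for synthetic reads with known ground truth: chimeric
#' reads whose segment counts follow the geometric model and whose source
#' species follow the shrinkage-rate Markov chain, circular-origin bridge
#' reads, and multialigned reads (equal-score hits to a planted homologous
#' species pair). Used to test chimera detection and abundance estimation
#' without running an aligner.
#'
#' @param community Output of [makeCommunity()].
#' @param n_reads Number of reads.
#' @param p_geom Geometric success probability for segment counts.
#' @param s Shrinkage rate of the source chain.
#' @param multi_frac Fraction of nonchimeric reads planted as multialigned
#'   between the first shared-block pair (requires `shared_blocks`).
#' @param bridge_frac Fraction of nonchimeric reads planted as
#'   circular-origin bridges (requires a circular species).
#' @param segment_length Mean segment length (bp); lengths are drawn
#'   lognormal around it.
#' @param gap_length Mean gap length (bp).
#' @param mapq MAPQ written on planted records.
#' @param seed Integer seed.
#' @param path Output PAF path (default under the community directory).
#' @return List with `paf` (path), `alignments` (parsed subalignment
#'   tables), and `truth` (data.frame: read_id, n_segments, is_bridge,
#'   is_multi, species of each segment as a comma-joined string, aligned
#'   bases charged per species as a named list column `bases`).
#' @export
makeAlignmentFixture <- function(community, n_reads = 500, p_geom = 0.9,
                                 s = 0.8, multi_frac = 0, bridge_frac = 0,
                                 segment_length = 2000, gap_length = 50,
                                 mapq = 60, seed = 1L, path = NULL) {
  set.seed(seed)
  gs <- community$genomes
  prof <- community$profile
  sizes <- genomeSizes(gs)
  contig_of <- stats::setNames(names(gs@seqSpecies), gs@seqSpecies)
  model <- sourceModel(prof, s)
  circ_sp <- names(gs@topology)[gs@topology == "circular"]
  lines <- character()
  truth <- list()
  rlen <- function() max(200L, round(stats::rlnorm(1, log(segment_length), 0.4)))
  for (r in seq_len(n_reads)) {
    rid <- sprintf("read%05d", r)
    k <- sampleSegmentCount(p_geom, 1)
    u <- stats::runif(1)
    is_multi <- k == 1 && !is.null(community$shared) && u < multi_frac
    is_bridge <- k == 1 && length(circ_sp) > 0 && !is_multi &&
      u < multi_frac + bridge_frac
    if (is_multi) {
      blk <- community$shared[1, ]
      len <- min(rlen(), blk$length - 10)
      off <- sample.int(blk$length - len, 1) - 1
      read_len <- len
      rec <- function(sp, bstart, tp) {
        contig <- contig_of[[sp]]
        sprintf("%s\t%d\t%d\t%d\t+\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%s",
                rid, read_len, 0L, len, contig, as.integer(sizes[[sp]]),
                as.integer(bstart + off), as.integer(bstart + off + len),
                len, len, mapq, paste0("tp:A:", tp))
      }
      lines <- c(lines, rec(blk$a, blk$a_start, "P"),
                 rec(blk$b, blk$b_start, "S"))
      truth[[r]] <- data.frame(read_id = rid, n_segments = 1,
                               is_bridge = FALSE, is_multi = TRUE,
                               chain = blk$a, bases = read_len,
                               stringsAsFactors = FALSE)
    } else if (is_bridge) {
      sp <- if (length(circ_sp) == 1) circ_sp else sample(circ_sp, 1)
      contig <- contig_of[[sp]]
      L <- as.integer(sizes[[sp]])
      len <- min(rlen(), L - 10)
      l1 <- max(50L, round(len / 2))
      l2 <- len - l1
      if (l2 < 50) { l2 <- 50L; l1 <- len - l2 }
      read_len <- len
      lines <- c(lines,
                 sprintf("%s\t%d\t%d\t%d\t+\t%s\t%d\t%d\t%d\t%d\t%d\t%d\ttp:A:P",
                         rid, read_len, 0L, l1, contig, L, L - l1, L,
                         l1, l1, mapq),
                 sprintf("%s\t%d\t%d\t%d\t+\t%s\t%d\t%d\t%d\t%d\t%d\t%d\ttp:A:P",
                         rid, read_len, l1, len, contig, L, 0L, l2,
                         l2, l2, mapq))
      truth[[r]] <- data.frame(read_id = rid, n_segments = 1,
                               is_bridge = TRUE, is_multi = FALSE,
                               chain = sp, bases = read_len,
                               stringsAsFactors = FALSE)
    } else {
      chain <- sampleSpeciesChain(k, model)
      lens <- vapply(seq_len(k), function(i) rlen(), numeric(1))
      gaps <- if (k > 1) pmax(0, round(stats::rnorm(k - 1, gap_length,
                                                    gap_length / 4)))
      else numeric()
      qs <- cumsum(c(0, lens[-k] + gaps))
      read_len <- as.integer(sum(lens) + sum(gaps))
      used <- list()
      for (i in seq_len(k)) {
        sp <- chain[i]
        contig <- contig_of[[sp]]
        L <- as.integer(sizes[[sp]])
        len <- as.integer(min(lens[i], L - 1))
        rr <- random_ref_interval(L, len, used[[contig]])
        used[[contig]] <- rbind(used[[contig]], rr)
        lines <- c(lines,
                   sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\ttp:A:P",
                           rid, read_len, as.integer(qs[i]),
                           as.integer(qs[i] + len),
                           sample(c("+", "-"), 1), contig, L,
                           as.integer(rr[1]), as.integer(rr[2]),
                           len, len, mapq))
      }
      truth[[r]] <- data.frame(read_id = rid, n_segments = k,
                               is_bridge = FALSE, is_multi = FALSE,
                               chain = paste(chain, collapse = ","),
                               bases = read_len,
                               stringsAsFactors = FALSE)
    }
  }
  if (is.null(path))
    path <- file.path(community$paths$dir %||% tempdir(), "planted.paf")
  writeLines(lines, path)
  alignments <- parseAlignments(path, format = "paf",
                                species_map = community$paths$species_map)
  list(paf = path, alignments = alignments, truth = do.call(rbind, truth))
}
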