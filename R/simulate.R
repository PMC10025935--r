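#' Perturb an abundance profile within deviation bounds
#'
#' Draws one relative error per species uniformly between the deviation
#' boundaries, then assigns the errors to species by rank-matching absolute
#' error magnitude against genome size -- larger deviations go to larger
#' genomes (ties broken by species name) -- applies `p * (1 + e)`, clamps
#' at zero, and renormalizes to a total of 1.
#'
#' @param profile An [AbundanceProfile-class].
#' @param lo,hi Relative deviation bounds, `lo <= hi` (e.g. -0.1, 0.1).
#' @param genome_sizes Named numeric of genome sizes (bp) for rank
#'   matching; when NULL, errors are assigned in species order.
#' @return An [AbundanceProfile-class] with attribute `errors`: the raw
#'   (pre-normalization) relative error assigned to each species.
#' @export
perturbAbundances <- function(profile, lo, hi, genome_sizes = NULL) {
  if (lo > hi) stop("lo must be <= hi")
  p <- abundances(profile)
  n <- length(p)
  e <- stats::runif(n, lo, hi)
  sp_order <- if (!is.null(genome_sizes)) {
    missing <- setdiff(names(p), names(genome_sizes))
    if (length(missing))
      stop("missing genome size for: ", paste(missing, collapse = ", "))
    names(p)[order(-genome_sizes[names(p)], names(p))]
  } else names(p)
  e_sorted <- e[order(-abs(e))]
  err <- stats::setNames(numeric(n), names(p))
  err[sp_order] <- e_sorted
  p2 <- p * (1 + err)
  p2[p2 < 0] <- 0
  out <- abundanceProfile(p2)
  attr(out, "errors") <- err
  out
}

#' Allocate a total base budget across species
#'
#' `budget_i = round(p_i * total_bases)`; reads for a species are simulated
#' until its budget is exhausted (the last read may overshoot), which makes
#' abundance mean DNA-weight fraction, consistent with base-level
#' quantification.
#'
#' @param profile An [AbundanceProfile-class].
#' @param total_bases Total bases to simulate (> 0).
#' @return Named numeric base budgets.
#' @export
allocateBases <- function(profile, total_bases) {
  if (total_bases <= 0) stop("total_bases must be positive")
  round(abundances(profile) * total_bases)
}

#' Extract a fragment from a reference contig
#'
#' Circular contigs wrap past the origin at most once (the fragment is a
#' rotation); on linear contigs a start too close to the end is resampled
#' uniformly so the fragment fits. Reverse-strand fragments are
#' reverse-complemented.
#'
#' @param genomes A [GenomeSet-class].
#' @param seq_id Contig id.
#' @param start 0-based start position on the forward strand.
#' @param length Fragment length (<= contig length).
#' @param strand "+" or "-".
#' @return List with `sequence`, the possibly resampled `start`, and
#'   `wrapped` flag.
#' @export
extractFragment <- function(genomes, seq_id, start, length, strand = "+") {
  if (!seq_id %in% names(genomes@sequences))
    stop("unknown contig: ", seq_id)
  contig <- genomes@sequences[[seq_id]]
  L <- Biostrings::nchar(contig)
  if (length > L)
    stop("fragment length ", length, " exceeds contig length ", L)
  sp <- genomes@seqSpecies[[seq_id]]
  circular <- genomes@topology[[sp]] == "circular"
  wrapped <- FALSE
  if (circular) {
    if (start + length > L) {
      wrapped <- TRUE
      seq <- paste0(as.character(Biostrings::subseq(contig, start + 1, L)),
                    as.character(Biostrings::subseq(contig, 1,
                                                    start + length - L)))
    } else {
      seq <- as.character(Biostrings::subseq(contig, start + 1,
                                             start + length))
    }
  } else {
    if (start + length > L) {
      start <- if (L == length) 0 else
        sample.int(L - length + 1, 1) - 1
    }
    seq <- as.character(Biostrings::subseq(contig, start + 1, start + length))
  }
  if (strand == "-") seq <- revcomp(seq)
  list(sequence = seq, start = start, wrapped = wrapped)
}

# cached lookup tables for a GenomeSet: contig widths, contigs per species,
# and topology flags, so the simulation loop never touches S4 accessors
genome_index <- function(genomes) {
  widths <- stats::setNames(as.numeric(Biostrings::width(genomes@sequences)),
                            names(genomes@sequences))
  sp <- genomes@seqSpecies[names(genomes@sequences)]
  list(widths = widths,
       ids_by_species = split(names(widths), sp),
       circular = stats::setNames(genomes@topology == "circular",
                                  names(genomes@topology)))
}

# pick a contig of a species, proportional to contig length, that can host
# a fragment of the requested length; NULL when none can
pick_contig <- function(index, species, min_len) {
  ids <- index$ids_by_species[[species]]
  w <- index$widths[ids]
  ok <- w >= min_len
  if (!any(ok)) return(NULL)
  ids <- ids[ok]
  w <- w[ok]
  i <- if (length(ids) == 1) 1L else sample.int(length(ids), 1, prob = w)
  list(seq_id = ids[i], length = unname(w[i]))
}

#' Simulate one read
#'
#' Draws the segment count from the geometric model (one segment makes a
#' nonchimeric read), the source-species chain from the shrinkage-rate
#' Markov model, segment lengths from the chimeric-segment KDE (or the
#' aligned-read KDE for nonchimeric reads), gap lengths from the gap KDE,
#' head/tail unaligned junk from the alignment-ratio model, extracts the
#' fragments (wrapping circular contigs), collates them with random junk in
#' the gaps, and introduces basecall errors.
#'
#' @param models Model bundle: list with `chimeric`
#'   ([ChimericProfile-class]), `aligned` ([LengthKDE-class]),
#'   `align_ratio` ([AlignRatioModel-class] or NULL), `error`
#'   ([ErrorModel-class] or NULL).
#' @param genomes A [GenomeSet-class].
#' @param profile An [AbundanceProfile-class] (start probabilities).
#' @param read_index Integer index used in the read id.
#' @param s Shrinkage-rate override; default: the profile's trained value.
#' @param first_species Optional forced source species of the first
#'   segment (used by the base-budget allocator).
#' @param emit_sequence Build the nucleotide sequence (TRUE) or only the
#'   ground truth (FALSE), for abundance-only simulations.
#' @param with_qualities Simulate per-base Phred qualities (requires a
#'   quality-trained error model).
#' @param max_segments Segment-count truncation (default 10).
#' @param index Optional cached genome lookup (internal; built once per
#'   batch by [simulateMetagenome()]).
#' @return List describing the simulated read: `sequence` (or NULL),
#'   `qualities` (or NULL), `segments` data.frame (species, seq_id,
#'   ref_start, ref_end, strand, wrapped, length), `gaps`, `head_junk`,
#'   `tail_junk`, `error_log`, `read_index`.
#' @export
simulateRead <- function(models, genomes, profile, read_index = 1L,
                         s = NULL, first_species = NULL,
                         emit_sequence = TRUE, with_qualities = FALSE,
                         max_segments = 10, index = NULL) {
  chim <- models$chimeric
  s <- s %||% chim@shrinkageRate
  if (is.null(index)) index <- genome_index(genomes)
  can_chimera <- !is.null(chim@gapModel) && !is.null(chim@segmentModel)
  k <- if (can_chimera)
    sampleSegmentCount(chim@pGeom, 1, max_segments) else 1L
  src <- sourceModel(profile, s)
  chain <- if (is.null(first_species)) {
    sampleSpeciesChain(k, src)
  } else if (k == 1) {
    first_species
  } else {
    c(first_species, sampleSpeciesChain(k, src)[-1])
  }
  lens <- if (k == 1) sampleLengths(models$aligned, 1)
  else sampleLengths(chim@segmentModel, k)
  gaps <- if (k > 1) sampleLengths(chim@gapModel, k - 1, min_clip = 0)
  else integer()
  seq_id <- character(k)
  starts <- numeric(k)
  strand <- character(k)
  wrapped <- logical(k)
  frag_seq <- character(k)
  for (i in seq_len(k)) {
    pc <- NULL
    for (try in 1:20) {
      pc <- pick_contig(index, chain[i], lens[i])
      if (!is.null(pc)) break
      lens[i] <- if (k == 1) sampleLengths(models$aligned, 1)
      else sampleLengths(chim@segmentModel, 1)
    }
    if (is.null(pc)) { # clamp to the species' largest contig
      ids <- index$ids_by_species[[chain[i]]]
      w <- index$widths[ids]
      pc <- list(seq_id = ids[which.max(w)], length = max(w))
      lens[i] <- max(w)
    }
    contig_len <- pc$length
    circular <- index$circular[[chain[i]]]
    start <- if (circular) sample.int(contig_len, 1) - 1 else
      sample.int(contig_len - lens[i] + 1, 1) - 1
    seq_id[i] <- pc$seq_id
    starts[i] <- start
    strand[i] <- sample(c("+", "-"), 1)
    wrapped[i] <- circular && start + lens[i] > contig_len
    if (emit_sequence) {
      frag <- extractFragment(genomes, pc$seq_id, start, lens[i], strand[i])
      frag_seq[i] <- frag$sequence
    }
  }
  seg_df <- data.frame(species = chain, seq_id = seq_id,
                       ref_start = starts, ref_end = starts + lens,
                       strand = strand, wrapped = wrapped, length = lens,
                       sequence = if (emit_sequence) frag_seq else
                         NA_character_,
                       stringsAsFactors = FALSE)
  S <- sum(lens)
  ratio <- if (!is.null(models$align_ratio))
    sampleAlignRatio(models$align_ratio) else c(head_frac = 0.5,
                                                unaligned_frac = 0)
  total_unaligned <- round(ratio[["unaligned_frac"]] /
                             (1 - ratio[["unaligned_frac"]]) * S)
  ht <- max(0, total_unaligned - sum(gaps))
  head_junk <- round(ratio[["head_frac"]] * ht)
  tail_junk <- ht - head_junk
  read <- list(segments = seg_df[, setdiff(names(seg_df), "sequence")],
               gaps = as.numeric(gaps), head_junk = head_junk,
               tail_junk = tail_junk, read_index = read_index,
               sequence = NULL, qualities = NULL, error_log = NULL)
  if (emit_sequence) {
    comp <- if (!is.null(models$error)) models$error@baseComposition else NULL
    parts <- character(2 * k + 1)
    parts[1] <- random_dna(head_junk, comp)
    for (i in seq_len(k)) {
      parts[2 * i] <- seg_df$sequence[i]
      parts[2 * i + 1] <- if (i < k) random_dna(gaps[i], comp) else
        random_dna(tail_junk, comp)
    }
    template <- paste(parts, collapse = "")
    if (!is.null(models$error)) {
      mut <- introduceErrors(template, models$error)
      read$template <- template # pre-error read, for ground-truth replay
      read$sequence <- mut$sequence
      read$error_log <- mut$log
      if (with_qualities)
        read$qualities <- assignQualities(mut$log, models$error)
    } else {
      read$sequence <- template
      if (with_qualities)
        stop("quality simulation requires an error model with quality ",
             "distributions")
    }
  }
  read
}

#' Simulate a multi-sample metagenome
#'
#' For each sample: optionally perturbs the target profile within the
#' deviation bounds, converts the requested read count into a total base
#' budget using the mean of the aligned-read length model, allocates the
#' budget across species, and draws reads -- charging each segment's bases
#' to its own species -- until every budget is exhausted. The source
#' species of each read's first segment is drawn proportionally to the
#' remaining budgets, so realized base fractions track the (perturbed)
#' profile. Every sample uses a seed derived from the master seed and the
#' sample id, so adding a sample never changes another sample's reads.
#'
#' @param genomes A [GenomeSet-class] covering every species in the
#'   profiles.
#' @param profiles Named list `sample id -> AbundanceProfile` (a single
#'   profile is accepted and named "sample1").
#' @param models Model bundle as in [simulateRead()].
#' @param n_reads Reads per sample (converted to a base budget), or NULL
#'   when `total_bases` is given.
#' @param total_bases Base budget per sample (overrides `n_reads`).
#' @param deviation Optional `c(lo, hi)` relative deviation bounds.
#' @param s Shrinkage-rate override.
#' @param seed Master seed (integer).
#' @param output_prefix When non-NULL, write
#'   `{prefix}_{sample}.fasta/.fastq`, `{prefix}_{sample}_truth.tsv` and
#'   `{prefix}_{sample}_abundance_report.tsv`.
#' @param format "fasta" or "fastq".
#' @param emit_sequences Build sequences (TRUE) or ground truth only.
#' @param with_qualities Simulate Phred qualities (FASTQ).
#' @return Named list per sample: `reads` (list), `truth` (data.frame),
#'   `report` (data.frame with target, perturbed and realized abundance per
#'   species), and any file paths written.
#' @export
simulateMetagenome <- function(genomes, profiles, models, n_reads = NULL,
                               total_bases = NULL, deviation = NULL,
                               s = NULL, seed = 1L, output_prefix = NULL,
                               format = c("fasta", "fastq"),
                               emit_sequences = TRUE,
                               with_qualities = FALSE) {
  format <- match.arg(format)
  if (is(profiles, "AbundanceProfile")) profiles <- list(sample1 = profiles)
  if (is.null(names(profiles)))
    names(profiles) <- paste0("sample", seq_along(profiles))
  sizes <- genomeSizes(genomes)
  out <- list()
  for (sid in names(profiles)) {
    prof <- profiles[[sid]]
    missing <- setdiff(names(abundances(prof)), speciesNames(genomes))
    if (length(missing))
      stop("profile species missing a genome: ",
           paste(missing, collapse = ", "))
    set.seed(derive_seed(seed, sid))
    perturbed <- if (!is.null(deviation)) {
      perturbAbundances(prof, deviation[1], deviation[2],
                        genome_sizes = sizes)
    } else prof
    tb <- total_bases
    if (is.null(tb)) {
      if (is.null(n_reads)) stop("give n_reads or total_bases")
      mean_len <- mean(switch(models$aligned@transform,
                              log = exp(models$aligned@points),
                              log1p = expm1(models$aligned@points),
                              identity = models$aligned@points))
      tb <- n_reads * mean_len
    }
    budgets <- allocateBases(perturbed, tb)
    index <- genome_index(genomes)
    remaining <- budgets
    charged <- stats::setNames(numeric(length(budgets)), names(budgets))
    reads <- list()
    idx <- 0L
    while (any(remaining > 0)) {
      idx <- idx + 1L
      first <- sample_one(names(remaining), pmax(remaining, 0))
      rd <- simulateRead(models, genomes, perturbed, read_index = idx,
                         s = s, first_species = first,
                         emit_sequence = emit_sequences,
                         with_qualities = with_qualities, index = index)
      for (i in seq_len(nrow(rd$segments))) {
        sp <- rd$segments$species[i]
        len <- rd$segments$length[i]
        charged[sp] <- charged[sp] + len
        remaining[sp] <- remaining[sp] - len
      }
      reads[[idx]] <- rd
    }
    report <- data.frame(species = names(budgets),
                         target = abundances(prof)[names(budgets)],
                         perturbed = abundances(perturbed)[names(budgets)],
                         realized = charged / sum(charged),
                         stringsAsFactors = FALSE)
    if (!is.null(deviation))
      report$raw_error <- attr(perturbed, "errors")[names(budgets)]
    res <- list(reads = reads, truth = truth_table(reads), report = report)
    if (!is.null(output_prefix)) {
      stem <- paste0(output_prefix, "_", sid)
      rp <- paste0(stem, ".", format)
      res$paths <- writeReads(reads, rp, format = format,
                              truth_path = paste0(stem, "_truth.tsv"))
      rep_path <- paste0(stem, "_abundance_report.tsv")
      write.table(report, rep_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      res$paths$report <- rep_path
    }
    out[[sid]] <- res
  }
  out
}
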