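#' Pairwise compatibility of two subalignments
#'
#' Two subalignments of the same read are compatible when their query
#' intervals overlap by at most `slack` bases and their reference intervals
#' either lie on different contigs or overlap by at most `slack` bases. The
#' slack absorbs the few-base overlaps long-read aligners routinely emit at
#' split boundaries.
#'
#' @param a,b Single-row subalignment data.frames (or 1-row slices).
#' @param slack Permitted overlap (bp), default 10.
#' @return Logical flag.
#' @export
compatibleAlignments <- function(a, b, slack = 10) {
  if (a$read_id != b$read_id)
    stop("compatibility is defined within one read")
  q_ov <- interval_overlap(a$query_start, a$query_end,
                           b$query_start, b$query_end)
  if (q_ov > slack) return(FALSE)
  if (a$ref_seq != b$ref_seq) return(TRUE)
  interval_overlap(a$ref_start, a$ref_end, b$ref_start, b$ref_end) <= slack
}

# pairwise compatibility matrix for the rows of a subalignment table
compat_matrix <- function(df, slack) {
  n <- nrow(df)
  ok <- matrix(TRUE, n, n)
  for (i in seq_len(n)) {
    q_ov <- interval_overlap(df$query_start[i], df$query_end[i],
                             df$query_start, df$query_end)
    r_ov <- interval_overlap(df$ref_start[i], df$ref_end[i],
                             df$ref_start, df$ref_end)
    same_ref <- df$ref_seq == df$ref_seq[i]
    ok[i, ] <- q_ov <= slack & (!same_ref | r_ov <= slack)
  }
  diag(ok) <- FALSE
  ok
}

build_compatible_set <- function(df, read_len) {
  if (nrow(df) > 1) {
    ord <- order(df$query_start, df$query_end)
    if (is.unsorted(ord)) df <- df[ord, , drop = FALSE]
  }
  if (is.null(df$wrapped)) df$wrapped <- FALSE
  n <- nrow(df)
  gaps <- if (n > 1)
    pmax(0, df$query_start[-1] - df$query_end[-n]) else numeric()
  new("CompatibleSet",
      readId = df$read_id[1],
      readLength = read_len,
      segments = df,
      gaps = as.numeric(gaps),
      headUnaligned = as.numeric(df$query_start[1]),
      tailUnaligned = as.numeric(max(0, read_len - df$query_end[n])),
      totalAligned = sum(df$aligned_bases),
      minMapq = min(df$mapq),
      isChimeric = n >= 2)
}

# exhaustive subset search over <= max_exact subalignments
best_set_exact <- function(df, ok) {
  n <- nrow(df)
  nsub <- bitwShiftL(1L, n)
  incompat <- integer(n)
  for (i in seq_len(n)) {
    m <- 0L
    for (j in seq_len(n)) if (!ok[i, j]) m <- bitwOr(m, bitwShiftL(1L, j - 1L))
    incompat[i] <- m
  }
  valid <- logical(nsub)
  total <- numeric(nsub)
  valid[1] <- TRUE
  best_mask <- 0L
  best_key <- NULL
  for (s in seq_len(nsub - 1L)) {
    i <- 0L
    repeat { # lowest set bit
      if (bitwAnd(s, bitwShiftL(1L, i)) != 0L) break
      i <- i + 1L
    }
    rest <- bitwAnd(s, bitwNot(bitwShiftL(1L, i)))
    if (!valid[rest + 1L] || bitwAnd(rest, incompat[i + 1L]) != 0L) next
    valid[s + 1L] <- TRUE
    total[s + 1L] <- total[rest + 1L] + df$aligned_bases[i + 1L]
    idx <- which(bitwAnd(s, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    key <- list(total = total[s + 1L],
                mapq = mean(df$mapq[idx]),
                k = length(idx),
                qs = df$query_start[idx][order(df$query_start[idx])])
    if (is.null(best_key) || better_set_key(key, best_key)) {
      best_key <- key
      best_mask <- s
    }
  }
  which(bitwAnd(best_mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
}

# selection order: total aligned length, then mean MAPQ, then fewer
# segments, then lexicographically smaller query-start tuple
better_set_key <- function(a, b) {
  if (a$total != b$total) return(a$total > b$total)
  if (abs(a$mapq - b$mapq) > 1e-12) return(a$mapq > b$mapq)
  if (a$k != b$k) return(a$k < b$k)
  la <- min(length(a$qs), length(b$qs))
  for (i in seq_len(la)) {
    if (a$qs[i] != b$qs[i]) return(a$qs[i] < b$qs[i])
  }
  FALSE
}

# weighted interval scheduling on query space, reference compatibility
# enforced greedily on backtrack; used above the exact-search cap
best_set_wis <- function(df, slack) {
  ord <- order(df$query_end, df$query_start)
  df2 <- df[ord, , drop = FALSE]
  n <- nrow(df2)
  score <- numeric(n)
  prev <- integer(n)
  for (i in seq_len(n)) {
    score[i] <- df2$aligned_bases[i]
    prev[i] <- 0L
    for (j in seq_len(i - 1L)) {
      if (df2$query_end[j] - df2$query_start[i] <= slack &&
          score[j] + df2$aligned_bases[i] > score[i]) {
        score[i] <- score[j] + df2$aligned_bases[i]
        prev[i] <- j
      }
    }
  }
  i <- which.max(score)
  chain <- integer()
  while (i > 0L) {
    chain <- c(i, chain)
    i <- prev[i]
  }
  keep <- integer()
  for (i in chain) {
    ok <- TRUE
    for (j in keep) {
      if (df2$ref_seq[i] == df2$ref_seq[j] &&
          interval_overlap(df2$ref_start[i], df2$ref_end[i],
                           df2$ref_start[j], df2$ref_end[j]) > slack) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, i)
  }
  ord[keep]
}

#' Best compatible alignment set of one read
#'
#' Exhaustively searches the subalignments of a read for the compatible set
#' (pairwise non-overlapping in query and reference space, up to `slack`)
#' that maximizes the total aligned length; ties are broken by higher mean
#' MAPQ, then fewer segments, then the lexicographically smallest
#' query-start tuple. Secondary alignments and segments whose query span is
#' below `min_segment` never enter the search. The search is exact up to
#' `max_exact` subalignments (all subsets); beyond that a
#' weighted-interval-scheduling dynamic program on query space is used,
#' with reference compatibility enforced on backtrack.
#'
#' @param subalns Subalignment data.frame for one read (all rows share
#'   `read_id`).
#' @param slack Permitted pairwise overlap in bp (default 10).
#' @param min_segment Minimum query span of a segment in bp (default 100);
#'   shorter supplementary hits are spurious more often than chimeric.
#' @param max_exact Subalignment count up to which the subset search is
#'   exhaustive (default 12).
#' @return A [CompatibleSet-class].
#' @export
bestCompatibleSet <- function(subalns, slack = 10, min_segment = 100,
                              max_exact = 12) {
  if (is.null(subalns) || nrow(subalns) == 0)
    stop("no subalignments supplied")
  if (length(unique(subalns$read_id)) != 1)
    stop("all subalignments must share one read_id")
  read_len <- max(subalns$read_length)
  cand <- subalns[!subalns$is_secondary &
                    (subalns$query_end - subalns$query_start) >= min_segment, ,
                  drop = FALSE]
  if (nrow(cand) == 0) {
    # everything filtered: fall back to the single best-aligned record so
    # the read is not lost from downstream tallies
    cand <- subalns[which.max(subalns$aligned_bases), , drop = FALSE]
  }
  if (nrow(cand) == 1)
    return(build_compatible_set(cand, read_len))
  idx <- if (nrow(cand) <= max_exact) {
    best_set_exact(cand, compat_matrix(cand, slack))
  } else {
    best_set_wis(cand, slack)
  }
  build_compatible_set(cand[idx, , drop = FALSE], read_len)
}

#' Merge subalignments bridging the origin of a circular contig
#'
#' Reads spanning the start/end junction of a circular replicon split into
#' two subalignments that meet at the contig terminus. Two query-adjacent
#' segments on the same circular contig and strand are concatenated into a
#' single wrapped segment when (for `+`) the first ends within
#' `end_tolerance` of the contig end and the second starts within
#' `end_tolerance` of position 0 (mirrored for `-`). Merging is applied
#' iteratively and the chimeric flag is recomputed; such reads are not
#' chimeric artifacts. Linear genomes pass through unchanged.
#'
#' @param cs A [CompatibleSet-class].
#' @param genomes A [GenomeSet-class] giving contig lengths and topologies.
#' @param end_tolerance Distance to the terminus in bp (default 50).
#' @return A [CompatibleSet-class], possibly with fewer segments.
#' @export
mergeCircularBridge <- function(cs, genomes, end_tolerance = 50) {
  seg <- cs@segments
  if (is.null(seg$wrapped)) seg$wrapped <- FALSE
  contig_len <- stats::setNames(
    as.numeric(Biostrings::width(genomes@sequences)),
    names(genomes@sequences))
  repeat {
    n <- nrow(seg)
    merged <- FALSE
    if (n >= 2) for (i in seq_len(n - 1)) {
      a <- seg[i, ]
      b <- seg[i + 1, ]
      if (a$ref_seq != b$ref_seq || a$strand != b$strand) next
      if (!a$ref_seq %in% names(contig_len)) next
      sp <- genomes@seqSpecies[[a$ref_seq]]
      if (genomes@topology[[sp]] != "circular") next
      L <- contig_len[[a$ref_seq]]
      bridges <- if (a$strand == "+") {
        (L - a$ref_end) <= end_tolerance && b$ref_start <= end_tolerance
      } else {
        a$ref_start <= end_tolerance && (L - b$ref_end) <= end_tolerance
      }
      if (!bridges) next
      m <- a
      m$query_start <- min(a$query_start, b$query_start)
      m$query_end <- max(a$query_end, b$query_end)
      if (a$strand == "+") {
        m$ref_start <- a$ref_start
        m$ref_end <- b$ref_end # wrapped: end is on the far side of origin
      } else {
        m$ref_start <- b$ref_start
        m$ref_end <- a$ref_end
      }
      m$aligned_bases <- a$aligned_bases + b$aligned_bases
      m$mapq <- min(a$mapq, b$mapq)
      m$cigar <- NA_character_
      m$wrapped <- TRUE
      seg <- rbind(if (i > 1) seg[seq_len(i - 1), ], m,
                   if (i + 1 < n) seg[seq(i + 2, n), ])
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  build_compatible_set(seg, cs@readLength)
}

#' Fit the head/tail unaligned-ratio model from compatible sets
#'
#' @param sets List of [CompatibleSet-class] objects.
#' @return An [AlignRatioModel-class].
#' @export
fitAlignRatioModel <- function(sets) {
  hf <- uf <- numeric()
  for (cs in sets) {
    unaligned <- cs@headUnaligned + cs@tailUnaligned + sum(cs@gaps)
    total <- cs@readLength
    if (total <= 0 || unaligned >= total) next
    ht <- cs@headUnaligned + cs@tailUnaligned
    hf <- c(hf, if (ht > 0) cs@headUnaligned / ht else 0.5)
    uf <- c(uf, unaligned / total)
  }
  new("AlignRatioModel", headFrac = hf, unalignedFrac = uf)
}

#' Profile chimeric reads from best compatible alignment sets
#'
#' Fits the chimeric-read model: the geometric segment-count parameter by
#' maximum likelihood (`p = N / sum(segment counts)` on support
#' \{1, 2, ...\}), the chimeric fraction, KDE length models for chimeric
#' segment and gap lengths, and the shrinkage rate of the source-species
#' Markov model via [learnShrinkage()] on consecutive segment pairs within
#' chimeric reads.
#'
#' @param sets List of [CompatibleSet-class] objects (after circular-bridge
#'   merging).
#' @param abundance Optional [AbundanceProfile-class] used by the shrinkage
#'   estimator; when NULL, a base-level profile is tallied from the sets
#'   themselves.
#' @param min_pairs Minimum pair count per first species for the shrinkage
#'   estimate (default 20).
#' @param fallback_s Shrinkage value used (with a warning) when no species
#'   reaches `min_pairs` (default 0.75).
#' @return A [ChimericProfile-class].
#' @export
profileChimeras <- function(sets, abundance = NULL, min_pairs = 20,
                            fallback_s = 0.75) {
  if (!length(sets)) stop("no compatible sets to profile")
  counts <- vapply(sets, function(s) nrow(s@segments), numeric(1))
  p_geom <- length(counts) / sum(counts)
  chim <- counts >= 2
  gap_samples <- unlist(lapply(sets[chim], function(s) s@gaps))
  seg_samples <- unlist(lapply(sets[chim], function(s) {
    s@segments$query_end - s@segments$query_start
  }))
  gap_model <- if (length(gap_samples) >= 2)
    fitLengthModel(gap_samples, transform = "log1p") else NULL
  seg_model <- if (length(seg_samples) >= 2)
    fitLengthModel(seg_samples, transform = "log") else NULL
  pairs <- do.call(rbind, lapply(sets[chim], function(s) {
    sp <- s@segments$ref_species
    if (length(sp) < 2) return(NULL)
    cbind(sp[-length(sp)], sp[-1])
  }))
  if (is.null(abundance)) {
    all_seg <- do.call(rbind, lapply(sets, function(s)
      s@segments[, c("ref_species", "aligned_bases")]))
    bases <- tapply(all_seg$aligned_bases, all_seg$ref_species, sum)
    abundance <- abundanceProfile(stats::setNames(as.numeric(bases),
                                                  names(bases)))
  }
  per_species <- numeric()
  s_hat <- fallback_s
  if (!is.null(pairs) && nrow(pairs)) {
    est <- tryCatch(
      learnShrinkage(pairs, abundance, min_pairs = min_pairs,
                     per_species = TRUE),
      error = function(e) {
        warning("shrinkage estimation failed (", conditionMessage(e),
                "); using fallback s = ", fallback_s)
        NULL
      })
    if (!is.null(est)) {
      s_hat <- est$s
      per_species <- est$per_species
    }
  } else if (any(chim)) {
    warning("no overlapping segment pairs; using fallback s = ", fallback_s)
  }
  new("ChimericProfile", pGeom = p_geom, chimericFraction = mean(chim),
      nReads = length(sets), segmentModel = seg_model, gapModel = gap_model,
      shrinkageRate = s_hat, perSpeciesShrinkage = per_species)
}

#' Characterize a training dataset end to end
#'
#' Orchestrates the characterization stage: finds each read's best
#' compatible alignment set, merges circular-origin bridges, profiles
#' chimeras, fits the aligned-read length KDE and the alignment-ratio
#' model, and (when CIGARs with `=`/`X` are available) the basecall-error
#' model.
#'
#' @param alignments Named list `read id -> subalignment data.frame` from
#'   [parseAlignments()].
#' @param genomes Optional [GenomeSet-class] (required for circular-bridge
#'   merging).
#' @param abundance Optional expected [AbundanceProfile-class] for the
#'   shrinkage estimator; the estimated profile is used when NULL.
#' @param slack,min_segment,end_tolerance See [bestCompatibleSet()] and
#'   [mergeCircularBridge()].
#' @return List with elements `sets`, `chimeric` ([ChimericProfile-class]),
#'   `aligned` (read-length [LengthKDE-class]), `align_ratio`
#'   ([AlignRatioModel-class]), `error` ([ErrorModel-class] or NULL), and
#'   `abundance` (base-level [AbundanceProfile-class] estimate, ECB mode).
#' @export
characterizeReads <- function(alignments, genomes = NULL, abundance = NULL,
                              slack = 10, min_segment = 100,
                              end_tolerance = 50) {
  sets <- lapply(alignments, bestCompatibleSet, slack = slack,
                 min_segment = min_segment)
  if (!is.null(genomes))
    sets <- lapply(sets, mergeCircularBridge, genomes = genomes,
                   end_tolerance = end_tolerance)
  est <- estimateAbundance(alignments, mode = "ECB", genomes = genomes,
                           slack = slack, min_segment = min_segment,
                           sets = sets)
  chim <- profileChimeras(sets, abundance = abundance %||% est)
  read_lengths <- vapply(sets, function(s) s@readLength, numeric(1))
  aligned_kde <- fitLengthModel(read_lengths, transform = "log")
  ratio <- fitAlignRatioModel(sets)
  cigars_ok <- vapply(alignments, function(df)
    any(!is.na(df$cigar) & grepl("[=X]", df$cigar)), logical(1))
  err <- if (any(cigars_ok)) {
    fitErrorModel(do.call(rbind, alignments))
  } else NULL
  list(sets = sets, chimeric = chim, aligned = aligned_kde,
       align_ratio = ratio, error = err, abundance = est)
}

#' Per-read chimera classification table
#'
#' @param sets List of [CompatibleSet-class] objects.
#' @return data.frame with `read_id, n_segments, is_chimeric, wrapped`.
#' @export
classifyReads <- function(sets) {
  do.call(rbind, lapply(sets, function(s) {
    data.frame(read_id = s@readId, n_segments = nrow(s@segments),
               is_chimeric = s@isChimeric,
               wrapped = any(s@segments$wrapped),
               stringsAsFactors = FALSE)
  }))
}
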