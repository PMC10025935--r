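#' @import methods
NULL

EVENT_TYPES <- c("match", "mismatch", "insertion", "deletion")

#' AbundanceProfile: relative genomic DNA-weight fractions per species
#'
#' A named vector of relative abundances, one entry per species, in units of
#' relative genomic DNA weight (fractions of total DNA mass). Entries are
#' non-negative and sum to 1.
#'
#' @slot entries Named numeric vector of relative abundances.
#' @export
setClass("AbundanceProfile", representation(entries = "numeric"))

setValidity("AbundanceProfile", function(object) {
  e <- object@entries
  if (is.null(names(e)) || any(!nzchar(names(e))))
    return("all abundance entries must be named by species")
  if (anyDuplicated(names(e)))
    return("duplicated species names in abundance profile")
  if (any(e < 0))
    return("abundances must be non-negative")
  if (length(e) && abs(sum(e) - 1) > 1e-9)
    return(sprintf("abundances must sum to 1 (got %.12f)", sum(e)))
  TRUE
})

#' Construct an AbundanceProfile
#'
#' @param x Named numeric vector of (possibly unnormalized) non-negative
#'   weights per species, or a 2-column data.frame (species, abundance).
#' @param normalize Divide by the total so entries sum to 1 (default TRUE).
#' @return An [AbundanceProfile-class] object.
#' @examples
#' abundanceProfile(c(A = 600, B = 400))
#' @export
abundanceProfile <- function(x, normalize = TRUE) {
  if (is.data.frame(x)) {
    v <- as.numeric(x[[2]])
    names(v) <- as.character(x[[1]])
    x <- v
  }
  if (normalize) {
    s <- sum(x)
    if (s <= 0) stop("total abundance weight must be positive")
    x <- x / s
  }
  new("AbundanceProfile", entries = x)
}

#' @describeIn abundanceProfile Extract the named abundance vector.
#' @param object An AbundanceProfile (or SourceModel).
#' @export
setGeneric("abundances", function(object) standardGeneric("abundances"))

#' @export
setMethod("abundances", "AbundanceProfile", function(object) object@entries)

setMethod("show", "AbundanceProfile", function(object) {
  cat(sprintf("AbundanceProfile with %d species\n", length(object@entries)))
  print(round(sort(object@entries, decreasing = TRUE), 6))
})

#' SourceModel: Markov model for source species of chimeric segments
#'
#' First-order observable Markov chain over species. The first segment of a
#' chimeric read is drawn from the community abundance profile; each
#' subsequent segment is drawn from a transition distribution in which the
#' probabilities of all species other than the previous one are scaled down
#' by the shrinkage rate `s` (0 < s <= 1) and the self-transition absorbs
#' the freed mass. `s = 1` recovers independent draws from the abundance
#' profile (homogeneously suspended DNA).
#'
#' @slot abundance An [AbundanceProfile-class]: start probabilities.
#' @slot s Shrinkage rate, dimensionless in (0, 1].
#' @export
setClass("SourceModel",
         representation(abundance = "AbundanceProfile", s = "numeric"))

setValidity("SourceModel", function(object) {
  if (length(object@s) != 1 || is.na(object@s) || object@s <= 0 || object@s > 1)
    return("shrinkage rate s must be a single value in (0, 1]")
  TRUE
})

#' Construct a SourceModel
#'
#' @param abundance An [AbundanceProfile-class] or named numeric weights.
#' @param s Shrinkage rate in (0, 1].
#' @return A [SourceModel-class] object.
#' @export
sourceModel <- function(abundance, s = 1) {
  if (!is(abundance, "AbundanceProfile"))
    abundance <- abundanceProfile(abundance)
  new("SourceModel", abundance = abundance, s = s)
}

#' @export
setMethod("abundances", "SourceModel", function(object) object@abundance@entries)

#' Shrinkage rate accessor
#' @param object A SourceModel or ChimericProfile.
#' @export
setGeneric("shrinkageRate", function(object) standardGeneric("shrinkageRate"))

#' @export
setMethod("shrinkageRate", "SourceModel", function(object) object@s)

setMethod("show", "SourceModel", function(object) {
  cat(sprintf("SourceModel: %d species, shrinkage rate s = %.4f\n",
              length(abundances(object)), object@s))
})

#' LengthKDE: Gaussian kernel density model of a length distribution
#'
#' Lengths (reads, chimeric segments, inter-segment gaps) are modelled by a
#' Gaussian KDE fitted in a transformed space: `log` for strictly positive
#' lengths spanning orders of magnitude, `log1p` for lengths admitting zero
#' (gaps), or `identity`. Sampling resamples a training point and adds
#' Gaussian noise at the fitted bandwidth, then back-transforms.
#'
#' @slot points Numeric vector of transformed training samples.
#' @slot bandwidth Kernel bandwidth in transformed space (Scott's rule).
#' @slot transform One of "log", "log1p", "identity".
#' @slot n Number of training samples.
#' @slot trainMin,trainMax Range of the raw training samples (bp).
#' @export
setClass("LengthKDE",
         representation(points = "numeric", bandwidth = "numeric",
                        transform = "character", n = "integer",
                        trainMin = "numeric", trainMax = "numeric"))

setValidity("LengthKDE", function(object) {
  if (object@n < 2) return("a fitted length model needs at least 2 samples")
  if (!object@transform %in% c("log", "log1p", "identity"))
    return("transform must be log, log1p or identity")
  if (object@bandwidth < 0) return("bandwidth must be non-negative")
  TRUE
})

setMethod("show", "LengthKDE", function(object) {
  cat(sprintf("LengthKDE (%s space): n = %d, range [%g, %g] bp, bw = %.4g\n",
              object@transform, object@n, object@trainMin, object@trainMax,
              object@bandwidth))
})

#' AlignRatioModel: empirical head/tail unaligned-ratio model
#'
#' Joint empirical distribution of (head_unaligned / total_unaligned) and
#' (total_unaligned / read_length) observed on training reads, where the
#' total unaligned length counts head, tail and inter-segment gaps. Sampling
#' draws a training pair. An untrained model yields no extra unaligned
#' sequence and a uniform head/tail split.
#'
#' @slot headFrac Numeric vector in \[0,1\]: head share of head+tail.
#' @slot unalignedFrac Numeric vector in \[0,1): unaligned share of read.
#' @export
setClass("AlignRatioModel",
         representation(headFrac = "numeric", unalignedFrac = "numeric"))

setValidity("AlignRatioModel", function(object) {
  if (length(object@headFrac) != length(object@unalignedFrac))
    return("headFrac and unalignedFrac must be paired")
  if (length(object@headFrac) &&
      (any(object@headFrac < 0 | object@headFrac > 1) ||
       any(object@unalignedFrac < 0 | object@unalignedFrac >= 1)))
    return("ratios must lie in [0,1] (unaligned fraction < 1)")
  TRUE
})

setMethod("show", "AlignRatioModel", function(object) {
  if (length(object@headFrac) == 0) cat("AlignRatioModel: untrained\n")
  else cat(sprintf("AlignRatioModel: %d training reads, median unaligned fraction %.3f\n",
                   length(object@headFrac), stats::median(object@unalignedFrac)))
})

#' ChimericProfile: fitted chimeric-read model
#'
#' Geometric segment-count model (support \{1, 2, ...\}, mean 1/p), the
#' observed chimeric fraction, KDE length models for chimeric segments and
#' the gaps between them, and the shrinkage rate of the source-species
#' Markov model.
#'
#' @slot pGeom Geometric success probability (0 < p <= 1).
#' @slot chimericFraction Fraction of reads with >= 2 segments after
#'   circular-bridge merging.
#' @slot nReads Number of reads profiled.
#' @slot segmentModel A [LengthKDE-class] for chimeric segment lengths, or
#'   NULL when no chimeras were observed.
#' @slot gapModel A [LengthKDE-class] for inter-segment gap lengths, or NULL.
#' @slot shrinkageRate Estimated shrinkage rate s.
#' @slot perSpeciesShrinkage Named numeric: per-first-species estimates.
#' @export
setClass("ChimericProfile",
         representation(pGeom = "numeric", chimericFraction = "numeric",
                        nReads = "integer", segmentModel = "ANY",
                        gapModel = "ANY", shrinkageRate = "numeric",
                        perSpeciesShrinkage = "numeric"))

setValidity("ChimericProfile", function(object) {
  if (object@pGeom <= 0 || object@pGeom > 1)
    return("pGeom must be in (0, 1]")
  if (object@chimericFraction < 0 || object@chimericFraction > 1)
    return("chimericFraction must be in [0, 1]")
  TRUE
})

#' @describeIn ChimericProfile-class Geometric success probability.
#' @param object A ChimericProfile.
#' @export
setGeneric("pGeom", function(object) standardGeneric("pGeom"))

#' @export
setMethod("pGeom", "ChimericProfile", function(object) object@pGeom)

#' Mean number of segments per read (1 / pGeom)
#' @param object A ChimericProfile.
#' @export
setGeneric("meanSegments", function(object) standardGeneric("meanSegments"))

#' @export
setMethod("meanSegments", "ChimericProfile", function(object) 1 / object@pGeom)

#' Fraction of reads classified chimeric
#' @param object A ChimericProfile.
#' @export
setGeneric("chimericFraction", function(object) standardGeneric("chimericFraction"))

#' @export
setMethod("chimericFraction", "ChimericProfile", function(object) object@chimericFraction)

#' @export
setMethod("shrinkageRate", "ChimericProfile", function(object) object@shrinkageRate)

setMethod("show", "ChimericProfile", function(object) {
  cat(sprintf(paste0(
    "ChimericProfile over %d reads\n",
    "  geometric p = %.4f (mean %.3f segments/read)\n",
    "  chimeric fraction = %.4f\n",
    "  shrinkage rate s = %.3f\n"),
    object@nReads, object@pGeom, 1 / object@pGeom,
    object@chimericFraction, object@shrinkageRate))
})

#' CompatibleSet: one read's best compatible alignment set
#'
#' An ordered (by query start) set of subalignments of one read that are
#' pairwise non-overlapping in query space and in reference space (up to a
#' small slack), representing the read's best explanation. A read whose
#' best set holds two or more segments after circular-bridge merging is
#' chimeric.
#'
#' @slot readId Read identifier.
#' @slot readLength Read length (bp).
#' @slot segments data.frame of subalignment rows (see [parseAlignments()])
#'   plus a `wrapped` logical column for merged circular-origin bridges.
#' @slot gaps Query-space distances (bp) between consecutive segments.
#' @slot headUnaligned,tailUnaligned Unaligned bp before/after the set.
#' @slot totalAligned Sum of aligned bases over segments.
#' @slot minMapq Minimum MAPQ over segments.
#' @slot isChimeric TRUE iff >= 2 segments (after merging).
#' @export
setClass("CompatibleSet",
         representation(readId = "character", readLength = "numeric",
                        segments = "data.frame", gaps = "numeric",
                        headUnaligned = "numeric", tailUnaligned = "numeric",
                        totalAligned = "numeric", minMapq = "numeric",
                        isChimeric = "logical"))

setValidity("CompatibleSet", function(object) {
  n <- nrow(object@segments)
  if (n < 1) return("a compatible set holds at least one segment")
  if (length(object@gaps) != n - 1)
    return("gaps must have one entry fewer than segments")
  if (any(object@gaps < 0)) return("gaps must be non-negative")
  if (object@isChimeric != (n >= 2))
    return("isChimeric must equal (number of segments >= 2)")
  TRUE
})

#' Number and table of segments in a CompatibleSet
#' @param object A CompatibleSet.
#' @export
setGeneric("segmentTable", function(object) standardGeneric("segmentTable"))

#' @export
setMethod("segmentTable", "CompatibleSet", function(object) object@segments)

#' Is the read chimeric?
#' @param object A CompatibleSet.
#' @export
setGeneric("isChimeric", function(object) standardGeneric("isChimeric"))

#' @export
setMethod("isChimeric", "CompatibleSet", function(object) object@isChimeric)

#' Total aligned bases of a CompatibleSet
#' @param object A CompatibleSet.
#' @export
setGeneric("totalAligned", function(object) standardGeneric("totalAligned"))

#' @export
setMethod("totalAligned", "CompatibleSet", function(object) object@totalAligned)

setMethod("show", "CompatibleSet", function(object) {
  cat(sprintf("CompatibleSet for read '%s': %d segment(s), %d aligned bp%s\n",
              object@readId, nrow(object@segments),
              as.integer(object@totalAligned),
              if (object@isChimeric) " [chimeric]" else ""))
})

#' ErrorModel: empirical basecall-event model
#'
#' First-order chain over basecall event types (match, mismatch, insertion,
#' deletion) with empirical run-length distributions per event type.
#' Consecutive runs always differ in type, so the transition matrix has a
#' zero diagonal. Substituted bases are drawn uniformly from the three
#' alternatives; inserted bases follow the trained base composition.
#' Optional per-event Phred quality distributions support FASTQ simulation.
#'
#' @slot transitions 4x4 row-stochastic matrix over event types.
#' @slot startProbs Distribution of the first event type of an alignment.
#' @slot runLengths Named list of integer vectors: empirical run lengths.
#' @slot baseComposition Named numeric over A,C,G,T.
#' @slot qualities Named list of integer Phred samples per event type
#'   (possibly empty when no FASTQ training data were provided).
#' @export
setClass("ErrorModel",
         representation(transitions = "matrix", startProbs = "numeric",
                        runLengths = "list", baseComposition = "numeric",
                        qualities = "list"))

setValidity("ErrorModel", function(object) {
  tr <- object@transitions
  if (!all(dim(tr) == c(4, 4))) return("transitions must be 4x4")
  rs <- rowSums(tr)
  if (any(abs(rs[rs > 0] - 1) > 1e-9))
    return("non-empty transition rows must sum to 1")
  if (any(diag(tr) != 0))
    return("runs never self-transition: diagonal must be zero")
  if (any(unlist(object@runLengths) < 1))
    return("run lengths must be >= 1")
  TRUE
})

setMethod("show", "ErrorModel", function(object) {
  r <- errorRates(object)
  cat(sprintf(paste0("ErrorModel: per-template-base rates ",
                     "mismatch %.4f, insertion %.4f, deletion %.4f%s\n"),
              r["mismatch"], r["insertion"], r["deletion"],
              if (length(object@qualities)) " (with quality model)" else ""))
})

#' GenomeSet: a reference metagenome with per-species topology
#'
#' All reference contigs of a community in one DNAStringSet, with maps from
#' contig id to species and from species to topology (linear or circular).
#'
#' @slot sequences A [Biostrings::DNAStringSet] of all contigs, named by
#'   contig id.
#' @slot seqSpecies Named character: contig id -> species.
#' @slot topology Named character: species -> "linear" or "circular".
#' @export
setClass("GenomeSet",
         representation(sequences = "ANY", seqSpecies = "character",
                        topology = "character"))

setValidity("GenomeSet", function(object) {
  if (!is(object@sequences, "DNAStringSet"))
    return("sequences must be a DNAStringSet")
  if (!all(names(object@sequences) %in% names(object@seqSpecies)))
    return("every contig needs a species assignment")
  if (!all(object@topology %in% c("linear", "circular")))
    return("topology values must be 'linear' or 'circular'")
  if (!all(unique(object@seqSpecies) %in% names(object@topology)))
    return("every species needs a topology entry")
  TRUE
})

#' Construct a GenomeSet from in-memory sequences
#'
#' @param sequences A named [Biostrings::DNAStringSet] (or named character
#'   vector) of contigs.
#' @param seqSpecies Named character mapping contig id to species. Defaults
#'   to one species per contig, named after the contig.
#' @param topology Named character species -> "linear"/"circular";
#'   unspecified species default to linear.
#' @return A [GenomeSet-class] object.
#' @export
genomeSet <- function(sequences, seqSpecies = NULL, topology = character()) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all contigs must be named")
  if (is.null(seqSpecies)) {
    seqSpecies <- stats::setNames(names(sequences), names(sequences))
  }
  species <- unique(seqSpecies)
  topo <- stats::setNames(rep("linear", length(species)), species)
  if (length(topology)) {
    bad <- setdiff(names(topology), species)
    if (length(bad))
      stop("topology given for unknown species: ", paste(bad, collapse = ", "))
    topo[names(topology)] <- topology
  }
  new("GenomeSet", sequences = sequences, seqSpecies = seqSpecies,
      topology = topo)
}

#' Species names of a GenomeSet
#' @param object A GenomeSet.
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))

#' @export
setMethod("speciesNames", "GenomeSet", function(object)
  unique(unname(object@seqSpecies)))

#' Total genome size (bp) per species
#' @param object A GenomeSet.
#' @return Named numeric vector of summed contig lengths per species.
#' @export
setGeneric("genomeSizes", function(object) standardGeneric("genomeSizes"))

#' @export
setMethod("genomeSizes", "GenomeSet", function(object) {
  w <- Biostrings::width(object@sequences)
  sp <- object@seqSpecies[names(object@sequences)]
  out <- tapply(w, sp, sum)
  stats::setNames(as.numeric(out), names(out))[speciesNames(object)]
})

#' Topology of a species
#' @param object A GenomeSet.
#' @param species Species name(s); default all.
#' @export
topologyOf <- function(object, species = NULL) {
  stopifnot(is(object, "GenomeSet"))
  if (is.null(species)) return(object@topology)
  if (!all(species %in% names(object@topology)))
    stop("unknown species: ",
         paste(setdiff(species, names(object@topology)), collapse = ", "))
  object@topology[species]
}

setMethod("show", "GenomeSet", function(object) {
  sz <- genomeSizes(object)
  cat(sprintf("GenomeSet: %d species, %d contig(s), %.3f Mbp total\n",
              length(sz), length(object@sequences), sum(sz) / 1e6))
  for (sp in names(sz))
    cat(sprintf("  %s: %s bp (%s)\n", sp, format(sz[[sp]], big.mark = ","),
                object@topology[[sp]]))
})
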