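#' Transition distribution of the source-species Markov chain
#'
#' Given the previous segment's species `A`, every other species `i`
#' receives probability `s * p_i` and the self-transition absorbs the rest:
#' `P(A | A) = 1 - s * sum_{i != A} p_i`. At `s = 1` the distribution equals
#' the abundance profile (independent sources); smaller `s` inflates
#' same-species adjacency, reflecting DNA molecules of one species
#' clustering near the pore.
#'
#' @param prev Species of the previous segment.
#' @param model A [SourceModel-class].
#' @return Named numeric distribution over species (sums to 1).
#' @export
transitionDistribution <- function(prev, model) {
  p <- abundances(model)
  if (!prev %in% names(p)) stop("unknown species: ", prev)
  out <- model@s * p
  out[prev] <- 1 - model@s * sum(p[names(p) != prev])
  out
}

#' Explicit transition matrix of the source-species chain
#'
#' @param model A [SourceModel-class].
#' @return Row-stochastic matrix with one row per species.
#' @export
transitionMatrix <- function(model) {
  sp <- names(abundances(model))
  t(vapply(sp, transitionDistribution, numeric(length(sp)), model = model))
}

#' Learn the shrinkage rate from overlapping segment pairs
#'
#' All segments of chimeric reads are divided into overlapping (consecutive)
#' pairs. For each first species `A` with at least `min_pairs`
#' observations, the observed switch probability is divided by the mass it
#' would have at `s = 1`:
#' `s_A = P(second != A | first = A) / sum_{i != A} p_i`. The shrinkage
#' rate is the unweighted mean of the per-species estimates (pair-count
#' weighting available via `weighted`), clamped to (0, 1].
#'
#' @param pairs Two-column matrix or data.frame of (first, second) species.
#' @param abundance An [AbundanceProfile-class] or named numeric weights.
#' @param min_pairs Minimum observations per first species (default 20);
#'   low-abundance species below it are excluded from the mean.
#' @param weighted Weight species estimates by pair counts (default FALSE).
#' @param per_species Also return the per-species estimates.
#' @return The shrinkage rate `s`, or (with `per_species = TRUE`) a list
#'   with elements `s` and `per_species`.
#' @export
learnShrinkage <- function(pairs, abundance, min_pairs = 20,
                           weighted = FALSE, per_species = FALSE) {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (is.null(dim(pairs)) || ncol(pairs) != 2 || nrow(pairs) == 0)
    stop("pairs must be a non-empty 2-column matrix of species names")
  if (!is(abundance, "AbundanceProfile"))
    abundance <- abundanceProfile(abundance)
  p <- abundances(abundance)
  sp_pairs <- unique(as.vector(pairs))
  missing_p <- setdiff(sp_pairs, names(p)[p > 0])
  if (length(missing_p))
    stop("species observed in pairs but absent (or zero) in the abundance ",
         "profile: ", paste(missing_p, collapse = ", "))
  from <- pairs[, 1]
  switched <- pairs[, 1] != pairs[, 2]
  n_a <- table(from)
  qualifying <- names(n_a)[n_a >= min_pairs]
  qualifying <- qualifying[p[qualifying] < 1] # need other-species mass
  if (!length(qualifying))
    stop("no species has >= ", min_pairs, " segment pairs; supply more ",
         "chimeric reads or use the fallback shrinkage rate (default 0.75)")
  s_a <- vapply(qualifying, function(a) {
    mean(switched[from == a]) / sum(p[names(p) != a])
  }, numeric(1))
  s <- if (weighted) {
    sum(s_a * as.numeric(n_a[qualifying])) / sum(n_a[qualifying])
  } else mean(s_a)
  s <- min(1, max(s, 1e-9))
  if (per_species) list(s = s, per_species = s_a) else s
}

#' Sample a chain of source species for one chimeric read
#'
#' The first segment's species is drawn from the abundance profile; each
#' subsequent one from [transitionDistribution()] given its predecessor.
#'
#' @param k Number of segments (>= 1).
#' @param model A [SourceModel-class].
#' @return Character vector of `k` species.
#' @export
sampleSpeciesChain <- function(k, model) {
  if (k < 1) stop("k must be >= 1")
  p <- abundances(model)
  sp <- names(p)
  out <- character(k)
  out[1] <- sample_one(sp, p)
  if (k > 1) for (i in 2:k) {
    out[i] <- sample_one(sp, transitionDistribution(out[i - 1], model))
  }
  out
}

#' Sample consecutive segment-pair species in bulk
#'
#' Vectorized equivalent of drawing `n` two-segment chains: the first
#' species from the abundance profile, the second from the transition
#' distribution. Used for shrinkage-rate recovery experiments.
#'
#' @param n Number of pairs.
#' @param model A [SourceModel-class].
#' @return n x 2 character matrix of (first, second) species.
#' @export
sampleSegmentPairs <- function(n, model) {
  p <- abundances(model)
  sp <- names(p)
  first <- sp[sample.int(length(sp), n, replace = TRUE, prob = p)]
  stay_prob <- 1 - model@s * (1 - p[first])
  to <- first
  move <- stats::runif(n) >= stay_prob
  # given a switch, the target is drawn from p restricted to other species;
  # rejection sampling from p is exact for that conditional
  idx <- which(move)
  while (length(idx)) {
    draw <- sp[sample.int(length(sp), length(idx), replace = TRUE, prob = p)]
    ok <- draw != first[idx]
    to[idx[ok]] <- draw[ok]
    idx <- idx[!ok]
  }
  cbind(first, to, deparse.level = 0)
}
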