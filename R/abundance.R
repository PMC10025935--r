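#' Tally aligned bases (or reads) per species
#'
#' Accumulates the evidence for abundance estimation. With chimeric
#' awareness on, every segment of each read's best compatible alignment set
#' contributes its aligned bases to its source species; otherwise only the
#' primary alignment contributes. A counted segment whose read has a
#' near-equivalent alignment to another species (aligned bases within
#' `score_equiv` of the counted segment, MAPQ within `mapq_equiv`, covering
#' the same query region) becomes a multialigned segment whose bases are
#' held back for EM assignment. At read level each read/segment counts 1
#' instead of its bases.
#'
#' @param sets Named list of [CompatibleSet-class] per read (used when
#'   `chimera_aware`); may be NULL otherwise.
#' @param alignments Named list `read id -> subalignment data.frame` (all
#'   alignments, including secondary, for the multialignment pool).
#' @param level "base" (aligned bases) or "read" (unit counts).
#' @param chimera_aware Use best compatible sets (TRUE) or primary
#'   alignments only (FALSE).
#' @param score_equiv Fraction of the counted segment's aligned bases a
#'   competitor must reach (default 0.9).
#' @param mapq_equiv Largest MAPQ difference for a competitor (default 10).
#' @param min_query_overlap Fraction of the counted segment's query span a
#'   competitor must overlap (default 0.5).
#' @return List with `unique` (named numeric tally), `multi` (list of
#'   `list(read_id, bases, candidates)`), and `n_unaligned` (reads with no
#'   usable alignment).
#' @export
tallyAlignments <- function(sets, alignments, level = c("base", "read"),
                            chimera_aware = TRUE, score_equiv = 0.9,
                            mapq_equiv = 10, min_query_overlap = 0.5) {
  level <- match.arg(level)
  unique_count <- numeric()
  multi <- list()
  n_unaligned <- 0L
  add <- function(tab, sp, x) {
    tab[sp] <- if (sp %in% names(tab)) tab[[sp]] + x else x
    tab
  }
  for (rid in names(alignments)) {
    alns <- alignments[[rid]]
    if (is.null(alns) || !nrow(alns)) {
      n_unaligned <- n_unaligned + 1L
      next
    }
    a_sp <- alns$ref_species
    a_qs <- alns$query_start
    a_qe <- alns$query_end
    a_ab <- alns$aligned_bases
    a_mq <- alns$mapq
    counted <- if (chimera_aware) {
      cs <- sets[[rid]]
      if (is.null(cs)) stop("no compatible set for read ", rid)
      cs@segments
    } else {
      keep <- which(alns$is_primary & !alns$is_secondary)
      if (!length(keep)) {
        n_unaligned <- n_unaligned + 1L
        next
      }
      alns[keep[which.max(a_ab[keep])], , drop = FALSE]
    }
    c_sp <- counted$ref_species
    c_qs <- counted$query_start
    c_qe <- counted$query_end
    c_ab <- counted$aligned_bases
    c_mq <- counted$mapq
    single_species <- all(a_sp == c_sp[1])
    for (i in seq_along(c_sp)) {
      weight <- if (level == "base") c_ab[i] else 1
      cand <- character()
      if (!single_species) {
        o <- a_sp != c_sp[i]
        if (any(o)) {
          span <- c_qe[i] - c_qs[i]
          near <- o &
            interval_overlap(c_qs[i], c_qe[i], a_qs, a_qe) >=
              min_query_overlap * span &
            a_ab >= score_equiv * c_ab[i] &
            abs(a_mq - c_mq[i]) <= mapq_equiv
          cand <- unique(a_sp[near])
        }
      }
      if (length(cand)) {
        multi[[length(multi) + 1L]] <-
          list(read_id = rid, bases = weight,
               candidates = sort(unique(c(c_sp[i], cand))))
      } else {
        unique_count <- add(unique_count, c_sp[i], weight)
      }
    }
  }
  list(unique = unique_count, multi = multi, n_unaligned = n_unaligned)
}

#' EM disambiguation of multialigned bases
#'
#' Uniquely aligned bases seed the abundance profile. The E step assigns
#' each multialigned segment's bases to its candidate species
#' proportionally to the current abundances restricted to those candidates;
#' the M step renormalizes unique plus assigned bases into a new profile.
#' Iteration stops when the largest per-species change falls below
#' `rel_tol` times the smallest positive abundance (default: 1% of the
#' minimum). Species with zero unique bases and no candidate mass stay at
#' zero. When all candidates of a segment have zero abundance its bases are
#' split equally.
#'
#' @param unique Named numeric tally of uniquely aligned bases (at least
#'   one positive entry).
#' @param multi List of `list(bases, candidates)` multialigned segments.
#' @param rel_tol Convergence threshold relative to the minimum abundance
#'   (default 0.01).
#' @param max_iter Iteration cap (default 1000).
#' @return An [AbundanceProfile-class]; the iteration count is attached as
#'   attribute `iterations`.
#' @export
emAbundance <- function(unique, multi = list(), rel_tol = 0.01,
                        max_iter = 1000) {
  if (!length(unique) || sum(unique) <= 0)
    stop("no uniquely aligned bases: cannot seed the abundance profile")
  species <- sort(base::unique(c(names(unique),
                                 unlist(lapply(multi, `[[`, "candidates")))))
  u <- stats::setNames(numeric(length(species)), species)
  u[names(unique)] <- unique
  abun <- u / sum(u)
  if (!length(multi)) {
    out <- abundanceProfile(abun, normalize = FALSE)
    attr(out, "iterations") <- 0L
    return(out)
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    assigned <- stats::setNames(numeric(length(species)), species)
    for (m in multi) {
      w <- abun[m$candidates]
      tot <- sum(w)
      frac <- if (tot > 0) w / tot else
        rep(1 / length(w), length(w))
      assigned[m$candidates] <- assigned[m$candidates] + m$bases * frac
    }
    counts <- u + assigned
    new_abun <- counts / sum(counts)
    diff <- max(abs(new_abun - abun))
    abun <- new_abun
    if (diff < rel_tol * min(abun[abun > 0]) || iter >= max_iter) break
  }
  out <- abundanceProfile(abun, normalize = FALSE)
  attr(out, "iterations") <- iter
  out
}

#' Estimate microbial abundances from alignments
#'
#' Dispatches the quantification modes of the ablation family:
#' \describe{
#'   \item{B}{base level, primary alignments only, no EM}
#'   \item{CB}{base level with chimeric read detection}
#'   \item{EB}{base level with EM}
#'   \item{ECB}{base level, chimeric detection, EM (the full method)}
#'   \item{CR}{read level with chimeric detection (each segment counts 1)}
#'   \item{ER}{read level with EM (each primary read counts 1)}
#' }
#' Modes without EM split multialigned evidence equally among candidates in
#' a single pass.
#'
#' @param alignments Named list `read id -> subalignment data.frame`.
#' @param mode One of "B", "CB", "EB", "ECB", "CR", "ER".
#' @param genomes Optional [GenomeSet-class] for circular-bridge merging in
#'   chimera-aware modes.
#' @param slack,min_segment Passed to [bestCompatibleSet()].
#' @param rel_tol EM convergence threshold (default 0.01).
#' @param sets Optional precomputed compatible sets (named by read id).
#' @param ... Passed to [tallyAlignments()].
#' @return An [AbundanceProfile-class].
#' @export
estimateAbundance <- function(alignments,
                              mode = c("ECB", "B", "CB", "EB", "CR", "ER"),
                              genomes = NULL, slack = 10, min_segment = 100,
                              rel_tol = 0.01, sets = NULL, ...) {
  mode <- match.arg(mode)
  chimera_aware <- grepl("C", mode)
  use_em <- grepl("E", mode)
  level <- if (grepl("R", mode)) "read" else "base"
  if (chimera_aware && is.null(sets)) {
    sets <- lapply(alignments, bestCompatibleSet, slack = slack,
                   min_segment = min_segment)
    if (!is.null(genomes))
      sets <- lapply(sets, mergeCircularBridge, genomes = genomes)
  }
  t <- tallyAlignments(sets, alignments, level = level,
                       chimera_aware = chimera_aware, ...)
  if (use_em) return(emAbundance(t$unique, t$multi, rel_tol = rel_tol))
  u <- t$unique
  for (m in t$multi) {
    share <- m$bases / length(m$candidates)
    for (sp in m$candidates)
      u[sp] <- (if (sp %in% names(u)) u[[sp]] else 0) + share
  }
  abundanceProfile(u[sort(names(u))])
}

#' Convert DNA-weight abundances to relative genome copy numbers
#'
#' Abundances are in units of relative genomic DNA weight; dividing by the
#' genome size and renormalizing yields relative copy numbers.
#'
#' @param profile An [AbundanceProfile-class].
#' @param genome_sizes Named numeric of genome sizes (bp); must cover every
#'   species with positive abundance.
#' @return Named numeric of relative copy numbers (sums to 1).
#' @export
copyNumbers <- function(profile, genome_sizes) {
  p <- abundances(profile)
  need <- names(p)[p > 0]
  missing <- setdiff(need, names(genome_sizes))
  if (length(missing))
    stop("missing genome size for: ", paste(missing, collapse = ", "))
  if (any(genome_sizes[need] <= 0))
    stop("genome sizes must be positive")
  c_raw <- stats::setNames(numeric(length(p)), names(p))
  c_raw[need] <- p[need] / genome_sizes[need]
  c_raw / sum(c_raw)
}

#' Deviation between estimated and expected abundances
#'
#' Per-species percent deviation `(estimated - expected)/expected * 100`,
#' plus the summary statistics used to benchmark estimators: the summation
#' of absolute percent errors, R-squared, and the standard deviation of
#' residuals; optionally the same on log10-transformed abundances, which
#' keeps low-abundance species from being overshadowed.
#'
#' @param estimated,expected [AbundanceProfile-class] objects over the same
#'   species.
#' @param log10_stats Also compute log-scale R-squared/SD over species with
#'   positive abundance in both profiles (default TRUE).
#' @return List with `per_species` (named percent deviations; `Inf` where
#'   expected is 0 but estimated is not, excluded from the summation with a
#'   warning) and `summary`.
#' @export
deviationReport <- function(estimated, expected, log10_stats = TRUE) {
  est <- abundances(estimated)
  exp_ <- abundances(expected)
  if (!setequal(names(est), names(exp_)))
    stop("estimated and expected profiles must cover the same species")
  exp_ <- exp_[names(est)]
  dev <- ifelse(exp_ > 0, (est - exp_) / exp_ * 100,
                ifelse(est > 0, Inf, 0))
  if (any(is.infinite(dev)))
    warning("species with expected abundance 0 but positive estimate: ",
            paste(names(dev)[is.infinite(dev)], collapse = ", "),
            " (excluded from the percent-error summation)")
  finite <- is.finite(dev)
  resid <- est - exp_
  r2 <- if (stats::var(exp_) > 0) {
    stats::cor(est, exp_)^2
  } else if (max(abs(resid)) < 1e-12) 1 else NA_real_
  summary <- list(sum_abs_percent_error = sum(abs(dev[finite])),
                  r_squared = r2,
                  sd_residuals = stats::sd(resid))
  if (log10_stats) {
    pos <- est > 0 & exp_ > 0
    if (sum(pos) >= 3) {
      le <- log10(est[pos])
      lx <- log10(exp_[pos])
      summary$log_r_squared <- stats::cor(le, lx)^2
      summary$log_sd_residuals <- stats::sd(le - lx)
    }
  }
  list(per_species = dev, summary = summary)
}
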