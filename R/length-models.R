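#' Fit a kernel density length model
#'
#' Gaussian KDE fitted in transformed space: `log` (default for read and
#' segment lengths, which span orders of magnitude), `log1p` (for gap
#' lengths, which admit zero), or `identity`. The default bandwidth is the
#' Sheather-Jones plug-in ([stats::bw.SJ()]), which tracks the multimodal
#' length distributions these data exhibit; Scott's rule
#' `sd(x) * n^(-1/5)` is the fallback when the plug-in cannot be computed
#' (tiny or degenerate samples).
#'
#' @param samples Numeric vector of lengths in bp (>= 2 values; `log`
#'   requires all positive, `log1p` all non-negative).
#' @param transform One of "log", "log1p", "identity".
#' @param bandwidth Optional bandwidth override (transformed space).
#' @return A [LengthKDE-class].
#' @export
fitLengthModel <- function(samples, transform = c("log", "log1p", "identity"),
                           bandwidth = NULL) {
  transform <- match.arg(transform)
  samples <- as.numeric(samples)
  if (length(samples) < 2)
    stop("need at least 2 samples to fit a length model; ",
         "fall back to empirical resampling for smaller inputs")
  if (transform == "log" && any(samples <= 0))
    stop("log-space KDE requires positive lengths")
  if (transform == "log1p" && any(samples < 0))
    stop("log1p-space KDE requires non-negative lengths")
  pts <- switch(transform, log = log(samples), log1p = log1p(samples),
                identity = samples)
  if (is.null(bandwidth)) {
    bandwidth <- tryCatch(stats::bw.SJ(pts), error = function(e)
      stats::sd(pts) * length(pts)^(-1 / 5))
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1e-8
  }
  new("LengthKDE", points = pts, bandwidth = bandwidth,
      transform = transform, n = length(samples),
      trainMin = min(samples), trainMax = max(samples))
}

#' Sample integer lengths from a fitted KDE
#'
#' Resamples a training point, adds Gaussian noise at the fitted bandwidth,
#' back-transforms, rounds, and clips to `[min_clip, max_clip]`.
#'
#' @param model A [LengthKDE-class].
#' @param n Number of draws (>= 0).
#' @param min_clip Lower clip in bp (default 1; use 0 for gap models).
#' @param max_clip Upper clip in bp (default: training maximum x 1.1).
#' @return Integer vector of `n` lengths.
#' @export
sampleLengths <- function(model, n, min_clip = 1, max_clip = NULL) {
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(integer())
  if (is.null(max_clip)) max_clip <- round(model@trainMax * 1.1)
  t <- model@points[sample.int(length(model@points), n, replace = TRUE)] +
    stats::rnorm(n, 0, model@bandwidth)
  raw <- switch(model@transform, log = exp(t), log1p = expm1(t),
                identity = t)
  as.integer(pmin(pmax(round(raw), min_clip), max_clip))
}

#' Kernel density of a fitted length model
#'
#' Density of the KDE evaluated on the raw (bp) scale, with the Jacobian of
#' the fitted transform applied.
#'
#' @param model A [LengthKDE-class].
#' @param x Lengths (bp) at which to evaluate.
#' @return Numeric densities.
#' @export
densityLengths <- function(model, x) {
  tx <- switch(model@transform, log = log(x), log1p = log1p(x),
               identity = x)
  jac <- switch(model@transform, log = 1 / x, log1p = 1 / (1 + x),
                identity = rep(1, length(x)))
  d <- vapply(tx, function(t)
    mean(stats::dnorm(t, model@points, model@bandwidth)), numeric(1))
  d * jac
}

#' Sample per-read segment counts from the geometric model
#'
#' Segment counts follow a geometric distribution on support \{1, 2, ...\}
#' with success probability `p` (mean `1/p`); a read with two or more
#' segments is chimeric, so the chimeric fraction is `1 - p`. Counts above
#' `max_segments` are redrawn (truncation by resampling).
#'
#' @param p Geometric success probability in (0, 1].
#' @param n Number of draws.
#' @param max_segments Truncation point (default 10).
#' @return Integer vector of segment counts (each >= 1).
#' @export
sampleSegmentCount <- function(p, n = 1, max_segments = 10) {
  if (p <= 0 || p > 1) stop("p must be in (0, 1]")
  k <- stats::rgeom(n, p) + 1L
  idx <- which(k > max_segments)
  while (length(idx)) {
    k[idx] <- stats::rgeom(length(idx), p) + 1L
    idx <- idx[k[idx] > max_segments]
  }
  k
}

#' Maximum-likelihood geometric parameter from segment counts
#'
#' For counts on support \{1, 2, ...\} the MLE is `n / sum(counts)`.
#'
#' @param counts Integer vector of per-read segment counts.
#' @return Estimated success probability.
#' @export
geometricMLE <- function(counts) {
  if (!length(counts) || any(counts < 1))
    stop("counts must be a non-empty vector of values >= 1")
  length(counts) / sum(counts)
}

#' Sample head/tail unaligned ratios
#'
#' Draws a (head fraction, unaligned fraction) pair from the trained
#' empirical joint distribution; an untrained model yields no unaligned
#' sequence beyond the gaps and a uniform head/tail split.
#'
#' @param model An [AlignRatioModel-class].
#' @return Named numeric `c(head_frac, unaligned_frac)`.
#' @export
sampleAlignRatio <- function(model) {
  if (length(model@headFrac) == 0)
    return(c(head_frac = 0.5, unaligned_frac = 0))
  i <- sample.int(length(model@headFrac), 1)
  c(head_frac = model@headFrac[i], unaligned_frac = model@unalignedFrac[i])
}
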