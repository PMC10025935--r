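write_kde_file <- function(model, path) {
  header <- sprintf("#transform=%s\tbandwidth=%.10g", model@transform,
                    model@bandwidth)
  writeLines(c(header, format(model@points, digits = 12)), path)
}

read_kde_file <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  kv <- strsplit(hdr, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  pts <- as.numeric(lines[-1])
  raw <- switch(vals[["transform"]], log = exp(pts), log1p = expm1(pts),
                identity = pts)
  new("LengthKDE", points = pts,
      bandwidth = as.numeric(vals[["bandwidth"]]),
      transform = vals[["transform"]], n = length(pts),
      trainMin = min(raw), trainMax = max(raw))
}

#' Write a trained model bundle to a directory
#'
#' Serializes the characterization output as plain text: KDE length models
#' (`kde_aligned_reads.model`, `kde_segments.model`, `kde_gaps.model`),
#' `chimeric_profile.json` (geometric parameter, chimeric fraction,
#' shrinkage rate with per-species estimates), `align_ratio.tsv`, and when
#' an error model was fitted, `error_model.json` plus
#' `error_run_lengths.tsv` and `error_qualities.tsv`.
#'
#' @param models Model bundle from [characterizeReads()] (elements
#'   `chimeric`, `aligned`, `align_ratio`, `error`; extra elements are
#'   ignored).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeModelDir <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chim <- models$chimeric
  write_kde_file(models$aligned, file.path(dir, "kde_aligned_reads.model"))
  if (!is.null(chim@segmentModel))
    write_kde_file(chim@segmentModel, file.path(dir, "kde_segments.model"))
  if (!is.null(chim@gapModel))
    write_kde_file(chim@gapModel, file.path(dir, "kde_gaps.model"))
  jsonlite::write_json(
    list(p_geom = chim@pGeom, mean_segments = 1 / chim@pGeom,
         chimeric_fraction = chim@chimericFraction, n_reads = chim@nReads,
         shrinkage_rate = chim@shrinkageRate,
         per_species_shrinkage = as.list(chim@perSpeciesShrinkage)),
    file.path(dir, "chimeric_profile.json"), auto_unbox = TRUE, digits = NA)
  ratio <- models$align_ratio
  if (!is.null(ratio) && length(ratio@headFrac))
    write.table(data.frame(head_frac = ratio@headFrac,
                           unaligned_frac = ratio@unalignedFrac),
                file.path(dir, "align_ratio.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  err <- models$error
  if (!is.null(err)) {
    jsonlite::write_json(
      list(transitions = as.data.frame(err@transitions),
           start_probs = as.list(err@startProbs),
           base_composition = as.list(err@baseComposition)),
      file.path(dir, "error_model.json"), digits = NA)
    rl <- do.call(rbind, lapply(names(err@runLengths), function(t)
      data.frame(type = t, length = err@runLengths[[t]])))
    write.table(rl, file.path(dir, "error_run_lengths.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (length(err@qualities)) {
      q <- do.call(rbind, lapply(names(err@qualities), function(t)
        data.frame(type = t, phred = err@qualities[[t]])))
      write.table(q, file.path(dir, "error_qualities.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a trained model bundle from a directory
#'
#' Inverse of [writeModelDir()].
#'
#' @param dir Model directory.
#' @return Model bundle list (`chimeric`, `aligned`, `align_ratio`,
#'   `error`) as consumed by [simulateRead()] and [simulateMetagenome()].
#' @export
readModelDir <- function(dir) {
  aligned <- read_kde_file(file.path(dir, "kde_aligned_reads.model"))
  segf <- file.path(dir, "kde_segments.model")
  gapf <- file.path(dir, "kde_gaps.model")
  cj <- jsonlite::read_json(file.path(dir, "chimeric_profile.json"),
                            simplifyVector = TRUE)
  chim <- new("ChimericProfile", pGeom = cj$p_geom,
              chimericFraction = cj$chimeric_fraction,
              nReads = as.integer(cj$n_reads),
              segmentModel = if (file.exists(segf)) read_kde_file(segf) else NULL,
              gapModel = if (file.exists(gapf)) read_kde_file(gapf) else NULL,
              shrinkageRate = cj$shrinkage_rate,
              perSpeciesShrinkage = unlist(cj$per_species_shrinkage) %||%
                numeric())
  ratiof <- file.path(dir, "align_ratio.tsv")
  ratio <- if (file.exists(ratiof)) {
    tab <- read.table(ratiof, header = TRUE, sep = "\t")
    new("AlignRatioModel", headFrac = tab$head_frac,
        unalignedFrac = tab$unaligned_frac)
  } else new("AlignRatioModel", headFrac = numeric(),
             unalignedFrac = numeric())
  errf <- file.path(dir, "error_model.json")
  err <- NULL
  if (file.exists(errf)) {
    ej <- jsonlite::read_json(errf, simplifyVector = TRUE)
    trans <- as.matrix(ej$transitions)
    dimnames(trans) <- list(EVENT_TYPES, EVENT_TYPES)
    rl <- read.table(file.path(dir, "error_run_lengths.tsv"), header = TRUE,
                     sep = "\t")
    runs <- split(as.integer(rl$length), rl$type)
    qf <- file.path(dir, "error_qualities.tsv")
    quals <- if (file.exists(qf)) {
      qt <- read.table(qf, header = TRUE, sep = "\t")
      split(as.integer(qt$phred), qt$type)
    } else list()
    err <- new("ErrorModel", transitions = trans,
               startProbs = unlist(ej$start_probs)[EVENT_TYPES],
               runLengths = runs,
               baseComposition = unlist(ej$base_composition)[BASES],
               qualities = quals)
  }
  list(chimeric = chim, aligned = aligned, align_ratio = ratio, error = err)
}
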