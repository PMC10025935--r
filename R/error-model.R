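# collapse CIGAR ops into basecall-event runs; requires =/X (M is ambiguous
# without an MD tag)
cigar_event_runs <- function(cigar) {
  ops <- cigar_ops(cigar)
  keep <- ops$op %in% c("=", "X", "I", "D")
  if (any(ops$op == "M"))
    stop("error-model fitting requires CIGARs with =/X match columns ",
         "(or MD-resolvable matches); got an ambiguous 'M' operation")
  len <- ops$len[keep]
  op <- ops$op[keep]
  type <- c("=" = "match", "X" = "mismatch", "I" = "insertion",
            "D" = "deletion")[op]
  # adjacent ops of the same type merge into one run
  if (length(type) > 1) {
    grp <- cumsum(c(TRUE, type[-1] != type[-length(type)]))
    len <- as.integer(tapply(len, grp, sum))
    type <- type[!duplicated(grp)]
  }
  list(type = unname(type), len = len)
}

#' Fit the basecall-error model from alignments
#'
#' Walks the CIGAR string of every alignment, extracts runs of match,
#' mismatch, insertion and deletion events, and accumulates the first-order
#' event-transition counts, per-event empirical run-length distributions,
#' and (when per-read Phred qualities are supplied) per-event quality
#' distributions. Transition rows receive Laplace smoothing (`alpha`) over
#' event types that were observed at all; runs never self-transition.
#'
#' @param alignments Subalignment data.frame (or list of them) whose
#'   `cigar` column uses `=`/`X`.
#' @param qualities Optional named list `read id -> integer Phred vector`
#'   aligned to the read; used to fit per-event quality distributions.
#' @param alpha Laplace smoothing pseudo-count for transitions (default 1).
#' @return An [ErrorModel-class].
#' @export
fitErrorModel <- function(alignments, qualities = NULL, alpha = 1) {
  if (is.list(alignments) && !is.data.frame(alignments))
    alignments <- do.call(rbind, alignments)
  cig <- alignments$cigar
  if (is.null(cig) || all(is.na(cig)))
    stop("error-model fitting requires alignments with CIGAR strings")
  alignments <- alignments[!is.na(cig) & nzchar(cig), , drop = FALSE]
  trans <- matrix(0, 4, 4, dimnames = list(EVENT_TYPES, EVENT_TYPES))
  start <- stats::setNames(numeric(4), EVENT_TYPES)
  runs <- stats::setNames(vector("list", 4), EVENT_TYPES)
  quals <- stats::setNames(vector("list", 4), EVENT_TYPES)
  for (r in seq_len(nrow(alignments))) {
    ev <- cigar_event_runs(alignments$cigar[r])
    if (!length(ev$type)) next
    start[ev$type[1]] <- start[ev$type[1]] + 1
    for (t in EVENT_TYPES)
      runs[[t]] <- c(runs[[t]], ev$len[ev$type == t])
    if (length(ev$type) > 1) {
      for (i in seq_len(length(ev$type) - 1))
        trans[ev$type[i], ev$type[i + 1]] <-
          trans[ev$type[i], ev$type[i + 1]] + 1
    }
    if (!is.null(qualities)) {
      q <- qualities[[alignments$read_id[r]]]
      if (!is.null(q)) {
        qpos <- alignments$query_start[r]
        for (i in seq_along(ev$type)) {
          t <- ev$type[i]
          if (t %in% c("match", "mismatch", "insertion")) {
            quals[[t]] <- c(quals[[t]], q[(qpos + 1):(qpos + ev$len[i])])
            qpos <- qpos + ev$len[i]
          }
        }
      }
    }
  }
  observed <- EVENT_TYPES[vapply(runs, length, integer(1)) > 0]
  for (from in EVENT_TYPES) {
    row <- trans[from, ]
    targets <- setdiff(observed, from)
    if (length(targets)) row[targets] <- row[targets] + alpha
    row[setdiff(EVENT_TYPES, targets)] <- 0
    tot <- sum(row)
    trans[from, ] <- if (tot > 0) row / tot else 0
  }
  if (sum(start) > 0) start <- start / sum(start)
  quals <- quals[vapply(quals, length, integer(1)) > 0]
  new("ErrorModel", transitions = trans, startProbs = start,
      runLengths = lapply(runs[observed], as.integer),
      baseComposition = stats::setNames(rep(0.25, 4), BASES),
      qualities = quals)
}

#' Construct an ErrorModel from target per-base rates
#'
#' Convenience constructor for simulation and testing: builds a model whose
#' stationary per-template-base mismatch/insertion/deletion rates match the
#' requested values, with geometric run lengths of the given means.
#'
#' @param mismatch,insertion,deletion Target per-template-base rates.
#' @param mean_len Named numeric of mean run lengths per error type
#'   (default 1 for each error type).
#' @param match_run_cap Longest match run to tabulate (default 1000).
#' @param qualities Optional named list of Phred samples per event type.
#' @return An [ErrorModel-class].
#' @export
errorModelFromRates <- function(mismatch = 0.05, insertion = 0.03,
                                deletion = 0.04,
                                mean_len = c(mismatch = 1, insertion = 1,
                                             deletion = 1),
                                match_run_cap = 1000, qualities = list()) {
  ev_rate <- c(mismatch = mismatch / mean_len[["mismatch"]],
               insertion = insertion / mean_len[["insertion"]],
               deletion = deletion / mean_len[["deletion"]])
  # events per template base, excluding bases consumed inside error runs
  p_err <- sum(ev_rate)
  if (p_err >= 0.5) stop("combined error rate too high for this model")
  mean_match <- (1 - mismatch - deletion) / p_err
  runs <- list(
    match = as.integer(pmax(1, stats::qgeom(
      stats::ppoints(2000), 1 / mean_match) + 1L)),
    mismatch = as.integer(pmax(1, stats::qgeom(
      stats::ppoints(200), 1 / mean_len[["mismatch"]]) + 1L)),
    insertion = as.integer(pmax(1, stats::qgeom(
      stats::ppoints(200), 1 / mean_len[["insertion"]]) + 1L)),
    deletion = as.integer(pmax(1, stats::qgeom(
      stats::ppoints(200), 1 / mean_len[["deletion"]]) + 1L)))
  runs$match <- pmin(runs$match, as.integer(match_run_cap))
  w <- ev_rate / p_err
  trans <- matrix(0, 4, 4, dimnames = list(EVENT_TYPES, EVENT_TYPES))
  trans["match", c("mismatch", "insertion", "deletion")] <- w
  for (e in c("mismatch", "insertion", "deletion")) {
    # after an error run, return to a match run
    trans[e, "match"] <- 1
  }
  start <- c(match = 1, mismatch = 0, insertion = 0, deletion = 0)
  new("ErrorModel", transitions = trans, startProbs = start,
      runLengths = runs,
      baseComposition = stats::setNames(rep(0.25, 4), BASES),
      qualities = qualities)
}

#' Stationary per-template-base error rates of an ErrorModel
#'
#' Computed analytically from the event chain: the stationary event-type
#' frequencies (left eigenvector of the transition matrix) weighted by mean
#' run lengths, normalized by template-consuming bases (match, mismatch,
#' deletion).
#'
#' @param model An [ErrorModel-class].
#' @return Named numeric: `mismatch`, `insertion`, `deletion` rates.
#' @export
errorRates <- function(model) {
  observed <- names(model@runLengths)
  if (identical(observed, "match") || length(observed) <= 1)
    return(c(mismatch = 0, insertion = 0, deletion = 0))
  P <- model@transitions[observed, observed, drop = FALSE]
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  pi_ <- Re(e$vectors[, i])
  pi_ <- pi_ / sum(pi_)
  names(pi_) <- observed
  mean_len <- vapply(model@runLengths, mean, numeric(1))
  bases <- pi_ * mean_len[observed]
  consuming <- intersect(c("match", "mismatch", "deletion"), observed)
  denom <- sum(bases[consuming])
  out <- c(mismatch = 0, insertion = 0, deletion = 0)
  for (t in c("mismatch", "insertion", "deletion"))
    if (t %in% observed) out[t] <- bases[[t]] / denom
  out
}

sample_run_length <- function(model, type) {
  v <- model@runLengths[[type]]
  v[sample.int(length(v), 1)]
}

#' Introduce basecall errors into a template sequence
#'
#' Walks the event chain over the template: alternating runs of match,
#' mismatch, insertion and deletion are sampled from the model until the
#' template is consumed. Substituted bases are drawn uniformly from the
#' three alternatives; inserted bases follow the model's base composition.
#' The event log records, for every run, its type, 0-based template
#' position, length, and the emitted bases (NA for match/deletion), which
#' makes the mutation exactly replayable.
#'
#' @param seq Template nucleotide string (non-empty).
#' @param model An [ErrorModel-class].
#' @return List with `sequence` (mutated string) and `log` (data.frame
#'   `type, template_pos, length, bases`).
#' @export
introduceErrors <- function(seq, model) {
  n <- nchar(seq)
  if (n == 0) stop("empty template sequence")
  tmpl <- strsplit(seq, "", fixed = TRUE)[[1]]
  observed <- names(model@runLengths)
  if (identical(observed, "match")) {
    return(list(sequence = seq,
                log = data.frame(type = "match", template_pos = 0L,
                                 length = n, bases = NA_character_,
                                 stringsAsFactors = FALSE)))
  }
  comp <- model@baseComposition[BASES]
  type <- sample_one(observed, model@startProbs[observed])
  pos <- 1L
  out <- vector("list", 256L)
  log_type <- character(256L)
  log_pos <- integer(256L)
  log_len <- integer(256L)
  log_bases <- character(256L)
  nrun <- 0L
  repeat {
    len <- sample_run_length(model, type)
    remaining <- n - pos + 1L
    emitted <- NA_character_
    chunk <- NULL
    if (type == "match") {
      len <- min(len, remaining)
      chunk <- tmpl[pos:(pos + len - 1L)]
      pos <- pos + len
    } else if (type == "mismatch") {
      len <- min(len, remaining)
      orig <- tmpl[pos:(pos + len - 1L)]
      # uniform draw over the three alternative bases, vectorized
      chunk <- ALT_BASES[cbind(match(orig, BASES),
                               sample.int(3L, len, replace = TRUE))]
      emitted <- paste(chunk, collapse = "")
      pos <- pos + len
    } else if (type == "deletion") {
      len <- min(len, remaining)
      pos <- pos + len
    } else { # insertion
      chunk <- sample(BASES, len, replace = TRUE, prob = comp)
      emitted <- paste(chunk, collapse = "")
    }
    nrun <- nrun + 1L
    if (nrun > length(log_type)) { # grow geometrically
      grow <- length(log_type)
      out <- c(out, vector("list", grow))
      log_type <- c(log_type, character(grow))
      log_pos <- c(log_pos, integer(grow))
      log_len <- c(log_len, integer(grow))
      log_bases <- c(log_bases, character(grow))
    }
    out[[nrun]] <- chunk
    log_type[nrun] <- type
    log_pos[nrun] <- pos - 1L - if (type == "insertion") 0L else len
    log_len[nrun] <- len
    log_bases[nrun] <- emitted
    if (pos > n) break
    row <- model@transitions[type, observed]
    if (sum(row) <= 0) type <- "match" else type <- sample_one(observed, row)
  }
  idx <- seq_len(nrun)
  list(sequence = paste(unlist(out[idx]), collapse = ""),
       log = data.frame(type = log_type[idx], template_pos = log_pos[idx],
                        length = log_len[idx], bases = log_bases[idx],
                        stringsAsFactors = FALSE))
}

#' Replay an event log against its template
#'
#' Applies a recorded event log to the original template and returns the
#' mutated read; by construction this reproduces [introduceErrors()]'s
#' output exactly.
#'
#' @param seq Template nucleotide string.
#' @param log Event-log data.frame from [introduceErrors()].
#' @return Mutated sequence string.
#' @export
replayEventLog <- function(seq, log) {
  tmpl <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- vector("list", nrow(log))
  for (i in seq_len(nrow(log))) {
    type <- log$type[i]
    pos <- log$template_pos[i]
    len <- log$length[i]
    if (type == "match") {
      out[[i]] <- tmpl[(pos + 1):(pos + len)]
    } else if (type %in% c("mismatch", "insertion")) {
      out[[i]] <- strsplit(log$bases[i], "", fixed = TRUE)[[1]]
    } # deletion emits nothing
  }
  paste(unlist(out), collapse = "")
}

#' Assign per-base Phred qualities from an event log
#'
#' Draws each emitted base's quality from the event-type-conditional Phred
#' distribution of the model; deletions emit no base. The result has the
#' same length as the mutated read.
#'
#' @param log Event-log data.frame from [introduceErrors()].
#' @param model An [ErrorModel-class] with fitted quality distributions.
#' @return Phred+33-encoded quality string.
#' @export
assignQualities <- function(log, model) {
  if (!length(model@qualities))
    stop("model has no quality distributions; train with FASTQ input or ",
         "write FASTA output instead")
  draw <- function(type, n) {
    v <- model@qualities[[type]] %||% model@qualities[["match"]]
    if (is.null(v)) v <- unlist(model@qualities)
    v[sample.int(length(v), n, replace = TRUE)]
  }
  phreds <- integer(0)
  for (i in seq_len(nrow(log))) {
    type <- log$type[i]
    if (type == "deletion") next
    phreds <- c(phreds, draw(type, log$length[i]))
  }
  intToUtf8(pmin(phreds, 93L) + 33L)
}
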