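#' @importFrom utils read.table write.table
NULL

SUBALN_COLS <- c("read_id", "read_length", "query_start", "query_end",
                 "ref_species", "ref_seq", "ref_start", "ref_end", "strand",
                 "aligned_bases", "mapq", "is_primary", "is_secondary",
                 "cigar")

# split a CIGAR string into (lengths, ops)
cigar_ops <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) stop("empty CIGAR string")
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)
  if (m[[1]][1] == -1 || sum(attr(m[[1]], "match.length")) != nchar(cigar))
    stop("malformed CIGAR string: ", cigar)
  tok <- regmatches(cigar, m)[[1]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", tok)),
       op = sub("^\\d+", "", tok))
}

cigar_ref_span <- function(ops) sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
cigar_query_aln_span <- function(ops) sum(ops$len[ops$op %in% c("M", "I", "=", "X")])
cigar_aligned_bases <- function(ops) sum(ops$len[ops$op %in% c("M", "=", "X")])

# full read length including soft and hard clips
cigar_read_length <- function(ops) {
  sum(ops$len[ops$op %in% c("M", "I", "S", "H", "=", "X")])
}

cigar_left_clip <- function(ops) {
  n <- length(ops$op)
  i <- 1L
  clip <- 0L
  while (i <= n && ops$op[i] %in% c("S", "H")) {
    clip <- clip + ops$len[i]
    i <- i + 1L
  }
  clip
}

cigar_right_clip <- function(ops) {
  cigar_left_clip(list(len = rev(ops$len), op = rev(ops$op)))
}

empty_subalignments <- function() {
  df <- data.frame(read_id = character(), read_length = numeric(),
                   query_start = numeric(), query_end = numeric(),
                   ref_species = character(), ref_seq = character(),
                   ref_start = numeric(), ref_end = numeric(),
                   strand = character(), aligned_bases = numeric(),
                   mapq = numeric(), is_primary = logical(),
                   is_secondary = logical(), cigar = character(),
                   stringsAsFactors = FALSE)
  df
}

validate_subalignments <- function(df) {
  missing <- setdiff(SUBALN_COLS, names(df))
  if (length(missing))
    stop("subalignment table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(df)) {
    if (any(df$query_start >= df$query_end))
      stop("query_start must be < query_end")
    if (any(df$ref_start >= df$ref_end))
      stop("ref_start must be < ref_end")
    if (any(df$aligned_bases > df$query_end - df$query_start))
      stop("aligned_bases must not exceed the query span")
    if (any(df$mapq < 0)) stop("mapq must be >= 0")
    if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  df
}

resolve_species <- function(ref_seq, species_map = NULL, species_sep = "|") {
  if (!is.null(species_map)) {
    if (is.character(species_map) && length(species_map) == 1 &&
        file.exists(species_map)) {
      tab <- read.table(species_map, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE)
      species_map <- stats::setNames(tab[[2]], tab[[1]])
    }
    unknown <- setdiff(unique(ref_seq), names(species_map))
    if (length(unknown))
      stop("reference sequence id(s) not in species map: ",
           paste(unknown, collapse = ", "))
    return(unname(species_map[ref_seq]))
  }
  vapply(strsplit(ref_seq, species_sep, fixed = TRUE), `[`, "", 1L)
}

#' Parse read-to-reference alignments into per-read subalignment tables
#'
#' Reads a PAF file (12 mandatory columns plus optional tags, as written by
#' minimap2) or a SAM file and converts every alignment record -- primary,
#' supplementary and secondary -- into one subalignment row. All
#' coordinates are 0-based half-open; query coordinates are reported on the
#' original read orientation for both strands (PAF convention; SAM
#' reverse-strand records are flipped at the boundary). Records are grouped
#' by read id.
#'
#' The species of each reference contig is taken from `species_map`
#' (a named vector `contig id -> species`, or a path to a two-column TSV);
#' without a map, the first token of the contig id before `species_sep` is
#' used.
#'
#' @param path Path to the alignment file.
#' @param format "paf", "sam", or "auto" (by file extension).
#' @param species_map Optional contig-to-species map (named character or TSV
#'   path). Unknown contig ids raise an error listing the ids.
#' @param species_sep Delimiter used to derive species from contig ids when
#'   no map is given (default `"|"`).
#' @return Named list, one element per read id, each a data.frame with one
#'   row per subalignment and columns `read_id, read_length, query_start,
#'   query_end, ref_species, ref_seq, ref_start, ref_end, strand,
#'   aligned_bases, mapq, is_primary, is_secondary, cigar`.
#' @export
parseAlignments <- function(path, format = c("auto", "paf", "sam"),
                            species_map = NULL, species_sep = "|") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sam", "bam")) "sam" else "paf"
  }
  df <- switch(format,
               paf = parse_paf(path, species_map, species_sep),
               sam = parse_sam(path, species_map, species_sep))
  validate_subalignments(df)
  if (!nrow(df)) return(structure(list(), names = character()))
  split(df, factor(df$read_id, levels = unique(df$read_id)))
}

parse_paf <- function(path, species_map, species_sep) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_subalignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 12))
    stop("malformed PAF line ", which(nfield < 12)[1],
         ": fewer than 12 columns")
  get <- function(i) vapply(fields, `[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(get(i)))
    if (anyNA(v))
      stop("malformed PAF line ", which(is.na(v))[1],
           ": non-numeric ", what)
    v
  }
  strand <- get(5)
  if (!all(strand %in% c("+", "-")))
    stop("malformed PAF line ", which(!strand %in% c("+", "-"))[1],
         ": bad strand")
  tags <- lapply(fields, function(f) if (length(f) > 12) f[13:length(f)] else character())
  tag_val <- function(tg, prefix) {
    hit <- tg[startsWith(tg, prefix)]
    if (length(hit)) substring(hit[1], nchar(prefix) + 1) else NA_character_
  }
  tp <- vapply(tags, tag_val, "", "tp:A:")
  cg <- vapply(tags, tag_val, "", "cg:Z:")
  aligned <- num(10, "residue matches")
  # with a cg tag, aligned bases are the exact match+mismatch columns
  has_cg <- !is.na(cg)
  if (any(has_cg))
    aligned[has_cg] <- vapply(cg[has_cg],
                              function(x) cigar_aligned_bases(cigar_ops(x)),
                              numeric(1))
  ref_seq <- get(6)
  df <- data.frame(
    read_id = get(1),
    read_length = num(2, "query length"),
    query_start = num(3, "query start"),
    query_end = num(4, "query end"),
    ref_species = resolve_species(ref_seq, species_map, species_sep),
    ref_seq = ref_seq,
    ref_start = num(8, "target start"),
    ref_end = num(9, "target end"),
    strand = strand,
    aligned_bases = aligned,
    mapq = num(12, "mapq"),
    is_primary = is.na(tp) | tp == "P",
    is_secondary = !is.na(tp) & tp == "S",
    cigar = cg,
    stringsAsFactors = FALSE)
  df
}

parse_sam <- function(path, species_map, species_sep) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  dest <- tempfile(fileext = ".bam")
  bam <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(rec$qname)
  if (!n) return(empty_subalignments())
  ops <- lapply(rec$cigar, cigar_ops)
  read_len <- vapply(ops, cigar_read_length, numeric(1))
  lclip <- vapply(ops, cigar_left_clip, integer(1))
  qspan <- vapply(ops, cigar_query_aln_span, numeric(1))
  rspan <- vapply(ops, cigar_ref_span, numeric(1))
  qs <- lclip
  qe <- lclip + qspan
  minus <- as.character(rec$strand) == "-"
  # SAM stores reverse-strand alignments on the reverse-complemented read;
  # report query coordinates on the original read orientation
  qs2 <- ifelse(minus, read_len - qe, qs)
  qe2 <- ifelse(minus, read_len - qs, qe)
  ref_seq <- as.character(rec$rname)
  flag <- rec$flag
  df <- data.frame(
    read_id = rec$qname,
    read_length = read_len,
    query_start = qs2,
    query_end = qe2,
    ref_species = resolve_species(ref_seq, species_map, species_sep),
    ref_seq = ref_seq,
    ref_start = rec$pos - 1,
    ref_end = rec$pos - 1 + rspan,
    strand = ifelse(minus, "-", "+"),
    aligned_bases = vapply(ops, cigar_aligned_bases, numeric(1)),
    mapq = as.numeric(rec$mapq),
    is_primary = bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L,
    is_secondary = bitwAnd(flag, 256L) != 0L,
    cigar = rec$cigar,
    stringsAsFactors = FALSE)
  df
}

#' Write subalignments as PAF
#'
#' Inverse of [parseAlignments()] for the PAF path: writes one PAF line per
#' subalignment with `tp:A:` and (when present) `cg:Z:` tags, so that
#' parse -> write -> parse round-trips preserve every field.
#'
#' @param alignments A subalignment data.frame or a list of them (as
#'   returned by [parseAlignments()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeAlignmentsPAF <- function(alignments, path) {
  if (is.list(alignments) && !is.data.frame(alignments))
    alignments <- do.call(rbind, alignments)
  validate_subalignments(alignments)
  tp <- ifelse(alignments$is_secondary, "tp:A:S", "tp:A:P")
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%s",
                   alignments$read_id, as.integer(alignments$read_length),
                   as.integer(alignments$query_start),
                   as.integer(alignments$query_end),
                   alignments$strand, alignments$ref_seq,
                   0L, # target length not tracked; placeholder column
                   as.integer(alignments$ref_start),
                   as.integer(alignments$ref_end),
                   as.integer(alignments$aligned_bases),
                   as.integer(pmax(alignments$ref_end - alignments$ref_start,
                                   alignments$query_end - alignments$query_start)),
                   as.integer(alignments$mapq), tp)
  has_cg <- !is.na(alignments$cigar) & nzchar(alignments$cigar)
  lines[has_cg] <- paste0(lines[has_cg], "\tcg:Z:", alignments$cigar[has_cg])
  writeLines(lines, path)
  invisible(path)
}
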