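# shared fixtures and independent oracles for the test suite

# quick constructor for subalignment tables
subaln <- function(read_id = "r1", read_length = 1000, qs, qe,
                   species = "A", contig = paste0(species, "|c"),
                   rs = 0, re = qe - qs, strand = "+",
                   aligned = qe - qs, mapq = 60, primary = TRUE,
                   secondary = FALSE, cigar = NA_character_) {
  data.frame(read_id = read_id, read_length = read_length,
             query_start = qs, query_end = qe, ref_species = species,
             ref_seq = contig, ref_start = rs, ref_end = re,
             strand = strand, aligned_bases = aligned, mapq = mapq,
             is_primary = primary, is_secondary = secondary,
             cigar = cigar, stringsAsFactors = FALSE)
}

# independent pairwise-compatibility predicate (plain arithmetic)
oracle_compat <- function(df, i, j, slack = 0) {
  qov <- max(0, min(df$query_end[i], df$query_end[j]) -
               max(df$query_start[i], df$query_start[j]))
  if (qov > slack) return(FALSE)
  if (df$ref_seq[i] != df$ref_seq[j]) return(TRUE)
  rov <- max(0, min(df$ref_end[i], df$ref_end[j]) -
               max(df$ref_start[i], df$ref_start[j]))
  rov <= slack
}

# brute-force maximum compatible-set total over all subsets (n <= ~12)
oracle_best_total <- function(df, slack = 0) {
  n <- nrow(df)
  best <- 0
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) != 0)
    ok <- TRUE
    if (length(idx) > 1) {
      for (a in seq_along(idx)[-1]) {
        for (b in seq_len(a - 1)) {
          if (!oracle_compat(df, idx[a], idx[b], slack)) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) best <- max(best, sum(df$aligned_bases[idx]))
  }
  best
}

# random compatibility instance for property tests
random_instance <- function(n, read_len = 1000, contigs = c("c1", "c2", "c3")) {
  qs <- sample.int(read_len - 100, n)
  qe <- pmin(read_len, qs + sample(30:300, n, replace = TRUE))
  ctg <- sample(contigs, n, replace = TRUE)
  rs <- sample.int(5000, n)
  subaln(read_id = "rx", read_length = read_len, qs = qs, qe = qe,
         species = ctg, contig = ctg, rs = rs, re = rs + (qe - qs),
         aligned = qe - qs, mapq = sample(0:60, n, replace = TRUE))
}

# independent EM fixed-point iterator (matrix formulation, run to machine
# precision)
oracle_em_fixed_point <- function(unique, multi, tol = 1e-14,
                                  max_iter = 100000) {
  species <- sort(base::unique(c(names(unique),
                                 unlist(lapply(multi, `[[`, "candidates")))))
  u <- setNames(numeric(length(species)), species)
  u[names(unique)] <- unique
  memb <- vapply(multi, function(m) species %in% m$candidates,
                 logical(length(species)))
  memb <- matrix(memb, nrow = length(species))
  bases <- vapply(multi, `[[`, numeric(1), "bases")
  p <- u / sum(u)
  for (i in seq_len(max_iter)) {
    denom <- as.numeric(t(memb) %*% p)
    frac <- memb * rep(p, times = length(bases)) /
      rep(pmax(denom, .Machine$double.xmin), each = length(species))
    counts <- u + as.numeric(frac %*% bases)
    p2 <- counts / sum(counts)
    if (max(abs(p2 - p)) < tol) return(p2)
    p <- p2
  }
  p
}

# ten-species logarithmically spaced community profile (octave spacing)
log_profile <- function(n = 10, ratio = 2) {
  w <- ratio^-(seq_len(n) - 1)
  abundanceProfile(setNames(w, sprintf("sp%02d", seq_len(n))))
}

# tiny genome set with one circular species
toy_genomes <- function(circ_len = 1000, lin_len = 1000) {
  set.seed(99)
  seqs <- c(circA = paste(sample(c("A", "C", "G", "T"), circ_len, TRUE),
                          collapse = ""),
            linB = paste(sample(c("A", "C", "G", "T"), lin_len, TRUE),
                         collapse = ""))
  genomeSet(seqs, setNames(c("A", "B"), c("circA", "linB")),
            c(A = "circular", B = "linear"))
}
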