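# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# overlap length of two half-open intervals [s1,e1) and [s2,e2)
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# deterministic 31-bit seed derived from a master seed and a string label,
# so each sample's reads are reproducible independently of batch composition
derive_seed <- function(master, label) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

BASES <- c("A", "C", "G", "T")

# row i: the three alternatives to BASES[i], for substitution draws
ALT_BASES <- t(vapply(BASES, function(b) setdiff(BASES, b), character(3)))

random_dna <- function(n, composition = NULL) {
  if (n <= 0) return("")
  if (is.null(composition))
    composition <- stats::setNames(rep(0.25, 4), BASES)
  paste(sample(BASES, n, replace = TRUE, prob = composition[BASES]),
        collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# weighted sampling of one name; tolerates zero-sum by erroring
sample_one <- function(names, prob) {
  if (length(names) == 1) return(names)
  names[sample.int(length(names), 1, prob = prob)]
}

stop_na <- function(x, what) {
  if (any(is.na(x))) stop("missing/NA values in ", what)
  x
}
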