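err_aln <- function(cigar, read_id = "r1") {
  subaln(read_id = read_id, qs = 0, qe = 30, cigar = cigar)
}

test_that("CIGAR walks decompose into event runs with correct transitions", {
  m <- fitErrorModel(err_aln("10=1X5=1I4="), alpha = 0)
  expect_equal(sort(m@runLengths$match), c(4L, 5L, 10L))
  expect_equal(m@runLengths$mismatch, 1L)
  expect_equal(m@runLengths$insertion, 1L)
  tr <- m@transitions
  expect_equal(tr["match", "mismatch"], 0.5)
  expect_equal(tr["match", "insertion"], 0.5)
  expect_equal(tr["mismatch", "match"], 1)
  expect_equal(unname(diag(tr)), rep(0, 4))
  expect_error(fitErrorModel(err_aln("30M")), "=/X")
  expect_error(fitErrorModel(subaln(qs = 0, qe = 10)), "CIGAR")
})

test_that("perfect alignments produce a zero-error model and identity mutation", {
  m <- fitErrorModel(rbind(err_aln("30="), err_aln("25=", "r2")))
  expect_equal(errorRates(m), c(mismatch = 0, insertion = 0, deletion = 0))
  out <- introduceErrors("ACGTACGTAC", m)
  expect_equal(out$sequence, "ACGTACGTAC")
  expect_equal(out$log$type, "match")
})

test_that("planted error rates are recovered by mutation and refitting", {
  model <- errorModelFromRates(mismatch = 0.05, insertion = 0.03,
                               deletion = 0.04)
  rates <- errorRates(model)
  expect_lt(abs(rates[["mismatch"]] - 0.05), 0.003)
  expect_lt(abs(rates[["insertion"]] - 0.03), 0.003)
  expect_lt(abs(rates[["deletion"]] - 0.04), 0.003)
  set.seed(71)
  template <- paste(sample(c("A", "C", "G", "T"), 3e5, TRUE), collapse = "")
  mut <- introduceErrors(template, model)
  # realized per-base rates from the event log
  tally <- tapply(mut$log$length, mut$log$type, sum)
  consumed <- sum(tally[c("match", "mismatch", "deletion")], na.rm = TRUE)
  expect_equal(consumed, nchar(template))
  expect_lt(abs(tally[["mismatch"]] / consumed - 0.05), 0.003)
  expect_lt(abs(tally[["insertion"]] / consumed - 0.03), 0.003)
  expect_lt(abs(tally[["deletion"]] / consumed - 0.04), 0.003)
  # double fit: refitting on the realized runs reproduces the rates
  runs <- mut$log
  cig <- paste0(runs$length,
                c(match = "=", mismatch = "X", insertion = "I",
                  deletion = "D")[runs$type], collapse = "")
  refit <- fitErrorModel(subaln(qs = 0, qe = nchar(mut$sequence),
                                read_length = nchar(mut$sequence),
                                aligned = 1, cigar = cig))
  rr <- errorRates(refit)
  expect_lt(abs(rr[["mismatch"]] - 0.05), 0.005)
  expect_lt(abs(rr[["insertion"]] - 0.03), 0.005)
  expect_lt(abs(rr[["deletion"]] - 0.04), 0.005)
})

test_that("event logs replay exactly and forced logs apply single events", {
  # forced single deletion: AAAA -> AAA
  log <- data.frame(type = c("match", "deletion", "match"),
                    template_pos = c(0L, 1L, 2L), length = c(1L, 1L, 2L),
                    bases = NA_character_)
  expect_equal(replayEventLog("AAAA", log), "AAA")
  model <- errorModelFromRates()
  set.seed(72)
  for (i in 1:10) {
    template <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                      collapse = "")
    mut <- introduceErrors(template, model)
    expect_identical(replayEventLog(template, mut$log), mut$sequence)
  }
})

test_that("quality simulation follows per-event distributions", {
  q_model <- errorModelFromRates(
    qualities = list(match = rep(20L, 10), mismatch = rep(6L, 10),
                     insertion = rep(8L, 10)))
  no_q <- errorModelFromRates()
  set.seed(73)
  template <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  mut <- introduceErrors(template, q_model)
  expect_error(assignQualities(mut$log, no_q), "FASTA")
  q <- assignQualities(mut$log, q_model)
  expect_equal(nchar(q), nchar(mut$sequence))
  phred <- utf8ToInt(q) - 33L
  # degenerate per-event histograms: all-match runs are uniformly Q20 and
  # mismatch bases are strictly lower quality than match bases
  expect_true(all(phred %in% c(20L, 6L, 8L)))
  is_match <- rep(mut$log$type, mut$log$length)[
    rep(mut$log$type, mut$log$length) != "deletion"]
  expect_lt(mean(phred[is_match == "mismatch"]),
            mean(phred[is_match == "match"]))
})
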