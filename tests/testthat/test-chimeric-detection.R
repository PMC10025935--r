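test_that("pairwise compatibility honours query slack and reference overlap", {
  a <- subaln(qs = 0, qe = 500, species = "A", contig = "cA")
  b <- subaln(qs = 500, qe = 900, species = "B", contig = "cB")
  expect_true(compatibleAlignments(a, b, slack = 0))
  b2 <- subaln(qs = 450, qe = 900, species = "B", contig = "cB")
  expect_false(compatibleAlignments(a, b2, slack = 0))
  expect_true(compatibleAlignments(a, b2, slack = 50))
  # same contig, disjoint query but overlapping reference
  a3 <- subaln(qs = 0, qe = 400, contig = "cA", rs = 100, re = 600)
  b3 <- subaln(qs = 500, qe = 900, contig = "cA", rs = 300, re = 800)
  expect_false(compatibleAlignments(a3, b3, slack = 0))
})

test_that("best compatible set maximizes total aligned length", {
  one <- subaln(qs = 100, qe = 600)
  cs <- bestCompatibleSet(one, min_segment = 1)
  expect_false(isChimeric(cs))
  expect_equal(totalAligned(cs), 500)
  # A 0..100, B 90..200, C 120..250 on distinct contigs: optimum is {A, C}
  df <- subaln(qs = c(0, 90, 120), qe = c(100, 200, 250),
               species = c("A", "B", "C"),
               contig = c("cA", "cB", "cC"), rs = 0,
               re = c(100, 110, 130), read_length = 250)
  cs <- bestCompatibleSet(df, slack = 0, min_segment = 1)
  expect_equal(totalAligned(cs), 230)
  expect_equal(segmentTable(cs)$ref_species, c("A", "C"))
  expect_true(isChimeric(cs))
  expect_error(bestCompatibleSet(df[0, ]), "no subalignments")
})

test_that("exact search equals the brute-force subset optimum", {
  set.seed(2024)
  for (trial in 1:200) {
    df <- random_instance(8)
    cs <- bestCompatibleSet(df, slack = 0, min_segment = 1)
    expect_equal(totalAligned(cs), oracle_best_total(df, slack = 0))
  }
})

test_that("circular-origin bridges merge and drop the chimeric flag", {
  gs <- toy_genomes(circ_len = 1000)
  # seg1 query 0..300 -> ref 700..1000 (+), seg2 query 300..500 -> ref 0..200
  df <- subaln(qs = c(0, 300), qe = c(300, 500), species = "A",
               contig = "circA", rs = c(700, 0), re = c(1000, 200),
               read_length = 500)
  cs <- bestCompatibleSet(df, min_segment = 1)
  expect_true(isChimeric(cs))
  merged <- mergeCircularBridge(cs, gs)
  expect_false(isChimeric(merged))
  expect_equal(nrow(segmentTable(merged)), 1)
  expect_true(segmentTable(merged)$wrapped)
  expect_equal(totalAligned(merged), totalAligned(cs))
  # the same intervals on a linear contig stay split
  df_lin <- df
  df_lin$ref_seq <- "linB"
  df_lin$ref_species <- "B"
  cs_lin <- mergeCircularBridge(bestCompatibleSet(df_lin, min_segment = 1), gs)
  expect_true(isChimeric(cs_lin))
  expect_equal(nrow(segmentTable(cs_lin)), 2)
  # three-way: a wrap followed by a genuine chimera stays chimeric with 2 segments
  df3 <- rbind(df, subaln(qs = 520, qe = 800, species = "B", contig = "linB",
                          rs = 100, re = 380, read_length = 800))
  df3$read_length <- 800
  cs3 <- mergeCircularBridge(bestCompatibleSet(df3, min_segment = 1), gs)
  expect_equal(nrow(segmentTable(cs3)), 2)
  expect_true(isChimeric(cs3))
  expect_equal(sum(segmentTable(cs3)$wrapped), 1)
})

test_that("minus-strand bridges merge with mirrored orientation", {
  gs <- toy_genomes(circ_len = 1000)
  # read moves backwards along the reference: first segment near origin
  df <- subaln(qs = c(0, 300), qe = c(300, 500), species = "A",
               contig = "circA", rs = c(0, 800), re = c(300, 1000),
               strand = "-", read_length = 500)
  merged <- mergeCircularBridge(bestCompatibleSet(df, min_segment = 1), gs)
  expect_false(isChimeric(merged))
  expect_true(segmentTable(merged)$wrapped)
})

test_that("chimeric profiling recovers the geometric MLE and fraction", {
  mk <- function(counts) {
    lapply(seq_along(counts), function(i) {
      k <- counts[i]
      qs <- seq(0, by = 600, length.out = k)
      df <- subaln(read_id = paste0("r", i), qs = qs, qe = qs + 500,
                   species = paste0("s", seq_len(k)),
                   contig = paste0("s", seq_len(k), "|c"),
                   rs = 0, re = 500, read_length = max(qs) + 500)
      bestCompatibleSet(df, min_segment = 1)
    })
  }
  prof <- suppressWarnings(profileChimeras(mk(c(1, 1, 1, 2))))
  expect_equal(pGeom(prof), 0.8)
  expect_equal(meanSegments(prof), 1.25)
  expect_equal(chimericFraction(prof), 0.25)
  prof1 <- profileChimeras(mk(c(1, 1, 1)))
  expect_equal(pGeom(prof1), 1)
  expect_equal(chimericFraction(prof1), 0)
  expect_null(prof1@gapModel)
})

test_that("segment-count sampling and the MLE invert each other at scale", {
  set.seed(5)
  k <- sampleSegmentCount(1 / 1.03, 100000)
  expect_lt(abs(mean(k) - 1.03), 0.01)
  expect_lt(abs(geometricMLE(k) - 1 / 1.03), 0.01)
})

test_that("fixture round trip: planted chimeras are recovered and detection shrinks unaligned regions", {
  comm <- makeCommunity(n_species = 5, genome_sizes = 40000, seed = 21)
  fix <- makeAlignmentFixture(comm, n_reads = 1000, p_geom = 0.85, s = 0.9,
                              seed = 22)
  sets <- lapply(fix$alignments, bestCompatibleSet, min_segment = 50)
  cls <- classifyReads(sets)
  expect_equal(cls$n_segments, fix$truth$n_segments)
  prof <- profileChimeras(sets, abundance = comm$profile, min_pairs = 5)
  expect_lt(abs(pGeom(prof) - 0.85), 0.03)
  # merging invariants: never fewer aligned bases, never more segments
  merged <- lapply(sets, mergeCircularBridge, genomes = comm$genomes)
  for (i in seq_along(sets)) {
    expect_gte(totalAligned(merged[[i]]), totalAligned(sets[[i]]))
    expect_lte(nrow(segmentTable(merged[[i]])), nrow(segmentTable(sets[[i]])))
  }
  # detection never lengthens the unaligned region relative to the primary
  for (rid in names(fix$alignments)) {
    alns <- fix$alignments[[rid]]
    prim <- alns[alns$is_primary, ][1, ]
    unaligned_primary <- prim$read_length -
      (prim$query_end - prim$query_start)
    cs <- sets[[rid]]
    unaligned_best <- cs@headUnaligned + cs@tailUnaligned + sum(cs@gaps)
    expect_lte(unaligned_best, unaligned_primary)
  }
})
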