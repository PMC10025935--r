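sim_models <- function(with_error = TRUE, p_geom = 0.85, s = 0.8,
                       seg_mean = 800, read_mean = 1200) {
  set.seed(1234)
  seg_kde <- fitLengthModel(rlnorm(400, log(seg_mean), 0.3))
  gap_kde <- fitLengthModel(pmax(0, round(rlnorm(400, log(40), 0.5))),
                            transform = "log1p")
  chim <- new("ChimericProfile", pGeom = p_geom, chimericFraction = 1 - p_geom,
              nReads = 400L, segmentModel = seg_kde, gapModel = gap_kde,
              shrinkageRate = s, perSpeciesShrinkage = numeric())
  list(chimeric = chim,
       aligned = fitLengthModel(rlnorm(400, log(read_mean), 0.4)),
       align_ratio = new("AlignRatioModel", headFrac = runif(50),
                         unalignedFrac = runif(50, 0, 0.1)),
       error = if (with_error) errorModelFromRates() else NULL)
}

test_that("abundance perturbation rank-matches errors to genome sizes", {
  p <- abundanceProfile(c(a = 0.5, b = 0.3, c = 0.2))
  # identity bounds leave the profile untouched
  set.seed(81)
  expect_equal(abundances(perturbAbundances(p, 0, 0)), abundances(p))
  # degenerate one-value band: uniform inflation renormalizes away
  q <- perturbAbundances(p, 0.1, 0.1, genome_sizes = c(a = 5e6, b = 4e6,
                                                       c = 2e6))
  expect_equal(abundances(q), abundances(p)) # uniform inflation renormalizes
  expect_equal(unname(attr(q, "errors")), rep(0.1, 3))
  # bound check over many draws
  set.seed(82)
  for (i in 1:200) {
    q <- perturbAbundances(p, -0.1, 0.1, genome_sizes = c(a = 5e6, b = 4e6,
                                                          c = 2e6))
    e <- attr(q, "errors")
    expect_true(all(e >= -0.1 & e <= 0.1))
    # larger genomes carry the larger absolute errors
    expect_true(abs(e[["a"]]) >= abs(e[["b"]]) &&
                  abs(e[["b"]]) >= abs(e[["c"]]))
  }
  expect_error(perturbAbundances(p, 0.2, 0.1), "lo must be <= hi")
})

test_that("base allocation is proportional and exhaustive", {
  p <- abundanceProfile(c(A = 0.7, B = 0.3))
  expect_equal(allocateBases(p, 10000), c(A = 7000, B = 3000))
  expect_equal(allocateBases(abundanceProfile(c(A = 1)), 5000), c(A = 5000))
  expect_error(allocateBases(p, 0), "positive")
})

test_that("fragment extraction wraps circular contigs and clamps linear ones", {
  gs <- genomeSet(c(circ = "ACGTT", lin = "ACGTT"),
                  setNames(c("C", "L"), c("circ", "lin")),
                  c(C = "circular", L = "linear"))
  f <- extractFragment(gs, "circ", start = 3, length = 4)
  expect_equal(f$sequence, "TTAC") # rotation past the origin
  expect_true(f$wrapped)
  set.seed(83)
  g <- extractFragment(gs, "lin", start = 3, length = 4)
  expect_false(g$wrapped)
  expect_lte(g$start + 4, 5) # resampled to fit
  expect_equal(g$sequence, substr("ACGTT", g$start + 1, g$start + 4))
  # reverse complement on the minus strand
  expect_equal(extractFragment(gs, "circ", 0, 5, strand = "-")$sequence,
               "AACGT")
  expect_error(extractFragment(gs, "lin", 0, 6), "exceeds contig length")
})

test_that("single reads carry consistent ground truth and honour the species chain", {
  comm <- makeCommunity(n_species = 3, genome_sizes = 20000, seed = 84)
  models <- sim_models()
  set.seed(85)
  rd <- simulateRead(models, comm$genomes, comm$profile,
                     first_species = "sp2")
  expect_equal(rd$segments$species[1], "sp2")
  # length identity: segments + gaps + head + tail = pre-error length
  pre_len <- sum(rd$segments$length) + sum(rd$gaps) + rd$head_junk +
    rd$tail_junk
  expect_equal(nchar(rd$template %||% rd$sequence), pre_len)
  # ground-truth replay: re-extracting each segment reproduces the
  # pre-error read exactly
  offset <- rd$head_junk
  for (i in seq_len(nrow(rd$segments))) {
    seg <- rd$segments[i, ]
    frag <- extractFragment(comm$genomes, seg$seq_id, seg$ref_start,
                            seg$length, seg$strand)
    expect_equal(substr(rd$template, offset + 1, offset + seg$length),
                 frag$sequence)
    offset <- offset + seg$length +
      if (i < nrow(rd$segments)) rd$gaps[i] else 0
  }
  # error log replays onto the emitted sequence
  expect_identical(replayEventLog(rd$template, rd$error_log), rd$sequence)
})

test_that("chimeric segment species are i.i.d. from the profile at s = 1", {
  comm <- makeCommunity(n_species = 3, genome_sizes = 20000,
                        abundance = c(sp1 = .5, sp2 = .3, sp3 = .2),
                        seed = 86)
  models <- sim_models(with_error = FALSE, p_geom = 0.4)
  set.seed(87)
  species <- character()
  for (i in 1:3000) {
    rd <- simulateRead(models, comm$genomes, comm$profile, s = 1,
                       emit_sequence = FALSE)
    if (nrow(rd$segments) >= 2) species <- c(species, rd$segments$species)
  }
  tab <- table(factor(species, levels = c("sp1", "sp2", "sp3")))
  expect_gt(chisq.test(tab, p = abundances(comm$profile))$p.value, 1e-4)
})

test_that("wrapped segments only ever come from circular species", {
  comm <- makeCommunity(n_species = 3, genome_sizes = 3000,
                        topology = c("circular", "linear", "circular"),
                        seed = 88)
  models <- sim_models(with_error = FALSE, seg_mean = 500, read_mean = 800)
  set.seed(89)
  wrapped_sp <- character()
  for (i in 1:500) {
    rd <- simulateRead(models, comm$genomes, comm$profile,
                       emit_sequence = FALSE)
    w <- rd$segments$species[rd$segments$wrapped]
    wrapped_sp <- c(wrapped_sp, w)
  }
  expect_gt(length(wrapped_sp), 0)
  expect_true(all(topologyOf(comm$genomes, wrapped_sp) == "circular"))
})

test_that("multi-sample simulation is reproducible and tracks the profile", {
  comm <- makeCommunity(n_species = 4, genome_sizes = 15000,
                        abundance = c(sp1 = .4, sp2 = .3, sp3 = .2,
                                      sp4 = .1), seed = 90)
  models <- sim_models(seg_mean = 500, read_mean = 700)
  run <- function() simulateMetagenome(
    comm$genomes, list(s1 = comm$profile, s2 = comm$profile), models,
    n_reads = 60, seed = 2024)
  r1 <- run()
  r2 <- run()
  expect_identical(r1$s1$truth, r2$s1$truth)
  expect_identical(vapply(r1$s2$reads, `[[`, "", "sequence"),
                   vapply(r2$s2$reads, `[[`, "", "sequence"))
  # per-sample seeds: dropping a sample leaves the other untouched
  solo <- simulateMetagenome(comm$genomes, list(s2 = comm$profile), models,
                             n_reads = 60, seed = 2024)
  expect_identical(solo$s2$truth, r1$s2$truth)
  # deviation bounds surface in the report before normalization
  r3 <- simulateMetagenome(comm$genomes, list(s1 = comm$profile), models,
                           n_reads = 40, deviation = c(-0.1, 0.1),
                           seed = 7)$s1
  expect_true(all(r3$report$raw_error >= -0.1 & r3$report$raw_error <= 0.1))
  # files: FASTA + truth + abundance report
  prefix <- tempfile("simout")
  r4 <- simulateMetagenome(comm$genomes, list(sA = comm$profile), models,
                           n_reads = 20, seed = 3,
                           output_prefix = prefix)
  expect_true(file.exists(paste0(prefix, "_sA.fasta")))
  expect_true(file.exists(paste0(prefix, "_sA_truth.tsv")))
  expect_true(file.exists(paste0(prefix, "_sA_abundance_report.tsv")))
  truth <- read.table(paste0(prefix, "_sA_truth.tsv"), header = TRUE,
                      sep = "\t")
  expect_equal(nrow(truth),
               sum(vapply(r4$sA$reads, function(r) nrow(r$segments), 1L)))
})

test_that("realized base fractions track the target profile", {
  comm <- makeCommunity(
    n_species = 7, genome_sizes = 20000, seed = 91,
    abundance = setNames(2^-(0:6), paste0("sp", 1:7)))
  models <- sim_models(with_error = FALSE, seg_mean = 600, read_mean = 900)
  sim <- simulateMetagenome(comm$genomes, comm$profile, models,
                            n_reads = 20000, seed = 10,
                            emit_sequences = FALSE)[[1]]
  rep_ <- sim$report
  expect_true(all(abs(rep_$realized - rep_$target) < 0.005))
})
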