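test_that("tallies route segment bases to species and hold back multialigned segments", {
  alns <- list(r1 = rbind(
    subaln(qs = 0, qe = 500, species = "A", contig = "A|c"),
    subaln(qs = 550, qe = 850, species = "B", contig = "B|c", rs = 100,
           re = 400, aligned = 300, primary = FALSE)))
  sets <- list(r1 = bestCompatibleSet(alns$r1, min_segment = 1))
  t <- tallyAlignments(sets, alns, level = "base", chimera_aware = TRUE)
  expect_equal(t$unique, c(A = 500, B = 300))
  expect_length(t$multi, 0)
  # equal-score hits to two species become one multialigned segment
  alns2 <- list(r2 = rbind(
    subaln(read_id = "r2", qs = 0, qe = 400, species = "A", contig = "A|c"),
    subaln(read_id = "r2", qs = 0, qe = 400, species = "B", contig = "B|c",
           primary = FALSE, secondary = TRUE)))
  sets2 <- list(r2 = bestCompatibleSet(alns2$r2, min_segment = 1))
  t2 <- tallyAlignments(sets2, alns2, level = "base", chimera_aware = TRUE)
  expect_length(t2$unique, 0)
  expect_equal(t2$multi[[1]]$bases, 400)
  expect_equal(t2$multi[[1]]$candidates, c("A", "B"))
  # read level without chimera awareness counts the primary read once
  t3 <- tallyAlignments(NULL, alns, level = "read", chimera_aware = FALSE)
  expect_equal(t3$unique, c(A = 1))
})

test_that("EM reproduces hand-iterated results and the fixed-point oracle", {
  # no multialignments: normalized unique counts, zero iterations
  r0 <- emAbundance(c(A = 600, B = 400))
  expect_equal(abundances(r0), c(A = 0.6, B = 0.4))
  expect_equal(attr(r0, "iterations"), 0L)
  # fixed point reached in one step: E assigns 90/10, M restores 0.9/0.1
  r1 <- emAbundance(c(A = 900, B = 100),
                    list(list(bases = 100, candidates = c("A", "B"))))
  expect_equal(abundances(r1), c(A = 0.9, B = 0.1), tolerance = 1e-12)
  # three species, two overlapping multialigned segments
  unique <- c(A = 500, B = 300, C = 200)
  multi <- list(list(bases = 100, candidates = c("A", "B")),
                list(bases = 100, candidates = c("B", "C")))
  one_step <- emAbundance(unique, multi, rel_tol = Inf) # stops after 1 E/M
  expect_equal(abundances(one_step), c(A = 0.46875, B = 0.33125, C = 0.2),
               tolerance = 1e-12)
  converged <- emAbundance(unique, multi, rel_tol = 1e-12)
  oracle <- oracle_em_fixed_point(unique, multi)
  expect_equal(abundances(converged), oracle, tolerance = 1e-9)
  expect_error(emAbundance(c(A = 0)), "uniquely aligned")
})

test_that("EM invariants: sum-to-one, fixed point, candidate symmetry", {
  set.seed(41)
  for (trial in 1:10) {
    sp <- paste0("s", 1:5)
    unique <- setNames(sample(100:1000, 5), sp)
    multi <- lapply(1:6, function(i)
      list(bases = sample(50:200, 1), candidates = sort(sample(sp, 2))))
    out <- emAbundance(unique, multi, rel_tol = 0.01)
    p <- abundances(out)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
    # applying one more E/M step moves nothing beyond the tolerance
    assigned <- setNames(numeric(5), sp)
    for (m in multi) {
      w <- p[m$candidates] / sum(p[m$candidates])
      assigned[m$candidates] <- assigned[m$candidates] + m$bases * w
    }
    p2 <- (unique + assigned) / sum(unique + assigned)
    expect_lt(max(abs(p2 - p)), 0.01 * min(p[p > 0]) + 1e-12)
  }
  # symmetric evidence yields identical abundances
  out <- emAbundance(c(A = 400, B = 400, C = 200),
                     list(list(bases = 120, candidates = c("A", "B"))))
  p <- abundances(out)
  expect_equal(p[["A"]], p[["B"]])
})

test_that("EM resolves a rare species sharing a homologous region with a dominant one", {
  # dominant A and rare B (100:1) share a region: most of B's reads are
  # multialigned, so non-EM equal splitting overestimates B far more
  unique <- c(A = 100000, B = 1000)
  multi <- replicate(20, list(bases = 500, candidates = c("A", "B")),
                     simplify = FALSE)
  em <- abundances(emAbundance(unique, multi))
  truth <- c(A = 100 / 101, B = 1 / 101)
  split_equally <- (unique + c(A = 5000, B = 5000)) /
    sum(unique + 10000)
  expect_lt(abs(em[["B"]] - truth[["B"]]),
            abs(split_equally[["B"]] - truth[["B"]]))
})

test_that("estimation modes agree without multialignments and dispatch EM otherwise", {
  comm <- makeCommunity(n_species = 4, genome_sizes = 30000, seed = 51)
  fix <- makeAlignmentFixture(comm, n_reads = 300, p_geom = 0.9, seed = 52)
  base_modes <- c("B", "CB", "EB", "ECB")
  res <- lapply(base_modes, function(m)
    abundances(estimateAbundance(fix$alignments, mode = m)))
  names(res) <- base_modes
  # single-segment reads dominate and there are no multialignments: the
  # chimera-aware and EM variants must agree exactly at base level
  expect_equal(res$EB, res$B, tolerance = 1e-12)
  expect_equal(res$ECB, res$CB, tolerance = 1e-12)
  expect_error(estimateAbundance(fix$alignments, mode = "XX"))
})

test_that("chimera-aware base-level estimation beats primary-only on chimeric data", {
  comm <- makeCommunity(n_species = 4, genome_sizes = 30000,
                        abundance = c(sp1 = .4, sp2 = .3, sp3 = .2,
                                      sp4 = .1), seed = 53)
  fix <- makeAlignmentFixture(comm, n_reads = 2000, p_geom = 0.6, s = 1,
                              seed = 54)
  truth <- abundances(comm$profile)
  err <- function(mode) {
    est <- abundances(estimateAbundance(fix$alignments, mode = mode))
    est <- est[names(truth)]
    est[is.na(est)] <- 0
    sum(abs(est - truth))
  }
  # primary-only drops every non-first segment of chimeric reads
  expect_lt(err("CB"), err("B") + 1e-9)
})

test_that("copy numbers divide abundances by genome size and renormalize", {
  p <- abundanceProfile(c(A = 0.6, B = 0.4))
  cn <- copyNumbers(p, c(A = 6e6, B = 2e6))
  expect_equal(cn, c(A = 1 / 3, B = 2 / 3))
  expect_equal(copyNumbers(p, c(A = 1e6, B = 1e6)), abundances(p))
  expect_equal(copyNumbers(abundanceProfile(c(A = 1)), c(A = 5e6)),
               c(A = 1))
  expect_error(copyNumbers(p, c(A = 6e6)), "missing genome size")
})

test_that("deviation reports percent errors, R-squared and log-scale variants", {
  est <- abundanceProfile(c(A = 0.55, B = 0.45))
  exp_ <- abundanceProfile(c(A = 0.5, B = 0.5))
  rep_ <- deviationReport(est, exp_, log10_stats = FALSE)
  expect_equal(rep_$per_species, c(A = 10, B = -10))
  expect_equal(rep_$summary$sum_abs_percent_error, 20)
  same <- deviationReport(exp_, exp_, log10_stats = FALSE)
  expect_equal(unname(same$per_species), c(0, 0))
  expect_equal(same$summary$r_squared, 1)
  # log-scale statistics are computed on log10 abundances
  e1 <- abundanceProfile(c(A = .9, B = .09, C = .009, D = .001))
  e2 <- abundanceProfile(c(A = .89, B = .1, C = .009, D = .001))
  rep2 <- deviationReport(e2, e1)
  expect_true(rep2$summary$log_r_squared <= 1)
  expect_equal(rep2$summary$log_r_squared,
               cor(log10(abundances(e2)), log10(abundances(e1)))^2)
  # expected zero with positive estimate is flagged infinite and warned
  ez <- abundanceProfile(c(A = 1, B = 0), normalize = FALSE)
  ep <- abundanceProfile(c(A = 0.99, B = 0.01))
  expect_warning(r3 <- deviationReport(ep, ez), "excluded")
  expect_true(is.infinite(r3$per_species[["B"]]))
})
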