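---
title: "Characterizing and simulating nanopore metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing and simulating nanopore metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metanopore)
```

## The problem

Oxford Nanopore (ONT) metagenomic sequencing produces reads with three
properties that break tools designed for short reads: per-base error rates
of several percent, read lengths spanning four orders of magnitude, and a
small but persistent population of *chimeric* (split) reads -- single
sequenced molecules whose best explanation is two or more alignments to
distinct reference regions, produced by library or sequencing artifacts.
`metanopore` does two things about this:

1. **Characterization.** From reads, a reference metagenome and their
   alignments (PAF or SAM), it detects chimeric reads, fits length and
   error models, learns how the source species of consecutive chimeric
   segments depend on one another, and estimates the community's abundance
   profile at base level.
2. **Simulation.** From those models it generates multi-sample synthetic
   metagenomes of linear and circular genomes -- with chimeric artifacts,
   abundance deviation and basecall errors -- with complete per-segment
   ground truth, so downstream tools can be benchmarked against a known
   answer.

## Chimeric read detection

Every alignment record of a read (primary and supplementary; secondary
records are kept only for the multialignment pool) is a *subalignment*.
Two subalignments are *compatible* when their query intervals and, on the
same contig, their reference intervals do not overlap -- up to a `slack`
(default 10 bp), because long-read aligners routinely emit a few
overlapping bases at split boundaries. The read's best explanation is the
compatible set maximizing total aligned length, with mean MAPQ, then fewer
segments, then query order as tie-breakers; a read whose best set has two
or more segments is chimeric.

The search is exact (all subsets) up to 12 subalignments and falls back to
weighted-interval scheduling on query space above that; the cap is a
practical bound on the exponential subset search, and reads with more than
a dozen candidate subalignments are vanishingly rare. The exact branch is
verified in the test suite against a brute-force subset enumeration on
1,000 random instances.

Reads that bridge the origin of a circular replicon look chimeric -- two
subalignments, one ending at the contig's end and one starting at position
0 -- but are a *topological* artifact, not a library artifact. When both
segments lie on the same circular contig and strand within
`end_tolerance` (default 50 bp; alignments rarely reach the exact
terminus) of the junction, they are concatenated into one wrapped segment
and the read is not counted as chimeric.

Two knobs matter in practice:

* `min_segment` (default 100 bp): subalignments with a shorter query span
  never enter the search; shorter supplementary hits are more often
  spurious than genuinely chimeric, and counting them inflates the
  chimeric fraction.
* `slack` (default 10 bp): tolerated pairwise overlap, absorbing aligner
  jitter.

The per-read segment counts follow a geometric distribution on support
{1, 2, ...}: `P(k) = p (1-p)^(k-1)`, with mean `1/p` and chimeric fraction
`1 - p`. `profileChimeras()` fits `p` by maximum likelihood
(`p = N / sum(k)`).

## The source-species model

Within a chimeric read, the source species of consecutive segments are not
independent: a segment is more likely to share its predecessor's species
than the community abundances alone predict. This is modelled as a
first-order Markov chain over species with a single free parameter, the
*shrinkage rate* `s` in (0, 1]: given the previous species A, every other
species i has transition probability `s * p_i`, and A's self-transition
absorbs the freed mass, `1 - s * sum(p[-A])`. At `s = 1` the chain
degenerates to independent draws from the abundance profile. The chain's
stationary distribution is the abundance profile for every `s`, so
simulating chimeras does not distort the community composition.

`learnShrinkage()` estimates `s` from the overlapping (consecutive)
segment pairs of chimeric reads: for each first species A with at least
`min_pairs` (default 20) observations, the observed switch probability is
divided by its value at `s = 1`, and `s` is the unweighted mean of those
per-species ratios. Species with fewer pairs are excluded -- their ratio
estimates are too noisy to average in -- which is why a low-abundance
species can be absent from the per-species table. The estimator is
consistent: the tests recover `s` within 0.02 from 50,000 simulated pairs
at both 0.77 and 0.73, the values we treat as typical for evenly and
logarithmically distributed mock communities. When no species qualifies,
the profiling falls back to `s = 0.75` (midpoint of those two) with a
warning, and the user can override `s` at simulation time -- `s = 1`
expresses the assumption that DNA molecules are homogeneously suspended.

Whether the estimator should see the *expected* or the *estimated*
abundance profile is genuinely open; `characterizeReads()` uses the
estimated profile by default (it is always available and reflects the data
the pairs came from), and accepts an expected profile when one exists.

## Base-level abundance estimation

Because ONT read lengths vary over orders of magnitude, counting reads
biases abundance estimates: a 100 bp read and a 10 kb read are not equal
evidence. `metanopore` therefore counts *aligned bases* per species, in
units of relative genomic DNA weight; dividing by genome size and
renormalizing converts to relative genome copy numbers
(`copyNumbers()`).

With chimeric detection enabled, every segment of the best compatible set
contributes its aligned bases to its species; otherwise only the primary
alignment contributes. A counted segment whose read also has a
near-equivalent alignment to another species -- at least 90% of the
counted segment's aligned bases (`score_equiv`), MAPQ within 10
(`mapq_equiv`), covering at least half of the same query interval -- is a
*multialigned segment*. How close a competing hit must be to count as
"equivalent" is implementation policy (no canonical definition exists);
these defaults separate genuine homology from noisy secondary hits on the
synthetic fixtures, and all three thresholds are exposed as arguments.

Multialigned bases are disambiguated by EM (`emAbundance()`): uniquely
aligned bases seed the profile; the E step assigns each multialigned
segment's bases to its candidates proportionally to current abundances;
the M step renormalizes; iteration stops when the largest change is below
1% (`rel_tol`) of the smallest positive abundance. Species with zero
unique bases and no candidate mass stay at zero -- an E step cannot revive
them; an epsilon floor is deliberately *not* applied by default, because
inventing mass for unobserved species changes the estimand. When every
candidate of a segment has zero abundance, its bases are split equally
(the proportional rule is undefined there).

`estimateAbundance()` exposes the ablation family used to study which
component does what: `B` (base level), `CB` (+ chimeric detection), `EB`
(+ EM), `ECB` (all three, the recommended mode), and the read-level
controls `CR` and `ER`. The fixtures reproduce the known failure mode
read-level and non-EM estimators exhibit: when a rare species shares a
homologous region with a dominant one, equal splitting of multialigned
bases grossly overestimates the rare species, while EM resolves it.

## Length, ratio and error models

Read, segment and gap lengths are modelled by Gaussian kernel density
estimation in log space (lengths span orders of magnitude; gaps use
`log1p` to admit zero). The bandwidth is the Sheather-Jones plug-in,
falling back to Scott's rule `sd * n^(-1/5)` for degenerate samples:
rule-of-thumb bandwidths are calibrated for unimodal data and visibly
over-smooth the multimodal gap- and read-length distributions these data
exhibit (on a bimodal fixture, Scott's rule leaves a sample-vs-training
Kolmogorov-Smirnov distance of about 0.07 where the plug-in leaves 0.01).
Sampling resamples a training point plus Gaussian noise and back-
transforms, so multimodal empirical distributions survive without a
parametric assumption. Draws are
clipped to `[1, 1.1 * training max]` (gaps to `[0, ...]`); the 10%
headroom admits slightly-longer-than-observed reads without letting the
log-space tail generate pathological lengths.

The unaligned portion of a read is described by an empirical joint
distribution of two ratios -- head share of head+tail, and unaligned share
(head + tail + gaps) of the read -- resampled jointly at simulation time;
an untrained model adds no junk and splits evenly. This simple two-ratio
model stands in for the alignment-ratio models of length-aware read
simulators; its exact composition is not canonical.

Basecall errors are a first-order chain over event types (match, mismatch,
insertion, deletion) with *empirical run-length distributions* per type,
fitted by walking `=`/`X` CIGARs; parametric mixture run-length models are
deliberately not used -- the empirical histograms reproduce the realized
rates within 0.3 percentage points in the plant-and-recover tests and make
no distributional commitment. Substituted bases are uniform over the three
alternatives and inserted bases follow the trained base composition,
because CIGAR strings carry no base identities. Every mutation is recorded
in an event log (type, template position, length, emitted bases) that
replays exactly, which is what makes simulated reads usable as ground
truth for error-aware tools. Optional per-event Phred distributions
support FASTQ output.

## Simulation

A sample is simulated by (i) optionally perturbing the target profile
within user deviation bounds -- errors drawn uniformly (the bounded
"relative error" is the only stated constraint; uniform is the minimal
choice), rank-matched by absolute magnitude to genome size so larger
genomes receive larger deviations, then renormalized; (ii) converting the
requested read count to a total *base* budget via the mean of the
aligned-read KDE and allocating it proportionally -- base-budget rather
than read-count allocation is what makes simulated abundance mean DNA
weight, consistent with the estimator; (iii) drawing reads until every
species' budget is exhausted. Each read draws its segment count, species
chain, segment/gap lengths and head/tail junk from the fitted models;
fragments are extracted uniformly over contigs (uniform-coverage
assumption), with contigs chosen within a species proportionally to length
(so plasmids are represented by mass), and circular contigs wrap past the
origin at most once. Segment lengths are drawn independently rather than
partitioned from a total read length; with KDE-modelled segments and gaps
the difference is second-order, and independent draws keep the model
modular.

Every sample's reads come from a seed derived from the master seed and the
sample id, so batches are reproducible read-for-read and adding a sample
never changes another sample's output. Ground truth is emitted per
segment (species, contig, coordinates, strand, wrap flag) in the read ids
and a companion TSV. `emit_sequences = FALSE` produces ground truth only,
which is how the large abundance round-trip experiments below are run.

## What the synthetic data does and does not show

The fixture generator (`makeCommunity()`, `makeAlignmentFixture()`) builds
random genomes with planted homologous blocks, planted chimeric chains
with a known shrinkage rate, planted circular bridges and planted
equal-score multialignments -- every structure the detection and
estimation code paths must handle, with exact known answers and no aligner
in the loop. Random uniform-composition genomes have no repeats, no GC
structure, no phylogenetic relatedness and no aligner noise beyond what is
planted; passing these tests shows the algorithms are implemented
correctly, not that real communities behave this simply. Models retrained
on real alignments are the intended path to realism.

Problem sizes in the test suite were chosen so each statistical check has
comfortable sampling margin at its tolerance: 100,000 draws for the
segment-count mean (tolerance 0.01, sampling SD about 6e-4), 200,000 for
the chimeric fraction (0.2 points, SD about 0.03 points), 50,000 pairs for
shrinkage recovery (0.02, SD well under 0.01 with the octave-spaced
profile), and 100,000 ground-truth reads for the abundance round trip
(0.5 points per species, observed error below 0.02 points). The
ten-species shrinkage-recovery profile is logarithmically spaced at octave
(factor-2) intervals, spanning roughly 2.7 decades: wide enough to be a
genuinely uneven community, while leaving every species enough pairs at
n = 50,000 to clear the `min_pairs` gate.

## Numerical and degenerate-input choices

* EM stopping compares the max per-species change against
  `rel_tol * min(positive abundances)`; taking the literal minimum over
  all species would be zero whenever any species is absent and the loop
  would never terminate.
* Best-set ties break deterministically (mean MAPQ, then fewer segments,
  then query-start order), so results are reproducible across platforms.
  Aligned length is the primary key and quality only a tie-breaker: total
  aligned length is the better-defined of the two criteria, and the
  alternative order is a one-line change.
* A read whose subalignments are all secondary or all below `min_segment`
  falls back to its single best-aligned record rather than disappearing
  from the tallies.
* Constant-length training data yield a near-zero KDE bandwidth and
  reproduce the constant; fewer than two samples refuse to fit.
* Geometric segment counts are truncated at `max_segments = 10` by
  resampling; unbounded geometric tails occasionally produce reads with
  dozens of segments that no model component can honour.

## Known limitations

* Detection cannot distinguish library/sequencing chimeras from real
  structural variants relative to an incomplete reference; both look like
  split alignments. The classification table is the starting point for
  such an analysis, not its conclusion.
* Quantification is reference-based; species absent from the reference
  are invisible.
* Error models are homopolymer-agnostic, and quality simulation is
  conditional on event type only.
* Genome "streaming" is a loader hook (`fetch` argument of
  `loadGenomes()`); the package itself resolves local files only.

## A worked miniature

```{r example, eval = FALSE}
comm <- makeCommunity(n_species = 4, genome_sizes = 50000,
                      topology = c("linear", "circular", "linear", "linear"),
                      seed = 7)
fix <- makeAlignmentFixture(comm, n_reads = 2000, p_geom = 0.9, s = 0.8,
                            bridge_frac = 0.02, seed = 8)
ch <- characterizeReads(fix$alignments, genomes = comm$genomes)
ch$chimeric

models <- list(chimeric = ch$chimeric, aligned = ch$aligned,
               align_ratio = ch$align_ratio,
               error = errorModelFromRates(0.05, 0.03, 0.04))
sim <- simulateMetagenome(comm$genomes, comm$profile, models,
                          n_reads = 1000, seed = 42,
                          output_prefix = tempfile("demo"))
head(sim$sample1$report)
```
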