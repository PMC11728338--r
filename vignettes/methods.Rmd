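---
title: "HiCdci: models, parameters and design choices"
author: "HiCdci authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HiCdci: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

HiCdci analyses condition-paired Hi-C experiments in which a cell state
transition (the motivating system is naive iPSC differentiation to primordial
germ cell-like cells, PGCLCs) may create new chromatin contacts near
transcriptionally activated endogenous retrovirus loci (HML-2/HERV-K). The
package takes binned intra-chromosomal contact matrices per condition and
replicate, and produces: balanced matrices, TAD partitions, differential
chromatin interaction (DCI) regions, replicate-consensus DCIs matched to TAD
boundaries, locus-proximity statistics, and TAD size-distribution
comparisons. This vignette documents the models behind each stage, the
parameters that matter, and the design decisions that were genuinely open.

# ICE balancing

`iceNormalize()` implements iterative correction: each contact entry is
repeatedly divided by the product of its row and column bias estimates until
the per-bin marginal sums (diagonal excluded) have coefficient of variation
at most `tol` (default `1e-5`, at most `maxIter = 200` sweeps). Two
implementation details deserve note:

* **Square-root damping.** The bias update uses `sqrt(marginal / mean)`. The
  undamped update has the same fixed points, but on a strictly
  intra-chromosomal (block-diagonal) matrix it possesses an undamped
  oscillation mode *between* chromosomes: each block balances internally
  while the block means swap around the global mean indefinitely. The damped
  update removes that mode exactly and converges on both single- and
  multi-chromosome inputs.
* **Low-coverage masking.** Bins with zero marginal, or marginal below the
  2nd percentile of nonzero marginals (`maskQuantile = 0.02`), are masked
  before correction: their rows and columns are zeroed and they are excluded
  from the convergence statistic. Diagonal entries are excluded from the
  marginals but still rescaled by the squared bin bias.

The zero pattern is preserved exactly, and an already-balanced matrix is a
fixed point.

# TAD calling

The caller follows the unsupervised-clustering idea of ClusterTAD-style
domain detection: describe every bin by its contact profile, cluster bins,
and read domains off maximal runs of same-cluster bins.

**Features.** For a chromosome with per-diagonal mean contact \(E(d)\), the
observed/expected matrix is \(OE_{ij} = M_{ij} / E(|i-j|)\). The feature
vector of bin \(i\) is `log1p(OE[i, ])` in absolute chromosome coordinates,
zeroed beyond a band of `windowBins` (default 10) bins. Three properties
motivated this definition over alternatives we evaluated:

* Decay correction is essential — raw contact rows are dominated by the
  distance trend, not by domain membership.
* Absolute (not offset-relative) coordinates are essential — features indexed
  by relative offset are translation invariant, so k-means groups bins by
  *phase within* a domain rather than by domain, and every label transition
  sits at a fixed offset from a boundary instead of on it.
* The band suppresses long-range entries that carry no domain signal; with
  full rows, megabase-scale domains on a 30-Mb chromosome are swamped by
  noise dimensions.

Bins masked during balancing inherit the feature row of their nearest
unmasked bin; otherwise the zeroed low-coverage chromosome ends form
spurious two-bin domains at exactly the masked positions.

**Segmentation.** `segmentByClustering()` runs `stats::kmeans` (10 restarts,
fixed seed, 100 iterations) with `k` centers; runs shorter than `minTadBins`
(default 2 bins = 200 kb, the smallest published size class) are merged into
the neighbouring run with the more similar centroid.

**Quality and model selection.** `tadQuality()` scores a partition as the
mean *linear* O/E over intra-domain pairs minus the mean over inter-domain
pairs at separations up to the partition's largest domain. Because every
diagonal of O/E has mean exactly 1, the score is centred at 0 for an
uninformative partition at any separation profile; on `log1p` values the
separation-dependent Jensen offset instead rewards the degenerate
one-domain partition, and on raw counts the decay rewards maximal
over-segmentation — both failure modes we observed and rejected.
`callBestTads()` evaluates `k` in `2:min(40, n/4)` plus a
single-spanning-domain baseline (quality 0) and returns the arg-max, ties
toward fewer clusters. The baseline means a chromosome without domain
structure beyond noise level is returned unsegmented (measured noise
partitions score below 0 on this contrast).

# DCI scoring

`dciProfile()` compares, for every bin \(i\), the two conditions' contact
vectors to bins \(i-w \dots i+w\) with a paired t-like statistic on
`log1p` counts: \(\mathrm{score}(i) = \bar d / (s_d / \sqrt{n})\), where
\(d\) are the paired differences, positions zero in both matrices are
dropped, and the score is 0 for fewer than 3 informative positions. Both
matrices are first rescaled to their common mean total sum, removing
sequencing-depth differences. Swapping the conditions negates every score
exactly.

Two deliberate choices:

* **Raw, depth-matched input.** Marginal-equalizing normalization (ICE)
  forces both conditions onto identical coverage profiles, which *absorbs* a
  localized fold change into the bias vectors almost exactly — after ICE the
  windowed mean difference over a planted window is near zero. Differential
  callers for Hi-C (diffHic, multiHiCcompare) likewise test raw counts with
  depth normalization; the pipeline therefore feeds raw matrices to this
  stage while using ICE-balanced matrices for TAD calling.
* **`windowBins = 5`** (a 500-kb flank at 100-kb resolution). The paired
  statistic over a window of \(n\) positions with \(k\) truly changed
  entries is bounded near \(\sqrt{n k/(n-k)}\); a 1-Mb window dilutes a
  4–5-bin differential window to the verge of the calling threshold, while a
  500-kb window keeps it comfortably above.

`callDciRegions()` turns the profile into regions: maximal runs of at least
`minBins = 2` bins with score beyond `scoreThreshold = 2` (sign by
direction), merging runs separated by a single sub-threshold bin.

# Consensus and boundary matching

`intersectReplicates()` computes the per-base positions covered by regions
in at least `minSupport` replicates (default: all, the strictest reading of
"conserved across replicates") via coverage accumulation, and merges them
into maximal intervals. `matchToTadBoundaries()` keeps consensus regions
whose gap distance to the nearest TAD boundary is within `maxDistance`
(default 100 kb, one bin — the resolution floor for "close overlap") in
*every* replicate of the comparison condition, recording the per-replicate
distances.

# Proximity statistics

`nearestDistance()` uses interval gap distance — 0 for overlapping or
touching intervals, otherwise the separating base pairs — restricted to the
same chromosome; a locus on a chromosome without regions is an error rather
than an infinite distance, since cross-chromosome base-pair distance is
meaningless. Ties resolve to the leftmost region.

`spearmanAssoc()` ranks with average-rank tie handling and refers
\(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) to a t distribution with \(n-2\) df
(two-sided). This t approximation, applied to a coefficient of −0.5953 with
n = 19, yields 0.0072 at four decimals — the package's check against the
published analysis.

`permutationTest()` measures the mean nearest distance of the
(rank-filtered) loci and compares it with `nPerm` (default 2000)
re-placements of either the regions (`mode = "regions"`, the default,
matching a null in which the conserved regions are scattered across the
genome) or the loci (`mode = "loci"`, matching a null of random locus
locations against fixed boundaries). Placement draws a chromosome with
probability proportional to its length and a start uniform over the valid
positions, preserves interval lengths, and permits overlaps. The one-sided
p-value uses the add-one estimator \((1 + \#\{\text{null} \le
\text{obs}\})/(n_{perm}+1)\), which cannot return 0 and matches the
granularity of a 2000-round test. A permuted locus landing on a chromosome
without any counterpart region contributes no distance to that permutation's
mean (under the default two-chromosome genome this has probability about
\(2^{-19}\)). `rankSubsetAnalysis()` reuses one placement stream across rank
subsets, so subset p-values are directly comparable; the placement stream
always covers the full element set, making a filtered run reproducible
independent of the filter.

Expression ranks are quartile ranks of the loci ordered by descending
normalized count (`ceiling(4 * position / n)`); with 19 loci the groups have
sizes 4, 5, 5, 5.

# TAD size statistics

`tadSizesByChrom()` pools domain sizes across replicates within each
condition and applies the two-sided Mann–Whitney U test per chromosome
(normal approximation with tie and continuity correction, i.e.
`wilcox.test(exact = FALSE, correct = TRUE)`); the normal approximation
stays within 0.02 of the exact enumeration p for group sizes of five to
eight, and the exact test is neither needed nor used at the pooled sizes the
pipeline produces. `sizeBinFrequencies()` classifies domains into the
published classes [0.2–1), [1–1.5), [1.5–2), [2–2.5) Mb plus an overflow
class, excludes domains under 200 kb, computes per-condition,
per-chromosome class fractions (replicates pooled), and tests each class
across chromosomes. The per-chromosome fraction was chosen as the sampling
unit because it yields a defined, configurable sample per group; it is the
one place where the published analysis leaves the unit unstated.
`starAnnotation()` maps p-values exactly as the published legend does — the
legend's unmapped interval (1e-5, 1e-4] is annotated `"***+"` and reported,
not silently bridged.

# The synthetic-data generator

`simulationConfig()` fixes the study conditions for all tests: two 30-Mb
chromosomes at 100-kb resolution (300 bins each), expected counts
\(\mu(i,j) = A(1+|i-j|)^{-\alpha}(1+\beta\,[\text{same TAD}])\) with
\(\alpha = 1\), \(A = 500\) (deep-coverage Hi-C puts hundreds of contacts
between adjacent 100-kb bins), \(\beta = 1.5\), Poisson noise, and TAD sizes
uniform on 6–15 bins (0.6–1.5 Mb, the megabase scale of human TADs). TAD
partitions tile each chromosome completely. Condition B scales entries with
both bins inside a planted differential window by the window's fold factor
before sampling; replicates share the planted truth and differ only in
noise. `simulateBundle()` by default anchors the differential windows at
planted TAD boundaries, emulating differential contacts that form new
domain boundaries — the scenario under study.

Expressed loci (default 19, each 9 kb — a full-length HML-2 provirus) come
in two modes. In `"independent"` mode loci are placed uniformly
(chromosome by length, start uniform) with expression drawn independently —
the same placement law the permutation test uses, so a mode-`"loci"`
permutation test on such data is calibrated by exchangeability, exactly. In
`"inverse"` mode each locus sits at a log-uniform gap distance (10 kb to
5 Mb) from a random planted window and its expected expression is
\(S\, d_0/(d+d_0)\) with \(d_0 = 100\) kb (halving the distance roughly
doubles the expression), times lognormal noise with \(\sigma = 0.3\). The
broad log-uniform law matters: it places top-rank loci proximally while
leaving low-rank loci at megabase distances comparable to the null, so the
planted signal is concentrated in the top expression ranks — the qualitative
structure the rank-subset analysis is designed to detect. A narrow distance
law would make *every* subset maximally significant and erase the contrast.

What the generator does **not** emulate: A/B compartments, kb-scale loops,
nested domain hierarchy, sequence-dependent bias (GC, mappability),
inter-chromosomal contacts, and overdispersed (negative binomial) counts.
Tests passing on these simulations therefore demonstrate correctness of the
algorithms under a clean planted-truth model, not performance on real
libraries.

# Problem sizes and determinism

The test suite and the acceptance script run at desk scale, chosen as the
package's own evaluation design: 500 synthetic datasets with 500
permutations for null calibration, 50 datasets with 2000 permutations for
power and rank ordering, 20 simulated 300-bin matrices for boundary
recovery, 10 condition pairs each for differential recovery and null
behaviour, and the default 3-replicate bundle executed twice for bitwise
determinism. Every stochastic step takes an explicit seed; k-means restarts
are seeded, permutation streams derive from the user seed, and the pipeline
manifest records configuration, seeds and MD5 checksums of all inputs and
outputs while deliberately containing no wall-clock fields, so a rerun of
the same configuration is bitwise identical.

# Known limitations

* The TAD caller returns a single flat partition; nested or overlapping
  domain structure is out of scope.
* The DCI statistic is a self-contained windowed paired score; no claim of
  numerical equivalence with any external differential-interaction tool is
  made, and no transcription-factor enrichment step is included.
* Permutation nulls place intervals without a mappability blacklist and
  permit overlaps among placed intervals.
* No multiple-testing correction is applied across rank subsets, matching
  the analysis the package reproduces.
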