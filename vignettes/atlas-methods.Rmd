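---
title: "Methods: building an intracellular pseudo-organ expression atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building an intracellular pseudo-organ expression atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`siphonatlas` builds a transcript-accumulation atlas for a siphonous
(single-celled, multinucleate) macroalga sampled across pseudo-organs —
apex, pinnule, rachis, frond base, stolon, holdfast — from a
transcript-by-sample count matrix, and intersects it with a second
species' expression atlas through best-BLAST-hit homology.  Everything
upstream of the count matrix (read processing, assembly, abundance
estimation, BLAST, GO annotation) is out of scope; those results are
consumed as files.

# Normalization model

Counts are first filtered by total abundance: a transcript is kept when
its counts summed over *all* samples reach `min_total` (default 30).
Between-sample scaling uses the trimmed mean of M-values (TMM): for each
sample against a reference, per-transcript log2 count-proportion ratios
(M) and mean log2 abundances (A) are computed over transcripts nonzero in
both samples; the most extreme 30% of M values and 5% of A values are
trimmed two-sided, and the factor is 2 to the inverse-variance-weighted
mean of the remaining M values.  The reference is the sample whose
75th-percentile count fraction is closest to the mean of those quantiles,
overridable with `ref_sample`.  Factors are rescaled to geometric mean 1
so normalized counts per million (CPM) are comparable across runs.  The
trim fractions and precision weighting are the method's canonical
parameters; the method itself names only the trimming idea.  Filtering is
applied before factor computation (the conventional order); both steps
are independent functions, so the other order is available by composition.

Count cells must be integers.  Expectation-maximization abundance
estimators emit fractional expected counts, so `read_count_matrix()`
rounds half-to-even by default (`round_counts = TRUE`); set it to `FALSE`
to make fractional input an error instead.  How fractional estimates
should be handled is genuinely undetermined upstream, which is why this
is a flag rather than a fixed rule.

# Differential abundance

All pseudo-organ pairs (15 pairs for six organs) are tested with an exact
negative-binomial test under a single common dispersion.  This is a
deliberate simplification of the full edgeR-style machinery (no
quantile adjustment, no tagwise shrinkage): it captures the stated
analysis — pairwise NB tests at FDR < 0.05 — with a self-contained,
oracle-checkable method.  Per-pair transcript lists are therefore not
claimed to be identical to what a full edgeR analysis would produce.

* **Library equalization.** Counts are scaled to the geometric mean of
  the TMM-effective library sizes and rounded, so the test can condition
  on pooled counts.
* **Dispersion.** The common dispersion maximizes the conditional NB
  likelihood (including count-factorial constants) over a log-spaced
  grid refined by golden-section search.  The likelihood is compared
  against its exact Poisson limit; sub-Poisson data return dispersion 0.
* **Exact test.** Conditional on a transcript's pooled count, the
  probability of a split at least as extreme as observed is accumulated
  from the conditional NB (at dispersion 0: binomial) distribution; the
  smaller tail is doubled and capped at 1.  Two-sided tail doubling was
  chosen for symmetry and testability.
* **FDR.** Benjamini–Hochberg step-up within each pair (delegated to
  `stats::p.adjust` after validation).  Transcripts significant in at
  least one pair form the DE union passed to clustering.

# Profiles, PCA and the self-organizing map

CPM values are averaged across replicates per pseudo-organ and each
transcript's profile is scaled to mean 0, variance 1 (n−1 denominator)
across organs.  Constant rows cannot be scaled and are dropped with a
warning naming them.  Because every scaled row sums to zero, six-organ
profiles occupy a five-dimensional subspace and the sixth principal
component carries no variance; PCA is available in both orientations
(transcripts as observations, or samples/organs as observations).

The SOM is a 3×2 hexagonal grid trained online for 100 iterations with
the learning rate decreasing linearly from 0.05 to 0.01.  Choices the
training schedule leaves open were fixed as follows, all seed-controlled
and configurable:

* **Initialization** from a seeded random sample of data rows.
* **Neighbourhood**: bubble (1 inside the radius, 0 outside), with the
  radius decreasing linearly from 2/3 of the maximum inter-unit grid
  distance to 0 — close to the defaults of the field's SOM package while
  remaining fully deterministic.
* **Hexagon coordinates**: odd-row offset layout (even rows shifted half
  a unit, rows √3/2 apart), giving unit distance between neighbouring
  units; distances are Euclidean in this plane.
* **Ties** in winner selection go to the lowest unit index.
* **Node numbering** is row-major over the grid.  Node labels are
  arbitrary, so all comparisons against planted truth use best
  label matching (exhaustive over label permutations), never fixed
  numbering.

Per-node summaries report the member count, the median scaled profile,
and the organs whose median scaled abundance exceeds zero.

# Choosing the number of clusters

`validate_cluster_numbers()` retrains the SOM `n_runs` times per
candidate grid with seeds derived from a master seed by a counter, fits a
linear discriminant model on principal components 1–5 against each run's
cluster labels, and records the fraction of each cluster's members
re-predicted into their own cluster.  The LDA is the standard Gaussian
model — class means, pooled within-class covariance, log-priors
proportional to class sizes (a flag switches to equal priors); a ridge of
`1e-8 · trace/d` is added when the pooled covariance is numerically
singular, which can happen for tiny clusters on collinear PCs.
Reassignment is evaluated on the fitting data itself, matching the
fit-then-predict usage this procedure is modelled on.

The recommendation rule is a codified form of "reassignment has not yet
dropped": the largest cluster count whose median fraction is at least
0.8 *and* within 0.05 of the median at the smallest grid.  Both numbers
are exposed, and the raw per-run fractions are always returned so any
other rule can be applied.

**A caveat worth knowing.** On data consisting of well-separated planted
clusters, self-prediction reassignment is a weak redundancy signal: a
converged SOM assigns points to nearest-codebook cells, which are convex
and almost linearly separable, so the discriminant model re-predicts them
almost perfectly *even when the grid has more units than the data has
clusters* (splitting a single Gaussian blob in two still reassigns at
~99%).  Median reassignment therefore declines only slightly past the
true cluster number on such data, and the threshold rule tends to accept
the largest grid tested.  Large drops require overlapping or unstable
cluster regions (for example interleaved duplicate codebooks, which do
occur in a minority of runs and produce fractions near the class prior).
The per-run fraction distributions — particularly their lower quartiles —
are more informative than the median on clean data, which is why they are
emitted in full.

# GO enrichment

Per node, each GO term annotated to at least one transcript of the
clustered universe is tested for over-representation with the upper-tail
hypergeometric probability, BH-adjusted across terms within the node (a
flag pools across nodes).  With transcript lengths available, a
length-aware variant replaces the hypergeometric with the Wallenius
noncentral hypergeometric distribution: the cluster-membership rate is
regressed on length in up to 20 quantile bins, smoothed monotonically by
isotonic regression (both directions fitted, the better one kept), each
transcript receives its bin's rate as a selection weight, and a term's
odds is the mean weight inside the category over the mean weight outside.
The isotonic binned weighting is a simpler, deterministic stand-in for
spline-based weighting; the `method` column records which test produced
each row.  The Wallenius tail itself is computed exactly by dynamic
programming over draws, which is stable for any odds (and reduces to the
classical hypergeometric at odds 1).  GO graph propagation is out of
scope — the annotation is taken as given.

# Cross-species atlas intersection

Each source transcript with a best hit whose subject belongs to the
foreign atlas inherits that subject's node; unmatched transcripts are
excluded and tallied by reason.  For every source node, the observed
distribution of its members over foreign nodes is compared to the null —
the proportion of *all* foreign transcripts per foreign node — with the
Pearson chi-squared statistic (df = foreign nodes − 1).  Using all
foreign transcripts for the null is the literal reading of the
procedure's description; restricting the null to hit transcripts is a
one-line change on the membership table passed in.  Expected counts
below 5 trigger a warning rather than an automatic continuity
correction.  Best-hit reduction is made deterministic by a total order:
bit score, then e-value, then percent identity, then subject ID.

# The synthetic atlas

`generate_atlas()` emulates the sampling design of a six-pseudo-organ
atlas: replicates (5, 5, 5, 5, 5, 4) — five per organ, four for the
holdfast — negative-binomial counts with variance `mu + phi mu^2`, and a
planted fraction of transcripts following one of six hand-authored
prototype profiles arranged along the apical–basal axis (apex-high;
pinnule+rachis; rachis+frond-base; frond-base+stolon; stolon+holdfast;
holdfast-high), with the high organs at 4-fold the baseline.  Defaults:
2,000 transcripts, 50% unstructured (flat) transcripts, dispersion 0.1,
expected depth 5×10⁵ per sample, log-normal per-transcript baselines
(sdlog 1).  Structured transcripts additionally receive gene-level
multiplicative log-normal noise on their per-organ intensity
(`profile_noise_sd = 0.45`), calibrated so the within-node interquartile
spread of scaled abundance is about half a scaled unit — the spread a
real atlas shows around its node medians.  Null transcripts are exactly
flat.  Every sample's expected column sum equals the depth, which
deliberately builds in the composition bias TMM exists to remove.

Companion generators plant ground truth for the downstream stages: a
foreign atlas with 9 nodes and 4,500 transcripts plus a homolog table
whose foreign-node choices follow a configurable source-by-foreign
association matrix (uniform rows = no association; synthesized e-values
log-uniform below 1e-5 so none are filtered); and a GO annotation with
one term per node planted at a configurable enrichment odds (default 8)
over log-normal contig lengths, optionally length-coupled, with an
optional FASTA of random sequence.

What the generator does *not* emulate: sequence content, read-level
error, multi-mapping ambiguity in abundance estimation, correlated
replicates, batch effects, a continuum of accumulation profiles between
nodes, or GO term dependence.  Passing tests therefore demonstrate the
pipeline's internal correctness and its behaviour under idealized planted
structure, not performance on real atlas data.

# Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated data
at desk scale: the default 2,000-transcript atlas for end-to-end checks,
100 SOM runs × 5 grids on 2,000 scaled profiles for the cluster-number
procedure, 2,000-transcript null simulations for type-I calibration, and
toy fixtures with hand-computable answers for every statistic (TMM
against a from-definition loop, the exact test against binomial tails,
the hypergeometric against exhaustive enumeration, the chi-squared
against the reference goodness-of-fit test, LDA against a point-by-point
Bayes-rule oracle and the reference implementation).  Scaling contracts
are asserted to 1e-9; distributional identities to 1e-9; cross-library
agreement to 1e-6.  All stochastic steps flow from explicit integer
seeds; validation runs derive per-run seeds from the master seed by a
counter, making every result bit-reproducible.

# Limitations

* The exact NB test with one common dispersion is a documented
  approximation; per-pair gene lists from shrinkage-based tools will
  differ, mainly for transcripts with atypical variability.
* The recommendation rule for the cluster number is heuristic and, on
  cleanly separated data, insensitive (see the caveat above); inspect
  the emitted fraction distributions.
* GO annotations are used as given; enrichment inherits whatever
  ascertainment bias the annotation carries beyond transcript length.
* Best-hit homology is not orthology; the atlas intersection measures
  association of accumulation patterns, not evolutionary relationships.
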