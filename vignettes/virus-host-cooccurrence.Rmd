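---
title: "Inferring virus-host links from marker-gene co-occurrence"
author: "vhlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring virus-host links from marker-gene co-occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhlink)
```

## The inference problem

Poly-A selected metatranscriptomes from productive coastal waters capture
messages from eukaryotic plankton together with transcripts of the viruses
replicating inside them. Marker genes give each group a handle: the major
capsid protein (MCP) for giant dsDNA viruses, RNA-dependent RNA polymerase
(RdRP) for RNA viruses, the replication-associated protein (Rep) for ssDNA
viruses, and the RNA polymerase II large subunit (RPB1) for the eukaryotes
themselves (rRNA markers are depleted by the poly-A selection). Since a
DNA virus can only be transcribed inside a host cell, an active infection
should leave a strong positive correlation between viral and host marker
expression across a time series. `vhlink` turns that expectation into a
testable clustering procedure and emits candidate virus-host association
networks.

The pipeline's input is deliberately downstream: a contigs-by-samples
matrix of mapped read counts, contig annotations, and per-sample metadata
(site, temporal order, in-situ versus nutrient-amendment treatment,
library size). Assembly, HMM marker screening and read mapping are
upstream concerns of other tools.

## Normalization: RCK

Libraries differ in depth by orders of magnitude, and contigs differ in
length, so raw mapped counts are not comparable. Counts are first
*rarefied* to a common depth and then divided by contig length in
kilobases ("rarefied counts per kilobase", RCK):

* **Expected mode (default):** `count * depth / library_size`. This is
  the expected value of subsampling, is deterministic, and keeps the
  pipeline reproducible without a seed. Column totals of rarefied mapped
  counts equal `depth * mapped_fraction` exactly.
* **Subsample mode:** a seeded multivariate-hypergeometric draw of
  `depth` fragments per library without replacement, with the unmapped
  remainder treated as one extra category so that mapped totals scale
  with each library's mapped fraction. This is the classical rarefaction
  and is exposed for users who want integer counts.

The rarefaction depth defaults to the smallest library size (`"auto"`),
the standard convention when no depth is prescribed. Rarefaction is by
*total* library fragments; normalizing by total *mapped* fragments
instead can be emulated by supplying column sums as library sizes.

## Similarity and clustering

Co-occurrence is measured by the Pearson correlation `r` between RCK
profiles across all samples — in-situ and amendment libraries pooled,
because amendment incubations sample the same virus-host couplings under
perturbed conditions and add degrees of freedom to the correlation.
Correlations are computed on untransformed RCK by default for fidelity to
the field workflow; `log_transform = TRUE` switches to
`log10(RCK + pseudocount)` when robustness to the scale of expression
matters more. A contig with a zero-variance profile has no defined
correlation; it is excluded from clustering with a warning rather than
silently given r = 0.

Clustering is group-average (UPGMA) agglomeration in similarity space:
always merge the pair of clusters with the highest mean cross-pair
similarity. This is run as `stats::hclust(method = "average")` on
`d = 1 - r`, which is mathematically identical, and heights are reported
back on the similarity scale. Group-average linkage is reducible, so merge
heights never invert. Ties in merge order are resolved by the underlying
implementation deterministically for a given input; because all
significance decisions depend only on cluster membership and heights, tie
resolution does not affect downstream results except between exactly
equivalent trees.

## The SIMPROF test

A dendrogram always produces clusters, significant or not. The
similarity-profile (SIMPROF) permutation test asks whether a group of
contigs has any internal multivariate structure worth interpreting. For a
group of *m* contigs its *similarity profile* is the sorted vector of all
*m(m−1)/2* pairwise correlations. Under the null hypothesis that values
are exchangeable across contigs within each sample, a null profile is
obtained by independently permuting each sample's column. The test:

1. builds the mean ordered profile `s̄` from `B1 = 1000` permutations;
2. scores the observed departure `π = Σ_k |s_k − s̄_k|`;
3. scores `B2 = 999` further permuted profiles against the same `s̄`;
4. reports `p = (1 + #{π_perm ≥ π_obs}) / (1 + B2)`.

The add-one estimator keeps `p ≥ 1/(1+B2)`; significance is declared at
`p < α` with `α = 0.05`. The B1/B2 split of the configured "1,000
permutations" follows the convention of the method's reference
implementation; both counts are configurable. Groups smaller than three
are declared homogeneous without testing — a one-element profile has no
dispersion to test. Within permuted profiles an undefined correlation
(a permuted row that happens to be constant, possible with tied counts)
is recorded as 0; observed zero-variance members are excluded before
profiling instead.

Applied recursively from the root, the test recurses into the children of
every significant node and emits each non-significant (or untestable)
subtree as one homogeneous cluster, yielding *statistically distinct*
clusters. Node p-values are reported uncorrected for multiplicity; the
recursive procedure is a gatekeeping scheme, and no correction is applied
across nodes. Every node derives its permutation seed by hashing its
sorted member ids together with the run seed, so results are independent
of contig input order and of whether nodes are visited serially or not.

The permutation kernel is implemented in C++ (Rcpp) and draws from R's
RNG, so `set.seed()` governs it; the 400-dataset calibration experiment
below runs in seconds.

## Networks and dynamics

Clusters containing at least one viral and one eukaryotic contig are the
virus-host candidates. Within each such cluster, every contig pair whose
correlation is significant at `P ≤ 0.1` (inclusive, two-sided t test on
`r` with `n − 2` degrees of freedom) becomes an edge. The threshold is a
screening level, deliberately more permissive than the clustering α.
Significant negative correlations are kept but flagged `positive = FALSE`
— biologically, an active infection predicts a positive correlation, so a
`positive_edges_only` filter is available (default off). A run with no
mixed clusters returns an empty network with a warning, not an error.

Viral temporal dynamics are classified from in-situ samples only, in
temporal order, using the max/min fold range of RCK at detected time
points: fold ≤ 10 at full detection is steady-state ("within an order of
magnitude"), fold ≥ 100 is boom-and-bust ("two orders of magnitude"), and
a contig undetected at some time points counts as boom-and-bust when its
burst reaches 100 times the detection floor — the pattern of a virus
absent early in a bloom and erupting at the end. The floor defaults to
one tenth of the smallest positive RCK in the matrix, so true zeros do
not produce infinite folds; it is configurable. Folds between the two
thresholds are `INTERMEDIATE`; fewer than two detected time points is
`INSUFFICIENT_DATA`. The order-of-magnitude wording these thresholds
implement is qualitative in origin; the cutoffs 10 and 100 are this
package's operationalization and are exposed as `steady_fold_max` and
`bust_fold_min`.

## The synthetic-community generator

`simulate_community()` emulates the survey design the pipeline targets:
five in-situ time points (a ~4-week bloom series) plus three amendment
libraries, planted virus-host pairs among background contigs, library
sizes of 1e5-1e6 fragments (a desk-scale stand-in for tens of millions of
reads), contig lengths 300-8000 bp, and negative-binomial counts
(`variance = mu + dispersion * mu^2`; Poisson at dispersion 0), with
about 2% of each library mapping to the marker contigs.

Latent log10 expression drives everything. A planted host's in-situ
profile is drawn with an exact target fold range for its regime — between
0.2 and 0.9 decades for steady profiles (fold ≤ 10) and 2.2 to 3.2
decades for boom-and-bust (fold ≥ 100). Its paired virus is
`coupling * host + (1 − coupling) * noise` on the log scale, rescaled
affinely to its own regime range (affine maps preserve the log-scale
correlation). Amendment columns are jittered replicates of the final time
point, and the coupling applies across them too: an infection persists in
the incubation bottles, which is exactly why pooling amendment libraries
adds statistical power rather than noise. `simulate_null()` instead draws
every latent value i.i.d., giving communities with no multivariate
structure for type-I calibration.

What the generator does *not* emulate: compositional coupling between
contigs sharing a host community, phylogenetic structure, assembly
artifacts (chimeras, fragmented transcripts), strain microdiversity, and
tag-along correlations from shared environmental drivers. Passing the
recovery tests therefore shows the statistics behave as designed, not
that every edge in real data is an infection; the network is a screen for
candidate relationships.

```{r quick-demo}
sim <- simulate_community(simulation_params(seed = 1, n_planted_pairs = 2,
                                            n_background_virus = 4,
                                            n_background_euk = 4))
rck <- rck_normalize(sim$counts)
round(rck$rck[1:4, 1:4], 2)
```

## Numerical and design choices

* **Expected-mode rarefaction as default:** "rarefied" suggests
  subsampling, but no draw procedure or seed is prescribed by convention;
  the deterministic expectation aids reproducibility and testing, and the
  seeded subsample mode remains available.
* **`>225 bp` as a strict inequality:** the filter keeps
  `length_bp ≥ 226`.
* **Edge significance by t test:** only the threshold `P ≤ 0.1` is
  standard; the conventional t test on r is used and documented so a
  permutation p could be swapped in.
* **Two-sided p-values** for edges, with the sign recorded per edge.
* **Strict `p < α`** for SIMPROF significance.
* **Detection floor** (dynamics): smallest positive RCK / 10.
* **Validation problem sizes:** type-I calibration uses 400 null
  communities of 20 contigs x 8 samples at the full 1,000 + 999
  permutations; planted-pair recovery uses 50 replicates at coupling
  0.97 and dispersion 0.001; the UPGMA oracle comparison uses 100 random
  8-object matrices. These sizes give two-decimal Monte-Carlo resolution
  on the quantities checked while keeping the suite fast.

## Known limitations

Correlation is not causation: co-occurring contigs may share a host
community, a nutrient response, or a bloom phase rather than an
infection. RNA-virus contigs can originate from free particles as well as
active infections, so their edges warrant extra caution. With few samples
(the minimum is three) the t-based edge p-values are coarse, and the
SIMPROF permutation space is small; more time points sharpen everything.
Finally, the pipeline treats contigs as independent units — fragmented
assemblies of one transcript appear as distinct, strongly correlated
contigs and can inflate cluster sizes.
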