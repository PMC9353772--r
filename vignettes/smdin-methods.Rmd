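---
title: "Profiling samples by the graph properties of mass-difference networks"
author: "smdin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling samples by the graph properties of mass-difference networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdin)
```

## The idea

Ultrahigh-resolution mass spectrometry (FT-ICR, Orbitrap) measures neutral
monoisotopic masses accurately enough — relative errors below 1 ppm — that
the *difference* between two detected masses can be attributed to a specific
chemical transformation. A methylation replaces an H by a CH~3~ group, a net
elemental change of +CH~2~ and a mass change of exactly 14.015650 Da; a
(de)hydration changes the mass by 18.010565 Da; and so on. Given a curated
list of such transformations — mass-difference-based building blocks, MDBs —
one can connect every pair of detected features whose mass difference
matches an MDB's delta mass within tolerance. The result is a
*mass-difference network* (MDiN): nodes are detected masses, edges are
putative chemical transformations. No metabolite identification, pathway
database or prior biological knowledge is needed.

This package implements a sample-level use of these networks. For each
sample of an aligned untargeted-metabolomics matrix, the features detected
in that sample induce a subnetwork (the *sMDiN*; isolated nodes are dropped
because a feature that relates to nothing is uninformative here). The
central hypothesis is that the *graph properties* of these per-sample
networks are a signature of the sample: classes of samples differ in which
metabolites they contain, therefore in which transformations are possible
between the detected masses, therefore in the topology and edge composition
of their sMDiNs. Graph metrics take the role that intensity pretreatment
(normalization, transformation, scaling) plays in conventional workflows —
and, notably, they use only feature *occurrence*, discarding the intensity
values that dominate classical analysis and carry most of its technical
variability.

## The building blocks

`defaultMDBs()` ships 15 transformations chosen to be small (< 80 Da),
ubiquitous in biochemistry, and to cover all six common metabolite elements
(C, H, N, O, P, S): deamination O(–NH), transamination NH~3~(–O),
(de)hydrogenation H~2~, methylation CH~2~, oxygenation O,
condensation/dehydration H~2~O, formidoyl transfer NCH, formylation CO,
hydroxymethylation, –SH transfer S, acetylation C~2~H~2~O, carbamoyl
transfer CONH, (de)carboxylation CO~2~, sulfation SO~3~ and phosphorylation
PO~3~H. `defaultMDBs(includeGlycation = TRUE)` adds carboxymethylation
(CHCOOH) and carboxyethylation (CCH~3~COOH), relevant where methylglyoxal
chemistry (glycation) is of interest, e.g. in yeast glyoxalase mutants.

Delta masses are always recomputed from the elemental composition with
monoisotopic atomic masses fixed at IUPAC/CODATA values to nine decimals
(`monoisotopicMass()`), so the numbers are reproducible to the last printed
digit rather than copied. One labelling subtlety: the hydroxymethylation
entry is labelled `CHOH` for continuity with the MDB lists in circulation,
but the composition behind its delta mass (29.002740 Da) is CHO; the naive
reading of the label (CH~2~O) would be 30.010565 Da and is *not* what those
lists use.

```{r}
mdbMasses(defaultMDBs())
```

## Building networks

`buildMDiN()` matches every unordered feature pair against every MDB. The
paper-level convention "1 ppm tolerance" leaves the reference mass
unstated; we use

$$\mathrm{tol}(u, v) = \mathrm{ppm} \times 10^{-6} \times \max(m_u, m_v),$$

because mass-measurement error scales with the measured masses (a ppm of
the *difference* — a few Da — would be physically unattainable by any
instrument). `toleranceRef = "sum"` switches to $m_u + m_v$ for
compatibility with tools that use that convention; it is about twice as
permissive. Matching is undirected (a gain one way is a loss the other),
ties are kept (if two MDBs both match a pair, both edges are created — no
best-match selection), and a pair may in principle carry parallel edges
with distinct labels, although with the default table below 5000 Da at
1 ppm this cannot actually occur. Internally a sort-and-window search makes
construction near-linear per MDB, but the contract — verified
property-style in the test suite — is exact equality with the brute-force
scan over all pairs and all MDBs.

`deriveSMDiN()` induces the subgraph on the features present in one sample
and removes degree-0 nodes. Because an edge depends only on its two
endpoint masses, this is identical to building the network from scratch on
the sample's masses (also a tested invariant). `summarizeNetwork()` reports
the usual characteristics table: node/edge counts, largest component,
percentage of connected nodes (against the full feature universe), and the
diameter and radius of the largest component.

## The six profile metrics

Each metric maps a set of sMDiNs to a samples × features matrix
(`ProfileMatrix`) that any clustering or classification method can consume.
Absence is always encoded as 0, never missing.

**Degree** (`degreeProfile`): the number of incident edges per feature;
parallel MDB edges count separately (degree is about transformation
opportunities, and two different transformations are two opportunities).
Columns are the mass features.

**Betweenness** (`betweennessProfile`): for node $v$, $\sum_{\{s,t\}}
\sigma(s,t|v)/\sigma(s,t)$ over unordered pairs excluding $v$, where
$\sigma$ counts shortest paths. Unnormalized — note that igraph and
networkx default to this but many wrappers rescale; the suite pins the
convention against a brute-force path-count oracle. Paths are computed on
the simple-graph skeleton (a parallel edge adds no new routes).

**Closeness** (`closenessProfile`): the component-corrected form
$$C(v) = \frac{n-1}{N-1}\cdot\frac{n-1}{\sum_{u} d(u,v)},$$
with $n$ the size of $v$'s connected component and $N$ the sMDiN's node
count. The $\tfrac{n-1}{N-1}$ factor penalizes nodes sitting in small
fragments, which matters because sMDiNs are usually disconnected.

**MDB impact, MDBI** (`mdbiProfile`): the fraction of the sample's edges
carried by each MDB. This compresses a network of thousands of nodes to 15
(or 17) interpretable chemistry features; rows sum to 1 whenever the
network has edges, and an empty network contributes an all-zero row.

**Weighted MDB impact, WMDBI** (`wmdbiProfile`): as MDBI, but each edge is
weighted by the summed *importance* of its two endpoints, where importance
is the normalized gini importance of a random forest fit to the degree
profiles (`nodeImportanceFromDegree`). Edges between class-discriminative
nodes therefore count more. This injects supervision into an otherwise
per-sample metric — which is why, in the evaluation harness, the importance
vector is refit inside each training fold rather than once globally.
Samples whose edges all carry zero weight fall back to their MDBI row, and
an all-constant degree profile falls back to uniform importances.

**Graphlet-correlation features, GCD-11** (`gcdProfile`): per sample, count
for every node how often it occupies each automorphism orbit of the
connected 2–4-node graphlets (`countGraphletOrbits`; 15 orbits, of which
the canonical non-redundant subset is {0, 1, 2, 4, 5, 6, 7, 8, 9, 10, 11}),
Spearman-correlate the 11 orbit-count columns, and use the unique
off-diagonal correlations as the sample's topology signature. With 11
orbits there are $\binom{11}{2} = 55$ such pairs; the commonly quoted "60
correlations" fits neither 55 nor the 66 obtained with the diagonal, so the
package exposes 55 by default and 66 via `includeDiagonal = TRUE` rather
than guessing at a third convention. One all-ones dummy node is appended
before correlating so constant orbit columns (common in sparse networks)
never produce undefined correlations; any residual undefined value is
mapped to 0. Orbit counting enumerates each connected 3- and 4-node induced
subgraph exactly once (ESU scheme) and classifies it by its within-subgraph
degree sequence; the suite verifies exact agreement with all-subset
enumeration.

## The intensity baseline

The package also implements the conventional intensity pipeline the network
metrics are meant to be compared against (`idtPipeline`): imputation →
normalization → generalized log → Pareto scaling.

* Imputation: `imputeFifthMin` (one fifth of the per-sample minimum, a
  detection-limit surrogate appropriate when values are missing because
  they are absent) or `imputeRandomForest` (missForest-style iterative
  imputation, 50 trees, each feature regressed on its 100 most
  |Pearson|-correlated features on the current completed matrix, iterating
  until the squared change in imputed cells stops decreasing, at most 10
  rounds).
* Normalization: `normalizeReferenceFeature` (divide by a spiked standard
  located by mass, e.g. leucine enkephalin, [M−H]⁻ 554.262022) or
  `normalizePQN`. PQN follows the canonical quotient-normalization
  procedure: integral-normalize each spectrum, build the mean reference
  from the integral-normalized spectra, then divide each sample by its
  median quotient. The integral step is what makes the operation exactly
  invariant to per-sample dilution — with quotients taken against a mean of
  *raw* spectra, scaling one sample perturbs the reference and the
  invariance only holds approximately.
* `glogTransform`: $g(x) = \log_2\!\big((x + \sqrt{x^2+\lambda})/2\big)$,
  which is exactly $\log_2 x$ at $\lambda = 0$. The default $\lambda$ is
  the square of the smallest intensity of the (normalized) training matrix
  — a detection-limit-scale softening; it must be computed on the
  post-normalization scale, since normalization can change the intensity
  scale by orders of magnitude.
* `paretoScale`: center each feature and divide by the square root of its
  standard deviation, keeping large fold-changes influential (post-scaling
  variance equals the pre-scaling SD, a tested identity).

With a train/test split the pipeline enforces the standard leakage guards:
train filtered to features in ≥ 2 training samples; test restricted to the
training universe; test features seen only once imputed by the 1/5-minimum
rule instead of the forest; features absent from the test set filled with
the training minimum; glog λ and Pareto center/scale fitted on train and
applied to test. Network profiles need none of this (each sMDiN is computed
from its own sample alone) — except WMDBI, whose importance vector is
train-only by construction.

## Evaluation harness

Clustering: `hcaCluster` (UPGMA on Euclidean distances) with three
dendrogram statistics. *Correct clustering*: percentage of classes whose
samples form a pure node in the tree. *Discrimination distance*: for each
correctly clustered class, the height gap between the merge forming the
pure class node and the merge absorbing it, normalized by the maximum merge
height (mean over classes, 0 for incorrect classes). The phrase "distance
between the class node and the next closest node" admits a second reading —
the absorption height itself — which is available via
`variant = "absorption"`; the gap is the default because it measures how
long the class survives as a separate entity, which is the robustness the
statistic is meant to capture. *Correct first cluster*: percentage of
samples whose first merge joins only own-class samples (joining an existing
pure own-class cluster counts).

K-means (`kmeansCluster`, `kmeansEval`): Euclidean, k = number of classes,
best of 20 restarts by inertia. A class is correct only if some cluster
equals it exactly (homogeneity *and* completeness — deliberately stricter
than the dendrogram criterion); the discrimination distance of a correct
class is its centroid's distance to the nearest other centroid over the
maximum pairwise centroid distance; the adjusted Rand index gives a
chance-corrected per-pair view.

Classifiers: `rfClassifyCV` (random forest, 100 trees) and
`plsdaClassifyCV` (PLS-DA via a hand-written PLS2-NIPALS engine,
`plsNipals`, validated in the suite against its full-rank equivalence with
ordinary least squares). Both use stratified k-fold cross-validation
re-drawn over 20 iterations, with all randomness derived from one master
seed (per-iteration/per-fold sub-seeds), making every accuracy
bit-reproducible. PLS-DA one-hot-encodes multiclass responses (predicted
class = argmax, ties to the lowest class index) or uses a 0/1 response with
a 0.5 threshold for two classes; predictors are autoscaled inside each
training fold; the component count is either fixed or chosen by maximizing
Q² under internal stratified CV. `permutationTest` reports the add-one
estimator $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n)$, which never
returns 0 (floor 1/501 at the conventional 500 permutations), and
`rocAucCV` pools out-of-fold scores for a cross-validated ROC/AUC.

## The synthetic generator

Because the method consumes *occurrence patterns*, realistic synthetic data
must have (i) masses that actually differ by MDB deltas, (ii) sub-ppm mass
error and (iii) class-structured presence/absence. `generateDataset()`
builds exactly that: random CHNOPS seed formulas inside standard
elemental-ratio plausibility bounds (H/C 0.2–3.1, O/C ≤ 1.5, N/C ≤ 1.3,
S/C ≤ 0.8, P/C ≤ 0.3, P/O ≤ 0.34, ≥ 1 C and H, masses 80–1000 Da), grown
into families by repeated application of MDB deltas (each accepted
application is a recorded *planted edge*); per-class enrichment by applying
one class-specific MDB to a subset of core features, so each class
over-expresses features reachable by "its" transformation; one uniform
relative mass error per feature (a feature has a single consensus mass in
an aligned matrix, so the error is per-feature, not per-sample); Bernoulli
presence (core features 0.8 everywhere; enriched features 0.9 in-class,
0.1 elsewhere); log-normal intensities (meanlog 14, sdlog 1 — the scale of
FT-ICR peak heights) that exist purely so the intensity pipeline can be
exercised, since the network metrics never read them.

Default study size is 3 classes × 5 replicates over ~300 features — small
multiclass designs with triplicate-to-quintuplicate sampling being the
regime the method targets — with 20 replicates per class used where a
statistic (marker recovery, permutation behavior) needs more samples. At a
0.2 ppm mass error the planted edges are recovered by construction: the
worst-case residual, 0.4 ppm of the larger mass, is strictly inside the
1 ppm window, and the recovery invariant (≥ 99%) is tested rather than
assumed.

What the generator does *not* emulate — and therefore what green tests do
not certify about real data: correlated presence across samples (presence
is Bernoulli-independent given class), adducts and isotopologues, in-source
fragmentation, retention-time structure, chimeric features from imperfect
alignment, and false-positive edges between unrelated compounds, which in
real high-mass regions are common enough that the tolerance choice matters.
The package's claims on real data rest on the method, not on these tests.

## Numerical choices and edge cases

* Tolerance reference mass: `max` (default) or `sum`, above.
* Duplicate-mass merging (`mergeDuplicateMasses`): masses equal after
  rounding to 6 decimals are merged; occurrence is the union and
  co-occurring intensities are summed by default (configurable). Only the
  union can matter downstream: the network layer never reads intensities.
* Zero intensities are treated as missing on ingestion by default
  (`zeroIsMissing`), because alignment tools emit 0 for absence and
  occurrence is the method's information source.
* Empty networks: all-zero profile rows, zero summaries, zero GCD
  signatures — never NA or an error.
* UPGMA ties follow `stats::hclust`'s deterministic lowest-pair rule;
  K-means ties resolve by the best-of-restarts inertia rule under the
  derived sub-seed; `stats::kmeans`'s Hartigan–Wong algorithm rejects
  k = n, so that edge case (every sample its own cluster, zero inertia)
  runs under Lloyd.
* All master seeds are fanned out to sub-seeds below 2³¹ by a fixed integer
  recurrence, so no two stochastic components ever share a stream by
  accident.

## Problem sizes in the test suite

The property-style tests run the brute-force oracles at the largest sizes
at which exhaustive computation is exact and fast: edge construction
against the full pair scan on 100 random mass sets of up to 200 features;
orbit counts against all-subset enumeration on 50 random graphs of up to
30 nodes; centralities against textbook path-count/BFS implementations on
graphs of up to 30 nodes; recovery and classification checks on the
generator's default study sizes. These sizes were chosen as the point where
the oracles are unarguably correct; the implementations themselves scale
well beyond them.

## Limitations

Everything downstream of `buildMDiN()` inherits its assumptions: mass
accuracy near 1 ppm (lower-resolution data produce too many spurious
matches), enough features for the sMDiNs to be non-trivially connected, and
a *balanced* missingness regime — with too few missing values all sMDiNs
look alike, with too many they are too sparse to have topology. Edges are
hypotheses, not reactions: a matching mass difference can arise from an
unrelated pair of compounds, and nothing here curates such false positives
(formula propagation and elemental-ratio edge filtering are deliberate
non-goals). Isobaric compounds collapse onto single nodes. And WMDBI is not
an unsupervised metric; its good behavior in clustering comparisons partly
reflects the supervision it embeds.
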