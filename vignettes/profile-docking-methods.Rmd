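---
title: "Profile re-ranking and kinase similarity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile re-ranking and kinase similarity: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profiledock)
```

## The problem

A selectivity profile names a set of kinases, each either a target
(binding desired) or an anti-target (binding to be designed out). Given
independent docking campaigns — one ranked molecule list per protein
structure — the package re-scores every molecule by how well its pattern
of docking ranks matches the profile, and provides four kinase-similarity
measures to estimate up front how compatible (or conflicting) the
profile's members are.

## The combined profile score

Per structure, a molecule's scaled rank is $R_{k,s} = r_{k,s}/m_{k,s}$,
its ordinal rank over the number of molecules docked. Per kinase the
structures are collapsed to the single best value — $\min_s R_{k,s}$ for
targets, and for anti-targets the maximum of the *inverted* scaled rank —
and log-transformed to give $P_k \le 0$. The score of a molecule for an
$N$-kinase profile is

$$S = \frac{1}{N}\sum_{k=1}^{N} P_k +
      \frac{\max_k P_k - \min_k P_k}{2},$$

sorted ascending. Three properties worth knowing (all are enforced by
property-style tests):

* **Log-base invariance of the ordering.** Both the mean and the spread
  are homogeneous in $P$, so changing the base rescales $S$ by a positive
  constant. The default base 10 only sets the reported magnitudes; it is
  configurable on `profile_spec()`.
* **Translation equivariance and permutation invariance.**
  $S(P + c) = S(P) + c$; member order does not matter.
* **Balance penalty.** For $N \ge 3$, improving the already-best
  component by $\delta$ *increases* $S$ by $\delta(1/2 - 1/N)$: the score
  deliberately refuses to reward making a strong target even stronger at
  the cost of balance.

### The anti-target inversion offset

A straight inversion $R = 1 - r/m$ maps the worst-ranked molecule
($r = m$) to $R = 0$, where the log is undefined. The package uses
$R = 1 - (r-1)/m$, which maps ranks $1..m$ onto $[1/m, 1]$ — exactly the
range the target side has — and preserves the rank ordering. This is a
deliberate regularisation of the inverted rank, chosen over alternatives
(clamping at $\varepsilon$, dropping the molecule) because it keeps the
two roles symmetric and needs no tuning constant.

### Coverage, ties, duplicates

* **Coverage rule.** A molecule is scored only if it has a rank in at
  least one structure of *every* member kinase; others are dropped and
  counted. Imputation would invent data, but a `missing_as_worst` option
  (rank $m+1$) exists for libraries docked incompletely on purpose.
* **Tie-breaking.** Equal docking scores get ordinal ranks with the
  lexicographic molecule id as secondary key. Reproducibility across
  platforms matters more here than tie symmetry, because the score
  consumes integer ranks.
* **Duplicates.** Repeated rows for one molecule keep the best score,
  mirroring keeping a molecule's best pose. Scores are lower-is-better by
  default with a flag to invert.

## Similarity measures

* **LigProfSim** filters bioactivity records to binding assays reporting
  IC50, keeps the minimum value per compound/kinase (within and across
  assays — the "most active" rule; taking the minimum across assays too
  is our convention, since only within-assay dedup is standard), and calls a pair
  active below 500 nM (strictly — the boundary is inactive). The pair
  similarity is common-actives over common-tested; the diagonal is
  promiscuity. Records with a ">" relation qualifier are dropped because
  the reported value is only a lower bound on IC50.
* **PocSeqSim** counts identical residues over the fixed 85-position
  pocket alignment. A gap matches nothing, including another gap: with no
  residue present there is nothing to be identical to. This depresses
  identity slightly for gappy atypical kinases relative to a
  gap-matching convention.
* **IFPSim** compares 595-bit interaction fingerprints (85 residues × 7
  interaction types, residue-major bit order) with Tanimoto similarity,
  after keeping only orthosteric-ligand entries and, per PDB structure,
  the highest-quality chain/alt-model entry (quality ties broken by the
  lexicographically smallest entry key — a deterministic stand-in for
  "first"). All-zero fingerprint pairs are defined as similarity 0 with a
  warning rather than NaN. DFG/αC annotations are carried and filterable;
  no conformation filter is applied by default.
* **DockRankSim** intersects the top-$n$ (default 25,000, configurable;
  the cutoff is conventional, not optimised) of two runs, renumbers ranks
  within the intersection, and takes the Spearman correlation — computed
  by `stats::cor`; since upstream ranks are ordinal the renumbered ranks
  are tie-free permutations, which an internal assertion enforces.
  Intersections smaller than 2 give NaN rather than an error so large
  matrices degrade gracefully.

All kinase-level matrices reduce structure pairs by the maximum, and the
diagonal uses *distinct* structure pairs (NaN for single-structure
kinases), so diagonals measure within-kinase conformational agreement,
not trivial self-identity.

Row summaries (`summarize_similarity`) include the diagonal, so a
kinase's mean reflects similarity to every panel member including itself;
the s.d. is the sample (n−1) form by default with a population switch.
Cross-measure correlation (`compare_measures`) uses only off-diagonal
upper-triangle entries — self-similarity means something different in
every measure — with a parametric two-sided Pearson test by default.

## The synthetic-data generator

The generator defines the desk-scale study conditions; it emulates the
*statistical structure* of the real inputs, not their content:

* **Docking runs.** Each molecule has a standard-normal reference
  affinity; kinase $k$'s latent affinity is
  $\rho\,z_{\mathrm{ref}} + \sqrt{1-\rho^2}\,z_k$, and each structure
  adds independent noise (s.d. 0.3 by default — enough to make
  within-kinase structure pairs agree strongly but not perfectly).
  $\rho$ controls the expected rank correlation interpretably.
* **Bioactivity tables.** The exact-count mode places pair compounds
  (tested on both kinases; the planned number active on both at 100 nM,
  the rest inactive at 1000 nM on both) and fills the remaining marginals
  with kinase-private compounds, erroring on infeasible plans
  (pair actives > pair tested, or pair counts exceeding marginals). It
  reproduces planned promiscuity and pair ratios exactly. A stochastic
  Bernoulli mode serves property tests.
* **Pocket sequences** mutate exactly $k$ of 85 positions of a common
  base to different residues, giving identity $(85-k)/85$ by
  construction.
* **Fingerprints** flip each of the 595 template bits independently at a
  planned rate; expected Tanimoto decreases monotonically in the rate.

Random streams are split per kinase and structure (hashed sub-seeds), so
adding a kinase never perturbs the others' outputs, and every generator
is a pure function of its configuration and seed.

What the generator does **not** emulate: real chemistry (no molecular
graphs), assay heterogeneity and censoring beyond the ">" qualifier,
realistic fingerprint bit correlations (real interaction bits cluster on
hinge residues), or alignment gap structure. Passing tests therefore
demonstrate correctness of the bookkeeping and statistics on data with
known ground truth — not docking accuracy on real kinases.

## Problem sizes and numerics

The test suite runs the generators at 10–10,000 molecules; the
parameter-recovery check uses pairs of 10,000-molecule runs with top-500
intersections over 50 seeds per latent-correlation setting, sizes at
which the Monte-Carlo means separate cleanly while the whole suite stays
around a minute. Rank correlations on enumerated permutations up to
$k = 8$ are compared against the closed form
$1 - 6\sum d_i^2 / (k(k^2-1))$ exactly. Matrix symmetry and range checks
tolerate $10^{-12}$ of floating noise; everything constructed by exact
counting is asserted without tolerance.

## Known limitations

* The score consumes ranks only; it cannot distinguish a confident
  docking hit from a marginal one within the same rank, and relies on
  the library being large enough for scaled ranks to be meaningful.
* LigProfSim inherits the sparsity of bioactivity databases: pairs with
  few commonly tested compounds give noisy ratios, and the counts
  companion table should always be consulted alongside the matrix.
* The independence assumption behind `expected_profile_hit_rate` is
  optimistic for similar kinases, where hit events correlate.
* PocStrucSim-style cavity-graph comparison is out of scope (the
  underlying graph method is proprietary); the remaining measures stand
  on their own.
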