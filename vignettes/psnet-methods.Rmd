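---
title: "Classifying patients with similarity networks: models and methods"
author: "psnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying patients with similarity networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnet)
```

# The model

`psnet` performs supervised patient classification in the patient
similarity network (PSN) framework. Every *feature* is a network: patients
are nodes, and an edge weight encodes how similar two patients are under
one view of the data — a whole data type, a single variable, or a
pathway's worth of genes. Because all inputs are converted into the same
representation, heterogeneous data types (expression, clinical variables,
methylation, ...) integrate trivially, missing data degrade individual
edges instead of whole samples, and the learned model remains
interpretable: its parameters are per-network weights, and a network has a
biological name.

Classification is a recommender-style two-step:

1. **Feature selection.** For each class, networks are scored by how well
   they connect members of that class to each other relative to everyone
   else, using repeated query-driven regularized regression on resampled
   subsets of the class's training members.
2. **Prediction.** Selected networks are averaged into an integrated
   network per class; label propagation from each class's training members
   ranks all patients by similarity to that class, and a held-out patient
   is assigned the class that ranks it highest.

# Similarity metrics

For a single continuous variable with cohort values $G$, the similarity of
patients $a, b$ is the normalized similarity

$$S(a,b,G) = 1 - \frac{|a-b|}{\max(G)-\min(G)} \in [0,1],$$

and a data type with $k \le 5$ variables uses the mean of the per-variable
similarities, $S'$. Data types with six or more variables use Pearson
correlation of the two patients' profiles; pathway-level features use
Pearson correlation restricted to a gene set's members (sets are kept when
10–200 of their genes are present, the conventional range that avoids both
unstable correlations and uninformative catch-all sets). Correlations use
pairwise-complete observations with at least `minPairs = 3` complete
pairs; an edge whose correlation is undefined (constant profile, too few
pairs) is omitted rather than imputed.

Two locally scaled kernels are available for variable-level models:
Euclidean (`eucscale`) or correlation distance $d = 1-r$ (`pearscale`)
passed through

$$w = \exp\!\left(-\frac{d^2}{\mu\,\bar\varepsilon}\right), \qquad
\bar\varepsilon = \tfrac{1}{3}\left(\varepsilon_i + \varepsilon_j + d\right),$$

where $\varepsilon_i$ is the mean distance from patient $i$ to its
`kNeighbors` nearest neighbours (defaults $\mu = 0.5$, `kNeighbors = 20`).
Averaging the pair distance into the bandwidth follows the local-scaling
construction used in similarity network fusion; both constants are
config-exposed because no single choice suits all data sets.

# Sparsification

Dense correlation networks carry many weak, noisy edges. Pruning uses
three parameters: a weight `cutoff` (edges below it are removed), `topX`
(an edge survives if it is among either endpoint's `topX` strongest —
the endpoint-union rule keeps the result symmetric), and an optional
global cap `maxEdges` (keep the globally strongest edges). When the cap is
set, any patient left with no edges is re-attached through its single
strongest original edge, raised to the cutoff if below it — this
guarantees that every patient, in particular every held-out patient,
remains reachable by label propagation. Ties are always broken by weight
descending then partner identifier, making the operation deterministic and
idempotent.

Defaults: correlation networks use cutoff 0.3 and topX 50; the predictor
additionally caps pathway networks at 3000 edges (activating the
re-attachment guarantee); exponentially scaled networks use the smallest
positive representable weight as cutoff, since their weights are strictly
positive by construction.

# Query-driven network weighting

Given a query $Q$ (a subset of one class's training members) inside a
universe of $n$ training patients, define the zero-mean label vector

$$u_i = \begin{cases} n_o/n & i \in Q\\ -n_q/n & \text{otherwise},\end{cases}$$

with $n_q = |Q|$, $n_o = n - n_q$. Each network contributes one column to
a design matrix over unordered patient pairs (entry: its edge weight, 0 if
absent), and ridge regression with an unpenalized intercept fits these
columns to the target $t_{ij} = u_i u_j$: a network enriched in
query–query edges and depleted in query–other edges earns a positive
coefficient. Non-negativity is enforced by drop-and-refit — networks with
non-positive coefficients (at or below $10^{-10}$, the numerical-noise
floor) are removed and the reduced system re-solved until all remaining
coefficients are positive; the feature set strictly shrinks, so the loop
terminates. The ridge penalty defaults to $\lambda = 1$.

**Which pairs enter the regression.** Pairs between two non-query patients
are excluded by default (`includeNonQueryPairs = FALSE`). Non-query
patients are not known to share a class, so rewarding edges among them
treats an unwarranted assumption as signal; empirically, including those
pairs (whose target value $n_q^2/n^2$ is positive) lets a substantial
fraction of pure-noise networks earn stably positive weights round after
round, because a network's edge-density imbalance across pair types is a
fixed property of the network. Exclusion sharpens the contrast to
query–query versus query–other edges and markedly reduces spurious
positives for the class that carries signal. The toggle restores the
inclusive target.

# Feature scoring and selection

Feature selection must not reflect one lucky query. For each class,
`nRounds = 10` rounds each draw a without-replacement subsample
(`queryFraction = 0.8`, minimum 2) of the class's training members, fit
network weights, and award +1 to every network with a positive
coefficient. The score of a (class, feature) pair is therefore an integer
in $0..10$, and features reaching `threshold = 9` are selected — the
"9 of 10 resamplings" convention. Per-class random streams are derived by
hashing the class label with the master seed, so results do not depend on
the order in which classes are processed.

An honest caveat, verified by simulation with this package's own
generator: the score's null distribution is *not* well controlled within a
single split. A noise network's fitted-coefficient sign depends on a fixed
property of its edge placement, so the 10 rounds are far from independent
coin flips, and on label-permuted data roughly 15–25% of noise networks
still reach 9 of 10. Within-split selection is consequently a weak filter
for a class with little structure of its own; robustness comes from the
class with genuine signal (where informative networks absorb the target
and noise survivors become rare) and, across splits, from
`consistencyAcrossSplits()`, which reports the highest score a feature
attains in at least 70% of train/test splits and the set attaining the
maximum score in every split. Calibrating the score's null distribution
(e.g. by label permutation) is deliberately out of scope.

# Classification

Each class's database is rebuilt over training *and* test patients from
the selected features, re-sparsified with the identical configuration,
and combined by uniform averaging (missing edges contribute 0; the sum is
normalized by the total combining weight, so unit-interval inputs give a
unit-interval result). Label propagation solves

$$f = (I + \lambda_{prop} L_{sym})^{-1} y,$$

with $L_{sym}$ the symmetric-normalized graph Laplacian (isolated nodes
keep $f_i = y_i$), the query bias $y_i = 1$ for the class's training
members and the mean label $(n_q - n_o)/(n_q + n_o)$ elsewhere, and
$\lambda_{prop} = 1$. A conjugate-gradient solver (`iterativePropagate`)
matches the closed form to any requested tolerance for larger cohorts.
Ranks (ties broken by patient identifier) are rescaled to normalized ranks
$r = 1 - (rank - 1)/(n - 1) \in [0,1]$, which are comparable across
databases; a test patient is assigned the class with the highest $r$
(ties to the lexicographically smallest label), and the binary decision
score is the difference of the two normalized ranks.

**Shared versus per-class databases.** With `databaseMode = "union"` (the
default) both class databases contain the union of features selected for
any class, so the two rankings are computed in the same similarity space
and differ only in their query. This matters when one class carries most
of the coherent structure: in a cohort where only one class has a planted
signature, the signal-less class selects only overfit noise networks, its
normalized rank is uninformative for held-out patients (rank-only AUROC
near 0.5 while the other class's rank alone ranks perfectly), and the
rank difference dilutes a perfect statistic with noise. Computing both
ranks on the shared feature space removes that failure mode entirely in
our simulations while leaving the symmetric-signal case unchanged.
`databaseMode = "per-class"` restores the strict per-class design. In
either mode, a class whose selection is empty falls back, loudly, to all
features.

# Evaluation

AUROC uses the rank (Wilcoxon) formula, counting tied scores 0.5; AUPR is
the step integral of the precision–recall curve evaluated at distinct
score thresholds; accuracy is the fraction of correct assignments.
Multiclass problems are handled one-vs-rest with macro averages. The
predictor repeats everything over `nSplits` stratified 80:20 train/test
splits (class proportions preserved to rounding) and reports per-split
metrics plus their mean and SD. All preprocessing that estimates anything
— median imputation, lasso prefiltering (an L1-penalized logistic model
with internally cross-validated penalty; variables with non-zero
coefficients are retained) — runs inside each split on the training
partition only, and its statistics are applied, frozen, to the test
partition.

# Integrated-network reporting

For interpretation, the networks of consistently top-scoring features are
averaged into a single integrated PSN over all patients. Similarity is
converted edge-wise to dissimilarity $d = 1 - w$ (absent edges stay
absent, rather than being assigned an arbitrary maximal distance), and
weighted shortest paths are computed with Dijkstra's algorithm (via
igraph). Class separation compares mean shortest-path distance over
unordered same-class pairs against cross-class pairs with a one-tailed
Wilcoxon–Mann–Whitney test; with 20 or fewer combined pairs the p-value
is computed exactly by permutation enumeration over midrank sums (which
handles ties, unlike the standard exact algorithm), otherwise by the
tie-corrected normal approximation. Unreachable pairs are excluded from
the means and reported as a count. Two display filters are provided:
keep the shortest 40% of edge distances, or (figure style) drop edges
below weight 0.7 and keep the top 20% of each node's edges.

# The synthetic cohort

`simulateCohort()` emulates a two-class cohort with a gene-expression
layer, non-overlapping gene sets, and optional clinical variables.
Baseline expression is standard normal; in each *predictive* set, genes
are shifted in the case class by the effect size $d$ with alternating
sign across the set's genes. The sign alternation is essential, not
cosmetic: patient-wise Pearson correlation is invariant to adding a
constant to every component of a profile, so a shift that is uniform
across a set's genes would be invisible to pathway similarity. With
alternating signs each predictive gene still has a standardized
between-class difference of magnitude $d$, while the set's genes jointly
form a signature that raises case–case correlation to roughly
$d^2/(d^2+1)$ and leaves other pairs near zero. Missingness, when
requested, is completely at random — sufficient for testing that
imputation is leak-free, though real missingness rarely is MCAR.

Default conditions (60 patients per class, 30 sets of 20 genes, 3
predictive sets, $d = 1.5$) give a strongly but not trivially separable
cohort; the test suite and the acceptance script run it with 5 stratified
splits, and module tests use a scaled-down version (20 per class, 6 sets)
where a quick turnaround matters. What passing these simulations does
*not* show: robustness to correlated baseline expression, batch effects,
class-imbalanced cohorts, non-MCAR missingness, or signatures expressed
as covariance rather than mean structure — real multi-omic cohorts have
all of these.

# Numerical and design choices

* Six variables sit exactly on the metric boundary; they use Pearson
  (correlation stabilizes as variables accumulate, and the minimum-sample
  argument favors it at six).
* Negative correlations are kept in raw networks and removed by the 0.3
  cutoff at sparsification, not clamped.
* Coefficients at or below $10^{-10}$ count as non-positive in the
  drop-and-refit loop (pure numerical noise, e.g. a network collinear
  with the intercept).
* All tie-breaks (rank ties, top-list ties, class ties) are resolved by
  identifier order, so identical seeds reproduce byte-identical reports
  on any platform.
* Seeds for splits, per-class resampling streams, and fold assignments
  are derived from the master seed by hashing stage labels, keeping every
  derived seed a valid 32-bit integer.

# Limitations

The regression that weights networks is linear in edge weights and blind
to non-linear class structure; the score's within-split null is
permissive (see above), so single-split feature lists should be read
cautiously and cross-split consistency preferred; per-class databases
assume every class has enough training members (at least 3, realistically
far more) to query and resample; and transductive classification —
similarities between training and test patients are computed, test labels
are not — means new patients require recomputing their similarity edges
against the cohort.
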