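---
title: "Multi-objective discovery of phospho-signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective discovery of phospho-signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretosig)
```

## The problem

A response-prediction signature is a small set of phosphorylation sites
whose joint quantitative pattern separates drug-sensitive from
drug-resistant samples. A good signature is not only discriminative: it
should be small enough to assay in clinical routine, and its proteins
should be biologically tied to the drug's mechanism, for instance through
interactions with the drug target. `paretosig` treats these three demands
as separate objectives and searches for the whole set of optimal
trade-offs (the Pareto front) rather than a single best compromise.

Inputs are a sites-by-samples matrix of log10-transformed quantification
ratios with missing values, a binary response label per sample
(sensitive = +1, resistant = −1), a protein–protein interaction edge list
with confidence scores, and a drug-target protein identifier. Protein
identifiers in the matrix and in the edge list must already share a
namespace; `join_failure_report()` lists the proteins that fail to join,
and no identifier mapping is attempted.

## Candidate prefiltering

The optimizer works on a candidate set of at most `top_k` (default 100)
sites, built by a fixed pipeline:

1. **Presence filter.** Keep sites quantified in at least `min_presence`
   (default 2/3) of the samples of *each* class.
2. **Fold-change filter.** Keep sites whose class means (over present
   values) differ by at least `log10(min_fold)`; the default `min_fold = 4`
   corresponds to a 4-fold ratio change, additive on the log10 scale.
3. **Rank combination.** Each surviving site is ranked separately by a
   panel of two-sample statistics — absolute class-mean difference, the
   magnitude of the Welch t statistic, and the distance of the Wilcoxon
   rank-sum statistic from its null mean — and scored by the mean of the
   three ranks. The panel is configurable (`rank_stats`); combining ranks
   of several statistics is more robust at n ≈ 20 than any single test,
   and ties are broken lexicographically by site id so the order is total
   and deterministic.
4. **One site per protein, top k.** Walking the ranking, a site is kept
   only if its protein is not yet represented, until `top_k` sites are
   collected. The resulting order defines the chromosome positions.

No multiple-testing correction is applied here: the filter's task is
search-space reduction, not inference.

## The three objectives

A signature is encoded as a binary chromosome over the candidate set.
All three objectives are minimized.

**Size** is the number of selected sites.

**Separation** measures generalization, not fit. For each training sample
a linear soft-margin SVM (cost `svm_cost = 1`, no feature scaling) is
trained on the remaining samples restricted to the selected sites, and a
sigmoid posterior model

$$p_i = \frac{1}{1 + \exp(A f_i + B)}, \qquad B \equiv 0$$

is fitted to that fold's training decision values, mapping the decision
value $f_i$ of the held-out sample to a posterior probability of
resistance. Fixing $B = 0$ pins the separating hyperplane to $p = 0.5$.
The slope $A$ minimizes the regularized negative log-likelihood with
smoothed targets $(N_1+1)/(N_1+2)$ and $1/(N_0+2)$; because the problem
is convex in one dimension it is solved with a damped Newton iteration
(gradient $\sum_i f_i (t_i - p_i)$, Hessian $\sum_i f_i^2 p_i (1-p_i)$),
which is deterministic and immune to the flat likelihood tails that
defeat bracketing minimizers when the classes are perfectly separated.
The objective is the negative worst per-sample probability margin,

$$s = -\min_i \left( c_i \left( \tfrac{1}{2} - p_i \right) + \tfrac{1}{2} \right) \in [-1, 0],$$

with $c_i = +1$ for sensitive and $-1$ for resistant samples. A fold in
which a class vanishes contributes the worst margin 0.

Missing values are imputed, inside each leave-one-out fold and from that
fold's training samples only, by the per-site mean of the two class
means — the same scheme used later for validation samples, so training
and deployment share one mechanism and no information leaks from the
held-out sample into its own imputation.

**Relevance** ties a signature to the drug target. Edges with interaction
confidence $s > 0.9$ are kept and transformed into penalties
$\rho = 1 / (-\log_{10}(1 - s))$, which maps the retained range
$[0.9, 0.999]$ onto $[1, 1/3]$: higher-confidence edges are cheaper to
traverse, with deliberately pronounced differences near the top of the
scale. The relevance of a signature is the mean Dijkstra
(minimum-penalty) distance of its *distinct* proteins to the target.
Proteins absent from the network or disconnected from the target receive
a fallback distance of the largest finite node-to-target distance plus
one — finite, worse than any connected protein, and scale-aware; it is a
configuration knob (`fallback_distance`) because no principled universal
constant exists. A literal variant of the penalty,
$\rho = 1 - \log_{10}(1-s)$, is kept behind `penalty_form = "literal"`
for comparison; it is increasing on the retained range (2 → 4) and is
not used by default.

The all-zero chromosome is never sent to the SVM: it is scored
(size 0, separation 0, relevance = fallback), which keeps evaluation
total, and genetic operators repair all-zero outputs by setting one
random bit.

## The search

`evolve()` is a standard elitist NSGA-II loop: population of
`population_size` (default 200) chromosomes initialized with 10% of bits
set, fitness by fast non-dominated sorting, diversity by crowding
distance with infinite crowding at the front boundaries, 5-way tournament
selection with the crowded-comparison operator (front rank, then
crowding, then a random draw), single-point crossover with probability
0.8, per-bit flip mutation with probability 0.02, and survivor selection
of the best N from the merged parent+offspring pool. Evaluation results
are memoized by bit pattern, so re-encountered chromosomes — common in
late generations — cost nothing.

Termination is by stagnation *in feature space*: the run stops once the
set of first-front bit patterns is unchanged for
`stagnation_generations` (default 200) consecutive generations. Set
equality of chromosomes is stricter than equality of objective vectors
and is the natural reading of "the front stopped changing". A
`max_generations` cap (default 5000) guards against pathological inputs.
A single seeded RNG stream drives initialization, selection, crossover
and mutation in a fixed order, making full runs bit-reproducible.

## From front to signatures

Front solutions with separation ≥ `separation_cutoff` (default −0.6) are
removed: the multi-objective search legitimately returns very small,
network-proximal signatures that barely discriminate, and discarding
undesired regions of the front afterwards is the standard post hoc
weighting step. The strict inequality means a solution at exactly the
cutoff is removed.

The surviving solutions are clustered in feature space — Ward linkage on
Euclidean distances between the raw binary vectors (`ward.D2`, no
scaling: all coordinates are already on the same 0/1 scale) — and the
dendrogram is cut into `n_clusters` groups (default 4, a knob because no
principled cut criterion exists at these sizes; labels follow dendrogram
leaf order so they are stable). Each cluster is represented by the
member closest to its centroid; exact distance ties go to the better
separation score, residual ties to the lowest solution index.

Each representative is turned into a final predictor: a linear SVM
(cost 1) on the full training set with the same class-mean imputation,
plus a sigmoid calibrated on the training decision values. Validation
samples are imputed from *training* class means (a validation site
missing entirely is imputed the same way, with a warning), predicted,
and scored by accuracy — a sample at exactly $p = 0.5$ counts as
incorrect — and by the average probability distance
$\frac{1}{N}\sum_i (0.5 - p_i)\,c_i \in [-0.5, 0.5]$, a
confidence-weighted score where larger is better.

## The synthetic-data generator

`generate_dataset()` produces the desk-scale datasets the package is
developed and tested against: two classes of log10-ratio profiles with
`n_informative` planted sites (default 3) carrying a between-class mean
shift of `effect_log10` with alternating sign, i.i.d. Gaussian cell
noise (`noise_sd`), independent MCAR missingness (`missing_rate`), and a
PPI graph of high-confidence edges (confidences in (0.9, 0.999]) plus
sub-threshold decoys, with the planted proteins wired within two
high-confidence hops of the target. Validation samples come from the
same generative model with the effect attenuated by
`validation_attenuation` (default 0.8), a mild domain shift emulating
transfer to a related tumour type.

Default calibration: `effect_log10 = 1.0` (a 10-fold change, comfortably
above the 4-fold candidate filter) and `noise_sd = 0.15`. The separation
objective is a worst-case (minimum) margin over ~20 samples, so it is
governed by the most extreme noise draw, not the average one; with
weaker effects the planted truth itself lands above the −0.6 retention
cutoff and the generated study would contradict the workflow it is meant
to exercise. The chosen values place true-signature separations in the
−0.6 to −0.9 range, the regime the front filter expects of usable
signatures. MCAR missingness at 15% keeps the 2/3-presence filter and
both imputation paths active without dominating the worst-case margin.

What the generator does *not* emulate: intensity-dependent (non-random)
missingness, correlated sites within pathways, ratio compression, or
site-localization error. Green tests on synthetic data therefore
demonstrate the correctness of the machinery and recoverability of
planted truth under the stated model — not performance on real
phosphoproteomes.

Test problem sizes are deliberately modest and are the package's own
choices: 500 sites × 20 training + 6 validation samples with population
100 and stagnation window 50 for end-to-end recovery, a 10-bit chromosome
space for exhaustive-front comparison (all 1,023 non-empty signatures
enumerable), and graphs of at most 8 nodes wherever exhaustive path
enumeration serves as the Dijkstra oracle.

## Numerical choices and degenerate inputs

* Penalty transform endpoints: $\rho(0.9) = 1$, $\rho(0.999) = 1/3$;
  strictly decreasing in between. The transform accepts the closed lower
  boundary (s = 0.9) while the network builder retains only edges
  strictly above the threshold.
* SVM determinism: the dual problem is convex and `e1071`'s solver is
  run with fixed settings and `scale = FALSE`; decision values are
  computed directly from the support vectors, so repeated evaluation is
  bit-stable within a run. Training is invariant to sample order up to
  solver tolerance.
* Ties: ranking ties break by site id; tournament ties by crowding then
  RNG; centroid-distance ties by separation then solution index;
  duplicate chromosomes are allowed in the population (memoization makes
  them cheap) and deduplicated only in the reported front.
* Degenerate cases: single-class LOO folds score margin 0; an empty
  front after separation filtering is an error advising a cutoff change;
  a target absent from the filtered network triggers a warning and the
  fallback distance for every protein.

## Limitations

* The relevance score inherits every bias of the interaction database:
  well-studied proteins are closer to everything, and unannotated
  proteins are penalized by the fallback constant.
* The separation objective is a minimum over samples and therefore
  sensitive to a single outlying sample or label error; with ~20
  samples, one bad draw dominates the score.
* Ward clustering of binary vectors and the choice of four clusters are
  pragmatic, not model-based; silhouette inspection of the cut is left
  to the analyst.
* Runtime is dominated by the LOOCV SVM inside the separation objective
  (samples × SVM fits per newly seen chromosome); memoization and the
  small candidate space keep desk-scale runs in seconds-to-minutes, but
  matrices with thousands of candidates would need a cheaper surrogate
  or parallel evaluation.
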