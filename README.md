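# paretosig

Multi-objective discovery of phosphorylation-site signatures that predict
drug response.

Most signature-discovery methods optimize prediction accuracy alone and
return a single marker panel. `paretosig` instead treats signature
discovery as a three-objective minimization over binary site-selection
vectors and returns the whole Pareto front of optimal trade-offs between:

* **size** — the number of phosphosites in the signature;
* **separation** — the negative worst per-sample posterior-probability
  margin, `-min_i(c_i(½ − p_i) + ½) ∈ [−1, 0]`, from a leave-one-out
  cross-validation of a linear SVM (cost C = 1) whose decision values are
  calibrated by a one-parameter sigmoid `p = 1/(1 + exp(A·f))` with the
  offset fixed at 0;
* **relevance** — the mean minimum-penalty (Dijkstra) distance of the
  signature's proteins to a drug-target protein in a protein–protein
  interaction network, keeping edges with confidence s > 0.9 and
  weighting them by `ρ = 1/(−log10(1 − s))`, which maps confidences
  0.9 → 0.999 onto penalties 1 → 1/3.

Candidate sites are prefiltered (≥ 2/3 present per class, ≥ 4-fold mean
class difference on the log10 ratio scale, rank combination of
two-sample statistics, one site per protein, top 100), searched with an
elitist NSGA-II genetic algorithm (population 200, 5-way tournament,
single-point crossover p = 0.8, bit-flip mutation p = 0.02, stagnation
termination on the first front), and post-processed: solutions with
separation ≥ −0.6 are removed, the rest are Ward-clustered in feature
space, one representative per cluster is picked by centroid distance,
and each representative becomes a final linear-SVM predictor that can be
validated on an independent sample set.

The package targets computational biologists working with quantitative
(phospho)proteomic response cohorts; everything runs on plain delimited
text (site matrix, label table, STRING-style edge list).

## Worked example

A synthetic cohort with three planted discriminative sites whose
proteins sit close to the drug target:

```r
library(paretosig)

ds <- generate_dataset(synthetic_config(seed = 2))
cfg <- default_config()
cfg$population_size        <- 100
cfg$stagnation_generations <- 50
cfg$max_generations        <- 500
cfg$seed                   <- 2

res <- run_pipeline(ds$train, ds$train_labels, ds$ppi, ds$target,
                    validation = ds$validation,
                    validation_labels = ds$validation_labels,
                    config = cfg)
res
#> pareto_result: 3 candidates, 53 generations, 4 filtered front solutions, 4 representatives
#> validation summary:
#>  signature size  accuracy avg_prob_distance
#>    Pareto1    1 0.8333333         0.2853803
#>    Pareto2    2 0.8333333         0.2796076
#>    Pareto3    2 1.0000000         0.3472343
#>    Pareto4    3 1.0000000         0.3222785

res$solutions
#>   solution                            sites size separation relevance cluster representative
#> 1        1                       PROT001_S1    1 -0.7019835 0.3333333       1           TRUE
#> 2        2            PROT001_S1;PROT002_S2    2 -0.7329949 0.5833333       2           TRUE
#> 3        3            PROT001_S1;PROT003_S3    2 -0.7238145 0.3333333       3           TRUE
#> 4        4 PROT001_S1;PROT003_S3;PROT002_S2    3 -0.7550878 0.5000000       4           TRUE
```

Reading the table: each row is a Pareto-optimal signature. `separation`
is the worst held-out posterior margin (−1 is perfect, values above the
−0.6 cutoff were removed); `relevance` is the mean penalty-weighted
network distance to the target (0.333 is one maximally confident
interaction away). The strongest planted site `PROT001_S1` appears in
every signature; growing signatures trade size against better
separation. On the six independent validation samples the two larger
signatures predict perfectly, and the `avg_prob_distance` column is the
confidence-weighted score `mean((0.5 − p_i)·c_i) ∈ [−0.5, 0.5]`.

`write_signature_report(res, "out/")` exports the solution table, the
per-sample predictions, the generation log and a JSON report;
`write_manifest(cfg, "out/")` records the effective configuration. A
thin command-line wrapper with `simulate` / `prefilter` / `discover`
subcommands is installed under `inst/scripts/paretosig.R`.

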