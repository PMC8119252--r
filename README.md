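# solifenet

Network psychometrics for binary questionnaire data, built around the
43-item short Oxford-Liverpool Inventory of Feelings and Experiences
(sO-LIFE), a yes/no schizotypy questionnaire with four a priori subscales:
Unusual Experiences (12 items), Cognitive Disorganisation (11), Impulsive
Nonconformity (10) and Introvertive Anhedonia (10). The package is for
researchers who want to model such item sets as a network — items as
nodes, conditional associations as edges — and ask whether data-driven
communities reproduce the questionnaire's subscale structure, which items
are central, and how stable all of it is.

## What it computes

Responses x ∈ {0,1}^p are modelled by an Ising model

    P(x) ∝ exp( Σᵢ τᵢ xᵢ + Σ_{i<j} J_ij xᵢ xⱼ ),

estimated nodewise ("eLasso"): each item is regressed on all others with
an ℓ1-penalised logistic regression, the penalty is chosen by the extended
BIC (EBIC = −2ℓ + k ln n + 2γk ln(p−1), default γ = 1), and an edge is
kept when both of its two regressions select it (AND rule), with weight
equal to the mean slope. On the estimated network the package provides:

* **Communities** — fast-greedy modularity maximisation on |J|, with
  partition agreement against the a priori subscales scored by normalised
  mutual information and optimal-matching percent overlap;
* **Centralities** — expected influence (Σⱼ J_ij), strength, closeness and
  betweenness on 1/|J| distances, and node predictability (correct
  classification from the estimated neighbourhood, raw and normalised);
* **Stability** — split-half Spearman correlations of the edge vector and
  a case-resampling bootstrap with quantile intervals and bootstrapped
  centrality-difference tests;
* **Community-level comparisons** — Kruskal–Wallis omnibus with
  Mann–Whitney post hocs and Cliff's Δ on centralities by community and on
  |edge weights| within/between communities (zero edges included);
* **A synthetic Ising generator** with four planted blocks (12/11/10/10),
  exact per-block sampling and threshold calibration to target endorsement
  rates, so every stage is verifiable against known ground truth;
* **Scoring utilities** — subscale sums, Table-style descriptives
  (mean/SD/median/IQR/skewness g1/excess kurtosis g2), KR-20/Cronbach α,
  and first-order partial correlations.

## Worked example

Run the full pipeline on generated data with known ground truth:

```r
library(solifenet)
report <- run_pipeline(generator = list(n = 5000),
                       config = pipeline_config(gamma = 1, n_splits = 5,
                                                seed = 1))
print(report)
```

```
== Network pipeline report ==
Network: 43 nodes, 162 edges (density 0.179)
Partition of 43 nodes into 4 communities (Q = 0.747)
Agreement with reference: overlap 100.0%, NMI 1.000 (4 vs 4 communities)
Split-half stability (5 splits, gamma = 1): median rho = 0.975, range 0.951-0.985
-- closeness by community --
Kruskal-Wallis chi-squared(3) = 13.43, p = 0.003798
Pairwise Mann-Whitney tests (run because omnibus p < 0.05 ):
     group_a     group_b  u       p cliffs_delta
 community_1 community_2 44 0.18576       -0.333
 community_1 community_3 12 0.00174       -0.800
 ...
-- betweenness by community --
Kruskal-Wallis chi-squared(3) = 0.78, p = 0.8534
No pairwise tests (omnibus not significant at 0.05 )
```

Reading it: the estimator found a sparse 43-node network whose fast-greedy
partition recovers the four planted blocks exactly (overlap 100%,
NMI = 1); half-sample networks correlate ρ ≈ 0.98 with the full-sample
network; and closeness differs across communities (the blocks were
calibrated to different endorsement-rate profiles) while betweenness and
expected influence do not.

For empirical data the entry point is the same, with a CSV and the shipped
item catalog supplying the subscale reference:

```r
cat43 <- load_catalog()
data  <- load_responses("responses.csv", catalog = cat43)
report <- run_pipeline(data = data, catalog = cat43,
                       config = pipeline_config(gamma = 1))
```

`run_pipeline(..., out_dir = "out")` writes the edge list, thresholds,
GraphML, partition and centrality CSVs and a JSON report. A thin CLI over
the same functions ships in `inst/scripts/solifenet-cli.R` (subcommands
`estimate`, `communities`, `centrality`, `stability`, `compare`,
`simulate`, `run-all`).

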