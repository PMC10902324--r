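# mlmod — multilayer network communities and persistence modules for rare-disease cohorts

`mlmod` implements a multilayer-network workflow for explaining phenotypic
severity in small patient cohorts. The motivating setting is a rare disease
(such as a congenital myasthenic syndrome) where all patients share one causal
mutation but split into severe and not-severe phenotypes, and the question is
whether group-specific genetic variants (compound-heterozygous variants,
CNVs) are *functionally related* to the known causal genes. Because such
cohorts are far too small for genome-wide statistics, the workflow leans on
public knowledge networks instead: several gene networks (protein–protein
interactions, shared pathways, shared metabolites) are stacked into a
multilayer network and clustered jointly, and the patient gene lists are
interpreted through the community structure.

## The model

Each layer `l` is an undirected weighted gene graph. A single partition `P`
of the union node set is scored by the resolution-parametrized multilayer
modularity

    Q(P; γ) = Σ_l Σ_{c ∈ P} [ w_c^(l) / W_l − γ · ( d_c^(l) / 2 W_l )² ]

where `w_c` is the intra-community edge weight, `d_c` the community degree,
`W_l` the layer's total weight and `γ > 0` the resolution: larger `γ`
penalizes large communities. `Q` is maximized by a seeded generalized
Louvain algorithm (local moves over all layers at once, then condensation,
repeated to convergence).

On top of a single partition, the package adds *persistence*: communities
are detected at a grid of resolutions (default `γ ∈ {0.5, 1, …, 4}`), and a
**module** is a set of genes of interest that share a community at `≥ n`
grid values (a connected component of the thresholded co-membership graph).
Significance machinery mirrors the study design:

* **catalog validation** — are known disease gene sets co-clustered more
  than size-matched random sets ("balanced" randomizations)?
* **label-shuffle null** — is the largest causal-anchored module of the
  severe (or not-severe) group larger than expected under random severity
  labels? Add-one permutation p-values, BH adjustment across candidate
  sizes, and the minimum significant module size.
* **clinical association** — two-tailed Fisher exact tests of severity
  against binary clinical variables.

Seeded generators (`simulate_multilayer`, `simulate_cohort`,
`simulate_catalog`) produce planted-partition multilayer networks and
synthetic cohorts/catalogs so the whole pipeline runs and is validated
without any external data.

## Worked example

```r
library(mlmod)

sim <- simulate_multilayer(seed = 11)      # 3 planted communities of 30, 3 layers
sim$network
#> <ml_network>  3 layers, 90 nodes in the universe
#>   L1                     90 nodes      387 edges  W = 387
#>   L2                     90 nodes      384 edges  W = 384
#>   L3                     90 nodes      422 edges  W = 422

sw <- sweep_resolutions(sim$network, seed = 5)
sw
#> <ml_sweep>  8 resolutions over 90 nodes
#>   gamma seed      Q communities
#> 1   0.5    5 2.3094           3
#> 2   1.0    6 1.8060           3
#> 3   1.5    7 1.3026           3
#> 4   2.0    8 0.7992           3
#> 5   2.5    9 0.4286           8
#> 6   3.0   10 0.2603          13
#> 7   3.5   11 0.1520          21
#> 8   4.0   12 0.0858          25
```

The three planted communities are recovered exactly up to `γ = 2`; at higher
resolution the modularity optimum legitimately splits them into smaller
blocks (see the methods vignette on the resolution limit). A synthetic
20-patient cohort (8 severe / 12 not-severe) plants severe-private variants
in community 1; the label-shuffle test finds the severe module and calibrates
the minimum significant size, while the not-severe group stays null:

```r
coh <- simulate_cohort(sim$truth, seed = 7)
ms <- module_size_significance(sw, coh$cohort, coh$causal,
                               n = 4, R = 200, seed = 13)
ms
#> <ml_module_significance>
#>   severe     observed anchored module size 10, p = 0.004975, k_min = 9
#>   not_severe observed anchored module size 7, p = 0.9502, k_min = none
```

Here `p` is the add-one label-shuffle p-value of the observed largest
causal-anchored module, and `k_min = 9` is the smallest module size that
random severity labels are not expected to produce (BH-adjusted at
α = 0.05).

The clinical-association helper reproduces the kind of cohort-table test
used for treatment variables — for a cohort of 8 severe patients (4
treated) and 12 not-severe patients (9 treated):

```r
fisher_exact_2x2(matrix(c(4, 4, 9, 3), 2, byrow = TRUE))
#> [1] 0.3563467
```

A full configuration-driven run (layers + cohort + catalog from files,
all reports as JSON/TSV) is available through `simulate_workspace()` /
`run_pipeline()`, or from the shell via the thin CLI in `inst/cli/mlmod.R`
(subcommands `simulate`, `detect`, `sweep`, `modules`, `validate-catalog`,
`validate-cohort`, `assoc`, `similarity`, `pipeline`).

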