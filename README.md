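# taacgh — topological association analysis of copy-number profiles

`taacgh` detects copy-number aberrations associated with a phenotype (e.g. a
breast-cancer molecular subtype) in aCGH-style log2-ratio profiles, using
topological signatures instead of per-probe cutoffs. It is aimed at
statistical-genomics analysts working with probe-by-patient copy-number
matrices who want a multiscale association test and a compact set of
per-patient predictors for subtype classification.

## Method

Each chromosome arm is cut into consecutive segments of 20 probes
(overlapping by 10). For a fixed segment, each patient's ordered values
`x_1, ..., x_20` are embedded as the sliding-window point cloud
`{(x_i, x_{i+1})} ⊂ R²`, and the Vietoris–Rips filtration of the cloud
(simplex filtration value = largest pairwise vertex distance) is summarised
by its persistence diagram `D = {(b, d)}`. Three curve summaries are
supported, all evaluated on a shared filtration grid and using reduced
homology in dimension 0:

* **Betti curve** `β(t) = #{(b,d) ∈ D : t ∈ (b, d]}`
* **lifespan curve** `ℓ(t) = Σ {(d − b) : t ∈ (b, d]}`
* **persistence landscape** `λ(k, t)` = k-th largest value of
  `[min(t − b, d − t)]₊`

The segment statistic is the L2 norm of the difference between the average
test-group and control-group curves; significance comes from a label
permutation test, with Benjamini–Hochberg FDR control across all segments.
Significant, maximally non-intersecting segments yield per-patient binary
indicators (leave-one-out curve-similarity for segments, Student-t
center-of-mass intervals for whole arms) that feed a forward-selection
logistic classifier under AIC, evaluated by confusion matrices and
leave-one-out cross-validation.

The package also ships the simulation engine used to benchmark the curves
(single contiguous aberrations of mean μ, sd σ, length λ and penetrance MIX
in 60/60-patient cohorts) and exact calculators for bottleneck-distance
stability bounds on Betti and lifespan curves, with a brute-force
clique-complex oracle and perturbation experiments that verify the bounds
numerically.

## Worked example

```r
library(taacgh)

## a simulated cohort: 60 test patients carrying a 10-probe gain
## (mean 1, sd 0.2) on a 20-probe segment, 60 pure-noise controls
cfg <- simConfig(mu = 1, sigma = 0.2, lambda = 10, mix = 1, nSims = 1)
cohort <- simulateCohort(cfg, seed = 1)

res <- runTAaCGH(cohort, "Test", kind = "lifespan", nPerm = 199, seed = 1)
res[, c("Name", "Statistic", "P", "Q", "Significant")]
#>   Name Statistic     P    Q Significant
#> 1 1qs1  17.73965 0.005 0.005        TRUE
```

The single 20-probe segment (`1qs1`) is flagged: the lifespan curves of the
aberrant group sit far from the control average (L2 statistic 17.7), no
permutation reached the observed statistic (p = 1/200 with add-one
smoothing), and the segment survives FDR. On a pure-noise cohort
(`mu = 0`) the same call leaves `Significant` FALSE.

Nearest-mean patient classification on the same condition reproduces the
benchmark operating characteristics:

```r
runClassificationExperiment(simConfig(mu = 1, sigma = 0.2, lambda = 10,
                                      mix = 1, nSims = 50),
                            kind = "lifespan", seed = 20)
#>   mu sigma lambda mix nSims Sensitivity Specificity
#> 1  1   0.2     10   1    50   0.9876667           1
```

i.e. 98.8% average sensitivity and 100% specificity over 50 cohorts.

A command-line wrapper for the main workflows is in
`inst/cli/taacgh.R` (subcommands `simulate`, `assoc`, `classify`,
`bounds-check`).

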