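# prefilterBench

Benchmarking what pre-filters buy you before sparse feature selection on
paired mRNA/microRNA two-class expression studies.

## The problem

Case-control expression studies measure far more features than samples
(in the motivating hypertrophic-cardiomyopathy study: 18,756 genes and
819 mature microRNAs on 106 patients and 20 controls). Embedded feature
selection such as L1-penalized logistic regression works better and
faster if the feature space is cut down first, either **statistically**
(keep differentially expressed features, two-sample t-test at p ≤ 0.05)
or **biologically** (keep genes annotated to functional terms enriched in
a list of known disease genes, or microRNAs with a validated target among
those genes), or both. This package builds the four canonical dataset
types per layer —

| type | filter |
|---|---|
| 1 | none (all measured features) |
| 2 | t-test, p ≤ α |
| 3 | disease-knowledge (term enrichment / target map) |
| 4 | intersection of 2 and 3 |

— with one type-3/4 variant per term collection (BP, MF, CC, Pathway)
for mRNA, giving 10 mRNA + 4 microRNA datasets, and evaluates each with
the same machinery: L1 logistic selection, stratified 5-fold
cross-validated AUC and precision on pooled held-out scores, percent
feature reduction, cross-dataset overlap, and enriched-term coverage.

The core pieces are implemented in the package: the enrichment test is
the hypergeometric upper tail
P(X ≥ n) with explicit background universe; the selector minimizes
L(w, b) + λ‖w‖₁ (mean logistic log-loss, unpenalized intercept) by
monotone FISTA with backtracking and KKT-based convergence, with λ chosen
by inner cross-validation from λ_max downward; AUC is the midrank
estimator (ties count one half). A seeded generator of synthetic paired
studies with planted differential signal, disease-biased term
collections, seed lists and target maps makes the whole pipeline runnable
and testable with no external data. See the vignette in `vignettes/` for
the models, conventions and numerical choices.

## Worked example

```r
library(prefilterBench)

study <- simulateStudy(simulationConfig(rngSeed = 42))
study
#> SyntheticStudy: 500 genes, 60 microRNAs, 60 paired samples
#>   classes: control=30, case=30
#>   collections: BP, MF, CC, Pathway
#>   seed genes: 40; target pairs: 300
#>   planted: 50 DE genes, 9 DE microRNAs

ds <- buildAll(study = study)      # the 14 pre-filtered datasets
ds$mrna.type2
#> FilteredDataset type2: 75 features x 60 samples
#>   classes: control=30, case=30
#>   filter: Welch t-test p <= 0.05 (500 -> 75)

percentReduction(nrow(ds$mrna.type1), nrow(ds$mrna.type2))
#> [1] 85

sel <- selectFeatures(ds$mrna.type2, solverConfig(seed = 42))
sel
#> SelectionResult for type2: 35 features at lambda = 0.000353
#>   warning: fit did not converge

cv <- crossValidate(ds$mrna.type2, solverConfig(seed = 42), k = 5, seed = 42)
sprintf("pooled CV AUC %.3f, precision %.3f", cv$auc, cv$precision)
#> [1] "pooled CV AUC 1.000, precision 1.000"

mean(study@truth$deGenes %in% rownames(ds$mrna.type2))  # planted recall
#> [1] 1
```

Reading the numbers: the t-filter kept 75 of 500 genes (85% reduction)
while retaining all 50 planted differential genes; the L1 fit on the
filtered data selects 35 features and classifies the held-out samples
perfectly (this synthetic study, with a 1.5-sd planted shift across 50
genes, is an easy problem by design). The inner cross-validation here
chose the smallest penalty on its grid, where the near-separable fit hits
the iteration cap — the selection is still returned and the
non-convergence is flagged rather than hidden.

For the end-to-end comparison across all 14 datasets use
`runPipeline()`, and `renderReport()` to write the per-dataset table
(raw variables / selected features / reduction / AUC / precision / time),
the overlap section and the term-coverage section as TSV, JSON or
markdown.

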