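# contactImpute

Imputation of missing 3D chromatin contact maps by deep tensor
factorization.

## The problem

Chromosome-conformation assays — dilution Hi-C, in situ Hi-C, micro-C,
DNase Hi-C, ChIA-PET, PLAC-seq, DNA SPRITE — each produce, for a given
biosample (cell line or tissue), a *contact map*: a symmetric matrix of
contact counts between pairs of fixed-width genomic bins. Arranging all
experiments into a biosample-by-assay grid, most cells are empty: running
every assay in every biosample is infeasible. `contactImpute` predicts
those unobserved contact maps from the observed ones, so that analyses
that need complete grids — systematic comparison of biosamples, of
assays, and clustering of either — become possible.

The package is aimed at computational genomicists who already have
binned contact matrices (dense or sparse bin-pair text formats) and a
manifest describing which (biosample, assay) combination each belongs
to.

## The model

Every contact-map entry is indexed by four coordinates: biosample `b`,
assay `a`, and two genomic bins `i`, `j`. The model learns an embedding
vector for each biosample (16 factors by default), each assay (128),
each genomic bin (128), and each bin-pair separation `|i - j|` (128).
For a query `(b, a, i, j)` the four relevant rows (position rows for
both `i` and `j`) are concatenated and passed through a multilayer
perceptron (4 hidden layers of 256 rectified-linear units, dropout 0.4)
whose single linear output is the predicted normalized contact value:

```
ŷ(b, a, i, j) = MLP([ E_bio[b], E_assay[a], E_pos[min(i,j)], E_pos[max(i,j)], E_dist[|i-j|] ])
```

Queries are canonicalized to `min(i, j), max(i, j)` before lookup, so
predictions are exactly symmetric in the two positions; whole-map
predictions are reflected across the diagonal. Training minimizes mean
squared error with Adam (initial learning rate 1e-4) on batches of
randomly sampled off-diagonal entries of the training maps; after each
epoch the full validation MSE is computed and the best-validation epoch
is kept.

Before modeling, each map is normalized the same way: `log(x + 1)`
transform; removal of bins whose marginal count deviates from the
median by more than 10 median absolute deviations in any *training* map
(the same mask is applied to validation/test maps, avoiding leakage);
and scaling so each map's entries sum to 1e5, removing read-depth
differences.

Mean baselines (`rowMeanImpute`, `columnMeanImpute`, `crossMeanImpute` —
averages over maps sharing the assay, the biosample, or either),
contact-map summaries (contact decay profile, compartment eigenvector,
insulation score), per-distance correlations, entity-correlation
matrices with hierarchical clustering, and a synthetic grid generator
with planted decay/compartment/TAD/interaction structure complete the
workflow.

## Worked example

```r
library(contactImpute)

# synthetic 6 biosamples x 5 assays x 120 bins grid, 30% of cells hidden
acc   <- generateAcceptanceGrid(seed = 1)
split <- splitExperiments(acc$observed, seed = acc$splitSeed)
prep  <- preprocessGrid(acc$observed, split)

model <- trainContactModel(prep$grid, split,
                           defaultHyperparams(epochs = 15L,
                                              batchSize = 2000L,
                                              batchesPerEpoch = 100L,
                                              patience = 5L),
                           seed = 1001)
model
#> ContactModel (mlp): 6 biosamples x 5 assays, 120 bins
#>   factors: 16/128/128/128 (biosample/assay/position/distance)
#>   MLP: 4 x 256 units, dropout 0.4, lr 1e-04
#>   trained: best epoch 3, validation MSE 7.955745

# compare against the cross-mean baseline on the validation maps
v <- split[split$split == "validation", ]
round(sapply(seq_len(nrow(v)), function(r) {
  obs <- mapAt(prep$grid, v$biosample[r], v$assay[r])
  c(model = mapMSE(predictContactMap(model, v$biosample[r], v$assay[r],
                                     template = obs), obs),
    cross = mapMSE(crossMeanImpute(prep$grid, v$biosample[r],
                                   v$assay[r], split = split), obs))
}), 2)
#>       [,1] [,2] [,3]  [,4]  [,5]
#> model 6.48 4.44 5.96 16.46  6.43
#> cross 5.71 2.66 2.63 18.67 16.33
```

On this grid the trained model reaches a mean validation MSE of 7.96
versus 9.20 for the cross-mean baseline (13.5% lower): the model
recovers biosample-specific distance decay and compartment structure
that the averaging baselines blur. An imputed-complete grid for
downstream comparison is one call away:

```r
full <- completeGrid(prep$grid, method = "model", model = model)
corr <- entityCorrelation(full, axis = "assay", feature = "decay")
plot(clusterEntities(corr))
```

A command-line wrapper over the same functions (subcommands `simulate`,
`preprocess`, `split`, `train`, `search`, `impute`, `features`,
`evaluate`, `compare`) is installed at
`system.file("scripts", "contact-impute.R", package = "contactImpute")`.

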