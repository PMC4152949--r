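# psedhs

Sequence-based prediction of DNase I hypersensitive sites (DHS).

DHS are nucleosome-depleted chromatin regions that mark regulatory DNA —
promoters, enhancers, insulators, silencers. Mapping them computationally
from bare sequence is attractive because DHS show little primary-sequence
conservation but do differ in dinucleotide usage (enrichment of CC, CG, GC,
GG steps) and in the local DNA geometry those steps imply. `psedhs` is for
computational genomicists who want that classifier as a reproducible,
scriptable pipeline: encoding, redundancy filtering, model selection,
evaluation and simulation in one package.

## The method

Each sequence `R_1 ... R_L` becomes a **pseudo dinucleotide composition
(PseDNC)** vector of dimension `16 + λ`:

```
d_u = f_u / (1 + w Σ_j θ_j)            u = 1..16
d_u = w θ_{u-16} / (1 + w Σ_j θ_j)     u = 17..16+λ
```

with `f_u` the 16 overlapping dinucleotide frequencies and

```
θ_j = (1/(L-1-j)) Σ_i Θ(R_i R_{i+1}, R_{i+j} R_{i+j+1})
```

the j-tier structural correlation factors, where `Θ(x, y)` is the mean
squared difference of six standardized dinucleotide structural properties
(twist, tilt, roll, shift, slide, rise). An RBF-kernel SVM
(`K(x,y) = exp(-γ‖x−y‖²)`, libsvm via e1071) classifies the vectors; the
four parameters `(w, λ, C, γ)` are optimized jointly by stratified 5-fold
cross-validated grid search, and models are assessed by the jackknife
(leave-one-out) protocol with Sn, Sp, Acc and MCC. Training sets are
de-redundated by greedy clustering at a pairwise-identity threshold
(default 0.6). A first-order Markov simulator generates two-class sequence
sets whose positive class is enriched in CC/CG/GC/GG steps, so the whole
pipeline is testable without downloads.

Note: the bundled structural-property table is a clearly labelled
*synthetic stand-in* in realistic crystallographic ranges
(`inst/extdata/dinucleotide_properties_synthetic.tsv`); supply a published
table via `read_property_table()` to reproduce published numbers. See the
methods vignette (`vignettes/dhs-psednc-methods.Rmd`) for the model,
numerical choices and known limitations.

## Worked example

```r
library(psedhs)

train <- simulate_dhs_dataset(n_pos = 60, n_neg = 60, delta = 1.5,
                              length_min = 200, length_max = 300, seed = 42)
train
#> <dhs_dataset 'simulated (delta = 1.5, seed = 42)'> 120 sequence(s): positive=60, negative=60; lengths 201-300

params <- model_params(w = 0.2, lambda = 6, C = 512, gamma = 2^-7)
jackknife(train, params)
#> <dhs_metrics> protocol: jackknife
#>   TP = 60  FN = 0  TN = 60  FP = 0
#>   Sn = 100.00%  Sp = 100.00%  Acc = 100.00%  MCC = 1.00

enc   <- encode_dataset(train, w = params$w, lambda = params$lambda)
model <- svm_train(enc$features, enc$labels, params$C, params$gamma)
new   <- simulate_dhs_dataset(n_pos = 3, n_neg = 3, delta = 1.5, seed = 7)
predict(model, encode_dataset(new, 0.2, 6)$features)
#>         label decision_value
#> pos1 positive      0.9951432
#> pos2 positive      0.6954938
#> pos3 positive      0.8835934
#> neg1 negative     -1.0234904
#> neg2 negative     -0.8108036
#> neg3 negative     -0.9081611
```

The jackknife report counts each sequence's held-out call: `Sn` is the
fraction of true DHS recovered, `Sp` the fraction of non-DHS recognized,
`Acc` overall accuracy and `MCC` the balanced correlation of calls with
truth (1 = perfect, 0 = chance). At this simulated contrast (`delta = 1.5`,
a strong CC/CG/GC/GG enrichment) the problem is fully separable, hence the
perfect report; decision values give the signed margin distance from the separating
surface (positive favors DHS).

A command-line front end wraps the same functions
(`inst/cli/psedhs.R`: `simulate`, `filter`, `encode`, `gridsearch`,
`train`, `evaluate`, `predict`), e.g.

```sh
Rscript inst/cli/psedhs.R simulate --n-pos 200 --n-neg 200 --delta 1 \
    --seed 0 --out-pos pos.fa --out-neg neg.fa
Rscript inst/cli/psedhs.R evaluate --pos pos.fa --neg neg.fa \
    --protocol jackknife --w 0.2 --lambda 6 --C 512 --gamma 0.0078125 \
    --out report.json
```

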