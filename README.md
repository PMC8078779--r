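# omixaug

GAN-based sample augmentation for cancer-stage classification from paired
DNA-mutation / mRNA-expression cohorts.

## The problem

Tumour cohorts with matched mutation and expression profiles and complete
pathologic staging (I–IV) are small and badly imbalanced — often a few dozen
samples against ~20,000 genes, with minority stages contributing as few as a
dozen cases. Classifiers trained on such data overfit and ignore minority
stages. `omixaug` implements a pipeline for this setting, aimed at
computational biologists who want to train stage classifiers (or benchmark
augmentation strategies) on small multi-omics cohorts:

1. **Mutation-guided gene selection.** A random forest predicts stage from
   the binary mutation matrix; each gene's Gini importance is tested against
   a stage-label permutation null, and genes with permutation p-value
   p < 0.004 (the default gate) are kept. Formally, for gene g with observed
   importance I_g and B permutation refits,
   p_g = (1 + #{b : I_g^(b) ≥ I_g}) / (1 + B).
2. **Batch correction** of the selected-gene expression matrix with
   parametric empirical-Bayes ComBat.
3. **Per-stage GAN augmentation.** For each stage s, a generator
   G_s : R^m → R^m (one 256-unit hidden layer) is trained adversarially
   against a discriminator on that stage's training expression. Latent
   vectors are drawn coordinate-wise from N(μ_g, σ_g) — the per-gene mean and
   SD of the training data — rather than a standard normal. Augmentation at
   fold k emits exactly k·n_s synthetic samples per stage, conserving the
   stage ratio.
4. **Classification and evaluation.** A 1-D CNN (conv 20→40 filters,
   kernel 5, pool 2, dense 64, softmax), a DNN (64/32/4 ReLU, softmax) and a
   random forest (100 trees, seed 123456) behind one interface, evaluated by
   repeated stratified 70/30 splits with accuracy and macro-F1, Welch
   t-tests, PCA diagnostics, subsampling and fold-sweep experiments.

Baseline augmenters are included for comparison: per-stage Gaussian sampling
with halved SD (**MS**), **SMOTE** to the majority-stage count, and a
denoising-autoencoder expansion (**DA**) that turns n samples with m genes
into n·⌊m/5⌋ + n via window-corrupted reconstructions.

A synthetic cohort simulator with planted, tunable stage signal
(`make_synthetic_cohort()`) makes the whole pipeline testable without any
external data.

## Worked example

```r
library(omixaug)

# a synthetic cohort: 60 samples per stage, 100 genes, 25 informative
syn    <- make_synthetic_cohort(synthetic_config(n_genes = 100,
                                                 n_informative = 25, seed = 1))
cohort <- syn$cohort

# mutation-guided gene selection at p < 0.004
ranking <- permutation_pvalues(cohort$mutation, cohort$stages,
                               fs_config(n_permutations = 300, seed = 1))
genes   <- select_features(ranking, p_threshold = 0.004)
length(genes)
#> [1] 16

# original data vs selected genes vs 5-fold GAN augmentation, 1D-CNN
cfg <- experiment_config(variants = c("Ori", "FS", "GAN5"),
                         classifiers = "1DCNN", repeats = 3, base_seed = 1,
                         gan = gan_config(epochs = 100),
                         cnn = cnn_config(epochs = 100))
res <- run_experiment(cohort, cfg, selected_genes = genes)
summarize_results(res)
#>   variant classifier n accuracy_mean accuracy_sd macro_f1_mean macro_f1_sd
#> 1      FS      1DCNN 3         0.880      0.0212         0.879      0.0220
#> 2    GAN5      1DCNN 3         0.894      0.0289         0.893      0.0300
#> 3     Ori      1DCNN 3         0.829      0.0212         0.827      0.0191

compare_ttest(res$accuracy[res$variant == "GAN5"],
              res$accuracy[res$variant == "Ori"])
#> [1] 0.0396
```

Reading the output: `Ori` trains on all 100 genes and plateaus at 0.83 mean
accuracy over three repeated 70/30 splits; restricting to the 16
mutation-selected genes (`FS`) lifts it to 0.88; training the CNN on 5×
GAN-generated samples (`GAN5`, stage ratios preserved) reaches 0.89 with the
difference to `Ori` significant at p ≈ 0.04 (Welch). Macro-F1 tracks
accuracy because the cohort is balanced; on imbalanced cohorts
(`stage_counts = c(12, 24, 29, 12)`) the two diverge and macro-F1 is the
metric to watch.

A command-line interface covering the same steps
(`synth`, `prepare`, `select`, `normalize`, `augment`, `experiment`) ships at
`inst/cli/omixaug.R`:

```sh
Rscript inst/cli/omixaug.R synth --preset read-like --seed 1 --out cohort/
Rscript inst/cli/omixaug.R augment --split-cohort cohort/ --method gan --fold 5 --seed 1 --out aug/
```

## Scope notes

Mutation input is a pre-binarised gene-level matrix (MAF/VCF parsing is out
of scope); stage labels are mapped from Roman/Arabic/"Stage X" forms; the
simulator does not attempt realistic RNA-seq count distributions. See the
methods vignette (`vignettes/methods.Rmd`) for the full model description,
numerical choices and limitations.
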