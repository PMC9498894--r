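# motifconv

Interpretable convolutional regression of DNA sequence activity.

## The problem

Massively parallel reporter assays (MPRA) measure the enhancer activity of
thousands of candidate DNA sequences at once. Convolutional neural
networks fit such data well, but their kernels are arbitrary real
matrices, so discovering *which sequence motifs drive activity* normally
requires a separate post hoc interpretation pipeline with its own tuning
parameters.

`motifconv` removes that step by construction. Every first-layer kernel is
constrained — through a temperature-α softmax applied position-wise to a
free weight matrix `X` —

    T[i,j] = exp(α·X[i,j]) / Σ_j' exp(α·X[i,j'])

to be a row-stochastic `L×4` matrix: a position weight matrix (PWM) in the
field's standard sense. The convolution scores every window `s` of a
sequence by the background-corrected log-likelihood ratio

    LLR(s) = Σ_i Σ_j ln(T[i,j] / B[j]) · s[i,j]

against a genomic base composition `B` (default A 0.295, C 0.205, G 0.205,
T 0.295). Both strands are scanned with shared kernels and pooled jointly,
one value per filter, followed by dropout and a single-node linear head —
so each motif pairs with exactly one dense weight, whose sign reads out as
candidate **activator** (+) or **repressor** (−). Trained kernels can be
exported in MEME minimal format and searched against motif databases
(HOCOMOCO etc.) with external tools such as Tomtom, or used to scan any
new sequence set.

The package includes: the full training stack (Adam, glorot init, L2,
dropout, early stopping — implemented in vectorized base R, no deep
learning framework required), 10-fold cross-validation with 81/9/10
train/validation/test splits scored by Spearman correlation, a grid
search, a conventional-CNN baseline, information-content (ICP) analytics
with a Welch one-sided test against reference motif sets, a synthetic MPRA
generator with planted motifs, and a CLI.

## Worked example

Recover planted motifs from synthetic data (defaults plant one activator,
weight +1, and one repressor, weight −1, in sequences drawn from the
genomic background):

```r
library(motifconv)

sim  <- simulate_mpra(simulation_spec(n_sequences = 600, seq_length = 100, seed = 1))
sim$data
#> <mpra_dataset> 600 sequences of length 100; activity range [-18.2, 17.5]

fold <- make_folds(sim$data, k = 10, seed = 1)[[1]]   # 81/9/10 split
cfg  <- model_config(n_filters = 4, filter_length = 12, max_epochs = 40, seed = 2)
fit  <- train_model(build_multinom_cnn(cfg),
                    motifconv:::subset_dataset(sim$data, fold$train_ids),
                    motifconv:::subset_dataset(sim$data, fold$validation_ids))
fit
#> <multinom_cnn> 4 multinomial kernels of length 12 (alpha 120), trained (best epoch 15)

test <- motifconv:::subset_dataset(sim$data, fold$test_ids)
spearman_cor(test$activities, predict(fit, test))
#> [1] 0.888

motifs <- extract_motifs(fit)
recovery_report(sim$truth, motifs)[, c("true_motif", "best_learned",
                                       "correlation", "learned_weight", "sign_match")]
#>   true_motif best_learned correlation learned_weight sign_match
#> 1  activator   filter_003   0.9973800      0.1271131       TRUE
#> 2  repressor   filter_004   0.9065714     -0.5889949       TRUE

motifs[[3]]
#> <motif> filter_003: length 12, activator, weight 0.1271

round(vapply(motifs, icp, 0), 3)   # specificity, bits per position
#> [1] 0.064 0.040 1.158 0.093
```

The held-out Spearman correlation of 0.888 says the model ranks unseen
sequences' activities almost as the ground truth does; the recovery table
shows each planted motif matched by a learned kernel (flattened-PWM
Pearson correlation 0.997 and 0.907) with the correct regulatory sign;
the ICP column shows which filters learned specific motifs (1.16
bits/position) versus near-background ones.

Export and database comparison:

```r
write_meme(motifs, "motifs.meme")            # -> Tomtom / FIMO etc.
ref <- read_meme("motifs.meme")              # or e.g. a HOCOMOCO MEME file
compare_icp(ref, motifs)                     # Welch test: reference < learned?
```

## Command line

```sh
Rscript inst/cli/motifconv simulate --out runs/sim --seed 1
Rscript inst/cli/motifconv train    --data runs/sim/activity_table.tsv --out runs/fit --seed 1
Rscript inst/cli/motifconv cv      --data runs/sim/activity_table.tsv --out runs/cv --folds 10
Rscript inst/cli/motifconv extract --checkpoint runs/fit/checkpoint.json --out runs/motifs
Rscript inst/cli/motifconv scan    --motifs runs/motifs/motifs.meme --fasta query.fa --out runs/hits
```

Every run writes a `manifest.json` and a `run.log` and is deterministic
given `--seed`.

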