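# mdassoc

Microbe–drug association prediction from bipartite interaction profiles.

## The problem

Curated databases record thousands of experimentally confirmed
interactions between drugs and microbes, but testing every remaining
pair in the laboratory is infeasible. Arranged as a binary adjacency
matrix `S` (`Nr` drugs × `Nm` microbes, `S[i,j] = 1` for a known
association), the known interactions define a sparse bipartite network,
and candidate discovery becomes link prediction on it: rank the unknown
cells so that true associations come first. `mdassoc` is for
computational biologists who want a self-contained, seeded, testable
implementation of a feature-fusion scorer for this task, including the
cross-validation and ablation machinery needed to evaluate it honestly.

## The method

Two kinds of node feature are extracted and fused:

1. **Inter-node features.** Gaussian interaction-profile kernel
   similarities `Gr(i,j) = exp(−μ‖Rs(i) − Rs(j)‖²)` (bandwidth
   `μ = 1 / mean‖Rs(i)‖²`; rows `Rs` for drugs, columns for microbes)
   are column-normalized into a transition matrix `M`, and a restart
   random walk `q ← λMq + (1−λ)e` (default `λ = 0.1`) is iterated to its
   fixed point `q_i = (1−λ)(I−λM)⁻¹e_i`, giving diffusion-profile
   matrices `DR` (drugs) and `MR` (microbes).
2. **Attribute features.** Cosine profile similarity plus optional
   external drug-structural (`Sr`) and microbe-functional (`Fm`)
   similarity matrices each train an independent stacked autoencoder
   (widths 128/64/32, greedy layer-wise pretraining then end-to-end Adam
   fine-tuning of the reconstruction loss `‖X − X′‖²`), whose output
   layer is enhanced by multi-head self-attention over nodes (default 4
   heads, residual connection). The post-attention reconstructions
   `SAEr1, SAEr2, SAEm1, SAEm2` are the attribute features.

Features are concatenated with adjacency copies into integrated
matrices

```
IFMr = [DR | S | SAEr1 | S | SAEr2 | S]        (Nr × 3(Nr+Nm))
IFMm = [Sᵀ | MR | Sᵀ | SAEm1 | Sᵀ | SAEm2]     (Nm × 3(Nr+Nm))
```

and every pair is scored as `Score = logistic(IFMr · IFMmᵀ)`. Ranking
uses the raw logits (identical ordering; the logistic saturates in
double precision at this column count).

The package also ships a k-fold cross-validation harness with
leakage-safe per-fold recomputation of all features from the
training-masked adjacency, a paired attention ablation, a learning-rate ×
heads hyperparameter sweep, and a seeded synthetic generator that plants
co-cluster structure so the whole pipeline is testable without any
download. See the vignette (`vignettes/microbe-drug-prediction.Rmd`) for
the full model account.

## Worked example

```r
library(mdassoc)
options(mdassoc.verbose = FALSE)

# a seeded synthetic benchmark: 60 drugs x 30 microbes, 3 planted co-clusters
gen <- generate_synthetic(synthetic_spec(n_drugs = 60, n_microbes = 30,
                                         n_blocks = 3, seed = 7))
print(gen$dataset)
#> <mda_dataset> 60 drugs x 30 microbes, 205 known associations

# external similarity stand-ins derived from the planted blocks
ext <- make_external_similarities(gen$drug_blocks, gen$microbe_blocks,
                                  reliability = 0.9, seed = 8)

# 5-fold cross-validation of the full pipeline
cv <- run_cv(gen$dataset,
             pipeline_config(sae = sae_config(hidden_sizes = c(32, 16),
                                              heads = 2, epochs = 60,
                                              pretrain_epochs = 15)),
             cv_config(k = 5, seed = 1), Sr = ext$Sr, Fm = ext$Fm)
print(cv)
#> <mda_cv_result> 5-fold: AUC 0.8355 +/- 0.0100 (5 fold runs)

# score every pair on the full data and list the top novel candidates
res <- run_pipeline(list(
  input = list(synthetic = list(n_drugs = 60, n_microbes = 30,
                                n_blocks = 3, seed = 7)),
  seed = 11,
  sae = list(hidden_sizes = c(32, 16), heads = 2,
             epochs = 60, pretrain_epochs = 15),
  run_cv = FALSE, out_dir = NULL))
head(res$ranked[, c("drug", "microbe", "logit", "rank")], 5)
#>     drug   microbe    logit rank
#> 1 drug21 microbe01 13.74593    1
#> 2 drug43 microbe04 12.28892    2
#> 3 drug21 microbe19 12.27035    3
#> 4 drug39 microbe02 11.60248    4
#> 5 drug57 microbe29 11.33439    5
```

The cross-validated AUC is the probability that a held-out true
association outranks a random unknown pair; 0.84 on this small benchmark
means the pipeline recovers most of the planted co-cluster signal from
the masked training data alone. The ranked list contains only pairs
*not* already known, ordered by logit — these are the candidates one
would take forward.

To run on real data instead, point the config at a two-column
(drug, microbe) TSV/CSV and optional labeled square similarity CSVs:

```r
run_pipeline(list(input = list(associations = "associations.tsv"),
                  drug_structural_csv = "sr.csv",      # optional
                  microbe_functional_csv = "fm.csv",   # optional
                  seed = 42, ablation = TRUE, out_dir = "out/"))
```

A thin command-line wrapper covers the same stages:

```sh
exec/mdassoc simulate --drugs 200 --microbes 60 --blocks 4 --seed 7 --out sim/
exec/mdassoc similarity --associations sim/associations.tsv --measure gaussian --entity drug --out gr.csv
exec/mdassoc cv --config run.yaml --k 5 --out out/
```

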