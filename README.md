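# scsemivae

Semisupervised zero-inflated negative binomial variational autoencoders
for single-cell RNA-seq, with CITE-seq surface proteins as the
supervision signal.

## The problem

Single-cell RNA-seq counts are plagued by dropout: inefficient mRNA
capture turns truly expressed genes into zeros, which corrupts both
imputation and the low-dimensional cell-state representations that
downstream analyses rely on.  CITE-seq experiments measure
antibody-derived tag (ADT) counts for a panel of surface proteins in
the same cells, and those measurements are largely dropout-free.
`scsemivae` uses them as *biological augmentation*: protein levels,
available for some or all cells, constrain the latent space of a count
VAE so that imputed expression and latent codes become more
biologically faithful — while requiring **no** protein input at
inference time.

The package targets computational biologists who want a dependency-light,
fully reproducible R implementation: model, gating, benchmark, metrics
and data generator are all here, with analytic gradients (no deep
learning framework required).

## The model

Counts `x_i` for cell `i` are modeled through a latent code
`z_i ∈ R^d` with prior `z ~ N(0, I)`:

```
q(z | x)  = N(mu(x), diag(sigma^2(x)))          (encoder)
x_j | z   ~ ZINB(mu_j(z), theta_j, pi_j(z))     (gene head)
y_p | z   ~ Bernoulli(p_p(z))  or  NB           (label head)
```

The encoder and a shared decoder trunk are dense networks (default 2
layers x 128 units, 32 latent units); the gene and label heads are
linear projections of the trunk.  `theta_j` is a free per-gene inverse
dispersion.  Training minimizes

```
L = -ELBO(x) + gamma * L_y
```

where `L_y` is the label negative log-likelihood averaged over labeled
cells only and `gamma` (default 20) sets the importance of the
supervised task.  `gamma = 0` recovers the unsupervised count VAE.

Raw ADT counts are converted to supervision targets by a per-protein
two-component Gaussian mixture on `log1p` counts: the posterior
probability of the high-abundance component ("probabilized" labels in
`[0,1]`) feeds the Bernoulli head, and can be thresholded into binary
presence/absence calls.

A binomial corruption benchmark (25% of entries replaced by
`Binomial(n, 0.2)` draws), an evaluation battery (marker gene/protein
Pearson+Spearman correlation, latent-space classifier F1, pooled
ARI/NMI/silhouette/UCA clustering score, importance-weighted marginal
log-likelihood) and a ground-truth synthetic CITE-seq generator round
out the toolkit.

## Worked example

```r
library(scsemivae)

sim  <- simulate_citeseq(sim_spec(seed = 101))      # 500 x 100, 3 types
plab <- probabilize_proteins(sim$proteins)          # GMM gating
split <- split_train_test(sim$counts$cell_ids, 0.9, seed = 101)

model <- scvae_model(n_genes = 100, n_proteins = 5, seed = 1)
model <- fit_scvae(model, subset_cells(sim$counts, cells = split$train),
                   labels = plab,
                   training = training_config(gamma = 20, max_epochs = 100,
                                              patience = Inf, seed = 1))

den <- impute(model, sim$counts)                    # denoised expression
marker_correlation(den, clr_normalize(sim$proteins), sim$pairs)$score
#> [1] 0.749995
clustering_score(encode(model, sim$counts), sim$labels, seed = 1)$pooled
#> [1] 0.9362454
```

The marker score is the mean over the five designated marker
gene/protein pairs of the Pearson and Spearman correlations between
denoised marker expression and the CLR-normalized protein level.  The
pooled clustering score is the mean of ARI, NMI, rescaled silhouette
and UCA against the true cell types, in `[0,1]`.  For comparison,
`scripts/acceptance.R` computes the same two quantities as medians
over five seeds for `gamma = 20` and `gamma = 0`: at seed 1 they come
out 0.76 vs 0.37 (marker correlation) and 0.92 vs 0.77 (pooled
clustering) — the protein supervision restores the marker signal that
dropout destroys and sharpens the type structure of the latent
space.

The same pipeline is scriptable from a shell via the installed
`scsemivae` executable (`simulate`, `fit-gmm`, `train`, `impute`,
`predict`, `evaluate`, `benchmark` subcommands); every run writes a
manifest with its resolved options and seed.

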