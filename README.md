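# pairdecon

Joint deconvolution and purification of paired bulk multi-omics data.

## The problem

Bulk molecular profiles are mixtures over cellular subpopulations. When the
same tissues are profiled in two modalities — bulk RNA-seq paired with
ATAC-seq, DNA methylation or mass-spectrometry proteomics — both profiles
share one cellular landscape, but annotated single-cell references usually
exist only for RNA. `pairdecon` estimates per-sample cell-type proportions
for *both* modalities and recovers per-sample cell-type-specific
("purified") profiles, using a single-cell RNA reference in one modality
only and no cross-modality feature links. It is aimed at researchers
dissociating tumor or developing-tissue cohorts where the non-RNA modality
has no usable single-cell reference.

## The model

For each sample, feature g of modality i obeys

    E(y_ig) = sum_c x_igc * p_c * s_ic ,        theta_ic = p_c * s_ic

with shared cell-count fractions `p`, modality-specific size factors `s_i`,
and pure cell-type profiles `X_i`. The pipeline has three stages:

1. **Joint non-negative matrix factorization** of the transformed paired
   bulk matrices, `min ||Y1 - P0 diag(s1) X1'||^2 + ||Y2 - P0 diag(s2) X2'||^2`
   subject to nonnegativity and simplex rows of `P0`, by block-coordinate
   projected gradient descent — this pre-purifies an internal non-RNA
   signature panel from the target cohort itself.
2. **Coupled pseudo-bulk simulation**: RNA pseudo-bulks aggregate reference
   cells under Dirichlet ground-truth fractions with knockout sparsity;
   non-RNA pseudo-bulks mix the stage-1 panel (raw scale) under
   *proportionally shifted* fractions (each entry scaled by U(0.9, 1.1))
   with Poisson noise.
3. **Shared-encoder / dual-decoder network** trained on the simulated pairs
   (L1 deconvolution + reconstruction losses), then adapted per target
   sample with anchored alternating updates, emitting proportions and
   per-sample signature matrices.

A Dirichlet-Multinomial prior estimated from multi-subject cell counts
initializes the shared fractions; Lin's CCC / MAE / Pearson r and a
Wilcoxon + Benjamini-Hochberg cell-type-specific differential-expression
(ctsDE) pipeline evaluate the output.

## Worked example

Everything below is synthetic and runs in about two minutes.

```r
library(pairdecon)

# synthetic study: 4 cell types, 300 features per modality, 10 target samples
sp  <- fixture_spec(k = 4, m1 = 300, m2 = 300, n_cells_per_type = 300,
                    n_targets = 10, seed = 2)
sig <- make_signatures(sp)            # ground-truth marker-structured panels
ref <- make_sc_reference(sig, sp)     # annotated single-cell RNA reference
tc  <- make_target_cohort(sig, sp, perturb_sd = 0.1)  # bulk cohort + truth

cfg <- pipeline_config(k = 4, modality2 = "atac",
                       sim = list(N = 2000, n_cells = 400), seed = 7)
run <- run_pipeline(tc$bulk, ref, cfg,
                    truth = list(Theta1 = tc$Theta1, Theta2 = tc$Theta2))
print(run)
#> <pipeline_run>
#> <deconv_result> 10 samples x 4 cell types; mean recon L1 0.9446 -> 0.8411
#>   modality 1: <metric_report> CCC 0.9147 | MAE 0.0785 | r 0.9520
#>   modality 2: <metric_report> CCC 0.8649 | MAE 0.1109 | r 0.9407
```

The two `metric_report` lines compare estimated against true cell fractions
over the whole cohort (flattened samples x cell types): concordance (CCC)
above 0.86 in both modalities, mean absolute error near or below 0.1 on
fractions in [0, 1], and Pearson r above 0.94 — on targets whose signatures were
deliberately perturbed away from the reference. `run$result` additionally
holds the latent shared fractions and, per sample, the adapted
(cell-type-specific) signature matrices; `purified_matrix(run$result,
"type1", modality = 2)` extracts one cell type's purified profiles across
the cohort for downstream differential testing with `ctsde_test()`.

A thin command-line front-end over the same functions lives in
`inst/cli/pairdecon.R` (`fixtures`, `prior`, `run` subcommands).

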