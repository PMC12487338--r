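---
title: "Joint deconvolution of paired bulk multi-omics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint deconvolution of paired bulk multi-omics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pairdecon)
```

## The problem

A bulk molecular profile of a tissue is a mixture over its cellular
subpopulations. When the same tissues are profiled in two modalities — bulk
RNA-seq paired with ATAC-seq, DNA methylation or mass-spectrometry
proteomics — the two profiles share one underlying cellular landscape, but
annotated single-cell references usually exist only for the RNA side.
`pairdecon` dissociates such paired cohorts into per-sample cell-type
proportions for *both* modalities and per-sample cell-type-specific
("purified") profiles, using a single-cell RNA reference in one modality
only, with no requirement that features be linked across modalities.

For sample $j$, feature $g$ in modality $i$, the generative model is

$$ E(y_{ig}) = \sum_{c=1}^{k} x_{igc}\,p_c\,s_{ic}, $$

where $p_c$ are the shared cell-count fractions, $s_{ic}$ are
modality-specific cell size factors converting shared counts into
modality-specific abundance fractions $\theta_{ic} = p_c s_{ic}$, and
$x_{igc}$ is the pure cell-type-$c$ value of feature $g$.

The pipeline has three stages.

## Stage 1: joint non-negative factorization

Both bulk matrices are first moved to a common scale: `log1p` for count-like
modalities (RNA, ATAC, proteomics) and $-\log\beta$ for DNAm beta values
(clipped to $[10^{-6}, 1]$ so $\beta = 0$ stays finite). `log1p` rather than
a plain log is used because bulk count matrices contain zeros and no
pseudocount is otherwise defined.

The paired matrices are then factorized jointly,

$$ \min_{\eta \ge 0} \;\; \lVert Y_1 - P_0\,\mathrm{diag}(s_1)\,X_1^\top \rVert_2^2
 + \lVert Y_2 - P_0\,\mathrm{diag}(s_2)\,X_2^\top \rVert_2^2, $$

by block-coordinate projected gradient descent: each block ($X_1$, $X_2$,
$s_1$, $s_2$, $P_0$) takes a gradient step, is clamped to the nonnegative
orthant, and each row of $P_0$ is renormalized to the simplex; a step is
accepted only if the joint objective does not increase (per-block
backtracking with step re-expansion), so the loss trace is nonincreasing by
construction. The $P_0$ gradient is projected onto the simplex tangent space
(row-centred) before the step; without this the radial gradient component
interacts with the renormalization and can stall the block.

Two design points deserve emphasis:

* **Shared size factors.** The size factors are one length-$k$ vector per
  modality, shared across samples (`shared_size_factors = TRUE`). With
  per-sample factors the product $P_0 \odot S_i$ is fully free and the two
  modalities decouple — the factorization separates into two independent
  NMFs and the "joint" structure carries no information. The per-sample mode
  is kept only as a diagnostic switch.
* **Reference-informed initialization.** $P_0$ rows are initialized from a
  Dirichlet centred on the prior mean with concentration
  $v/(1 + \texttt{subj\_var}\cdot v)$ — `subj_var` expresses how much
  cellular composition varies between target tissues. $X_1$ is initialized
  at the scaled per-type mean expression of the annotated single-cell
  reference when one is available (per-feature bulk means otherwise); this
  both anchors the latent cell types to labels and conditions the otherwise
  weakly identified factorization on small cohorts. $X_2$ starts at
  per-feature bulk means with mild multiplicative noise: wide initialization
  noise in $X_2$ survives optimization in directions the mixture data cannot
  identify and would contaminate the simulated training data downstream.

Because the factorization is exchangeable in the cell types, the fitted
columns are labeled afterwards by matching $X_1$ columns against the
reference's per-type mean profiles (optimal assignment on Pearson
correlation, exhaustive over permutations — exact for the small $k$ used
here) and the permutation is applied to both modalities
(`align_internal_reference()`).

The prior $(\pi, v)$ itself is the Dirichlet-Multinomial maximum-likelihood
estimate on an external multi-subject cell-count table
(`estimate_dm_prior()`): moment-matching start, digamma fixed-point updates
of $\alpha = v\pi$ with a likelihood-monotonicity safeguard, a final 1-D
refinement of $v$, and a cap `v_cap = 1e6` reached when subjects are
(near-)proportional. Whether counts come from all reference subjects or a
target-matched subset is a caller choice. Cell types never observed get a
$\pi$ floor of $10^{-4}$ so downstream Dirichlet draws never degenerate.

## Stage 2: coupled pseudo-bulk simulation

Training data for the network are simulated, not collected:

* RNA fractions $\theta_1 \sim \mathrm{Dir}(\xi_0 \mathbf 1_k)$ with
  $\xi_0 = 1$ (each type's expected share is $1/k$); each type is then
  independently knocked out (set exactly to zero) with probability 0.2,
  never all at once, and the row renormalized — so training covers
  compositions with absent populations.
* Non-RNA fractions are the *proportional shift* of $\theta_1$: each entry
  multiplied by an independent $U(0.9, 1.1)$ draw (90–110 % of its value),
  the same knockout policy applied, and renormalized. This preserves the
  shared cellular landscape while injecting cross-modality variability.
* The RNA pseudo-bulk aggregates real reference cells: per-type cell numbers
  are the largest-remainder rounding of $\theta_1 \cdot n_\text{cells}$
  (default 500), sampled without replacement where possible.
* The non-RNA pseudo-bulk uses the Stage-1 panel: the pre-purified profiles
  are transformed back to the original scale and mixed there,
  $\bar y_2 = \mathrm{expm1}(X_2)\,\theta_2$, then Poisson-resampled.
  Mixing on the raw scale matters: real bulk signal accumulates linearly
  over cells, and mixing in log space (a geometric mean) produces training
  data whose feature dispersion is several-fold wider than any real cohort,
  which measurably breaks the encoder at test time. DNAm is the exception
  and stays on the negative-log scale throughout. Stage-1 proportions are
  deliberately *not* reused here — the simulation draws its own ground
  truth.

`N = 5000` pairs by default, always larger than the target cohort.
Fixture-scale runs in the test-suite use `N` of 600–2000 with 300–400 cells
per pseudo-bulk, sized so the whole suite runs on one CPU in minutes.

## Stage 3: shared-encoder, dual-decoder network

The concatenated, per-sample normalized profiles enter a five-layer encoder
(CELU activations after layers 1–4) ending in a clamp-and-normalize head, so
the latent vector $\hat p$ is a valid fraction vector. Two connection layers
give modality proportions $\hat\theta_i = \hat p\,\hat S_i$; each decoder is
a product of five weight matrices without activations or biases, wrapped in
a ReLU so the implied signature matrix
$\hat X_i = \mathrm{ReLU}(W_i^1 \cdots W_i^5)$ is nonnegative, and
$\hat y_i = \hat p\,\hat S_i\,\hat X_i$. Reported proportions are
clamped-and-renormalized; the raw product feeds the decoders.

The printed form of CELU one occasionally sees,
$\min(0, \alpha e^{x/\alpha - 1})$, is identically zero on the negative
branch (the argument is always positive), i.e. it collapses to ReLU; the
standard $\min(0, \alpha(e^{x/\alpha} - 1))$ is used, with a
`literal = TRUE` escape hatch.

**Input normalization.** Each sample is divided by its mean feature value
per modality, then each feature is z-scored. Training data use their own
feature statistics, stored in the model; a target *cohort* is standardized
by its own statistics when it has at least five samples
(`standardize = "cohort"`). This self-calibration removes feature-level
location/scale disparity between simulated training data and real cohorts —
the dominant failure mode when reference and target differ — while
preserving the across-sample variation that carries the composition signal.
A constant offset added to the standardized values (to make them positive)
was tried and rejected: it collapses the signal-to-mean ratio and training
stalls.

**Losses and routing.** Training minimizes
$L_d + \lambda_r L_r$ with mean-reduced L1 terms: the deconvolution loss
$L_d$ compares reported proportions with the simulated ground truth in both
modalities and reaches the encoder and connection layers; the reconstruction
loss $L_r$ compares decoded profiles with the (standardized) inputs and
additionally reaches the decoders. The weight $\lambda_r = 0.1$
(`recon_weight`) exists because the two mean-reduced terms have very
different gradient scales through the shared encoder: unweighted, the
reconstruction gradient on the RNA branch — whose transformed bulk is *not*
linear in the proportions, unlike the non-RNA branch — overwhelms the
proportion signal roughly 4:1 and biases one modality's proportions
(observable as one modality saturating near-perfect concordance while the
other stalls). Optimization is mini-batch Adam (`batch_size = 64`,
`epochs = 250`, learning rate $10^{-3}$); the last encoder bias is
initialized at 1 so the clamp-and-normalize head starts away from its dead
zone, where gradients vanish permanently.

Encoder widths taper $m_1{+}m_2 \to 128 \to 64 \to 32 \to 16 \to k$ and the
decoder chains mirror them. Wider stacks (512–64) were tried and train
slower to a worse optimum at these feature counts; widths are configurable.

**Adaptive stage.** For each target sample, starting from a copy of the
trained weights, two anchored steps alternate: a *signature-anchored* step
updates only the decoders against target reconstruction plus an L1 anchor to
the pre-adaptation signature matrices, and a *proportion-anchored* step
updates only the encoder and connection layers against target
reconstruction plus an L1 anchor to the pre-adaptation proportions. Anchors
are frozen snapshots (co-updating them is less stable). The returned state
is the reconstruction-best checkpoint over all cycles including the start,
so adaptation can never degrade the target reconstruction loss. The
signature anchor carries weight `anchor_weight = 3`: a stronger anchor keeps
per-sample signature deviations selective — only features the target data
truly demands move — which directly controls false positives in downstream
differential testing. Proportion estimation uses a gentle adaptation rate
($10^{-5}$); purification for differential analysis benefits from a stronger
one ($10^{-3}$), consistent with the observation that purification quality
is far more hyperparameter-sensitive than composition estimation.

Purified outputs per sample are the adapted signature matrices
(de-standardized back to the transformed scale) and their
proportion-weighted version; `purified_matrix()` extracts one cell type
across the cohort, optionally on the raw scale. Differential testing is best
run on the *unweighted* adapted signatures: the weighted profiles multiply
every feature by the sample's estimated proportion, so any systematic
proportion difference between groups leaks into all features at once.

## Evaluation stack

Cohort accuracy is reported as Lin's concordance correlation coefficient
(population moments; penalizes location and scale shifts, so
$|CCC| \le |r|$), mean absolute error and Pearson $r$, computed on the
flattened sample-by-cell-type proportion pairs (per-cell-type breakdowns are
also emitted; flattening matches single-number-per-method reporting).

Cell-type-specific differential features are called per feature with a
two-sided Wilcoxon rank-sum test (exact for combined $n \le 25$, normal
approximation with continuity correction and midranks otherwise),
Benjamini–Hochberg adjustment across retained features, and calls at
FDR $< 0.05$. Features with zero variance across samples are invalid and
excluded first, and a purified result enters differential analysis only with
at least 300 valid features. Detection quality against planted truth is
summarized as sensitivity, specificity and F1.

## What the synthetic fixtures emulate — and what they do not

`make_signatures()` plants disjoint marker blocks ($m/2k$ features per type,
elevated `marker_fold = 5` over an independent background); the single-cell
reference draws Poisson counts around those signatures with per-cell size
factors; target cohorts mix signatures under flat-Dirichlet proportions
(matching the training prior) with Poisson noise at depth
`n_cells_bulk = 500`, and a log-normal perturbation of the signatures
(SD 0.1) emulates reference-to-target disparity. The two-group cohorts draw
a *shared* baseline log-profile per cell type from a multivariate normal
(diagonal, SD 0.3) around the log signatures and add the planted log fold
change to marker features of designated types in one group only — so at
LFC 0 the groups' generating means are identical by construction, and the
planted mean ratio is exactly $e^{\text{LFC}}$.

These fixtures are marker-structured idealizations: real data carry
batch effects, correlated backgrounds, ambient contamination, doublets and
annotation errors that they do not emulate. Passing tests demonstrate the
machinery is correct and self-consistent, not that field performance on any
given tissue will match the fixture numbers.

## Numerical choices and degenerate inputs

* Factorization convergence: relative objective change below `tol = 1e-6`
  (cap 2000 sweeps); a warning is raised when no decrease occurs within the
  first 10 sweeps. Smaller cohorts are fit with the same tolerance; the
  conditioning, not the tolerance, limits panel quality there.
* Knockout resampling guarantees at least one surviving type; simplex
  renormalization guards against all-zero rows by falling back to uniform.
* DNAm betas are clipped to $[10^{-6}, 1]$; the inverse transform re-clips
  to $[0, 1]$.
* All stochastic steps consume an explicit seed and save/restore the
  caller's RNG state; every stage is bitwise reproducible on a single
  thread.
* Ties in signature matching are resolved by the optimal-assignment value;
  ties in feature selection break deterministically by feature name.

## Known limitations

* Cell-type labels of the purified non-RNA panel can swap when two rare
  types have similar fractions and correlated signatures; the labeling step
  reports its match correlations so this is visible.
* The adaptive stage cannot repair a panel the factorization did not
  identify; on very small cohorts (a handful of samples) the non-RNA panel
  is the accuracy bottleneck.
* Exactly two modalities are supported; a triple-modality extension would
  need a third decoder and factorization block.
* Purified profiles inherit the transformed scale; raw-scale exports
  invert the transform but are not count-calibrated.
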