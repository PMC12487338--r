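#' Specification for synthetic fixtures
#'
#' Controls the generators that emulate every input class of the pipeline:
#' marker-structured signatures, a single-cell RNA reference, target bulk
#' cohorts with known proportions, and two-group cohorts with planted
#' cell-type-specific differential features.
#'
#' @param k Cell types.
#' @param m1,m2 Feature counts for the RNA / non-RNA modality.
#' @param n_cells_per_type Cells per type in the single-cell reference.
#' @param marker_fold Elevation of a type's marker block over background
#'   (> 1).
#' @param n_targets Target cohort size.
#' @param shift_low,shift_high Cross-modality proportional-shift interval for
#'   target ground truth.
#' @param n_cells_bulk Cells' worth of signal per bulk sample (Poisson depth).
#' @param lfc Planted log fold change for the two-group cohort.
#' @param n_de_per_type Planted DE features per designated cell type.
#' @param de_cell_types Indices of cell types carrying planted DE.
#' @param group_sizes Two-group cohort sizes `c(nA, nB)`.
#' @param mvn_sd Log-scale SD of the multivariate-normal draw of group mean
#'   profiles (diagonal covariance).
#' @param spec2 Non-RNA modality name.
#' @param seed Integer seed; every fixture is reproducible from (spec, seed).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(k = 4L, m1 = 300L, m2 = 300L, n_cells_per_type = 200L,
                         marker_fold = 5, n_targets = 10L,
                         shift_low = 0.9, shift_high = 1.1,
                         n_cells_bulk = 500L, lfc = 1, n_de_per_type = 25L,
                         de_cell_types = c(1L, 2L), group_sizes = c(50L, 50L),
                         mvn_sd = 0.3, spec2 = "proteomics", seed = 1L) {
  stopifnot(k >= 2, m1 >= 2 * k, m2 >= 2 * k, marker_fold > 1, lfc >= 0,
            n_de_per_type >= 1, length(group_sizes) == 2)
  structure(list(k = as.integer(k), m1 = as.integer(m1), m2 = as.integer(m2),
                 n_cells_per_type = as.integer(n_cells_per_type),
                 marker_fold = marker_fold, n_targets = as.integer(n_targets),
                 shift_low = shift_low, shift_high = shift_high,
                 n_cells_bulk = as.integer(n_cells_bulk), lfc = lfc,
                 n_de_per_type = as.integer(n_de_per_type),
                 de_cell_types = as.integer(de_cell_types),
                 group_sizes = as.integer(group_sizes), mvn_sd = mvn_sd,
                 spec2 = spec2, seed = as.integer(seed)),
            class = "fixture_spec")
}

marker_blocks <- function(m, k) {
  block <- floor(m / (2 * k))
  lapply(seq_len(k), function(c) seq.int((c - 1) * block + 1, c * block))
}

#' Generate ground-truth marker-structured signature matrices
#'
#' Each cell type owns a disjoint marker block of `m / (2k)` features whose
#' mean is elevated `marker_fold`-fold over background; the remaining
#' features are independent background. Values are raw-scale expected
#' per-cell abundances.
#'
#' @param spec A [fixture_spec()].
#' @return A `signature_set`: `X1` (m1 x k), `X2` (m2 x k), marker index
#'   lists `markers1`, `markers2`, `cell_types`.
#' @export
make_signatures <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  build <- function(m, k, fold) {
    X <- matrix(stats::runif(m * k, 0.5, 1.5), m, k)
    blocks <- marker_blocks(m, k)
    for (c in seq_len(k)) X[blocks[[c]], c] <- X[blocks[[c]], c] * fold
    list(X = X, blocks = blocks)
  }
  b1 <- build(spec$m1, spec$k, spec$marker_fold)
  b2 <- build(spec$m2, spec$k, spec$marker_fold)
  ct <- paste0("type", seq_len(spec$k))
  colnames(b1$X) <- colnames(b2$X) <- ct
  rownames(b1$X) <- paste0("gene", seq_len(spec$m1))
  rownames(b2$X) <- paste0("feat", seq_len(spec$m2))
  structure(list(X1 = b1$X, X2 = b2$X, markers1 = b1$blocks,
                 markers2 = b2$blocks, cell_types = ct, spec = spec),
            class = "signature_set")
}

#' Generate a single-cell RNA reference around the RNA signatures
#'
#' Cells are drawn per type with Poisson noise around the type's RNA
#' signature column scaled by a per-cell size factor; labels and donor IDs
#' are attached. This is deliberately a simple marker-structured emulation of
#' a preprocessed, annotated reference, not a single-cell simulator.
#'
#' @param signatures A [make_signatures()] result.
#' @param spec A [fixture_spec()].
#' @return An [single_cell_reference()].
#' @export
make_sc_reference <- function(signatures, spec) {
  stopifnot(inherits(signatures, "signature_set"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed + 1L)
  k <- spec$k; m <- spec$m1; npc <- spec$n_cells_per_type
  counts <- matrix(0L, k * npc, m)
  types <- character(k * npc)
  row <- 0L
  for (c in seq_len(k)) {
    lam <- signatures$X1[, c]
    for (i in seq_len(npc)) {
      row <- row + 1L
      size <- stats::runif(1, 0.8, 1.2)
      counts[row, ] <- stats::rpois(m, lam * size)
      types[row] <- signatures$cell_types[c]
    }
  }
  colnames(counts) <- rownames(signatures$X1)
  single_cell_reference(counts, types,
                        sample_ids = paste0("donor", (seq_len(k * npc) %% 3L) + 1L))
}

#' Generate a target bulk cohort with known proportions
#'
#' RNA proportions are Dirichlet-drawn; non-RNA proportions are obtained by
#' [proportional_shift()] with the spec's interval. Bulk profiles are Poisson
#' draws around signature-weighted sums at depth `n_cells_bulk`, then moved
#' to the transformed scale.
#'
#' @param signatures A [make_signatures()] result.
#' @param spec A [fixture_spec()].
#' @param perturb_sd Optional log-normal perturbation SD applied to the
#'   signatures before mixing (emulates reference-to-target disparity; 0 =
#'   targets generated from the exact signatures).
#' @return List with `bulk` (a [bulk_multiome()]), `Theta1`, `Theta2` (ground
#'   truth) and the (possibly perturbed) generating signatures.
#' @export
make_target_cohort <- function(signatures, spec, perturb_sd = 0) {
  stopifnot(inherits(signatures, "signature_set"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed + 2L)
  k <- spec$k; n <- spec$n_targets
  X1 <- signatures$X1; X2 <- signatures$X2
  if (perturb_sd > 0) {
    X1 <- X1 * matrix(exp(stats::rnorm(length(X1), 0, perturb_sd)), nrow(X1))
    X2 <- X2 * matrix(exp(stats::rnorm(length(X2), 0, perturb_sd)), nrow(X2))
  }
  Theta1 <- rdirichlet_rows(n, rep(1 / k, k), k)  # flat, as in the training prior
  Theta2 <- t(vapply(seq_len(n), function(j) {
    proportional_shift(Theta1[j, ], spec$shift_low, spec$shift_high)
  }, numeric(k)))
  if (spec$shift_low == 1 && spec$shift_high == 1) Theta2 <- Theta1
  depth <- spec$n_cells_bulk
  Y1 <- t(vapply(seq_len(n), function(j) {
    stats::rpois(spec$m1, depth * drop(X1 %*% Theta1[j, ]))
  }, numeric(spec$m1)))
  Y2 <- t(vapply(seq_len(n), function(j) {
    stats::rpois(spec$m2, depth * drop(X2 %*% Theta2[j, ]))
  }, numeric(spec$m2)))
  colnames(Y1) <- rownames(signatures$X1)
  colnames(Y2) <- rownames(signatures$X2)
  colnames(Theta1) <- colnames(Theta2) <- signatures$cell_types
  bulk <- bulk_multiome(transform_forward(Y1, "rna"),
                        transform_forward(Y2, spec$spec2),
                        spec1 = "rna", spec2 = spec$spec2)
  list(bulk = bulk, Theta1 = Theta1, Theta2 = Theta2,
       gen_X1 = X1, gen_X2 = X2)
}

#' Generate a two-group cohort with planted cell-type-specific DE
#'
#' A shared baseline log-profile per cell type is drawn from a multivariate
#' normal (diagonal covariance, SD `mvn_sd`) around the log signatures; the
#' planted log fold change is added to `n_de_per_type` marker features of the
#' designated cell types in group A only, in both modalities. At `lfc = 0`
#' the two groups' generating means are identical by construction. Bulk
#' samples mix the exponentiated group means under Dirichlet proportions with
#' Poisson noise.
#'
#' @param signatures A [make_signatures()] result.
#' @param spec A [fixture_spec()] (uses `lfc`, `n_de_per_type`,
#'   `de_cell_types`, `group_sizes`, `mvn_sd`).
#' @return List with `bulkA`, `bulkB` ([bulk_multiome()]s), ground-truth
#'   proportions per group, group mean profile arrays, and per-cell-type DE
#'   truth flag lists `de_truth1`, `de_truth2` (logical per feature).
#' @export
make_ctsde_cohort <- function(signatures, spec) {
  stopifnot(inherits(signatures, "signature_set"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed + 3L)
  k <- spec$k
  plant <- function(X, markers, m) {
    de <- lapply(seq_len(k), function(c) rep(FALSE, m))
    muA <- matrix(0, m, k); muB <- matrix(0, m, k)
    for (c in seq_len(k)) {
      base <- log(X[, c]) + stats::rnorm(m, 0, spec$mvn_sd)
      lfc_vec <- rep(0, m)
      if (c %in% spec$de_cell_types) {
        idx <- markers[[c]][seq_len(min(spec$n_de_per_type, length(markers[[c]])))]
        lfc_vec[idx] <- spec$lfc
        de[[c]][idx] <- spec$lfc != 0
      }
      muA[, c] <- exp(base + lfc_vec)
      muB[, c] <- exp(base)
    }
    list(muA = muA, muB = muB, de = de)
  }
  p1 <- plant(signatures$X1, signatures$markers1, spec$m1)
  p2 <- plant(signatures$X2, signatures$markers2, spec$m2)
  gen_group <- function(ng, muA1, muA2) {
    Theta1 <- rdirichlet_rows(ng, rep(1 / k, k), 10 * k)
    Theta2 <- t(vapply(seq_len(ng), function(j) {
      proportional_shift(Theta1[j, ], spec$shift_low, spec$shift_high)
    }, numeric(k)))
    depth <- spec$n_cells_bulk
    Y1 <- t(vapply(seq_len(ng), function(j) {
      stats::rpois(spec$m1, depth * drop(muA1 %*% Theta1[j, ]))
    }, numeric(spec$m1)))
    Y2 <- t(vapply(seq_len(ng), function(j) {
      stats::rpois(spec$m2, depth * drop(muA2 %*% Theta2[j, ]))
    }, numeric(spec$m2)))
    colnames(Y1) <- rownames(signatures$X1)
    colnames(Y2) <- rownames(signatures$X2)
    list(bulk = bulk_multiome(transform_forward(Y1, "rna"),
                              transform_forward(Y2, spec$spec2),
                              spec1 = "rna", spec2 = spec$spec2),
         Theta1 = Theta1, Theta2 = Theta2)
  }
  gA <- gen_group(spec$group_sizes[1], p1$muA, p2$muA)
  gB <- gen_group(spec$group_sizes[2], p1$muB, p2$muB)
  list(bulkA = gA$bulk, bulkB = gB$bulk,
       Theta1A = gA$Theta1, Theta2A = gA$Theta2,
       Theta1B = gB$Theta1, Theta2B = gB$Theta2,
       mu1A = p1$muA, mu1B = p1$muB, mu2A = p2$muA, mu2B = p2$muB,
       de_truth1 = p1$de, de_truth2 = p2$de,
       cell_types = signatures$cell_types)
}

#' Simulate a multi-subject cell-count table from a Dirichlet-Multinomial
#'
#' @param n_subjects Rows.
#' @param pi Mean proportions (simplex).
#' @param v Concentration.
#' @param total Cells per subject (scalar or vector).
#' @param seed Optional seed.
#' @return n_subjects x k integer matrix.
#' @export
simulate_cell_counts <- function(n_subjects, pi, v, total = 500L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  total <- rep_len(total, n_subjects)
  P <- rdirichlet_rows(n_subjects, pi, v)
  out <- t(vapply(seq_len(n_subjects), function(i) {
    drop(stats::rmultinom(1, total[i], P[i, ]))
  }, numeric(length(pi))))
  colnames(out) <- names(pi)
  out
}
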