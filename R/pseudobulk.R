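#' Single-cell RNA reference container
#'
#' @param counts cells x genes matrix of nonnegative integer counts.
#' @param cell_types Length-cells character vector of cell-type labels.
#' @param sample_ids Length-cells character vector of donor/sample labels.
#' @return An `sc_reference` object.
#' @export
single_cell_reference <- function(counts, cell_types, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("reference counts must be nonnegative", call. = FALSE)
  if (length(cell_types) != nrow(counts)) {
    stop("cell_types must have one label per cell (row)", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- rep("sample1", nrow(counts))
  structure(list(counts = counts, cell_types = as.character(cell_types),
                 sample_ids = as.character(sample_ids)),
            class = "sc_reference")
}

#' @export
print.sc_reference <- function(x, ...) {
  cat(sprintf("<sc_reference> %d cells x %d genes, %d cell types\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$cell_types))))
  invisible(x)
}

# knockout mask: each type independently zeroed with prob `rate`, but never
# all active types at once (re-drawn); returns logical "survives" vector
draw_knockout_mask <- function(active, rate) {
  if (rate <= 0) return(active)
  repeat {
    keep <- active & (stats::runif(length(active)) >= rate)
    if (any(keep)) return(keep)
  }
}

#' Simulate ground-truth RNA cell-type fractions
#'
#' Rows are drawn from a symmetric Dirichlet with concentration `xi0` per type
#' (so each type's expected fraction is `1/k`), then sparsified: each type is
#' independently knocked out (set to exactly zero) with probability
#' `knockout_rate`, never all types at once, and the row is renormalized.
#'
#' @param N Number of rows (training samples).
#' @param k Number of cell types.
#' @param xi0 Symmetric Dirichlet concentration per type (default 1, flat).
#' @param knockout_rate Per-type knockout probability in `[0, 1)`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return N x k matrix; rows on the simplex, knocked-out entries exactly 0.
#' @export
simulate_rna_proportions <- function(N, k, xi0 = 1, knockout_rate = 0.2,
                                     seed = NULL) {
  stopifnot(N >= 1, k >= 2, xi0 > 0, knockout_rate >= 0, knockout_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  Theta <- rdirichlet_rows(N, rep(1 / k, k), xi0 * k)
  if (knockout_rate > 0) {
    for (j in seq_len(N)) {
      keep <- draw_knockout_mask(rep(TRUE, k), knockout_rate)
      Theta[j, !keep] <- 0
      Theta[j, ] <- Theta[j, ] / sum(Theta[j, ])
    }
  }
  Theta
}

#' Proportional shift of a fraction vector to a second modality
#'
#' Multiplies each fraction by an independent Uniform(`low`, `high`) factor,
#' applies the same knockout policy as the RNA simulation (independent
#' re-draw; entries already zero stay zero), and renormalizes to the simplex.
#' This couples the non-RNA ground truth to the RNA ground truth while
#' introducing cross-modality variability.
#'
#' @param theta1 Length-k fraction vector on the simplex.
#' @param low,high Uniform shift bounds, `0 < low <= high` (defaults 0.9, 1.1:
#'   each fraction is scaled to between 90 and 110 percent of its value).
#' @param knockout_rate Per-type knockout probability (default 0).
#' @param seed Optional seed; `NULL` uses the current stream.
#' @return Length-k fraction vector on the simplex.
#' @export
proportional_shift <- function(theta1, low = 0.9, high = 1.1,
                               knockout_rate = 0, seed = NULL) {
  stopifnot(low > 0, high >= low, abs(sum(theta1) - 1) < 1e-6, all(theta1 >= 0))
  if (!is.null(seed)) set.seed(seed)
  theta2 <- theta1 * stats::runif(length(theta1), low, high)
  if (knockout_rate > 0) {
    keep <- draw_knockout_mask(theta2 > 0, knockout_rate)
    theta2[!keep] <- 0
  }
  theta2 / sum(theta2)
}

# largest-remainder rounding of theta * n_cells to integers summing to n_cells
largest_remainder_counts <- function(theta, n_cells) {
  raw <- theta * n_cells
  base <- floor(raw)
  deficit <- n_cells - sum(base)
  if (deficit > 0) {
    rem <- raw - base
    rem[theta == 0] <- -1  # knocked-out types never receive remainder cells
    add <- order(rem, decreasing = TRUE)[seq_len(deficit)]
    base[add] <- base[add] + 1
  }
  base
}

#' Aggregate an RNA pseudo-bulk sample from the single-cell reference
#'
#' Converts fractions to per-type cell numbers by largest-remainder rounding
#' of `theta1 * n_cells`, samples that many cells per type without replacement
#' (falling back to with-replacement with a warning when the reference is too
#' small), and sums their count rows.
#'
#' @param ref An [single_cell_reference()].
#' @param theta1 Length-k fractions; names or order must match `cell_types`.
#' @param cell_types Ordered cell-type labels defining the columns of theta.
#' @param n_cells Total cells aggregated per pseudo-bulk sample.
#' @param seed Optional seed; `NULL` uses the current stream.
#' @return Length-m1 vector of raw-scale aggregated counts.
#' @export
build_rna_pseudobulk <- function(ref, theta1, cell_types, n_cells = 500,
                                 seed = NULL) {
  stopifnot(inherits(ref, "sc_reference"), n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  per_type <- largest_remainder_counts(theta1, n_cells)
  out <- numeric(ncol(ref$counts))
  for (c in seq_along(cell_types)) {
    nc <- per_type[c]
    if (nc == 0) next
    pool <- which(ref$cell_types == cell_types[c])
    if (length(pool) == 0) {
      stop(sprintf("no reference cells for cell type '%s'", cell_types[c]),
           call. = FALSE)
    }
    if (length(pool) >= nc) {
      idx <- pool[sample.int(length(pool), nc)]
    } else {
      warning(sprintf("cell type '%s': %d cells requested, %d available; sampling with replacement",
                      cell_types[c], nc, length(pool)), call. = FALSE)
      idx <- pool[sample.int(length(pool), nc, replace = TRUE)]
    }
    out <- out + colSums(ref$counts[idx, , drop = FALSE])
  }
  out
}

#' Simulate a non-RNA pseudo-bulk sample from the internal reference panel
#'
#' For count-like modalities (ATAC, proteomics) the pre-purified panel is
#' first transformed back to the original (non-log) scale and the mean
#' mixed-cell profile is the raw-scale weighted sum `expm1(X2) %*% theta2`,
#' which is then Poisson-resampled — mixing on the raw scale matches how real
#' bulk signal accumulates over cells. DNAm stays on the negative-log scale
#' throughout: the mean is `X2 %*% theta2` and the Poisson draw happens on
#' that scale.
#'
#' @param X2 m2 x k internal (pre-purified) reference panel, transformed scale.
#' @param theta2 Length-k fraction vector.
#' @param spec [modality_spec()] of the non-RNA modality.
#' @param seed Optional seed; `NULL` uses the current stream.
#' @return List with `value` (length-m2 Poisson draw), `mean` (the Poisson
#'   mean on the generation scale) and `scale` (`"raw"` or `"neglog"`).
#' @export
build_nonrna_pseudobulk <- function(X2, theta2, spec, seed = NULL) {
  spec <- as_modality_spec(spec)
  X2 <- as.matrix(X2)
  stopifnot(ncol(X2) == length(theta2))
  if (any(X2 < 0)) stop("internal reference panel must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lambda <- if (spec$transform == "neglog") drop(X2 %*% theta2)
            else drop(expm1(X2) %*% theta2)
  if (any(lambda < 0)) stop("negative Poisson mean: upstream projection is broken", call. = FALSE)
  list(value = stats::rpois(length(lambda), lambda), mean = lambda,
       scale = if (spec$transform == "neglog") "neglog" else "raw")
}

#' Simulation configuration for training-set generation
#'
#' @param N Number of paired training samples (default 5000).
#' @param xi0 Symmetric Dirichlet concentration for RNA fractions.
#' @param knockout_rate Per-type knockout probability (default 0.2).
#' @param shift_low,shift_high Proportional-shift bounds (default 0.9, 1.1).
#' @param n_cells Cells aggregated per RNA pseudo-bulk (default 500).
#' @param subj_var Between-sample heterogeneity; only used when
#'   `hetero_boost = TRUE`, where it widens the shift interval to
#'   `(shift_low - subj_var, shift_high + subj_var)`.
#' @param hetero_boost Enable the optional shift-interval widening (default
#'   `FALSE`).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(N = 5000L, xi0 = 1, knockout_rate = 0.2,
                       shift_low = 0.9, shift_high = 1.1, n_cells = 500L,
                       subj_var = 0.05, hetero_boost = FALSE, seed = 1L) {
  stopifnot(N >= 1, xi0 > 0, knockout_rate >= 0, knockout_rate < 1,
            shift_low > 0, shift_high >= shift_low, n_cells >= 1)
  structure(list(N = as.integer(N), xi0 = xi0, knockout_rate = knockout_rate,
                 shift_low = shift_low, shift_high = shift_high,
                 n_cells = as.integer(n_cells), subj_var = subj_var,
                 hetero_boost = hetero_boost, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate the paired pseudo-bulk training set
#'
#' Step 2 of the pipeline: RNA pseudo-bulk aggregated from the single-cell
#' reference under Dirichlet ground-truth fractions with knockout sparsity,
#' and non-RNA pseudo-bulk simulated from the internal reference panel under
#' proportionally shifted fractions with Poisson noise. RNA training data are
#' transformed with the RNA spec so training and target scales match; the
#' non-RNA draws are returned on the transformed scale likewise (DNAm draws
#' are already on the negative-log scale).
#'
#' @param ref An [single_cell_reference()] subset to the RNA feature panel.
#' @param X2 m2 x k internal reference panel from
#'   [extract_internal_reference()].
#' @param cell_types Ordered cell-type labels.
#' @param cfg A [sim_config()].
#' @param spec1,spec2 Modality specs.
#' @return A `training_set`: `Y1_train` (N x m1, transformed), `Y2_train`
#'   (N x m2, transformed), `Theta1`, `Theta2` (N x k ground truth),
#'   `scale_notes`, and the generation config.
#' @export
generate_training_set <- function(ref, X2, cell_types, cfg = sim_config(),
                                  spec1 = "rna", spec2 = "atac") {
  stopifnot(inherits(ref, "sc_reference"), inherits(cfg, "sim_config"))
  spec1 <- as_modality_spec(spec1); spec2 <- as_modality_spec(spec2)
  k <- length(cell_types)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  lo <- cfg$shift_low; hi <- cfg$shift_high
  if (cfg$hetero_boost) {
    lo <- max(lo - cfg$subj_var, 1e-3)
    hi <- hi + cfg$subj_var
  }
  Theta1 <- simulate_rna_proportions(cfg$N, k, cfg$xi0, cfg$knockout_rate)
  Theta2 <- matrix(0, cfg$N, k)
  Y1 <- matrix(0, cfg$N, ncol(ref$counts))
  Y2 <- matrix(0, cfg$N, nrow(X2))
  for (j in seq_len(cfg$N)) {
    Theta2[j, ] <- proportional_shift(Theta1[j, ], lo, hi, cfg$knockout_rate)
    Y1[j, ] <- build_rna_pseudobulk(ref, Theta1[j, ], cell_types, cfg$n_cells)
    Y2[j, ] <- build_nonrna_pseudobulk(X2, Theta2[j, ], spec2)$value
  }
  Y1t <- transform_forward(Y1, spec1)
  Y2t <- if (spec2$transform == "neglog") Y2 else transform_forward(Y2, spec2)
  colnames(Y1t) <- colnames(ref$counts)
  colnames(Y2t) <- rownames(X2)
  colnames(Theta1) <- colnames(Theta2) <- cell_types
  structure(
    list(Y1_train = Y1t, Y2_train = Y2t, Theta1 = Theta1, Theta2 = Theta2,
         cell_types = cell_types, spec1 = spec1, spec2 = spec2, config = cfg,
         scale_notes = c(Y1_train = "transformed (log1p of aggregated counts)",
                         Y2_train = if (spec2$transform == "neglog")
                           "neglog scale (Poisson drawn on neglog scale)"
                         else "transformed (log1p of raw-scale Poisson draws)")),
    class = "training_set"
  )
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> N = %d paired pseudo-bulk samples; m1 = %d, m2 = %d, k = %d\n",
              nrow(x$Y1_train), ncol(x$Y1_train), ncol(x$Y2_train), ncol(x$Theta1)))
  invisible(x)
}
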