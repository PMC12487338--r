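#' Paired bulk multi-omics container
#'
#' Holds the two sample-matched bulk matrices on the transformed scale
#' (see [transform_forward()]), with their modality specs. Rows are samples in
#' the same order in both matrices.
#'
#' @param Y1 n x m1 transformed RNA matrix (samples x genes).
#' @param Y2 n x m2 transformed non-RNA matrix (samples x features).
#' @param spec1,spec2 [modality_spec()] for each matrix (names accepted).
#' @param sample_ids Optional sample labels (default rownames of `Y1`).
#' @return A `bulk_multiome` object.
#' @export
bulk_multiome <- function(Y1, Y2, spec1 = "rna", spec2 = "atac",
                          sample_ids = NULL) {
  Y1 <- as.matrix(Y1); Y2 <- as.matrix(Y2)
  if (nrow(Y1) != nrow(Y2)) stop("Y1 and Y2 must have the same samples (rows)", call. = FALSE)
  if (nrow(Y1) < 1L) stop("at least one sample is required", call. = FALSE)
  if (any(!is.finite(Y1)) || any(!is.finite(Y2))) stop("non-finite entries in bulk matrices", call. = FALSE)
  if (any(Y1 < 0) || any(Y2 < 0)) stop("transformed bulk matrices must be nonnegative", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- rownames(Y1)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(Y1)))
  rownames(Y1) <- rownames(Y2) <- sample_ids
  structure(
    list(Y1 = Y1, Y2 = Y2, sample_ids = sample_ids,
         spec1 = as_modality_spec(spec1), spec2 = as_modality_spec(spec2)),
    class = "bulk_multiome"
  )
}

#' @export
print.bulk_multiome <- function(x, ...) {
  cat(sprintf("<bulk_multiome> %d samples; %s: %d features, %s: %d features\n",
              nrow(x$Y1), x$spec1$name, ncol(x$Y1), x$spec2$name, ncol(x$Y2)))
  invisible(x)
}

#' Configuration for the joint factorization
#'
#' @param k Number of cell types (>= 2).
#' @param prior A [estimate_dm_prior()] result (or any list with `pi`, `v`)
#'   used to initialize the shared per-sample fractions.
#' @param step_size Initial projected-gradient step (adapted by backtracking).
#' @param tol Relative-change convergence threshold on the objective.
#' @param max_iter Iteration cap.
#' @param subj_var Between-sample composition heterogeneity; inflates the
#'   dispersion of the Dirichlet initialization (effective concentration
#'   `v / (1 + subj_var * v)`).
#' @param shared_size_factors If `TRUE` (default), one length-k size-factor
#'   vector per modality shared across samples, which is what couples the two
#'   modalities through the common fractions; per-sample factors
#'   (`FALSE`) make the joint factorization separable and are kept only as a
#'   diagnostic mode.
#' @param X1_init Optional m1 x k matrix initializing the RNA signature block
#'   (e.g. scaled per-type mean expression of an annotated single-cell
#'   reference); multiplied by mild uniform noise. Default `NULL` initializes
#'   from per-feature bulk means.
#' @param seed Integer seed controlling the random initialization.
#' @return A `jnmf_config` list.
#' @export
jnmf_config <- function(k, prior, step_size = 1e-3, tol = 1e-6,
                        max_iter = 2000L, subj_var = 0.05,
                        shared_size_factors = TRUE, X1_init = NULL,
                        seed = 1L) {
  stopifnot(k >= 2, step_size > 0, tol > 0, max_iter >= 1, subj_var >= 0)
  if (length(prior$pi) != k) stop("prior dimension does not match k", call. = FALSE)
  if (!is.null(X1_init)) {
    X1_init <- as.matrix(X1_init)
    if (ncol(X1_init) != k || any(X1_init < 0)) {
      stop("X1_init must be a nonnegative m1 x k matrix", call. = FALSE)
    }
  }
  structure(list(k = as.integer(k), prior = prior, step_size = step_size,
                 tol = tol, max_iter = as.integer(max_iter),
                 subj_var = subj_var, shared_size_factors = shared_size_factors,
                 X1_init = X1_init, seed = as.integer(seed)),
            class = "jnmf_config")
}

# squared-error objective of Eqs-style bilinear model, both modalities
jnmf_loss_value <- function(state, bulk) {
  Th1 <- state$P0 * state$S1
  Th2 <- state$P0 * state$S2
  sum((bulk$Y1 - Th1 %*% t(state$X1))^2) + sum((bulk$Y2 - Th2 %*% t(state$X2))^2)
}

project_simplex_rows <- function(P) {
  P <- pmax(P, 0)
  rs <- rowSums(P)
  bad <- rs <= 0
  if (any(bad)) {
    P[bad, ] <- 1 / ncol(P)
    rs[bad] <- 1
  }
  P / rs
}

#' Initialize the joint factorization state
#'
#' Rows of the shared fraction matrix `P0` are drawn from a Dirichlet centred
#' on the prior mean with concentration `v / (1 + subj_var * v)` (larger
#' `subj_var` gives more dispersed compositions); signature matrices start at
#' per-feature bulk means times positive uniform noise; size factors start at
#' one. Fully reproducible given `cfg$seed`.
#'
#' @param bulk A [bulk_multiome()].
#' @param cfg A [jnmf_config()].
#' @return A `jnmf_state` with fields `X1`, `X2`, `P0`, `S1`, `S2`,
#'   `loss_trace`.
#' @export
init_jnmf <- function(bulk, cfg) {
  stopifnot(inherits(bulk, "bulk_multiome"), inherits(cfg, "jnmf_config"))
  n <- nrow(bulk$Y1); m1 <- ncol(bulk$Y1); m2 <- ncol(bulk$Y2); k <- cfg$k
  if (k > min(m1, m2)) stop("k exceeds the number of available features", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  v_eff <- cfg$prior$v / (1 + cfg$subj_var * cfg$prior$v)
  P0 <- rdirichlet_rows(n, cfg$prior$pi, v_eff)
  X1 <- if (!is.null(cfg$X1_init)) {
    if (nrow(cfg$X1_init) != m1) stop("X1_init rows do not match Y1 features", call. = FALSE)
    cfg$X1_init * matrix(stats::runif(m1 * k, 0.9, 1.1), m1, k)
  } else {
    matrix(colMeans(bulk$Y1), m1, k) * matrix(stats::runif(m1 * k, 0.5, 1.5), m1, k)
  }
  X2 <- matrix(colMeans(bulk$Y2), m2, k) * matrix(stats::runif(m2 * k, 0.5, 1.5), m2, k)
  S1 <- matrix(1, n, k)
  S2 <- matrix(1, n, k)
  steps <- list(X1 = cfg$step_size, X2 = cfg$step_size, S1 = cfg$step_size,
                S2 = cfg$step_size, P0 = cfg$step_size)
  state <- structure(list(X1 = X1, X2 = X2, P0 = P0, S1 = S1, S2 = S2,
                          steps = steps, loss_trace = numeric(0),
                          cell_types = cfg$prior$cell_types),
                     class = "jnmf_state")
  state$loss_trace <- jnmf_loss_value(state, bulk)
  state
}

jnmf_block_grad <- function(state, bulk, block, shared) {
  Th1 <- state$P0 * state$S1
  Th2 <- state$P0 * state$S2
  g <- switch(block,
    X1 = 2 * crossprod(Th1 %*% t(state$X1) - bulk$Y1, Th1),
    X2 = 2 * crossprod(Th2 %*% t(state$X2) - bulk$Y2, Th2),
    S1 = 2 * ((Th1 %*% t(state$X1) - bulk$Y1) %*% state$X1) * state$P0,
    S2 = 2 * ((Th2 %*% t(state$X2) - bulk$Y2) %*% state$X2) * state$P0,
    P0 = {
      gp <- 2 * ((Th1 %*% t(state$X1) - bulk$Y1) %*% state$X1) * state$S1 +
            2 * ((Th2 %*% t(state$X2) - bulk$Y2) %*% state$X2) * state$S2
      gp - rowMeans(gp)  # tangent to the simplex, so small steps descend
    }
  )
  if (shared && block %in% c("S1", "S2")) {
    g <- matrix(colMeans(g), nrow(g), ncol(g), byrow = TRUE)
  }
  if (any(!is.finite(g))) {
    stop(sprintf("non-finite gradient (block %s) at iteration %d",
                 block, length(state$loss_trace)), call. = FALSE)
  }
  g
}

#' One projected-gradient sweep of the joint factorization
#'
#' Updates each parameter block in turn (X1, X2, S1, S2, then the shared
#' fractions P0) with a projected gradient step against the joint squared
#' loss: clamp to the nonnegative orthant, renormalize each row of `P0` to
#' the simplex, and accept the block step only if the objective does not
#' increase (backtracking halves the per-block step otherwise; accepted
#' steps re-expand it). When no decrease is possible a block is left
#' unchanged, so the loss trace is nonincreasing by construction.
#'
#' @param state A `jnmf_state`.
#' @param bulk A [bulk_multiome()].
#' @param cfg A [jnmf_config()].
#' @return Updated `jnmf_state` with the new objective appended to
#'   `loss_trace`.
#' @export
jnmf_step <- function(state, bulk, cfg) {
  loss_cur <- state$loss_trace[length(state$loss_trace)]
  for (block in c("X1", "X2", "S1", "S2", "P0")) {
    g <- jnmf_block_grad(state, bulk, block, cfg$shared_size_factors)
    s0 <- state$steps[[block]]
    s <- s0
    for (bt in 1:30) {
      cand <- state
      if (block == "P0") {
        cand$P0 <- project_simplex_rows(state$P0 - s * g)
      } else {
        cand[[block]] <- pmax(state[[block]] - s * g, 0)
      }
      loss_new <- jnmf_loss_value(cand, bulk)
      if (is.finite(loss_new) && loss_new <= loss_cur + 1e-12) {
        cand$steps[[block]] <- s * 1.5
        state <- cand
        loss_cur <- loss_new
        break
      }
      s <- s / 2
      if (bt == 30) state$steps[[block]] <- s0 / 2  # retry smaller next sweep
    }
  }
  state$loss_trace <- c(state$loss_trace, loss_cur)
  state
}

#' Fit the joint non-negative factorization of a paired bulk multiome
#'
#' Iterates [jnmf_step()] from [init_jnmf()] until the relative objective
#' change drops below `cfg$tol` or `cfg$max_iter` is reached. The result
#' carries the shared per-sample fractions `P0`, modality-specific size
#' factors `S1`, `S2`, and the two nonnegative signature matrices `X1`
#' (m1 x k) and `X2` (m2 x k) on the transformed scale.
#'
#' @inheritParams jnmf_step
#' @return A fitted `jnmf_state` with `converged` flag and `loss_trace`.
#' @examples
#' \donttest{
#' sp <- fixture_spec(k = 2, m1 = 60, m2 = 60, n_targets = 10, seed = 3)
#' sig <- make_signatures(sp)
#' tc <- make_target_cohort(sig, sp)
#' prior <- uniform_prior(2)
#' fit <- jnmf_fit(tc$bulk, jnmf_config(k = 2, prior = prior, max_iter = 300))
#' }
#' @export
jnmf_fit <- function(bulk, cfg) {
  if (all(bulk$Y1 == 0) && all(bulk$Y2 == 0)) stop("empty bulk input", call. = FALSE)
  state <- init_jnmf(bulk, cfg)
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    state <- jnmf_step(state, bulk, cfg)
    lt <- state$loss_trace
    n <- length(lt)
    if (it == 10L && lt[n] >= lt[1] * (1 - 1e-12)) {
      warning("degenerate factorization: no loss decrease in the first 10 iterations",
              call. = FALSE)
    }
    if (abs(lt[n] - lt[n - 1]) / max(lt[n - 1], 1) < cfg$tol) {
      converged <- TRUE
      break
    }
  }
  state$converged <- converged
  state$Theta1 <- project_simplex_rows(state$P0 * state$S1)
  state$Theta2 <- project_simplex_rows(state$P0 * state$S2)
  state
}

#' @export
print.jnmf_state <- function(x, ...) {
  cat(sprintf("<jnmf_state> k = %d, %d samples; %d iterations, loss %.6g\n",
              ncol(x$P0), nrow(x$P0), length(x$loss_trace) - 1L,
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Extract the internal reference panel from a fitted factorization
#'
#' Returns the two signature matrices recovered in Step 1, used downstream as
#' internal reference panels for pseudo-bulk simulation. Deliberately does not
#' expose the fitted per-sample proportions: simulation draws its own ground
#' truth fractions.
#'
#' @param state A fitted `jnmf_state`.
#' @param spec1,spec2 Modality specs matching the fitted bulk matrices.
#' @return A `signature_pair`: list with `X1` (m1 x k), `X2` (m2 x k) on the
#'   transformed scale, per-modality mean size factors `s1`, `s2`, and the
#'   modality specs.
#' @export
extract_internal_reference <- function(state, spec1 = "rna", spec2 = "atac") {
  stopifnot(inherits(state, "jnmf_state"))
  structure(
    list(X1 = state$X1, X2 = state$X2,
         s1 = colMeans(state$S1), s2 = colMeans(state$S2),
         spec1 = as_modality_spec(spec1), spec2 = as_modality_spec(spec2),
         cell_types = state$cell_types),
    class = "signature_pair"
  )
}

#' Label internal reference columns against the single-cell reference
#'
#' The factorization recovers signature columns only up to a permutation of
#' the cell types. This matches the RNA signature columns `X1` to the
#' per-type mean expression profiles of the annotated single-cell reference
#' (optimal assignment on Pearson correlation, computed on the transformed
#' scale) and applies the same column permutation to both modalities, so the
#' non-RNA panel inherits the labels through the shared fractions.
#'
#' @param sig A `signature_pair` from [extract_internal_reference()].
#' @param ref An [single_cell_reference()] whose genes match the rows of
#'   `sig$X1`.
#' @param cell_types Ordered cell-type labels defining the output column
#'   order (default: sorted unique reference labels).
#' @return The `signature_pair` with columns permuted and labeled.
#' @export
align_internal_reference <- function(sig, ref, cell_types = NULL) {
  stopifnot(inherits(sig, "signature_pair"), inherits(ref, "sc_reference"))
  if (is.null(cell_types)) cell_types <- sort(unique(ref$cell_types))
  if (nrow(sig$X1) != ncol(ref$counts)) {
    stop("reference genes do not match the RNA signature rows", call. = FALSE)
  }
  ref_means <- vapply(cell_types, function(ct) {
    transform_forward(colMeans(ref$counts[ref$cell_types == ct, , drop = FALSE]),
                      sig$spec1)
  }, numeric(ncol(ref$counts)))
  mc <- match_columns(sig$X1, ref_means)
  sig$X1 <- sig$X1[, mc$perm, drop = FALSE]
  sig$X2 <- sig$X2[, mc$perm, drop = FALSE]
  sig$s1 <- sig$s1[mc$perm]
  sig$s2 <- sig$s2[mc$perm]
  colnames(sig$X1) <- colnames(sig$X2) <- cell_types
  sig$cell_types <- cell_types
  sig$match_correlations <- mc$correlations
  sig
}

#' A flat prior helper
#'
#' Convenience constructor for a symmetric `dm_prior` (equal mean fractions),
#' for callers without external cell-count tables.
#'
#' @param k Number of cell types.
#' @param v Concentration (default 10).
#' @param cell_types Optional labels.
#' @return A `dm_prior`.
#' @export
uniform_prior <- function(k, v = 10, cell_types = NULL) {
  structure(list(pi = rep(1 / k, k), v = v, cell_types = cell_types,
                 loglik = NA_real_, converged = NA, n_iter = NA_integer_),
            class = "dm_prior")
}

# save/restore global RNG so seeded helpers do not disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
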