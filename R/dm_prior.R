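#' Dirichlet-Multinomial log-likelihood of a cell-count table
#'
#' Log-likelihood of subject-level cell-type counts under a
#' Dirichlet-Multinomial model with mean proportions `pi` and concentration
#' `v` (so the Dirichlet parameter is `alpha = v * pi`). Multinomial
#' coefficients are omitted: they do not depend on `(pi, v)`.
#'
#' @param counts Subjects x cell-types matrix of nonnegative counts.
#' @param pi Length-k simplex vector of mean proportions.
#' @param v Positive concentration scalar.
#' @return Scalar log-likelihood (up to the parameter-free multinomial term).
#' @export
dm_loglik <- function(counts, pi, v) {
  counts <- as.matrix(counts)
  stopifnot(length(pi) == ncol(counts), v > 0, all(pi >= 0))
  alpha <- v * pi
  totals <- rowSums(counts)
  # guard lgamma(0) for zero-probability types with zero counts
  alpha_pos <- pmax(alpha, .Machine$double.xmin)
  per_cell <- sweep(lgamma(sweep(counts, 2, alpha_pos, "+")), 2, lgamma(alpha_pos), "-")
  sum(lgamma(v) - lgamma(totals + v)) + sum(per_cell)
}

dm_validate_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (nrow(counts) < 2L) stop("insufficient subjects", call. = FALSE)
  if (ncol(counts) < 2L) stop("at least two cell types are required", call. = FALSE)
  if (any(rowSums(counts) <= 0)) {
    stop("every subject must have a positive total cell count", call. = FALSE)
  }
  counts
}

# Moment-matching start for the DM concentration: match the between-subject
# variance of observed proportions to the DM variance of a proportion,
# Var(p_c) ~= pi_c (1 - pi_c) / (1 + v) for large totals.
dm_moment_init <- function(counts, v_cap) {
  p <- counts / rowSums(counts)
  pi0 <- colMeans(p)
  vv <- apply(p, 2, stats::var)
  ok <- is.finite(vv) & vv > 1e-12 & pi0 > 0 & pi0 < 1
  if (!any(ok)) {
    v0 <- v_cap
  } else {
    v_c <- pi0[ok] * (1 - pi0[ok]) / vv[ok] - 1
    v_c <- v_c[is.finite(v_c) & v_c > 0]
    v0 <- if (length(v_c)) min(stats::median(v_c), v_cap) else v_cap
  }
  list(pi = pi0, v = max(v0, 1e-3))
}

#' Estimate a Dirichlet-Multinomial prior from multi-subject cell counts
#'
#' Maximum-likelihood estimate of the Dirichlet-Multinomial prior `(pi, v)`
#' used to initialize per-sample cell-count fractions downstream. Starts from
#' moment matching, then refines `alpha = v * pi` by a digamma fixed-point
#' iteration with a likelihood-monotonicity safeguard and a final 1-D
#' refinement of `v`. When subjects are (near-)proportional the likelihood is
#' unbounded in `v`; `v` is then clamped at `v_cap`.
#'
#' @param counts Subjects x cell-types matrix of nonnegative integer counts
#'   (rows: subjects, columns: annotated cell types). Needs at least two
#'   subjects with positive totals.
#' @param v_cap Upper bound for the concentration (default `1e6`).
#' @param pi_floor Floor assigned to cell types never observed in any subject
#'   (all-zero columns), so downstream Dirichlet draws never degenerate.
#' @param tol,max_iter Fixed-point convergence controls.
#' @return An object of class `dm_prior`: list with `pi` (simplex vector, named
#'   after the count columns), `v`, `loglik`, `converged`, `n_iter`.
#' @examples
#' set.seed(1)
#' tab <- t(stats::rmultinom(20, 400, prob = c(0.5, 0.3, 0.2)))
#' estimate_dm_prior(tab)
#' @export
estimate_dm_prior <- function(counts, v_cap = 1e6, pi_floor = 1e-4,
                              tol = 1e-8, max_iter = 500L) {
  counts <- dm_validate_counts(counts)
  stopifnot(v_cap > 0, pi_floor > 0, pi_floor < 1)
  k <- ncol(counts)
  type_names <- colnames(counts)
  totals <- rowSums(counts)

  zero_cols <- colSums(counts) == 0
  if (any(zero_cols)) {
    warning(sprintf("%d cell type(s) with zero counts across all subjects; assigned pi floor %g",
                    sum(zero_cols), pi_floor), call. = FALSE)
  }

  init <- dm_moment_init(counts, v_cap)
  alpha <- pmax(init$pi, 1e-10) * init$v
  ll_init <- dm_loglik(counts, alpha / sum(alpha), min(sum(alpha), v_cap))

  ll_old <- ll_init
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    A <- sum(alpha)
    denom <- sum(digamma(totals + A) - digamma(A))
    numer <- colSums(digamma(sweep(counts, 2, alpha, "+"))) - nrow(counts) * digamma(alpha)
    alpha_new <- alpha * numer / denom
    alpha_new[!is.finite(alpha_new) | alpha_new < 1e-10] <- 1e-10
    if (sum(alpha_new) >= v_cap) {
      alpha_new <- alpha_new / sum(alpha_new) * v_cap
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    ll_new <- dm_loglik(counts, alpha_new / sum(alpha_new), sum(alpha_new))
    if (ll_new < ll_old - 1e-12) break  # safeguard: keep the last monotone iterate
    delta <- max(abs(alpha_new / sum(alpha_new) - alpha / sum(alpha)),
                 abs(sum(alpha_new) - sum(alpha)) / max(sum(alpha), 1))
    alpha <- alpha_new
    ll_old <- ll_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  pi_hat <- alpha / sum(alpha)
  v_hat <- min(sum(alpha), v_cap)
  # 1-D refinement of v at fixed pi (also rescues a stalled fixed point)
  opt <- stats::optimize(function(lv) dm_loglik(counts, pi_hat, exp(lv)),
                         lower = log(1e-3), upper = log(v_cap), maximum = TRUE)
  if (opt$objective > dm_loglik(counts, pi_hat, v_hat) + 1e-10) {
    v_hat <- min(exp(opt$maximum), v_cap)
  }
  # near-proportional rows: the profile in v is flat at the boundary
  if (exp(opt$maximum) > 0.99 * v_cap) v_hat <- v_cap

  if (any(zero_cols)) {
    pi_hat[zero_cols] <- pi_floor
    pi_hat <- pi_hat / sum(pi_hat)
  }
  ll_final <- dm_loglik(counts, pi_hat, v_hat)
  if (ll_final < ll_init) {
    # never return worse than the moment-matched start
    pi_hat <- init$pi
    if (any(zero_cols)) {
      pi_hat[zero_cols] <- pi_floor
      pi_hat <- pi_hat / sum(pi_hat)
    }
    v_hat <- min(init$v, v_cap)
    ll_final <- dm_loglik(counts, pi_hat, v_hat)
  }

  names(pi_hat) <- type_names
  structure(
    list(pi = as.numeric(pi_hat), v = v_hat, cell_types = type_names,
         loglik = ll_final, converged = converged, n_iter = iter),
    class = "dm_prior"
  )
}

#' @export
print.dm_prior <- function(x, ...) {
  cat("<dm_prior> Dirichlet-Multinomial prior\n")
  cat("  pi:", paste(sprintf("%.4f", x$pi), collapse = " "), "\n")
  cat(sprintf("  v: %.4g  (loglik %.4f, %d fixed-point iterations)\n",
              x$v, x$loglik, x$n_iter))
  invisible(x)
}

#' Write / read a prior as a small JSON block
#' @param prior A `dm_prior`.
#' @param path File path.
#' @return `read_dm_prior` returns a `dm_prior`; `write_dm_prior` returns
#'   `path` invisibly.
#' @export
write_dm_prior <- function(prior, path) {
  stopifnot(inherits(prior, "dm_prior"))
  jsonlite::write_json(list(pi = prior$pi, v = prior$v,
                            cell_types = prior$cell_types),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dm_prior
#' @export
read_dm_prior <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(pi = as.numeric(x$pi), v = as.numeric(x$v),
                 cell_types = x$cell_types,
                 loglik = NA_real_, converged = NA, n_iter = NA_integer_),
            class = "dm_prior")
}

# Draw rows from Dirichlet(v * pi) via gamma variates.
rdirichlet_rows <- function(n, pi, v) {
  alpha <- pmax(pi * v, 1e-8)
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}
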