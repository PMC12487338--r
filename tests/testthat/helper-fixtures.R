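# shared helpers: tiny noise-free factorization problems and small fixtures

# well-separated signatures directly on the factorization (transformed) scale
make_separated_signatures <- function(m, k, lo = 0.1, hi = 0.5,
                                      marker_lo = 3, marker_hi = 6) {
  X <- matrix(stats::runif(m * k, lo, hi), m, k)
  block <- floor(m / (2 * k))
  for (c in seq_len(k)) {
    X[((c - 1) * block + 1):(c * block), c] <- stats::runif(block, marker_lo, marker_hi)
  }
  X
}

# noise-free paired bulk constructed exactly as P0 %*% diag(s) %*% t(X),
# with one size-factor vector per modality (the shared-factor model)
make_noise_free_bulk <- function(n, m, k, seed) {
  set.seed(seed)
  X1 <- make_separated_signatures(m, k)
  X2 <- make_separated_signatures(m, k)
  P0 <- pairdecon:::rdirichlet_rows(n, rep(1 / k, k), 2)
  s1 <- stats::runif(k, 0.8, 1.2)
  s2 <- stats::runif(k, 0.8, 1.2)
  list(bulk = bulk_multiome(P0 %*% diag(s1) %*% t(X1),
                            P0 %*% diag(s2) %*% t(X2), "rna", "atac"),
       X1 = X1, X2 = X2, P0 = P0, s1 = s1, s2 = s2)
}

# small training set built around a known transformed-scale panel
make_tiny_training <- function(N = 120, m = 40, k = 2, seed = 5) {
  sp <- fixture_spec(k = k, m1 = m, m2 = m, n_cells_per_type = 60,
                     n_targets = 5, n_cells_bulk = 120, seed = seed)
  sig <- make_signatures(sp)
  ref <- make_sc_reference(sig, sp)
  X2t <- transform_forward(sig$X2 * 30, "atac")
  tset <- generate_training_set(ref, X2t, sig$cell_types,
                                sim_config(N = N, n_cells = 60, seed = seed + 1),
                                "rna", "atac")
  list(spec = sp, sig = sig, ref = ref, X2t = X2t, tset = tset)
}

tiny_train_config <- function(epochs = 6, seed = 3) {
  train_config(epochs = epochs, batch_size = 32,
               hidden = c(16L, 12L, 8L, 6L), dec_hidden = c(6L, 8L, 12L, 16L),
               adapt_steps = 5L, seed = seed)
}
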