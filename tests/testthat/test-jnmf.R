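test_that("initialization is deterministic and respects the prior", {
  nf <- make_noise_free_bulk(n = 12, m = 60, k = 3, seed = 4)
  cfg <- jnmf_config(k = 3, prior = uniform_prior(3), seed = 11)
  s1 <- init_jnmf(nf$bulk, cfg)
  s2 <- init_jnmf(nf$bulk, cfg)
  expect_identical(s1$P0, s2$P0)
  expect_identical(s1$X1, s2$X1)
  expect_true(all(s1$X1 >= 0) && all(s1$P0 >= 0))
  expect_equal(rowSums(s1$P0), rep(1, 12), tolerance = 1e-12)
})

test_that("subj_var -> 0 with a strong prior concentrates rows on pi", {
  # Dirichlet variance oracle: with concentration v, Var(p_c) ~ pi_c(1-pi_c)/v
  nf <- make_noise_free_bulk(n = 1000, m = 20, k = 3, seed = 6)
  pri <- uniform_prior(3, v = 1e6)
  st <- init_jnmf(nf$bulk, jnmf_config(k = 3, prior = pri, subj_var = 0, seed = 1))
  expect_lt(max(abs(st$P0 - 1 / 3)), 1e-2)
  # larger subj_var disperses the initialization
  st2 <- init_jnmf(nf$bulk, jnmf_config(k = 3, prior = pri, subj_var = 1, seed = 1))
  expect_gt(stats::sd(st2$P0), 10 * stats::sd(st$P0))
})

test_that("a fixed point of the objective is left unchanged", {
  set.seed(8)
  n <- 6; m <- 30; k <- 2
  X1 <- make_separated_signatures(m, k)
  X2 <- make_separated_signatures(m, k)
  P0 <- pairdecon:::rdirichlet_rows(n, rep(1 / k, k), 3)
  bulk <- bulk_multiome(P0 %*% t(X1), P0 %*% t(X2), "rna", "atac")
  cfg <- jnmf_config(k = k, prior = uniform_prior(k), seed = 1)
  st <- init_jnmf(bulk, cfg)
  st$X1 <- X1; st$X2 <- X2; st$P0 <- P0
  st$S1 <- matrix(1, n, k); st$S2 <- matrix(1, n, k)
  st$loss_trace <- pairdecon:::jnmf_loss_value(st, bulk)
  expect_lt(st$loss_trace, 1e-20)
  st2 <- jnmf_step(st, bulk, cfg)
  expect_equal(st2$X1, st$X1, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(st2$P0, st$P0, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("every sweep keeps all blocks nonnegative and the loss nonincreasing", {
  for (seed in 1:20) {
    nf <- make_noise_free_bulk(n = 8, m = 40, k = 3, seed = 100 + seed)
    cfg <- jnmf_config(k = 3, prior = uniform_prior(3), seed = seed)
    st <- init_jnmf(nf$bulk, cfg)
    for (i in 1:8) st <- jnmf_step(st, nf$bulk, cfg)
    expect_true(all(st$X1 >= 0) && all(st$X2 >= 0) &&
                  all(st$S1 >= 0) && all(st$S2 >= 0) && all(st$P0 >= 0))
    expect_true(all(diff(st$loss_trace) <= 1e-9))
    expect_equal(unname(rowSums(st$P0)), rep(1, 8), tolerance = 1e-6)
  }
})

test_that("gradient steps clamp negative intermediates to exactly zero", {
  nf <- make_noise_free_bulk(n = 6, m = 30, k = 2, seed = 3)
  cfg <- jnmf_config(k = 2, prior = uniform_prior(2), step_size = 10, seed = 2)
  st <- init_jnmf(nf$bulk, cfg)
  st <- jnmf_step(st, nf$bulk, cfg)
  # huge initial step forces the projection to act somewhere over a few sweeps
  for (i in 1:5) st <- jnmf_step(st, nf$bulk, cfg)
  expect_true(all(st$X1 >= 0))
  expect_true(min(st$X1) >= 0)
})

test_that("noise-free factorization is recovered (small instance)", {
  nf <- make_noise_free_bulk(n = 12, m = 60, k = 2, seed = 7)
  fit <- jnmf_fit(nf$bulk, jnmf_config(k = 2, prior = uniform_prior(2),
                                       max_iter = 1500, seed = 5))
  lt <- fit$loss_trace
  expect_lt(lt[length(lt)] / lt[1], 1e-3)
  expect_gte(min(match_columns(fit$X2, nf$X2)$correlations), 0.9)
  sig <- extract_internal_reference(fit, "rna", "atac")
  expect_identical(dim(sig$X2), c(60L, 2L))
  expect_true(all(sig$X1 >= 0) && all(sig$X2 >= 0))
})

test_that("degenerate inputs raise the documented errors", {
  Y0 <- matrix(0, 4, 10)
  bulk0 <- bulk_multiome(Y0, Y0, "rna", "atac")
  expect_error(jnmf_fit(bulk0, jnmf_config(k = 2, prior = uniform_prior(2))),
               "empty bulk input")
  nf <- make_noise_free_bulk(n = 5, m = 8, k = 2, seed = 1)
  expect_error(init_jnmf(nf$bulk, jnmf_config(k = 9, prior = uniform_prior(9))),
               "exceeds")
})

test_that("internal reference columns are relabeled against the reference", {
  h <- make_tiny_training(N = 10, m = 40, k = 2, seed = 12)
  # build a signature pair with deliberately swapped columns
  X1ref <- vapply(sort(unique(h$ref$cell_types)), function(ct) {
    transform_forward(colMeans(h$ref$counts[h$ref$cell_types == ct, ]), "rna")
  }, numeric(40))
  sig <- structure(list(X1 = X1ref[, c(2, 1)], X2 = h$X2t[, c(2, 1)],
                        s1 = c(1, 2), s2 = c(3, 4),
                        spec1 = modality_spec("rna"), spec2 = modality_spec("atac"),
                        cell_types = NULL),
                   class = "signature_pair")
  out <- align_internal_reference(sig, h$ref)
  expect_identical(out$cell_types, sort(unique(h$ref$cell_types)))
  expect_equal(out$X1, X1ref, ignore_attr = TRUE)
  expect_equal(out$s2, c(4, 3))
  expect_gte(min(out$match_correlations), 0.99)
})
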