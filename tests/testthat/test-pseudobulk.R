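test_that("simulated fractions live on the simplex with exact knockout zeros", {
  Th <- simulate_rna_proportions(400, 4, xi0 = 1, knockout_rate = 0.3, seed = 1)
  expect_equal(rowSums(Th), rep(1, 400), tolerance = 1e-8)
  expect_true(all(Th >= 0))
  expect_true(any(Th == 0))              # knockout produces exact zeros
  expect_true(all(rowSums(Th > 0) >= 1)) # never all types knocked out
  Th0 <- simulate_rna_proportions(200, 3, knockout_rate = 0, seed = 2)
  expect_true(all(Th0 > 0))
})

test_that("symmetric Dirichlet draws are balanced across types", {
  Th <- simulate_rna_proportions(5000, 4, xi0 = 1, knockout_rate = 0, seed = 7)
  expect_true(all(abs(colMeans(Th) - 0.25) < 0.02))
})

test_that("proportional shift honours its contracts", {
  th <- c(0.4, 0.3, 0.2, 0.1)
  expect_identical(proportional_shift(th, 1, 1, seed = 1), th)  # identity shift
  set.seed(5)
  for (i in 1:50) {
    out <- proportional_shift(th, 0.9, 1.1)
    expect_equal(sum(out), 1, tolerance = 1e-8)
    expect_true(all(out >= 0))
  }
  # zeros stay zero
  thz <- c(0.5, 0, 0.5, 0)
  out <- proportional_shift(thz, 0.9, 1.1, seed = 3)
  expect_identical(out[c(2, 4)], c(0, 0))
})

test_that("largest-remainder rounding hits the cell budget exactly", {
  expect_identical(pairdecon:::largest_remainder_counts(c(0.5, 0.5), 10), c(5, 5))
  set.seed(11)
  for (i in 1:30) {
    th <- as.numeric(pairdecon:::rdirichlet_rows(1, rep(0.25, 4), 2))
    cnt <- pairdecon:::largest_remainder_counts(th, 137)
    expect_equal(sum(cnt), 137)
    expect_true(all(cnt >= 0))
  }
  # knocked-out types receive no cells
  cnt <- pairdecon:::largest_remainder_counts(c(0.999, 0, 0.001), 10)
  expect_equal(cnt[2], 0)
})

test_that("RNA pseudo-bulk aggregates sampled cells and conserves counts", {
  counts <- rbind(c(5, 0, 2), c(0, 7, 1))
  ref <- single_cell_reference(counts, c("a", "b"))
  out <- build_rna_pseudobulk(ref, c(1, 0), c("a", "b"), n_cells = 1, seed = 1)
  expect_equal(out, c(5, 0, 2))
  h <- make_tiny_training(N = 5, m = 40, k = 2, seed = 9)
  set.seed(2)
  th <- c(0.3, 0.7)
  y <- build_rna_pseudobulk(h$ref, th, h$sig$cell_types, n_cells = 20, seed = 4)
  expect_true(all(y >= 0) && all(y == round(y)))
  expect_error(suppressWarnings(
    build_rna_pseudobulk(ref, c(0.5, 0.5), c("a", "missing"),
                         n_cells = 4, seed = 1)),
    "no reference cells")
})

test_that("non-RNA pseudo-bulk mixes on the generation scale", {
  set.seed(6)
  X2 <- transform_forward(matrix(stats::runif(40 * 3, 1, 30), 40, 3), "atac")
  th <- c(0.2, 0.5, 0.3)
  d <- build_nonrna_pseudobulk(X2, th, "atac", seed = 1)
  expect_equal(d$mean, drop(expm1(X2) %*% th), tolerance = 1e-12)
  expect_identical(d$scale, "raw")
  # a zeroed type has no influence
  X2b <- X2; X2b[, 3] <- X2b[, 3] * 100
  d2 <- build_nonrna_pseudobulk(X2b, c(0.4, 0.6, 0), "atac", seed = 1)
  d3 <- build_nonrna_pseudobulk(X2, c(0.4, 0.6, 0), "atac", seed = 1)
  expect_identical(d2$value, d3$value)
  # zero mean gives all-zero draws
  z <- build_nonrna_pseudobulk(matrix(0, 10, 2), c(0.5, 0.5), "atac", seed = 2)
  expect_identical(z$value, rep(0L, 10))
  # dnam stays on the negative-log scale
  Xd <- matrix(stats::runif(20, 0.5, 5), 10, 2)
  dd <- build_nonrna_pseudobulk(Xd, c(0.5, 0.5), "dnam", seed = 3)
  expect_equal(dd$mean, drop(Xd %*% c(0.5, 0.5)))
  expect_identical(dd$scale, "neglog")
})

test_that("Poisson resampling is unbiased around the mixture mean", {
  set.seed(13)
  X2 <- transform_forward(matrix(stats::runif(30 * 2, 2, 40), 30, 2), "atac")
  th <- c(0.6, 0.4)
  lam <- drop(expm1(X2) %*% th)
  reps <- vapply(1:2000, function(i) build_nonrna_pseudobulk(X2, th, "atac")$value,
                 numeric(30))
  z <- (rowMeans(reps) - lam) / sqrt(lam / 2000)
  expect_lt(max(abs(z)), 4.5)
  expect_gte(mean(abs(z) <= 3), 0.95)
})

test_that("training-set generation is reproducible and internally consistent", {
  h <- make_tiny_training(N = 30, m = 40, k = 2, seed = 21)
  t1 <- generate_training_set(h$ref, h$X2t, h$sig$cell_types,
                              sim_config(N = 30, n_cells = 60, seed = 77), "rna", "atac")
  t2 <- generate_training_set(h$ref, h$X2t, h$sig$cell_types,
                              sim_config(N = 30, n_cells = 60, seed = 77), "rna", "atac")
  expect_identical(t1$Y1_train, t2$Y1_train)
  expect_identical(t1$Theta2, t2$Theta2)
  expect_equal(rowSums(t1$Theta1), rep(1, 30), tolerance = 1e-8)
  expect_equal(rowSums(t1$Theta2), rep(1, 30), tolerance = 1e-8)
  expect_true(all(is.finite(t1$Y1_train)) && all(is.finite(t1$Y2_train)))
  # knocked-out entries are exactly zero in both modalities' truth
  expect_true(all((t1$Theta1 == 0) >= 0))
  expect_true(all(t1$Theta2[t1$Theta1 == 0] == 0))
})

test_that("per-sample RNA and shifted non-RNA fractions stay tightly coupled", {
  set.seed(99)
  cors <- vapply(1:1000, function(i) {
    th1 <- as.numeric(pairdecon:::rdirichlet_rows(1, rep(0.25, 4), 4))
    stats::cor(th1, proportional_shift(th1, 0.9, 1.1))
  }, numeric(1))
  expect_gte(stats::median(cors), 0.98)
})
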