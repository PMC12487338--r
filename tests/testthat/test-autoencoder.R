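test_that("celu matches its closed form and is monotone", {
  expect_equal(celu(2), 2)
  expect_equal(celu(0), 0)
  expect_equal(celu(-1), exp(-1) - 1, tolerance = 1e-12)
  expect_equal(celu(-2, alpha = 0.5), 0.5 * (exp(-4) - 1), tolerance = 1e-12)
  x <- seq(-6, 6, by = 0.01)
  expect_true(all(diff(celu(x)) >= 0))
  expect_true(all(diff(celu(x, alpha = 2)) >= 0))
  # the literal printed variant collapses to ReLU (its negative branch is
  # min(0, positive) = 0), which is why the standard form is the default
  expect_equal(celu(c(-3, -1, 2), literal = TRUE), c(0, 0, 2))
})

test_that("backpropagation matches finite differences on all blocks", {
  set.seed(7)
  cfg <- tiny_train_config()
  m1 <- 9; m2 <- 7; k <- 3; B <- 4
  params <- pairdecon:::ae_init_params(m1, m2, k, cfg)
  Y1n <- pairdecon:::normalize_rows(matrix(stats::runif(B * m1), B))
  Y2n <- pairdecon:::normalize_rows(matrix(stats::runif(B * m2), B))
  T1 <- pairdecon:::rdirichlet_rows(B, rep(1 / k, k), 5)
  T2 <- pairdecon:::rdirichlet_rows(B, rep(1 / k, k), 5)
  lossfun <- function(p) {
    fw <- pairdecon:::ae_forward(p, Y1n, Y2n)
    mean(abs(T1 - fw$theta1)) + mean(abs(T2 - fw$theta2)) +
      mean(abs(Y1n - fw$yhat1)) + mean(abs(Y2n - fw$yhat2))
  }
  fw <- pairdecon:::ae_forward(params, Y1n, Y2n)
  g <- pairdecon:::ae_backward(
    params, fw,
    dYhat1 = sign(fw$yhat1 - Y1n) / (B * m1),
    dYhat2 = sign(fw$yhat2 - Y2n) / (B * m2),
    dTheta1 = sign(fw$theta1 - T1) / (B * k),
    dTheta2 = sign(fw$theta2 - T2) / (B * k)
  )
  eps <- 1e-6
  check_block <- function(get, set, gv) {
    idx <- sample(length(get(params)), min(8, length(get(params))))
    for (ii in idx) {
      pp <- params; x <- get(pp); x[ii] <- x[ii] + eps; pp <- set(pp, x)
      up <- lossfun(pp)
      pp <- params; x <- get(pp); x[ii] <- x[ii] - eps; pp <- set(pp, x)
      dn <- lossfun(pp)
      # absolute comparison: finite differences of an L1 loss carry ~1e-10
      # round-off, while true gradient entries span 1e-7 .. 1e-1
      expect_lt(abs((up - dn) / (2 * eps) - gv[ii]), 2e-8)
    }
  }
  check_block(function(p) p$enc_W[[1]], function(p, x) { p$enc_W[[1]][] <- x; p }, g$enc_W[[1]])
  check_block(function(p) p$enc_W[[5]], function(p, x) { p$enc_W[[5]][] <- x; p }, g$enc_W[[5]])
  check_block(function(p) p$enc_b[[3]], function(p, x) { p$enc_b[[3]][] <- x; p }, g$enc_b[[3]])
  check_block(function(p) p$S1, function(p, x) { p$S1[] <- x; p }, g$S1)
  check_block(function(p) p$dec1[[1]], function(p, x) { p$dec1[[1]][] <- x; p }, g$dec1[[1]])
  check_block(function(p) p$dec2[[5]], function(p, x) { p$dec2[[5]][] <- x; p }, g$dec2[[5]])
})

test_that("proportions_from_latent applies the connection layers", {
  set.seed(3)
  k <- 4
  p <- pairdecon:::rdirichlet_rows(5, rep(1 / k, k), 5)
  I <- diag(k)
  out <- proportions_from_latent(p, I, I)
  expect_equal(out$theta1, p, tolerance = 1e-7)
  # scale invariance of the simplex projection
  out2 <- proportions_from_latent(p, 2 * I, I)
  expect_equal(out2$theta1, p, tolerance = 1e-7)
  # random case against the direct product oracle
  S1 <- matrix(stats::rnorm(16, 0.5, 0.3), 4)
  out3 <- proportions_from_latent(p, S1, I)
  raw <- p %*% S1
  expect_equal(attr(out3, "raw1"), raw, tolerance = 1e-12)
  R <- pmax(raw, 0) + 1e-8
  expect_equal(out3$theta1, R / rowSums(R), tolerance = 1e-12)
})

test_that("decode is the ReLU-wrapped five-matrix product", {
  set.seed(5)
  W <- lapply(list(c(3, 4), c(4, 5), c(5, 6), c(6, 4), c(4, 8)),
              function(d) matrix(stats::rnorm(prod(d)), d[1], d[2]))
  th <- matrix(c(0.2, 0.3, 0.5), 1)
  out <- decode(th, W)
  M <- W[[1]] %*% W[[2]] %*% W[[3]] %*% W[[4]] %*% W[[5]]
  expect_equal(out$X, pmax(M, 0), tolerance = 1e-12)
  expect_true(all(out$X >= 0))
  expect_equal(out$yhat, th %*% pmax(M, 0), tolerance = 1e-12)
  W0 <- lapply(W, function(x) x * 0)
  out0 <- decode(th, W0)
  expect_true(all(out0$X == 0) && all(out0$yhat == 0))
})

test_that("encode yields simplex latents, deterministically, batched or not", {
  h <- make_tiny_training(N = 40, m = 40, k = 2, seed = 33)
  m <- train_deconvolver(h$tset, tiny_train_config(epochs = 2, seed = 4))
  Y1 <- h$tset$Y1_train[1:6, ]; Y2 <- h$tset$Y2_train[1:6, ]
  p <- encode(m, Y1, Y2)
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p >= 0))
  expect_identical(p, encode(m, Y1, Y2))
  p_rows <- t(vapply(1:6, function(j) drop(encode(m, Y1[j, ], Y2[j, ])),
                     numeric(2)))
  expect_equal(p_rows, p, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("training reduces the loss and is bitwise reproducible", {
  h <- make_tiny_training(N = 120, m = 40, k = 2, seed = 5)
  cfg <- tiny_train_config(epochs = 8, seed = 3)
  m1 <- train_deconvolver(h$tset, cfg)
  m2 <- train_deconvolver(h$tset, cfg)
  expect_identical(m1$params, m2$params)
  tot <- m1$history$L_d + m1$history$L_r
  expect_lt(tot[8], tot[1])
  ls <- training_losses(list(Y1 = h$tset$Y1_train, Y2 = h$tset$Y2_train,
                             Theta1 = h$tset$Theta1, Theta2 = h$tset$Theta2), m1)
  expect_true(all(ls >= 0))
})

test_that("training losses match a hand-computed L1 oracle", {
  h <- make_tiny_training(N = 20, m = 40, k = 2, seed = 15)
  m <- train_deconvolver(h$tset, tiny_train_config(epochs = 2, seed = 9))
  batch <- list(Y1 = h$tset$Y1_train[1:2, ], Y2 = h$tset$Y2_train[1:2, ],
                Theta1 = h$tset$Theta1[1:2, ], Theta2 = h$tset$Theta2[1:2, ])
  fw <- pairdecon:::ae_forward(m$params,
                               standardize_input(batch$Y1, m$stats1),
                               standardize_input(batch$Y2, m$stats2))
  expected_Ld <- mean(abs(batch$Theta1 - fw$theta1)) +
    mean(abs(batch$Theta2 - fw$theta2))
  got <- training_losses(batch, m)
  expect_equal(unname(got["L_d"]), expected_Ld, tolerance = 1e-12)
})

test_that("adaptation is a no-op at zero steps and never degrades reconstruction", {
  h <- make_tiny_training(N = 120, m = 40, k = 2, seed = 5)
  m <- train_deconvolver(h$tset, tiny_train_config(epochs = 6, seed = 3))
  tc <- make_target_cohort(h$sig, h$spec)
  for (j in 1:3) {
    r0 <- adapt_sample(m, tc$bulk$Y1[j, ], tc$bulk$Y2[j, ], adapt_steps = 0)
    expect_false(r0$adapted)
    expect_identical(r0$recon_before, r0$recon_after)
    r <- adapt_sample(m, tc$bulk$Y1[j, ], tc$bulk$Y2[j, ], adapt_steps = 8)
    expect_lte(r$recon_after, r$recon_before)
    expect_equal(sum(r$theta1), 1, tolerance = 1e-6)
    expect_true(all(r$theta1 >= 0) && all(r$X1 >= 0))
  }
})

test_that("cohort purification stacks per-sample adaptations", {
  h <- make_tiny_training(N = 120, m = 40, k = 2, seed = 5)
  m <- train_deconvolver(h$tset, tiny_train_config(epochs = 6, seed = 3))
  tc <- make_target_cohort(h$sig, h$spec)
  res <- purify_cohort(m, tc$bulk, adapt_steps = 4)
  expect_equal(unname(rowSums(res$Theta1)), rep(1, nrow(tc$bulk$Y1)), tolerance = 1e-6)
  expect_equal(unname(rowSums(res$Theta2)), rep(1, nrow(tc$bulk$Y1)), tolerance = 1e-6)
  expect_true(all(res$recon_after <= res$recon_before + 1e-12))
  expect_length(res$purified1, nrow(tc$bulk$Y1))
  expect_true(all(res$purified1[[1]] >= 0))
  # n = 1 cohort equals a single adaptation call (training statistics apply)
  b1 <- bulk_multiome(tc$bulk$Y1[1, , drop = FALSE], tc$bulk$Y2[1, , drop = FALSE],
                      "rna", "atac")
  r1 <- purify_cohort(m, b1, adapt_steps = 4)
  a1 <- adapt_sample(m, tc$bulk$Y1[1, ], tc$bulk$Y2[1, ], adapt_steps = 4)
  expect_equal(drop(r1$Theta1), a1$theta1, tolerance = 1e-12, ignore_attr = TRUE)
  # feature-order mismatch is caught
  bad <- tc$bulk
  colnames(bad$Y1)[2] <- "not_a_gene"
  expect_error(purify_cohort(m, bad), "mismatch")
  # purified_matrix extracts a samples x features view
  M <- purified_matrix(res, 1, modality = 2, weighted = FALSE)
  expect_identical(dim(M), c(5L, 40L))
  expect_true(all(purified_matrix(res, 1, modality = 2, scale = "raw") >= 0))
})
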