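test_that("signature generation plants disjoint, elevated marker blocks", {
  sp <- fixture_spec(k = 4, m1 = 160, m2 = 160, marker_fold = 5, seed = 3)
  sig <- make_signatures(sp)
  # disjointness
  all_idx <- unlist(sig$markers1)
  expect_identical(anyDuplicated(all_idx), 0L)
  # marker elevation over background, per type
  for (c in 1:4) {
    mk <- sig$markers1[[c]]
    bg <- setdiff(seq_len(160), unlist(sig$markers1))
    expect_gte(mean(sig$X1[mk, c]), 3 * mean(sig$X1[bg, c]))
  }
  # columns are well separated
  cors <- stats::cor(sig$X1)
  expect_lte(max(cors[upper.tri(cors)]), 0.5)
  expect_true(all(sig$X1 >= 0) && all(sig$X2 >= 0))
})

test_that("single-cell reference reflects its signatures", {
  sp <- fixture_spec(k = 3, m1 = 120, m2 = 120, n_cells_per_type = 200, seed = 6)
  sig <- make_signatures(sp)
  ref <- make_sc_reference(sig, sp)
  expect_true(all(ref$counts >= 0) && all(ref$counts == round(ref$counts)))
  for (c in 1:3) {
    mu <- colMeans(ref$counts[ref$cell_types == sig$cell_types[c], ])
    expect_gte(stats::cor(mu, sig$X1[, c]), 0.9)
  }
  ref2 <- make_sc_reference(sig, sp)
  expect_identical(ref$counts, ref2$counts)
})

test_that("target cohorts carry exact ground truth", {
  sp <- fixture_spec(k = 3, m1 = 90, m2 = 90, n_targets = 8,
                     shift_low = 1, shift_high = 1, seed = 4)
  sig <- make_signatures(sp)
  tc <- make_target_cohort(sig, sp)
  expect_identical(tc$Theta1, tc$Theta2)  # identity shift
  expect_equal(rowSums(tc$Theta1), rep(1, 8), tolerance = 1e-8)
  sp2 <- fixture_spec(k = 3, m1 = 90, m2 = 90, n_targets = 8, seed = 4)
  t1 <- make_target_cohort(sig, sp2)
  t2 <- make_target_cohort(sig, sp2)
  expect_identical(t1$bulk$Y1, t2$bulk$Y1)
  expect_false(identical(t1$Theta1, t1$Theta2))
})

test_that("fixture bulk matches signature-times-proportions in expectation", {
  sp <- fixture_spec(k = 2, m1 = 60, m2 = 60, n_targets = 400,
                     n_cells_bulk = 200, seed = 9)
  sig <- make_signatures(sp)
  tc <- make_target_cohort(sig, sp)
  raw <- expm1(tc$bulk$Y1)
  lam <- 200 * t(sig$X1 %*% t(tc$Theta1))
  z <- (colMeans(raw) - colMeans(lam)) / sqrt(colMeans(lam) / 400 +
                                                apply(lam, 2, stats::var) / 400)
  expect_lt(max(abs(z)), 5)
})

test_that("the two-group cohort plants its differential signal exactly", {
  sp <- fixture_spec(k = 3, m1 = 120, m2 = 120, lfc = 1, n_de_per_type = 10,
                     de_cell_types = c(1, 2), group_sizes = c(6, 6), seed = 5)
  sig <- make_signatures(sp)
  co <- make_ctsde_cohort(sig, sp)
  # the planted mean ratio equals exp(lfc) exactly on the mean parameters
  de1 <- which(co$de_truth1[[1]])
  expect_length(de1, 10)
  expect_equal(co$mu1A[de1, 1] / co$mu1B[de1, 1], rep(exp(1), 10),
               tolerance = 1e-12)
  nulls <- which(!co$de_truth1[[1]])
  expect_equal(co$mu1A[nulls, 1], co$mu1B[nulls, 1], tolerance = 1e-12)
  # type 3 carries no planted signal
  expect_false(any(co$de_truth1[[3]]))
  # lfc = 0 gives an exact null cohort on the generating means
  sp0 <- fixture_spec(k = 3, m1 = 120, m2 = 120, lfc = 0, group_sizes = c(6, 6),
                      seed = 5)
  co0 <- make_ctsde_cohort(sig, sp0)
  expect_identical(co0$mu1A, co0$mu1B)
  expect_false(any(unlist(co0$de_truth1)))
})

test_that("cell-count simulation is reproducible and respects totals", {
  tab <- simulate_cell_counts(25, c(0.2, 0.5, 0.3), v = 12, total = 400, seed = 8)
  expect_identical(dim(tab), c(25L, 3L))
  expect_true(all(rowSums(tab) == 400))
  tab2 <- simulate_cell_counts(25, c(0.2, 0.5, 0.3), v = 12, total = 400, seed = 8)
  expect_identical(tab, tab2)
})
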