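ccc_oracle <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (vx + vy + (mx - my)^2)
}

test_that("concordance penalizes location shifts and matches its definition", {
  x <- as.numeric(1:10)
  expect_equal(lins_ccc(x, x), 1)
  expect_lt(lins_ccc(x, x + 2), 1)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  set.seed(17)
  for (i in 1:20) {
    a <- stats::rnorm(50); b <- 0.5 * a + stats::rnorm(50, sd = 0.4)
    expect_equal(lins_ccc(a, b), ccc_oracle(a, b), tolerance = 1e-10)
    # symmetry and the |CCC| <= |r| bound
    expect_equal(lins_ccc(a, b), lins_ccc(b, a), tolerance = 1e-12)
    expect_lte(abs(lins_ccc(a, b)), abs(pearson_r(a, b)) + 1e-12)
  }
})

test_that("zero-variance conventions hold", {
  expect_equal(lins_ccc(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_warning(v <- lins_ccc(c(1, 1, 1), c(2, 2, 2)), "constant")
  expect_equal(v, 0)
  expect_warning(v2 <- lins_ccc(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_equal(v2, 0)
})

test_that("mae matches hand computations and flags exact agreement", {
  expect_equal(mae(c(0.2, 0.8), c(0.3, 0.7)), 0.1)
  expect_equal(mae(1:5, 1:5), 0)
  set.seed(4)
  a <- stats::runif(30); b <- stats::runif(30)
  expect_equal(mae(a, b), mean(abs(a - b)), tolerance = 1e-14)
})

test_that("cohort metrics flatten proportion matrices and break down by type", {
  set.seed(9)
  truth <- pairdecon:::rdirichlet_rows(20, rep(0.25, 4), 4)
  est <- pmax(truth + matrix(stats::rnorm(80, sd = 0.05), 20), 0)
  est <- est / rowSums(est)
  rep <- proportion_metrics(est, truth)
  expect_equal(rep$ccc, ccc_oracle(as.numeric(est), as.numeric(truth)),
               tolerance = 1e-10)
  expect_identical(nrow(rep$per_cell_type), 4L)
  expect_true(all(rep$per_cell_type$mae >= 0))
})

test_that("rank-sum testing excludes invalid features and adjusts with BH", {
  set.seed(3)
  A <- cbind(const = rep(2, 10), matrix(stats::rnorm(10 * 5), 10))
  B <- cbind(const = rep(2, 12), matrix(stats::rnorm(12 * 5, mean = 2), 12))
  colnames(A) <- colnames(B) <- c("const", paste0("g", 1:5))
  rep <- ctsde_test(A, B)
  expect_false(rep$table$tested[1])
  expect_true(is.na(rep$table$raw_p[1]))
  expect_equal(rep$n_tested, 5L)
  tab <- rep$table[rep$table$tested, ]
  expect_equal(tab$adj_p, stats::p.adjust(tab$raw_p, "BH"))
  expect_true(all(tab$adj_p >= tab$raw_p - 1e-15))
  expect_true(all(rep$table$call == (!is.na(rep$table$adj_p) &
                                       rep$table$adj_p < 0.05)))
  expect_error(ctsde_test(A[1:2, ], B[1:2, ]), "at least 3")
  expect_error(ctsde_test(A[, 1, drop = FALSE], B[, 1, drop = FALSE]),
               "zero variance")
})

test_that("planted mean shifts are recovered with high F1", {
  set.seed(23)
  m <- 400; n_de <- 50
  truth <- c(rep(TRUE, n_de), rep(FALSE, m - n_de))
  A <- matrix(stats::rnorm(100 * m), 100)
  B <- matrix(stats::rnorm(100 * m), 100)
  B[, 1:n_de] <- B[, 1:n_de] + 1.5
  rep <- ctsde_test(A, B, truth = truth)
  expect_gte(rep$f1, 0.8)
  expect_gte(rep$sensitivity, 0.9)
})

test_that("detection metrics match the confusion-matrix oracle", {
  expect_equal(unname(de_detection_metrics(c(TRUE, FALSE), c(TRUE, FALSE))),
               c(1, 1, 1))
  r <- de_detection_metrics(rep(FALSE, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(r[c("sensitivity", "f1")]), c(0, 0))
  set.seed(8)
  for (i in 1:10) {
    calls <- stats::runif(40) > 0.6
    truth <- stats::runif(40) > 0.7
    got <- de_detection_metrics(calls, truth)
    tp <- sum(calls & truth); fp <- sum(calls & !truth)
    fn <- sum(!calls & truth); tn <- sum(!calls & !truth)
    expect_equal(unname(got["sensitivity"]), tp / (tp + fn))
    expect_equal(unname(got["specificity"]), tn / (tn + fp))
  }
})

test_that("the minimum-valid-features filter applies the 300 boundary", {
  set.seed(2)
  mk <- function(n_valid, m = 320) {
    M <- matrix(1, 10, m)
    if (n_valid > 0) M[, seq_len(n_valid)] <- stats::rnorm(10 * n_valid)
    M
  }
  expect_false(min_valid_features_filter(mk(299))$pass)
  expect_true(min_valid_features_filter(mk(300))$pass)
  r <- min_valid_features_filter(matrix(5, 8, 10))
  expect_false(r$pass)
  expect_equal(r$n_valid, 0L)
})

test_that("column matching finds the planted permutation", {
  set.seed(12)
  truth <- matrix(stats::rnorm(50 * 4), 50)
  est <- truth[, c(3, 1, 4, 2)] + matrix(stats::rnorm(200, sd = 0.1), 50)
  mc <- match_columns(est, truth)
  expect_equal(mc$perm, c(2, 4, 1, 3), ignore_attr = TRUE)
  expect_gte(min(mc$correlations), 0.9)
})
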