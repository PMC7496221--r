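test_that("likelihood-ratio test matches closed-form chi-square values", {
  design <- two_cond_design()
  # identical data in all conditions: lambda = 1, stat = 0, p = 1
  x <- matrix(c(6, 9, 6, 9), 1)
  k <- matrix(1, 1, 4)
  res <- lrt_pixels(x, k, matrix(0.1, 1, 4), design)
  expect_equal(res$lrt_stat, 0, tolerance = 1e-9)
  expect_equal(res$p, 1)
  # stat = 16 with two degrees of freedom: p = exp(-8)
  expect_equal(pchisq(16, df = 2, lower.tail = FALSE), exp(-8))
  # degrees of freedom follow |C| - 1
  expect_equal(length(design$conditions) - 1L, 1L)
  reps3 <- c("A1", "A2", "B1", "B2", "C1", "C2")
  d3 <- study_design(c("A", "B", "C"), reps3,
                     stats::setNames(substr(reps3, 1, 1), reps3))
  x3 <- matrix(c(5, 7, 30, 34, 5, 6), 1)
  r3 <- lrt_pixels(x3, matrix(1, 1, 6), matrix(0.05, 1, 6), d3)
  expect_equal(r3$p, pchisq(r3$lrt_stat, df = 2, lower.tail = FALSE))
  # all-zero pixel: boundary fit, p forced to 1
  r0 <- lrt_pixels(matrix(0, 1, 4), k, matrix(0.1, 1, 4), design)
  expect_equal(r0$p, 1)
  expect_equal(r0$lrt_stat, 0)
})

test_that("LRT reduces to the Poisson deviance test as dispersion vanishes", {
  set.seed(51)
  design <- two_cond_design()
  n <- 50
  x <- matrix(rpois(n * 4, 30), n, 4)
  k <- matrix(1, n, 4)
  res <- lrt_pixels(x, k, matrix(1e-14, n, 4), design)
  # brute-force oracle: Poisson deviance with group/grand means by grid
  # refinement around the closed-form optimum
  dev_stat <- function(xr) {
    muA <- mean(xr[1:2]); muB <- mean(xr[3:4]); mu0 <- mean(xr)
    ll <- function(mu, xs) sum(dpois(xs, mu, log = TRUE))
    2 * (ll(muA, xr[1:2]) + ll(muB, xr[3:4]) - ll(mu0, xr))
  }
  oracle <- apply(x, 1, dev_stat)
  expect_equal(res$lrt_stat, oracle, tolerance = 1e-6)
})

test_that("the statistic is invariant to replicate relabeling", {
  set.seed(52)
  design <- two_cond_design()
  n <- 40
  x <- matrix(rnbinom(n * 4, mu = 25, size = 5), n, 4)
  k <- matrix(exp(rnorm(n * 4, 0, 0.2)), n, 4)
  a <- matrix(0.12, n, 4)
  res1 <- lrt_pixels(x, k, a, design)
  res2 <- lrt_pixels(x[, c(2, 1, 4, 3)], k[, c(2, 1, 4, 3)], a, design)
  expect_equal(res1$lrt_stat, res2$lrt_stat, tolerance = 1e-8)
})

test_that("BH over loop pixels follows the step-up procedure", {
  expect_equal(fdr_over_loops(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(fdr_over_loops(0.2), 0.2)
  expect_equal(fdr_over_loops(rep(1, 5)), rep(1, 5))
  expect_identical(fdr_over_loops(numeric(0)), numeric(0))
})

test_that("clustering uses 4-connectivity with a minimum size", {
  cl <- cluster_pixels(c(1L, 1L, 2L), c(5L, 6L, 5L), min_size = 3L)
  expect_equal(cl, rep(1L, 3))
  expect_true(is.na(cluster_pixels(4L, 9L, min_size = 3L)))
  # diagonal neighbours are separate components
  cl2 <- cluster_pixels(c(1L, 2L), c(5L, 6L), min_size = 1L)
  expect_equal(length(unique(cl2)), 2L)
})

test_that("classification labels the strongest condition with tie flags", {
  zbar <- rbind(c(5, 2), c(3, 3), c(1, 4))
  cls <- classify_pixels(zbar, significant = c(TRUE, TRUE, FALSE),
                         cluster = c(1L, 1L, 1L),
                         conditions = c("A", "B"))
  expect_equal(cls$class, c("A", "A", "constitutive"))
  expect_equal(cls$tie, c(FALSE, TRUE, FALSE))
  # dropped cluster -> unclassified
  cls2 <- classify_pixels(zbar, significant = c(TRUE, TRUE, TRUE),
                          cluster = c(NA, 1L, 1L),
                          conditions = c("A", "B"))
  expect_equal(cls2$class[1], "unclassified")
})

test_that("sample-variance dispersion follows the moment formula", {
  design <- two_cond_design()
  px <- data.table::data.table(
    x_A1 = c(4, 10), x_A2 = c(4, 2), x_B1 = c(4, 6), x_B2 = c(4, 6),
    k_A1 = 1, k_A2 = 1, k_B1 = 1, k_B2 = 1,
    z_A1 = c(4, 10), z_A2 = c(4, 2), z_B1 = c(4, 6), z_B2 = c(4, 6))
  a <- alternative_dispersion("sample_variance", px, design)
  # sigma2 = 32, zbar = 6 -> alpha = (32 - 6) / 36
  expect_equal(a[2, "A1"], (32 - 6) / 36, ignore_attr = TRUE)
  # sigma2 <= zbar -> floored at 1e-7
  expect_equal(a[1, "A1"], 1e-7, ignore_attr = TRUE)
  expect_equal(a[2, "B1"], 1e-7, ignore_attr = TRUE)
  # hand value from the defining arithmetic: s2 = 6, zbar = 2
  expect_equal(max(1e-7, (6 - 2) / 2^2), 1)
  d1 <- study_design(c("A", "B"), c("r1", "r2"),
                     c(r1 = "A", r2 = "B"))
  expect_error(alternative_dispersion("sample_variance", px[, 1:8], d1),
               ">= 2 replicates")
})

test_that("the Poisson model is anti-conservative on overdispersed nulls", {
  set.seed(53)
  design <- two_cond_design()
  n <- 4000
  x <- matrix(rnbinom(n * 4, mu = 40, size = 1 / 0.2), n, 4)
  k <- matrix(1, n, 4)
  p_pois <- lrt_pixels(x, k, matrix(0, n, 4), design)$p
  expect_gt(mean(p_pois < 0.05), 0.05)
  p_nb <- lrt_pixels(x, k, matrix(0.2, n, 4), design)$p
  expect_lt(abs(mean(p_nb < 0.05) - 0.05), 0.02)
})
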