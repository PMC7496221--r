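test_that("NB log pmf matches hand-evaluated values and the Poisson limit", {
  expect_equal(exp(nb_logpmf(0, 1, 1)), 0.5)
  expect_equal(exp(nb_logpmf(1, 1, 1)), 0.25)
  expect_equal(nb_logpmf(3, 2, 1e-10), dpois(3, 2, log = TRUE),
               tolerance = 1e-8)
  expect_equal(nb_logpmf(0, 0, 0.5), 0)  # point mass at zero mean
  expect_error(nb_logpmf(2, 0, 0.5), "positive count")
  # agrees with stats::dnbinom in the size/mu parameterization
  expect_equal(nb_logpmf(7, 4, 0.3),
               dnbinom(7, size = 1 / 0.3, mu = 4, log = TRUE))
})

test_that("qCML recovers a known dispersion with equal scaling factors", {
  set.seed(31)
  n <- 5000
  x <- cbind(rnbinom(n, mu = 20, size = 10), rnbinom(n, mu = 20, size = 10))
  k <- matrix(1, n, 2)
  a <- qcml_dispersion(x, k)
  expect_gt(a, 0.08)
  expect_lt(a, 0.12)
  # oracle: with equal scaling the pseudocounts equal the raw counts and
  # qCML reduces to direct conditional ML on the raw data
  cll <- function(alpha) loopdiffr:::qcml_cll(alpha, x)
  a_oracle <- exp(optimize(function(la) cll(exp(la)),
                           interval = log(c(1e-7, 10)),
                           maximum = TRUE, tol = 1e-8)$maximum)
  expect_equal(a, a_oracle, tolerance = 1e-3)
})

test_that("Poisson data pins the dispersion at the lower bound", {
  set.seed(32)
  x <- cbind(rpois(4000, 20), rpois(4000, 20))
  a <- qcml_dispersion(x, matrix(1, 4000, 2))
  expect_lt(a, 1e-3)
})

test_that("quantile map is the identity when scalings coincide", {
  x <- 0:40
  xt <- loopdiffr:::q2q_pseudocounts(x, mu_source = rep(12, 41),
                                     mu_target = rep(12, 41), alpha = 0.1)
  expect_equal(xt, as.numeric(x), tolerance = 1e-9)
  # a larger source mean maps counts downward
  xt2 <- loopdiffr:::q2q_pseudocounts(20, 24, 12, 0.1)
  expect_lt(xt2, 20)
})

test_that("NB mean fit solves the score equation under scaling", {
  design <- two_cond_design()
  # single observation: x = 8, k = 2 -> mu = 4 for any dispersion
  mu <- loopdiffr:::fit_mu_mle(matrix(8), matrix(2), matrix(0.7))
  expect_equal(mu, 4, tolerance = 1e-8)
  # all k equal, alpha -> 0: mu = mean(x) / k
  x <- matrix(c(3, 9, 6, 2), 1)
  mu2 <- loopdiffr:::fit_mu_mle(x, matrix(2, 1, 4), matrix(1e-14, 1, 4))
  expect_equal(mu2, mean(x) / 2, tolerance = 1e-7)
  # identical counts and scalings in both conditions: all fits agree
  xx <- matrix(c(5, 7, 5, 7), 1)
  kk <- matrix(1, 1, 4)
  alt <- fit_mu(xx, kk, matrix(0.1, 1, 4), design, "alt")
  null <- fit_mu(xx, kk, matrix(0.1, 1, 4), design, "null")
  expect_equal(unname(alt[1, "A"]), unname(alt[1, "B"]))
  expect_equal(unname(alt[1, "A"]), unname(null[1, 1]), tolerance = 1e-8)
  # all-zero pixel sits at the boundary
  expect_equal(loopdiffr:::fit_mu_mle(matrix(0, 1, 2), matrix(1, 1, 2),
                                      matrix(0.1, 1, 2)), 0)
})

test_that("rolling-variance weights follow the stated arithmetic", {
  # v = 16 -> w = (1/16)^(1/4) = 0.5 ; w_int = floor(w / min w)
  expect_equal((1 / 16)^(1 / 4), 0.5)
  set.seed(5)
  at <- 0.3 * exp(-(4:200) / 30) + 0.05 + rnorm(197, 0, 0.002)
  dm <- smooth_ddr(at, 4L, 200L)
  expect_equal(unname(dm$w), unname((1 / dm$v)^(1 / 4)))
  expect_equal(unname(dm$w_int),
               unname(pmax(floor(dm$w / min(dm$w)), 1)))
  # left-edge fill: v constant on [min_dist, min_dist + 10)
  left <- dm$v[dm$dists < 14]
  expect_true(all(left == dm$v[dm$dists == 14]))
  # right-edge fill: max over the interior
  expect_equal(unname(dm$v[dm$dists == 200]),
               max(dm$v[dm$dists >= 14 & dm$dists <= 191]))
  expect_true(all(is.finite(dm$alpha_hat) & dm$alpha_hat > 0))
})

test_that("the switch distance is the first increase of the raw curve", {
  at <- c(0.50, 0.40, 0.45, rep(0.45, 37))
  at[4:40] <- 0.45 - (1:37) * 1e-4   # decreasing afterwards
  dm <- smooth_ddr(at, 4L, 43L)
  expect_equal(dm$d_star, 6L)
  expect_equal(unname(dm$alpha_hat[dm$dists == 4]), 0.50)
  expect_equal(unname(dm$alpha_hat[dm$dists == 5]), 0.40)
  # from d* on the smoothed curve is used
  expect_equal(unname(dm$alpha_hat[dm$dists >= 6]),
               dm$g[dm$dists >= 6])
  # monotone non-increasing raw curve: smooth curve everywhere
  dm2 <- smooth_ddr(rev(sort(at)), 4L, 43L)
  expect_equal(dm2$d_star, 4L)
  expect_error(smooth_ddr(rep(0.1, 10), 4L, 13L), "at least")
})

test_that("per-distance qCML tolerates gaps and missing distances", {
  set.seed(41)
  px <- data.table::data.table(
    dist = rep(c(4L, 5L, 7L), each = 300),
    x_A1 = rnbinom(900, mu = 15, size = 10),
    x_A2 = rnbinom(900, mu = 15, size = 10),
    k_A1 = 1, k_A2 = 1)
  raw <- estimate_raw_ddr(px, c("A1", "A2"), 4L, 8L)
  expect_true(is.na(raw[["6"]]))
  expect_true(is.na(raw[["8"]]))
  expect_true(all(is.finite(raw[c("4", "5", "7")])))
})
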