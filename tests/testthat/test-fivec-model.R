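test_that("sample moments are the mean and unbiased variance", {
  mk <- function(vals) {
    n <- 60
    mid <- seq(2000, by = 4000, length.out = n)
    mats <- lapply(vals, function(v) {
      m <- matrix(v, n, n); diag(m) <- 0; m
    })
    names(mats) <- paste0("A", seq_along(vals))
    fivec_counts(lapply(mats, function(m) list(r1 = m)),
                 list(r1 = mid),
                 stats::setNames(rep("A", length(vals)), names(mats)))
  }
  mom <- sample_moments(mk(c(4, 6)), "A")$r1
  expect_equal(mom$mu[1, 2], 5)
  expect_equal(mom$s2[1, 2], 2)
  mom2 <- sample_moments(mk(c(7, 7)), "A")$r1
  expect_equal(mom2$s2[1, 2], 0)
  mom3 <- sample_moments(mk(c(0, 10)), "A")$r1
  expect_equal(mom3$mu[1, 2], 5)
  expect_equal(mom3$s2[1, 2], 50)
  expect_error(sample_moments(mk(4), "A"), ">= 2 replicates")
})

test_that("MVR fit recovers an exact quadratic mean-variance law", {
  # construct two replicates whose sample moments lie exactly on
  # s2 = 0.05 mu^2 + mu: pairs (mu + e, mu - e) have variance 2 e^2
  set.seed(81)
  n <- 200
  mid <- seq(2000, by = 4000, length.out = n)
  dmat <- abs(outer(mid, mid, `-`))
  mu <- 150 * ((dmat + 4000) / 4000)^(-0.6)
  A <- 0.05
  e <- sqrt((A * mu^2 + mu) / 2)
  m1 <- mu + e; m2 <- mu - e
  m2[m2 < 0] <- 0; m1 <- 2 * mu - m2
  diag(m1) <- diag(m2) <- 0
  fc <- fivec_counts(list(A1 = list(r = m1), A2 = list(r = m2)),
                     list(r = mid), c(A1 = "A", A2 = "A"))
  mv <- fit_mvr(fc, "A")
  fitted <- mv$windows$A[is.finite(mv$windows$A)]
  expect_equal(fitted, rep(A, length(fitted)), tolerance = 1e-6)
  expect_equal(mv$windows$Abar, rep(A, nrow(mv$windows)),
               tolerance = 1e-6)
})

test_that("Poisson-like moments give zero dispersion and mu <= 1 is excluded", {
  n <- 150
  mid <- seq(2000, by = 4000, length.out = n)
  dmat <- abs(outer(mid, mid, `-`))
  mu <- 40 * ((dmat + 4000) / 4000)^(-0.5)
  e <- sqrt(mu / 2)
  m1 <- mu + e; m2 <- mu - e
  diag(m1) <- diag(m2) <- 0
  fc <- fivec_counts(list(A1 = list(r = m1), A2 = list(r = m2)),
                     list(r = mid), c(A1 = "A", A2 = "A"))
  mv <- fit_mvr(fc, "A")
  expect_equal(max(abs(mv$windows$Abar)), 0, tolerance = 1e-8)

  # interactions with mean <= 1 are excluded: windows where every pair
  # has mean exactly 1 (and huge apparent variance) yield no fit at all
  m1b <- m1; m2b <- m2
  far <- dmat > 3e5 & dmat < 4e5
  m1b[far] <- 2; m2b[far] <- 0   # mean 1, variance 2 per pair
  fcb <- fivec_counts(list(A1 = list(r = m1b), A2 = list(r = m2b)),
                      list(r = mid), c(A1 = "A", A2 = "A"))
  mvb <- fit_mvr(fcb, "A")
  sel <- mvb$windows$start >= 3.1e5 & mvb$windows$end <= 3.9e5
  expect_true(all(is.na(mvb$windows$A[sel])))
})

test_that("variance blending averages and clamps to the NB domain", {
  expect_equal(blend_variance(4, 2, mu = 1), 3)
  expect_equal(blend_variance(4, 2, mu = 1, alpha_w = 1, beta_w = 0), 4)
  # below-mean blend clamps to the Poisson edge
  expect_equal(blend_variance(1, 1, mu = 5), 5 * (1 + 1e-9))
  expect_error(blend_variance(1, 1, mu = 1, alpha_w = -1), "non-negative")
})

test_that("simulated replicates match the requested moments and seed", {
  set.seed(82)
  n <- 140
  mid <- seq(2000, by = 4000, length.out = n)
  dmat <- abs(outer(mid, mid, `-`))
  mu <- 120 * ((dmat + 4000) / 4000)^(-0.5)
  v <- mu + 0.1 * mu^2
  counts <- lapply(1:2, function(s) loopdiffr:::rnb_symmetric(mu, v))
  names(counts) <- c("A1", "A2")
  fc <- fivec_counts(lapply(counts, function(m) list(r = m)),
                     list(r = mid), c(A1 = "A", A2 = "A"))
  sim1 <- simulate_5c_replicates(fc, "A", n_sim = 3, seed = 7)
  sim2 <- simulate_5c_replicates(fc, "A", n_sim = 3, seed = 7)
  expect_identical(sim1$counts, sim2$counts)
  expect_equal(length(sim1$counts), 3L)
  # moments across many simulated replicates track the generating mean
  simbig <- simulate_5c_replicates(fc, "A", n_sim = 12, seed = 9)
  arr <- simplify2array(lapply(simbig$counts, `[[`, "r"))
  mu_hat <- apply(arr, c(1, 2), mean)
  sel <- upper.tri(mu) & mu > 20
  expect_lt(median(abs(mu_hat[sel] - (mu + 0)[sel]) /
                     pmax(sample_moments(fc, "A")$r$mu[sel], 1)), 0.2)
})

test_that("simulated and real replicates correlate comparably", {
  syn <- small_5c()
  fc <- syn$fc
  real <- cor(as.vector(fc$counts$A1$region1[upper.tri(diag(120))]),
              as.vector(fc$counts$A2$region1[upper.tri(diag(120))]),
              method = "spearman")
  sim <- simulate_5c_replicates(fc, "A", n_sim = 2, seed = 31)
  m1 <- sim$counts[[1]]$region1; m2 <- sim$counts[[2]]$region1
  simc <- cor(m1[upper.tri(m1)], m2[upper.tri(m2)], method = "spearman")
  expect_lt(abs(simc - real), 0.05)
})

test_that("the synthetic 5C baseline is deterministic with labeled truth", {
  syn1 <- make_synthetic_5c_baseline(seed = 12)
  syn2 <- make_synthetic_5c_baseline(seed = 12)
  expect_identical(syn1$fc$counts, syn2$fc$counts)
  expect_identical(syn1$truth, syn2$truth)
  expect_setequal(unique(syn1$truth$class),
                  c("A", "B", "C", "A+B", "A+C", "B+C"))
})
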