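test_that("synthetic baseline is deterministic and respects parameters", {
  b1 <- make_synthetic_baseline(n_bins = 300L, n_loops = 20L,
                                max_dist = 100L, seed = 9L)
  b2 <- make_synthetic_baseline(n_bins = 300L, n_loops = 20L,
                                max_dist = 100L, seed = 9L)
  expect_identical(b1$pixels, b2$pixels)
  expect_identical(b1$loops$pixels, b2$loops$pixels)
  expect_equal(n_loops(b1$loops), 20L)
  # no loops: pure power law, empty loop list
  b0 <- make_synthetic_baseline(n_bins = 300L, n_loops = 0L,
                                max_dist = 100L, seed = 9L)
  expect_equal(n_loops(b0$loops), 0L)
  expect_equal(b0$pixels$z, 1000 * b0$pixels$dist^(-1), tolerance = 1e-12)
  # enrichment 1: loops indistinguishable from background
  be <- make_synthetic_baseline(n_bins = 300L, n_loops = 20L,
                                max_dist = 100L, enrichment = 1,
                                seed = 9L)
  expect_equal(be$pixels$z, 1000 * be$pixels$dist^(-1), tolerance = 1e-12)
})

test_that("perturbation applies the effect size to loops and half to shells", {
  base <- make_synthetic_baseline(n_bins = 300L, n_loops = 10L,
                                  max_dist = 100L, seed = 14L)
  pert <- label_and_perturb(base, beta = 0.3, p_diff = 1, seed = 14L)
  lpx <- base$loops$pixels
  merged <- merge(pert$pixels, lpx[, .(i, j, loop_id)], by = c("i", "j"))
  merged[, cat := pert$loop_labels[loop_id]]
  up_a <- merged[cat == "up_A"]
  expect_true(nrow(up_a) > 0)
  expect_equal(up_a$mu_A, up_a$z * 1.3)
  expect_equal(up_a$mu_B, up_a$z)
  expect_true(all(up_a$t == 1L))
  down_b <- merged[cat == "down_B"]
  expect_equal(down_b$mu_B, down_b$z * 0.7)
  expect_equal(down_b$mu_A, down_b$z)
  # an adjacent non-loop pixel gets half the effect
  one <- up_a[1]
  shell <- pert$pixels[i == one$i - 1L & j == one$j]
  if (nrow(shell) == 1L) {
    expect_equal(shell$mu_A, shell$z * 1.15)
    expect_equal(shell$t, 0L)
  }
  # worked numbers: z = 10, beta = 0.3 -> 13 on the loop, 11.5 adjacent
  expect_equal(10 * (1 + 0.3), 13)
  expect_equal(10 * (1 + 0.3 / 2), 11.5)
})

test_that("beta = 0 and constitutive loops leave the field unchanged", {
  base <- make_synthetic_baseline(n_bins = 300L, n_loops = 10L,
                                  max_dist = 100L, seed = 15L)
  p0 <- label_and_perturb(base, beta = 0, p_diff = 0.5, seed = 15L)
  expect_equal(p0$pixels$mu_A, p0$pixels$z)
  expect_equal(p0$pixels$mu_B, p0$pixels$z)
  pc <- label_and_perturb(base, beta = 0.4, p_diff = 0, seed = 15L)
  expect_equal(pc$pixels$mu_A, pc$pixels$z)
  expect_true(all(pc$pixels$t == 0L))
  expect_error(label_and_perturb(base, beta = 1.2, p_diff = 0.5),
               "beta")
})

test_that("condition labels are exchangeable by symmetry", {
  base <- make_synthetic_baseline(n_bins = 300L, n_loops = 12L,
                                  max_dist = 100L, seed = 16L)
  pert <- label_and_perturb(base, beta = 0.5, p_diff = 0.8, seed = 16L)
  # swapping A<->B in the category map must swap the two mean fields
  swap <- c(up_A = "up_B", down_A = "down_B", up_B = "up_A",
            down_B = "down_A", constitutive = "constitutive")
  swapped <- swap[pert$loop_labels]
  names(swapped) <- names(pert$loop_labels)
  pert2 <- label_and_perturb(base, beta = 0.5, p_diff = 0.8,
                             labels = swapped)
  expect_equal(pert$pixels$mu_A, pert2$pixels$mu_B)
  expect_equal(pert$pixels$mu_B, pert2$pixels$mu_A)
  expect_equal(pert$pixels$t, pert2$pixels$t)
})

test_that("sampling reproduces the requested NB moments", {
  px <- data.table::data.table(i = 0:9999, j = 10L:10009L,
                               dist = 10L, z = 100)
  px[, `:=`(mu_A = z, mu_B = z, t = 0L)]
  design <- study_design(c("A", "B"), c("A1", "B1"),
                         c(A1 = "A", B1 = "B"))
  # near-Poisson limit: sample mean within the CLT band
  cm <- bias_and_sample(list(pixels = px), design,
                        alpha_fun = function(d) rep(0, length(d)),
                        n_bins = 10100L, seed = 4L)
  mean_a <- sum(cm$A1$entries$count) / 10000
  expect_gt(mean_a, 97); expect_lt(mean_a, 103)
  # dispersion 0.1 at mu 100: variance close to mu + alpha mu^2 = 1100
  px5 <- px[rep(1:10000, 5)]
  px5[, `:=`(i = 0:49999, j = 10L:50009L)]
  cm2 <- bias_and_sample(list(pixels = px5), design,
                         alpha_fun = function(d) rep(0.1, length(d)),
                         n_bins = 50100L, seed = 5L)
  counts <- merge(px5[, .(i, j)], cm2$A1$entries, by = c("i", "j"),
                  all.x = TRUE)
  counts[is.na(count), count := 0]
  expect_equal(var(counts$count), 1100, tolerance = 0.1)
  # bias doubling a row doubles expected counts there
  bias <- rep(1, 10100); bias[1] <- 2
  cm3 <- bias_and_sample(list(pixels = px), design,
                         alpha_fun = function(d) rep(0, length(d)),
                         bias = list(A1 = bias, B1 = bias),
                         n_bins = 10100L, seed = 6L)
  row0 <- cm3$A1$entries[i == 0]$count
  expect_gt(row0, 130)  # Poisson(200): far above the mu = 100 rows
  # determinism
  cm4 <- bias_and_sample(list(pixels = px), design,
                         alpha_fun = function(d) rep(0, length(d)),
                         n_bins = 10100L, seed = 4L)
  expect_identical(cm4$A1$entries, cm$A1$entries)
})

test_that("truth prevalence equals the planted differential fraction", {
  base <- make_synthetic_baseline(n_bins = 600L, n_loops = 100L,
                                  max_dist = 150L, seed = 18L)
  for (pd in c(0, 0.4, 1)) {
    pert <- label_and_perturb(base, beta = 0.3, p_diff = pd, seed = 18L)
    truth <- merge(loop_footprint(base$loops),
                   pert$pixels[, .(i, j, t)], by = c("i", "j"))
    expect_equal(estimate_truth_prevalence(truth), pd, tolerance = 1e-9)
  }
})
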