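# Shared fixtures built in code. Sizes are kept small; statistically
# demanding checks live in test-acceptance.R with their own sizes.

library(data.table)

two_cond_design <- function(n_rep = 2L, min_dist = 4L, max_dist = 120L) {
  reps <- c(paste0("A", seq_len(n_rep)), paste0("B", seq_len(n_rep)))
  study_design(
    conditions = c("A", "B"), replicates = reps,
    condition_of = stats::setNames(substr(reps, 1, 1), reps),
    min_dist_bins = min_dist, max_dist_bins = max_dist)
}

# small dense contact matrix from a dense symmetric base matrix
cm_from_dense <- function(M, chrom = "chr1", replicate_id = "A1") {
  idx <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  contact_matrix(chrom, nrow(M), idx[, 1] - 1L, idx[, 2] - 1L,
                 M[idx], replicate_id = replicate_id)
}

# one cached small simulated experiment reused across integration tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_hic_experiment(
        n_bins = 400L, n_loops = 40L, beta = 0.6, p_diff = 0.4,
        max_dist = 120L, seed = 3L)
    }
    cache
  }
})

small_call <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      cache <<- hic_call(sim$counts, sim$loops, sim$design, fdr = 0.05,
                         filter_min_nonzero = 5L, filter_window = 100L)
    }
    cache
  }
})

# small synthetic 5C dataset shared by the 5C test files
small_5c <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_synthetic_5c_baseline(seed = 5L)
    cache
  }
})

small_5c_is <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fivec_is_pipeline(small_5c()$fc)
    cache
  }
})
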