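#' Construct a 5C counts container
#'
#' Holds dense symmetric fragment-level matrices of normalized counts for
#' several conditions, replicates and genomic regions, plus fragment
#' midpoints per region. The diagonal is ignored throughout.
#'
#' @param counts nested named list: `counts[[replicate]][[region]]` is an
#'   `n_r x n_r` symmetric non-negative matrix.
#' @param midpoints named list per region of fragment midpoints in bp.
#' @param condition_of named character vector replicate -> condition.
#' @return object of class `fivec_counts`.
#' @export
fivec_counts <- function(counts, midpoints, condition_of) {
  reps <- names(counts)
  stopifnot(all(reps %in% names(condition_of)))
  regions <- names(midpoints)
  for (r in reps) {
    stopifnot(identical(sort(names(counts[[r]])), sort(regions)))
    for (rg in regions) {
      m <- counts[[r]][[rg]]
      if (!isSymmetric(unname(m), tol = 1e-8)) {
        stop("matrix for ", r, "/", rg, " is not symmetric")
      }
      if (any(m < 0)) stop("negative counts in ", r, "/", rg)
      if (nrow(m) != length(midpoints[[rg]])) {
        stop("matrix size does not match midpoints in ", rg)
      }
    }
  }
  structure(list(counts = counts, midpoints = midpoints,
                 condition_of = condition_of[reps],
                 conditions = unique(unname(condition_of[reps]))),
            class = "fivec_counts")
}

#' @export
print.fivec_counts <- function(x, ...) {
  cat("fivec_counts:", length(x$counts), "replicates (",
      paste(x$conditions, collapse = ", "), "),",
      length(x$midpoints), "regions\n")
  invisible(x)
}

fivec_reps_of <- function(fc, condition) {
  names(fc$condition_of)[fc$condition_of == condition]
}

#' Per-interaction sample moments within one condition
#'
#' Arithmetic mean and unbiased sample variance of the normalized counts
#' across the condition's replicates, per region.
#'
#' @param fc a [fivec_counts].
#' @param condition condition label (needs >= 2 replicates).
#' @return named list per region with matrices `mu` and `s2`.
#' @export
sample_moments <- function(fc, condition) {
  reps <- fivec_reps_of(fc, condition)
  if (length(reps) < 2L) stop("need >= 2 replicates in ", condition)
  out <- list()
  for (rg in names(fc$midpoints)) {
    mats <- lapply(reps, function(r) fc$counts[[r]][[rg]])
    arr <- simplify2array(mats)
    mu <- apply(arr, c(1, 2), mean)
    s2 <- apply(arr, c(1, 2), stats::var)
    out[[rg]] <- list(mu = mu, s2 = s2)
  }
  out
}

# Sliding-window scheme over genomic distance: fine windows near the
# diagonal where counts are dense, coarser ones further out.
mvr_windows <- function() {
  r1 <- seq(0, 150e3 - 12e3, by = 4e3)
  r2 <- seq(151e3, 600e3 - 24e3, by = 8e3)
  r3 <- seq(601e3, 1000e3 - 60e3, by = 24e3)
  data.table(
    start = c(r1, r2, r3),
    end = c(r1 + 12e3, r2 + 24e3, r3 + 60e3),
    regime = rep(1:3, c(length(r1), length(r2), length(r3))))
}

#' Fit the mean-variance relationship of 5C counts for one condition
#'
#' Pools per-interaction sample moments across all regions into overlapping
#' distance windows (12 kb windows / 4 kb step below 150 kb, 24 kb / 8 kb
#' to 600 kb, 60 kb / 24 kb to 1 Mb) and fits `s2 = A * mu^2 + mu` per
#' window by least squares on `(s2 - mu) ~ mu^2`, constrained `A >= 0`.
#' Interactions with `mu <= 1` or `mu` more than 2.5 standard deviations
#' above the window's mean of means are excluded from fitting. The fitted
#' `A` values are LOWESS-smoothed against the window median distance
#' (fraction `smooth_frac`), giving final `Abar` per window.
#'
#' @param fc a [fivec_counts].
#' @param condition condition label.
#' @param smooth_frac LOWESS fraction (default 0.5).
#' @param min_points windows with fewer surviving interactions than this
#'   get `A = NA`, filled by the smoother (default 3).
#' @return object of class `mvr_model` with the window table (`start`,
#'   `end`, `mid`, `A`, `Abar`) and the condition label.
#' @export
fit_mvr <- function(fc, condition, smooth_frac = 0.5, min_points = 3L) {
  mom <- sample_moments(fc, condition)
  rows <- list()
  for (rg in names(mom)) {
    mid <- fc$midpoints[[rg]]
    n <- length(mid)
    ut <- which(upper.tri(mom[[rg]]$mu), arr.ind = TRUE)
    rows[[rg]] <- data.table(
      dist = abs(mid[ut[, 2]] - mid[ut[, 1]]),
      mu = mom[[rg]]$mu[ut], s2 = mom[[rg]]$s2[ut])
  }
  pts <- rbindlist(rows)
  win <- mvr_windows()
  win[, mid := NA_real_]
  win[, A := NA_real_]
  for (wi in seq_len(nrow(win))) {
    sel <- pts[dist >= win$start[wi] & dist < win$end[wi]]
    if (!nrow(sel)) {
      win$mid[wi] <- (win$start[wi] + win$end[wi]) / 2
      next
    }
    win$mid[wi] <- median(sel$dist)
    keep <- sel$mu > 1
    if (sum(keep) >= 2L) {
      mm <- mean(sel$mu[keep]); ss <- sd(sel$mu[keep])
      if (is.finite(ss) && ss > 0) keep <- keep & sel$mu <= mm + 2.5 * ss
    }
    sel <- sel[keep]
    if (nrow(sel) < min_points) next
    A <- sum(sel$mu^2 * (sel$s2 - sel$mu)) / sum(sel$mu^4)
    win$A[wi] <- max(A, 0)
  }
  ok <- is.finite(win$A)
  if (!any(ok)) stop("no window had enough interactions to fit the MVR")
  fit <- stats::lowess(win$mid[ok], win$A[ok], f = smooth_frac, iter = 0)
  sm <- unique(data.table(x = fit$x, y = fit$y), by = "x")
  win[, Abar := pmax(stats::approx(sm$x, sm$y, xout = win$mid,
                                   rule = 2)$y, 0)]
  structure(list(windows = win, condition = condition,
                 smooth_frac = smooth_frac),
            class = "mvr_model")
}

#' @export
print.mvr_model <- function(x, ...) {
  cat("mvr_model (", x$condition, "):", nrow(x$windows), "windows; Abar",
      sprintf("%.4g-%.4g", min(x$windows$Abar), max(x$windows$Abar)), "\n")
  invisible(x)
}

#' Smoothed dispersion at given genomic distances
#'
#' Uses the window whose midpoint is nearest to the queried distance;
#' distances beyond the last window reuse its value.
#'
#' @param model an `mvr_model`.
#' @param dist_bp distances in bp.
#' @return `Abar` values.
#' @export
mvr_dispersion <- function(model, dist_bp) {
  mids <- model$windows$mid
  idx <- vapply(dist_bp, function(d) which.min(abs(mids - d)), integer(1))
  model$windows$Abar[idx]
}

#' Blend model-predicted and observed variances
#'
#' `sigma2_bar = alpha_w * sigma2_hat + beta_w * s2`, clamped from below to
#' `mu * (1 + 1e-9)` wherever `mu > 0` so that an NB distribution with that
#' mean/variance pair exists (at the clamp the draw degenerates to Poisson).
#'
#' @param sigma2_hat predicted variance (`Abar * mu^2 + mu`).
#' @param s2 observed sample variance.
#' @param mu sample mean (for the clamp).
#' @param alpha_w,beta_w blend weights (defaults 0.5 and 0.5).
#' @return blended variance.
#' @export
blend_variance <- function(sigma2_hat, s2, mu, alpha_w = 0.5,
                           beta_w = 0.5) {
  if (alpha_w < 0 || beta_w < 0) stop("weights must be non-negative")
  pmax(alpha_w * sigma2_hat + beta_w * s2, mu * (1 + 1e-9))
}

# draw one symmetric NB matrix from (mu, var) parameterization
rnb_symmetric <- function(mu, v) {
  n <- nrow(mu)
  ut <- upper.tri(mu, diag = TRUE)
  m <- mu[ut]; vv <- v[ut]
  x <- numeric(length(m))
  pos <- m > 0
  pois <- pos & vv <= m * (1 + 1e-12)
  x[pois] <- rpois(sum(pois), m[pois])
  nb <- pos & !pois
  if (any(nb)) {
    size <- m[nb]^2 / (vv[nb] - m[nb])
    x[nb] <- rnbinom(sum(nb), mu = m[nb], size = size)
  }
  out <- matrix(0, n, n)
  out[ut] <- x
  out <- out + t(out)
  diag(out) <- diag(out) / 2
  out
}

#' Simulate pseudoreplicates of one 5C condition
#'
#' Draws `n_sim` replicate matrices per region from
#' `NB(mu, sigma2_bar)` where `mu` is the condition's per-interaction
#' sample mean and `sigma2_bar` blends the MVR-predicted and observed
#' variances. This is the null-set generator for the empirical-FDR
#' procedure.
#'
#' @param fc a [fivec_counts].
#' @param condition condition whose replicates seed the model (the most
#'   dispersed condition gives the most conservative empirical FDR).
#' @param n_sim number of simulated replicates (default 6).
#' @param alpha_w,beta_w variance blend weights (default 0.5 / 0.5).
#' @param seed master seed.
#' @param mvr optionally a pre-fitted `mvr_model`.
#' @return a [fivec_counts] of `n_sim` replicates named
#'   `<condition>_sim<k>`, all mapped to condition `<condition>`.
#' @export
simulate_5c_replicates <- function(fc, condition, n_sim = 6L,
                                   alpha_w = 0.5, beta_w = 0.5,
                                   seed = 1L, mvr = NULL) {
  mom <- sample_moments(fc, condition)
  if (is.null(mvr)) mvr <- fit_mvr(fc, condition)
  out <- list()
  for (k in seq_len(n_sim)) {
    rep_name <- sprintf("%s_sim%d", condition, k)
    mats <- list()
    for (rg in names(mom)) {
      mu <- mom[[rg]]$mu
      s2 <- mom[[rg]]$s2
      mid <- fc$midpoints[[rg]]
      dmat <- abs(outer(mid, mid, `-`))
      Abar <- matrix(mvr_dispersion(mvr, as.vector(dmat)), nrow(mu))
      sig2hat <- Abar * mu^2 + mu
      v <- blend_variance(sig2hat, s2, mu, alpha_w, beta_w)
      mats[[rg]] <- with_seed(substream_seed(seed, "5c", condition, k, rg),
                              rnb_symmetric(mu, v))
    }
    out[[rep_name]] <- mats
  }
  fivec_counts(out, fc$midpoints,
               stats::setNames(rep(condition, n_sim), names(out)))
}

#' Generate a synthetic multi-condition 5C dataset with known truth
#'
#' Fragment midpoints are laid out with irregular spacing; the background
#' mean decays as a power law of distance; 2x2-fragment loop foci are
#' planted for each looping class (every nonempty proper subset of the
#' conditions), enriched in the member conditions only. Counts are drawn
#' as NB with variance `mu + A(d) * mu^2` where the dispersion `A(d)`
#' rises toward short distances.
#'
#' @param conditions condition labels (default A, B, C).
#' @param n_replicates replicates per condition (default 2).
#' @param n_frags fragments per region (default 120).
#' @param n_regions number of regions (default 2).
#' @param n_per_class planted loops per looping class (default 2).
#' @param enrichment loop strength multiplier (default 6).
#' @param scale background mean at zero distance (default 200).
#' @param decay power-law exponent (default 1).
#' @param dispersion_fun `A(d)` in bp (default declining exponential plus
#'   floor).
#' @param seed master seed.
#' @return list with `fc` (a [fivec_counts]), `truth` (data.table of
#'   planted loci: region, i, j, class) and the generator parameters.
#' @export
make_synthetic_5c_baseline <- function(conditions = c("A", "B", "C"),
                                       n_replicates = 2L, n_frags = 120L,
                                       n_regions = 2L, n_per_class = 2L,
                                       enrichment = 6, scale = 200,
                                       decay = 1,
                                       dispersion_fun = function(d)
                                         0.02 + 0.15 * exp(-d / 1e5),
                                       seed = 1L) {
  classes <- fivec_classes(conditions)
  regions <- sprintf("region%d", seq_len(n_regions))
  midpoints <- list()
  mu0 <- list()
  truth <- list()
  for (rg in regions) {
    midpoints[[rg]] <- with_seed(substream_seed(seed, "frag", rg), {
      cumsum(runif(n_frags, 2500, 5500))
    })
    mid <- midpoints[[rg]]
    dmat <- abs(outer(mid, mid, `-`))
    mu0[[rg]] <- scale * ((dmat + 4000) / 4000)^(-decay)
  }
  # per-condition mean fields with planted class-specific foci
  mu_cond <- lapply(conditions, function(cc) mu0)
  names(mu_cond) <- conditions
  truth <- with_seed(substream_seed(seed, "truth"), {
    rows <- list()
    for (rg in regions) {
      mid <- midpoints[[rg]]
      taken <- matrix(FALSE, n_frags, n_frags)
      for (ci in seq_along(classes)) {
        lab <- paste(classes[[ci]], collapse = "+")
        placed <- 0L
        attempts <- 0L
        while (placed < n_per_class && attempts < 500L) {
          attempts <- attempts + 1L
          i0 <- sample(1:(n_frags - 1L), 1L)
          j0 <- sample(1:(n_frags - 1L), 1L)
          if (i0 >= j0 - 2L) next
          d <- abs(mid[j0] - mid[i0])
          if (d < 6e4 || d > 9e5) next
          blk_i <- i0 + 0:1; blk_j <- j0 + 0:1
          guard_i <- max(1, i0 - 2):min(n_frags, i0 + 3)
          guard_j <- max(1, j0 - 2):min(n_frags, j0 + 3)
          if (any(taken[guard_i, guard_j])) next
          taken[blk_i, blk_j] <- TRUE
          placed <- placed + 1L
          for (cc in classes[[ci]]) {
            for (ii in blk_i) for (jj in blk_j) {
              mu_cond[[cc]][[rg]][ii, jj] <-
                mu_cond[[cc]][[rg]][ii, jj] * enrichment
              mu_cond[[cc]][[rg]][jj, ii] <-
                mu_cond[[cc]][[rg]][ii, jj]
            }
          }
          rows[[length(rows) + 1L]] <- data.table(
            region = rg, i = i0, j = j0, class = lab)
        }
      }
    }
    rbindlist(rows)
  })
  counts <- list()
  condition_of <- character(0)
  for (cc in conditions) {
    for (s in seq_len(n_replicates)) {
      rep_name <- sprintf("%s%d", cc, s)
      mats <- list()
      for (rg in regions) {
        mu <- mu_cond[[cc]][[rg]]
        mid <- midpoints[[rg]]
        dmat <- abs(outer(mid, mid, `-`))
        v <- mu + dispersion_fun(dmat) * mu^2
        mats[[rg]] <- with_seed(
          substream_seed(seed, "counts", rep_name, rg),
          rnb_symmetric(mu, v))
      }
      counts[[rep_name]] <- mats
      condition_of[rep_name] <- cc
    }
  }
  list(fc = fivec_counts(counts, midpoints, condition_of),
       truth = truth, conditions = conditions,
       enrichment = enrichment, seed = seed)
}
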