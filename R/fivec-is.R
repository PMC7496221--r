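#' Balance and bin one 5C region matrix
#'
#' Knight-Ruiz balances the fragment-level matrix (zero rows are excluded
#' from balancing and masked), then averages balanced counts onto a
#' regular bin grid: `B[k, l]` is the arithmetic mean of balanced counts
#' over fragment pairs whose midpoints fall within the `smooth_span`
#' window centered on the 4 kb grid positions of bins `k` and `l`
#' (`smooth_span = bin_size` gives plain binning). Empty windows are `NA`.
#'
#' @param mat symmetric fragment matrix of normalized counts.
#' @param midpoints fragment midpoints in bp.
#' @param bin_size grid step in bp (default 4000).
#' @param smooth_span smoothing window width in bp (default 16000).
#' @return list with `B` (binned matrix, `NA` = masked), `bin_centers`
#'   (bp), and the per-fragment balancing vector.
#' @export
balance_and_bin <- function(mat, midpoints, bin_size = 4000,
                            smooth_span = 16000) {
  n <- length(midpoints)
  span_bp <- max(midpoints) - min(midpoints)
  if (span_bp < bin_size) stop("region smaller than one bin")
  keep <- which(rowSums(mat) > 0)
  bal <- matrix(NA_real_, n, n)
  x <- rep(NA_real_, n)
  if (length(keep) >= 2L) {
    sub <- mat[keep, keep, drop = FALSE]
    xk <- kr_core(sub, tol = 1e-6)
    # scale so the balanced matrix keeps the original overall magnitude
    bsub <- sub * outer(xk, xk)
    bsub <- bsub * sum(sub) / sum(bsub)
    bal[keep, keep] <- bsub
    x[keep] <- xk
  }
  centers <- seq(min(midpoints) + bin_size / 2, max(midpoints),
                 by = bin_size)
  m <- length(centers)
  half <- smooth_span / 2
  # fragment -> window membership (windows overlap when smooth_span >
  # bin_size)
  members <- lapply(centers, function(ct) {
    which(midpoints >= ct - half & midpoints < ct + half)
  })
  B <- matrix(NA_real_, m, m)
  for (k in seq_len(m)) {
    fk <- members[[k]]
    if (!length(fk)) next
    for (l in k:m) {
      fl <- members[[l]]
      if (!length(fl)) next
      vals <- bal[fk, fl, drop = FALSE]
      if (k == l) {
        vals <- vals[upper.tri(vals)]
      } else {
        # drop self pairs (same fragment in both windows)
        self <- intersect(fk, fl)
        if (length(self)) {
          vals[cbind(match(self, fk), match(self, fl))] <- NA
        }
      }
      mv <- mean(vals, na.rm = TRUE)
      if (is.finite(mv)) B[k, l] <- B[l, k] <- mv
    }
  }
  list(B = B, bin_centers = centers, balancing = x)
}

# footprint mean with NA masking via shift-accumulate
shift_sum <- function(M, offsets) {
  m <- nrow(M)
  valid <- is.finite(M)
  Mz <- ifelse(valid, M, 0)
  tot <- matrix(0, m, m)
  cnt <- matrix(0, m, m)
  for (o in offsets) {
    di <- o[1]; dj <- o[2]
    src_i <- (1 + max(0, di)):(m + min(0, di))
    src_j <- (1 + max(0, dj)):(m + min(0, dj))
    dst_i <- src_i - di
    dst_j <- src_j - dj
    tot[dst_i, dst_j] <- tot[dst_i, dst_j] + Mz[src_i, src_j]
    cnt[dst_i, dst_j] <- cnt[dst_i, dst_j] + valid[src_i, src_j]
  }
  list(sum = tot, count = cnt, size = length(offsets))
}

#' Local expected matrix from donut and lower-left footprints
#'
#' For each pixel the expected value is the distance-decay expectation at
#' that pixel scaled by the ratio of observed to decay-expected signal
#' over a local footprint: a donut annulus (window radius `w`, inner
#' exclusion radius `p`, same-row/column bands removed) and a lower-left
#' quadrant (toward the diagonal), taking the elementwise maximum of the
#' two. Pixels whose footprint has fewer than `min_frac` valid cells are
#' masked.
#'
#' @param B binned matrix from [balance_and_bin()] (NA = masked).
#' @param p inner exclusion radius in bins (default 2).
#' @param w footprint radius in bins (default 6).
#' @param min_frac minimum fraction of valid footprint cells (default 0.5).
#' @return matrix `E` of expected values (NA = masked).
#' @export
local_expected <- function(B, p = 2L, w = 6L, min_frac = 0.5) {
  if (p >= w) stop("p must be smaller than w")
  m <- nrow(B)
  if (m <= 2 * w) stop("matrix too small for footprint radius w")
  # global distance-decay expectation: per-diagonal mean of B
  decay <- vapply(0:(m - 1), function(d) {
    idx <- cbind(seq_len(m - d), seq_len(m - d) + d)
    mean(B[idx], na.rm = TRUE)
  }, numeric(1))
  decay[!is.finite(decay)] <- NA_real_
  D <- matrix(decay[abs(row(B) - col(B)) + 1L], m, m)
  donut <- list()
  ll <- list()
  for (di in -w:w) for (dj in -w:w) {
    cheb <- max(abs(di), abs(dj))
    if (cheb > w || cheb <= p) next
    if (di == 0L || dj == 0L) next
    donut[[length(donut) + 1L]] <- c(di, dj)
  }
  for (di in 1:w) for (dj in -w:-1) {
    if (di <= p && dj >= -p) next
    ll[[length(ll) + 1L]] <- c(di, dj)
  }
  Bv <- B; Bv[!is.finite(D)] <- NA  # cells without decay are unusable
  e_for <- function(offsets) {
    so <- shift_sum(Bv, offsets)
    sd_ <- shift_sum(ifelse(is.finite(Bv), D, NA), offsets)
    ok <- so$count >= min_frac * so$size & sd_$sum > 0
    e <- ifelse(ok, so$sum / sd_$sum * D, NA_real_)
    e
  }
  DE <- e_for(donut)
  LL <- e_for(ll)
  E <- pmax(DE, LL, na.rm = TRUE)
  E[!is.finite(B)] <- NA_real_
  E
}

#' Log-logistic right-tail p values for observed/expected enrichments
#'
#' Fits a two-parameter log-logistic distribution to all unmasked
#' positive obs/exp ratios of one region by maximum likelihood (a
#' logistic fit on the log scale) and returns the survival function at
#' each ratio.
#'
#' @param B observed binned matrix.
#' @param E expected matrix from [local_expected()].
#' @param min_values minimum unmasked ratios needed for a stable fit
#'   (default 50).
#' @return list with `P` (matrix of right-tail p values, NA = masked) and
#'   the fitted `scale` and `shape`.
#' @export
loglogistic_pvalues <- function(B, E, min_values = 50L) {
  ratio <- B / E
  ok <- is.finite(ratio) & ratio > 0
  vals <- log(ratio[ok & upper.tri(ratio)])
  if (length(vals) < min_values) {
    stop("fewer than ", min_values, " unmasked obs/exp values; ",
         "log-logistic fit unstable")
  }
  nll <- function(par) {
    mloc <- par[1]; s <- exp(par[2])
    zz <- (vals - mloc) / s
    -sum(-zz - log(s) - 2 * log1p(exp(-zz)))
  }
  fit <- optim(c(median(vals), log(max(sd(vals) * sqrt(3) / pi, 1e-3))),
               nll, method = "BFGS")
  mloc <- fit$par[1]; s <- exp(fit$par[2])
  P <- matrix(NA_real_, nrow(B), ncol(B))
  P[ok] <- plogis((log(ratio[ok]) - mloc) / s, lower.tail = FALSE)
  list(P = P, scale = exp(mloc), shape = 1 / s)
}

#' Interaction-score transform of p values
#'
#' `IS = -10 * log2(p)`; larger scores mean stronger loops. `p = 0` is
#' clipped to the smallest positive double with a warning.
#'
#' @param p p values in (0, 1].
#' @return interaction scores (>= 0).
#' @export
is_transform <- function(p) {
  if (any(p == 0, na.rm = TRUE)) {
    warning("p = 0 clipped to .Machine$double.xmin")
    p[!is.na(p) & p == 0] <- .Machine$double.xmin
  }
  -10 * log2(p)
}

#' z-score transform of p values
#'
#' Standard-normal quantile of `1 - p`; under the null the z-scores are
#' standard normal.
#'
#' @param p p values in (0, 1].
#' @return z-scores.
#' @export
z_transform <- function(p) {
  if (any(p == 0, na.rm = TRUE)) {
    warning("p = 0 clipped to .Machine$double.xmin")
    p[!is.na(p) & p == 0] <- .Machine$double.xmin
  }
  qnorm(1 - p)
}

#' Run the full 5C interaction-score pipeline
#'
#' For every replicate and region: Knight-Ruiz balancing, binning with
#' smoothing, donut / lower-left local expected, log-logistic right-tail
#' p values, and IS / z transforms. Bin pairs within `min_sep` bp of each
#' other are masked before model fitting and never reappear downstream.
#' Identical processing is applied to experimental and simulated counts.
#'
#' @param fc a [fivec_counts] (real or simulated).
#' @param bin_size,smooth_span binning parameters in bp.
#' @param p,w donut footprint parameters in bins.
#' @param min_sep short-range mask in bp (default 20000).
#' @return object of class `fivec_is`: nested list
#'   `scores[[replicate]][[region]]` with `IS`, `Z`, `P` matrices, plus
#'   `bin_centers` per region and the condition map.
#' @export
fivec_is_pipeline <- function(fc, bin_size = 4000, smooth_span = 16000,
                              p = 2L, w = 6L, min_sep = 20000) {
  scores <- list()
  bin_centers <- list()
  for (r in names(fc$counts)) {
    scores[[r]] <- list()
    for (rg in names(fc$midpoints)) {
      bb <- balance_and_bin(fc$counts[[r]][[rg]], fc$midpoints[[rg]],
                            bin_size = bin_size,
                            smooth_span = smooth_span)
      B <- bb$B
      ctr <- bb$bin_centers
      sep <- abs(outer(ctr, ctr, `-`))
      B[sep < min_sep] <- NA_real_
      E <- local_expected(B, p = p, w = w)
      pv <- loglogistic_pvalues(B, E)
      scores[[r]][[rg]] <- list(IS = is_transform(pv$P),
                                Z = z_transform(pv$P), P = pv$P)
      bin_centers[[rg]] <- ctr
    }
  }
  structure(list(scores = scores, bin_centers = bin_centers,
                 condition_of = fc$condition_of),
            class = "fivec_is")
}
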