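#' Negative binomial log pmf in mean/dispersion parameterization
#'
#' Numerically stable log of the NB pmf with mean `mu` and dispersion
#' `alpha` (variance `mu + alpha * mu^2`). `alpha = 0` dispatches to the
#' Poisson pmf, its limiting distribution. Non-integer (pseudo)counts are
#' admitted through the log-Gamma form.
#'
#' @param x counts (non-negative, possibly non-integer pseudocounts).
#' @param mu means (`mu = 0` allowed only where `x = 0`).
#' @param alpha dispersions (>= 0), recycled against `x`.
#' @return log probabilities.
#' @export
nb_logpmf <- function(x, mu, alpha) {
  n <- max(length(x), length(mu), length(alpha))
  x <- rep_len(x, n); mu <- rep_len(mu, n); alpha <- rep_len(alpha, n)
  if (any(mu < 0)) stop("mu must be non-negative")
  if (any(mu == 0 & x > 0)) stop("mu = 0 with positive count")
  out <- numeric(n)
  zero_mu <- mu == 0
  out[zero_mu] <- 0   # point mass at 0
  pois <- !zero_mu & alpha < 1e-8
  if (any(pois)) {
    out[pois] <- x[pois] * log(mu[pois]) - mu[pois] - lgamma(x[pois] + 1)
  }
  nb <- !zero_mu & !pois
  if (any(nb)) {
    r <- 1 / alpha[nb]
    m <- mu[nb]; xx <- x[nb]
    out[nb] <- lgamma(r + xx) - lgamma(xx + 1) - lgamma(r) +
      r * (log(r) - log(r + m)) + xx * (log(m) - log(r + m))
  }
  out
}

# Vectorized NB mean MLE with fixed scaling factors and dispersions.
# Solves sum_r (x_r - mu k_r) / (1 + alpha_r mu k_r) = 0 per row by
# bisection (the score is decreasing in mu and bracketed by min/max x/k).
# x, k, alpha: matrices n_pixels x n_reps. Returns mu vector (0 when all
# counts are zero).
fit_mu_mle <- function(x, k, alpha, iters = 60L) {
  x <- as.matrix(x); k <- as.matrix(k)
  alpha <- if (is.matrix(alpha)) alpha else
    matrix(alpha, nrow(x), ncol(x), byrow = length(alpha) == ncol(x))
  ratio <- x / k
  lo <- apply(ratio, 1, min)
  hi <- apply(ratio, 1, max)
  mu <- rowSums(x) / rowSums(k)
  allzero <- rowSums(x) == 0
  lo[allzero] <- hi[allzero] <- 0
  score <- function(mu) rowSums((x - mu * k) / (1 + alpha * mu * k))
  for (it in seq_len(iters)) {
    mid <- (lo + hi) / 2
    s <- score(mid)
    pos <- s > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  mu <- (lo + hi) / 2
  mu[allzero] <- 0
  mu
}

#' Fit NB interaction-strength means for one pixel set
#'
#' Maximum-likelihood fit of the replicate-independent mean `mu` under the
#' model `X_r ~ NB(mu * k_r, alpha_r)` with scaling factors `k_r`
#' (bias * bias * size factor) and dispersions held fixed. With
#' `constraint = "null"` one shared `mu` is fitted across all replicates of
#' all conditions; with `"alt"` one `mu` per condition.
#'
#' @param x,k numeric matrices, pixels x replicates.
#' @param alpha dispersion per replicate column (vector or matrix),
#'   typically the condition's DDR value at the pixel's distance.
#' @param design a [study_design] whose replicate order matches the columns.
#' @param constraint `"null"` or `"alt"`.
#' @return matrix of fitted means: one column (`mu0`) for the null fit, one
#'   column per condition for the alternative fit.
#' @export
fit_mu <- function(x, k, alpha, design, constraint = c("alt", "null")) {
  constraint <- match.arg(constraint)
  x <- as.matrix(x); k <- as.matrix(k)
  alpha <- if (is.matrix(alpha)) alpha else
    matrix(alpha, nrow(x), ncol(x), byrow = TRUE)
  if (constraint == "null") {
    out <- matrix(fit_mu_mle(x, k, alpha), ncol = 1,
                  dimnames = list(NULL, "mu0"))
    return(out)
  }
  out <- matrix(NA_real_, nrow(x), length(design$conditions),
                dimnames = list(NULL, design$conditions))
  for (cc in design$conditions) {
    cols <- which(design$condition_of == cc)
    out[, cc] <- fit_mu_mle(x[, cols, drop = FALSE],
                            k[, cols, drop = FALSE],
                            alpha[, cols, drop = FALSE])
  }
  out
}

# Quantile map of counts onto the geometric-mean scaling scale.
# Mid-p piecewise-linear CDF matching between NB(mu * k_r, alpha) (source)
# and NB(mu * kbar, alpha) (target); identity when the two coincide.
q2q_pseudocounts <- function(x, mu_source, mu_target, alpha) {
  size <- 1 / max(alpha, 1e-10)
  f_src_x <- pnbinom(x, size = size, mu = mu_source)
  f_src_xm1 <- ifelse(x >= 1, pnbinom(x - 1, size = size, mu = mu_source), 0)
  u <- 0.5 * (f_src_xm1 + f_src_x)
  mid_cdf <- function(m) {
    fm <- pnbinom(m, size = size, mu = mu_target)
    fm1 <- ifelse(m >= 1, pnbinom(m - 1, size = size, mu = mu_target), 0)
    0.5 * (fm1 + fm)
  }
  m <- qnbinom(pmin(u, 1 - 1e-15), size = size, mu = mu_target)
  # adjust m to the smallest integer with mid-p CDF >= u
  for (step in 1:100) {
    Mm <- mid_cdf(m)
    too_low <- Mm < u
    if (!any(too_low)) break
    m[too_low] <- m[too_low] + 1L
  }
  for (step in 1:100) {
    Mlow <- ifelse(m >= 1, mid_cdf(m - 1), 0)
    too_high <- m >= 1 & Mlow >= u
    if (!any(too_high)) break
    m[too_high] <- m[too_high] - 1L
  }
  Mm <- mid_cdf(m)
  Mm1 <- ifelse(m >= 1, mid_cdf(m - 1), 0)
  gap <- Mm - Mm1
  frac <- ifelse(gap > 0, (u - Mm1) / gap, 1)
  xt <- (m - 1) + frac
  pmax(xt, 0)
}

# Conditional log likelihood of pseudocounts at one distance (the qCML
# objective): sum over pixels of
#   sum_r lgamma(xt_r + 1/a) + lgamma(n/a) - lgamma(sum_r xt_r + n/a)
#   - n * lgamma(1/a)
qcml_cll <- function(alpha, xt) {
  r <- 1 / alpha
  n <- ncol(xt)
  sum(lgamma(xt + r)) + nrow(xt) * lgamma(n * r) -
    sum(lgamma(rowSums(xt) + n * r)) - nrow(xt) * n * lgamma(r)
}

#' Estimate one distance's dispersion by quantile-adjusted conditional ML
#'
#' Iterates (1) per-pixel NB mean fits with the current dispersion and the
#' fixed per-replicate scaling factors, (2) quantile mapping of raw counts
#' to pseudocounts on the geometric-mean scaling scale, and (3) a
#' conditional-maximum-likelihood dispersion update, until the dispersion
#' changes by less than `tol`.
#'
#' @param x counts matrix, pixels x replicates (one condition).
#' @param k matching scaling factors `b[i] * b[j] * s[d]`.
#' @param alpha_init initial dispersion guess (default 0.01).
#' @param tol stop when `|delta alpha| < tol` (default 1e-4).
#' @param bounds search interval for the dispersion (default `[1e-7, 10]`).
#' @param max_iter cap on outer iterations.
#' @return the dispersion estimate (scalar).
#' @export
qcml_dispersion <- function(x, k, alpha_init = 0.01, tol = 1e-4,
                            bounds = c(1e-7, 10), max_iter = 50L) {
  x <- as.matrix(x); k <- as.matrix(k)
  if (ncol(x) < 2L) stop("qCML needs at least two replicates")
  if (nrow(x) < 1L) stop("no pixels supplied")
  kbar <- exp(rowMeans(log(k)))
  alpha <- alpha_init
  for (it in seq_len(max_iter)) {
    mu <- fit_mu_mle(x, k, matrix(alpha, nrow(x), ncol(x)))
    mu <- pmax(mu, 1e-8)
    xt <- x
    for (r in seq_len(ncol(x))) {
      if (all(abs(k[, r] - kbar) < 1e-12)) next
      xt[, r] <- q2q_pseudocounts(x[, r], mu * k[, r], mu * kbar, alpha)
    }
    opt <- optimize(function(la) qcml_cll(exp(la), xt),
                    interval = log(bounds), maximum = TRUE, tol = 1e-6)
    alpha_new <- exp(opt$maximum)
    if (abs(alpha_new - alpha) < tol) return(alpha_new)
    alpha <- alpha_new
  }
  alpha
}

#' Estimate the raw distance-dispersion relationship for one condition
#'
#' Runs [qcml_dispersion()] at every tested distance, pooling pixels across
#' chromosomes.
#'
#' @param pixels data.table with columns `dist` plus count columns
#'   `x_<rep>` and scaling columns `k_<rep>` for the condition's replicates
#'   (tested pixels only).
#' @param reps replicate ids of the condition.
#' @param min_dist,max_dist distance range in bins.
#' @param ... passed to [qcml_dispersion()].
#' @return numeric vector of raw dispersions indexed by
#'   `min_dist:max_dist` (NA where no tested pixels).
#' @export
estimate_raw_ddr <- function(pixels, reps, min_dist, max_dist, ...) {
  xcols <- paste0("x_", reps)
  kcols <- paste0("k_", reps)
  dists <- min_dist:max_dist
  out <- rep(NA_real_, length(dists))
  split_px <- split(pixels, pixels$dist)
  for (idx in seq_along(dists)) {
    sub <- split_px[[as.character(dists[idx])]]
    if (is.null(sub) || nrow(sub) == 0L) next
    out[idx] <- qcml_dispersion(as.matrix(sub[, ..xcols]),
                                as.matrix(sub[, ..kcols]), ...)
  }
  names(out) <- dists
  out
}

#' Smooth a raw distance-dispersion relationship
#'
#' Builds the final per-distance dispersion curve from raw per-distance
#' estimates: a centered rolling sample variance (window `window`) with
#' edge fills estimates each point's sampling variance `v`; unscaled
#' weights are `w = v^(-1/4)`; integer duplication weights are
#' `floor(w / min(w))`; a single-pass locally weighted linear (tricube)
#' fit on the duplicated points with fraction
#' `15 / (max(w_int) * mean(w))` (overridable) gives the smooth curve
#' `g(d)`; the final curve uses the raw estimates below the first distance
#' at which they increase, and `g(d)` from there on.
#'
#' @param alpha_tilde raw dispersions indexed by `min_dist:max_dist`
#'   (NA gaps are linearly interpolated before smoothing and carry zero
#'   duplication weight).
#' @param min_dist,max_dist distance range in bins.
#' @param window rolling-variance window size (default 20).
#' @param lowess_frac optional LOWESS fraction override.
#' @return object of class `dispersion_model` with elements `alpha_tilde`,
#'   `v`, `w`, `w_int`, `g`, `d_star`, `alpha_hat`, `dists`,
#'   `lowess_frac`.
#' @export
smooth_ddr <- function(alpha_tilde, min_dist, max_dist, window = 20L,
                       lowess_frac = NULL) {
  dists <- min_dist:max_dist
  nd <- length(dists)
  if (nd < window) stop("need at least ", window, " distances to smooth")
  at <- as.numeric(alpha_tilde)
  gap <- !is.finite(at)
  if (all(gap)) stop("no finite raw dispersion estimates")
  if (any(gap)) {
    at <- stats::approx(dists[!gap], at[!gap], xout = dists, rule = 2)$y
  }
  half <- window %/% 2
  left_anchor <- min_dist + half          # first fully interior distance
  right_anchor <- max_dist - half + 1L    # last fully interior distance
  v <- rep(NA_real_, nd)
  interior <- which(dists >= left_anchor & dists <= right_anchor)
  for (idx in interior) {
    d <- dists[idx]
    win <- at[(idx - half):(idx + half - 1L)]
    v[idx] <- stats::var(win)
  }
  v[dists < left_anchor] <- v[dists == left_anchor]
  v[dists > right_anchor] <- max(v[interior], na.rm = TRUE)
  v <- pmax(v, 1e-300)
  w <- (1 / v)^(1 / 4)
  w_int <- pmax(floor(w / min(w)), 1L)
  w_int[gap] <- 0L
  frac <- lowess_frac %||% (15 / (max(w_int) * mean(w)))
  frac <- min(max(frac, 2 / sum(w_int)), 1)
  xd <- rep(dists, times = w_int)
  yd <- rep(at, times = w_int)
  fit <- stats::lowess(xd, yd, f = frac, iter = 0)
  g_tab <- unique(data.table(x = fit$x, y = fit$y), by = "x")
  g <- stats::approx(g_tab$x, g_tab$y, xout = dists, rule = 2)$y
  inc <- which(diff(at) > 0 & !gap[-1] & !gap[-nd])
  d_star <- if (length(inc)) dists[min(inc) + 1L] else min_dist
  alpha_hat <- ifelse(dists < d_star, at, g)
  alpha_hat <- pmax(alpha_hat, 1e-7)
  names(alpha_hat) <- names(at) <- names(v) <- names(w) <- dists
  structure(
    list(alpha_tilde = at, v = v, w = w, w_int = w_int, g = g,
         d_star = d_star, alpha_hat = alpha_hat, dists = dists,
         lowess_frac = frac),
    class = "dispersion_model"
  )
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat("dispersion_model: distances", min(x$dists), "-", max(x$dists),
      "; switch distance", x$d_star,
      sprintf("; lowess fraction %.4g\n", x$lowess_frac))
  invisible(x)
}

#' Look up final dispersions at given distances
#' @param model a `dispersion_model`.
#' @param d integer distances in bins.
#' @return numeric vector of dispersions (errors outside the fitted range).
#' @export
ddr_alpha <- function(model, d) {
  idx <- match(d, model$dists)
  if (anyNA(idx)) stop("dispersion undefined at distance ",
                       d[which(is.na(idx))[1]])
  unname(model$alpha_hat[idx])
}
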