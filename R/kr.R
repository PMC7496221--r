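#' Knight-Ruiz matrix balancing
#'
#' Finds the diagonal scaling of a symmetric non-negative matrix that makes
#' all row sums equal, using the Knight-Ruiz Newton iteration with an inner
#' conjugate-gradient solve. Exposed for small dense matrices; Hi-C callers
#' should use [kr_balance()], which handles exclusion bookkeeping.
#'
#' @param A symmetric non-negative square matrix with support (apply
#'   [filter_sparse_rows()] first for sparse Hi-C data).
#' @param tol convergence tolerance on the residual of the balanced row sums
#'   (the balanced matrix's row-sum variance is of order `tol^2`).
#' @param max_iter maximum outer Newton iterations.
#' @return positive vector `x` such that `diag(x) %*% A %*% diag(x)` has all
#'   row sums equal to 1.
#' @keywords internal
kr_core <- function(A, tol = 1e-6, max_iter = 3000L) {
  n <- nrow(A)
  e <- rep(1, n)
  delta <- 0.1; Delta <- 3
  g <- 0.9; etamax <- 0.1; eta <- etamax
  stop_tol <- tol * 0.5
  x <- e
  rt <- tol^2
  v <- x * (A %*% x)[, 1]
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  iter <- 0L
  while (rout > rt) {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("Knight-Ruiz balancing did not converge; ",
           "apply stronger sparsity filtering")
    }
    k <- 0L; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * (A %*% (x * p))[, 1] + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > 200L) break
    }
    x <- x * y
    v <- x * (A %*% x)[, 1]
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / max(res_norm, .Machine$double.eps))
  }
  x
}

#' Estimate a locus-specific bias vector by matrix balancing
#'
#' Balances one replicate's contact matrix with the Knight-Ruiz algorithm and
#' returns multiplicative per-bin bias factors under the model
#' `x[i,j] = mu * b[i] * b[j]`: dividing counts by `b[i] * b[j]` equalizes
#' row sums. The bias vector is rescaled so the mean over retained bins is 1;
#' bins whose rescaled bias falls above `max_bias` or below `min_bias` are
#' then excluded (set to `NA`) and the remaining factors re-normalized to
#' mean 1.
#'
#' @param m a [contact_matrix], ideally after [filter_sparse_rows()].
#' @param tol,max_iter passed to the balancing iteration.
#' @param min_bias,max_bias outlier cutoffs on the mean-1 scale
#'   (defaults 0.1 and 10).
#' @return numeric vector of length `n_bins` with `NA` at excluded bins.
#' @export
kr_balance <- function(m, tol = 1e-6, max_iter = 3000L,
                       min_bias = 0.1, max_bias = 10) {
  dense <- as_dense(m)
  keep <- setdiff(which(rowSums(dense) > 0), m$excluded_bins + 1L)
  b <- rep(NA_real_, m$n_bins)
  if (length(keep) < 2L) return(b)
  x <- kr_core(dense[keep, keep, drop = FALSE], tol = tol,
               max_iter = max_iter)
  bias <- 1 / x
  bias <- bias / mean(bias)
  out <- bias < min_bias | bias > max_bias
  if (any(out)) {
    bias[out] <- NA_real_
    bias <- bias / mean(bias, na.rm = TRUE)
  }
  b[keep] <- bias
  b
}
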