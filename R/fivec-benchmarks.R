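#' One-way ANOVA with BH correction across pixels
#'
#' Classical fixed-effects one-way F test applied independently to every
#' pixel's values grouped by condition, with Benjamini-Hochberg
#' correction over all tested pixels. Degenerate pixels are flagged: zero
#' within-group variance with nonzero between-group variance gives p = 0;
#' all values identical gives p = 1.
#'
#' @param values numeric matrix, pixels x replicates.
#' @param condition_of condition label per column.
#' @return data.table with `F`, `p`, `q`, `flag`.
#' @export
anova_bh <- function(values, condition_of) {
  values <- as.matrix(values)
  conds <- unique(condition_of)
  k <- length(conds)
  if (k < 2L) stop("need at least two conditions")
  if (any(table(condition_of) < 2L)) {
    stop("need at least two replicates per condition")
  }
  n <- ncol(values)
  grand <- rowMeans(values)
  ssb <- rep(0, nrow(values))
  ssw <- rep(0, nrow(values))
  for (cc in conds) {
    cols <- which(condition_of == cc)
    gm <- rowMeans(values[, cols, drop = FALSE])
    ssb <- ssb + length(cols) * (gm - grand)^2
    ssw <- ssw + rowSums((values[, cols, drop = FALSE] - gm)^2)
  }
  df1 <- k - 1L
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  flag <- rep("", nrow(values))
  degen0 <- ssw < 1e-300 & ssb > 1e-300
  degen1 <- ssw < 1e-300 & ssb <= 1e-300
  p[degen0] <- 0; flag[degen0] <- "zero_within_variance"
  p[degen1] <- 1; flag[degen1] <- "all_identical"
  f[degen1] <- 0
  data.table(F = f, p = p, q = p.adjust(p, "BH"), flag = flag)
}

#' Likelihood-ratio test on z-scores under unit-variance normal shifts
#'
#' Models each pixel's replicate z-scores as unit-variance normals with a
#' condition-specific shift (alternative) or one shared shift (null); the
#' maximum-likelihood shifts are the condition means and the grand mean.
#' The statistic is twice the log likelihood ratio evaluated from the
#' normal densities, chi-square with `|C| - 1` degrees of freedom under
#' the null.
#'
#' @param z numeric matrix, pixels x replicates; rows containing NaN are
#'   skipped (flagged, p = NA).
#' @param condition_of condition label per column.
#' @return data.table with per-condition means `mu_<cond>`, `mu0`,
#'   `T_lrt`, `p`, `q`, `flag`.
#' @export
lrt3d_z <- function(z, condition_of) {
  z <- as.matrix(z)
  conds <- unique(condition_of)
  if (length(conds) < 2L) stop("need at least two conditions")
  ok <- rowSums(!is.finite(z)) == 0
  mu0 <- rowMeans(z)
  ll_alt <- ll_null <- rep(0, nrow(z))
  out <- data.table(mu0 = mu0)
  for (cc in conds) {
    cols <- which(condition_of == cc)
    muc <- rowMeans(z[, cols, drop = FALSE])
    data.table::set(out, j = paste0("mu_", cc), value = muc)
    for (cl in cols) {
      ll_alt <- ll_alt + stats::dnorm(z[, cl], mean = muc, log = TRUE)
      ll_null <- ll_null + stats::dnorm(z[, cl], mean = mu0, log = TRUE)
    }
  }
  stat <- pmax(2 * (ll_alt - ll_null), 0)
  df <- length(conds) - 1L
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  stat[!ok] <- NA_real_
  p[!ok] <- NA_real_
  qq <- rep(NA_real_, nrow(out))
  qq[ok] <- p.adjust(p[ok], "BH")
  data.table::set(out, j = "T_lrt", value = stat)
  data.table::set(out, j = "p", value = p)
  data.table::set(out, j = "q", value = qq)
  data.table::set(out, j = "flag", value = ifelse(ok, "", "non_finite_z"))
  out
}

#' Classify significant pixels from the z-score LRT
#'
#' Pixels with `q` above the FDR target are constitutive. Significant
#' pixels rank their condition means in decreasing order (A' > B' > C');
#' the class is `{A'}` when the top gap exceeds the bottom gap
#' (`|muA' - muB'| > |muB' - muC'|`), else `{A', B'}`. Two-condition
#' designs label the top condition. Exact ties in the ranking fall back
#' to design condition order and are flagged.
#'
#' @param result table from [lrt3d_z()].
#' @param conditions ordered condition labels.
#' @param fdr target FDR (default 0.02).
#' @return data.table with `class` and `tie` columns.
#' @export
lrt3d_classify <- function(result, conditions, fdr = 0.02) {
  mu <- as.matrix(result[, paste0("mu_", conditions), with = FALSE])
  n <- nrow(mu)
  cls <- rep("constitutive", n)
  tie <- rep(FALSE, n)
  sig <- !is.na(result$q) & result$q <= fdr
  if (any(sig)) {
    for (r in which(sig)) {
      ord <- order(mu[r, ], decreasing = TRUE)
      tie[r] <- anyDuplicated(mu[r, ]) > 0
      if (length(conditions) == 2L) {
        cls[r] <- conditions[ord[1]]
      } else {
        gap_top <- abs(mu[r, ord[1]] - mu[r, ord[2]])
        gap_bot <- abs(mu[r, ord[2]] - mu[r, ord[3]])
        cls[r] <- if (gap_top > gap_bot) {
          conditions[ord[1]]
        } else {
          class_label(conditions[sort(ord[1:2])])
        }
      }
    }
  }
  cls[is.na(result$q)] <- NA_character_
  data.table(class = cls, tie = tie)
}
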