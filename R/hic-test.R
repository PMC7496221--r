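#' Per-pixel negative-binomial likelihood-ratio test
#'
#' For each pixel, fits the condition-specific interaction strengths
#' (alternative model) and a single shared strength (null model) by maximum
#' likelihood, holding bias, size factors and dispersion fixed, and forms
#' the statistic `-2 log lambda`, referred to a chi-square distribution
#' with `|C| - 1` degrees of freedom (right-tail p values).
#'
#' @param x,k numeric matrices, pixels x replicates (columns in the order
#'   of `design$replicates`).
#' @param alpha dispersion matrix (pixels x replicates) or per-replicate
#'   vector; typically each replicate column carries its condition's DDR
#'   value at the pixel's distance.
#' @param design a [study_design].
#' @return data.table with `mu0`, `mu_<cond>` columns, `lrt_stat` and `p`.
#' @export
lrt_pixels <- function(x, k, alpha, design) {
  if (length(design$conditions) < 2L) stop("need at least two conditions")
  x <- as.matrix(x); k <- as.matrix(k)
  alpha <- if (is.matrix(alpha)) alpha else
    matrix(alpha, nrow(x), ncol(x), byrow = TRUE)
  mu_alt <- fit_mu(x, k, alpha, design, constraint = "alt")
  mu0 <- fit_mu(x, k, alpha, design, constraint = "null")[, 1]
  ll_alt <- ll_null <- numeric(nrow(x))
  for (ci in seq_along(design$conditions)) {
    cols <- which(design$condition_of == design$conditions[ci])
    for (cl in cols) {
      ll_alt <- ll_alt + nb_logpmf(x[, cl], mu_alt[, ci] * k[, cl],
                                   alpha[, cl])
      ll_null <- ll_null + nb_logpmf(x[, cl], mu0 * k[, cl], alpha[, cl])
    }
  }
  stat <- pmax(2 * (ll_alt - ll_null), 0)
  df <- length(design$conditions) - 1L
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  allzero <- rowSums(x) == 0
  stat[allzero] <- 0
  p[allzero] <- 1
  out <- data.table(mu0 = mu0, stat = stat, p = p)
  for (ci in seq_along(design$conditions)) {
    out[[paste0("mu_", design$conditions[ci])]] <- mu_alt[, ci]
  }
  data.table::setnames(out, "stat", "lrt_stat")
  out
}

#' Benjamini-Hochberg q values over the loop-pixel set
#'
#' The FDR is controlled only over pixels lying in the union of the input
#' loop footprints, pooled across chromosomes.
#'
#' @param p p values for the loop pixels.
#' @return BH step-up q values.
#' @export
fdr_over_loops <- function(p) {
  if (!length(p)) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Cluster pixels into contiguous components
#'
#' Connected components under 4-connectivity (pixels sharing a matrix
#' edge); components smaller than `min_size` are discarded and their pixels
#' left unclustered (`NA`). Applied separately to the significant and
#' insignificant pixel sets by the pipeline.
#'
#' @param i,j pixel coordinates.
#' @param min_size minimum cluster size (default 3).
#' @return integer cluster labels with `NA` for pixels in dropped
#'   components.
#' @export
cluster_pixels <- function(i, j, min_size = 3L) {
  comp <- pixel_components(i, j)
  if (!length(comp)) return(integer(0))
  sizes <- tabulate(comp)
  out <- ifelse(sizes[comp] >= min_size, comp, NA_integer_)
  match(out, sort(unique(out[!is.na(out)])))
}

#' Classify clustered pixels by their strongest condition
#'
#' Retained significant pixels are labeled with the condition whose
#' normalized mean is highest (ties broken by design condition order and
#' flagged); retained insignificant loop pixels are labeled
#' `"constitutive"`; pixels dropped by the minimum-cluster-size rule are
#' `"unclassified"`.
#'
#' @param zbar matrix of per-condition normalized means
#'   (pixels x conditions, columns in design order).
#' @param significant logical vector.
#' @param cluster integer cluster labels (`NA` = dropped), as returned by
#'   [cluster_pixels()] applied within the significant and insignificant
#'   sets.
#' @param conditions condition labels in design order.
#' @return data.table with `class` and logical `tie` columns.
#' @export
classify_pixels <- function(zbar, significant, cluster, conditions) {
  zbar <- as.matrix(zbar)
  n <- nrow(zbar)
  best <- max.col(zbar, ties.method = "first")
  nbest <- rowSums(zbar == zbar[cbind(seq_len(n), best)])
  cls <- rep("unclassified", n)
  keep <- !is.na(cluster)
  cls[keep & significant] <- conditions[best[keep & significant]]
  cls[keep & !significant] <- "constitutive"
  data.table(class = cls, tie = significant & keep & nbest > 1L)
}

#' Alternative dispersion providers for benchmarking
#'
#' Drop-in replacements for the pooled distance-dispersion relationship in
#' [lrt_pixels()]:
#' * `poisson` - dispersion 0 everywhere (Poisson likelihood-ratio test);
#' * `global_nb` - one qCML dispersion per condition, fitted over all loop
#'   pixels irrespective of distance;
#' * `sample_variance` - per-pixel dispersion from the within-condition
#'   sample variance, `max(1e-7, (s2 - zbar) / zbar^2)`.
#'
#' @param mode one of `"poisson"`, `"global_nb"`, `"sample_variance"`.
#' @param pixels tested loop-pixel table (with `x_`, `k_`, `z_` columns).
#' @param design a [study_design].
#' @return pixels x replicates dispersion matrix aligned with
#'   `design$replicates`.
#' @export
alternative_dispersion <- function(mode = c("poisson", "global_nb",
                                            "sample_variance"),
                                   pixels, design) {
  mode <- match.arg(mode)
  n <- nrow(pixels)
  reps <- design$replicates
  out <- matrix(0, n, length(reps), dimnames = list(NULL, reps))
  if (mode == "poisson") return(out)
  for (cc in design$conditions) {
    rc <- replicates_of(design, cc)
    cols <- match(rc, reps)
    if (mode == "global_nb") {
      a <- qcml_dispersion(
        as.matrix(pixels[, paste0("x_", rc), with = FALSE]),
        as.matrix(pixels[, paste0("k_", rc), with = FALSE]))
      out[, cols] <- a
    } else {
      if (length(rc) < 2L) {
        stop("sample_variance mode needs >= 2 replicates per condition")
      }
      zmat <- as.matrix(pixels[, paste0("z_", rc), with = FALSE])
      zb <- rowMeans(zmat)
      s2 <- apply(zmat, 1, stats::var)
      a <- pmax(1e-7, (s2 - zb) / zb^2)
      a[!is.finite(a)] <- 1e-7
      out[, cols] <- a
    }
  }
  out
}
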