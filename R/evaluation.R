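#' ROC curve and AUROC for a differential-call score
#'
#' Standard ROC of a score (typically `1 - q`) against Boolean truth
#' labels, with AUROC computed by the rank (Mann-Whitney) formula, which
#' equals the trapezoid area with tie-averaging.
#'
#' @param score numeric scores (higher = more confidently differential).
#' @param truth 0/1 truth labels.
#' @return list with `curve` (data.table of `fpr`, `tpr`) and `auroc`.
#' @export
roc_auroc <- function(score, truth) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) stop("both truth classes must be present")
  r <- rank(score)
  auroc <- (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(truth[ord] == 1L)
  fp <- cumsum(truth[ord] == 0L)
  keep <- c(diff(score[ord]) != 0, TRUE)
  curve <- data.table(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
  list(curve = curve, auroc = auroc)
}

#' Observed FDR as a function of the q-value threshold
#'
#' At each threshold, calls are the pixels with `q <= threshold`; the
#' observed FDR is `FP / (FP + TP)` against the truth labels, 0 when there
#' are no calls.
#'
#' @param q q values.
#' @param truth 0/1 truth labels.
#' @param thresholds thresholds in (0, 1].
#' @return data.table with `threshold`, `n_calls`, `fdr`.
#' @export
fdr_control_curve <- function(q, truth,
                              thresholds = c(0.01, 0.05, 0.1, 0.2, 0.5, 1)) {
  truth <- as.integer(truth)
  rows <- lapply(thresholds, function(th) {
    called <- q <= th
    n <- sum(called)
    fdr <- if (n == 0L) 0 else sum(truth[called] == 0L) / n
    data.table(threshold = th, n_calls = n, fdr = fdr)
  })
  rbindlist(rows)
}

#' Power (TPR) as a function of the q-value threshold
#'
#' @param q q values.
#' @param truth 0/1 truth labels; at least one positive required.
#' @param thresholds thresholds in (0, 1].
#' @return data.table with `threshold`, `tpr`.
#' @export
power_curve <- function(q, truth,
                        thresholds = c(0.01, 0.05, 0.1, 0.2, 0.5, 1)) {
  truth <- as.integer(truth)
  npos <- sum(truth == 1L)
  if (npos == 0L) stop("no true positives: power undefined")
  rows <- lapply(thresholds, function(th) {
    data.table(threshold = th,
               tpr = sum(truth == 1L & q <= th) / npos)
  })
  rbindlist(rows)
}

#' Assign loop pixels to distance strata
#'
#' Short/medium/long strata on the genomic anchor distance, with
#' left-closed, right-open boundaries: `[0, short)`, `[short, long)`,
#' `[long, Inf)`.
#'
#' @param dist_bp interaction distances in base pairs.
#' @param short_bp,long_bp boundaries (defaults 400 kb and 800 kb).
#' @return factor with levels `short`, `medium`, `long`.
#' @export
distance_strata <- function(dist_bp, short_bp = 4e5, long_bp = 8e5) {
  cut(dist_bp, breaks = c(-Inf, short_bp, long_bp, Inf),
      labels = c("short", "medium", "long"), right = FALSE)
}

#' Distance-stratified performance evaluation
#'
#' Loops are stratified by anchor distance; within each stratum the BH-FDR
#' procedure is re-run on that stratum's p values before computing FDR and
#' power curves, and a ROC is computed from the re-adjusted scores. Empty
#' strata (or strata with one truth class) are omitted with a warning.
#'
#' @param p p values per loop pixel.
#' @param truth 0/1 truth labels.
#' @param dist_bp interaction distances in bp.
#' @param thresholds q-value thresholds.
#' @param short_bp,long_bp stratum boundaries.
#' @return named list per stratum with `n`, `q`, `fdr_curve`,
#'   `power_curve`, `auroc` (NA when undefined).
#' @export
distance_stratified_eval <- function(p, truth, dist_bp,
                                     thresholds = c(0.01, 0.05, 0.1, 1),
                                     short_bp = 4e5, long_bp = 8e5) {
  strata <- distance_strata(dist_bp, short_bp, long_bp)
  out <- list()
  for (st in levels(strata)) {
    sel <- strata == st
    if (!any(sel)) {
      warning("empty stratum: ", st)
      next
    }
    qs <- p.adjust(p[sel], method = "BH")
    ts <- as.integer(truth[sel])
    auroc <- if (length(unique(ts)) == 2L) {
      roc_auroc(1 - qs, ts)$auroc
    } else NA_real_
    pw <- if (any(ts == 1L)) power_curve(qs, ts, thresholds) else NULL
    out[[st]] <- list(n = sum(sel), q = qs,
                      fdr_curve = fdr_control_curve(qs, ts, thresholds),
                      power_curve = pw, auroc = auroc)
  }
  out
}

#' Low-p distance bias on a null simulation
#'
#' On data with no truly differential loops, computes the global 5th
#' percentile of the loop-pixel p values and, per distance stratum, the
#' proportion of pixels below it. An unbiased model gives about 0.05 in
#' every stratum.
#'
#' @param p p values per loop pixel (null simulation).
#' @param dist_bp interaction distances in bp.
#' @param prob percentile (default 0.05).
#' @param short_bp,long_bp stratum boundaries.
#' @return data.table with `stratum`, `n`, `proportion`.
#' @export
low_p_distance_bias <- function(p, dist_bp, prob = 0.05,
                                short_bp = 4e5, long_bp = 8e5) {
  cutoff <- quantile(p, prob, type = 7, names = FALSE)
  strata <- distance_strata(dist_bp, short_bp, long_bp)
  rows <- lapply(levels(strata), function(st) {
    sel <- strata == st
    if (!any(sel)) return(NULL)
    data.table(stratum = st, n = sum(sel),
               proportion = mean(p[sel] < cutoff))
  })
  rbindlist(rows)
}
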