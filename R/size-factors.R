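#' Estimate distance-dependent size factors
#'
#' Distance-dependent variant of the median-of-ratios method. Balanced
#' counts `y = x / (b[i] * b[j])` for pixels that are nonzero in every
#' replicate and lie within the tested distance range are grouped into
#' `n_groups` equal-count groups by interaction distance; each group's size
#' factor for replicate r is the median over the group of
#' `y[r] / geometric mean over replicates of y`. Per-distance factors
#' `s[r, d]` are obtained by piecewise-linear interpolation of the group
#' factors against the group mean distances, constant beyond the outermost
#' anchors.
#'
#' Pixels with a zero count in any replicate are ineligible for the pooling
#' and are excluded from further analysis downstream (they cannot pass the
#' normalized-mean filter applied before testing).
#'
#' @param counts named list (one per replicate id) of [contact_matrix]
#'   objects for the same chromosome.
#' @param bias named list of bias vectors from [kr_balance()], parallel to
#'   `counts`.
#' @param design a [study_design].
#' @param n_groups number of equal-count distance groups (default 100).
#' @return object of class `size_factor_model`: list with `s` (named list of
#'   numeric vectors indexed by distance `0:max_dist_bins`), `anchors`
#'   (data.table of group mean distance and group factors per replicate) and
#'   `n_groups`.
#' @export
estimate_size_factors <- function(counts, bias, design, n_groups = 100L) {
  reps <- design$replicates
  if (length(reps) < 2L) stop("size factors need at least two replicates")
  stopifnot(all(reps %in% names(counts)), all(reps %in% names(bias)))
  wide <- NULL
  for (r in reps) {
    m <- counts[[r]]
    b <- bias[[r]]
    ent <- m$entries[count > 0]
    ent <- ent[j - i <= design$max_dist_bins]
    y <- ent$count / (b[ent$i + 1L] * b[ent$j + 1L])
    dt <- data.table(i = ent$i, j = ent$j, y = y)
    dt <- dt[is.finite(y)]
    data.table::setnames(dt, "y", paste0("y_", r))
    wide <- if (is.null(wide)) dt else
      merge(wide, dt, by = c("i", "j"), all = FALSE)
  }
  ycols <- paste0("y_", reps)
  wide <- wide[stats::complete.cases(wide)]
  if (nrow(wide) < n_groups) {
    stop("fewer eligible pixels (", nrow(wide), ") than groups (",
         n_groups, "); reduce n_groups")
  }
  wide[, dist := j - i]
  setorder(wide, dist)
  wide[, grp := ceiling(seq_len(.N) / (.N / n_groups))]
  ymat <- as.matrix(wide[, ..ycols])
  geo <- exp(rowMeans(log(ymat)))
  anchors <- wide[, .(dist_mean = mean(dist)), by = grp]
  s <- list()
  for (k in seq_along(reps)) {
    rat <- ymat[, k] / geo
    med <- data.table(grp = wide$grp, ratio = rat)[
      , .(s = median(ratio)), by = grp]
    anchors[[paste0("s_", reps[k])]] <- med$s[match(anchors$grp, med$grp)]
    s[[reps[k]]] <- stats::approx(
      x = anchors$dist_mean, y = anchors[[paste0("s_", reps[k])]],
      xout = 0:design$max_dist_bins, rule = 2
    )$y
  }
  structure(list(s = s, anchors = anchors[, -"grp"], n_groups = n_groups),
            class = "size_factor_model")
}

#' @export
print.size_factor_model <- function(x, ...) {
  rng <- range(unlist(x$s))
  cat("size_factor_model:", length(x$s), "replicates,",
      x$n_groups, "distance groups; factor range",
      sprintf("%.4g-%.4g", rng[1], rng[2]), "\n")
  invisible(x)
}

#' Bias- and size-factor-normalize a contact matrix
#'
#' Computes `z[i,j] = x[i,j] / (b[i] * b[j] * s[j - i])` for every retained
#' pixel within the size-factor distance range. Pixels touching an excluded
#' bin are absent from the output.
#'
#' @param m a [contact_matrix].
#' @param bias bias vector from [kr_balance()] (NA = excluded bin).
#' @param size_factors numeric vector of per-distance factors indexed by
#'   `d + 1` for `d = 0, ..., max_dist_bins` (one replicate's entry of a
#'   `size_factor_model`), or a single number.
#' @param include_zeros if `TRUE`, emit explicit `z = 0` rows for retained
#'   in-range pixels with zero count (needed for condition means).
#' @param min_dist,max_dist distance range in bins to keep.
#' @return data.table with columns `i`, `j`, `z`.
#' @export
normalize_counts <- function(m, bias, size_factors,
                             min_dist = 0L, max_dist = length(size_factors) - 1L,
                             include_zeros = FALSE) {
  ent <- m$entries[j - i >= min_dist & j - i <= max_dist]
  if (include_zeros) {
    allpix <- rbindlist(lapply(min_dist:max_dist, function(d) {
      if (m$n_bins <= d) return(NULL)
      ii <- 0:(m$n_bins - 1L - d)
      data.table(i = ii, j = ii + d)
    }))
    ent <- merge(allpix, ent, by = c("i", "j"), all.x = TRUE)
    ent[is.na(count), count := 0]
  }
  bi <- bias[ent$i + 1L]
  bj <- bias[ent$j + 1L]
  s <- if (length(size_factors) == 1L) size_factors else
    size_factors[ent$j - ent$i + 1L]
  z <- ent$count / (bi * bj * s)
  out <- data.table(i = ent$i, j = ent$j, z = z)
  out[is.finite(z)]
}
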