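#' Looping classes for a condition set
#'
#' All nonempty proper subsets of the conditions: singles first (in design
#' order), then pairs for three-condition designs.
#'
#' @param conditions character vector of 2 or 3 condition labels.
#' @return list of character vectors (class membership sets).
#' @export
fivec_classes <- function(conditions) {
  nc <- length(conditions)
  if (!nc %in% c(2L, 3L)) stop("2 or 3 conditions supported")
  singles <- lapply(conditions, identity)
  if (nc == 2L) return(singles)
  pairs <- utils::combn(conditions, 2, simplify = FALSE)
  c(singles, pairs)
}

class_label <- function(members) paste(members, collapse = "+")

#' Classification thresholds and sweep configuration
#'
#' @param b background threshold on interaction scores; pixels whose IS is
#'   below `b` in every replicate are background
#'   (default `-10 * log2(0.8)`).
#' @param g baseline significance threshold; a candidate loop needs all
#'   replicates of at least one condition above `g`
#'   (default `-10 * log2(0.165)`).
#' @param tau target empirical FDR (default 0.02).
#' @param sweep difference-threshold grid in IS units (default 0.5 to 40
#'   by 0.5).
#' @param min_cluster_size minimum pixels per retained cluster (default 3).
#' @return a list of class `classify_config`.
#' @export
classify_config <- function(b = -10 * log2(0.8), g = -10 * log2(0.165),
                            tau = 0.02,
                            sweep = seq(0.5, 40, by = 0.5),
                            min_cluster_size = 3L) {
  if (b >= g) stop("background threshold must lie below significance")
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  if (any(diff(sweep) <= 0) || any(sweep <= 0)) {
    stop("sweep must be strictly increasing and positive")
  }
  structure(list(b = b, g = g, tau = tau, sweep = sweep,
                 min_cluster_size = min_cluster_size),
            class = "classify_config")
}

# stack one region's IS matrices into an m x m x reps array
is_array <- function(fis, region) {
  mats <- lapply(fis$scores, function(sc) sc[[region]]$IS)
  simplify2array(mats)
}

#' Background mask from interaction scores
#'
#' A pixel is background when the maximum IS over all replicates of all
#' conditions is below `b`. Background pixels are excluded from testing.
#'
#' @param arr `m x m x reps` IS array for one region.
#' @param b background threshold.
#' @return logical matrix (NA where all replicates are masked).
#' @export
background_filter <- function(arr, b) {
  if (length(dim(arr)) != 3L || dim(arr)[3] < 1L) {
    stop("need at least one replicate")
  }
  slices <- lapply(seq_len(dim(arr)[3]), function(s) arr[, , s])
  mx <- Reduce(function(a, b2) pmax(a, b2, na.rm = TRUE), slices)
  mx < b
}

#' Candidate-loop mask from interaction scores
#'
#' A pixel is a candidate loop when in at least one condition every
#' replicate's IS exceeds `g` (max over conditions of the min over
#' replicates).
#'
#' @param arr `m x m x reps` IS array.
#' @param condition_of replicate -> condition map aligned with the third
#'   dimension.
#' @param g significance threshold.
#' @return logical matrix.
#' @export
significance_filter <- function(arr, condition_of, g) {
  conds <- unique(condition_of)
  best <- NULL
  for (cc in conds) {
    idx <- which(condition_of == cc)
    mn <- Reduce(pmin, lapply(idx, function(s) arr[, , s]))
    best <- if (is.null(best)) mn else pmax(best, mn, na.rm = FALSE)
  }
  out <- best > g
  out[is.na(out)] <- FALSE
  out
}

# Precompute the d-independent per-region ingredients of the
# classification: background/candidate masks, per-condition significance,
# and the ordered-pair minimum differences delta(t, u) = min(IS_t) -
# max(IS_u) over replicate pairs.
region_class_stats <- function(arr, condition_of, conditions, config) {
  slices <- lapply(seq_len(dim(arr)[3]), function(s) arr[, , s])
  masked <- Reduce(`&`, lapply(slices, is.na))
  bg <- background_filter(arr, config$b)
  bg[is.na(bg)] <- TRUE
  mins <- maxs <- list()
  for (cc in conditions) {
    idx <- which(condition_of == cc)
    if (!length(idx)) stop("no replicates for condition ", cc)
    mins[[cc]] <- Reduce(pmin, slices[idx])
    maxs[[cc]] <- Reduce(pmax, slices[idx])
  }
  sig <- lapply(mins, function(mn) !is.na(mn) & mn > config$g)
  delta <- list()
  for (t in conditions) for (u in setdiff(conditions, t)) {
    delta[[paste(t, u)]] <- mins[[t]] - maxs[[u]]
  }
  list(masked = masked, bg = bg, sig = sig,
       candidate = Reduce(`|`, sig), delta = delta,
       conditions = conditions, dim = dim(arr)[1:2])
}

# Independent per-class membership predicates at threshold d. Every
# condition in each predicate tightens with d, so memberships (and the
# sweep counts built on them) are non-increasing in d. A pixel may
# satisfy a single-condition and a dual predicate simultaneously; final
# labels resolve that by giving the more specific single-condition class
# precedence.
class_membership <- function(st, d) {
  conditions <- st$conditions
  ge <- function(x) !is.na(x) & x >= d
  out <- list()
  for (cl in fivec_classes(conditions)) {
    if (length(cl) == 1L) {
      t <- cl
      hit <- st$sig[[t]]
      for (u in setdiff(conditions, t)) {
        hit <- hit & ge(st$delta[[paste(t, u)]])
      }
    } else {
      t <- cl[1]; tp <- cl[2]
      u <- setdiff(conditions, cl)
      hit <- st$sig[[t]] & st$sig[[tp]] &
        ge(st$delta[[paste(t, u)]]) & ge(st$delta[[paste(tp, u)]])
    }
    out[[class_label(cl)]] <- hit & !st$bg & st$candidate
  }
  out
}

classify_from_stats <- function(st, d) {
  conditions <- st$conditions
  ge <- function(x) !is.na(x) & x >= d
  out <- matrix("nonsignificant", st$dim[1], st$dim[2])
  out[st$bg] <- "background"
  any_sep <- Reduce(`|`, lapply(st$delta, ge))
  all_sig <- Reduce(`&`, st$sig)
  membership <- class_membership(st, d)
  assigned <- matrix(FALSE, st$dim[1], st$dim[2])
  for (cl in names(membership)) {
    hit <- membership[[cl]] & !assigned
    out[hit] <- cl
    assigned <- assigned | hit
  }
  const <- all_sig & !any_sep & !assigned & !st$bg
  out[const] <- "constitutive"
  out[st$candidate & !assigned & !const & !st$bg] <- "other"
  out[st$masked] <- NA_character_
  out
}

#' Preliminary looping classification at one difference threshold
#'
#' Implements the minimum-difference thresholding over replicate pairs:
#' for conditions t and u, `delta(t, u) = min over replicate pairs of
#' (IS in t - IS in u)`, which equals `min(IS_t) - max(IS_u)`. A pixel is
#' * class `{t}` when t passes significance and `delta(t, u) >= d`
#'   against every other condition u;
#' * class `{t, t'}` (three conditions) when both pass significance and
#'   both beat the remaining condition by `d`; a pixel qualifying for a
#'   single-condition class keeps that more specific label;
#' * `constitutive` when every condition passes significance and no
#'   ordered condition pair separates by `d`;
#' * `other` for remaining candidate pixels; `background` /
#'   `nonsignificant` otherwise; `NA` where masked.
#'
#' @param arr `m x m x reps` IS array for one region.
#' @param condition_of replicate -> condition map.
#' @param conditions ordered condition labels.
#' @param d difference threshold (IS units).
#' @param config a [classify_config()] (for `b` and `g`).
#' @return character matrix of labels.
#' @export
difference_classify <- function(arr, condition_of, conditions, d, config) {
  st <- region_class_stats(arr, condition_of, conditions, config)
  classify_from_stats(st, d)
}

# counts of upper-triangle pixels per differential class membership, one
# row per sweep threshold; stats precomputed once per region. Because
# memberships are counted independently, every column is non-increasing
# in the threshold.
count_classes_sweep <- function(fis, conditions, config) {
  classes <- vapply(fivec_classes(conditions), class_label, character(1))
  counts <- matrix(0, length(config$sweep), length(classes),
                   dimnames = list(NULL, classes))
  for (rg in names(fis$bin_centers)) {
    arr <- is_array(fis, rg)
    st <- region_class_stats(arr, fis$condition_of, conditions, config)
    ut <- upper.tri(matrix(0, st$dim[1], st$dim[2]))
    for (di in seq_along(config$sweep)) {
      mem <- class_membership(st, config$sweep[di])
      for (ci in seq_along(classes)) {
        counts[di, ci] <- counts[di, ci] +
          sum(mem[[classes[ci]]][ut], na.rm = TRUE)
      }
    }
  }
  counts
}

#' Empirical-FDR threshold sweep and final classification
#'
#' Classifies the experimental replicate set and each null replicate set
#' (same-condition simulated replicates relabeled to the experimental
#' conditions) at every difference threshold in the sweep. The empirical
#' FDR of class h at threshold d is the mean null call count divided by
#' the experimental call count (0 when there are no experimental calls).
#' For each class the selected threshold is the one whose eFDR is closest
#' to the target `tau` while remaining below it; the final labels come
#' from classifying the experimental set at each class's own threshold
#' (when several classes claim one pixel at their respective thresholds,
#' the earlier class in `fivec_classes` order wins).
#'
#' @param exp_fis `fivec_is` of the experimental replicates.
#' @param null_fis_list list of `fivec_is` objects, one per null replicate
#'   set, each with replicate -> condition maps matching the experimental
#'   design.
#' @param conditions ordered condition labels.
#' @param config a [classify_config()].
#' @return object of class `efdr_map`: `table` (data.table of class, d,
#'   n_exp, n_null, efdr), `selected` (class -> d or NA), `labels` (final
#'   label matrix per region), `config`.
#' @export
efdr_map <- function(exp_fis, null_fis_list, conditions, config) {
  classes <- vapply(fivec_classes(conditions), class_label, character(1))
  n_exp <- count_classes_sweep(exp_fis, conditions, config)
  n_null <- 0 * n_exp
  for (nf in null_fis_list) {
    n_null <- n_null + count_classes_sweep(nf, conditions, config)
  }
  n_null <- n_null / max(length(null_fis_list), 1L)
  efdr <- ifelse(n_exp == 0, 0, n_null / pmax(n_exp, 1e-300))
  tab <- data.table(
    class = rep(classes, each = length(config$sweep)),
    d = rep(config$sweep, times = length(classes)),
    n_exp = as.vector(n_exp), n_null = as.vector(n_null),
    efdr = as.vector(efdr))
  selected <- stats::setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    sub <- tab[class == cl]
    selected[cl] <- select_efdr_threshold(sub$d, sub$efdr, config$tau)
    if (is.na(selected[cl])) {
      warning("no sweep threshold reaches eFDR < tau for class ", cl)
    }
  }
  labels <- list()
  for (rg in names(exp_fis$bin_centers)) {
    arr <- is_array(exp_fis, rg)
    st <- region_class_stats(arr, exp_fis$condition_of, conditions,
                             config)
    lab <- classify_from_stats(st, max(config$sweep))
    # strip differential labels assigned at the (arbitrary) top threshold
    lab[lab %in% classes] <- "other"
    claimed <- matrix(FALSE, st$dim[1], st$dim[2])
    for (cl in classes) {
      if (is.na(selected[cl])) next
      mem <- class_membership(st, selected[cl])[[cl]]
      hit <- mem & !claimed
      lab[hit] <- cl
      claimed <- claimed | hit
    }
    labels[[rg]] <- lab
  }
  structure(list(table = tab, selected = selected, labels = labels,
                 conditions = conditions, config = config),
            class = "efdr_map")
}

#' Pick the difference threshold matching a target empirical FDR
#'
#' Returns the threshold whose eFDR is closest to `tau` while remaining
#' below it (ties broken toward the smaller threshold). `NA` when no
#' threshold achieves `eFDR < tau`.
#'
#' @param d sweep thresholds.
#' @param efdr matching empirical FDR values.
#' @param tau target eFDR.
#' @return selected threshold or `NA`.
#' @export
select_efdr_threshold <- function(d, efdr, tau) {
  ok <- which(is.finite(efdr) & efdr < tau)
  if (!length(ok)) return(NA_real_)
  best <- ok[which.max(efdr[ok])]
  d[best]
}

#' @export
print.efdr_map <- function(x, ...) {
  cat("efdr_map: classes", paste(names(x$selected), collapse = ", "), "\n")
  for (cl in names(x$selected)) {
    n <- sum(vapply(x$labels, function(lb) {
      sum(lb[upper.tri(lb)] == cl, na.rm = TRUE)
    }, numeric(1)))
    cat(sprintf("  %-8s d* = %-6s final calls = %d\n", cl,
                format(x$selected[cl]), n))
  }
  invisible(x)
}

#' Cluster final 5C classifications by spatial adjacency
#'
#' 4-connected components within each differential class per region;
#' components below the minimum size are relabeled `unclassified`.
#'
#' @param emap an `efdr_map`.
#' @return data.table of clustered pixels: `region`, `i`, `j`, `class`,
#'   `cluster_id`.
#' @export
cluster_classified <- function(emap) {
  classes <- names(emap$selected)
  rows <- list()
  next_id <- 0L
  for (rg in names(emap$labels)) {
    lab <- emap$labels[[rg]]
    for (cl in classes) {
      idx <- which(!is.na(lab) & lab == cl & upper.tri(lab),
                   arr.ind = TRUE)
      if (!nrow(idx)) next
      comp <- cluster_pixels(idx[, 1], idx[, 2],
                             min_size = emap$config$min_cluster_size)
      keep <- !is.na(comp)
      rows[[length(rows) + 1L]] <- data.table(
        region = rg, i = idx[, 1], j = idx[, 2],
        class = ifelse(keep, cl, "unclassified"),
        cluster_id = comp + next_id)
      next_id <- next_id + max(c(comp, 0L), na.rm = TRUE)
    }
  }
  if (!length(rows)) {
    return(data.table(region = character(0), i = integer(0),
                      j = integer(0), class = character(0),
                      cluster_id = integer(0)))
  }
  rbindlist(rows)
}
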