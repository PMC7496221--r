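#' Assemble the per-pixel analysis table for one chromosome
#'
#' Joins raw counts, combined scaling factors `k = b[i] * b[j] * s[d]` and
#' normalized counts `z = x / k` across replicates for every pixel in the
#' tested distance range whose bins are retained in every replicate.
#' Pixels absent from a replicate's sparse entries are explicit zeros.
#'
#' @param counts named list (replicate id -> [contact_matrix]) for one
#'   chromosome.
#' @param bias named list of bias vectors ([kr_balance()]).
#' @param sfm a `size_factor_model` from [estimate_size_factors()].
#' @param design a [study_design].
#' @return data.table keyed by (i, j) with `dist`, per-replicate `x_<rep>`,
#'   `k_<rep>`, `z_<rep>` columns.
#' @export
assemble_pixel_table <- function(counts, bias, sfm, design) {
  reps <- design$replicates
  base <- NULL
  for (r in reps) {
    m <- counts[[r]]
    ent <- m$entries[j - i >= design$min_dist_bins &
                       j - i <= design$max_dist_bins]
    if (is.null(base)) {
      nb <- m$n_bins
      base <- rbindlist(lapply(design$min_dist_bins:design$max_dist_bins,
                               function(d) {
        if (nb <= d) return(NULL)
        ii <- 0:(nb - 1L - d)
        data.table(i = ii, j = ii + d)
      }))
      setkeyv(base, c("i", "j"))
    }
    base <- merge(base, ent, by = c("i", "j"), all.x = TRUE)
    base[is.na(count), count := 0]
    kvec <- bias[[r]][base$i + 1L] * bias[[r]][base$j + 1L] *
      sfm$s[[r]][base$j - base$i + 1L]
    data.table::setnames(base, "count", paste0("x_", r))
    data.table::set(base, j = paste0("k_", r), value = kvec)
  }
  kcols <- paste0("k_", reps)
  keep <- Reduce(`&`, lapply(kcols, function(cn) is.finite(base[[cn]])))
  base <- base[keep]
  base[, dist := j - i]
  for (r in reps) {
    data.table::set(base, j = paste0("z_", r),
                    value = base[[paste0("x_", r)]] / base[[paste0("k_", r)]])
  }
  base
}

#' Per-condition normalized means and the tested mask
#'
#' Computes `zbar_c = mean over the condition's replicates of z` for every
#' pixel and flags a pixel as tested when its normalized mean is at least 1
#' in every condition (pixels below that are underpowered and excluded). By
#' default pixels with a zero raw count in any replicate are also excluded,
#' matching the size-factor eligibility rule.
#'
#' @param pixels table from [assemble_pixel_table()].
#' @param design a [study_design].
#' @param min_mean tested-mask threshold on each condition mean (default 1).
#' @param require_all_nonzero drop pixels with a zero count in any
#'   replicate (default TRUE).
#' @return `pixels` with added `zbar_<cond>` columns and a logical `tested`
#'   column.
#' @export
condition_means <- function(pixels, design, min_mean = 1,
                            require_all_nonzero = TRUE) {
  tested <- rep(TRUE, nrow(pixels))
  for (cc in design$conditions) {
    reps <- replicates_of(design, cc)
    if (!length(reps)) stop("condition ", cc, " has no replicates")
    zc <- rowMeans(as.matrix(pixels[, paste0("z_", reps), with = FALSE]))
    data.table::set(pixels, j = paste0("zbar_", cc), value = zc)
    tested <- tested & zc >= min_mean
  }
  if (require_all_nonzero) {
    xmat <- as.matrix(
      pixels[, paste0("x_", design$replicates), with = FALSE])
    tested <- tested & rowSums(xmat == 0) == 0
  }
  pixels[, tested := tested]
  pixels
}
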