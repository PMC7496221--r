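#' Describe a multi-condition replicate design
#'
#' A study design names the biological conditions, the replicates, the mapping
#' of replicate to condition, the bin size, and the tested distance range.
#' All downstream Hi-C functions take one of these objects.
#'
#' @param conditions character vector of condition labels (at least two), in
#'   the order used for deterministic tie-breaking.
#' @param replicates character vector of replicate ids.
#' @param condition_of named character vector mapping each replicate id to its
#'   condition label.
#' @param bin_size bin width in base pairs (default 10000).
#' @param min_dist_bins,max_dist_bins tested interaction distance range in
#'   bins; defaults 4 and 500 (40 kb to 5 Mb at 10 kb bins). Interactions
#'   below `min_dist_bins` or beyond `max_dist_bins` are excluded throughout.
#' @return an object of class `study_design`.
#' @examples
#' design <- study_design(
#'   conditions = c("A", "B"),
#'   replicates = c("A1", "A2", "B1", "B2"),
#'   condition_of = c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
#' )
#' @export
study_design <- function(conditions, replicates, condition_of,
                         bin_size = 10000L,
                         min_dist_bins = 4L, max_dist_bins = 500L) {
  conditions <- as.character(conditions)
  replicates <- as.character(replicates)
  if (length(conditions) < 2L) stop("need at least two conditions")
  if (anyDuplicated(conditions)) stop("duplicate condition labels")
  if (anyDuplicated(replicates)) stop("duplicate replicate ids")
  if (!all(replicates %in% names(condition_of))) {
    stop("every replicate must be mapped to a condition")
  }
  condition_of <- condition_of[replicates]
  if (!all(condition_of %in% conditions)) {
    stop("condition_of maps to unknown condition labels")
  }
  if (any(table(factor(condition_of, levels = conditions)) < 1L)) {
    stop("each condition needs at least one replicate")
  }
  min_dist_bins <- as.integer(min_dist_bins)
  max_dist_bins <- as.integer(max_dist_bins)
  if (min_dist_bins < 1L) stop("min_dist_bins must be >= 1")
  if (max_dist_bins <= min_dist_bins) stop("max_dist_bins must exceed min_dist_bins")
  structure(
    list(conditions = conditions, replicates = replicates,
         condition_of = condition_of, bin_size = as.integer(bin_size),
         min_dist_bins = min_dist_bins, max_dist_bins = max_dist_bins),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", length(x$conditions), "conditions,",
      length(x$replicates), "replicates\n")
  for (cc in x$conditions) {
    cat(" ", cc, ":", paste(replicates_of(x, cc), collapse = ", "), "\n")
  }
  cat("  bin size", x$bin_size, "bp; tested distances",
      x$min_dist_bins, "-", x$max_dist_bins, "bins\n")
  invisible(x)
}

#' Replicates belonging to one condition
#' @param design a `study_design`.
#' @param condition condition label.
#' @return character vector of replicate ids.
#' @export
replicates_of <- function(design, condition) {
  design$replicates[design$condition_of == condition]
}
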