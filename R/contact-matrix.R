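#' Construct a binned intrachromosomal contact matrix
#'
#' Stores one replicate's raw counts for one chromosome as upper-triangular
#' sparse triplets with 0-based bin indices. Lower-triangle input entries are
#' mirrored to (min, max) order and duplicates are summed, so any unsorted
#' triplet dump canonicalizes to the same object.
#'
#' @param chrom chromosome label.
#' @param n_bins number of bins on the chromosome.
#' @param i,j 0-based bin indices (any order; mirrored to i <= j).
#' @param count non-negative integer counts.
#' @param replicate_id replicate identifier.
#' @return an object of class `contact_matrix` with a `data.table` of
#'   canonical entries (`i`, `j`, `count`), `n_bins`, `chrom`,
#'   `replicate_id`, and an (initially empty) `excluded_bins` set.
#' @export
contact_matrix <- function(chrom, n_bins, i = integer(0), j = integer(0),
                           count = numeric(0), replicate_id = NA_character_) {
  n_bins <- as.integer(n_bins)
  if (length(i) != length(j) || length(i) != length(count)) {
    stop("i, j, count must have equal length")
  }
  if (any(count < 0)) {
    stop("negative count at entry ", which(count < 0)[1])
  }
  if (length(i) && (min(i, j) < 0L || max(i, j) >= n_bins)) {
    stop("bin index out of range [0, n_bins)")
  }
  dt <- data.table(i = as.integer(pmin(i, j)), j = as.integer(pmax(i, j)),
                   count = as.numeric(count))
  if (nrow(dt)) {
    dt <- dt[, .(count = sum(count)), by = .(i, j)]
    setkeyv(dt, c("i", "j"))
  }
  structure(
    list(chrom = as.character(chrom), n_bins = n_bins, entries = dt,
         replicate_id = as.character(replicate_id),
         excluded_bins = integer(0)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix", x$chrom, "replicate", x$replicate_id, ":",
      x$n_bins, "bins,", nrow(x$entries), "entries,",
      length(x$excluded_bins), "excluded bins\n")
  invisible(x)
}

#' Read contact matrices from sparse triplet text
#'
#' Reads tab-separated `chrom  bin_i  bin_j  count` triplets for one
#' replicate and returns one canonical [contact_matrix] per chromosome.
#' Counts must be non-negative integers; offending lines are reported by
#' line number.
#'
#' @param path path to a triplet TSV (no header).
#' @param replicate_id replicate id the file belongs to; must be listed in
#'   `design` when a design is supplied.
#' @param n_bins named integer vector of bins per chromosome, or a single
#'   integer applied to all chromosomes.
#' @param design optional [study_design] used to validate the replicate id.
#' @return named list of `contact_matrix`, one per chromosome.
#' @export
read_contacts <- function(path, replicate_id, n_bins, design = NULL) {
  if (!is.null(design) && !(replicate_id %in% design$replicates)) {
    stop("unknown replicate id: ", replicate_id)
  }
  dt <- if (file.exists(path) && file.size(path) <= 1L) {
    data.table()
  } else {
    tryCatch(
      data.table::fread(path, header = FALSE, sep = "\t",
                        colClasses = list(character = 1)),
      error = function(e) stop("cannot read ", path, ": ",
                               conditionMessage(e))
    )
  }
  if (nrow(dt) == 0L) {
    chroms <- if (is.null(names(n_bins))) "chr" else names(n_bins)
    out <- lapply(chroms, function(cc) {
      contact_matrix(cc, n_bins[[1]], replicate_id = replicate_id)
    })
    names(out) <- chroms
    return(out)
  }
  if (ncol(dt) != 4L) stop("expected 4 columns (chrom, bin_i, bin_j, count)")
  data.table::setnames(dt, c("chrom", "i", "j", "count"))
  bad <- which(dt$count < 0)
  if (length(bad)) stop("negative count on line ", bad[1])
  nonint <- which(abs(dt$count - round(dt$count)) > 1e-9)
  if (length(nonint)) stop("non-integer count on line ", nonint[1])
  out <- lapply(split(dt, by = "chrom", keep.by = TRUE), function(sub) {
    nb <- if (length(n_bins) == 1L && is.null(names(n_bins))) {
      n_bins
    } else {
      if (!sub$chrom[1] %in% names(n_bins)) {
        stop("no n_bins entry for chromosome ", sub$chrom[1])
      }
      n_bins[[sub$chrom[1]]]
    }
    contact_matrix(sub$chrom[1], nb, sub$i, sub$j, sub$count,
                   replicate_id = replicate_id)
  })
  out[order(names(out))]
}

#' Write a contact matrix as sparse triplet text
#' @param m a [contact_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(m, path) {
  dt <- data.table(chrom = m$chrom, i = m$entries$i, j = m$entries$j,
                   count = m$entries$count)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Dense symmetric matrix view of a contact matrix
#' @param m a [contact_matrix].
#' @return an `n_bins` x `n_bins` symmetric numeric matrix.
#' @export
as_dense <- function(m) {
  out <- matrix(0, m$n_bins, m$n_bins)
  if (nrow(m$entries)) {
    idx <- cbind(m$entries$i + 1L, m$entries$j + 1L)
    out[idx] <- m$entries$count
    out[idx[, c(2, 1), drop = FALSE]] <- m$entries$count
  }
  out
}

#' Exclude bins with sparse near-diagonal coverage
#'
#' A bin is excluded when it has fewer than `min_nonzero` nonzero entries
#' within the first `window` entries counting from the diagonal in either
#' direction. All entries touching an excluded bin are removed. Because
#' removing one bin's entries can drop a neighbour below the threshold, the
#' rule is applied repeatedly until no further bin fails, which makes the
#' operation idempotent.
#'
#' @param m a [contact_matrix].
#' @param min_nonzero minimum nonzero near-diagonal entries to retain a bin
#'   (default 25).
#' @param window how far from the diagonal to look, in bins (default 300).
#' @return `m` with entries touching excluded bins dropped and
#'   `excluded_bins` recording the exclusion set (union with any prior set).
#' @export
filter_sparse_rows <- function(m, min_nonzero = 25L, window = 300L) {
  repeat {
    near <- m$entries[count > 0 & j - i <= window]
    occ <- integer(m$n_bins)
    if (nrow(near)) {
      occ <- tabulate(c(near$i, near$j[near$j != near$i]) + 1L,
                      nbins = m$n_bins)
    }
    retained <- setdiff(seq_len(m$n_bins) - 1L, m$excluded_bins)
    failing <- retained[occ[retained + 1L] < min_nonzero]
    if (!length(failing)) break
    m$excluded_bins <- sort(union(m$excluded_bins, failing))
    m$entries <- m$entries[!(i %in% failing) & !(j %in% failing)]
  }
  m
}
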