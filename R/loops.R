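#' Build a loop list from per-loop pixel memberships
#'
#' A loop is a named set of contact-matrix pixels (0-based, upper triangular)
#' on one chromosome, optionally tagged with a condition of origin or a
#' simulation truth category. The list is stored as one pixel-level
#' `data.table` with columns `loop_id`, `chrom`, `i`, `j`, `tag`.
#'
#' @param pixels a data.frame with columns `loop_id`, `chrom`, `i`, `j` and
#'   optionally `tag`.
#' @return an object of class `loop_list`.
#' @export
loop_list <- function(pixels) {
  dt <- as.data.table(pixels)
  if (!nrow(dt)) {
    dt <- data.table(loop_id = character(0), chrom = character(0),
                     i = integer(0), j = integer(0), tag = character(0))
  }
  if (!"tag" %in% names(dt)) dt[, tag := NA_character_]
  dt[, `:=`(i = as.integer(pmin(i, j)), j = as.integer(pmax(i, j)),
            loop_id = as.character(loop_id), chrom = as.character(chrom))]
  dt <- unique(dt, by = c("loop_id", "chrom", "i", "j"))
  setkeyv(dt, c("chrom", "i", "j"))
  structure(list(pixels = dt), class = "loop_list")
}

#' @export
print.loop_list <- function(x, ...) {
  cat("loop_list:", length(unique(x$pixels$loop_id)), "loops,",
      nrow(x$pixels), "member pixels\n")
  invisible(x)
}

#' Number of loops in a loop list
#' @param x a [loop_list].
#' @export
n_loops <- function(x) length(unique(x$pixels$loop_id))

#' Read loops from BEDPE
#'
#' Each BEDPE record (`chrom1 start1 end1 chrom2 start2 end2 [name]`,
#' 0-based half-open coordinates) becomes one loop whose member pixels are
#' all (i, j) bin pairs covered by the interval pair, stored with i <= j.
#' Intervals are snapped to the bin grid (floor of start, ceiling of end).
#' Interchromosomal records are skipped with a warning; records with
#' `end <= start` are rejected.
#'
#' @param path BEDPE file path.
#' @param bin_size bin width in bp.
#' @return a [loop_list].
#' @export
read_loops_bedpe <- function(path, bin_size = 10000L) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (nrow(dt) == 0L) return(loop_list(NULL))
  if (ncol(dt) < 6L) stop("BEDPE needs at least 6 columns")
  data.table::setnames(dt, 1:6, c("chrom1", "start1", "end1",
                                  "chrom2", "start2", "end2"))
  name <- if (ncol(dt) >= 7L) as.character(dt[[7]]) else
    sprintf("loop_%d", seq_len(nrow(dt)))
  if (any(dt$end1 <= dt$start1 | dt$end2 <= dt$start2)) {
    stop("BEDPE record with end <= start")
  }
  inter <- dt$chrom1 != dt$chrom2
  if (any(inter)) {
    warning(sum(inter), " interchromosomal record(s) skipped")
  }
  rows <- lapply(which(!inter), function(r) {
    b1 <- seq.int(floor(dt$start1[r] / bin_size),
                  ceiling(dt$end1[r] / bin_size) - 1L)
    b2 <- seq.int(floor(dt$start2[r] / bin_size),
                  ceiling(dt$end2[r] / bin_size) - 1L)
    grid <- expand.grid(i = b1, j = b2)
    data.table(loop_id = name[r], chrom = dt$chrom1[r],
               i = pmin(grid$i, grid$j), j = pmax(grid$i, grid$j))
  })
  loop_list(rbindlist(rows))
}

#' Write loops (or classified clusters) as BEDPE
#'
#' Each loop becomes one record with the bounding intervals of its member
#' pixels; the `tag` (class label or truth category) goes in the name field.
#'
#' @param loops a [loop_list].
#' @param path output path.
#' @param bin_size bin width in bp.
#' @return `path`, invisibly.
#' @export
write_loops_bedpe <- function(loops, path, bin_size = 10000L) {
  px <- loops$pixels
  if (!nrow(px)) {
    cat("", file = path)
    return(invisible(path))
  }
  rec <- px[, .(chrom1 = chrom[1],
                start1 = min(i) * bin_size, end1 = (max(i) + 1L) * bin_size,
                chrom2 = chrom[1],
                start2 = min(j) * bin_size, end2 = (max(j) + 1L) * bin_size,
                name = ifelse(is.na(tag[1]), loop_id[1], tag[1])),
            by = loop_id][, -"loop_id"]
  data.table::fwrite(rec, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Union footprint of a loop list
#' @param loops a [loop_list].
#' @return data.table of unique (chrom, i, j) pixels.
#' @export
loop_footprint <- function(loops) {
  unique(loops$pixels[, .(chrom, i, j)])
}
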