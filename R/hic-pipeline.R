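#' Call differential loops on Hi-C contact matrices
#'
#' End-to-end differential loop analysis across two or more conditions:
#' sparse-row filtering and Knight-Ruiz bias vectors per replicate and
#' chromosome, distance-dependent median-of-ratios size factors,
#' per-condition distance-dispersion estimation (qCML pooled across
#' chromosomes, precision-weighted LOWESS smoothing), a per-pixel
#' negative-binomial likelihood-ratio test at loop pixels,
#' Benjamini-Hochberg FDR control over the pooled loop-pixel p values,
#' 4-connected clustering of significant and insignificant pixels, and
#' strongest-condition classification.
#'
#' @param counts nested named list: `counts[[replicate]][[chrom]]` is a
#'   [contact_matrix]. A flat list of matrices (one chromosome) is also
#'   accepted.
#' @param loops a [loop_list] with the union of per-condition loop calls.
#' @param design a [study_design].
#' @param fdr q-value threshold for significance (default 0.01).
#' @param min_cluster_size minimum pixels per retained cluster (default 3).
#' @param dispersion one of `"pooled_ddr"` (default), `"poisson"`,
#'   `"global_nb"`, `"sample_variance"`.
#' @param lowess_frac optional LOWESS fraction override for the DDR fit.
#' @param n_groups distance groups for size-factor estimation.
#' @param filter_min_nonzero,filter_window sparse-row filter parameters.
#' @param sparse_filter apply [filter_sparse_rows()] first (default TRUE).
#' @return object of class `hic_result`: list with `pixels` (the tested
#'   loop-pixel table with means, statistics, `p`, `q`, `class`,
#'   `cluster_id`), `all_pixels` summary counts, `dispersion` (per
#'   condition `dispersion_model` when pooled), `size_factors`, `bias`,
#'   `design` and the call parameters.
#' @export
hic_call <- function(counts, loops, design, fdr = 0.01,
                     min_cluster_size = 3L,
                     dispersion = c("pooled_ddr", "poisson", "global_nb",
                                    "sample_variance"),
                     lowess_frac = NULL, n_groups = 100L,
                     filter_min_nonzero = 25L, filter_window = 300L,
                     sparse_filter = TRUE) {
  dispersion <- match.arg(dispersion)
  if (inherits(counts[[1]], "contact_matrix")) {
    counts <- lapply(counts, function(m) {
      stats::setNames(list(m), m$chrom)
    })
  }
  chroms <- names(counts[[design$replicates[1]]])
  bias <- list()
  sfms <- list()
  tables <- list()
  for (ch in chroms) {
    ch_counts <- lapply(counts, `[[`, ch)[design$replicates]
    if (sparse_filter) {
      ch_counts <- lapply(ch_counts, filter_sparse_rows,
                          min_nonzero = filter_min_nonzero,
                          window = filter_window)
    }
    ch_bias <- lapply(ch_counts, kr_balance)
    sfm <- estimate_size_factors(ch_counts, ch_bias, design,
                                 n_groups = n_groups)
    tab <- assemble_pixel_table(ch_counts, ch_bias, sfm, design)
    tab <- condition_means(tab, design)
    tab[, chrom := ch]
    bias[[ch]] <- ch_bias
    sfms[[ch]] <- sfm
    tables[[ch]] <- tab
  }
  pixels <- rbindlist(tables)
  tested <- pixels[tested == TRUE]

  ddr <- NULL
  if (dispersion == "pooled_ddr") {
    ddr <- list()
    for (cc in design$conditions) {
      reps <- replicates_of(design, cc)
      if (length(reps) < 2L) {
        stop("pooled dispersion estimation needs >= 2 replicates in ", cc)
      }
      raw <- estimate_raw_ddr(tested, reps, design$min_dist_bins,
                              design$max_dist_bins)
      ddr[[cc]] <- smooth_ddr(raw, design$min_dist_bins,
                              design$max_dist_bins,
                              lowess_frac = lowess_frac)
    }
  }

  fp <- loop_footprint(loops)
  lp <- merge(tested, fp, by = c("chrom", "i", "j"))
  if (!nrow(lp)) stop("no tested pixels under the loop footprint")
  reps <- design$replicates
  x <- as.matrix(lp[, paste0("x_", reps), with = FALSE])
  k <- as.matrix(lp[, paste0("k_", reps), with = FALSE])
  alpha <- switch(
    dispersion,
    pooled_ddr = {
      a <- matrix(0, nrow(lp), length(reps), dimnames = list(NULL, reps))
      for (r in reps) {
        a[, r] <- ddr_alpha(ddr[[design$condition_of[[r]]]], lp$dist)
      }
      a
    },
    alternative_dispersion(dispersion, lp, design)
  )
  res <- lrt_pixels(x, k, alpha, design)
  lp <- cbind(lp[, c("chrom", "i", "j", "dist",
                     paste0("zbar_", design$conditions)), with = FALSE],
              res)
  lp[, q := fdr_over_loops(p)]
  lp[, significant := q <= fdr]

  clvec <- rep(NA_integer_, nrow(lp))
  offset <- 0L
  for (ch in unique(lp$chrom)) {
    for (sig in c(TRUE, FALSE)) {
      sel <- which(lp$chrom == ch & lp$significant == sig)
      if (!length(sel)) next
      cl <- cluster_pixels(lp$i[sel], lp$j[sel],
                           min_size = min_cluster_size)
      clvec[sel] <- cl + offset
      offset <- offset + max(c(cl, 0L), na.rm = TRUE)
    }
  }
  lp[, cluster_id := clvec]
  zbar <- as.matrix(lp[, paste0("zbar_", design$conditions), with = FALSE])
  cls <- classify_pixels(zbar, lp$significant, lp$cluster_id,
                         design$conditions)
  lp[, `:=`(class = cls$class, tie = cls$tie)]

  structure(
    list(pixels = lp,
         n_tested = nrow(tested), n_pixels = nrow(pixels),
         dispersion = ddr, dispersion_mode = dispersion,
         size_factors = sfms, bias = bias, design = design,
         fdr = fdr, min_cluster_size = min_cluster_size),
    class = "hic_result"
  )
}

#' @export
print.hic_result <- function(x, ...) {
  cat("hic_result:", nrow(x$pixels), "loop pixels tested (",
      x$n_tested, "tested pixels overall );",
      sum(x$pixels$significant), "significant at q <=", x$fdr, "\n")
  cat("  classes:", paste(names(table(x$pixels$class)),
                          table(x$pixels$class), collapse = ", "), "\n")
  invisible(x)
}

#' Write pixel-level and cluster-level results
#'
#' Emits a pixel-level TSV (genomic coordinates, per-condition means, LRT
#' statistic, p, q, class, cluster id) and a cluster-level BEDPE whose name
#' field carries the class label. Both round-trip through
#' `data.table::fread` / [read_loops_bedpe()].
#'
#' @param result a `hic_result`.
#' @param pixel_path output TSV path.
#' @param cluster_path output BEDPE path (optional).
#' @return `pixel_path`, invisibly.
#' @export
write_results <- function(result, pixel_path, cluster_path = NULL) {
  bs <- result$design$bin_size
  px <- result$pixels
  out <- data.table(
    chrom = px$chrom,
    start1 = px$i * bs, end1 = (px$i + 1L) * bs,
    start2 = px$j * bs, end2 = (px$j + 1L) * bs)
  for (cc in result$design$conditions) {
    data.table::set(out, j = paste0("zbar_", cc),
                    value = px[[paste0("zbar_", cc)]])
  }
  for (col in c("lrt_stat", "p", "q", "class", "cluster_id")) {
    data.table::set(out, j = col, value = px[[col]])
  }
  data.table::fwrite(out, pixel_path, sep = "\t")
  if (!is.null(cluster_path)) {
    keep <- px[!is.na(cluster_id)]
    cl <- loop_list(keep[, .(loop_id = sprintf("cluster_%d", cluster_id),
                             chrom, i, j, tag = class)])
    write_loops_bedpe(cl, cluster_path, bin_size = bs)
  }
  invisible(pixel_path)
}
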