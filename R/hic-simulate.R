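#' Default distance-dispersion curve for simulations
#'
#' Decreases over the shortest distances and flattens, the qualitative
#' shape seen in real Hi-C dispersion trends.
#'
#' @param d distances in bins.
#' @param floor_alpha asymptotic dispersion (default 0.05).
#' @param short_extra added dispersion at the shortest tested distance
#'   (default 0.25).
#' @param min_dist distance at which the decay starts (default 4).
#' @param rate decay length in bins (default 5).
#' @return dispersions.
#' @export
sim_ddr_default <- function(d, floor_alpha = 0.05, short_extra = 0.25,
                            min_dist = 4L, rate = 5) {
  floor_alpha + short_extra * exp(-(d - min_dist) / rate)
}

#' Generate a synthetic Hi-C baseline mean field with planted loops
#'
#' The background follows a power-law distance decay
#' `z = scale * (j - i)^(-decay)`; `n_loops` non-overlapping 2x2-pixel
#' loop foci are multiplied by `enrichment`. Deterministic given `seed`.
#'
#' @param n_bins number of bins (default 2000).
#' @param n_loops number of planted loops (default 200).
#' @param decay power-law exponent (default 1).
#' @param enrichment multiplicative loop strength over background
#'   (default 4).
#' @param scale background intensity at distance 1 (default 1000, chosen
#'   so the mean stays well above the tested-pixel filter across the
#'   distance range).
#' @param min_dist,max_dist tested distance range in bins.
#' @param chrom chromosome label for the synthetic matrix.
#' @param seed integer seed.
#' @param max_attempts re-draws allowed for overlapping loops.
#' @return list with `pixels` (data.table `i`, `j`, `dist`, `z`), `loops`
#'   (a [loop_list] of the planted foci), `n_bins`, `min_dist`,
#'   `max_dist`, `chrom`.
#' @export
make_synthetic_baseline <- function(n_bins = 2000L, n_loops = 200L,
                                    decay = 1, enrichment = 4,
                                    scale = 1000, min_dist = 4L,
                                    max_dist = 500L, chrom = "chrS",
                                    seed = 1L, max_attempts = 50L) {
  stopifnot(n_bins > max_dist, decay > 0, enrichment > 0, scale > 0)
  pixels <- rbindlist(lapply(min_dist:max_dist, function(d) {
    ii <- 0:(n_bins - 1L - d)
    data.table(i = ii, j = ii + d, dist = d)
  }))
  pixels[, z := scale * dist^(-decay)]
  loop_px <- NULL
  if (n_loops > 0L) {
    loop_px <- with_seed(substream_seed(seed, "baseline"), {
      anchors <- data.table(i = integer(0), j = integer(0))
      out <- vector("list", n_loops)
      placed <- 0L
      attempts <- 0L
      while (placed < n_loops) {
        attempts <- attempts + 1L
        if (attempts > max_attempts * n_loops) {
          stop("could not place ", n_loops, " non-overlapping loops")
        }
        d <- sample((min_dist + 2L):(max_dist - 2L), 1L)
        i0 <- sample(0:(n_bins - 2L - d - 1L), 1L)
        j0 <- i0 + d
        # require clearance so loop foci plus their adjacency shells
        # never touch
        if (nrow(anchors) &&
            any(abs(anchors$i - i0) <= 4L & abs(anchors$j - j0) <= 4L)) {
          next
        }
        placed <- placed + 1L
        anchors <- rbind(anchors, data.table(i = i0, j = j0))
        grid <- expand.grid(i = i0 + 0:1, j = j0 + 0:1)
        out[[placed]] <- data.table(
          loop_id = sprintf("sim_loop_%04d", placed),
          chrom = chrom, i = grid$i, j = grid$j)
      }
      rbindlist(out)
    })
    pixels[loop_px, z := z * enrichment, on = c("i", "j")]
  }
  loops <- loop_list(loop_px)
  list(pixels = pixels, loops = loops, n_bins = n_bins,
       min_dist = min_dist, max_dist = max_dist, chrom = chrom)
}

#' Label loops and perturb the mean field for two artificial conditions
#'
#' A fraction `p_diff` of the planted loops is truly differential, split
#' across four categories (up in A, down in A, up in B, down in B); the
#' rest stay constitutive. Counts are balanced: exactly
#' `round(p_diff * n_loops)` loops are differential, divided as evenly as
#' possible among the categories, with the assignment randomized by
#' `seed`. Loop pixels of an up-in-A loop get `mu_A = (1 + beta) * z`;
#' down-in-A gets `(1 - beta) * z`; condition B is analogous. Non-loop
#' pixels 4-adjacent to a perturbed loop receive half the effect in the
#' matching condition and carry truth label 0.
#'
#' @param baseline from [make_synthetic_baseline()].
#' @param beta fractional effect size in `[0, 1]`.
#' @param p_diff fraction of truly differential loops.
#' @param seed integer seed.
#' @param labels optional pre-assigned category per loop id (named
#'   character vector with values in `up_A`, `down_A`, `up_B`, `down_B`,
#'   `constitutive`); overrides the random assignment.
#' @return list with `pixels` (data.table `i`, `j`, `dist`, `mu_A`,
#'   `mu_B`, `t`), `loop_labels` (loop id -> category) and `loops`.
#' @export
label_and_perturb <- function(baseline, beta, p_diff, seed = 1L,
                              labels = NULL) {
  if (beta < 0 || beta > 1) {
    stop("beta must lie in [0, 1]; down-perturbations would go negative")
  }
  ids <- unique(baseline$loops$pixels$loop_id)
  nl <- length(ids)
  cats <- c("up_A", "down_A", "up_B", "down_B")
  if (is.null(labels)) {
    n_diff <- round(p_diff * nl)
    cat_counts <- rep(n_diff %/% 4L, 4L)
    extra <- n_diff %% 4L
    labels <- with_seed(substream_seed(seed, "labels"), {
      if (extra > 0L) {
        lucky <- sample(4L, extra)
        cat_counts[lucky] <- cat_counts[lucky] + 1L
      }
      lab <- c(rep(cats, times = cat_counts),
               rep("constitutive", nl - n_diff))
      sample(lab)
    })
    names(labels) <- ids
  } else {
    stopifnot(all(ids %in% names(labels)),
              all(labels %in% c(cats, "constitutive")))
    labels <- labels[ids]
  }
  px <- data.table::copy(baseline$pixels)
  px[, `:=`(mu_A = z, mu_B = z, t = 0L)]
  lpx <- data.table::copy(baseline$loops$pixels)
  lpx[, cat := labels[loop_id]]
  member <- unique(lpx[, .(i, j)])
  for (ct in cats) {
    sub <- lpx[cat == ct]
    if (!nrow(sub)) next
    sign <- if (grepl("^up", ct)) 1 else -1
    col <- if (grepl("_A$", ct)) "mu_A" else "mu_B"
    px[sub, (col) := z * (1 + sign * beta), on = c("i", "j")]
    px[sub, t := 1L, on = c("i", "j")]
    shell <- rbindlist(lapply(list(c(1L, 0L), c(-1L, 0L), c(0L, 1L),
                                   c(0L, -1L)), function(dd) {
      data.table(i = sub$i + dd[1], j = sub$j + dd[2])
    }))
    shell <- unique(shell)[!member, on = c("i", "j")]
    px[shell, (col) := z * (1 + sign * beta / 2), on = c("i", "j")]
  }
  list(pixels = px, loop_labels = labels, loops = baseline$loops)
}

#' Impose biases and sample raw pseudoreplicate contact matrices
#'
#' For each pseudoreplicate the true mean field of its condition is scaled
#' by the matched bias vector and per-distance size factors, then counts
#' are drawn as `NB(mu_biased, alpha(d))` (Poisson when the dispersion is
#' 0). Each pseudoreplicate uses its own seed substream, so adding one
#' never changes the others.
#'
#' @param perturbed from [label_and_perturb()].
#' @param design a [study_design] naming the pseudoreplicates.
#' @param alpha_fun function of distance (bins) returning the dispersion
#'   used for sampling (default [sim_ddr_default()]).
#' @param bias named list per replicate of per-bin bias vectors (default
#'   identity).
#' @param size_factors named list per replicate of per-distance factors
#'   indexed `0:max_dist` (default identity).
#' @param n_bins number of bins.
#' @param chrom chromosome label.
#' @param seed integer master seed.
#' @return named list of [contact_matrix], one per pseudoreplicate.
#' @export
bias_and_sample <- function(perturbed, design,
                            alpha_fun = sim_ddr_default,
                            bias = NULL, size_factors = NULL,
                            n_bins, chrom = "chrS", seed = 1L) {
  px <- perturbed$pixels
  alpha <- alpha_fun(px$dist)
  if (any(!is.finite(alpha) | alpha < 0)) {
    stop("dispersion curve undefined or negative at a needed distance")
  }
  out <- list()
  for (r in design$replicates) {
    cc <- design$condition_of[[r]]
    mu <- px[[paste0("mu_", cc)]]
    b <- if (is.null(bias)) rep(1, n_bins) else bias[[r]]
    s <- if (is.null(size_factors)) NULL else size_factors[[r]]
    sv <- if (is.null(s)) 1 else s[px$dist + 1L]
    mu_biased <- mu * b[px$i + 1L] * b[px$j + 1L] * sv
    counts <- with_seed(substream_seed(seed, "draw", r), {
      x <- numeric(length(mu_biased))
      pois <- alpha < 1e-12
      x[pois] <- rpois(sum(pois), mu_biased[pois])
      if (any(!pois)) {
        x[!pois] <- rnbinom(sum(!pois), mu = mu_biased[!pois],
                            size = 1 / alpha[!pois])
      }
      x
    })
    keep <- counts > 0
    out[[r]] <- contact_matrix(chrom, n_bins, px$i[keep], px$j[keep],
                               counts[keep], replicate_id = r)
  }
  out
}

#' Simulate a two-condition Hi-C experiment with known truth
#'
#' Convenience wrapper: builds a synthetic baseline, labels and perturbs
#' loops, and samples pseudoreplicates.
#'
#' @param n_bins,n_loops,decay,enrichment,scale,min_dist,max_dist,chrom
#'   passed to [make_synthetic_baseline()].
#' @param beta,p_diff passed to [label_and_perturb()].
#' @param n_replicates pseudoreplicates per artificial condition
#'   (default 2).
#' @param alpha_fun sampling dispersion curve.
#' @param bin_size bin width in bp.
#' @param seed master seed.
#' @return list with `counts` (per pseudoreplicate), `design`, `loops`,
#'   `truth` (loop-pixel table with `t`), `loop_labels`, `baseline`,
#'   `perturbed`.
#' @export
simulate_hic_experiment <- function(n_bins = 2000L, n_loops = 200L,
                                    beta = 0.3, p_diff = 0.4,
                                    n_replicates = 2L,
                                    decay = 1, enrichment = 4,
                                    scale = 1000, min_dist = 4L,
                                    max_dist = 500L, bin_size = 10000L,
                                    alpha_fun = sim_ddr_default,
                                    chrom = "chrS", seed = 1L) {
  reps <- c(paste0("A", seq_len(n_replicates)),
            paste0("B", seq_len(n_replicates)))
  design <- study_design(
    conditions = c("A", "B"), replicates = reps,
    condition_of = stats::setNames(substr(reps, 1, 1), reps),
    bin_size = bin_size, min_dist_bins = min_dist,
    max_dist_bins = max_dist)
  baseline <- make_synthetic_baseline(
    n_bins = n_bins, n_loops = n_loops, decay = decay,
    enrichment = enrichment, scale = scale, min_dist = min_dist,
    max_dist = max_dist, chrom = chrom, seed = seed)
  perturbed <- label_and_perturb(baseline, beta = beta, p_diff = p_diff,
                                 seed = seed)
  counts <- bias_and_sample(perturbed, design, alpha_fun = alpha_fun,
                            n_bins = n_bins, chrom = chrom, seed = seed)
  truth <- merge(loop_footprint(baseline$loops),
                 perturbed$pixels[, .(i, j, t)], by = c("i", "j"))
  list(counts = counts, design = design, loops = baseline$loops,
       truth = truth, loop_labels = perturbed$loop_labels,
       baseline = baseline, perturbed = perturbed)
}

#' Fraction of loop pixels that are truly differential
#'
#' @param truth data.table with a `t` column over the loop-pixel set (as
#'   returned in `simulate_hic_experiment()$truth`).
#' @return the exact fraction with `t = 1`.
#' @export
estimate_truth_prevalence <- function(truth) {
  if (!nrow(truth)) return(0)
  mean(truth$t == 1L)
}
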