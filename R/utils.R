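#' @importFrom data.table data.table := setkeyv setorder as.data.table rbindlist
#' @importFrom stats p.adjust qchisq pchisq dpois ppois qnorm pnorm plogis
#' @importFrom stats dnbinom pnbinom qnbinom rnbinom rpois optimize optim
#' @importFrom stats median quantile sd var lowess approx runif setNames
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  "i", "j", "count", "chrom", "dist", "y", "geo", "ratio", "grp", "z",
  "cond", "rep_id", "n_nonzero", "..keep", "value", "truth", "N"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a master seed
#'
#' All stochastic entry points accept one master seed and fan it out to
#' independent named substreams so that, e.g., adding a pseudoreplicate does
#' not change the draws of existing ones.
#'
#' @param seed master integer seed.
#' @param ... character or integer labels identifying the substream.
#' @return an integer seed below 2^31.
#' @keywords internal
substream_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utils::head(charToRaw(labels), 64L)
  h <- 0
  for (b in as.integer(bytes)) h <- (h * 131 + b) %% 2147483629
  as.integer((h + as.numeric(seed)) %% 2147483629) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Connected components of pixels under 4-connectivity
#'
#' Two pixels are connected when they share an edge in matrix space
#' (|di| + |dj| = 1). Union-find over the pixel set.
#'
#' @param i,j integer vectors of pixel coordinates (equal length).
#' @return integer vector of component labels (1-based, arbitrary order).
#' @keywords internal
pixel_components <- function(i, j) {
  n <- length(i)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  key <- paste(i, j)
  idx <- stats::setNames(seq_len(n), key)
  for (d in list(c(1L, 0L), c(0L, 1L))) {
    nb <- idx[paste(i + d[1], j + d[2])]
    hit <- which(!is.na(nb))
    for (a in hit) {
      ra <- find(a); rb <- find(nb[[a]])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
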