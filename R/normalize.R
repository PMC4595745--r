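# Trimmed mean of M-values (TMM) normalization.
#
# Composition-bias correction for count data: per-sample scaling factors are
# the precision-weighted mean of gene-wise log2 expression ratios against a
# reference sample, after double trimming by log-ratio (M) and average
# log-abundance (A). Factors are rescaled to have product 1, so they modify
# relative, not total, library size.

tmm_pair <- function(obs, ref, lib_obs, lib_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(NA_real_)
  o <- obs[keep]; r <- ref[keep]
  p_o <- o / lib_obs; p_r <- r / lib_ref
  M <- log2(p_o / p_r)
  A <- (log2(p_o) + log2(p_r)) / 2
  # asymptotic variance of M under binomial sampling; weight = 1/v
  v <- (lib_obs - o) / (lib_obs * o) + (lib_ref - r) / (lib_ref * r)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(NA_real_)
  2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
}

#' TMM normalization factors
#'
#' The reference sample is the one whose upper-quartile CPM is closest to the
#' mean upper-quartile across samples. For every other sample, gene-wise
#' log2 ratios of depth-normalized proportions against the reference (M) and
#' average log2 abundances (A) are computed over genes observed in both;
#' the most extreme `trim_m` fraction of M values and `trim_a` fraction of A
#' values are trimmed from each tail, and the factor is 2 to the
#' precision-weighted mean of the surviving M values (weights: inverse
#' asymptotic binomial variance). Factors are rescaled so their product is 1.
#'
#' Apply the expression filter before calling; spike-in rows should normally
#' be excluded.
#'
#' @param counts a [count_matrix()] or plain counts matrix (filtered).
#' @param trim_m two-sided trim fraction on M (default 0.3).
#' @param trim_a two-sided trim fraction on A (default 0.05).
#' @param lib_size optional library sizes; defaults to the column sums of
#'   `counts` (pass the full-matrix library sizes to normalize against
#'   unfiltered depth).
#' @return Named numeric vector of factors (product 1), with the reference
#'   sample id in attribute `"reference"`.
#' @examples
#' m <- matrix(rpois(300, 50), 50, 6,
#'             dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
#' tmm_factors(m)
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05, lib_size = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (ncol(m) < 2) stop("TMM needs at least 2 samples")
  if (is.null(lib_size)) lib_size <- colSums(m)
  check_lib_sizes(stats::setNames(lib_size, colnames(m)))
  uq <- apply(sweep(m, 2, lib_size, "/"), 2, stats::quantile, p = 0.75)
  ref_j <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref_j) return(1)
    fj <- tmm_pair(m[, j], m[, ref_j], lib_size[j], lib_size[ref_j],
                   trim_m, trim_a)
    if (is.na(fj)) {
      warning("no usable genes against reference for sample ",
              colnames(m)[j], "; factor set to 1")
      fj <- 1
    }
    fj
  }, numeric(1))
  f <- f / exp(mean(log(f)))   # geometric mean 1 <=> product 1
  names(f) <- colnames(m)
  attr(f, "reference") <- colnames(m)[ref_j]
  f
}
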