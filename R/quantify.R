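# Gene-level quantification: CPM, FPKM, TPM, expression filter, group means.
# Library size is the column sum over ALL rows, spike-ins included; TPM is
# FPKM rescaled so each column sums to 1e6 over the rows in the denominator.

expression_matrix <- function(m, unit) {
  attr(m, "unit") <- unit
  class(m) <- c("expression_matrix", class(m))
  m
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix [", attr(x, "unit"), "]: ", nrow(x), " genes x ",
      ncol(x), " samples\n", sep = "")
  invisible(x)
}

check_lib_sizes <- function(lib) {
  bad <- names(lib)[lib <= 0]
  if (length(bad))
    stop("zero library size in sample(s): ", paste(bad, collapse = ", "))
}

#' Counts per million
#'
#' `CPM[g, j] = counts[g, j] / libsize_j * 1e6`, with the library size taken
#' over all rows of the matrix (spike-ins included).
#'
#' @param counts a [count_matrix()].
#' @return An `expression_matrix` with unit `"CPM"`.
#' @export
compute_cpm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  lib <- lib_sizes(counts)
  check_lib_sizes(lib)
  expression_matrix(sweep(counts$counts, 2, lib, "/") * 1e6, "CPM")
}

#' Fragments per kilobase per million mapped reads
#'
#' Read counts divided by the summed exon length of the gene in kilobases,
#' then by the library size in millions:
#' `FPKM[g, j] = counts[g, j] / length_kb_g / (libsize_j / 1e6)`.
#'
#' @param counts a [count_matrix()].
#' @return An `expression_matrix` with unit `"FPKM"`.
#' @export
compute_fpkm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  lib <- lib_sizes(counts)
  check_lib_sizes(lib)
  m <- counts$counts / counts$exon_length_kb
  expression_matrix(sweep(m, 2, lib / 1e6, "/"), "FPKM")
}

#' Rescale FPKM to transcripts per million
#'
#' `TPM[g, j] = FPKM[g, j] / sum_g FPKM[g, j] * 1e6`; every column of the
#' result sums to 1e6 over the rows entering the denominator.
#'
#' @param fpkm an `expression_matrix` with unit `"FPKM"`.
#' @param denominator_rows optional logical/character/integer selector of the
#'   rows forming the per-column denominator (default: all rows). Rows outside
#'   the selection are still rescaled by the same factor.
#' @return An `expression_matrix` with unit `"TPM"`.
#' @export
fpkm_to_tpm <- function(fpkm, denominator_rows = NULL) {
  if (!identical(attr(fpkm, "unit"), "FPKM"))
    stop("fpkm_to_tpm expects an FPKM expression_matrix")
  denom_m <- if (is.null(denominator_rows)) fpkm else fpkm[denominator_rows, , drop = FALSE]
  cs <- colSums(denom_m)
  bad <- colnames(fpkm)[cs <= 0]
  if (length(bad)) stop("all-zero FPKM column(s): ", paste(bad, collapse = ", "))
  expression_matrix(sweep(unclass(fpkm), 2, cs, "/") * 1e6, "TPM")
}

#' Transcripts per million from counts
#'
#' Convenience wrapper: [compute_fpkm()] then [fpkm_to_tpm()].
#'
#' @param counts a [count_matrix()].
#' @param exclude_spikes if `TRUE`, spike-in rows are dropped from the TPM
#'   denominator (they still receive TPM values on the gene scale). Default
#'   `FALSE`: "sum of all FPKM" is taken literally over every row, so that
#'   spike-ins carry TPM on the same scale used for calibration.
#' @return An `expression_matrix` with unit `"TPM"`.
#' @export
compute_tpm <- function(counts, exclude_spikes = FALSE) {
  fpkm <- compute_fpkm(counts)
  denom <- if (exclude_spikes) !counts$is_spike else NULL
  fpkm_to_tpm(fpkm, denom)
}

#' Expression filter
#'
#' Keeps genes with CPM strictly greater than `min_cpm` in at least
#' `min_samples` samples, preserving input order. The default thresholds
#' (CPM > 1 in >= 3 samples) match the filter applied before model fitting.
#'
#' @param counts a [count_matrix()].
#' @param min_cpm strict CPM threshold (default 1).
#' @param min_samples minimum number of samples exceeding it (default 3).
#' @param exclude_spikes drop spike-in rows from the returned list
#'   (default `TRUE`; library sizes still include them).
#' @return Character vector of retained gene ids, in input order.
#' @export
filter_expressed <- function(counts, min_cpm = 1, min_samples = 3,
                             exclude_spikes = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  if (min_samples > ncol(counts$counts))
    stop("min_samples exceeds the number of samples")
  cpm <- compute_cpm(counts)
  keep <- rowSums(cpm > min_cpm) >= min_samples
  if (exclude_spikes) keep <- keep & !counts$is_spike
  rownames(counts$counts)[keep]
}

#' Per-group mean CPM
#'
#' Arithmetic mean of CPM across the samples of each (cell_type, condition)
#' group. Used both for the DEG abundance criterion (mean CPM > 20 in at
#' least one group) and for the MDS gene filter.
#'
#' @param cpm an `expression_matrix` with unit `"CPM"` (or any gene x sample
#'   matrix).
#' @param design validated design matching the columns of `cpm`.
#' @return Matrix genes x groups of group means.
#' @export
group_mean_cpm <- function(cpm, design) {
  design <- sample_design(design)
  if (!all(design$sample_id %in% colnames(cpm)))
    stop("design contains samples absent from the expression matrix")
  grp <- design_groups(design)
  if (any(table(grp) == 0)) stop("empty group in design")
  out <- sapply(levels(grp), function(g) {
    idx <- design$sample_id[grp == g]
    rowMeans(cpm[, idx, drop = FALSE])
  })
  if (!is.matrix(out))
    out <- matrix(out, nrow = nrow(cpm), dimnames = list(NULL, levels(grp)))
  rownames(out) <- rownames(cpm)
  out
}
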