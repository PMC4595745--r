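#' Gene-by-sample count matrix with gene annotation
#'
#' Container for gene-level read counts together with the per-gene exon length
#' (in kilobases) needed for FPKM/TPM and a flag marking spike-in rows.
#' All quantification and differential-expression functions in this package
#' take a `count_matrix` as input.
#'
#' @param counts integer matrix, genes x samples, with unique row and column
#'   names. Entries must be non-negative whole numbers.
#' @param exon_length_kb numeric vector of summed exon lengths in kilobases,
#'   one per gene, all strictly positive. Recycled names are taken from
#'   `counts` when unnamed.
#' @param is_spike logical vector marking spike-in rows (e.g. ERCC controls).
#'   Defaults to all `FALSE`.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `exon_length_kb` and `is_spike`.
#' @examples
#' m <- matrix(c(3L, 7L, 0L, 10L), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' cm <- count_matrix(m, exon_length_kb = c(1, 2))
#' lib_sizes(cm)
#' @export
count_matrix <- function(counts, exon_length_kb, is_spike = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids")
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite and numeric")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  exon_length_kb <- as.numeric(exon_length_kb)
  if (length(exon_length_kb) != nrow(counts))
    stop("exon_length_kb must have one entry per gene")
  if (any(!is.finite(exon_length_kb)) || any(exon_length_kb <= 0))
    stop("exon_length_kb must be strictly positive")
  names(exon_length_kb) <- rownames(counts)
  if (is.null(is_spike)) is_spike <- rep(FALSE, nrow(counts))
  is_spike <- as.logical(is_spike)
  if (length(is_spike) != nrow(counts) || anyNA(is_spike))
    stop("is_spike must be a logical vector with one entry per gene")
  if (all(is_spike)) stop("count matrix must contain at least one non-spike gene")
  names(is_spike) <- rownames(counts)
  structure(list(counts = counts, exon_length_kb = exon_length_kb,
                 is_spike = is_spike),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples (",
      sum(x$is_spike), "spike-ins )\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by gene and/or sample
#'
#' @param x a [count_matrix()].
#' @param genes gene ids or row indices (default all).
#' @param samples sample ids or column indices (default all).
#' @return A `count_matrix` restricted to the requested rows/columns.
#' @export
subset_counts <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(genes)) genes <- rownames(x$counts)
  if (is.null(samples)) samples <- colnames(x$counts)
  count_matrix(x$counts[genes, samples, drop = FALSE],
               x$exon_length_kb[genes],
               x$is_spike[genes])
}

#' Library sizes (column sums over all rows, spike-ins included)
#'
#' @param x a [count_matrix()].
#' @return Named numeric vector of per-sample totals.
#' @export
lib_sizes <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  colSums(x$counts)
}

#' Sample design table for a sorted-cell experiment
#'
#' Validates a per-sample table carrying the cell type, condition and number
#' of sorted cells pooled into each tube, and (optionally) checks it against
#' a count matrix.
#'
#' @param design data.frame with columns `sample_id`, `cell_type`,
#'   `condition`, `n_cells`.
#' @param counts optional [count_matrix()]; when given, `design` must have
#'   exactly one row per count column.
#' @return The validated design, with `sample_id` as character and group
#'   labels as factors, rows ordered to match `counts` when supplied.
#' @export
sample_design <- function(design, counts = NULL) {
  need <- c("sample_id", "cell_type", "condition", "n_cells")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design is missing column(s): ", paste(miss, collapse = ", "))
  design$sample_id <- as.character(design$sample_id)
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  design$cell_type <- factor(design$cell_type)
  design$condition <- factor(design$condition)
  design$n_cells <- as.numeric(design$n_cells)
  if (any(!is.finite(design$n_cells)) || any(design$n_cells <= 0) ||
      any(design$n_cells != round(design$n_cells)))
    stop("n_cells must be positive integers")
  grp <- table(droplevels(interaction(design$cell_type, design$condition, sep = ".")))
  if (any(grp < 2))
    stop("each (cell_type, condition) group needs at least 2 samples; offending: ",
         paste(names(grp)[grp < 2], collapse = ", "))
  if (!is.null(counts)) {
    stopifnot(inherits(counts, "count_matrix"))
    sm <- colnames(counts$counts)
    missing_in_design <- setdiff(sm, design$sample_id)
    if (length(missing_in_design))
      stop("sample(s) in counts but not in design: ",
           paste(missing_in_design, collapse = ", "))
    extra <- setdiff(design$sample_id, sm)
    if (length(extra))
      stop("sample(s) in design but not in counts: ", paste(extra, collapse = ", "))
    design <- design[match(sm, design$sample_id), , drop = FALSE]
    rownames(design) <- NULL
  }
  design
}

#' Group labels for a design (cell_type.condition)
#'
#' @param design a validated design table.
#' @return Factor of per-sample group labels.
#' @export
design_groups <- function(design) {
  droplevels(interaction(design$cell_type, design$condition, sep = ".",
                         lex.order = TRUE))
}
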