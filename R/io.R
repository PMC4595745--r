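# Readers and writers for the plain-text artifacts the pipeline touches:
# counts (TSV or MatrixMarket triplet), design TSV, ERCC reference TSV,
# gene sets (GMT) and results TSV. TSV dialect: tab-separated, UTF-8,
# "#"-prefixed comment header lines.

read_tsv_commented <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

header_lines <- function(config = NULL, seed = NULL) {
  ln <- character(0)
  if (!is.null(seed)) ln <- c(ln, paste0("# seed=", seed))
  if (!is.null(config))
    ln <- c(ln, paste0("# config_hash=", config_hash(config)))
  ln
}

write_tsv_commented <- function(df, path, config = NULL, seed = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  hl <- header_lines(config, seed)
  if (length(hl)) writeLines(hl, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample count matrix
#'
#' Two on-disk layouts are supported. `format = "tsv"`: a tab-separated table
#' with columns `gene_id`, `length_kb`, optionally `is_spike`, followed by one
#' column per sample; lines starting with `#` are ignored. `format = "mtx"`:
#' a MatrixMarket coordinate file (1-based indices) with two sidecar files,
#' `<path>.genes.tsv` (columns `gene_id`, `length_kb`, optional `is_spike`)
#' and `<path>.samples.tsv` (column `sample_id`).
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"mtx"`.
#' @return A [count_matrix()]. Non-integer or negative entries are rejected.
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- read_tsv_commented(path)
    if (!"gene_id" %in% names(df)) stop("counts TSV must have a gene_id column")
    if (!"length_kb" %in% names(df)) stop("counts TSV is missing the length_kb column")
    spike <- if ("is_spike" %in% names(df)) as.logical(df$is_spike) else NULL
    samp <- setdiff(names(df), c("gene_id", "length_kb", "is_spike"))
    if (!length(samp)) stop("counts TSV has no sample columns")
    m <- as.matrix(df[, samp, drop = FALSE])
    rownames(m) <- df$gene_id
    count_matrix(m, df$length_kb, spike)
  } else {
    m <- as.matrix(Matrix::readMM(path))
    gf <- paste0(path, ".genes.tsv"); sf <- paste0(path, ".samples.tsv")
    if (!file.exists(gf) || !file.exists(sf))
      stop("mtx sidecar files not found: ", gf, " / ", sf)
    genes <- read_tsv_commented(gf)
    samples <- read_tsv_commented(sf)
    if (!all(c("gene_id", "length_kb") %in% names(genes)))
      stop("mtx gene sidecar must have gene_id and length_kb columns")
    if (nrow(genes) != nrow(m) || nrow(samples) != ncol(m))
      stop("mtx dimensions disagree with sidecar files")
    dimnames(m) <- list(genes$gene_id, samples$sample_id)
    spike <- if ("is_spike" %in% names(genes)) as.logical(genes$is_spike) else NULL
    count_matrix(m, genes$length_kb, spike)
  }
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]; round-trips bit-identically on valid input.
#'
#' @param x a [count_matrix()].
#' @param path output path.
#' @param format `"tsv"` or `"mtx"`.
#' @param config,seed optional run configuration and seed recorded as `#`
#'   header comment lines (TSV) or sidecar headers (MTX).
#' @return The path, invisibly.
#' @export
write_counts <- function(x, path, format = c("tsv", "mtx"),
                         config = NULL, seed = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(x$counts),
                     length_kb = x$exon_length_kb,
                     is_spike = x$is_spike,
                     x$counts, check.names = FALSE)
    write_tsv_commented(df, path, config, seed)
  } else {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    write_tsv_commented(
      data.frame(gene_id = rownames(x$counts), length_kb = x$exon_length_kb,
                 is_spike = x$is_spike),
      paste0(path, ".genes.tsv"), config, seed)
    write_tsv_commented(data.frame(sample_id = colnames(x$counts)),
                        paste0(path, ".samples.tsv"), config, seed)
  }
  invisible(path)
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample_id`, `cell_type`, `condition`,
#'   `n_cells`.
#' @param counts optional [count_matrix()] to cross-validate against; an error
#'   names any sample present in one but not the other.
#' @return A validated design data.frame (see [sample_design()]).
#' @export
read_design <- function(path, counts = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sample_design(read_tsv_commented(path), counts)
}

#' Write a design table
#' @param design validated design.
#' @param path output path.
#' @param config,seed optional header metadata.
#' @return The path, invisibly.
#' @export
write_design <- function(design, path, config = NULL, seed = NULL) {
  write_tsv_commented(design, path, config, seed)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (class `gene_set_collection`).
#'   Empty sets are rejected.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with no members: ", f[1])
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) stop("empty gene set: ", f[1])
    sets[[f[1]]] <- unique(members)
  }
  gene_set_collection(sets)
}

#' Construct a gene-set collection
#' @param sets named list of character vectors; empty sets rejected.
#' @return Class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named")
  if (any(lengths(sets) == 0)) stop("empty gene sets are not allowed")
  sets <- lapply(sets, as.character)
  structure(sets, class = "gene_set_collection")
}

#' Write gene sets in GMT format
#' @param sets a `gene_set_collection` or named list.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an ERCC spike-in reference table
#'
#' @param path TSV with columns `spike_id`, `length_kb`, `copies_per_tube`.
#' @return data.frame of class `spikein_reference`.
#' @export
read_ercc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  spikein_reference(read_tsv_commented(path))
}

#' Construct/validate a spike-in reference
#' @param ref data.frame with `spike_id`, `length_kb`, `copies_per_tube`.
#' @return Validated data.frame of class `spikein_reference`.
#' @export
spikein_reference <- function(ref) {
  need <- c("spike_id", "length_kb", "copies_per_tube")
  miss <- setdiff(need, names(ref))
  if (length(miss)) stop("spike-in reference missing column(s): ",
                         paste(miss, collapse = ", "))
  ref$spike_id <- as.character(ref$spike_id)
  if (anyDuplicated(ref$spike_id)) stop("duplicate spike_id")
  if (any(ref$length_kb <= 0)) stop("length_kb must be > 0")
  if (any(ref$copies_per_tube < 0)) stop("copies_per_tube must be >= 0")
  class(ref) <- c("spikein_reference", "data.frame")
  ref
}

#' Write a spike-in reference table
#' @param ref a `spikein_reference`.
#' @param path output path.
#' @param config,seed optional header metadata.
#' @return The path, invisibly.
#' @export
write_ercc <- function(ref, path, config = NULL, seed = NULL) {
  write_tsv_commented(as.data.frame(ref), path, config, seed)
}

#' Write differential-expression results
#'
#' Emits the long-format results table (gene, contrast, log2fc, t, p, q,
#' per-group mean CPM, deg_flag) as TSV with full precision, plus `#`
#' seed/config header lines when supplied.
#'
#' @param de a `de_result` (see [fit_moderated()], [call_deg()]).
#' @param path output path.
#' @param config,seed optional header metadata.
#' @return The path, invisibly.
#' @export
write_results <- function(de, path, config = NULL, seed = NULL) {
  stopifnot(inherits(de, "de_result"))
  tab <- de$table
  cpm <- de$group_cpm[match(tab$gene, rownames(de$group_cpm)), , drop = FALSE]
  colnames(cpm) <- paste0("cpm.", colnames(cpm))
  out <- cbind(tab, as.data.frame(cpm, check.names = FALSE))
  # full precision so q-values survive a round-trip
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) formatC(v, digits = 17, format = "g"))
  write_tsv_commented(out, path, config, seed)
}

#' Read back a results table written by [write_results()]
#' @param path results TSV.
#' @return data.frame in long format.
#' @export
read_results <- function(path) {
  read_tsv_commented(path)
}

#' Run configuration
#'
#' Bundles the seed and the thresholds that define a pipeline run, so they
#' can be recorded in every output header.
#'
#' @param seed integer master seed.
#' @param q_max q-value cutoff for DEG calls.
#' @param lfc_min minimum absolute log2 fold-change.
#' @param cpm_min minimum group-mean CPM (in at least one group).
#' @param filter_min_cpm,filter_min_samples expression-filter thresholds.
#' @param n_permutations permutations for the empirical-FDR study.
#' @param out_dir output directory recorded for provenance.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, q_max = 0.05, lfc_min = 1, cpm_min = 20,
                       filter_min_cpm = 1, filter_min_samples = 3,
                       n_permutations = 1000L, out_dir = ".") {
  stopifnot(q_max > 0, lfc_min > 0, cpm_min > 0, filter_min_cpm > 0,
            filter_min_samples > 0, n_permutations > 0)
  structure(list(seed = as.integer(seed), q_max = q_max, lfc_min = lfc_min,
                 cpm_min = cpm_min, filter_min_cpm = filter_min_cpm,
                 filter_min_samples = filter_min_samples,
                 n_permutations = as.integer(n_permutations),
                 out_dir = out_dir),
            class = "run_config")
}

#' Stable hash of a run configuration
#'
#' MD5 of the deparsed configuration, used to stamp output headers.
#'
#' @param config any R object, typically a [run_config()].
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config), tf)
  unname(tools::md5sum(tf))
}
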