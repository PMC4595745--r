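# Sample- and gene-structure analysis: correlation-distance MDS, hierarchical
# clustering of DEG, marker-based purity QC, and the spliced-isoform
# fraction test.

#' Correlation pseudo-distance between samples
#'
#' `1 - Pearson correlation` of `log2(expression + 1)` between sample pairs,
#' computed over robustly expressed genes: those whose group-mean CPM exceeds
#' `cpm_min` in at least one (cell_type, condition) group.
#'
#' @param expr gene x sample expression matrix used for the correlation
#'   (typically TPM).
#' @param cpm matching CPM matrix used only for the gene filter; defaults to
#'   `expr` (then the filter is on `expr` itself).
#' @param design validated design table (needed for the group-mean filter).
#' @param cpm_min strict group-mean CPM threshold (default 20).
#' @param exclude_genes optional gene ids dropped before the calculation
#'   (e.g. the canonical markers Agrp, Npy, Pomc).
#' @param log if `TRUE` (default) correlate `log2(expr + 1)`.
#' @return Symmetric sample x sample distance matrix in \[0, 2\] with zero
#'   diagonal.
#' @export
correlation_distance <- function(expr, cpm = expr, design, cpm_min = 20,
                                 exclude_genes = NULL, log = TRUE) {
  if (ncol(expr) < 3) stop("need at least 3 samples")
  gm <- group_mean_cpm(cpm, design)
  keep <- rownames(expr)[apply(gm, 1, max)[rownames(expr)] > cpm_min]
  keep <- setdiff(keep, exclude_genes)
  if (length(keep) < 2) stop("fewer than 2 genes pass the CPM filter")
  x <- expr[keep, , drop = FALSE]
  if (log) x <- log2(x + 1)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant expression profile in sample(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(x)
  diag(d) <- 0
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes it, and
#' returns the top-`k` coordinates scaled by the square roots of the
#' (non-negative) eigenvalues. If fewer than `k` eigenvalues are positive,
#' the dimension is reduced with a warning.
#'
#' @param dist symmetric zero-diagonal distance matrix.
#' @param k target dimension (default 2).
#' @return A list of class `mds_embedding`: `points` (samples x k, centered
#'   at the origin), `eig` (all eigenvalues, descending), `k`.
#' @export
classical_mds <- function(dist, k = 2) {
  dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist), tol = 1e-8) || any(abs(diag(dist)) > 1e-12))
    stop("dist must be symmetric with zero diagonal")
  fit <- stats::cmdscale(dist, k = min(k, nrow(dist) - 1), eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  if (n_pos < k) {
    warning("only ", n_pos, " positive eigenvalue(s); returning ",
            max(n_pos, 0), " dimension(s)")
    k_use <- max(n_pos, 0)
  } else k_use <- k
  pts <- fit$points
  if (is.null(dim(pts)) || ncol(pts) < k_use)
    pts <- matrix(pts, nrow = nrow(dist))
  pts <- pts[, seq_len(k_use), drop = FALSE]
  if (k_use == 0) pts <- matrix(0, nrow(dist), 0)
  rownames(pts) <- rownames(dist)
  structure(list(points = pts, eig = eig, k = k_use), class = "mds_embedding")
}

#' Hierarchical clustering of DEG
#'
#' Standardizes each gene's expression across samples, computes the
#' gene-gene Pearson correlation matrix, and clusters on `1 - r` with
#' agglomerative linkage. Genes with zero variance across samples are
#' excluded with a warning.
#'
#' @param expr gene x sample expression matrix (typically TPM).
#' @param genes gene ids to cluster (e.g. a DEG list), length >= 2.
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return A list of class `cluster_result`: `tree` (hclust), `order` (gene
#'   ids in dendrogram order), `cor` (gene-gene correlations), `max_expr`
#'   (per-gene maximum across samples).
#' @export
cluster_deg <- function(expr, genes, linkage = "average") {
  genes <- intersect(genes, rownames(expr))
  if (length(genes) < 2) stop("need at least 2 genes present in expr")
  x <- expr[genes, , drop = FALSE]
  v <- apply(x, 1, stats::sd)
  if (any(v == 0)) {
    warning("excluding zero-variance gene(s): ",
            paste(genes[v == 0], collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
    if (nrow(x) < 2) stop("fewer than 2 genes with non-zero variance")
  }
  z <- t(scale(t(x)))
  r <- stats::cor(t(z))
  tree <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  structure(list(tree = tree, order = rownames(x)[tree$order], cor = r,
                 max_expr = apply(expr[rownames(x), , drop = FALSE], 1, max)),
            class = "cluster_result")
}

#' Marker-based purity report
#'
#' For each non-neuronal marker gene, the fold-depletion of its expression in
#' the sorted samples relative to its expression in the purified reference
#' cell type: `(reference + pseudocount) / (sample mean + pseudocount)`.
#' High folds across all marker sets indicate low contamination.
#'
#' @param expr gene x sample expression matrix (TPM scale).
#' @param marker_sets a `gene_set_collection` of marker genes per
#'   contaminant cell type.
#' @param reference_profiles matrix markers x reference cell types (or a
#'   single reference column) on the same expression scale.
#' @param design optional design; when given, the sample mean is taken per
#'   (cell_type, condition) group and the minimum fold over groups is
#'   reported per marker.
#' @param pseudocount added to both numerator and denominator (default 1).
#' @return A list of class `purity_report`: `per_marker` (data.frame with
#'   set, gene, reference, sample_mean, fold_depletion), `per_set`
#'   (data.frame with set, min_fold, median_fold).
#' @export
purity_report <- function(expr, marker_sets, reference_profiles,
                          design = NULL, pseudocount = 1) {
  stopifnot(inherits(marker_sets, "gene_set_collection"))
  reference_profiles <- as.matrix(reference_profiles)
  rows <- list()
  for (nm in names(marker_sets)) {
    for (g in marker_sets[[nm]]) {
      if (!(g %in% rownames(expr)) || !(g %in% rownames(reference_profiles))) {
        warning("marker ", g, " absent from expression or reference; skipped")
        next
      }
      ref <- max(reference_profiles[g, ])
      if (is.null(design)) {
        smean <- mean(expr[g, ])
      } else {
        gm <- group_mean_cpm(expr[g, , drop = FALSE], design)
        smean <- max(gm)   # worst group (least depleted)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        set = nm, gene = g, reference = ref, sample_mean = smean,
        fold_depletion = (ref + pseudocount) / (smean + pseudocount),
        stringsAsFactors = FALSE)
    }
  }
  per_marker <- do.call(rbind, rows)
  if (is.null(per_marker)) stop("no marker genes found")
  per_set <- do.call(rbind, lapply(split(per_marker, per_marker$set), function(d)
    data.frame(set = d$set[1], min_fold = min(d$fold_depletion),
               median_fold = stats::median(d$fold_depletion))))
  rownames(per_set) <- NULL
  structure(list(per_marker = per_marker, per_set = per_set),
            class = "purity_report")
}

#' @export
print.purity_report <- function(x, ...) {
  cat("purity_report:\n")
  print(x$per_set)
  invisible(x)
}

#' Spliced-isoform fraction test
#'
#' Per-sample fraction `spliced / (spliced + unspliced)`; unpaired one-tailed
#' two-sample t-test (alternative: `alt_group` mean greater than `ref_group`
#' mean), pooled variance by default. Samples with zero total are excluded
#' with a warning. Alternatively, supply rounded summary statistics via
#' `summary` to test printed group means/SEMs directly.
#'
#' @param spliced,unspliced named per-sample counts of the two isoforms.
#' @param design validated design table.
#' @param group_var design column defining the groups (default
#'   `"condition"`).
#' @param ref_group,alt_group the two group levels compared; the alternative
#'   hypothesis is `alt_group > ref_group`.
#' @param var_equal pooled variance (default `TRUE`); `FALSE` gives Welch.
#' @param summary optional list with elements `mean`, `sem`, `n`, each a
#'   length-2 vector named by group (`ref_group`, `alt_group`); when given,
#'   counts/design are ignored. `mean`/`sem` may be on any common scale
#'   (e.g. percent).
#' @return A list of class `splicing_fraction`: `fractions` (per sample, NA
#'   for zero totals), `group_stats` (mean, sem, n per group), `t`, `df`,
#'   `p` (one-tailed).
#' @export
splicing_fraction_test <- function(spliced = NULL, unspliced = NULL,
                                   design = NULL, group_var = "condition",
                                   ref_group = "fed", alt_group = "FD",
                                   var_equal = TRUE, summary = NULL) {
  if (!is.null(summary)) {
    m <- summary$mean; se <- summary$sem; nn <- summary$n
    stopifnot(all(c(ref_group, alt_group) %in% names(m)))
    s <- se * sqrt(nn)
    n1 <- nn[[ref_group]]; n2 <- nn[[alt_group]]
    m1 <- m[[ref_group]]; m2 <- m[[alt_group]]
    s1 <- s[[ref_group]]; s2 <- s[[alt_group]]
    if (var_equal) {
      sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
      tt <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    } else {
      v1 <- s1^2 / n1; v2 <- s2^2 / n2
      tt <- (m2 - m1) / sqrt(v1 + v2)
      df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    }
    gs <- data.frame(group = c(ref_group, alt_group), mean = c(m1, m2),
                     sem = c(se[[ref_group]], se[[alt_group]]), n = c(n1, n2))
    return(structure(list(fractions = NULL, group_stats = gs, t = tt, df = df,
                          p = stats::pt(tt, df, lower.tail = FALSE)),
                     class = "splicing_fraction"))
  }

  stopifnot(!is.null(spliced), !is.null(unspliced), !is.null(design))
  design <- sample_design(design)
  samp <- design$sample_id
  if (is.null(names(spliced))) names(spliced) <- samp
  if (is.null(names(unspliced))) names(unspliced) <- samp
  tot <- spliced[samp] + unspliced[samp]
  frac <- ifelse(tot > 0, spliced[samp] / tot, NA_real_)
  if (any(tot == 0))
    warning("excluding sample(s) with zero isoform total: ",
            paste(samp[tot == 0], collapse = ", "))
  grp <- as.character(design[[group_var]])
  f1 <- frac[grp == ref_group & !is.na(frac)]
  f2 <- frac[grp == alt_group & !is.na(frac)]
  if (length(f1) < 2 || length(f2) < 2)
    stop("each compared group needs at least 2 usable samples")
  n1 <- length(f1); n2 <- length(f2)
  m1 <- mean(f1); m2 <- mean(f2)
  v1 <- stats::var(f1); v2 <- stats::var(f2)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    if (!is.finite(df)) df <- n1 + n2 - 2
  }
  # degenerate (zero-variance) input: identical group means give t = 0,
  # otherwise the separation is infinitely strong
  tt <- if (se == 0) {
    if (m2 == m1) 0 else sign(m2 - m1) * Inf
  } else (m2 - m1) / se
  gs <- data.frame(group = c(ref_group, alt_group),
                   mean = c(m1, m2),
                   sem = c(sqrt(v1 / n1), sqrt(v2 / n2)),
                   n = c(n1, n2))
  structure(list(fractions = frac, group_stats = gs,
                 t = tt, df = df,
                 p = stats::pt(tt, df, lower.tail = FALSE)),
            class = "splicing_fraction")
}

#' @export
print.splicing_fraction <- function(x, ...) {
  cat("splicing_fraction: t =", format(x$t, digits = 4), "df =",
      format(x$df, digits = 4), "one-tailed p =", format(x$p, digits = 3), "\n")
  print(x$group_stats)
  invisible(x)
}
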