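# Hypergeometric gene-set over-representation among DEG, and DEG-overlap
# (Venn) summaries.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` members of a `K`-gene set when sampling `n` genes without
#' replacement from a universe of `N`. Computed in log space, so it does not
#' overflow for universes of tens of thousands of genes.
#'
#' @param N universe size.
#' @param K set members in the universe.
#' @param n number of drawn genes (e.g. DEG count).
#' @param k observed overlap.
#' @return The upper-tail probability; exactly 1 when `k = 0`.
#' @examples
#' hypergeom_upper(16513, 113, 1346, 20)  # 7.5e-4 to two significant figures
#' @export
hypergeom_upper <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  if (any(c(N, K, n, k) < 0) || any(c(N, K, n, k) != round(c(N, K, n, k))))
    stop("N, K, n, k must be non-negative integers")
  if (K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need k <= min(K, n) <= N")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation among DEG
#'
#' One-sided (upper-tail) hypergeometric test of each gene set against each
#' contrast's DEG list. Sets are intersected with the universe before
#' counting; the universe defaults to the expression-filtered genes that
#' entered the fit. A set disjoint from the universe yields `K = 0` and is
#' flagged degenerate (p = 1).
#'
#' @param deg a `de_result` after [call_deg()], or a character vector of DEG
#'   ids (then `universe` is required and a single unnamed contrast is
#'   assumed).
#' @param sets a `gene_set_collection`.
#' @param universe character vector of gene ids; defaults to
#'   `deg$filtered_genes` for a `de_result`.
#' @param adjust if `TRUE` (default), add BH-adjusted q-values across sets
#'   within each contrast.
#' @return data.frame with columns `contrast`, `set`, `N`, `K`, `n`, `k`,
#'   `p`, `frac_up` (fraction of overlapping DEG with positive log2fc, NA
#'   for plain gene-list input), `degenerate`, and `q` when `adjust`.
#' @export
test_set_overrepresentation <- function(deg, sets, universe = NULL,
                                        adjust = TRUE) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (inherits(deg, "de_result")) {
    if (is.null(deg$table$deg_flag)) stop("run call_deg() first")
    if (is.null(universe)) universe <- deg$filtered_genes
    if (is.null(universe)) stop("universe is required")
    tab <- deg$table
    lists <- split(tab[tab$deg_flag, c("gene", "log2fc")], tab$contrast[tab$deg_flag])
    contrasts <- unique(tab$contrast)
    lists <- lapply(stats::setNames(contrasts, contrasts), function(ct)
      tab[tab$deg_flag & tab$contrast == ct, c("gene", "log2fc")])
  } else {
    if (is.null(universe)) stop("universe is required for gene-list input")
    lists <- list(all = data.frame(gene = as.character(deg), log2fc = NA_real_))
  }
  universe <- unique(as.character(universe))
  N <- length(universe)
  out <- list()
  for (ct in names(lists)) {
    dg <- lists[[ct]]
    dg <- dg[dg$gene %in% universe, , drop = FALSE]
    n <- nrow(dg)
    for (nm in names(sets)) {
      set_u <- intersect(sets[[nm]], universe)
      K <- length(set_u)
      overlap <- dg$gene %in% set_u
      k <- sum(overlap)
      degenerate <- K == 0
      p <- if (degenerate) 1 else hypergeom_upper(N, K, n, k)
      frac_up <- if (k > 0 && !all(is.na(dg$log2fc)))
        mean(dg$log2fc[overlap] > 0) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        contrast = ct, set = nm, N = N, K = K, n = n, k = k, p = p,
        frac_up = frac_up, degenerate = degenerate,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (adjust) res$q <- stats::ave(res$p, res$contrast, FUN = adjust_bh)
  rownames(res) <- NULL
  res
}

#' DEG-overlap (Venn) region counts
#'
#' Exclusive and shared region counts for two or three gene lists.
#'
#' @param deg_lists named list of 2 or 3 character vectors.
#' @return Named integer vector: one entry per non-empty membership pattern,
#'   named by the list names joined with `&` (e.g. `"A"`, `"A&B"`).
#' @examples
#' deg_overlap(list(A = c("a", "b"), B = c("b", "c")))
#' @export
deg_overlap <- function(deg_lists) {
  if (!is.list(deg_lists) || length(deg_lists) < 2 || length(deg_lists) > 3)
    stop("deg_overlap takes a named list of 2 or 3 gene vectors")
  if (is.null(names(deg_lists))) names(deg_lists) <- LETTERS[seq_along(deg_lists)]
  deg_lists <- lapply(deg_lists, unique)
  all_genes <- unique(unlist(deg_lists))
  member <- vapply(deg_lists, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(deg_lists)))
  pattern <- apply(member, 1, function(r)
    paste(names(deg_lists)[r], collapse = "&"))
  # all patterns, including empty regions
  nm <- names(deg_lists)
  combos <- unlist(lapply(seq_along(nm), function(sz)
    utils::combn(nm, sz, paste, collapse = "&", simplify = FALSE)))
  counts <- stats::setNames(integer(length(combos)), combos)
  tab <- table(pattern)
  counts[names(tab)] <- as.integer(tab)
  counts
}
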