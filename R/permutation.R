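# Label-permutation evaluation of the DEG pipeline and its empirical FDR:
# the multiset of (cell_type, condition) labels is rearranged across samples,
# the full pipeline is re-run, and the mean permuted DEG count is expressed
# as a percentage of the observed DEG count.

#' Permute group labels across samples
#'
#' Uniformly random rearrangement of the multiset of (cell_type, condition)
#' label pairs across samples; group sizes are preserved exactly. The
#' sample-specific `n_cells` stays with its tube. The identity labeling is
#' not excluded.
#'
#' @param design validated design table.
#' @param seed optional seed for a deterministic draw.
#' @return A design table with permuted `cell_type`/`condition`.
#' @export
permute_labels <- function(design, seed = NULL) {
  design <- sample_design(design)
  if (nlevels(design_groups(design)) < 2) stop("need at least 2 groups")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(design))
  design$cell_type <- design$cell_type[idx]
  design$condition <- design$condition[idx]
  design
}

#' Empirical false discovery rate from permuted DEG counts
#'
#' `100 * mean(permuted) / observed`, in percent.
#'
#' @param observed observed DEG count (must be > 0).
#' @param permuted vector of DEG counts under label permutations.
#' @return Percent empirical FDR.
#' @examples
#' empirical_fdr(826, 1.7)  # 0.2% after rounding to one decimal
#' @export
empirical_fdr <- function(observed, permuted) {
  if (any(permuted < 0) || observed < 0) stop("counts must be non-negative")
  if (observed == 0)
    stop("empirical FDR is undefined when the observed DEG count is 0")
  100 * mean(permuted) / observed
}

#' Label-permutation study of the DEG pipeline
#'
#' Runs [run_de()] on the observed labels, then for each of `n_perm`
#' permutations rearranges the (cell_type, condition) labels and re-runs the
#' full pipeline (expression filter, TMM, precision weights, moderated fit,
#' BH adjustment, DEG criteria), recording the per-contrast DEG counts. The
#' empirical FDR per contrast is `100 * mean(permuted counts) / observed
#' count`, reported as `NA` (flagged) for contrasts with zero observed DEG.
#'
#' @param counts a [count_matrix()].
#' @param design validated design table.
#' @param n_perm number of permutations (default 1000).
#' @param seed master seed; permutation `i` uses a substream derived from it.
#' @param refit if `TRUE` (default) the TMM factors and variance trend are
#'   recomputed inside every permutation; `FALSE` reuses the observed
#'   normalization (labels only enter the design).
#' @param ... thresholds passed on to [run_de()].
#' @return A list of class `perm_result`: `n_perm`, `observed` (named
#'   per-contrast counts), `perm_counts` (n_perm x contrasts matrix), `mean`,
#'   `sd`, `fdr_percent` (NA where observed is 0, with `fdr_undefined`
#'   flags), `seed`.
#' @export
run_permutation_study <- function(counts, design, n_perm = 1000, seed = 1,
                                  refit = TRUE, ...) {
  design <- sample_design(design, counts)
  de_obs <- run_de(counts, design, ...)
  contr <- colnames(de_obs$contrasts)
  observed <- vapply(contr, function(ct) {
    sum(de_obs$table$deg_flag[de_obs$table$contrast == ct])
  }, numeric(1))

  set.seed(as.integer(seed))
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  cpm_f <- compute_cpm(counts)[de_obs$filtered_genes, , drop = FALSE]

  perm_counts <- matrix(NA_real_, n_perm, length(contr),
                        dimnames = list(NULL, contr))
  for (i in seq_len(n_perm)) {
    pdes <- permute_labels(design, seed = perm_seeds[i])
    if (refit) {
      dp <- run_de(counts, pdes, ...)
    } else {
      # reuse the observed normalization and precision weights; only the
      # design (hence the fitted group means) changes
      v <- de_obs$voom
      v$design <- design_matrix(pdes)
      dp <- fit_moderated(v, de_obs$contrasts)
      dp <- call_deg(dp, group_cpm = group_mean_cpm(cpm_f, pdes))
    }
    perm_counts[i, ] <- vapply(contr, function(ct) {
      sum(dp$table$deg_flag[dp$table$contrast == ct])
    }, numeric(1))
  }

  mean_p <- colMeans(perm_counts)
  sd_p <- apply(perm_counts, 2, stats::sd)
  fdr <- ifelse(observed > 0, 100 * mean_p / observed, NA_real_)
  structure(list(n_perm = n_perm, observed = observed,
                 perm_counts = perm_counts, mean = mean_p, sd = sd_p,
                 fdr_percent = fdr, fdr_undefined = observed == 0,
                 seed = as.integer(seed)),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("perm_result (", x$n_perm, " permutations):\n", sep = "")
  out <- data.frame(observed = x$observed,
                    perm_mean = round(x$mean, 3),
                    perm_sd = round(x$sd, 3),
                    empirical_fdr_pct = round(x$fdr_percent, 2))
  print(out)
  invisible(x)
}
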