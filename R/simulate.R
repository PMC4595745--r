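# Synthetic pooled sorted-neuron RNA-seq generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# 2 cell-type x 2 condition design with 5-6 replicates per group,
# negative-binomial gene counts with group effects on the log2 scale, an
# asymmetric programmed DEG fraction, an ERCC-style 2-fold dilution ladder
# captured by a Poisson model whose detection probability depends on
# copies x kb, a spliced/unspliced isoform pair split binomially from a
# parent gene, and trace non-neuronal marker contamination. Ground truth is
# recorded for recovery tests.

default_markers <- function() {
  list(
    astrocyte        = c("Gfap", "Aqp4", "Slc1a3", "Aldh1l1"),
    oligodendrocyte  = c("Mbp", "Mobp", "Plp1", "Mog"),
    microglia        = c("Cx3cr1", "C1qa", "C1qb", "Tmem119"),
    endothelial      = c("Cldn5", "Flt1", "Pecam1", "Slco1a4")
  )
}

#' Simulation parameters
#'
#' Defaults describe the study conditions the package targets: four groups
#' (AGRP/POMC x fed/FD) with n = 5, 6, 5, 5 replicates; log-normal baseline
#' abundances and per-gene NB dispersions; programmed DEG fractions asymmetric
#' between the cell types (roughly 5% of genes respond to deprivation in AGRP
#' neurons, 0.3% in POMC neurons, 4% differ between cell types at baseline);
#' a 92-spike 2-fold dilution ladder with Poisson capture at
#' `capture_rate = ln(2)/22` expected reads per (copy x kb), which places the
#' true 50% detection point at 22 copies x kb; an Xbp1-like spliced/unspliced
#' pair with spliced fractions 7.4% (fed) and 15.6% (FD); and 0.1% trace
#' contamination by 16 non-neuronal marker genes. Library size defaults to
#' ~1e6 reads: a desk-scale depth, exposed as a parameter.
#'
#' @param n_genes number of (non-spike) genes.
#' @param groups data.frame with columns `cell_type`, `condition`, `n`.
#' @param lib_size_mean,lib_size_cv expected per-sample gene reads and
#'   its coefficient of variation (log-normal).
#' @param abund_meanlog,abund_sdlog log-normal law of baseline relative
#'   abundance.
#' @param length_meanlog,length_sdlog log-normal law of exon length (kb).
#' @param disp_meanlog,disp_sdlog log-normal law of per-gene NB dispersion.
#' @param deg_fraction named per-contrast DEG proportions; names are
#'   `"<group1>-<group2>"` contrast labels.
#' @param lfc_lo,lfc_hi true |log2 fold-change| of programmed DEG is drawn
#'   from Uniform(lfc_lo, lfc_hi) with random sign.
#' @param n_spike_levels,spikes_per_level,spike_base_copies 2-fold ladder:
#'   `copies = spike_base_copies * 2^(0:(n_spike_levels-1))`, each level
#'   carrying `spikes_per_level` spikes.
#' @param spike_length_range range (kb) of spike lengths, drawn uniformly.
#' @param capture_rate expected spike reads per (copy x kb) at unit depth
#'   factor; the true 50% detection point is `ln(2)/capture_rate`.
#' @param n_cells_mean,n_cells_sd,n_cells_range sorted cells per tube
#'   (normal, rounded, clamped to the range).
#' @param splicing_gene,spliced_fraction name of the spliced/unspliced parent
#'   gene and its per-condition spliced fraction.
#' @param contamination_fraction trace abundance of each non-neuronal marker,
#'   as a fraction of the reference cell-type abundance.
#' @param marker_reference_tpm expression of each marker in its reference
#'   (contaminant) cell type, TPM scale.
#' @param seed default master seed used by [generate_dataset()].
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 5000,
                       groups = data.frame(
                         cell_type = c("AGRP", "AGRP", "POMC", "POMC"),
                         condition = c("fed", "FD", "fed", "FD"),
                         n = c(5L, 6L, 5L, 5L)),
                       lib_size_mean = 1e6, lib_size_cv = 0.3,
                       abund_meanlog = 1, abund_sdlog = 2,
                       length_meanlog = log(1.5), length_sdlog = 0.6,
                       disp_meanlog = log(0.05), disp_sdlog = 0.5,
                       deg_fraction = c("AGRP.FD-AGRP.fed" = 0.05,
                                        "POMC.FD-POMC.fed" = 0.003,
                                        "AGRP.fed-POMC.fed" = 0.042),
                       lfc_lo = 1, lfc_hi = 3,
                       n_spike_levels = 23, spikes_per_level = 4,
                       spike_base_copies = 1 / 32,
                       spike_length_range = c(0.25, 2),
                       capture_rate = log(2) / 22,
                       n_cells_mean = 102, n_cells_sd = 40.5,
                       n_cells_range = c(44, 214),
                       splicing_gene = "Xbp1",
                       spliced_fraction = c(fed = 0.074, FD = 0.156),
                       contamination_fraction = 0.001,
                       marker_reference_tpm = 1000,
                       seed = 1L) {
  stopifnot(n_genes > 20, all(groups$n >= 2),
            all(deg_fraction >= 0 & deg_fraction <= 1),
            capture_rate > 0, spike_base_copies >= 0,
            lfc_lo > 0, lfc_hi >= lfc_lo,
            all(spliced_fraction >= 0 & spliced_fraction <= 1))
  structure(as.list(environment()), class = "sim_params")
}

sim_group_labels <- function(groups) {
  paste(groups$cell_type, groups$condition, sep = ".")
}

# Effects matrix (genes x groups, log2) from per-contrast DEG assignments.
# A contrast "G1-G2" moving a gene applies its lfc to group G1; when G1 and
# G2 differ in cell type, the lfc is applied to every group of G1's cell
# type, so the cell-type difference holds in both conditions.
apply_contrast_effect <- function(E, contrast, idx, lfc, groups) {
  gl <- sim_group_labels(groups)
  parts <- strsplit(contrast, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% gl))
    stop("deg_fraction name is not a '<group1>-<group2>' contrast over the ",
         "simulated groups: ", contrast)
  g1 <- which(gl == parts[1]); g2 <- which(gl == parts[2])
  if (groups$cell_type[g1] != groups$cell_type[g2]) {
    cols <- which(groups$cell_type == groups$cell_type[g1])
  } else {
    cols <- g1
  }
  E[idx, cols] <- E[idx, cols] + lfc
  E
}

#' Generate a synthetic dataset with recorded ground truth
#'
#' Gene count `g` in sample `j` is drawn
#' `NB(mean = L_j * p_gj, dispersion = phi_g)` where `p_gj` is the gene's
#' relative abundance after applying its group effects on the log2 scale and
#' renormalizing within the sample; spike `i` is drawn
#' `Poisson(capture_rate * copies_i * length_i_kb * d_j)` with depth factor
#' `d_j = L_j / lib_size_mean`; the spliced/unspliced pair is a binomial
#' split of a high-abundance parent gene with the condition's spliced
#' fraction. Identical seeds give bit-identical output.
#'
#' @param params a [sim_params()].
#' @param seed master seed (default `params$seed`); per-stage substreams are
#'   derived from it.
#' @return A list with elements `counts` ([count_matrix()]), `design`
#'   (validated design table), `ercc` (`spikein_reference`), `sets`
#'   (`gene_set_collection` of marker sets plus a random control set), and
#'   `truth` (class `sim_truth`: per-gene true log2 fold-changes and DEG
#'   flags per contrast, the expected count matrix and per-gene dispersions,
#'   the true detection midpoint in copies x kb, the true copies per cell at
#'   1 TPM, the true spliced fractions, and the seed).
#' @examples
#' sim <- generate_dataset(sim_params(n_genes = 300), seed = 7)
#' sim$counts
#' head(sim$truth$genes)
#' @export
generate_dataset <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  seed <- as.integer(seed)
  set.seed(seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 6)

  groups <- params$groups
  gl <- sim_group_labels(groups)
  n_genes <- params$n_genes

  ## -- stage 1: gene-level parameters ------------------------------------
  set.seed(stage_seed[1])
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  markers <- default_markers()
  marker_ids <- unlist(markers, use.names = FALSE)
  if (length(marker_ids) + 2 > n_genes) stop("n_genes too small for marker panel")
  gene_ids[seq_along(marker_ids)] <- marker_ids
  splice_parent <- params$splicing_gene
  gene_ids[length(marker_ids) + 1L] <- splice_parent

  len_kb <- stats::rlnorm(n_genes, params$length_meanlog, params$length_sdlog)
  q <- stats::rlnorm(n_genes, params$abund_meanlog, params$abund_sdlog)
  phi <- stats::rlnorm(n_genes, params$disp_meanlog, params$disp_sdlog)
  names(len_kb) <- names(q) <- names(phi) <- gene_ids

  # trace contamination: markers sit at a small fraction of their reference
  # abundance in the contaminant cell type
  q_total <- sum(q)
  q[marker_ids] <- params$contamination_fraction *
    params$marker_reference_tpm / 1e6 * q_total
  # splice parent: robustly expressed so per-sample fractions are stable
  q[splice_parent] <- 3e-4 * q_total

  ## -- stage 2: programmed DEG -------------------------------------------
  set.seed(stage_seed[2])
  E <- matrix(0, n_genes, nrow(groups), dimnames = list(gene_ids, gl))
  eligible <- setdiff(gene_ids, c(marker_ids, splice_parent))
  contrasts <- names(params$deg_fraction)
  assigned <- matrix(FALSE, n_genes, length(contrasts),
                     dimnames = list(gene_ids, contrasts))
  for (ct in contrasts) {
    n_deg <- round(params$deg_fraction[[ct]] * n_genes)
    if (n_deg > length(eligible))
      stop("requested DEG exceed available genes for contrast ", ct)
    if (n_deg == 0) next
    idx <- sample(eligible, n_deg)
    lfc <- sample(c(-1, 1), n_deg, replace = TRUE) *
      stats::runif(n_deg, params$lfc_lo, params$lfc_hi)
    E <- apply_contrast_effect(E, ct, idx, lfc, groups)
    assigned[idx, ct] <- TRUE
  }

  ## -- stage 3: samples ---------------------------------------------------
  set.seed(stage_seed[3])
  n_samp <- sum(groups$n)
  grp_of_sample <- rep(seq_len(nrow(groups)), groups$n)
  sample_ids <- unlist(lapply(seq_len(nrow(groups)), function(g)
    paste0(gl[g], "_", seq_len(groups$n[g]))))
  s2 <- log(1 + params$lib_size_cv^2)
  L <- stats::rlnorm(n_samp, log(params$lib_size_mean) - s2 / 2, sqrt(s2))
  n_cells <- round(stats::rnorm(n_samp, params$n_cells_mean, params$n_cells_sd))
  n_cells <- pmin(pmax(n_cells, params$n_cells_range[1]), params$n_cells_range[2])

  design <- data.frame(sample_id = sample_ids,
                       cell_type = groups$cell_type[grp_of_sample],
                       condition = groups$condition[grp_of_sample],
                       n_cells = n_cells)

  ## -- stage 4: gene counts ----------------------------------------------
  set.seed(stage_seed[4])
  mu <- matrix(0, n_genes, n_samp, dimnames = list(gene_ids, sample_ids))
  for (j in seq_len(n_samp)) {
    qj <- q * 2^E[, grp_of_sample[j]]
    mu[, j] <- L[j] * qj / sum(qj)
  }
  cnt <- matrix(stats::rnbinom(n_genes * n_samp, mu = mu, size = rep(1 / phi, n_samp)),
                n_genes, n_samp, dimnames = dimnames(mu))

  ## -- stage 5: spike-ins -------------------------------------------------
  set.seed(stage_seed[5])
  n_spikes <- params$n_spike_levels * params$spikes_per_level
  spike_ids <- sprintf("ERCC-%04d", seq_len(n_spikes))
  copies <- params$spike_base_copies *
    2^rep(0:(params$n_spike_levels - 1), each = params$spikes_per_level)
  spike_len <- stats::runif(n_spikes, params$spike_length_range[1],
                            params$spike_length_range[2])
  d <- L / params$lib_size_mean
  spike_mu <- outer(params$capture_rate * copies * spike_len, d)
  dimnames(spike_mu) <- list(spike_ids, sample_ids)
  spike_cnt <- matrix(stats::rpois(length(spike_mu), spike_mu),
                      n_spikes, n_samp, dimnames = dimnames(spike_mu))
  ercc <- spikein_reference(data.frame(spike_id = spike_ids,
                                       length_kb = spike_len,
                                       copies_per_tube = copies))

  ## -- stage 6: spliced/unspliced split ----------------------------------
  set.seed(stage_seed[6])
  frac <- params$spliced_fraction[as.character(design$condition)]
  parent_cnt <- cnt[splice_parent, ]
  spliced <- stats::rbinom(n_samp, parent_cnt, frac)
  child <- rbind(spliced, parent_cnt - spliced)
  rownames(child) <- paste0(splice_parent, c("_spliced", "_unspliced"))

  keep <- setdiff(gene_ids, splice_parent)
  all_cnt <- rbind(cnt[keep, , drop = FALSE], child, spike_cnt)
  all_len <- c(len_kb[keep], rep(len_kb[splice_parent], 2), spike_len)
  is_spike <- c(rep(FALSE, length(keep) + 2), rep(TRUE, n_spikes))
  names(all_len) <- rownames(all_cnt)
  counts <- count_matrix(all_cnt, all_len, is_spike)

  ## -- ground truth -------------------------------------------------------
  true_lfc <- vapply(contrasts, function(ct) {
    parts <- strsplit(ct, "-", fixed = TRUE)[[1]]
    E[, parts[1]] - E[, parts[2]]
  }, numeric(n_genes))
  truth_genes <- data.frame(gene = gene_ids, check.names = FALSE)
  for (ct in contrasts) {
    truth_genes[[paste0("lfc.", ct)]] <- true_lfc[, ct]
    truth_genes[[paste0("deg.", ct)]] <- assigned[, ct]
  }

  # expected-count TPM calibration truth: copies per TPM is constant across
  # spikes within a sample; divide by sorted-cell count for copies per cell
  mu_child <- rbind(frac * mu[splice_parent, ], (1 - frac) * mu[splice_parent, ])
  dimnames(mu_child) <- list(rownames(child), sample_ids)
  mu_all <- rbind(mu[keep, , drop = FALSE], mu_child, spike_mu)
  # spike i has expected FPKM = capture_rate * copies_i * d_j * 1e6 / lib_j,
  # so copies/TPM = sum(FPKM) * lib_j / (capture_rate * d_j * 1e12)
  #              = sum(mu/length) / (capture_rate * d_j * 1e6),
  # identical for every spike within a sample
  copies_per_tpm <- colSums(mu_all / all_len) / (params$capture_rate * d * 1e6)
  copies_per_cell <- copies_per_tpm / n_cells

  truth <- structure(list(
    genes = truth_genes,
    expected_counts = mu_all,
    dispersion = phi,
    x50 = log(2) / params$capture_rate,
    copies_per_cell_by_sample = stats::setNames(copies_per_cell, sample_ids),
    copies_per_cell = mean(copies_per_cell),
    spliced_fraction = params$spliced_fraction,
    seed = seed), class = "sim_truth")

  sets <- markers
  set.seed(stage_seed[2] + 1L)
  sets$random_control <- sample(eligible, min(200, length(eligible)))
  reference_profiles <- matrix(params$marker_reference_tpm,
                               nrow = length(marker_ids), ncol = 1,
                               dimnames = list(marker_ids, "reference"))

  list(counts = counts, design = sample_design(design, counts), ercc = ercc,
       sets = gene_set_collection(sets), truth = truth,
       reference_profiles = reference_profiles)
}

#' Generate a null dataset (no group effects)
#'
#' Identical machinery to [generate_dataset()] with every programmed effect
#' forced to zero: DEG fractions are zeroed and the spliced fraction is made
#' equal across conditions. Library sizes still vary, so raw counts differ
#' across samples under the null.
#'
#' @inheritParams generate_dataset
#' @return Same structure as [generate_dataset()]; `truth$genes` reports zero
#'   true DEG in all contrasts.
#' @export
generate_null_dataset <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  params$deg_fraction[] <- 0
  params$spliced_fraction[] <- params$spliced_fraction[[1]]
  generate_dataset(params, seed)
}

#' Write a generated dataset to a directory
#'
#' Emits counts.tsv, design.tsv, ercc.tsv, sets.gmt and truth.tsv, with the
#' seed and configuration hash stamped in each TSV header.
#'
#' @param sim output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @param params the [sim_params()] used (for the config hash).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, params = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- sim$truth$seed
  write_counts(sim$counts, file.path(dir, "counts.tsv"), config = params, seed = seed)
  write_design(sim$design, file.path(dir, "design.tsv"), config = params, seed = seed)
  write_ercc(sim$ercc, file.path(dir, "ercc.tsv"), config = params, seed = seed)
  write_gmt(sim$sets, file.path(dir, "sets.gmt"))
  write_tsv_commented(sim$truth$genes, file.path(dir, "truth.tsv"),
                      config = params, seed = seed)
  invisible(dir)
}
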