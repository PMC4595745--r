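# ERCC spike-in calibration: assay sensitivity (the 50% detection point on
# the copies x kb axis) and absolute scale (transcript copies per cell at
# 1 TPM).

#' Fit the spike-in detection curve
#'
#' Detection is presence/absence: a spike counts as detected in a sample when
#' its read count reaches `detect_threshold` (default 1). Outcomes are pooled
#' across samples and fit by a maximum-likelihood binomial regression of
#' detection on log10(copies x kb). The 50% detection point `x50` is the
#' abundance at which the fitted curve crosses 0.5, with a profile-likelihood
#' 95% confidence interval obtained by profiling the slope at fixed candidate
#' midpoints.
#'
#' The default link is complementary log-log: when reads are captured as a
#' Poisson process with rate proportional to copies x kb, the probability of
#' seeing at least one read is exactly `1 - exp(-rate * x)`, which is a
#' cloglog model in log(x) with unit slope, so the cloglog fit recovers the
#' true midpoint without bias. A symmetric logistic (`link = "logit"`) is
#' also available; for that link `x50 = 10^(-intercept/slope)`.
#'
#' When the data are perfectly separated (every level fully detected, fully
#' undetected, or split without overlap) no finite fit exists; the result is
#' flagged `censored` with `x50` bounded by the separating interval and no
#' error is thrown.
#'
#' @param counts a [count_matrix()] whose spike rows will be used, or a plain
#'   spikes x samples count matrix.
#' @param ref a `spikein_reference` ([read_ercc()]); rows are matched to the
#'   spike ids of `counts`.
#' @param detect_threshold minimum read count to call a spike detected.
#' @param link binomial link: `"cloglog"` (default) or `"logit"`.
#' @param conf_level confidence level for the x50 interval.
#' @return A list of class `detection_curve`: `intercept`, `slope`, `x50`
#'   (copies x kb), `ci` (length-2), `censored` (logical), `n_levels`, and
#'   the pooled per-observation data in `data`.
#' @examples
#' sim <- generate_dataset(sim_params(n_genes = 300), seed = 1)
#' dc <- fit_detection_curve(sim$counts, sim$ercc)
#' dc$x50
#' @export
fit_detection_curve <- function(counts, ref, detect_threshold = 1,
                                link = c("cloglog", "logit"),
                                conf_level = 0.95) {
  link <- match.arg(link)
  m <- if (inherits(counts, "count_matrix")) {
    counts$counts[counts$is_spike, , drop = FALSE]
  } else as.matrix(counts)
  ref <- spikein_reference(as.data.frame(ref))
  ids <- intersect(rownames(m), ref$spike_id)
  if (!length(ids)) stop("no spike ids shared between counts and reference")
  m <- m[ids, , drop = FALSE]
  ref <- ref[match(ids, ref$spike_id), ]
  x_ckb <- ref$copies_per_tube * ref$length_kb
  pos <- x_ckb > 0
  m <- m[pos, , drop = FALSE]; x_ckb <- x_ckb[pos]

  lx <- rep(log10(x_ckb), ncol(m))
  det <- as.vector(m >= detect_threshold)
  n_levels <- length(unique(signif(x_ckb, 10)))
  if (n_levels < 6)
    warning("fewer than 6 distinct copies x kb levels; fit may be unstable")

  res <- list(n_levels = n_levels, link = link,
              data = data.frame(log10_ckb = lx, detected = det),
              conf_level = conf_level)
  # linear-predictor value at which the fitted probability is 0.5
  eta50 <- if (link == "logit") 0 else log(log(2))
  fam <- stats::binomial(link = link)

  # perfect separation: no overlap between detected and undetected abundances
  if (all(det) || !any(det) ||
      max(lx[!det]) < min(lx[det])) {
    lo <- if (any(!det)) 10^max(lx[!det]) else 0
    hi <- if (any(det)) 10^min(lx[det]) else Inf
    res <- c(res, list(intercept = NA_real_, slope = NA_real_,
                       x50 = sqrt(max(lo, .Machine$double.xmin) *
                                    min(hi, .Machine$double.xmax)),
                       ci = c(lo, hi), censored = TRUE))
    class(res) <- "detection_curve"
    return(res)
  }

  fit <- suppressWarnings(stats::glm(det ~ lx, family = fam))
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  lx50 <- (eta50 - a) / b
  x50 <- 10^lx50

  # profile likelihood over the midpoint m: eta = eta50 + b (x - m)
  off <- rep(eta50, length(lx))
  prof_dev <- function(mid) {
    f <- suppressWarnings(
      stats::glm(det ~ 0 + I(lx - mid) + offset(off), family = fam))
    f$deviance
  }
  dev0 <- prof_dev(lx50)
  cut <- dev0 + stats::qchisq(conf_level, 1)
  grid <- seq(lx50 - 3, lx50 + 3, length.out = 241)
  devs <- vapply(grid, prof_dev, numeric(1))
  inside <- grid[devs <= cut]
  ci <- if (length(inside)) 10^range(inside) else c(NA_real_, NA_real_)

  res <- c(res, list(intercept = a, slope = b, x50 = x50, ci = ci,
                     censored = FALSE))
  class(res) <- "detection_curve"
  res
}

#' @export
print.detection_curve <- function(x, ...) {
  if (x$censored) {
    cat("detection_curve: censored (perfect separation); x50 bounded in [",
        format(x$ci[1], digits = 3), ", ", format(x$ci[2], digits = 3),
        "] copies x kb\n", sep = "")
  } else {
    cat("detection_curve: x50 =", format(x$x50, digits = 3),
        "copies x kb (", format(100 * x$conf_level), "% CI",
        format(x$ci[1], digits = 3), "-", format(x$ci[2], digits = 3), ")\n")
  }
  invisible(x)
}

#' Transcript copies per cell at 1 TPM
#'
#' For each sample, an ordinary least-squares fit of log10(copies per tube)
#' on log10(TPM) over the detected spikes (TPM > 0); the copies corresponding
#' to 1 TPM is `10^intercept`, divided by the number of sorted cells in the
#' tube to give copies per cell. Samples with fewer than `min_spikes`
#' detected spikes, or whose detected spikes span less than `min_decades`
#' decades of copy number, are excluded with a warning.
#'
#' By default (`robust_only = TRUE`) the regression uses only spikes detected
#' in every sample of the matrix. Spikes near the detection limit enter the
#' data conditionally on being observed, which inflates their TPM and drags
#' the fitted intercept down; restricting to consistently detected spikes
#' removes that conditioning bias while keeping several decades of ladder.
#'
#' @param tpm an `expression_matrix` with unit `"TPM"` containing the spike
#'   rows (e.g. from [compute_tpm()] on the full matrix), or a plain matrix
#'   of spike TPM.
#' @param ref a `spikein_reference`.
#' @param design validated design table supplying `n_cells` per sample.
#' @param min_spikes,min_decades per-sample inclusion rules (defaults 6, 2).
#' @param robust_only restrict to spikes detected (TPM > 0) in all samples
#'   (default `TRUE`).
#' @return A list of class `copies_per_tpm`: `per_sample` (data.frame with
#'   intercept, slope, copies at 1 TPM, n_cells, copies per cell),
#'   `copies_per_cell_mean`, `copies_per_cell_sd`, `n_samples_used`.
#' @export
fit_copies_per_tpm <- function(tpm, ref, design, min_spikes = 6,
                               min_decades = 2, robust_only = TRUE) {
  ref <- spikein_reference(as.data.frame(ref))
  ids <- intersect(rownames(tpm), ref$spike_id)
  if (!length(ids)) stop("no spike ids shared between TPM matrix and reference")
  tpm <- tpm[ids, , drop = FALSE]
  copies <- ref$copies_per_tube[match(ids, ref$spike_id)]
  design <- sample_design(design)
  if (!all(colnames(tpm) %in% design$sample_id))
    stop("TPM samples missing from design")
  robust <- if (robust_only) rowSums(tpm > 0) == ncol(tpm) else rep(TRUE, nrow(tpm))

  rows <- lapply(colnames(tpm), function(s) {
    det <- tpm[, s] > 0 & copies > 0 & robust
    if (sum(det) < min_spikes) {
      warning("sample ", s, " excluded: only ", sum(det), " detected spikes")
      return(NULL)
    }
    cp <- copies[det]
    if (diff(range(log10(cp))) < min_decades) {
      warning("sample ", s, " excluded: detected spikes span < ",
              min_decades, " decades")
      return(NULL)
    }
    fit <- stats::lm(log10(cp) ~ log10(tpm[det, s]))
    a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
    nc <- design$n_cells[design$sample_id == s]
    data.frame(sample_id = s, intercept = a, slope = b,
               copies_at_1tpm = 10^a, n_cells = nc,
               copies_per_cell = 10^a / nc)
  })
  per_sample <- do.call(rbind, rows)
  if (is.null(per_sample) || !nrow(per_sample))
    stop("no sample had enough detected spikes for the copies-per-TPM fit")
  structure(list(per_sample = per_sample,
                 copies_per_cell_mean = mean(per_sample$copies_per_cell),
                 copies_per_cell_sd = stats::sd(per_sample$copies_per_cell),
                 n_samples_used = nrow(per_sample)),
            class = "copies_per_tpm")
}

#' @export
print.copies_per_tpm <- function(x, ...) {
  cat("copies_per_tpm: 1 TPM = ",
      format(x$copies_per_cell_mean, digits = 3), " +/- ",
      format(x$copies_per_cell_sd, digits = 3),
      " copies/cell (", x$n_samples_used, " samples)\n", sep = "")
  invisible(x)
}
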