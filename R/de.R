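# Precision-weighted moderated differential expression.
#
# The engine follows the canonical published recipe for count data: log2-CPM
# with a 0.5 count offset and libsize+1 denominator; a lowess trend of
# sqrt(residual sd) against mean log2 count; inverse-fourth-power precision
# weights from the trend; gene-wise weighted least squares; empirical-Bayes
# shrinkage of residual variances towards a common prior with prior degrees
# of freedom estimated by moment matching on log variances (trigamma
# inversion); moderated t with augmented degrees of freedom; and
# Benjamini-Hochberg adjustment.

#' Group-means design matrix
#'
#' One indicator column per (cell_type, condition) group, no intercept.
#'
#' @param design validated design table.
#' @return Numeric design matrix, samples x groups.
#' @export
design_matrix <- function(design) {
  grp <- design_groups(design)
  X <- stats::model.matrix(~ 0 + grp)
  colnames(X) <- levels(grp)
  rownames(X) <- design$sample_id
  X
}

#' Default contrasts for a 2 cell-type x 2 condition design
#'
#' Builds the three comparisons reported for this design: deprived minus fed
#' within each cell type, and cell type 1 minus cell type 2 at the reference
#' condition.
#'
#' @param design validated design table.
#' @param condition_ref reference condition (default `"fed"`).
#' @return Matrix groups x contrasts with `"<group1>-<group2>"` column names.
#' @export
default_contrasts <- function(design, condition_ref = "fed") {
  grp <- levels(design_groups(design))
  cts <- sort(unique(as.character(design$cell_type)))
  conds <- unique(as.character(design$condition))
  alt <- setdiff(conds, condition_ref)
  cols <- list()
  for (ct in cts) for (a in alt) {
    g1 <- paste(ct, a, sep = "."); g2 <- paste(ct, condition_ref, sep = ".")
    if (all(c(g1, g2) %in% grp)) cols[[paste0(g1, "-", g2)]] <- c(g1, g2)
  }
  if (length(cts) >= 2) {
    g1 <- paste(cts[1], condition_ref, sep = ".")
    g2 <- paste(cts[2], condition_ref, sep = ".")
    if (all(c(g1, g2) %in% grp)) cols[[paste0(g1, "-", g2)]] <- c(g1, g2)
  }
  C <- matrix(0, length(grp), length(cols), dimnames = list(grp, names(cols)))
  for (nm in names(cols)) {
    C[cols[[nm]][1], nm] <- 1
    C[cols[[nm]][2], nm] <- -1
  }
  C
}

#' Log-CPM transform with mean-variance precision weights
#'
#' Computes `y = log2((count + 0.5) / (libsize * factor + 1) * 1e6)`, fits
#' each gene's linear model, smooths sqrt residual standard deviation against
#' mean log2 count with lowess, and assigns every observation the weight
#' `predicted_sd^-4` read off the trend at its fitted log2 count (clamped to
#' the trend's range at the extremes).
#'
#' @param counts filtered [count_matrix()] or plain matrix (no all-zero rows).
#' @param design design matrix (samples x coefficients, full rank) or a
#'   validated design table (converted with [design_matrix()]).
#' @param factors normalization factors from [tmm_factors()] (default: all 1).
#' @param lib_size optional library sizes (default: column sums of `counts`;
#'   pass full-matrix sizes when `counts` is a filtered submatrix).
#' @param span lowess span (default 0.5).
#' @return A list of class `voom_fit`: `E` (log2-CPM matrix), `weights`
#'   (same shape, strictly positive), `trend` (data.frame `x`, `y` of the
#'   lowess curve), `design`, `lib_size` (effective, after factors).
#' @export
voom_transform <- function(counts, design, factors = NULL, lib_size = NULL,
                           span = 0.5) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  X <- if (is.matrix(design)) design else design_matrix(sample_design(design))
  if (nrow(X) != ncol(m)) stop("design rows must match count columns")
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  if (is.null(lib_size)) lib_size <- colSums(m)
  if (is.null(factors)) factors <- rep(1, ncol(m))
  eff_lib <- lib_size * factors
  n <- ncol(m); p <- ncol(X)
  if (n <= p) stop("need more samples than design coefficients")

  y <- t(log2(t(m + 0.5) / (eff_lib + 1) * 1e6))
  fit <- stats::lm.fit(X, t(y))
  res <- as.matrix(fit$residuals)
  sigma <- sqrt(colSums(res^2) / (n - p))
  if (any(!is.finite(sigma)))
    stop("non-finite residual sd; remove all-zero genes before fitting")

  # mean log2 count scale for the trend
  sx <- rowMeans(y) + mean(log2(eff_lib + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  lo <- stats::lowess(sx, sy, f = span)
  trend_fun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)

  fitted_y <- t(X %*% as.matrix(fit$coefficients))   # genes x samples
  fitted_logcount <- t(log2(t(2^fitted_y / 1e6) * (eff_lib + 1)))
  pred_sd <- trend_fun(fitted_logcount)
  pred_sd <- pmax(pred_sd, 1e-6)
  w <- matrix(pred_sd^-4, nrow(y), ncol(y), dimnames = dimnames(y))

  structure(list(E = y, weights = w,
                 trend = data.frame(x = lo$x, y = lo$y),
                 design = X, lib_size = eff_lib),
            class = "voom_fit")
}

# Newton inversion of the trigamma function (x > 0 with trigamma(y) = x)
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    y <- 0.5 + 1 / xi
    for (i in 1:75) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif) / y < 1e-10) break
    }
    y
  }, numeric(1))
}

# Moment-matching estimate of the variance prior (d0, s0^2) from gene-wise
# residual variances s2 on df degrees of freedom, via the scaled-F /
# log-variance representation.
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- sum((e - ebar)^2) / (length(e) - 1) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    list(d0 = Inf, s02 = exp(ebar))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    list(d0 = d0, s02 = s02)
  }
}

#' Weighted linear fit with empirical-Bayes moderated t-statistics
#'
#' Per gene: weighted least squares with the observation weights from
#' [voom_transform()]; residual variance `s_g^2` on `d_g` degrees of freedom;
#' shrinkage `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` with the prior
#' `(d0, s0^2)` estimated across genes by moment matching on log variances;
#' moderated `t = coefficient / (unscaled_se * s~_g)` referred to a
#' t-distribution on `d0 + d_g` degrees of freedom. Contrast coefficients are
#' the adjusted log2 fold-changes. q-values are Benjamini-Hochberg adjusted
#' within each contrast.
#'
#' @param voom a `voom_fit`.
#' @param contrasts matrix coefficients x contrasts (e.g.
#'   [default_contrasts()]); each column a linear combination of design
#'   coefficients.
#' @param d0 force the prior degrees of freedom: `0` gives ordinary weighted
#'   least-squares t, `Inf` fully shrinks every variance to `s0^2`. Default
#'   `NULL` estimates d0 from the data.
#' @return A list of class `de_result`: `table` (long data.frame with
#'   columns gene, contrast, log2fc, t, p, q), `d0`, `s02`, `df_residual`,
#'   `s2` (gene residual variances), `s2_post`, plus `group_cpm` slot filled
#'   by [run_de()].
#' @export
fit_moderated <- function(voom, contrasts, d0 = NULL) {
  stopifnot(inherits(voom, "voom_fit"))
  X <- voom$design
  E <- voom$E; W <- voom$weights
  n <- ncol(E); p <- ncol(X)
  dg <- n - p
  if (dg <= 0) stop("saturated design: no residual degrees of freedom")
  if (!is.matrix(contrasts)) contrasts <- matrix(contrasts, ncol = 1)
  if (nrow(contrasts) != p) stop("contrast rows must match design coefficients")
  if (is.null(colnames(contrasts)))
    colnames(contrasts) <- paste0("c", seq_len(ncol(contrasts)))
  G <- nrow(E); C <- ncol(contrasts)

  coef <- se_unscaled <- matrix(NA_real_, G, C,
                                dimnames = list(rownames(E), colnames(contrasts)))
  s2 <- numeric(G)
  for (g in seq_len(G)) {
    w <- W[g, ]; yv <- E[g, ]
    xw <- X * w
    XtWX <- crossprod(X, xw)
    R <- chol(XtWX)
    beta <- backsolve(R, forwardsolve(t(R), crossprod(xw, yv)))
    r <- yv - drop(X %*% beta)
    s2[g] <- sum(w * r^2) / dg
    cov_un <- chol2inv(R)
    coef[g, ] <- crossprod(contrasts, beta)
    se_unscaled[g, ] <- sqrt(pmax(diag(crossprod(contrasts, cov_un %*% contrasts)), 0))
  }

  if (is.null(d0)) {
    prior <- estimate_variance_prior(s2, dg)
  } else {
    prior <- list(d0 = d0, s02 = estimate_variance_prior(s2, dg)$s02)
  }
  d0v <- prior$d0
  s2_post <- if (is.infinite(d0v)) rep(prior$s02, G)
             else (d0v * prior$s02 + dg * s2) / (d0v + dg)
  df_total <- if (is.infinite(d0v)) Inf else d0v + dg

  tstat <- coef / (se_unscaled * sqrt(s2_post))
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)

  tab <- data.frame(
    gene = rep(rownames(E), C),
    contrast = rep(colnames(contrasts), each = G),
    log2fc = as.vector(coef),
    t = as.vector(tstat),
    p = as.vector(pval),
    stringsAsFactors = FALSE)
  tab$q <- stats::ave(tab$p, tab$contrast, FUN = adjust_bh)

  structure(list(table = tab, d0 = d0v, s02 = prior$s02, df_residual = dg,
                 s2 = stats::setNames(s2, rownames(E)),
                 s2_post = stats::setNames(s2_post, rownames(E)),
                 contrasts = contrasts, group_cpm = NULL),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("de_result:", length(unique(x$table$gene)), "genes,",
      length(unique(x$table$contrast)), "contrast(s); d0 =",
      format(x$d0, digits = 4), "\n")
  if (!is.null(x$table$deg_flag)) {
    print(tapply(x$table$deg_flag, x$table$contrast, sum))
  }
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1, returned in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Apply the DEG criteria
#'
#' Flags genes with `q < q_max`, `|log2fc| > lfc_min` and group-mean CPM
#' greater than `cpm_min` in at least one (cell_type, condition) group.
#'
#' @param de a `de_result` with `group_cpm` present (see [run_de()]), or
#'   supply `group_cpm` here.
#' @param q_max q-value cutoff (default 0.05).
#' @param lfc_min strict absolute log2 fold-change cutoff (default 1).
#' @param cpm_min strict group-mean CPM cutoff (default 20).
#' @param group_cpm optional genes x groups matrix overriding `de$group_cpm`.
#' @return The `de_result` with a logical `deg_flag` column added to
#'   `table`.
#' @export
call_deg <- function(de, q_max = 0.05, lfc_min = 1, cpm_min = 20,
                     group_cpm = NULL) {
  stopifnot(inherits(de, "de_result"))
  if (is.null(group_cpm)) group_cpm <- de$group_cpm
  if (is.null(group_cpm)) stop("group-mean CPM required for the abundance criterion")
  max_cpm <- apply(group_cpm, 1, max)[de$table$gene]
  de$table$deg_flag <- de$table$q < q_max &
    abs(de$table$log2fc) > lfc_min &
    max_cpm > cpm_min
  de$group_cpm <- group_cpm
  de$thresholds <- c(q_max = q_max, lfc_min = lfc_min, cpm_min = cpm_min)
  de
}

#' DEG gene lists per contrast
#' @param de a `de_result` after [call_deg()].
#' @return Named list of character vectors of flagged genes per contrast.
#' @export
deg_lists <- function(de) {
  stopifnot(inherits(de, "de_result"), !is.null(de$table$deg_flag))
  split(de$table$gene[de$table$deg_flag], de$table$contrast[de$table$deg_flag])
}

#' Run the full differential-expression pipeline
#'
#' Expression filter (CPM > `filter_min_cpm` in at least
#' `filter_min_samples` samples, spike-ins excluded) -> TMM factors ->
#' log-CPM with precision weights -> moderated fit over the default (or
#' supplied) contrasts -> BH adjustment -> DEG criteria against raw
#' group-mean CPM.
#'
#' @param counts a [count_matrix()].
#' @param design design table (validated against `counts`).
#' @param contrasts optional contrast matrix (default [default_contrasts()]).
#' @param q_max,lfc_min,cpm_min DEG thresholds (defaults 0.05, 1, 20).
#' @param filter_min_cpm,filter_min_samples expression-filter thresholds
#'   (defaults 1, 3).
#' @param condition_ref reference condition for the default contrasts.
#' @param d0 optional forced prior degrees of freedom (see
#'   [fit_moderated()]).
#' @return A `de_result` with `deg_flag` set; also carries `filtered_genes`
#'   and `norm_factors`.
#' @examples
#' sim <- generate_dataset(sim_params(n_genes = 400), seed = 3)
#' de <- run_de(sim$counts, sim$design)
#' de
#' @export
run_de <- function(counts, design, contrasts = NULL,
                   q_max = 0.05, lfc_min = 1, cpm_min = 20,
                   filter_min_cpm = 1, filter_min_samples = 3,
                   condition_ref = "fed", d0 = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  design <- sample_design(design, counts)
  keep <- filter_expressed(counts, filter_min_cpm, filter_min_samples,
                           exclude_spikes = TRUE)
  if (length(keep) < 2) stop("fewer than 2 genes pass the expression filter")
  lib <- lib_sizes(counts)
  sub <- counts$counts[keep, , drop = FALSE]
  # zero-variance safety: drop genes with zero counts everywhere (cannot
  # happen after the CPM filter, but guard for custom thresholds)
  sub <- sub[rowSums(sub) > 0, , drop = FALSE]

  f <- tmm_factors(sub, lib_size = lib)
  X <- design_matrix(design)
  if (is.null(contrasts)) contrasts <- default_contrasts(design, condition_ref)
  v <- voom_transform(sub, X, factors = f, lib_size = lib)
  de <- fit_moderated(v, contrasts, d0 = d0)

  cpm <- compute_cpm(counts)
  gm <- group_mean_cpm(cpm[keep, , drop = FALSE], design)
  de <- call_deg(de, q_max, lfc_min, cpm_min, group_cpm = gm)
  de$filtered_genes <- keep
  de$norm_factors <- f
  de$voom <- v
  de
}
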