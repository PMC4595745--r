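test_that("TMM factors are 1 for identical or purely depth-shifted columns", {
  set.seed(2)
  base <- rpois(50, 60) + 1L
  m <- matrix(rep(base, 4), ncol = 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  f <- tmm_factors(m)
  expect_equal(unname(f), rep(1, 4), tolerance = 1e-12, ignore_attr = TRUE)

  m2 <- cbind(A = base, B = base * 2L)
  rownames(m2) <- paste0("g", 1:50)
  f2 <- tmm_factors(m2)
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("TMM matches the naive double-trimmed weighted mean and edgeR", {
  set.seed(13)
  m <- matrix(rpois(50 * 6, 80) + 1L, 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  # one high-abundance contaminant in one sample induces composition bias
  m[1, 3] <- 60000L
  f <- tmm_factors(m)
  expect_equal(unname(f), oracle_tmm(m), tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(f[3], 1)  # contaminated sample is scaled down

  skip_if_not_installed("edgeR")
  fe <- edgeR::calcNormFactors(edgeR::DGEList(m), method = "TMM")$samples$norm.factors
  expect_equal(unname(f), fe, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("precision weights are flat for homoscedastic data and valid always", {
  des <- toy_design(c(3, 3, 3, 3))
  X <- design_matrix(des)
  # pseudo-counts whose log-variance does not depend on the mean:
  # constant counts plus small uniform jitter at two abundance tiers
  set.seed(6)
  m <- rbind(
    matrix(1000L + sample(-5:5, 60, TRUE), 5, 12),
    matrix(100000L + sample(-547:547, 60, TRUE), 5, 12))
  dimnames(m) <- list(paste0("g", 1:10), des$sample_id)
  v <- voom_transform(m, X)
  w <- v$weights
  expect_true(all(is.finite(w)) && all(w > 0))
  expect_lt(max(w) / min(w), 1.5)

  sim <- generate_dataset(sim_params(n_genes = 500), seed = 9)
  de_counts <- sim$counts$counts[filter_expressed(sim$counts), ]
  v2 <- voom_transform(de_counts, design_matrix(sim$design),
                       lib_size = lib_sizes(sim$counts))
  expect_true(all(is.finite(v2$weights)) && all(v2$weights > 0))
  # NB mean-variance: the sd trend decreases over the bulk of the range
  tr <- v2$trend
  mid <- tr$x > quantile(tr$x, 0.1) & tr$x < quantile(tr$x, 0.9)
  expect_lt(stats::cor(tr$x[mid], tr$y[mid]), -0.5)
  expect_error(voom_transform(de_counts, cbind(X = rep(1, 21), Y = rep(1, 21))),
               "full rank")
})

test_that("voom transform and weights match limma on generator data", {
  skip_if_not_installed("limma")
  sim <- generate_dataset(sim_params(n_genes = 400), seed = 14)
  keep <- filter_expressed(sim$counts)
  m <- sim$counts$counts[keep, ]
  lib <- lib_sizes(sim$counts)
  f <- tmm_factors(m, lib_size = lib)
  X <- design_matrix(sim$design)
  mine <- voom_transform(m, X, factors = f, lib_size = lib)
  ref <- limma::voom(m, X, lib.size = lib * f, span = 0.5)
  expect_equal(mine$E, ref$E, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(mine$weights, ref$weights, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("moderated t has the correct no-shrinkage and full-shrinkage limits", {
  des <- toy_design(c(3, 3, 2, 2))
  X <- design_matrix(des)
  set.seed(8)
  y <- matrix(rnorm(10 * 10, 8, 1), 10, 10,
              dimnames = list(paste0("g", 1:10), des$sample_id))
  v <- structure(list(E = y, weights = matrix(1, 10, 10, dimnames = dimnames(y)),
                      trend = NULL, design = X, lib_size = rep(1e6, 10)),
                 class = "voom_fit")
  C <- default_contrasts(des)

  # d0 = 0: moderated t equals the ordinary weighted-LS t
  d <- fit_moderated(v, C, d0 = 0)
  g <- "g3"; ct <- "AGRP.FD-AGRP.fed"
  a_idx <- des$sample_id[des$cell_type == "AGRP" & des$condition == "FD"]
  b_idx <- des$sample_id[des$cell_type == "AGRP" & des$condition == "fed"]
  # group-means model: coefficient is the difference of group means
  row <- d$table[d$table$gene == g & d$table$contrast == ct, ]
  expect_equal(row$log2fc, mean(y[g, a_idx]) - mean(y[g, b_idx]),
               tolerance = 1e-12)
  # residual variance pools all four groups
  resid <- unlist(lapply(levels(design_groups(des)), function(gr) {
    idx <- des$sample_id[design_groups(des) == gr]
    y[g, idx] - mean(y[g, idx])
  }))
  s2 <- sum(resid^2) / (10 - 4)
  t_hand <- row$log2fc / sqrt(s2 * (1 / 3 + 1 / 3))
  expect_equal(row$t, t_hand, tolerance = 1e-12)

  # d0 = Inf: every denominator variance equals s0^2
  dinf <- fit_moderated(v, C, d0 = Inf)
  expect_equal(unname(dinf$s2_post), rep(dinf$s02, 10), tolerance = 1e-12)

  # shrinkage monotonicity: estimated-d0 |t| lies between the two limits
  dest <- fit_moderated(v, C)
  for (gg in rownames(y)) {
    t0 <- abs(d$table$t[d$table$gene == gg & d$table$contrast == ct])
    tinf <- abs(dinf$table$t[dinf$table$gene == gg & dinf$table$contrast == ct])
    tm <- abs(dest$table$t[dest$table$gene == gg & dest$table$contrast == ct])
    expect_gte(tm, min(t0, tinf) - 1e-10)
    expect_lte(tm, max(t0, tinf) + 1e-10)
  }
})

test_that("two-group fit reproduces the textbook pooled t-test", {
  # 2 groups only, n = 3 vs 3, equal weights
  d <- data.frame(sample_id = paste0("s", 1:6),
                  cell_type = "AGRP",
                  condition = rep(c("fed", "FD"), each = 3),
                  n_cells = 50)
  X <- design_matrix(sample_design(d))
  set.seed(10)
  y <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(paste0("g", 1:5), d$sample_id))
  v <- structure(list(E = y, weights = matrix(1, 5, 6, dimnames = dimnames(y)),
                      trend = NULL, design = X, lib_size = rep(1e6, 6)),
                 class = "voom_fit")
  C <- matrix(c(1, -1), 2, 1, dimnames = list(colnames(X), "AGRP.FD-AGRP.fed"))
  if (colnames(X)[1] != "AGRP.FD") C <- C[c(2, 1), , drop = FALSE]
  fit <- fit_moderated(v, C, d0 = 0)
  for (g in rownames(y)) {
    tt <- stats::t.test(y[g, 4:6], y[g, 1:3], var.equal = TRUE)
    row <- fit$table[fit$table$gene == g, ]
    expect_equal(row$log2fc, unname(tt$estimate[1] - tt$estimate[2]),
                 tolerance = 1e-10)
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated fit agrees with the limma empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  sim <- generate_dataset(sim_params(n_genes = 300), seed = 18)
  keep <- filter_expressed(sim$counts)
  m <- sim$counts$counts[keep, ]
  lib <- lib_sizes(sim$counts)
  f <- tmm_factors(m, lib_size = lib)
  X <- design_matrix(sim$design)
  C <- default_contrasts(sim$design)

  mine <- fit_moderated(voom_transform(m, X, f, lib), C)

  ref_v <- limma::voom(m, X, lib.size = lib * f, span = 0.5)
  ref_fit <- limma::eBayes(limma::contrasts.fit(limma::lmFit(ref_v, X), C))
  expect_equal(mine$d0, ref_fit$df.prior, tolerance = 1e-6)
  expect_equal(mine$s02, ref_fit$s2.prior, tolerance = 1e-6)
  for (j in colnames(C)) {
    tt <- limma::topTable(ref_fit, coef = j, number = Inf, sort.by = "none")
    sub <- mine$table[mine$table$contrast == j, ]
    expect_equal(sub$log2fc, tt$logFC, tolerance = 1e-8)
    expect_equal(sub$t, tt$t, tolerance = 1e-6)
    expect_equal(sub$p, tt$P.Value, tolerance = 1e-6)
    expect_equal(sub$q, tt$adj.P.Val, tolerance = 1e-6)
  }
})

test_that("BH step-up matches hand computation and p.adjust", {
  expect_equal(adjust_bh(c(0.05, 0.05)), c(0.05, 0.05))
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
  set.seed(30)
  p <- runif(200)
  expect_equal(adjust_bh(p), stats::p.adjust(p, "BH"), tolerance = 1e-14)
  perm <- sample(200)
  expect_equal(adjust_bh(p[perm]), adjust_bh(p)[perm], tolerance = 1e-14)
})

test_that("DEG criteria combine q, fold-change and abundance", {
  tab <- data.frame(gene = c("a", "b", "c"), contrast = "x",
                    log2fc = c(1.5, 0.9, 2.0), t = 1, p = 0.01,
                    q = c(0.04, 0.04, 0.04))
  de <- structure(list(table = tab, group_cpm = NULL), class = "de_result")
  gcpm <- rbind(a = c(25, 5), b = c(25, 5), c = c(10, 15))
  colnames(gcpm) <- c("g1", "g2")
  out <- call_deg(de, group_cpm = gcpm)
  expect_identical(out$table$deg_flag, c(TRUE, FALSE, FALSE))
})

test_that("programmed effects are recovered essentially without bias", {
  errs <- unlist(lapply(1:4, function(s) {
    sim <- generate_dataset(sim_params(n_genes = 1500), seed = 600 + s)
    de <- run_de(sim$counts, sim$design)
    tr <- sim$truth$genes
    gm <- group_mean_cpm(compute_cpm(sim$counts), sim$design)
    ct <- "AGRP.FD-AGRP.fed"
    sub <- de$table[de$table$contrast == ct, ]
    tl <- tr[[paste0("lfc.", ct)]][match(sub$gene, tr$gene)]
    base <- gm[sub$gene, "AGRP.fed"]
    sel <- !is.na(tl) & abs(tl) >= 1 & base >= 20
    sub$log2fc[sel] - tl[sel]
  }))
  expect_lt(abs(mean(errs)), 0.15)
})

test_that("detection power sits at the configured target", {
  # the generator's dispersion defaults target ~80% significance power for a
  # twofold change at n = 5 vs 6; DEG calls on the default effect range
  # (|lfc| in [1,3]) should recover most programmed DEG
  pw <- unlist(lapply(1:3, function(s) {
    p <- sim_params(n_genes = 1500, lfc_lo = 1, lfc_hi = 1 + 1e-9)
    sim <- generate_dataset(p, seed = 700 + s)
    de <- run_de(sim$counts, sim$design)
    tr <- sim$truth$genes
    gm <- group_mean_cpm(compute_cpm(sim$counts), sim$design)
    ct <- "AGRP.FD-AGRP.fed"
    sub <- de$table[de$table$contrast == ct, ]
    m <- match(sub$gene, tr$gene)
    deg <- tr[[paste0("deg.", ct)]][m]
    sel <- !is.na(deg) & deg & gm[sub$gene, "AGRP.fed"] >= 20
    mean(sub$q[sel] < 0.05)
  }))
  expect_gt(mean(pw), 0.65)
  expect_lt(mean(pw), 0.95)

  sens <- unlist(lapply(1:2, function(s) {
    sim <- generate_dataset(sim_params(n_genes = 1500), seed = 710 + s)
    de <- run_de(sim$counts, sim$design)
    tr <- sim$truth$genes
    gm <- group_mean_cpm(compute_cpm(sim$counts), sim$design)
    ct <- "AGRP.FD-AGRP.fed"
    sub <- de$table[de$table$contrast == ct, ]
    m <- match(sub$gene, tr$gene)
    deg <- tr[[paste0("deg.", ct)]][m]
    sel <- !is.na(deg) & deg & gm[sub$gene, "AGRP.fed"] >= 20
    mean(sub$deg_flag[sel])
  }))
  expect_gt(mean(sens), 0.85)
})

test_that("saturated designs and zero-residual fits are rejected", {
  d <- data.frame(sample_id = paste0("s", 1:4), cell_type = "AGRP",
                  condition = rep(c("fed", "FD"), each = 2), n_cells = 10)
  X <- design_matrix(sample_design(d))
  y <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), d$sample_id))
  v <- structure(list(E = y, weights = matrix(1, 2, 4, dimnames = dimnames(y)),
                      design = diag(4), lib_size = rep(1, 4)),
                 class = "voom_fit")
  expect_error(fit_moderated(v, diag(4)[, 1, drop = FALSE]), "saturated")
})
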