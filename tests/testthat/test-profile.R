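make_profile_fixture <- function(seed = 1, n_genes = 60) {
  set.seed(seed)
  des <- toy_design(c(2, 2, 2, 2))
  m <- matrix(rpois(n_genes * 8, 200), n_genes, 8,
              dimnames = list(paste0("g", seq_len(n_genes)), des$sample_id))
  list(des = des, expr = m)
}

test_that("correlation distance matches a naive pairwise loop", {
  fx <- make_profile_fixture(3)
  cpm <- compute_cpm(toy_counts(fx$expr))
  d <- correlation_distance(cpm, cpm, fx$des, cpm_min = 20)
  # oracle on the same filtered, logged matrix
  gm <- group_mean_cpm(cpm, fx$des)
  keep <- rownames(cpm)[apply(gm, 1, max) > 20]
  want <- oracle_cor_dist(log2(unclass(cpm)[keep, ] + 1))
  expect_equal(unname(d), unname(want), tolerance = 1e-12)
  expect_true(all(d >= -1e-12 & d <= 2 + 1e-12))
  expect_equal(unname(diag(d)), rep(0, 8))

  # identical samples at distance 0; anti-correlated at distance 2
  x <- rbind(a = c(1, 5, 9), b = c(2, 4, 8), cc = c(3, 3, 7))
  colnames(x) <- paste0("s", 1:3)
  x2 <- cbind(x, s4 = x[, 1])
  des2 <- toy_design(c(2, 2, 2, 2))[1:4, ]
  des2$sample_id <- colnames(x2)
  des2 <- sample_design(rbind(des2, des2[0, ]))
  d2 <- correlation_distance(x2, matrix(100, 3, 4, dimnames = dimnames(x2)),
                             des2, cpm_min = 20, log = FALSE)
  expect_equal(d2["s1", "s4"], 0, tolerance = 1e-12)
  y <- x2; y[, 2] <- -y[, 1] + 10   # exact anti-correlation in linear space
  d3 <- correlation_distance(y, matrix(100, 3, 4, dimnames = dimnames(y)),
                             des2, cpm_min = 20, log = FALSE)
  expect_equal(d3["s1", "s2"], 2, tolerance = 1e-12)

  # constant profile -> error naming the sample
  z <- x2; z[, 3] <- 5
  expect_error(correlation_distance(z, matrix(100, 3, 4, dimnames = dimnames(z)),
                                    des2, cpm_min = 20, log = FALSE), "s3")
  # exclusion list removes genes from the computation
  d4 <- correlation_distance(x2, matrix(100, 3, 4, dimnames = dimnames(x2)),
                             des2, cpm_min = 20, log = FALSE,
                             exclude_genes = "a")
  want4 <- oracle_cor_dist(x2[c("b", "cc"), ])
  expect_equal(unname(d4), unname(want4), tolerance = 1e-12)
})

test_that("classical MDS reproduces Euclidean configurations and the oracle", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4), c(2, 5))
  D <- as.matrix(stats::dist(pts))
  rownames(D) <- colnames(D) <- paste0("s", 1:4)
  emb <- classical_mds(D, k = 2)
  expect_equal(as.matrix(stats::dist(emb$points)), D, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unname(colSums(emb$points)), c(0, 0), tolerance = 1e-9)
  expect_true(all(diff(emb$eig) <= 1e-9))

  # oracle agreement up to rotation/reflection: compare embedded distances
  om <- oracle_mds(D, 2)
  expect_equal(as.matrix(stats::dist(om)), as.matrix(stats::dist(emb$points)),
               tolerance = 1e-9, ignore_attr = TRUE)

  # all-zero distances: coincident points at the origin
  z <- matrix(0, 4, 4, dimnames = dimnames(D))
  embz <- suppressWarnings(classical_mds(z, k = 2))
  expect_true(all(abs(embz$points) < 1e-12))

  # sample order invariance via output distance matrices
  perm <- c(3, 1, 4, 2)
  emb_p <- classical_mds(D[perm, perm], k = 2)
  expect_equal(as.matrix(stats::dist(emb_p$points)), D[perm, perm],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("MDS separates the two simulated cell types", {
  sim <- generate_dataset(sim_params(n_genes = 1200), seed = 19)
  tpm <- compute_tpm(sim$counts)
  cpm <- compute_cpm(sim$counts)
  d <- correlation_distance(tpm, cpm, sim$design, cpm_min = 20)
  same <- c(); diff_ct <- c()
  ct <- sim$design$cell_type[match(rownames(d), sim$design$sample_id)]
  for (i in seq_len(nrow(d) - 1)) for (j in (i + 1):nrow(d)) {
    if (ct[i] == ct[j]) same <- c(same, d[i, j]) else diff_ct <- c(diff_ct, d[i, j])
  }
  expect_lt(stats::wilcox.test(same, diff_ct, alternative = "less")$p.value,
            0.01)
  emb <- classical_mds(d, k = 2)
  expect_equal(nrow(emb$points), 21)
})

test_that("gene clustering merges by correlation and matches naive linkage", {
  s <- seq(1, 8)
  expr <- rbind(up1 = s, up2 = 2 * s + 3,            # r = 1
                down = -s + 20,                      # r = -1 vs up
                noise = c(5, 1, 6, 2, 7, 1, 8, 3))
  colnames(expr) <- paste0("s", 1:8)
  cl2 <- cluster_deg(expr, c("up1", "up2"))
  expect_equal(cl2$tree$height, 0, tolerance = 1e-12)
  cl2b <- cluster_deg(expr, c("up1", "down"))
  expect_equal(cl2b$tree$height, 2, tolerance = 1e-12)

  set.seed(12)
  e6 <- matrix(rnorm(6 * 10), 6, 10,
               dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  cl <- cluster_deg(e6, rownames(e6), linkage = "average")
  D <- 1 - stats::cor(t(e6))   # row standardization leaves correlations unchanged
  expect_equal(sort(cl$tree$height), oracle_average_linkage_heights(D),
               tolerance = 1e-10)
  expect_setequal(cl$order, rownames(e6))
  expect_equal(unname(diag(cl$cor)), rep(1, 6))
  expect_true(isSymmetric(cl$cor))

  flat <- rbind(e6, constant = rep(3, 10))
  expect_warning(cluster_deg(flat, rownames(flat)), "zero-variance")
})

test_that("purity report computes pseudocount-protected fold depletions", {
  sets <- gene_set_collection(list(glia = c("m1", "m2"), vasc = "m3"))
  expr <- rbind(m1 = rep(1, 4), m2 = rep(9, 4), m3 = rep(0, 4),
                other = rep(50, 4))
  colnames(expr) <- paste0("s", 1:4)
  ref <- matrix(c(1000, 1000, 500), 3, 1, dimnames = list(c("m1", "m2", "m3"), "ref"))
  rep1 <- purity_report(expr, sets, ref)
  pm <- rep1$per_marker
  expect_equal(pm$fold_depletion[pm$gene == "m1"], 1001 / 2)
  expect_equal(pm$fold_depletion[pm$gene == "m3"], 501 / 1)
  expect_equal(rep1$per_set$min_fold[rep1$per_set$set == "glia"], 1001 / 10)
  # equal expression -> fold 1
  expr2 <- expr; expr2["m1", ] <- 1000
  rep2 <- purity_report(expr2, sets, ref)
  expect_equal(rep2$per_marker$fold_depletion[rep2$per_marker$gene == "m1"], 1)
  # absent marker skipped with warning
  expect_warning(
    purity_report(expr[-1, , drop = FALSE], sets, ref), "skipped")
})

test_that("programmed trace contamination yields high marker folds", {
  sim <- generate_dataset(sim_params(n_genes = 800), seed = 23)
  tpm <- compute_tpm(sim$counts)
  markers <- sim$sets
  markers$random_control <- NULL
  rep1 <- purity_report(tpm, gene_set_collection(unclass(markers)),
                        sim$reference_profiles, design = sim$design)
  expect_true(all(rep1$per_set$min_fold > 100))
})

test_that("splicing fraction test reduces to the pooled two-sample t", {
  des <- toy_design(c(3, 3, 2, 2))[1:6, ]
  des <- sample_design(des)
  sp <- c(10, 12, 9, 30, 34, 28)
  un <- c(90, 88, 91, 70, 66, 72)
  names(sp) <- names(un) <- des$sample_id
  out <- splicing_fraction_test(sp, un, des)
  f <- sp / (sp + un)
  fed <- f[des$condition == "fed"]; fd <- f[des$condition == "FD"]
  tt <- stats::t.test(fd, fed, alternative = "greater", var.equal = TRUE)
  expect_equal(out$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(out$p, tt$p.value, tolerance = 1e-12)
  expect_equal(out$df, unname(tt$parameter), tolerance = 1e-12)
  expect_true(all(out$fractions >= 0 & out$fractions <= 1))

  # identical group fractions: t = 0, one-tailed p = 0.5
  sp2 <- rep(c(10, 20, 10), 2); un2 <- rep(c(90, 180, 90), 2)
  names(sp2) <- names(un2) <- des$sample_id
  out2 <- splicing_fraction_test(sp2, un2, des)
  expect_equal(out2$t, 0, tolerance = 1e-12)
  expect_equal(out2$p, 0.5, tolerance = 1e-12)

  # zero-total sample excluded with a warning
  sp3 <- sp; un3 <- un; sp3[2] <- 0; un3[2] <- 0
  expect_warning(splicing_fraction_test(sp3, un3, des), "zero")
})

test_that("summary-statistic mode matches hand-derived pooled algebra", {
  out <- splicing_fraction_test(
    summary = list(mean = c(fed = 10, FD = 20),
                   sem = c(fed = 2, FD = 3), n = c(fed = 4, FD = 4)))
  s1 <- 2 * 2; s2 <- 3 * 2
  sp2 <- (3 * s1^2 + 3 * s2^2) / 6
  t_hand <- 10 / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$df, 6)
  expect_equal(out$p, stats::pt(t_hand, 6, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("generator splicing signal is detected by the one-tailed test", {
  # AGRP samples only, as in the motivating experiment
  sim <- generate_dataset(sim_params(n_genes = 400), seed = 29)
  des <- sim$design[sim$design$cell_type == "AGRP", ]
  cnt <- sim$counts$counts
  out <- splicing_fraction_test(cnt["Xbp1_spliced", des$sample_id],
                                cnt["Xbp1_unspliced", des$sample_id],
                                sample_design(des))
  expect_gt(out$group_stats$mean[out$group_stats$group == "FD"],
            out$group_stats$mean[out$group_stats$group == "fed"])
})
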