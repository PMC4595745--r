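# Independent brute-force oracles and tiny fixture builders. These share no
# code with the package implementation: direct formulas, explicit loops,
# exhaustive enumeration.

toy_counts <- function(m, len = rep(1, nrow(m)), spike = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  count_matrix(m, len, spike)
}

toy_design <- function(n_per = c(2, 2, 2, 2), ids = NULL) {
  grp <- data.frame(cell_type = c("AGRP", "AGRP", "POMC", "POMC"),
                    condition = c("fed", "FD", "fed", "FD"))
  d <- grp[rep(1:4, n_per), ]
  d$sample_id <- if (is.null(ids))
    paste0(d$cell_type, ".", d$condition, "_", unlist(lapply(n_per, seq_len)))
  else ids
  d$n_cells <- 100
  sample_design(d[, c("sample_id", "cell_type", "condition", "n_cells")])
}

# direct double-trimmed weighted-mean TMM (explicit per-sample loop)
oracle_tmm <- function(m, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(m)
  uq <- vapply(seq_len(ncol(m)), function(j)
    unname(stats::quantile(m[, j] / lib[j], 0.75)), numeric(1))
  r <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    if (j == r) { f[j] <- 1; next }
    ok <- which(m[, j] > 0 & m[, r] > 0)
    M <- A <- v <- numeric(length(ok))
    for (i in seq_along(ok)) {
      g <- ok[i]
      po <- m[g, j] / lib[j]; pr <- m[g, r] / lib[r]
      M[i] <- log2(po / pr)
      A[i] <- (log2(po) + log2(pr)) / 2
      v[i] <- (lib[j] - m[g, j]) / (lib[j] * m[g, j]) +
        (lib[r] - m[g, r]) / (lib[r] * m[g, r])
    }
    if (max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    kM <- rank(M) >= floor(n * trim_m) + 1 & rank(M) <= n - floor(n * trim_m)
    kA <- rank(A) >= floor(n * trim_a) + 1 & rank(A) <= n - floor(n * trim_a)
    keep <- kM & kA
    f[j] <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f / exp(mean(log(f)))
}

# exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # treat items 1..K as the set
  mean(hits >= k)
}

# Torgerson MDS from first principles
oracle_mds <- function(D, k = 2) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- seq_len(k)
  e$vectors[, keep, drop = FALSE] %*% diag(sqrt(pmax(e$values[keep], 0)), k)
}

# pairwise 1 - Pearson r by explicit loops
oracle_cor_dist <- function(x) {
  n <- ncol(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- 1 - stats::cor(x[, i], x[, j])
  diag(d) <- 0
  d
}

# naive average-linkage agglomeration on a distance matrix; returns sorted
# merge heights
oracle_average_linkage_heights <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      h <- mean(D[clusters[[a]], clusters[[b]]])
      if (h < best[1]) best <- c(h, a, b)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# grid-search ML fit of the detection model eta = eta50 + b*(lx - lx50);
# two-stage refinement to ~3 significant figures on x50
oracle_detection_x50 <- function(lx, det, link = "cloglog") {
  linkinv <- if (link == "cloglog") function(e) -expm1(-exp(e)) else stats::plogis
  eta50 <- if (link == "cloglog") log(log(2)) else 0
  loglik <- function(lx50, b) {
    p <- pmin(pmax(linkinv(eta50 + b * (lx - lx50)), 1e-12), 1 - 1e-12)
    sum(det * log(p) + (1 - det) * log(1 - p))
  }
  grid_fit <- function(l_rng, b_rng, n = 60) {
    ls <- seq(l_rng[1], l_rng[2], length.out = n)
    bs <- seq(b_rng[1], b_rng[2], length.out = n)
    ll <- outer(ls, bs, Vectorize(loglik))
    idx <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    c(ls[idx[1]], bs[idx[2]], ls[2] - ls[1], bs[2] - bs[1])
  }
  f <- grid_fit(c(-2, 4), c(0.05, 12))
  for (i in 1:3)
    f <- grid_fit(c(f[1] - 2 * f[3], f[1] + 2 * f[3]),
                  c(max(f[2] - 2 * f[4], 1e-3), f[2] + 2 * f[4]))
  10^f[1]
}
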