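#' PCA of a standardized genotype matrix
#'
#' Columns are centered by `2p` and scaled by `sqrt(2p(1-p))` (p =
#' alternate-allele frequency) before a singular value decomposition, the
#' normalization under which leading eigenvalues of unstructured data follow
#' Tracy-Widom fluctuations. Scores are `U D`, loadings are unit-norm right
#' singular vectors, eigenvalues are `d^2 / (n - 1)`.
#'
#' @param g a complete [genotype_matrix()] with no monomorphic markers.
#' @param n_axes number of axes to return (default `min(n - 1, m)`).
#' @return object of class `snp_pca`: `scores` (n x K), `loadings` (m x K),
#'   `eigenvalues` (K, descending), `eigenvalues_all` (full spectrum),
#'   `n_significant` (NA until [tracy_widom_axes()] is applied), `n`, `m`.
#' @export
snp_pca <- function(g, n_axes = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$dosage)) ck_stop("snp_pca needs a complete matrix")
  n <- nrow(g$dosage); m <- ncol(g$dosage)
  p <- colMeans(g$dosage) / 2
  constant <- colSums(g$dosage != rep(g$dosage[1L, ], each = n)) == 0L
  if (any(p <= 0 | p >= 1) || any(constant)) {
    ck_stop("monomorphic marker(s) present; filter before PCA")
  }
  if (is.null(n_axes)) n_axes <- min(n - 1L, m)
  if (n_axes > min(n - 1L, m)) ck_stop("n_axes exceeds matrix rank bound")
  X <- sweep(sweep(g$dosage, 2L, 2 * p, "-"), 2L, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(X, nu = min(n - 1L, m), nv = n_axes)
  ev_all <- sv$d^2 / (n - 1)
  scores <- sv$u[, seq_len(n_axes), drop = FALSE] %*%
    diag(sv$d[seq_len(n_axes)], n_axes, n_axes)
  rownames(scores) <- g$accession_ids
  loadings <- sv$v
  rownames(loadings) <- g$marker_ids
  structure(list(scores = scores, loadings = loadings,
                 eigenvalues = ev_all[seq_len(n_axes)],
                 eigenvalues_all = ev_all[seq_len(min(n - 1L, m))],
                 n_significant = NA_integer_, n = n, m = m,
                 total_variance = sum(ev_all)),
            class = "snp_pca")
}

# Tracy-Widom (GOE) upper-tail quantiles; linear interpolation in log10(alpha).
tw_quantile <- function(alpha) {
  tab_a <- c(0.20, 0.10, 0.05, 0.025, 0.01, 0.005, 0.001)
  tab_q <- c(-0.1654, 0.4501, 0.9793, 1.4538, 2.0234, 2.4224, 3.2724)
  if (alpha <= 0) return(Inf)
  if (alpha >= tab_a[1]) return(tab_q[1])
  if (alpha <= tab_a[length(tab_a)]) return(tab_q[length(tab_q)])
  stats::approx(log10(tab_a), tab_q, xout = log10(alpha))$y
}

#' Count Tracy-Widom-significant PCA axes
#'
#' Successive eigenvalues are normalized with the moment-matching estimate of
#' the effective column count (Patterson-style): for the i-th eigenvalue the
#' remaining spectrum is treated as a Wishart sample, the effective number of
#' variables is estimated from its first two moments, and the centered/scaled
#' statistic is compared to the Tracy-Widom GOE quantile at `alpha`. Counting
#' stops at the first non-significant axis.
#'
#' @param p a [snp_pca()] result (eigenvalues from the standardized matrix).
#' @param n,m panel dimensions (default from `p`).
#' @param alpha test level (default 0.05).
#' @return integer count of leading significant axes.
#' @export
tracy_widom_axes <- function(p, n = p$n, m = p$m, alpha = 0.05) {
  stopifnot(inherits(p, "snp_pca"))
  if (n < 3) ck_stop("need at least 3 accessions for the Tracy-Widom test")
  if (alpha <= 0) return(0L)
  q <- tw_quantile(alpha)
  ev <- p$eigenvalues_all
  ev <- ev[ev > 1e-12]
  nsig <- 0L
  for (i in seq_along(ev)) {
    rem <- ev[i:length(ev)]
    mprime <- length(rem)
    if (mprime < 2L) break
    s1 <- sum(rem); s2 <- sum(rem^2)
    n_eff <- ((mprime + 1) * s1^2) / ((mprime - 1) * s2 - s1^2)
    if (!is.finite(n_eff) || n_eff <= 1) break
    ell <- mprime * rem[1] / s1
    sq_n <- sqrt(n_eff - 1); sq_m <- sqrt(mprime)
    mu <- (sq_n + sq_m)^2 / n_eff
    sig <- (sq_n + sq_m) / n_eff * (1 / sq_n + 1 / sq_m)^(1 / 3)
    x <- (ell - mu) / sig
    if (x > q) nsig <- nsig + 1L else break
  }
  nsig
}

#' K-means clustering over a range of K with BIC model choice
#'
#' Clusters accessions on the Tracy-Widom-significant PC scores (or the first
#' `d` axes when significance has not been computed). For each candidate K the
#' best of `nstart` seeded K-means restarts is kept and scored by the BIC of a
#' spherical Gaussian mixture evaluated at the K-means solution (component
#' means = centers, shared variance = WSS/(nd), mixing weights = cluster
#' shares; parameter count `(K-1) + Kd + 1`). A classification/WSS-based BIC
#' decreases monotonically in K on clustered data, so the proper mixture
#' likelihood is used instead. The model at the BIC minimum is returned unless
#' `force_k` overrides it (germplasm knowledge may legitimately overrule the
#' BIC argmin).
#'
#' @param p a [snp_pca()] result; set `p$n_significant` (via
#'   [tracy_widom_axes()]) or pass `d`.
#' @param k_range candidate cluster counts (default 1:10).
#' @param seed RNG seed.
#' @param d number of leading score columns to cluster on.
#' @param nstart K-means restarts per K (default 10).
#' @param force_k optional fixed K overriding the BIC choice.
#' @return object of class `cluster_model`: `k`, `assignments` (named),
#'   `memberships` (n x k, row-stochastic), `bic_curve`, `centers`, `Q`
#'   (NULL until [dapc_covariates()]).
#' @export
kmeans_bic <- function(p, k_range = 1:10, seed = 1L,
                       d = NULL, nstart = 10L, force_k = NULL) {
  stopifnot(inherits(p, "snp_pca"))
  if (is.null(d)) {
    d <- if (!is.na(p$n_significant)) p$n_significant else ncol(p$scores)
  }
  if (is.na(d) || d < 1L) ck_stop("need at least one significant axis to cluster on")
  d <- min(d, ncol(p$scores))
  X <- p$scores[, seq_len(d), drop = FALSE]
  n <- nrow(X)
  if (max(k_range) >= n) ck_stop("k_range upper bound must be below n")
  bic <- setNames(numeric(length(k_range)), paste0("k", k_range))
  fits <- vector("list", length(k_range))
  with_seed(seed, {
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      if (k == 1L) {
        ctr <- colMeans(X)
        wss <- sum(sweep(X, 2L, ctr, "-")^2)
        fits[[i]] <- list(cluster = rep(1L, n), centers = matrix(ctr, 1L),
                          tot.withinss = wss)
      } else {
        fits[[i]] <- kmeans(X, centers = k, nstart = nstart, iter.max = 50L)
      }
      bic[i] <- kmeans_gmm_bic(X, fits[[i]], k)
    }
  })
  k_best <- if (is.null(force_k)) k_range[which.min(bic)] else as.integer(force_k)
  fit <- fits[[match(k_best, k_range)]]
  if (is.null(fit)) ck_stop("force_k outside k_range")
  assignments <- setNames(as.integer(fit$cluster), rownames(X))
  memberships <- matrix(0, n, k_best,
                        dimnames = list(rownames(X), paste0("c", seq_len(k_best))))
  memberships[cbind(seq_len(n), assignments)] <- 1
  structure(list(k = k_best, assignments = assignments,
                 memberships = memberships, bic_curve = bic,
                 centers = fit$centers, d = d, Q = NULL),
            class = "cluster_model")
}

#' Discriminant-analysis memberships and GWAS structure covariates
#'
#' Fits linear discriminant axes on the retained PC scores with the K-means
#' labels as classes (the DAPC construction). Memberships become the LDA
#' posterior class probabilities; the structure covariate matrix `Q` holds the
#' `min(k - 1, d)` discriminant coordinates, column-centered, which is full
#' rank by construction and avoids the sum-to-one singularity of raw
#' memberships.
#'
#' @param p a [snp_pca()] result.
#' @param c a [kmeans_bic()] cluster model with `k >= 2`.
#' @return the cluster model with `memberships` replaced by LDA posteriors and
#'   `Q` filled (n x (k-1), centered).
#' @export
dapc_covariates <- function(p, c) {
  stopifnot(inherits(p, "snp_pca"), inherits(c, "cluster_model"))
  if (c$k < 2L) ck_stop("DAPC needs at least 2 clusters")
  if (any(table(c$assignments) < 2L)) ck_stop("every cluster needs >= 2 members")
  X <- p$scores[, seq_len(c$d), drop = FALSE]
  fit <- MASS::lda(X, grouping = factor(c$assignments))
  pr <- predict(fit, as.data.frame(X))
  memberships <- pr$posterior
  rownames(memberships) <- rownames(X)
  # LDA yields min(k - 1, d) discriminants; take all available
  n_ld <- min(c$k - 1L, ncol(pr$x))
  Q <- pr$x[, seq_len(n_ld), drop = FALSE]
  Q <- scale(Q, center = TRUE, scale = FALSE)
  rownames(Q) <- rownames(X)
  colnames(Q) <- paste0("LD", seq_len(ncol(Q)))
  c$memberships <- memberships
  c$Q <- Q
  c
}

# BIC of a spherical Gaussian mixture evaluated at a k-means fit.
kmeans_gmm_bic <- function(X, fit, k) {
  n <- nrow(X); d <- ncol(X)
  s2 <- max(fit$tot.withinss / (n * d), 1e-12)
  pi_c <- as.numeric(table(factor(fit$cluster, levels = seq_len(k)))) / n
  # n x k squared distances to centers
  d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(fit$centers) +
    outer(rep(1, n), rowSums(fit$centers^2))
  d2 <- pmax(d2, 0)
  logdens <- sweep(-d2 / (2 * s2), 2L, log(pi_c), "+") -
    (d / 2) * log(2 * pi * s2)
  mx <- apply(logdens, 1L, max)
  ll <- sum(mx + log(rowSums(exp(logdens - mx))))
  params <- (k - 1) + k * d + 1
  -2 * ll + params * log(n)
}

# Weir-Cockerham (1984) per-locus variance components for a set of demes.
# dosage: n x m complete matrix; pops: integer labels. Returns list(a, b, c)
# vectors of length m (loci with undefined components set to 0).
wc_components <- function(dosage, pops) {
  pops <- as.integer(factor(pops))
  r <- max(pops)
  ni <- tabulate(pops)                      # individuals per pop
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  m <- ncol(dosage)
  pmat <- matrix(0, r, m); hmat <- matrix(0, r, m)
  for (k in seq_len(r)) {
    dk <- dosage[pops == k, , drop = FALSE]
    pmat[k, ] <- colMeans(dk) / 2
    hmat[k, ] <- colMeans(dk == 1)
  }
  pbar <- colSums(pmat * ni) / (r * nbar)
  s2 <- colSums(ni * sweep(pmat, 2L, pbar, "-")^2) / ((r - 1) * nbar)
  hbar <- colSums(hmat * ni) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a[!is.finite(a)] <- 0; b[!is.finite(b)] <- 0; cc[!is.finite(cc)] <- 0
  list(a = a, b = b, c = cc)
}

#' Weir-Cockerham Fst between genetic clusters
#'
#' Multi-locus theta estimated by the ratio of sums of the among-population,
#' among-individual and within-individual variance components across loci, for
#' every cluster pair and for all clusters jointly.
#'
#' @param g a complete [genotype_matrix()].
#' @param c a `cluster_model` (or a vector of cluster labels) with `k >= 2`
#'   and every cluster of size >= 2.
#' @return object of class `fst_table`: `labels`, symmetric `fst` matrix with
#'   `NA` diagonal, and `overall`.
#' @export
pairwise_fst <- function(g, c) {
  stopifnot(inherits(g, "genotype_matrix"))
  labels <- if (inherits(c, "cluster_model")) c$assignments else c
  if (length(labels) != nrow(g$dosage)) ck_stop("one cluster label per accession")
  if (anyNA(g$dosage)) ck_stop("pairwise_fst needs a complete matrix")
  f <- factor(labels)
  if (nlevels(f) < 2L) ck_stop("need at least 2 clusters")
  if (any(table(f) < 2L)) ck_stop("every cluster needs >= 2 members")
  lev <- levels(f)
  k <- length(lev)
  theta <- function(idx, pops) {
    comp <- wc_components(g$dosage[idx, , drop = FALSE], pops)
    denom <- sum(comp$a + comp$b + comp$c)
    if (denom == 0) return(NA_real_)
    sum(comp$a) / denom
  }
  fst <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      idx <- which(f %in% lev[c(i, j)])
      fst[i, j] <- fst[j, i] <- theta(idx, droplevels(f[idx]))
    }
  }
  overall <- theta(seq_along(f), f)
  structure(list(labels = lev, fst = fst, overall = overall),
            class = "fst_table")
}

#' Per-cluster diversity summary table
#'
#' One row per cluster plus a whole-collection row, reporting cluster size,
#' panel share, Shannon index, expected heterozygosity, mean Rogers distance
#' and the rare-allele ratio (rare defined on the whole panel). Metrics are
#' the evaluation-module formulas applied with the cluster as the "core".
#'
#' @param g a complete [genotype_matrix()].
#' @param c a `cluster_model` or label vector.
#' @param d optional precomputed [rogers_distance()] matrix.
#' @param rare_maf rare-allele MAF bound (default 0.10).
#' @return data.frame with columns cluster, n, ratio, SH, He, MRD, RAR.
#' @export
cluster_summary <- function(g, c, d = NULL, rare_maf = 0.10) {
  stopifnot(inherits(g, "genotype_matrix"))
  labels <- if (inherits(c, "cluster_model")) c$assignments else c
  f <- factor(labels)
  if (any(table(f) == 0L)) ck_stop("empty cluster")
  if (is.null(d)) d <- rogers_distance(g)
  n <- nrow(g$dosage)
  rows <- lapply(c(levels(f), ".whole"), function(lv) {
    idx <- if (lv == ".whole") seq_len(n) else which(f == lv)
    data.frame(cluster = if (lv == ".whole") "whole" else lv,
               n = length(idx), ratio = length(idx) / n,
               SH = eval_sh(g, idx), He = eval_he(g, idx),
               MRD = if (length(idx) >= 2L) eval_mrd(d, idx) else 0,
               RAR = eval_rar(g, idx, rare_maf = rare_maf))
  })
  do.call(rbind, rows)
}
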