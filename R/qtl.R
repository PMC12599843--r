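#' Simulate polygenic traits with known causal SNPs
#'
#' For each chromosome, `per_chrom_traits` traits are generated: causal
#' markers are drawn uniformly without replacement from that chromosome,
#' effects are standard normal, and the causal score is rescaled so its
#' realized variance equals `h2_qtl`. A polygenic term is drawn from the
#' kinship covariance (rescaled to variance `h2_poly`) and white noise fills
#' the remainder; the trait is finally standardized to unit variance. The
#' whole simulation is seeded.
#'
#' @param g a complete [genotype_matrix()].
#' @param per_chrom_traits traits per chromosome (default 2).
#' @param qtl_per_trait causal markers per trait (default 31).
#' @param h2_qtl,h2_poly variance shares of the causal score and polygenic
#'   term (defaults 0.4, 0.2; must sum below 1).
#' @param seed RNG seed.
#' @param K optional precomputed [kinship_vanraden()] result.
#' @return object of class `trait_simulation`: `trait_values` (n x T),
#'   `causal_index`, `effects` (per-trait lists), `trait_chrom`, `h2_qtl`,
#'   `h2_poly`, `realized_h2_qtl` (the causal share after standardization;
#'   it deviates from the target only through the sampled covariance between
#'   the causal score and the polygenic term), `seed`.
#' @export
simulate_traits <- function(g, per_chrom_traits = 2L, qtl_per_trait = 31L,
                            h2_qtl = 0.4, h2_poly = 0.2, seed = 1L, K = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (h2_qtl < 0 || h2_poly < 0 || h2_qtl + h2_poly > 1) {
    ck_stop("need h2_qtl + h2_poly <= 1 with non-negative shares")
  }
  chroms <- unique(g$chrom)
  per_chr <- table(g$chrom)
  if (any(per_chr < qtl_per_trait)) {
    ck_stop("some chromosome has fewer than qtl_per_trait markers")
  }
  if (is.null(K)) K <- kinship_vanraden(g)
  n <- nrow(g$dosage)
  ek <- eigen(K$K, symmetric = TRUE)
  ev <- pmax(ek$values, 0)
  n_traits <- length(chroms) * per_chrom_traits
  Y <- matrix(0, n, n_traits,
              dimnames = list(g$accession_ids, paste0("trait", seq_len(n_traits))))
  causal <- vector("list", n_traits)
  effects <- vector("list", n_traits)
  trait_chrom <- character(n_traits)
  realized <- numeric(n_traits)
  h2_noise <- 1 - h2_qtl - h2_poly
  scale_to <- function(x, v) {
    s <- sd(x)
    if (s < 1e-12) return(rep(0, length(x)))
    x / s * sqrt(v)
  }
  with_seed(seed, {
    t_i <- 0L
    for (ch in chroms) {
      idx_ch <- which(g$chrom == ch)
      for (tt in seq_len(per_chrom_traits)) {
        t_i <- t_i + 1L
        caus <- sort(sample(idx_ch, qtl_per_trait))
        b <- rnorm(qtl_per_trait)
        score <- as.numeric(g$dosage[, caus, drop = FALSE] %*% b)
        score <- scale_to(score, h2_qtl)
        poly <- as.numeric(ek$vectors %*% (sqrt(ev) * rnorm(n)))
        poly <- scale_to(poly, h2_poly)
        noise <- scale_to(rnorm(n), h2_noise)
        y <- score + poly + noise
        Y[, t_i] <- y / sd(y)
        causal[[t_i]] <- caus
        effects[[t_i]] <- b
        trait_chrom[t_i] <- ch
        realized[t_i] <- h2_qtl / var(y)
      }
    }
  })
  structure(list(trait_values = Y, causal_index = causal, effects = effects,
                 trait_chrom = trait_chrom, h2_qtl = h2_qtl,
                 h2_poly = h2_poly, realized_h2_qtl = realized, seed = seed),
            class = "trait_simulation")
}

#' Mixed-linear-model association scan
#'
#' Fits the null model `y = mu 1 + Q c + g + e` with `g ~ N(0, K sigma_g^2)`
#' and `e ~ N(0, I sigma_e^2)` by REML on the eigendecomposition of `K`
#' (profiled over `delta = sigma_e^2 / sigma_g^2`), then score-tests each
#' SNP with the variance components fixed at their null estimates (the
#' P3D/EMMAX approach). A single decomposition is reused across SNPs.
#'
#' @param g a complete [genotype_matrix()].
#' @param y numeric trait vector of length n.
#' @param Q covariate matrix (n x c, full column rank) or NULL.
#' @param K a [kinship_vanraden()] result (non-PSD input is ridged with a
#'   warning).
#' @param threshold optional significance level; when given, the
#'   `significant` marker set is filled.
#' @return object of class `gwas_result`: `pvalues`, `beta` (per marker),
#'   `sigma_g2`, `sigma_e2`, `delta`, `lambda_gc`, `threshold`,
#'   `significant`, plus the marker map.
#' @export
mlm_gwas <- function(g, y, Q = NULL, K, threshold = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$dosage)
  if (length(y) != n) ck_stop("y must have one value per accession")
  X0 <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    X0 <- cbind(X0, Q)
  }
  if (qr(X0)$rank < ncol(X0)) ck_stop("collinear covariate column in Q")
  Km <- K$K
  ek <- eigen(Km, symmetric = TRUE)
  if (min(ek$values) < -1e-8 * max(abs(ek$values))) {
    warning("kinship matrix not PSD; adding ridge", call. = FALSE)
    Km <- Km + diag(1e-6 - min(ek$values), n)
    ek <- eigen(Km, symmetric = TRUE)
  }
  lam <- pmax(ek$values, 0)
  Ut <- t(ek$vectors)
  ys <- as.numeric(Ut %*% y)
  X0s <- Ut %*% X0
  p0 <- ncol(X0)
  reml_neg <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (lam + delta)
    sw <- sqrt(w)
    Xw <- X0s * sw
    yw <- ys * sw
    fit <- qr(Xw)
    res <- qr.resid(fit, yw)
    rss <- sum(res^2)
    sg2 <- rss / (n - p0)
    xtx_w <- crossprod(Xw)
    xtx <- crossprod(X0s)
    ll <- -0.5 * ((n - p0) * log(2 * pi * sg2) + sum(log(lam + delta)) +
                    determinant(xtx_w, logarithm = TRUE)$modulus -
                    determinant(xtx, logarithm = TRUE)$modulus + (n - p0))
    -as.numeric(ll)
  }
  opt <- optimize(reml_neg, interval = c(-12, 12))
  delta <- exp(opt$minimum)
  w <- 1 / (lam + delta)
  sw <- sqrt(w)
  Xw <- X0s * sw
  yw <- ys * sw
  fit0 <- qr(Xw)
  sg2 <- sum(qr.resid(fit0, yw)^2) / (n - p0)
  se2 <- delta * sg2
  # rotate and weight all SNPs at once, then project out the null design
  Gs <- (Ut %*% g$dosage) * sw
  ey <- qr.resid(fit0, yw)
  Ex <- qr.resid(fit0, Gs)
  xy <- colSums(Ex * ey)
  xx <- colSums(Ex^2)
  beta <- ifelse(xx > 1e-12, xy / xx, 0)
  stat <- ifelse(xx > 1e-12, xy^2 / (sg2 * xx), 0)
  pv <- pchisq(stat, df = 1, lower.tail = FALSE)
  pv[pv <= 0] <- .Machine$double.xmin
  names(pv) <- g$marker_ids
  res <- structure(list(pvalues = pv, beta = setNames(beta, g$marker_ids),
                        sigma_g2 = sg2, sigma_e2 = se2, delta = delta,
                        lambda_gc = NA_real_, threshold = threshold,
                        significant = character(0),
                        chrom = g$chrom, pos = g$pos,
                        marker_ids = g$marker_ids),
                   class = "gwas_result")
  res$lambda_gc <- genomic_lambda(res)
  if (!is.null(threshold)) {
    res$significant <- g$marker_ids[pv < threshold]
  }
  res
}

#' Genomic-control inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / 0.4549364`, the ratio of the observed
#' median association chi-square to its null median. Values near 1 indicate
#' calibrated tests.
#'
#' @param r a [mlm_gwas()] result, or a numeric vector of p-values.
#' @return scalar lambda.
#' @export
genomic_lambda <- function(r) {
  p <- if (inherits(r, "gwas_result")) r$pvalues else as.numeric(r)
  if (length(p) < 100L) {
    warning("fewer than 100 tests; lambda is noisy", call. = FALSE)
  }
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}

#' Effective-number-of-tests significance threshold
#'
#' Per chromosome, the eigenvalues of the marker-marker correlation matrix
#' are computed and the effective test count is the smallest number of
#' leading eigenvalues whose sum exceeds `c_explained` of the trace; the
#' genome-wide effective count is the sum over chromosomes and the threshold
#' is `alpha / Meff` (the simpleM construction).
#'
#' @param g a complete [genotype_matrix()].
#' @param c_explained variance fraction defining the effective count
#'   (default 0.995).
#' @param alpha genome-wide level (default 0.05).
#' @return the per-test significance threshold, with attribute `meff`.
#' @export
gao_threshold <- function(g, c_explained = 0.995, alpha = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (ncol(g$dosage) < 2L) ck_stop("need at least 2 markers")
  if (anyNA(g$dosage)) ck_stop("gao_threshold needs a complete matrix")
  meff <- 0L
  for (ch in unique(g$chrom)) {
    idx <- which(g$chrom == ch)
    if (length(idx) == 1L) { meff <- meff + 1L; next }
    cc <- suppressWarnings(cor(g$dosage[, idx, drop = FALSE]))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    cum <- cumsum(ev)
    meff <- meff + which(cum >= c_explained * sum(ev))[1]
  }
  structure(alpha / meff, meff = meff)
}

#' Ratio of core-recovered QTLs to whole-collection QTLs
#'
#' Per trait, a significant marker of the core scan counts as "common" when a
#' significant whole-collection marker of the same trait lies within
#' `window_bp` (0 means exact marker identity). The returned ratio pools
#' traits: total common core hits over total whole-collection hits.
#'
#' @param whole,core lists of [mlm_gwas()] results (same traits, same map),
#'   each with `significant` filled.
#' @param window_bp matching window in base pairs (default 0).
#' @return proportion (can exceed 1 only if a core finds several hits near
#'   one whole-collection hit with a wide window; 0 windows keep it in
#'   \[0, 1\]).
#' @export
qtl_overlap <- function(whole, core, window_bp = 0) {
  if (inherits(whole, "gwas_result")) whole <- list(whole)
  if (inherits(core, "gwas_result")) core <- list(core)
  if (length(whole) != length(core)) ck_stop("trait lists differ in length")
  n_whole <- sum(vapply(whole, function(r) length(r$significant), 0L))
  if (n_whole == 0L) ck_stop("no whole-collection QTLs; ratio undefined")
  n_common <- 0L
  for (t in seq_along(whole)) {
    ws <- whole[[t]]$significant
    cs <- core[[t]]$significant
    if (length(cs) == 0L || length(ws) == 0L) next
    if (window_bp == 0) {
      n_common <- n_common + sum(cs %in% ws)
    } else {
      wi <- match(ws, whole[[t]]$marker_ids)
      ci <- match(cs, core[[t]]$marker_ids)
      for (j in ci) {
        hit <- any(core[[t]]$chrom[j] == whole[[t]]$chrom[wi] &
                     abs(core[[t]]$pos[j] - whole[[t]]$pos[wi]) <= window_bp)
        if (hit) n_common <- n_common + 1L
      }
    }
  }
  n_common / n_whole
}

#' QTL-recovery benchmark over a set of core selections
#'
#' Runs the mixed-model scan for every simulated trait on the whole panel
#' once, then on each core collection (subsetting the trait vector, the
#' whole-panel structure covariates, the kinship and the genotypes to the
#' core members; covariates are not recomputed so the structure correction
#' stays comparable across cores). Significance uses the simpleM threshold,
#' recomputed on each core's genotype block. Reports the per-core common-QTL
#' ratio and per-trait inflation factors.
#'
#' @param g a complete [genotype_matrix()].
#' @param traits a [simulate_traits()] result.
#' @param selections list of [optimize_core()] results (or a single one).
#' @param clusters a [dapc_covariates()] cluster model supplying `Q`
#'   (NULL for no covariates).
#' @param K a [kinship_vanraden()] result.
#' @param alpha,c_explained threshold parameters passed to [gao_threshold()].
#' @param window_bp QTL matching window (default 0, exact identity).
#' @param labels optional method label per selection.
#' @return object of class `benchmark_report`: `per_core` data.frame (method,
#'   replicate, qtl_ratio, mean core lambda), `aggregate` (mean/sd per
#'   method), `whole_lambda` per trait, `whole_scans`, `n_whole_qtl`.
#' @export
run_benchmark <- function(g, traits, selections, clusters = NULL, K,
                          alpha = 0.05, c_explained = 0.995, window_bp = 0,
                          labels = NULL) {
  stopifnot(inherits(traits, "trait_simulation"))
  if (inherits(selections, "core_selection")) selections <- list(selections)
  Q <- if (!is.null(clusters)) clusters$Q else NULL
  thr_whole <- gao_threshold(g, c_explained, alpha)
  n_traits <- ncol(traits$trait_values)
  whole <- lapply(seq_len(n_traits), function(t) {
    mlm_gwas(g, traits$trait_values[, t], Q = Q, K = K, threshold = thr_whole)
  })
  n_whole_qtl <- sum(vapply(whole, function(r) length(r$significant), 0L))
  if (is.null(labels)) {
    labels <- vapply(selections, function(s) {
      paste(s$config$criteria$name, collapse = "_")
    }, "")
  }
  rows <- vector("list", length(selections))
  for (i in seq_along(selections)) {
    sel <- selections[[i]]
    idx <- match(sel$selected_ids, g$accession_ids)
    if (anyNA(idx)) ck_stop("selection contains accessions outside the panel")
    if (length(idx) < (if (is.null(Q)) 0L else ncol(Q)) + 2L) {
      ck_stop("core smaller than covariate count + 2")
    }
    g_c <- subset_genotypes(g, accessions = idx)
    K_c <- structure(list(ids = g_c$accession_ids, K = K$K[idx, idx]),
                     class = "kinship_matrix")
    Q_c <- if (!is.null(Q)) Q[idx, , drop = FALSE] else NULL
    thr_c <- gao_threshold(g_c, c_explained, alpha)
    core <- lapply(seq_len(n_traits), function(t) {
      mlm_gwas(g_c, traits$trait_values[idx, t], Q = Q_c, K = K_c,
               threshold = thr_c)
    })
    rows[[i]] <- data.frame(
      method = labels[i],
      replicate = i,
      qtl_ratio = qtl_overlap(whole, core, window_bp = window_bp),
      mean_lambda = mean(vapply(core, function(r) r$lambda_gc, 0)))
  }
  per_core <- do.call(rbind, rows)
  per_core$replicate <- stats::ave(seq_len(nrow(per_core)), per_core$method,
                                   FUN = seq_along)
  agg <- do.call(rbind, lapply(split(per_core, per_core$method), function(d) {
    data.frame(method = d$method[1], mean_qtl_ratio = mean(d$qtl_ratio),
               sd_qtl_ratio = if (nrow(d) > 1) sd(d$qtl_ratio) else NA_real_)
  }))
  rownames(agg) <- NULL
  structure(list(per_core = per_core, aggregate = agg,
                 whole_lambda = vapply(whole, function(r) r$lambda_gc, 0),
                 whole_scans = whole, n_whole_qtl = n_whole_qtl),
            class = "benchmark_report")
}
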