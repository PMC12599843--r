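#' Generate a structured inbred-line SNP panel (Balding-Nichols model)
#'
#' Ancestral allele frequencies are drawn uniformly from `maf_range`; each
#' cluster's frequencies are Beta-distributed around them with the
#' Balding-Nichols parameterization `Beta(p(1-F)/F, (1-p)(1-F)/F)`, so the
#' divergence parameter `fst` is (in expectation) the Weir-Cockerham theta of
#' the panel. Genotypes are drawn per cluster with inbreeding coefficient
#' `selfing` (heterozygote probability `2pq(1 - selfing)`), so a panel of
#' inbred lines has almost no heterozygous calls. Within chromosomes an
#' optional first-order autoregressive Gaussian copula (`rho`) correlates
#' adjacent markers to give LD pruning and effective-test-count estimation
#' realistic structure; the chain resets at chromosome boundaries and leaves
#' the per-marker marginals untouched. Markers are split evenly across
#' chromosomes with sorted uniform positions.
#'
#' @param n_per_cluster integer vector of cluster sizes.
#' @param fst divergence parameter in (0, 1).
#' @param m marker count.
#' @param n_chrom chromosome count.
#' @param maf_range ancestral allele-frequency bounds (default c(0.1, 0.9)).
#' @param selfing inbreeding coefficient in \[0, 1\] (default 0.98).
#' @param rho adjacent-marker latent correlation (default 0.6; 0 disables).
#' @param seed RNG seed.
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth` (a
#'   `cluster_model` with the generating labels).
#' @export
generate_panel <- function(n_per_cluster, fst, m, n_chrom = 1L,
                           maf_range = c(0.1, 0.9), selfing = 0.98,
                           rho = 0.6, seed = 1L) {
  if (fst <= 0 || fst >= 1) ck_stop("fst must be in (0, 1)")
  if (sum(n_per_cluster) < 2L) ck_stop("need at least 2 accessions")
  if (m < n_chrom) ck_stop("need at least one marker per chromosome")
  if (selfing < 0 || selfing > 1) ck_stop("selfing must be in [0, 1]")
  k <- length(n_per_cluster)
  n <- sum(n_per_cluster)
  chrom_sizes <- diff(round(seq(0, m, length.out = n_chrom + 1L)))
  chrom <- rep(paste0("chr", sprintf("%02d", seq_len(n_chrom))), chrom_sizes)
  with_seed(seed, {
    pos <- unlist(lapply(chrom_sizes, function(s) {
      sort(sample.int(1e8, s))
    }), use.names = FALSE)
    p0 <- runif(m, maf_range[1], maf_range[2])
    shape_scale <- (1 - fst) / fst
    pk <- matrix(0, k, m)
    for (cl in seq_len(k)) {
      pk[cl, ] <- rbeta(m, p0 * shape_scale, (1 - p0) * shape_scale)
    }
    pk <- pmin(pmax(pk, 1e-4), 1 - 1e-4)
    labels <- rep(seq_len(k), n_per_cluster)
    dosage <- matrix(0, n, m)
    chrom_start <- cumsum(c(1L, chrom_sizes))[seq_len(n_chrom)]
    for (cl in seq_len(k)) {
      rows <- which(labels == cl)
      nc <- length(rows)
      # latent AR(1) per individual, reset at chromosome starts
      Z <- matrix(rnorm(nc * m), nc, m)
      if (rho > 0) {
        sq <- sqrt(1 - rho^2)
        is_start <- rep(FALSE, m); is_start[chrom_start] <- TRUE
        for (j in 2:m) {
          if (!is_start[j]) Z[, j] <- rho * Z[, j - 1L] + sq * Z[, j]
        }
      }
      U <- pnorm(Z)
      p <- pk[cl, ]; q <- 1 - p
      f <- selfing
      p0g <- q^2 + f * p * q        # P(dosage 0)
      p1g <- 2 * p * q * (1 - f)    # P(dosage 1)
      t0 <- matrix(p0g, nc, m, byrow = TRUE)
      t1 <- matrix(p0g + p1g, nc, m, byrow = TRUE)
      dosage[rows, ] <- (U > t0) + (U > t1)
    }
    ids <- sprintf("acc%04d", seq_len(n))
    mk <- sprintf("%s_%d", chrom, pos)
    g <- genotype_matrix(dosage, chrom, pos, accession_ids = ids,
                         marker_ids = mk)
    assignments <- setNames(labels, ids)
    memberships <- matrix(0, n, k, dimnames = list(ids, paste0("c", seq_len(k))))
    memberships[cbind(seq_len(n), labels)] <- 1
    truth <- structure(list(k = k, assignments = assignments,
                            memberships = memberships,
                            bic_curve = NULL, centers = NULL,
                            d = NA_integer_, Q = NULL),
                       class = "cluster_model")
    list(genotypes = g, truth = truth)
  })
}

#' Generate passport-style traits tied to cluster structure
#'
#' Categorical traits get cluster-dependent category probabilities (a shared
#' baseline tilted per cluster by `cluster_effect` on the log scale);
#' quantitative traits are cluster mean shifts plus unit Gaussian noise.
#' `cluster_effect = 0` makes every trait independent of structure.
#'
#' @param truth a `cluster_model` (e.g. from [generate_panel()]).
#' @param n_cat,n_quant numbers of categorical and quantitative traits.
#' @param cluster_effect association strength (default 1).
#' @param seed RNG seed.
#' @return data.frame of traits, accession ids as row names; categorical
#'   columns are factors.
#' @export
generate_traits <- function(truth, n_cat = 10L, n_quant = 2L,
                            cluster_effect = 1, seed = 1L) {
  stopifnot(inherits(truth, "cluster_model"))
  labels <- truth$assignments
  n <- length(labels)
  k <- truth$k
  with_seed(seed, {
    out <- list()
    for (j in seq_len(n_cat)) {
      n_lev <- sample(2:5, 1L)
      base <- rgamma(n_lev, 1)
      base <- base / sum(base)
      probs <- matrix(0, k, n_lev)
      for (cl in seq_len(k)) {
        tilt <- exp(cluster_effect * rnorm(n_lev))
        pr <- base * tilt
        probs[cl, ] <- pr / sum(pr)
      }
      vals <- vapply(seq_len(n), function(i) {
        sample.int(n_lev, 1L, prob = probs[labels[i], ])
      }, 0L)
      out[[paste0("cat", j)]] <- factor(paste0("L", vals),
                                        levels = paste0("L", seq_len(n_lev)))
    }
    for (j in seq_len(n_quant)) {
      mu <- rnorm(k)
      out[[paste0("quant", j)]] <- cluster_effect * mu[labels] + rnorm(n)
    }
    df <- as.data.frame(out)
    rownames(df) <- names(labels)
    df
  })
}

#' The package's canonical desk-scale panel
#'
#' Six Balding-Nichols clusters of sizes 140/190/45/45/120/60 (n = 600, the
#' cluster shares mirroring a worldwide flax germplasm: roughly 23/31/7/8/20/11
#' percent), 3,000 SNPs on 15 chromosomes (200 each), divergence 0.19,
#' inbreeding coefficient 0.98, plus 10 categorical and 2 quantitative
#' passport-style traits. All cross-module tests and the acceptance runs use
#' this fixture.
#'
#' @param seed RNG seed.
#' @return list with `genotypes`, `traits`, `truth`.
#' @export
standard_fixture <- function(seed = 1L) {
  panel <- generate_panel(n_per_cluster = c(140L, 190L, 45L, 45L, 120L, 60L),
                          fst = 0.19, m = 3000L, n_chrom = 15L,
                          maf_range = c(0.1, 0.9), selfing = 0.98,
                          rho = 0.6, seed = seed)
  traits <- generate_traits(panel$truth, n_cat = 10L, n_quant = 2L,
                            cluster_effect = 1,
                            seed = as.integer(seed) + 1000L)
  list(genotypes = panel$genotypes, traits = traits, truth = panel$truth)
}
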