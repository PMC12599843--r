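test_that("simulate_traits hits its variance targets and bookkeeping", {
  g <- mini_panel()$genotypes
  K <- mini_aux()$kinship
  sim <- simulate_traits(g, per_chrom_traits = 2, qtl_per_trait = 5,
                         h2_qtl = 0.4, h2_poly = 0.2, seed = 4, K = K)
  expect_equal(ncol(sim$trait_values), 8L)  # 4 chromosomes x 2 traits
  expect_equal(sum(lengths(sim$causal_index)), 4 * 2 * 5)
  for (t in seq_along(sim$causal_index)) {
    expect_false(anyDuplicated(sim$causal_index[[t]]) > 0)
    expect_true(all(g$chrom[sim$causal_index[[t]]] == sim$trait_chrom[t]))
  }
  expect_equal(apply(sim$trait_values, 2, sd), rep(1, 8), ignore_attr = TRUE,
               tolerance = 1e-10)
  # realized causal variance share near target across seeds; the recorded
  # share is definitional, the regression estimate corroborates it but also
  # absorbs the score/polygenic sampling covariance, hence the looser band
  for (s in 1:5) {
    sm <- simulate_traits(g, 1, 5, 0.4, 0.2, seed = s, K = K)
    expect_lt(abs(sm$realized_h2_qtl[1] - 0.4), 0.1)
    score <- as.numeric(g$dosage[, sm$causal_index[[1]]] %*% sm$effects[[1]])
    b_hat <- cov(sm$trait_values[, 1], score) / var(score)
    expect_lt(abs(b_hat^2 * var(score) - 0.4), 0.2)
  }
  # zero-noise, zero-polygenic limit: trait is an exact linear function
  sm0 <- simulate_traits(g, 1, 5, h2_qtl = 1, h2_poly = 0, seed = 2, K = K)
  score <- as.numeric(g$dosage[, sm0$causal_index[[1]]] %*% sm0$effects[[1]])
  expect_lt(sum(lm(sm0$trait_values[, 1] ~ score)$residuals^2), 1e-9)
  expect_error(simulate_traits(g, 1, 500), "fewer than")
  same <- simulate_traits(g, 1, 5, seed = 4, K = K)
  again <- simulate_traits(g, 1, 5, seed = 4, K = K)
  expect_identical(same$trait_values, again$trait_values)
})

test_that("mlm_gwas is calibrated under the null and finds a planted signal", {
  set.seed(61)
  n <- 150; m <- 800
  pr <- runif(m, 0.1, 0.9)
  d <- matrix(rbinom(n * m, 2, rep(pr, each = n)), n, m)
  g <- genotype_matrix(d, rep("1", m), seq_len(m))
  Kid <- structure(list(ids = g$accession_ids, K = diag(n)),
                   class = "kinship_matrix")
  y <- rnorm(n)
  r <- mlm_gwas(g, y, Q = NULL, K = Kid)
  expect_gt(suppressWarnings(ks.test(r$pvalues, "punif"))$p.value, 0.01)
  # planted large effect: genome-wide minimum p at the causal SNP
  x <- d[, 17]
  y2 <- x * sqrt(0.5 / var(x)) + rnorm(n, sd = sqrt(0.5))
  r2 <- mlm_gwas(g, y2, Q = NULL, K = Kid)
  expect_equal(which.min(r2$pvalues), 17L, ignore_attr = TRUE)
})

test_that("mlm_gwas with K = I reduces to the OLS score test", {
  set.seed(62)
  n <- 80; m <- 60
  pr <- runif(m, 0.2, 0.8)
  d <- matrix(rbinom(n * m, 2, rep(pr, each = n)), n, m)
  g <- genotype_matrix(d, rep("1", m), seq_len(m))
  Kid <- structure(list(ids = g$accession_ids, K = diag(n)),
                   class = "kinship_matrix")
  y <- rnorm(n)
  r <- suppressWarnings(mlm_gwas(g, y, Q = NULL, K = Kid))  # < 100 tests
  # closed-form OLS score test with null variance RSS0 / (n - 1)
  yc <- y - mean(y)
  s2 <- sum(yc^2) / (n - 1)
  p_ref <- vapply(seq_len(m), function(j) {
    xc <- d[, j] - mean(d[, j])
    stat <- sum(xc * yc)^2 / (s2 * sum(xc^2))
    pchisq(stat, 1, lower.tail = FALSE)
  }, 0)
  expect_equal(unname(r$pvalues), p_ref, tolerance = 1e-6)
})

test_that("mlm_gwas is equivariant under joint accession permutation", {
  g <- mini_panel()$genotypes
  aux <- mini_aux()
  y <- rnorm(length(g$accession_ids))
  r1 <- mlm_gwas(g, y, Q = aux$clusters$Q, K = aux$kinship)
  set.seed(3); perm <- sample(length(y))
  gp <- subset_genotypes(g, accessions = perm)
  Kp <- structure(list(ids = gp$accession_ids,
                       K = aux$kinship$K[perm, perm]), class = "kinship_matrix")
  r2 <- mlm_gwas(gp, y[perm], Q = aux$clusters$Q[perm, , drop = FALSE], K = Kp)
  expect_equal(r1$pvalues, r2$pvalues, tolerance = 1e-6)
  expect_error(mlm_gwas(g, y, Q = cbind(1, aux$clusters$Q), K = aux$kinship),
               "collinear")
})

test_that("genomic_lambda has its fixed points and monotonicity", {
  expect_equal(genomic_lambda(rep(0.5, 200)), 1, tolerance = 1e-6)
  inflated <- 0L
  in_band <- 0L
  for (s in 1:5) {
    set.seed(70 + s)
    p <- runif(10000)
    l <- genomic_lambda(p)
    if (l >= 0.95 && l <= 1.05) in_band <- in_band + 1L
    if (genomic_lambda(p / 2) > l) inflated <- inflated + 1L
  }
  expect_gte(in_band, 4L)
  expect_equal(inflated, 5L)
  expect_warning(genomic_lambda(runif(50)), "noisy")
})

test_that("gao_threshold counts effective tests from correlation spectra", {
  x1 <- c(0, 0, 2, 2, 0, 2); x2 <- c(0, 2, 0, 2, 2, 0)  # orthogonal
  g4 <- genotype_matrix(cbind(a = x1, b = x1, c = x2, d = x2),
                        rep("1", 4), 1:4)
  thr <- gao_threshold(g4, alpha = 0.05)
  expect_equal(attr(thr, "meff"), 2L)  # eigenvalues {2, 2, 0, 0}
  g2 <- genotype_matrix(cbind(a = x1, b = x1), c("1", "1"), 1:2)
  thr2 <- gao_threshold(g2, alpha = 0.05)
  expect_equal(attr(thr2, "meff"), 1L)
  expect_equal(as.numeric(thr2), 0.05)
  gi <- genotype_matrix(cbind(a = x1, b = x2), c("1", "1"), 1:2)
  expect_equal(attr(gao_threshold(gi), "meff"), 2L)  # independent markers
  # matches a brute-force full-matrix computation on one chromosome
  g <- subset_genotypes(mini_panel()$genotypes,
                        markers = which(mini_panel()$genotypes$chrom == "chr01"))
  ev <- eigen(cor(g$dosage), symmetric = TRUE, only.values = TRUE)$values
  meff_ref <- which(cumsum(pmax(ev, 0)) >= 0.995 * sum(pmax(ev, 0)))[1]
  expect_equal(attr(gao_threshold(g), "meff"), meff_ref)
})

test_that("qtl_overlap pools common hits over traits", {
  mk <- paste0("m", 1:6)
  mk_res <- function(sig) {
    structure(list(significant = sig, marker_ids = mk,
                   chrom = rep("1", 6), pos = 1:6), class = "gwas_result")
  }
  expect_equal(qtl_overlap(mk_res(mk[1:4]), mk_res(mk[1:4])), 1)
  expect_equal(qtl_overlap(mk_res(mk[1:3]), mk_res(mk[4:6])), 0)
  expect_equal(qtl_overlap(mk_res(mk[1:4]), mk_res(mk[1:2])), 0.5)
  # windowed matching
  w <- mk_res("m1"); cc <- mk_res("m2")
  expect_equal(qtl_overlap(w, cc, window_bp = 0), 0)
  expect_equal(qtl_overlap(w, cc, window_bp = 5), 1)
  expect_error(qtl_overlap(mk_res(character(0)), mk_res(mk[1])), "undefined")
})

test_that("run_benchmark: whole panel recovers everything; rows per core", {
  g <- mini_panel()$genotypes
  aux <- mini_aux()
  sim <- simulate_traits(g, per_chrom_traits = 1, qtl_per_trait = 5,
                         h2_qtl = 0.5, h2_poly = 0.2, seed = 10,
                         K = aux$kinship)
  whole_sel <- as_selection(g$accession_ids, "whole")
  set.seed(31)
  small_sel <- as_selection(sample(g$accession_ids, 30), "small")
  br <- run_benchmark(g, sim, list(whole_sel, small_sel),
                      clusters = aux$clusters, K = aux$kinship,
                      labels = c("whole", "small"))
  expect_equal(nrow(br$per_core), 2L)
  expect_gt(br$n_whole_qtl, 0L)
  expect_equal(br$per_core$qtl_ratio[br$per_core$method == "whole"], 1)
  expect_lt(br$per_core$qtl_ratio[br$per_core$method == "small"], 1)
})
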