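make_dist <- function(d, ids = NULL) {
  if (is.null(ids)) ids <- paste0("a", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d), class = "rogers_dist")
}

test_that("crit_ane averages nearest-entry distances over all accessions", {
  # points 0, 1, 10 with scaled distances
  d <- make_dist(as.matrix(dist(c(0, 1, 10))) / 20)
  expect_equal(crit_ane(d, 1L), mean(c(0, 1 / 20, 10 / 20)))
  expect_equal(crit_ane(d, 1:3), 0)  # all selected
  # adding an entry never increases A-NE
  set.seed(3)
  dd <- make_dist(as.matrix(dist(runif(8))))
  for (s in list(c(1), c(1, 4), c(2, 5, 7))) {
    for (add in setdiff(1:8, s)) {
      expect_lte(crit_ane(dd, c(s, add)), crit_ane(dd, s) + 1e-12)
    }
  }
  expect_error(crit_ane(d, integer(0)), "empty")
})

test_that("crit_ene is the mean distance to the closest other entry", {
  d0 <- make_dist(matrix(0, 2, 2))
  expect_equal(crit_ene(d0, 1:2), 0)  # identical pair
  tri <- make_dist(matrix(0.4, 3, 3) - diag(0.4, 3))
  expect_equal(crit_ene(tri, 1:3), 0.4)
  # 4-point line: best 2-subset by E-NE is the two endpoints
  line <- make_dist(as.matrix(dist(c(0, 1, 2, 10))) / 20)
  pairs <- utils::combn(4, 2, simplify = FALSE)
  vals <- vapply(pairs, function(s) crit_ene(line, s), 0)
  expect_equal(pairs[[which.max(vals)]], c(1L, 4L))
  expect_error(crit_ene(d0, 1L), "at least 2")
})

test_that("selection criteria agree with the evaluation formulas", {
  g <- mini_panel()$genotypes
  set.seed(12)
  for (k in c(5, 20)) {
    s <- sample(length(g$accession_ids), k)
    expect_equal(crit_he(g, s), eval_he(g, s), tolerance = 1e-12)
    expect_equal(crit_sh(g, s), eval_sh(g, s), tolerance = 1e-12)
    expect_equal(crit_cv(g, s), eval_cv(g, s), tolerance = 1e-12)
  }
  expect_equal(crit_cv(g, seq_along(g$accession_ids)), 1)
  mono <- genotype_matrix(rbind(c(0, 2), c(0, 2), c(2, 0)), c("1", "1"), 1:2)
  expect_equal(crit_he(mono, 1:2), 0)
  expect_equal(crit_sh(mono, 1:2), 0)
})

test_that("crit_cdmean is bounded, symmetric under clones, spreads families", {
  tiny <- tiny_panel()
  K <- tiny$aux$kinship
  cd <- suppressWarnings(crit_cdmean(K, c(1, 3, 7)))
  expect_gte(cd, 0); expect_lte(cd, 1)
  # duplicated individual: swapping one clone for the other changes nothing
  d <- tiny$g$dosage[c(1:7, 1), ]
  rownames(d) <- paste0("s", 1:8)
  keep <- which(apply(d, 2, function(x) length(unique(x)) > 1))
  g2 <- genotype_matrix(d[, keep], tiny$g$chrom[keep], tiny$g$pos[keep])
  K2 <- kinship_vanraden(g2)
  v1 <- suppressWarnings(crit_cdmean(K2, c(1L, 3L, 5L)))
  v2 <- suppressWarnings(crit_cdmean(K2, c(8L, 3L, 5L)))  # 8 is clone of 1
  expect_equal(v1, v2, tolerance = 1e-8)
  # two-family block structure: the best 2-subset takes one entry per family
  fam <- rbind(matrix(c(0, 0, 2, 2), 4, 8, byrow = FALSE)[, c(1, 1, 1, 1, 2, 2, 2, 2)])
  set.seed(8)
  fam <- fam + matrix(sample(0:2, 32, TRUE), 4, 8) * 0  # deterministic blocks
  fam[1:2, 1:4] <- 2; fam[3:4, 1:4] <- 0
  fam[1:2, 5:8] <- 0; fam[3:4, 5:8] <- 2
  fam[, 1] <- c(2, 2, 0, 2)  # break exact duplication a little
  gf <- genotype_matrix(fam, rep("1", 8), 1:8 * 10L)
  Kf <- kinship_vanraden(gf)
  subs <- utils::combn(4, 2, simplify = FALSE)
  vals <- vapply(subs, function(s) suppressWarnings(crit_cdmean(Kf, s)), 0)
  best <- subs[[which.max(vals)]]
  expect_equal(sort(c(sum(best <= 2), sum(best >= 3))), c(1L, 1L))
})

test_that("crit_avg_grm enumerates to one-per-family and is permutation-safe", {
  ids <- paste0("a", 1:4)
  K <- structure(list(ids = ids,
                      K = matrix(c(1, .9, 0, 0, .9, 1, 0, 0,
                                   0, 0, 1, .8, 0, 0, .8, 1), 4, 4,
                                 dimnames = list(ids, ids))),
                 class = "kinship_matrix")
  subs <- utils::combn(4, 2, simplify = FALSE)
  vals <- vapply(subs, function(s) crit_avg_grm(K, s), 0)
  best <- subs[[which.min(vals)]]
  expect_true(xor(best[1] <= 2, best[2] <= 2))
  expect_equal(crit_avg_grm(K, c(1, 2)), 0.9)  # near-clones
  expect_equal(crit_avg_grm(K, c(3, 1, 4)), crit_avg_grm(K, c(4, 3, 1)))
  expect_error(crit_avg_grm(K, 2L), "at least 2")
})

test_that("crit_dopt: rank deficiency, q = 1 extremes, order invariance", {
  scores <- cbind(c(-3, -1, 0, 0.5, 2, 4), c(1, -1, 0, 2, -2, 1))
  rownames(scores) <- paste0("a", 1:6)
  p <- structure(list(scores = scores, n_significant = 2L), class = "snp_pca")
  dup <- p
  dup$scores <- rbind(scores, a7 = scores[1, ])
  expect_identical(crit_dopt(dup, c(1L, 7L), q = 2), -Inf)
  subs <- utils::combn(6, 2, simplify = FALSE)
  vals <- vapply(subs, function(s) crit_dopt(p, s, q = 1), 0)
  expect_equal(sort(subs[[which.max(vals)]]), c(1L, 6L))  # largest |PC1|
  expect_equal(crit_dopt(p, c(2, 5, 6), q = 2), crit_dopt(p, c(6, 2, 5), q = 2))
})

test_that("combine_objectives normalizes, flips, weights and clamps", {
  bounds <- list(SH = c(0, 1), ANE = c(0, 0.5))
  crit <- data.frame(name = c("SH", "ANE"), weight = c(0.5, 0.5))
  # equal normalized values -> combined equals that value
  v <- combine_objectives(crit, c(SH = 0.3, ANE = 0.35), bounds)
  expect_equal(v, 0.5 * 0.3 + 0.5 * (1 - 0.7))
  one <- combine_objectives(data.frame(name = "SH", weight = 1),
                            c(SH = 0.8), bounds)
  expect_equal(one, 0.8)
  expect_warning(
    clamped <- combine_objectives(data.frame(name = "SH", weight = 1),
                                  c(SH = 1.4), bounds),
    "clamped")
  expect_equal(clamped, 1)
  # a dominated subset scores below its dominator
  lo <- combine_objectives(crit, c(SH = 0.2, ANE = 0.4), bounds)
  hi <- combine_objectives(crit, c(SH = 0.6, ANE = 0.1), bounds)
  expect_lt(lo, hi)
  expect_error(combine_objectives(data.frame(name = "XX", weight = 1),
                                  c(XX = 1), list(XX = c(0, 1))), "unknown")
})

test_that("all optimizers reach the exhaustive optimum on small instances", {
  tiny <- tiny_panel()
  g <- tiny$g; aux <- tiny$aux
  for (k in c(3L, 4L)) {
    for (crit in c("ANE", "ENE", "HE", "SH", "CV", "CDmean", "AvgGRM", "Dopt")) {
      best <- enumerate_best(g, aux, crit, k)$best
      for (optm in c("random_descent", "local_search", "hill_climb", "genetic")) {
        cfg <- selection_config(k, crit, optm, seed = 11L, n_restarts = 20L,
                                iterations = if (optm == "genetic") 40L else 400L,
                                dopt_q = 2L)
        res <- suppressWarnings(optimize_core(g, aux, cfg))
        expect_equal(res$final_value, best, tolerance = 1e-9,
                     label = paste(crit, optm, "k =", k))
      }
    }
  }
})

test_that("optimizer contracts: fixed ids, determinism, monotone trace", {
  tiny <- tiny_panel()
  g <- tiny$g; aux <- tiny$aux
  cfg <- selection_config(4, "SH", "local_search", seed = 2L,
                          fixed_ids = g$accession_ids[c(2, 9)],
                          iterations = 300L)
  r1 <- optimize_core(g, aux, cfg)
  r2 <- optimize_core(g, aux, cfg)
  expect_identical(r1$selected_ids, r2$selected_ids)
  expect_true(all(c(g$accession_ids[2], g$accession_ids[9]) %in% r1$selected_ids))
  expect_true(all(diff(r1$objective_trace) >= 0))
  # fixed set of size k: nothing to optimize
  cfg2 <- selection_config(3, "SH", "hill_climb", seed = 1L,
                           fixed_ids = g$accession_ids[1:3])
  r3 <- optimize_core(g, aux, cfg2)
  expect_identical(sort(r3$selected_ids), sort(g$accession_ids[1:3]))
  expect_length(r3$objective_trace, 1L)
  expect_error(optimize_core(g, aux, selection_config(50, "SH")), "infeasible")
  expect_error(selection_config(3, "NOPE"), "unknown")
})

test_that("replicate_selections varies seeds and keeps the fixed set", {
  tiny <- tiny_panel()
  g <- tiny$g; aux <- tiny$aux
  cfg <- selection_config(4, "ENE", "random_descent", seed = 5L,
                          fixed_ids = g$accession_ids[1], iterations = 60L)
  reps <- replicate_selections(g, aux, cfg, n_rep = 6, base_seed = 100L)
  expect_length(reps, 6L)
  for (r in reps) expect_true(g$accession_ids[1] %in% r$selected_ids)
  # short budget on a rugged landscape: replicate outcomes differ
  finals <- vapply(reps, function(r) r$final_value, 0)
  expect_gt(var(finals), 0)
})
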