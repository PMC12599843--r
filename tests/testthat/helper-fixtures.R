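# Shared in-memory fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A hand-sized genotype matrix with known values.
toy_genotypes <- function() {
  d <- rbind(a1 = c(0, 0, 1, 2),
             a2 = c(0, 1, 1, 2),
             a3 = c(2, 2, 0, 0),
             a4 = c(2, 1, 0, 0))
  genotype_matrix(d, chrom = rep("1", 4), pos = c(10L, 20L, 30L, 40L),
                  marker_ids = paste0("m", 1:4))
}

# Desk-scale structured panel for unit tests (smaller than the standard
# fixture): 3 clusters, n = 120, m = 400 on 4 chromosomes.
mini_panel <- function() {
  cached("mini_panel", {
    p <- generate_panel(n_per_cluster = c(50L, 40L, 30L), fst = 0.2, m = 400L,
                        n_chrom = 4L, seed = 101L)
    p$genotypes <- filter_maf(p$genotypes, 0.01)
    p
  })
}

mini_panel_traits <- function() {
  cached("mini_traits",
         generate_traits(mini_panel()$truth, n_cat = 6L, n_quant = 2L,
                         cluster_effect = 1, seed = 55L))
}

mini_aux <- function() {
  cached("mini_aux", prepare_aux(mini_panel()$genotypes, seed = 5L))
}

# Tiny panel (n = 12) for exhaustive-enumeration oracles.
tiny_panel <- function(seed = 3L) {
  cached(paste0("tiny_panel", seed), {
    p <- generate_panel(c(6L, 6L), fst = 0.2, m = 30L, n_chrom = 2L,
                        seed = seed)
    g <- filter_maf(p$genotypes, 0.01)
    aux <- list(dist = rogers_distance(g),
                kinship = kinship_vanraden(g),
                pca = snp_pca(g))
    aux$pca$n_significant <- 1L
    list(g = g, aux = aux)
  })
}

# Exhaustive best value of a single criterion over all size-k subsets,
# larger-is-better orientation (the optimizer's own convention).
enumerate_best <- function(g, aux, crit, k, dopt_q = 2L) {
  n <- length(g$accession_ids)
  subs <- utils::combn(n, k, simplify = FALSE)
  vals <- vapply(subs, function(s) {
    switch(crit,
           ANE = -crit_ane(aux$dist, s),
           ENE = crit_ene(aux$dist, s),
           HE = crit_he(g, s),
           SH = crit_sh(g, s),
           CV = crit_cv(g, s),
           CDmean = suppressWarnings(crit_cdmean(aux$kinship, s)),
           AvgGRM = -crit_avg_grm(aux$kinship, s),
           Dopt = crit_dopt(aux$pca, s, q = dopt_q))
  }, 0)
  list(best = max(vals), values = vals, subsets = subs)
}

# Wrap a plain id vector as a core_selection (for benchmarking fixed sets).
as_selection <- function(ids, label = "manual") {
  structure(list(selected_ids = ids,
                 config = list(criteria = data.frame(name = label, weight = 1))),
            class = "core_selection")
}
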