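#' Selection run configuration
#'
#' @param size target core size.
#' @param criteria criterion names (character) or a data.frame with columns
#'   `name`, `weight`; names in ANE, ENE, HE, SH, CV, CDmean, AvgGRM, Dopt.
#'   Weights are normalized to sum to 1.
#' @param optimizer one of `"random_descent"`, `"local_search"` (simulated
#'   annealing), `"hill_climb"`, `"genetic"`.
#' @param fixed_ids accession ids that must be in every emitted core.
#' @param seed integer RNG seed.
#' @param iterations proposal budget; defaults per optimizer (3,000 for
#'   hill climbing, 20,000 annealing proposals, 300 GA generations, 3,000
#'   random-descent proposals).
#' @param n_restarts independent restarts, best kept (default 1).
#' @param lambda_ratio CDmean variance ratio (default 1, i.e. h2 = 0.5).
#' @param dopt_q D-optimality PC dimension (default: significant axes,
#'   capped at size - 1).
#' @param pop_size,n_generations genetic-algorithm knobs (defaults 40, 300).
#' @return a `selection_config` list.
#' @export
selection_config <- function(size, criteria, optimizer = c("local_search",
                             "random_descent", "hill_climb", "genetic"),
                             fixed_ids = character(0), seed = 1L,
                             iterations = NULL, n_restarts = 1L,
                             lambda_ratio = 1, dopt_q = NULL,
                             pop_size = 40L, n_generations = 300L) {
  optimizer <- match.arg(optimizer)
  criteria <- normalize_criteria(criteria)
  if (is.null(iterations)) {
    iterations <- switch(optimizer, hill_climb = 3000L, local_search = 20000L,
                         random_descent = 3000L, genetic = n_generations)
  }
  structure(list(size = as.integer(size), criteria = criteria,
                 optimizer = optimizer, fixed_ids = as.character(fixed_ids),
                 seed = as.integer(seed), iterations = as.integer(iterations),
                 n_restarts = as.integer(n_restarts),
                 lambda_ratio = lambda_ratio, dopt_q = dopt_q,
                 pop_size = as.integer(pop_size),
                 n_generations = as.integer(n_generations)),
            class = "selection_config")
}

#' Optimize a core collection subset
#'
#' Starts from a uniformly random subset of the configured size containing
#' the fixed accessions and improves it by swap moves under the configured
#' optimizer:
#' * `random_descent` — random swap proposals, improvements accepted;
#' * `local_search` — simulated annealing with geometric cooling over the
#'   same swap neighborhood;
#' * `hill_climb` — first-improvement hill climbing for exactly
#'   `cfg$iterations` proposals;
#' * `genetic` — a (mu+lambda) genetic algorithm with uniform subset
#'   crossover repaired to size k and swap mutation.
#'
#' Fixed accessions are never swapped out; the best-so-far objective trace is
#' non-decreasing; runs are reproducible from the seed.
#'
#' @param g a complete [genotype_matrix()].
#' @param aux list of precomputed structures as required by the criteria:
#'   `dist` ([rogers_distance()]), `kinship` ([kinship_vanraden()]), `pca`
#'   ([snp_pca()]).
#' @param cfg a [selection_config()].
#' @return object of class `core_selection`: `selected_ids` (sorted by panel
#'   order), `config`, `objective_trace` (best-so-far), `final_value`,
#'   `raw_values` (per-criterion raw values of the final core).
#' @export
optimize_core <- function(g, aux = list(), cfg) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "selection_config"))
  n <- length(g$accession_ids)
  k <- cfg$size
  fixed <- match(cfg$fixed_ids, g$accession_ids)
  if (anyNA(fixed)) {
    ck_stop("fixed accession(s) not in panel: ",
            paste(cfg$fixed_ids[is.na(fixed)], collapse = ", "))
  }
  if (k > n || k < max(1L, length(fixed))) ck_stop("infeasible core size")
  obj <- make_objective(g, aux, cfg$criteria, size = k, seed = cfg$seed,
                        lambda_ratio = cfg$lambda_ratio, dopt_q = cfg$dopt_q)
  free_pool <- setdiff(seq_len(n), fixed)
  n_free <- k - length(fixed)

  run_once <- function(seed) {
    with_seed(seed, {
      start <- c(fixed, sample(free_pool, n_free))
      if (n_free == 0L) {
        v <- obj$value(start)
        return(list(idx = start, trace = v, value = v))
      }
      switch(cfg$optimizer,
             random_descent = swap_search(obj, start, fixed, n, cfg$iterations,
                                          anneal = FALSE),
             hill_climb = swap_search(obj, start, fixed, n, cfg$iterations,
                                      anneal = FALSE),
             local_search = swap_search(obj, start, fixed, n, cfg$iterations,
                                        anneal = TRUE),
             genetic = ga_search(obj, fixed, free_pool, n_free, cfg))
    })
  }
  seeds <- cfg$seed + (seq_len(cfg$n_restarts) - 1L) * 10007L
  best <- NULL
  for (s in seeds) {
    res <- run_once(s)
    if (is.null(best) || res$value > best$value) best <- res
  }
  sel <- sort(best$idx)
  structure(list(selected_ids = g$accession_ids[sel],
                 selected_idx = sel,
                 config = cfg,
                 objective_trace = best$trace,
                 final_value = best$value,
                 raw_values = obj$raw(sel)),
            class = "core_selection")
}

# Swap-move chain shared by random descent, hill climbing and annealing.
swap_search <- function(obj, start, fixed, n, iterations, anneal,
                        t0 = 0.1, t_end = 1e-4) {
  cur <- obj$init(start)
  best <- cur
  best_idx <- start
  trace <- numeric(iterations)
  in_set <- logical(n)
  in_set[start] <- TRUE
  removable <- setdiff(start, fixed)
  cool <- if (anneal) (t_end / t0)^(1 / max(1, iterations)) else 1
  temp <- t0
  for (it in seq_len(iterations)) {
    out_id <- removable[sample.int(length(removable), 1L)]
    repeat {
      in_id <- sample.int(n, 1L)
      if (!in_set[in_id]) break
    }
    cand <- obj$propose(out_id, in_id)
    accept <- if (cand > cur) TRUE else if (anneal) {
      runif(1) < exp((cand - cur) / temp)
    } else FALSE
    if (accept) {
      obj$commit()
      cur <- cand
      in_set[out_id] <- FALSE; in_set[in_id] <- TRUE
      removable[removable == out_id] <- in_id
      if (cur > best) { best <- cur; best_idx <- obj$current() }
    }
    if (anneal) temp <- temp * cool
    trace[it] <- best
  }
  list(idx = best_idx, trace = trace, value = best)
}

# (mu + lambda) genetic algorithm on fixed-size subsets.
ga_search <- function(obj, fixed, free_pool, n_free, cfg) {
  pop_size <- cfg$pop_size
  gens <- cfg$iterations
  mu <- max(2L, pop_size %/% 2L)
  lambda <- pop_size - mu
  pop <- replicate(pop_size,
                   c(fixed, sample(free_pool, n_free)), simplify = FALSE)
  fit <- vapply(pop, obj$value, 0)
  trace <- numeric(gens)
  for (gen in seq_len(gens)) {
    ord <- order(fit, decreasing = TRUE)
    pop <- pop[ord]; fit <- fit[ord]
    parents <- pop[seq_len(mu)]
    offspring <- vector("list", lambda)
    for (i in seq_len(lambda)) {
      pr <- sample.int(mu, 2L)
      u_free <- unique(c(setdiff(parents[[pr[1]]], fixed),
                         setdiff(parents[[pr[2]]], fixed)))
      child_free <- if (length(u_free) >= n_free) {
        sample(u_free, n_free)
      } else {
        c(u_free, sample(setdiff(free_pool, u_free), n_free - length(u_free)))
      }
      # swap mutation
      if (runif(1) < 0.3 && n_free >= 1L) {
        out_pos <- sample.int(n_free, 1L)
        pool <- setdiff(free_pool, child_free)
        if (length(pool)) child_free[out_pos] <- pool[sample.int(length(pool), 1L)]
      }
      offspring[[i]] <- c(fixed, child_free)
    }
    off_fit <- vapply(offspring, obj$value, 0)
    pop <- c(parents, offspring)
    fit <- c(fit[seq_len(mu)], off_fit)
    trace[gen] <- max(fit)
  }
  trace <- cummax(trace)
  b <- which.max(fit)
  list(idx = pop[[b]], trace = trace, value = fit[b])
}

#' @export
print.core_selection <- function(x, ...) {
  cat(sprintf("core_selection: %d accessions | %s via %s | objective %.6g\n",
              length(x$selected_ids),
              paste(x$config$criteria$name, collapse = "+"),
              x$config$optimizer, x$final_value))
  invisible(x)
}

#' Replicated core selections
#'
#' Runs [optimize_core()] `n_rep` times; replicate `r` uses seed
#' `base_seed + r`.
#'
#' @inheritParams optimize_core
#' @param n_rep number of replicates (default 10).
#' @param base_seed base RNG seed.
#' @return list of `core_selection` objects.
#' @export
replicate_selections <- function(g, aux = list(), cfg, n_rep = 10L,
                                 base_seed = cfg$seed) {
  if (n_rep < 1L) ck_stop("n_rep must be at least 1")
  lapply(seq_len(n_rep), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- as.integer(base_seed + r)
    optimize_core(g, aux, cfg_r)
  })
}
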