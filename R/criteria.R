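# Canonical criterion vocabulary. `direction` +1 = maximize, -1 = minimize.
CRITERIA <- data.frame(
  name = c("ANE", "ENE", "HE", "SH", "CV", "CDmean", "AvgGRM", "Dopt"),
  direction = c(-1, 1, 1, 1, 1, 1, -1, 1),
  stringsAsFactors = FALSE)

#' Selection criteria for core subsets
#'
#' The eight raw subset criteria. Distance criteria take a
#' [rogers_distance()] object, frequency criteria a [genotype_matrix()],
#' relatedness criteria a [kinship_vanraden()] matrix and D-optimality a
#' [snp_pca()] result.
#'
#' * `crit_ane` — accession-to-nearest-entry: mean over *all* accessions of
#'   the distance to the closest selected entry (0 for entries themselves);
#'   minimized for representativeness.
#' * `crit_ene` — entry-to-nearest-entry: mean over entries of the distance
#'   to the closest other entry; maximized for spread.
#' * `crit_he`, `crit_sh`, `crit_cv` — subset expected heterozygosity,
#'   Shannon index and allelic coverage (coverage relative to the full
#'   panel); maximized.
#' * `crit_cdmean` — mean coefficient of determination of genotypic-value
#'   predictions for unselected candidates under the mixed model; maximized.
#' * `crit_avg_grm` — mean off-diagonal kinship within the subset; minimized
#'   to maximize subset genetic variance.
#' * `crit_dopt` — log-determinant of the cross-product of the subset's
#'   first `q` PC score columns; maximized (rank-deficient subsets score
#'   `-Inf`).
#'
#' @param d a `rogers_dist` object.
#' @param g a `genotype_matrix`.
#' @param K a `kinship_matrix`.
#' @param p a `snp_pca` result.
#' @param subset accession indices or ids.
#' @param lambda_ratio residual-to-genetic variance ratio `sigma_e^2 /
#'   sigma_g^2` for CDmean (1 corresponds to h2 = 0.5).
#' @param q number of PC dimensions for D-optimality.
#' @return scalar criterion value.
#' @name criteria
NULL

#' @rdname criteria
#' @export
crit_ane <- function(d, subset) {
  idx <- resolve_subset(d$ids, subset)
  mean(row_mins(d$d[, idx, drop = FALSE]))
}

#' @rdname criteria
#' @export
crit_ene <- function(d, subset) {
  idx <- resolve_subset(d$ids, subset)
  if (length(idx) < 2L) ck_stop("E-NE needs at least 2 entries")
  dm <- d$d[idx, idx]
  diag(dm) <- Inf
  mean(row_mins(dm))
}

#' @rdname criteria
#' @export
crit_he <- function(g, subset) eval_he(g, subset)

#' @rdname criteria
#' @export
crit_sh <- function(g, subset) eval_sh(g, subset)

#' @rdname criteria
#' @export
crit_cv <- function(g, subset) eval_cv(g, subset)

#' @rdname criteria
#' @export
crit_cdmean <- function(K, subset, lambda_ratio = 1) {
  stopifnot(inherits(K, "kinship_matrix"))
  idx <- resolve_subset(K$ids, subset)
  if (lambda_ratio <= 0) ck_stop("lambda_ratio must be positive")
  pre <- cdmean_precompute(K, lambda_ratio)
  cdmean_value(pre, idx)
}

# Invert K once (ridged if needed); reused across subset evaluations. A
# VanRaden K built from column-centered dosages always has the 1-vector in
# its null space, so near-singularity is the rule, not the exception.
cdmean_precompute <- function(K, lambda_ratio) {
  Km <- K$K
  if (rcond(Km) < 1e-10) {
    warning("singular kinship matrix; adding ridge 1e-6", call. = FALSE)
    Km <- Km + diag(1e-6 * mean(diag(Km)), nrow(Km))
  }
  Kinv <- solve(Km)
  list(K = Km, Kinv = Kinv, B = Km / lambda_ratio, lambda = lambda_ratio,
       dK = diag(Km))
}

# CDmean via Woodbury: A = Z'MZ + lambda K^-1 with Z the subset incidence and
# M the subset-level projector orthogonal to the intercept. CD_i =
# (K - lambda A^-1)_ii / K_ii, averaged over candidates outside the subset.
cdmean_value <- function(pre, idx) {
  k <- length(idx)
  n <- nrow(pre$B)
  Mk <- diag(k) - matrix(1 / k, k, k)
  Bss <- pre$B[idx, idx]
  inner <- diag(k) + Bss %*% Mk
  sol <- tryCatch(solve(inner), error = function(e) NULL)
  if (is.null(sol)) return(0)
  Bs <- pre$B[, idx, drop = FALSE]
  # diag(lambda * A^-1) = lambda * (diag(B) - rowSums((Bs Mk sol) * Bs))
  corr <- rowSums((Bs %*% (Mk %*% sol)) * Bs)
  lamAinv_diag <- pre$lambda * (diag(pre$B) - corr)
  cd <- (pre$dK - lamAinv_diag) / pre$dK
  cand <- setdiff(seq_len(n), idx)
  if (length(cand) == 0L) return(mean(pmin(pmax(cd, 0), 1)))
  mean(pmin(pmax(cd[cand], 0), 1))
}

#' @rdname criteria
#' @export
crit_avg_grm <- function(K, subset) {
  stopifnot(inherits(K, "kinship_matrix"))
  idx <- resolve_subset(K$ids, subset)
  if (length(idx) < 2L) ck_stop("average relatedness needs at least 2 entries")
  Ks <- K$K[idx, idx]
  (sum(Ks) - sum(diag(Ks))) / (length(idx) * (length(idx) - 1L))
}

#' @rdname criteria
#' @export
crit_dopt <- function(p, subset, q = NULL) {
  stopifnot(inherits(p, "snp_pca"))
  idx <- resolve_subset(rownames(p$scores), subset)
  if (is.null(q)) {
    q <- if (!is.na(p$n_significant) && p$n_significant >= 1L) {
      p$n_significant
    } else {
      ncol(p$scores)
    }
    q <- min(q, max(1L, length(idx) - 1L))
  }
  if (length(idx) < q) ck_stop("subset smaller than the PC dimension q")
  S <- p$scores[idx, seq_len(q), drop = FALSE]
  ld <- determinant(crossprod(S), logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  as.numeric(ld$modulus)
}

#' Weighted scalarization of multiple criteria
#'
#' Maps each raw criterion value to \[0, 1\] via `(v - min) / (max - min)`
#' over the supplied bounds, flips minimization-type criteria (A-NE, average
#' relatedness) so that larger is always better, and returns the weighted sum.
#' Weights are normalized to sum to 1. Values outside the bounds are clamped
#' with a warning (bounds are typically estimated from random subsets, so an
#' optimized subset may legitimately exceed them).
#'
#' @param criteria data.frame with columns `name`, `weight`.
#' @param raw_values named numeric vector of raw criterion values.
#' @param bounds named list of `c(min, max)` per criterion.
#' @param clamp clamp out-of-bounds values (TRUE, the contract) or extrapolate
#'   linearly (used internally during optimization).
#' @return scalar combined objective (larger is better).
#' @export
combine_objectives <- function(criteria, raw_values, bounds, clamp = TRUE) {
  criteria <- normalize_criteria(criteria)
  total <- 0
  for (i in seq_len(nrow(criteria))) {
    nm <- criteria$name[i]
    b <- bounds[[nm]]
    if (is.null(b) || !all(is.finite(b)) || b[2] <= b[1]) {
      ck_stop("bounds for ", nm, " must be finite with min < max")
    }
    v <- raw_values[[nm]]
    u <- (v - b[1]) / (b[2] - b[1])
    if (clamp && (u < 0 || u > 1)) {
      warning("criterion ", nm, " outside its normalization bounds; clamped",
              call. = FALSE)
      u <- min(max(u, 0), 1)
    }
    dir <- CRITERIA$direction[CRITERIA$name == nm]
    if (dir < 0) u <- 1 - u
    total <- total + criteria$weight[i] * u
  }
  total
}

normalize_criteria <- function(criteria) {
  if (is.character(criteria)) {
    criteria <- data.frame(name = criteria, weight = 1 / length(criteria))
  }
  criteria <- as.data.frame(criteria)
  if (is.null(criteria$weight)) criteria$weight <- 1 / nrow(criteria)
  unknown <- setdiff(criteria$name, CRITERIA$name)
  if (length(unknown)) ck_stop("unknown criterion: ", paste(unknown, collapse = ", "))
  if (any(criteria$weight <= 0)) ck_stop("criterion weights must be positive")
  criteria$weight <- criteria$weight / sum(criteria$weight)
  criteria
}

# Build a subset-objective evaluator for the optimizers. Exposes a stateless
# `value(idx)` plus a stateful swap API (`init`/`propose`/`commit`) under
# which the allele-count state of the frequency criteria (HE, SH, CV) is
# updated in O(m) per proposed swap instead of recomputed from the k x m
# dosage block. For a single criterion the (monotone) normalization is
# skipped; for multi-objective runs the linear map is applied without
# clamping so the objective stays strictly monotone beyond bounds estimated
# from random subsets.
make_objective <- function(g, aux, criteria, size, seed,
                           lambda_ratio = 1, dopt_q = NULL, n_bound_subsets = 200L) {
  criteria <- normalize_criteria(criteria)
  need <- criteria$name
  pre <- list()
  if (any(need %in% c("ANE", "ENE"))) {
    if (is.null(aux$dist)) ck_stop("distance matrix required for A-NE/E-NE")
    pre$d <- aux$dist
  }
  if (any(need %in% c("CDmean", "AvgGRM"))) {
    if (is.null(aux$kinship)) ck_stop("kinship matrix required for CDmean/AvgGRM")
    pre$K <- aux$kinship
    if ("CDmean" %in% need) pre$cd <- cdmean_precompute(aux$kinship, lambda_ratio)
  }
  if ("Dopt" %in% need) {
    if (is.null(aux$pca)) ck_stop("PCA required for D-optimality")
    pre$pca <- aux$pca
    q <- dopt_q
    if (is.null(q)) {
      q <- if (!is.na(aux$pca$n_significant) && aux$pca$n_significant >= 1L) {
        aux$pca$n_significant
      } else {
        ncol(aux$pca$scores)
      }
    }
    pre$q <- min(q, size - 1L, ncol(aux$pca$scores))
  }
  use_freq <- any(need %in% c("HE", "SH", "CV"))
  if (use_freq) {
    pre$whole_alleles <- rowSums(allele_frequencies(g)$allele_presence)
    pre$whole_alleles[pre$whole_alleles == 0] <- 1L
  }
  n <- length(g$accession_ids)
  dosage <- g$dosage

  # frequency-criterion values from allele-count state (altsum: summed
  # dosages; refc/altc: carrier counts per locus within the subset)
  freq_raw <- function(nm, st, k) {
    p <- st$altsum / (2 * k)
    switch(nm,
           HE = mean(2 * p * (1 - p)),
           SH = {
             q <- 1 - p
             # p * log2(pmax(p, tiny)) is exactly 0 at p = 0
             mean(-(p * log2(pmax(p, 1e-300)) + q * log2(pmax(q, 1e-300))))
           },
           CV = mean(((st$refc > 0) + (st$altc > 0)) / pre$whole_alleles))
  }
  freq_state <- function(idx) {
    d <- dosage[idx, , drop = FALSE]
    list(altsum = colSums(d), refc = colSums(d < 2), altc = colSums(d > 0))
  }
  freq_shift <- function(st, out_id, in_id) {
    ro <- dosage[out_id, ]; ri <- dosage[in_id, ]
    list(altsum = st$altsum - ro + ri,
         refc = st$refc - (ro < 2) + (ri < 2),
         altc = st$altc - (ro > 0) + (ri > 0))
  }
  raw_one <- function(nm, idx, st = NULL) {
    if (nm %in% c("HE", "SH", "CV")) {
      if (is.null(st)) st <- freq_state(idx)
      return(freq_raw(nm, st, length(idx)))
    }
    switch(nm,
           ANE = crit_ane(pre$d, idx),
           ENE = crit_ene(pre$d, idx),
           CDmean = cdmean_value(pre$cd, idx),
           AvgGRM = crit_avg_grm(pre$K, idx),
           Dopt = crit_dopt(pre$pca, idx, q = pre$q))
  }

  single <- nrow(criteria) == 1L
  bounds <- NULL
  if (!single) {
    # estimate normalization bounds from random size-k subsets
    bounds <- with_seed((seed * 7919L) %% .Machine$integer.max, {
      samp <- replicate(n_bound_subsets, sample.int(n, size), simplify = FALSE)
      vals <- lapply(criteria$name, function(nm) {
        v <- vapply(samp, function(s) raw_one(nm, s), 0)
        v <- v[is.finite(v)]
        if (length(v) == 0L) v <- c(-1, 1)
        rng <- range(v)
        if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1e-9
        rng
      })
      setNames(vals, criteria$name)
    })
  }
  dirs <- CRITERIA$direction[match(criteria$name, CRITERIA$name)]
  if (!single) {
    b_min <- vapply(bounds[criteria$name], `[`, 0, 1L)
    b_rng <- vapply(bounds[criteria$name], function(b) b[2] - b[1], 0)
  }
  combine <- function(raw) {
    if (single) return(dirs[1] * raw[[1]])
    u <- (unlist(raw, use.names = FALSE) - b_min) / b_rng
    u[dirs < 0] <- 1 - u[dirs < 0]
    sum(criteria$weight * u)
  }
  value_of <- function(idx, st = NULL) {
    raw <- setNames(lapply(criteria$name, raw_one, idx = idx, st = st),
                    criteria$name)
    combine(raw)
  }

  st_env <- new.env(parent = emptyenv())
  list(
    value = function(idx) value_of(idx),
    raw = function(idx) {
      setNames(vapply(criteria$name, function(nm) raw_one(nm, idx), 0),
               criteria$name)
    },
    bounds = bounds,
    init = function(idx) {
      st_env$idx <- idx
      st_env$st <- if (use_freq) freq_state(idx) else NULL
      st_env$pending <- NULL
      value_of(idx, st_env$st)
    },
    propose = function(out_id, in_id) {
      new_idx <- c(st_env$idx[st_env$idx != out_id], in_id)
      new_st <- if (use_freq) freq_shift(st_env$st, out_id, in_id) else NULL
      st_env$pending <- list(idx = new_idx, st = new_st)
      value_of(new_idx, new_st)
    },
    commit = function() {
      if (is.null(st_env$pending)) ck_stop("no pending swap to commit")
      st_env$idx <- st_env$pending$idx
      st_env$st <- st_env$pending$st
      st_env$pending <- NULL
      invisible(NULL)
    },
    current = function() st_env$idx
  )
}
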