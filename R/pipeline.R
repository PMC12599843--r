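# The canonical 20 method labels and their criterion/optimizer bindings.
METHOD_TABLE <- local({
  def <- list(
    CDmean = list(c("CDmean"), "hill_climb"),
    CV = list(c("CV"), "local_search"),
    Avg_GRM = list(c("AvgGRM"), "genetic"),
    ANE_CV = list(c("ANE", "CV"), "local_search"),
    ANE = list(c("ANE"), "random_descent"),
    `D-opt+Avg_GRM` = list(c("Dopt", "AvgGRM"), "genetic"),
    `D-opt` = list(c("Dopt"), "genetic"),
    ENE = list(c("ENE"), "random_descent"),
    ANE_ENE = list(c("ANE", "ENE"), "local_search"),
    SH_CV = list(c("SH", "CV"), "local_search"),
    ANE_SH = list(c("ANE", "SH"), "local_search"),
    ANE_SH_CV = list(c("ANE", "SH", "CV"), "local_search"),
    ANE_HE = list(c("ANE", "HE"), "local_search"),
    SH = list(c("SH"), "local_search"),
    HE_SH = list(c("HE", "SH"), "local_search"),
    HE_CV = list(c("HE", "CV"), "local_search"),
    ENE_SH = list(c("ENE", "SH"), "local_search"),
    HE = list(c("HE"), "local_search"),
    ENE_HE = list(c("ENE", "HE"), "local_search"),
    ENE_CV = list(c("ENE", "CV"), "local_search"))
  def
})

#' The twenty canonical method x criterion combinations
#'
#' @return data.frame with columns `label`, `criteria` (plus-separated),
#'   `optimizer`. Multi-criterion methods use equal weights (0.5/0.5 for
#'   pairs, one third each for the triple).
#' @export
core_methods <- function() {
  data.frame(label = names(METHOD_TABLE),
             criteria = vapply(METHOD_TABLE, function(x) paste(x[[1]], collapse = "+"), ""),
             optimizer = vapply(METHOD_TABLE, function(x) x[[2]], ""),
             row.names = NULL)
}

method_config <- function(label, size, seed, iterations = NULL, ...) {
  if (!label %in% names(METHOD_TABLE)) {
    ck_stop("unknown method label '", label, "'; see core_methods()")
  }
  def <- METHOD_TABLE[[label]]
  selection_config(size = size, criteria = def[[1]], optimizer = def[[2]],
                   seed = seed, iterations = iterations, ...)
}

#' Precompute the auxiliary structures a selection sweep needs
#'
#' Rogers distances, VanRaden kinship, standardized PCA with Tracy-Widom
#' axis count, K-means/BIC clustering and DAPC covariates, computed once and
#' shared by every method.
#'
#' @param g a complete [genotype_matrix()].
#' @param seed RNG seed for the clustering.
#' @param k_range candidate cluster counts.
#' @param n_axes PCA axes to retain (default `min(n - 1, 50)`, plenty for
#'   desk-scale panels).
#' @param force_k optional fixed cluster count.
#' @param tw_alpha Tracy-Widom level (default 0.05).
#' @return list with `dist`, `kinship`, `pca`, `clusters`.
#' @export
prepare_aux <- function(g, seed = 1L, k_range = 1:10, n_axes = NULL,
                        force_k = NULL, tw_alpha = 0.05) {
  n <- length(g$accession_ids)
  if (is.null(n_axes)) n_axes <- min(n - 1L, 50L)
  d <- rogers_distance(g)
  K <- kinship_vanraden(g)
  p <- snp_pca(g, n_axes = n_axes)
  p$n_significant <- tracy_widom_axes(p, alpha = tw_alpha)
  cl <- kmeans_bic(p, k_range = k_range, seed = seed,
                   d = max(1L, min(p$n_significant, n_axes)),
                   force_k = force_k)
  if (cl$k >= 2L) cl <- dapc_covariates(p, cl)
  list(dist = d, kinship = K, pca = p, clusters = cl)
}

#' Run a method-comparison sweep
#'
#' For each requested method label, `n_rep` replicate cores are optimized
#' (replicate r seeded with `seed + r`), every core is scored with the full
#' evaluation metric set, the QTL-recovery benchmark is run (unless
#' disabled), and the composite index is standardized across all resulting
#' reports. Deterministic given (`g`, arguments, `seed`).
#'
#' @param g a complete [genotype_matrix()].
#' @param methods character vector of method labels (see [core_methods()]).
#' @param size core size.
#' @param n_rep replicates per method (default 10).
#' @param seed base seed.
#' @param traits optional trait table (row names = accession ids) for MD.
#' @param aux precomputed [prepare_aux()] list (computed when NULL).
#' @param qtl logical: run the QTL benchmark (default TRUE).
#' @param sim a [simulate_traits()] result to reuse; simulated internally
#'   (seeded) when NULL and `qtl` is TRUE.
#' @param iterations optional per-optimizer proposal budget override.
#' @param out_dir optional directory; when given, the report table, composite
#'   index table, selections and a run manifest are written as TSV/JSON.
#' @param verbose print stage progress.
#' @param ... further [selection_config()] arguments.
#' @return list with `reports` (per-core evaluation rows incl. QTL and I),
#'   `selections`, `benchmark`, `aux`.
#' @export
run_sweep <- function(g, methods, size, n_rep = 10L, seed = 1L, traits = NULL,
                      aux = NULL, qtl = TRUE, sim = NULL, iterations = NULL,
                      out_dir = NULL, verbose = TRUE, ...) {
  say <- function(...) if (verbose) message("[corekit] ", sprintf(...))
  bad <- setdiff(methods, names(METHOD_TABLE))
  if (length(bad)) ck_stop("unknown method label(s): ", paste(bad, collapse = ", "))
  if (is.null(aux)) {
    say("computing distances, kinship, PCA and clustering")
    aux <- prepare_aux(g, seed = seed)
  }
  selections <- list()
  labels <- character(0)
  for (mlab in methods) {
    say("selecting %d replicate core(s) of size %d with %s", n_rep, size, mlab)
    cfg <- method_config(mlab, size = size, seed = seed,
                         iterations = iterations, ...)
    sel <- replicate_selections(g, aux, cfg, n_rep = n_rep, base_seed = seed)
    selections <- c(selections, sel)
    labels <- c(labels, rep(mlab, n_rep))
  }
  say("evaluating %d core(s)", length(selections))
  reports <- do.call(rbind, lapply(seq_along(selections), function(i) {
    evaluate_core(g, selections[[i]]$selected_ids, d = aux$dist,
                  whole_pca = aux$pca, traits = traits,
                  method_label = labels[i], replicate = i)
  }))
  reports$replicate <- stats::ave(seq_len(nrow(reports)), reports$method,
                                  FUN = seq_along)
  bench <- NULL
  if (qtl) {
    if (is.null(sim)) {
      say("simulating traits")
      sim <- simulate_traits(g, seed = seed, K = aux$kinship)
    }
    say("running the QTL-recovery benchmark")
    bench <- run_benchmark(g, sim, selections,
                           clusters = if (aux$clusters$k >= 2L) aux$clusters else NULL,
                           K = aux$kinship, labels = labels)
    reports$QTL <- bench$per_core$qtl_ratio
  }
  if (!anyNA(reports$QTL) && nrow(reports) >= 2L) {
    reports <- composite_index(reports)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(reports, file.path(out_dir, "evaluation_reports.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    agg <- aggregate_reports(reports)
    write.table(agg, file.path(out_dir, "method_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (i in seq_along(selections)) {
      fn <- sprintf("core_%s_rep%02d.txt", gsub("[^A-Za-z0-9]+", "-", labels[i]),
                    reports$replicate[i])
      writeLines(selections[[i]]$selected_ids, file.path(out_dir, fn))
    }
    manifest <- list(methods = methods, size = size, n_rep = n_rep,
                     seed = seed, n = length(g$accession_ids),
                     m = length(g$marker_ids),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(reports = reports, selections = selections, benchmark = bench,
       aux = aux)
}

#' Mean and standard deviation of every metric per method
#'
#' @param reports stacked evaluation reports (from [run_sweep()]).
#' @return data.frame, one row per method, mean and sd columns per metric.
#' @export
aggregate_reports <- function(reports) {
  metrics <- intersect(c("SH", "He", "MRD", "RAR", "CV", "KL", "COR", "MD",
                         "QTL", "I"), names(reports))
  rows <- lapply(split(reports, reports$method), function(d) {
    out <- data.frame(method = d$method[1])
    for (mt in metrics) {
      out[[mt]] <- mean(d[[mt]])
      out[[paste0("sd_", mt)]] <- if (nrow(d) > 1) sd(d[[mt]]) else NA_real_
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Build the final core around a fixed pre-list
#'
#' Locks a breeder-style pre-selected accession list into the core and
#' optimizes the remaining slots with the given method (SH_CV by default,
#' the best-compromise combination), then scores the result against the
#' whole collection.
#'
#' @param g a complete [genotype_matrix()].
#' @param fixed_ids accession ids that must be selected (all must exist).
#' @param size total core size (> number of fixed ids).
#' @param method method label (default "SH_CV").
#' @param seed RNG seed.
#' @param aux precomputed [prepare_aux()] (computed when NULL).
#' @param traits optional trait table for the MD metric.
#' @param iterations optional proposal budget override.
#' @param ... further [selection_config()] arguments.
#' @return list with `selection` (a `core_selection`) and `report` (a
#'   one-row [evaluate_core()] data.frame).
#' @export
build_final_core <- function(g, fixed_ids, size, method = "SH_CV", seed = 1L,
                             aux = NULL, traits = NULL, iterations = NULL, ...) {
  fixed_ids <- unique(as.character(fixed_ids))
  missing_ids <- setdiff(fixed_ids, g$accession_ids)
  if (length(missing_ids)) {
    ck_stop("fixed id(s) absent from panel: ", paste(missing_ids, collapse = ", "))
  }
  if (length(fixed_ids) >= size) ck_stop("size must exceed the fixed list")
  if (is.null(aux)) aux <- prepare_aux(g, seed = seed)
  cfg <- method_config(method, size = size, seed = seed,
                       iterations = iterations, ...)
  cfg$fixed_ids <- fixed_ids
  sel <- optimize_core(g, aux, cfg)
  rep <- evaluate_core(g, sel$selected_ids, d = aux$dist, whole_pca = aux$pca,
                       traits = traits, method_label = method)
  list(selection = sel, report = rep)
}
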