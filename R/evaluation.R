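resolve_subset <- function(ids_universe, subset) {
  idx <- if (is.character(subset)) match(subset, ids_universe) else as.integer(subset)
  if (length(idx) == 0L) ck_stop("subset is empty")
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > length(ids_universe))) {
    ck_stop("subset contains unknown accessions")
  }
  if (anyDuplicated(idx)) ck_stop("subset contains duplicates")
  idx
}

subset_freq <- function(g, idx) {
  d <- g$dosage[idx, , drop = FALSE]
  colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
}

#' Expected heterozygosity of a subset
#'
#' Mean over loci of `1 - sum(p_i^2)` with allele frequencies computed on the
#' subset; for biallelic markers this is `mean(2 p q)`, bounded by 0.5.
#'
#' @param g a [genotype_matrix()].
#' @param subset accession indices or ids (the "core"); defaults to all.
#' @return scalar in \[0, 0.5\].
#' @export
eval_he <- function(g, subset = seq_along(g$accession_ids)) {
  idx <- resolve_subset(g$accession_ids, subset)
  p <- subset_freq(g, idx)
  mean(2 * p * (1 - p), na.rm = TRUE)
}

#' Shannon diversity index of a subset
#'
#' Per-locus allele-frequency entropy in bits (`-p log2 p - q log2 q`, with
#' `0 log 0 = 0`), averaged over loci. 1 at p = 0.5, 0 for monomorphic loci.
#'
#' @inheritParams eval_he
#' @return scalar in \[0, 1\].
#' @export
eval_sh <- function(g, subset = seq_along(g$accession_ids)) {
  idx <- resolve_subset(g$accession_ids, subset)
  p <- subset_freq(g, idx)
  q <- 1 - p
  plog <- function(x) ifelse(x > 0, x * log2(x), 0)
  mean(-plog(p) - plog(q), na.rm = TRUE)
}

#' Mean Rogers distance within a subset
#'
#' Mean of the pairwise Rogers distances over unordered pairs of subset
#' members.
#'
#' @param d a [rogers_distance()] result (or any symmetric distance object
#'   with fields `ids`, `d`).
#' @param subset accession indices or ids, at least 2.
#' @return scalar in \[0, 1\].
#' @export
eval_mrd <- function(d, subset) {
  idx <- resolve_subset(d$ids, subset)
  if (length(idx) < 2L) ck_stop("MRD needs at least 2 accessions")
  dm <- d$d[idx, idx]
  sum(dm[upper.tri(dm)]) / choose(length(idx), 2)
}

#' Rare-allele retention ratio
#'
#' `R` is the number of whole-panel markers with MAF below `rare_maf`; `H` is
#' how many of those are still segregating (both alleles present) within the
#' subset. Returns `H / R`. In an inbred panel "segregating" rather than
#' "heterozygous" is the operative reading: rare alleles survive as the
#' alternate homozygote.
#'
#' @inheritParams eval_he
#' @param rare_maf whole-panel MAF bound defining "rare" (default 0.10).
#' @return scalar in \[0, 1\].
#' @export
eval_rar <- function(g, subset = seq_along(g$accession_ids), rare_maf = 0.10) {
  idx <- resolve_subset(g$accession_ids, subset)
  af <- allele_frequencies(g)
  rare <- which(!is.na(af$maf) & af$maf < rare_maf & af$maf > 0)
  if (length(rare) == 0L) {
    ck_stop("no rare markers in the whole collection; drop the RAR metric")
  }
  d <- g$dosage[idx, rare, drop = FALSE]
  seg <- colSums(d > 0, na.rm = TRUE) > 0 & colSums(d < 2, na.rm = TRUE) > 0
  mean(seg)
}

#' Allelic coverage of a subset
#'
#' Mean over loci of the number of alleles observed in the subset divided by
#' the number observed in the whole collection at the same locus.
#'
#' @inheritParams eval_he
#' @return scalar in (0, 1\].
#' @export
eval_cv <- function(g, subset = seq_along(g$accession_ids)) {
  idx <- resolve_subset(g$accession_ids, subset)
  whole <- allele_frequencies(g)$allele_presence
  d <- g$dosage[idx, , drop = FALSE]
  sub_ref <- colSums(d < 2, na.rm = TRUE) > 0
  sub_alt <- colSums(d > 0, na.rm = TRUE) > 0
  a_whole <- rowSums(whole)
  a_sub <- (sub_ref & whole[, "ref"]) + (sub_alt & whole[, "alt"])
  ok <- a_whole > 0
  mean(a_sub[ok] / a_whole[ok])
}

#' Kullback-Leibler divergence of core vs whole allele frequencies
#'
#' `sum_j p_j log(p_j / q_j)` (natural log) where the minor allele is defined
#' on the whole collection and the same allele is tracked in the subset;
#' `p_j` is its subset frequency, `q_j` its whole-collection frequency. Zero
#' frequencies are floored at `epsilon` before the ratio. The truncated sum is
#' not guaranteed non-negative; it is exactly 0 when the distributions agree.
#'
#' @inheritParams eval_he
#' @param epsilon zero-frequency floor; default `1 / (2 * |subset| + 1)`.
#' @return scalar.
#' @export
eval_kl <- function(g, subset = seq_along(g$accession_ids), epsilon = NULL) {
  idx <- resolve_subset(g$accession_ids, subset)
  if (is.null(epsilon)) epsilon <- 1 / (2 * length(idx) + 1)
  alt_w <- allele_frequencies(g)$alt_freq
  # the whole-collection minor allele; track that same allele in the subset
  minor_is_alt <- alt_w <= 0.5
  q <- ifelse(minor_is_alt, alt_w, 1 - alt_w)
  alt_s <- subset_freq(g, idx)
  p <- ifelse(minor_is_alt, alt_s, 1 - alt_s)
  keep <- !is.na(p) & !is.na(q)
  p <- p[keep]; q <- q[keep]
  p[p == 0] <- epsilon
  q[q == 0] <- epsilon
  sum(p * log(p / q))
}

#' Eigenvalue-weighted correlation of principal components, core vs whole
#'
#' A PCA is run independently on the subset; the absolute Pearson correlation
#' `r_i` of same-rank marker-loading vectors is Fisher z-transformed, averaged
#' with whole-panel eigenvalue weights over the whole panel's Tracy-Widom
#' significant axes, and back-transformed. Correlations are clipped just below
#' 1 so that `core = whole` maps to 1.
#'
#' @inheritParams eval_he
#' @param whole_pca a [snp_pca()] of the whole panel with `n_significant` set
#'   (computed internally when NULL).
#' @param n_axes number of axes to compare (default: whole-panel significant
#'   count, at least 1).
#' @return scalar in \[0, 1\].
#' @export
eval_cor <- function(g, subset = seq_along(g$accession_ids), whole_pca = NULL,
                     n_axes = NULL) {
  idx <- resolve_subset(g$accession_ids, subset)
  if (is.null(whole_pca)) {
    whole_pca <- snp_pca(g)
    whole_pca$n_significant <- tracy_widom_axes(whole_pca)
  }
  if (is.null(n_axes)) {
    n_axes <- max(1L, whole_pca$n_significant, na.rm = TRUE)
  }
  if (length(idx) < n_axes + 1L) {
    ck_stop("subset must exceed the number of compared axes")
  }
  sub <- subset_genotypes(g, accessions = idx)
  # drop markers monomorphic within the subset; compare loadings on shared set
  p_sub <- colMeans(sub$dosage) / 2
  poly <- which(p_sub > 0 & p_sub < 1)
  if (length(poly) < 2L) ck_stop("subset is essentially monomorphic")
  sub_pca <- snp_pca(subset_genotypes(sub, markers = poly),
                     n_axes = min(n_axes, length(idx) - 1L, length(poly)))
  shared <- match(rownames(sub_pca$loadings), rownames(whole_pca$loadings))
  k <- min(n_axes, ncol(sub_pca$loadings))
  r <- vapply(seq_len(k), function(i) {
    abs(cor(whole_pca$loadings[shared, i], sub_pca$loadings[, i]))
  }, 0)
  r <- pmin(r, 1 - 1e-12)
  z <- atanh(r)
  w <- whole_pca$eigenvalues[seq_len(k)]
  tanh(sum(w * z) / sum(w))
}

#' Phenotypic mean-difference ratio, core vs whole
#'
#' Redundant categorical traits are first removed greedily: scanning trait
#' pairs in column order, the later member of any categorical pair with
#' Cramer's V above `v_max` is dropped. Each surviving trait is then tested
#' core vs whole (categorical: chi-square goodness of fit of the subset's
#' category counts against whole-collection proportions; quantitative:
#' two-sample Kolmogorov-Smirnov). MD is the fraction of surviving traits
#' that differ significantly at `alpha`; no multiplicity correction.
#'
#' @param t a trait table: data.frame of traits with accession ids as row
#'   names (factors/characters are categorical, numerics quantitative).
#' @param subset accession indices or ids.
#' @param alpha significance level (default 0.05).
#' @param v_max Cramer's V redundancy bound (default 0.7).
#' @return scalar in \[0, 1\].
#' @export
eval_md <- function(t, subset, alpha = 0.05, v_max = 0.7) {
  stopifnot(is.data.frame(t))
  idx <- resolve_subset(rownames(t), subset)
  is_cat <- vapply(t, function(x) is.factor(x) || is.character(x), TRUE)
  keep <- rep(TRUE, ncol(t))
  cats <- which(is_cat)
  if (length(cats) >= 2L) {
    for (i in seq_along(cats)[-length(cats)]) {
      if (!keep[cats[i]]) next
      for (j in seq((i + 1L), length(cats))) {
        if (!keep[cats[j]]) next
        v <- cramers_v(t[[cats[i]]], t[[cats[j]]])
        if (!is.na(v) && v > v_max) keep[cats[j]] <- FALSE
      }
    }
  }
  surv <- which(keep)
  if (length(surv) == 0L) ck_stop("all traits dropped by the redundancy filter")
  sig <- 0L
  for (j in surv) {
    x <- t[[j]]
    pval <- if (is_cat[j]) {
      f <- factor(x)
      probs <- as.numeric(table(f)) / length(f)
      obs <- table(factor(x[idx], levels = levels(f)))
      nz <- probs > 0
      suppressWarnings(chisq.test(as.numeric(obs[nz]), p = probs[nz]))$p.value
    } else {
      suppressWarnings(ks.test(x[idx], x))$p.value
    }
    if (!is.na(pval) && pval < alpha) sig <- sig + 1L
  }
  sig / length(surv)
}

# Cramer's V between two categorical vectors.
cramers_v <- function(x, y) {
  tab <- table(factor(x), factor(y))
  if (min(dim(tab)) < 2L) return(NA_real_)
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE))$statistic
  n <- sum(tab)
  unname(sqrt(chi / (n * (min(dim(tab)) - 1L))))
}

#' Evaluate a core collection against the whole panel
#'
#' Convenience wrapper computing the full metric set for one subset. The
#' QTL-recovery component is filled by [run_benchmark()], not here.
#'
#' @param g a complete [genotype_matrix()].
#' @param subset accession indices or ids.
#' @param d precomputed [rogers_distance()] (computed when NULL).
#' @param whole_pca precomputed whole-panel [snp_pca()] with `n_significant`.
#' @param traits optional trait table for MD.
#' @param method_label,replicate bookkeeping labels.
#' @return one-row data.frame (class `evaluation_report`) with columns
#'   method, replicate, SH, He, MRD, RAR, CV, KL, COR, MD, QTL, I.
#' @export
evaluate_core <- function(g, subset, d = NULL, whole_pca = NULL, traits = NULL,
                          method_label = "core", replicate = 1L) {
  idx <- resolve_subset(g$accession_ids, subset)
  if (is.null(d)) d <- rogers_distance(g)
  res <- data.frame(
    method = method_label, replicate = replicate,
    SH = eval_sh(g, idx), He = eval_he(g, idx), MRD = eval_mrd(d, idx),
    RAR = eval_rar(g, idx), CV = eval_cv(g, idx), KL = eval_kl(g, idx),
    COR = eval_cor(g, idx, whole_pca = whole_pca),
    MD = if (is.null(traits)) NA_real_ else eval_md(traits, g$accession_ids[idx]),
    QTL = NA_real_, I = NA_real_)
  class(res) <- c("evaluation_report", class(res))
  res
}

#' Composite index over a pool of evaluation reports
#'
#' Each of the seven components (SH, He, RAR, CV, COR, KL, QTL) is z-scored
#' across the supplied reports (sample standard deviation; a zero-variance
#' component contributes 0 for every report) and combined as
#' `I = (SH* + He* + RAR* + CV* + COR* - KL* + QTL*) / 7`. MD is deliberately
#' not part of the index. Standardization is relative to the pool, so `I`
#' values only compare reports standardized together.
#'
#' @param reports a data.frame of stacked [evaluate_core()] rows (>= 2 rows)
#'   with the QTL column filled.
#' @return the reports with the `I` column filled.
#' @export
composite_index <- function(reports) {
  reports <- as.data.frame(reports)
  if (nrow(reports) < 2L) ck_stop("composite index needs at least 2 reports")
  comp <- c("SH", "He", "RAR", "CV", "COR", "KL", "QTL")
  if (any(!comp %in% names(reports)) || anyNA(reports[comp])) {
    ck_stop("all seven index components must be present and complete")
  }
  zs <- lapply(reports[comp], function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  reports$I <- (zs$SH + zs$He + zs$RAR + zs$CV + zs$COR - zs$KL + zs$QTL) / 7
  reports
}
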