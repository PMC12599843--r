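#' Drop markers, then accessions, exceeding a missing-data rate
#'
#' Two fixed passes: markers whose missing fraction exceeds `max_rate` are
#' removed first, then accessions whose missing fraction (computed on the
#' surviving markers) exceeds `max_rate`. Running the marker pass first
#' retains more accessions, which is the point of a germplasm QC step.
#'
#' @param g a [genotype_matrix()].
#' @param max_rate maximum tolerated missing fraction (default 0.5).
#' @return a filtered `genotype_matrix`.
#' @export
filter_missingness <- function(g, max_rate = 0.5) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (max_rate < 0 || max_rate > 1) ck_stop("max_rate must be in [0, 1]")
  miss_m <- colMeans(is.na(g$dosage))
  keep_m <- miss_m <= max_rate
  if (!any(keep_m)) ck_stop("all markers exceed the missingness threshold")
  g <- subset_genotypes(g, markers = which(keep_m))
  miss_a <- rowMeans(is.na(g$dosage))
  keep_a <- miss_a <= max_rate
  if (sum(keep_a) < 2L) ck_stop("fewer than 2 accessions survive missingness filtering")
  subset_genotypes(g, accessions = which(keep_a))
}

#' Replace missing calls by the per-marker modal dosage
#'
#' A deterministic stand-in for statistical imputation: each missing cell
#' takes the most frequent dosage at its marker, ties broken toward the lower
#' dosage.
#'
#' @param g a [genotype_matrix()].
#' @return a complete `genotype_matrix`.
#' @export
impute_mode <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  miss_cols <- which(colSums(is.na(d)) > 0L)
  if (length(miss_cols) == 0L) return(g)
  for (j in miss_cols) {
    x <- d[, j]
    obs <- x[!is.na(x)]
    if (length(obs) == 0L) {
      ck_stop("marker ", g$marker_ids[j], " is fully missing; drop it first")
    }
    cnt <- tabulate(obs + 1L, nbins = 3L)  # counts of dosages 0,1,2
    mode_d <- which.max(cnt) - 1L          # which.max takes the first max: tie -> lower
    x[is.na(x)] <- mode_d
    d[, j] <- x
  }
  genotype_matrix(d, g$chrom, g$pos, g$accession_ids, g$marker_ids)
}

#' Keep markers with minor allele frequency above a threshold
#'
#' MAF is computed over non-missing calls; retention is strict
#' (`maf > min_maf`), so monomorphic markers are always removed when
#' `min_maf >= 0`.
#'
#' @param g a [genotype_matrix()].
#' @param min_maf retention threshold (default 0.01).
#' @return a filtered `genotype_matrix`.
#' @export
filter_maf <- function(g, min_maf = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"))
  af <- allele_frequencies(g)
  keep <- !is.na(af$maf) & af$maf > min_maf
  if (!any(keep)) ck_stop("no markers pass the MAF filter")
  subset_genotypes(g, markers = which(keep))
}

#' Windowed LD pruning of a genotype matrix
#'
#' Within each sliding window of `window` markers (per chromosome, markers in
#' map order), pairs of retained markers with squared Pearson correlation of
#' dosages above `r2_max` are broken up by removing the lower-MAF member
#' (ties: the marker at the later position). The window advances by `step`
#' markers. The procedure is deterministic for fixed input.
#'
#' @param g a complete [genotype_matrix()].
#' @param window window size in markers (default 50).
#' @param step slide in markers (default 5).
#' @param r2_max pruning threshold on r-squared (default 0.4).
#' @return the pruned `genotype_matrix`.
#' @export
ld_prune <- function(g, window = 50, step = 5, r2_max = 0.4) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (window < 2) ck_stop("window must be at least 2 markers")
  if (step < 1) ck_stop("step must be at least 1")
  if (anyNA(g$dosage)) ck_stop("ld_prune needs a complete matrix; impute first")
  maf <- allele_frequencies(g)$maf
  keep <- rep(TRUE, length(g$marker_ids))
  for (ch in unique(g$chrom)) {
    idx <- which(g$chrom == ch)  # already position-sorted
    m_ch <- length(idx)
    starts <- seq(1L, max(1L, m_ch - 1L), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, m_ch)]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2L) break
        cc <- suppressWarnings(cor(g$dosage[, act, drop = FALSE]))
        r2 <- cc^2
        r2[!is.finite(r2)] <- 0
        diag(r2) <- 0
        mx <- max(r2)
        if (mx <= r2_max) break
        hit <- which(r2 == mx, arr.ind = TRUE)[1L, ]
        a <- act[hit[1L]]; b <- act[hit[2L]]
        # drop the lower-MAF member; tie -> later position (larger index)
        drop <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else max(a, b)
        keep[drop] <- FALSE
      }
    }
  }
  if (!any(keep)) ck_stop("LD pruning removed every marker")
  subset_genotypes(g, markers = which(keep))
}
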