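#' Pairwise Rogers distance matrix
#'
#' For biallelic dosage data the per-locus Rogers distance between accessions
#' reduces to `|x_a - x_b| / 2`; the pairwise distance is the mean over loci.
#' It is a metric with values in \[0, 1\]: 0 for identical genotypes, 1 for
#' opposite homozygotes at every locus.
#'
#' @param g a complete [genotype_matrix()].
#' @return list of class `rogers_dist` with `ids` and the n x n symmetric
#'   matrix `d`.
#' @export
rogers_distance <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$dosage)) ck_stop("rogers_distance needs a complete matrix")
  m <- ncol(g$dosage)
  if (m == 0L) ck_stop("no markers")
  d <- as.matrix(stats::dist(g$dosage, method = "manhattan")) / (2 * m)
  dimnames(d) <- list(g$accession_ids, g$accession_ids)
  structure(list(ids = g$accession_ids, d = d), class = "rogers_dist")
}

#' VanRaden genomic relationship matrix
#'
#' `K = Z Z' / (2 * sum p_k (1 - p_k))` where `Z` is the dosage matrix with
#' each column centered by twice its alternate-allele frequency. Monomorphic
#' markers contribute nothing to either numerator or denominator; if every
#' marker is monomorphic the denominator vanishes and an error is raised.
#'
#' @param g a complete [genotype_matrix()].
#' @return list of class `kinship_matrix` with `ids` and the symmetric PSD
#'   matrix `K`.
#' @export
kinship_vanraden <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$dosage)) ck_stop("kinship_vanraden needs a complete matrix")
  p <- colMeans(g$dosage) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) ck_stop("all markers are monomorphic; kinship undefined")
  Z <- sweep(g$dosage, 2L, 2 * p, "-")
  K <- tcrossprod(Z) / denom
  dimnames(K) <- list(g$accession_ids, g$accession_ids)
  structure(list(ids = g$accession_ids, K = K), class = "kinship_matrix")
}
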