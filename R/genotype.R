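#' Genotype matrix container
#'
#' A `genotype_matrix` holds the dosage-coded genotypes of an inbred-line
#' panel: `n` accessions by `m` biallelic SNPs, each call counting copies of
#' the alternate allele (0, 1, 2, or `NA` for missing), plus a marker map
#' (chromosome, base-pair position). Markers are always stored sorted by
#' (chromosome, position); positions are 1-based as in VCF.
#'
#' @param dosage numeric matrix, accessions in rows, markers in columns;
#'   values in \{0, 1, 2, NA\}. Row names are taken as accession ids and
#'   column names as marker ids when present.
#' @param chrom character vector of per-marker chromosome labels.
#' @param pos integer vector of per-marker positions (positive).
#' @param accession_ids,marker_ids optional explicit ids; default to dimnames
#'   or generated `acc1..accn` / `mk1..mkm`.
#' @return An object of class `genotype_matrix` with fields `accession_ids`,
#'   `marker_ids`, `chrom`, `pos`, `dosage`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 0), 2, 2), chrom = c("1", "1"),
#'                      pos = c(100L, 200L))
#' dim_genotypes(g)
#' @export
genotype_matrix <- function(dosage, chrom, pos, accession_ids = NULL,
                            marker_ids = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  n <- nrow(dosage); m <- ncol(dosage)
  if (n < 2L) ck_stop("a genotype matrix needs at least 2 accessions")
  if (m < 1L) ck_stop("a genotype matrix needs at least 1 marker")
  if (is.null(accession_ids)) {
    accession_ids <- rownames(dosage)
    if (is.null(accession_ids)) accession_ids <- paste0("acc", seq_len(n))
  }
  if (is.null(marker_ids)) {
    marker_ids <- colnames(dosage)
    if (is.null(marker_ids)) marker_ids <- paste0("mk", seq_len(m))
  }
  accession_ids <- as.character(accession_ids)
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(accession_ids)) ck_stop("duplicate accession ids")
  if (anyDuplicated(marker_ids)) ck_stop("duplicate marker ids")
  if (length(accession_ids) != n || length(marker_ids) != m) {
    ck_stop("id lengths do not match dosage dimensions")
  }
  chrom <- as.character(chrom); pos <- as.integer(pos)
  if (length(chrom) != m || length(pos) != m) {
    ck_stop("chrom/pos must have one entry per marker")
  }
  if (any(is.na(pos)) || any(pos < 1L)) ck_stop("positions must be positive integers")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) ck_stop("dosage values must be in {0, 1, 2, NA}")
  ord <- order(chrom, pos)
  dosage <- dosage[, ord, drop = FALSE]
  dimnames(dosage) <- list(accession_ids, marker_ids[ord])
  structure(
    list(accession_ids = accession_ids, marker_ids = marker_ids[ord],
         chrom = chrom[ord], pos = pos[ord], dosage = dosage),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$dosage))
  cat(sprintf(
    "genotype_matrix: %d accessions x %d markers on %d chromosome(s), %s missing\n",
    length(x$accession_ids), length(x$marker_ids),
    length(unique(x$chrom)),
    sprintf("%.2f%%", 100 * nmiss / length(x$dosage))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`.
#' @export
dim_genotypes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  c(n = length(g$accession_ids), m = length(g$marker_ids))
}

#' Subset a genotype matrix by accessions and/or markers
#'
#' @param g a `genotype_matrix`.
#' @param accessions indices or ids of accessions to keep (default all).
#' @param markers indices or ids of markers to keep (default all).
#' @return a `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(g, accessions = NULL, markers = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  ai <- seq_along(g$accession_ids)
  mi <- seq_along(g$marker_ids)
  if (!is.null(accessions)) {
    ai <- if (is.character(accessions)) match(accessions, g$accession_ids) else as.integer(accessions)
    if (any(is.na(ai)) || any(ai < 1L) || any(ai > length(g$accession_ids))) {
      ck_stop("unknown accession in subset")
    }
  }
  if (!is.null(markers)) {
    mi <- if (is.character(markers)) match(markers, g$marker_ids) else as.integer(markers)
    if (any(is.na(mi))) ck_stop("unknown marker in subset")
  }
  genotype_matrix(g$dosage[ai, mi, drop = FALSE], g$chrom[mi], g$pos[mi],
                  accession_ids = g$accession_ids[ai],
                  marker_ids = g$marker_ids[mi])
}

#' Per-marker allele frequencies
#'
#' Computes, over non-missing calls, the alternate-allele frequency, the minor
#' allele frequency, and which of the two alleles are observed at all.
#'
#' @param g a `genotype_matrix`.
#' @return list with fields `alt_freq` (in \[0,1\]), `maf` (in \[0,0.5\]) and
#'   `allele_presence`, an m x 2 logical matrix (ref observed, alt observed).
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  ncall <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  alt_freq <- ifelse(ncall > 0, alt / (2 * ncall), NA_real_)
  pres <- cbind(ref = colSums(d < 2, na.rm = TRUE) > 0,
                alt = colSums(d > 0, na.rm = TRUE) > 0)
  rownames(pres) <- g$marker_ids
  list(alt_freq = setNames(alt_freq, g$marker_ids),
       maf = setNames(pmin(alt_freq, 1 - alt_freq), g$marker_ids),
       allele_presence = pres)
}

#' Read genotypes from VCF, PLINK text, or a dosage TSV
#'
#' Three plain-text dialects are supported. `vcf`: VCF 4.x, GT field only;
#' multi-allelic records are skipped with a message. `plink_text`: a
#' whitespace-delimited .ped with its companion .map (pass the .ped path; the
#' .map is found by extension swap or via `map_path`). `matrix_tsv`: a
#' tab-separated table whose header row holds marker ids, first column holds
#' accession ids and cells are dosages in \{0,1,2,NA\}; the marker map is
#' parsed from ids of the form `chr_pos` when possible, otherwise markers are
#' placed on one pseudo-chromosome at consecutive positions.
#'
#' Samples are inbred lines: heterozygous calls become dosage 1.
#'
#' @param path input file path.
#' @param format one of `"vcf"`, `"plink_text"`, `"matrix_tsv"`.
#' @param map_path optional .map path for `plink_text`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_text", "matrix_tsv"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) ck_stop("cannot read '", path, "'")
  switch(format,
         vcf = read_vcf_gt(path),
         plink_text = read_plink_text(path, map_path),
         matrix_tsv = read_matrix_tsv(path))
}

# Minimal GT-only parser for uncompressed biallelic VCF text.
read_vcf_gt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) ck_stop("no #CHROM header line in VCF")
  fields <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(fields) < 10L) ck_stop("VCF has no sample columns")
  samples <- fields[-(1:9)]
  if (anyDuplicated(samples)) ck_stop("duplicate accession id in VCF")
  body <- lines[-seq_len(hdr)]
  body <- body[!startsWith(body, "#")]
  rows <- strsplit(body, "\t", fixed = TRUE)
  n_skip <- 0L
  chrom <- character(0); pos <- integer(0); ids <- character(0)
  dos <- list()
  for (r in rows) {
    if (length(r) < 10L) next
    alt <- r[5]
    if (grepl(",", alt, fixed = TRUE)) { n_skip <- n_skip + 1L; next }
    gt_idx <- match("GT", strsplit(r[9], ":", fixed = TRUE)[[1]])
    if (is.na(gt_idx)) ck_stop("VCF record without GT field")
    calls <- vapply(strsplit(r[-(1:9)], ":", fixed = TRUE), `[`, "", gt_idx)
    al <- strsplit(calls, "[/|]")
    d <- vapply(al, function(a) {
      if (any(a == ".")) return(NA_real_)
      sum(as.numeric(a))
    }, 0)
    chrom <- c(chrom, r[1]); pos <- c(pos, as.integer(r[2]))
    id <- r[3]
    ids <- c(ids, if (is.na(id) || id == ".") paste0(r[1], "_", r[2]) else id)
    dos[[length(dos) + 1L]] <- d
  }
  if (n_skip > 0L) message(n_skip, " multi-allelic VCF record(s) skipped")
  if (length(dos) == 0L) ck_stop("no biallelic markers in VCF")
  mat <- do.call(cbind, dos)
  dimnames(mat) <- list(samples, ids)
  genotype_matrix(mat, chrom, pos)
}

read_plink_text <- function(ped_path, map_path = NULL) {
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(map_path)) ck_stop("cannot read map file '", map_path, "'")
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4L) ck_stop(".map needs 4 columns (chrom, id, cM, pos)")
  ped <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE)
  m <- nrow(map)
  if (ncol(ped) != 6L + 2L * m) ck_stop(".ped column count does not match .map")
  ids <- as.character(ped[[2]])
  if (anyDuplicated(ids)) ck_stop("duplicate accession id in .ped")
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(m), drop = FALSE])
  dos <- matrix(NA_real_, nrow(ped), m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    al <- al[!al %in% c("0", "N", "-")]
    lev <- sort(unique(al))
    if (length(lev) > 2L) ck_stop("marker ", map[[2]][j], " is not biallelic")
    if (length(lev) == 0L) next
    # alternate allele = the rarer one (ties: later in sort order)
    cnt <- table(factor(al, levels = lev))
    alt <- lev[max(which(cnt == min(cnt)))]  # rarer allele; tie -> later level
    if (length(lev) == 1L) alt <- lev        # monomorphic: count that allele
    miss <- a1[, j] %in% c("0", "N", "-") | a2[, j] %in% c("0", "N", "-")
    dos[, j] <- (a1[, j] == alt) + (a2[, j] == alt)
    dos[miss, j] <- NA_real_
  }
  dimnames(dos) <- list(ids, as.character(map[[2]]))
  genotype_matrix(dos, as.character(map[[1]]), as.integer(map[[4]]))
}

read_matrix_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    row.names = 1L, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  mat <- as.matrix(tab)
  storage.mode(mat) <- "double"
  ids <- colnames(mat)
  parsed <- regmatches(ids, regexec("^(.+)_([0-9]+)$", ids))
  ok <- lengths(parsed) == 3L
  if (all(ok)) {
    chrom <- vapply(parsed, `[`, "", 2L)
    pos <- as.integer(vapply(parsed, `[`, "", 3L))
  } else {
    chrom <- rep("1", ncol(mat))
    pos <- seq_len(ncol(mat))
  }
  genotype_matrix(mat, chrom, pos)
}

#' Write a genotype matrix as a dosage TSV
#'
#' Inverse of `read_genotypes(format = "matrix_tsv")` when marker ids encode
#' `chr_pos`.
#'
#' @param g a `genotype_matrix`.
#' @param path output path.
#' @export
write_matrix_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- data.frame(accession = g$accession_ids, g$dosage,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
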