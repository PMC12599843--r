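test_that("VCF parsing maps GT to dosage, skips multi-allelic records", {
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
           "1\t100\tsnp1\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
           "1\t200\tsnp2\tA\tG,T\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
           "1\t300\tsnp3\tC\tT\t.\t.\t.\tGT\t./.\t0|0\t1|1",
           "2\t50\tsnp4\tG\tC\t.\t.\t.\tGT\t1/1\t1/1\t0/0",
           "2\t80\tsnp5\tG\tA\t.\t.\t.\tGT\t0/0\t0/0\t0/1",
           "2\t90\tsnp6\tT\tA\t.\t.\t.\tGT\t0/1\t0/1\t0/0")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_message(g <- read_genotypes(path, "vcf"), "multi-allelic")
  expect_equal(unname(dim_genotypes(g)), c(3L, 5L))  # tri-allelic skipped
  expect_equal(unname(g$dosage[, "snp1"]), c(0, 1, 2))
  expect_equal(unname(g$dosage[, "snp3"]), c(NA, 0, 2))
  expect_equal(g$chrom, c("1", "1", "2", "2", "2"))
})

test_that("matrix_tsv round-trips, including missing cells", {
  g <- toy_genotypes()
  g$dosage[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(g, path)
  g2 <- read_genotypes(path, "matrix_tsv")
  expect_equal(g2$dosage, g$dosage)
  expect_true(is.na(g2$dosage[2, 3]))
})

test_that("PLINK text parsing counts the minor allele", {
  map <- c("1\tmk1\t0\t100", "1\tmk2\t0\t200")
  ped <- c("F1 I1 0 0 0 -9 A A A G",
           "F2 I2 0 0 0 -9 A G G G",
           "F3 I3 0 0 0 -9 G G 0 0")
  pp <- withr::local_tempfile(fileext = ".ped")
  mp <- sub("\\.ped$", ".map", pp)
  writeLines(ped, pp); writeLines(map, mp)
  g <- read_genotypes(pp, "plink_text")
  # mk1: alleles A,A | A,G | G,G -> G is minor (3 of 6)? counts A=3 G=3 tie ->
  # later sort level G; dosages count G copies
  expect_equal(unname(g$dosage[, "mk1"]), c(0, 1, 2))
  expect_equal(unname(g$dosage[, "mk2"]), c(1, 0, NA))
})

test_that("constructor validates and sorts the marker map", {
  d <- matrix(c(0, 1, 2, 0), 2, 2)
  g <- genotype_matrix(d, chrom = c("2", "1"), pos = c(5L, 9L))
  expect_equal(g$chrom, c("1", "2"))
  expect_error(genotype_matrix(matrix(3, 2, 1), "1", 1L), "dosage")
  expect_error(genotype_matrix(matrix(0, 2, 2, dimnames = list(c("a", "a"), NULL)),
                               c("1", "1"), c(1L, 2L)), "duplicate")
})

test_that("filter_missingness removes markers first, then accessions", {
  d <- rbind(c(NA, 0, 1, 2), c(NA, NA, NA, 0), c(NA, 1, 1, 1), c(2, 2, 0, 0))
  g <- genotype_matrix(d, rep("1", 4), 1:4 * 10L)
  f <- filter_missingness(g, 0.5)
  # marker 1 is 75% missing -> dropped; then accession 2 misses 2 of 3 -> dropped
  expect_equal(unname(dim_genotypes(f)), c(3L, 3L))
  expect_false("acc2" %in% f$accession_ids)
  g2 <- toy_genotypes()
  expect_equal(filter_missingness(g2)$dosage, g2$dosage)  # identity, no NA
})

test_that("impute_mode fills with modal dosage, ties toward lower", {
  d <- rbind(c(0, 0, NA), c(0, 2, 2), c(2, NA, 0), c(NA, 2, NA))
  g <- genotype_matrix(d, rep("1", 3), c(1L, 2L, 3L))
  f <- impute_mode(g)
  expect_equal(unname(f$dosage[, 1]), c(0, 0, 2, 0))  # mode 0
  expect_equal(unname(f$dosage[, 2]), c(0, 2, 2, 2))  # mode 2
  expect_equal(unname(f$dosage[, 3]), c(0, 2, 0, 0))  # tie 0/2 -> 0
  expect_equal(impute_mode(f)$dosage, f$dosage)       # complete -> identity
  g$dosage[, 2] <- NA
  expect_error(impute_mode(g), "fully missing")
})

test_that("filter_maf keeps strictly-above-threshold markers", {
  d <- cbind(rep(0, 100), c(1, rep(0, 99)), c(1, 1, 1, 1, rep(0, 96)))
  d <- rbind(d, d[1:2, ])  # n = 102 -> freqs 0, ~0.0049, ~0.0196
  g <- genotype_matrix(d, rep("1", 3), c(1L, 2L, 3L))
  f <- filter_maf(g, 0.01)
  expect_equal(length(f$marker_ids), 1L)
  expect_error(filter_maf(g, 0.49), "no markers")
})

test_that("ld_prune drops one member of each high-r2 pair, deterministically", {
  set.seed(9)
  x <- sample(0:2, 40, replace = TRUE)
  y <- sample(0:2, 40, replace = TRUE)
  # duplicated marker pair: r2 = 1 -> exactly one survives
  g <- genotype_matrix(cbind(m1 = x, m2 = x, m3 = y), rep("1", 3), c(1L, 5L, 9L))
  f <- ld_prune(g, window = 3, step = 1, r2_max = 0.4)
  expect_equal(length(f$marker_ids), 2L)
  expect_true("m3" %in% f$marker_ids)
  # three mutually duplicated equal-MAF markers -> one retained
  g3 <- genotype_matrix(cbind(m1 = x, m2 = x, m3 = x), rep("1", 3), c(1L, 5L, 9L))
  expect_equal(length(ld_prune(g3, window = 3, step = 1)$marker_ids), 1L)
  # r2_max >= 1 is the identity
  expect_equal(ld_prune(g, window = 3, step = 1, r2_max = 1)$marker_ids,
               g$marker_ids)
  expect_error(ld_prune(g, window = 1), "window")
})

test_that("ld_prune leaves mutually independent markers untouched", {
  g <- mini_panel()$genotypes
  f <- ld_prune(g, window = 20, step = 5, r2_max = 0.4)
  expect_lt(length(f$marker_ids), length(g$marker_ids))  # copula LD pruned
  f2 <- ld_prune(f, window = 20, step = 5, r2_max = 0.4)
  expect_equal(f2$marker_ids, f$marker_ids)  # idempotent
})

test_that("QC filters are idempotent", {
  g <- mini_panel()$genotypes
  expect_equal(filter_missingness(filter_missingness(g))$dosage,
               filter_missingness(g)$dosage)
  expect_equal(filter_maf(filter_maf(g))$dosage, filter_maf(g)$dosage)
})

test_that("rogers_distance matches the per-locus formula and is a metric", {
  g <- toy_genotypes()
  d <- rogers_distance(g)
  expect_equal(unname(diag(d$d)), rep(0, 4))
  # a1 vs a2 differ by 1 dosage at marker 2 only: mean(|diff|/2) = 1/8
  expect_equal(d$d["a1", "a2"], 1 / 8)
  # opposite homozygotes at every locus -> 1
  g2 <- genotype_matrix(rbind(rep(0, 3), rep(2, 3)), rep("1", 3), 1:3)
  expect_equal(rogers_distance(g2)$d[1, 2], 1)
  # one locus, dosages 1 vs 2 -> 0.5
  g3 <- genotype_matrix(rbind(a = 1, b = 2), "1", 1L)
  expect_equal(rogers_distance(g3)$d[1, 2], 0.5)
  # metric properties on a random 10 x 20 panel
  set.seed(11)
  gm <- genotype_matrix(matrix(sample(0:2, 200, TRUE), 10, 20),
                        rep("1", 20), 1:20)
  dm <- rogers_distance(gm)$d
  expect_equal(dm, t(dm))
  expect_true(all(dm >= 0))
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
  }
})

test_that("kinship_vanraden equals the brute-force double loop", {
  set.seed(21)
  for (rep in 1:3) {
    n <- sample(4:10, 1); m <- sample(5:20, 1)
    d <- matrix(sample(0:2, n * m, TRUE), n, m)
    d[, 1] <- c(0, 2, rep(0:1, length.out = n - 2))  # guarantee polymorphism
    g <- genotype_matrix(d, rep("1", m), seq_len(m))
    K <- kinship_vanraden(g)$K
    p <- colMeans(d) / 2
    denom <- 2 * sum(p * (1 - p))
    Kref <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      Kref[i, j] <- sum((d[i, ] - 2 * p) * (d[j, ] - 2 * p)) / denom
    }
    expect_equal(unname(K), Kref, tolerance = 1e-10)
  }
})

test_that("kinship of identical inbred accessions ties self- and cross-terms", {
  d <- rbind(a = c(0, 2, 2, 0), b = c(0, 2, 2, 0), c = c(2, 0, 0, 2),
             e = c(0, 0, 2, 2))
  g <- genotype_matrix(d, rep("1", 4), 1:4 * 10L)
  K <- kinship_vanraden(g)$K
  expect_equal(K[1, 2], K[1, 1])
  # column-centered Z: K row sums weighted by 1-vector vanish
  expect_equal(sum(K), 0, tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})
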