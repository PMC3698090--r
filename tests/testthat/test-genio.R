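test_that("VCF genotypes become minor-allele doses with correct MAF", {
  path <- withr::local_tempfile(fileext = ".vcf")
  gt <- rbind(c("0/0", "0/1", "1/1", "0/0", "0/0"),
              c("1/1", "1/1", "1/1", "1/1", "1/0"),
              c("0/0", "./.", "0/1", "0/0", "0/0"))
  write_vcf_fixture(path, rep("1", 3), c(100, 200, 300), rep("A", 3),
                    rep("T", 3), gt, paste0("S", 1:5))
  gm <- read_vcf_genotypes(path)
  # site 1: direct dose count
  expect_equal(unname(gm$counts[, 1]), c(0, 1, 2, 0, 0))
  expect_equal(gm$maf[1], 0.3)
  # site 2: alt frequency 0.9 -> coding flipped
  expect_true(gm$variants$flipped[2])
  expect_equal(unname(gm$counts[, 2]), c(0, 0, 0, 0, 1))
  expect_equal(gm$maf[2], 0.1)
  # site 3: missing genotype preserved, MAF over non-missing
  expect_true(is.na(gm$counts[2, 3]))
  expect_equal(gm$maf[3], 1 / 8)
})

test_that("three-subject single-site example gives doses (0,1,2), maf 0.5", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(path, "1", 50, "C", "G",
                    matrix(c("0/0", "0/1", "1/1"), nrow = 1), paste0("S", 1:3))
  gm <- read_vcf_genotypes(path)
  expect_equal(unname(gm$counts[, 1]), c(0, 1, 2))
  expect_equal(gm$maf, 0.5)
})

test_that("VCF region filter is 1-based inclusive and errors when empty", {
  path <- withr::local_tempfile(fileext = ".vcf")
  gt <- rbind(c("0/1", "0/0"), c("0/0", "0/1"), c("0/1", "0/1"))
  write_vcf_fixture(path, rep("7", 3), c(10, 20, 30), rep("A", 3),
                    rep("C", 3), gt, c("S1", "S2"))
  gm <- read_vcf_genotypes(path, region = "7:20-30")
  expect_equal(gm$variants$pos, c(20L, 30L))
  expect_error(read_vcf_genotypes(path, region = "7:40-50"), "no variants")
  expect_error(read_vcf_genotypes(path, region = "nonsense"), "chrom:start-end")
})

test_that("simulated genotypes round-trip through VCF unchanged", {
  pool <- gen_pool(n_haps = 40, n_sites = 10, p_min = 0.02, seed = 7)
  coh <- null_cohort(pool, n = 20, seed = 3)
  gm <- coh$gm
  path <- withr::local_tempfile(fileext = ".vcf")
  dose_to_gt <- c("0/0", "0/1", "1/1")
  gt <- t(matrix(dose_to_gt[gm$counts + 1], nrow = nrow(gm$counts)))
  write_vcf_fixture(path, rep("1", ncol(gm$counts)), gm$variants$pos,
                    rep("A", ncol(gm$counts)), rep("G", ncol(gm$counts)),
                    gt, gm$subjects)
  back <- read_vcf_genotypes(path)
  expect_equal(unname(back$counts), unname(gm$counts))
  expect_equal(back$subjects, gm$subjects)
  expect_equal(back$variants$pos, gm$variants$pos)
  expect_equal(back$maf, gm$maf)
})

test_that("genotype TSV round-trips and rejects bad cells", {
  gm <- toy_gm(matrix(c(0, 1, 2, 0, 1, 1), nrow = 3,
                      dimnames = list(paste0("S", 1:3), c("v1", "v2"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(gm, path)
  back <- read_genotype_table(path)
  expect_equal(back$counts, gm$counts)
  expect_equal(back$variants$id, gm$variants$id)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tS1\tS2", "v1\t0\t3"), bad)
  expect_error(read_genotype_table(bad), "0, 1, 2")
})

test_that("phenotype table detects trait kind and covariates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tpheno\tage", "S1\t1\t50", "S2\t0\t61", "S3\t1\t44"),
             path)
  pc <- read_phenotype_table(path)
  expect_s3_class(pc, "pheno_covar")
  expect_equal(pc$trait_kind, "dichotomous")
  expect_equal(colnames(pc$covariates), "age")

  qt <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tpheno", "S1\t1.5", "S2\t-0.3"), qt)
  expect_equal(read_phenotype_table(qt)$trait_kind, "quantitative")
})

test_that("subject alignment intersects by ID with a warning", {
  gm <- toy_gm(matrix(rep(c(0, 1), 10), nrow = 5,
                      dimnames = list(paste0("S", 1:5), NULL)))
  pc <- pheno_covar(c("S9", "S3", "S1", "S2"), c(1, 0, 1, 0))
  expect_warning(al <- align_subjects(gm, pc), "dropped")
  expect_equal(al$gm$subjects, c("S1", "S2", "S3"))
  expect_equal(al$pc$id, al$gm$subjects)
  # by-ID pairing: S3 kept its own phenotype
  expect_equal(al$pc$phenotype[al$pc$id == "S3"], 0)
})

test_that("compute_maf matches direct counts and is flip-invariant", {
  expect_equal(compute_maf(c(0, 1, 2, 1)), 0.5)
  expect_equal(compute_maf(c(0, 0, 0, 1)), 0.125)
  expect_error(compute_maf(c(NA, NA)), "missing")
  set.seed(11)
  for (i in 1:20) {
    g <- sample(0:2, 30, replace = TRUE)
    expect_equal(compute_maf(g), compute_maf(2 - g))
  }
})

test_that("sample MAF of a simulated variant matches the pool frequency", {
  pool <- shared_pool()
  set.seed(5)
  j <- which.max(pool$freq)  # most common site: tightest binomial check
  p <- pool$freq[j]
  i1 <- sample.int(nrow(pool$haps), 4000, replace = TRUE)
  i2 <- sample.int(nrow(pool$haps), 4000, replace = TRUE)
  g <- pool$haps[i1, j] + pool$haps[i2, j]
  se <- sqrt(p * (1 - p) / (2 * 4000))
  expect_lt(abs(compute_maf(g) - p), 4 * se)
})

test_that("monomorphic variants are dropped with a message", {
  counts <- cbind(a = c(0, 0, 0), b = c(0, 1, 2))
  expect_message(gm <- genotype_matrix(counts), "monomorphic")
  expect_equal(gm$variants$id, "b")
})

test_that("duplicate subject or variant IDs are rejected", {
  expect_error(genotype_matrix(matrix(0:1, 2, 1),
                               subjects = c("S1", "S1")), "duplicate")
  expect_error(
    genotype_matrix(matrix(c(0, 1, 0, 1), 2, 2),
                    variants = data.frame(id = c("v", "v"))), "duplicate")
})
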