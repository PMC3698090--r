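test_that("generated pools are reproducible and match the target spectrum", {
  pool1 <- gen_pool(seed = 61)
  pool2 <- gen_pool(seed = 61)
  expect_identical(pool1, pool2)
  expect_false(identical(pool1$haps, gen_pool(seed = 62)$haps))

  # realized frequencies follow the truncated 1/x spectrum
  p_min <- 5e-4
  cdf <- function(p) log(p / p_min) / log(0.5 / p_min)
  u <- cdf(pmin(pmax(pool1$freq, p_min), 0.5))
  D <- suppressWarnings(stats::ks.test(u, "punif"))$statistic
  expect_lt(unname(D), 0.1)

  # most rare sites sit below MAF 0.01, as in resequenced gene regions
  rare <- pool1$freq[pool1$freq <= 0.04]
  expect_gt(length(rare), 150)
  frac_below_01 <- mean(rare < 0.01)
  expect_gt(frac_below_01, 0.5)
  expect_lt(frac_below_01, 0.9)
})

test_that("same-block sites show elevated LD relative to cross-block", {
  pool <- gen_pool(n_haps = 1000, n_sites = 100, block_len = 20, seed = 63)
  informative <- which(pool$freq >= 0.01)
  h <- pool$haps[, informative]
  blocks <- ceiling(informative / 20)
  r2 <- suppressWarnings(cor(h))^2
  same <- outer(blocks, blocks, "==")
  off_diag <- upper.tri(r2)
  within <- r2[off_diag & same]
  across <- r2[off_diag & !same]
  expect_gt(mean(within, na.rm = TRUE), 5 * mean(across, na.rm = TRUE))
  expect_lt(mean(across, na.rm = TRUE), 0.02)
})

test_that("phased VCF pools load with per-haplotype alleles", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(path, "5", 1000, "A", "G",
                    matrix(c("0|1", "1|1"), nrow = 1), c("S1", "S2"))
  pool <- load_pool_from_phased_vcf(path)
  expect_equal(nrow(pool$haps), 4)
  # alt frequency 3/4 -> minor-oriented frequency 1/4
  expect_equal(pool$freq, 0.25)

  unph <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(unph, "5", 1000, "A", "G",
                    matrix(c("0/1", "1|1"), nrow = 1), c("S1", "S2"))
  expect_error(load_pool_from_phased_vcf(unph), "unphased")
  expect_s3_class(load_pool_from_phased_vcf(unph, force_phase_as_is = TRUE),
                  "haplotype_pool")
})

test_that("pools round-trip through phased VCF and TSV", {
  pool <- gen_pool(n_haps = 40, n_sites = 12, p_min = 0.05, seed = 64)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf_from_pool(pool, vcf)
  back <- load_pool_from_phased_vcf(vcf)
  expect_equal(back$haps, pool$haps, ignore_attr = TRUE)
  expect_equal(back$freq, pool$freq)
  expect_equal(back$positions, pool$positions)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pool(pool, tsv)
  back2 <- read_pool(tsv)
  expect_equal(back2$haps, pool$haps, ignore_attr = TRUE)
  expect_equal(back2$positions, pool$positions)
})

test_that("phased VCF region filter is 1-based inclusive", {
  path <- withr::local_tempfile(fileext = ".vcf")
  gt <- rbind(c("0|1", "0|0"), c("0|0", "0|1"), c("0|1", "1|1"))
  write_vcf_fixture(path, rep("5", 3), c(10, 20, 30), rep("A", 3),
                    rep("C", 3), gt, c("S1", "S2"))
  pool <- load_pool_from_phased_vcf(path, region = "5:10-20")
  expect_equal(pool$positions, c(10L, 20L))
})

test_that("scenario parameters follow the distribution mapping", {
  ks <- vapply(1:7, function(d)
    scenario_spec(d, 0.05)$k, numeric(1))
  expect_equal(ks, c(1, 1, 1.5, 1.5, 2, 2, 2.5))
  mm <- vapply(1:7, function(d)
    scenario_spec(d, 0.05)$mean_multiplier, numeric(1))
  expect_equal(mm, c(2, 2, 1, 1, 0.5, 0.5, 0))
  nf <- vapply(1:7, function(d)
    scenario_spec(d, 0.05)$neg_fraction, numeric(1))
  expect_equal(nf, c(0, 0.2, 0, 0.2, 0, 0.2, 0))
  expect_equal(scenario_spec(1, 0.05)$sigma_scale, 1)
  expect_equal(scenario_spec(1, 0.1)$sigma_scale, 0.7)
  expect_equal(scenario_spec(1, 0.2)$sigma_scale, 0.5)
  expect_error(scenario_spec(1, 0.15), "sigma_scale")
})

test_that("effect scale follows -0.04 log(p) / k and decreases in p", {
  # pool with an exact MAF 0.01 site
  H <- 1000
  haps <- cbind(c(rep(1, 10), rep(0, H - 10)),   # p = 0.01
                c(rep(1, 30), rep(0, H - 30)),   # p = 0.03
                c(rep(1, 2), rep(0, H - 2)))     # p = 0.002
  pool <- haplotype_pool(haps, c(100, 200, 300))
  spec <- scenario_spec(1, 0.99, sigma_scale = 1)
  eff <- draw_effects(pool, spec, seed = 65)
  expect_setequal(eff$causal_sites, 1:3)
  sv <- eff$sigma_v[match(1, eff$causal_sites)]
  expect_equal(sv, -0.04 * log(0.01), tolerance = 1e-12)
  expect_equal(sv, 0.1842, tolerance = 1e-3)
  # rarer site, larger scale
  ord <- order(pool$freq[eff$causal_sites])
  expect_true(all(diff(eff$sigma_v[ord]) <= 0))
  # log10 option
  eff10 <- draw_effects(pool, spec, log_base = "log10", seed = 65)
  expect_equal(eff10$sigma_v[match(1, eff10$causal_sites)],
               -0.04 * log10(0.01), tolerance = 1e-12)
})

test_that("effect draws match their scenario distribution", {
  H <- 1000
  haps <- cbind(c(rep(1, 10), rep(0, H - 10)))
  pool <- haplotype_pool(haps, 1)
  spec1 <- scenario_spec(1, 0.99, sigma_scale = 1)
  spec2 <- scenario_spec(2, 0.99, sigma_scale = 1)
  spec7 <- scenario_spec(7, 0.99, sigma_scale = 1)
  sv <- -0.04 * log(0.01)
  b1 <- vapply(1:800, function(i)
    draw_effects(pool, spec1, seed = i)$beta, numeric(1))
  expect_lt(abs(mean(b1) - 2 * sv), 4 * sv / sqrt(800))
  expect_lt(abs(sd(b1) / sv - 1), 0.15)
  # distribution 7 is mean zero by construction
  b7 <- vapply(1:800, function(i)
    draw_effects(pool, spec7, seed = i)$beta, numeric(1))
  expect_lt(abs(mean(b7)), 4 * sv / sqrt(800))
  # distribution 2 flips about 20% of sign draws
  s2 <- vapply(1:800, function(i)
    draw_effects(pool, spec2, seed = i)$sign, integer(1))
  expect_gt(mean(s2 < 0), 0.14)
  expect_lt(mean(s2 < 0), 0.26)
  # the 10%-causal scale multiplier shrinks both mean and sd
  spec1b <- scenario_spec(1, 0.99, sigma_scale = 0.7)
  b1b <- vapply(1:400, function(i)
    draw_effects(pool, spec1b, seed = i)$beta, numeric(1))
  expect_lt(abs(mean(b1b) - 0.7 * 2 * sv), 4 * 0.7 * sv / sqrt(400))
})

test_that("intercept calibration hits the target prevalence", {
  pool <- shared_pool()
  # closed form with no effects
  spec <- scenario_spec(7, 0, sigma_scale = 1)
  eff0 <- draw_effects(pool, spec, seed = 66)
  expect_equal(calibrate_intercept(pool, eff0, 0.10), qlogis(0.10))

  spec1 <- scenario_spec(1, 0.2)
  eff <- draw_effects(pool, spec1, seed = 67)
  mu0 <- calibrate_intercept(pool, eff, 0.10, n_mc = 1e5, seed = 68)
  # realized prevalence on a fresh sample
  set.seed(69)
  H <- nrow(pool$haps)
  s <- ramltest:::genetic_scores(pool, eff,
                                 sample.int(H, 1e5, replace = TRUE),
                                 sample.int(H, 1e5, replace = TRUE))
  expect_lt(abs(mean(plogis(mu0 + s)) - 0.10), 0.005)
  # doubling effects and recalibrating restores the target
  eff2 <- eff
  eff2$beta <- 2 * eff$beta
  mu0b <- calibrate_intercept(pool, eff2, 0.10, n_mc = 1e5, seed = 68)
  s2 <- 2 * s
  expect_lt(abs(mean(plogis(mu0b + s2)) - 0.10), 0.005)
})

test_that("cohorts reach exact case/control targets and fixed-seed identity", {
  pool <- shared_pool()
  spec <- scenario_spec(3, 0.1, n_cases = 150, n_controls = 100)
  eff <- draw_effects(pool, spec, seed = 70)
  mu0 <- calibrate_intercept(pool, eff, n_mc = 2e4)
  coh1 <- simulate_cohort(pool, eff, mu0, spec, seed = 71)
  coh2 <- simulate_cohort(pool, eff, mu0, spec, seed = 71)
  expect_identical(coh1$gm$counts, coh2$gm$counts)
  expect_equal(sum(coh1$pc$phenotype == 1), 150)
  expect_equal(sum(coh1$pc$phenotype == 0), 100)
  # genotype dose is the sum of two pool haplotypes
  expect_true(all(coh1$gm$counts %in% 0:2))
})

test_that("null cohorts show no case-control dose difference", {
  pool <- shared_pool()
  coh <- null_cohort(pool, n = 600, seed = 72)
  ca <- colMeans(coh$gm$counts[coh$pc$phenotype == 1, , drop = FALSE])
  co <- colMeans(coh$gm$counts[coh$pc$phenotype == 0, , drop = FALSE])
  common <- coh$gm$maf > 0.05
  expect_gt(stats::t.test(ca[common] - co[common])$p.value, 0.001)
})

test_that("a single strong causal variant shows the expected odds ratio", {
  # beta = log 2 at a common-ish site
  H <- 2000
  set.seed(73)
  haps <- cbind(rbinom(H, 1, 0.2), rbinom(H, 1, 0.3))
  pool <- haplotype_pool(haps, c(10, 20))
  eff <- structure(list(causal_sites = 1L, beta = log(2), sign = 1L,
                        sigma_v = 0.1),
                   class = "effect_assignment")
  mu0 <- calibrate_intercept(pool, eff, 0.10)
  spec <- scenario_spec(1, 0.05, n_cases = 3000, n_controls = 3000)
  coh <- simulate_cohort(pool, eff, mu0, spec, seed = 74)
  y <- coh$pc$phenotype
  j <- match("v10", coh$gm$variants$id)
  f_ca <- mean(coh$gm$counts[y == 1, j]) / 2
  f_co <- mean(coh$gm$counts[y == 0, j]) / 2
  or_allele <- (f_ca / (1 - f_ca)) / (f_co / (1 - f_co))
  expect_gt(or_allele, 1.75)
  expect_lt(or_allele, 2.3)
})

test_that("accrual failure is reported when prevalence is unreachable", {
  pool <- gen_pool(n_haps = 50, n_sites = 10, p_min = 0.02, seed = 75)
  spec <- scenario_spec(7, 0, n_cases = 50, n_controls = 10,
                        sigma_scale = 1)
  eff <- draw_effects(pool, spec, seed = 76)
  expect_error(
    simulate_cohort(pool, eff, qlogis(1e-4), spec, seed = 77,
                    max_draws = 2000),
    "accrual")
})
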