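# fixtures are built in code at test time; nothing binary is stored

# minimal VCF writer for genotype matrices / haplotype pairs
write_vcf_fixture <- function(path, chrom, pos, ref, alt, gt_rows,
                              samples) {
  # gt_rows: character matrix, variants x samples, entries like "0/1" or "0|1"
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(chrom)[1], ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], paste0("var", i), ref[i], alt[i], ".", "PASS",
            ".", "GT", gt_rows[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# phased VCF from a haplotype pool (two consecutive rows per sample)
write_phased_vcf_from_pool <- function(pool, path, chrom = "1") {
  H <- nrow(pool$haps)
  stopifnot(H %% 2 == 0)
  n_sam <- H / 2
  gt <- matrix("", nrow = ncol(pool$haps), ncol = n_sam)
  for (s in seq_len(n_sam)) {
    a <- pool$haps[2 * s - 1, ]
    b <- pool$haps[2 * s, ]
    gt[, s] <- paste0(a, "|", b)
  }
  write_vcf_fixture(path, rep(chrom, ncol(pool$haps)), pool$positions,
                    rep("A", ncol(pool$haps)), rep("G", ncol(pool$haps)),
                    gt, paste0("S", seq_len(n_sam)))
}

# small genotype matrix with known doses
toy_gm <- function(counts, ...) {
  suppressMessages(genotype_matrix(counts, ...))
}

# balanced case-control phenotype for n subjects
toy_pheno <- function(n, subjects = paste0("S", seq_len(n))) {
  pheno_covar(subjects, rep(c(1, 0), each = n / 2))
}

# a small cohort simulated under the global null, reused by several tests
null_cohort <- function(pool, n = 200, seed = 1) {
  spec <- scenario_spec(7, 0, n_cases = n / 2, n_controls = n / 2,
                        sigma_scale = 1)
  eff <- draw_effects(pool, spec, seed = seed)
  coh <- simulate_cohort(pool, eff, qlogis(0.1), spec, seed = seed + 1)
  coh
}

# shared medium pool (built once per test run)
shared_pool <- local({
  pool <- NULL
  function() {
    if (is.null(pool)) pool <<- gen_pool(seed = 20240901)
    pool
  }
})
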