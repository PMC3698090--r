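#' Genotype matrix container
#'
#' Builds the aligned subjects-by-variants matrix of minor-allele counts used
#' throughout the package. Counts are doses in \{0, 1, 2\} (NA for missing).
#' Columns whose alternate-allele frequency exceeds 0.5 are flipped so that
#' the \emph{minor} allele is always the one counted; the flip is recorded in
#' the variant table. Monomorphic variants (MAF 0 after orientation) carry no
#' association information and are dropped with a message.
#'
#' @param counts integer matrix, subjects in rows, variants in columns,
#'   entries in \{0, 1, 2\} or NA.
#' @param variants data frame with one row per column of `counts`; columns
#'   `id`, `chrom`, `pos`, `ref`, `alt` (missing columns are filled with
#'   placeholders).
#' @param subjects character vector of subject IDs (defaults to rownames).
#' @param drop_monomorphic drop zero-MAF variants (default TRUE).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `counts`, `variants` (with a logical `flipped` column), `subjects` and
#'   `maf` (per-variant minor allele frequency, the method's p).
#' @export
genotype_matrix <- function(counts, variants = NULL, subjects = NULL,
                            drop_monomorphic = TRUE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  bad <- !is.na(counts) & !(counts %in% c(0, 1, 2))
  if (any(bad)) {
    stop("genotype counts must be 0, 1, 2 or NA; first offending value: ",
         counts[which(bad)[1L]])
  }
  n <- nrow(counts)
  m <- ncol(counts)
  if (is.null(subjects)) {
    subjects <- rownames(counts)
    if (is.null(subjects)) subjects <- paste0("S", seq_len(n))
  }
  if (anyDuplicated(subjects)) stop("duplicate subject IDs")
  if (length(subjects) != n) stop("subjects length does not match rows")
  if (is.null(variants)) {
    variants <- data.frame(id = colnames(counts) %||% paste0("V", seq_len(m)))
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (nrow(variants) != m) stop("variant table does not match columns")
  if (is.null(variants$id)) variants$id <- paste0("V", seq_len(m))
  for (col in c("chrom", "ref", "alt")) {
    if (is.null(variants[[col]])) variants[[col]] <- NA_character_
  }
  if (is.null(variants$pos)) variants$pos <- NA_integer_
  if (anyDuplicated(variants$id)) stop("duplicate variant IDs")

  # orient to the minor allele
  f <- colMeans(counts, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  if (any(flip)) counts[, flip] <- 2 - counts[, flip]
  variants$flipped <- flip

  n_obs <- colSums(!is.na(counts))
  if (any(n_obs == 0L)) stop("variant with all genotypes missing: ",
                             variants$id[which(n_obs == 0L)[1L]])
  maf <- colSums(counts, na.rm = TRUE) / (2 * n_obs)

  if (drop_monomorphic && any(maf == 0)) {
    k <- sum(maf == 0)
    message("dropping ", k, " monomorphic variant", if (k > 1L) "s")
    keep <- maf > 0
    counts <- counts[, keep, drop = FALSE]
    variants <- variants[keep, , drop = FALSE]
    maf <- maf[keep]
  }
  rownames(counts) <- subjects
  colnames(counts) <- variants$id
  rownames(variants) <- NULL

  structure(
    list(counts = counts, variants = variants, subjects = subjects,
         maf = unname(maf)),
    class = "genotype_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$subjects), "subjects x",
      nrow(x$variants), "variants\n")
  if (nrow(x$variants)) {
    cat("  MAF range:", format(min(x$maf), digits = 3), "-",
        format(max(x$maf), digits = 3), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Subset a genotype matrix by variant index
#' @param gm a `genotype_matrix`.
#' @param j variant indices (integer or logical).
#' @return a `genotype_matrix` restricted to the selected variants.
#' @export
subset_variants <- function(gm, j) {
  stopifnot(inherits(gm, "genotype_matrix"))
  structure(
    list(counts = gm$counts[, j, drop = FALSE],
         variants = gm$variants[j, , drop = FALSE],
         subjects = gm$subjects,
         maf = gm$maf[j]),
    class = "genotype_matrix"
  )
}

#' Minor allele frequency of one dose vector
#'
#' MAF is `min(f, 1 - f)` with `f = sum(dose) / (2 * n)` over non-missing
#' entries, so it is invariant to allele-coding flips (`g` vs `2 - g`).
#'
#' @param counts dose vector in \{0, 1, 2\}, NA allowed.
#' @return frequency in [0, 0.5].
#' @export
compute_maf <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (!length(counts)) stop("all genotypes missing")
  f <- sum(counts) / (2 * length(counts))
  min(f, 1 - f)
}

#' Phenotype and covariate container
#'
#' @param id subject IDs.
#' @param phenotype numeric vector; binary \{0,1\} for dichotomous traits.
#' @param covariates optional numeric matrix/data frame of covariates.
#' @param trait_kind "auto" (detect), "dichotomous" or "quantitative".
#' @return An object of class `pheno_covar`.
#' @export
pheno_covar <- function(id, phenotype, covariates = NULL,
                        trait_kind = c("auto", "dichotomous", "quantitative")) {
  trait_kind <- match.arg(trait_kind)
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate subject IDs in phenotype data")
  phenotype <- as.numeric(phenotype)
  if (length(phenotype) != length(id)) stop("phenotype length mismatch")
  if (anyNA(phenotype)) stop("missing phenotype values are not supported")
  if (trait_kind == "auto") {
    trait_kind <- if (all(phenotype %in% c(0, 1))) "dichotomous"
                  else "quantitative"
  }
  if (trait_kind == "dichotomous") {
    if (!all(phenotype %in% c(0, 1))) stop("dichotomous phenotype must be 0/1")
    if (length(unique(phenotype)) < 2L)
      stop("dichotomous phenotype must contain both classes")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != length(id)) stop("covariate row mismatch")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    if (anyNA(covariates)) stop("missing covariate values are not supported")
  }
  structure(list(id = id, phenotype = phenotype, covariates = covariates,
                 trait_kind = trait_kind),
            class = "pheno_covar")
}

#' @exportS3Method base::print
print.pheno_covar <- function(x, ...) {
  cat("pheno_covar:", length(x$id), "subjects,", x$trait_kind, "trait")
  if (x$trait_kind == "dichotomous")
    cat(" (", sum(x$phenotype == 1), "cases /", sum(x$phenotype == 0),
        "controls )")
  cat(",", if (is.null(x$covariates)) 0L else ncol(x$covariates),
      "covariates\n")
  invisible(x)
}

#' Align genotype and phenotype data on shared subjects
#'
#' Takes the intersection of subject IDs, preserving the genotype matrix
#' order; warns when subjects are dropped. Alignment is by ID, never by
#' position, so no phenotype is ever paired with another subject's genotypes.
#'
#' @param gm a `genotype_matrix`.
#' @param pc a `pheno_covar`.
#' @return list with aligned `gm` and `pc`.
#' @export
align_subjects <- function(gm, pc) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(pc, "pheno_covar"))
  common <- intersect(gm$subjects, pc$id)
  if (!length(common)) stop("no subjects shared between genotype and phenotype")
  dropped <- (length(gm$subjects) - length(common)) +
             (length(pc$id) - length(common))
  if (dropped > 0L)
    warning(dropped, " subject record(s) without a match were dropped")
  gi <- match(common, gm$subjects)
  pi <- match(common, pc$id)
  gm2 <- structure(
    list(counts = gm$counts[gi, , drop = FALSE],
         variants = gm$variants, subjects = common, maf = gm$maf),
    class = "genotype_matrix")
  # MAF is recomputed on the aligned (combined case-control) sample
  n_obs <- colSums(!is.na(gm2$counts))
  if (any(n_obs == 0L)) stop("variant with all genotypes missing after alignment")
  gm2$maf <- unname(colSums(gm2$counts, na.rm = TRUE) / (2 * n_obs))
  pc2 <- pheno_covar(common, pc$phenotype[pi],
                     if (!is.null(pc$covariates))
                       pc$covariates[pi, , drop = FALSE],
                     trait_kind = pc$trait_kind)
  list(gm = gm2, pc = pc2)
}

parse_region <- function(region) {
  if (is.null(region)) return(NULL)
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L) stop("region must be 'chrom:start-end', got: ", region)
  list(chrom = m[2L], start = as.integer(m[3L]), end = as.integer(m[4L]))
}

#' Read genotypes from a VCF file
#'
#' Extracts the GT field from an SNV VCF and returns minor-allele doses.
#' Sites with more than one alternate allele are dropped (or rejected)
#' rather than split. Regions use 1-based inclusive coordinates.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param region optional "chrom:start-end" filter, 1-based inclusive.
#' @param multiallelic "drop" (default) or "error".
#' @return a `genotype_matrix`.
#' @export
read_vcf_genotypes <- function(path, region = NULL,
                               multiallelic = c("drop", "error")) {
  multiallelic <- match.arg(multiallelic)
  parsed <- read_vcf_gt(path, region, multiallelic)
  dose <- apply(parsed$gt, c(1, 2), gt_to_dose)
  genotype_matrix(t(dose), variants = parsed$variants,
                  subjects = colnames(parsed$gt))
}

# shared VCF reading for genotypes and phased haplotypes
read_vcf_gt <- function(path, region, multiallelic) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("no variants in VCF: ", path)
  keep <- rep(TRUE, nrow(fix))
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    if (multiallelic == "error") stop("multi-allelic site at line for ",
                                      fix$CHROM[multi][1L], ":",
                                      fix$POS[multi][1L])
    keep <- keep & !multi
  }
  reg <- parse_region(region)
  if (!is.null(reg)) {
    pos <- as.integer(fix$POS)
    keep <- keep & fix$CHROM == reg$chrom & pos >= reg$start & pos <= reg$end
  }
  if (!any(keep)) stop("no variants in region: ", region)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[
    is.na(ids) | ids == "."]
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  list(gt = gt, variants = variants)
}

gt_to_dose <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1L]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles != "0")
}

#' Read a genotype table (TSV)
#'
#' Expects variants as rows and subjects as columns: first column is the
#' variant ID, the header row carries subject IDs, cells are doses 0/1/2 or
#' NA.
#'
#' @param path TSV file.
#' @return a `genotype_matrix`.
#' @export
read_genotype_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("genotype table needs an ID column plus subjects")
  ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (any(!is.na(mat) & !(mat %in% c(0, 1, 2))))
    stop("genotype cells must be 0, 1, 2 or NA")
  if (anyDuplicated(colnames(mat))) stop("duplicate subject IDs")
  genotype_matrix(t(mat), variants = data.frame(id = ids),
                  subjects = colnames(mat))
}

#' Write a genotype table (TSV)
#' @param gm a `genotype_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  tab <- data.frame(id = gm$variants$id, t(gm$counts), check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table (TSV)
#'
#' Columns: `id`, `pheno`, then any number of covariate columns.
#'
#' @param path TSV file.
#' @return a `pheno_covar`.
#' @export
read_phenotype_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "pheno") %in% names(tab)))
    stop("phenotype table must have columns 'id' and 'pheno'")
  covs <- setdiff(names(tab), c("id", "pheno"))
  pheno_covar(tab$id, tab$pheno,
              if (length(covs)) as.matrix(tab[, covs, drop = FALSE]))
}
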