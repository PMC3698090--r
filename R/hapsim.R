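#' Haplotype pool container
#'
#' A pool of phased haplotypes over variant sites, the sampling frame for
#' cohort simulation. Columns are oriented so the minor allele is coded 1;
#' sites that are monomorphic in the pool are dropped.
#'
#' @param haps binary matrix, haplotypes in rows, sites in columns.
#' @param positions integer site coordinates (1-based).
#' @param region_label free-text label for the region.
#' @return An object of class `haplotype_pool`: list with `haps`, `freq`
#'   (per-site minor allele frequency, the simulator's p), `positions`,
#'   `region_label`.
#' @export
haplotype_pool <- function(haps, positions = NULL, region_label = "pool") {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "double"
  if (any(!(haps %in% c(0, 1)))) stop("haplotypes must be binary 0/1")
  if (is.null(positions)) positions <- seq_len(ncol(haps))
  positions <- as.integer(positions)
  if (length(positions) != ncol(haps)) stop("positions length mismatch")
  f <- colMeans(haps)
  flip <- f > 0.5
  if (any(flip)) haps[, flip] <- 1 - haps[, flip]
  f <- colMeans(haps)
  keep <- f > 0
  if (!all(keep)) {
    haps <- haps[, keep, drop = FALSE]
    positions <- positions[keep]
    f <- f[keep]
  }
  if (!ncol(haps)) stop("pool has no polymorphic sites")
  colnames(haps) <- paste0("v", positions)
  structure(list(haps = haps, freq = unname(f), positions = positions,
                 region_label = region_label),
            class = "haplotype_pool")
}

#' @exportS3Method base::print
print.haplotype_pool <- function(x, ...) {
  n_rare <- sum(x$freq <= 0.04)
  cat("haplotype_pool '", x$region_label, "': ", nrow(x$haps),
      " haplotypes x ", ncol(x$haps), " sites\n", sep = "")
  cat("  ", n_rare, " rare sites (MAF <= 0.04), ",
      sum(x$freq < 0.01), " below 0.01\n", sep = "")
  invisible(x)
}

#' Generate a synthetic haplotype pool
#'
#' Builds a panel that emulates the rare-variant profile of a resequenced
#' gene region: site frequencies follow a 1/x-shaped spectrum truncated to
#' `[p_min, 0.5]` (so most rare sites sit below MAF 0.01), and haplotypes
#' are mosaics of block founders so that nearby sites show block-wise
#' linkage disequilibrium. A small fraction of sites duplicate the carrier
#' set of an earlier site in the same block, producing the perfectly
#' correlated pairs that motivate proxy clustering.
#'
#' @param n_haps number of haplotypes (default 2000).
#' @param n_sites number of variant sites (default 320).
#' @param p_min lower truncation of the frequency spectrum (default 5e-4).
#' @param n_founders founder haplotypes per block (default 8).
#' @param block_len sites per LD block (default 20).
#' @param dup_prob probability a site replicates an earlier same-block
#'   carrier set (default 0.08).
#' @param seed optional integer seed.
#' @param region_label label for the pool.
#' @return a `haplotype_pool`.
#' @export
gen_pool <- function(n_haps = 2000, n_sites = 320, p_min = 5e-4,
                     n_founders = 8, block_len = 20, dup_prob = 0.08,
                     seed = NULL, region_label = "synthetic") {
  stopifnot(n_sites >= 10, n_haps >= 2 * n_founders, p_min > 0, p_min < 0.5)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  H <- n_haps
  # inverse-CDF draw from density proportional to 1/x on [p_min, 0.5]
  p_target <- p_min * (0.5 / p_min)^runif(n_sites)
  blocks <- ceiling(seq_len(n_sites) / block_len)
  n_blocks <- max(blocks)
  founder_of <- matrix(sample.int(n_founders, H * n_blocks, replace = TRUE),
                       nrow = H)
  haps <- matrix(0, nrow = H, ncol = n_sites)
  for (j in seq_len(n_sites)) {
    b <- blocks[j]
    first_in_block <- which(blocks == b)[1L]
    if (j > first_in_block && runif(1) < dup_prob) {
      src <- sample(seq.int(first_in_block, j - 1L), 1L)
      haps[, j] <- haps[, src]
      next
    }
    n_carriers <- min(max(1L, round(p_target[j] * H)), floor(H / 2))
    lineage <- which(founder_of[, b] == sample.int(n_founders, 1L))
    if (n_carriers <= length(lineage)) {
      carriers <- sample(lineage, n_carriers)
    } else {
      extra <- sample(setdiff(seq_len(H), lineage),
                      n_carriers - length(lineage))
      carriers <- c(lineage, extra)
    }
    haps[carriers, j] <- 1
  }
  span <- max(40000L, n_sites * 20L)
  positions <- sort(sample.int(span, n_sites))
  haplotype_pool(haps, positions, region_label)
}

#' Load a haplotype pool from a phased VCF
#'
#' Each sample contributes two haplotypes, split on the phase separator
#' `|`. Regions use 1-based inclusive coordinates.
#'
#' @param path VCF file with phased GT.
#' @param region optional "chrom:start-end" filter.
#' @param force_phase_as_is treat unphased `/` genotypes as if phased
#'   (default FALSE: unphased genotypes are an error).
#' @param region_label label; defaults to the region or file name.
#' @return a `haplotype_pool`.
#' @export
load_pool_from_phased_vcf <- function(path, region = NULL,
                                      force_phase_as_is = FALSE,
                                      region_label = NULL) {
  parsed <- read_vcf_gt(path, region, multiallelic = "drop")
  gt <- parsed$gt
  if (!force_phase_as_is) {
    unphased <- !is.na(gt) & grepl("/", gt, fixed = TRUE)
    if (any(unphased))
      stop("unphased genotype(s) found (e.g. ", gt[unphased][1L],
           "); phased '|' GT required unless force_phase_as_is = TRUE")
  }
  if (anyNA(gt) || any(grepl("\\.", gt)))
    stop("missing alleles are not supported in a haplotype pool")
  split_alleles <- function(x) as.numeric(strsplit(x, "[|/]")[[1L]] != "0")
  n_var <- nrow(gt)
  n_sam <- ncol(gt)
  haps <- matrix(0, nrow = 2L * n_sam, ncol = n_var)
  for (s in seq_len(n_sam)) {
    al <- vapply(gt[, s], split_alleles, numeric(2L))
    haps[2L * s - 1L, ] <- al[1L, ]
    haps[2L * s, ] <- al[2L, ]
  }
  if (is.null(region_label))
    region_label <- if (!is.null(region)) region else basename(path)
  haplotype_pool(haps, parsed$variants$pos, region_label)
}

#' Write / read a haplotype pool as TSV
#'
#' Plain-text interchange format: haplotypes as rows, sites as columns,
#' header `v<position>` per site, first column a haplotype index.
#'
#' @param pool a `haplotype_pool`.
#' @param path TSV path.
#' @return `path` invisibly ([write_pool()]); a `haplotype_pool`
#'   ([read_pool()]).
#' @export
write_pool <- function(pool, path) {
  stopifnot(inherits(pool, "haplotype_pool"))
  tab <- data.frame(hap = seq_len(nrow(pool$haps)), pool$haps,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool
#' @param region_label label for the loaded pool.
#' @export
read_pool <- function(path, region_label = basename(path)) {
  tab <- read.delim(path, check.names = FALSE)
  if (names(tab)[1L] != "hap") stop("not a pool TSV (no 'hap' column)")
  haps <- as.matrix(tab[, -1L, drop = FALSE])
  positions <- as.integer(sub("^v", "", colnames(haps)))
  if (anyNA(positions)) stop("pool TSV column names must be v<position>")
  haplotype_pool(haps, positions, region_label)
}

#' Scenario specification for the disease simulator
#'
#' Defines one of the seven effect-distribution scenarios. Writing sigma_v
#' for the per-variant effect scale, the associated-effect distributions are
#' N(2 sigma_v, sigma_v^2) for distributions 1-2, N(sigma_v, sigma_v^2) for
#' 3-4, N(sigma_v/2, sigma_v^2) for 5-6 and N(0, sigma_v^2) for 7;
#' even-numbered distributions flip 20% of causal variants to the mirrored
#' negative-mean distribution. The scale divisor k is 1, 1, 1.5, 1.5, 2, 2,
#' 2.5 for distributions 1-7, and the overall effect scale is multiplied by
#' 0.7 (10% causal) or 0.5 (20% causal) so that the scenarios have broadly
#' comparable power.
#'
#' @param distribution_id integer 1-7.
#' @param prop_causal fraction of rare sites that are causal; 0.05, 0.10 and
#'   0.20 map to effect scales 1, 0.7 and 0.5. Other values (including 0,
#'   the global null) need an explicit `sigma_scale`.
#' @param n_cases,n_controls cohort design (default 2000 each).
#' @param effect_boost multiplier on the effect scale (1.25 for the
#'   4000+4000 design; default 1).
#' @param prevalence population disease prevalence (default 0.10).
#' @param sigma_scale override for the causal-fraction effect scale.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(distribution_id, prop_causal,
                          n_cases = 2000, n_controls = 2000,
                          effect_boost = 1, prevalence = 0.10,
                          sigma_scale = NULL) {
  stopifnot(distribution_id %in% 1:7, prop_causal >= 0, prop_causal < 1,
            n_cases >= 1, n_controls >= 1, prevalence > 0, prevalence < 1,
            effect_boost > 0)
  k_map <- c(1, 1, 1.5, 1.5, 2, 2, 2.5)
  mean_map <- c(2, 2, 1, 1, 0.5, 0.5, 0)
  if (is.null(sigma_scale)) {
    scale_map <- c(`0.05` = 1, `0.1` = 0.7, `0.2` = 0.5)
    key <- as.character(prop_causal)
    if (!key %in% names(scale_map))
      stop("no default effect scale for prop_causal = ", prop_causal,
           "; supply sigma_scale explicitly")
    sigma_scale <- unname(scale_map[key])
  }
  structure(list(
    distribution_id = as.integer(distribution_id),
    prop_causal = prop_causal,
    k = k_map[distribution_id],
    mean_multiplier = mean_map[distribution_id],
    neg_fraction = if (distribution_id %% 2L == 0L) 0.2 else 0,
    sigma_scale = sigma_scale,
    effect_boost = effect_boost,
    prevalence = prevalence,
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls)),
    class = "scenario_spec")
}

#' @exportS3Method base::print
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "scenario_spec: distribution %d, %.0f%% causal (k = %g, mean = %g sigma, %0.f%% negative)\n",
    x$distribution_id, 100 * x$prop_causal, x$k, x$mean_multiplier,
    100 * x$neg_fraction))
  cat(sprintf("  effect scale %g x boost %g; prevalence %.2f; %d cases / %d controls\n",
              x$sigma_scale, x$effect_boost, x$prevalence, x$n_cases,
              x$n_controls))
  invisible(x)
}

#' Draw per-variant causal effects for a scenario
#'
#' Causal sites are drawn uniformly without replacement among the pool's
#' rare sites (MAF <= `rare_max`). The per-site effect scale ties effect
#' size to frequency,
#' \deqn{\sigma_v = \mathrm{scale} \times \mathrm{boost} \times
#'   \frac{-0.04 \log p_v}{k},}
#' so rarer variants carry larger effects on average; the log is natural by
#' default. The log-odds effect beta is N(m sigma_v, sigma_v^2) with m the
#' scenario's mean multiplier, mirrored to N(-m sigma_v, sigma_v^2) with the
#' scenario's negative fraction.
#'
#' @param pool a `haplotype_pool`.
#' @param spec a `scenario_spec`.
#' @param rare_max rare-site threshold (default 0.04).
#' @param log_base "natural" (default) or "log10".
#' @param scale_mean_only apply the causal-fraction scale (and boost) to the
#'   mean only, leaving the spread unscaled (default FALSE: the whole
#'   distribution is scaled, preserving its mean:sd ratio).
#' @param seed optional integer seed.
#' @return An object of class `effect_assignment`: `causal_sites` (column
#'   indices into the pool), `beta`, `sign`, `sigma_v`.
#' @export
draw_effects <- function(pool, spec, rare_max = 0.04,
                         log_base = c("natural", "log10"),
                         scale_mean_only = FALSE, seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(spec, "scenario_spec"))
  log_base <- match.arg(log_base)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  rare <- which(pool$freq > 0 & pool$freq <= rare_max)
  if (!length(rare)) stop("pool has no rare sites at MAF <= ", rare_max)
  n_causal <- round(spec$prop_causal * length(rare))
  if (spec$prop_causal > 0 && n_causal < 1L)
    stop("prop_causal * number of rare sites is below 1")
  if (n_causal == 0L) {
    return(structure(list(causal_sites = integer(0), beta = numeric(0),
                          sign = integer(0), sigma_v = numeric(0)),
                     class = "effect_assignment"))
  }
  sites <- sort(sample(rare, n_causal))
  logp <- if (log_base == "natural") log(pool$freq[sites])
          else log10(pool$freq[sites])
  base_scale <- -0.04 * logp / spec$k
  if (scale_mean_only) {
    sigma_v <- spec$effect_boost * base_scale
    mean_scale <- spec$sigma_scale
  } else {
    sigma_v <- spec$sigma_scale * spec$effect_boost * base_scale
    mean_scale <- 1
  }
  sgn <- ifelse(runif(n_causal) < spec$neg_fraction, -1L, 1L)
  beta <- rnorm(n_causal,
                mean = sgn * spec$mean_multiplier * mean_scale * sigma_v,
                sd = sigma_v)
  structure(list(causal_sites = sites, beta = beta, sign = sgn,
                 sigma_v = sigma_v),
            class = "effect_assignment")
}

#' @exportS3Method base::print
print.effect_assignment <- function(x, ...) {
  cat("effect_assignment:", length(x$causal_sites), "causal sites")
  if (length(x$beta))
    cat(sprintf("; beta in [%.3f, %.3f], %d negative-mean",
                min(x$beta), max(x$beta), sum(x$sign < 0)))
  cat("\n")
  invisible(x)
}

# per-individual genetic score: sum of beta over carried causal alleles
genetic_scores <- function(pool, effects, i1, i2) {
  if (!length(effects$causal_sites)) return(rep(0, length(i1)))
  cs <- effects$causal_sites
  dose <- pool$haps[i1, cs, drop = FALSE] + pool$haps[i2, cs, drop = FALSE]
  as.numeric(dose %*% effects$beta)
}

#' Calibrate the baseline log-odds to a target prevalence
#'
#' Solves E[expit(mu0 + s)] = prevalence by root-finding, where s is the
#' genetic score of a random haplotype pair and the expectation is Monte
#' Carlo over `n_mc` pairs drawn with replacement from the pool (fixed
#' seed, so the calibration is deterministic). With no causal effects the
#' closed form logit(prevalence) is returned.
#'
#' @param pool a `haplotype_pool`.
#' @param effects an `effect_assignment`.
#' @param prevalence target population prevalence (default 0.10).
#' @param n_mc Monte-Carlo sample size (default 1e5).
#' @param seed seed for the Monte-Carlo draw (default 1).
#' @return baseline log-odds `mu0`.
#' @export
calibrate_intercept <- function(pool, effects, prevalence = 0.10,
                                n_mc = 1e5, seed = 1L) {
  stopifnot(inherits(pool, "haplotype_pool"),
            inherits(effects, "effect_assignment"),
            prevalence > 0, prevalence < 1)
  if (!length(effects$causal_sites) || all(effects$beta == 0))
    return(qlogis(prevalence))
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  H <- nrow(pool$haps)
  s <- genetic_scores(pool, effects, sample.int(H, n_mc, replace = TRUE),
                      sample.int(H, n_mc, replace = TRUE))
  f <- function(mu0) mean(plogis(mu0 + s)) - prevalence
  lower <- qlogis(prevalence) - max(s) - 1
  upper <- qlogis(prevalence) - min(s) + 1
  if (f(lower) > 0 || f(upper) < 0) stop("prevalence root not bracketed")
  uniroot(f, c(lower, upper), tol = 1e-8)$root
}

#' Simulate a case-control cohort from a haplotype pool
#'
#' Individuals are built by drawing two haplotypes with replacement; disease
#' risk is expit(mu0 + s) under the log-additive model with genetic score s,
#' and case/control status is Bernoulli in that risk. Drawing continues
#' until the target numbers of cases and controls are both collected
#' (sampling cases and controls at random from the population).
#'
#' @param pool a `haplotype_pool`.
#' @param effects an `effect_assignment`.
#' @param mu0 calibrated baseline log-odds (see [calibrate_intercept()]).
#' @param spec a `scenario_spec` (supplies n_cases, n_controls).
#' @param seed optional integer seed.
#' @param max_draws accrual cap before erroring (default
#'   `500 * (n_cases + n_controls) / prevalence` individuals).
#' @return An object of class `simulated_cohort`: `gm` (a
#'   `genotype_matrix`), `pc` (a `pheno_covar` with 0/1 phenotype), `truth`
#'   (list: effects, spec, mu0), `n_drawn` (population draws needed).
#' @export
simulate_cohort <- function(pool, effects, mu0, spec, seed = NULL,
                            max_draws = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"),
            inherits(effects, "effect_assignment"),
            inherits(spec, "scenario_spec"))
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (is.null(max_draws))
    max_draws <- ceiling(500 * (spec$n_cases + spec$n_controls) /
                         spec$prevalence)
  H <- nrow(pool$haps)
  need_ca <- spec$n_cases
  need_co <- spec$n_controls
  ca_i1 <- integer(0); ca_i2 <- integer(0)
  co_i1 <- integer(0); co_i2 <- integer(0)
  drawn <- 0L
  batch <- ceiling(1.3 * max(need_ca / spec$prevalence,
                             need_co / (1 - spec$prevalence)))
  while ((length(ca_i1) < need_ca || length(co_i1) < need_co) &&
         drawn < max_draws) {
    nb <- min(batch, max_draws - drawn)
    i1 <- sample.int(H, nb, replace = TRUE)
    i2 <- sample.int(H, nb, replace = TRUE)
    risk <- plogis(mu0 + genetic_scores(pool, effects, i1, i2))
    y <- rbinom(nb, 1L, risk)
    drawn <- drawn + nb
    is_ca <- y == 1L
    if (length(ca_i1) < need_ca) {
      add <- which(is_ca)[seq_len(min(sum(is_ca), need_ca - length(ca_i1)))]
      ca_i1 <- c(ca_i1, i1[add]); ca_i2 <- c(ca_i2, i2[add])
    }
    if (length(co_i1) < need_co) {
      add <- which(!is_ca)[seq_len(min(sum(!is_ca), need_co - length(co_i1)))]
      co_i1 <- c(co_i1, i1[add]); co_i2 <- c(co_i2, i2[add])
    }
  }
  if (length(ca_i1) < need_ca || length(co_i1) < need_co)
    stop("case/control accrual failed within ", max_draws, " draws")
  i1 <- c(ca_i1, co_i1)
  i2 <- c(ca_i2, co_i2)
  counts <- pool$haps[i1, , drop = FALSE] + pool$haps[i2, , drop = FALSE]
  subjects <- paste0("I", seq_along(i1))
  rownames(counts) <- subjects
  gm <- suppressMessages(genotype_matrix(
    counts,
    variants = data.frame(id = colnames(pool$haps), pos = pool$positions),
    subjects = subjects))
  pc <- pheno_covar(subjects, c(rep(1, need_ca), rep(0, need_co)),
                    trait_kind = "dichotomous")
  structure(list(gm = gm, pc = pc,
                 truth = list(effects = effects, spec = spec, mu0 = mu0),
                 n_drawn = drawn),
            class = "simulated_cohort")
}

#' @exportS3Method base::print
print.simulated_cohort <- function(x, ...) {
  cat("simulated_cohort:", sum(x$pc$phenotype == 1), "cases /",
      sum(x$pc$phenotype == 0), "controls;",
      ncol(x$gm$counts), "polymorphic sites;",
      length(x$truth$effects$causal_sites), "causal\n")
  invisible(x)
}
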