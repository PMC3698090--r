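#' Permuted phenotype matrix
#'
#' Uniform random shuffles of the phenotype vector, one column per
#' permutation; covariate rows stay fixed. Reproducible from `seed` without
#' disturbing the caller's RNG state.
#'
#' @param y phenotype vector.
#' @param B number of permutations.
#' @param seed integer seed.
#' @return numeric matrix `length(y)` x `B`.
#' @export
permutation_matrix <- function(y, B, seed) {
  stopifnot(B >= 1)
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  vapply(seq_len(B), function(b) y[sample.int(length(y))], numeric(length(y)))
}

# permutation Lambda values for one chunk, sharing the pre-computed proxies.
# Without covariates the null fit is permutation-invariant (the intercept-only
# fitted mean and the residual variance depend only on the multiset of
# phenotype values), so z for all permutations is a single matrix product;
# with covariates the null model is refit per permutation.
perm_lambdas <- function(P_kept, pc, null, V_kept, Yperm, bounds) {
  n <- nrow(P_kept)
  has_cov <- !is.null(pc$covariates)
  if (!has_cov) {
    res <- Yperm - matrix(null$fitted, n, ncol(Yperm))
    scale <- if (pc$trait_kind == "quantitative") 1 / null$sigma2 else 1
    U <- crossprod(P_kept, res) * scale
    Z <- U / sqrt(V_kept)
    return(lambda_many(Z, bounds))
  }
  vapply(seq_len(ncol(Yperm)), function(b) {
    pcb <- pheno_covar(pc$id, Yperm[, b], pc$covariates, pc$trait_kind)
    nb <- fit_null(pcb)
    scb <- score_z(P_kept, nb)
    if (!length(scb$z)) return(0)
    lambda_many(matrix(scb$z, ncol = 1L), bounds)
  }, numeric(1L))
}

#' Rare admixture maximum likelihood association test
#'
#' Runs the full pipeline on a region: restrict to rare variants
#' (MAF <= `maf_max`), single-link cluster correlated variants
#' (r^2 > `r2_threshold`) and collapse each group to a max-dose proxy,
#' compute the per-proxy signed score-test z under the covariate-only null
#' model, maximise the admixture log-likelihood over the bounded
#' (alpha, eta, sigma) box, and assess the statistic Lambda by phenotype
#' permutation. Clustering and proxies depend only on genotypes and are
#' computed once, then reused across permutations.
#'
#' The p-value estimator is (1 + b) / (1 + B) where b counts permutations
#' with Lambda at least the observed value; it is never exactly zero. With
#' `adaptive = TRUE` permutation stops early once the 99% CI of the running
#' p-value lies entirely above `max(alpha_targets)`; the estimator is
#' unchanged.
#'
#' @param gm a `genotype_matrix`.
#' @param pc a `pheno_covar` (aligned by subject ID automatically).
#' @param maf_max rare-variant MAF threshold (default 0.04).
#' @param maf_in compute the filtering MAF on "all" subjects (default) or
#'   on "controls" only (dichotomous traits).
#' @param r2_threshold LD grouping threshold (default 0.9).
#' @param bounds a [raml_bounds()] object.
#' @param B number of permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @param adaptive early-stop permutation for clearly null results
#'   (default FALSE).
#' @param alpha_targets significance levels the adaptive rule must preserve.
#' @param chunk permutations per adaptive batch.
#' @return An object of class `raml_test`: the observed statistic
#'   `lambda_obs`, permutation counts `n_perm` and `n_exceed`, `p_value`,
#'   the mixture `fit` ([maximize_raml()]), `n_rare_variants`, `n_proxies`,
#'   `seed`, and a `reason` code ("ok" or "no_rare_variants" /
#'   "no_informative_proxies", in which case p_value = 1).
#' @export
raml_test <- function(gm, pc, maf_max = 0.04, maf_in = c("all", "controls"),
                      r2_threshold = 0.9,
                      bounds = raml_bounds(), B = 9999L, seed = 1L,
                      adaptive = FALSE, alpha_targets = c(0.05, 0.01, 0.001),
                      chunk = 100L) {
  maf_in <- match.arg(maf_in)
  al <- align_subjects(gm, pc)
  gm <- al$gm
  pc <- al$pc
  if (maf_in == "controls") {
    if (pc$trait_kind != "dichotomous")
      stop("maf_in = 'controls' needs a dichotomous trait")
    ctrl <- gm$counts[pc$phenotype == 0, , drop = FALSE]
    n_obs <- colSums(!is.na(ctrl))
    f <- ifelse(n_obs > 0, colSums(ctrl, na.rm = TRUE) / (2 * n_obs), 0)
    maf_ctrl <- pmin(f, 1 - f)
    rare <- subset_variants(gm, maf_ctrl > 0 & maf_ctrl <= maf_max &
                              gm$maf > 0)
  } else {
    rare <- rare_filter(gm, maf_max)
  }
  empty <- function(reason, n_rare, n_prox) {
    structure(list(lambda_obs = 0, n_perm = 0L, n_exceed = 0L, p_value = 1,
                   fit = NULL, n_rare_variants = n_rare, n_proxies = n_prox,
                   seed = seed, reason = reason,
                   perm_lambdas = numeric(0)),
              class = "raml_test")
  }
  if (ncol(rare$counts) == 0L) return(empty("no_rare_variants", 0L, 0L))
  prox <- cluster_proxies(rare, r2_threshold)
  P <- prox$proxies
  # mean-impute missing proxy doses once; permutations never touch genotypes
  if (anyNA(P)) {
    for (j in which(colSums(is.na(P)) > 0L)) {
      pj <- P[, j]
      pj[is.na(pj)] <- mean(pj, na.rm = TRUE)
      P[, j] <- pj
    }
  }
  null <- fit_null(pc)
  sc <- score_z(P, null)
  if (!length(sc$z))
    return(empty("no_informative_proxies", ncol(rare$counts), ncol(P)))
  P_kept <- P[, sc$keep, drop = FALSE]
  fit <- maximize_raml(sc$z, bounds)
  # observed Lambda through the same computational path as the permutations
  lambda_obs <- lambda_many(matrix(sc$z, ncol = 1L), bounds)

  # permutations are drawn chunk-wise from a single seeded stream, identical
  # to the columns of permutation_matrix(phenotype, B, seed), without ever
  # materialising all B shuffles
  old_rng <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  y <- pc$phenotype
  lam <- numeric(0)
  done <- 0L
  stop_level <- max(alpha_targets)
  chunk <- max(25L, as.integer(chunk))
  while (done < B) {
    take <- min(chunk, B - done)
    Yc <- vapply(seq_len(take), function(b) y[sample.int(length(y))],
                 numeric(length(y)))
    lam <- c(lam, perm_lambdas(P_kept, pc, null, sc$V[sc$keep], Yc, bounds))
    done <- done + take
    if (adaptive && done >= 100L && done < B) {
      b <- sum(lam >= lambda_obs)
      p_hat <- (1 + b) / (1 + done)
      lo <- p_hat - qnorm(0.995) * sqrt(p_hat * (1 - p_hat) / done)
      if (lo > stop_level) break
    }
  }
  b <- sum(lam >= lambda_obs)
  structure(list(lambda_obs = lambda_obs, n_perm = done, n_exceed = b,
                 p_value = (1 + b) / (1 + done), fit = fit,
                 n_rare_variants = ncol(rare$counts), n_proxies = ncol(P),
                 seed = seed, reason = "ok", perm_lambdas = lam),
            class = "raml_test")
}

#' @exportS3Method base::print
print.raml_test <- function(x, ...) {
  cat("RAML rare-variant association test\n")
  cat(sprintf("  rare variants: %d, proxy variants: %d\n",
              x$n_rare_variants, x$n_proxies))
  if (x$reason != "ok")
    cat("  note:", x$reason, "\n")
  cat(sprintf("  Lambda = %.6g, permutations = %d (exceedances = %d)\n",
              x$lambda_obs, x$n_perm, x$n_exceed))
  cat(sprintf("  permutation p-value = %.4g\n", x$p_value))
  invisible(x)
}

#' @export
summary.raml_test <- function(object, ...) {
  out <- list(
    p_value = object$p_value,
    lambda_obs = object$lambda_obs,
    n_perm = object$n_perm,
    n_exceed = object$n_exceed,
    n_rare_variants = object$n_rare_variants,
    n_proxies = object$n_proxies,
    params = if (!is.null(object$fit)) coef(object$fit),
    reason = object$reason,
    seed = object$seed)
  class(out) <- "summary.raml_test"
  out
}

#' @exportS3Method base::print
print.summary.raml_test <- function(x, ...) {
  cat("RAML test summary\n")
  cat(sprintf("  p = %.4g  (Lambda = %.5g over %d permutations, %d exceed)\n",
              x$p_value, x$lambda_obs, x$n_perm, x$n_exceed))
  cat(sprintf("  %d rare variants collapsed to %d proxies\n",
              x$n_rare_variants, x$n_proxies))
  if (!is.null(x$params))
    cat(sprintf("  fitted mixture: alpha = %.4f, eta = %.3f, sigma = %.3f\n",
                x$params["alpha"], x$params["eta"], x$params["sigma"]))
  if (x$reason != "ok") cat("  note:", x$reason, "\n")
  invisible(x)
}

#' @export
coef.raml_test <- function(object, ...) {
  if (is.null(object$fit)) return(c(alpha = NA_real_, eta = NA_real_,
                                    sigma = NA_real_))
  coef(object$fit)
}

#' Permutation-null histogram for a RAML test
#'
#' Plots the permutation distribution of Lambda with the observed statistic
#' marked.
#'
#' @param x a `raml_test`.
#' @param ... passed to [graphics::hist()].
#' @exportS3Method graphics::plot
plot.raml_test <- function(x, ...) {
  if (!length(x$perm_lambdas)) {
    warning("no permutation statistics to plot")
    return(invisible(x))
  }
  graphics::hist(x$perm_lambdas, breaks = 30,
                 main = "Permutation distribution of Lambda",
                 xlab = expression(Lambda), ...)
  graphics::abline(v = x$lambda_obs, col = "red", lwd = 2)
  invisible(x)
}
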