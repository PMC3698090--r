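#' Fit the covariate-only null model
#'
#' For dichotomous traits this is a logistic regression of the phenotype on
#' the covariates (intercept only when none are supplied); for quantitative
#' traits an ordinary least-squares fit. The fitted means and variance
#' weights feed the per-variant score test.
#'
#' @param pc a `pheno_covar`.
#' @return An object of class `raml_null`: list with `fitted` (per-subject
#'   expected phenotype), `weights` (variance weights: \eqn{\hat y (1-\hat
#'   y)} for logistic, \eqn{1/\hat\sigma^2} scaling folded in for linear),
#'   `design` (model matrix incl. intercept), `trait_kind`, `sigma2` (linear
#'   only; MLE with denominator n).
#' @export
fit_null <- function(pc) {
  stopifnot(inherits(pc, "pheno_covar"))
  n <- length(pc$phenotype)
  X <- cbind(`(Intercept)` = rep(1, n), pc$covariates)
  if (qr(X)$rank < ncol(X)) {
    # name a culprit: first column whose removal restores full rank
    for (j in seq_len(ncol(X))[-1L]) {
      if (qr(X[, -j, drop = FALSE])$rank == qr(X)$rank)
        stop("collinear covariate design; offending column: ", colnames(X)[j])
    }
    stop("collinear covariate design")
  }
  y <- pc$phenotype
  if (pc$trait_kind == "dichotomous") {
    fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
    mu <- fit$fitted.values
    eps <- 1e-8
    if (!fit$converged || any(mu < eps) || any(mu > 1 - eps)) {
      # locate a separating covariate if there is one
      for (j in seq_len(ncol(X))[-1L]) {
        tab <- table(X[, j] > median(X[, j]), y)
        if (any(tab == 0L))
          stop("separation in null model; offending column: ", colnames(X)[j])
      }
      stop("null logistic model did not converge (separation?)")
    }
    w <- mu * (1 - mu)
    out <- list(fitted = mu, weights = w, design = X,
                trait_kind = "dichotomous", sigma2 = NULL)
  } else {
    fit <- lm.fit(X, y)
    mu <- fit$fitted.values
    sigma2 <- sum((y - mu)^2) / n
    if (sigma2 <= 0) stop("null residual variance is zero")
    w <- rep(1 / sigma2, n)
    out <- list(fitted = mu, weights = w, design = X,
                trait_kind = "quantitative", sigma2 = sigma2)
  }
  out$y <- y
  class(out) <- "raml_null"
  out
}

#' @exportS3Method base::print
print.raml_null <- function(x, ...) {
  cat("raml_null:", x$trait_kind, "null model,", length(x$fitted),
      "subjects,", ncol(x$design) - 1L, "covariate(s)\n")
  invisible(x)
}

# Projection pieces reused across variants: for design X and weights w,
# the efficient score variance of g is  g'Wg - g'WX (X'WX)^{-1} X'Wg.
null_projection <- function(null) {
  X <- null$design
  w <- null$weights
  XtWX <- crossprod(X, X * w)
  list(X = X, w = w, XtWX_inv = solve(XtWX))
}

#' Signed score-test z-statistics for variant dose vectors
#'
#' The per-variant evidence is the signed z from the score test of adding
#' the variant to the null model: \eqn{z = U / \sqrt{V}} with
#' \eqn{U = \sum_i g_i (y_i - \hat y_i)} and V the efficient score variance
#' (covariates projected out). Under no association z is asymptotically
#' standard normal; z > 0 means the minor allele is enriched in cases (or
#' associated with higher trait values). Missing doses are mean-imputed so
#' every variant is tested on the full sample.
#'
#' @param G dose matrix (subjects x variants) or a single dose vector.
#' @param null a `raml_null` from [fit_null()].
#' @return list with `z` (finite signed statistics), `keep` (logical per
#'   input variant; FALSE where the efficient variance was not positive,
#'   e.g. a constant dose), `U` and `V`.
#' @export
score_z <- function(G, null) {
  stopifnot(inherits(null, "raml_null"))
  if (is.null(dim(G))) G <- matrix(G, ncol = 1L)
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  if (nrow(G) != length(null$fitted)) stop("dose rows do not match null model")
  if (anyNA(G)) {
    for (j in which(colSums(is.na(G)) > 0L)) {
      gj <- G[, j]
      gj[is.na(gj)] <- mean(gj, na.rm = TRUE)
      G[, j] <- gj
    }
  }
  pr <- null_projection(null)
  resid <- null$y - null$fitted
  scale <- if (null$trait_kind == "quantitative") 1 / null$sigma2 else 1
  U <- as.numeric(crossprod(G, resid)) * scale
  GtWX <- crossprod(G, pr$X * pr$w)
  V <- colSums(G * (G * pr$w)) - rowSums((GtWX %*% pr$XtWX_inv) * GtWX)
  keep <- is.finite(V) & V > 1e-10
  z <- rep(NA_real_, ncol(G))
  z[keep] <- U[keep] / sqrt(V[keep])
  list(z = z[keep], keep = keep, U = U, V = V)
}
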