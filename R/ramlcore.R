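#' Parameter box for the admixture likelihood
#'
#' The mixture parameters are constrained to plausible ranges for genetic
#' association: most variants are expected to be null, so the associated
#' fraction alpha is capped; associated-effect means eta cover strong
#' protective to strong deleterious effects; sigma^2 has a floor expressing
#' the minimum believable variability of associated effects. The sigma^2
#' ceiling keeps the box compact for the bounded optimiser; with |eta| <= 5 a
#' larger spread is practically indistinguishable.
#'
#' @param alpha_max upper bound for the associated fraction (default 0.2).
#' @param eta_min,eta_max bounds for the mean associated effect (default -5, 5).
#' @param sigma2_min floor for the effect variance (default 0.25).
#' @param sigma2_max ceiling for the effect variance (default 25).
#' @param alpha_min numerical floor for alpha (default 1e-6); the null is the
#'   limit alpha -> 0.
#' @return list of class `raml_bounds`.
#' @export
raml_bounds <- function(alpha_max = 0.2, eta_min = -5, eta_max = 5,
                        sigma2_min = 0.25, sigma2_max = 25,
                        alpha_min = 1e-6) {
  stopifnot(alpha_min > 0, alpha_max > alpha_min, alpha_max <= 1,
            eta_max > eta_min, sigma2_min > 0, sigma2_max > sigma2_min)
  structure(list(alpha_min = alpha_min, alpha_max = alpha_max,
                 eta_min = eta_min, eta_max = eta_max,
                 sigma2_min = sigma2_min, sigma2_max = sigma2_max),
            class = "raml_bounds")
}

#' Marginal density of z for an associated variant
#'
#' If a variant is associated, its latent mean effect mu is N(eta, sigma^2)
#' and the observed score statistic is mu plus standard normal noise, so
#' marginally z ~ N(eta, 1 + sigma^2).
#'
#' @param z observed statistic(s).
#' @param eta mean associated effect.
#' @param sigma standard deviation of the associated effect (>= 0).
#' @return density value(s).
#' @export
marginal_alt_density <- function(z, eta, sigma) {
  stopifnot(sigma >= 0)
  dnorm(z, mean = eta, sd = sqrt(1 + sigma^2))
}

#' Admixture mixture log-likelihood
#'
#' Each proxy variant is associated with probability alpha (statistic from
#' N(eta, 1 + sigma^2)) or null (N(0, 1)). Relative to the all-null model
#' the log-likelihood is
#' \deqn{l(\alpha,\eta,\sigma) = \sum_i \log\left[(1-\alpha) +
#'   \frac{\alpha}{\sqrt{1+\sigma^2}} \exp\left(-\tfrac12\left(
#'   \frac{(z_i-\eta)^2}{1+\sigma^2} - z_i^2\right)\right)\right]}
#' evaluated in log space so that large |z| cannot overflow. At alpha -> 0
#' the value tends to 0: the null model is a boundary limit.
#'
#' @param z vector of signed proxy-variant z-statistics.
#' @param alpha,eta,sigma mixture parameters.
#' @return the log-likelihood value (a scalar).
#' @export
mixture_loglik <- function(z, alpha, eta, sigma) {
  stopifnot(is.numeric(z), all(is.finite(z)), alpha >= 0, alpha <= 1,
            sigma >= 0)
  cpp_mixture_loglik(as.numeric(z), alpha, eta, sigma^2)
}

# pure-R reference evaluation through the two-component mixture densities;
# kept for cross-checking the stabilised form
mixture_loglik_ref <- function(z, alpha, eta, sigma) {
  l1 <- marginal_alt_density(z, eta, sigma)
  l0 <- dnorm(z)
  sum(log((1 - alpha) * l0 + alpha * l1)) - sum(log(l0))
}

# deterministic start lattice over (eta, sigma); alpha is profiled out
start_lattice <- function(bounds) {
  etas <- c(-2, 0, 2)
  sig <- c(0.5, 1, 2)
  grid <- expand.grid(eta = etas, sigma2 = sig^2)
  grid$eta <- pmin(pmax(grid$eta, bounds$eta_min), bounds$eta_max)
  grid$sigma2 <- pmin(pmax(grid$sigma2, bounds$sigma2_min), bounds$sigma2_max)
  unique(grid)
}

coarse_grid <- function(bounds) {
  list(etas = seq(bounds$eta_min, bounds$eta_max, length.out = 41L),
       ss = unique(pmin(pmax(
         c(0.25, 0.35, 0.5, 0.75, 1, 1.5, 2, 3, 4.5, 7, 10, 15, 20, 25),
         bounds$sigma2_min), bounds$sigma2_max)))
}

#' Maximize the admixture log-likelihood
#'
#' Maximizes the mixture log-likelihood over the bounded box. The
#' log-likelihood is concave in alpha for fixed (eta, sigma^2), so alpha is
#' profiled out exactly (1-D bisection on the derivative) and the bounded
#' search runs over (eta, sigma^2) only, with the BOBYQA bound-constrained
#' quadratic-approximation optimiser started from a deterministic lattice
#' plus the best points of a coarse profile-likelihood scan — the
#' log-likelihood can be multimodal in eta. The returned statistic Lambda is
#' clamped at 0, the null boundary value.
#'
#' @param z vector of signed proxy-variant z-statistics.
#' @param bounds a [raml_bounds()] object.
#' @return An object of class `raml_fit`: list with `alpha`, `eta`, `sigma`,
#'   `loglik` (Lambda >= 0), `n_starts`, `start_that_won`, `converged`,
#'   `n_z`, and the input `bounds`.
#' @export
maximize_raml <- function(z, bounds = raml_bounds()) {
  stopifnot(inherits(bounds, "raml_bounds"))
  z <- as.numeric(z)
  if (!length(z)) stop("need at least one z-statistic")
  if (!all(is.finite(z))) stop("z-statistics must be finite")

  cg <- coarse_grid(bounds)
  scan <- cpp_profile_grid(z, cg$etas, cg$ss, bounds$alpha_min,
                           bounds$alpha_max)
  top <- order(scan, decreasing = TRUE)[seq_len(min(3L, length(scan)))]
  scan_starts <- data.frame(
    eta = cg$etas[(top - 1L) %% length(cg$etas) + 1L],
    sigma2 = cg$ss[(top - 1L) %/% length(cg$etas) + 1L])
  starts <- unique(rbind(start_lattice(bounds), scan_starts))

  negpl <- function(par) {
    -cpp_profile_ll(z, par[1L], par[2L], bounds$alpha_min,
                    bounds$alpha_max)$loglik
  }
  lower <- c(bounds$eta_min, bounds$sigma2_min)
  upper <- c(bounds$eta_max, bounds$sigma2_max)
  best <- NULL
  best_val <- Inf
  won <- NA_integer_
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(as.numeric(starts[i, ]), lower + 1e-8), upper - 1e-8)
    fit <- tryCatch(
      minqa::bobyqa(p0, negpl, lower = lower, upper = upper,
                    control = list(rhobeg = 0.4, rhoend = 1e-8,
                                   maxfun = 2000L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- identical(fit$ierr, 0L) || isTRUE(fit$ierr == 0)
    any_conv <- any_conv || conv
    if (fit$fval < best_val) {
      best_val <- fit$fval
      best <- fit$par
      won <- i
    }
  }
  if (is.null(best)) {
    # fall back to the best coarse-scan point; flagged, never an exception
    best <- as.numeric(scan_starts[1L, ])
    best_val <- negpl(best)
    won <- NA_integer_
    any_conv <- FALSE
  }
  pr <- cpp_profile_ll(z, best[1L], best[2L], bounds$alpha_min,
                       bounds$alpha_max)
  loglik <- max(0, pr$loglik)
  structure(list(alpha = pr$alpha, eta = best[1L], sigma = sqrt(best[2L]),
                 loglik = loglik, n_starts = nrow(starts),
                 start_that_won = won, converged = any_conv,
                 n_z = length(z), bounds = bounds),
            class = "raml_fit")
}

#' @exportS3Method base::print
print.raml_fit <- function(x, ...) {
  cat("RAML admixture likelihood fit (", x$n_z, " proxy z-statistics)\n",
      sep = "")
  cat(sprintf("  alpha = %.4f, eta = %.4f, sigma = %.4f\n",
              x$alpha, x$eta, x$sigma))
  cat(sprintf("  Lambda (max log-likelihood vs null) = %.6g\n", x$loglik))
  if (!x$converged) cat("  warning: optimiser did not report convergence\n")
  invisible(x)
}

#' @export
coef.raml_fit <- function(object, ...) {
  c(alpha = object$alpha, eta = object$eta, sigma = object$sigma)
}

#' @export
logLik.raml_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, class = "logLik")
}

#' Simulate z-statistics from a fitted admixture model
#'
#' Draws each statistic from the null N(0, 1) with probability 1 - alpha and
#' from the associated marginal N(eta, 1 + sigma^2) otherwise.
#'
#' @param object a `raml_fit`.
#' @param nsim number of replicate vectors.
#' @param seed optional seed.
#' @param m number of statistics per vector (defaults to the fitted count).
#' @param ... unused.
#' @return a list of numeric vectors (length `nsim`).
#' @export
simulate.raml_fit <- function(object, nsim = 1, seed = NULL, m = NULL, ...) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (is.null(m)) m <- object$n_z
  lapply(seq_len(nsim), function(i) {
    assoc <- runif(m) < object$alpha
    ifelse(assoc, rnorm(m, object$eta, sqrt(1 + object$sigma^2)), rnorm(m))
  })
}

# draw z under given true parameters (model-based simulation used by the
# parameter-recovery checks)
simulate_model_z <- function(m, alpha, eta, sigma) {
  assoc <- runif(m) < alpha
  ifelse(assoc, rnorm(m, eta, sqrt(1 + sigma^2)), rnorm(m))
}

# fast path used by the permutation loop: same profile objective, a lighter
# coarse scan + multi-start simplex refinement entirely in C++. The observed
# statistic is pushed through this same function so that observed and
# permuted Lambda share one computational path.
lambda_many <- function(Zmat, bounds = raml_bounds()) {
  etas <- seq(bounds$eta_min, bounds$eta_max, length.out = 21L)
  ss <- unique(pmin(pmax(c(0.25, 0.5, 1, 2, 4, 8, 16, 25),
                         bounds$sigma2_min), bounds$sigma2_max))
  cpp_lambda_many(Zmat, etas, ss, bounds$eta_min, bounds$eta_max,
                  bounds$sigma2_min, bounds$sigma2_max, bounds$alpha_min,
                  bounds$alpha_max)
}
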