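#' Power of the RAML test over replicate simulations
#'
#' For each scenario, draws `n_replicates` independent (effects, cohort)
#' pairs from the pool, runs the full permutation test on each, and
#' tabulates the proportion of replicates significant at each threshold.
#' Causal sites and effects are re-drawn every replicate, so power averages
#' over the scenario's effect distribution. Every replicate's RNG streams
#' are derived arithmetically from (`seed`, scenario index, replicate
#' index); results are therefore independent of scheduling and `n_workers`
#' (accepted for interface compatibility; replicates run serially).
#'
#' @param pool a `haplotype_pool`.
#' @param specs a `scenario_spec` or list of them.
#' @param n_replicates replicates per scenario (default 200).
#' @param thresholds significance thresholds (default 0.05, 0.01, 0.001).
#' @param B_max permutation budget per replicate (default 10000; adaptive
#'   early stopping resolves clearly null replicates quickly).
#' @param maf_max,r2_threshold,bounds test configuration (see
#'   [raml_test()]).
#' @param calib_n_mc Monte-Carlo size for prevalence calibration.
#' @param seed master seed.
#' @param n_workers accepted and validated; execution is serial.
#' @return An object of class `power_table`: a data frame with one row per
#'   scenario (`region_label`, `distribution_id`, `prop_causal`, `design`,
#'   `n_replicates`, `n_failed`) and, per threshold t, power percentage
#'   `power_p<t>` with Monte-Carlo standard error `se_p<t>`; the replicate
#'   p-values are attached as attribute `p_values`.
#' @export
run_power <- function(pool, specs, n_replicates = 200,
                      thresholds = c(0.05, 0.01, 0.001), B_max = 10000L,
                      maf_max = 0.04, r2_threshold = 0.9,
                      bounds = raml_bounds(), calib_n_mc = 5e4,
                      seed = 1L, n_workers = 1L) {
  stopifnot(inherits(pool, "haplotype_pool"), n_replicates >= 1,
            n_workers >= 1)
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1L), "scenario_spec")))
  thresholds <- sort(thresholds, decreasing = TRUE)
  rows <- vector("list", length(specs))
  pvals <- vector("list", length(specs))
  base <- (as.integer(seed) %% 10000L) * 100000L
  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    pv <- rep(NA_real_, n_replicates)
    fail <- character(0)
    for (i in seq_len(n_replicates)) {
      rs <- base + (s - 1L) * 10L * n_replicates + 10L * (i - 1L)
      res <- tryCatch({
        eff <- draw_effects(pool, spec, rare_max = maf_max, seed = rs)
        mu0 <- calibrate_intercept(pool, eff, spec$prevalence,
                                   n_mc = calib_n_mc, seed = rs + 1L)
        coh <- simulate_cohort(pool, eff, mu0, spec, seed = rs + 2L)
        raml_test(coh$gm, coh$pc, maf_max = maf_max,
                  r2_threshold = r2_threshold, bounds = bounds,
                  B = B_max, seed = rs + 3L, adaptive = TRUE,
                  alpha_targets = thresholds)$p_value
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) fail <- c(fail, res) else pv[i] <- res
    }
    ok <- !is.na(pv)
    if (mean(ok) < 0.95)
      warning(sprintf("scenario %d: only %d/%d replicates completed",
                      s, sum(ok), n_replicates))
    pw <- vapply(thresholds, function(t) mean(pv[ok] < t), numeric(1L))
    se <- sqrt(pw * (1 - pw) / sum(ok))
    row <- data.frame(region_label = pool$region_label,
                      distribution_id = spec$distribution_id,
                      prop_causal = spec$prop_causal,
                      design = paste0(spec$n_cases, "+", spec$n_controls),
                      n_replicates = sum(ok),
                      n_failed = length(fail))
    for (k in seq_along(thresholds)) {
      row[[paste0("power_p", sub("^0\\.", "", thresholds[k]))]] <- 100 * pw[k]
      row[[paste0("se_p", sub("^0\\.", "", thresholds[k]))]] <- 100 * se[k]
    }
    row$seed <- as.integer(seed)
    rows[[s]] <- row
    pvals[[s]] <- pv
  }
  out <- do.call(rbind, rows)
  attr(out, "p_values") <- pvals
  attr(out, "thresholds") <- thresholds
  class(out) <- c("power_table", "data.frame")
  out
}

#' @exportS3Method base::print
print.power_table <- function(x, ...) {
  cat("RAML power table (", nrow(x), " scenario(s) )\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a power table to report files
#'
#' Writes a TSV mirroring the scenario-by-threshold layout (and, when
#' `json_path` is given and jsonlite is installed, a JSON report including
#' standard errors and configuration echo).
#'
#' @param pt a `power_table`.
#' @param tsv_path output TSV path.
#' @param json_path optional JSON path.
#' @return `tsv_path`, invisibly.
#' @export
write_power_table <- function(pt, tsv_path, json_path = NULL) {
  stopifnot(inherits(pt, "power_table"))
  df <- as.data.frame(pt)
  write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for JSON output")
    jsonlite::write_json(
      list(table = df, thresholds = attr(pt, "thresholds"),
           p_values = attr(pt, "p_values")),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}

#' @rdname write_power_table
#' @param path TSV written by [write_power_table()].
#' @export
read_power_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(df) <- c("power_table", "data.frame")
  df
}
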