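# Estimator accuracy: Lin's concordance correlation coefficient, binned
# bias summaries, and simulation comparison grids.

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moments, following Lin's original estimator. Unlike the Pearson
#' correlation, the CCC penalizes location and scale shifts: `ccc(x, x + a)`
#' is below 1 for any non-zero `a`.
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value in
#'   either vector are dropped (with a message when any are).
#' @return The concordance correlation coefficient in \[-1, 1\].
#' @examples
#' lins_ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
lins_ccc <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length")
  ok <- is.finite(x) & is.finite(y)
  if (sum(!ok) > 0)
    message("dropping ", sum(!ok), " incomplete pair(s)")
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 2L)
    stop("need at least 2 complete pairs to compute a concordance")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0)
    stop("degenerate input: both variances and the mean difference are zero")
  2 * sxy / denom
}

# Reporting bins: right-closed, [0.0,0.1], (0.1,0.2], ..., (0.4,0.5] --
# note these differ from the left-closed bias-correction fitting bins.
report_bin_labels <- function() {
  c("[0.0,0.1]", "(0.1,0.2]", "(0.2,0.3]", "(0.3,0.4]", "(0.4,0.5]")
}

report_bin_index <- function(x) {
  idx <- findInterval(x, c(0, 0.1, 0.2, 0.3, 0.4, 0.5), left.open = TRUE,
                      rightmost.closed = FALSE)
  idx[x <= 0.1] <- 1L
  pmin(pmax(idx, 1L), 5L)
}

#' Accuracy report: overall and per-bin concordance and bias
#'
#' Compares estimated against true frequencies overall and within five
#' frequency bins (binned on the true value, right-closed edges as used in
#' reporting tables). Pairs with a missing estimate are dropped pairwise.
#'
#' @param truth,estimated Aligned numeric vectors (same variants, same
#'   order).
#' @return An object of class `"accuracy_report"`: list with `overall`
#'   (one-row `data.frame`: `ccc`, `mean_bias`, `n`) and `by_bin` (five
#'   rows; `ccc` is `NA` for bins with fewer than 2 pairs).
#' @export
accuracy_report <- function(truth, estimated) {
  if (length(truth) != length(estimated))
    stop("'truth' and 'estimated' must be aligned vectors of equal length")
  ok <- is.finite(truth) & is.finite(estimated)
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message("dropping ", n_drop, " variant(s) without a complete pair")
  truth <- truth[ok]
  estimated <- estimated[ok]

  overall <- data.frame(
    ccc = lins_ccc(truth, estimated),
    mean_bias = mean(estimated - truth),
    n = length(truth)
  )
  bin <- report_bin_index(truth)
  by_bin <- do.call(rbind, lapply(seq_len(5L), function(k) {
    i <- bin == k
    data.frame(
      bin = report_bin_labels()[k],
      ccc = if (sum(i) >= 2L) lins_ccc(truth[i], estimated[i]) else NA_real_,
      mean_bias = if (any(i)) mean(estimated[i] - truth[i]) else NA_real_,
      n = sum(i)
    )
  }))
  structure(list(overall = overall, by_bin = by_bin, n_dropped = n_drop),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, digits = 4, ...) {
  cat("Overall: CCC =", round(x$overall$ccc, digits),
      " mean bias =", signif(x$overall$mean_bias, digits),
      " n =", x$overall$n, "\n")
  print(transform(x$by_bin, ccc = round(ccc, digits),
                  mean_bias = signif(mean_bias, digits)), row.names = FALSE)
  invisible(x)
}

#' Simulation comparison grid for the two reconstruction routes
#'
#' For each scenario row: simulates a study, fits per-variant logistic
#' regressions (adjusted for the scenario's covariates), reconstructs case
#' and control frequencies via both routes -- the total-AF route from the
#' fitted OR plus the true total frequency, the SE route from the fitted OR
#' and SE -- and reports Lin's CCC between estimates and truth. The total-AF
#' route is scored on the allele-anchored frequency scale; the SE route on
#' the folded minor-allele scale, each against the matching truth.
#'
#' @param scenarios A `data.frame` with columns `n_case`, `n_control` and
#'   optionally `n_covariates` (default 0), `n_variants` (default 10000),
#'   `n_causal` (default 100).
#' @param seed Base seed; scenario `i` runs with `seed + i - 1`.
#' @return `scenarios` with appended columns `ccc_case_af`,
#'   `ccc_control_af`, `ccc_case_se`, `ccc_control_se` and `failed`.
#' @export
comparison_grid <- function(scenarios, seed = 1L) {
  stopifnot(is.data.frame(scenarios),
            all(c("n_case", "n_control") %in% names(scenarios)))
  defaults <- list(n_covariates = 0L, n_variants = 10000L, n_causal = 100L)
  for (nm in names(defaults))
    if (is.null(scenarios[[nm]])) scenarios[[nm]] <- defaults[[nm]]

  res <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    out <- try(grid_one_scenario(sc, seed = seed + i - 1L), silent = TRUE)
    if (inherits(out, "try-error")) {
      warning("scenario ", i, " failed: ", attr(out, "condition")$message)
      data.frame(ccc_case_af = NA_real_, ccc_control_af = NA_real_,
                 ccc_case_se = NA_real_, ccc_control_se = NA_real_,
                 failed = TRUE)
    } else {
      cbind(out, failed = FALSE)
    }
  })
  cbind(scenarios, do.call(rbind, res))
}

grid_one_scenario <- function(sc, seed) {
  study <- simulate_gwas(n_case = sc$n_case, n_control = sc$n_control,
                         n_variants = sc$n_variants, n_causal = sc$n_causal,
                         n_covariates = sc$n_covariates, seed = seed)
  fit <- suppressWarnings(fit_pervariant_logistic(study))
  af <- suppressWarnings(
    casecontrol_af(fit$or, study$af_total,
                   n_case = sc$n_case, n_control = sc$n_control))
  se <- suppressWarnings(
    casecontrol_se(fit$or, fit$se,
                   alleles_case = 2 * sc$n_case,
                   alleles_control = 2 * sc$n_control))
  fold <- function(f) pmin(f, 1 - f)
  data.frame(
    ccc_case_af = lins_ccc(study$af_case, af$af_case),
    ccc_control_af = lins_ccc(study$af_control, af$af_control),
    ccc_case_se = lins_ccc(fold(study$af_case), se$maf_case),
    ccc_control_se = lins_ccc(fold(study$af_control), se$maf_control)
  )
}

#' Write a comparison grid with a machine-readable run manifest
#'
#' Writes the grid as tab-separated text and, alongside it, a JSON manifest
#' (scenario configurations, base seed, per-method CCCs) for regression
#' testing of simulation runs.
#'
#' @param grid Output of [comparison_grid()].
#' @param path Output TSV path; the manifest is written to the same path
#'   with extension `.manifest.json`.
#' @param seed The base seed the grid was run with (recorded in the
#'   manifest).
#' @return Invisibly, the two paths written.
#' @export
write_grid <- function(grid, path, seed = NA) {
  utils::write.table(grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  manifest <- list(seed = seed, scenarios = grid)
  mpath <- sub("(\\.[^.]+)?$", ".manifest.json", path)
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(grid = path, manifest = mpath))
}
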