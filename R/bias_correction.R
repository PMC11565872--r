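# Proxy-panel bias correction for SE-derived minor allele frequencies.
#
# When the source GWAS adjusted for covariates, the SE-based route
# systematically underestimates common-variant MAFs. A reference panel
# (e.g. a gnomAD ancestry group) supplies proxy MAFs treated as stand-in
# truth: within five MAF bins a second-order polynomial regression of the
# estimated total MAF on the proxy MAF is fitted, the departure of the
# fitted curve from the identity line is the estimated bias, and that bias
# is subtracted from the case, control and total MAF estimates of every
# variant -- including variants absent from the proxy panel.

# Fitting bins: left-closed on the first four, closed on [0.4, 0.5].
BIAS_BIN_BREAKS <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5)

bias_bin_labels <- function() {
  c("[0.0,0.1)", "[0.1,0.2)", "[0.2,0.3)", "[0.3,0.4)", "[0.4,0.5]")
}

# bin index in 1..5 for maf in [0, 0.5]; values at 0.1/0.2/0.3/0.4 go to the
# upper bin (left-closed convention)
bias_bin_index <- function(maf) {
  idx <- findInterval(maf, BIAS_BIN_BREAKS, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), 5L)
}

#' Harmonize GWAS variants with a proxy frequency panel
#'
#' Matches variants between SE-derived MAF estimates and a proxy panel
#' (reference MAFs standing in for the unknown true study MAFs) by
#' chromosome and position, applying the usual summary-statistics
#' harmonization rules: variants whose allele pairs differ are removed, and
#' proxy frequencies reported on the opposing allele are flipped
#' (`f -> 1 - f`) before folding to the minor allele.
#'
#' @param gwas A `data.frame` with columns `chrom`, `pos`, `effect_allele`,
#'   `other_allele` and `maf_total` (the SE-derived total MAF estimate).
#' @param proxy A `data.frame` with columns `chrom`, `pos`, `ref`, `alt` and
#'   `maf`, where `maf` is anchored to the `alt` allele. Chromosome labels
#'   are normalized (`"chr1"` matches `"1"`); positions are 1-based.
#' @return A `data.frame` with columns `chrom`, `pos`,
#'   `estimated_total_maf`, `proxy_maf` (folded to \[0, 0.5\]) and
#'   `flip_applied`.
#' @export
harmonize_proxy <- function(gwas, proxy) {
  need_g <- c("chrom", "pos", "effect_allele", "other_allele", "maf_total")
  need_p <- c("chrom", "pos", "ref", "alt", "maf")
  if (!all(need_g %in% names(gwas)))
    stop("'gwas' must have columns: ", paste(need_g, collapse = ", "))
  if (!all(need_p %in% names(proxy)))
    stop("'proxy' must have columns: ", paste(need_p, collapse = ", "))

  gkey <- paste0(normalize_chrom(gwas$chrom), ":", gwas$pos)
  pkey <- paste0(normalize_chrom(proxy$chrom), ":", proxy$pos)
  if (anyDuplicated(gkey))
    stop("duplicate variant keys in 'gwas': ",
         paste(utils::head(gkey[duplicated(gkey)], 5), collapse = ", "))
  if (anyDuplicated(pkey))
    stop("duplicate variant keys in 'proxy': ",
         paste(utils::head(pkey[duplicated(pkey)], 5), collapse = ", "))

  m <- match(gkey, pkey)
  keep <- !is.na(m)
  if (!any(keep))
    stop("no variants overlap between the GWAS estimates and the proxy panel")
  g <- gwas[keep, , drop = FALSE]
  p <- proxy[m[keep], , drop = FALSE]

  ea <- toupper(g$effect_allele); oa <- toupper(g$other_allele)
  ref <- toupper(p$ref); alt <- toupper(p$alt)
  same <- alt == ea & ref == oa
  flipped <- alt == oa & ref == ea
  ok <- same | flipped
  if (!any(ok))
    stop("no variants remain after removing allele-pair mismatches")

  f <- ifelse(flipped, 1 - p$maf, p$maf)[ok]
  out <- data.frame(
    chrom = g$chrom[ok],
    pos = g$pos[ok],
    estimated_total_maf = g$maf_total[ok],
    proxy_maf = pmin(f, 1 - f),
    flip_applied = flipped[ok]
  )
  rownames(out) <- NULL
  out
}

normalize_chrom <- function(x) sub("^chr", "", as.character(x))

#' Fit the binned polynomial bias model
#'
#' Within each of the five MAF bins (binned on the proxy MAF) fits the
#' ordinary-least-squares model
#' `estimated_total_maf = b0 + b1 * proxy + b2 * proxy^2`. The bias at MAF
#' `x` in a bin is `B(x) = (b0 + b1 x + b2 x^2) - x`, the departure of the
#' fitted curve from the identity line. Bins with fewer pairs than
#' `min_bin_n` borrow the nearest populated bin's polynomial (a three
#' parameter fit on very few points is unstable); per-bin fits are
#' independent, so the bias function may be discontinuous at bin edges.
#'
#' @param pairs Output of [harmonize_proxy()]: a `data.frame` with columns
#'   `estimated_total_maf` and `proxy_maf`, both in \[0, 0.5\].
#' @param min_bin_n Minimum pair count for a bin to be fitted directly.
#' @return An object of class `"bias_model"`: a list with `coefficients`
#'   (5 x 3 matrix of `b0`, `b1`, `b2` per bin), `n` (pairs per bin),
#'   `fallback` (index of the bin each row was fitted from) and `breaks`.
#' @export
fit_bias_model <- function(pairs, min_bin_n = 30) {
  need <- c("estimated_total_maf", "proxy_maf")
  if (!all(need %in% names(pairs)))
    stop("'pairs' must have columns: ", paste(need, collapse = ", "))
  est <- pairs$estimated_total_maf
  prox <- pairs$proxy_maf
  keep <- is.finite(est) & is.finite(prox)
  est <- est[keep]; prox <- prox[keep]
  if (any(prox < 0 | prox > 0.5) || any(est < 0 | est > 0.5))
    stop("MAFs must lie in [0, 0.5]")

  bin <- bias_bin_index(prox)
  n_bin <- tabulate(bin, nbins = 5L)
  fitted_bins <- which(n_bin >= min_bin_n)
  if (length(fitted_bins) == 0L)
    stop("no MAF bin has at least ", min_bin_n,
         " harmonized pairs; cannot fit the bias model")

  coefs <- matrix(NA_real_, nrow = 5L, ncol = 3L,
                  dimnames = list(bias_bin_labels(), c("b0", "b1", "b2")))
  for (k in fitted_bins) {
    i <- bin == k
    fit <- stats::lm.fit(cbind(1, prox[i], prox[i]^2), est[i])
    coefs[k, ] <- fit$coefficients
  }
  fallback <- seq_len(5L)
  empty <- setdiff(seq_len(5L), fitted_bins)
  if (length(empty) > 0L) {
    for (k in empty)
      fallback[k] <- fitted_bins[which.min(abs(fitted_bins - k))]
    coefs[empty, ] <- coefs[fallback[empty], , drop = FALSE]
    warning("bin(s) ", paste(bias_bin_labels()[empty], collapse = ", "),
            " have fewer than ", min_bin_n,
            " pairs; borrowing the nearest fitted bin's polynomial")
  }

  structure(list(coefficients = coefs, n = n_bin, fallback = fallback,
                 breaks = BIAS_BIN_BREAKS, min_bin_n = min_bin_n),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  cat("Binned polynomial bias model (estimated MAF ~ proxy MAF)\n")
  tab <- cbind(round(x$coefficients, 6), n = x$n)
  print(tab)
  if (any(x$fallback != seq_len(5)))
    cat("Bins fitted by fallback:",
        paste(bias_bin_labels()[x$fallback != seq_len(5)], collapse = ", "),
        "\n")
  invisible(x)
}

# bias B(m) evaluated at MAF m with bin assignment by m itself
bias_at <- function(model, maf) {
  k <- bias_bin_index(maf)
  co <- model$coefficients
  (co[k, 1] + co[k, 2] * maf + co[k, 3] * maf^2) - maf
}

#' Remove the estimated bias from SE-derived MAF estimates
#'
#' Assigns each variant to a MAF bin by its estimated total MAF, evaluates
#' the bin's bias polynomial at that estimate, and subtracts the same bias
#' from the case, control and total MAF estimates. The bias model maps
#' proxy (truth) MAF to estimated MAF, but at application time only the
#' estimate is available -- also for variants absent from the proxy panel --
#' so the bias is evaluated at the estimate, which is first-order consistent
#' when the bias is small.
#'
#' @param estimates A `data.frame` with columns `maf_case`, `maf_control`
#'   and `maf_total` (output of [casecontrol_se()], possibly with further
#'   columns, which are preserved).
#' @param model A fitted [fit_bias_model()] object.
#' @return `estimates` with three appended columns `maf_case_adj`,
#'   `maf_control_adj`, `maf_total_adj`, clamped to \[0, 0.5\].
#' @export
apply_bias_correction <- function(estimates, model) {
  stopifnot(inherits(model, "bias_model"))
  need <- c("maf_case", "maf_control", "maf_total")
  if (!all(need %in% names(estimates)))
    stop("'estimates' must have columns: ", paste(need, collapse = ", "))
  m <- estimates$maf_total
  if (any(m < 0 - 1e-12 | m > 0.5 + 1e-12, na.rm = TRUE))
    stop("'maf_total' estimates must lie in [0, 0.5]")

  bias <- rep(NA_real_, length(m))
  ok <- is.finite(m)
  bias[ok] <- bias_at(model, pmin(pmax(m[ok], 0), 0.5))

  clamp <- function(x) pmin(pmax(x, 0), 0.5)
  estimates$maf_case_adj <- clamp(estimates$maf_case - bias)
  estimates$maf_control_adj <- clamp(estimates$maf_control - bias)
  estimates$maf_total_adj <- clamp(estimates$maf_total - bias)
  estimates
}

#' Read a proxy frequency panel from delimited text
#'
#' @param path Path to a delimited text file.
#' @param columns Named character vector mapping the canonical fields
#'   `chrom`, `pos`, `ref`, `alt`, `maf` to the file's column headers.
#' @param delim Field delimiter.
#' @return A `data.frame` with canonical columns, suitable for
#'   [harmonize_proxy()].
#' @export
read_proxy_panel <- function(path,
                             columns = c(chrom = "chrom", pos = "pos",
                                         ref = "ref", alt = "alt",
                                         maf = "maf"),
                             delim = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", "", "NaN", "."),
                          check.names = FALSE)
  missing_cols <- setdiff(unname(columns), names(df))
  if (length(missing_cols) > 0)
    stop("proxy panel is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(
    chrom = as.character(df[[columns[["chrom"]]]]),
    pos = as.integer(df[[columns[["pos"]]]]),
    ref = as.character(df[[columns[["ref"]]]]),
    alt = as.character(df[[columns[["alt"]]]]),
    maf = as.numeric(df[[columns[["maf"]]]])
  )
  out
}
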