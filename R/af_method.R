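# Case/control allele-frequency reconstruction from the odds ratio and the
# total-sample (case + control aggregated) effect-allele frequency.
#
# Writing the allelic 2x2 table as effect/other allele counts a,b (cases) and
# c,d (controls), the odds ratio OR = ad/(bc) together with the sample-size
# weighted identity
#   AF_total = (Ncase*AF_case + Ncontrol*AF_control) / Ntotal
# pins down AF_control as a root of a quadratic
#   A x^2 + B x + C = 0
#   A = (Ncontrol/Ncase) (OR - 1)
#   B = OR (1 - (Ntotal/Ncase) AF_total) + (Ncontrol + Ntotal*AF_total)/Ncase
#   C = -(Ntotal/Ncase) AF_total
# with exactly one root in [0,1] whenever OR != 1; AF_case then follows from
# the weighted identity.

#' Reconstruct case and control allele frequencies for one variant
#'
#' Solves the control-frequency quadratic given a per-allele odds ratio, the
#' total-sample effect-allele frequency, and the case/control sample sizes,
#' then recovers the case frequency from the sample-size weighted mean
#' identity. The effect-allele anchoring of the input frequency is preserved:
#' the returned frequencies refer to the same allele as `af_total`.
#'
#' @param or Odds ratio per effect allele; positive and finite.
#' @param af_total Total-sample effect-allele frequency in \[0, 1\]. This
#'   should be an allele-anchored frequency, not a folded minor allele
#'   frequency: folding the input loses the allele anchoring and adds
#'   variability to the estimates.
#' @param n_case,n_control Case and control sample sizes (individuals).
#' @param root_tol Acceptance window for the selected root: a root within
#'   `[-root_tol, 1 + root_tol]` is accepted and clamped to \[0, 1\].
#'   Guards against floating-point noise at boundary frequencies.
#'
#' @return A list with elements `af_case` and `af_control`, both in \[0, 1\].
#' @examples
#' # A table of 300/700 effect/other alleles in cases and 200/800 in controls
#' solve_casecontrol_af(or = 12 / 7, af_total = 0.25,
#'                      n_case = 500, n_control = 500)
#' @seealso [casecontrol_af()] for the vectorized version,
#'   [solve_casecontrol_se()] for the standard-error route.
#' @export
solve_casecontrol_af <- function(or, af_total, n_case, n_control,
                                 root_tol = 1e-8) {
  stopifnot(length(or) == 1L, length(af_total) == 1L,
            length(n_case) == 1L, length(n_control) == 1L)
  if (!is.finite(or) || or <= 0)
    stop("'or' must be a positive, finite odds ratio (got ", or, ")")
  if (!is.finite(af_total) || af_total < 0 || af_total > 1)
    stop("'af_total' must lie in [0, 1] (got ", af_total, ")")
  if (!is.finite(n_case) || n_case < 1 || !is.finite(n_control) ||
      n_control < 1)
    stop("'n_case' and 'n_control' must be positive sample sizes")

  out <- af_quadratic_solve(or, af_total, n_case, n_control, root_tol)
  if (is.na(out[["af_control"]]))
    stop("no control-frequency root in [0, 1] for or=", or,
         ", af_total=", af_total)
  out
}

#' Reconstruct case/control allele frequencies for a vector of variants
#'
#' Vectorized form of [solve_casecontrol_af()]. Rows with invalid inputs
#' (non-positive or non-finite odds ratio, total frequency outside \[0, 1\])
#' or without a root in \[0, 1\] yield `NA` estimates and a single summary
#' warning rather than a failure.
#'
#' @inheritParams solve_casecontrol_af
#' @param or,af_total Numeric vectors of equal length (or length 1, recycled
#'   via the usual rules for `n_case`/`n_control`).
#' @return A `data.frame` with columns `af_case` and `af_control`.
#' @export
casecontrol_af <- function(or, af_total, n_case, n_control, root_tol = 1e-8) {
  n <- length(or)
  if (length(af_total) != n)
    stop("'or' and 'af_total' must have the same length")
  if (n == 0L)
    return(data.frame(af_case = numeric(0), af_control = numeric(0)))
  bad <- !is.finite(or) | or <= 0 | !is.finite(af_total) |
    af_total < 0 | af_total > 1
  res <- af_quadratic_solve(ifelse(bad, 1, or),
                            ifelse(bad, 0.5, af_total),
                            n_case, n_control, root_tol)
  res$af_case[bad] <- NA_real_
  res$af_control[bad] <- NA_real_
  n_bad <- sum(bad | is.na(res$af_control))
  if (n_bad > 0)
    warning(n_bad, " variant(s) had invalid inputs or no admissible root; ",
            "returned as NA")
  res
}

# Core solver; vectorized over or/af_total. Returns raw roots selected in
# [-tol, 1+tol], clamped to [0,1]. The quadratic is solved with the stable
# formulation q = -(B + sign(B) sqrt(disc))/2, roots q/A and C/q, because B
# can dominate A*C by orders of magnitude at rare variants.
af_quadratic_solve <- function(or, af_total, n_case, n_control,
                               root_tol = 1e-8) {
  n_total <- n_case + n_control
  r_tot <- n_total / n_case     # Ntotal/Ncase
  r_con <- n_control / n_case   # Ncontrol/Ncase

  A <- r_con * (or - 1)
  B <- or * (1 - r_tot * af_total) + (n_control + n_total * af_total) / n_case
  C <- -r_tot * af_total

  in_window <- function(x) !is.na(x) & x >= -root_tol & x <= 1 + root_tol

  # OR = 1 collapses the quadratic to B x + C = 0 with B = Ntotal/Ncase,
  # hence x = af_total exactly; solving it linearly avoids cancellation.
  linear <- (or == 1)
  disc <- B * B - 4 * A * C
  disc[disc < 0 & disc > -1e-12 * B * B] <- 0
  q <- -(B + sign(B) * sqrt(pmax(disc, 0))) / 2
  root1 <- q / A
  root2 <- ifelse(q == 0, NA_real_, C / q)
  if (any(linear)) {
    lin_root <- -C / B
    root1[linear] <- lin_root[linear]
    root2[linear] <- NA_real_
  }
  root1[disc < 0] <- NA_real_
  root2[disc < 0] <- NA_real_

  ok1 <- in_window(root1)
  ok2 <- in_window(root2) & !ok1
  af_control <- ifelse(ok1, root1, ifelse(ok2, root2, NA_real_))
  af_case <- r_tot * af_total - r_con * af_control

  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  data.frame(af_case = clamp01(af_case), af_control = clamp01(af_control))
}

#' Odds ratio from a log-odds effect estimate
#'
#' @param beta Log-odds (logistic regression) effect estimate; finite.
#' @return `exp(beta)`.
#' @export
or_from_beta <- function(beta) {
  if (any(!is.finite(beta)))
    stop("'beta' must be finite")
  exp(beta)
}

#' Standard error of the log odds ratio from beta and p-value
#'
#' Recovers the Wald standard error as `|beta| / z` where `z` is the upper
#' `1 - p/2` standard-normal quantile. The quantile is evaluated through the
#' upper tail (`qnorm(p/2, lower.tail = FALSE)`) so that genome-wide
#' significant p-values (e.g. `1e-100`) do not lose precision.
#'
#' @param beta Log-odds effect estimate; non-zero and finite.
#' @param p Two-sided p-value in (0, 1). Subnormal values (below about
#'   `2.2e-308`) carry no usable precision and raise an underflow error:
#'   use the test statistic directly instead.
#' @return Standard error(s) of the log odds ratio.
#' @export
se_from_beta_p <- function(beta, p) {
  if (any(!is.finite(beta)) || any(beta == 0))
    stop("'beta' must be finite and non-zero")
  if (any(!is.finite(p)) || any(p >= 1))
    stop("'p' must lie in (0, 1)")
  if (any(p < .Machine$double.xmin))
    stop("p-value underflow (p < ", format(.Machine$double.xmin),
         "): derive the SE from the test statistic instead")
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  abs(beta) / z
}
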