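# Minor-allele-frequency reconstruction from the odds ratio and the standard
# error of the log odds ratio.
#
# With allele counts a,b (effect/other, cases) and c,d (controls) and group
# allele numbers N1 = a + b, N2 = c + d, the pair (OR, SE) satisfies
#   OR   = a d / (b c)
#   SE^2 = 1/a + 1/b + 1/c + 1/d
# Eliminating a, b, c leaves a quadratic in d:
#   d^2 [SE^2 + (1-OR)^2 / (OR N1)]
#   + d [2 N2 (1-OR)/N1 - SE^2 N2]
#   + N2 (OR N2 / N1 + 1) = 0
# Each admissible root materializes a full table via
#   c = N2 - d,  a = OR N1 (N2 - d) / (OR N2 + d (1 - OR)),  b = N1 - a.
# Both roots can describe internally consistent tables (they correspond to
# the two allele labelings compatible with the same OR and SE); the method
# assumes the frequency being solved for is the minor allele, so the root
# whose implied control frequency is <= 0.5 is selected and all outputs are
# folded to [0, 0.5]. Allele anchoring is therefore lost: outputs are minor
# allele frequencies, not effect-allele frequencies.

#' Reconstruct case and control minor allele frequencies from OR and SE
#'
#' Recovers the 2x2 allele-count table consistent with an odds ratio and the
#' standard error of its log, given the total allele numbers in cases and
#' controls (`2 * N` per group for autosomes; see
#' [allele_number_sex_chrom()] for X/Y). Returns folded minor allele
#' frequencies: the connection between the reported effect allele and the
#' estimated frequency is lost by construction.
#'
#' @param or Odds ratio; positive and finite.
#' @param se Standard error of the log odds ratio; positive and finite.
#' @param alleles_case,alleles_control Total allele numbers per group
#'   (at least 2 each).
#' @return A list with `maf_case`, `maf_control` and `maf_total`, all in
#'   \[0, 0.5\]. `maf_total` is the allele-number-weighted pooled minor
#'   allele frequency, folded after pooling.
#' @examples
#' # Table a=300, b=700 (cases), c=200, d=800 (controls)
#' solve_casecontrol_se(or = 12 / 7,
#'                      se = sqrt(1 / 300 + 1 / 700 + 1 / 200 + 1 / 800),
#'                      alleles_case = 1000, alleles_control = 1000)
#' @export
solve_casecontrol_se <- function(or, se, alleles_case, alleles_control) {
  stopifnot(length(or) == 1L, length(se) == 1L)
  if (!is.finite(or) || or <= 0)
    stop("'or' must be a positive, finite odds ratio (got ", or, ")")
  if (!is.finite(se) || se <= 0)
    stop("'se' must be a positive, finite standard error (got ", se, ")")
  if (alleles_case < 2 || alleles_control < 2)
    stop("allele numbers must be at least 2 per group")
  res <- se_table_solve(or, se, alleles_case, alleles_control)
  if (is.na(res$maf_control))
    stop("no allele-count table with all cells in range is consistent with ",
         "or=", or, ", se=", se, ": no solution for this variant")
  res
}

#' Reconstruct case/control minor allele frequencies for a vector of variants
#'
#' Vectorized form of [solve_casecontrol_se()]. Rows with invalid inputs or
#' without a consistent positive allele-count table yield `NA` with a single
#' summary warning.
#'
#' @inheritParams solve_casecontrol_se
#' @return A `data.frame` with columns `maf_case`, `maf_control`,
#'   `maf_total`.
#' @export
casecontrol_se <- function(or, se, alleles_case, alleles_control) {
  n <- length(or)
  if (length(se) != n)
    stop("'or' and 'se' must have the same length")
  if (n == 0L)
    return(data.frame(maf_case = numeric(0), maf_control = numeric(0),
                      maf_total = numeric(0)))
  bad <- !is.finite(or) | or <= 0 | !is.finite(se) | se <= 0
  res <- se_table_solve(ifelse(bad, 1, or), ifelse(bad, 1, se),
                        alleles_case, alleles_control)
  for (col in names(res)) res[[col]][bad] <- NA_real_
  n_bad <- sum(bad | is.na(res$maf_control))
  if (n_bad > 0)
    warning(n_bad, " variant(s) had invalid inputs or no consistent ",
            "allele-count table; returned as NA")
  res
}

# Vectorized table solver. Real-valued (non-integer) cells are accepted:
# SEs from logistic regressions do not arise from exact tables.
se_table_solve <- function(or, se, n1, n2) {
  se2 <- se * se
  u <- 1 - or
  A <- se2 + u * u / (or * n1)
  B <- 2 * n2 * u / n1 - se2 * n2
  C <- n2 * (or * n2 / n1 + 1)

  disc <- B * B - 4 * A * C
  # near-degenerate discriminant treated as a double root (OR ~ 1)
  disc[disc < 0 & disc > -1e-12 * B * B] <- 0
  has_root <- disc >= 0
  sq <- sqrt(pmax(disc, 0))
  q <- -(B + sign(B) * sq) / 2
  d1 <- q / A
  d2 <- ifelse(q == 0, NA_real_, C / q)

  materialize <- function(d) {
    cc <- n2 - d
    a <- or * n1 * cc / (or * n2 + d * u)
    b <- n1 - a
    list(a = a, b = b, c = cc, d = d,
         valid = is.finite(d) & d > 0 & cc > 0 & is.finite(a) & a > 0 &
           b > 0)
  }
  t1 <- materialize(d1)
  t2 <- materialize(d2)

  # the method assumes the solved allele is the minor allele: when both
  # roots give admissible tables, keep the one whose control frequency is
  # <= 0.5 (smaller control count on ties)
  f1 <- t1$c / n2
  f2 <- t2$c / n2
  pick1 <- t1$valid & (!t2$valid |
                         (f1 <= 0.5 & f2 > 0.5) |
                         ((f1 <= 0.5) == (f2 <= 0.5) & f1 <= f2))
  pick2 <- t2$valid & !pick1
  sel <- function(field) {
    ifelse(pick1, t1[[field]],
           ifelse(pick2, t2[[field]], NA_real_))
  }
  a <- sel("a"); b <- sel("b"); cc <- sel("c"); d <- sel("d")
  a[!has_root] <- NA_real_; b[!has_root] <- NA_real_
  cc[!has_root] <- NA_real_; d[!has_root] <- NA_real_

  data.frame(
    maf_case = pmin(a, b) / n1,
    maf_control = pmin(cc, d) / n2,
    maf_total = pmin(a + cc, b + d) / (n1 + n2)
  )
}

#' Group allele numbers for sex-chromosome variants
#'
#' The SE-based reconstruction works on total allele numbers rather than
#' sample sizes, so X and Y chromosome variants need karyotype-aware counts:
#' XX individuals carry two X alleles and no Y allele, XY individuals one of
#' each.
#'
#' @param n_xx_case,n_xy_case,n_xx_control,n_xy_control Individual counts by
#'   sex-chromosome karyotype in cases and controls; non-negative, with at
#'   least one non-zero count per group for the requested chromosome.
#' @param chromosome `"X"` or `"Y"`.
#' @return Named numeric vector `c(alleles_case = , alleles_control = )`.
#' @examples
#' allele_number_sex_chrom(300, 200, 400, 100, "X")  # c(800, 900)
#' allele_number_sex_chrom(300, 200, 400, 100, "Y")  # c(200, 100)
#' @export
allele_number_sex_chrom <- function(n_xx_case, n_xy_case,
                                    n_xx_control, n_xy_control,
                                    chromosome = c("X", "Y")) {
  chromosome <- match.arg(chromosome)
  counts <- c(n_xx_case, n_xy_case, n_xx_control, n_xy_control)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("karyotype counts must be non-negative")
  if (chromosome == "X") {
    out <- c(alleles_case = 2 * n_xx_case + n_xy_case,
             alleles_control = 2 * n_xx_control + n_xy_control)
  } else {
    out <- c(alleles_case = n_xy_case, alleles_control = n_xy_control)
  }
  if (any(out == 0))
    stop("zero total alleles on chromosome ", chromosome,
         " in one group; cannot reconstruct frequencies")
  out
}
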