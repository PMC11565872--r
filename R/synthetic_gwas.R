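# Synthetic case/control GWAS generator.
#
# Emulates the structure of a single-cohort binary-trait GWAS: biallelic
# genotypes drawn under Hardy-Weinberg equilibrium, a latent liability
# composed of a standardized polygenic score, optional covariate effects and
# Gaussian noise, and case status assigned by thresholding the liability so
# the case/control counts are met exactly. Per-variant logistic regressions
# on the realized data supply the (OR, SE) summary statistics that the
# reconstruction routes consume, and the realized case/control split defines
# the true allele frequencies they are judged against.

#' Simulate a case/control GWAS with per-variant summary statistics
#'
#' Generates genotypes for `n_variants` biallelic variants in
#' `n_case + n_control` individuals (HWE, population alternate-allele
#' frequencies drawn uniformly from `maf_range`), assigns Gaussian effect
#' sizes to `n_causal` randomly chosen variants, and builds a liability as
#'
#' `liability = genetic score + covariate score + noise`
#'
#' with the genetic score standardized to explain `h2_genetic` of the
#' liability variance and the covariate score `h2_covariate` (when
#' covariates are present). Individuals with the `n_case` largest
#' liabilities are cases, so the case/control counts are exact. Covariates
#' mimic a typical GWAS adjustment set: one binary covariate resembling
#' biological sex (probability 0.5); with `n_covariates = 3`, additionally a
#' five-level categorical covariate and a normal covariate with mean 30 and
#' standard deviation 20 (an age-like variable).
#'
#' @param n_case,n_control Number of cases and controls (exact).
#' @param n_variants Number of simulated variants.
#' @param n_causal Number of causal variants (`<= n_variants`).
#' @param n_covariates 0, 1 or 3 covariates entering the liability and the
#'   per-variant regressions.
#' @param h2_genetic Fraction of liability variance explained by the
#'   polygenic score.
#' @param h2_covariate Fraction of liability variance explained by the
#'   covariate score; ignored (treated as 0) when `n_covariates = 0`.
#' @param maf_range Interval from which population alternate-allele
#'   frequencies are drawn, a sub-interval of (0, 0.5].
#' @param seed Optional integer seed; the same seed reproduces the study
#'   exactly.
#' @return An object of class `"gwas_sim"`: a list with the genotype matrix
#'   (`genotypes`, individuals x variants, dosages 0/1/2 of the alternate
#'   allele), `covariates` (`data.frame` or `NULL`), `phenotype` (0/1),
#'   `causal` (logical), `effects`, population frequencies `maf_pop`, true
#'   realized frequencies `af_case`, `af_control`, `af_total`, and the
#'   configuration.
#' @examples
#' study <- simulate_gwas(n_case = 100, n_control = 100, n_variants = 50,
#'                        n_causal = 5, seed = 1)
#' head(study$af_case)
#' @export
simulate_gwas <- function(n_case, n_control, n_variants = 10000L,
                          n_causal = 100L, n_covariates = 0L,
                          h2_genetic = 0.2, h2_covariate = 0.2,
                          maf_range = c(0.05, 0.5), seed = NULL) {
  if (!n_covariates %in% c(0L, 1L, 3L))
    stop("'n_covariates' must be 0, 1 or 3")
  if (n_causal > n_variants)
    stop("'n_causal' cannot exceed 'n_variants'")
  if (n_case < 1 || n_control < 1)
    stop("'n_case' and 'n_control' must be positive")
  h2_cov <- if (n_covariates == 0L) 0 else h2_covariate
  if (h2_genetic < 0 || h2_cov < 0 || h2_genetic + h2_cov >= 1)
    stop("variance fractions must be non-negative and sum to less than 1")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("'maf_range' must be a sub-interval of (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)

  n <- as.integer(n_case + n_control)
  m <- as.integer(n_variants)

  maf_pop <- stats::runif(m, maf_range[1], maf_range[2])
  G <- matrix(stats::rbinom(n * m, 2L, rep(maf_pop, each = n)),
              nrow = n, ncol = m)

  causal_idx <- sample.int(m, n_causal)
  causal <- logical(m)
  causal[causal_idx] <- TRUE
  effects <- numeric(m)

  genetic <- numeric(n)
  if (n_causal > 0L && h2_genetic > 0) {
    effects[causal_idx] <- stats::rnorm(n_causal)
    Gc <- G[, causal_idx, drop = FALSE]
    Gs <- scale(Gc)
    Gs[is.nan(Gs)] <- 0  # monomorphic causal variant contributes nothing
    raw <- as.vector(Gs %*% effects[causal_idx])
    s <- stats::sd(raw)
    if (s > 0) genetic <- raw / s * sqrt(h2_genetic)
  }

  covariates <- NULL
  covscore <- numeric(n)
  if (n_covariates >= 1L) {
    covariates <- data.frame(sex = stats::rbinom(n, 1L, 0.5))
    if (n_covariates == 3L) {
      covariates$group <- sample.int(5L, n, replace = TRUE)
      covariates$age <- stats::rnorm(n, 30, 20)
    }
    Xc <- covariate_design(covariates)
    raw <- as.vector(scale(Xc) %*% rep(1, ncol(Xc)))
    s <- stats::sd(raw)
    if (s > 0 && h2_cov > 0) covscore <- raw / s * sqrt(h2_cov)
  }

  noise <- stats::rnorm(n, sd = sqrt(1 - h2_genetic - h2_cov))
  liability <- genetic + covscore + noise

  # threshold at the Ncase-th order statistic: counts are exact
  phenotype <- integer(n)
  phenotype[order(liability, decreasing = TRUE)[seq_len(n_case)]] <- 1L

  afs <- split_afs(G, phenotype, n_case, n_control)

  structure(c(list(genotypes = G, covariates = covariates,
                   phenotype = phenotype, causal = causal,
                   effects = effects, maf_pop = maf_pop),
              afs,
              list(config = list(n_case = as.integer(n_case),
                                 n_control = as.integer(n_control),
                                 n_variants = m, n_causal = as.integer(n_causal),
                                 n_covariates = as.integer(n_covariates),
                                 h2_genetic = h2_genetic,
                                 h2_covariate = h2_cov,
                                 maf_range = maf_range, seed = seed))),
            class = "gwas_sim")
}

# dummy-coded covariate design (no intercept column): binary sex as is,
# 5-level categorical as 4 indicators, numeric age as is
covariate_design <- function(covariates) {
  cols <- list(sex = covariates$sex)
  if (!is.null(covariates$group)) {
    for (lev in 2:5)
      cols[[paste0("group", lev)]] <- as.numeric(covariates$group == lev)
    cols$age <- covariates$age
  }
  do.call(cbind, cols)
}

split_afs <- function(G, phenotype, n_case, n_control) {
  case <- phenotype == 1L
  ac_case <- colSums(G[case, , drop = FALSE])
  ac_total <- colSums(G)
  af_case <- ac_case / (2 * n_case)
  af_control <- (ac_total - ac_case) / (2 * n_control)
  af_total <- ac_total / (2 * (n_case + n_control))
  list(af_case = af_case, af_control = af_control, af_total = af_total)
}

#' @export
print.gwas_sim <- function(x, ...) {
  cfg <- x$config
  cat("Simulated case/control GWAS\n")
  cat("  variants:", cfg$n_variants, "(", cfg$n_causal, "causal )\n")
  cat("  cases:", cfg$n_case, " controls:", cfg$n_control, "\n")
  cat("  covariates:", cfg$n_covariates,
      " h2 genetic:", cfg$h2_genetic,
      " h2 covariate:", cfg$h2_covariate, "\n")
  invisible(x)
}

#' True allele frequencies from the realized case/control split
#'
#' @param study A [simulate_gwas()] object.
#' @return A `data.frame` with per-variant `af_case`, `af_control`,
#'   `af_total` (alternate-allele frequencies counted from the genotypes)
#'   and the `causal` flag.
#' @export
true_afs <- function(study) {
  stopifnot(inherits(study, "gwas_sim"))
  data.frame(af_case = study$af_case, af_control = study$af_control,
             af_total = study$af_total, causal = study$causal)
}

#' Per-variant logistic regression summary statistics
#'
#' Fits one logistic regression per variant with additive dosage coding
#' (0/1/2), optionally adjusted for the study covariates, and returns Wald
#' summary statistics. Without covariates the fit runs as a vectorized
#' Newton-Raphson on genotype-by-status counts (identical to `glm()` to
#' machine precision); with covariates each variant is fitted with
#' `stats::glm.fit()`. Monomorphic, separated or non-converged variants are
#' returned as `NA` with a summary warning.
#'
#' @param study A [simulate_gwas()] object.
#' @param include_covariates Adjust for the study's covariates (if any).
#' @return A `data.frame` with columns `beta`, `se`, `or`, `p`, `converged`.
#' @export
fit_pervariant_logistic <- function(study, include_covariates = TRUE) {
  stopifnot(inherits(study, "gwas_sim"))
  y <- study$phenotype
  if (length(unique(y)) < 2L)
    stop("phenotype must contain both cases and controls")
  use_cov <- include_covariates && !is.null(study$covariates)
  fit <- if (use_cov) {
    logistic_glm_covariates(study$genotypes, y,
                            covariate_design(study$covariates))
  } else {
    logistic_newton_counts(study$genotypes, y)
  }
  n_fail <- sum(!fit$converged)
  if (n_fail > 0)
    warning(n_fail, " variant(s) monomorphic, separated or non-converged; ",
            "summary statistics returned as NA")
  fit$or <- exp(fit$beta)
  fit$p <- 2 * stats::pnorm(abs(fit$beta) / fit$se, lower.tail = FALSE)
  fit[, c("beta", "se", "or", "p", "converged")]
}

#' Write a simulated study to delimited text
#'
#' Writes the per-variant summary-statistics table (`sumstats.tsv`,
#' canonical headers) and the truth table (`truth.tsv`: variant key, true
#' case/control/total frequencies, causal flag). Optionally writes the
#' genotypes as a minimal GT-only VCF (`genotypes.vcf`) for
#' interoperability; variants are placed on a single synthetic chromosome
#' at consecutive positions.
#'
#' @param study A [simulate_gwas()] object.
#' @param dir Output directory (created if missing).
#' @param sumstats Per-variant statistics, e.g. from
#'   [fit_pervariant_logistic()]; fitted here (with covariates when present)
#'   if `NULL`.
#' @param vcf Also write a GT-only VCF of the genotypes.
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir, sumstats = NULL, vcf = FALSE) {
  stopifnot(inherits(study, "gwas_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(sumstats))
    sumstats <- suppressWarnings(fit_pervariant_logistic(study))
  m <- study$config$n_variants
  key <- data.frame(chromosome = rep("1", m),
                    base_pair_location = seq_len(m),
                    effect_allele = rep("G", m),
                    other_allele = rep("A", m))
  ss <- cbind(key,
              data.frame(odds_ratio = sumstats$or, beta = sumstats$beta,
                         standard_error = sumstats$se, p_value = sumstats$p,
                         effect_allele_frequency = study$af_total))
  ss_path <- file.path(dir, "sumstats.tsv")
  utils::write.table(ss, ss_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  truth <- cbind(key[, 1:2],
                 data.frame(af_case = study$af_case,
                            af_control = study$af_control,
                            af_total = study$af_total,
                            causal = as.integer(study$causal)))
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  paths <- c(sumstats = ss_path, truth = truth_path)
  if (vcf) {
    vcf_path <- file.path(dir, "genotypes.vcf")
    write_gt_vcf(study, vcf_path)
    paths <- c(paths, vcf = vcf_path)
  }
  invisible(paths)
}

# minimal VCF 4.2 with GT fields only; alternate allele G, dosage = count of G
write_gt_vcf <- function(study, path) {
  G <- study$genotypes
  n <- nrow(G)
  m <- ncol(G)
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT",
                     paste0("sample", seq_len(n))), collapse = "\t"), con)
  for (j in seq_len(m)) {
    writeLines(paste(c("1", j, paste0("var", j), "A", "G", ".", "PASS", ".",
                       "GT", gt_codes[G[, j] + 1L]), collapse = "\t"), con)
  }
  invisible(path)
}
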