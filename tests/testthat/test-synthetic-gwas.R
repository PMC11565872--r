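# Liability-threshold GWAS simulator and per-variant logistic fits.

small_study <- function(...) {
  simulate_gwas(n_case = 150, n_control = 350, n_variants = 80,
                n_causal = 8, seed = 42, ...)
}

test_that("the same seed reproduces the study bit for bit", {
  s1 <- small_study()
  s2 <- small_study()
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotype, s2$phenotype)
  expect_identical(s1$af_case, s2$af_case)
  s3 <- simulate_gwas(n_case = 150, n_control = 350, n_variants = 80,
                      n_causal = 8, seed = 43)
  expect_false(identical(s1$genotypes, s3$genotypes))
})

test_that("case and control counts are exact by construction", {
  s <- small_study()
  expect_identical(sum(s$phenotype == 1L), 150L)
  expect_identical(sum(s$phenotype == 0L), 350L)
  s2 <- simulate_gwas(n_case = 600, n_control = 5400, n_variants = 20,
                      n_causal = 2, seed = 1)
  expect_identical(sum(s2$phenotype), 600L)
})

test_that("true frequencies recompute from the genotype split", {
  s <- small_study()
  case <- s$phenotype == 1L
  expect_equal(s$af_case, colSums(s$genotypes[case, ]) / (2 * 150))
  expect_equal(s$af_control, colSums(s$genotypes[!case, ]) / (2 * 350))
  # weighted-mean identity on realized data
  expect_equal((150 * s$af_case + 350 * s$af_control) / 500, s$af_total,
               tolerance = 1e-12)
  tr <- true_afs(s)
  expect_identical(tr$af_case, s$af_case)
  expect_identical(sum(tr$causal), 8L)
})

test_that("covariate configurations build the documented design", {
  s0 <- small_study()
  expect_null(s0$covariates)
  s1 <- small_study(n_covariates = 1)
  expect_identical(names(s1$covariates), "sex")
  expect_true(all(s1$covariates$sex %in% 0:1))
  s3 <- small_study(n_covariates = 3)
  expect_identical(names(s3$covariates), c("sex", "group", "age"))
  expect_true(all(s3$covariates$group %in% 1:5))
  expect_error(small_study(n_covariates = 2), "0, 1 or 3")
})

test_that("invalid configurations are rejected", {
  expect_error(simulate_gwas(100, 100, n_variants = 5, n_causal = 10),
               "cannot exceed")
  expect_error(simulate_gwas(100, 100, n_variants = 5, n_causal = 1,
                             h2_genetic = 0.6, h2_covariate = 0.5,
                             n_covariates = 1),
               "variance fractions")
  expect_error(simulate_gwas(100, 100, maf_range = c(0, 0.6)), "maf_range")
})

test_that("a 2x2 logistic fit equals the closed-form table estimate", {
  # carriers/non-carriers: 30/70 in cases, 20/80 in controls
  G <- matrix(c(rep(1L, 30), rep(0L, 70), rep(1L, 20), rep(0L, 80)),
              ncol = 1)
  y <- c(rep(1L, 100), rep(0L, 100))
  fit <- logistic_newton_counts(G, y)
  expect_equal(fit$beta, log(30 * 80 / (70 * 20)), tolerance = 1e-8)
  expect_equal(fit$se, sqrt(1 / 30 + 1 / 70 + 1 / 20 + 1 / 80),
               tolerance = 1e-8)
})

test_that("the vectorized Newton fit matches glm to machine precision", {
  set.seed(77)
  s <- small_study()
  fit <- suppressWarnings(fit_pervariant_logistic(s))
  for (j in c(3, 17, 55)) {
    ref <- stats::glm(s$phenotype ~ s$genotypes[, j], family = binomial())
    expect_equal(fit$beta[j], unname(coef(ref)[2]), tolerance = 1e-6)
    # glm's own IRLS stopping rule limits agreement of the SEs
    expect_equal(fit$se[j], unname(sqrt(vcov(ref)[2, 2])), tolerance = 1e-5)
  }
})

test_that("covariate-adjusted fits match glm and differ from unadjusted", {
  s <- small_study(n_covariates = 3)
  fit_adj <- suppressWarnings(fit_pervariant_logistic(s))
  fit_raw <- suppressWarnings(
    fit_pervariant_logistic(s, include_covariates = FALSE))
  j <- which(!is.na(fit_adj$beta))[5]
  X <- data.frame(g = s$genotypes[, j], s$covariates)
  ref <- stats::glm(s$phenotype ~ g + sex + factor(group) + age,
                    data = X, family = binomial())
  expect_equal(fit_adj$beta[j], unname(coef(ref)["g"]), tolerance = 1e-6)
  expect_equal(fit_adj$se[j], unname(sqrt(vcov(ref)["g", "g"])),
               tolerance = 1e-6)
  expect_false(isTRUE(all.equal(fit_adj$beta, fit_raw$beta)))
})

test_that("monomorphic variants come back missing with a warning", {
  s <- small_study()
  s$genotypes[, 4] <- 0L
  expect_warning(fit <- fit_pervariant_logistic(s), "monomorphic")
  expect_true(is.na(fit$beta[4]))
  expect_true(is.na(fit$or[4]))
})

test_that("a null simulation is calibrated", {
  s <- simulate_gwas(n_case = 400, n_control = 400, n_variants = 2000,
                     n_causal = 0, h2_genetic = 0, seed = 314)
  fit <- suppressWarnings(fit_pervariant_logistic(s))
  p <- fit$p[!is.na(fit$p)]
  expect_gt(length(p), 1900)
  expect_lt(abs(mean(fit$beta, na.rm = TRUE)), 0.01)
  frac <- mean(p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(p)) + 0.005)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))  # ties from discrete counts
  expect_gt(ks$p.value, 0.001)
})

test_that("fitted effects track simulated causal effects", {
  s <- simulate_gwas(n_case = 1500, n_control = 1500, n_variants = 400,
                     n_causal = 80, seed = 2718)
  fit <- suppressWarnings(fit_pervariant_logistic(s))
  i <- s$causal & !is.na(fit$beta)
  expect_gt(cor(fit$beta[i], s$effects[i], method = "spearman"), 0.5)
})

test_that("study writer produces readable sumstats, truth, and VCF", {
  dir <- withr::local_tempdir()
  s <- simulate_gwas(n_case = 30, n_control = 30, n_variants = 12,
                     n_causal = 2, seed = 5)
  paths <- write_study(s, dir, vcf = TRUE)
  ss <- read_sumstats(paths[["sumstats"]])
  expect_identical(nrow(ss), 12L)
  truth <- read.table(paths[["truth"]], header = TRUE, sep = "\t")
  expect_equal(truth$af_case, s$af_case)
  vcf <- readLines(paths[["vcf"]])
  expect_identical(sum(!startsWith(vcf, "#")), 12L)
  body <- strsplit(vcf[!startsWith(vcf, "#")][1], "\t")[[1]]
  gt <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)[body[-(1:9)]]
  expect_identical(unname(gt), s$genotypes[, 1])
})
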