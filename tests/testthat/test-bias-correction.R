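# Harmonization, binned polynomial bias model, and correction.

make_pairs <- function(proxy, estimated) {
  data.frame(chrom = "1", pos = seq_along(proxy),
             estimated_total_maf = estimated, proxy_maf = proxy,
             flip_applied = FALSE)
}

test_that("harmonization keeps matches, flips opposing anchors, drops mismatches", {
  gwas <- data.frame(chrom = c("1", "1", "1"), pos = c(100, 200, 300),
                     effect_allele = c("A", "G", "A"),
                     other_allele = c("G", "A", "T"),
                     maf_total = c(0.1, 0.2, 0.3))
  proxy <- data.frame(chrom = c("1", "chr1", "1"), pos = c(100, 200, 300),
                      ref = c("G", "G", "G"), alt = c("A", "A", "A"),
                      maf = c(0.2, 0.8, 0.5))
  out <- harmonize_proxy(gwas, proxy)
  # variant 3 removed: allele pair A/T vs A/G
  expect_identical(nrow(out), 2L)
  # variant 1: same anchor, kept as is
  expect_false(out$flip_applied[1])
  expect_equal(out$proxy_maf[1], 0.2)
  # variant 2: proxy anchored to the opposing allele, flipped then folded
  expect_true(out$flip_applied[2])
  expect_equal(out$proxy_maf[2], 0.2)
})

test_that("harmonization errors on duplicates and empty overlap", {
  gwas <- data.frame(chrom = "1", pos = c(100, 100),
                     effect_allele = "A", other_allele = "G",
                     maf_total = 0.1)
  proxy <- data.frame(chrom = "1", pos = 100, ref = "G", alt = "A",
                      maf = 0.2)
  expect_error(harmonize_proxy(gwas, proxy), "duplicate")
  expect_error(
    harmonize_proxy(gwas[1, ], transform(proxy, pos = 999)),
    "no variants overlap")
})

test_that("identity data fits the identity polynomial with zero bias", {
  set.seed(5)
  proxy <- runif(500, 0, 0.5)
  model <- fit_bias_model(make_pairs(proxy, proxy))
  expect_equal(unname(model$coefficients[, "b0"]), rep(0, 5),
               tolerance = 1e-9)
  expect_equal(unname(model$coefficients[, "b1"]), rep(1, 5),
               tolerance = 1e-8)
  expect_equal(unname(model$coefficients[, "b2"]), rep(0, 5),
               tolerance = 1e-8)
  est <- data.frame(maf_case = proxy, maf_control = proxy, maf_total = proxy)
  adj <- apply_bias_correction(est, model)
  expect_equal(adj$maf_case_adj, est$maf_case, tolerance = 1e-9)
  expect_equal(adj$maf_total_adj, est$maf_total, tolerance = 1e-9)
})

test_that("noiseless shrinkage and curvature are recovered exactly", {
  set.seed(6)
  proxy <- runif(2000, 0, 0.5)
  # linear shrinkage: estimated = 0.9 * proxy => bias B(x) = -0.1 x
  model <- fit_bias_model(make_pairs(proxy, 0.9 * proxy))
  for (k in 1:5) {
    x <- 0.1 * k - 0.05
    bias <- model$coefficients[k, 1] + model$coefficients[k, 2] * x +
      model$coefficients[k, 3] * x^2 - x
    expect_equal(bias, -0.1 * x, tolerance = 1e-6)
  }
  # a variant with estimate m gets adjusted_total = m + 0.1 m = 1.1 m
  est <- data.frame(maf_case = 0.18, maf_control = 0.18, maf_total = 0.18)
  adj <- apply_bias_correction(est, model)
  expect_equal(adj$maf_total_adj, 1.1 * 0.18, tolerance = 1e-6)
  # quadratic term: estimated = proxy - 0.02 proxy^2
  model2 <- fit_bias_model(make_pairs(proxy, proxy - 0.02 * proxy^2))
  expect_equal(unname(model2$coefficients[, "b2"]), rep(-0.02, 5),
               tolerance = 1e-6)
})

test_that("adjusted values are clamped to [0, 0.5]", {
  set.seed(8)
  proxy <- runif(300, 0.4, 0.5)
  # inflation model pushes adjustments below the estimate; build the
  # opposite: estimated below proxy so correction pushes values up
  model <- suppressWarnings(fit_bias_model(make_pairs(proxy, 0.8 * proxy)))
  est <- data.frame(maf_case = 0.49, maf_control = 0.01, maf_total = 0.49)
  adj <- apply_bias_correction(est, model)
  expect_true(all(adj$maf_case_adj <= 0.5 & adj$maf_case_adj >= 0))
  expect_true(all(adj$maf_control_adj <= 0.5 & adj$maf_control_adj >= 0))
})

test_that("sparse bins borrow the nearest fitted polynomial", {
  set.seed(12)
  proxy <- runif(200, 0, 0.2)  # only bins 1-2 populated
  expect_warning(model <- fit_bias_model(make_pairs(proxy, 0.9 * proxy)),
                 "borrowing")
  expect_identical(model$fallback[4:5], c(2L, 2L))
  expect_false(any(is.na(model$coefficients)))
  expect_error(fit_bias_model(make_pairs(proxy[1:5], proxy[1:5])),
               "cannot fit")
})

test_that("correction improves concordance under monotone shrinkage with noise", {
  set.seed(99)
  n <- 5000
  true_maf <- runif(n, 0.01, 0.5)
  # monotone shrinkage worsening with MAF plus noise, the qualitative
  # signature of covariate-induced underestimation
  shrink <- function(m) m - 0.3 * m^2
  est_total <- pmin(pmax(shrink(true_maf) + rnorm(n, 0, 0.005), 0), 0.5)
  est <- data.frame(maf_case = est_total, maf_control = est_total,
                    maf_total = est_total)
  pairs <- make_pairs(true_maf, est_total)
  model <- fit_bias_model(pairs)
  adj <- apply_bias_correction(est, model)
  expect_gt(lins_ccc(true_maf, adj$maf_total_adj),
            lins_ccc(true_maf, est_total))
  expect_lt(mean(abs(adj$maf_total_adj - true_maf)),
            mean(abs(est_total - true_maf)))
  # per populated bin as well
  bin <- findInterval(true_maf, c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                      rightmost.closed = TRUE)
  for (k in 1:5) {
    i <- bin == k
    expect_lt(mean(abs(adj$maf_total_adj[i] - true_maf[i])),
              mean(abs(est_total[i] - true_maf[i])))
  }
  # fitting on a 10% subset suffices
  sub <- sample(n, n %/% 10)
  model_sub <- fit_bias_model(pairs[sub, ])
  adj_sub <- apply_bias_correction(est, model_sub)
  expect_gt(lins_ccc(true_maf, adj_sub$maf_total_adj),
            lins_ccc(true_maf, est_total))
})

test_that("unbiased estimates are left nearly unchanged", {
  set.seed(15)
  n <- 4000
  true_maf <- runif(n, 0.01, 0.5)
  noise_sd <- 0.01
  est_total <- pmin(pmax(true_maf + rnorm(n, 0, noise_sd), 0), 0.5)
  est <- data.frame(maf_case = est_total, maf_control = est_total,
                    maf_total = est_total)
  model <- fit_bias_model(make_pairs(true_maf, est_total))
  adj <- apply_bias_correction(est, model)
  expect_lt(mean(abs(adj$maf_total_adj - est_total)), noise_sd)
})
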