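# Forward-construction oracles: build integer allele-count tables, compute
# the summary statistics a GWAS would publish, and keep the truth for
# round-trip checks.

# random integer 2x2 allele tables; frequencies drawn from `freq_range`
# (use (0, 0.5) for the minor-anchored domain of the SE route)
random_tables <- function(n, freq_range = c(0.01, 0.99),
                          size_range = c(50, 5000)) {
  n_case <- sample(size_range[1]:size_range[2], n, replace = TRUE)
  n_control <- sample(size_range[1]:size_range[2], n, replace = TRUE)
  f_case <- runif(n, freq_range[1], freq_range[2])
  f_control <- runif(n, freq_range[1], freq_range[2])
  a <- pmax(1, pmin(2 * n_case - 1, round(2 * n_case * f_case)))
  c <- pmax(1, pmin(2 * n_control - 1, round(2 * n_control * f_control)))
  data.frame(a = a, b = 2 * n_case - a, c = c, d = 2 * n_control - c,
             n_case = n_case, n_control = n_control)
}

table_or <- function(t) t$a * t$d / (t$b * t$c)
table_se <- function(t) sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
table_af_total <- function(t) (t$a + t$c) / (2 * (t$n_case + t$n_control))
table_af_case <- function(t) t$a / (2 * t$n_case)
table_af_control <- function(t) t$c / (2 * t$n_control)

fold <- function(f) pmin(f, 1 - f)
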