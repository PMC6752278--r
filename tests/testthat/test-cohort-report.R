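test_that("carrier percentages reproduce the printed worked examples", {
  expect_equal(carrier_percentage(105, 2243), 4.68)
  expect_equal(carrier_percentage(1073, 32369), 3.31)
  expect_equal(carrier_percentage(257, 32369), 0.79)
  expect_equal(carrier_percentage(32, 2243), 1.43)
  expect_equal(carrier_percentage(109, 2243), 4.86)
  expect_equal(carrier_percentage(0, 10), 0)
  expect_error(carrier_percentage(1, 0), "precondition")
  expect_error(carrier_percentage(5, 3), "precondition")
})

test_that("complementary carrier fractions sum to 100 before rounding", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(10:50000, 1); k <- sample(0:n, 1)
    expect_equal(100 * k / n + 100 * (n - k) / n, 100)
    expect_equal(carrier_percentage(k, n, 6) + carrier_percentage(n - k, n, 6),
                 100, tolerance = 1e-4)
  }
})

test_that("z-test matches high-precision normal-tail reference values", {
  # reference tail probabilities computed with 60-digit arithmetic
  # (erfc(z/sqrt(2)); frozen):
  ref <- tibble::tibble(
    z = c(0.5, 1, 2.5, 7, 15, 22.5, 30),
    log_p = c(-0.4827645810336733, -1.1478744644493182,
              -4.388501096718745, -26.69116031825113,
              -115.43823766515175, -256.46627230962424,
              -453.62809677578325))
  for (i in seq_len(nrow(ref))) {
    # choose p0, n so that p_hat = p0 + z * se is exact
    p0 <- 0.3; n <- 10000
    se <- sqrt(p0 * (1 - p0) / n)
    out <- one_proportion_ztest(p0 + ref$z[i] * se, p0, n)
    expect_equal(out$z, ref$z[i], tolerance = 1e-12)
    expect_equal(log(out$p_two_sided), ref$log_p[i], tolerance = 1e-12)
    expect_equal(out$log10_p, ref$log_p[i] / log(10), tolerance = 1e-12)
  }
})

test_that("the extreme rapid-metabolizer comparison reproduces in magnitude", {
  # rounded inputs: 30.8% observed vs 26.9% reference in 42,092 individuals
  out <- one_proportion_ztest(0.308, 0.269, 42092)
  expect_gt(out$p_two_sided, 1.64e-73)
  expect_lt(out$p_two_sided, 1.64e-71)
  # the p-value survives in log space rather than underflowing
  huge <- one_proportion_ztest(0.9, 0.046, 42092)
  expect_true(is.finite(huge$log10_p))
  expect_lt(huge$log10_p, -300)
})

test_that("z-test identities and monotonicity hold", {
  null <- one_proportion_ztest(0.25, 0.25, 500)
  expect_equal(null$z, 0)
  expect_equal(null$p_two_sided, 1)
  expect_error(one_proportion_ztest(0.5, 0, 10), "precondition")
  expect_error(one_proportion_ztest(0.5, 1, 10), "precondition")
  # decreasing in |p_hat - p0| at fixed n
  deltas <- seq(0, 0.2, by = 0.02)
  ps <- vapply(deltas, function(d) {
    one_proportion_ztest(0.3 + d, 0.3, 2000)$log10_p
  }, numeric(1))
  expect_true(all(diff(ps) < 0 | (deltas[-1] == deltas[-length(deltas)])))
  # decreasing in n at fixed nonzero difference
  ns <- c(50, 500, 5000, 50000)
  pn <- vapply(ns, function(n) {
    one_proportion_ztest(0.35, 0.3, n)$log10_p
  }, numeric(1))
  expect_true(all(diff(pn) < 0))
  # symmetric in the sign of the difference
  expect_equal(one_proportion_ztest(0.35, 0.3, 100)$p_two_sided,
               one_proportion_ztest(0.25, 0.3, 100)$p_two_sided)
})

test_that("tidy() and glance() expose broom-shaped z-test results", {
  out <- one_proportion_ztest(0.308, 0.269, 42092)
  td <- tidy(out)
  expect_named(td, c("estimate", "null.value", "statistic", "p.value",
                     "log10.p.value", "parameter", "method", "alternative"))
  expect_equal(td$statistic, out$z)
  gl <- glance(out)
  expect_equal(gl$nobs, 42092)
})

test_that("actionable fraction counts samples with any high-risk gene", {
  phen <- tidyr::expand_grid(sample = sprintf("S%d", 1:10),
                             gene = c("G1", "G2")) |>
    dplyr::mutate(high_risk = FALSE)
  expect_equal(actionable_fraction(phen), 0)
  phen$high_risk[phen$sample == "S1" & phen$gene == "G1"] <- TRUE
  expect_equal(actionable_fraction(phen), 0.10)
  # NA (indeterminate) never counts as at-risk
  phen$high_risk[phen$sample == "S2"] <- NA
  expect_equal(actionable_fraction(phen), 0.10)
})

test_that("simulated per-gene risks combine as 1 - prod(1 - r)", {
  set.seed(404)
  risks <- c(G1 = 0.30, G2 = 0.10, G3 = 0.55)
  n <- 20000
  phen <- tidyr::expand_grid(sample = sprintf("S%05d", seq_len(n)),
                             gene = names(risks)) |>
    dplyr::mutate(high_risk = stats::runif(dplyr::n()) < risks[gene])
  got <- actionable_fraction(phen)
  expected <- 1 - prod(1 - risks)
  # binomial 99% interval around the closed form
  half <- stats::qnorm(0.995) * sqrt(expected * (1 - expected) / n)
  expect_gt(got, expected - half)
  expect_lt(got, expected + half)
})

test_that("DDD impact is exposure times risk, summable to a portfolio", {
  one <- ddd_impact(55, 0.998)
  expect_equal(one$affected_ddd, 54.89)
  expect_gte(one$affected_ddd, 50)  # "at least 50 daily doses per 1000"
  expect_equal(ddd_impact(10, 0)$affected_ddd, 0)
  expect_equal(ddd_impact(10, 1)$affected_ddd, 10)
  multi <- ddd_impact(c(17.62, 7.08, 9.16), c(0.637, 0.284, 0.0765),
                      scope = c("CYP2C19", "CYP2C9", "CYP2D6"))
  expect_true(all(multi$affected_ddd <= multi$ddd_per_1000))
  port <- portfolio_impact(multi)
  expect_equal(port$affected_ddd, sum(multi$affected_ddd))
  expect_error(ddd_impact(-1, 0.5), "precondition")
})

test_that("cohort summaries are normalised and sample-order invariant", {
  spec <- default_simulation_spec(n_samples = 120, seed = 17)
  sim <- simulate_cohort(spec)
  res <- call_pgx_cohort(sim$vcf, sim$tables, sim$maps, cnv = sim$cnv)
  s1 <- summarize_cohort(res$haplotypes, res$phenotypes)
  # frequencies sum to 1 within every gene and category
  for (tab in list(s1$allele_freqs, s1$status_rates, s1$diplotype_freqs,
                   s1$phenotype_freqs)) {
    sums <- tapply(tab$freq, tab$gene, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
  # status counts cover two haplotypes per sample and gene
  per_gene <- tapply(s1$status_rates$count, s1$status_rates$gene, sum)
  expect_true(all(per_gene == 2 * s1$n_samples))
  per_gene_dip <- tapply(s1$diplotype_freqs$count, s1$diplotype_freqs$gene,
                         sum)
  expect_true(all(per_gene_dip == s1$n_samples))
  # permutation invariance
  perm <- sample(nrow(res$haplotypes))
  s2 <- summarize_cohort(res$haplotypes[perm, ],
                         res$phenotypes[sample(nrow(res$phenotypes)), ])
  expect_equal(as.data.frame(s1$allele_freqs), as.data.frame(s2$allele_freqs))
  expect_equal(as.data.frame(s1$phenotype_freqs),
               as.data.frame(s2$phenotype_freqs))
  # tidy()/glance() shapes
  td <- tidy(s1)
  expect_named(td, c("category", "gene", "level", "count", "freq"))
  gl <- glance(s1)
  expect_equal(gl$n_samples, 120)
})

test_that("frequency plots build without error", {
  spec <- default_simulation_spec(n_samples = 60, seed = 3)
  sim <- simulate_cohort(spec)
  res <- call_pgx_cohort(sim$vcf, sim$tables, sim$maps)
  s <- summarize_cohort(res$haplotypes, res$phenotypes)
  p1 <- plot_allele_frequencies(s)
  p2 <- autoplot(s, type = "phenotypes")
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
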