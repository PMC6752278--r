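#' Carrier percentage
#'
#' `100 * k / n`, rounded half away from zero to `decimals` places — the
#' convention for all printed carrier frequencies (e.g. 105 of 2243
#' HLA-B*57:01 carriers prints as 4.68).
#'
#' @param k Carrier count(s), `0 <= k <= n`.
#' @param n Cohort size(s), `> 0`.
#' @param decimals Decimal places (default 2).
#' @return Numeric percentage(s).
#' @examples
#' carrier_percentage(1073, 32369)  # 3.31
#' @export
carrier_percentage <- function(k, n, decimals = 2) {
  if (any(n <= 0)) abort("precondition error: n must be positive")
  if (any(k < 0 | k > n)) abort("precondition error: need 0 <= k <= n")
  round_half_out(100 * k / n, decimals)
}

#' One-proportion z-test with log-space tail probabilities
#'
#' Tests an observed proportion against a reference proportion with the
#' normal approximation, `z = (p_hat - p0) / sqrt(p0 (1 - p0) / n)`. The
#' two-sided tail probability is evaluated in log space
#' (`pnorm(..., log.p = TRUE)`), so extreme comparisons (|z| well beyond 38,
#' p-values around 1e-150) retain their magnitude as `log10_p` instead of
#' underflowing to zero.
#'
#' @param p_hat Observed proportion.
#' @param p0 Reference proportion, strictly inside (0, 1).
#' @param n Sample count, `>= 1`.
#' @return A `pgx_ztest` object (also a one-row tibble): `p_hat`, `p0`, `n`,
#'   `z`, `p_two_sided`, `log10_p`.
#' @examples
#' one_proportion_ztest(0.308, 0.269, 42092)
#' @export
one_proportion_ztest <- function(p_hat, p0, n) {
  stopifnot(length(p_hat) == 1, length(p0) == 1, length(n) == 1)
  if (p0 <= 0 || p0 >= 1) {
    abort("precondition error: p0 must lie strictly inside (0, 1)")
  }
  if (n < 1) abort("precondition error: n must be >= 1")
  z <- (p_hat - p0) / sqrt(p0 * (1 - p0) / n)
  log_p <- log(2) + pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
  log_p <- min(log_p, 0)  # two-sided cap at 1
  out <- tibble(p_hat = p_hat, p0 = p0, n = n, z = z,
                p_two_sided = exp(log_p), log10_p = log_p / log(10))
  class(out) <- c("pgx_ztest", class(out))
  out
}

#' @exportS3Method base::print
print.pgx_ztest <- function(x, ...) {
  cat(sprintf("One-proportion z-test: p_hat=%.4g vs p0=%.4g (n=%d)\n",
              x$p_hat, x$p0, as.integer(x$n)))
  cat(sprintf("  z = %.4f, two-sided p = %.3g (log10 p = %.3f)\n",
              x$z, x$p_two_sided, x$log10_p))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.pgx_ztest <- function(x, ...) {
  tibble(estimate = x$p_hat, null.value = x$p0, statistic = x$z,
         p.value = x$p_two_sided, log10.p.value = x$log10_p,
         parameter = x$n, method = "one-proportion z-test",
         alternative = "two.sided")
}

#' @rdname tidiers
#' @export
glance.pgx_ztest <- function(x, ...) {
  tibble(statistic = x$z, p.value = x$p_two_sided, log10.p.value = x$log10_p,
         nobs = x$n)
}

#' Fraction of individuals with at least one actionable phenotype
#'
#' The proportion of samples flagged high-risk for one or more genes — the
#' cohort-level "nonstandard dosing information required based on at least
#' one gene" figure.
#'
#' @param phenotypes Tibble with `sample`, `gene`, `high_risk` (logical, `NA`
#'   for indeterminate calls; `NA`s count as not-at-risk).
#' @return Proportion in \\[0, 1\\].
#' @export
actionable_fraction <- function(phenotypes) {
  per_sample <- phenotypes |>
    group_by(.data$sample) |>
    summarise(any_risk = any(.data$high_risk %in% TRUE), .groups = "drop")
  if (nrow(per_sample) == 0) abort("precondition error: no samples")
  mean(per_sample$any_risk)
}

#' Drug-consumption impact of high-risk phenotypes
#'
#' Multiplies population drug exposure (defined daily doses per 1000
#' inhabitants per day) by the fraction of individuals carrying a high-risk
#' phenotype for the linked gene(s): the daily doses dispensed to individuals
#' for whom dosing guidance deviates from standard.
#'
#' @param ddd_per_1000 Numeric vector of DDD/1000 inhabitants/day.
#' @param risk_fraction Matching vector of high-risk proportions in \\[0, 1\\].
#' @param scope Character vector naming each row (gene or drug); default
#'   `"portfolio"`.
#' @return Tibble `scope`, `ddd_per_1000`, `risk_fraction`, `affected_ddd`.
#' @examples
#' ddd_impact(55, 0.998)  # 54.89 affected DDD/1000 inhabitants/day
#' @export
ddd_impact <- function(ddd_per_1000, risk_fraction, scope = "portfolio") {
  if (any(ddd_per_1000 < 0) || any(risk_fraction < 0 | risk_fraction > 1)) {
    abort("precondition error: ddd >= 0 and risk_fraction in [0, 1]")
  }
  tibble(scope = scope, ddd_per_1000 = ddd_per_1000,
         risk_fraction = risk_fraction,
         affected_ddd = ddd_per_1000 * risk_fraction)
}

#' Sum per-drug impacts into a portfolio impact
#'
#' @param impact Tibble from [ddd_impact()].
#' @return One-row tibble with `scope = "portfolio"`, summed exposures and
#'   affected doses, and the exposure-weighted mean risk fraction.
#' @export
portfolio_impact <- function(impact) {
  tibble(scope = "portfolio",
         ddd_per_1000 = sum(impact$ddd_per_1000),
         risk_fraction = sum(impact$affected_ddd) /
           sum(impact$ddd_per_1000),
         affected_ddd = sum(impact$affected_ddd))
}

#' Summarise cohort calls into frequency tables
#'
#' Aggregates haplotype calls and phenotype calls into the cohort's allele,
#' diplotype, phenotype and status frequency tables. Allele frequencies are
#' computed over haplotypes with a resolved label (single or composite —
#' composite labels are counted as their own category); status rates over all
#' haplotypes; diplotype and phenotype frequencies over samples.
#'
#' @param hap_calls Haplotype-call tibble (from [call_gene_cohort()],
#'   possibly CNV-adjusted; several genes may be stacked).
#' @param phen_calls Phenotype tibble (from [phenotype_gene_cohort()]).
#' @return A `starcall_summary` object: list of tibbles `allele_freqs`,
#'   `diplotype_freqs`, `phenotype_freqs`, `status_rates`, plus `n_samples`.
#' @export
summarize_cohort <- function(hap_calls, phen_calls) {
  n_samples <- dplyr::n_distinct(hap_calls$sample)
  allele_freqs <- hap_calls |>
    filter(.data$status %in% c("single", "composite")) |>
    count(.data$gene, label = .data$resolved_label, name = "count") |>
    group_by(.data$gene) |>
    mutate(freq = .data$count / sum(.data$count)) |>
    ungroup()
  status_rates <- hap_calls |>
    count(.data$gene, .data$status, name = "count") |>
    group_by(.data$gene) |>
    mutate(freq = .data$count / sum(.data$count)) |>
    ungroup()
  diplotype_freqs <- phen_calls |>
    mutate(diplotype = if_else(is.na(.data$diplotype), "(unresolved)",
                               .data$diplotype)) |>
    count(.data$gene, .data$diplotype, name = "count") |>
    group_by(.data$gene) |>
    mutate(freq = .data$count / sum(.data$count)) |>
    ungroup()
  phenotype_freqs <- phen_calls |>
    mutate(phenotype = if_else(is.na(.data$phenotype), "(indeterminate)",
                               .data$phenotype)) |>
    count(.data$gene, .data$phenotype, name = "count") |>
    group_by(.data$gene) |>
    mutate(freq = .data$count / sum(.data$count)) |>
    ungroup()
  structure(list(n_samples = n_samples, allele_freqs = allele_freqs,
                 diplotype_freqs = diplotype_freqs,
                 phenotype_freqs = phenotype_freqs,
                 status_rates = status_rates),
            class = "starcall_summary")
}

#' @exportS3Method base::print
print.starcall_summary <- function(x, ...) {
  cat("<starcall_summary> ", x$n_samples, " samples, ",
      dplyr::n_distinct(x$allele_freqs$gene), " genes\n", sep = "")
  cat("Top alleles:\n")
  print(utils::head(arrange(x$allele_freqs, dplyr::desc(.data$freq)), 8))
  invisible(x)
}

#' Tidiers for starcallr result objects
#'
#' [generics::tidy()] and [generics::glance()] methods. `tidy()` on a
#' `starcall_summary` returns one long tibble of all frequency categories;
#' `glance()` returns one row of cohort-level counts.
#'
#' @param x A `pgx_ztest` or `starcall_summary` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.starcall_summary <- function(x, ...) {
  bind_rows(
    mutate(rename(x$allele_freqs, level = "label"), category = "allele"),
    mutate(rename(x$diplotype_freqs, level = "diplotype"),
           category = "diplotype"),
    mutate(rename(x$phenotype_freqs, level = "phenotype"),
           category = "phenotype"),
    mutate(rename(x$status_rates, level = "status"), category = "status")) |>
    select("category", "gene", "level", "count", "freq")
}

#' @rdname tidiers
#' @export
glance.starcall_summary <- function(x, ...) {
  tibble(n_samples = x$n_samples,
         n_genes = dplyr::n_distinct(x$status_rates$gene),
         ambiguous_rate = with(x$status_rates,
                               sum(count[status == "ambiguous"]) /
                                 sum(count)),
         no_match_rate = with(x$status_rates,
                              sum(count[status == "no_match"]) / sum(count)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
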